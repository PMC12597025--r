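#' Run the full assembly analysis pipeline
#'
#' Orchestrates the analysis chain on either supplied tables or a simulated
#' study: taxon aggregation, focal-taxon subsetting, relativization, per-
#' sample diversity, copy-number scaling, Bray-Curtis dissimilarity,
#' group-wise multivariate dispersion and the null-model beta-deviation.
#' Optionally writes all result tables, an exclusion log and a reproducibility
#' manifest to `out_dir`.
#'
#' Exactly one of `counts`/`metadata` or `params` must be supplied.  Samples
#' excluded at any stage (zero focal reads; zero or missing copy number) are
#' recorded once each, with a reason, in the exclusion log.
#'
#' @param counts a [count_table], or path to a counts TSV
#'   (see [read_count_table()]).
#' @param metadata a metadata data.frame or path to a metadata TSV
#'   (see [read_sample_metadata()]).
#' @param params an [assembly_params] object (or a list of its arguments) to
#'   simulate the study instead of reading it.
#' @param config optional path to a YAML file (or a list) supplying any of
#'   the above arguments; explicit arguments win over config values.
#' @param mapping optional named vector mapping taxa to families, passed to
#'   [aggregate_taxa()].
#' @param focal focal taxon labels; default all taxa after aggregation.
#' @param group_by metadata columns whose cross defines the dispersion
#'   groups (default `immigration_level` x `instar`).
#' @param sqrt_dist,bias_adjust dispersion settings (defaults on, the
#'   standard configuration).
#' @param n_reps null-model replicates (default 1000).
#' @param seed master seed; defaults to `params$seed` for simulated runs,
#'   otherwise required.
#' @param pool a [taxon_pool] (or named per-group list) for the null model;
#'   default an equal-proportion pool over the focal taxa, the inoculum
#'   design of the motivating experiment.
#' @param out_dir optional output directory; created if needed.
#' @return (invisibly) an object of class `"assembly_report"` with elements
#'   `diversity`, `dispersion`, `deviation`, `exclusions`, `group_info`,
#'   `manifest`, plus the intermediate tables.
#' @export
run_pipeline <- function(counts = NULL, metadata = NULL, params = NULL,
                         config = NULL, mapping = NULL, focal = NULL,
                         group_by = c("immigration_level", "instar"),
                         sqrt_dist = TRUE, bias_adjust = TRUE,
                         n_reps = 1000, seed = NULL, pool = NULL,
                         out_dir = NULL) {
  if (!is.null(config)) {
    cfg <- if (is.character(config)) yaml::read_yaml(config) else config
    if (is.null(counts) && !is.null(cfg$counts)) counts <- cfg$counts
    if (is.null(metadata) && !is.null(cfg$metadata)) metadata <- cfg$metadata
    if (is.null(params) && !is.null(cfg$params)) params <- cfg$params
    if (is.null(mapping) && !is.null(cfg$mapping))
      mapping <- unlist(cfg$mapping)
    if (is.null(focal) && !is.null(cfg$focal)) focal <- cfg$focal
    if (missing(group_by) && !is.null(cfg$group_by)) group_by <- cfg$group_by
    if (missing(sqrt_dist) && !is.null(cfg$sqrt_dist)) sqrt_dist <- cfg$sqrt_dist
    if (missing(bias_adjust) && !is.null(cfg$bias_adjust))
      bias_adjust <- cfg$bias_adjust
    if (missing(n_reps) && !is.null(cfg$n_reps)) n_reps <- cfg$n_reps
    if (is.null(seed) && !is.null(cfg$seed)) seed <- cfg$seed
    if (is.null(out_dir) && !is.null(cfg$out_dir)) out_dir <- cfg$out_dir
  }
  simulated <- !is.null(params)
  if (simulated == !is.null(counts))
    stop2("supply exactly one of 'counts'+'metadata' or 'params'")

  study <- NULL
  if (simulated) {
    if (!inherits(params, "assembly_params"))
      params <- do.call(assembly_params, params)
    study <- simulate_study(params)
    tab <- study$counts
    meta <- study$metadata
    if (is.null(seed)) seed <- params$seed
  } else {
    tab <- if (is.character(counts)) read_count_table(counts) else
      count_table(counts, table_unit(counts))
    meta <- if (is.character(metadata)) read_sample_metadata(metadata) else
      metadata
  }
  if (is.null(seed)) stop2("a 'seed' is required (the null model is stochastic)")
  miss_meta <- setdiff(rownames(tab), meta$sample_id)
  if (length(miss_meta))
    stop2("stage metadata: no metadata for sample(s): ",
          paste(miss_meta, collapse = ", "))
  missing_cols <- setdiff(group_by, names(meta))
  if (length(missing_cols))
    stop2("stage metadata: group_by column(s) missing: ",
          paste(missing_cols, collapse = ", "))

  exclusions <- data.frame(sample_id = character(), reason = character(),
                           stringsAsFactors = FALSE)
  note_excluded <- function(ids, reason) {
    if (length(ids))
      exclusions <<- rbind(exclusions, data.frame(
        sample_id = ids, reason = reason, stringsAsFactors = FALSE))
  }

  if (!is.null(mapping)) tab <- aggregate_taxa(tab, mapping)
  if (is.null(focal)) focal <- colnames(tab)
  ftab <- withCallingHandlers(
    subset_focal(tab, focal),
    warning = function(w) invokeRestart("muffleWarning"))
  note_excluded(attr(ftab, "excluded"), "zero focal reads")

  cn <- stats::setNames(meta$copy_number, meta$sample_id)[rownames(ftab)]
  bad_cn <- rownames(ftab)[is.na(cn) | cn <= 0]
  note_excluded(bad_cn, "zero or missing copy_number")
  ftab <- as_count_table(
    unclass(ftab)[setdiff(rownames(ftab), bad_cn), , drop = FALSE],
    table_unit(ftab))
  if (nrow(ftab) < 2L)
    stop2("stage subset_focal: fewer than 2 samples remain after exclusions")

  rel <- relativize(ftab)
  diversity <- diversity_table(rel, meta)
  cs <- copy_scale(rel, meta)

  mrows <- meta[match(rownames(rel), meta$sample_id), , drop = FALSE]
  glab <- apply(mrows[, group_by, drop = FALSE], 1L, paste, collapse = "_")
  names(glab) <- rownames(rel)
  group_info <- unique(data.frame(group = unname(glab),
                                  mrows[, group_by, drop = FALSE],
                                  stringsAsFactors = FALSE, row.names = NULL))

  d <- bray_curtis(rel)
  dispersion <- withCallingHandlers(
    beta_dispersion(d, glab, sqrt_dist = sqrt_dist,
                    bias_adjust = bias_adjust),
    warning = function(w) invokeRestart("muffleWarning"))

  if (is.null(pool)) pool <- taxon_pool(colnames(ftab))
  deviation <- withCallingHandlers(
    beta_deviation(cs, glab, pool, n_reps = n_reps, seed = seed,
                   sqrt_dist = sqrt_dist, bias_adjust = bias_adjust),
    warning = function(w) invokeRestart("muffleWarning"))

  disp_tab <- merge(group_info, dispersion$groups, by = "group", sort = TRUE)
  disp_tab$sqrt_dist <- sqrt_dist
  disp_tab$bias_adjust <- bias_adjust
  dev_tab <- merge(group_info, deviation$groups, by = "group", sort = TRUE)

  model_input <- merge(
    merge(diversity, meta, by = "sample_id", sort = TRUE),
    data.frame(sample_id = names(glab), group = unname(glab),
               stringsAsFactors = FALSE),
    by = "sample_id", sort = TRUE)
  model_input <- merge(model_input,
                       dev_tab[, c("group", "observed_beta", "ses")],
                       by = "group", all.x = TRUE, sort = TRUE)

  manifest <- list(
    package = "betadev",
    package_version = as.character(utils::packageVersion("betadev")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed, n_reps = n_reps,
    sqrt_dist = sqrt_dist, bias_adjust = bias_adjust,
    group_by = group_by, focal = focal,
    input = if (simulated) "simulated" else
      list(counts = if (is.character(counts)) counts else "in-memory",
           metadata = if (is.character(metadata)) metadata else "in-memory"),
    params = if (simulated) unclass(params) else NULL)

  report <- structure(list(
    diversity = diversity, dispersion = disp_tab, deviation = dev_tab,
    per_sample_distances = dispersion$samples, exclusions = exclusions,
    group_info = group_info, model_input = model_input,
    counts = ftab, relative = rel, copy_scaled = cs,
    dispersion_fit = dispersion, deviation_fit = deviation,
    study = study, manifest = manifest), class = "assembly_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wcsv <- function(x, f) utils::write.csv(
      x, file.path(out_dir, f), row.names = FALSE, quote = FALSE)
    wcsv(diversity, "diversity.csv")
    wcsv(disp_tab, "dispersion.csv")
    wcsv(dispersion$samples, "distances.csv")
    wcsv(dev_tab, "deviation.csv")
    wcsv(model_input, "model_input.csv")
    writeLines(if (nrow(exclusions))
      paste(exclusions$sample_id, exclusions$reason, sep = "\t") else
        character(0), file.path(out_dir, "exclusions.log"))
    jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    if (simulated) {
      write_count_table(study$counts, file.path(out_dir, "counts.tsv"))
      utils::write.table(study$metadata, file.path(out_dir, "metadata.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(unclass(params), file.path(out_dir, "truth.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  invisible(report)
}

#' @export
print.assembly_report <- function(x, digits = 4, ...) {
  cat("Assembly analysis report\n")
  cat(sprintf("%d samples analysed, %d excluded, %d groups\n",
              nrow(x$diversity), nrow(x$exclusions), nrow(x$group_info)))
  cat("\nDispersion (beta-diversity) by group:\n")
  print(format(x$dispersion[, c("group", "n", "beta")], digits = digits),
        row.names = FALSE)
  cat("\nBeta-deviation (SES) by group:\n")
  print(format(x$deviation[, c("group", "n", "observed_beta", "null_mean",
                               "null_sd", "ses")], digits = digits),
        row.names = FALSE)
  invisible(x)
}
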