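#' Parameters for the synthetic immigration-gradient experiment
#'
#' Bundles and validates the knobs of the generative model emulating the
#' experimental design: a fixed species pool at equal proportions diluted
#' over several orders of magnitude, probabilistic colonization of replicate
#' hosts, within-host growth with optional fitness differences plus
#' demographic drift, and destructive sampling at two larval stages.
#'
#' Key defaults mirror the motivating experiment: a 5-family pool, a top
#' inoculum density of 1.69e5 CFU/uL diluted over five orders of magnitude
#' (exponents 0 to -5), and 7 replicate hosts per immigration x instar cell
#' (the experimental cells held 5-9).  `colonization_scale` is the inoculum
#' dose volume in uL (2 uL per host), so the expected propagule number per
#' taxon is `colonization_scale * density * proportion`.
#'
#' @param n_taxa number of focal taxa in the pool.
#' @param taxon_ids labels; default the five focal bacterial families, the
#'   first (Enterobacteriaceae) being the advantaged taxon when
#'   `selection > 0`.
#' @param dilution_exponents strictly decreasing integers; one immigration
#'   treatment per exponent, density `base_density * 10^e`.
#' @param base_density inoculum density of the top treatment (CFU/uL).
#' @param replicates_per_cell hosts per treatment x stage cell.
#' @param colonization_scale dose volume (uL) mapping density to expected
#'   propagules.
#' @param establishment_prob per-propagule probability of establishing in
#'   the gut.
#' @param selection selection strength `s`: the first taxon's growth factor
#'   is `growth_rate * (1 + s)`; `s = 0` gives pure drift (all taxa
#'   exchangeable).
#' @param growth_rate shared per-generation growth factor.
#' @param fitness optional explicit per-taxon growth factors (overrides
#'   `selection`/`growth_rate`); all must be positive.
#' @param carrying_capacity within-host ceiling on deterministic growth.
#' @param drift_size maximum number of individuals resampled each generation;
#'   communities below it are resampled at their own (smaller) size, so small
#'   communities drift harder (effective community size).
#' @param n_generations_between_stages bacterial generations between the
#'   3rd-instar and 5th-instar samples.
#' @param n_lineages,n_plants numbers of host lineages and rearing plants
#'   assigned at random to hosts (random-effect structure of the design).
#' @param background_taxa number of non-focal taxa colonizing naturally
#'   (default 0 = off); when on, each host receives all background taxa at
#'   log-normal abundances with median `background_scale`.
#' @param background_scale median abundance of background taxa.
#' @param measurement_noise sdlog of multiplicative log-normal noise on the
#'   qPCR-like total (copy_number); 0 disables.
#' @param seed integer seed for the whole simulated study.
#' @return a validated list of class `"assembly_params"`.
#' @export
assembly_params <- function(n_taxa = 5,
                            taxon_ids = c("Enterobacteriaceae",
                                          "Comamonadaceae",
                                          "Bacillaceae",
                                          "Xanthomonadaceae",
                                          "Pseudomonadaceae")[seq_len(n_taxa)],
                            dilution_exponents = 0:-5,
                            base_density = 1.69e5,
                            replicates_per_cell = 7,
                            colonization_scale = 2,
                            establishment_prob = 0.3,
                            selection = 0,
                            growth_rate = 2,
                            fitness = NULL,
                            carrying_capacity = 1e5,
                            drift_size = 2000,
                            n_generations_between_stages = 12,
                            n_lineages = 4,
                            n_plants = 10,
                            background_taxa = 0,
                            background_scale = 50,
                            measurement_noise = 0.1,
                            seed = 1) {
  if (length(taxon_ids) != n_taxa || anyDuplicated(taxon_ids))
    stop2("'taxon_ids' must be ", n_taxa, " unique labels")
  if (is.unsorted(rev(dilution_exponents), strictly = TRUE))
    stop2("'dilution_exponents' must be strictly decreasing")
  if (is.null(fitness)) fitness <- growth_rate * c(1 + selection,
                                                   rep(1, n_taxa - 1L))
  if (length(fitness) != n_taxa || any(fitness <= 0))
    stop2("'fitness' must be ", n_taxa, " positive growth factors")
  if (carrying_capacity < 1) stop2("'carrying_capacity' must be >= 1")
  if (establishment_prob < 0 || establishment_prob > 1)
    stop2("'establishment_prob' must be in [0, 1]")
  structure(list(
    n_taxa = n_taxa, taxon_ids = taxon_ids,
    dilution_exponents = dilution_exponents, base_density = base_density,
    replicates_per_cell = replicates_per_cell,
    colonization_scale = colonization_scale,
    establishment_prob = establishment_prob,
    selection = selection, growth_rate = growth_rate, fitness = fitness,
    carrying_capacity = carrying_capacity, drift_size = drift_size,
    n_generations_between_stages = n_generations_between_stages,
    n_lineages = n_lineages, n_plants = n_plants,
    background_taxa = background_taxa, background_scale = background_scale,
    measurement_noise = measurement_noise, seed = seed
  ), class = "assembly_params")
}

#' @export
print.assembly_params <- function(x, ...) {
  cat(sprintf(
    "assembly_params: %d taxa, %d treatments (densities %g..%g), %d reps/cell\n",
    x$n_taxa, length(x$dilution_exponents),
    x$base_density * 10^max(x$dilution_exponents),
    x$base_density * 10^min(x$dilution_exponents), x$replicates_per_cell))
  cat(sprintf("selection s = %g | drift_size = %d | generations = %d | seed = %d\n",
              x$selection, as.integer(x$drift_size),
              as.integer(x$n_generations_between_stages), as.integer(x$seed)))
  invisible(x)
}

#' Build one treatment pool per dilution level
#'
#' @param params an [assembly_params] object.
#' @return named list of [taxon_pool]s (names `"d<exponent>"`), each with
#'   equal proportions and density `base_density * 10^exponent`.
#' @export
make_pool <- function(params) {
  stopifnot(inherits(params, "assembly_params"))
  pools <- lapply(params$dilution_exponents, function(e)
    taxon_pool(params$taxon_ids,
               total_density = params$base_density * 10^e))
  names(pools) <- paste0("d", params$dilution_exponents)
  pools
}

#' Simulate colonization of one host from a treatment pool
#'
#' Propagules of each taxon arrive as a Poisson draw with mean
#' `colonization_scale * total_density * proportion`; each propagule
#' independently establishes with probability `establishment_prob`.  At high
#' density all taxa establish almost surely; at strong dilution the founding
#' community is small or empty — the colonization bottleneck that makes
#' assembly outcomes susceptible to chance.
#'
#' @param pool a [taxon_pool].
#' @param params an [assembly_params] object.
#' @return named integer vector of established founders per taxon.
#' @export
simulate_colonization <- function(pool, params) {
  lambda <- params$colonization_scale * pool$total_density * pool$rel_proportions
  propagules <- stats::rpois(length(lambda), lambda)
  established <- stats::rbinom(length(lambda), propagules,
                               params$establishment_prob)
  stats::setNames(as.numeric(established), pool$taxon_ids)
}

#' Simulate within-host dynamics between larval stages
#'
#' A discrete growth-then-resample scheme spanning the drift-selection axis
#' with one parameter: each generation, counts are multiplied by the
#' per-taxon fitness factors (rescaled proportionally if the total would
#' exceed `carrying_capacity`), then the next generation is drawn
#' multinomially with `min(drift_size, total)` individuals.  Small
#' communities are therefore resampled at their own size and drift strongly;
#' large ones are buffered.  With equal fitness the expected composition is
#' unchanged every generation (a martingale), so only drift moves it; taxa
#' hitting zero stay extinct.
#'
#' @param community named numeric vector of founding counts.
#' @param params an [assembly_params] object.
#' @return named numeric vector of counts after
#'   `n_generations_between_stages` generations.
#' @export
simulate_ontogeny <- function(community, params) {
  counts <- as.numeric(community)
  fit <- params$fitness
  if (length(fit) != length(counts))
    stop2("community and fitness lengths differ")
  for (gen in seq_len(params$n_generations_between_stages)) {
    w <- counts * fit
    tot <- sum(w)
    if (tot == 0) break
    if (tot > params$carrying_capacity) {
      w <- w * (params$carrying_capacity / tot)
      tot <- params$carrying_capacity
    }
    n_next <- min(params$drift_size, round(tot))
    if (n_next < 1) {
      counts[] <- 0
      break
    }
    counts <- drop(stats::rmultinom(1L, n_next, prob = w / tot))
  }
  stats::setNames(as.numeric(counts), names(community))
}

#' Simulate a full immigration-gradient study
#'
#' For every treatment (dilution level) and replicate, independent hosts are
#' colonized; the 3rd-instar sample records the founding community of one
#' host, and the 5th-instar sample records a different host of the same
#' treatment after within-host growth and drift (mirroring destructive
#' sampling: no host is measured twice).  Each sample's `copy_number` is its
#' realized total with multiplicative log-normal measurement noise, emulating
#' a qPCR total-abundance assay.  Hosts are assigned at random to lineages
#' and rearing plants so downstream mixed-model random effects have
#' structure to estimate.
#'
#' @param params an [assembly_params] object (its `seed` drives all draws).
#' @return an object of class `"simulated_study"`: list with `counts` (a
#'   [count_table], rows = samples of both stages), `metadata` (data.frame
#'   `sample_id, immigration_level, instar, plant_id, lineage_id,
#'   copy_number, treatment`), `pools` (per-treatment [taxon_pool]s) and
#'   `truth` (the generating parameters).
#' @export
simulate_study <- function(params = assembly_params()) {
  stopifnot(inherits(params, "assembly_params"))
  pools <- make_pool(params)
  with_local_seed(params$seed, {
    rows <- list(); meta <- list()
    for (tlab in names(pools)) {
      pool <- pools[[tlab]]
      for (instar in c(3L, 5L)) {
        for (r in seq_len(params$replicates_per_cell)) {
          sid <- sprintf("%s_i%d_r%d", tlab, instar, r)
          comm <- simulate_colonization(pool, params)
          if (instar == 5L) comm <- simulate_ontogeny(comm, params)
          if (params$background_taxa > 0) {
            bg <- stats::rlnorm(params$background_taxa,
                                meanlog = log(params$background_scale),
                                sdlog = 1)
            names(bg) <- paste0("background_", seq_len(params$background_taxa))
            comm <- c(comm, round(bg))
          }
          total <- sum(comm)
          noise <- if (params$measurement_noise > 0)
            stats::rlnorm(1L, 0, params$measurement_noise) else 1
          rows[[sid]] <- comm
          meta[[sid]] <- data.frame(
            sample_id = sid,
            immigration_level = pool$total_density,
            instar = instar,
            plant_id = paste0("plant_", sample.int(params$n_plants, 1L)),
            lineage_id = paste0("lineage_", sample.int(params$n_lineages, 1L)),
            copy_number = total * noise,
            treatment = tlab,
            stringsAsFactors = FALSE)
        }
      }
    }
    taxa <- c(params$taxon_ids,
              if (params$background_taxa > 0)
                paste0("background_", seq_len(params$background_taxa)))
    if (length(rows)) {
      counts <- do.call(rbind, rows)
      rownames(counts) <- names(rows)
      metadata <- do.call(rbind, c(meta, make.row.names = FALSE))
    } else {
      counts <- matrix(numeric(0), 0L, length(taxa),
                       dimnames = list(character(0), taxa))
      metadata <- data.frame(sample_id = character(),
                             immigration_level = numeric(),
                             instar = integer(), plant_id = character(),
                             lineage_id = character(),
                             copy_number = numeric(),
                             treatment = character(),
                             stringsAsFactors = FALSE)
    }
    structure(list(counts = count_table(counts, "reads"),
                   metadata = metadata,
                   pools = pools,
                   truth = params),
              class = "simulated_study")
  })
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf(
    "simulated_study: %d samples (%d treatments x 2 instars x %d reps), %d taxa\n",
    nrow(x$counts), length(x$pools), x$truth$replicates_per_cell,
    ncol(x$counts)))
  cat(sprintf("selection s = %g, seed = %d\n",
              x$truth$selection, as.integer(x$truth$seed)))
  invisible(x)
}
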