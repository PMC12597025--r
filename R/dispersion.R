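#' Beta-diversity as multivariate dispersion
#'
#' Quantifies among-sample compositional variation (beta-diversity) within
#' groups as the mean distance of each sample to its group's spatial median
#' (or centroid) in principal-coordinate space.  The default configuration —
#' square-root transform of the dissimilarities, spatial median center, and
#' \eqn{\sqrt{n/(n-1)}} small-sample bias adjustment — counteracts the two
#' known ways small groups and semimetric dissimilarities force dispersion
#' estimates toward zero.
#'
#' The pipeline is: optional [sqrt_transform()] of `d`, a single [pcoa()] of
#' all samples, per-group [spatial_median()] (per axis block), per-sample
#' [distance_to_median()] with the subtractive clamped metric, optional
#' [bias_adjust()], then the group mean.  Groups with fewer than 2 samples
#' carry no dispersion information and are skipped with a warning.
#'
#' @param d a [stats::dist] object or symmetric dissimilarity matrix with
#'   sample labels (e.g. from [bray_curtis()]).
#' @param groups factor/character vector of group labels, either named by
#'   sample id or in the order of the samples in `d`.
#' @param sqrt_dist apply the square-root transform first (default `TRUE`).
#' @param bias_adjust apply the small-sample adjustment (default `TRUE`).
#' @param center `"median"` (spatial median, default) or `"centroid"`.
#' @return an object of class `"beta_dispersion"`: list with `samples` (a
#'   data.frame `sample_id, group, distance`), `groups` (a data.frame
#'   `group, n, beta`), `skipped` (labels of undersized groups), the flags,
#'   and the `ordination`.
#' @seealso [beta_deviation()] for the null-model standardized effect size.
#' @examples
#' m <- matrix(runif(40), 8, 5,
#'             dimnames = list(paste0("s", 1:8), paste0("t", 1:5)))
#' d <- bray_curtis(count_table(m))
#' beta_dispersion(d, rep(c("a", "b"), each = 4))
#' @export
beta_dispersion <- function(d, groups, sqrt_dist = TRUE, bias_adjust = TRUE,
                            center = c("median", "centroid")) {
  center <- match.arg(center)
  m <- as_dissim_matrix(d)
  ids <- rownames(m)
  if (!is.null(names(groups))) {
    miss <- setdiff(ids, names(groups))
    if (length(miss)) stop2("no group for sample(s): ", paste(miss, collapse = ", "))
    groups <- groups[ids]
  } else if (length(groups) != length(ids)) {
    stop2("'groups' must have one label per sample")
  }
  groups <- factor(as.character(groups))

  sizes <- table(groups)
  skipped <- names(sizes)[sizes < 2]
  if (length(skipped))
    warn2("group(s) with n < 2 skipped: ", paste(skipped, collapse = ", "))

  if (sqrt_dist) m <- sqrt_transform(m)
  ord <- pcoa(m)

  samples <- data.frame(sample_id = character(), group = character(),
                        distance = numeric(), stringsAsFactors = FALSE)
  grp_tab <- data.frame(group = character(), n = integer(), beta = numeric(),
                        stringsAsFactors = FALSE)
  for (g in setdiff(levels(groups), skipped)) {
    idx <- which(groups == g)
    ctr <- if (center == "median") {
      spatial_median(ord, subset = idx)
    } else {
      list(real = colMeans(ord$real[idx, , drop = FALSE]),
           imag = colMeans(ord$imag[idx, , drop = FALSE]))
    }
    z <- distance_to_median(ord, ctr, subset = idx)
    if (bias_adjust) z <- bias_adjust(z, length(idx))
    samples <- rbind(samples, data.frame(
      sample_id = ids[idx], group = g, distance = unname(z),
      stringsAsFactors = FALSE))
    grp_tab <- rbind(grp_tab, data.frame(
      group = g, n = length(idx), beta = mean(z), stringsAsFactors = FALSE))
  }
  structure(list(samples = samples, groups = grp_tab, skipped = skipped,
                 sqrt_dist = sqrt_dist, bias_adjust = bias_adjust,
                 center = center, ordination = ord),
            class = "beta_dispersion")
}

#' @export
print.beta_dispersion <- function(x, digits = 4, ...) {
  cat("Multivariate dispersion (beta-diversity)\n")
  cat(sprintf("center: spatial %s | sqrt_dist: %s | bias_adjust: %s\n",
              x$center, x$sqrt_dist, x$bias_adjust))
  print(format(x$groups, digits = digits), row.names = FALSE)
  if (length(x$skipped))
    cat("skipped (n < 2):", paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.beta_dispersion <- function(object, ...) {
  s <- stats::aggregate(distance ~ group, data = object$samples,
                        FUN = function(z) c(min = min(z), mean = mean(z),
                                            max = max(z), sd = stats::sd(z)))
  out <- cbind(object$groups, do.call(rbind, lapply(s$distance, round, 4)))
  class(out) <- c("summary.beta_dispersion", "data.frame")
  out
}

#' @export
as.data.frame.beta_dispersion <- function(x, ...) x$groups

#' @export
coef.beta_dispersion <- function(object, ...) {
  stats::setNames(object$groups$beta, object$groups$group)
}

#' @export
plot.beta_dispersion <- function(x, ...) {
  graphics::boxplot(distance ~ group, data = x$samples,
                    ylab = "distance to group spatial median",
                    xlab = "group", ...)
  invisible(x)
}
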