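#' Principal coordinates analysis retaining imaginary axes
#'
#' Metric embedding of a dissimilarity matrix: Gower double-centering of
#' \eqn{-D^2/2} followed by eigendecomposition.  Axes with positive
#' eigenvalues are the usual real coordinates (scaled by \eqn{\sqrt\lambda});
#' axes with negative eigenvalues — produced by semimetric inputs such as
#' Bray-Curtis — are kept as an "imaginary" block scaled by
#' \eqn{\sqrt{|\lambda|}}, so that for every sample pair the squared input
#' dissimilarity is recovered as (squared real distance) minus (squared
#' imaginary distance).  Eigenvalues with \eqn{|\lambda| \le 10^{-8}
#' \max|\lambda|} are treated as numerically zero and dropped.
#'
#' @param d a [stats::dist] object or square symmetric zero-diagonal matrix.
#' @param tol relative eigenvalue tolerance for rank detection.
#' @return an object of class `"pcoa_ord"`: a list with `sample_ids`, `real`
#'   (n x k+ matrix), `imag` (n x k- matrix), `eig` (all retained
#'   eigenvalues, descending) and `trace` (of the centered matrix).
#' @export
pcoa <- function(d, tol = 1e-8) {
  m <- as_dissim_matrix(d)
  n <- nrow(m)
  a <- -0.5 * m^2
  # Gower double-centering: (I - 11'/n) A (I - 11'/n)
  g <- sweep(a, 2L, colMeans(a))
  g <- sweep(g, 1L, rowMeans(g))
  e <- eigen(g, symmetric = TRUE)
  keep <- abs(e$values) > tol * max(abs(e$values), .Machine$double.eps)
  eig <- e$values[keep]
  vec <- e$vectors[, keep, drop = FALSE]
  vec <- vec %*% diag(sqrt(abs(eig)), nrow = length(eig))
  rownames(vec) <- rownames(m)
  pos <- eig > 0
  structure(list(
    sample_ids = rownames(m),
    real = vec[, pos, drop = FALSE],
    imag = vec[, !pos, drop = FALSE],
    eig = eig,
    trace = sum(diag(g))
  ), class = "pcoa_ord")
}

#' @export
print.pcoa_ord <- function(x, ...) {
  cat(sprintf("pcoa_ord: %d samples, %d real axes, %d imaginary axes\n",
              length(x$sample_ids), ncol(x$real), ncol(x$imag)))
  cat("eigenvalues:", format(utils::head(x$eig, 8), digits = 4),
      if (length(x$eig) > 8) "...\n" else "\n")
  invisible(x)
}

# Geometric median by damped Weiszfeld iteration.  Deterministic: starts at
# the coordinate-wise median; n = 1 returns the point, n = 2 the midpoint
# (the symmetric representative of the non-unique minimizer on a segment).
weiszfeld <- function(X, tol = 1e-10, maxit = 1000L) {
  if (!is.matrix(X)) X <- matrix(X, ncol = 1L)
  if (ncol(X) == 0L) return(numeric(0))
  if (nrow(X) == 1L) return(drop(X[1L, ]))
  if (nrow(X) == 2L) return(colMeans(X))
  y <- apply(X, 2L, stats::median)
  for (it in seq_len(maxit)) {
    dif <- sweep(X, 2L, y)
    dst <- sqrt(rowSums(dif^2))
    if (any(dst < 1e-14)) {
      # iterate sits on a data point: damp by nudging with a small step
      dst <- pmax(dst, 1e-12)
    }
    w <- 1 / dst
    y_new <- colSums(X * w) / sum(w)
    if (sqrt(sum((y_new - y)^2)) < tol) return(y_new)
    y <- y_new
  }
  y
}

#' Spatial (geometric) median of a point configuration
#'
#' The point minimizing the summed distances to a set of points.  For an
#' ordination with imaginary axes the median is computed per block — once on
#' the real axes and once on the imaginary axes — because a joint objective
#' under the subtractive metric is unbounded below.  Solved by damped
#' Weiszfeld iteration (movement < 1e-10, max 1000 iterations); `n = 2`
#' returns the midpoint, the symmetric representative of the degenerate
#' minimizer.
#'
#' @param x a `"pcoa_ord"` object or a plain numeric matrix of points
#'   (rows = points).
#' @param subset optional row indices / sample ids selecting one group.
#' @return for a matrix, a numeric vector; for an ordination, a list with
#'   elements `real` and `imag`.
#' @export
spatial_median <- function(x, subset = NULL) {
  if (inherits(x, "pcoa_ord")) {
    idx <- if (is.null(subset)) seq_along(x$sample_ids) else subset
    list(real = weiszfeld(x$real[idx, , drop = FALSE]),
         imag = weiszfeld(x$imag[idx, , drop = FALSE]))
  } else {
    if (!is.matrix(x)) x <- as.matrix(x)
    if (!is.null(subset)) x <- x[subset, , drop = FALSE]
    weiszfeld(x)
  }
}

#' Distance of each sample to a group center in ordination space
#'
#' With imaginary axes present, the squared distance is the squared real-block
#' distance minus the squared imaginary-block distance; negative values —
#' which arise for semimetric dissimilarities — are clamped to zero:
#' \eqn{z = \sqrt{\max(0,\, d_{real}^2 - d_{imag}^2)}}.
#'
#' @param x a `"pcoa_ord"` object or numeric matrix of points.
#' @param center a list with `real` and `imag` components (from
#'   [spatial_median()]) or a numeric vector for plain matrices.
#' @param subset optional row selection.
#' @return nonnegative numeric vector of distances, one per (selected) sample.
#' @export
distance_to_median <- function(x, center, subset = NULL) {
  if (inherits(x, "pcoa_ord")) {
    if (!is.list(center) || !all(c("real", "imag") %in% names(center)))
      stop2("'center' must be a list with components 'real' and 'imag'")
    if (length(center$real) != ncol(x$real) ||
        length(center$imag) != ncol(x$imag))
      stop2("center and ordination have mismatched axis structure")
    idx <- if (is.null(subset)) seq_along(x$sample_ids) else subset
    d2r <- rowSums(sweep(x$real[idx, , drop = FALSE], 2L, center$real)^2)
    d2i <- if (ncol(x$imag))
      rowSums(sweep(x$imag[idx, , drop = FALSE], 2L, center$imag)^2) else 0
    sqrt(pmax(0, d2r - d2i))
  } else {
    if (!is.matrix(x)) x <- as.matrix(x)
    if (!is.null(subset)) x <- x[subset, , drop = FALSE]
    if (length(center) != ncol(x))
      stop2("center and points have mismatched dimensions")
    sqrt(rowSums(sweep(x, 2L, center)^2))
  }
}

#' Small-sample bias adjustment of distances to a group center
#'
#' Multiplies each within-group distance by \eqn{\sqrt{n/(n-1)}}, offsetting
#' the downward bias of dispersion estimates in small groups.
#'
#' @param distances nonnegative numeric vector.
#' @param n group size; must be at least 2.
#' @return adjusted distances.
#' @export
bias_adjust <- function(distances, n) {
  if (!is.numeric(n) || length(n) != 1L || n < 2)
    stop2("bias adjustment requires group size n >= 2")
  distances * sqrt(n / (n - 1))
}
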