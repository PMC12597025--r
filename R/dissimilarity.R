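#' Pairwise Bray-Curtis dissimilarity among samples
#'
#' \deqn{d(x, y) = 1 - \frac{2\sum_i \min(x_i, y_i)}{\sum_i x_i + \sum_i y_i}}
#' Computed with [vegan::vegdist()].  On relative-abundance rows (both rows
#' summing to 1) this equals half the L1 distance between the rows.  A pair
#' of samples that are both all-zero has no defined dissimilarity and is an
#' error.
#'
#' @param x a [count_table] (any unit) or nonnegative numeric matrix with
#'   samples as rows.
#' @return a [stats::dist] object with sample labels.
#' @export
bray_curtis <- function(x) {
  if (inherits(x, "count_table")) x <- unclass(x)
  if (!is.matrix(x) || !is.numeric(x) || any(x < 0))
    stop2("'x' must be a nonnegative numeric matrix")
  if (nrow(x) < 2L) stop2("need at least 2 samples")
  zero <- rowSums(x) == 0
  if (sum(zero) >= 2L)
    stop2("Bray-Curtis undefined for pairs of all-zero samples: ",
          paste(rownames(x)[zero], collapse = ", "))
  d <- vegan::vegdist(x, method = "bray")
  attr(d, "Labels") <- rownames(x)
  d
}

#' Element-wise square-root transform of a dissimilarity matrix
#'
#' A monotone transform that makes semimetric dissimilarities such as
#' Bray-Curtis "more Euclidean" (fewer/less negative eigenvalues in the
#' principal-coordinate decomposition), reducing the loss of dispersion
#' signal to negative squared distances.
#'
#' @param d a [stats::dist] object or square symmetric matrix with
#'   nonnegative entries.
#' @return an object of the same shape with square-rooted entries.
#' @export
sqrt_transform <- function(d) {
  if (any(d < 0, na.rm = TRUE)) stop2("dissimilarities must be nonnegative")
  sqrt(d)
}

# Coerce dist / matrix to a validated square symmetric matrix with labels.
as_dissim_matrix <- function(d) {
  m <- as.matrix(d)
  if (nrow(m) != ncol(m)) stop2("dissimilarity matrix must be square")
  if (max(abs(m - t(m))) > 1e-12) stop2("dissimilarity matrix must be symmetric")
  if (any(abs(diag(m)) > 1e-12)) stop2("dissimilarity matrix must have zero diagonal")
  if (is.null(rownames(m))) {
    rownames(m) <- colnames(m) <- paste0("s", seq_len(nrow(m)))
  }
  m
}
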