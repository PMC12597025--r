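#' Hill diversity of a relative-abundance vector
#'
#' Effective number of taxa of order `q`:
#' \deqn{^qD = \left(\sum_i p_i^q\right)^{1/(1-q)}}
#' with the limits `q = 0` (richness: the count of taxa with \eqn{p_i > 0})
#' and `q = 1` (exponential Shannon).  `q = 2` is the inverse of Simpson's
#' dominance, \eqn{1 / \sum_i p_i^2}.  Richness uses a strict presence
#' threshold `p_i > 0`; no pseudo-count floor is applied, because input
#' tables are already filtered and any floor would be an extra modelling
#' choice.
#'
#' @param p numeric vector of relative abundances summing to 1 (within 1e-9).
#' @param q diversity order, a nonnegative real; the analyses here use 0
#'   (richness) and 2 (inverse Simpson).
#' @return the effective number of taxa, a scalar in `[1, length(p)]` for a
#'   valid `p`.
#' @examples
#' hill_diversity(c(0.2, 0.2, 0.2, 0.2, 0.2), q = 2)  # even community: 5
#' hill_diversity(c(0.5, 0.3, 0.2), q = 2)            # 1 / 0.38
#' @export
hill_diversity <- function(p, q) {
  if (!length(p)) stop2("'p' is empty")
  if (anyNA(p) || any(p < 0)) stop2("'p' must be nonnegative and non-missing")
  if (abs(sum(p) - 1) > 1e-9)
    stop2("'p' must sum to 1 (got ", format(sum(p)), "); relativize first")
  if (!is.numeric(q) || length(q) != 1L || q < 0)
    stop2("'q' must be a single nonnegative number")
  pos <- p[p > 0]
  if (q == 0) return(length(pos))
  if (q == 1) return(exp(-sum(pos * log(pos))))
  sum(pos^q)^(1 / (1 - q))
}

#' Per-sample alpha-diversity and community-size table
#'
#' Computes, for every sample of a relative-abundance table, richness
#' (Hill `q = 0`), inverse Simpson diversity (Hill `q = 2`) and — when
#' per-sample copy numbers are supplied — community size (total 16S copy
#' number).
#'
#' @param x a [count_table]; relativized internally if needed.
#' @param copy_number optional named numeric vector or metadata data.frame
#'   (columns `sample_id`, `copy_number`) giving per-sample total abundance.
#' @return a data.frame with columns `sample_id`, `richness_q0`,
#'   `inv_simpson_q2` and `community_size` (`NA` when no copy number given).
#' @export
diversity_table <- function(x, copy_number = NULL) {
  x <- count_table(x, table_unit(x))
  rel <- if (table_unit(x) == "relative") x else relativize(x)
  out <- data.frame(
    sample_id = rownames(rel),
    richness_q0 = apply(rel, 1L, hill_diversity, q = 0),
    inv_simpson_q2 = apply(rel, 1L, hill_diversity, q = 2),
    community_size = NA_real_,
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (!is.null(copy_number)) {
    if (is.data.frame(copy_number)) {
      cn <- copy_number$copy_number
      names(cn) <- copy_number$sample_id
      copy_number <- cn
    }
    out$community_size <- unname(copy_number[out$sample_id])
  }
  out
}
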