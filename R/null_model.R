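#' Define a treatment species pool
#'
#' The regional pool available to colonize hosts: taxon labels, their
#' relative proportions in the inoculum, and the total density (e.g. CFU/uL).
#' The motivating experimental design uses five bacterial families at equal
#' proportions, so `proportions` defaults to `1/k` each.
#'
#' @param taxon_ids character vector of taxon labels.
#' @param proportions numeric vector summing to 1 (default equal).
#' @param total_density nonnegative total density of the pool.
#' @return an object of class `"taxon_pool"`.
#' @export
taxon_pool <- function(taxon_ids,
                       proportions = rep(1 / length(taxon_ids), length(taxon_ids)),
                       total_density = 1) {
  if (!length(taxon_ids) || anyDuplicated(taxon_ids))
    stop2("'taxon_ids' must be non-empty and unique")
  if (length(proportions) != length(taxon_ids))
    stop2("'proportions' must match 'taxon_ids' in length")
  if (any(proportions < 0) || abs(sum(proportions) - 1) > 1e-9)
    stop2("'proportions' must be nonnegative and sum to 1")
  if (!is.numeric(total_density) || total_density < 0)
    stop2("'total_density' must be nonnegative")
  structure(list(taxon_ids = as.character(taxon_ids),
                 rel_proportions = as.numeric(proportions),
                 total_density = as.numeric(total_density)),
            class = "taxon_pool")
}

#' @export
print.taxon_pool <- function(x, ...) {
  cat(sprintf("taxon_pool: %d taxa, total density %g\n",
              length(x$taxon_ids), x$total_density))
  print(stats::setNames(x$rel_proportions, x$taxon_ids))
  invisible(x)
}

#' Draw one null community preserving richness and size
#'
#' Randomly assembles a community from the pool under the two observed
#' constraints: exactly `S` taxa present and exactly `N` individuals in
#' total.  `S` taxa are first drawn without replacement with probability
#' proportional to the pool proportions; each receives one founding
#' individual, and the remaining `N - S` individuals are distributed
#' multinomially with probabilities proportional to the selected taxa's pool
#' proportions (renormalized).  Both constraints hold exactly in every draw,
#' with no rejection sampling.
#'
#' @param pool a [taxon_pool].
#' @param S observed richness; `1 <= S <=` number of pool taxa.
#' @param N observed community size; `N >= S`.
#' @return named integer vector over all pool taxa, with exactly `S`
#'   positive entries summing to `N`.
#' @export
build_null_community <- function(pool, S, N) {
  k <- length(pool$taxon_ids)
  if (S < 1 || S > k) stop2("richness S must be in [1, ", k, "]")
  if (N < S) stop2("community size N (", N, ") must be >= richness S (", S, ")")
  picked <- if (k == 1L) 1L else
    sample.int(k, S, replace = FALSE, prob = pool$rel_proportions)
  counts <- stats::setNames(numeric(k), pool$taxon_ids)
  counts[picked] <- 1
  if (N > S) {
    pr <- pool$rel_proportions[picked]
    counts[picked] <- counts[picked] +
      drop(stats::rmultinom(1L, N - S, prob = pr / sum(pr)))
  }
  counts
}

# One group-level beta: relativize -> Bray-Curtis -> (sqrt) -> PCoA ->
# spatial median -> clamped distances -> (bias adjust) -> mean.  This is the
# same pipeline as beta_dispersion() run on the group's own samples, kept
# lean because the null model calls it n_reps times per group.
group_beta <- function(counts, sqrt_dist = TRUE, bias = TRUE,
                       center = "median") {
  rel <- counts / rowSums(counts)
  d <- vegan::vegdist(rel, method = "bray")
  if (sqrt_dist) d <- sqrt(d)
  ord <- pcoa(d)
  ctr <- if (center == "median") spatial_median(ord) else
    list(real = colMeans(ord$real), imag = colMeans(ord$imag))
  z <- distance_to_median(ord, ctr)
  if (bias) z <- bias_adjust(z, nrow(counts))
  mean(z)
}

#' Standardized beta-deviation (SES) from an abundance-constrained null model
#'
#' Compares each group's observed beta-diversity (multivariate dispersion of
#' its samples) against the distribution expected if every host community
#' were assembled by stochastic sampling from the treatment pool, while
#' preserving each host's observed taxon richness and total community size.
#' The standardized effect size is
#' \deqn{SES = (\beta_{obs} - \bar\beta_{null}) / sd(\beta_{null}),}
#' where the mean and standard deviation are taken over `n_reps` null
#' replicates (SD with denominator `n_reps - 1`).  SES near 0 indicates
#' assembly indistinguishable from drift (stochastic sampling); negative SES
#' indicates compositional convergence (homogenizing selection); positive
#' SES, divergence.
#'
#' Per-host constraints `(S, N)` are taken from the [integerize]d table.
#' Observed and null beta values use the identical dispersion pipeline (same
#' `sqrt_dist`/`bias_adjust`/`center`), computed within each group's own
#' samples.  Randomization streams are keyed per group label from the master
#' seed, so results for one group are unaffected by adding or removing other
#' groups.
#'
#' @param x a [count_table] of per-sample abundances (typically
#'   `copy_scaled`); all-zero rows must be excluded beforehand.
#' @param groups group labels, named by sample id or in row order of `x`.
#' @param pool a [taxon_pool] covering the taxa of `x`, or a named list of
#'   pools (one per group label).
#' @param n_reps number of null replicates (default 1000).
#' @param seed integer master seed (required: the null model is stochastic).
#' @param sqrt_dist,bias_adjust,center dispersion settings, as in
#'   [beta_dispersion()].
#' @return an object of class `"beta_deviation"`: list with `groups` (a
#'   data.frame `group, n, observed_beta, null_mean, null_sd, ses, n_reps,
#'   degenerate`), `null_betas` (n_reps x n_groups matrix of replicate
#'   betas), and the settings.
#' @export
beta_deviation <- function(x, groups, pool, n_reps = 1000, seed,
                           sqrt_dist = TRUE, bias_adjust = TRUE,
                           center = c("median", "centroid")) {
  center <- match.arg(center)
  if (missing(seed) || is.null(seed))
    stop2("a 'seed' is required: the null model is stochastic")
  if (n_reps < 2) stop2("'n_reps' must be at least 2")
  x <- count_table(x, table_unit(x))
  ids <- rownames(x)
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
  use_groups <- setdiff(levels(groups), skipped)

  counts_int <- integerize(x)

  res <- vector("list", length(use_groups))
  null_mat <- matrix(NA_real_, nrow = n_reps, ncol = length(use_groups),
                     dimnames = list(NULL, use_groups))
  for (j in seq_along(use_groups)) {
    g <- use_groups[j]
    idx <- which(groups == g)
    pg <- if (inherits(pool, "taxon_pool")) pool else {
      if (is.null(pool[[g]])) stop2("no pool supplied for group '", g, "'")
      pool[[g]]
    }
    extra <- setdiff(colnames(x), pg$taxon_ids)
    if (length(extra))
      stop2("table taxa absent from pool for group '", g, "': ",
            paste(extra, collapse = ", "))
    obs <- unclass(counts_int)[idx, , drop = FALSE]
    S <- rowSums(obs > 0)
    N <- rowSums(obs)
    if (any(S < 1))
      stop2("sample(s) with zero abundance in group '", g,
            "': exclude them with subset_focal() first")
    observed_beta <- group_beta(unclass(x)[idx, , drop = FALSE],
                                sqrt_dist, bias_adjust, center)
    nulls <- with_local_seed(sub_seed(seed, g), {
      vapply(seq_len(n_reps), function(r) {
        sim <- t(vapply(seq_along(idx), function(i)
          build_null_community(pg, S[i], N[i]),
          numeric(length(pg$taxon_ids))))
        colnames(sim) <- pg$taxon_ids
        group_beta(sim[, colnames(x), drop = FALSE],
                   sqrt_dist, bias_adjust, center)
      }, numeric(1))
    })
    null_mat[, j] <- nulls
    null_mean <- mean(nulls)
    null_sd <- stats::sd(nulls)
    degenerate <- null_sd <= 0
    res[[j]] <- data.frame(
      group = g, n = length(idx), observed_beta = observed_beta,
      null_mean = null_mean, null_sd = null_sd,
      ses = if (degenerate) NA_real_ else (observed_beta - null_mean) / null_sd,
      n_reps = n_reps, degenerate = degenerate, stringsAsFactors = FALSE)
  }
  structure(list(groups = do.call(rbind, res), null_betas = null_mat,
                 skipped = skipped, n_reps = n_reps, seed = seed,
                 sqrt_dist = sqrt_dist, bias_adjust = bias_adjust,
                 center = center),
            class = "beta_deviation")
}

#' @export
print.beta_deviation <- function(x, digits = 4, ...) {
  cat("Beta-deviation (standardized effect size vs. abundance-constrained null)\n")
  cat(sprintf("n_reps: %d | sqrt_dist: %s | bias_adjust: %s | center: %s\n",
              x$n_reps, x$sqrt_dist, x$bias_adjust, x$center))
  print(format(x$groups[, c("group", "n", "observed_beta", "null_mean",
                            "null_sd", "ses")], digits = digits),
        row.names = FALSE)
  if (any(x$groups$degenerate))
    cat("note: degenerate group(s) with null SD = 0; SES undefined there\n")
  if (length(x$skipped))
    cat("skipped (n < 2):", paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.beta_deviation <- function(object, ...) {
  g <- object$groups
  cat(sprintf("%d group(s); mean SES %.3f; %d group(s) with |SES| > 1.96\n",
              nrow(g), mean(g$ses, na.rm = TRUE),
              sum(abs(g$ses) > 1.96, na.rm = TRUE)))
  invisible(g)
}

#' @export
as.data.frame.beta_deviation <- function(x, ...) x$groups

#' @export
coef.beta_deviation <- function(object, ...) {
  stats::setNames(object$groups$ses, object$groups$group)
}

#' @export
plot.beta_deviation <- function(x, ...) {
  g <- x$groups
  graphics::plot(seq_len(nrow(g)), g$ses, xaxt = "n", xlab = "group",
                 ylab = "beta-deviation (SES)", pch = 19,
                 ylim = range(c(g$ses, -2.5, 2.5), na.rm = TRUE), ...)
  graphics::axis(1, at = seq_len(nrow(g)), labels = g$group, las = 2,
                 cex.axis = 0.7)
  graphics::abline(h = 0, lty = 1)
  graphics::abline(h = c(-1.96, 1.96), lty = 3)
  invisible(x)
}
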