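test_that("taxon_pool validates proportions and density", {
  p <- taxon_pool(paste0("t", 1:5))
  expect_equal(p$rel_proportions, rep(0.2, 5))
  expect_error(taxon_pool(c("a", "a")), "unique")
  expect_error(taxon_pool(c("a", "b"), c(0.7, 0.2)), "sum to 1")
  expect_error(taxon_pool("a", 1, -3), "nonnegative")
})

test_that("build_null_community hits forced outcomes", {
  pool <- taxon_pool(paste0("t", 1:5))
  set.seed(1)
  expect_equal(unname(build_null_community(pool, 5, 5)), rep(1, 5))
  one <- build_null_community(pool, 1, 50)
  expect_equal(sum(one), 50)
  expect_equal(sum(one > 0), 1L)
  expect_error(build_null_community(pool, 3, 2), "N.*S")
  expect_error(build_null_community(pool, 6, 10), "richness")
})

test_that("null draws preserve richness and size exactly, with correct moments", {
  pool <- taxon_pool(paste0("t", 1:5))
  set.seed(101)
  draws <- replicate(1000, build_null_community(pool, 3, 100))
  expect_true(all(colSums(draws) == 100))
  expect_true(all(colSums(draws > 0) == 3))
  # equal pool: unconditional per-taxon mean = N/k = 20 within 3 SE
  means <- rowMeans(draws)
  se <- apply(draws, 1, sd) / sqrt(ncol(draws))
  expect_true(all(abs(means - 20) < 3 * se))
  # conditional on selection, mean count is N/S for an equal pool
  cond <- mean(draws[draws > 0])
  expect_equal(cond, 100 / 3, tolerance = 0.05)
})

test_that("beta_deviation reports internally consistent SES", {
  pool <- taxon_pool(paste0("t", 1:4))
  set.seed(55)
  m <- t(replicate(6, build_null_community(pool, sample(2:4, 1),
                                           sample(50:500, 1))))
  rownames(m) <- paste0("s", 1:6)
  bd <- beta_deviation(count_table(m), rep("g", 6), pool,
                       n_reps = 50, seed = 7)
  g <- bd$groups
  expect_equal(g$ses, (g$observed_beta - g$null_mean) / g$null_sd)
  expect_equal(g$n_reps, 50)
  expect_false(g$degenerate)
  expect_equal(dim(bd$null_betas), c(50L, 1L))
  expect_error(beta_deviation(count_table(m), rep("g", 6), pool, n_reps = 50),
               "seed")
})

test_that("beta_deviation is reproducible and group streams are independent", {
  pool <- taxon_pool(paste0("t", 1:5))
  set.seed(77)
  m <- t(replicate(8, build_null_community(pool, sample(2:5, 1),
                                           sample(100:1000, 1))))
  rownames(m) <- paste0("s", 1:8)
  ct <- count_table(m)
  grp <- rep(c("g1", "g2"), each = 4)
  b1 <- beta_deviation(ct, grp, pool, n_reps = 40, seed = 3)
  b2 <- beta_deviation(ct, grp, pool, n_reps = 40, seed = 3)
  expect_identical(b1$groups, b2$groups)  # bit-reproducible
  # dropping g2 leaves g1's draws untouched (keyed substreams)
  b3 <- beta_deviation(count_table(m[1:4, ]), rep("g1", 4), pool,
                       n_reps = 40, seed = 3)
  expect_identical(b1$null_betas[, "g1"], b3$null_betas[, "g1"])
  b4 <- beta_deviation(ct, grp, pool, n_reps = 40, seed = 4)
  expect_false(identical(b1$groups$ses, b4$groups$ses))
})

test_that("homogenizing selection drives SES negative, more so with dominance", {
  pool <- taxon_pool(paste0("t", 1:5))
  ses_at <- function(frac) {
    # all samples dominated by t1 at `frac`, remainder split over two taxa
    set.seed(500)
    m <- t(sapply(1:8, function(i) {
      rest <- sample(2:5, 2)
      v <- numeric(5)
      v[1] <- round(1000 * frac)
      v[rest] <- round(1000 * (1 - frac) / 2)
      v
    }))
    dimnames(m) <- list(paste0("s", 1:8), paste0("t", 1:5))
    beta_deviation(count_table(m), rep("g", 8), pool,
                   n_reps = 200, seed = 9)$groups$ses
  }
  weak <- ses_at(0.6)
  strong <- ses_at(0.95)
  expect_lt(strong, 0)
  expect_lt(strong, weak)
})

test_that("degenerate null distributions are flagged, not infinite", {
  # S = k and N = S forces every null draw to the same community
  pool <- taxon_pool(paste0("t", 1:3))
  m <- rbind(s1 = c(1, 1, 1), s2 = c(1, 1, 1))
  colnames(m) <- pool$taxon_ids
  bd <- suppressWarnings(beta_deviation(count_table(m), rep("g", 2), pool,
                                        n_reps = 20, seed = 2))
  expect_true(bd$groups$degenerate)
  expect_true(is.na(bd$groups$ses))
})
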