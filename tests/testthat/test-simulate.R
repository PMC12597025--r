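test_that("make_pool builds the dilution series with equal proportions", {
  p <- assembly_params()
  pools <- make_pool(p)
  expect_length(pools, 6)
  expect_equal(pools[["d0"]]$total_density, 1.69e5)
  expect_equal(pools[["d-5"]]$total_density, 1.69)
  dens <- vapply(pools, `[[`, numeric(1), "total_density")
  expect_equal(unname(dens[-length(dens)] / dens[-1]), rep(10, 5))
  for (pl in pools) expect_equal(pl$rel_proportions, rep(0.2, 5))
})

test_that("assembly_params validates its inputs", {
  expect_error(assembly_params(dilution_exponents = c(0, 0, -1)), "decreasing")
  expect_error(assembly_params(fitness = c(1, 1, 1, 1, -2)), "positive")
  expect_error(assembly_params(establishment_prob = 1.2))
  p <- assembly_params(selection = 0.5)
  expect_equal(p$fitness, 2 * c(1.5, 1, 1, 1, 1))
})

test_that("colonization matches its Poisson-binomial moments", {
  params <- assembly_params(colonization_scale = 1, establishment_prob = 0.4)
  pool <- taxon_pool(paste0("t", 1:5), total_density = 50)
  expect_equal(unname(simulate_colonization(
    taxon_pool(paste0("t", 1:5), total_density = 0), params)), rep(0, 5))
  set.seed(71)
  draws <- replicate(10000, simulate_colonization(pool, params))
  expected <- 1 * 50 * 0.2 * 0.4  # scale * density * proportion * estab
  means <- rowMeans(draws)
  se <- apply(draws, 1, sd) / sqrt(ncol(draws))
  expect_true(all(abs(means - expected) < 3 * se))
  # at high density all taxa establish; at low density fewer than all
  set.seed(72)
  high <- simulate_colonization(taxon_pool(paste0("t", 1:5),
                                           total_density = 1e5), params)
  expect_true(all(high > 0))
  low <- replicate(500, sum(simulate_colonization(
    taxon_pool(paste0("t", 1:5), total_density = 2), params) > 0))
  expect_lt(mean(low), 5)
})

test_that("single-taxon communities are absorbing and capped", {
  params <- assembly_params(drift_size = 500,
                            n_generations_between_stages = 8)
  set.seed(81)
  out <- simulate_ontogeny(c(t1 = 20, t2 = 0, t3 = 0, t4 = 0, t5 = 0), params)
  expect_equal(sum(out > 0), 1L)
  expect_equal(names(out)[out > 0], "t1")
  expect_equal(sum(out), 500)  # grown to the resampling bound
  # empty community stays empty
  expect_equal(sum(simulate_ontogeny(setNames(numeric(5), paste0("t", 1:5)),
                                     params)), 0)
})

test_that("neutral drift is a martingale in expected composition", {
  params <- assembly_params(selection = 0, drift_size = 400,
                            n_generations_between_stages = 6)
  init <- c(t1 = 10, t2 = 10, t3 = 20, t4 = 5, t5 = 5)
  p0 <- init / sum(init)
  set.seed(91)
  finals <- replicate(2000, {
    out <- simulate_ontogeny(init, params)
    out / sum(out)
  })
  means <- rowMeans(finals)
  se <- apply(finals, 1, sd) / sqrt(ncol(finals))
  expect_true(all(abs(means - p0) < 3 * se))
})

test_that("strong selection drives the advantaged taxon to dominance", {
  params <- assembly_params(selection = 1, drift_size = 5000)
  pool <- taxon_pool(params$taxon_ids, total_density = 1.69e5)
  set.seed(95)
  finals <- replicate(100, {
    comm <- simulate_colonization(pool, params)
    out <- simulate_ontogeny(comm, params)
    out[1] / sum(out)
  })
  expect_gt(mean(finals), 0.8)
})

test_that("taxa are exchangeable under s = 0", {
  params <- assembly_params(selection = 0, drift_size = 300,
                            n_generations_between_stages = 6)
  pool <- taxon_pool(params$taxon_ids, total_density = 20)
  set.seed(97)
  runs <- replicate(200, {
    out <- simulate_ontogeny(simulate_colonization(pool, params), params)
    if (sum(out) > 0) out / sum(out) else rep(NA_real_, 5)
  })
  ks <- suppressWarnings(ks.test(runs[1, ], runs[2, ]))
  expect_gt(ks$p.value, 0.01)
})

test_that("simulate_study bookkeeping, metadata and reproducibility", {
  params <- assembly_params(replicates_per_cell = 3, seed = 5)
  st <- simulate_study(params)
  expect_equal(nrow(st$counts), 6 * 2 * 3)
  expect_equal(ncol(st$counts), 5)
  expect_setequal(unique(st$metadata$instar), c(3L, 5L))
  expect_equal(nrow(st$metadata), nrow(st$counts))
  expect_true(all(st$metadata$copy_number >= 0))
  expect_true(all(st$metadata$lineage_id %in% paste0("lineage_", 1:4)))
  st2 <- simulate_study(params)
  expect_identical(unclass(st$counts), unclass(st2$counts))
  expect_identical(st$metadata, st2$metadata)
  # empty study when replicates_per_cell = 0
  st0 <- simulate_study(assembly_params(replicates_per_cell = 0, seed = 5))
  expect_equal(nrow(st0$metadata), 0L)
})

test_that("community size at the first stage increases with immigration", {
  st <- simulate_study(assembly_params(replicates_per_cell = 6, seed = 8))
  md <- st$metadata[st$metadata$instar == 3, ]
  mean_size <- tapply(md$copy_number, md$immigration_level, mean)
  lev <- as.numeric(names(mean_size))
  expect_equal(cor(log10(lev), log10(mean_size + 1), method = "spearman"), 1)
})

test_that("background taxa are generated and excluded by subset_focal", {
  params <- assembly_params(replicates_per_cell = 2, background_taxa = 3,
                            seed = 12)
  st <- simulate_study(params)
  expect_equal(ncol(st$counts), 8)
  expect_true(all(paste0("background_", 1:3) %in% colnames(st$counts)))
  out <- suppressWarnings(subset_focal(st$counts, params$taxon_ids))
  expect_equal(colnames(out), params$taxon_ids)
})
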