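test_that("count_table validates labels, signs and relative sums", {
  m <- matrix(1:6, 2, 3, dimnames = list(c("s1", "s2"), c("A", "B", "C")))
  expect_s3_class(count_table(m), "count_table")
  expect_error(count_table(unname(m)), "names")
  m2 <- m; rownames(m2) <- c("s1", "s1")
  expect_error(count_table(m2), "duplicate sample")
  m3 <- m; m3[1, 2] <- -4
  expect_error(count_table(m3), "negative abundance.*s1.*B")
  rel <- m / rowSums(m)
  expect_s3_class(count_table(rel, "relative"), "count_table")
  expect_error(count_table(m, "relative"), "row sums")
})

test_that("aggregate_taxa sums members, conserves totals, handles unmapped", {
  m <- matrix(c(3, 4, 2, 1, 0, 5), nrow = 1,
              dimnames = list("s1", paste0("t", 1:6)))
  ct <- count_table(m)
  map <- c(t1 = "famA", t2 = "famA", t3 = "famB", t4 = "famB", t5 = "famC")
  out <- aggregate_taxa(ct, map)
  expect_equal(unname(out["s1", "famA"]), 7)       # (3, 4) -> 7
  expect_equal(unname(out["s1", "unassigned"]), 5) # t6 bucketed
  expect_equal(rowSums(out), rowSums(ct))          # totals conserved
  expect_error(aggregate_taxa(ct, map, policy = "strict"), "t6")

  # one taxon per group: identity up to renaming
  idmap <- setNames(paste0("g", 1:6), paste0("t", 1:6))
  out2 <- aggregate_taxa(ct, idmap)
  expect_equal(unname(unclass(out2)), unname(unclass(ct)))

  # totals conserved on random float tables
  set.seed(42)
  big <- count_table(matrix(runif(60, 0, 10), 6, 10,
                            dimnames = list(paste0("s", 1:6), paste0("t", 1:10))))
  rmap <- setNames(sample(c("x", "y", "z"), 10, TRUE), paste0("t", 1:10))
  expect_equal(rowSums(aggregate_taxa(big, rmap)), rowSums(big),
               tolerance = 1e-9)
})

test_that("subset_focal keeps focal columns and logs zero-focal exclusions", {
  set.seed(3)
  m <- rand_counts(4, 7)
  focal <- paste0("t", 1:5)
  m["s3", focal] <- 0
  m["s3", "t6"] <- 9  # s3 has reads, but none focal
  ct <- count_table(m)
  expect_warning(out <- subset_focal(ct, focal), "s3")
  expect_equal(colnames(out), focal)
  expect_false("s3" %in% rownames(out))
  expect_equal(attr(out, "excluded"), "s3")
  expect_error(subset_focal(ct, c("t1", "nope")), "nope")
  expect_error(subset_focal(ct, character(0)))
  # focal = all taxa is the identity
  expect_equal(unclass(subset_focal(ct, colnames(ct)))[rownames(m), ],
               unclass(ct)[rownames(m), ])
})

test_that("relativize divides rows by their sums and rejects zero rows", {
  m <- matrix(c(2, 3, 5, 0, 0, 7), 2, 3, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("A", "B", "C")))
  rel <- relativize(count_table(m))
  expect_equal(unname(rel["s1", ]), c(0.2, 0.3, 0.5))
  expect_equal(unname(rel["s2", ]), c(0, 0, 1))
  expect_equal(table_unit(rel), "relative")
  m0 <- rbind(m, s3 = c(0, 0, 0))
  expect_error(relativize(count_table(m0)), "s3.*subset_focal")
})

test_that("copy_scale restores per-sample totals to the copy number", {
  m <- matrix(c(0.2, 0.8, 0.5, 0.5), 2, 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("A", "B")))
  rel <- count_table(m, "relative")
  cs <- copy_scale(rel, c(s1 = 1000, s2 = 38))
  expect_equal(unname(cs["s1", ]), c(200, 800))
  expect_equal(unname(rowSums(cs)), c(1000, 38), tolerance = 1e-6)
  expect_equal(table_unit(cs), "copy_scaled")
  # (0.5, 0.3, 0.2) x 38 by direct multiplication
  one <- count_table(matrix(c(0.5, 0.3, 0.2), 1,
                            dimnames = list("s1", c("A", "B", "C"))),
                     "relative")
  expect_equal(unname(copy_scale(one, c(s1 = 38))["s1", ]), c(19, 11.4, 7.6))
  expect_error(copy_scale(rel, c(s1 = 1000)), "s2")
  expect_warning(cs0 <- copy_scale(rel, c(s1 = 0, s2 = 38)), "s1")
  expect_equal(unname(cs0["s1", ]), c(0, 0))
  expect_error(copy_scale(count_table(matrix(1:4, 2, 2,
    dimnames = list(c("s1", "s2"), c("A", "B")))), c(s1 = 1, s2 = 1)),
    "relative")
})

test_that("integerize rounds but preserves presence", {
  expect_equal(integerize(c(200.0, 800.0)), c(200, 800))
  expect_equal(integerize(c(0.4, 99.6)), c(1, 100))
  expect_equal(integerize(c(0, 0, 38.2)), c(0, 0, 38))
  # presence pattern survives for any nonnegative vector
  set.seed(9)
  for (i in 1:20) {
    v <- rexp(6) * 10^sample(-2:3, 6, TRUE) * rbinom(6, 1, 0.6)
    expect_identical(integerize(v) > 0, v > 0)
  }
})
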