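# Shared fixture builders.  Callers control RNG with set.seed().

# random count matrix with sample/taxon names and a sprinkling of zeros
rand_counts <- function(n, k, lambda = 8, zero_frac = 0.25) {
  m <- matrix(rpois(n * k, lambda), n, k,
              dimnames = list(paste0("s", seq_len(n)),
                              paste0("t", seq_len(k))))
  m[sample(length(m), floor(zero_frac * length(m)))] <- 0
  # no all-zero rows
  empty <- rowSums(m) == 0
  m[empty, 1L] <- 1
  m
}

# random point on the k-simplex
rand_simplex <- function(k) {
  x <- rexp(k)
  x / sum(x)
}

# direct Bray-Curtis formula, the independent oracle for bray_curtis()
bc_formula <- function(x, y) 1 - 2 * sum(pmin(x, y)) / (sum(x) + sum(y))

# brute-force geometric computation of group dispersion for Euclidean point
# clouds: spatial median and distances in the ORIGINAL coordinates, no
# ordination step
direct_dispersion <- function(pts, bias = FALSE) {
  ctr <- spatial_median(pts)
  z <- sqrt(rowSums(sweep(pts, 2L, ctr)^2))
  if (bias) z <- z * sqrt(nrow(pts) / (nrow(pts) - 1))
  mean(z)
}

# verify the PCoA reconstruction identity: squared real-block distances minus
# squared imaginary-block distances reproduce the squared input dissimilarity
pcoa_reconstruction_error <- function(ord, d) {
  m <- as.matrix(d)
  n <- nrow(m)
  err <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d2 <- sum((ord$real[i, ] - ord$real[j, ])^2) -
      sum((ord$imag[i, ] - ord$imag[j, ])^2)
    err <- max(err, abs(d2 - m[i, j]^2))
  }
  err
}
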