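# Shared fixtures and independent brute-force oracles.

# A tiny 2-endpoint moments set with known, well-separated moments.
toy_moments <- function() {
  cov <- matrix(c(4, 1, 1, 2), 2, 2, dimnames = list(c("e1", "e2"),
                                                     c("e1", "e2")))
  moments_set(
    endpoint_panel(c("e1", "e2"), direction = c(1L, 1L)),
    list(
      cell_moments("WT", 12, "baseline", mean = c(10, 5), cov = cov),
      cell_moments("HET", 12, "baseline", mean = c(14, 8), cov = cov)
    )
  )
}

# Single-endpoint moments with a given standardized genotype effect d
# (unit SD in both genotypes).
single_endpoint_moments <- function(d, age = 12) {
  cov <- matrix(1, 1, 1, dimnames = list("ep", "ep"))
  moments_set(
    endpoint_panel("ep", direction = 1L),
    list(
      cell_moments("WT", age, "baseline", mean = 0, cov = cov),
      cell_moments("HET", age, "baseline", mean = d, cov = cov)
    )
  )
}

# A vector with exactly the requested mean and (n-1)-denominator SD, built by
# affine transform of a fixed base vector.
vector_with_summary <- function(mean, sd, n, base_seed = 42) {
  set.seed(base_seed)
  z <- rnorm(n)
  z <- (z - mean(z)) / stats::sd(z) # exact mean 0, sd 1
  mean + sd * z
}

# Exhaustive-permutation p for the two-sample KS statistic (all label
# assignments of the pooled sample).
perm_ks_p <- function(x, y) {
  pool <- c(x, y)
  n1 <- length(x)
  ks_stat <- function(a, b) {
    v <- sort(unique(c(a, b)))
    max(abs(stats::ecdf(a)(v) - stats::ecdf(b)(v)))
  }
  d0 <- ks_stat(x, y)
  idx <- utils::combn(length(pool), n1)
  ds <- apply(idx, 2, function(ii) ks_stat(pool[ii], pool[-ii]))
  mean(ds >= d0 - 1e-12)
}

# Exhaustive-permutation p for the (tie-corrected) Kruskal-Wallis H of two
# groups.
perm_kw_p <- function(x, y) {
  pool <- c(x, y)
  n1 <- length(x)
  H <- function(a, b) suppressWarnings(
    stats::kruskal.test(list(a, b))$statistic)
  h0 <- H(x, y)
  idx <- utils::combn(length(pool), n1)
  hs <- apply(idx, 2, function(ii) H(pool[ii], pool[-ii]))
  mean(hs >= h0 - 1e-12)
}

# Long-format two-group data frame for the rank-based tests.
two_groups <- function(x, y) {
  data.frame(value = c(x, y),
             group = rep(c("g1", "g2"), c(length(x), length(y))))
}
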