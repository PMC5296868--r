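# Internal helpers shared across modules.

# Deterministic stream derivation: one user-facing seed, per-component seeds
# derived from (seed, key...) so results are reproducible under reordering of
# cells, replicates or grid points. Kept in [0, 2^31 - 2]; every arithmetic
# step stays below 2^53 so the double computation is exact.
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  m <- 2147483647 # 2^31 - 1, prime
  h <- abs(as.numeric(seed)) %% m
  key <- paste(vapply(list(...), function(x) paste(format(x), collapse = ","),
                      character(1)), collapse = "|")
  for (code in utf8ToInt(key)) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a single finite number in [%s, %s]", name,
                 format(lower), format(upper)), call. = FALSE)
  }
  invisible(x)
}

assert_count <- function(x, name, lower = 0) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x != round(x) || x < lower) {
    stop(sprintf("`%s` must be a single integer >= %d", name, lower), call. = FALSE)
  }
  invisible(as.integer(x))
}
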