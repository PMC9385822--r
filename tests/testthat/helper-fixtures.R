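# Distinct-score fixtures built in code; seeds fixed for reproducibility.

gaussian_sample <- function(n = 300, seed = 101,
                            direction = "higher_better",
                            mean = 50, sd = 10) {
  set.seed(seed)
  normative_sample(rnorm(n, mean, sd), direction)
}

# Exact binomial CDF by direct summation (independent of stats::pbinom).
binom_cdf_by_sum <- function(k, n, p) {
  i <- 0:k
  sum(choose(n, i) * p^i * (1 - p)^(n - i))
}

# Exhaustive-scan rank oracles built on the summation CDF.
otl_rank_oracle <- function(n, tail = 0.05, conf = 0.95) {
  feasible <- which(vapply(1:n, function(k) {
    binom_cdf_by_sum(k - 1, n, tail) <= 1 - conf
  }, logical(1)))
  if (!length(feasible)) NA_integer_ else max(feasible)
}

itl_rank_oracle <- function(n, tail = 0.05, conf = 0.95) {
  min(which(vapply(1:n, function(k) {
    binom_cdf_by_sum(k, n, tail) >= conf
  }, logical(1))))
}

# Legible reference-table rows, n / OTL / ITL / ES1-2 / ES2-3 / median.
reference_rows <- function() {
  m <- rbind(
    c(100, 2, 9, 18, 34, 51),
    c(125, 3, 10, 23, 43, 63),
    c(150, 3, 12, 27, 51, 76),
    c(175, 4, 14, 32, 60, 88),
    c(200, 5, 15, 37, 69, 101),
    c(250, 7, 18, 46, 85, 126),
    c(275, 8, 20, 51, 94, 138),
    c(300, 9, 21, 56, 103, 151),
    c(600, 21, 39, 114, 207, 301))
  colnames(m) <- c("n", "otl", "itl", "es1_es2", "es2_es3", "median")
  m
}
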