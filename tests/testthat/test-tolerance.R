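test_that("OTL and ITL ranks reproduce the published values", {
  expect_identical(otl_rank(300), 9L)
  expect_identical(itl_rank(300), 21L)
  expect_identical(otl_rank(1000), 39L)
  expect_identical(itl_rank(1000), 62L)
  expect_identical(otl_rank(100), 2L)
  expect_identical(itl_rank(100), 9L)
})

test_that("ranks agree with the exhaustive binomial-summation oracle", {
  for (n in c(59, 60, 75, 100, 137, 150, 200)) {
    expect_identical(otl_rank(n), otl_rank_oracle(n), label = paste("OTL n =", n))
    expect_identical(itl_rank(n), itl_rank_oracle(n), label = paste("ITL n =", n))
  }
  # non-default specification
  expect_identical(otl_rank(100, tolerance_spec(0.1, 0.9)),
                   otl_rank_oracle(100, 0.1, 0.9))
  expect_identical(itl_rank(100, tolerance_spec(0.1, 0.9)),
                   itl_rank_oracle(100, 0.1, 0.9))
})

test_that("rank pair is ordered and non-decreasing in n", {
  ns <- seq(59, 1200, by = 7)
  otl <- vapply(ns, otl_rank, integer(1))
  itl <- vapply(ns, itl_rank, integer(1))
  expect_true(all(otl <= itl))
  expect_true(all(diff(otl) >= 0))
  expect_true(all(diff(itl) >= 0))
})

test_that("samples below the minimum size raise an informative error", {
  expect_error(otl_rank(58), "sample too small.*minimum n = 59")
  expect_no_error(otl_rank(59))
  expect_identical(min_n_for_otl(), 59L)
  expect_error(
    np_tolerance_limits(gaussian_sample(n = 40), tolerance_spec()),
    "sample too small")
})

test_that("tolerance limit scores are the order statistics counted from the deficit tail", {
  s_lo <- gaussian_sample(n = 300, seed = 11, direction = "higher_better")
  tl <- np_tolerance_limits(s_lo)
  expect_equal(tl$otl_score, sort(s_lo$scores)[9])
  expect_equal(tl$itl_score, sort(s_lo$scores)[21])

  # timed-test direction: the 9th worst is the 292nd in ascending order
  s_hi <- gaussian_sample(n = 300, seed = 11, direction = "lower_better")
  tl <- np_tolerance_limits(s_hi)
  expect_equal(tl$otl_score, sort(s_hi$scores)[292])
  expect_identical(ascending_position(9L, 300L, "lower_better"), 292L)
  # OTL weakly worse than ITL on the deficit side
  expect_true(tl$otl_score >= tl$itl_score)
})

test_that("95/95 OTL coverage holds under Monte-Carlo sampling", {
  # continuous, deliberately skewed parent; true 5th percentile known
  set.seed(202)
  n <- 300
  k <- otl_rank(n)
  q05 <- qlnorm(0.05)
  hits <- replicate(2000, sort(rlnorm(n))[k] <= q05)
  phat <- mean(hits)
  expect_gte(phat, 0.95 - 2 * sqrt(0.95 * 0.05 / 2000))
  # OTL's exact nominal coverage is 1 - pbinom(k - 1, n, 0.05) >= 0.95
  nominal_otl <- 1 - pbinom(k - 1, n, 0.05)
  expect_gte(nominal_otl, 0.95)
  expect_lt(abs(phat - nominal_otl), 3 * sqrt(nominal_otl * (1 - nominal_otl) / 2000))
  # ITL side: empirical rate of the ITL order statistic clearing the true
  # 5th percentile matches its exact nominal value pbinom(k - 1, n, 0.05)
  # (slightly below 0.95 under the rank rule pinned by the published table)
  ki <- itl_rank(n)
  nominal_itl <- pbinom(ki - 1, n, 0.05)
  hits_i <- replicate(2000, sort(rlnorm(n))[ki] >= q05)
  expect_lt(abs(mean(hits_i) - nominal_itl),
            3 * sqrt(nominal_itl * (1 - nominal_itl) / 2000))
})

test_that("parametric one-sided tolerance limit matches its frozen oracle and asymptotics", {
  # k-factor for n = 50 verified beforehand by Monte-Carlo coverage
  expect_equal(parametric_lower_tl(0, 1, 50), -2.06499341775, tolerance = 1e-9)
  # direction flip mirrors the limit
  expect_equal(parametric_lower_tl(0, 1, 50, direction = "lower_better"),
               2.06499341775, tolerance = 1e-9)
  # k(n) decreases toward the standard-normal 95th percentile
  ks <- -vapply(c(10, 50, 200, 1000, 1e5), function(n)
    parametric_lower_tl(0, 1, n), numeric(1))
  expect_true(all(diff(ks) < 0))
  expect_equal(ks[5], qnorm(0.95), tolerance = 5e-3)
  # limit sits strictly on the deficit side of the mean
  expect_lt(parametric_lower_tl(50, 10, 300), 50)
  expect_error(parametric_lower_tl(0, 0, 50), "positive")
  expect_error(parametric_lower_tl(0, 1, 1), ">= 2")
})

test_that("normality check flags skewed samples and accepts Gaussian ones", {
  set.seed(77)
  skewed <- rlnorm(300, 0, 0.5)
  r <- normality_test(skewed)
  expect_lt(r$p_value, 0.001)
  expect_true(r$W > 0 && r$W <= 1)
  # near-linear QQ for an exact symmetric sequence
  expect_gt(normality_test(c(-2, -1, 0, 1, 2))$W, 0.98)
  expect_error(normality_test(c(1, 2)), "between 3 and 5000")
  # p-values roughly uniform under the null (coarse Kolmogorov check)
  set.seed(88)
  ps <- replicate(200, normality_test(rnorm(200))$p_value)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})
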