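test_that("median rank and rank cutoffs reproduce the published values", {
  expect_identical(median_rank(300), 151L)
  expect_identical(median_rank(100), 51L)
  expect_identical(median_rank(1), 1L)
  expect_identical(rank_cutoffs(9, 151), c(56L, 103L))
  expect_identical(rank_cutoffs(39, 501), c(193L, 347L))
  expect_identical(rank_cutoffs(5L, 8L), c(6L, 7L))
  expect_error(rank_cutoffs(151, 151), "median rank must exceed")
})

test_that("z-score cutoffs trisect the standardized interval to the mean", {
  expect_equal(zscore_cutoffs(0, 1, -1.763), c(-1.763 * 2 / 3, -1.763 / 3))
  expect_equal(zscore_cutoffs(5, 2, 5), c(5, 5))
  # location/scale equivariance
  b <- zscore_cutoffs(0, 1, -1.763)
  expect_equal(zscore_cutoffs(100, 15, 100 - 1.763 * 15), 100 + 15 * b)
  expect_error(zscore_cutoffs(0, 0, -1), "positive")
})

test_that("direct cutoffs trisect the score interval between OTL and median", {
  expect_equal(round(direct_cutoffs(72.86, 42.35), 2), c(62.69, 52.52))
  # endpoints printed to 2 decimals determine the trisection only to ~0.01:
  # exact arithmetic on (6.79, 38.21) gives 17.2633/27.7367
  expect_equal(direct_cutoffs(6.79, 38.21), c(17.26333, 27.73667),
               tolerance = 1e-6)
  expect_lt(max(abs(direct_cutoffs(6.79, 38.21) - c(17.26, 27.73))), 0.011)
  expect_equal(direct_cutoffs(0, 3), c(1, 2))
  expect_error(direct_cutoffs(2, 2), "coincide")
})

test_that("nearest_rank locates observations and breaks ties toward the median", {
  s <- normative_sample(c(10, 20, 30, 40, 50), "higher_better")
  expect_identical(nearest_rank(s, 30), 3L)
  # 25 is midway between ranks 2 and 3; median rank is 3
  expect_identical(nearest_rank(s, 25), 3L)
  expect_identical(nearest_rank(s, 25, tie = "deficit"), 2L)
  # direction-aware: for a timed test rank 1 is the highest score
  s2 <- normative_sample(c(10, 20, 30, 40, 50), "lower_better")
  expect_identical(nearest_rank(s2, 50), 1L)
})

test_that("rank norms carry the published rank limits for n = 300", {
  s <- gaussian_sample(n = 300, seed = 5)
  nm <- build_norms(s, "rank")
  expect_identical(nm$rank_limits,
                   list(otl = 9L, itl = 21L, c1 = 56L, c2 = 103L, median = 151L))
  ord <- sort(s$scores)
  expect_equal(unname(nm$boundary_scores), ord[c(9, 56, 103, 151)])
})

test_that("boundary endpoints are identical across the three methods", {
  for (kind in c("skew_lower_better", "skew_higher_better", "gaussian")) {
    s <- generate_sample(kind, seed = 9)
    nms <- lapply(c("rank", "zscore", "direct"), function(m) build_norms(s, m))
    b0 <- vapply(nms, function(x) x$boundary_scores[["b0"]], numeric(1))
    b3 <- vapply(nms, function(x) x$boundary_scores[["b3"]], numeric(1))
    expect_equal(diff(range(b0)), 0, label = kind)
    expect_equal(diff(range(b3)), 0, label = kind)
  }
})

test_that("rank-method intermediate densities are near-equal for distinct scores", {
  # the floor-step rule sends the integer-division remainder (0, 1 or 2
  # ranks) to the block adjoining the median, so ES1 == ES2 always and
  # ES3 exceeds them by at most 2 (e.g. n = 250: 39/39/41)
  set.seed(31)
  for (n in c(99, 137, 250, 300, 500, 1000)) {
    for (direction in c("higher_better", "lower_better")) {
      s <- normative_sample(runif(n), direction)
      dr <- density_report(s, build_norms(s, "rank"))
      counts <- dr$count[2:4]
      expect_identical(counts[1], counts[2])
      expect_lte(max(counts) - min(counts), 2)
      span <- diff(c(otl_rank(n),
                     if (direction == "lower_better" && n %% 2 == 0)
                       n + 1L - median_rank(n) else median_rank(n)))
      expect_identical(counts[3] - counts[1], as.integer(span %% 3))
    }
  }
})

test_that("density tables reproduce the published rank and z-method rows", {
  # timed-test sample, n = 300: equal thirds of 141 ranks
  sA <- generate_sample("skew_lower_better", n = 300, seed = 13)
  drA <- density_report(sA, build_norms(sA, "rank"))
  expect_identical(drA$count[2:4], c(47L, 47L, 47L))
  expect_identical(drA$pct[2:4], c(15.67, 15.67, 15.67))
  # recall-test sample, n = 300: the median observation joins ES3
  sB <- generate_sample("skew_higher_better", n = 300, seed = 13)
  drB <- density_report(sB, build_norms(sB, "rank"))
  expect_identical(drB$count[2:4], c(47L, 47L, 48L))
  # Gaussian n = 1000: 154 per category (15.4%)
  sC <- generate_sample("gaussian", n = 1000, seed = 13)
  drC <- density_report(sC, build_norms(sC, "rank"))
  expect_identical(drC$count[2:4], c(154L, 154L, 154L))
  expect_identical(drC$pct[2:4], c(15.4, 15.4, 15.4))
  # z-method densities equal consecutive boundary-rank differences:
  # with boundary ranks 39/120/278/501 the counts are 81/158/223
  ord <- sort(sC$scores)
  nmz <- build_norms(sC, "zscore")
  nmz$boundary_scores[c("b1", "b2")] <- ord[c(120, 278)]
  drz <- density_report(sC, nmz)
  expect_identical(drz$count[2:4], c(81L, 158L, 223L))
})

test_that("rank limits are invariant to the score distribution at fixed n and direction", {
  limits <- lapply(c("skew_higher_better", "gaussian"), function(kind) {
    s <- generate_sample(kind, n = 300, seed = 17)
    build_norms(s, "rank")$rank_limits
  })
  expect_identical(limits[[1]], limits[[2]])
})

test_that("negating scores and flipping direction preserves rank norms for odd n", {
  s <- gaussian_sample(n = 299, seed = 23, direction = "higher_better")
  flipped <- normative_sample(-s$scores, "lower_better")
  a <- build_norms(s, "rank")
  b <- build_norms(flipped, "rank")
  expect_identical(a$rank_limits, b$rank_limits)
  expect_equal(unname(a$boundary_scores), -unname(b$boundary_scores))
})

test_that("z and direct methods converge on Gaussian data, diverge on skewed data", {
  # across replicates the typical boundary ranks of the two methods agree
  c1 <- matrix(NA_real_, 60, 2)
  c2 <- matrix(NA_real_, 60, 2)
  for (i in 1:60) {
    s <- generate_sample("gaussian", seed = 400 + i)
    nz <- build_norms(s, "zscore")
    nd <- build_norms(s, "direct")
    c1[i, ] <- c(nz$rank_limits$c1, nd$rank_limits$c1)
    c2[i, ] <- c(nz$rank_limits$c2, nd$rank_limits$c2)
  }
  expect_lte(abs(median(c1[, 1]) - median(c1[, 2])), 2)
  expect_lte(abs(median(c2[, 1]) - median(c2[, 2])), 2)
  # skew disagreement: rank-method ES1 density exceeds the z-method's,
  # consistently, for ceiling-affected recall-like samples
  wins <- vapply(1:60, function(i) {
    s <- generate_sample("skew_higher_better", seed = 500 + i)
    drr <- density_report(s, build_norms(s, "rank"))
    drz <- density_report(s, build_norms(s, "zscore"))
    drr$count[2] > drz$count[2]
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("tied scores at a boundary all fall in the worse category", {
  scores <- c(rep(1, 5), rep(2, 10), rep(3, 50), rep(4, 100), rep(5, 135))
  s <- normative_sample(scores, "higher_better")
  nm <- build_norms(s, "rank")
  es <- classify_batch(scores, nm, median_rule = "es3")$es
  # every observation sharing a boundary value gets one category
  for (v in unique(scores)) expect_length(unique(es[scores == v]), 1)
  dr <- density_report(s, nm)
  expect_identical(sum(dr$count), s$n)
})
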