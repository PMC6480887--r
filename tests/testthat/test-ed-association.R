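test_that("depth frequencies normalize allele depths", {
  expect_equal(depth_frequencies(c(10, 0, 0, 0)), c(1, 0, 0, 0))
  expect_equal(depth_frequencies(c(5, 5, 0, 0)), c(0.5, 0.5, 0, 0))
  expect_equal(depth_frequencies(c(30, 10)), c(0.75, 0.25))
  expect_error(depth_frequencies(c(0, 0)), "total depth")
  expect_error(depth_frequencies(c(-1, 5)), "non-negative")
  expect_error(depth_frequencies(3), "length")
})

test_that("ED statistic matches closed forms and is symmetric and bounded", {
  expect_equal(ed_statistic(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(ed_statistic(c(1, 0, 0, 0), c(0, 1, 0, 0)), sqrt(2))
  expect_equal(ed_statistic(c(0.5, 0.5, 0, 0), c(1, 0, 0, 0)), sqrt(0.5))
  expect_error(ed_statistic(c(1, 0), c(1, 0, 0)), "length")

  set.seed(42)
  for (i in 1:50) {
    k <- sample(2:6, 1)
    a <- depth_frequencies(rpois(k, 10) + 1)
    b <- depth_frequencies(rpois(k, 10) + 1)
    expect_equal(ed_statistic(a, b), ed_statistic(b, a))
    expect_gte(ed_statistic(a, b), 0)
    expect_lte(ed_statistic(a, b), sqrt(2) + 1e-12)
  }
})

test_that("ED on frequencies is invariant to depth scaling", {
  set.seed(7)
  for (i in 1:25) {
    dm <- rpois(4, 20) + 1
    ds <- rpois(4, 20) + 1
    m <- sample(2:10, 1)
    ed1 <- ed_statistic(depth_frequencies(dm), depth_frequencies(ds))
    ed2 <- ed_statistic(depth_frequencies(dm * m), depth_frequencies(ds * m))
    expect_equal(ed1, ed2)
  }
})

test_that("power transform is the stated power and monotone", {
  expect_equal(power_transform(0), 0)
  expect_equal(power_transform(1, 5), 1)
  expect_equal(power_transform(sqrt(2), 5), 2^2.5)
  expect_error(power_transform(-0.1), "non-negative")
  expect_error(power_transform(1, 0.5), ">= 1")
  ed <- sort(runif(20, 0, sqrt(2)))
  expect_true(all(diff(power_transform(ed, 5)) >= 0))
})

test_that("profile fit handles constants and single sites", {
  pos <- seq(1e5, 1e6, by = 1e5)
  expect_equal(fit_profile(pos, rep(3.7, 10), 2e5), rep(3.7, 10))
  expect_equal(fit_profile(pos, rep(3.7, 10), 5e6), rep(3.7, 10))
  expect_equal(fit_profile(12345, 0.42, 1e6), 0.42)
  expect_error(fit_profile(numeric(), numeric(), 1e6), "empty")
  expect_error(fit_profile(c(1, 1, 2), c(0, 0, 0), 1e6), "increasing")
  expect_error(fit_profile(c(1, 2), c(0, 0), 0), "bandwidth")
})

test_that("profile fit at an isolated spike matches the direct-summation oracle", {
  pos <- seq(1000, 5000, by = 1000)
  val <- c(0, 0, 1, 0, 0)
  f <- fit_profile(pos, val, bandwidth = 1500)
  oracle <- brute_fit_profile(pos, val, bandwidth = 1500)
  expect_equal(f, oracle, tolerance = 1e-12)
  # center sees its two zero neighbours: strictly between 1/3 and 1
  expect_gt(f[3], 1 / 3)
  expect_lt(f[3], 1)
  # fitted values stay within the raw range of their windows
  expect_true(all(f >= 0 & f <= 1))
})

test_that("profile fit equals the O(n^2) oracle on random series up to 1000 sites", {
  set.seed(101)
  for (n in c(2, 17, 250, 1000)) {
    pos <- sort(sample.int(5e6, n))
    val <- rexp(n)
    for (kern in c("tricube", "triangular", "uniform")) {
      bw <- sample(c(5e4, 5e5, 2e6), 1)
      expect_equal(fit_profile(pos, val, bw, kern),
                   brute_fit_profile(pos, val, bw, kern),
                   tolerance = 1e-12)
    }
  }
})

test_that("association threshold reproduces center + multiplier x spread", {
  th <- association_threshold(rep(0.7, 10))
  expect_equal(th$threshold, 0.7)
  expect_equal(th$spread, 0)

  x <- c(0, 0, 0, 0, 1)
  th <- association_threshold(x, multiplier = 3, robust = FALSE)
  expect_equal(th$threshold, brute_threshold(x, 3), tolerance = 1e-12)
  expect_equal(th$center, mean(x))
  expect_equal(th$threshold, th$center + 3 * th$spread)

  set.seed(5)
  x <- rexp(200)
  t2 <- association_threshold(x, multiplier = 2, robust = FALSE)$threshold
  t3 <- association_threshold(x, multiplier = 3, robust = FALSE)$threshold
  expect_lte(t2, t3)
  expect_error(association_threshold(0.5), "at least 2")
})

test_that("robust threshold agrees with classical on symmetric noise, resists a plateau", {
  set.seed(9)
  x <- rnorm(5000, 1, 0.1)
  tr <- association_threshold(x, robust = TRUE)$threshold
  tc <- association_threshold(x, robust = FALSE)$threshold
  expect_equal(tr, tc, tolerance = 0.02)
  # a signal plateau on 15% of the genome drags mean+3SD above the
  # plateau itself but leaves the robust threshold below it
  y <- c(rnorm(4250, 0.01, 0.001), rep(5.6, 750))
  expect_gt(association_threshold(y, robust = FALSE)$threshold, max(y))
  expect_lt(association_threshold(y, robust = TRUE)$threshold, max(y))
})

test_that("ed_scan fits per class and chromosome and exposes methods", {
  cfg <- toy_config(seed = 3)
  sites <- simulate_pool_depths(simulate_marker_map(cfg), cfg)
  fit <- ed_scan(sites, bandwidth = 4e5)
  s <- fit$sites
  expect_setequal(unique(s$class), c("SNP", "InDel"))
  expect_equal(s$ed_powered, s$ed^5)
  expect_true(all(s$fitted >= 0))
  expect_true(all(s$ed <= sqrt(2) + 1e-12))
  # fitted recomputable per class/chromosome from the stored series
  snp <- s[s$class == "SNP", ]
  expect_equal(snp$fitted,
               fit_profile(snp$pos, snp$ed_powered, 4e5),
               tolerance = 1e-12)
  expect_named(fit$thresholds, c("InDel", "SNP"))
  expect_length(fitted(fit, class = "SNP"), nrow(snp))
  expect_equal(residuals(fit), s$ed_powered - s$fitted)
  expect_output(print(fit), "Euclidean-Distance genome scan")
  expect_output(print(summary(fit)), "threshold")
})

test_that("null scans rarely exceed the classical mean + 3 SD threshold", {
  # the genome must span many smoothing bandwidths for the genome-wide
  # spread estimate to be meaningful (see vignette)
  cfg <- null_config(len = 10e6, seed = 31)
  sites <- simulate_pool_depths(simulate_marker_map(cfg), cfg)
  fit <- ed_scan(sites)
  for (cl in names(fit$thresholds)) {
    f <- fit$sites$fitted[fit$sites$class == cl]
    thr <- association_threshold(f, robust = FALSE)$threshold
    expect_lt(mean(f > thr), 0.01)
  }
})
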