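test_that("RMA slope is sign(r) * sd(y)/sd(x), intercept through the means", {
  x <- c(1, 2, 3, 4, 5)
  f <- rma_fit(x, x)
  expect_equal(f$slope, 1)
  expect_equal(f$intercept, 0)
  expect_equal(f$r, 1)

  f2 <- rma_fit(x, 2 * x + 3)
  expect_equal(f2$slope, 2)
  expect_equal(f2$intercept, 3)

  # brute-force oracle on random small datasets
  set.seed(41)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    xr <- rnorm(n); yr <- rnorm(n) + 0.5 * xr
    fr <- rma_fit(xr, yr)
    r_o <- sum((xr - mean(xr)) * (yr - mean(yr))) /
      sqrt(sum((xr - mean(xr))^2) * sum((yr - mean(yr))^2))
    slope_o <- sign(r_o) * sqrt(sum((yr - mean(yr))^2) /
                                  sum((xr - mean(xr))^2))
    expect_equal(fr$slope, slope_o, tolerance = 1e-12)
    expect_equal(fr$r, r_o, tolerance = 1e-12)
    # reciprocal symmetry: slope of x on y is 1/slope of y on x
    expect_equal(rma_fit(yr, xr)$slope, 1 / fr$slope, tolerance = 1e-12)
    expect_equal(sign(fr$slope), sign(fr$r))
  }

  expect_error(rma_fit(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(rma_fit(1:2, 2:3), "at least 3")
})

test_that("log-scale equivariance: rescaling raw x shifts only the intercept", {
  set.seed(4)
  raw_x <- exp(rnorm(12, 2, 0.5)); raw_y <- exp(rnorm(12, 1, 0.4))
  f1 <- rma_fit(log10(raw_x), log10(raw_y))
  f2 <- rma_fit(log10(raw_x * 37), log10(raw_y))
  expect_equal(f1$slope, f2$slope, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(f1$intercept, f2$intercept)))
})

test_that("slope = 0 test is the correlation t-test", {
  set.seed(14)
  for (i in 1:10) {
    x <- rnorm(10); y <- rnorm(10) + i / 5 * x
    f <- rma_fit(x, y)
    z <- test_slope_zero(f)
    expect_equal(z$t, f$r * sqrt(8 / (1 - f$r^2)), tolerance = 1e-12)
    expect_equal(z$p, cor.test(x, y)$p.value, tolerance = 1e-10)
  }
  # r -> 1 with n fixed drives p -> 0
  x <- 1:8
  p_seq <- sapply(c(1, 0.3, 0.05, 0.005), function(sd) {
    set.seed(2); rma_fit(x, x + rnorm(8, 0, sd))$p0
  })
  expect_true(all(diff(p_seq) < 0))
})

test_that("Clarke's slope = 1 test has non-integer df and is monotone", {
  x <- c(0.5, 1.1, 1.8, 2.4, 3.0, 3.7, 4.1, 4.9)
  f <- rma_fit(x, 0.4 * x + rnorm(8, 0, 0.05))
  one <- test_slope_one(f)
  expect_gt(one$T, 0)
  expect_false(one$df == round(one$df))
  expect_lt(one$df, f$n - 2)

  # slope exactly 1 -> T = 0, p = 1
  f1 <- rma_fit(x, x + 1)
  expect_equal(f1$T1, 0)
  expect_equal(f1$p1, 1)

  # T increases monotonically as the hypothesized slope moves away
  f4 <- rma_fit(x, 0.4 * x + c(0, 0.04, -0.03, 0.02, 0.05, -0.02, 0.01, -0.04))
  Ts <- sapply(c(1, 1.5, 2.5, 4), function(b0) test_slope_one(f4, b0)$T)
  expect_true(all(diff(Ts) > 0))

  # gating: may not test slope = 1 without a detectable slope
  set.seed(100)
  flat <- rma_fit(rnorm(10), rnorm(10))
  if (flat$p0 >= 0.05) expect_error(test_slope_one(flat), "gated")
})

test_that("relationship shapes follow the log-log slope rule", {
  set.seed(8)
  x <- seq(0, 3, length.out = 20)

  shallow <- rma_fit(x, 0.37 * x + rnorm(20, 0, 0.1))
  expect_lt(shallow$p0, 0.05)
  expect_lt(shallow$p1, 0.05)
  expect_equal(shallow$shape, "ascending-decelerating")

  steep <- rma_fit(x, 2.2 * x + rnorm(20, 0, 0.1))
  expect_equal(steep$shape, "ascending-accelerating")

  prop <- rma_fit(x, x + rnorm(20, 0, 0.05))
  expect_equal(prop$shape, "proportional")

  none <- rma_fit(x, rnorm(20, 0, 1))
  if (none$p0 >= 0.05) {
    expect_equal(none$shape, "none")
    expect_true(is.na(none$T1))
  }
})

test_that("configured density-dependence slopes are recovered from surveys", {
  # medium-size recovery run; the acceptance suite runs the full harness
  fits <- sapply(1:30, function(s) {
    sv <- generate_survey(recovery_config(beta = 0.37, seed = 4000 + s))
    x <- cell_means(core_density(sv), "density_m2")
    y <- cell_means(net_density(sv), "density_m3")
    ok <- x$mean > 0 & y$mean > 0
    rma_fit(log10_strict(x$mean[ok]), log10_strict(y$mean[ok]))$slope
  })
  expect_gt(quantile(fits, 0.975), 0.37)
  expect_lt(quantile(fits, 0.025), 0.37 * 1.15)
  expect_equal(median(fits), 0.37, tolerance = 0.12)
})
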