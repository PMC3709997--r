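test_that("observed swimmer proportions are the unweighted mean over nets", {
  # two nets concentrated in different classes -> (0.5, 0.5)
  nets <- list(rep(1.2, 10), rep(2.2, 30))
  p <- observed_swimmer_proportions(nets)
  expect_equal(unname(p[c("1-1.5", "2-2.5")]), c(0.5, 0.5))
  expect_equal(sum(p), 1)
  # identical nets equal any single net
  same <- list(c(1.2, 2.2, 5.1), c(1.2, 2.2, 5.1))
  expect_equal(observed_swimmer_proportions(same),
               observed_swimmer_proportions(same[1]))
  # pooled-counts alternative differs when net totals are unequal
  pooled <- tabulate(histogram_class(unlist(nets)), 20) / 40
  expect_false(isTRUE(all.equal(unname(p), pooled)))
  expect_equal(pooled[c(1, 3)], c(0.25, 0.75))
  expect_error(observed_swimmer_proportions(list(numeric(0))), "no net")
})

test_that("bootstrap limits trim exactly 25 values per tail at B = 1000", {
  set.seed(42)
  res <- runif(300, 1, 8)
  swim <- split(sample(res, 150, TRUE), rep(1:3, 50))
  out <- bootstrap_size_comparison(res, swim, B = 1000, seed = 1)
  expect_equal(out$status, "analysed")
  expect_equal(out$trim, 25)
  expect_equal(out$m, 150)
  # limits are the 26th and 975th order statistics: verify on a re-run with
  # the same seed by recomputing the bootstrap proportions directly
  set.seed(1)
  cls <- histogram_class(res)
  draws <- sample(cls, 150 * 1000, replace = TRUE)
  boot <- matrix(tabulate(draws + 20 * (rep(1:1000, each = 150) - 1),
                          nbins = 20000), nrow = 20) / 150
  for (k in c(2, 7, 15)) {
    s <- sort(boot[k, ])
    expect_equal(out$table$lower[k], s[26])
    expect_equal(out$table$upper[k], s[975])
  }
  expect_true(all(out$table$lower <= out$table$expected + 1e-12))
  expect_true(all(out$table$upper >= out$table$expected - 1e-12))
  # widening the trim from 25 to 50 per tail narrows no interval
  out2 <- bootstrap_size_comparison(res, swim, B = 1000, seed = 1)
  set.seed(1)
  draws2 <- sample(cls, 150 * 1000, replace = TRUE)
  boot2 <- matrix(tabulate(draws2 + 20 * (rep(1:1000, each = 150) - 1),
                           nbins = 20000), nrow = 20) / 150
  lower50 <- apply(boot2, 1, function(v) sort(v)[51])
  upper50 <- apply(boot2, 1, function(v) sort(v)[950])
  expect_true(all(lower50 >= out2$table$lower))
  expect_true(all(upper50 <= out2$table$upper))
})

test_that("seeded bootstraps are reproducible and thresholds are enforced", {
  set.seed(7)
  res <- runif(200, 1, 9)
  swim <- split(runif(120, 1, 9), rep(1:4, 30))
  a <- bootstrap_size_comparison(res, swim, seed = 99)
  b <- bootstrap_size_comparison(res, swim, seed = 99)
  expect_identical(a$table, b$table)

  small <- bootstrap_size_comparison(res[1:50], swim, seed = 1)
  expect_equal(small$status, "not analysed")
  expect_match(small$reason, "100")
  few_swim <- bootstrap_size_comparison(res, list(runif(60, 1, 9)), seed = 1)
  expect_equal(few_swim$status, "not analysed")
  expect_error(bootstrap_size_comparison(res, swim, B = 50), "at least 100")
})

test_that("a one-class resident distribution flags any different swimmer", {
  res <- rep(2.1, 150)  # all residents in [2, 2.5)
  swim <- list(rep(2.1, 60), c(rep(2.1, 59), 5.2))
  out <- bootstrap_size_comparison(res, swim, seed = 3)
  k <- histogram_class(2.1)
  expect_equal(out$table$lower[k], 1)
  expect_equal(out$table$upper[k], 1)
  expect_true(all(out$table$upper[-k] == 0))
  expect_equal(out$table$flag[k], "under")        # observed mean < 1
  expect_equal(out$table$flag[histogram_class(5.2)], "over")
})

test_that("G statistic equals the closed-form likelihood ratio", {
  # two-category toy with known value
  O <- c(male_small = 30, male_large = 70, female_small = 40,
         female_large = 20, female_ovig = 10)
  E <- c(male_small = 50, male_large = 50, female_small = 30,
         female_large = 30, female_ovig = 10)
  out <- g_test_stages(E * 2, O)
  oracle <- 2 * sum(O * log(O / (E * 2 / sum(E * 2) * sum(O))))
  expect_equal(out$G, oracle, tolerance = 1e-9)
  expect_equal(out$df, 4)
  expect_equal(out$p, pchisq(oracle, 4, lower.tail = FALSE))

  # the printed two-category arithmetic: 2*(30 ln 0.6 + 70 ln 1.4)
  expect_equal(2 * (30 * log(30 / 50) + 70 * log(70 / 50)), 16.4565,
               tolerance = 1e-4)

  # random tables against an independently coded oracle
  set.seed(12)
  for (i in 1:20) {
    Or <- setNames(rpois(5, 60) + 1, names(O))
    Er <- setNames(rpois(5, 80) + 1, names(O))
    got <- g_test_stages(Er, Or)
    Es <- Er / sum(Er) * sum(Or)
    expect_equal(got$G, 2 * sum(Or * log(Or / Es)), tolerance = 1e-9)
  }

  # observed equal to expected (after scaling) -> G = 0, p = 1
  eq <- g_test_stages(O * 3, O)
  expect_equal(eq$G, 0, tolerance = 1e-12)
  expect_equal(eq$p, 1)
})

test_that("empty expected stages are pooled by the stated rules", {
  E <- c(male_small = 60, male_large = 0, female_small = 50,
         female_large = 40, female_ovig = 30)
  O <- c(male_small = 40, male_large = 25, female_small = 30,
         female_large = 20, female_ovig = 10)
  out <- g_test_stages(E, O)
  expect_true(out$pooled)
  expect_equal(out$df, 3)  # large males folded into small males
  expect_false("male_large" %in% out$stages)
  # the folded male category carries both observed counts
  expect_equal(unname(out$observed_pct["male_small"]),
               100 * 65 / sum(O))

  # large females fold into ovigerous females
  E2 <- E; E2["male_large"] <- 20; E2["female_large"] <- 0
  out2 <- g_test_stages(E2, O)
  expect_equal(out2$df, 3)
  expect_false("female_large" %in% out2$stages)

  # zero observed counts contribute 0 (O ln O limit)
  O3 <- O; O3["female_ovig"] <- 0
  out3 <- g_test_stages(E, O3)
  expect_true(is.finite(out3$G))

  # below the >100 thresholds the cell is not analysed
  small <- g_test_stages(E * 0.5, O)
  expect_equal(small$status, "not analysed")
})
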