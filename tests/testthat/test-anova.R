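test_that("balanced sums of squares match the linear-model oracle exactly", {
  for (seed in c(5, 6)) {
    d <- balanced_anova_data(a = 3, b = 2, c = 2, n = 2, seed = seed)
    ms <- mean_squares(d)
    orc <- lm_anova_oracle(d)
    # oracle rows: round, site, nightf (= night within round), round:site,
    # site:nightf (= site x night(round)), residuals
    expect_equal(ms$SS[ms$source == "round"], orc["round", "Sum Sq"],
                 tolerance = 1e-10)
    expect_equal(ms$SS[ms$source == "site"], orc["site", "Sum Sq"],
                 tolerance = 1e-10)
    expect_equal(ms$SS[ms$source == "round_site"],
                 orc["round:site", "Sum Sq"], tolerance = 1e-10)
    expect_equal(ms$SS[ms$source == "night_round"],
                 orc["nightf", "Sum Sq"], tolerance = 1e-10)
    expect_equal(ms$SS[ms$source == "site_night_round"],
                 orc["site:nightf", "Sum Sq"], tolerance = 1e-10)
    expect_equal(ms$SS[ms$source == "error"],
                 orc["Residuals", "Sum Sq"], tolerance = 1e-10)
    expect_equal(ms$df, orc[c("round", "site", "round:site", "nightf",
                              "site:nightf", "Residuals"), "Df"])
    # the decomposition is exhaustive on balanced data
    expect_equal(sum(ms$SS), sum((d$y - mean(d$y))^2), tolerance = 1e-10)
  }
})

test_that("hand-computed 2x2x2x2 toy decomposition is reproduced", {
  # y = site effect (+/- 1) + round effect (+/- 0.5), no night effect, no noise
  d <- expand.grid(site = c("S1", "S2"), round = c("R1", "R2"),
                   night = c("N1", "N2"), rep = 1:2,
                   stringsAsFactors = FALSE)
  d$y <- ifelse(d$site == "S1", -1, 1) + ifelse(d$round == "R1", -0.5, 0.5)
  ms <- mean_squares(d)
  # SS_site = n_tot/2 * (2*1^2) ... by hand: 16 obs, site deviations +/-1
  expect_equal(ms$SS[ms$source == "site"], 16)
  expect_equal(ms$SS[ms$source == "round"], 4)
  expect_equal(ms$SS[ms$source %in% c("round_site", "night_round",
                                      "site_night_round", "error")],
               rep(0, 4))
  expect_equal(ms$MS[ms$source == "site"], 16)

  # all-equal responses give all-zero mean squares
  d$y <- 2
  expect_equal(mean_squares(d)$MS, rep(0, 6))
})

test_that("empty cells are reported by name", {
  d <- balanced_anova_data(a = 2, b = 2, c = 2, n = 2)
  d <- d[!(d$site == "S2" & d$round == "R2" & d$night == "N1"), ]
  expect_error(mean_squares(d), "S2.R2.N1")
})

test_that("unbalanced designs use the harmonic-mean replicate count", {
  d <- balanced_anova_data(a = 3, b = 2, c = 2, n = 3, seed = 8)
  d <- d[-c(1, 2, 5), ]  # unbalance a few cells
  ms <- mean_squares(d)
  k <- attr(ms, "constants")
  counts <- table(interaction(d$site, d$round, d$night))
  expect_equal(k$n, harmonic_mean(as.numeric(counts)))
  expect_equal(ms$df[ms$source == "error"], nrow(d) - 3 * 2 * 2)
  expect_equal(harmonic_mean(c(2, 3, 6)), 3)
})

test_that("F and quasi-F ratios follow the random-model denominators", {
  ms <- c(round = 4, site = 6, round_site = 2, night_round = 1,
          site_night_round = 0.5, error = 0.25)
  f <- f_ratios(ms)
  expect_equal(f$F[f$source == "site"], 6 / 2)
  expect_equal(f$F[f$source == "round_site"], 2 / 0.5)
  expect_equal(f$F[f$source == "night_round"], 1 / 0.5)
  expect_equal(f$F[f$source == "site_night_round"], 0.5 / 0.25)
  expect_equal(f$F[f$source == "round"], (4 + 0.5) / (1 + 2))
  expect_true(is.na(f$F[f$source == "error"]))

  # all mean squares equal -> all ratios 1
  eq <- f_ratios(setNames(rep(2, 6), names(ms)))
  expect_equal(eq$F[-6], rep(1, 5))

  # zero denominator flags, not errors
  z <- f_ratios(c(round = 1, site = 1, round_site = 0, night_round = 0,
                  site_night_round = 1, error = 1))
  expect_true(is.nan(z$F[z$source == "site"]))
})

test_that("variance components implement the expected-mean-square algebra", {
  k <- design_constants(9, 3, 3, 241 / 81)
  vc <- variance_components(table2_ms, k)
  expect_equal(vc$component[vc$source == "error"], 0.047)
  # all-equal mean squares: everything but error vanishes
  vc0 <- variance_components(setNames(rep(0.3, 6),
                                      names(table2_ms)), k)
  expect_equal(vc0$component, c(0, 0, 0, 0, 0, 0.3))
  expect_equal(vc0$pct_variation, c(0, 0, 0, 0, 0, 100))
  # negative raw estimates are kept raw and truncated for reporting
  neg <- table2_ms
  neg["site"] <- 0.5  # below MS_RS
  vcn <- variance_components(neg, k)
  expect_lt(vcn$component_raw[vcn$source == "site"], 0)
  expect_equal(vcn$component[vcn$source == "site"], 0)
  # percentages sum to 100
  expect_equal(sum(vc$pct_variation), 100, tolerance = 1e-9)
  expect_equal(sum(vcn$pct_variation), 100, tolerance = 1e-9)
})

test_that("Satterthwaite df shrink toward the dominating mean square", {
  # equal contributions
  expect_equal(satterthwaite_df(c(1, 1), c(10, 10)), 20)
  # one mean square dominates -> df approach its df
  expect_equal(satterthwaite_df(c(100, 1e-9), c(4, 40)), 4,
               tolerance = 1e-6)
  q <- quasi_f_p(setNames(rep(1, 6), names(table2_ms)),
                 setNames(c(2, 8, 16, 6, 48, 160), names(table2_ms)))
  expect_equal(q$F, 1)
  expect_gt(q$p, 0.3)
  # p monotone decreasing in F for fixed df
  p <- pf(c(1, 2, 4, 8), 3.2, 12.7, lower.tail = FALSE)
  expect_true(all(diff(p) < 0))
})

test_that("site effect type-I error is calibrated under the null", {
  set.seed(2024)
  template <- expand.grid(site = paste0("S", 1:4), round = paste0("R", 1:2),
                          night = paste0("N", 1:2), rep = 1:2,
                          stringsAsFactors = FALSE)
  hits <- replicate(1000, {
    template$y <- rnorm(nrow(template))
    f <- f_ratios(mean_squares(template))
    f$p[f$source == "site"] < 0.05
  })
  expect_gt(mean(hits), 0.03)
  expect_lt(mean(hits), 0.07)
})

test_that("varcomp_anova recovers a planted dominant site component", {
  set.seed(77)
  d <- expand.grid(site = paste0("S", 1:6), round = paste0("R", 1:3),
                   night = paste0("N", 1:3), rep = 1:3,
                   stringsAsFactors = FALSE)
  site_eff <- setNames(rnorm(6, 0, 2), paste0("S", 1:6))
  d$y <- site_eff[d$site] + rnorm(nrow(d))
  out <- varcomp_anova(d)
  expect_s3_class(out, "anova_table")
  expect_equal(out$component[out$source == "error"], 1, tolerance = 0.35)
  expect_gt(out$pct_variation[out$source == "site"], 50)
})
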