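test_that("net density expands the subsample and normalizes by volume", {
  sv <- tiny_survey()
  # 5 individuals at fraction 1/2 in 10 m^3 -> 1 ind m^-3
  d <- net_density(sv)
  expect_equal(d$density_m3, rep(1, nrow(d)))

  # against an independent re-count oracle with a random stage filter
  preds <- stage_predicates(sv$scheme)
  d15 <- net_density(sv, preds[["<1.5"]])
  oracle <- sapply(sv$nets$sample_id, function(id) {
    ind <- sv$net_individuals[sv$net_individuals$sample_id == id, ]
    sum(ind$length_mm < 1.5) / 0.5 / 10
  })
  expect_equal(d15$density_m3, unname(oracle))

  # empty sample -> 0
  sv2 <- sv
  sv2$net_individuals <- sv2$net_individuals[0, ]
  expect_equal(net_density(sv2)$density_m3, rep(0, nrow(sv2$nets)))
})

test_that("core density uses area with no subsampling", {
  sv <- tiny_survey()
  d <- core_density(sv)
  # 6 individuals in a 7-cm corer (pi * 0.035^2 m^2) ~ 1559 ind m^-2
  expect_equal(d$density_m2, d$count / 0.00385)
  expect_equal(10 / (pi * 0.035^2), 2597, tolerance = 1e-3)

  # adult filter equals a brute-force length > 4 re-count
  preds <- stage_predicates(sv$scheme)
  da <- core_density(sv, preds$adult)
  oracle <- sapply(sv$cores$sample_id, function(id) {
    ind <- sv$core_individuals[sv$core_individuals$sample_id == id, ]
    sum(ind$length_mm > 4 & ind$sex != "juvenile") / 0.00385
  })
  expect_equal(da$density_m2, unname(oracle))
})

test_that("size-class and adult-stage counts partition the totals; densities add", {
  sv <- generate_survey(survey_config(seed = 3))
  preds <- stage_predicates(sv$scheme)
  tot <- net_density(sv)
  class_sum <- Reduce(`+`, lapply(sv$scheme$size_class_labels, function(cl)
    net_density(sv, preds[[cl]])$density_m3))
  expect_equal(class_sum, tot$density_m3)

  adult <- core_density(sv, preds$adult)
  stage_sum <- Reduce(`+`, lapply(sv$scheme$adult_stages, function(st)
    core_density(sv, preds[[st]])$density_m2))
  expect_equal(stage_sum, adult$density_m2)
})

test_that("subsample expansion is unbiased for the full count", {
  set.seed(17)
  true_n <- 400
  f <- 1 / 8
  est <- replicate(2000, rbinom(1, true_n, f) / f)
  expect_equal(mean(est), true_n, tolerance = 0.02)
})

test_that("biomass follows the length-weight power law", {
  sv <- tiny_survey()
  sv$cores$core_area_m2 <- 1
  # linear params: one 2-mm individual on 1 m^2 weighs 2 mg
  one <- sv
  one$core_individuals <- make_individuals(sv$cores$sample_id[1], 2)
  b <- biomass_per_m2(one, allometry_params(1, 1))
  expect_equal(b$biomass_mg_m2[b$sample_id == sv$cores$sample_id[1]], 2)
  expect_equal(sum(b$biomass_mg_m2), 2)

  # doubling lengths with exponent 3 multiplies biomass by 8
  p3 <- allometry_params(0.01, 3)
  small <- sv
  small$core_individuals <- make_individuals(
    rep(sv$cores$sample_id[1:3], each = 4), rep(c(1.1, 2.3, 3.2, 4.8), 3),
    sex = rep(c("juvenile", "juvenile", "juvenile", "female"), 3))
  doubled <- small
  doubled$core_individuals$length_mm <- 2 * small$core_individuals$length_mm
  expect_equal(biomass_per_m2(doubled, p3)$biomass_mg_m2,
               8 * biomass_per_m2(small, p3)$biomass_mg_m2)

  # independent summation oracle on the random fixture
  b1 <- biomass_per_m2(sv, p3)
  oracle <- sapply(sv$cores$sample_id, function(id) {
    ind <- sv$core_individuals[sv$core_individuals$sample_id == id, ]
    sum(0.01 * ind$length_mm^3)
  })
  expect_equal(b1$biomass_mg_m2, unname(oracle))

  expect_error(biomass_per_m2(sv), "allometry")
})

test_that("density transforms behave and fail loudly where undefined", {
  expect_equal(log10_plus1(c(0, 9, 99)), c(0, 1, 2))
  x <- c(0, 0.3, 12, 4000)
  expect_equal(inv_log10_plus1(log10_plus1(x)), x, tolerance = 1e-12)
  expect_error(log10_plus1(-1), "requires")
  expect_equal(log10_strict(100), 2)
  expect_error(log10_strict(0), "positive")
})

test_that("surveys round-trip through the delimited-text dialect", {
  sv <- generate_survey(survey_config(seed = 11, n_sites = 3))
  dir <- withr::local_tempdir()
  write_survey(sv, dir)
  expect_setequal(list.files(dir),
                  c("nets.tsv", "net_individuals.tsv", "cores.tsv",
                    "core_individuals.tsv"))
  back <- read_survey(dir)
  for (tab in c("nets", "cores", "net_individuals", "core_individuals")) {
    got <- back[[tab]]
    want <- sv[[tab]]
    rownames(got) <- rownames(want) <- NULL
    num <- vapply(want, is.numeric, logical(1))
    expect_equal(got[!num], want[!num])
    expect_equal(got[num], want[num], tolerance = 1e-9)
  }
})

test_that("survey validation names the offending record", {
  sv <- tiny_survey()
  bad <- sv
  bad$nets$filtered_volume_m3[3] <- 0
  expect_error(validate_survey(bad), bad$nets$sample_id[3])
  bad <- sv
  bad$nets$subsample_fraction[1] <- 1.5
  expect_error(validate_survey(bad), "subsample_fraction")
  bad <- sv
  bad$core_individuals$sex[2] <- "female"  # length <= 4 but sexed
  expect_error(validate_survey(bad), "longer")
})
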