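stage_keys <- c("<1.5", "1.5-2.5", "2.5-4", "male_small", "male_large",
                "female_small", "female_large", "female_ovig")

default_length_models <- list(
  "<1.5"        = c(mean = 1.20, sd = 0.15, lo = 1.00, hi = 1.499),
  "1.5-2.5"     = c(mean = 1.90, sd = 0.30, lo = 1.50, hi = 2.499),
  "2.5-4"       = c(mean = 3.10, sd = 0.40, lo = 2.50, hi = 3.999),
  male_small    = c(mean = 5.00, sd = 0.50, lo = 4.01, hi = 5.999),
  male_large    = c(mean = 6.80, sd = 0.60, lo = 6.00, hi = 9.00),
  female_small  = c(mean = 5.00, sd = 0.50, lo = 4.01, hi = 5.999),
  female_large  = c(mean = 6.90, sd = 0.60, lo = 6.00, hi = 9.50),
  female_ovig   = c(mean = 6.50, sd = 1.00, lo = 4.70, hi = 10.80)
)

#' Configuration of a synthetic survey
#'
#' Describes the hierarchical sampling design (9 mudflat sites, 3 sampling
#' rounds, 3 nights per round, 3 plankton nets per site-night with a dropout
#' probability producing the realistic 7--9 nets per site-round, and 12
#' sediment cores per site-round) together with the statistical structure the
#' analyses assume: the allocation of log10 swimmer density variance across
#' the Round / Site / Round x Site / Night(Round) / Site x Night(Round) /
#' Error strata, per-stage log-log slopes of swimmer density on resident
#' density, per-stage swimming over-representation multipliers, a
#' female-biased adult sex ratio, and overdispersed count noise.
#'
#' Default variance components (log10 scale: 0.068, 0.396, 0.097, 0.027,
#' 0.068, 0.047) and default density-dependence slopes are anchored to the
#' magnitudes observed in upper Bay of Fundy field surveys, with the Site
#' stratum dominating.
#'
#' @param n_sites,n_rounds,n_nights,n_nets,n_cores Design sizes.
#' @param net_dropout Probability a deployed net yields no usable sample.
#' @param variance_components Named variance (not fraction) of log10 swimmer
#'   density per stratum: `round`, `site`, `round_site`, `night_round`,
#'   `site_night_round`, `error`.
#' @param resident_variance Named variance of log10 resident density at the
#'   `round`, `site` and `round_site` strata. Part of the swimmer variance at
#'   those strata is carried by the density dependence
#'   (`dd_reference_slope^2 * resident_variance`); the remainder is
#'   swimming-specific, so each swimmer stratum variance must be at least the
#'   carried part.
#' @param mean_log10_swim Grand mean log10 total swimmer density (ind. m^-3).
#' @param mean_log10_resident Grand mean log10 total resident density
#'   (ind. m^-2).
#' @param dd_slope_by_stage Named log-log slope of expected swimmer density on
#'   resident density, per stage key.
#' @param dd_reference_slope Slope used to map the swimmer site/round/cell
#'   structure back onto resident densities.
#' @param overrep_multipliers Per-stage swimming propensity multipliers.
#' @param juvenile_fractions Resident composition of the three juvenile size
#'   classes (fractions of total; adults take the remainder).
#' @param sex_ratio_female_to_male Adult females per male.
#' @param ovigerous_fraction Fraction of adult females that are ovigerous.
#' @param male_large_fraction,female_large_fraction Fraction of (non-ovigerous)
#'   adults of each sex that are large (> 6 mm).
#' @param composition_sd Site-by-round log10 noise on resident stage shares
#'   (0 = identical composition everywhere).
#' @param activity_dependence Extra log10 swimmer-density coefficients on the
#'   centred log10 adult resident density, named by stage key; the default
#'   builds the negative dependence of large-juvenile (2.5--4 mm) swimming on
#'   resident adult density seen in the field.
#' @param intersex_fraction_swim,intersex_fraction_mud Fraction of male-stage
#'   individuals recorded as intersex among swimmers / residents.
#' @param dispersion Negative-binomial size parameter for count noise
#'   (`Inf` = Poisson).
#' @param volume_meanlog,volume_sdlog Log-normal parameters (natural log) of
#'   the filtered water volume per net, m^3.
#' @param core_area_m2 Area of one sediment core (7 cm diameter corer).
#' @param target_processed Folsom splitting halves a sample until the
#'   processed count is at most this.
#' @param max_splits Maximum number of Folsom halvings (1/2^max_splits).
#' @param length_models Per-stage truncated-normal length models
#'   (`mean`, `sd`, `lo`, `hi`, mm).
#' @param allometry `NULL`, or a list/[allometry_params()] with `coefficient`
#'   and `exponent` for biomass.
#' @param seed Integer seed making the survey reproducible.
#'
#' @return A `survey_config` object (validated list).
#' @export
survey_config <- function(n_sites = 9, n_rounds = 3, n_nights = 3,
                          n_nets = 3, n_cores = 12, net_dropout = 0.08,
                          variance_components = c(round = 0.068, site = 0.396,
                                                  round_site = 0.097,
                                                  night_round = 0.027,
                                                  site_night_round = 0.068,
                                                  error = 0.047),
                          resident_variance = c(round = 0.05, site = 1.0,
                                                round_site = 0.15),
                          mean_log10_swim = 1.0,
                          mean_log10_resident = 3.3,
                          dd_slope_by_stage = c("<1.5" = 0.30,
                                                "1.5-2.5" = 0.22,
                                                "2.5-4" = 0.18,
                                                male_small = 0.15,
                                                male_large = 0.06,
                                                female_small = 0.15,
                                                female_large = 0.06,
                                                female_ovig = 0.03),
                          dd_reference_slope = 0.37,
                          overrep_multipliers = c("<1.5" = 2.0,
                                                  "1.5-2.5" = 1.0,
                                                  "2.5-4" = 1.2,
                                                  male_small = 1.3,
                                                  male_large = 0.5,
                                                  female_small = 2.0,
                                                  female_large = 0.5,
                                                  female_ovig = 0.4),
                          juvenile_fractions = c("<1.5" = 0.30,
                                                 "1.5-2.5" = 0.20,
                                                 "2.5-4" = 0.15),
                          sex_ratio_female_to_male = 2,
                          ovigerous_fraction = 0.3,
                          male_large_fraction = 0.3,
                          female_large_fraction = 0.4,
                          composition_sd = 0.15,
                          activity_dependence = c("2.5-4" = -0.4),
                          intersex_fraction_swim = 0.02,
                          intersex_fraction_mud = 0.02,
                          dispersion = 8,
                          volume_meanlog = log(500), volume_sdlog = 0.4,
                          core_area_m2 = pi * 0.035^2,
                          target_processed = 200, max_splits = 9,
                          length_models = default_length_models,
                          allometry = NULL,
                          seed = 1L) {
  cfg <- as.list(environment())
  validate_survey_config(cfg)
  class(cfg) <- "survey_config"
  cfg
}

validate_survey_config <- function(cfg) {
  with(cfg, {
    stopifnot(n_sites >= 2, n_rounds >= 2, n_nights >= 2, n_nets >= 1,
              n_cores >= 1, net_dropout >= 0, net_dropout < 1)
    if (!setequal(names(variance_components), anova_sources)) {
      stop("variance_components must name exactly: ",
           paste(anova_sources, collapse = ", "))
    }
    if (any(variance_components < 0)) {
      stop("variance components must be >= 0")
    }
    if (!setequal(names(resident_variance),
                  c("round", "site", "round_site"))) {
      stop("resident_variance must name round, site, round_site")
    }
    if (any(resident_variance < 0)) stop("resident variances must be >= 0")
    carried <- dd_reference_slope^2 * resident_variance
    if (any(variance_components[names(carried)] < carried - 1e-12)) {
      stop("swimmer variance at the round/site/round_site strata cannot be ",
           "smaller than dd_reference_slope^2 * resident_variance")
    }
    if (!all(stage_keys %in% names(dd_slope_by_stage))) {
      stop("dd_slope_by_stage must name every stage")
    }
    if (any(dd_slope_by_stage < 0)) stop("dd slopes must be >= 0")
    stopifnot(dd_reference_slope > 0)
    if (!all(stage_keys %in% names(overrep_multipliers))) {
      stop("overrep_multipliers must name every stage")
    }
    if (any(juvenile_fractions < 0) || sum(juvenile_fractions) >= 1) {
      stop("juvenile_fractions must be >= 0 and sum to < 1 ",
           "(adults take the remainder)")
    }
    stopifnot(sex_ratio_female_to_male > 0,
              ovigerous_fraction >= 0, ovigerous_fraction <= 1,
              male_large_fraction >= 0, male_large_fraction <= 1,
              female_large_fraction >= 0, female_large_fraction <= 1,
              composition_sd >= 0, dispersion > 0,
              volume_sdlog >= 0, core_area_m2 > 0,
              target_processed >= 1, max_splits >= 0)
  })
  invisible(cfg)
}

#' Resident stage composition implied by a configuration
#'
#' Expands the composition knobs (juvenile class fractions, female-biased sex
#' ratio, ovigerous fraction, large-size fractions) into the share of total
#' resident density held by each of the eight stages.
#'
#' @param config A [survey_config()].
#' @return Named numeric vector over the stage keys, summing to 1.
#' @export
resident_stage_shares <- function(config) {
  adult <- 1 - sum(config$juvenile_fractions)
  p_f <- config$sex_ratio_female_to_male / (1 + config$sex_ratio_female_to_male)
  male <- adult * (1 - p_f)
  female <- adult * p_f
  ovig <- female * config$ovigerous_fraction
  nonovig <- female - ovig
  shares <- c(
    config$juvenile_fractions[stage_keys[1:3]],
    male_small = unname(male * (1 - config$male_large_fraction)),
    male_large = unname(male * config$male_large_fraction),
    female_small = unname(nonovig * (1 - config$female_large_fraction)),
    female_large = unname(nonovig * config$female_large_fraction),
    female_ovig = unname(ovig)
  )
  stats::setNames(as.numeric(shares), stage_keys)
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  p <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  pmin(pmax(stats::qnorm(p, mean, sd), lo), hi)
}

rcount <- function(n, mu, size) {
  mu <- pmax(mu, 0)
  if (is.infinite(size)) stats::rpois(n, mu) else
    stats::rnbinom(n, mu = mu, size = size)
}

stage_sex <- function(stage) {
  ifelse(grepl("^male", stage), "male",
         ifelse(grepl("^female", stage), "female", "juvenile"))
}

# Draw individuals (length/sex/ovigery) for given per-stage counts.
draw_individuals <- function(counts_by_stage, config, intersex_fraction) {
  stages <- rep(names(counts_by_stage), counts_by_stage)
  n <- length(stages)
  if (!n) {
    return(data.frame(length_mm = numeric(0), sex = character(0),
                      ovigerous = logical(0)))
  }
  len <- numeric(n)
  for (s in unique(stages)) {
    lm <- config$length_models[[s]]
    idx <- which(stages == s)
    len[idx] <- rtrunc_norm(length(idx), lm["mean"], lm["sd"],
                            lm["lo"], lm["hi"])
  }
  sex <- stage_sex(stages)
  male <- which(sex == "male")
  if (length(male) && intersex_fraction > 0) {
    flip <- male[stats::runif(length(male)) < intersex_fraction]
    sex[flip] <- "intersex"
  }
  data.frame(length_mm = round(len, 3), sex = sex,
             ovigerous = stages == "female_ovig")
}

#' Generate a complete synthetic survey
#'
#' Simulates a survey with the configured hierarchical variance structure and
#' density dependence, and returns it together with the generating truth.
#'
#' The generative model, on the log10 scale: a latent resident density
#' surface is drawn per site-by-round cell from independent normal Round,
#' Site and Round x Site effects with the configured resident variances.
#' Each stage's expected swimmer density follows
#' `10^(intercept + slope_s * (L_resident - mean) + extra_activity_terms)`,
#' multiplied by shared swimming-specific effects: extra Round/Site/cell
#' variation (whatever the density dependence does not carry), Night(Round)
#' and Site x Night(Round) effects, and a net-level error, all with the
#' configured swimmer variances. The per-stage intercept allocates the
#' grand-mean swimmer density over stages in proportion to resident share
#' times over-representation multiplier. When all stage slopes equal the
#' reference slope and the swimmer round/site/cell variance is exactly the
#' carried part, the log-log relation between cell-mean swimmer and resident
#' density has the configured slope by construction. Counts per net and per core are
#' drawn from an overdispersed (negative binomial) distribution around the
#' expectations; nets are Folsom-subsampled to the target processed count;
#' body lengths come from per-stage truncated normals. Identical
#' configuration (including seed) yields a bit-identical survey.
#'
#' @param config A [survey_config()].
#' @return An `amphipod_survey` whose `truth` attribute holds a
#'   `truth_record`: the per-cell latent resident density, per-stage expected
#'   swimmer density and the generating configuration.
#' @export
generate_survey <- function(config = survey_config()) {
  validate_survey_config(config)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  a <- config$n_sites; b <- config$n_rounds; cc <- config$n_nights
  sites <- paste0("S", seq_len(a))
  rounds <- paste0("R", seq_len(b))
  nights <- paste0("N", seq_len(cc))
  vc <- config$variance_components
  vr <- config$resident_variance
  bref <- config$dd_reference_slope

  # latent resident density surface (site x round)
  res_round <- stats::rnorm(b, 0, sqrt(vr["round"]))
  res_site <- stats::rnorm(a, 0, sqrt(vr["site"]))
  res_rs <- matrix(stats::rnorm(a * b, 0, sqrt(vr["round_site"])), a, b)
  L_res <- config$mean_log10_resident + outer(res_site, res_round, "+") +
    res_rs

  # swimming-specific variance beyond what the density dependence carries
  ex <- pmax(vc[c("round", "site", "round_site")] -
               bref^2 * vr[c("round", "site", "round_site")], 0)
  eff_round <- stats::rnorm(b, 0, sqrt(ex["round"]))
  eff_site <- stats::rnorm(a, 0, sqrt(ex["site"]))
  eff_rs <- matrix(stats::rnorm(a * b, 0, sqrt(ex["round_site"])), a, b)
  eff_nr <- matrix(stats::rnorm(b * cc, 0, sqrt(vc["night_round"])), b, cc)
  eff_snr <- array(stats::rnorm(a * b * cc, 0, sqrt(vc["site_night_round"])),
                   dim = c(a, b, cc))
  m_extra <- outer(eff_site, eff_round, "+") + eff_rs      # a x b

  shares <- resident_stage_shares(config)
  comp_noise <- matrix(0, a * b, length(stage_keys))
  if (config$composition_sd > 0) {
    comp_noise <- matrix(stats::rnorm(a * b * length(stage_keys), 0,
                                      config$composition_sd),
                         a * b, length(stage_keys))
  }
  # per-cell resident stage densities (ind m^-2), composition renormalized
  share_cell <- sweep(10^comp_noise, 2, shares, "*")
  share_cell <- share_cell / rowSums(share_cell)
  D_res <- share_cell * 10^as.vector(L_res)                # (a*b) x stages
  colnames(D_res) <- stage_keys
  adult_cols <- stage_keys[4:8]
  log_adult <- log10(rowSums(D_res[, adult_cols, drop = FALSE]))
  adult_dev <- log_adult - mean(log_adult)

  swim_share <- shares * config$overrep_multipliers[stage_keys]
  swim_share <- swim_share / sum(swim_share)
  alpha <- config$mean_log10_swim + log10(swim_share)
  beta <- config$dd_slope_by_stage[stage_keys]
  gamma <- stats::setNames(numeric(length(stage_keys)), stage_keys)
  if (length(config$activity_dependence)) {
    gamma[names(config$activity_dependence)] <-
      config$activity_dependence
  }

  # expected log10 swimmer density per cell x stage (before night/net effects)
  Ldev <- as.vector(L_res) - config$mean_log10_resident
  y_cell <- outer(Ldev, as.numeric(beta)) +
    outer(adult_dev, as.numeric(gamma)) +
    matrix(alpha, a * b, length(stage_keys), byrow = TRUE) +
    as.vector(m_extra)
  colnames(y_cell) <- stage_keys

  truth_cells <- data.frame(
    site = rep(sites, times = b), round = rep(rounds, each = a),
    log10_resident = as.vector(L_res),
    log10_adult_resident = log_adult,
    stats::setNames(as.data.frame(y_cell),
                    paste0("log10_swim_", stage_keys)),
    check.names = FALSE
  )

  nets <- list(); net_ind <- list(); k <- 0L
  for (j in seq_len(b)) for (i in seq_len(a)) {
    cell_idx <- (j - 1L) * a + i
    for (h in seq_len(cc)) {
      for (net in seq_len(config$n_nets)) {
        if (stats::runif(1) < config$net_dropout) next
        k <- k + 1L
        vol <- stats::rlnorm(1, config$volume_meanlog, config$volume_sdlog)
        e <- stats::rnorm(1, 0, sqrt(vc["error"]))
        mu_stage <- 10^(y_cell[cell_idx, ] + eff_nr[j, h] +
                          eff_snr[i, j, h] + e) * vol
        n_true <- rcount(length(stage_keys), mu_stage, config$dispersion)
        total <- sum(n_true)
        splits <- 0L
        while (total * 2^(-splits) > config$target_processed &&
               splits < config$max_splits) splits <- splits + 1L
        frac <- 2^(-splits)
        n_proc <- if (splits > 0) stats::rbinom(length(n_true), n_true, frac)
                  else n_true
        names(n_proc) <- stage_keys
        sid <- sprintf("%s_%s_%s_net%d", sites[i], rounds[j], nights[h], net)
        nets[[k]] <- data.frame(
          sample_id = sid, site = sites[i], round = rounds[j],
          night = nights[h], net = net, subsample_fraction = frac,
          filtered_volume_m3 = vol
        )
        ind <- draw_individuals(n_proc, config, config$intersex_fraction_swim)
        if (nrow(ind)) {
          ind$sample_id <- sid
          net_ind[[k]] <- ind
        }
      }
    }
  }

  cores <- list(); core_ind <- list(); k2 <- 0L
  for (j in seq_len(b)) for (i in seq_len(a)) {
    cell_idx <- (j - 1L) * a + i
    mu_stage <- D_res[cell_idx, ] * config$core_area_m2
    for (core in seq_len(config$n_cores)) {
      k2 <- k2 + 1L
      n_core <- rcount(length(stage_keys), mu_stage, config$dispersion)
      names(n_core) <- stage_keys
      sid <- sprintf("%s_%s_core%d", sites[i], rounds[j], core)
      cores[[k2]] <- data.frame(sample_id = sid, site = sites[i],
                                round = rounds[j], core = core,
                                core_area_m2 = config$core_area_m2)
      ind <- draw_individuals(n_core, config, config$intersex_fraction_mud)
      if (nrow(ind)) {
        ind$sample_id <- sid
        core_ind[[k2]] <- ind
      }
    }
  }

  bind <- function(lst, proto) {
    lst <- Filter(Negate(is.null), lst)
    if (!length(lst)) return(proto)
    do.call(rbind, lst)
  }
  empty_ind <- data.frame(sample_id = character(0), length_mm = numeric(0),
                          sex = character(0), ovigerous = logical(0))
  sv <- survey(
    nets = bind(nets, NULL),
    net_individuals = bind(net_ind, empty_ind)[, names(empty_ind)],
    cores = bind(cores, NULL),
    core_individuals = bind(core_ind, empty_ind)[, names(empty_ind)]
  )
  attr(sv, "truth") <- structure(
    list(cells = truth_cells, stage_shares = shares,
         swim_shares = swim_share, config = config),
    class = "truth_record"
  )
  sv
}

#' Configuration for parameter-recovery experiments
#'
#' Builds a [survey_config()] in which the log-log density dependence is the
#' only channel linking swimmers to residents: every stage slope equals
#' `beta`, the swimmer round/site/cell variance is exactly the part carried
#' by the density dependence (`beta^2 *` the resident variance), composition
#' noise and extra activity dependence are off, and count noise is Poisson.
#' Under this configuration the site-by-round log-log relation between
#' swimmer and resident density has structural slope `beta`, so fitted RMA
#' slopes can be compared against a known truth; with `beta` left at the
#' field-like default the configuration doubles as a variance-component
#' recovery harness (swimmer densities are high enough that the
#' `log10(x + 1)` analysis transform is essentially `log10`).
#'
#' @param beta Structural log-log slope shared by all stages.
#' @param seed Seed passed through.
#' @param ... Further overrides passed to [survey_config()].
#' @return A `survey_config`.
#' @export
recovery_config <- function(beta = 0.37, seed = 1L, ...) {
  vr <- c(round = 0.08, site = 0.35, round_site = 0.12)
  slopes <- stats::setNames(rep(beta, length(stage_keys)), stage_keys)
  survey_config(
    resident_variance = vr,
    variance_components = c(beta^2 * vr,
                            night_round = 0.005, site_night_round = 0.010,
                            error = 0.020),
    dd_slope_by_stage = slopes,
    dd_reference_slope = beta,
    mean_log10_swim = 3.0,
    mean_log10_resident = 3.6,
    composition_sd = 0,
    activity_dependence = numeric(0),
    dispersion = Inf,
    net_dropout = 0,
    target_processed = 150,
    volume_meanlog = log(30),
    seed = seed,
    ...
  )
}

#' Truth record of a synthetic survey
#' @param x An `amphipod_survey` produced by [generate_survey()].
#' @return The `truth_record`, or `NULL` for field data.
#' @export
survey_truth <- function(x) attr(x, "truth")

#' @export
print.truth_record <- function(x, ...) {
  cat("Truth record:", nrow(x$cells), "site x round cells; seed",
      x$config$seed, "\n")
  invisible(x)
}

#' Draw null swimmers from the resident size distribution
#'
#' Samples `m` individuals with replacement from the pooled resident lengths
#' (the null hypothesis of the size-distribution comparison: swimmers are a
#' random subsample of the mud residents) and assigns them round-robin to
#' `n_nets` plankton nets of unit volume with no subsampling.
#'
#' @param core_individuals Individuals table of the pooled cores (needs
#'   `length_mm`, `sex`, `ovigerous`).
#' @param m Number of swimmers to draw; > 0.
#' @param n_nets Number of nets to spread the draw over.
#' @param replace Sample with replacement (the bootstrap reading; `FALSE`
#'   with `m` equal to the resident count yields a permutation).
#' @return Data frame of swimmer individuals with a `sample_id` net column.
#' @export
generate_null_swimmers <- function(core_individuals, m, n_nets = 9,
                                   replace = TRUE) {
  if (!nrow(core_individuals)) stop("pooled residents are empty")
  if (!is.finite(m) || m <= 0) stop("m must be > 0")
  if (!replace && m > nrow(core_individuals)) {
    stop("m exceeds the resident count with replace = FALSE")
  }
  idx <- sample.int(nrow(core_individuals), m, replace = replace)
  out <- core_individuals[idx, c("length_mm", "sex", "ovigerous"),
                          drop = FALSE]
  out$sample_id <- paste0("null_net", rep_len(seq_len(n_nets), m))
  rownames(out) <- NULL
  out
}
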