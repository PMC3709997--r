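#' Standardized swimming activity
#'
#' Divides the density of a swimming stage (ind. m^-3, site-by-round mean
#' over nets) by the same stage's resident density in the mud (ind. m^-2,
#' mean over cores): swimming activity relative to availability. Cells with a
#' zero resident denominator are excluded (`NA`) with a warning.
#'
#' @param swim_density Per-cell swimmer densities of the stage of interest.
#' @param mud_density Per-cell resident densities of the same stage.
#' @return Numeric vector of activities (m^-3 per m^-2); `NA` where
#'   undefined.
#' @export
standardized_activity <- function(swim_density, mud_density) {
  stopifnot(length(swim_density) == length(mud_density))
  if (any(swim_density < 0, na.rm = TRUE) ||
      any(mud_density < 0, na.rm = TRUE)) {
    stop("densities must be non-negative")
  }
  zero <- !is.na(mud_density) & mud_density == 0
  if (any(zero)) {
    warning(sum(zero), " cell(s) excluded: zero resident density")
  }
  out <- swim_density / mud_density
  out[zero] <- NA_real_
  out
}

#' Pearson correlation between activity and a resident covariate
#'
#' Standard Pearson correlation on the untransformed per-cell values, with
#' `df = n - 2` and a two-sided p-value. Cells with a missing member are
#' dropped; at least 3 complete cells are required. A constant input yields
#' an undefined-correlation flag (`NA` with status) rather than an error.
#'
#' @param activity Per-cell standardized swimming activity of the stage of
#'   interest.
#' @param covariate Per-cell resident density of the covariate stage.
#' @return List with `r`, `df`, `p`, `n`, `status`.
#' @export
propensity_correlation <- function(activity, covariate) {
  ok <- is.finite(activity) & is.finite(covariate)
  a <- activity[ok]; b <- covariate[ok]
  n <- length(a)
  if (n < 3) stop("propensity correlation needs at least 3 complete cells")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    return(list(r = NA_real_, df = n - 2, p = NA_real_, n = n,
                status = "undefined: constant input"))
  }
  r <- stats::cor(a, b)
  df <- n - 2
  t <- r * sqrt(df / (1 - r^2))
  list(r = r, df = df, p = 2 * stats::pt(abs(t), df, lower.tail = FALSE),
       n = n, status = "ok")
}

#' Patchiness (variance-to-mean ratio)
#'
#' `var(x) / mean(x)` with the unbiased (n - 1) sample variance. Values above
#' 1 indicate aggregation; Poisson-like counts give about 1; constants give
#' 0. A non-positive mean is undefined (`NA` with a warning).
#'
#' @param values Replicate values (e.g. per-core densities or per-cell
#'   means).
#' @return The variance-to-mean ratio, or `NA` when the mean is not
#'   positive.
#' @export
patchiness <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2) stop("patchiness needs at least 2 values")
  m <- mean(values)
  if (m <= 0) {
    warning("patchiness undefined: mean is not positive")
    return(NA_real_)
  }
  stats::var(values) / m
}

#' Default battery of propensity stage pairs
#'
#' The standard question list: juvenile swimming classes against total
#' resident adults; male swimming stages against resident female stages
#' (total, non-ovigerous total, small and large non-ovigerous, ovigerous);
#' and female swimming stages against resident male stages (total, small,
#' large).
#'
#' @return Data frame with columns `swim_stage`, `resident_stage`.
#' @export
propensity_battery_pairs <- function() {
  juv <- c("<1.5", "1.5-2.5", "2.5-4")
  males <- c("male", "male_small", "male_large")
  females <- c("female", "female_small", "female_large")
  fem_cov <- c("female", "female_nonovig", "female_small", "female_large",
               "female_ovig")
  male_cov <- c("male", "male_small", "male_large")
  rbind(
    data.frame(swim_stage = juv, resident_stage = "adult"),
    expand.grid(swim_stage = males, resident_stage = fem_cov,
                stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE),
    expand.grid(swim_stage = females, resident_stage = male_cov,
                stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  )
}

#' Propensity correlations for a whole survey
#'
#' For every stage pair in the battery: computes site-by-round mean swimmer
#' and resident densities for the swimming stage, forms the standardized
#' swimming activity, and correlates it (Pearson, untransformed) with the
#' site-by-round resident density of the covariate stage. Each correlation
#' addresses a distinct null hypothesis, so no family-wise correction is
#' applied.
#'
#' @param x An `amphipod_survey`.
#' @param pairs Stage pairs, as from [propensity_battery_pairs()].
#' @return Data frame: `swim_stage`, `resident_stage`, `n_cells`, `r`, `df`,
#'   `p`, `status`.
#' @export
propensity_battery <- function(x, pairs = propensity_battery_pairs()) {
  preds <- stage_predicates(x$scheme)
  need <- unique(c(pairs$swim_stage, pairs$resident_stage))
  miss <- setdiff(need, names(preds))
  if (length(miss)) stop("unknown stage(s): ", paste(miss, collapse = ", "))

  swim_cell <- function(stage) {
    cell_means(net_density(x, preds[[stage]]), "density_m3")
  }
  mud_cell <- function(stage) {
    cell_means(core_density(x, preds[[stage]]), "density_m2")
  }
  mud_cache <- new.env()
  mud <- function(stage) {
    if (is.null(mud_cache[[stage]])) mud_cache[[stage]] <- mud_cell(stage)
    mud_cache[[stage]]
  }

  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    sw <- pairs$swim_stage[i]; cov <- pairs$resident_stage[i]
    s <- swim_cell(sw); m_own <- mud(sw); m_cov <- mud(cov)
    stopifnot(identical(s[c("site", "round")], m_own[c("site", "round")]))
    act <- suppressWarnings(standardized_activity(s$mean, m_own$mean))
    ct <- tryCatch(propensity_correlation(act, m_cov$mean),
                   error = function(e) {
                     list(r = NA_real_, df = NA_real_, p = NA_real_,
                          n = sum(is.finite(act) & is.finite(m_cov$mean)),
                          status = paste("not analysed:", conditionMessage(e)))
                   })
    data.frame(swim_stage = sw, resident_stage = cov, n_cells = ct$n,
               r = ct$r, df = ct$df, p = ct$p, status = ct$status,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
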