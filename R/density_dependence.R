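#' Reduced major axis (Model II) regression
#'
#' Fits the RMA line of `y` on `x` (both already log10-transformed
#' site-by-round means in the dispersal pipeline): slope
#' `sign(r) * sd(y)/sd(x)`, intercept through the means. RMA is the Model II
#' choice when the predictor (resident density estimated from 12 cores) is
#' itself measured with error. The standard error of the slope is
#' `|slope| * sqrt((1 - r^2)/(n - 2))`.
#'
#' Two hypothesis tests accompany the fit. The slope = 0 test is the standard
#' Student's t on the correlation, `t = r * sqrt((n-2)/(1-r^2))` with `n - 2`
#' df. When (and only when) that test is significant at `alpha`, the slope is
#' tested against 1 with Clarke's T (see [test_slope_one()]), whose degrees of
#' freedom are non-integer. The fitted relationship is then classified by
#' [classify_shape()]: on the log-log scale a slope below 1 is an ascending
#' but decelerating relationship (a decreasing proportion swims as resident
#' density rises), a slope of 1 is proportional, and a slope above 1 is
#' ascending and accelerating.
#'
#' @param x,y Paired finite numeric vectors (log10 scale), `n >= 3`.
#' @param alpha Significance level gating the slope = 1 test.
#' @param slope_null Hypothesized slope for Clarke's test.
#' @return An `rma_fit` object: `slope`, `intercept`, `se_slope`, `r`, `n`,
#'   `df0`, `t0`, `p0`, and (when gated in) `T1`, `df1`, `p1`, plus `shape`.
#' @export
rma_fit <- function(x, y, alpha = 0.05, slope_null = 1) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("rma_fit needs at least 3 paired finite values")
  sdx <- stats::sd(x); sdy <- stats::sd(y)
  if (sdx == 0) stop("undefined fit: x has zero variance")
  if (sdy == 0) stop("undefined fit: y has zero variance")
  r <- stats::cor(x, y)
  slope <- (if (r < 0) -1 else 1) * sdy / sdx
  intercept <- mean(y) - slope * mean(x)
  se <- abs(slope) * sqrt((1 - r^2) / (n - 2))

  fit <- structure(list(slope = slope, intercept = intercept, se_slope = se,
                        r = r, n = n, alpha = alpha, slope_null = slope_null,
                        df0 = n - 2, t0 = NA_real_, p0 = NA_real_,
                        T1 = NA_real_, df1 = NA_real_, p1 = NA_real_,
                        shape = "none"),
                   class = "rma_fit")
  z <- test_slope_zero(fit)
  fit$t0 <- z$t; fit$p0 <- z$p
  if (is.finite(fit$p0) && fit$p0 < alpha) {
    one <- test_slope_one(fit, slope_null)
    fit$T1 <- one$T; fit$df1 <- one$df; fit$p1 <- one$p
  }
  fit$shape <- classify_shape(fit, alpha)
  fit
}

#' Test an RMA slope against zero
#'
#' Student's t on the correlation coefficient:
#' `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees of freedom,
#' two-sided. Significance of the RMA slope against 0 is equivalent to
#' significance of the correlation.
#'
#' @param fit An `rma_fit`.
#' @return List with `t`, `df`, `p`.
#' @export
test_slope_zero <- function(fit) {
  stopifnot(inherits(fit, "rma_fit"))
  r <- fit$r; df <- fit$n - 2
  t <- if (abs(r) >= 1) Inf * sign(r) else r * sqrt(df / (1 - r^2))
  list(t = t, df = df, p = 2 * stats::pt(abs(t), df, lower.tail = FALSE))
}

#' Clarke's T-test of an RMA slope against a hypothesized value
#'
#' Tests `|slope| = slope_null` (here 1) on the log scale:
#' `T = |ln(|slope| / slope_null)| / sqrt((1 - r^2) / (n - 2))`,
#' the delta-method standard error of the log RMA slope, referred to a
#' Student's t distribution with Clarke's effective (non-integer) degrees of
#' freedom `nu = (n - 2) / (1 + r^2 * (2 + r^2) / 7)`. Two-sided p.
#'
#' The test is gated: it may only be run when the slope = 0 test was
#' significant (no point asking whether an undetectable slope differs
#' from 1).
#'
#' @param fit An `rma_fit`.
#' @param slope_null Hypothesized slope (> 0).
#' @return List with `T`, `df`, `p`.
#' @export
test_slope_one <- function(fit, slope_null = 1) {
  stopifnot(inherits(fit, "rma_fit"), slope_null > 0)
  if (!is.na(fit$p0) && fit$p0 >= fit$alpha) {
    stop("slope = ", slope_null, " test is gated on a significant slope = 0 test")
  }
  n <- fit$n; r <- fit$r
  df <- (n - 2) / (1 + r^2 * (2 + r^2) / 7)
  babs <- abs(fit$slope)
  if (babs == slope_null) {
    return(list(T = 0, df = df, p = 1))
  }
  s <- sqrt((1 - r^2) / (n - 2))
  if (s == 0) return(list(T = Inf, df = df, p = 0))
  T <- abs(log(babs / slope_null)) / s
  list(T = T, df = df, p = 2 * stats::pt(T, df, lower.tail = FALSE))
}

#' Classify the shape of a density-dependence relationship
#'
#' Applies the log-log slope rule: no detectable relationship (`p0 >= alpha`)
#' is `"none"`; a slope significantly below 1 is `"ascending-decelerating"`
#' (proportionally less swimming at higher resident density); significantly
#' above 1 is `"ascending-accelerating"`; otherwise `"proportional"`.
#'
#' @param fit An `rma_fit`.
#' @param alpha Significance level.
#' @return One of `"none"`, `"ascending-decelerating"`,
#'   `"ascending-accelerating"`, `"proportional"`.
#' @export
classify_shape <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "rma_fit"))
  if (is.na(fit$p0) || fit$p0 >= alpha) return("none")
  p1 <- fit$p1
  if (is.na(p1)) {
    # ungated recompute (classify may be called at a different alpha)
    g <- fit
    g$p0 <- 0
    p1 <- test_slope_one(g, fit$slope_null)$p
  }
  if (p1 < alpha && abs(fit$slope) < fit$slope_null) {
    "ascending-decelerating"
  } else if (p1 < alpha && abs(fit$slope) > fit$slope_null) {
    "ascending-accelerating"
  } else {
    "proportional"
  }
}

#' @export
print.rma_fit <- function(x, ...) {
  cat(sprintf("RMA fit (n = %d): slope = %.3f +/- %.3f, intercept = %.3f, r = %.3f\n",
              x$n, x$slope, x$se_slope, x$intercept, x$r))
  cat(sprintf("  H0 slope=0: t[%d] = %.2f, p = %s\n", x$df0, x$t0,
              format.pval(x$p0, digits = 3)))
  if (!is.na(x$T1)) {
    cat(sprintf("  H0 slope=%g (Clarke): T[%.1f] = %.2f, p = %s\n",
                x$slope_null, x$df1, x$T1, format.pval(x$p1, digits = 3)))
  }
  cat("  shape:", x$shape, "\n")
  invisible(x)
}
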