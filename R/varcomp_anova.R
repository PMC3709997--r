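#' Design constants for the random-model ANOVA
#'
#' The variance-component denominators use `a` sites, `b` rounds, `c` nights
#' per round and `n`, the harmonic mean of the number of replicate samples per
#' night (non-integer in unbalanced designs).
#'
#' @param a,b,c Integers >= 2: number of sites, rounds, nights per round.
#' @param n Harmonic mean of per-night replicate counts; > 0.
#' @return A `design_constants` object.
#' @export
design_constants <- function(a, b, c, n) {
  stopifnot(a >= 2, b >= 2, c >= 2, a == round(a), b == round(b),
            c == round(c), is.finite(n), n > 0)
  structure(list(a = a, b = b, c = c, n = n), class = "design_constants")
}

#' Harmonic mean
#' @param x Positive numeric vector.
#' @return `length(x) / sum(1/x)`.
#' @export
harmonic_mean <- function(x) {
  stopifnot(all(is.finite(x)), all(x > 0))
  length(x) / sum(1 / x)
}

anova_sources <- c("round", "site", "round_site", "night_round",
                   "site_night_round", "error")

source_display <- c(round = "Round", site = "Site",
                    round_site = "Round x Site",
                    night_round = "Night(Round)",
                    site_night_round = "Night(Round) x Site",
                    error = "Error")

#' Sums of squares and mean squares for the crossed/nested random layout
#'
#' Decomposes a per-replicate response over Site (crossed), Round (crossed)
#' and Night nested in Round, with replicate samples within each
#' site-by-round-by-night cell. Unbalanced replication is handled the
#' classical unweighted-means way: sums of squares among cells are computed
#' from the cell means and scaled by the harmonic mean of the per-cell
#' replicate counts, while the error sum of squares pools the within-cell
#' deviations. On balanced data this is the exact textbook decomposition
#' (total SS equals the sum of the parts).
#'
#' @param data Data frame with columns `site`, `round`, `night` and the
#'   response named by `response` (already transformed).
#' @param response Name of the response column.
#' @return Data frame with one row per source (`source`, `df`, `SS`, `MS`),
#'   carrying the [design_constants()] as attribute `"constants"`.
#' @export
mean_squares <- function(data, response = "y") {
  stopifnot(all(c("site", "round", "night", response) %in% names(data)))
  y <- data[[response]]
  if (any(!is.finite(y))) stop("response contains non-finite values")
  site <- factor(data$site)
  round_ <- factor(data$round)
  night <- factor(data$night)
  a <- nlevels(site); b <- nlevels(round_); c <- nlevels(night)

  cell <- interaction(site, round_, night, drop = FALSE, lex.order = TRUE)
  counts <- table(cell)
  if (any(counts == 0)) {
    empty <- names(counts)[which(counts == 0)[1]]
    stop("empty site x round x night cell: ", empty)
  }
  n_h <- harmonic_mean(as.numeric(counts))

  # cell means as an a x b x c array
  M <- tapply(y, list(site, round_, night), mean)
  grand <- mean(M)
  m_i <- apply(M, 1, mean)                 # site
  m_j <- apply(M, 2, mean)                 # round
  m_ij <- apply(M, c(1, 2), mean)          # site x round
  m_jk <- apply(M, c(2, 3), mean)          # round x night
  ss_round <- n_h * a * c * sum((m_j - grand)^2)
  ss_site <- n_h * b * c * sum((m_i - grand)^2)
  ss_rs <- n_h * c * sum(sweep(sweep(m_ij, 1, m_i), 2, m_j - grand)^2)
  ss_nr <- n_h * a * sum(sweep(m_jk, 1, m_j)^2)
  resid <- M
  for (j in seq_len(b)) {
    resid[, j, ] <- M[, j, ] - outer(m_ij[, j] - m_j[j], rep(1, c)) -
      matrix(m_jk[j, ], a, c, byrow = TRUE)
  }
  ss_snr <- n_h * sum(resid^2)
  cell_mean_per_obs <- ave(y, cell, FUN = mean)
  ss_e <- sum((y - cell_mean_per_obs)^2)

  df <- c(b - 1, a - 1, (a - 1) * (b - 1), b * (c - 1),
          (a - 1) * b * (c - 1), length(y) - a * b * c)
  ss <- c(ss_round, ss_site, ss_rs, ss_nr, ss_snr, ss_e)
  out <- data.frame(source = anova_sources, df = df, SS = ss, MS = ss / df,
                    stringsAsFactors = FALSE)
  attr(out, "constants") <- design_constants(a, b, c, n_h)
  out
}

as_ms_vector <- function(ms) {
  if (is.data.frame(ms)) {
    v <- stats::setNames(ms$MS, ms$source)
  } else {
    v <- ms
  }
  miss <- setdiff(anova_sources, names(v))
  if (length(miss)) stop("missing mean square(s): ", paste(miss, collapse = ", "))
  v[anova_sources]
}

#' F and quasi-F ratios for the random model
#'
#' Builds the test statistic for every testable source. All sources but Round
#' have a single valid denominator mean square: Site is tested over Round x
#' Site, Round x Site over Night(Round) x Site, Night(Round) over
#' Night(Round) x Site, and Night(Round) x Site over the error. No single
#' mean square is a valid error term for Round, so a quasi-F is formed from
#' sums: `(MS_R + MS_SN(R)) / (MS_N(R) + MS_RS)`, with Satterthwaite degrees
#' of freedom synthesized for both composites when `df` is supplied.
#'
#' @param ms A [mean_squares()] table, or a named vector of the six mean
#'   squares (`round`, `site`, `round_site`, `night_round`,
#'   `site_night_round`, `error`).
#' @param df Optional named vector/table of degrees of freedom per source;
#'   taken from `ms` when it is a `mean_squares` table. Needed for p-values.
#' @return Data frame with `source`, `df`, `MS`, `F` (quasi-F for Round;
#'   `NA` for error), `df_num`, `df_den` and `p`. A zero denominator yields
#'   `NaN`/`NA` (an undefined-ratio flag), not an error.
#' @export
f_ratios <- function(ms, df = NULL) {
  v <- as_ms_vector(ms)
  if (any(v < 0)) stop("mean squares must be non-negative")
  if (is.null(df) && is.data.frame(ms)) {
    df <- stats::setNames(ms$df, ms$source)
  }
  ratio <- function(num, den) if (den > 0) num / den else NaN

  fvals <- c(
    round = ratio(v["round"] + v["site_night_round"],
                  v["night_round"] + v["round_site"]),
    site = ratio(v["site"], v["round_site"]),
    round_site = ratio(v["round_site"], v["site_night_round"]),
    night_round = ratio(v["night_round"], v["site_night_round"]),
    site_night_round = ratio(v["site_night_round"], v["error"]),
    error = NA_real_
  )

  out <- data.frame(source = anova_sources,
                    df = if (is.null(df)) NA_real_ else
                      as.numeric(df[anova_sources]),
                    MS = as.numeric(v),
                    F = as.numeric(fvals),
                    df_num = NA_real_, df_den = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  if (!is.null(df)) {
    d <- stats::setNames(as.numeric(df[anova_sources]), anova_sources)
    pairs <- list(site = c("site", "round_site"),
                  round_site = c("round_site", "site_night_round"),
                  night_round = c("night_round", "site_night_round"),
                  site_night_round = c("site_night_round", "error"))
    for (src in names(pairs)) {
      i <- match(src, out$source)
      out$df_num[i] <- d[pairs[[src]][1]]
      out$df_den[i] <- d[pairs[[src]][2]]
    }
    i <- match("round", out$source)
    out$df_num[i] <- satterthwaite_df(v[c("round", "site_night_round")],
                                      d[c("round", "site_night_round")])
    out$df_den[i] <- satterthwaite_df(v[c("night_round", "round_site")],
                                      d[c("night_round", "round_site")])
    ok <- !is.na(out$F) & is.finite(out$F) & !is.na(out$df_num) &
      !is.na(out$df_den)
    out$p[ok] <- stats::pf(out$F[ok], out$df_num[ok], out$df_den[ok],
                           lower.tail = FALSE)
  }
  out
}

#' Satterthwaite degrees of freedom for a sum of mean squares
#'
#' For a composite `sum(ms)` of independent mean squares with degrees of
#' freedom `df`, returns `sum(ms)^2 / sum(ms^2/df)`. The result shrinks
#' toward the df of the dominating mean square.
#'
#' @param ms Mean squares entering the sum.
#' @param df Their degrees of freedom.
#' @return Effective (generally non-integer) degrees of freedom.
#' @export
satterthwaite_df <- function(ms, df) {
  stopifnot(length(ms) == length(df), all(df > 0))
  if (sum(ms) == 0) return(NA_real_)
  sum(ms)^2 / sum(ms^2 / df)
}

#' p-value for the Round quasi-F
#'
#' Convenience wrapper: given the six mean squares and their df, computes the
#' Round quasi-F and its p-value from the F distribution with Satterthwaite
#' degrees of freedom for both the numerator and denominator composites.
#'
#' @param ms Named mean squares (see [f_ratios()]).
#' @param df Named degrees of freedom.
#' @return List with `F`, `df_num`, `df_den`, `p`.
#' @export
quasi_f_p <- function(ms, df) {
  v <- as_ms_vector(ms)
  d <- stats::setNames(as.numeric(df[anova_sources]), anova_sources)
  fval <- (v["round"] + v["site_night_round"]) /
    (v["night_round"] + v["round_site"])
  df_num <- satterthwaite_df(v[c("round", "site_night_round")],
                             d[c("round", "site_night_round")])
  df_den <- satterthwaite_df(v[c("night_round", "round_site")],
                             d[c("night_round", "round_site")])
  list(F = unname(fval), df_num = df_num, df_den = df_den,
       p = unname(stats::pf(fval, df_num, df_den, lower.tail = FALSE)))
}

#' Variance components of the random model
#'
#' Estimates each source's variance component from the expected-mean-square
#' algebra of the fully random layout:
#' Round `(MS_R + MS_SN(R) - MS_RS - MS_N(R)) / (a c n)`,
#' Site `(MS_S - MS_RS) / (b c n)`,
#' Round x Site `(MS_RS - MS_SN(R)) / (c n)`,
#' Night(Round) `(MS_N(R) - MS_SN(R)) / (a n)`,
#' Night(Round) x Site `(MS_SN(R) - MS_e) / n`, and Error `MS_e`.
#' Negative estimates are kept in `component_raw` and truncated to zero in
#' `component` (the classical convention) before percentages are formed.
#'
#' @param ms Mean squares (table or named vector, see [f_ratios()]).
#' @param constants A [design_constants()]; taken from a [mean_squares()]
#'   table's attribute when omitted.
#' @return Data frame with `source`, `component_raw`, `component` and
#'   `pct_variation` (percentages sum to 100).
#' @export
variance_components <- function(ms, constants = attr(ms, "constants")) {
  v <- as_ms_vector(ms)
  if (is.null(constants)) stop("design constants are required")
  stopifnot(inherits(constants, "design_constants"))
  a <- constants$a; b <- constants$b; cc <- constants$c; n <- constants$n
  raw <- c(
    round = (v[["round"]] + v[["site_night_round"]] - v[["round_site"]] -
               v[["night_round"]]) / (a * cc * n),
    site = (v[["site"]] - v[["round_site"]]) / (b * cc * n),
    round_site = (v[["round_site"]] - v[["site_night_round"]]) / (cc * n),
    night_round = (v[["night_round"]] - v[["site_night_round"]]) / (a * n),
    site_night_round = (v[["site_night_round"]] - v[["error"]]) / n,
    error = v[["error"]]
  )
  comp <- pmax(raw, 0)
  pct <- if (sum(comp) > 0) 100 * comp / sum(comp) else rep(NA_real_, 6)
  data.frame(source = anova_sources, component_raw = as.numeric(raw),
             component = as.numeric(comp), pct_variation = as.numeric(pct),
             stringsAsFactors = FALSE)
}

#' Fully random three-factor ANOVA with variance components
#'
#' One-call wrapper: computes the mean squares, F/quasi-F ratios, p-values and
#' variance components for a per-replicate response over Site, Round and
#' Night(Round). The response must already be transformed (the pipeline
#' applies `log10(datum + 1)` to densities before calling this).
#'
#' @inheritParams mean_squares
#' @return An `anova_table`: data frame with `source`, `df`, `MS`, `F`,
#'   `df_num`, `df_den`, `p`, `component`, `pct_variation`, plus the design
#'   constants as attribute.
#' @export
varcomp_anova <- function(data, response = "y") {
  ms <- mean_squares(data, response)
  f <- f_ratios(ms)
  vc <- variance_components(ms)
  out <- cbind(f, vc[, c("component_raw", "component", "pct_variation")])
  attr(out, "constants") <- attr(ms, "constants")
  class(out) <- c("anova_table", class(out))
  out
}

#' @export
print.anova_table <- function(x, digits = 3, ...) {
  k <- attr(x, "constants")
  cat("Random-model ANOVA (Site x Round, Night nested in Round)\n")
  if (!is.null(k)) {
    cat(sprintf("  a = %d sites, b = %d rounds, c = %d nights, n = %.3f (harmonic mean)\n",
                k$a, k$b, k$c, k$n))
  }
  df <- data.frame(
    Source = source_display[x$source],
    df = x$df,
    MS = round(x$MS, digits),
    F = ifelse(is.na(x$F), "", formatC(x$F, digits = 1, format = "f")),
    p = ifelse(is.na(x$p), "", format.pval(x$p, digits = 2)),
    Component = round(x$component, digits),
    `%Var` = round(x$pct_variation, 1),
    check.names = FALSE
  )
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write an ANOVA table as delimited text
#' @param x An `anova_table`.
#' @param path Output file path (TSV).
#' @return `path`, invisibly.
#' @export
write_anova_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
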