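#' Observed swimmer size-class proportions (mean over nets)
#'
#' Computes each net's size-class proportions on the 0.5-mm histogram grid
#' and averages them, unweighted, across nets. This is the observed
#' distribution the bootstrap interval is compared against: a mean over the
#' 7--9 usable nets of a site-by-round cell, not the pooled-count proportion
#' (the two differ when nets caught unequal numbers).
#'
#' @param lengths_by_net List of numeric vectors: measured swimmer body
#'   lengths per net. Nets with no measured swimmer are dropped; at least one
#'   usable net is required.
#' @param scheme A [stage_scheme()].
#' @return Named numeric vector of per-class mean proportions (sums to 1).
#' @export
observed_swimmer_proportions <- function(lengths_by_net,
                                         scheme = stage_scheme()) {
  lengths_by_net <- Filter(length, lengths_by_net)
  if (!length(lengths_by_net)) stop("no net has any measured swimmer")
  n_class <- length(scheme$histogram_edges) - 1L
  props <- vapply(lengths_by_net, function(l) {
    tabulate(histogram_class(l, scheme), nbins = n_class) / length(l)
  }, numeric(n_class))
  stats::setNames(rowMeans(props), histogram_labels(scheme))
}

#' Bootstrap comparison of swimmer and resident size distributions
#'
#' Tests whether swimmers are a random subsample of the mud residents.
#' `B` times, `m` body lengths are drawn with replacement from the pooled
#' resident lengths (where `m` is the actual number of swimmers measured in
#' the nets) and binned on the 0.5-mm grid. For each class the `B` bootstrap
#' proportions are sorted and the 25 smallest and 25 largest values (at
#' `B = 1000`; generally `round(0.025 B)` per tail) are removed; the extreme
#' remaining values are the 95% confidence limits. Classes whose observed
#' mean-over-nets proportion falls outside the limits are flagged `over` or
#' `under`.
#'
#' The comparison is only made for cells with at least 100 measured swimmers
#' and at least 100 residents; below that the result carries status
#' `"not analysed"` (mirroring the survey exclusions) instead of limits.
#'
#' @param resident_lengths Pooled resident body lengths (mm), typically from
#'   12 cores of one site-by-round cell.
#' @param swimmer_lengths_by_net List of per-net swimmer lengths (mm).
#' @param B Bootstrap iterations (>= 100).
#' @param seed Optional integer seed for the resampling.
#' @param scheme A [stage_scheme()].
#' @return A `bootstrap_comparison`: list with `status`, and when analysed a
#'   `table` (per class: `expected`, `lower`, `upper`, `observed`, `flag`)
#'   plus `B`, `m`, `n_residents`, `trim`.
#' @export
bootstrap_size_comparison <- function(resident_lengths,
                                      swimmer_lengths_by_net,
                                      B = 1000, seed = NULL,
                                      scheme = stage_scheme()) {
  if (B < 100) stop("B must be at least 100")
  swimmer_lengths_by_net <- Filter(length, swimmer_lengths_by_net)
  m <- sum(lengths(swimmer_lengths_by_net))
  n_res <- length(resident_lengths)
  base <- list(B = B, m = m, n_residents = n_res)
  if (m < 100 || n_res < 100) {
    return(structure(c(list(status = "not analysed",
                            reason = sprintf(
                              "requires >= 100 swimmers and >= 100 residents (have %d, %d)",
                              m, n_res)), base),
                     class = "bootstrap_comparison"))
  }
  if (!is.null(seed)) set.seed(seed)

  n_class <- length(scheme$histogram_edges) - 1L
  res_class <- histogram_class(resident_lengths, scheme)
  expected <- tabulate(res_class, nbins = n_class) / n_res

  draws <- sample(res_class, m * B, replace = TRUE)
  iter <- rep(seq_len(B), each = m)
  counts <- tabulate(draws + n_class * (iter - 1L), nbins = n_class * B)
  boot <- matrix(counts, nrow = n_class) / m          # class x B

  trim <- round(0.025 * B)
  sorted <- apply(boot, 1, sort)                      # B x class
  lower <- sorted[trim + 1L, ]
  upper <- sorted[B - trim, ]

  observed <- observed_swimmer_proportions(swimmer_lengths_by_net, scheme)
  flag <- ifelse(observed > upper, "over",
                 ifelse(observed < lower, "under", "ns"))
  tab <- data.frame(class = histogram_labels(scheme), expected = expected,
                    lower = lower, upper = upper,
                    observed = as.numeric(observed), flag = flag,
                    stringsAsFactors = FALSE)
  structure(c(list(status = "analysed", table = tab, trim = trim), base),
            class = "bootstrap_comparison")
}

#' @export
print.bootstrap_comparison <- function(x, ...) {
  cat("Bootstrap size-distribution comparison:", x$status, "\n")
  if (x$status == "analysed") {
    cat(sprintf("  B = %d, m = %d swimmers, %d residents; trimmed %d per tail\n",
                x$B, x$m, x$n_residents, x$trim))
    sig <- x$table[x$table$flag != "ns", c("class", "observed", "flag")]
    if (nrow(sig)) print(sig, row.names = FALSE) else
      cat("  no class outside the 95% limits\n")
  } else {
    cat(" ", x$reason, "\n")
  }
  invisible(x)
}

pool_partner <- c(male_large = "male_small", male_small = "male_large",
                  female_large = "female_ovig", female_ovig = "female_large",
                  female_small = "female_large")

#' G-test of adult stage structure with category pooling
#'
#' Compares the observed stage composition of swimming adults against the
#' composition expected from the mud resident adults with the likelihood-ratio
#' G statistic, `G = 2 * sum(O * ln(O / E'))`, where the expected counts are
#' scaled to the observed total. Stages with zero expected count are pooled
#' before computing: large males into small males, and large non-ovigerous
#' females into ovigerous females (small males mature into large males;
#' ovigerous females are typically the largest), with the degrees of freedom
#' reduced accordingly (`df = stages - 1 < 4` after pooling). Zero observed
#' counts contribute 0 (the `O * ln O` limit).
#'
#' The test requires more than 100 resident adults and more than 100 swimming
#' adults; otherwise the result carries status `"not analysed"`.
#'
#' @param expected Named counts of resident adults per stage
#'   (`male_small`, `male_large`, `female_small`, `female_large`,
#'   `female_ovig`).
#' @param observed Named counts of swimming adults per stage (same names);
#'   subsample-expanded counts should be rounded to integers upstream.
#' @param min_count Applicability threshold (both totals must exceed it).
#' @return A `stage_g_test`: list with `status` and, when analysed, `G`,
#'   `df`, `p`, `stages` (post-pooling), `expected_pct`, `observed_pct`,
#'   `pooled` (logical).
#' @export
g_test_stages <- function(expected, observed, min_count = 100) {
  scheme_stages <- stage_scheme()$adult_stages
  stopifnot(all(scheme_stages %in% names(expected)),
            all(scheme_stages %in% names(observed)))
  E <- expected[scheme_stages]
  O <- observed[scheme_stages]
  if (any(E < 0) || any(O < 0)) stop("counts must be non-negative")
  if (sum(E) <= min_count || sum(O) <= min_count) {
    return(structure(list(
      status = "not analysed",
      reason = sprintf("requires > %d resident and > %d swimming adults (have %g, %g)",
                       min_count, min_count, sum(E), sum(O))
    ), class = "stage_g_test"))
  }

  pooled <- FALSE
  while (any(E == 0) && length(E) > 2) {
    z <- names(E)[E == 0][1]
    partner <- pool_partner[[z]]
    if (!partner %in% names(E)) partner <- setdiff(names(E), z)[1]
    E[partner] <- E[partner] + E[z]
    O[partner] <- O[partner] + O[z]
    E <- E[names(E) != z]
    O <- O[names(O) != z]
    pooled <- TRUE
  }
  if (any(E == 0)) stop("expected counts are zero in all but one stage")

  E_scaled <- E / sum(E) * sum(O)
  terms <- ifelse(O > 0, O * log(O / E_scaled), 0)
  G <- 2 * sum(terms)
  df <- length(E) - 1L
  structure(list(
    status = "analysed", G = unname(G), df = df,
    p = unname(stats::pchisq(G, df, lower.tail = FALSE)),
    stages = names(E), pooled = pooled,
    expected_pct = 100 * E / sum(E), observed_pct = 100 * O / sum(O)
  ), class = "stage_g_test")
}

#' @export
print.stage_g_test <- function(x, ...) {
  cat("G-test of adult stage structure:", x$status, "\n")
  if (x$status == "analysed") {
    cat(sprintf("  G[%d] = %.2f, p = %s%s\n", x$df, x$G,
                format.pval(x$p, digits = 3),
                if (x$pooled) " (stages pooled)" else ""))
  } else cat(" ", x$reason, "\n")
  invisible(x)
}
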