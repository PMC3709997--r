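#' Staging scheme for Corophium volutator surveys
#'
#' Defines the size-class breakpoints, the 0.5-mm histogram grid and the adult
#' stage labels used throughout the package. Size classes follow the
#' conventional survey bins (< 1.5, 1.5--2.5, 2.5--4, 4--6 and > 6 mm body
#' length, tip of rostrum to end of telson). Adults are individuals strictly
#' longer than 4 mm; they are sexed, and split into small (4--6 mm) and large
#' (> 6 mm) males and non-ovigerous females, plus ovigerous females of any
#' size. All bins are half-open, closed on the left, so every length maps to
#' exactly one class; the final histogram bin is closed on both sides.
#'
#' @param size_class_edges Interior breakpoints (mm) of the size classes.
#' @param histogram_from,histogram_to,histogram_by Histogram grid (mm): 0.5-mm
#'   increments from 1 to 11 by default.
#' @param adult_threshold_mm Length (mm) above which (strictly) an individual
#'   is an adult.
#' @param large_threshold_mm Length (mm) at and above which an adult is
#'   "large".
#'
#' @return An object of class `stage_scheme`.
#' @export
#' @examples
#' sch <- stage_scheme()
#' classify_stage(5.0, "female", FALSE, sch)
stage_scheme <- function(size_class_edges = c(1.5, 2.5, 4, 6),
                         histogram_from = 1, histogram_to = 11,
                         histogram_by = 0.5,
                         adult_threshold_mm = 4,
                         large_threshold_mm = 6) {
  if (any(diff(size_class_edges) <= 0)) {
    stop("size_class_edges must be strictly increasing")
  }
  hist_edges <- seq(histogram_from, histogram_to, by = histogram_by)
  if (length(hist_edges) < 2) stop("histogram grid needs at least one bin")
  labels <- c(
    paste0("<", size_class_edges[1]),
    paste0(size_class_edges[-length(size_class_edges)], "-",
           size_class_edges[-1]),
    paste0(">", size_class_edges[length(size_class_edges)])
  )
  structure(
    list(
      size_class_edges = size_class_edges,
      size_class_labels = labels,
      histogram_edges = hist_edges,
      adult_threshold_mm = adult_threshold_mm,
      large_threshold_mm = large_threshold_mm,
      adult_stages = c("male_small", "male_large",
                       "female_small", "female_large", "female_ovig")
    ),
    class = "stage_scheme"
  )
}

#' @export
print.stage_scheme <- function(x, ...) {
  cat("Stage scheme\n")
  cat("  size classes:", paste(x$size_class_labels, collapse = ", "), "mm\n")
  cat("  histogram:   ", x$histogram_edges[1], "to",
      x$histogram_edges[length(x$histogram_edges)], "mm in",
      diff(x$histogram_edges)[1], "mm bins\n")
  cat("  adults:      > ", x$adult_threshold_mm, " mm; large >= ",
      x$large_threshold_mm, " mm; stages ",
      paste(x$adult_stages, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Labels for the adult stages
#'
#' Human-readable names for the five adult stages, in scheme order.
#'
#' @param scheme A [stage_scheme()].
#' @return Named character vector mapping stage keys to display names.
#' @export
adult_stage_labels <- function(scheme = stage_scheme()) {
  c(male_small = "small male", male_large = "large male",
    female_small = "small non-ovigerous female",
    female_large = "large non-ovigerous female",
    female_ovig = "ovigerous female")[scheme$adult_stages]
}

sex_levels <- c("juvenile", "male", "female", "intersex")

check_lengths <- function(length_mm, scheme, what = "individual") {
  upper <- scheme$histogram_edges[length(scheme$histogram_edges)]
  bad <- which(!is.finite(length_mm) | length_mm <= 0 | length_mm > upper)
  if (length(bad)) {
    stop(sprintf(
      "%s %d has body length %s mm outside the supported range (0, %g]",
      what, bad[1], format(length_mm[bad[1]]), upper
    ))
  }
  invisible(TRUE)
}

#' Classify individuals into size classes and adult stages
#'
#' Assigns each individual to exactly one size class and, for adults
#' (body length strictly greater than the adult threshold), to one of the five
#' adult stages. Intersex individuals are functional males and receive male
#' stage labels. Size bins are closed on the left and open on the right; the
#' top size class and the "large" adult stages are unbounded above (within the
#' supported length range).
#'
#' @param length_mm Body length(s), mm.
#' @param sex One of `"juvenile"`, `"male"`, `"female"`, `"intersex"`
#'   (recycled).
#' @param ovigerous Logical; egg-carrying (females only, recycled).
#' @param scheme A [stage_scheme()].
#'
#' @return A data frame with columns `size_class` (factor over the scheme's
#'   class labels) and `adult_stage` (factor over the adult stage keys, `NA`
#'   for juveniles).
#' @export
classify_stage <- function(length_mm, sex = "juvenile", ovigerous = FALSE,
                           scheme = stage_scheme()) {
  n <- length(length_mm)
  sex <- rep_len(as.character(sex), n)
  ovigerous <- rep_len(as.logical(ovigerous), n)
  if (!all(sex %in% sex_levels)) {
    stop("sex must be one of: ", paste(sex_levels, collapse = ", "))
  }
  if (any(ovigerous & sex != "female")) {
    stop("ovigerous implies sex = female")
  }
  check_lengths(length_mm, scheme)

  edges <- c(-Inf, scheme$size_class_edges, Inf)
  size_class <- cut(length_mm, breaks = edges,
                    labels = scheme$size_class_labels, right = FALSE)

  is_adult <- length_mm > scheme$adult_threshold_mm & sex != "juvenile"
  large <- length_mm >= scheme$large_threshold_mm
  stage <- rep(NA_character_, n)
  male_like <- sex %in% c("male", "intersex")
  stage[is_adult & male_like & !large] <- "male_small"
  stage[is_adult & male_like & large] <- "male_large"
  fem <- is_adult & sex == "female"
  stage[fem & ovigerous] <- "female_ovig"
  stage[fem & !ovigerous & !large] <- "female_small"
  stage[fem & !ovigerous & large] <- "female_large"

  data.frame(
    size_class = size_class,
    adult_stage = factor(stage, levels = scheme$adult_stages)
  )
}

#' Bin body lengths on the 0.5-mm histogram grid
#'
#' Assigns lengths to the scheme's histogram classes (by default \[1, 1.5),
#' \[1.5, 2), ..., \[10.5, 11\]). Lengths below the first edge are counted in
#' the first class (the survey grid starts at 1 mm but hatchlings slightly
#' under it are still measured); lengths above the last edge are an error.
#'
#' @param length_mm Body lengths, mm.
#' @param scheme A [stage_scheme()].
#' @return Integer vector of class indices in `1:(number of classes)`.
#' @export
histogram_class <- function(length_mm, scheme = stage_scheme()) {
  check_lengths(length_mm, scheme)
  edges <- scheme$histogram_edges
  idx <- findInterval(length_mm, edges, rightmost.closed = TRUE)
  pmax(idx, 1L)
}

#' Labels of the histogram classes
#' @param scheme A [stage_scheme()].
#' @return Character vector, one label per 0.5-mm class.
#' @export
histogram_labels <- function(scheme = stage_scheme()) {
  e <- scheme$histogram_edges
  paste0(e[-length(e)], "-", e[-1])
}
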