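#' Assemble an amphipod survey
#'
#' Bundles the two-level survey data: one metadata row per sample (net haul or
#' sediment core) and one row per measured individual, keyed by sample id.
#' Net samples carry the Folsom subsample fraction and the filtered water
#' volume; core samples carry the sampled area and are never subsampled.
#'
#' @param nets Data frame with columns `sample_id`, `site`, `round`, `night`,
#'   `net`, `subsample_fraction`, `filtered_volume_m3`.
#' @param net_individuals Data frame with columns `sample_id`, `length_mm`,
#'   `sex`, `ovigerous`.
#' @param cores Data frame with columns `sample_id`, `site`, `round`, `core`,
#'   `core_area_m2`.
#' @param core_individuals As `net_individuals`, for core samples.
#' @param scheme A [stage_scheme()] used for validation and staging.
#'
#' @return An object of class `amphipod_survey`.
#' @export
survey <- function(nets, net_individuals, cores, core_individuals,
                   scheme = stage_scheme()) {
  out <- structure(
    list(nets = as.data.frame(nets),
         net_individuals = as.data.frame(net_individuals),
         cores = as.data.frame(cores),
         core_individuals = as.data.frame(core_individuals),
         scheme = scheme),
    class = "amphipod_survey"
  )
  validate_survey(out)
  out
}

#' Validate an amphipod survey
#'
#' Checks the structural invariants: positive volumes and areas, subsample
#' fractions in (0, 1], positive in-range body lengths, legal sex codes,
#' ovigery restricted to females, sexed individuals longer than the adult
#' threshold, and individuals keyed to existing samples.
#'
#' @param x An `amphipod_survey`.
#' @return `x`, invisibly; errors name the offending row.
#' @export
validate_survey <- function(x) {
  stopifnot(inherits(x, "amphipod_survey"))
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      stop(what, " table is missing column(s): ", paste(miss, collapse = ", "))
    }
  }
  need(x$nets, c("sample_id", "site", "round", "night", "net",
                 "subsample_fraction", "filtered_volume_m3"), "nets")
  need(x$cores, c("sample_id", "site", "round", "core", "core_area_m2"),
       "cores")
  need(x$net_individuals, c("sample_id", "length_mm", "sex", "ovigerous"),
       "net_individuals")
  need(x$core_individuals, c("sample_id", "length_mm", "sex", "ovigerous"),
       "core_individuals")

  if (anyDuplicated(x$nets$sample_id)) stop("duplicate net sample_id")
  if (anyDuplicated(x$cores$sample_id)) stop("duplicate core sample_id")
  f <- x$nets$subsample_fraction
  if (any(!is.finite(f) | f <= 0 | f > 1)) {
    stop("net sample ", x$nets$sample_id[which(!is.finite(f) | f <= 0 | f > 1)[1]],
         ": subsample_fraction must be in (0, 1]")
  }
  v <- x$nets$filtered_volume_m3
  if (any(!is.finite(v) | v <= 0)) {
    stop("net sample ", x$nets$sample_id[which(!is.finite(v) | v <= 0)[1]],
         ": filtered_volume_m3 must be > 0")
  }
  a <- x$cores$core_area_m2
  if (any(!is.finite(a) | a <= 0)) {
    stop("core sample ", x$cores$sample_id[which(!is.finite(a) | a <= 0)[1]],
         ": core_area_m2 must be > 0")
  }

  check_individuals <- function(ind, samples, what) {
    if (!nrow(ind)) return(invisible(TRUE))
    orphan <- !(ind$sample_id %in% samples$sample_id)
    if (any(orphan)) {
      stop(what, " row ", which(orphan)[1], " references unknown sample_id '",
           ind$sample_id[which(orphan)[1]], "'")
    }
    check_lengths(ind$length_mm, x$scheme, what = paste(what, "row"))
    if (!all(ind$sex %in% sex_levels)) {
      stop(what, ": sex must be one of ", paste(sex_levels, collapse = ", "))
    }
    if (any(ind$ovigerous & ind$sex != "female")) {
      stop(what, " row ", which(ind$ovigerous & ind$sex != "female")[1],
           ": ovigerous implies sex = female")
    }
    sexed <- ind$sex != "juvenile"
    bad <- sexed & ind$length_mm <= x$scheme$adult_threshold_mm
    if (any(bad)) {
      stop(what, " row ", which(bad)[1], ": sexed individuals must be longer ",
           "than ", x$scheme$adult_threshold_mm, " mm")
    }
    invisible(TRUE)
  }
  check_individuals(x$net_individuals, x$nets, "net_individuals")
  check_individuals(x$core_individuals, x$cores, "core_individuals")
  invisible(x)
}

#' @export
print.amphipod_survey <- function(x, ...) {
  cat("Amphipod survey\n")
  cat(sprintf("  %d net samples (%d individuals) over %d site(s) x %d round(s)\n",
              nrow(x$nets), nrow(x$net_individuals),
              length(unique(x$nets$site)), length(unique(x$nets$round))))
  cat(sprintf("  %d core samples (%d individuals)\n",
              nrow(x$cores), nrow(x$core_individuals)))
  invisible(x)
}

#' Stage predicate constructors
#'
#' Returns the standard battery of stage selectors as predicate functions on
#' an individuals table. Each predicate takes the individuals data frame plus
#' the survey's staging scheme and returns a logical vector. `"total"` keeps
#' everyone; size classes select on body length; adult selectors use the
#' derived adult stage (intersex counts as male).
#'
#' @param scheme A [stage_scheme()].
#' @return Named list of predicate functions.
#' @export
stage_predicates <- function(scheme = stage_scheme()) {
  cls <- function(ind) classify_stage(ind$length_mm, ind$sex, ind$ovigerous,
                                      scheme)
  by_class <- function(label) {
    force(label)
    function(ind) cls(ind)$size_class == label
  }
  by_stage <- function(keys) {
    force(keys)
    function(ind) {
      st <- cls(ind)$adult_stage
      !is.na(st) & st %in% keys
    }
  }
  preds <- c(
    list(total = function(ind) rep(TRUE, nrow(ind))),
    stats::setNames(lapply(scheme$size_class_labels, by_class),
                    scheme$size_class_labels),
    list(
      adult = by_stage(scheme$adult_stages),
      male = by_stage(c("male_small", "male_large")),
      male_small = by_stage("male_small"),
      male_large = by_stage("male_large"),
      female = by_stage(c("female_small", "female_large", "female_ovig")),
      female_nonovig = by_stage(c("female_small", "female_large")),
      female_small = by_stage("female_small"),
      female_large = by_stage("female_large"),
      female_ovig = by_stage("female_ovig")
    )
  )
  preds
}

count_matching <- function(individuals, samples_ids, filter) {
  if (!nrow(individuals)) {
    return(stats::setNames(numeric(length(samples_ids)), samples_ids))
  }
  keep <- if (is.null(filter)) rep(TRUE, nrow(individuals)) else
    filter(individuals)
  tab <- table(factor(individuals$sample_id[keep], levels = samples_ids))
  stats::setNames(as.numeric(tab), samples_ids)
}

#' Swimmer density per net (ind. m^-3)
#'
#' Expands the processed count by the Folsom subsample fraction and divides by
#' the volume of water filtered through the net.
#'
#' @param x An `amphipod_survey`.
#' @param filter `NULL` for all individuals, or a predicate from
#'   [stage_predicates()].
#' @return The `nets` table with `count` (subsample-expanded) and
#'   `density_m3` columns.
#' @export
net_density <- function(x, filter = NULL) {
  validate_survey(x)
  n <- count_matching(x$net_individuals, x$nets$sample_id, filter)
  out <- x$nets
  out$count <- as.numeric(n) / out$subsample_fraction
  out$density_m3 <- out$count / out$filtered_volume_m3
  out
}

#' Resident density per core (ind. m^-2)
#'
#' Cores are never subsampled; the raw count is divided by the core area.
#'
#' @inheritParams net_density
#' @return The `cores` table with `count` and `density_m2` columns.
#' @export
core_density <- function(x, filter = NULL) {
  validate_survey(x)
  n <- count_matching(x$core_individuals, x$cores$sample_id, filter)
  out <- x$cores
  out$count <- as.numeric(n)
  out$density_m2 <- out$count / out$core_area_m2
  out
}

#' Length-weight allometry parameters
#'
#' Individual dry mass is modeled as `coefficient * length_mm ^ exponent`
#' (mg). No scientific default is shipped: the coefficients must come from a
#' calibrated length-weight relationship supplied through the configuration.
#'
#' @param coefficient Mass at 1 mm, mg; must be > 0.
#' @param exponent Allometric exponent; must be > 0.
#' @return An `allometry_params` object.
#' @export
allometry_params <- function(coefficient, exponent) {
  if (missing(coefficient) || missing(exponent)) {
    stop("allometry parameters are required (no built-in scientific default)")
  }
  stopifnot(is.finite(coefficient), coefficient > 0,
            is.finite(exponent), exponent > 0)
  structure(list(coefficient = coefficient, exponent = exponent),
            class = "allometry_params")
}

#' Resident biomass per core (mg m^-2)
#'
#' Sums allometric individual masses per core and divides by the core area.
#'
#' @param x An `amphipod_survey`.
#' @param params An [allometry_params()] object.
#' @return The `cores` table with a `biomass_mg_m2` column.
#' @export
biomass_per_m2 <- function(x, params) {
  if (missing(params) || is.null(params)) {
    stop("allometry parameters are required to compute biomass")
  }
  stopifnot(inherits(params, "allometry_params"))
  validate_survey(x)
  ind <- x$core_individuals
  mass <- if (nrow(ind)) params$coefficient * ind$length_mm ^ params$exponent
          else numeric(0)
  tot <- tapply(mass, factor(ind$sample_id, levels = x$cores$sample_id), sum)
  tot[is.na(tot)] <- 0
  out <- x$cores
  out$biomass_mg_m2 <- as.numeric(tot) / out$core_area_m2
  out
}

#' Density transforms
#'
#' `log10_plus1` is the heterogeneity-correcting transform applied to density
#' responses before ANOVA; `inv_log10_plus1` is its inverse. `log10_strict`
#' is the plain log10 used for the regression inputs and refuses non-positive
#' values rather than silently offsetting them.
#'
#' @param x Numeric.
#' @return Transformed numeric vector.
#' @export
log10_plus1 <- function(x) {
  if (any(!is.finite(x) | x < 0)) stop("log10_plus1 requires x >= 0")
  log10(x + 1)
}

#' @rdname log10_plus1
#' @export
inv_log10_plus1 <- function(x) 10^x - 1

#' @rdname log10_plus1
#' @export
log10_strict <- function(x) {
  if (any(!is.finite(x) | x <= 0)) {
    stop("log10_strict requires strictly positive input; got ",
         format(x[which(!is.finite(x) | x <= 0)[1]]))
  }
  log10(x)
}

#' Site-by-round cell means
#'
#' Averages a per-sample value (net density, core density or biomass) over all
#' samples in each site-by-round cell, the analysis unit for the regression
#' and propensity analyses.
#'
#' @param samples A per-sample table holding `site`, `round` and `value_col`.
#' @param value_col Name of the column to average.
#' @return Data frame with `site`, `round` and `mean` columns.
#' @export
cell_means <- function(samples, value_col) {
  agg <- stats::aggregate(samples[[value_col]],
                          by = list(site = samples$site,
                                    round = samples$round),
                          FUN = mean)
  names(agg)[3] <- "mean"
  agg[order(agg$round, agg$site), , drop = FALSE]
}

survey_files <- c(nets = "nets.tsv", net_individuals = "net_individuals.tsv",
                  cores = "cores.tsv",
                  core_individuals = "core_individuals.tsv")

#' Read and write surveys as delimited text
#'
#' A survey is stored as four UTF-8 tab-separated tables with one-line
#' headers: per-sample metadata (`nets.tsv`, `cores.tsv`) and per-individual
#' measurements (`net_individuals.tsv`, `core_individuals.tsv`) keyed by
#' `sample_id`.
#'
#' @param x An `amphipod_survey`.
#' @param dir Directory to write to / read from.
#' @param scheme A [stage_scheme()] for validation on read.
#' @return `write_survey` returns `dir` invisibly; `read_survey` returns an
#'   `amphipod_survey`.
#' @export
write_survey <- function(x, dir) {
  validate_survey(x)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(survey_files)) {
    utils::write.table(x[[nm]], file.path(dir, survey_files[[nm]]),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
  }
  invisible(dir)
}

#' @rdname write_survey
#' @export
read_survey <- function(dir, scheme = stage_scheme()) {
  tabs <- lapply(survey_files, function(f) {
    path <- file.path(dir, f)
    if (!file.exists(path)) stop("missing survey table: ", path)
    utils::read.delim(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  })
  for (nm in c("net_individuals", "core_individuals")) {
    tabs[[nm]]$ovigerous <- as.logical(tabs[[nm]]$ovigerous)
  }
  survey(tabs$nets, tabs$net_individuals, tabs$cores, tabs$core_individuals,
         scheme = scheme)
}
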