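anova_responses <- function(scheme = stage_scheme()) {
  c("total", scheme$size_class_labels, "male", "female_nonovig",
    "female_ovig")
}

rma_responses <- anova_responses

#' ANOVA battery over density responses
#'
#' Runs the random-model ANOVA on the `log10(density + 1)`-transformed
#' per-net density of each response stage (total, the five size classes,
#' males, non-ovigerous females, ovigerous females).
#'
#' @param x An `amphipod_survey`.
#' @param responses Stage names (keys of [stage_predicates()]).
#' @return Named list of `anova_table`s.
#' @export
anova_battery <- function(x, responses = anova_responses(x$scheme)) {
  preds <- stage_predicates(x$scheme)
  out <- lapply(responses, function(resp) {
    d <- net_density(x, preds[[resp]])
    d$y <- log10_plus1(d$density_m3)
    varcomp_anova(d, "y")
  })
  stats::setNames(out, responses)
}

split_lengths_by_net <- function(x, site, round) {
  nets <- x$nets[x$nets$site == site & x$nets$round == round, ]
  ind <- x$net_individuals[x$net_individuals$sample_id %in% nets$sample_id, ]
  split(ind$length_mm, factor(ind$sample_id, levels = nets$sample_id))
}

#' Size-distribution comparisons for every site-by-round cell
#'
#' @param x An `amphipod_survey`.
#' @param B Bootstrap iterations.
#' @param seed Base seed; each cell uses `seed + cell index`.
#' @return Named list of [bootstrap_size_comparison()] results
#'   (`site:round`).
#' @export
compare_distributions <- function(x, B = 1000, seed = NULL) {
  cells <- unique(x$cores[, c("site", "round")])
  cells <- cells[order(cells$round, cells$site), ]
  out <- list()
  for (i in seq_len(nrow(cells))) {
    st <- cells$site[i]; rd <- cells$round[i]
    core_ids <- x$cores$sample_id[x$cores$site == st & x$cores$round == rd]
    res <- x$core_individuals$length_mm[
      x$core_individuals$sample_id %in% core_ids]
    swim <- split_lengths_by_net(x, st, rd)
    out[[paste(st, rd, sep = ":")]] <- bootstrap_size_comparison(
      res, swim, B = B, seed = if (is.null(seed)) NULL else seed + i,
      scheme = x$scheme
    )
  }
  out
}

adult_stage_counts <- function(individuals, scheme, weights = NULL) {
  if (!nrow(individuals)) {
    return(stats::setNames(numeric(length(scheme$adult_stages)),
                           scheme$adult_stages))
  }
  st <- classify_stage(individuals$length_mm, individuals$sex,
                       individuals$ovigerous, scheme)$adult_stage
  w <- if (is.null(weights)) rep(1, nrow(individuals)) else weights
  keep <- !is.na(st)
  tab <- tapply(w[keep], st[keep], sum)
  tab[is.na(tab)] <- 0
  stats::setNames(as.numeric(tab[scheme$adult_stages]), scheme$adult_stages)
}

#' G-tests of adult stage structure for every site-by-round cell
#'
#' Expected stage counts come from the pooled cores; observed counts pool the
#' nets over the three nights, with each swimmer weighted by the inverse
#' Folsom subsample fraction and the stage totals rounded to whole animals.
#'
#' @param x An `amphipod_survey`.
#' @return Named list of [g_test_stages()] results (`site:round`).
#' @export
stage_structure_tests <- function(x) {
  cells <- unique(x$cores[, c("site", "round")])
  cells <- cells[order(cells$round, cells$site), ]
  out <- list()
  for (i in seq_len(nrow(cells))) {
    st <- cells$site[i]; rd <- cells$round[i]
    core_ids <- x$cores$sample_id[x$cores$site == st & x$cores$round == rd]
    res <- x$core_individuals[x$core_individuals$sample_id %in% core_ids, ]
    nets <- x$nets[x$nets$site == st & x$nets$round == rd, ]
    swim <- x$net_individuals[x$net_individuals$sample_id %in%
                                nets$sample_id, ]
    wf <- 1 / nets$subsample_fraction[match(swim$sample_id, nets$sample_id)]
    expected <- adult_stage_counts(res, x$scheme)
    observed <- round(adult_stage_counts(swim, x$scheme, weights = wf))
    out[[paste(st, rd, sep = ":")]] <- g_test_stages(expected, observed)
  }
  out
}

#' Density-dependence regression table
#'
#' For each swimming response (total density and stage densities) against
#' each available measure of resident abundance (total density; biomass when
#' allometry parameters are supplied): site-by-round means are formed, both
#' sides are log10-transformed (cells with a zero swimmer mean are excluded
#' with a warning, plain log10 being undefined there), and the RMA fit with
#' both slope tests and the shape label is reported.
#'
#' @param x An `amphipod_survey`.
#' @param allometry `NULL` or [allometry_params()] enabling the biomass
#'   predictor.
#' @param responses Swimming response stages.
#' @return Data frame, one row per response x predictor.
#' @export
density_dependence_table <- function(x, allometry = NULL,
                                     responses = rma_responses(x$scheme)) {
  preds <- stage_predicates(x$scheme)
  res_density <- cell_means(core_density(x), "density_m2")
  predictors <- list(density = res_density)
  if (!is.null(allometry)) {
    predictors$biomass <- cell_means(biomass_per_m2(x, allometry),
                                     "biomass_mg_m2")
  }
  rows <- list()
  for (pred_name in names(predictors)) {
    pv <- predictors[[pred_name]]
    for (resp in responses) {
      sw <- cell_means(net_density(x, preds[[resp]]), "density_m3")
      stopifnot(identical(sw[c("site", "round")], pv[c("site", "round")]))
      usable <- sw$mean > 0 & pv$mean > 0
      if (sum(!usable)) {
        warning(sum(!usable), " cell(s) with zero mean excluded from the ",
                resp, " ~ ", pred_name, " regression")
      }
      fit <- rma_fit(log10_strict(pv$mean[usable]),
                     log10_strict(sw$mean[usable]))
      rows[[length(rows) + 1L]] <- data.frame(
        response = resp, predictor = pred_name, n = fit$n,
        slope = fit$slope, se_slope = fit$se_slope, r = fit$r,
        df0 = fit$df0, t0 = fit$t0, p0 = fit$p0,
        df1 = fit$df1, T1 = fit$T1, p1 = fit$p1, shape = fit$shape,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Patchiness table
#'
#' Variance-to-mean ratio of the site-by-round mean swimmer density and
#' resident density for each stage of the standard battery.
#'
#' @param x An `amphipod_survey`.
#' @param stages Stage keys.
#' @return Data frame: `stage`, `swim_patchiness`, `resident_patchiness`.
#' @export
patchiness_table <- function(x, stages = anova_responses(x$scheme)) {
  preds <- stage_predicates(x$scheme)
  rows <- lapply(stages, function(s) {
    sw <- cell_means(net_density(x, preds[[s]]), "density_m3")$mean
    mu <- cell_means(core_density(x, preds[[s]]), "density_m2")$mean
    data.frame(stage = s,
               swim_patchiness = suppressWarnings(patchiness(sw)),
               resident_patchiness = suppressWarnings(patchiness(mu)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

read_allometry <- function(config) {
  al <- config$allometry
  if (is.null(al)) return(NULL)
  if (inherits(al, "allometry_params")) return(al)
  allometry_params(al$coefficient, al$exponent)
}

#' Read and write survey configurations (YAML)
#'
#' @param path YAML file.
#' @param config A [survey_config()].
#' @return `read_survey_config` returns a `survey_config`;
#'   `write_survey_config` returns `path` invisibly.
#' @export
read_survey_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (nm in c("variance_components", "resident_variance",
               "dd_slope_by_stage", "overrep_multipliers",
               "juvenile_fractions", "activity_dependence")) {
    if (nm %in% names(raw)) {
      raw[nm] <- list(if (length(raw[[nm]])) unlist(raw[[nm]]) else
        stats::setNames(numeric(0), character(0)))
    }
  }
  if (!is.null(raw$length_models)) {
    raw$length_models <- lapply(raw$length_models, unlist)
  }
  do.call(survey_config, raw)
}

#' @rdname read_survey_config
#' @export
write_survey_config <- function(config, path) {
  out <- lapply(unclass(config), function(x) {
    # yaml drops names on atomic vectors; store named vectors as maps
    if (is.atomic(x) && !is.null(names(x))) as.list(x) else x
  })
  out$length_models <- lapply(out$length_models, as.list)
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

config_digest <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_survey_config(config, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the complete dispersal analysis pipeline
#'
#' Orchestrates ingest, staging, transforms and the four analyses on one
#' survey: the ANOVA battery, the per-cell size-distribution bootstraps and
#' stage-structure G-tests, the density-dependence RMA table and the
#' propensity/patchiness tables. Analyses below their sample-size thresholds
#' are reported with an explicit skipped status, never silently dropped. The
#' bundle is deterministic under `seed` and, when `out_dir` is given, is
#' written as delimited-text reports plus a run manifest (config digest,
#' seed, input digests, per-analysis statuses).
#'
#' @param x An `amphipod_survey`, or `NULL` to simulate one from `config`.
#' @param config A [survey_config()] (used for simulation, allometry and
#'   bookkeeping).
#' @param seed Integer seed for the bootstrap resampling.
#' @param B Bootstrap iterations.
#' @param out_dir Optional directory for the report bundle.
#' @return Invisibly, a list with elements `anova`, `size_comparisons`,
#'   `g_tests`, `density_dependence`, `propensity`, `patchiness`,
#'   `manifest`.
#' @export
run_all <- function(x = NULL, config = survey_config(), seed = 1L,
                    B = 1000, out_dir = NULL) {
  if (is.null(x)) x <- generate_survey(config)
  validate_survey(x)
  allometry <- read_allometry(config)

  anova_res <- anova_battery(x)
  size_cmp <- compare_distributions(x, B = B, seed = seed)
  g_tests <- stage_structure_tests(x)
  dd <- withCallingHandlers(
    density_dependence_table(x, allometry = allometry),
    warning = function(w) invokeRestart("muffleWarning")
  )
  prop <- propensity_battery(x)
  patch <- patchiness_table(x)

  statuses <- c(
    anova = "done",
    size_comparisons = sprintf("done (%d analysed, %d skipped)",
                               sum(vapply(size_cmp, function(z)
                                 z$status == "analysed", logical(1))),
                               sum(vapply(size_cmp, function(z)
                                 z$status != "analysed", logical(1)))),
    g_tests = sprintf("done (%d analysed, %d skipped)",
                      sum(vapply(g_tests, function(z)
                        z$status == "analysed", logical(1))),
                      sum(vapply(g_tests, function(z)
                        z$status != "analysed", logical(1)))),
    density_dependence = if (is.null(allometry))
      "done (biomass predictor skipped: no allometry parameters)" else "done",
    propensity = "done", patchiness = "done"
  )
  manifest <- list(
    package_version = as.character(utils::packageVersion("amphidisp")),
    seed = seed, B = B,
    config_digest = config_digest(config),
    n_net_samples = nrow(x$nets), n_core_samples = nrow(x$cores),
    statuses = as.list(statuses)
  )

  bundle <- list(anova = anova_res, size_comparisons = size_cmp,
                 g_tests = g_tests, density_dependence = dd,
                 propensity = prop, patchiness = patch, manifest = manifest)
  if (!is.null(out_dir)) write_report_bundle(bundle, x, out_dir)
  invisible(bundle)
}

flatten_size_comparisons <- function(size_cmp) {
  rows <- lapply(names(size_cmp), function(nm) {
    z <- size_cmp[[nm]]
    cell <- strsplit(nm, ":", fixed = TRUE)[[1]]
    if (z$status != "analysed") {
      return(data.frame(site = cell[1], round = cell[2], class = NA,
                        expected = NA, lower = NA, upper = NA, observed = NA,
                        flag = "not analysed", stringsAsFactors = FALSE))
    }
    cbind(site = cell[1], round = cell[2], z$table)
  })
  do.call(rbind, rows)
}

flatten_g_tests <- function(g_tests) {
  rows <- lapply(names(g_tests), function(nm) {
    z <- g_tests[[nm]]
    cell <- strsplit(nm, ":", fixed = TRUE)[[1]]
    if (z$status != "analysed") {
      return(data.frame(site = cell[1], round = cell[2], G = NA, df = NA,
                        p = NA, pooled = NA, status = z$status,
                        stringsAsFactors = FALSE))
    }
    data.frame(site = cell[1], round = cell[2], G = z$G, df = z$df, p = z$p,
               pooled = z$pooled, status = z$status, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

write_report_bundle <- function(bundle, x, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  wt <- function(df, file) {
    utils::write.table(df, file.path(out_dir, file), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  anova_flat <- do.call(rbind, lapply(names(bundle$anova), function(resp) {
    cbind(response = resp, as.data.frame(bundle$anova[[resp]]))
  }))
  wt(anova_flat, "anova.tsv")
  wt(flatten_size_comparisons(bundle$size_comparisons),
     "size_comparisons.tsv")
  wt(flatten_g_tests(bundle$g_tests), "g_tests.tsv")
  wt(bundle$density_dependence, "density_dependence.tsv")
  wt(bundle$propensity, "propensity.tsv")
  wt(bundle$patchiness, "patchiness.tsv")
  yaml::write_yaml(bundle$manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}
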