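#' Run configuration for the end-to-end analysis
#'
#' @param input path to a long-format trough table, or `NULL` to use a
#'   synthetic preset.
#' @param covariates optional path to a covariate table.
#' @param preset synthetic preset name (`"primary"` or `"sensitivity"`),
#'   used when `input` is `NULL`.
#' @param min_measurements inclusion threshold (default 3).
#' @param target_low,target_high target band in mg/L (defaults 15, 20).
#' @param stable_cv stability threshold in CV% (default 20).
#' @param sensitivity_k if non-`NULL`, additionally rerun the comparison at
#'   this relaxed threshold (conventionally 2).
#' @param stratify_loading_dose if `TRUE`, rerun the pre-cohort comparison
#'   stratified by loading-dose receipt (requires covariates).
#' @param seed integer seed (synthetic input and any resampling).
#' @param out_dir output directory; `NULL` disables file output.
#' @return A list of class `run_config`.
#' @export
run_config <- function(input = NULL, covariates = NULL, preset = "primary",
                       min_measurements = 3L, target_low = 15,
                       target_high = 20, stable_cv = 20,
                       sensitivity_k = NULL, stratify_loading_dose = FALSE,
                       seed = 1L, out_dir = NULL) {
  tv_assert(target_low < target_high, "tv_config_error",
            "target_low must be below target_high")
  tv_assert(min_measurements >= 1, "tv_config_error",
            "min_measurements must be >= 1")
  structure(as.list(environment()), class = "run_config")
}

transition_matrix_to_list <- function(tm) {
  list(counts = unname(apply(tm$counts, 1L, as.list, simplify = FALSE)),
       probabilities = unname(apply(tm$probabilities, 1L, as.list,
                                    simplify = FALSE)),
       zones = zone_levels,
       n_transitions = tm$n_transitions,
       undefined_rows = tm$undefined_rows)
}

fmt1 <- function(x) formatC(x, format = "f", digits = 1)

#' Render a comparison table as aligned text
#'
#' Display rounding follows the usual reporting style: one decimal for
#' metric levels, three for p-values, two for effect sizes. The unrounded
#' values stay in the underlying data.frame / JSON summary.
#'
#' @param tab a `comparison_table` from [build_comparison_table()].
#' @return Character vector of lines, invisibly; printed as a side effect.
#' @export
format_comparison_table <- function(tab) {
  lines <- c(sprintf("%-16s %-22s %-22s %8s %8s %6s",
                     "metric", "pre median (IQR)", "post median (IQR)",
                     "p", "r_rb", "test"))
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    if (r$test == "fisher_exact") {
      pre_s <- sprintf("%d stable", as.integer(r$pre_median))
      post_s <- sprintf("%d stable", as.integer(r$post_median))
      eff <- "-"
    } else {
      pre_s <- sprintf("%s (%s-%s)", fmt1(r$pre_median), fmt1(r$pre_q25), fmt1(r$pre_q75))
      post_s <- sprintf("%s (%s-%s)", fmt1(r$post_median), fmt1(r$post_q25), fmt1(r$post_q75))
      eff <- formatC(r$effect_size_rrb, format = "f", digits = 2)
    }
    lines <- c(lines, sprintf("%-16s %-22s %-22s %8s %8s %6s",
                              r$metric, pre_s, post_s,
                              formatC(r$p_value, format = "f", digits = 3),
                              eff, r$test))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}

#' End-to-end variability analysis
#'
#' Reproduces the full analysis structure on file or synthetic input:
#' cohort accounting before/after the inclusion filter, per-patient
#' variability profiles, the pre/post comparison table, zone distribution
#' and pooled transition matrices per cohort, exploratory covariate
#' correlations in the post cohort (when covariates are available), and
#' optional sensitivity (relaxed inclusion threshold) and loading-dose
#' stratification reruns. With a single-cohort input the comparison stages
#' are skipped and logged; independent stages always run.
#'
#' When `out_dir` is set, the bundle is written to disk: `profiles_*.csv`,
#' `comparison.csv`, `zone_distribution.csv`, `transitions_*.csv`,
#' `correlations.csv`, a machine-readable `summary.json` holding every
#' reported number unrounded, and `run.log` recording all configuration
#' values and statistical method variants used. Identical input and
#' config produce an identical `summary.json`.
#'
#' @param config a [run_config()].
#' @return The report bundle as a list (class `trough_report`), invisibly
#'   when written to disk.
#' @export
run_analysis <- function(config = run_config()) {
  tv_assert(inherits(config, "run_config"), "tv_config_error",
            "config must come from run_config()")
  log_lines <- c("troughvar run",
                 sprintf("config: %s",
                         paste(sprintf("%s=%s", names(unclass(config)),
                                       vapply(unclass(config), function(v)
                                         if (is.null(v)) "NULL" else paste(format(v), collapse = ","),
                                         "")), collapse = " ")))
  covariates <- NULL
  if (is.null(config$input)) {
    pair <- make_paper_shaped_pair(config$preset, seed = config$seed)
    cohorts <- list(pre = pair$pre$cohort, post = pair$post$cohort)
    covariates <- rbind(pair$pre$covariates, pair$post$covariates)
    log_lines <- c(log_lines, sprintf("input: synthetic preset '%s'", config$preset))
  } else {
    cohorts <- read_trough_table(config$input)
    if (!is.null(config$covariates)) covariates <- read_covariates(config$covariates)
    log_lines <- c(log_lines, sprintf("input: %s", config$input))
  }

  accounting <- lapply(names(cohorts), function(lab) {
    filt <- filter_min_measurements(cohorts[[lab]], config$min_measurements)
    rep <- attr(filt, "filter_report")
    list(label = lab, filtered = filt, report = rep)
  })
  names(accounting) <- names(cohorts)
  filtered <- lapply(accounting, `[[`, "filtered")

  profiles <- lapply(filtered, function(coh) {
    if (n_patients(coh) == 0L) return(NULL)
    profile_cohort(coh, stable_cv = config$stable_cv,
                   zone_low = config$target_low, zone_high = config$target_high)
  })
  zone_dist <- lapply(filtered, function(coh)
    if (n_measurements(coh) > 0L)
      zone_distribution(coh, config$target_low, config$target_high) else NULL)
  transitions <- lapply(filtered, function(coh)
    if (n_patients(coh) > 0L)
      pooled_transition_matrix(coh, config$target_low, config$target_high) else NULL)

  two_sample <- length(filtered) == 2L && all(vapply(profiles, NROW, 0L) > 0L)
  comparison <- NULL
  if (two_sample) {
    comparison <- build_comparison_table(profiles[[1L]], profiles[[2L]])
    log_lines <- c(log_lines, sprintf(
      "comparison: mann-whitney methods = %s",
      paste(unique(comparison$method[comparison$test == "mann_whitney"]),
            collapse = ",")))
  } else {
    log_lines <- c(log_lines,
                   "comparison: skipped (needs two cohorts with >= 1 profile each)")
  }

  correlations <- NULL
  if (!is.null(covariates) && two_sample) {
    post_lab <- names(filtered)[2L]
    correlations <- tryCatch(
      explore_predictors(profiles[[post_lab]], covariates),
      tv_insufficient_data = function(e) NULL)
  }

  sensitivity <- NULL
  if (!is.null(config$sensitivity_k)) {
    sens_filtered <- lapply(cohorts, filter_min_measurements,
                            k = config$sensitivity_k)
    sens_profiles <- lapply(sens_filtered, function(coh)
      if (n_patients(coh) > 0L)
        profile_cohort(coh, stable_cv = config$stable_cv,
                       zone_low = config$target_low,
                       zone_high = config$target_high) else NULL)
    if (length(sens_profiles) == 2L && all(vapply(sens_profiles, NROW, 0L) > 0L))
      sensitivity <- list(
        k = config$sensitivity_k,
        n_patients = vapply(sens_filtered, n_patients, 0L),
        comparison = build_comparison_table(sens_profiles[[1L]],
                                            sens_profiles[[2L]]))
  }

  stratified <- NULL
  if (isTRUE(config$stratify_loading_dose) && !is.null(covariates)) {
    stratified <- tryCatch(
      stratified_rerun(filtered[[1L]], covariates, "loading_dose_given",
                       stable_cv = config$stable_cv,
                       zone_low = config$target_low,
                       zone_high = config$target_high),
      tv_error = function(e) {
        log_lines <<- c(log_lines,
                        sprintf("stratified rerun skipped: %s", conditionMessage(e)))
        NULL
      })
  }

  report <- structure(list(
    config = unclass(config)[setdiff(names(unclass(config)), "out_dir")],
    accounting = lapply(accounting, `[[`, "report"),
    profiles = profiles,
    zone_distribution = zone_dist,
    transitions = transitions,
    comparison = comparison,
    correlations = correlations,
    sensitivity = sensitivity,
    stratified = stratified,
    log = log_lines
  ), class = "trough_report")

  if (!is.null(config$out_dir)) {
    write_report(report, config$out_dir)
    return(invisible(report))
  }
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (lab in names(report$profiles)) {
    if (!is.null(report$profiles[[lab]]))
      utils::write.csv(report$profiles[[lab]],
                       file.path(out_dir, sprintf("profiles_%s.csv", lab)),
                       row.names = FALSE)
    if (!is.null(report$zone_distribution[[lab]]))
      utils::write.csv(report$zone_distribution[[lab]],
                       file.path(out_dir, sprintf("zone_distribution_%s.csv", lab)),
                       row.names = FALSE)
    tm <- report$transitions[[lab]]
    if (!is.null(tm)) {
      utils::write.csv(as.data.frame(tm$counts),
                       file.path(out_dir, sprintf("transitions_%s.csv", lab)))
    }
  }
  if (!is.null(report$comparison))
    utils::write.csv(as.data.frame(report$comparison),
                     file.path(out_dir, "comparison.csv"), row.names = FALSE)
  if (!is.null(report$correlations))
    utils::write.csv(report$correlations,
                     file.path(out_dir, "correlations.csv"), row.names = FALSE)
  summary_list <- report_summary_list(report)
  jsonlite::write_json(summary_list, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  writeLines(report$log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

report_summary_list <- function(report) {
  list(
    config = report$config,
    accounting = report$accounting,
    zone_distribution = lapply(report$zone_distribution, function(z)
      if (is.null(z)) NULL else as.list(as.data.frame(z))),
    transitions = lapply(report$transitions, function(tm)
      if (is.null(tm)) NULL else transition_matrix_to_list(tm)),
    comparison = if (is.null(report$comparison)) NULL else
      as.list(as.data.frame(report$comparison)),
    correlations = if (is.null(report$correlations)) NULL else
      as.list(report$correlations),
    sensitivity = if (is.null(report$sensitivity)) NULL else list(
      k = report$sensitivity$k,
      n_patients = as.list(report$sensitivity$n_patients),
      comparison = as.list(as.data.frame(report$sensitivity$comparison))),
    stratified = if (is.null(report$stratified)) NULL else
      as.list(as.data.frame(report$stratified))
  )
}

#' @export
print.trough_report <- function(x, ...) {
  cat("== cohort accounting ==\n")
  for (lab in names(x$accounting)) {
    a <- x$accounting[[lab]]
    cat(sprintf("  %s: %d/%d patients, %d/%d measurements retained (k=%d)\n",
                lab, a$patients_after, a$patients_before,
                a$measurements_after, a$measurements_before, a$k))
  }
  if (!is.null(x$comparison)) {
    cat("== comparison ==\n")
    format_comparison_table(x$comparison)
  }
  for (lab in names(x$transitions)) {
    if (is.null(x$transitions[[lab]])) next
    cat(sprintf("== transitions (%s) ==\n", lab))
    print(x$transitions[[lab]])
  }
  if (!is.null(x$correlations)) {
    cat("== covariate correlations with CV% (post cohort) ==\n")
    print(x$correlations, digits = 3)
  }
  invisible(x)
}

#' Within-cohort stratified comparison
#'
#' Splits one cohort's patients by a two-level covariate (e.g. receipt of
#' a weight-based loading dose) and compares the variability profiles of
#' the two strata with the same Mann-Whitney / rank-biserial layer used
#' for the pre/post comparison. Used to check whether a between-cohort
#' difference could be an artifact of one protocol component.
#'
#' @param cohort a filtered [trough_cohort()].
#' @param covariates covariate data.frame containing `patient_id` and the
#'   stratum column.
#' @param stratum_field name of a logical or two-level column.
#' @param levels optional length-2 vector selecting/ordering the strata.
#' @param stable_cv,zone_low,zone_high profile configuration.
#' @return A `comparison_table` with attribute `"strata"` naming the two
#'   groups (first = reference).
#' @export
stratified_rerun <- function(cohort, covariates, stratum_field,
                             levels = NULL, stable_cv = 20,
                             zone_low = 15, zone_high = 20) {
  tv_assert(stratum_field %in% names(covariates), "tv_schema_error",
            sprintf("stratum field '%s' not in covariates", stratum_field))
  profiles <- profile_cohort(cohort, stable_cv = stable_cv,
                             zone_low = zone_low, zone_high = zone_high)
  merged <- merge(profiles, covariates[, c("patient_id", stratum_field)],
                  by = "patient_id")
  strat <- merged[[stratum_field]]
  if (is.null(levels)) levels <- sort(unique(strat))
  tv_assert(length(levels) == 2L, "tv_config_error",
            sprintf("stratum field '%s' must have exactly two levels, found %d",
                    stratum_field, length(unique(strat))))
  g1 <- merged[strat == levels[1L], , drop = FALSE]
  g2 <- merged[strat == levels[2L], , drop = FALSE]
  if (nrow(g1) < 2L)
    tv_error("tv_insufficient_data",
             sprintf("stratum '%s' has fewer than 2 patients", format(levels[1L])))
  if (nrow(g2) < 2L)
    tv_error("tv_insufficient_data",
             sprintf("stratum '%s' has fewer than 2 patients", format(levels[2L])))
  out <- build_comparison_table(g1, g2)
  attr(out, "strata") <- levels
  out
}
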