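#' Construct a trough cohort
#'
#' A cohort bundles the ordered trough-concentration trajectories of a set
#' of patients sharing one cohort label (typically `"pre"` or `"post"` in a
#' pre/post protocol audit). Trajectories are stored as a named list of
#' numeric vectors (mg/L), ordered by within-patient measurement number.
#'
#' @param label single cohort label.
#' @param trajectories named list of positive numeric vectors; names are
#'   patient identifiers and must be unique.
#' @return An object of class `trough_cohort` with elements `label` and
#'   `trajectories`.
#' @examples
#' coh <- trough_cohort("pre", list(p1 = c(10, 16, 22), p2 = c(18, 19)))
#' n_patients(coh)
#' @export
trough_cohort <- function(label, trajectories) {
  tv_assert(is.character(label) && length(label) == 1L && !is.na(label),
            "tv_schema_error", "cohort label must be a single string")
  tv_assert(is.list(trajectories), "tv_schema_error",
            "trajectories must be a list of numeric vectors")
  ids <- names(trajectories)
  tv_assert(!is.null(ids) && !anyDuplicated(ids) && all(nzchar(ids)),
            "tv_integrity_error", "patient ids must be unique and non-empty")
  for (id in ids) {
    x <- trajectories[[id]]
    tv_assert(is.numeric(x) && length(x) >= 1L && all(is.finite(x)) && all(x > 0),
              "tv_validation_error",
              sprintf("trajectory of patient '%s' must be positive finite mg/L values", id))
  }
  structure(list(label = label, trajectories = trajectories),
            class = "trough_cohort")
}

#' @export
print.trough_cohort <- function(x, ...) {
  cat(sprintf("<trough_cohort '%s': %d patients, %d measurements>\n",
              x$label, n_patients(x), n_measurements(x)))
  invisible(x)
}

#' Cohort size accessors
#'
#' @param cohort a [trough_cohort()].
#' @return Integer count of patients / measurements.
#' @export
n_patients <- function(cohort) length(cohort$trajectories)

#' @rdname n_patients
#' @export
n_measurements <- function(cohort) sum(lengths(cohort$trajectories))

required_cols <- c("patient_id", "cohort", "seq_index", "trough_mg_per_l")

#' Read a long-format trough table
#'
#' Reads a delimited text file with one row per trough measurement and
#' columns `patient_id, cohort, seq_index, trough_mg_per_l` (an optional
#' `timestamp` column is carried as metadata but never used for ordering;
#' administrative sampling times are not trusted). Rows are grouped by
#' patient and ordered by `seq_index`.
#'
#' @param path file path.
#' @param sep field separator; `NULL` (default) autodetects comma vs tab
#'   from the header line.
#' @param dec decimal separator, `"."` or `","`.
#' @return A named list of [trough_cohort()] objects, one per cohort label
#'   present in the file (at most two labels are allowed; the comparison
#'   layer is strictly two-sample).
#' @seealso [write_trough_table()], [filter_min_measurements()]
#' @export
read_trough_table <- function(path, sep = NULL, dec = ".") {
  tv_assert(file.exists(path), "tv_schema_error",
            sprintf("file not found: %s", path))
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, dec = dec,
                          stringsAsFactors = FALSE, colClasses = "character",
                          check.names = FALSE)
  missing <- setdiff(required_cols, names(df))
  if (length(missing))
    tv_error("tv_schema_error",
             sprintf("missing required column(s): %s", paste(missing, collapse = ", ")))
  if (dec == ",") df$trough_mg_per_l <- gsub(",", ".", df$trough_mg_per_l, fixed = TRUE)
  conc <- suppressWarnings(as.numeric(df$trough_mg_per_l))
  bad <- which(is.na(conc) | conc <= 0)
  if (length(bad))
    tv_error("tv_validation_error",
             sprintf("non-positive or non-numeric concentration in data row(s): %s",
                     paste(utils::head(bad, 5L), collapse = ", ")))
  seq_index <- suppressWarnings(as.integer(df$seq_index))
  tv_assert(!anyNA(seq_index) && all(seq_index >= 1L), "tv_validation_error",
            "seq_index must be a positive integer in every row")
  cohorts_of_patient <- tapply(df$cohort, df$patient_id,
                               function(z) length(unique(z)))
  if (any(cohorts_of_patient > 1L))
    tv_error("tv_integrity_error",
             sprintf("patient(s) appear in more than one cohort: %s",
                     paste(names(cohorts_of_patient)[cohorts_of_patient > 1L], collapse = ", ")))
  dup <- duplicated(df[c("patient_id", "seq_index")])
  if (any(dup))
    tv_error("tv_integrity_error",
             sprintf("duplicate (patient_id, seq_index) in data row(s): %s",
                     paste(which(dup), collapse = ", ")))
  labels <- unique(df$cohort)
  if (length(labels) > 2L)
    tv_error("tv_schema_error",
             sprintf("at most two cohort labels are supported, found %d (%s)",
                     length(labels), paste(labels, collapse = ", ")))
  df$.conc <- conc
  df$.seq <- seq_index
  out <- lapply(labels, function(lab) {
    sub <- df[df$cohort == lab, , drop = FALSE]
    ids <- unique(sub$patient_id)
    trajs <- lapply(ids, function(id) {
      rows <- sub[sub$patient_id == id, , drop = FALSE]
      rows$.conc[order(rows$.seq)]
    })
    names(trajs) <- ids
    trough_cohort(lab, trajs)
  })
  names(out) <- labels
  out
}

#' Write cohorts back to a tidy trough table
#'
#' Emits the validated tidy CSV schema (`patient_id, cohort, seq_index,
#' trough_mg_per_l`); `read_trough_table()` on the result round-trips to
#' value-identical cohorts.
#'
#' @param cohorts a single [trough_cohort()] or a (named) list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trough_table <- function(cohorts, path) {
  if (inherits(cohorts, "trough_cohort")) cohorts <- list(cohorts)
  rows <- lapply(cohorts, function(coh) {
    do.call(rbind, lapply(names(coh$trajectories), function(id) {
      x <- coh$trajectories[[id]]
      data.frame(patient_id = id, cohort = coh$label,
                 seq_index = seq_along(x), trough_mg_per_l = x,
                 stringsAsFactors = FALSE)
    }))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Inclusion filter: minimum number of documented troughs
#'
#' Retains exactly the trajectories with at least `k` measurements. The
#' default `k = 3` reflects the usual requirement that a per-patient
#' coefficient of variation from fewer than three points is unstable;
#' `k = 2` reproduces the common sensitivity-analysis convention.
#'
#' @param cohort a [trough_cohort()].
#' @param k minimum trajectory length, `>= 1`.
#' @return A new `trough_cohort`; the attribute `"filter_report"` carries
#'   patient and measurement counts before and after filtering. The input
#'   is not modified.
#' @export
filter_min_measurements <- function(cohort, k = 3L) {
  tv_assert(inherits(cohort, "trough_cohort"), "tv_schema_error",
            "cohort must be a trough_cohort")
  tv_assert(is.numeric(k) && length(k) == 1L && k >= 1 && k == as.integer(k),
            "tv_config_error", "k must be a positive integer")
  keep <- lengths(cohort$trajectories) >= k
  out <- cohort
  out$trajectories <- cohort$trajectories[keep]
  attr(out, "filter_report") <- list(
    k = as.integer(k),
    patients_before = n_patients(cohort),
    patients_after = sum(keep),
    measurements_before = n_measurements(cohort),
    measurements_after = sum(lengths(out$trajectories))
  )
  out
}

#' Read a per-patient covariate table
#'
#' Expected columns: `patient_id, age, sex, egfr, weight_kg, therapy_days,
#' n_dose_adjustments, loading_dose_mg_per_kg, loading_dose_given`.
#' Numeric covariates must be nonnegative where present; missing values are
#' allowed and handled pairwise downstream.
#'
#' @param path file path (CSV or TSV, autodetected).
#' @param sep field separator; `NULL` autodetects.
#' @return A data.frame with one row per patient.
#' @export
read_covariates <- function(path, sep = NULL) {
  tv_assert(file.exists(path), "tv_schema_error",
            sprintf("file not found: %s", path))
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  tv_assert("patient_id" %in% names(df), "tv_schema_error",
            "covariate table must contain a patient_id column")
  tv_assert(!anyDuplicated(df$patient_id), "tv_integrity_error",
            "duplicate patient_id in covariate table")
  num_cols <- intersect(
    c("age", "egfr", "weight_kg", "therapy_days", "n_dose_adjustments",
      "loading_dose_mg_per_kg"), names(df))
  for (cl in num_cols) {
    v <- df[[cl]]
    tv_assert(is.numeric(v) && all(v >= 0, na.rm = TRUE), "tv_validation_error",
              sprintf("covariate '%s' must be nonnegative numeric", cl))
  }
  df
}
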