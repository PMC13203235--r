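check_traj <- function(x, min_len = 2L, what = "metric") {
  tv_assert(is.numeric(x) && all(is.finite(x)) && all(x > 0),
            "tv_validation_error", "trajectory must be positive finite mg/L values")
  if (length(x) < min_len)
    tv_error("tv_insufficient_data",
             sprintf("%s requires at least %d measurements, got %d",
                     what, min_len, length(x)))
  invisible(TRUE)
}

#' Per-patient coefficient of variation (CV%)
#'
#' 100 * SD / mean of one patient's trough series. The sample standard
#' deviation (n - 1 denominator) is used by default, the convention for the
#' small per-patient series typical of inpatient TDM; set
#' `sd_denominator = "n"` for the population form in sensitivity checks.
#'
#' @param x numeric vector of trough concentrations (mg/L), length >= 2.
#' @param sd_denominator `"n-1"` (sample, default) or `"n"` (population).
#' @return CV as a percentage (dimensionless; invariant under positive
#'   rescaling of `x`).
#' @examples
#' cv_percent(c(8, 30, 8, 30))  # ~66.9: oscillating exposure
#' cv_percent(c(17, 17, 17))    # 0: perfectly stable
#' @export
cv_percent <- function(x, sd_denominator = c("n-1", "n")) {
  check_traj(x, 2L, "cv_percent")
  sd_denominator <- match.arg(sd_denominator)
  n <- length(x)
  s <- stats::sd(x)
  if (sd_denominator == "n") s <- s * sqrt((n - 1) / n)
  100 * s / mean(x)
}

#' Swing index
#'
#' (Cmax - Cmin) / Cmean: relative peak-to-trough amplitude of the series.
#' Order-insensitive and dimensionless.
#'
#' @inheritParams cv_percent
#' @return Nonnegative dimensionless value.
#' @export
swing_index <- function(x) {
  check_traj(x, 2L, "swing_index")
  (max(x) - min(x)) / mean(x)
}

#' Mean absolute successive difference
#'
#' Mean of |C\[i+1\] - C\[i\]| over consecutive measurement pairs (mg/L).
#' Order-sensitive: it captures short-term movement between adjacent
#' troughs, unlike CV% or the swing index. Note this is the mean
#' *absolute* successive difference; the squared variant common elsewhere
#' in the time-series literature is available as [mssd_squared()] and is
#' never used by the default pipeline.
#'
#' @inheritParams cv_percent
#' @return Nonnegative value in mg/L.
#' @export
mssd <- function(x) {
  check_traj(x, 2L, "mssd")
  mean(abs(diff(x)))
}

#' Mean squared successive difference (non-default variant)
#'
#' @inheritParams cv_percent
#' @return Mean of squared consecutive differences (mg^2/L^2).
#' @export
mssd_squared <- function(x) {
  check_traj(x, 2L, "mssd_squared")
  mean(diff(x)^2)
}

#' Binary stability classification
#'
#' `TRUE` iff CV% is strictly below the threshold. The 20% default is the
#' conventional TDM boundary for acceptable intra-individual variability of
#' narrow-therapeutic-index drugs; it is an exploratory descriptor, not a
#' validated clinical cut-off.
#'
#' @param cv_pct coefficient of variation in percent.
#' @param threshold stability threshold in percent (default 20).
#' @return Logical.
#' @export
stability_flag <- function(cv_pct, threshold = 20) {
  tv_assert(is.numeric(cv_pct) && all(cv_pct >= 0), "tv_validation_error",
            "cv_pct must be nonnegative")
  cv_pct < threshold
}

#' Per-patient variability profiles for a cohort
#'
#' Computes the full per-patient metric vector for every trajectory in the
#' cohort: n, mean/min/max trough, CV%, swing index, MSSD, range, number of
#' zone changes, and the binary stability flag.
#'
#' @param cohort a [trough_cohort()], already filtered to the minimum
#'   measurement count (every trajectory must have length >= 2).
#' @param stable_cv stability threshold in CV% (default 20).
#' @param zone_low,zone_high target-band boundaries in mg/L (defaults 15
#'   and 20) used for zone-change counting.
#' @param sd_denominator passed to [cv_percent()].
#' @return A data.frame of class `variability_profiles` with one row per
#'   patient and columns `patient_id, cohort, n, mean, min, max, cv_pct,
#'   swing_index, mssd, range, n_zone_changes, stable`.
#' @seealso [summarize_profiles()] for median/IQR summaries.
#' @export
profile_cohort <- function(cohort, stable_cv = 20, zone_low = 15,
                           zone_high = 20, sd_denominator = c("n-1", "n")) {
  tv_assert(inherits(cohort, "trough_cohort"), "tv_schema_error",
            "cohort must be a trough_cohort")
  sd_denominator <- match.arg(sd_denominator)
  ids <- names(cohort$trajectories)
  rows <- lapply(ids, function(id) {
    x <- cohort$trajectories[[id]]
    res <- tryCatch({
      zones <- classify_zone(x, low = zone_low, high = zone_high)
      cv <- cv_percent(x, sd_denominator)
      data.frame(
        patient_id = id, cohort = cohort$label, n = length(x),
        mean = mean(x), min = min(x), max = max(x),
        cv_pct = cv, swing_index = swing_index(x), mssd = mssd(x),
        range = max(x) - min(x),
        n_zone_changes = count_zone_changes(zones),
        stable = stability_flag(cv, stable_cv),
        stringsAsFactors = FALSE)
    }, tv_insufficient_data = function(e) {
      tv_error("tv_insufficient_data",
               sprintf("patient '%s': %s", id, conditionMessage(e)))
    })
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("variability_profiles", "data.frame")
  out
}

profile_metrics <- c("cv_pct", "swing_index", "range", "mssd",
                     "n_zone_changes", "mean")

#' Median / IQR summary of a profile table
#'
#' Quartiles use linear interpolation between order statistics (R quantile
#' type 7, the 25th/75th-percentile convention assumed throughout the
#' reporting layer).
#'
#' @param profiles a `variability_profiles` data.frame from
#'   [profile_cohort()].
#' @return A data.frame with one row per metric: `metric, median, q25, q75`,
#'   plus an `n_stable` / `n_patients` attribute pair for the stability
#'   classification.
#' @export
summarize_profiles <- function(profiles) {
  tv_assert(inherits(profiles, "data.frame") && nrow(profiles) > 0,
            "tv_insufficient_data", "profiles must be a nonempty data.frame")
  rows <- lapply(profile_metrics, function(m) {
    q <- stats::quantile(profiles[[m]], c(0.25, 0.5, 0.75), type = 7,
                         names = FALSE)
    data.frame(metric = m, median = q[2], q25 = q[1], q75 = q[3],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_stable") <- sum(profiles$stable)
  attr(out, "n_patients") <- nrow(profiles)
  out
}
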