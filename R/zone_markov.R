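zone_levels <- c("subtherapeutic", "target", "supratherapeutic")

#' Classify trough concentrations into therapeutic zones
#'
#' Three-zone classification around the target band: below `low` is
#' subtherapeutic, above `high` supratherapeutic, and both boundary values
#' are classified as target (the band is read inclusively, with the
#' peripheral zones defined by strict inequalities).
#'
#' @param conc numeric vector of concentrations (mg/L), all positive.
#' @param low,high target-band boundaries in mg/L; defaults 15 and 20.
#' @return An ordered factor with levels
#'   `subtherapeutic < target < supratherapeutic`, same length as `conc`.
#' @examples
#' classify_zone(c(14.9, 15, 20, 20.1))
#' @export
classify_zone <- function(conc, low = 15, high = 20) {
  tv_assert(is.numeric(low) && is.numeric(high) && low < high,
            "tv_config_error", "target band requires low < high")
  tv_assert(is.numeric(conc) && all(is.finite(conc)) && all(conc > 0),
            "tv_validation_error", "concentrations must be positive")
  z <- ifelse(conc < low, zone_levels[1L],
              ifelse(conc > high, zone_levels[3L], zone_levels[2L]))
  factor(z, levels = zone_levels, ordered = TRUE)
}

#' Count zone changes along one zone sequence
#'
#' Number of consecutive pairs whose zones differ. Persistence pairs (same
#' zone twice in a row) are *not* counted; this is the per-patient
#' "zone transitions" summary statistic. The pooled Markov matrix, by
#' contrast, counts *all* consecutive pairs including persistence — see
#' [pooled_transition_matrix()]. The two notions are deliberately kept
#' under distinct names.
#'
#' @param zones a factor or character vector of zone labels (one patient's
#'   ordered sequence), length >= 2.
#' @return Integer count in `0 .. length(zones) - 1`.
#' @export
count_zone_changes <- function(zones) {
  if (length(zones) < 2L)
    tv_error("tv_insufficient_data",
             "zone-change counting requires at least 2 measurements")
  z <- as.character(zones)
  sum(z[-1L] != z[-length(z)])
}

new_transition_matrix <- function(counts) {
  row_sums <- rowSums(counts)
  probs <- counts / ifelse(row_sums > 0, row_sums, NA_real_)
  structure(list(
    counts = counts,
    probabilities = probs,
    n_transitions = sum(counts),
    undefined_rows = rownames(counts)[row_sums == 0]
  ), class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("<transition_matrix: %d pooled transitions>\n", x$n_transitions))
  cat("counts:\n"); print(x$counts)
  cat("row-conditional probabilities:\n")
  print(round(x$probabilities, digits))
  if (length(x$undefined_rows))
    cat("rows with no observed departures (probabilities undefined):",
        paste(x$undefined_rows, collapse = ", "), "\n")
  invisible(x)
}

#' Pooled first-order Markov zone-transition matrix
#'
#' Concatenates all within-patient consecutive zone pairs across the cohort
#' (no pair spans two patients) into a 3x3 count matrix: rows index the
#' zone of the preceding trough, columns the zone of the following trough.
#' Persistence pairs are included, so the total transition count always
#' equals total measurements minus the number of patients. Probabilities
#' are row-conditional; a row with no observed departures is reported as
#' undefined (`NA`) and flagged, never imputed.
#'
#' Patients with longer trajectories contribute proportionally more pairs;
#' see [patient_weighted_transition_matrix()] for an opt-in weighted
#' variant that averages per-patient matrices instead.
#'
#' @param cohort a [trough_cohort()] with at least one trajectory.
#' @param low,high target-band boundaries passed to [classify_zone()].
#' @return An object of class `transition_matrix` with elements `counts`
#'   (3x3 integer), `probabilities` (3x3, rows summing to 1 where defined),
#'   `n_transitions`, and `undefined_rows`.
#' @export
pooled_transition_matrix <- function(cohort, low = 15, high = 20) {
  tv_assert(inherits(cohort, "trough_cohort"), "tv_schema_error",
            "cohort must be a trough_cohort")
  if (n_patients(cohort) == 0L)
    tv_error("tv_insufficient_data", "cannot build a transition matrix from an empty cohort")
  counts <- matrix(0L, 3L, 3L, dimnames = list(zone_levels, zone_levels))
  for (x in cohort$trajectories) {
    if (length(x) < 2L) next
    z <- as.integer(classify_zone(x, low, high))
    for (i in seq_len(length(z) - 1L))
      counts[z[i], z[i + 1L]] <- counts[z[i], z[i + 1L]] + 1L
  }
  new_transition_matrix(counts)
}

#' Patient-weighted transition matrix (beyond the pooled convention)
#'
#' Averages per-patient row-conditional transition matrices over the
#' patients that have at least one observed departure from the row zone,
#' giving each such patient equal weight regardless of trajectory length.
#' This is an extension beyond the standard pooled analysis, provided for
#' sensitivity exploration of the length-weighting inherent in pooling.
#'
#' @inheritParams pooled_transition_matrix
#' @return A list with `probabilities` (3x3 matrix of averaged
#'   row-conditional probabilities, `NA` where no patient contributes),
#'   `n_patients_per_row`, and `pooled` (the corresponding pooled matrix).
#' @export
patient_weighted_transition_matrix <- function(cohort, low = 15, high = 20) {
  tv_assert(inherits(cohort, "trough_cohort"), "tv_schema_error",
            "cohort must be a trough_cohort")
  acc <- matrix(0, 3L, 3L, dimnames = list(zone_levels, zone_levels))
  nper <- matrix(0L, 3L, 3L, dimnames = list(zone_levels, zone_levels))
  for (x in cohort$trajectories) {
    if (length(x) < 2L) next
    z <- as.integer(classify_zone(x, low, high))
    cnt <- matrix(0L, 3L, 3L)
    for (i in seq_len(length(z) - 1L)) cnt[z[i], z[i + 1L]] <- cnt[z[i], z[i + 1L]] + 1L
    rs <- rowSums(cnt)
    for (r in which(rs > 0)) {
      acc[r, ] <- acc[r, ] + cnt[r, ] / rs[r]
      nper[r, ] <- nper[r, ] + 1L
    }
  }
  probs <- acc / ifelse(nper > 0, nper, NA_real_)
  list(probabilities = probs, n_patients_per_row = nper[, 1L],
       pooled = pooled_transition_matrix(cohort, low, high))
}

#' Zone distribution of all measurements in a cohort
#'
#' Tallies every documented trough (not just transitions) by zone.
#'
#' @inheritParams pooled_transition_matrix
#' @return A data.frame `zone, count, pct` whose percentages sum to 100.
#' @export
zone_distribution <- function(cohort, low = 15, high = 20) {
  tv_assert(inherits(cohort, "trough_cohort"), "tv_schema_error",
            "cohort must be a trough_cohort")
  if (n_measurements(cohort) == 0L)
    tv_error("tv_insufficient_data", "empty cohort")
  zones <- classify_zone(unlist(cohort$trajectories, use.names = FALSE), low, high)
  counts <- as.integer(table(zones))
  data.frame(zone = zone_levels, count = counts,
             pct = 100 * counts / sum(counts), stringsAsFactors = FALSE)
}
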