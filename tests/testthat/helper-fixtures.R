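# in-code fixtures shared across test files

write_fixture_csv <- function(lines, file = tempfile(fileext = ".csv")) {
  writeLines(lines, file)
  file
}

# 2 cohorts, 3 patients: a (3 meas), b (2 meas) in pre; c (3 meas) in post
fixture_six_rows <- function() {
  write_fixture_csv(c(
    "patient_id,cohort,seq_index,trough_mg_per_l",
    "a,pre,1,10", "a,pre,3,22", "a,pre,2,16",
    "b,pre,1,14", "b,pre,2,18",
    "c,post,2,19", "c,post,1,17", "c,post,3,21"))
}

# random valid cohort built directly from numeric vectors
random_cohort <- function(n_patients, label = "pre", min_len = 2,
                          max_len = 8, lo = 5, hi = 35) {
  trajs <- lapply(seq_len(n_patients), function(i)
    stats::runif(sample(min_len:max_len, 1L), lo, hi))
  names(trajs) <- sprintf("%s_p%03d", label, seq_len(n_patients))
  trough_cohort(label, trajs)
}

# independent O(n^2) oracle for the rank-biserial / Cliff's delta form
cliffs_delta_oracle <- function(a, b) {
  gt <- 0; lt <- 0
  for (x in a) for (y in b) {
    if (y > x) gt <- gt + 1
    if (x > y) lt <- lt + 1
  }
  (gt - lt) / (length(a) * length(b))
}

# exact Mann-Whitney two-sided p by full enumeration of group labelings
mw_enumeration_oracle <- function(a, b) {
  pooled <- c(a, b)
  n_a <- length(a)
  combos <- utils::combn(length(pooled), n_a)
  u_all <- apply(combos, 2L, function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n_a * (n_a + 1) / 2
  })
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  min(1, p)
}
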