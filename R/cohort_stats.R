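mw_u_stats <- function(a, b) {
  # U via midranks: U_a counts pairs with a > b, ties half credit
  n_a <- length(a); n_b <- length(b)
  r <- rank(c(a, b))
  u_a <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  list(u_a = u_a, u_b = n_a * n_b - u_a, n_a = n_a, n_b = n_b)
}

#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum comparison of two independent samples. When both samples are
#' tie-free and `n_a * n_b <= exact_limit`, the p-value is computed from
#' the exact null distribution of U; otherwise a normal approximation with
#' tie correction and continuity correction is used. The method actually
#' used is always part of the result, since exact and asymptotic p-values
#' can differ at small n.
#'
#' @param a,b numeric samples (nonempty).
#' @param exact_limit switch to the asymptotic method when `n_a * n_b`
#'   exceeds this bound (default 400) or when ties are present.
#' @return A list with `u_statistic` (U for sample `a`: number of (a, b)
#'   pairs with a > b, ties counting one half), `p_value`, `method`
#'   (`"exact"` or `"normal_approx"`), and the sample sizes.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mann_whitney <- function(a, b, exact_limit = 400) {
  tv_assert(is.numeric(a) && length(a) >= 1 && is.numeric(b) && length(b) >= 1,
            "tv_insufficient_data", "both samples must be nonempty numeric vectors")
  s <- mw_u_stats(a, b)
  ties <- anyDuplicated(c(a, b)) > 0
  if (!ties && s$n_a * s$n_b <= exact_limit) {
    u <- s$u_a  # integer when tie-free
    p <- 2 * min(stats::pwilcox(u, s$n_a, s$n_b),
                 1 - stats::pwilcox(u - 1, s$n_a, s$n_b))
    method <- "exact"
  } else {
    n <- s$n_a + s$n_b
    t_tab <- table(c(a, b))
    tie_term <- sum(t_tab^3 - t_tab) / (n * (n - 1))
    sigma2 <- s$n_a * s$n_b / 12 * ((n + 1) - tie_term)
    mu <- s$n_a * s$n_b / 2
    d <- s$u_a - mu
    z <- if (sigma2 <= 0) 0 else (d - sign(d) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal_approx"
  }
  list(u_statistic = s$u_a, p_value = min(1, p), method = method,
       n_a = s$n_a, n_b = s$n_b)
}

#' Rank-biserial correlation (Cliff's delta form)
#'
#' Nonparametric effect size for the two-sample comparison:
#' `(#pairs with b > a - #pairs with a > b) / (n_a * n_b)`, ties
#' contributing zero. With `a` the reference (pre) sample and `b` the
#' comparison (post) sample, the value is negative when `b` is
#' stochastically smaller — i.e. lower values in the post cohort give a
#' negative effect size. Equivalent to `2 * U_b / (n_a n_b) - 1` with
#' half-credit ties.
#'
#' @param a reference sample (e.g. pre-protocol cohort).
#' @param b comparison sample (e.g. post-protocol cohort).
#' @return Value in `[-1, 1]`.
#' @export
rank_biserial <- function(a, b) {
  tv_assert(is.numeric(a) && length(a) >= 1 && is.numeric(b) && length(b) >= 1,
            "tv_insufficient_data", "both samples must be nonempty numeric vectors")
  s <- mw_u_stats(a, b)
  (s$u_b - s$u_a) / (s$n_a * s$n_b)
}

#' Fisher's exact test for a 2x2 table (two-sided)
#'
#' Deterministic two-sided p-value by the point-probability method: with
#' margins fixed, the hypergeometric probabilities of all tables no more
#' probable than the observed one are summed (a relative tolerance of
#' 1e-7 guards against floating-point ties, matching common statistical
#' software).
#'
#' @param tab 2x2 matrix of nonnegative integer counts; rows are groups,
#'   columns outcome categories.
#' @return A list with `p_value` and the observed table.
#' @examples
#' fisher_exact_2x2(matrix(c(5, 46, 3, 14), 2, 2, byrow = TRUE))  # ~0.402
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  tv_assert(all(dim(tab) == c(2L, 2L)), "tv_validation_error", "table must be 2x2")
  tv_assert(is.numeric(tab) && all(tab >= 0) && all(tab == round(tab)),
            "tv_validation_error", "cells must be nonnegative integers")
  m <- sum(tab[, 1L]); n <- sum(tab[, 2L]); k <- sum(tab[1L, ])
  tv_assert(sum(tab) > 0, "tv_validation_error", "table must have a positive total")
  x <- tab[1L, 1L]
  support <- max(0L, k - n):min(k, m)
  dens <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(x, m, n, k)
  p <- sum(dens[dens <= p_obs * (1 + 1e-7)])
  list(p_value = min(1, p), table = tab)
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L), deparse.level = 0)
  }))
}

#' Spearman rank correlation
#'
#' Correlation of mid-ranks (Pearson correlation of average ranks, so ties
#' are handled naturally). The default two-sided p-value uses the
#' t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2
#' degrees of freedom; `method = "exact"` enumerates all rank permutations
#' (feasible up to n = 8; beyond that the approximation is used and
#' reported). Incomplete pairs are dropped (pairwise-complete).
#'
#' @param x,y numeric vectors of equal length; at least 3 complete pairs
#'   are required for a p-value.
#' @param method `"approx"` (default) or `"exact"`.
#' @return A list with `rho`, `p_value`, `n_pairs`, and `method`.
#' @export
spearman_rho <- function(x, y, method = c("approx", "exact")) {
  method <- match.arg(method)
  tv_assert(length(x) == length(y), "tv_validation_error",
            "x and y must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  tv_assert(n >= 3, "tv_insufficient_data",
            "at least 3 complete pairs are required")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    tv_error("tv_insufficient_data", "a variable with all-tied values has no rank correlation")
  rho <- stats::cor(rx, ry)
  if (method == "exact" && n <= 8L) {
    perms <- all_permutations(n)
    rhos <- apply(perms, 1L, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    used <- "exact_permutation"
  } else {
    if (abs(rho) >= 1) {
      p <- .Machine$double.xmin
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
    used <- "t_approx"
  }
  list(rho = rho, p_value = min(1, max(p, .Machine$double.xmin)),
       n_pairs = n, method = used)
}

#' Cohort comparison table of variability metrics
#'
#' Builds the standard pre/post comparison: one row per continuous metric
#' (CV%, swing index, range, MSSD, zone changes, mean trough) with median
#' and IQR per cohort, Mann-Whitney U, two-sided p, and rank-biserial
#' effect size (negative = lower in the post cohort); plus one row for the
#' binary stability classification tested with Fisher's exact test.
#' No multiplicity correction is applied by default (the comparisons are
#' reported raw, for reader interpretation); `holm = TRUE` appends a
#' Holm-adjusted column as a clearly non-default extra.
#'
#' A Shapiro-Wilk normality p-value per metric and cohort is attached as
#' the `"normality"` attribute for information only; it never changes
#' which test is run.
#'
#' @param pre,post `variability_profiles` data.frames from
#'   [profile_cohort()] computed under identical configuration.
#' @param exact_limit passed to [mann_whitney()].
#' @param holm if `TRUE`, append Holm-adjusted p-values.
#' @return A data.frame of class `comparison_table`: `metric, pre_median,
#'   pre_q25, pre_q75, post_median, post_q25, post_q75, u_statistic,
#'   p_value, effect_size_rrb, test, method`. The stability row carries
#'   counts in the median columns (`NA` quartiles) and `test = "fisher_exact"`.
#' @export
build_comparison_table <- function(pre, post, exact_limit = 400, holm = FALSE) {
  tv_assert(inherits(pre, "data.frame") && nrow(pre) > 0 &&
              inherits(post, "data.frame") && nrow(post) > 0,
            "tv_insufficient_data", "both cohorts must have at least one profile")
  rows <- lapply(profile_metrics, function(m) {
    a <- pre[[m]]; b <- post[[m]]
    qa <- stats::quantile(a, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    qb <- stats::quantile(b, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    mw <- mann_whitney(a, b, exact_limit)
    data.frame(metric = m,
               pre_median = qa[2], pre_q25 = qa[1], pre_q75 = qa[3],
               post_median = qb[2], post_q25 = qb[1], post_q75 = qb[3],
               u_statistic = mw$u_statistic, p_value = mw$p_value,
               effect_size_rrb = rank_biserial(a, b),
               test = "mann_whitney", method = mw$method,
               stringsAsFactors = FALSE)
  })
  tab2 <- matrix(c(sum(pre$stable), sum(!pre$stable),
                   sum(post$stable), sum(!post$stable)), 2L, 2L, byrow = TRUE)
  fe <- fisher_exact_2x2(tab2)
  rows[[length(rows) + 1L]] <- data.frame(
    metric = "stable_patients",
    pre_median = sum(pre$stable), pre_q25 = NA_real_, pre_q75 = NA_real_,
    post_median = sum(post$stable), post_q25 = NA_real_, post_q75 = NA_real_,
    u_statistic = NA_real_, p_value = fe$p_value,
    effect_size_rrb = NA_real_, test = "fisher_exact", method = "exact",
    stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (holm) out$p_holm <- stats::p.adjust(out$p_value, method = "holm")
  norm <- do.call(rbind, lapply(profile_metrics, function(m) {
    sw <- function(v) if (length(unique(v)) > 2 && length(v) >= 3 && length(v) <= 5000)
      stats::shapiro.test(v)$p.value else NA_real_
    data.frame(metric = m, pre_shapiro_p = sw(pre[[m]]),
               post_shapiro_p = sw(post[[m]]), stringsAsFactors = FALSE)
  }))
  attr(out, "normality") <- norm
  attr(out, "stable_table") <- tab2
  class(out) <- c("comparison_table", "data.frame")
  out
}

default_covariates <- c("age", "egfr", "weight_kg", "therapy_days",
                        "loading_dose_mg_per_kg", "n_dose_adjustments")

#' Exploratory covariate correlations with patient-level CV%
#'
#' Joins the profile table with the per-patient covariate table on
#' `patient_id` and reports a Spearman correlation of each covariate with
#' CV%. Patients missing from either table are dropped with a warning
#' giving the count. These are univariate, uncorrected, exploratory
#' associations.
#'
#' @param profiles a `variability_profiles` data.frame.
#' @param covariates data.frame as returned by [read_covariates()].
#' @param covariate_set character vector of covariate columns to test;
#'   defaults to age, eGFR, weight, therapy duration, loading dose and
#'   number of dose adjustments. Columns absent from `covariates` are
#'   skipped silently.
#' @param method passed to [spearman_rho()].
#' @return A data.frame `covariate, rho, p_value, n_pairs, method`.
#' @export
explore_predictors <- function(profiles, covariates,
                               covariate_set = default_covariates,
                               method = c("approx", "exact")) {
  method <- match.arg(method)
  merged <- merge(profiles[, c("patient_id", "cv_pct")], covariates,
                  by = "patient_id")
  n_lost <- nrow(profiles) - nrow(merged)
  if (nrow(merged) == 0L)
    tv_error("tv_insufficient_data", "no patients matched between profiles and covariates")
  if (n_lost > 0L)
    warning(sprintf("%d patient(s) without matching covariates dropped", n_lost))
  covariate_set <- intersect(covariate_set, names(merged))
  rows <- lapply(covariate_set, function(cv) {
    res <- tryCatch(spearman_rho(merged[[cv]], merged$cv_pct, method = method),
                    tv_insufficient_data = function(e) NULL)
    if (is.null(res)) return(NULL)
    data.frame(covariate = cv, rho = res$rho, p_value = res$p_value,
               n_pairs = res$n_pairs, method = res$method,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) tv_error("tv_insufficient_data", "no testable covariates")
  rownames(out) <- NULL
  out
}
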