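test_that("mann_whitney matches frozen small cases and reports its method", {
  res <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$u_statistic, 0)
  expect_equal(res$p_value, 0.1)  # 2/20 labelings as extreme
  expect_equal(res$method, "exact")
  # identical samples: p ~ 1 under the tie-corrected approximation
  res2 <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res2$method, "normal_approx")  # ties force the approximation
  expect_gte(res2$p_value, 0.99)
  expect_equal(rank_biserial(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_error(mann_whitney(numeric(0), 1), class = "tv_insufficient_data")
})

test_that("exact p agrees with the full enumeration oracle (tie-free, n <= 8)", {
  set.seed(81)
  sizes <- expand.grid(n_a = 2:8, n_b = 2:8)
  for (i in seq_len(nrow(sizes))) {
    x <- runif(sizes$n_a[i]); y <- runif(sizes$n_b[i])
    expect_equal(mann_whitney(x, y)$p_value, mw_enumeration_oracle(x, y),
                 tolerance = 1e-12,
                 info = sprintf("n_a=%d n_b=%d", sizes$n_a[i], sizes$n_b[i]))
  }
})

test_that("normal approximation tracks the exact p within 0.02 at n = 8 + 8", {
  set.seed(91)
  for (i in 1:40) {
    x <- rnorm(8); y <- rnorm(8, sample(c(0, 1), 1))
    p_exact <- mann_whitney(x, y, exact_limit = 400)$p_value
    p_approx <- mann_whitney(x, y, exact_limit = 0)$p_value
    expect_lt(abs(p_exact - p_approx), 0.02)
  }
})

test_that("rank_biserial matches the all-pairs Cliff's delta oracle", {
  expect_equal(rank_biserial(c(1, 2, 3), c(4, 5, 6)), 1)
  expect_equal(rank_biserial(c(4, 5, 6), c(1, 2, 3)), -1)
  set.seed(101)
  for (i in 1:50) {
    a <- sample(1:10, sample(2:12, 1), replace = TRUE)  # ties likely
    b <- sample(1:10, sample(2:12, 1), replace = TRUE)
    r <- rank_biserial(a, b)
    expect_equal(r, cliffs_delta_oracle(a, b), tolerance = 1e-12)
    expect_lte(abs(r), 1)
    # consistency with U: r = 2 U_b / (n_a n_b) - 1
    u_a <- mann_whitney(a, b)$u_statistic
    u_b <- length(a) * length(b) - u_a
    expect_equal(r, 2 * u_b / (length(a) * length(b)) - 1, tolerance = 1e-12)
  }
})

test_that("fisher_exact_2x2 reproduces the two-sided point-probability p", {
  expect_equal(round(fisher_exact_2x2(
    matrix(c(5, 46, 3, 14), 2, byrow = TRUE))$p_value, 3), 0.402)
  expect_equal(fisher_exact_2x2(matrix(c(0, 10, 0, 10), 2, byrow = TRUE))$p_value, 1)
  expect_error(fisher_exact_2x2(matrix(c(-1, 2, 3, 4), 2)),
               class = "tv_validation_error")
  # equality with the established reference implementation across random tables
  set.seed(111)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 8), 2, 2)
    if (sum(tab) == 0) next
    expect_equal(fisher_exact_2x2(tab)$p_value,
                 stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
  # two-sided p >= one-sided p (hypergeometric tail)
  tab <- matrix(c(5, 46, 3, 14), 2, byrow = TRUE)
  p_one <- stats::phyper(tab[1, 1], sum(tab[, 1]), sum(tab[, 2]), sum(tab[1, ]))
  expect_gte(fisher_exact_2x2(tab)$p_value, min(p_one, 1 - p_one))
})

test_that("spearman_rho handles monotone, tied and degenerate input", {
  x <- 1:10
  expect_equal(spearman_rho(x, x + 3)$rho, 1)
  expect_equal(spearman_rho(x, rev(x))$rho, -1)
  expect_true(spearman_rho(x, rev(x))$p_value > 0)
  expect_error(spearman_rho(1:4, 1:5), class = "tv_validation_error")
  expect_error(spearman_rho(1:2, 1:2), class = "tv_insufficient_data")
  expect_error(spearman_rho(rep(1, 5), 1:5), class = "tv_insufficient_data")
  # pairwise-complete handling
  res <- spearman_rho(c(1, 2, NA, 4, 5), c(2, 1, 3, 8, 10))
  expect_equal(res$n_pairs, 4L)
  # tied data equals the rank-Pearson oracle
  set.seed(121)
  for (i in 1:25) {
    x <- sample(1:6, 12, replace = TRUE)
    y <- sample(1:6, 12, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(spearman_rho(x, y)$rho, cor(rank(x), rank(y)), tolerance = 1e-12)
  }
})

test_that("exact permutation p for Spearman matches naive enumeration at n = 5", {
  set.seed(131)
  x <- runif(5); y <- runif(5)
  res <- spearman_rho(x, y, method = "exact")
  expect_equal(res$method, "exact_permutation")
  # naive oracle over all 120 permutations
  perms <- expand.grid(rep(list(1:5), 5))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 5), ]
  rhos <- apply(perms, 1, function(p) cor(rank(x), rank(y)[unlist(p)]))
  expect_equal(res$p_value, mean(abs(rhos) >= abs(res$rho) - 1e-12),
               tolerance = 1e-12)
})

test_that("comparison table layout, symmetry, and separation behaviour", {
  set.seed(141)
  coh <- random_cohort(12, "pre", min_len = 3)
  p <- profile_cohort(coh)
  tab_same <- build_comparison_table(p, transform(p, cohort = "post"))
  cont <- tab_same[tab_same$test == "mann_whitney", ]
  expect_equal(cont$effect_size_rrb, rep(0, nrow(cont)))
  expect_true(all(tab_same$p_value >= 0.99))
  expect_equal(tab_same$metric,
               c("cv_pct", "swing_index", "range", "mssd", "n_zone_changes",
                 "mean", "stable_patients"))
  # strict separation: every post metric below every pre metric => r_rb = -1
  pre_sep <- p
  post_sep <- p
  for (m in c("cv_pct", "swing_index", "range", "mssd", "n_zone_changes", "mean"))
    post_sep[[m]] <- pre_sep[[m]] / 1000 - 1000
  tab_sep <- build_comparison_table(pre_sep, post_sep)
  cont <- tab_sep[tab_sep$test == "mann_whitney", ]
  expect_equal(cont$effect_size_rrb, rep(-1, nrow(cont)))
  # stable-patient row goes through Fisher's exact test
  expect_equal(tab_same$test[tab_same$metric == "stable_patients"], "fisher_exact")
  # Holm column is optional and ordered correctly
  tab_h <- build_comparison_table(p, transform(p, cohort = "post"), holm = TRUE)
  expect_true(all(tab_h$p_holm >= tab_h$p_value))
  expect_error(build_comparison_table(p[0, ], p), class = "tv_insufficient_data")
})

test_that("stable-patient Fisher row reproduces the 2x2 construction", {
  # cohorts engineered to 5/51 and 3/17 stable
  mk <- function(label, n, n_stable) {
    stable_traj <- c(17, 17.5, 18)        # CV ~ 1.5% < 20
    wild_traj <- c(8, 30, 8, 30)          # CV ~ 67%
    trajs <- c(replicate(n_stable, stable_traj, simplify = FALSE),
               replicate(n - n_stable, wild_traj, simplify = FALSE))
    names(trajs) <- sprintf("%s%02d", label, seq_len(n))
    trough_cohort(label, trajs)
  }
  pre <- profile_cohort(mk("pre", 51, 5))
  post <- profile_cohort(mk("post", 17, 3))
  tab <- build_comparison_table(pre, post)
  expect_equal(attr(tab, "stable_table"),
               matrix(c(5, 46, 3, 14), 2, byrow = TRUE))
  expect_equal(round(tab$p_value[tab$metric == "stable_patients"], 3), 0.402)
})

test_that("explore_predictors joins, warns on unmatched, and recovers signals", {
  set.seed(151)
  coh <- random_cohort(40, min_len = 4)
  p <- profile_cohort(coh)
  cov <- data.frame(patient_id = p$patient_id[1:35],
                    age = p$cv_pct[1:35],          # identical -> rho = 1
                    egfr = rnorm(35))
  expect_warning(res <- explore_predictors(p, cov), "5 patient")
  expect_equal(res$rho[res$covariate == "age"], 1)
  expect_lte(max(abs(res$rho)), 1)
  expect_error(explore_predictors(p, data.frame(patient_id = "zzz", age = 1)),
               class = "tv_insufficient_data")
})

test_that("independent covariates show near-zero rho at large n", {
  set.seed(161)
  n <- 1000
  profiles <- data.frame(patient_id = sprintf("p%04d", 1:n),
                         cv_pct = rlnorm(n, log(40), 0.3))
  cov <- data.frame(patient_id = profiles$patient_id, age = rnorm(n))
  res <- explore_predictors(profiles, cov)
  expect_lt(abs(res$rho), 0.1)
})
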