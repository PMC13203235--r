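test_that("zone classification uses an inclusive target band", {
  z <- classify_zone(c(14.9, 15, 17.5, 20, 20.1))
  expect_equal(as.character(z),
               c("subtherapeutic", "target", "target", "target", "supratherapeutic"))
  expect_true(is.ordered(z))
  # configurable band
  expect_equal(as.character(classify_zone(14.5, low = 10, high = 14)),
               "supratherapeutic")
  expect_error(classify_zone(10, low = 20, high = 15), class = "tv_config_error")
  expect_error(classify_zone(-1), class = "tv_validation_error")
})

test_that("zone-change counting ignores persistence pairs", {
  expect_equal(count_zone_changes(c("s", "S", "s", "S")), 3)
  expect_equal(count_zone_changes(rep("target", 5)), 0)
  expect_equal(count_zone_changes(c("sub", "sub", "target", "target", "target")), 1)
  expect_error(count_zone_changes("sub"), class = "tv_insufficient_data")
  # changes + persistence pairs = consecutive pairs
  set.seed(51)
  for (i in 1:20) {
    z <- sample(c("a", "b", "c"), sample(2:10, 1), replace = TRUE)
    persist <- sum(z[-1] == z[-length(z)])
    expect_equal(count_zone_changes(z) + persist, length(z) - 1L)
  }
})

test_that("pooled matrix counts all consecutive pairs incl. persistence", {
  coh <- trough_cohort("pre", list(p1 = c(17, 18, 19)))  # all target
  tm <- pooled_transition_matrix(coh)
  expect_equal(tm$n_transitions, 2L)
  expect_equal(tm$counts["target", "target"], 2L)
  expect_equal(sum(tm$counts), 2L)
  expect_equal(unname(tm$probabilities["target", ]), c(0, 1, 0))
  # rows with no departures are flagged undefined, not imputed
  expect_setequal(tm$undefined_rows, c("subtherapeutic", "supratherapeutic"))
  expect_true(all(is.na(tm$probabilities["subtherapeutic", ])))
  expect_error(pooled_transition_matrix(trough_cohort("x", setNames(list(), character(0)))),
               class = "tv_insufficient_data")
})

test_that("transition identity and row-stochasticity hold on random cohorts", {
  set.seed(61)
  for (i in 1:10) {
    coh <- random_cohort(sample(3:25, 1))
    tm <- pooled_transition_matrix(coh)
    # identity: pooled transitions = measurements - patients
    expect_equal(tm$n_transitions, n_measurements(coh) - n_patients(coh))
    rs <- rowSums(tm$counts)
    for (r in rownames(tm$counts)) {
      if (rs[r] > 0) {
        expect_equal(sum(tm$probabilities[r, ]), 1, tolerance = 1e-12)
      } else {
        expect_true(r %in% tm$undefined_rows)
      }
    }
    expect_equal(tm$probabilities[rs > 0, , drop = FALSE] * rs[rs > 0],
                 tm$counts[rs > 0, , drop = FALSE] * 1.0, ignore_attr = TRUE)
  }
})

test_that("zone distribution tallies all measurements and is consistent with the matrix", {
  coh <- trough_cohort("pre", list(p1 = c(10, 17, 25, 18)))
  zd <- zone_distribution(coh)
  expect_equal(zd$count, c(1L, 2L, 1L))
  expect_equal(zd$pct, c(25, 50, 25))
  expect_equal(sum(zd$pct), 100)
  # all-target cohort
  zd2 <- zone_distribution(trough_cohort("x", list(a = c(16, 17), b = c(18, 19))))
  expect_equal(zd2$pct, c(0, 100, 0))
  # consistency: column marginals of the matrix + first-measurement zones
  # equal the full tally (brute-force oracle over the flattened list)
  set.seed(71)
  for (i in 1:5) {
    coh <- random_cohort(sample(3:15, 1))
    zd <- zone_distribution(coh)
    flat <- unlist(coh$trajectories, use.names = FALSE)
    oracle <- c(sum(flat < 15), sum(flat >= 15 & flat <= 20), sum(flat > 20))
    expect_equal(zd$count, oracle)
    tm <- pooled_transition_matrix(coh)
    firsts <- vapply(coh$trajectories, `[`, 0, 1L)
    first_zones <- table(classify_zone(firsts))
    expect_equal(unname(colSums(tm$counts) + as.integer(first_zones)), zd$count)
  }
})

test_that("patient-weighted variant equals pooled for equal-length single rows", {
  # two patients, same trajectory: weighted and pooled must agree
  coh <- trough_cohort("pre", list(a = c(10, 17, 25), b = c(10, 17, 25)))
  pw <- patient_weighted_transition_matrix(coh)
  pooled <- pooled_transition_matrix(coh)
  defined <- rowSums(pooled$counts) > 0
  expect_equal(pw$probabilities[defined, ], pooled$probabilities[defined, ],
               tolerance = 1e-12)
  # unequal lengths: the weighted variant removes length weighting
  coh2 <- trough_cohort("pre", list(
    long = c(10, 10, 10, 10, 10, 17),  # mostly sub->sub, one sub->target
    short = c(10, 17)))                # one sub->target
  pw2 <- patient_weighted_transition_matrix(coh2)
  pooled2 <- pooled_transition_matrix(coh2)
  # pooled: sub->target = 2/6; weighted: mean(1/5, 1) = 0.6
  expect_equal(pooled2$probabilities["subtherapeutic", "target"], 2 / 6)
  expect_equal(pw2$probabilities["subtherapeutic", "target"], mean(c(1 / 5, 1)))
})
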