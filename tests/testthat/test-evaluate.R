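test_that("Wilson interval matches the closed form and its oracle", {
  ci <- wilson_interval(50, 100)
  expect_equal(mean(ci), 0.5) # symmetric at p-hat = 0.5
  expect_equal(unname(wilson_interval(0, 10)[1]), 0)

  # independent oracle: the score interval from prop.test without correction
  for (case in list(c(8, 10), c(1, 50), c(30, 40), c(499, 500))) {
    ours <- wilson_interval(case[1], case[2])
    ref <- stats::prop.test(case[1], case[2], correct = FALSE)$conf.int
    expect_equal(unname(ours), as.numeric(ref), tolerance = 1e-9)
  }
  expect_error(wilson_interval(1, 0), "positive")
  expect_error(wilson_interval(5, 3), "0 <= n_success <= n")
})

test_that("branch probabilities on homogeneous cohorts are exact", {
  coh <- manual_cohort(10, true_age = 20, clavicle_stage = 4L, i3m = 0)
  bp <- estimate_branch_probabilities(coh)
  row <- bp$leaves[bp$leaves$branch == "clavicle_mature", ]
  expect_equal(row$n, 10)
  expect_equal(row$p_hat, 1)

  empty <- estimate_branch_probabilities(manual_cohort(0, numeric()))
  expect_equal(nrow(empty$leaves), 0)

  # no assessable molar anywhere: no I3M-band rows can appear
  coh2 <- manual_cohort(12, true_age = 19, clavicle_stage = 2L,
                        molar_assessable = FALSE)
  bp2 <- estimate_branch_probabilities(coh2)
  expect_false(any(grepl("^i3m_", bp2$leaves$branch)))
})

test_that("leaf counts partition the cohort and p-hat sits inside its interval", {
  coh <- simulate_cohort(simulator_config(), n = 4000, seed = 9)
  bp <- estimate_branch_probabilities(coh)
  expect_equal(sum(bp$leaves$n), nrow(coh))
  expect_true(all(bp$leaves$ci_low <= bp$leaves$p_hat + 1e-12))
  expect_true(all(bp$leaves$p_hat <= bp$leaves$ci_high + 1e-12))
})

test_that("Wilson intervals shrink as the branch sample grows", {
  coh <- simulate_cohort(simulator_config(), n = 8000, seed = 25)
  small <- estimate_branch_probabilities(coh[seq_len(1000), ])
  large <- estimate_branch_probabilities(coh)
  for (b in intersect(small$leaves$branch, large$leaves$branch)) {
    ws <- with(small$leaves[small$leaves$branch == b, ], ci_high - ci_low)
    wl <- with(large$leaves[large$leaves$branch == b, ], ci_high - ci_low)
    expect_lte(wl, ws)
  }
})

test_that("the clavicle-below-stage-4 marginal is reported alongside the leaves", {
  coh <- simulate_cohort(simulator_config(), n = 4000, seed = 9)
  bp <- estimate_branch_probabilities(coh)
  m <- bp$clavicle_below_stage4
  expect_false(is.null(m))
  expect_false(m$branch %in% bp$leaves$branch)
  expect_equal(m$n, sum(coh$clavicle_stage < 4))
  expect_equal(m$paper_value_percent, 46)
})

test_that("misclassification accounting flags only minors declared adult", {
  young <- manual_cohort(20, true_age = 15, clavicle_stage = 1L, i3m = 0.4,
                         teeth_closed = FALSE, tanner = 3L)
  r <- misclassification_report(young)
  expect_equal(r$minor_as_adult, 0)

  fused_adults <- manual_cohort(15, true_age = 20, clavicle_stage = 5L, i3m = 0)
  r2 <- misclassification_report(fused_adults)
  expect_equal(r2$adult_as_minor, 0)
  expect_equal(r2$minor_as_adult, 0)

  # a 17-year-old on the 96-percent branch is a flagged minor-as-adult case
  edge <- manual_cohort(1, true_age = 17.5, clavicle_stage = 2L, i3m = 0.05)
  r3 <- misclassification_report(edge)
  expect_equal(r3$minor_as_adult, 1)
  expect_equal(r3$minor_as_adult_subjects$branch, "i3m_low_clavicle_immature")
})

test_that("cohort summary cross-foots and has the published table shape", {
  coh <- simulate_cohort(simulator_config(), n = 2000, seed = 3)
  cs <- cohort_summary_table(coh)
  expect_identical(unname(cs$totals), unname(colSums(cs$counts)))
  expect_identical(colnames(cs$counts),
                   c("hand_m", "hand_f", "teeth_m", "teeth_f",
                     "molar_m", "molar_f", "clavicle_m", "clavicle_f"))
  # molar columns exclude unassessable molars
  expect_equal(sum(cs$counts[, c("molar_m", "molar_f")]),
               sum(coh$molar_assessable))
  expect_equal(sum(cs$counts[, c("teeth_m", "teeth_f")]), nrow(coh))

  empty <- cohort_summary_table(manual_cohort(0, numeric()))
  expect_identical(sum(empty$totals), 0L)
})
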