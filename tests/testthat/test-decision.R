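test_that("the four canonical branches reproduce the published probabilities", {
  o1 <- classify(canonical_subject(i3m = 0.05, clavicle_stage = 4))
  expect_equal(o1$classification, "ADULT")
  expect_equal(o1$adult_probability_percent, 99.9)
  expect_equal(o1$branch, "clavicle_mature")

  o2 <- classify(canonical_subject(i3m = 0.05, clavicle_stage = 2))
  expect_equal(o2$classification, "ADULT")
  expect_equal(o2$adult_probability_percent, 96)
  expect_equal(o2$branch, "i3m_low_clavicle_immature")

  o3 <- classify(canonical_subject(i3m = 0.10, clavicle_stage = 2))
  expect_equal(o3$classification, "PRESUMED_MINOR")
  expect_equal(o3$adult_probability_percent, 60)

  o4 <- classify(canonical_subject(i3m = 0.20, clavicle_stage = 2))
  expect_equal(o4$classification, "PRESUMED_MINOR")
  expect_equal(o4$adult_probability_percent, 16)
})

test_that("gate leaves end the traversal without a probability", {
  ab <- classify(canonical_subject(i3m = 0.05, clavicle_stage = 4,
                                   abnormal = TRUE))
  expect_equal(ab$classification, "INDETERMINATE")
  expect_true(is.na(ab$adult_probability_percent))
  expect_equal(ab$branch, "abnormal_growth")

  tn <- classify(canonical_subject(i3m = 0.05, clavicle_stage = 4,
                                   tanner = c(4L, 5L)))
  expect_equal(tn$classification, "PRESUMED_MINOR")
  expect_equal(tn$branch, "tanner_incomplete")
  expect_true(is.na(tn$adult_probability_percent))

  no_opt <- classify(canonical_subject(i3m = 0.05, clavicle_stage = 4,
                                       teeth_present = FALSE))
  expect_equal(no_opt$classification, "INDETERMINATE")
  expect_equal(no_opt$branch, "opt_missing")
})

test_that("an open mandibular apex dominates any other evidence (MINOR)", {
  # even a fused clavicle and closed third molar cannot override the gate
  o <- classify(canonical_subject(i3m = 0, clavicle_stage = 5,
                                  teeth_closed = c(rep(TRUE, 6), FALSE)))
  expect_equal(o$classification, "MINOR")
  expect_equal(o$branch, "teeth_incomplete")
  expect_true(is.na(o$adult_probability_percent))
})

test_that("the outcome never depends on the hand/wrist modality", {
  hands <- list(NULL, TRUE, FALSE,
                carpal_radiograph(list(unit_square(0.25, 0.25)),
                                  unit_square(0, 0, side = 2)))
  combos <- expand.grid(i3m = c(NA, 0, 0.05, 0.1, 0.2),
                        clav = c(NA, 1, 2, 3, 4, 5),
                        tanner = c(4L, 5L),
                        teeth_ok = c(TRUE, FALSE))
  for (r in seq_len(nrow(combos))) {
    outs <- lapply(hands, function(h) {
      s <- canonical_subject(
        i3m = if (is.na(combos$i3m[r])) NULL else combos$i3m[r],
        clavicle_stage = if (is.na(combos$clav[r])) NULL else combos$clav[r],
        tanner = c(combos$tanner[r], 5L),
        teeth_closed = c(rep(TRUE, 6), combos$teeth_ok[r]),
        hand = h)
      o <- classify(s)
      o$subject_id <- NULL
      o
    })
    for (k in 2:length(outs)) expect_identical(outs[[k]], outs[[1]])
  }
})

test_that("emitted probability is non-increasing in I3M, all else fixed", {
  probs4 <- vapply(c(0, 0.05, 0.079, 0.10, 0.149, 0.15, 0.3),
                   function(v) classify(canonical_subject(v, 4))$adult_probability_percent,
                   numeric(1))
  probs2 <- vapply(c(0, 0.05, 0.079, 0.10, 0.149, 0.15, 0.3),
                   function(v) classify(canonical_subject(v, 2))$adult_probability_percent,
                   numeric(1))
  expect_true(all(diff(probs4) <= 0))
  expect_true(all(diff(probs2) <= 0))
})

test_that("unassessable third molar routes through the clavicle", {
  fused <- classify(canonical_subject(i3m = NULL, clavicle_stage = 4))
  expect_equal(fused$classification, "ADULT")
  expect_equal(fused$adult_probability_percent, 99.9)

  # default policy: an unfused clavicle cannot establish majority
  unfused <- classify(canonical_subject(i3m = NULL, clavicle_stage = 2))
  expect_equal(unfused$classification, "INDETERMINATE")
  expect_equal(unfused$branch, "molar_unassessable_clavicle_immature")
  expect_true(is.na(unfused$adult_probability_percent))

  # alternative policy: the 96 percent figure is applied
  cfg96 <- decision_config(unassessable_molar_immature_clavicle_policy = "apply_96")
  alt <- classify(canonical_subject(i3m = NULL, clavicle_stage = 2), cfg96)
  expect_equal(alt$classification, "ADULT")
  expect_equal(alt$adult_probability_percent, 96)

  # no clavicle imaged at all: evidence is insufficient
  none <- classify(canonical_subject(i3m = NULL))
  expect_equal(none$classification, "INDETERMINATE")
  expect_equal(none$branch, "missing_evidence")
})

test_that("Schmeling stage 3 branches as below-4 and is annotated", {
  o <- classify(canonical_subject(i3m = 0.05, clavicle_stage = 3))
  expect_equal(o$adult_probability_percent, 96)
  expect_true(any(grepl("stage 3", o$notes)))
})

test_that("the adult declaration threshold splits ADULT from PRESUMED_MINOR", {
  strict <- decision_config(adult_declaration_threshold_percent = 97)
  o <- classify(canonical_subject(i3m = 0.05, clavicle_stage = 2), strict)
  expect_equal(o$adult_probability_percent, 96)
  expect_equal(o$classification, "PRESUMED_MINOR")
  o2 <- classify(canonical_subject(i3m = 0.05, clavicle_stage = 4), strict)
  expect_equal(o2$classification, "ADULT")
})

test_that("branch probabilities come from the configuration verbatim", {
  cfg <- decision_config()
  expect_equal(adult_probability_for_branch("clavicle_mature", cfg), 99.9)
  expect_equal(adult_probability_for_branch("i3m_low_clavicle_immature", cfg), 96)
  expect_equal(adult_probability_for_branch("i3m_mid", cfg), 60)
  expect_equal(adult_probability_for_branch("i3m_high", cfg), 16)
  expect_true(is.na(adult_probability_for_branch("teeth_incomplete", cfg)))
  expect_error(adult_probability_for_branch("not_a_leaf", cfg), "unknown branch")
})

test_that("every traversal reaches exactly one leaf with a non-empty path", {
  set.seed(5)
  for (i in 1:200) {
    s <- canonical_subject(
      i3m = sample(list(NULL, 0, stats::runif(1, 0, 0.3)), 1)[[1]],
      clavicle_stage = sample(list(NULL, 1, 2, 3, 4, 5), 1)[[1]],
      tanner = sample(1:5, 2, replace = TRUE),
      teeth_closed = sample(c(TRUE, FALSE), 7, replace = TRUE),
      abnormal = sample(c(TRUE, FALSE), 1, prob = c(0.1, 0.9)))
    o <- classify(s)
    expect_length(o$classification, 1)
    expect_true(o$branch %in% decision_branches())
    expect_gt(length(o$path), 0)
    expect_equal(o$path[length(o$path)], o$branch)
    # repeat traversal is deterministic
    expect_identical(classify(s), o)
  }
})

test_that("reports echo the decisive evidence", {
  minor <- classify(canonical_subject(i3m = 0, clavicle_stage = 5,
                                      teeth_closed = c(rep(TRUE, 6), FALSE)))
  expect_match(explain(minor), "teeth_incomplete")

  adult <- classify(canonical_subject(i3m = 0.05, clavicle_stage = 4))
  expect_match(explain(adult), "99.9")
  expect_match(explain(adult), "stage 4")

  indet <- classify(canonical_subject(i3m = NULL))
  expect_match(explain(indet), "clavicle")
  expect_match(explain(indet), "INDETERMINATE")
})
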