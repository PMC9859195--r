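test_that("cohort simulation is seed-deterministic and size-stable", {
  strip <- function(d) {
    d <- as.data.frame(d)
    attr(d, "config") <- NULL
    rownames(d) <- NULL
    d
  }
  cfg <- simulator_config(n_subjects = 80, seed = 7)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(strip(a), strip(b))

  # enlarging the cohort must not perturb earlier subjects
  big <- simulate_cohort(cfg, n = 160)
  expect_identical(strip(strip(big)[seq_len(80), ]), strip(a))

  # different seed, different cohort
  c2 <- simulate_cohort(cfg, seed = 8)
  expect_false(identical(a$true_age, c2$true_age))

  expect_identical(nrow(simulate_cohort(cfg, n = 0)), 0L)
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(123)
  x1 <- stats::runif(3)
  set.seed(123)
  invisible(simulate_cohort(simulator_config(n_subjects = 10, seed = 99)))
  x2 <- stats::runif(3)
  expect_identical(x1, x2)
})

test_that("population hard bounds hold for every subject", {
  coh <- simulate_cohort(simulator_config(), n = 5000, seed = 31)
  expect_equal(sum(!coh$hand_complete & coh$true_age >= 16), 0)
  teeth_ok <- Reduce(`&`, lapply(paste0("teeth_", 31:37), function(cn) coh[[cn]]))
  expect_equal(sum(!teeth_ok & coh$true_age >= 17), 0)
  expect_equal(sum(coh$clavicle_stage >= 4 & coh$true_age < 19), 0)
})

test_that("invalid bound configurations are rejected", {
  expect_error(simulator_config(hand_completion_age = list(mean = 15, sd = 1, lower = 13, upper = 16.5)),
               "<= 16")
  expect_error(simulator_config(teeth_completion_age = list(mean = 16, sd = 1, lower = 14, upper = 17.5)),
               "<= 17")
  expect_error(simulator_config(clavicle_fusion_age = list(mean = 20, sd = 1, lower = 18, upper = Inf)),
               ">= 19")
  expect_error(simulator_config(molar_unassessable_prob = 1.2), "\\[0, 1\\]")
  expect_error(simulator_config(age_range = c(24, 14)), "increasing")
})

test_that("per-subject I3M trajectories decay monotonically and close exactly", {
  coh <- simulate_cohort(simulator_config(), n = 30, seed = 5)
  for (i in seq_len(10)) {
    s <- coh[i, ]
    attr(s, "config") <- attr(coh, "config")
    ages <- seq(14, 24, by = 0.5)
    i3ms <- vapply(ages, function(a) {
      obs <- observe(s, a)
      if (!obs$third_molar$assessable) return(0)
      compute_i3m(obs$third_molar$measurement)
    }, numeric(1))
    expect_true(all(diff(i3ms) <= 1e-12))
    # exactly 0 at and after the closure age
    at_closure <- observe(s, s$i3m_closure_at)
    if (at_closure$third_molar$assessable) {
      expect_identical(compute_i3m(at_closure$third_molar$measurement), 0)
    }
    just_before <- observe(s, s$i3m_closure_at - 1e-6)
    if (just_before$third_molar$assessable && s$i3m_closure_at - 1e-6 > 14) {
      expect_gt(compute_i3m(just_before$third_molar$measurement), 0)
    }
  }
})

test_that("observation thresholds the latent event ages deterministically", {
  coh <- simulate_cohort(simulator_config(), n = 5, seed = 77)
  s <- coh[1, ]
  attr(s, "config") <- attr(coh, "config")

  young <- observe(s, 13)
  expect_false(teeth_complete(young$teeth))
  expect_lt(young$clavicle$schmeling_stage, 4)
  expect_lt(young$exam$tanner_pubic_hair, 5)

  old <- observe(s, max(s$clavicle_stage5_at, s$i3m_closure_at) + 1)
  expect_true(teeth_complete(old$teeth))
  expect_equal(old$exam$tanner_pubic_hair, 5L)
  expect_equal(old$clavicle$schmeling_stage, 5L)
  if (old$third_molar$assessable) {
    expect_identical(compute_i3m(old$third_molar$measurement), 0)
  }
})

test_that("third-molar assessability is independent of age", {
  coh <- simulate_cohort(simulator_config(), n = 20000, seed = 13)
  q <- cut(coh$true_age, stats::quantile(coh$true_age, 0:4 / 4),
           include.lowest = TRUE)
  tab <- table(q, coh$molar_assessable)
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)
})

test_that("per-subject classification agrees with the vectorised labeler", {
  coh <- simulate_cohort(simulator_config(), n = 300, seed = 21)
  vec <- ageflow:::.branch_of_cohort(coh)
  ass <- cohort_assessments(coh)
  for (i in seq_len(nrow(coh))) {
    expect_identical(classify(ass[[i]])$branch, vec[i])
  }
})

test_that("the table-weighted age option reproduces the packaged age mix", {
  coh <- simulate_cohort(simulator_config(age_distribution = "sample_table"),
                         n = 20000, seed = 17)
  expect_true(all(coh$true_age >= 14 & coh$true_age < 23))
  tab <- load_sample_distribution()
  w <- tab$counts[, "teeth_m"] + tab$counts[, "teeth_f"]
  emp <- tabulate(floor(coh$true_age) - 13, nbins = 9) / nrow(coh)
  expect_lt(max(abs(emp - w / sum(w))), 0.02)
})
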