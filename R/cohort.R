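#' Truncated-normal inverse CDF (internal)
#'
#' Maps a uniform draw through the inverse CDF of a normal truncated to
#' [lower, upper]. Inverse-CDF sampling keeps the per-subject draw count
#' fixed, which is what makes the cohort stream stable under extension.
#' @noRd
.qtruncnorm <- function(u, mean, sd, lower = -Inf, upper = Inf) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(plo + u * (phi - plo), mean, sd)
}

.tn <- function(mean, sd, lower = -Inf, upper = Inf) {
  list(mean = mean, sd = sd, lower = lower, upper = upper)
}

.check_tn <- function(x, what) {
  ok <- is.list(x) && all(c("mean", "sd", "lower", "upper") %in% names(x)) &&
    is.finite(x$mean) && is.finite(x$sd) && x$sd > 0 && x$lower < x$upper
  if (!ok) stop(sprintf("config validation error: %s must be a list with mean, sd > 0, lower < upper", what),
                call. = FALSE)
  invisible(x)
}

#' Synthetic maturation-cohort configuration
#'
#' Parameters of the seeded generator that emulates a cohort aged 14-24 with
#' the maturation constraints the model relies on. Event ages are drawn from
#' truncated normals whose hard bounds encode the published population
#' constraints and are enforced at validation time:
#' hand/wrist maturation completes by age 16, the seven left mandibular teeth
#' by 17, and the medial clavicular epiphysis never fuses (Schmeling stage 4)
#' before 19.
#'
#' Each subject's third molar maturity index follows a subject-level
#' exponential decay `I3M(age) = i0 * exp(-decay * (age - onset_age))`,
#' dropping to exactly 0 at the subject's apex-closure age. Closure age and
#' clavicle fusion age are positively coupled through a shared latent
#' maturation factor (Gaussian copula, correlation `maturation_correlation`),
#' which keeps the joint event "fused clavicle with I3M still above 0.08" as
#' rare as observed.
#'
#' @param n_subjects cohort size.
#' @param seed integer seed; the whole cohort is a pure function of
#'   (config, seed).
#' @param age_range numeric length 2, default c(14, 24) (years).
#' @param age_distribution `"uniform"` over `age_range`, or `"sample_table"` for the
#'   packaged sample-distribution weights (ages 14-22, uniform within year).
#' @param sex_ratio probability of male.
#' @param hand_completion_age,teeth_completion_age,tanner_completion_age,clavicle_fusion_age,stage5_delay
#'   truncated-normal parameter lists `list(mean, sd, lower, upper)` (years).
#' @param molar_unassessable_prob probability that the third molar cannot be
#'   assessed (agenesis, extraction, rotation, position), independent of age.
#' @param i3m_curve list with `i0_*` (index at `onset_age`), `decay_*`
#'   (per-year rate) truncated-normal parameters, `closure_*` (apex-closure
#'   age) truncated-normal parameters and `onset_age`.
#' @param maturation_correlation Gaussian-copula correlation between closure
#'   and clavicle fusion ages, in [0, 1).
#' @param abnormal_growth_prob probability of visible abnormal-growth signs.
#' @return an object of class `simulator_config`.
#' @export
simulator_config <- function(n_subjects = 1000L,
                             seed = 1L,
                             age_range = c(14, 24),
                             age_distribution = c("uniform", "sample_table"),
                             sex_ratio = 0.5,
                             hand_completion_age = .tn(15.0, 0.8, 13.0, 16.0),
                             teeth_completion_age = .tn(15.5, 0.7, 13.5, 17.0),
                             tanner_completion_age = .tn(14.3, 0.9, 12.5, 16.5),
                             molar_unassessable_prob = 0.06,
                             i3m_curve = list(i0_mean = 1.05, i0_sd = 0.20,
                                              i0_lower = 0.30, i0_upper = 2.0,
                                              decay_mean = 0.53, decay_sd = 0.10,
                                              decay_lower = 0.20, decay_upper = 1.20,
                                              closure_mean = 20.5, closure_sd = 1.3,
                                              closure_lower = 16, closure_upper = Inf,
                                              onset_age = 14),
                             clavicle_fusion_age = .tn(21.4, 1.5, 19.0, Inf),
                             stage5_delay = .tn(1.5, 0.5, 0.5, 3.0),
                             maturation_correlation = 0.5,
                             abnormal_growth_prob = 0) {
  age_distribution <- match.arg(age_distribution)
  cfg <- structure(list(
    n_subjects = as.integer(n_subjects), seed = as.integer(seed),
    age_range = as.numeric(age_range), age_distribution = age_distribution,
    sex_ratio = sex_ratio,
    hand_completion_age = hand_completion_age,
    teeth_completion_age = teeth_completion_age,
    tanner_completion_age = tanner_completion_age,
    molar_unassessable_prob = molar_unassessable_prob,
    i3m_curve = i3m_curve,
    clavicle_fusion_age = clavicle_fusion_age,
    stage5_delay = stage5_delay,
    maturation_correlation = maturation_correlation,
    abnormal_growth_prob = abnormal_growth_prob
  ), class = "simulator_config")
  validate_simulator_config(cfg)
}

#' Validate a simulator configuration
#'
#' Checks structural validity and the hard population bounds: hand/wrist
#' completion upper bound at most 16 years, seven-teeth completion upper
#' bound at most 17, clavicle fusion lower bound at least 19.
#'
#' @param cfg a `simulator_config`.
#' @return the config, invisibly usable, or an error.
#' @export
validate_simulator_config <- function(cfg) {
  stopifnot(inherits(cfg, "simulator_config"))
  if (cfg$n_subjects < 0L) {
    stop("config validation error: n_subjects must be non-negative", call. = FALSE)
  }
  if (length(cfg$age_range) != 2L || cfg$age_range[1L] >= cfg$age_range[2L]) {
    stop("config validation error: age_range must be increasing", call. = FALSE)
  }
  .check_tn(cfg$hand_completion_age, "hand_completion_age")
  .check_tn(cfg$teeth_completion_age, "teeth_completion_age")
  .check_tn(cfg$tanner_completion_age, "tanner_completion_age")
  .check_tn(cfg$clavicle_fusion_age, "clavicle_fusion_age")
  .check_tn(cfg$stage5_delay, "stage5_delay")
  if (cfg$hand_completion_age$upper > 16) {
    stop("config validation error: hand_completion_age upper bound must be <= 16 (published constraint)",
         call. = FALSE)
  }
  if (cfg$teeth_completion_age$upper > 17) {
    stop("config validation error: teeth_completion_age upper bound must be <= 17 (published constraint)",
         call. = FALSE)
  }
  if (cfg$clavicle_fusion_age$lower < 19) {
    stop("config validation error: clavicle_fusion_age lower bound must be >= 19 (published constraint)",
         call. = FALSE)
  }
  for (p in c("molar_unassessable_prob", "sex_ratio", "abnormal_growth_prob")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) {
      stop(sprintf("config validation error: %s must be in [0, 1]", p), call. = FALSE)
    }
  }
  if (cfg$maturation_correlation < 0 || cfg$maturation_correlation >= 1) {
    stop("config validation error: maturation_correlation must be in [0, 1)", call. = FALSE)
  }
  ic <- cfg$i3m_curve
  need <- c("i0_mean", "i0_sd", "i0_lower", "i0_upper", "decay_mean", "decay_sd",
            "decay_lower", "decay_upper", "closure_mean", "closure_sd",
            "closure_lower", "closure_upper", "onset_age")
  if (!all(need %in% names(ic))) {
    stop("config validation error: i3m_curve is missing parameters", call. = FALSE)
  }
  if (ic$i0_lower <= 0 || ic$decay_lower <= 0) {
    stop("config validation error: i3m_curve i0 and decay must be positive", call. = FALSE)
  }
  cfg
}

#' @export
print.simulator_config <- function(x, ...) {
  cat("Maturation-cohort simulator configuration\n")
  cat(sprintf("  n_subjects = %d, seed = %d, ages %s over [%.3g, %.3g)\n",
              x$n_subjects, x$seed, x$age_distribution,
              x$age_range[1L], x$age_range[2L]))
  f <- function(tn) sprintf("N(%.3g, %.3g) in [%.3g, %.3g]",
                            tn$mean, tn$sd, tn$lower, tn$upper)
  cat(sprintf("  hand complete    ~ %s\n", f(x$hand_completion_age)))
  cat(sprintf("  teeth complete   ~ %s\n", f(x$teeth_completion_age)))
  cat(sprintf("  Tanner 5 reached ~ %s\n", f(x$tanner_completion_age)))
  cat(sprintf("  clavicle stage 4 ~ %s (+ stage-5 delay ~ %s)\n",
              f(x$clavicle_fusion_age), f(x$stage5_delay)))
  cat(sprintf("  I3M: i0 ~ N(%.3g, %.3g), decay ~ N(%.3g, %.3g)/yr, closure ~ N(%.3g, %.3g) >= %.3g\n",
              x$i3m_curve$i0_mean, x$i3m_curve$i0_sd, x$i3m_curve$decay_mean,
              x$i3m_curve$decay_sd, x$i3m_curve$closure_mean,
              x$i3m_curve$closure_sd, x$i3m_curve$closure_lower))
  cat(sprintf("  P(molar unassessable) = %.3g; closure-fusion copula rho = %.2g\n",
              x$molar_unassessable_prob, x$maturation_correlation))
  invisible(x)
}

# number of uniforms consumed per subject (fixed: no rejection sampling)
.DRAWS_PER_SUBJECT <- 13L

# weighted age sampler: inverse CDF of the piecewise-uniform density
# over [14, 23) weighted by the packaged per-year orthopantomogram counts
.age_from_u <- function(u, cfg) {
  if (cfg$age_distribution == "uniform") {
    return(cfg$age_range[1L] + u * diff(cfg$age_range))
  }
  tab <- load_sample_distribution()
  w <- tab$counts[, "teeth_m"] + tab$counts[, "teeth_f"]
  years <- as.numeric(rownames(tab$counts))
  cw <- cumsum(w) / sum(w)
  idx <- findInterval(u, c(0, cw[-length(cw)]))
  frac <- (u - c(0, cw)[idx]) / (w[idx] / sum(w))
  years[idx] + frac
}

#' Simulate a synthetic maturation cohort
#'
#' Draws `n` subjects with a true (chronological, decimal) age and latent
#' maturation-event ages, then derives the observable multi-modality
#' assessment each subject would present at their true age. The cohort is a
#' pure function of (config, seed): identical inputs give byte-identical
#' output. Subjects consume a fixed block of random draws each, so enlarging
#' the cohort leaves earlier subjects unchanged.
#'
#' @param config a [simulator_config()].
#' @param n override for `config$n_subjects`.
#' @param seed override for `config$seed`.
#' @return a `maturation_cohort`: a data.frame with one row per subject
#'   carrying `subject_id`, `true_age`, `sex`, the latent event ages
#'   (`hand_complete_at`, `teeth_complete_at`, `tanner5_at`,
#'   `i3m_closure_at`, `clavicle_stage4_at`, `clavicle_stage5_at`), curve
#'   parameters (`i3m_i0`, `i3m_decay`), and the observed assessment columns
#'   (`tanner_pubic_hair`, `tanner_second`, `abnormal_growth`,
#'   `hand_complete`, `teeth_31` .. `teeth_37`, `molar_assessable`, `i3m`,
#'   `clavicle_stage`). The generating config is attached as attribute
#'   `"config"`.
#' @export
simulate_cohort <- function(config = simulator_config(), n = NULL, seed = NULL) {
  stopifnot(inherits(config, "simulator_config"))
  if (!is.null(n)) config$n_subjects <- as.integer(n)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  validate_simulator_config(config)
  n <- config$n_subjects

  if (n == 0L) {
    df <- .empty_cohort()
    attr(df, "config") <- config
    return(df)
  }

  # one seeded stream; per-subject blocks laid out row-wise
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  u <- matrix(stats::runif(n * .DRAWS_PER_SUBJECT), nrow = n,
              ncol = .DRAWS_PER_SUBJECT, byrow = TRUE)

  ic <- config$i3m_curve
  rho <- config$maturation_correlation
  z_shared <- stats::qnorm(u[, 3L])
  z_closure <- sqrt(rho) * z_shared + sqrt(1 - rho) * stats::qnorm(u[, 4L])
  z_clav <- sqrt(rho) * z_shared + sqrt(1 - rho) * stats::qnorm(u[, 5L])

  lat <- data.frame(
    subject_id = sprintf("S%06d", seq_len(n)),
    true_age = .age_from_u(u[, 1L], config),
    sex = ifelse(u[, 2L] < config$sex_ratio, "male", "female"),
    hand_complete_at = .qtruncnorm(u[, 8L], config$hand_completion_age$mean,
                                   config$hand_completion_age$sd,
                                   config$hand_completion_age$lower,
                                   config$hand_completion_age$upper),
    teeth_complete_at = .qtruncnorm(u[, 9L], config$teeth_completion_age$mean,
                                    config$teeth_completion_age$sd,
                                    config$teeth_completion_age$lower,
                                    config$teeth_completion_age$upper),
    tanner5_at = .qtruncnorm(u[, 10L], config$tanner_completion_age$mean,
                             config$tanner_completion_age$sd,
                             config$tanner_completion_age$lower,
                             config$tanner_completion_age$upper),
    i3m_closure_at = .qtruncnorm(stats::pnorm(z_closure), ic$closure_mean,
                                 ic$closure_sd, ic$closure_lower,
                                 ic$closure_upper),
    clavicle_stage4_at = .qtruncnorm(stats::pnorm(z_clav),
                                     config$clavicle_fusion_age$mean,
                                     config$clavicle_fusion_age$sd,
                                     config$clavicle_fusion_age$lower,
                                     config$clavicle_fusion_age$upper),
    i3m_i0 = .qtruncnorm(u[, 6L], ic$i0_mean, ic$i0_sd, ic$i0_lower, ic$i0_upper),
    i3m_decay = .qtruncnorm(u[, 7L], ic$decay_mean, ic$decay_sd,
                            ic$decay_lower, ic$decay_upper),
    molar_assessable = u[, 12L] >= config$molar_unassessable_prob,
    abnormal_growth = u[, 13L] < config$abnormal_growth_prob,
    stringsAsFactors = FALSE
  )
  lat$clavicle_stage5_at <- lat$clavicle_stage4_at +
    .qtruncnorm(u[, 11L], config$stage5_delay$mean, config$stage5_delay$sd,
                config$stage5_delay$lower, config$stage5_delay$upper)

  df <- cbind(lat, .derive_observed(lat, lat$true_age, config))
  class(df) <- c("maturation_cohort", "data.frame")
  attr(df, "config") <- config
  df
}

.empty_cohort <- function() {
  df <- data.frame(subject_id = character(), true_age = numeric(),
                   sex = character(), hand_complete_at = numeric(),
                   teeth_complete_at = numeric(), tanner5_at = numeric(),
                   i3m_closure_at = numeric(), clavicle_stage4_at = numeric(),
                   i3m_i0 = numeric(), i3m_decay = numeric(),
                   molar_assessable = logical(), abnormal_growth = logical(),
                   clavicle_stage5_at = numeric(), stringsAsFactors = FALSE)
  obs <- .derive_observed(df, numeric(), simulator_config(n_subjects = 0L))
  df <- cbind(df, obs)
  class(df) <- c("maturation_cohort", "data.frame")
  df
}

# deterministic observation model: latent event ages + an age |-> observables
.derive_observed <- function(lat, at_age, config) {
  obs <- data.frame(row.names = seq_along(at_age))
  tanner_gap <- lat$tanner5_at - at_age
  stage <- ifelse(tanner_gap <= 0, 5L, pmax(1L, 5L - ceiling(tanner_gap / 1.2)))
  obs$tanner_pubic_hair <- as.integer(pmin(stage, ifelse(tanner_gap <= 0, 5L, 4L)))
  obs$tanner_second <- obs$tanner_pubic_hair
  obs$hand_complete <- at_age >= lat$hand_complete_at

  # roots close in reverse FDI order; later teeth (molars) mature last
  n_open <- ifelse(at_age >= lat$teeth_complete_at, 0,
                   pmin(7, pmax(1, ceiling((lat$teeth_complete_at - at_age) / 0.8))))
  for (k in 1:7) {
    # tooth FDI 30+k is still open when it is among the n_open latest teeth
    obs[[paste0("teeth_", 30L + k)]] <- (8L - k) > n_open
  }

  obs$i3m <- ifelse(at_age >= lat$i3m_closure_at, 0,
                    lat$i3m_i0 * exp(-lat$i3m_decay *
                                       pmax(0, at_age - config$i3m_curve$onset_age)))
  obs$clavicle_stage <- ifelse(at_age >= lat$clavicle_stage5_at, 5L,
                        ifelse(at_age >= lat$clavicle_stage4_at, 4L,
                        ifelse(at_age >= lat$clavicle_stage4_at - 2.5, 3L,
                        ifelse(at_age >= lat$clavicle_stage4_at - 5.0, 2L, 1L))))
  obs$clavicle_stage <- as.integer(obs$clavicle_stage)
  obs
}

#' Observe a simulated subject at a given age
#'
#' Re-derives the observable assessment a simulated subject would present at
#' an arbitrary age (deterministic thresholding of the latent event ages; the
#' I3M value comes from the subject's decay curve, exactly 0 at and after the
#' closure age).
#'
#' @param s a one-row `maturation_cohort` (a single simulated subject).
#' @param at_age age in years at which to observe.
#' @return a [subject_assessment()].
#' @export
observe <- function(s, at_age) {
  stopifnot(inherits(s, "maturation_cohort"), nrow(s) == 1L,
            is.numeric(at_age), length(at_age) == 1L)
  config <- attr(s, "config")
  if (is.null(config)) config <- simulator_config(n_subjects = 0L)
  obs <- .derive_observed(s, at_age, config)
  .row_to_assessment(cbind(s[, c("subject_id", "sex", "molar_assessable",
                                 "abnormal_growth")], obs))
}

# build a subject_assessment from one row of observed columns
.row_to_assessment <- function(r) {
  teeth <- seven_teeth_assessment(
    stats::setNames(as.logical(unlist(r[paste0("teeth_", 31:37)])),
                    as.character(31:37)))
  molar <- if (isTRUE(r$molar_assessable)) {
    third_molar_assessment(TRUE, .i3m_as_measurement(r$i3m))
  } else {
    third_molar_assessment(FALSE)
  }
  subject_assessment(
    subject_id = r$subject_id,
    exam = physical_exam(r$tanner_pubic_hair, r$tanner_second, r$sex,
                         isTRUE(r$abnormal_growth)),
    hand = isTRUE(r$hand_complete),
    teeth = teeth,
    third_molar = molar,
    clavicle = clavicle_assessment(r$clavicle_stage))
}

# represent a target I3M value as a two-gap apex measurement on a 16 mm tooth
.i3m_as_measurement <- function(i3m, tooth_length = 16) {
  if (i3m <= 0) return(apex_measurement(numeric(), tooth_length))
  apex_measurement(rep(i3m * tooth_length / 2, 2L), tooth_length)
}

#' Materialise a cohort's observed rows as assessment objects
#'
#' @param cohort a `maturation_cohort`.
#' @return a list of [subject_assessment()] objects, one per row.
#' @export
cohort_assessments <- function(cohort) {
  stopifnot(inherits(cohort, "maturation_cohort"))
  lapply(seq_len(nrow(cohort)), function(i) .row_to_assessment(cohort[i, ]))
}

#' @export
print.maturation_cohort <- function(x, ...) {
  cat(sprintf("Synthetic maturation cohort: %d subjects", nrow(x)))
  if (nrow(x)) {
    cat(sprintf(", ages %.1f-%.1f, %.1f%% adult (true age >= 18)",
                min(x$true_age), max(x$true_age),
                100 * mean(x$true_age >= 18)))
  }
  cat("\n")
  if (nrow(x)) utils::str(utils::head(as.data.frame(x), 3))
  invisible(x)
}
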