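#' Physical examination record
#'
#' Tanner staging of the two secondary sexual characteristics (pubic hair in
#' both sexes; genital development in males, breast development in females)
#' plus a flag for visible signs of abnormal growth (endocrine disease,
#' precocious puberty and similar), which pre-empt any radiographic staging.
#'
#' @param tanner_pubic_hair,tanner_second integer Tanner stages in 1..5;
#'   stage 5 is full sexual maturity.
#' @param sex `"male"` or `"female"`.
#' @param abnormal_growth_signs logical; TRUE routes the subject to expert
#'   referral before any radiograph is considered.
#' @return an object of class `physical_exam`.
#' @export
physical_exam <- function(tanner_pubic_hair, tanner_second, sex,
                          abnormal_growth_signs = FALSE) {
  sex <- match.arg(sex, c("male", "female"))
  for (s in c(tanner_pubic_hair, tanner_second)) {
    if (length(s) != 1L || is.na(s) || s != as.integer(s) || s < 1L || s > 5L) {
      stop("validation error: Tanner stages must be integers in 1..5",
           call. = FALSE)
    }
  }
  stopifnot(is.logical(abnormal_growth_signs), length(abnormal_growth_signs) == 1L,
            !is.na(abnormal_growth_signs))
  structure(list(tanner_pubic_hair = as.integer(tanner_pubic_hair),
                 tanner_second = as.integer(tanner_second),
                 sex = sex,
                 abnormal_growth_signs = abnormal_growth_signs),
            class = "physical_exam")
}

#' Medial clavicular epiphysis staging
#'
#' Schmeling's five ossification stages of the medial clavicular epiphyseal
#' cartilage. Stage 4 (cartilage fully ossified) and stage 5 (epiphyseal scar
#' no longer visible) indicate completed fusion. Stage 3 (partial fusion) is
#' accepted as input but is not an approved estimation stage; it branches like
#' any stage below 4 and the decision carries a note.
#'
#' @param schmeling_stage integer in 1..5.
#' @return an object of class `clavicle_assessment`.
#' @export
clavicle_assessment <- function(schmeling_stage) {
  s <- schmeling_stage
  if (length(s) != 1L || is.na(s) || s != as.integer(s) || s < 1L || s > 5L) {
    stop("validation error: Schmeling stage must be an integer in 1..5",
         call. = FALSE)
  }
  structure(list(schmeling_stage = as.integer(s)), class = "clavicle_assessment")
}

#' Third molar assessment
#'
#' The lower left third molar is not always radiographically assessable
#' (agenesis, extraction, rotation, irregular position). When it is, the
#' assessment carries the open-apex measurement from which I3M is computed.
#'
#' @param assessable logical.
#' @param measurement an [apex_measurement()]; required iff `assessable`.
#' @return an object of class `third_molar_assessment`.
#' @export
third_molar_assessment <- function(assessable, measurement = NULL) {
  stopifnot(is.logical(assessable), length(assessable) == 1L, !is.na(assessable))
  if (assessable && !inherits(measurement, "apex_measurement")) {
    stop("validation error: an assessable third molar needs an apex_measurement",
         call. = FALSE)
  }
  if (!assessable && !is.null(measurement)) {
    stop("validation error: a non-assessable third molar cannot carry a measurement",
         call. = FALSE)
  }
  structure(list(assessable = assessable, measurement = measurement),
            class = "third_molar_assessment")
}

#' A subject's full multi-modality evidence bundle
#'
#' Everything known about one person that the decision tree may consult. The
#' physical examination is mandatory; every radiographic modality is optional
#' and may be absent (`NULL`).
#'
#' @param subject_id opaque identifier (coerced to character).
#' @param exam a [physical_exam()].
#' @param hand optional hand/wrist evidence: a [carpal_radiograph()], or a
#'   single logical completeness flag (TRUE = hand/wrist maturation complete).
#' @param teeth optional [seven_teeth_assessment()].
#' @param third_molar optional [third_molar_assessment()].
#' @param clavicle optional [clavicle_assessment()].
#' @return an object of class `subject_assessment`.
#' @export
subject_assessment <- function(subject_id, exam, hand = NULL, teeth = NULL,
                               third_molar = NULL, clavicle = NULL) {
  stopifnot(inherits(exam, "physical_exam"))
  if (!is.null(hand) && !inherits(hand, "carpal_radiograph")) {
    if (!(is.logical(hand) && length(hand) == 1L && !is.na(hand))) {
      stop("validation error: hand must be a carpal_radiograph or a single completeness flag",
           call. = FALSE)
    }
  }
  if (!is.null(teeth)) stopifnot(inherits(teeth, "seven_teeth_assessment"))
  if (!is.null(third_molar)) stopifnot(inherits(third_molar, "third_molar_assessment"))
  if (!is.null(clavicle)) stopifnot(inherits(clavicle, "clavicle_assessment"))
  structure(list(subject_id = as.character(subject_id), exam = exam,
                 hand = hand, teeth = teeth, third_molar = third_molar,
                 clavicle = clavicle),
            class = "subject_assessment")
}

#' Decision-model configuration
#'
#' Thresholds and branch probabilities of the step-wise model. The defaults
#' are the published values and are carried verbatim (as percentages), never
#' re-derived: 99.9 for a fused clavicle (Schmeling stage 4 or 5), 96 for
#' I3M < 0.08 with an unfused or unimaged clavicle, 60 for I3M in
#' [0.08, 0.15), 16 for I3M >= 0.15.
#'
#' `adult_declaration_threshold_percent` realises the legal split explicitly:
#' leaves whose probability reaches the threshold are declared ADULT; the
#' others fall under the statutory presumption of minor age.
#'
#' `unassessable_molar_immature_clavicle_policy` controls the one genuinely
#' ambiguous branch (third molar not assessable and clavicle below stage 4):
#' `"indeterminate"` (default) treats the clavicle below stage 4 as unusable
#' and presumes minor age; `"apply_96"` emits the 96 percent probability
#' instead.
#'
#' @param i3m_low_threshold,i3m_high_threshold I3M band cut-offs.
#' @param prob_clavicle_mature_percent,prob_clavicle_immature_percent,prob_mid_band_percent,prob_high_band_percent
#'   branch probabilities, in percent.
#' @param adult_declaration_threshold_percent minimum branch probability for an
#'   ADULT declaration.
#' @param unassessable_molar_immature_clavicle_policy `"indeterminate"` or
#'   `"apply_96"`.
#' @return an object of class `decision_config`.
#' @export
decision_config <- function(i3m_low_threshold = 0.08,
                            i3m_high_threshold = 0.15,
                            prob_clavicle_mature_percent = 99.9,
                            prob_clavicle_immature_percent = 96,
                            prob_mid_band_percent = 60,
                            prob_high_band_percent = 16,
                            adult_declaration_threshold_percent = 95,
                            unassessable_molar_immature_clavicle_policy =
                              c("indeterminate", "apply_96")) {
  policy <- match.arg(unassessable_molar_immature_clavicle_policy)
  if (!(i3m_low_threshold > 0 && i3m_high_threshold > i3m_low_threshold)) {
    stop("validation error: need 0 < i3m_low_threshold < i3m_high_threshold",
         call. = FALSE)
  }
  probs <- c(prob_clavicle_mature_percent, prob_clavicle_immature_percent,
             prob_mid_band_percent, prob_high_band_percent,
             adult_declaration_threshold_percent)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 100)) {
    stop("validation error: probabilities must lie in [0, 100]", call. = FALSE)
  }
  structure(list(
    i3m_low_threshold = i3m_low_threshold,
    i3m_high_threshold = i3m_high_threshold,
    prob_clavicle_mature_percent = prob_clavicle_mature_percent,
    prob_clavicle_immature_percent = prob_clavicle_immature_percent,
    prob_mid_band_percent = prob_mid_band_percent,
    prob_high_band_percent = prob_high_band_percent,
    adult_declaration_threshold_percent = adult_declaration_threshold_percent,
    unassessable_molar_immature_clavicle_policy = policy
  ), class = "decision_config")
}

#' @export
print.decision_config <- function(x, ...) {
  cat("Decision-model configuration\n")
  cat(sprintf("  I3M bands:            < %.3g | [%.3g, %.3g) | >= %.3g\n",
              x$i3m_low_threshold, x$i3m_low_threshold,
              x$i3m_high_threshold, x$i3m_high_threshold))
  cat(sprintf("  Branch probabilities: clavicle mature %.4g%% | low I3M %.4g%% | mid %.4g%% | high %.4g%%\n",
              x$prob_clavicle_mature_percent, x$prob_clavicle_immature_percent,
              x$prob_mid_band_percent, x$prob_high_band_percent))
  cat(sprintf("  Adult declaration at >= %.4g%%; unassessable-molar policy: %s\n",
              x$adult_declaration_threshold_percent,
              x$unassessable_molar_immature_clavicle_policy))
  invisible(x)
}

# leaf identifiers of the tree, in traversal order of first appearance
.LEAVES <- c("abnormal_growth", "tanner_incomplete", "opt_missing",
             "teeth_incomplete", "clavicle_mature",
             "i3m_low_clavicle_immature", "i3m_mid", "i3m_high",
             "molar_unassessable_clavicle_immature", "missing_evidence")

#' Leaf identifiers of the decision tree
#'
#' @return character vector of the leaf node names emitted in
#'   `DecisionOutcome$path` and the branch-probability tables.
#' @export
decision_branches <- function() .LEAVES

#' Adult probability attached to a decision-tree leaf
#'
#' Returns the configured adult probability (in percent) for the four
#' probability-bearing leaves, and `NA` for gate leaves (abnormal growth,
#' Tanner below 5, missing OPT, incomplete seven teeth, missing evidence),
#' for which no probability is published and none is invented.
#'
#' @param branch a leaf identifier from [decision_branches()].
#' @param config a [decision_config()].
#' @return probability in percent, or `NA_real_`.
#' @export
adult_probability_for_branch <- function(branch, config = decision_config()) {
  stopifnot(inherits(config, "decision_config"))
  if (length(branch) != 1L || !branch %in% .LEAVES) {
    stop(sprintf("unknown branch identifier: %s",
                 paste(branch, collapse = ", ")), call. = FALSE)
  }
  switch(branch,
    clavicle_mature = config$prob_clavicle_mature_percent,
    i3m_low_clavicle_immature = config$prob_clavicle_immature_percent,
    i3m_mid = config$prob_mid_band_percent,
    i3m_high = config$prob_high_band_percent,
    molar_unassessable_clavicle_immature =
      if (config$unassessable_molar_immature_clavicle_policy == "apply_96")
        config$prob_clavicle_immature_percent else NA_real_,
    NA_real_)
}

.outcome <- function(s, classification, leaf, prob, path, evidence, notes,
                     config) {
  if (classification == "ADULT" &&
      (is.na(prob) || prob < config$adult_declaration_threshold_percent)) {
    stop("internal contract violation: ADULT requires probability >= declaration threshold")
  }
  structure(list(subject_id = s$subject_id,
                 classification = classification,
                 adult_probability_percent = prob,
                 branch = leaf,
                 path = c(path, leaf),
                 evidence_used = evidence,
                 notes = notes),
            class = "age_decision")
}

#' Classify one subject through the step-wise age-of-majority model
#'
#' Deterministic traversal of the decision tree:
#' 1. visible signs of abnormal growth divert to expert referral
#'    (INDETERMINATE, minor age presumed);
#' 2. either Tanner characteristic below stage 5 ends the assessment
#'    (PRESUMED_MINOR, no probability);
#' 3. without an orthopantomogram the model cannot proceed (INDETERMINATE);
#'    any of the seven left mandibular teeth with an open apex means MINOR;
#' 4. with an assessable third molar, I3M below the low cut-off sends the
#'    model to the clavicle: Schmeling stage 4 or 5 yields ADULT at 99.9
#'    percent, a lower or unimaged clavicle yields the 96 percent branch
#'    (declared ADULT under the default threshold); the middle band yields
#'    PRESUMED_MINOR at 60 percent and the high band PRESUMED_MINOR at 16;
#' 5. with an unassessable (or missing) third molar, a fused clavicle still
#'    yields ADULT at 99.9 percent, otherwise the configured policy decides.
#'
#' The hand/wrist modality is never consulted: subjects with incomplete
#' hand/wrist maturation were all under 16 in the source sample, so the
#' orthopantomogram is needed regardless and carries all usable information.
#' The returned path records every node traversed, for audit.
#'
#' @param s a [subject_assessment()].
#' @param config a [decision_config()].
#' @return an object of class `age_decision` with fields `subject_id`,
#'   `classification` (`MINOR`, `ADULT`, `PRESUMED_MINOR` or `INDETERMINATE`),
#'   `adult_probability_percent` (NA for gate leaves), `branch`, `path`,
#'   `evidence_used` and `notes`.
#' @examples
#' s <- subject_assessment("x", physical_exam(5, 5, "male"),
#'   teeth = seven_teeth_assessment(rep(TRUE, 7)),
#'   third_molar = third_molar_assessment(TRUE, apex_measurement(c(0.4), 16)),
#'   clavicle = clavicle_assessment(4))
#' classify(s)
#' @export
classify <- function(s, config = decision_config()) {
  stopifnot(inherits(s, "subject_assessment"), inherits(config, "decision_config"))
  path <- character()
  notes <- character()
  evidence <- "physical_exam"

  path <- c(path, "physical_exam")
  if (s$exam$abnormal_growth_signs) {
    return(.outcome(s, "INDETERMINATE", "abnormal_growth", NA_real_, path,
                    evidence,
                    c(notes, "visible signs of abnormal growth: expert referral; minor age presumed pending assessment"),
                    config))
  }
  path <- c(path, "tanner_gate")
  if (s$exam$tanner_pubic_hair < 5L || s$exam$tanner_second < 5L) {
    return(.outcome(s, "PRESUMED_MINOR", "tanner_incomplete", NA_real_, path,
                    evidence,
                    c(notes, "secondary sexual characteristics not fully developed (Tanner below stage 5); statutory presumption of minor age"),
                    config))
  }

  path <- c(path, "seven_teeth_gate")
  if (is.null(s$teeth)) {
    return(.outcome(s, "INDETERMINATE", "opt_missing", NA_real_, path,
                    evidence,
                    c(notes, "orthopantomogram not available: seven-teeth maturation cannot be assessed; minor age presumed pending OPT"),
                    config))
  }
  evidence <- c(evidence, "teeth")
  if (!teeth_complete(s$teeth)) {
    return(.outcome(s, "MINOR", "teeth_incomplete", NA_real_, path, evidence,
                    c(notes, "at least one of the seven left mandibular teeth not completely mature"),
                    config))
  }

  path <- c(path, "third_molar_gate")
  molar_ok <- !is.null(s$third_molar) && s$third_molar$assessable
  clav <- if (is.null(s$clavicle)) NA_integer_ else s$clavicle$schmeling_stage
  if (!is.na(clav) && clav == 3L) {
    notes <- c(notes, "Schmeling stage 3 is not an approved estimation stage; treated as below stage 4")
  }

  if (molar_ok) {
    evidence <- c(evidence, "third_molar")
    i3m <- compute_i3m(s$third_molar$measurement)
    band <- as.character(i3m_band(i3m, config$i3m_low_threshold,
                                  config$i3m_high_threshold))
    path <- c(path, paste0("i3m_band_", tolower(band)))
    if (band == "BELOW_008") {
      path <- c(path, "clavicle_gate")
      if (!is.na(clav) && clav >= 4L) {
        evidence <- c(evidence, "clavicle")
        return(.outcome(s, "ADULT", "clavicle_mature",
                        config$prob_clavicle_mature_percent, path, evidence,
                        c(notes, sprintf("clavicle at Schmeling stage %d: fusion complete", clav)),
                        config))
      }
      if (!is.na(clav)) evidence <- c(evidence, "clavicle")
      prob <- config$prob_clavicle_immature_percent
      cls <- if (prob >= config$adult_declaration_threshold_percent) "ADULT" else "PRESUMED_MINOR"
      if (is.na(clav)) notes <- c(notes, "clavicle not imaged")
      return(.outcome(s, cls, "i3m_low_clavicle_immature", prob, path,
                      evidence, notes, config))
    }
    if (band == "MID_008_015") {
      return(.outcome(s, "PRESUMED_MINOR", "i3m_mid",
                      config$prob_mid_band_percent, path, evidence,
                      c(notes, "statutory presumption of minor age (adult probability below declaration threshold)"),
                      config))
    }
    return(.outcome(s, "PRESUMED_MINOR", "i3m_high",
                    config$prob_high_band_percent, path, evidence,
                    c(notes, "statutory presumption of minor age (adult probability below declaration threshold)"),
                    config))
  }

  # third molar not assessable (or absent)
  if (is.null(s$third_molar)) {
    notes <- c(notes, "third molar assessment missing; proceeding as not assessable")
  } else {
    notes <- c(notes, "third molar not radiographically assessable")
  }
  path <- c(path, "third_molar_unassessable", "clavicle_gate")
  if (!is.na(clav) && clav >= 4L) {
    evidence <- c(evidence, "clavicle")
    return(.outcome(s, "ADULT", "clavicle_mature",
                    config$prob_clavicle_mature_percent, path, evidence,
                    c(notes, sprintf("clavicle at Schmeling stage %d: fusion complete", clav)),
                    config))
  }
  if (is.na(clav)) {
    return(.outcome(s, "INDETERMINATE", "missing_evidence", NA_real_, path,
                    evidence,
                    c(notes, "no clavicle radiograph: evidence insufficient; minor age presumed"),
                    config))
  }
  evidence <- c(evidence, "clavicle")
  if (config$unassessable_molar_immature_clavicle_policy == "apply_96") {
    prob <- config$prob_clavicle_immature_percent
    cls <- if (prob >= config$adult_declaration_threshold_percent) "ADULT" else "PRESUMED_MINOR"
    return(.outcome(s, cls, "molar_unassessable_clavicle_immature", prob,
                    path, evidence, notes, config))
  }
  .outcome(s, "INDETERMINATE", "molar_unassessable_clavicle_immature",
           NA_real_, path, evidence,
           c(notes, "clavicle below Schmeling stage 4 cannot establish majority; minor age presumed"),
           config)
}

#' @export
print.age_decision <- function(x, ...) {
  prob <- if (is.na(x$adult_probability_percent)) "-"
          else sprintf("%.4g%%", x$adult_probability_percent)
  cat(sprintf("<age_decision %s: %s (adult probability %s) at leaf '%s'>\n",
              x$subject_id, x$classification, prob, x$branch))
  invisible(x)
}

#' @export
format.age_decision <- function(x, ...) explain(x)

#' @export
summary.age_decision <- function(object, ...) {
  cat(explain(object))
  invisible(object)
}

#' @export
as.data.frame.age_decision <- function(x, ...) {
  data.frame(subject_id = x$subject_id,
             classification = x$classification,
             adult_probability_percent = x$adult_probability_percent,
             branch = x$branch,
             path = paste(x$path, collapse = ">"),
             evidence_used = paste(x$evidence_used, collapse = ";"),
             notes = paste(x$notes, collapse = " | "),
             stringsAsFactors = FALSE)
}

#' Human-readable report of a decision outcome
#'
#' @param o an object to report on.
#' @param ... passed to methods.
#' @return a single character string (UTF-8, newline-separated).
#' @export
explain <- function(o, ...) UseMethod("explain")

#' @rdname explain
#' @export
explain.age_decision <- function(o, ...) {
  prob <- if (is.na(o$adult_probability_percent)) "not applicable (gate leaf)"
          else sprintf("%.4g%% (as published; carried verbatim)", o$adult_probability_percent)
  lines <- c(
    sprintf("Age-of-majority assessment for subject %s", o$subject_id),
    sprintf("  Classification:    %s", o$classification),
    sprintf("  Adult probability: %s", prob),
    sprintf("  Decision path:     %s", paste(o$path, collapse = " -> ")),
    sprintf("  Evidence used:     %s", paste(o$evidence_used, collapse = ", ")))
  if (length(o$notes)) {
    lines <- c(lines, "  Notes:", paste0("    - ", o$notes))
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}
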