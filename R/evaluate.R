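#' Wilson score confidence interval for a binomial proportion
#'
#' Closed-form Wilson bounds, preferred over the Wald interval for the small
#' branch counts that arise here (rare leaves, rare joint events).
#'
#' @param n_success number of successes (0..n).
#' @param n number of trials (> 0).
#' @param confidence confidence level, default 0.95.
#' @return named numeric vector `c(low, high)`, each in [0, 1].
#' @export
wilson_interval <- function(n_success, n, confidence = 0.95) {
  if (length(n) != 1L || n <= 0) {
    stop("undefined interval: n must be positive", call. = FALSE)
  }
  if (n_success < 0 || n_success > n) {
    stop("invalid counts: need 0 <= n_success <= n", call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  phat <- n_success / n
  den <- 1 + z^2 / n
  centre <- (phat + z^2 / (2 * n)) / den
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / den
  c(low = max(0, centre - half), high = min(1, centre + half))
}

# Vectorised decision-tree leaf assignment over a cohort data.frame.
# Same traversal as classify(); agreement is asserted by tests.
.branch_of_cohort <- function(df, config = decision_config()) {
  n <- nrow(df)
  branch <- rep(NA_character_, n)
  for (cn in c("clavicle_stage", "i3m")) {
    if (!cn %in% names(df)) df[[cn]] <- NA_real_
  }
  if (!"molar_assessable" %in% names(df)) df$molar_assessable <- FALSE
  if (!"abnormal_growth" %in% names(df)) df$abnormal_growth <- FALSE

  abnormal <- as.logical(df$abnormal_growth)
  branch[abnormal] <- "abnormal_growth"

  tanner_low <- is.na(branch) &
    (df$tanner_pubic_hair < 5L | df$tanner_second < 5L)
  branch[tanner_low] <- "tanner_incomplete"

  teeth_cols <- paste0("teeth_", 31:37)
  if (!all(teeth_cols %in% names(df))) {
    teeth_all <- rep(NA, n)
  } else {
    teeth_all <- Reduce(`&`, lapply(teeth_cols, function(cn) as.logical(df[[cn]])))
  }
  branch[is.na(branch) & is.na(teeth_all)] <- "opt_missing"
  branch[is.na(branch) & !teeth_all] <- "teeth_incomplete"

  open <- is.na(branch)
  assess <- as.logical(df$molar_assessable)
  clav_mature <- !is.na(df$clavicle_stage) & df$clavicle_stage >= 4L

  low <- open & assess & df$i3m < config$i3m_low_threshold
  branch[low & clav_mature] <- "clavicle_mature"
  branch[low & !clav_mature] <- "i3m_low_clavicle_immature"
  branch[open & assess & df$i3m >= config$i3m_low_threshold &
           df$i3m < config$i3m_high_threshold] <- "i3m_mid"
  branch[open & assess & df$i3m >= config$i3m_high_threshold] <- "i3m_high"

  branch[open & !assess & clav_mature] <- "clavicle_mature"
  branch[open & !assess & !clav_mature & !is.na(df$clavicle_stage)] <-
    "molar_unassessable_clavicle_immature"
  branch[open & !assess & is.na(df$clavicle_stage)] <- "missing_evidence"
  branch
}

# classification implied by a leaf under a config (mirrors classify())
.classification_of_branch <- function(branch, config = decision_config()) {
  thr <- config$adult_declaration_threshold_percent
  vapply(branch, function(b) {
    switch(b,
      abnormal_growth = "INDETERMINATE",
      opt_missing = "INDETERMINATE",
      missing_evidence = "INDETERMINATE",
      tanner_incomplete = "PRESUMED_MINOR",
      teeth_incomplete = "MINOR",
      clavicle_mature = "ADULT",
      i3m_low_clavicle_immature =
        if (config$prob_clavicle_immature_percent >= thr) "ADULT" else "PRESUMED_MINOR",
      i3m_mid = "PRESUMED_MINOR",
      i3m_high = "PRESUMED_MINOR",
      molar_unassessable_clavicle_immature =
        if (config$unassessable_molar_immature_clavicle_policy == "apply_96" &&
            config$prob_clavicle_immature_percent >= thr) "ADULT" else "INDETERMINATE",
      stop("unknown branch identifier: ", b))
  }, character(1L), USE.NAMES = FALSE)
}

#' Estimate conditional adult probabilities per decision branch
#'
#' Runs every subject of a cohort with known true ages through the decision
#' tree and tabulates, per reached leaf, the fraction whose true age is at
#' least 18, with Wilson confidence bounds. The clavicle-below-stage-4
#' marginal (all subjects with an unfused clavicle, irrespective of any other
#' evidence) is reported alongside the leaf table, not inside it, matching
#' how that figure is framed in the source.
#'
#' @param cohort a `maturation_cohort`, or any data.frame with the observed
#'   assessment columns plus `true_age`.
#' @param config a [decision_config()].
#' @param confidence confidence level for the Wilson bounds.
#' @param paper_values optional named vector of reference percentages to
#'   attach per branch (defaults to the published 99.9/96/60/16).
#' @return an object of class `branch_probability_table`: a list with
#'   `leaves` (data.frame: branch, n, n_adult, p_hat, ci_low, ci_high,
#'   paper_value_percent) and `clavicle_below_stage4` (one-row data.frame for
#'   the marginal).
#' @export
estimate_branch_probabilities <- function(cohort, config = decision_config(),
                                          confidence = 0.95,
                                          paper_values = c(
                                            clavicle_mature = 99.9,
                                            i3m_low_clavicle_immature = 96,
                                            i3m_mid = 60,
                                            i3m_high = 16)) {
  df <- as.data.frame(cohort)
  if (nrow(df) == 0L) {
    return(structure(list(leaves = data.frame(branch = character(),
                                              n = integer(), n_adult = integer(),
                                              p_hat = numeric(), ci_low = numeric(),
                                              ci_high = numeric(),
                                              paper_value_percent = numeric()),
                          clavicle_below_stage4 = NULL,
                          confidence = confidence),
                     class = "branch_probability_table"))
  }
  stopifnot("true_age" %in% names(df))
  branch <- .branch_of_cohort(df, config)
  adult <- df$true_age >= 18

  rows <- lapply(split(seq_len(nrow(df)), branch), function(idx) {
    n <- length(idx); na <- sum(adult[idx])
    ci <- wilson_interval(na, n, confidence)
    data.frame(n = n, n_adult = na, p_hat = na / n,
               ci_low = ci[["low"]], ci_high = ci[["high"]])
  })
  leaves <- do.call(rbind, rows)
  leaves <- cbind(branch = names(rows), leaves)
  rownames(leaves) <- NULL
  leaves$paper_value_percent <- unname(paper_values[leaves$branch])
  # stable order: tree traversal order
  leaves <- leaves[order(match(leaves$branch, .LEAVES)), , drop = FALSE]
  rownames(leaves) <- NULL

  below4 <- !is.na(df$clavicle_stage) & df$clavicle_stage < 4L
  marg <- NULL
  if (any(below4)) {
    n <- sum(below4); na <- sum(adult[below4])
    ci <- wilson_interval(na, n, confidence)
    marg <- data.frame(branch = "clavicle_below_stage4_marginal",
                       n = n, n_adult = na, p_hat = na / n,
                       ci_low = ci[["low"]], ci_high = ci[["high"]],
                       paper_value_percent = 46)
  }
  structure(list(leaves = leaves, clavicle_below_stage4 = marg,
                 confidence = confidence),
            class = "branch_probability_table")
}

#' @export
print.branch_probability_table <- function(x, ...) {
  cat(sprintf("Branch-conditional adult probabilities (Wilson %g%% CI)\n",
              100 * x$confidence))
  if (nrow(x$leaves) == 0L) {
    cat("  (empty cohort)\n")
    return(invisible(x))
  }
  show <- x$leaves
  show$p_hat <- sprintf("%.1f%%", 100 * show$p_hat)
  show$ci <- sprintf("[%.1f, %.1f]", 100 * x$leaves$ci_low, 100 * x$leaves$ci_high)
  show$ci_low <- show$ci_high <- NULL
  print(show, row.names = FALSE)
  if (!is.null(x$clavicle_below_stage4)) {
    m <- x$clavicle_below_stage4
    cat(sprintf("Marginal, clavicle below stage 4: %d/%d adult = %.1f%% [%.1f, %.1f] (reference 46%%)\n",
                m$n_adult, m$n, 100 * m$p_hat, 100 * m$ci_low, 100 * m$ci_high))
  }
  invisible(x)
}

#' Misclassification accounting against known true ages
#'
#' Counts true adults classified MINOR or PRESUMED_MINOR (safe, expected
#' under in dubio pro reo) and true minors classified ADULT (the error that
#' must be rare); the latter are flagged individually.
#'
#' @param cohort a `maturation_cohort` or data.frame with observed columns
#'   and `true_age`.
#' @param config a [decision_config()].
#' @return an object of class `misclassification_report`: list with counts,
#'   rates, and `minor_as_adult_subjects` (data.frame of flagged cases).
#' @export
misclassification_report <- function(cohort, config = decision_config()) {
  df <- as.data.frame(cohort)
  branch <- .branch_of_cohort(df, config)
  cls <- .classification_of_branch(branch, config)
  adult <- df$true_age >= 18

  adult_as_minor <- adult & cls %in% c("MINOR", "PRESUMED_MINOR")
  minor_as_adult <- !adult & cls == "ADULT"
  flagged <- df[minor_as_adult, intersect(c("subject_id", "true_age"), names(df)),
                drop = FALSE]
  if (nrow(flagged)) flagged$branch <- branch[minor_as_adult]

  structure(list(
    n = nrow(df),
    n_adult = sum(adult),
    n_minor = sum(!adult),
    adult_as_minor = sum(adult_as_minor),
    minor_as_adult = sum(minor_as_adult),
    adult_as_minor_rate = if (sum(adult)) sum(adult_as_minor) / sum(adult) else 0,
    minor_as_adult_rate = if (sum(!adult)) sum(minor_as_adult) / sum(!adult) else 0,
    minor_as_adult_subjects = flagged
  ), class = "misclassification_report")
}

#' @export
print.misclassification_report <- function(x, ...) {
  cat("Misclassification report\n")
  cat(sprintf("  %d subjects (%d adults, %d minors)\n", x$n, x$n_adult, x$n_minor))
  cat(sprintf("  adults under-classified (MINOR/PRESUMED_MINOR): %d (%.2f%% of adults)\n",
              x$adult_as_minor, 100 * x$adult_as_minor_rate))
  cat(sprintf("  minors classified ADULT:                        %d (%.2f%% of minors)\n",
              x$minor_as_adult, 100 * x$minor_as_adult_rate))
  if (nrow(x$minor_as_adult_subjects)) {
    cat("  flagged minor-as-adult cases:\n")
    print(utils::head(x$minor_as_adult_subjects, 20), row.names = FALSE)
  }
  invisible(x)
}

#' Sample-distribution summary in the published table shape
#'
#' Cross-tabulates a cohort by completed age year, sex and available
#' modality (hand, teeth, third molar, clavicle), in the same 8-column shape
#' as the published sample-distribution table, plus a totals row.
#'
#' For a simulated cohort every modality is counted as available except the
#' third molar when not assessable; for user-supplied data an absent column
#' counts as unavailable.
#'
#' @param cohort a `maturation_cohort` or data.frame with `true_age`, `sex`
#'   and (optionally) `hand_complete`, `teeth_31`..`teeth_37`,
#'   `molar_assessable`, `clavicle_stage` columns.
#' @return an object of class `cohort_summary`: list with `counts` (matrix,
#'   one row per age year, columns hand_m, hand_f, teeth_m, teeth_f, molar_m,
#'   molar_f, clavicle_m, clavicle_f) and `totals` (named vector of column
#'   sums).
#' @export
cohort_summary_table <- function(cohort) {
  df <- as.data.frame(cohort)
  cols <- c("hand_m", "hand_f", "teeth_m", "teeth_f",
            "molar_m", "molar_f", "clavicle_m", "clavicle_f")
  if (nrow(df) == 0L) {
    counts <- matrix(0L, nrow = 0L, ncol = 8L, dimnames = list(NULL, cols))
    return(structure(list(counts = counts,
                          totals = stats::setNames(integer(8L), cols)),
                     class = "cohort_summary"))
  }
  stopifnot(all(c("true_age", "sex") %in% names(df)))
  year <- floor(df$true_age)
  years <- sort(unique(year))
  has <- function(cn) if (cn %in% names(df)) !is.na(df[[cn]]) else rep(FALSE, nrow(df))
  avail <- cbind(hand = has("hand_complete"),
                 teeth = has("teeth_31"),
                 molar = if ("molar_assessable" %in% names(df))
                   as.logical(df$molar_assessable) else rep(FALSE, nrow(df)),
                 clavicle = has("clavicle_stage"))
  counts <- matrix(0L, nrow = length(years), ncol = 8L,
                   dimnames = list(as.character(years), cols))
  for (i in seq_along(years)) {
    for (m in 1:4) {
      for (s in 1:2) {
        sex <- c("male", "female")[s]
        counts[i, (m - 1L) * 2L + s] <-
          sum(year == years[i] & df$sex == sex & avail[, m])
      }
    }
  }
  structure(list(counts = counts, totals = colSums(counts)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Sample distribution by age, sex and anatomical region\n")
  cat(sprintf("%-6s %5s %5s %7s %7s %7s %7s %9s %9s\n", "Years",
              "HandM", "HandF", "TeethM", "TeethF", "MolarM", "MolarF",
              "ClavM", "ClavF"))
  for (i in seq_len(nrow(x$counts))) {
    cat(sprintf("%-6s %5d %5d %7d %7d %7d %7d %9d %9d\n",
                rownames(x$counts)[i],
                x$counts[i, 1L], x$counts[i, 2L], x$counts[i, 3L],
                x$counts[i, 4L], x$counts[i, 5L], x$counts[i, 6L],
                x$counts[i, 7L], x$counts[i, 8L]))
  }
  cat(sprintf("%-6s %5d %5d %7d %7d %7d %7d %9d %9d\n", "Total",
              x$totals[1L], x$totals[2L], x$totals[3L], x$totals[4L],
              x$totals[5L], x$totals[6L], x$totals[7L], x$totals[8L]))
  invisible(x)
}
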