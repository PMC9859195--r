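# CSV schema, version 1.0. Empty cell = modality absent; a literal "NA" is
# rejected to avoid silent coercion.
.SCHEMA_VERSION <- "1.0"
.SCHEMA_COLS <- c("schema_version", "subject_id", "sex", "tanner_pubic_hair",
                  "tanner_second", "abnormal_growth", "hand_complete", "bo_ca",
                  paste0("teeth_", 31:37), "molar_assessable", "molar_gaps",
                  "molar_tooth_length_mm", "clavicle_stage", "true_age")
.SAMPLE_TABLE_MD5 <- "d3e87eb74aa7cb7d646578c8b8ed8951"

#' Packaged sample-distribution table
#'
#' Loads the packaged reference table of sample counts by age year, sex and
#' anatomical region (hand/wrist, seven teeth, third molar, clavicle), as a
#' [cohort_summary_table()]-shaped object. The packaged CSV is
#' checksum-verified and cross-footed (the totals row must equal the column
#' sums) on every load.
#'
#' @return an object of class `cohort_summary`.
#' @export
load_sample_distribution <- function() {
  path <- system.file("extdata", "sample_distribution.csv",
                      package = "ageflow", mustWork = TRUE)
  if (unname(tools::md5sum(path)) != .SAMPLE_TABLE_MD5) {
    stop("integrity error: packaged sample-distribution table is corrupted (checksum mismatch)",
         call. = FALSE)
  }
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  counts <- as.matrix(x[x$age != "Total", -1L, drop = FALSE])
  rownames(counts) <- x$age[x$age != "Total"]
  storage.mode(counts) <- "integer"
  totals <- as.integer(x[x$age == "Total", -1L])
  names(totals) <- colnames(counts)
  if (!identical(unname(colSums(counts)), as.numeric(totals))) {
    stop("integrity error: totals row does not equal column sums", call. = FALSE)
  }
  structure(list(counts = counts, totals = totals), class = "cohort_summary")
}

.parse_flag <- function(x, row, col) {
  v <- tolower(trimws(x))
  if (v %in% c("true", "yes", "1")) return(TRUE)
  if (v %in% c("false", "no", "0")) return(FALSE)
  stop(sprintf("row %d: column %s must be a boolean, got '%s'", row, col, x),
       call. = FALSE)
}

.parse_num <- function(x, row, col) {
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v)) {
    stop(sprintf("row %d: column %s must be numeric, got '%s'", row, col, x),
         call. = FALSE)
  }
  v
}

.row_to_subject <- function(r, row, bo_ca_complete_cutoff = 1.0) {
  blank <- function(x) is.na(x) || !nzchar(trimws(x))
  if (any(vapply(r, function(x) identical(trimws(x), "NA"), logical(1L)))) {
    stop(sprintf("row %d: literal 'NA' is not accepted; leave the cell empty for an absent value", row),
         call. = FALSE)
  }
  ver <- strsplit(r[["schema_version"]], ".", fixed = TRUE)[[1L]]
  if (ver[1L] != strsplit(.SCHEMA_VERSION, ".", fixed = TRUE)[[1L]][1L]) {
    stop(sprintf("row %d: unsupported schema major version '%s'", row,
                 r[["schema_version"]]), call. = FALSE)
  }
  exam <- physical_exam(
    tanner_pubic_hair = .parse_num(r[["tanner_pubic_hair"]], row, "tanner_pubic_hair"),
    tanner_second = .parse_num(r[["tanner_second"]], row, "tanner_second"),
    sex = trimws(r[["sex"]]),
    abnormal_growth_signs = .parse_flag(r[["abnormal_growth"]], row, "abnormal_growth"))

  hand <- NULL
  if (!blank(r[["hand_complete"]])) {
    hand <- .parse_flag(r[["hand_complete"]], row, "hand_complete")
  } else if (!blank(r[["bo_ca"]])) {
    # no direct flag: completeness derived from the Bo/Ca ratio cutoff
    hand <- .parse_num(r[["bo_ca"]], row, "bo_ca") >= bo_ca_complete_cutoff
  }

  teeth <- NULL
  tcols <- paste0("teeth_", 31:37)
  tvals <- vapply(tcols, function(cn) r[[cn]], character(1L))
  if (!all(vapply(tvals, function(x) blank(x), logical(1L)))) {
    if (any(vapply(tvals, blank, logical(1L)))) {
      stop(sprintf("row %d: all seven teeth flags must be present together", row),
           call. = FALSE)
    }
    flags <- vapply(seq_along(tcols),
                    function(i) .parse_flag(tvals[i], row, tcols[i]), logical(1L))
    teeth <- seven_teeth_assessment(stats::setNames(flags, as.character(31:37)))
  }

  molar <- NULL
  if (!blank(r[["molar_assessable"]])) {
    assessable <- .parse_flag(r[["molar_assessable"]], row, "molar_assessable")
    if (assessable) {
      if (blank(r[["molar_tooth_length_mm"]])) {
        stop(sprintf("row %d: assessable third molar needs molar_tooth_length_mm", row),
             call. = FALSE)
      }
      gaps <- if (blank(r[["molar_gaps"]])) numeric() else
        vapply(strsplit(trimws(r[["molar_gaps"]]), ";")[[1L]],
               function(g) .parse_num(g, row, "molar_gaps"), numeric(1L))
      if (any(gaps < 0)) {
        stop(sprintf("row %d: negative apex gap", row), call. = FALSE)
      }
      molar <- third_molar_assessment(TRUE,
        apex_measurement(unname(gaps),
                         .parse_num(r[["molar_tooth_length_mm"]], row,
                                    "molar_tooth_length_mm")))
    } else {
      molar <- third_molar_assessment(FALSE)
    }
  }

  clav <- NULL
  if (!blank(r[["clavicle_stage"]])) {
    st <- .parse_num(r[["clavicle_stage"]], row, "clavicle_stage")
    if (st < 1 || st > 5 || st != as.integer(st)) {
      stop(sprintf("row %d: clavicle_stage must be an integer in 1..5, got %s",
                   row, r[["clavicle_stage"]]), call. = FALSE)
    }
    clav <- clavicle_assessment(st)
  }

  s <- subject_assessment(r[["subject_id"]], exam, hand = hand, teeth = teeth,
                          third_molar = molar, clavicle = clav)
  if (!blank(r[["true_age"]])) {
    attr(s, "true_age") <- .parse_num(r[["true_age"]], row, "true_age")
  }
  s
}

#' Read subject assessment records
#'
#' Reads the flat per-subject CSV schema (version 1.0) or its JSON
#' equivalent into [subject_assessment()] objects, order-preserving. Unknown
#' columns are rejected by name. In strict mode (default) the first malformed
#' row aborts the read; otherwise malformed rows are dropped and collected
#' into a structured error report attached as attribute `"errors"`
#' (data.frame with `row` and `message`).
#'
#' @param path input file.
#' @param format `"csv"` or `"json"` (default guessed from the extension).
#' @param strict abort on first malformed row?
#' @return list of `subject_assessment` objects; rows carrying a `true_age`
#'   get it attached as an attribute of the element.
#' @export
read_subjects <- function(path, format = c("auto", "csv", "json"),
                          strict = TRUE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)

  if (format == "csv") {
    raw <- utils::read.csv(path, colClasses = "character",
                           stringsAsFactors = FALSE, na.strings = NULL)
  } else {
    rec <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    raw <- as.data.frame(lapply(rec, function(col) {
      col <- as.character(col)
      col[is.na(col) | col == "NULL"] <- ""
      col
    }), stringsAsFactors = FALSE)
  }
  unknown <- setdiff(names(raw), .SCHEMA_COLS)
  if (length(unknown)) {
    stop("unknown column(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  missing_cols <- setdiff(.SCHEMA_COLS, names(raw))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }

  out <- vector("list", nrow(raw))
  errs <- list()
  for (i in seq_len(nrow(raw))) {
    res <- tryCatch(.row_to_subject(as.list(raw[i, , drop = FALSE]), i),
                    error = function(e) e)
    if (inherits(res, "error")) {
      if (strict) stop(conditionMessage(res), call. = FALSE)
      errs[[length(errs) + 1L]] <- data.frame(row = i,
                                              message = conditionMessage(res),
                                              stringsAsFactors = FALSE)
      out[i] <- list(NULL)
    } else {
      out[[i]] <- res
    }
  }
  out <- out[!vapply(out, is.null, logical(1L))]
  attr(out, "errors") <- if (length(errs)) do.call(rbind, errs) else
    data.frame(row = integer(), message = character(), stringsAsFactors = FALSE)
  out
}

.subject_to_row <- function(s) {
  blank <- ""
  molar <- s$third_molar
  hand_flag <- blank; bo_ca <- blank
  if (!is.null(s$hand)) {
    if (inherits(s$hand, "carpal_radiograph")) {
      bo_ca <- format(compute_bo_ca(s$hand), digits = 15)
    } else {
      hand_flag <- tolower(as.character(s$hand))
    }
  }
  teeth <- if (is.null(s$teeth)) rep(blank, 7L) else
    tolower(as.character(s$teeth$apices_closed))
  row <- c(schema_version = .SCHEMA_VERSION,
           subject_id = s$subject_id,
           sex = s$exam$sex,
           tanner_pubic_hair = as.character(s$exam$tanner_pubic_hair),
           tanner_second = as.character(s$exam$tanner_second),
           abnormal_growth = tolower(as.character(s$exam$abnormal_growth_signs)),
           hand_complete = hand_flag,
           bo_ca = bo_ca,
           stats::setNames(teeth, paste0("teeth_", 31:37)),
           molar_assessable = if (is.null(molar)) blank else
             tolower(as.character(molar$assessable)),
           molar_gaps = if (!is.null(molar) && molar$assessable)
             paste(format(molar$measurement$open_apex_gaps, digits = 15,
                          trim = TRUE), collapse = ";") else blank,
           molar_tooth_length_mm = if (!is.null(molar) && molar$assessable)
             format(molar$measurement$tooth_length, digits = 15) else blank,
           clavicle_stage = if (is.null(s$clavicle)) blank else
             as.character(s$clavicle$schmeling_stage),
           true_age = if (is.null(attr(s, "true_age"))) blank else
             format(attr(s, "true_age"), digits = 15))
  row
}

#' Write subject assessment records
#'
#' Inverse of [read_subjects()]: serialises assessments to the flat CSV
#' schema (UTF-8, comma-separated, `.` decimal separator, semicolon-joined
#' gap lists, empty cell = absent) or the JSON equivalent. Output is always
#' re-readable by [read_subjects()].
#'
#' @param subjects list of [subject_assessment()] objects.
#' @param path output file.
#' @param format `"csv"` or `"json"` (default guessed from the extension).
#' @return `path`, invisibly.
#' @export
write_subjects <- function(subjects, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  rows <- lapply(subjects, .subject_to_row)
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  if (length(rows) == 0L) {
    df <- as.data.frame(matrix(character(), ncol = length(.SCHEMA_COLS),
                               dimnames = list(NULL, .SCHEMA_COLS)),
                        stringsAsFactors = FALSE)
  }
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  } else {
    jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Serialise outcomes to a flat data.frame
#'
#' @param outcomes list of `age_decision` objects.
#' @return data.frame with one row per outcome.
#' @export
outcomes_frame <- function(outcomes) {
  do.call(rbind, lapply(outcomes, as.data.frame))
}

# ---- configuration (de)serialisation ------------------------------------

#' Read or write a decision-model configuration as JSON
#'
#' @param path JSON file.
#' @return `read_decision_config` returns a [decision_config()];
#'   `write_decision_config` returns `path` invisibly.
#' @export
read_decision_config <- function(path) {
  x <- jsonlite::fromJSON(path)
  x <- lapply(x, function(v) if (is.numeric(v)) as.numeric(v) else v)
  do.call(decision_config, x)
}

#' @rdname read_decision_config
#' @param config a [decision_config()].
#' @export
write_decision_config <- function(config, path) {
  stopifnot(inherits(config, "decision_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read or write a simulator configuration as JSON
#'
#' Infinite truncation bounds are stored as the string `"Inf"`.
#'
#' @param path JSON file.
#' @return `read_simulator_config` returns a [simulator_config()];
#'   `write_simulator_config` returns `path` invisibly.
#' @export
read_simulator_config <- function(path) {
  x <- jsonlite::fromJSON(path)
  denum <- function(v) {
    if (is.list(v)) lapply(v, denum)
    else if (is.character(v) && all(v %in% c("Inf", "-Inf"))) as.numeric(v)
    else v
  }
  do.call(simulator_config, denum(x))
}

#' @rdname read_simulator_config
#' @param config a [simulator_config()].
#' @export
write_simulator_config <- function(config, path) {
  stopifnot(inherits(config, "simulator_config"))
  ennum <- function(v) {
    if (is.list(v)) lapply(v, ennum)
    else if (is.numeric(v) && any(is.infinite(v))) as.character(v)
    else v
  }
  jsonlite::write_json(ennum(unclass(config)), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' Write and read back a simulated cohort as CSV
#'
#' @param cohort a `maturation_cohort`.
#' @param path CSV file.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` the
#'   cohort data.frame (class restored, generating config not preserved).
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "maturation_cohort"))
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(df) <- c("maturation_cohort", "data.frame")
  df
}
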