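#' Open-apex measurement of a tooth
#'
#' Records the widths of the still-open root apices of a tooth (distance in mm
#' between the inner sides of each open apex) together with the tooth length.
#' An empty gap vector means all apices are radiographically closed. Lower
#' third molars typically have two roots, hence up to two gaps, but any
#' non-negative number of gaps is accepted: the maturity index is a sum, so
#' single-rooted and multi-rooted variants need no special casing.
#'
#' @param open_apex_gaps numeric vector of gap widths in mm (possibly empty);
#'   every gap must be >= 0. Gaps at or below `closed_epsilon` are treated as
#'   closed.
#' @param tooth_length tooth length in mm, strictly positive.
#' @param closed_epsilon gaps `<= closed_epsilon` count as closed (default 0,
#'   i.e. exact); digitisation-noise handling is the caller's choice.
#' @return an object of class `apex_measurement`.
#' @seealso [compute_i3m()]
#' @export
apex_measurement <- function(open_apex_gaps = numeric(), tooth_length,
                             closed_epsilon = 0) {
  open_apex_gaps <- as.numeric(open_apex_gaps)
  tooth_length <- as.numeric(tooth_length)
  if (length(tooth_length) != 1L || !is.finite(tooth_length) || tooth_length <= 0) {
    stop("invalid measurement: tooth_length must be a single positive number",
         call. = FALSE)
  }
  if (anyNA(open_apex_gaps) || any(!is.finite(open_apex_gaps))) {
    stop("invalid measurement: apex gaps must be finite", call. = FALSE)
  }
  if (any(open_apex_gaps < 0)) {
    stop("invalid measurement: apex gaps must be non-negative", call. = FALSE)
  }
  if (closed_epsilon < 0) {
    stop("invalid measurement: closed_epsilon must be non-negative", call. = FALSE)
  }
  structure(list(open_apex_gaps = open_apex_gaps,
                 tooth_length = tooth_length,
                 closed_epsilon = closed_epsilon),
            class = "apex_measurement")
}

#' @export
print.apex_measurement <- function(x, ...) {
  cat(sprintf("<apex_measurement: %d open apex gap(s), tooth length %.2f mm, I3M = %.4f>\n",
              sum(x$open_apex_gaps > x$closed_epsilon), x$tooth_length,
              compute_i3m(x)))
  invisible(x)
}

#' Third molar maturity index (I3M)
#'
#' If every root apex is closed the index is exactly 0; otherwise it is the
#' sum of the open-apex gap widths divided by the tooth length. The index is
#' dimensionless, non-negative, and decreases towards 0 as the root apices
#' mature.
#'
#' The zero case is exact: an empty gap vector, or gaps all at or below the
#' measurement's `closed_epsilon`, yields `0` with no floating-point residue.
#'
#' @param m an [apex_measurement()].
#' @return the I3M value (>= 0).
#' @examples
#' compute_i3m(apex_measurement(c(1.5, 1.2), 15)) # 0.18
#' compute_i3m(apex_measurement(numeric(), 15))   # exactly 0
#' @export
compute_i3m <- function(m) {
  stopifnot(inherits(m, "apex_measurement"))
  gaps <- m$open_apex_gaps[m$open_apex_gaps > m$closed_epsilon]
  if (length(gaps) == 0L) return(0)
  sum(gaps) / m$tooth_length
}

#' Seven left mandibular teeth: apex-closure assessment
#'
#' Closure flags for the roots of the seven left mandibular teeth from the
#' central incisor to the second molar (FDI 31-37). Every flag must be a
#' definite TRUE/FALSE; a tooth that cannot be evaluated is an input error at
#' this layer, to be resolved upstream.
#'
#' @param apices_closed logical vector of length 7, optionally named with the
#'   FDI numbers "31".."37" (order is taken from the names when present).
#' @return an object of class `seven_teeth_assessment`.
#' @export
seven_teeth_assessment <- function(apices_closed) {
  fdi <- as.character(31:37)
  if (length(apices_closed) != 7L) {
    stop("invalid assessment: exactly seven teeth (FDI 31-37) are required",
         call. = FALSE)
  }
  if (!is.logical(apices_closed) || anyNA(apices_closed)) {
    stop("invalid assessment: each closure flag must be TRUE or FALSE",
         call. = FALSE)
  }
  if (!is.null(names(apices_closed))) {
    if (!setequal(names(apices_closed), fdi)) {
      stop("invalid assessment: names must be the FDI numbers 31..37",
           call. = FALSE)
    }
    apices_closed <- apices_closed[fdi]
  } else {
    names(apices_closed) <- fdi
  }
  structure(list(apices_closed = apices_closed),
            class = "seven_teeth_assessment")
}

#' @export
print.seven_teeth_assessment <- function(x, ...) {
  open <- names(x$apices_closed)[!x$apices_closed]
  if (length(open) == 0L) {
    cat("<seven_teeth_assessment: all apices closed>\n")
  } else {
    cat(sprintf("<seven_teeth_assessment: open apices at FDI %s>\n",
                paste(open, collapse = ", ")))
  }
  invisible(x)
}

#' Are all seven left mandibular teeth mature?
#'
#' @param t a [seven_teeth_assessment()].
#' @return TRUE iff all seven apices are closed.
#' @export
teeth_complete <- function(t) {
  stopifnot(inherits(t, "seven_teeth_assessment"))
  all(t$apices_closed)
}

#' Maturity band of an I3M value
#'
#' Partitions the non-negative axis at the published cut-offs into three
#' bands: `"BELOW_008"` for values below the low threshold, `"MID_008_015"`
#' from the low threshold up to (but excluding) the high threshold, and
#' `"AT_LEAST_015"` at or above the high threshold. The boundary value at the
#' low threshold is assigned to the middle (less-adult) band, the conservative
#' reading under in dubio pro reo.
#'
#' @param i3m non-negative I3M value(s); vectorised.
#' @param low,high band thresholds (defaults 0.08 and 0.15).
#' @return a factor with levels `BELOW_008`, `MID_008_015`, `AT_LEAST_015`.
#' @export
i3m_band <- function(i3m, low = 0.08, high = 0.15) {
  if (!(low > 0 && high > low)) {
    stop("invalid thresholds: need 0 < low < high", call. = FALSE)
  }
  if (anyNA(i3m) || any(i3m < 0)) {
    stop("invalid measurement: I3M must be non-negative", call. = FALSE)
  }
  lev <- c("BELOW_008", "MID_008_015", "AT_LEAST_015")
  band <- ifelse(i3m < low, lev[1L], ifelse(i3m < high, lev[2L], lev[3L]))
  factor(band, levels = lev)
}
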