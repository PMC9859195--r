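# Shared fixtures: canonical subjects, random simple polygons, and the
# Monte-Carlo point-in-union oracle used to cross-check the exact geometry.

unit_square <- function(x0 = 0, y0 = 0, side = 1) {
  polygon2d(cbind(c(0, side, side, 0) + x0, c(0, 0, side, side) + y0))
}

# random simple polygon around a centre: vertices at sorted angles with
# random radii, rejection-sampled because a large angular gap or a strongly
# re-entrant radius can still make the closing chords cross
random_simple_polygon <- function(n_vertices = 8, centre = c(0, 0),
                                  radius = 1) {
  for (attempt in 1:100) {
    ang <- sort(stats::runif(n_vertices, 0, 2 * pi))
    r <- stats::runif(n_vertices, 0.3 * radius, radius)
    p <- tryCatch(
      polygon2d(cbind(centre[1] + r * cos(ang), centre[2] + r * sin(ang))),
      error = function(e) NULL)
    if (!is.null(p)) return(p)
  }
  stop("could not draw a simple polygon in 100 attempts")
}

point_in_polygon <- function(px, py, v) {
  n <- nrow(v)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]; xj <- v[j, 1]; yj <- v[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# Monte-Carlo union-area estimate with its standard error
mc_union_area <- function(ps, n_points = 1e5) {
  vs <- lapply(ps, function(p) p$vertices)
  xs <- range(unlist(lapply(vs, function(v) v[, 1])))
  ys <- range(unlist(lapply(vs, function(v) v[, 2])))
  px <- stats::runif(n_points, xs[1], xs[2])
  py <- stats::runif(n_points, ys[1], ys[2])
  inside <- rep(FALSE, n_points)
  for (v in vs) inside <- inside | point_in_polygon(px, py, v)
  abb <- diff(xs) * diff(ys)
  p <- mean(inside)
  list(est = p * abb, se = abb * sqrt(p * (1 - p) / n_points))
}

# apex measurement realising a given I3M on a 15 mm tooth (two equal gaps)
i3m_measurement <- function(i3m, tooth_length = 15) {
  if (i3m <= 0) return(apex_measurement(numeric(), tooth_length))
  apex_measurement(rep(i3m * tooth_length / 2, 2), tooth_length)
}

# subject on the canonical path: Tanner 5/5, all seven teeth closed, third
# molar assessable with the given I3M, optional clavicle stage
canonical_subject <- function(i3m = NULL, clavicle_stage = NULL,
                              teeth_closed = rep(TRUE, 7),
                              tanner = c(5L, 5L), sex = "male",
                              abnormal = FALSE, hand = NULL,
                              teeth_present = TRUE, molar_present = TRUE,
                              id = "subj") {
  molar <- if (!molar_present) NULL
    else if (is.null(i3m)) third_molar_assessment(FALSE)
    else third_molar_assessment(TRUE, i3m_measurement(i3m))
  subject_assessment(
    id,
    physical_exam(tanner[1], tanner[2], sex, abnormal),
    hand = hand,
    teeth = if (teeth_present) seven_teeth_assessment(teeth_closed) else NULL,
    third_molar = molar,
    clavicle = if (is.null(clavicle_stage)) NULL else
      clavicle_assessment(clavicle_stage))
}

# minimal observed-cohort data.frame accepted by the evaluators
manual_cohort <- function(n, true_age, clavicle_stage = 2L, i3m = 0,
                          molar_assessable = TRUE, teeth_closed = TRUE,
                          tanner = 5L, sex = "male") {
  df <- data.frame(subject_id = sprintf("M%03d", seq_len(n)),
                   true_age = rep_len(true_age, n),
                   sex = rep_len(sex, n),
                   tanner_pubic_hair = rep_len(as.integer(tanner), n),
                   tanner_second = rep_len(as.integer(tanner), n),
                   abnormal_growth = rep_len(FALSE, n),
                   hand_complete = rep_len(TRUE, n),
                   molar_assessable = rep_len(molar_assessable, n),
                   i3m = rep_len(i3m, n),
                   clavicle_stage = rep_len(as.integer(clavicle_stage), n),
                   stringsAsFactors = FALSE)
  for (k in 31:37) df[[paste0("teeth_", k)]] <- rep_len(teeth_closed, n)
  df
}
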