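#' Simple 2-D polygon in millimetres
#'
#' Constructs a validated simple (non-self-intersecting) polygon from an
#' ordered set of vertices. The polygon is implicitly closed: the last vertex
#' connects back to the first. Vertex orientation (clockwise or
#' counter-clockwise) is irrelevant to every downstream computation.
#'
#' @param vertices a two-column numeric matrix (or data.frame, or a list of
#'   length-2 vectors) of (x, y) coordinates in mm, at least 3 rows.
#' @return an object of class `polygon2d`: a list with element `vertices`
#'   (numeric matrix, columns `x` and `y`).
#' @examples
#' p <- polygon2d(cbind(c(0, 4, 0), c(0, 0, 3)))
#' polygon_area(p) # 6
#' @export
polygon2d <- function(vertices) {
  if (is.data.frame(vertices)) vertices <- as.matrix(vertices)
  if (is.list(vertices) && !is.matrix(vertices)) {
    vertices <- do.call(rbind, lapply(vertices, function(v) as.numeric(v)))
  }
  if (!is.matrix(vertices) || ncol(vertices) != 2L || !is.numeric(vertices)) {
    stop("invalid geometry: vertices must be an n x 2 numeric matrix", call. = FALSE)
  }
  if (anyNA(vertices) || any(!is.finite(vertices))) {
    stop("invalid geometry: vertices must be finite", call. = FALSE)
  }
  # drop an explicitly repeated closing vertex
  n <- nrow(vertices)
  if (n >= 2L && all(vertices[1L, ] == vertices[n, ])) {
    vertices <- vertices[-n, , drop = FALSE]
    n <- n - 1L
  }
  if (n < 3L) {
    stop("invalid geometry: a polygon needs at least 3 vertices", call. = FALSE)
  }
  if (anyDuplicated(vertices)) {
    stop("invalid geometry: duplicated vertices", call. = FALSE)
  }
  colnames(vertices) <- c("x", "y")
  p <- structure(list(vertices = vertices), class = "polygon2d")
  if (.self_intersects(vertices)) {
    stop("invalid geometry: polygon is self-intersecting", call. = FALSE)
  }
  if (abs(.signed_area(vertices)) <= 0) {
    stop("invalid geometry: degenerate polygon with zero area", call. = FALSE)
  }
  p
}

#' @export
print.polygon2d <- function(x, ...) {
  cat(sprintf("<polygon2d: %d vertices, area %.4g mm^2>\n",
              nrow(x$vertices), polygon_area(x)))
  invisible(x)
}

as_polygon2d <- function(p) {
  if (inherits(p, "polygon2d")) p else polygon2d(p)
}

# shoelace formula, signed
.signed_area <- function(v) {
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

# orientation of ordered triple (counter-clockwise > 0)
.orient <- function(ax, ay, bx, by, cx, cy) {
  (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
}

.on_segment <- function(ax, ay, bx, by, px, py) {
  min(ax, bx) <= px && px <= max(ax, bx) &&
    min(ay, by) <= py && py <= max(ay, by)
}

# do closed segments (a,b) and (c,d) intersect?
.segments_intersect <- function(ax, ay, bx, by, cx, cy, dx, dy) {
  o1 <- .orient(ax, ay, bx, by, cx, cy)
  o2 <- .orient(ax, ay, bx, by, dx, dy)
  o3 <- .orient(cx, cy, dx, dy, ax, ay)
  o4 <- .orient(cx, cy, dx, dy, bx, by)
  if (((o1 > 0 && o2 < 0) || (o1 < 0 && o2 > 0)) &&
      ((o3 > 0 && o4 < 0) || (o3 < 0 && o4 > 0))) {
    return(TRUE)
  }
  (o1 == 0 && .on_segment(ax, ay, bx, by, cx, cy)) ||
    (o2 == 0 && .on_segment(ax, ay, bx, by, dx, dy)) ||
    (o3 == 0 && .on_segment(cx, cy, dx, dy, ax, ay)) ||
    (o4 == 0 && .on_segment(cx, cy, dx, dy, bx, by))
}

# self-intersection check over all non-adjacent edge pairs, O(n^2)
.self_intersects <- function(v) {
  n <- nrow(v)
  nxt <- c(seq_len(n)[-1L], 1L)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      # adjacent edges share a vertex; skip them (incl. edge n with edge 1)
      if (j == i + 1L || (i == 1L && j == n)) next
      if (.segments_intersect(v[i, 1L], v[i, 2L], v[nxt[i], 1L], v[nxt[i], 2L],
                              v[j, 1L], v[j, 2L], v[nxt[j], 1L], v[nxt[j], 2L])) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Area of a simple polygon
#'
#' Shoelace (Gauss) area of a validated [polygon2d()], in mm^2. The result is
#' the absolute enclosed area and does not depend on vertex orientation.
#'
#' @param p a `polygon2d` or anything [polygon2d()] accepts.
#' @return positive area in mm^2.
#' @export
polygon_area <- function(p) {
  p <- as_polygon2d(p)
  abs(.signed_area(p$vertices))
}

#' Area of the union of simple polygons
#'
#' Computes the exact area covered by the set union of simple polygons,
#' counting any overlapping region once. This is the "common area calculated
#' only once" rule needed for summed carpal bone areas.
#'
#' The algorithm is a vertical slab decomposition: the x-axis is cut at every
#' vertex abscissa and every pairwise edge intersection. Inside a slab no two
#' edges cross, so the covered vertical length is a linear function of x and
#' the midpoint rule integrates the union area exactly. No rasterisation or
#' sampling is involved.
#'
#' @param ps a list of `polygon2d` objects (or inputs accepted by
#'   [polygon2d()]). An empty list has union area 0 by convention.
#' @return area in mm^2, at most the sum of the individual areas, with
#'   equality exactly when the polygons are pairwise disjoint.
#' @examples
#' sq <- function(x0) polygon2d(cbind(c(0, 1, 1, 0) + x0, c(0, 0, 1, 1)))
#' union_area(list(sq(0), sq(0.5))) # 1.5
#' @export
union_area <- function(ps) {
  if (length(ps) == 0L) return(0)
  ps <- lapply(ps, as_polygon2d)

  # edge table: x1 y1 x2 y2, plus vertex abscissae
  edges <- do.call(rbind, lapply(ps, function(p) {
    v <- p$vertices
    n <- nrow(v)
    cbind(v[, 1L], v[, 2L], v[c(2:n, 1L), 1L], v[c(2:n, 1L), 2L])
  }))
  xs <- c(edges[, 1L], edges[, 3L])

  # pairwise proper intersections contribute interior slab boundaries
  m <- nrow(edges)
  for (i in seq_len(m - 1L)) {
    a <- edges[i, ]
    for (j in seq.int(i + 1L, m)) {
      b <- edges[j, ]
      d1x <- a[3L] - a[1L]; d1y <- a[4L] - a[2L]
      d2x <- b[3L] - b[1L]; d2y <- b[4L] - b[2L]
      den <- d1x * d2y - d1y * d2x
      if (den == 0) next # parallel/collinear: endpoints already critical
      t <- ((b[1L] - a[1L]) * d2y - (b[2L] - a[2L]) * d2x) / den
      u <- ((b[1L] - a[1L]) * d1y - (b[2L] - a[2L]) * d1x) / den
      if (t >= 0 && t <= 1 && u >= 0 && u <= 1) {
        xs <- c(xs, a[1L] + t * d1x)
      }
    }
  }

  xs <- sort(unique(xs))
  if (length(xs) < 2L) return(0)

  total <- 0
  for (k in seq_len(length(xs) - 1L)) {
    w <- xs[k + 1L] - xs[k]
    if (w <= 0) next
    xm <- (xs[k] + xs[k + 1L]) / 2
    # covered y-intervals at xm, per polygon (even-odd pairing), then merged
    ints <- NULL
    for (p in ps) {
      ys <- .crossings_at(p$vertices, xm)
      if (length(ys) >= 2L) {
        ys <- sort(ys)
        ints <- rbind(ints, matrix(ys, ncol = 2L, byrow = TRUE))
      }
    }
    if (is.null(ints)) next
    total <- total + w * .merged_length(ints)
  }
  total
}

# y-coordinates where the vertical line x = xm crosses the polygon boundary;
# xm never coincides with a vertex abscissa (those bound the slabs)
.crossings_at <- function(v, xm) {
  n <- nrow(v)
  x1 <- v[, 1L]; y1 <- v[, 2L]
  x2 <- v[c(2:n, 1L), 1L]; y2 <- v[c(2:n, 1L), 2L]
  hit <- (x1 - xm) * (x2 - xm) < 0
  y1[hit] + (xm - x1[hit]) / (x2[hit] - x1[hit]) * (y2[hit] - y1[hit])
}

# total length of the union of [lo, hi] intervals (two-column matrix)
.merged_length <- function(ints) {
  o <- order(ints[, 1L])
  lo <- ints[o, 1L]; hi <- ints[o, 2L]
  total <- 0
  cur_lo <- lo[1L]; cur_hi <- hi[1L]
  for (i in seq_along(lo)[-1L]) {
    if (lo[i] > cur_hi) {
      total <- total + (cur_hi - cur_lo)
      cur_lo <- lo[i]; cur_hi <- hi[i]
    } else if (hi[i] > cur_hi) {
      cur_hi <- hi[i]
    }
  }
  total + (cur_hi - cur_lo)
}

#' Hand/wrist radiograph measurements
#'
#' Bundles the delineated bone-region polygons (the eight carpal bones plus,
#' where delineated, the ulnar and radial epiphyses) and the carpal-region
#' polygon whose area is the normaliser Ca.
#'
#' @param bone_regions list of polygons (each accepted by [polygon2d()]);
#'   must be non-empty for a measurable radiograph.
#' @param carpal_region the carpal-region polygon.
#' @return an object of class `carpal_radiograph`.
#' @export
carpal_radiograph <- function(bone_regions, carpal_region) {
  if (length(bone_regions) == 0L) {
    stop("missing measurement: bone_regions must be non-empty", call. = FALSE)
  }
  bone_regions <- lapply(bone_regions, as_polygon2d)
  carpal_region <- as_polygon2d(carpal_region)
  ca <- polygon_area(carpal_region)
  for (b in bone_regions) {
    if (polygon_area(b) > ca) {
      stop("invalid geometry: a bone region is larger than the carpal region",
           call. = FALSE)
    }
  }
  structure(list(bone_regions = bone_regions, carpal_region = carpal_region),
            class = "carpal_radiograph")
}

#' @export
print.carpal_radiograph <- function(x, ...) {
  cat(sprintf("<carpal_radiograph: %d bone regions, Bo/Ca = %.4f>\n",
              length(x$bone_regions), compute_bo_ca(x)))
  invisible(x)
}

#' Carpal Bo/Ca skeletal maturity ratio
#'
#' Ratio of the union area of the delineated bone regions (Bo; overlapping
#' regions counted once) to the area of the carpal region (Ca). The ratio is
#' dimensionless and lies in (0, 1] whenever the bones lie within the carpal
#' region; it approaches 1 as hand/wrist ossification completes.
#'
#' @param r a [carpal_radiograph()].
#' @return the Bo/Ca ratio.
#' @export
compute_bo_ca <- function(r) {
  stopifnot(inherits(r, "carpal_radiograph"))
  union_area(r$bone_regions) / polygon_area(r$carpal_region)
}
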