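# Planar geometry helpers for axis-aligned rectangular grid cells.
# All coordinates are projected planar metres.  Geometries are lists with
# $type in c("point", "multipoint", "line", "polygon") and $coords a
# two-column matrix (x, y); polygons are implicitly closed rings.

#' Construct a geometry object
#'
#' Light-weight planar geometry container used by emission records and
#' area-weighting.  Coordinates are in the grid projection (metres).
#'
#' @param type One of `"point"`, `"multipoint"`, `"line"`, `"polygon"`.
#' @param coords Two-column numeric matrix of (x, y) vertices.  A polygon
#'   ring need not repeat its first vertex.
#' @return An object of class `rc_geometry`.
#' @export
geometry <- function(type = c("point", "multipoint", "line", "polygon"),
                     coords) {
  type <- match.arg(type)
  coords <- matrix(as.numeric(coords), ncol = 2)
  if (nrow(coords) == 0 || anyNA(coords)) {
    stop("invalid geometry: empty coordinates or NA", call. = FALSE)
  }
  if (type == "point" && nrow(coords) != 1) {
    stop("point geometry must have exactly one vertex", call. = FALSE)
  }
  if (type == "line" && nrow(coords) < 2) {
    stop("line geometry needs at least two vertices", call. = FALSE)
  }
  if (type == "polygon") {
    # drop an explicitly closed ring's duplicate last vertex
    n <- nrow(coords)
    if (n >= 2 && all(coords[1, ] == coords[n, ])) coords <- coords[-n, , drop = FALSE]
    if (nrow(coords) < 3) stop("polygon geometry needs at least three vertices", call. = FALSE)
  }
  structure(list(type = type, coords = coords), class = "rc_geometry")
}

#' Signed area of a polygon ring (shoelace formula)
#' @param coords Two-column matrix of ring vertices (open ring).
#' @return Signed area; positive for counter-clockwise rings.
#' @keywords internal
shoelace_area <- function(coords) {
  x <- coords[, 1]; y <- coords[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  0.5 * sum(x[j] * y - x * y[j])
}

# Sutherland-Hodgman clip of a polygon ring against one half-plane.
# keep(p) is TRUE inside; cross(p, q) returns the intersection with the edge.
clip_halfplane <- function(coords, keep, cross) {
  n <- nrow(coords)
  if (n == 0) return(coords)
  out <- matrix(numeric(0), ncol = 2)
  prev <- coords[n, ]
  prev_in <- keep(prev)
  for (i in seq_len(n)) {
    cur <- coords[i, ]
    cur_in <- keep(cur)
    if (cur_in) {
      if (!prev_in) out <- rbind(out, cross(prev, cur))
      out <- rbind(out, cur)
    } else if (prev_in) {
      out <- rbind(out, cross(prev, cur))
    }
    prev <- cur; prev_in <- cur_in
  }
  out
}

#' Clip a polygon ring to an axis-aligned rectangle
#' @param coords Open polygon ring, two-column matrix.
#' @param rect Numeric vector `c(xmin, xmax, ymin, ymax)`.
#' @return Clipped ring (possibly zero rows).
#' @keywords internal
clip_polygon_rect <- function(coords, rect) {
  cr <- function(a, b, t) a + t * (b - a)
  # west, east, south, north half-planes
  coords <- clip_halfplane(coords, function(p) p[1] >= rect[1],
    function(p, q) cr(p, q, (rect[1] - p[1]) / (q[1] - p[1])))
  coords <- clip_halfplane(coords, function(p) p[1] <= rect[2],
    function(p, q) cr(p, q, (rect[2] - p[1]) / (q[1] - p[1])))
  coords <- clip_halfplane(coords, function(p) p[2] >= rect[3],
    function(p, q) cr(p, q, (rect[3] - p[2]) / (q[2] - p[2])))
  coords <- clip_halfplane(coords, function(p) p[2] <= rect[4],
    function(p, q) cr(p, q, (rect[4] - p[2]) / (q[2] - p[2])))
  coords
}

#' Area of the intersection of a polygon and a rectangle
#' @keywords internal
polygon_rect_area <- function(coords, rect) {
  clipped <- clip_polygon_rect(coords, rect)
  if (nrow(clipped) < 3) return(0)
  abs(shoelace_area(clipped))
}

#' Area of the intersection of two axis-aligned rectangles
#' @keywords internal
rect_rect_area <- function(a, b) {
  w <- min(a[2], b[2]) - max(a[1], b[1])
  h <- min(a[4], b[4]) - max(a[3], b[3])
  if (w <= 0 || h <= 0) return(0)
  w * h
}

#' Length of a polyline inside an axis-aligned rectangle
#'
#' Clips each segment to the rectangle (Liang-Barsky parameterisation) and
#' sums the retained lengths.
#' @keywords internal
line_rect_length <- function(coords, rect) {
  total <- 0
  for (i in seq_len(nrow(coords) - 1)) {
    p <- coords[i, ]; q <- coords[i + 1, ]
    d <- q - p
    t0 <- 0; t1 <- 1
    ok <- TRUE
    for (k in 1:2) {
      lo <- rect[2 * k - 1]; hi <- rect[2 * k]
      if (d[k] == 0) {
        if (p[k] < lo || p[k] > hi) { ok <- FALSE; break }
      } else {
        ta <- (lo - p[k]) / d[k]; tb <- (hi - p[k]) / d[k]
        if (ta > tb) { tmp <- ta; ta <- tb; tb <- tmp }
        t0 <- max(t0, ta); t1 <- min(t1, tb)
        if (t0 > t1) { ok <- FALSE; break }
      }
    }
    if (ok) total <- total + (t1 - t0) * sqrt(sum(d^2))
  }
  total
}

#' Does a rectangle contain a point (half-open convention [min, max))
#' @keywords internal
rect_contains <- function(rect, x, y) {
  x >= rect[1] & x < rect[2] & y >= rect[3] & y < rect[4]
}

#' Bounding box of a geometry
#' @keywords internal
geometry_bbox <- function(geom) {
  c(min(geom$coords[, 1]), max(geom$coords[, 1]),
    min(geom$coords[, 2]), max(geom$coords[, 2]))
}

#' Centroid of a geometry (vertex mean for points/lines, area centroid for
#' polygons)
#' @keywords internal
geometry_centroid <- function(geom) {
  cc <- geom$coords
  if (geom$type == "polygon") {
    x <- cc[, 1]; y <- cc[, 2]
    n <- length(x)
    j <- c(n, seq_len(n - 1))
    cross <- x[j] * y - x * y[j]
    a <- 0.5 * sum(cross)
    if (abs(a) < 1e-12) return(colMeans(cc))
    cx <- sum((x[j] + x) * cross) / (6 * a)
    cy <- sum((y[j] + y) * cross) / (6 * a)
    return(c(cx, cy))
  }
  colMeans(cc)
}
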