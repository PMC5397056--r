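# Population surfaces: either a gridded raster of person counts or a table
# of polygons with a population attribute.  Used for grid sizing and for
# population-weighted exposure summaries.

#' Create a raster population surface
#'
#' @param values Numeric matrix of person counts per raster cell; rows index
#'   x (west to east), columns index y (south to north).
#' @param extent Numeric `c(xmin, xmax, ymin, ymax)` of the raster in
#'   projected metres.
#' @return An object of class `rc_population`.
#' @export
pop_raster <- function(values, extent) {
  values <- as.matrix(values)
  if (any(values < 0)) stop("population counts must be non-negative", call. = FALSE)
  if (extent[2] <= extent[1] || extent[4] <= extent[3]) {
    stop("invalid raster extent", call. = FALSE)
  }
  structure(list(kind = "raster", values = values, extent = as.numeric(extent)),
            class = "rc_population")
}

#' Create a polygon-table population surface
#'
#' @param polygons List of two-column coordinate matrices (open rings).
#' @param population Numeric vector of person counts, one per polygon.
#' @return An object of class `rc_population`.
#' @export
pop_polygons <- function(polygons, population) {
  if (length(polygons) != length(population)) {
    stop("one population value per polygon is required", call. = FALSE)
  }
  if (any(population < 0)) stop("population counts must be non-negative", call. = FALSE)
  polygons <- lapply(polygons, function(p) matrix(as.numeric(p), ncol = 2))
  areas <- vapply(polygons, function(p) abs(shoelace_area(p)), numeric(1))
  if (any(areas <= 0)) stop("degenerate population polygon", call. = FALSE)
  structure(list(kind = "polygons", polygons = polygons,
                 population = as.numeric(population), areas = areas),
            class = "rc_population")
}

#' Population inside an axis-aligned rectangle
#'
#' Raster cells and polygons are apportioned by fractional area overlap
#' (uniform density within each raster cell / polygon).
#'
#' @param pop An `rc_population` surface.
#' @param rect Numeric `c(xmin, xmax, ymin, ymax)`.
#' @return Person count (numeric scalar).
#' @export
population_in_rect <- function(pop, rect) {
  stopifnot(inherits(pop, "rc_population"))
  if (pop$kind == "raster") {
    ext <- pop$extent
    nx <- nrow(pop$values); ny <- ncol(pop$values)
    dx <- (ext[2] - ext[1]) / nx
    dy <- (ext[4] - ext[3]) / ny
    i0 <- max(1L, floor((rect[1] - ext[1]) / dx) + 1L)
    i1 <- min(nx, ceiling((rect[2] - ext[1]) / dx))
    j0 <- max(1L, floor((rect[3] - ext[3]) / dy) + 1L)
    j1 <- min(ny, ceiling((rect[4] - ext[3]) / dy))
    if (i0 > i1 || j0 > j1) return(0)
    total <- 0
    for (i in i0:i1) {
      cxlo <- ext[1] + (i - 1) * dx; cxhi <- cxlo + dx
      w <- min(cxhi, rect[2]) - max(cxlo, rect[1])
      if (w <= 0) next
      for (j in j0:j1) {
        cylo <- ext[3] + (j - 1) * dy; cyhi <- cylo + dy
        h <- min(cyhi, rect[4]) - max(cylo, rect[3])
        if (h <= 0) next
        total <- total + pop$values[i, j] * (w * h) / (dx * dy)
      }
    }
    return(total)
  }
  total <- 0
  for (k in seq_along(pop$polygons)) {
    ov <- polygon_rect_area(pop$polygons[[k]], rect)
    if (ov > 0) total <- total + pop$population[k] * ov / pop$areas[k]
  }
  total
}

#' Spatial extent of a population surface
#' @keywords internal
population_extent <- function(pop) {
  if (pop$kind == "raster") return(pop$extent)
  xs <- unlist(lapply(pop$polygons, function(p) range(p[, 1])))
  ys <- unlist(lapply(pop$polygons, function(p) range(p[, 2])))
  c(min(xs), max(xs), min(ys), max(ys))
}
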