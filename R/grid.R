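# Variable-resolution model grid: quadtree-style square horizontal cells
# (smaller where population is dense) crossed with fixed vertical layers.
# Horizontal refinement applies only below a cap height (default 1500 m);
# above it, every layer uses the coarsest (base) tiling.  Cell bounds use
# the half-open convention [min, max) with the origin at the domain
# south-west corner.

#' Grid configuration
#'
#' @param base_size Edge length (m) of the coarsest horizontal cell.
#' @param level_divisors Integer vector: the factor by which the cell edge
#'   shrinks at each refinement level.  The default `c(2, 2, 2, 2, 3)`
#'   spans the 48 km base down to exactly 1 km (48, 24, 12, 6, 3, 1 km).
#' @param min_cell_size Smallest allowed edge length (m).  Must be
#'   reachable on the divisor ladder, i.e. equal
#'   `base_size / prod(level_divisors[1:k])` for some `k`.
#' @param pop_threshold A column is split while its footprint population
#'   exceeds this count (persons).
#' @param layer_tops Increasing vector of vertical layer interface heights
#'   (m above ground); the first layer spans 0 to `layer_tops[1]`.
#' @param high_res_cap Height (m) above which only the base horizontal
#'   resolution is used.
#' @param domain Optional `c(xmin, xmax, ymin, ymax)`; defaults to the
#'   population surface extent.  Width and height must be integer
#'   multiples of `base_size`.
#'
#' @details Expressing sizes as a base length with per-level divisors,
#' rather than a single split factor, lets the ladder end on sizes that
#' are not a power-of-two fraction of the base: dividing 48 km by 2 four
#' times and then by 3 reaches exactly 1 km, reproducing the intended
#' 1--48 km range.
#' @return A list of class `grid_config`.
#' @export
grid_config <- function(base_size = 48000,
                        level_divisors = c(2, 2, 2, 2, 3),
                        min_cell_size = 1000,
                        pop_threshold = 1e4,
                        layer_tops = c(50, 150, 300, 500, 750, 1050, 1500,
                                       2200, 3100, 4000),
                        high_res_cap = 1500,
                        domain = NULL) {
  level_divisors <- as.integer(level_divisors)
  if (any(level_divisors < 2)) stop("config error: level divisors must be >= 2", call. = FALSE)
  sizes <- base_size / cumprod(c(1, level_divisors))
  if (!any(abs(sizes - min_cell_size) < 1e-6)) {
    stop("config error: min_cell_size is not reachable from base_size via the divisor ladder",
         call. = FALSE)
  }
  if (is.unsorted(layer_tops, strictly = TRUE) || layer_tops[1] <= 0) {
    stop("config error: layer_tops must be strictly increasing and positive", call. = FALSE)
  }
  structure(list(base_size = base_size, level_divisors = level_divisors,
                 min_cell_size = min_cell_size, pop_threshold = pop_threshold,
                 layer_tops = layer_tops, high_res_cap = high_res_cap,
                 domain = domain, sizes = sizes),
            class = "grid_config")
}

# level ladder edge length
level_size <- function(config, level) {
  config$base_size / prod(c(1, config$level_divisors)[seq_len(level + 1)])
}

# ---------------------------------------------------------------------------
# Column tilings.  A "column" is a square horizontal footprint shared by all
# layers below the cap height; above the cap every layer uses the base
# (level 0) tiling.

base_columns <- function(domain, base_size) {
  nx <- round((domain[2] - domain[1]) / base_size)
  ny <- round((domain[4] - domain[3]) / base_size)
  g <- expand.grid(ix = seq_len(nx) - 1L, iy = seq_len(ny) - 1L)
  data.frame(xmin = domain[1] + g$ix * base_size,
             xmax = domain[1] + (g$ix + 1) * base_size,
             ymin = domain[3] + g$iy * base_size,
             ymax = domain[3] + (g$iy + 1) * base_size,
             level = 0L)
}

split_column <- function(col, divisor) {
  d <- divisor
  sz <- (col$xmax - col$xmin) / d
  g <- expand.grid(ix = seq_len(d) - 1L, iy = seq_len(d) - 1L)
  data.frame(xmin = col$xmin + g$ix * sz, xmax = col$xmin + (g$ix + 1) * sz,
             ymin = col$ymin + g$iy * sz, ymax = col$ymin + (g$iy + 1) * sz,
             level = col$level + 1L)
}

order_columns <- function(cols) {
  cols[order(cols$ymin, cols$xmin), , drop = FALSE]
}

refine_columns_by_population <- function(cols, population, config) {
  out <- list()
  work <- split(cols, seq_len(nrow(cols)))
  while (length(work)) {
    col <- work[[1]]
    work <- work[-1]
    sz <- col$xmax - col$xmin
    pop <- population_in_rect(population,
                              c(col$xmin, col$xmax, col$ymin, col$ymax))
    if (pop > config$pop_threshold && sz > config$min_cell_size + 1e-9 &&
        col$level < length(config$level_divisors)) {
      kids <- split_column(col, config$level_divisors[col$level + 1L])
      work <- c(split(kids, seq_len(nrow(kids))), work)
    } else {
      col$population <- pop
      out[[length(out) + 1L]] <- col
    }
  }
  order_columns(do.call(rbind, out))
}

# ---------------------------------------------------------------------------

#' Build the static variable-resolution grid
#'
#' Columns are recursively split while their footprint population exceeds
#' the configured threshold and their edge length exceeds the minimum;
#' refinement applies only to layers whose bottom is below the cap height.
#'
#' @param population An [pop_raster()] / [pop_polygons()] surface covering
#'   the domain.
#' @param config A [grid_config()].
#' @return An object of class `vr_grid` with a `cells` data frame
#'   (id, layer, bounds, dx, dy, dz, population, boundary flags), the face
#'   topology, and column bookkeeping.
#' @export
build_static_grid <- function(population, config) {
  stopifnot(inherits(population, "rc_population"), inherits(config, "grid_config"))
  domain <- config$domain
  if (is.null(domain)) domain <- population_extent(population)
  ext <- population_extent(population)
  if (ext[1] > domain[1] + 1e-6 || ext[2] < domain[2] - 1e-6 ||
      ext[3] > domain[3] + 1e-6 || ext[4] < domain[4] - 1e-6) {
    stop("input error: population surface does not cover the domain", call. = FALSE)
  }
  for (d in c(domain[2] - domain[1], domain[4] - domain[3])) {
    if (abs(d / config$base_size - round(d / config$base_size)) > 1e-9) {
      stop("config error: domain size must be a multiple of base_size", call. = FALSE)
    }
  }
  base_cols <- order_columns(base_columns(domain, config$base_size))
  base_cols$population <- vapply(seq_len(nrow(base_cols)), function(i) {
    population_in_rect(population, unlist(base_cols[i, c("xmin", "xmax", "ymin", "ymax")]))
  }, numeric(1))
  fine_cols <- refine_columns_by_population(base_cols[, 1:5], population, config)
  new_vr_grid(fine_cols, base_cols, domain, config)
}

# Assemble the cell table and topology from column tilings.
new_vr_grid <- function(fine_cols, base_cols, domain, config) {
  layer_tops <- config$layer_tops
  zbot <- c(0, layer_tops[-length(layer_tops)])
  ztop <- layer_tops
  nlayer <- length(layer_tops)
  below_cap <- zbot < config$high_res_cap

  rownames(fine_cols) <- NULL
  rownames(base_cols) <- NULL
  cell_list <- vector("list", nlayer)
  for (k in seq_len(nlayer)) {
    cols <- if (below_cap[k]) fine_cols else base_cols
    cell_list[[k]] <- data.frame(
      layer = k - 1L,
      xmin = cols$xmin, xmax = cols$xmax, ymin = cols$ymin, ymax = cols$ymax,
      level = cols$level,
      zbot = zbot[k], ztop = ztop[k],
      population = cols$population,
      col_index = seq_len(nrow(cols)))
  }
  cells <- do.call(rbind, cell_list)
  cells$id <- seq_len(nrow(cells))
  cells$dx <- cells$xmax - cells$xmin
  cells$dy <- cells$ymax - cells$ymin
  cells$dz <- cells$ztop - cells$zbot
  cells$volume <- cells$dx * cells$dy * cells$dz
  cells$is_ground <- cells$layer == 0L
  cells$is_top <- cells$layer == nlayer - 1L
  eps <- 1e-6
  cells$is_lateral_boundary <- cells$xmin <= domain[1] + eps |
    cells$xmax >= domain[2] - eps | cells$ymin <= domain[3] + eps |
    cells$ymax >= domain[4] - eps

  grid <- structure(list(cells = cells, fine_columns = fine_cols,
                         base_columns = base_cols, domain = domain,
                         layer_tops = layer_tops, config = config,
                         below_cap = below_cap),
                    class = "vr_grid")
  grid$faces <- build_faces(grid)
  grid$column_stacks <- build_column_stacks(grid)
  grid
}

# Horizontal adjacency within one tiling: faces between column a (west or
# south) and b.  Returns data.frame(a, b, dir, shared) with `shared` the
# shared edge length; a/b are row indices into the tiling.
tiling_adjacency <- function(cols) {
  n <- nrow(cols)
  res <- list()
  for (i in seq_len(n)) {
    # east neighbors of i: xmin == i's xmax with y-overlap
    je <- which(abs(cols$xmin - cols$xmax[i]) < 1e-6)
    for (j in je) {
      ov <- min(cols$ymax[i], cols$ymax[j]) - max(cols$ymin[i], cols$ymin[j])
      if (ov > 1e-6) res[[length(res) + 1L]] <- c(i, j, 1, ov)
    }
    jn <- which(abs(cols$ymin - cols$ymax[i]) < 1e-6)
    for (j in jn) {
      ov <- min(cols$xmax[i], cols$xmax[j]) - max(cols$xmin[i], cols$xmin[j])
      if (ov > 1e-6) res[[length(res) + 1L]] <- c(i, j, 2, ov)
    }
  }
  if (!length(res)) {
    return(data.frame(a = integer(), b = integer(), dir = character(),
                      shared = numeric()))
  }
  m <- do.call(rbind, res)
  data.frame(a = as.integer(m[, 1]), b = as.integer(m[, 2]),
             dir = c("x", "y")[m[, 3]], shared = m[, 4])
}

# Vertical overlap between two tilings: rows (lower index, upper index,
# overlap area).
tiling_overlap <- function(lower, upper) {
  res <- list()
  for (i in seq_len(nrow(lower))) {
    a <- unlist(lower[i, c("xmin", "xmax", "ymin", "ymax")])
    cand <- which(upper$xmin < a[2] - 1e-6 & upper$xmax > a[1] + 1e-6 &
                  upper$ymin < a[4] - 1e-6 & upper$ymax > a[3] + 1e-6)
    for (j in cand) {
      b <- unlist(upper[j, c("xmin", "xmax", "ymin", "ymax")])
      ov <- rect_rect_area(a, b)
      if (ov > 1e-6) res[[length(res) + 1L]] <- c(i, j, ov)
    }
  }
  m <- do.call(rbind, res)
  data.frame(lower = as.integer(m[, 1]), upper = as.integer(m[, 2]),
             area = m[, 3])
}

# Full face table: data.frame(a, b, dir, area, fa, fb).  `a` is the west /
# south / lower cell.  `area` is the interface area (m^2).  fa (fb) is the
# fraction of cell a's (b's) face covered by the interface.
build_faces <- function(grid) {
  cells <- grid$cells
  nlayer <- length(grid$layer_tops)
  below_cap <- grid$below_cap
  # map (layer, col_index) -> cell id
  layer_offsets <- c(0, cumsum(tapply(cells$layer, cells$layer, length)))
  id_of <- function(layer, col_index) layer_offsets[layer + 1L] + col_index

  adj_fine <- tiling_adjacency(grid$fine_columns)
  adj_base <- tiling_adjacency(grid$base_columns)
  faces <- list()
  for (k in seq_len(nlayer)) {
    adj <- if (below_cap[k]) adj_fine else adj_base
    if (nrow(adj)) {
      a <- id_of(k - 1L, adj$a); b <- id_of(k - 1L, adj$b)
      dzk <- grid$layer_tops[k] - if (k == 1) 0 else grid$layer_tops[k - 1]
      ea <- ifelse(adj$dir == "x", cells$dy[a], cells$dx[a])
      eb <- ifelse(adj$dir == "x", cells$dy[b], cells$dx[b])
      faces[[length(faces) + 1L]] <- data.frame(
        a = a, b = b, dir = adj$dir, area = adj$shared * dzk,
        fa = adj$shared / ea, fb = adj$shared / eb)
    }
  }
  ov_fine <- data.frame(lower = seq_len(nrow(grid$fine_columns)),
                        upper = seq_len(nrow(grid$fine_columns)),
                        area = (grid$fine_columns$xmax - grid$fine_columns$xmin) *
                               (grid$fine_columns$ymax - grid$fine_columns$ymin))
  ov_base <- data.frame(lower = seq_len(nrow(grid$base_columns)),
                        upper = seq_len(nrow(grid$base_columns)),
                        area = (grid$base_columns$xmax - grid$base_columns$xmin) *
                               (grid$base_columns$ymax - grid$base_columns$ymin))
  ov_cross <- NULL
  for (k in seq_len(nlayer - 1)) {
    lower_fine <- below_cap[k]; upper_fine <- below_cap[k + 1]
    ov <- if (lower_fine && upper_fine) ov_fine
          else if (!lower_fine && !upper_fine) ov_base
          else {
            if (is.null(ov_cross)) ov_cross <- tiling_overlap(grid$fine_columns, grid$base_columns)
            ov_cross
          }
    a <- id_of(k - 1L, ov$lower); b <- id_of(k, ov$upper)
    faces[[length(faces) + 1L]] <- data.frame(
      a = a, b = b, dir = "z", area = ov$area,
      fa = ov$area / (cells$dx[a] * cells$dy[a]),
      fb = ov$area / (cells$dx[b] * cells$dy[b]))
  }
  out <- do.call(rbind, faces)
  rownames(out) <- NULL
  out
}

# Per fine column: the ids of its cells for every below-cap layer, ground
# first.  Used by the nonlocal (convective) mixing scheme.
build_column_stacks <- function(grid) {
  cells <- grid$cells
  nfine <- nrow(grid$fine_columns)
  lapply(seq_len(nfine), function(ci) {
    cells$id[cells$col_index == ci & cells$layer < sum(grid$below_cap) &
             grid$below_cap[cells$layer + 1L]]
  })
}

#' Face topology of a grid
#'
#' For every cell and each of the six faces (W, E, S, N, below, above),
#' the neighbouring cell ids and the fraction of the cell's face shared
#' with each neighbour.  Interior face fractions sum to 1; domain-boundary
#' faces have empty neighbour lists.
#'
#' @param grid A `vr_grid`.
#' @return A list with `faces` (the raw face table) and `neighbors`, a
#'   function `(id, side)` returning a data frame of `(id, f)` for side in
#'   `c("W","E","S","N","below","above")`.
#' @export
face_topology <- function(grid) {
  stopifnot(inherits(grid, "vr_grid"))
  fc <- grid$faces
  neighbors <- function(id, side) {
    switch(side,
      W = data.frame(id = fc$a[fc$b == id & fc$dir == "x"],
                     f  = fc$fb[fc$b == id & fc$dir == "x"]),
      E = data.frame(id = fc$b[fc$a == id & fc$dir == "x"],
                     f  = fc$fa[fc$a == id & fc$dir == "x"]),
      S = data.frame(id = fc$a[fc$b == id & fc$dir == "y"],
                     f  = fc$fb[fc$b == id & fc$dir == "y"]),
      N = data.frame(id = fc$b[fc$a == id & fc$dir == "y"],
                     f  = fc$fa[fc$a == id & fc$dir == "y"]),
      below = data.frame(id = fc$a[fc$b == id & fc$dir == "z"],
                         f  = fc$fb[fc$b == id & fc$dir == "z"]),
      above = data.frame(id = fc$b[fc$a == id & fc$dir == "z"],
                         f  = fc$fa[fc$a == id & fc$dir == "z"]),
      stop("unknown side", call. = FALSE))
  }
  list(faces = fc, neighbors = neighbors)
}

#' Validate grid tiling invariants
#'
#' Checks per-layer tiling (areas sum to the domain area, no pairwise
#' overlaps) and face-fraction closure on interior faces.
#'
#' @param grid A `vr_grid`.
#' @param tol Relative tolerance.
#' @return Invisibly `TRUE`; stops with a topology error otherwise.
#' @export
validate_grid <- function(grid, tol = 1e-9) {
  cells <- grid$cells
  domain_area <- (grid$domain[2] - grid$domain[1]) * (grid$domain[4] - grid$domain[3])
  for (k in unique(cells$layer)) {
    lk <- cells[cells$layer == k, ]
    if (abs(sum(lk$dx * lk$dy) - domain_area) > tol * domain_area) {
      stop("topology error: layer ", k, " does not tile the domain", call. = FALSE)
    }
    # overlap check via pairwise rect intersection on the (small) tiling
    o <- order(lk$xmin, lk$ymin)
    lk <- lk[o, ]
    for (i in seq_len(nrow(lk) - 1)) {
      j <- i + 1L
      while (j <= nrow(lk) && lk$xmin[j] < lk$xmax[i] - 1e-9) {
        ov <- rect_rect_area(unlist(lk[i, c("xmin", "xmax", "ymin", "ymax")]),
                             unlist(lk[j, c("xmin", "xmax", "ymin", "ymax")]))
        if (ov > 1e-6) stop("topology error: overlapping cells", call. = FALSE)
        j <- j + 1L
      }
    }
  }
  invisible(TRUE)
}

#' Area-weighted overlap of a geometry with a grid layer
#'
#' Splits a geometry over the cell footprints of one layer: by count for
#' (multi)points, by length for lines, by area for polygons.  Portions
#' outside the domain are dropped with a warning; weights are renormalised
#' to sum to 1 only when `renormalize = TRUE`.
#'
#' @param geom An [geometry()] object.
#' @param grid A `vr_grid`.
#' @param layer Vertical layer index (0 = ground).
#' @param renormalize Renormalise weights after dropping outside portions.
#' @return data.frame with columns `id` (cell id) and `weight`.
#' @export
area_weights <- function(geom, grid, layer = 0L, renormalize = FALSE) {
  stopifnot(inherits(geom, "rc_geometry"), inherits(grid, "vr_grid"))
  cells <- grid$cells[grid$cells$layer == layer, ]
  bb <- geometry_bbox(geom)
  cand <- cells[cells$xmax > bb[1] - 1e-9 & cells$xmin < bb[2] + 1e-9 &
                cells$ymax > bb[3] - 1e-9 & cells$ymin < bb[4] + 1e-9, ]
  w <- numeric(nrow(cand))
  total <- switch(geom$type,
    point = , multipoint = nrow(geom$coords),
    line = {
      d <- diff(geom$coords)
      sum(sqrt(rowSums(d^2)))
    },
    polygon = abs(shoelace_area(geom$coords)))
  if (total <= 0) stop("input error: degenerate geometry", call. = FALSE)
  for (i in seq_len(nrow(cand))) {
    rect <- unlist(cand[i, c("xmin", "xmax", "ymin", "ymax")])
    w[i] <- switch(geom$type,
      point = , multipoint =
        sum(rect_contains(rect, geom$coords[, 1], geom$coords[, 2])),
      line = line_rect_length(geom$coords, rect),
      polygon = polygon_rect_area(geom$coords, rect))
  }
  w <- w / total
  keep <- w > 0
  out <- data.frame(id = cand$id[keep], weight = w[keep])
  covered <- sum(out$weight)
  if (covered < 1 - 1e-9) {
    warning(sprintf("%.1f%% of geometry lies outside the domain and was dropped",
                    100 * (1 - covered)))
    if (renormalize && covered > 0) out$weight <- out$weight / covered
  }
  out
}

# ---------------------------------------------------------------------------
# Dynamic refinement

#' Refine or coarsen the grid from concentration gradients
#'
#' Each column's refinement score is its ground-cell population density
#' (persons per m^2) times the largest absolute total-PM2.5 difference to
#' any horizontal neighbour.  Columns with score above
#' `thresholds$split` are split one level; complete sibling sets whose
#' scores are all below `thresholds$merge` (default `split / 4`) are
#' merged.  Concentrations are re-interpolated conservatively (children
#' inherit the parent value; merges take the volume-weighted mean), so
#' total pollutant mass is preserved.
#'
#' @param grid A `vr_grid`.
#' @param concentrations Numeric matrix (cells x species) or vector on the
#'   current grid.
#' @param population The population surface.
#' @param thresholds List with `split` and optionally `merge` (> 0).
#' @return List with elements `grid` (the new `vr_grid`) and
#'   `concentrations` (re-interpolated to it).
#' @export
refine_dynamic <- function(grid, concentrations, population, thresholds) {
  stopifnot(inherits(grid, "vr_grid"))
  if (is.null(thresholds$merge)) thresholds$merge <- thresholds$split / 4
  if (thresholds$split <= 0 || thresholds$merge <= 0) {
    stop("config error: refinement thresholds must be positive", call. = FALSE)
  }
  conc <- as.matrix(concentrations)
  if (nrow(conc) != nrow(grid$cells)) {
    stop("concentrations are not defined on the current grid", call. = FALSE)
  }
  config <- grid$config
  cells <- grid$cells
  ground <- cells[cells$is_ground, ]
  ground <- ground[order(ground$col_index), ]
  # total PM2.5 per ground cell (last column when a matrix of all species is
  # given the caller passes total already; accept either)
  tot <- if (ncol(conc) == 1) conc[, 1] else rowSums(conc)
  fc <- grid$faces
  score <- numeric(nrow(ground))
  for (i in seq_len(nrow(ground))) {
    id <- ground$id[i]
    nb <- c(fc$b[fc$a == id & fc$dir != "z"], fc$a[fc$b == id & fc$dir != "z"])
    gmax <- if (length(nb)) max(abs(tot[id] - tot[nb])) else 0
    dens <- ground$population[i] / (ground$dx[i] * ground$dy[i])
    score[i] <- dens * gmax
  }
  cols <- grid$fine_columns
  rownames(cols) <- NULL
  new_cols <- list()
  i <- 1L
  # split pass
  for (i in seq_len(nrow(cols))) {
    col <- cols[i, ]
    sz <- col$xmax - col$xmin
    if (score[i] > thresholds$split && sz > config$min_cell_size + 1e-9 &&
        col$level < length(config$level_divisors)) {
      kids <- split_column(col[, 1:5], config$level_divisors[col$level + 1L])
      kids$population <- NA_real_
      kids$score <- score[i]
      new_cols[[length(new_cols) + 1L]] <- kids
    } else {
      col$score <- score[i]
      new_cols[[length(new_cols) + 1L]] <- col[, c(names(cols), "score")]
    }
  }
  cols2 <- do.call(rbind, new_cols)
  # merge pass: group level-L columns by their level-(L-1) parent rectangle
  merged <- list()
  used <- rep(FALSE, nrow(cols2))
  for (i in seq_len(nrow(cols2))) {
    if (used[i]) next
    col <- cols2[i, ]
    if (col$level > 0 && col$score < thresholds$merge) {
      d <- config$level_divisors[col$level]
      psz <- (col$xmax - col$xmin) * d
      pxmin <- grid$domain[1] + floor((col$xmin - grid$domain[1]) / psz) * psz
      pymin <- grid$domain[3] + floor((col$ymin - grid$domain[3]) / psz) * psz
      sib <- which(!used & cols2$level == col$level &
                   cols2$xmin >= pxmin - 1e-6 & cols2$xmax <= pxmin + psz + 1e-6 &
                   cols2$ymin >= pymin - 1e-6 & cols2$ymax <= pymin + psz + 1e-6)
      if (length(sib) == d * d && all(cols2$score[sib] < thresholds$merge)) {
        used[sib] <- TRUE
        merged[[length(merged) + 1L]] <- data.frame(
          xmin = pxmin, xmax = pxmin + psz, ymin = pymin, ymax = pymin + psz,
          level = col$level - 1L, population = NA_real_, score = NA_real_)
        next
      }
    }
    used[i] <- TRUE
    merged[[length(merged) + 1L]] <- col
  }
  cols3 <- order_columns(do.call(rbind, merged))[, 1:5]
  cols3$population <- vapply(seq_len(nrow(cols3)), function(i) {
    population_in_rect(population, unlist(cols3[i, c("xmin", "xmax", "ymin", "ymax")]))
  }, numeric(1))
  new_grid <- new_vr_grid(cols3, grid$base_columns, grid$domain, config)
  # conservative transfer: new value = sum(old value * overlap volume) / V_new
  newc <- matrix(0, nrow(new_grid$cells), ncol(conc))
  oldcells <- cells
  for (k in unique(new_grid$cells$layer)) {
    newk <- new_grid$cells[new_grid$cells$layer == k, ]
    oldk <- oldcells[oldcells$layer == k, ]
    for (i in seq_len(nrow(newk))) {
      a <- unlist(newk[i, c("xmin", "xmax", "ymin", "ymax")])
      cand <- which(oldk$xmin < a[2] - 1e-6 & oldk$xmax > a[1] + 1e-6 &
                    oldk$ymin < a[4] - 1e-6 & oldk$ymax > a[3] + 1e-6)
      acc <- numeric(ncol(conc))
      for (j in cand) {
        ov <- rect_rect_area(a, unlist(oldk[j, c("xmin", "xmax", "ymin", "ymax")]))
        if (ov > 0) acc <- acc + conc[oldk$id[j], ] * ov * oldk$dz[j]
      }
      newc[newk$id[i], ] <- acc / newk$volume[i]
    }
  }
  if (is.vector(concentrations)) newc <- drop(newc)
  list(grid = new_grid, concentrations = newc)
}

# ---------------------------------------------------------------------------

#' Export grid cells as GeoJSON polygons
#'
#' Writes one polygon feature per cell of the chosen layer(s), carrying
#' layer, dz, population and any extra per-cell attribute columns.
#'
#' @param grid A `vr_grid`.
#' @param file Output path.
#' @param layer Layer index or `NULL` for all layers.
#' @param attributes Optional data frame of extra per-cell columns (one row
#'   per grid cell, matched by id).
#' @export
grid_to_geojson <- function(grid, file, layer = 0L, attributes = NULL) {
  cells <- grid$cells
  if (!is.null(layer)) cells <- cells[cells$layer %in% layer, ]
  feats <- lapply(seq_len(nrow(cells)), function(i) {
    cc <- cells[i, ]
    ring <- list(c(cc$xmin, cc$ymin), c(cc$xmax, cc$ymin),
                 c(cc$xmax, cc$ymax), c(cc$xmin, cc$ymax), c(cc$xmin, cc$ymin))
    props <- list(id = cc$id, layer = cc$layer, dz = cc$dz,
                  population = cc$population)
    if (!is.null(attributes)) props <- c(props, as.list(attributes[cells$id[i], , drop = FALSE]))
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = list(ring)),
         properties = props)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
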