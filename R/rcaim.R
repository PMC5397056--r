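# User-facing model surface: one entry point returning a classed result
# with the usual inspection methods.

#' Solver control settings
#'
#' @param Cmax Maximum allowable Courant number (0, 1].
#' @param tol Relative convergence tolerance on the population-weighted
#'   mean total-PM2.5 change.
#' @param abs_floor Absolute convergence floor (ug m^-3).
#' @param check_every Convergence-monitoring window (iterations).
#' @param max_iter Iteration cap.
#' @param verbose Print convergence progress.
#' @return List of class `rcaim_control`.
#' @export
rcaim_control <- function(Cmax = 1.0, tol = 1e-6, abs_floor = 1e-9,
                          check_every = 100L, max_iter = 1e6,
                          verbose = FALSE) {
  if (Cmax <= 0 || Cmax > 1) stop("config error: Cmax must be in (0, 1]", call. = FALSE)
  if (tol <= 0 || abs_floor <= 0) stop("config error: tolerances must be positive", call. = FALSE)
  structure(list(Cmax = Cmax, tol = tol, abs_floor = abs_floor,
                 check_every = as.integer(check_every),
                 max_iter = max_iter, verbose = verbose),
            class = "rcaim_control")
}

#' Steady-state PM2.5 change from an emission intervention
#'
#' Solves the reduced-complexity steady-state transport/chemistry system
#' for the annual-average changes in the nine model species caused by the
#' given emission changes, and summarises the resulting total PM2.5 change
#' as area- and population-weighted ground-level means.
#'
#' @param emissions A list of [emission_record()]s, or path(s) to GeoJSON
#'   emission files.
#' @param grid A `vr_grid` (or omit and pass `archive`).
#' @param fields A `cell_fields` archive for the grid.
#' @param archive Path to an archive directory written by
#'   [write_archive()]; supplies both grid and fields.
#' @param control A [rcaim_control()].
#' @param refine Optional dynamic-refinement settings (list with
#'   `population`, `thresholds`, `every`); see [run_to_steady_state()].
#' @param units Emission unit when `emissions` are file paths.
#' @return An object of class `rcaim`.
#' @export
rcaim <- function(emissions, grid = NULL, fields = NULL, archive = NULL,
                  control = rcaim_control(), refine = NULL,
                  units = "short_ton") {
  if (!is.null(archive)) {
    ar <- read_archive(archive)
    grid <- ar$grid; fields <- ar$fields
  }
  if (is.null(grid) || is.null(fields)) {
    stop("supply either `archive` or both `grid` and `fields`", call. = FALSE)
  }
  if (is.character(emissions)) emissions <- read_emissions(emissions, units = units)
  if (inherits(emissions, "emission_record")) emissions <- list(emissions)
  src <- grid_emissions(emissions, grid, fields)
  st <- solver_state(grid, fields, src, Cmax = control$Cmax)
  if (!is.null(refine)) refine$records <- emissions
  res <- run_to_steady_state(st, tol = control$tol,
                             abs_floor = control$abs_floor,
                             check_every = control$check_every,
                             max_iter = control$max_iter,
                             refine = refine, verbose = control$verbose)
  grid <- res$state$grid
  tot <- res$total_pm25
  out <- list(concentrations = res$concentrations,
              total_pm25 = tot,
              grid = grid, fields = res$state$fields,
              source = res$state$source,
              dt = res$state$dt,
              iterations = res$iterations,
              converged = res$converged,
              trace = res$trace,
              exposure = list(
                population_weighted = weighted_mean_ground(tot, grid, "population"),
                area_weighted = weighted_mean_ground(tot, grid, "area")),
              control = control,
              call = match.call())
  class(out) <- "rcaim"
  out
}

#' @export
print.rcaim <- function(x, ...) {
  cat("Steady-state PM2.5 intervention model\n")
  cat(sprintf("  grid: %d cells (%d ground), %d layers\n",
              nrow(x$grid$cells), sum(x$grid$cells$is_ground),
              length(x$grid$layer_tops)))
  cat(sprintf("  time step: %.4g s; iterations: %d (%s)\n", x$dt, x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  population-weighted dPM2.5: %.6g ug/m3\n",
              x$exposure$population_weighted))
  cat(sprintf("  area-weighted dPM2.5:       %.6g ug/m3\n",
              x$exposure$area_weighted))
  invisible(x)
}

#' @export
summary.rcaim <- function(object, ...) {
  g <- object$grid$cells$is_ground
  sp <- object$concentrations[g, , drop = FALSE]
  tab <- data.frame(
    species = colnames(sp),
    pop_weighted = vapply(colnames(sp), function(s)
      weighted_mean_ground(sp[, s], object$grid, "population"), numeric(1)),
    area_weighted = vapply(colnames(sp), function(s)
      weighted_mean_ground(sp[, s], object$grid, "area"), numeric(1)),
    min = apply(sp, 2, min), max = apply(sp, 2, max))
  rownames(tab) <- NULL
  structure(list(species = tab,
                 exposure = object$exposure,
                 iterations = object$iterations,
                 converged = object$converged, dt = object$dt),
            class = "summary.rcaim")
}

#' @export
print.summary.rcaim <- function(x, ...) {
  cat("Ground-level concentration changes (ug/m3):\n")
  print(x$species, digits = 4)
  cat(sprintf("\nTotal PM2.5: pop-weighted %.6g, area-weighted %.6g ug/m3\n",
              x$exposure$population_weighted, x$exposure$area_weighted))
  cat(sprintf("%d iterations (dt = %.4g s), %s\n", x$iterations, x$dt,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
coef.rcaim <- function(object, ...) {
  g <- object$grid$cells$is_ground
  sp <- object$concentrations[g, , drop = FALSE]
  c(total_PM25 = object$exposure$population_weighted,
    stats::setNames(vapply(colnames(sp), function(s)
      weighted_mean_ground(sp[, s], object$grid, "population"), numeric(1)),
      colnames(sp)))
}

#' Rescale a solution to a proportionally scaled emission scenario
#'
#' The steady solution is linear in the emissions (fixed fields), so a
#' uniformly scaled scenario needs no re-solve.
#'
#' @param object An `rcaim` fit.
#' @param scale Scalar multiplier on all emissions.
#' @param ... Unused.
#' @return Scaled cells x species concentration matrix.
#' @export
predict.rcaim <- function(object, scale = 1, ...) {
  object$concentrations * scale
}

#' Map of the ground-level total PM2.5 change
#'
#' @param x An `rcaim` fit.
#' @param species Species column to draw, or `"total"` for total PM2.5.
#' @param ... Passed to [graphics::rect()].
#' @export
plot.rcaim <- function(x, species = "total", ...) {
  cells <- x$grid$cells
  g <- cells[cells$is_ground, ]
  v <- if (identical(species, "total")) x$total_pm25[g$id]
       else x$concentrations[g$id, species]
  rng <- range(v)
  pal <- grDevices::hcl.colors(64, "YlOrRd", rev = TRUE)
  idx <- if (diff(rng) > 0) {
    pmax(1, ceiling(64 * (v - rng[1]) / diff(rng)))
  } else rep(1L, length(v))
  graphics::plot(NA, xlim = x$grid$domain[1:2], ylim = x$grid$domain[3:4],
                 asp = 1, xlab = "x (m)", ylab = "y (m)",
                 main = sprintf("Ground-level d%s (ug/m3)",
                                if (identical(species, "total")) "PM2.5" else species))
  graphics::rect(g$xmin, g$ymin, g$xmax, g$ymax, col = pal[idx], border = NA, ...)
  invisible(x)
}

#' Export a solution's per-cell concentrations
#'
#' Writes the ground-layer cell polygons with all nine species plus total
#' PM2.5 as GeoJSON, and the full 3-D cell table as CSV.
#'
#' @param object An `rcaim` fit.
#' @param dir Output directory.
#' @return Invisibly the written paths.
#' @export
export_concentrations <- function(object, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  conc <- as.data.frame(object$concentrations)
  conc$total_PM25 <- object$total_pm25
  gj <- file.path(dir, "concentrations_ground.geojson")
  grid_to_geojson(object$grid, gj, layer = 0L, attributes = conc)
  cs <- file.path(dir, "concentrations.csv")
  full <- cbind(object$grid$cells[, c("id", "layer", "xmin", "xmax", "ymin",
                                      "ymax", "zbot", "ztop", "population")],
                conc)
  utils::write.csv(fmt_num_df(full), cs, row.names = FALSE)
  tr <- file.path(dir, "convergence_trace.csv")
  utils::write.csv(fmt_num_df(object$trace), tr, row.names = FALSE)
  invisible(c(gj, cs, tr))
}
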