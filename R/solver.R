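# The model core: advance the 9-species concentration-change field through
# CFL-limited pseudo-time steps — emissions, upwind mean advection,
# symmetric deviation advection, local-nonlocal mixing, first-order sulfur
# chemistry, dry/wet deposition, then instantaneous gas/particle
# partitioning — until the solution is steady.  Every process is linear in
# the concentrations, so the steady solution is linear in the emissions.

#' CFL-limited time step
#'
#' `dt = Cmax / (3 * max over cells of max((|U|+|Udev|)/dx,
#' (|V|+|Vdev|)/dy, |W|/dz))`.  A calm-wind floor keeps dt finite when all
#' winds are zero.
#'
#' @param grid A `vr_grid`.
#' @param fields A `cell_fields`.
#' @param Cmax Maximum allowable Courant number, in (0, 1].
#' @param wind_floor Floor (m s^-1) applied to the largest wind/size ratio
#'   denominatorwise, as `wind_floor / max(dx)`.
#' @return Time step (s).
#' @export
cfl_timestep <- function(grid, fields, Cmax = 1.0, wind_floor = 1e-3) {
  stopifnot(Cmax > 0, Cmax <= 1)
  cells <- grid$cells
  f <- fields$fields
  ratio <- pmax((abs(f$U) + f$Udev) / cells$dx,
                (abs(f$V) + f$Vdev) / cells$dy,
                abs(f$W) / cells$dz)
  m <- max(ratio, wind_floor / max(cells$dx))
  Cmax / (3 * m)
}

# ---------------------------------------------------------------------------
# Operator assembly.  The shared transport operator T (advection + deviation
# advection + mixing) is one sparse cells x cells matrix: dC/dt|transport =
# T %*% C, identical for every species.  Removal and chemistry are handled
# per species class in step().
#
# Face-value convention: per-cell stored U, V, W, Udev, Vdev, Kxx, Kyy, Kzz
# are the values at the cell's own West / South / Bottom face; an interior
# face takes the value stored by its East/North/Upper cell.  Domain-boundary
# faces on the E/N/top sides reuse the boundary cell's own stored value.

assemble_transport <- function(grid, fields) {
  cells <- grid$cells
  f <- fields$fields
  fc <- grid$faces
  n <- nrow(cells)
  V <- cells$volume
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add <- function(i, j, x) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, x)
  }

  a <- fc$a; b <- fc$b
  horiz <- fc$dir != "z"
  # face-normal mean wind and deviation (deviation horizontal only)
  u <- ifelse(fc$dir == "x", f$U[b], ifelse(fc$dir == "y", f$V[b], f$W[b]))
  udev <- ifelse(fc$dir == "x", f$Udev[b], ifelse(fc$dir == "y", f$Vdev[b], 0))
  kk <- ifelse(fc$dir == "x", f$Kxx[b], ifelse(fc$dir == "y", f$Kyy[b], f$Kzz[b]))
  del_a <- ifelse(fc$dir == "x", cells$dx[a], ifelse(fc$dir == "y", cells$dy[a], cells$dz[a]))
  del_b <- ifelse(fc$dir == "x", cells$dx[b], ifelse(fc$dir == "y", cells$dy[b], cells$dz[b]))
  A <- fc$area

  # upwind mean advection, flux form: each face debits the upwind cell and
  # credits the downwind cell, so interior advection conserves mass exactly
  donor <- ifelse(u >= 0, a, b)
  recv <- ifelse(u >= 0, b, a)
  flux <- abs(u) * A  # m^3 s^-1
  nzf <- flux > 0
  add(recv[nzf], donor[nzf], (flux / V[recv])[nzf])
  add(donor[nzf], donor[nzf], -(flux / V[donor])[nzf])

  # symmetric deviation advection (horizontal faces only)
  dsel <- horiz & udev > 0
  ex <- (udev * A)[dsel]
  add(a[dsel], b[dsel], ex / V[a[dsel]])
  add(a[dsel], a[dsel], -ex / V[a[dsel]])
  add(b[dsel], a[dsel], ex / V[b[dsel]])
  add(b[dsel], b[dsel], -ex / V[b[dsel]])

  # local turbulent diffusion on all faces: 2 K (C_b - C_a)/(del_a + del_b)
  ksel <- kk > 0
  kx <- (2 * kk / (del_a + del_b) * A)[ksel]
  add(a[ksel], b[ksel], kx / V[a[ksel]])
  add(a[ksel], a[ksel], -kx / V[a[ksel]])
  add(b[ksel], a[ksel], kx / V[b[ksel]])
  add(b[ksel], b[ksel], -kx / V[b[ksel]])

  # nonlocal convective mixing within each boundary-layer column: the
  # ground cell vents M2u*Cg upward, distributed over boundary-layer cells
  # with weights proportional to M2d_i*dz_i; each elevated cell returns
  # M2d_i*Ci directly to the ground cell.  Conserves column mass for any
  # coefficients; uniform concentration is a fixed point exactly when
  # M2u*dz_g = sum(M2d_i*dz_i) (the archive generator's contract).
  for (stack in grid$column_stacks) {
    g <- stack[1]
    m2u <- f$M2u[g]
    elev <- stack[-1]
    elev <- elev[cells$zbot[elev] < f$blh[g]]
    if (!length(elev)) next
    m2d <- f$M2d[elev]
    denom <- sum(m2d * cells$dz[elev])
    if (m2u > 0 && denom > 0) {
      wgt <- m2d * cells$dz[elev] / denom
      add(g, g, -m2u)
      add(elev, rep(g, length(elev)), m2u * cells$dz[g] * wgt / cells$dz[elev])
    }
    up <- m2d > 0
    if (any(up)) {
      add(elev[up], elev[up], -m2d[up])
      add(rep(g, sum(up)), elev[up], (m2d * cells$dz[elev] / cells$dz[g])[up])
    }
  }

  # open lateral/top boundaries: zero concentration-change outside.
  # Advection: outflow is a pure loss; inflow carries zero.  Deviation and
  # diffusion exchange with a zero-concentration ghost cell.
  eps <- 1e-6
  dom <- grid$domain
  ztop <- max(grid$layer_tops)
  for (i in which(cells$is_lateral_boundary | cells$is_top)) {
    sides <- list()
    if (cells$xmin[i] <= dom[1] + eps) sides <- c(sides, list(list(d = "x", sgn = -1)))
    if (cells$xmax[i] >= dom[2] - eps) sides <- c(sides, list(list(d = "x", sgn = 1)))
    if (cells$ymin[i] <= dom[3] + eps) sides <- c(sides, list(list(d = "y", sgn = -1)))
    if (cells$ymax[i] >= dom[4] - eps) sides <- c(sides, list(list(d = "y", sgn = 1)))
    if (cells$ztop[i] >= ztop - eps) sides <- c(sides, list(list(d = "z", sgn = 1)))
    for (s in sides) {
      if (s$d == "x") {
        un <- f$U[i]; ud <- f$Udev[i]; kf <- f$Kxx[i]
        Af <- cells$dy[i] * cells$dz[i]; del <- cells$dx[i]
      } else if (s$d == "y") {
        un <- f$V[i]; ud <- f$Vdev[i]; kf <- f$Kyy[i]
        Af <- cells$dx[i] * cells$dz[i]; del <- cells$dy[i]
      } else {
        un <- f$W[i]; ud <- 0; kf <- f$Kzz[i]
        Af <- cells$dx[i] * cells$dy[i]; del <- cells$dz[i]
      }
      outflow <- un * s$sgn > 0
      if (outflow) add(i, i, -abs(un) * Af / V[i])
      if (ud > 0) add(i, i, -ud * Af / V[i])
      if (kf > 0) add(i, i, -2 * kf / (2 * del) * Af / V[i])
    }
  }

  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
}

# per-species first-order removal rate (s^-1) for every cell: wet
# deposition everywhere + dry deposition in ground cells
removal_rates <- function(grid, fields) {
  cells <- grid$cells
  f <- fields$fields
  n <- nrow(cells)
  vs <- settling_velocity()
  vdd_gas <- function(rc) 1 / (f$ra + f$rb + rc)
  # particle deposition velocity with the settling-velocity modification
  vdd_part <- vs + 1 / (f$ra + f$rb + f$rc_particle + f$ra * f$rb * vs)
  classes <- list(
    particle = list(rwd = f$rwd_particle, vdd = vdd_part),
    SO2 = list(rwd = f$rwd_SO2, vdd = vdd_gas(f$rc_gas)),
    othergas = list(rwd = f$rwd_othergas, vdd = vdd_gas(f$rc_gas)))
  species_class <- c(pPM25 = "particle", VOC = "othergas", SOA = "particle",
                     SOx = "SO2", pSO4 = "particle", NOx = "othergas",
                     pNO3 = "particle", NH3 = "othergas", pNH4 = "particle")
  out <- matrix(0, n, length(SPECIES), dimnames = list(NULL, SPECIES))
  for (sp in SPECIES) {
    cl <- classes[[species_class[[sp]]]]
    r <- cl$rwd
    dry <- ifelse(cells$is_ground, cl$vdd / cells$dz, 0)
    dry[is.na(dry)] <- 0
    out[, sp] <- r + dry
  }
  out
}

# ---------------------------------------------------------------------------
# Solver state

#' Initialise solver state
#'
#' @param grid A `vr_grid`.
#' @param fields A `cell_fields` archive.
#' @param source A `source_field` from [grid_emissions()] (or a zero
#'   matrix).
#' @param Cmax Maximum Courant number.
#' @return A `solver_state` list: grid, fields, source, concentration
#'   matrix, precomputed operators, dt, iteration counter.
#' @export
solver_state <- function(grid, fields, source, Cmax = 1.0) {
  n <- nrow(grid$cells)
  if (is.null(dim(source))) source <- matrix(source, n, length(SPECIES),
                                             dimnames = list(NULL, SPECIES))
  source <- unclass(source)
  class(source) <- NULL
  attr(source, "class") <- NULL
  source <- matrix(as.numeric(source), n, length(SPECIES),
                   dimnames = list(NULL, SPECIES))
  dt <- cfl_timestep(grid, fields, Cmax)
  structure(list(grid = grid, fields = fields, source = source,
                 C = matrix(0, n, length(SPECIES), dimnames = list(NULL, SPECIES)),
                 transport = assemble_transport(grid, fields),
                 removal = removal_rates(grid, fields),
                 dt = dt, Cmax = Cmax, iteration = 0L),
            class = "solver_state")
}

# ---------------------------------------------------------------------------
# Individual operators (increments over one dt; returned, not applied).
# These exist for inspection and unit verification; step() applies the same
# mathematics via the precomputed sparse operator.

op_increments <- function(state, what = c("transport", "advection",
                                          "deviation", "mixing")) {
  what <- match.arg(what)
  # transport includes all three; the split pieces are recomputed on the fly
  tm <- switch(what,
    transport = state$transport,
    assemble_partial(state$grid, state$fields, what))
  as.matrix(tm %*% state$C) * state$dt
}

assemble_partial <- function(grid, fields, what) {
  # zero out the unrelated fields and reassemble
  fz <- fields
  f <- fz$fields
  if (what == "advection") {
    f$Udev[] <- 0; f$Vdev[] <- 0
    f$Kxx[] <- 0; f$Kyy[] <- 0; f$Kzz[] <- 0; f$M2u[] <- 0; f$M2d[] <- 0
  } else if (what == "deviation") {
    f$U[] <- 0; f$V[] <- 0; f$W[] <- 0
    f$Kxx[] <- 0; f$Kyy[] <- 0; f$Kzz[] <- 0; f$M2u[] <- 0; f$M2d[] <- 0
  } else if (what == "mixing") {
    f$U[] <- 0; f$V[] <- 0; f$W[] <- 0; f$Udev[] <- 0; f$Vdev[] <- 0
  }
  fz$fields <- f
  assemble_transport(grid, fz)
}

#' Upwind mean-advection increments over one time step
#' @param state A `solver_state`.
#' @return Cells x species increment matrix (ug m^-3); not applied.
#' @export
advect_mean <- function(state) op_increments(state, "advection")

#' Symmetric deviation-advection increments over one time step
#' @param state A `solver_state`.
#' @return Cells x species increment matrix (ug m^-3); not applied.
#' @export
advect_deviation <- function(state) op_increments(state, "deviation")

#' Local-nonlocal mixing increments over one time step
#' @param state A `solver_state`.
#' @return Cells x species increment matrix (ug m^-3); not applied.
#' @export
mix <- function(state) op_increments(state, "mixing")

#' First-order sulfur chemistry increments over one time step
#'
#' Moves `kS * C_SOx * dt` of (SO4-equivalent) sulfur mass irreversibly
#' from the SOx gas tracer to particulate sulfate.
#'
#' @param state A `solver_state`.
#' @return Cells x species increment matrix; only the SOx and pSO4 columns
#'   are nonzero.
#' @export
chem_sulfur <- function(state) {
  inc <- state$C * 0
  transfer <- state$fields$fields$kS * state$C[, "SOx"] * state$dt
  inc[, "SOx"] <- -transfer
  inc[, "pSO4"] <- transfer
  inc
}

#' Dry-deposition increments over one time step (ground cells only)
#' @param state A `solver_state`.
#' @return Cells x species increment matrix.
#' @export
dry_deposition <- function(state) {
  cells <- state$grid$cells
  rem <- removal_rates(state$grid, state$fields)
  wet <- wet_rates_only(state)
  -(rem - wet) * state$C * state$dt
}

#' Wet-deposition increments over one time step (all cells)
#' @param state A `solver_state`.
#' @return Cells x species increment matrix.
#' @export
wet_deposition <- function(state) {
  -wet_rates_only(state) * state$C * state$dt
}

wet_rates_only <- function(state) {
  f <- state$fields$fields
  cls <- c(pPM25 = "rwd_particle", VOC = "rwd_othergas", SOA = "rwd_particle",
           SOx = "rwd_SO2", pSO4 = "rwd_particle", NOx = "rwd_othergas",
           pNO3 = "rwd_particle", NH3 = "rwd_othergas", pNH4 = "rwd_particle")
  sapply(SPECIES, function(sp) f[[cls[[sp]]]])
}

#' Instantaneous gas/particle partitioning
#'
#' Redistributes each reversible pair (NOx/pNO3, NH3/pNH4, VOC/SOA) so the
#' particle phase holds the fraction fp of the pair total; the pair total
#' is conserved exactly.  Applied after all other operators in a step.
#'
#' @param C Cells x species concentration matrix.
#' @param fields A `cell_fields`.
#' @return The repartitioned matrix.
#' @export
partition <- function(C, fields) {
  f <- fields$fields
  fp <- list(NOx = f$fp_NO3, NH3 = f$fp_NH4, VOC = f$fp_org)
  for (pair in GAS_PARTICLE_PAIRS) {
    g <- pair[1]; p <- pair[2]
    tot <- C[, g] + C[, p]
    C[, p] <- tot * fp[[g]]
    C[, g] <- tot - C[, p]  # gas as the remainder: pair total exact bitwise
  }
  C
}

#' Advance the solver by one time step
#'
#' Adds the emission source, computes transport (mean advection, deviation
#' advection, mixing), sulfur chemistry and dry/wet deposition — all from
#' the start-of-step concentrations — applies their summed increments, and
#' finally repartitions the reversible gas/particle pairs.
#'
#' @param state A `solver_state`.
#' @return The advanced state.
#' @export
step <- function(state) {
  C0 <- state$C
  dt <- state$dt
  inc <- as.matrix(state$transport %*% C0) * dt
  inc <- inc - state$removal * C0 * dt
  transfer <- state$fields$fields$kS * C0[, "SOx"] * dt
  inc[, "SOx"] <- inc[, "SOx"] - transfer
  inc[, "pSO4"] <- inc[, "pSO4"] + transfer
  C1 <- C0 + inc + state$source * dt
  C1 <- partition(C1, state$fields)
  if (!all(is.finite(C1))) {
    bad <- which(!is.finite(C1), arr.ind = TRUE)[1, ]
    stop(sprintf("numerical blow-up at cell %d, species %s",
                 bad[1], SPECIES[bad[2]]), call. = FALSE)
  }
  state$C <- C1
  state$iteration <- state$iteration + 1L
  state
}

#' Iterate to the steady-state solution
#'
#' Repeats [step()] until the population-weighted mean total-PM2.5 change
#' is stable: convergence is declared when its relative change over a
#' monitoring window falls below `tol` (with an absolute floor for
#' near-zero scenarios), or when `max_iter` is reached (flagged
#' not-converged with a warning).
#'
#' @param state A `solver_state`.
#' @param tol Relative tolerance on the monitored mean.
#' @param abs_floor Absolute floor (ug m^-3) below which changes count as
#'   converged.
#' @param check_every Monitoring window (iterations).
#' @param max_iter Iteration cap.
#' @param refine Optional dynamic-refinement settings: list with
#'   `population`, `thresholds`, `every`; when given, the grid is
#'   re-examined every `every` iterations and the state rebuilt on the new
#'   grid with conservative re-interpolation.
#' @param verbose Print a convergence line every monitoring window.
#' @return List: `concentrations` (cells x species), `total_pm25`,
#'   `iterations`, `converged`, `trace` (monitor history data frame),
#'   `state` (final solver state).
#' @export
run_to_steady_state <- function(state, tol = 1e-6, abs_floor = 1e-9,
                                check_every = 100L, max_iter = 1e6,
                                refine = NULL, verbose = FALSE) {
  grid <- state$grid
  pw <- function(st) {
    g <- st$grid$cells$is_ground
    wts <- st$grid$cells$population[g]
    tot <- rowSums(st$C[g, PM25_COMPONENTS, drop = FALSE])
    if (sum(wts) <= 0) mean(tot) else sum(wts * tot) / sum(wts)
  }
  trace <- list()
  prev <- pw(state)
  converged <- FALSE
  if (all(state$source == 0) && all(state$C == 0)) {
    trace[[1]] <- data.frame(iteration = 0L, monitor = 0)
    return(list(concentrations = state$C,
                total_pm25 = rowSums(state$C[, PM25_COMPONENTS, drop = FALSE]),
                iterations = 0L, converged = TRUE,
                trace = do.call(rbind, trace), state = state))
  }
  repeat {
    for (k in seq_len(check_every)) state <- step(state)
    cur <- pw(state)
    trace[[length(trace) + 1L]] <- data.frame(iteration = state$iteration,
                                              monitor = cur)
    if (verbose && length(trace) %% 10 == 0) {
      message(sprintf("iter %d: pop-weighted dPM2.5 = %.6g", state$iteration, cur))
    }
    delta <- abs(cur - prev)
    if (delta <= abs_floor || delta <= tol * max(abs(cur), abs_floor)) {
      converged <- TRUE
      break
    }
    prev <- cur
    if (!is.null(refine) && state$iteration %% refine$every == 0) {
      res <- refine_dynamic(state$grid, state$C, refine$population,
                            refine$thresholds)
      state <- rebuild_state_on_grid(state, res$grid, res$concentrations,
                                     refine$records)
      prev <- pw(state)
    }
    if (state$iteration >= max_iter) break
  }
  if (!converged) warning("steady-state iteration hit max_iter without converging")
  list(concentrations = state$C,
       total_pm25 = rowSums(state$C[, PM25_COMPONENTS, drop = FALSE]),
       iterations = state$iteration, converged = converged,
       trace = do.call(rbind, trace), state = state)
}

# Rebuild state after dynamic refinement: regenerate fields on the new grid
# (same seed/params), re-grid the emissions, keep interpolated concentrations.
rebuild_state_on_grid <- function(state, new_grid, new_C, records) {
  meta <- state$fields$meta
  new_fields <- synthesize_archive(new_grid, seed = meta$seed,
                                   params = meta$params)
  new_source <- grid_emissions(records, new_grid, new_fields)
  ns <- solver_state(new_grid, new_fields, new_source, Cmax = state$Cmax)
  ns$C <- as.matrix(new_C)
  dimnames(ns$C) <- list(NULL, SPECIES)
  ns$iteration <- state$iteration
  ns
}
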