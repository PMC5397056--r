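# Shared fixtures: toy grids built in code and hand-specified field
# archives, plus independent dense oracles for the transport operators and
# the steady-state linear system.

# Uniform toy grid: nx x ny square columns of `size` metres, `layer_tops`
# vertical layers, no population-driven refinement.
toy_grid <- function(nx = 2, ny = 1, size = 1000,
                     layer_tops = c(50), population = 0,
                     pop_matrix = NULL) {
  domain <- c(0, nx * size, 0, ny * size)
  vals <- if (is.null(pop_matrix)) matrix(population, nx, ny) else pop_matrix
  pop <- pop_raster(vals, domain)
  cfg <- grid_config(base_size = size, level_divisors = c(2),
                     min_cell_size = size / 2,
                     pop_threshold = Inf,  # never split
                     layer_tops = layer_tops,
                     high_res_cap = max(layer_tops) + 1,
                     domain = domain)
  build_static_grid(pop, cfg)
}

# Hand-specified archive: every argument is a scalar (recycled) or a
# per-cell vector.  Ground-only resistances are set on ground cells only.
toy_fields <- function(grid, U = 0, V = 0, W = 0, Udev = 0, Vdev = 0,
                       Kxx = 0, Kyy = 0, Kzz = 0, M2u = 0, M2d = 0,
                       kS = 0, fp_NO3 = 0.5, fp_NH4 = 0.5, fp_org = 0.5,
                       blh = 1e4,
                       rwd_particle = 0, rwd_SO2 = 0, rwd_othergas = 0,
                       ra = 100, rb = 50, rc_gas = 50, rc_particle = 500) {
  n <- nrow(grid$cells)
  rc <- function(x) rep(x, length.out = n)
  f <- data.frame(id = grid$cells$id,
                  U = rc(U), V = rc(V), W = rc(W),
                  Udev = rc(Udev), Vdev = rc(Vdev),
                  Kxx = rc(Kxx), Kyy = rc(Kyy), Kzz = rc(Kzz),
                  M2u = rc(M2u), M2d = rc(M2d), kS = rc(kS),
                  fp_NO3 = rc(fp_NO3), fp_NH4 = rc(fp_NH4),
                  fp_org = rc(fp_org), blh = rc(blh),
                  rwd_particle = rc(rwd_particle), rwd_SO2 = rc(rwd_SO2),
                  rwd_othergas = rc(rwd_othergas),
                  ra = NA_real_, rb = NA_real_, rc_gas = NA_real_,
                  rc_particle = NA_real_)
  g <- grid$cells$is_ground
  f$ra[g] <- ra; f$rb[g] <- rb; f$rc_gas[g] <- rc_gas
  f$rc_particle[g] <- rc_particle
  ncols <- nrow(grid$fine_columns)
  plume <- data.frame(col = seq_len(ncols), windspeed = 3, ws_inv = 1 / 3,
                      ws_inv13 = 3^(-1 / 3), ws_inv14 = 3^(-1.4),
                      temperature = 288, s1 = 2e-4, stability_class = 0L,
                      blh = rep(blh, length.out = ncols))
  structure(list(fields = f, plume = plume,
                 grid_ref = list(n_cells = n),
                 meta = list(seed = 0L, params = scenario_params()),
                 hourly = NULL),
            class = "cell_fields")
}

# zero source matrix for a grid
zero_source <- function(grid) {
  matrix(0, nrow(grid$cells), length(model_species()),
         dimnames = list(NULL, model_species()))
}

# --------------------------------------------------------------------------
# Independent dense transport oracle: per-cell evaluation of the upwind,
# deviation and mixing equations through the face-topology neighbour lists.
# Returns the dense matrix M such that dC/dt = M %*% C.

oracle_transport_dense <- function(grid, fields,
                                   include = c("advection", "deviation",
                                               "mixing")) {
  cells <- grid$cells
  f <- fields$fields
  topo <- face_topology(grid)
  n <- nrow(cells)
  M <- matrix(0, n, n)
  eps <- 1e-6
  dom <- grid$domain
  ztop <- max(grid$layer_tops)
  for (i in seq_len(n)) {
    dxi <- cells$dx[i]; dyi <- cells$dy[i]; dzi <- cells$dz[i]
    for (side in c("W", "E", "S", "N", "below", "above")) {
      nb <- topo$neighbors(i, side)
      ax <- switch(side, W = , E = "x", S = , N = "y", "z")
      deli <- switch(ax, x = dxi, y = dyi, z = dzi)
      if (nrow(nb)) {
        for (r in seq_len(nrow(nb))) {
          j <- nb$id[r]; fr <- nb$f[r]
          # face value owner: the east/north/upper cell of the pair
          owner <- if (side %in% c("W", "S", "below")) i else j
          u <- switch(ax, x = f$U[owner], y = f$V[owner], z = f$W[owner])
          ud <- switch(ax, x = f$Udev[owner], y = f$Vdev[owner], z = 0)
          kf <- switch(ax, x = f$Kxx[owner], y = f$Kyy[owner], z = f$Kzz[owner])
          delj <- switch(ax, x = cells$dx[j], y = cells$dy[j], z = cells$dz[j])
          # sign of the face-normal wind pointing INTO cell i
          into_i <- if (side %in% c("W", "S", "below")) u else -u
          if ("advection" %in% include) {
            if (into_i >= 0) {
              M[i, j] <- M[i, j] + abs(into_i) * fr / deli * (into_i > 0)
            } else {
              M[i, i] <- M[i, i] - abs(into_i) * fr / deli
            }
          }
          if ("deviation" %in% include && ud > 0) {
            M[i, j] <- M[i, j] + ud * fr / deli
            M[i, i] <- M[i, i] - ud * fr / deli
          }
          if ("mixing" %in% include && kf > 0) {
            cc <- 2 * kf / (deli + delj) * fr / deli
            M[i, j] <- M[i, j] + cc
            M[i, i] <- M[i, i] - cc
          }
        }
      } else {
        # domain boundary face?
        is_boundary <- switch(side,
          W = cells$xmin[i] <= dom[1] + eps,
          E = cells$xmax[i] >= dom[2] - eps,
          S = cells$ymin[i] <= dom[3] + eps,
          N = cells$ymax[i] >= dom[4] - eps,
          below = FALSE,  # impermeable ground
          above = cells$ztop[i] >= ztop - eps)
        if (!is_boundary) next
        u <- switch(ax, x = f$U[i], y = f$V[i], z = f$W[i])
        ud <- switch(ax, x = f$Udev[i], y = f$Vdev[i], z = 0)
        kf <- switch(ax, x = f$Kxx[i], y = f$Kyy[i], z = f$Kzz[i])
        outward <- switch(side, W = -u, S = -u, below = -u, u)
        if ("advection" %in% include && outward > 0) {
          M[i, i] <- M[i, i] - outward / deli
        }
        if ("deviation" %in% include && ud > 0) {
          M[i, i] <- M[i, i] - ud / deli
        }
        if ("mixing" %in% include && kf > 0) {
          M[i, i] <- M[i, i] - 2 * kf / (2 * deli) / deli
        }
      }
    }
  }
  if ("mixing" %in% include) {
    # nonlocal convective exchange per boundary-layer column
    for (stack in grid$column_stacks) {
      g <- stack[1]
      elev <- stack[-1]
      elev <- elev[cells$zbot[elev] < f$blh[g]]
      if (!length(elev)) next
      m2u <- f$M2u[g]; m2d <- f$M2d[elev]
      denom <- sum(m2d * cells$dz[elev])
      if (m2u > 0 && denom > 0) {
        w <- m2d * cells$dz[elev] / denom
        M[g, g] <- M[g, g] - m2u
        for (r in seq_along(elev)) {
          M[elev[r], g] <- M[elev[r], g] +
            m2u * cells$dz[g] * w[r] / cells$dz[elev[r]]
        }
      }
      for (r in seq_along(elev)) {
        if (m2d[r] > 0) {
          M[elev[r], elev[r]] <- M[elev[r], elev[r]] - m2d[r]
          M[g, elev[r]] <- M[g, elev[r]] +
            m2d[r] * cells$dz[elev[r]] / cells$dz[g]
        }
      }
    }
  }
  M
}

# --------------------------------------------------------------------------
# Direct solve of the steady-state linear system by probing one solver step
# as an affine map on the stacked concentration vector: C' = M C + b, steady
# state solves (I - M) x = b.  `species` restricts the probe to a subspace
# that is closed under the step map (valid when sources live there too).

steady_direct <- function(state, species = model_species()) {
  sp_all <- model_species()
  n <- nrow(state$grid$cells)
  cols <- match(species, sp_all)
  m <- n * length(cols)
  pack <- function(C) as.vector(C[, cols])
  unpack <- function(x) {
    C <- matrix(0, n, length(sp_all), dimnames = list(NULL, sp_all))
    C[, cols] <- matrix(x, n, length(cols))
    C
  }
  st0 <- state
  st0$C[] <- 0
  b <- pack(step(st0)$C)
  M <- matrix(0, m, m)
  stz <- state
  stz$source[] <- 0
  for (k in seq_len(m)) {
    stz$C <- unpack(replace(numeric(m), k, 1))
    M[, k] <- pack(step(stz)$C)
  }
  x <- solve(diag(m) - M, b)
  unpack(x)
}

# total tracked mass (ug) of a concentration matrix on a grid
total_mass <- function(C, grid) sum(C * grid$cells$volume)

# per-cell, per-species first-order removal rates as the solver applies them
removal_rates_for_test <- function(state) {
  rcaim:::removal_rates(state$grid, state$fields)
}
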