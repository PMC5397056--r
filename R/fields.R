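# Annual-average per-cell parameter fields consumed by the solver, the
# hourly-to-annual preprocessor estimators, and a synthetic archive
# generator that emulates the structure of a comprehensive-model-derived
# archive so the whole model is testable without one.

SPECIES <- c("pPM25", "VOC", "SOA", "SOx", "pSO4", "NOx", "pNO3", "NH3", "pNH4")
GAS_PARTICLE_PAIRS <- list(c("NOx", "pNO3"), c("NH3", "pNH4"), c("VOC", "SOA"))
PM25_COMPONENTS <- c("pPM25", "pSO4", "pNO3", "pNH4", "SOA")

# Fixed aerosol properties (used only for dry deposition): diameter 0.3 um,
# density 1830 kg m^-3.
PARTICLE_DIAMETER <- 0.3e-6
PARTICLE_DENSITY <- 1830

#' Gravitational settling velocity of the model aerosol
#'
#' Stokes settling with the Cunningham slip correction for the fixed model
#' particle (0.3 um, 1830 kg m^-3).
#'
#' @param mu Dynamic viscosity of air (Pa s).
#' @param mfp Mean free path of air molecules (m).
#' @return Settling velocity (m s^-1).
#' @export
settling_velocity <- function(mu = 1.8e-5, mfp = 6.8e-8) {
  kn <- 2 * mfp / PARTICLE_DIAMETER
  cc <- 1 + kn * (1.257 + 0.4 * exp(-1.1 / kn))
  PARTICLE_DENSITY * PARTICLE_DIAMETER^2 * 9.81 * cc / (18 * mu)
}

# ---------------------------------------------------------------------------
# Hourly-to-annual estimators

#' Annual-average SO2 -> sulfate rate constant
#'
#' Computes a first-order oxidation rate constant for every hour — the sum
#' of a gas-phase term (termolecular SO2 + OH reaction, a function of
#' temperature and hydroxyl concentration) and an effective aqueous-phase
#' term (proportional to cloud fraction and liquid water content) — and
#' returns their arithmetic mean.  Averaging the hourly constants, rather
#' than evaluating the constant at mean inputs, preserves some of the
#' effect of the nonlinear temperature/oxidant dependence.
#'
#' @param hourly_T Hourly temperature series (K).
#' @param hourly_HO Hourly hydroxyl radical concentration (molecules cm^-3).
#' @param hourly_cloud Hourly cloud fraction in `[0, 1]`.
#' @param hourly_lwc Hourly cloud liquid water content (kg m^-3); defaults
#'   to 0 (no aqueous pathway).
#' @param consts Rate-expression constants: `k0_300`, `n` (low-pressure
#'   limit k0 = k0_300 * (300/T)^n * M), `kinf`, `M` (air number density,
#'   molecules cm^-3), `fc` (broadening factor), and `aq_coeff` (effective
#'   aqueous rate per unit cloud fraction and LWC, s^-1 / (kg m^-3)).
#' @return Annual-average rate constant kS (s^-1).
#' @export
average_rate_constant <- function(hourly_T, hourly_HO,
                                  hourly_cloud = rep(0, length(hourly_T)),
                                  hourly_lwc = rep(0, length(hourly_T)),
                                  consts = list(k0_300 = 3.3e-31, n = 4.3,
                                                kinf = 1.6e-12, M = 2.46e19,
                                                fc = 0.6, aq_coeff = 1e-2)) {
  n <- length(hourly_T)
  if (length(hourly_HO) != n || length(hourly_cloud) != n || length(hourly_lwc) != n) {
    stop("input error: hourly series must have equal lengths", call. = FALSE)
  }
  k0 <- consts$k0_300 * (300 / hourly_T)^consts$n * consts$M
  ratio <- k0 / consts$kinf
  kgas <- (k0 / (1 + ratio)) * consts$fc^(1 / (1 + log10(ratio)^2)) * hourly_HO
  kaq <- consts$aq_coeff * hourly_cloud * hourly_lwc
  mean(kgas + kaq)
}

#' Annual-average marginal gas/particle partitioning fraction
#'
#' The mean over consecutive time steps of the fraction of the total
#' (gas + particle) mass change residing in the particle phase.  Steps
#' with zero total mass change are skipped (reducing n); per-step
#' fractions outside `[0, 1]` (opposite-signed phase changes) are clamped,
#' keeping the estimate a valid fraction.
#'
#' @param m_gas Hourly gas-phase mass series (n >= 2).
#' @param m_particle Hourly particle-phase mass series.
#' @return Partitioning fraction fp in `[0, 1]`.
#' @export
partitioning_fraction <- function(m_gas, m_particle) {
  n <- length(m_gas)
  if (length(m_particle) != n) stop("input error: series lengths differ", call. = FALSE)
  if (n < 2) stop("input error: need at least two time steps", call. = FALSE)
  dg <- diff(m_gas)
  dp <- diff(m_particle)
  tot <- dp + dg
  keep <- tot != 0
  if (!any(keep)) stop("input error: no steps with nonzero total mass change", call. = FALSE)
  frac <- pmin(pmax(dp[keep] / tot[keep], 0), 1)
  mean(frac)
}

#' Annual-average absolute wind-speed deviation
#'
#' Mean over hours of the absolute difference between the hourly wind
#' component and its annual mean.  Zero iff the wind is constant.
#'
#' @param hourly_wind Hourly wind component series (m s^-1).
#' @param annual_mean Annual mean to deviate from; defaults to
#'   `mean(hourly_wind)`.
#' @return Mean absolute deviation (m s^-1).
#' @export
average_deviation <- function(hourly_wind, annual_mean = mean(hourly_wind)) {
  if (!length(hourly_wind)) stop("input error: empty series", call. = FALSE)
  mean(abs(hourly_wind - annual_mean))
}

#' Annual-average mixing coefficients for one column
#'
#' For every hour, computes boundary-layer mixing coefficients from a
#' simple similarity closure — convective (nonlocal) coefficients when the
#' surface heat flux is positive, local eddy diffusivities always — and
#' returns their arithmetic means.  The downward convective coefficients
#' are constructed so that, each hour and hence after averaging,
#' `M2u * dz[1] = sum(M2d[i] * dz[i])` over the boundary-layer cells,
#' which is the column-mass-consistency relation the solver's nonlocal
#' scheme relies on.
#'
#' @param hourly A data frame with hourly columns `blh` (boundary layer
#'   height, m, > 0), `ustar` (friction velocity, m s^-1), `hfx` (surface
#'   sensible heat flux, W m^-2), `temperature` (K), and `rho` (air
#'   density, kg m^-3).
#' @param layer_tops Vertical layer interface heights (m).
#' @param consts Closure constants: `kappa` (von Karman), `cp`, `m2u_coeff`
#'   (convective venting rate as a fraction of wstar / blh), `k_free`
#'   (free-troposphere background Kzz, m^2 s^-1), `kh_coeff` (horizontal
#'   diffusivity per unit ustar, m).
#' @return List with `M2u` (scalar, ground cell), `M2d` (one value per
#'   layer; zero above the mean boundary layer), `Kzz` (one value per
#'   interior vertical interface, i.e. per layer bottom face, the first
#'   entry — the ground — being zero), `Kxx`, `Kyy` (scalars), and
#'   `blh` (annual mean boundary layer height).
#' @export
average_mixing_coefficients <- function(hourly, layer_tops,
                                        consts = list(kappa = 0.4, cp = 1004,
                                                      m2u_coeff = 0.3,
                                                      k_free = 0.3,
                                                      kh_coeff = 300)) {
  req <- c("blh", "ustar", "hfx", "temperature", "rho")
  if (!all(req %in% names(hourly))) {
    stop("input error: hourly met needs columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (any(hourly$blh <= 0)) stop("input error: non-positive boundary layer height", call. = FALSE)
  nl <- length(layer_tops)
  zbot <- c(0, layer_tops[-nl])
  dz <- diff(c(0, layer_tops))
  nh <- nrow(hourly)
  blh <- hourly$blh; ustar <- hourly$ustar
  unstable <- hourly$hfx > 0
  wstar <- ifelse(unstable,
                  pmax(9.81 / hourly$temperature *
                         hourly$hfx / (hourly$rho * consts$cp) * blh, 0)^(1 / 3),
                  0)
  # number of layers whose bottom lies inside the boundary layer each hour
  nbl <- findInterval(blh, zbot + 1e-12)
  elev_dz <- cumsum(dz) - dz[1]           # sum of dz over layers 2..k
  has_elev <- unstable & nbl >= 2
  m2u <- ifelse(has_elev, consts$m2u_coeff * wstar / blh, 0)
  # uniform venting return: satisfies M2u*dz1 = sum(M2d_i*dz_i) each hour
  m2d <- matrix(0, nh, nl)
  for (k in 2:nl) {
    m2d[, k] <- ifelse(has_elev & nbl >= k, m2u * dz[1] / elev_dz[pmax(nbl, 2)], 0)
  }
  wm <- ifelse(unstable, pmax(ustar, 0.6 * wstar), ustar)
  zf <- layer_tops[-nl]  # interface heights (bottom faces of layers 2..nl)
  kzz <- matrix(0, nh, nl)
  for (k in seq_along(zf)) {
    kz <- ifelse(zf[k] < blh, consts$kappa * wm * zf[k] * (1 - zf[k] / blh)^2, 0)
    kzz[, k + 1] <- pmax(kz, consts$k_free)
  }
  kh <- consts$kh_coeff * mean(hourly$ustar)
  list(M2u = mean(m2u), M2d = colMeans(m2d), Kzz = colMeans(kzz),
       Kxx = kh, Kyy = kh, blh = mean(hourly$blh))
}

#' Wet scavenging rates (particle / SO2 / other gas)
#'
#' EMEP-style first-order wet deposition: a cloud-fraction-weighted
#' in-cloud term plus a precipitation-driven below-cloud term, with
#' separate effective coefficients per species class.
#'
#' @param precip Precipitation rate (m s^-1 of liquid water).
#' @param cloud_frac Cloud fraction in `[0, 1]`.
#' @param consts Scavenging coefficients per class.
#' @return Named list of rates (s^-1): `particle`, `SO2`, `othergas`.
#' @export
wet_scavenging_rates <- function(precip, cloud_frac,
                                 consts = list(w_in_particle = 1.0e6,
                                               w_in_SO2 = 0.3e6,
                                               w_in_othergas = 1.4e6,
                                               w_below_particle = 5.2e5,
                                               w_below_gas = 0,
                                               h_cloud = 1000)) {
  in_cloud <- function(w) cloud_frac * w * precip / consts$h_cloud
  below <- function(w) w * precip / consts$h_cloud
  list(particle = in_cloud(consts$w_in_particle) + below(consts$w_below_particle),
       SO2 = in_cloud(consts$w_in_SO2) + below(consts$w_below_gas),
       othergas = in_cloud(consts$w_in_othergas) + below(consts$w_below_gas))
}

# ---------------------------------------------------------------------------
# Synthetic archive generator

#' Default scenario parameters for the synthetic field generator
#'
#' The defaults emulate the annual-average conditions of a continental
#' mid-latitude domain: prevailing westerly flow with ground-level speeds
#' of 1--8 m s^-1 rising to about 30 m s^-1 at the domain top, hourly
#' variability around those means, convective boundary layers of
#' 300--1500 m, and positive deposition parameters in the ground layer.
#'
#' @param calm If `TRUE`, all winds and deviations are zero and mixing is
#'   minimal (useful for analytic tests).
#' @param wind_direction Prevailing direction (degrees, meteorological
#'   sense of the vector: 0 = eastward flow).
#' @param ground_speed_range Annual-mean ground wind speed band (m s^-1).
#' @param top_speed Annual-mean speed at the domain top (m s^-1).
#' @param n_hours Length of the synthetic hourly series behind each
#'   averaged quantity (8760 = one year; tests may shorten it).
#' @return A list of generator parameters.
#' @export
scenario_params <- function(calm = FALSE, wind_direction = 0,
                            ground_speed_range = c(1, 8), top_speed = 30,
                            n_hours = 8760) {
  list(calm = calm, wind_direction = wind_direction,
       ground_speed_range = ground_speed_range, top_speed = top_speed,
       n_hours = n_hours)
}

# smooth pseudo-random spatial field in [0,1] over cell centres
smooth_field <- function(x, y, domain, phases) {
  sx <- (x - domain[1]) / (domain[2] - domain[1])
  sy <- (y - domain[3]) / (domain[4] - domain[3])
  f <- 0.5 +
    0.25 * sin(2 * pi * (sx + phases[1])) * cos(2 * pi * (sy + phases[2])) +
    0.25 * sin(2 * pi * (2 * sx + phases[3]) + 2 * pi * (sy + phases[4]))
  pmin(pmax((f - min(f)) / max(max(f) - min(f), 1e-12), 0), 1)
}

#' Generate a synthetic annual-average field archive
#'
#' Produces a spatially smooth, physically plausible set of per-cell
#' annual-average fields for a grid, by synthesising short hourly series
#' for each column and running the same hourly-to-annual estimators the
#' preprocessor defines ([average_mixing_coefficients()],
#' [average_rate_constant()], [partitioning_fraction()],
#' [average_deviation()], [wet_scavenging_rates()]).  The same seed always
#' yields a bit-identical archive.
#'
#' @param grid A `vr_grid`.
#' @param seed Integer seed fixing all randomness.
#' @param params A [scenario_params()] list.
#' @param keep_hourly If `TRUE`, attach the generating hourly series of the
#'   first column (for inspection).
#' @return An object of class `cell_fields`: a data frame with one row per
#'   grid cell and the solver's field columns, plus per-column plume-rise
#'   parameters and metadata.
#' @export
synthesize_archive <- function(grid, seed = 1L, params = scenario_params(),
                               keep_hourly = FALSE) {
  stopifnot(inherits(grid, "vr_grid"))
  set.seed(seed)
  cells <- grid$cells
  n <- nrow(cells)
  domain <- grid$domain
  xc <- (cells$xmin + cells$xmax) / 2
  yc <- (cells$ymin + cells$ymax) / 2
  zc <- (cells$zbot + cells$ztop) / 2
  ztop_dom <- max(grid$layer_tops)
  phases <- stats::runif(8)

  f <- data.frame(id = cells$id)
  if (params$calm) {
    spd <- rep(0, n); dev_frac <- 0
  } else {
    g0 <- params$ground_speed_range
    ground_spd <- g0[1] + (g0[2] - g0[1]) *
      (0.02 + 0.96 * smooth_field(xc, yc, domain, phases[1:4]))
    # wind speed grows with height toward the domain-top value; no shear at
    # the ground-layer midpoint so ground speeds stay in the configured band
    zc0 <- min(zc)
    shear <- ((zc - zc0) / (ztop_dom - zc0))^0.7
    spd <- ground_spd * (1 - shear) + params$top_speed * shear
    dev_frac <- 0.5
  }
  ang <- params$wind_direction * pi / 180
  f$U <- spd * cos(ang)
  f$V <- spd * sin(ang)
  f$W <- rep(0, n)              # annual-mean vertical motion ~ 0
  f$Udev <- abs(f$U) * dev_frac
  f$Vdev <- pmax(abs(f$V) * dev_frac, spd * dev_frac * 0.3)

  nl <- length(grid$layer_tops)
  n_hours <- max(params$n_hours, 2)
  hours <- seq_len(n_hours)
  diurnal <- sin(2 * pi * hours / 24)
  seasonal <- sin(2 * pi * hours / n_hours)

  # per fine column: hourly met -> mixing, chemistry, partitioning fields
  ncol_fine <- length(grid$column_stacks)
  f$Kxx <- f$Kyy <- f$Kzz <- f$M2u <- f$M2d <- 0
  f$kS <- 0
  f$fp_NO3 <- f$fp_NH4 <- f$fp_org <- 0
  f$rwd_particle <- f$rwd_SO2 <- f$rwd_othergas <- 0
  f$blh <- 0
  plume <- data.frame(col = seq_len(ncol_fine), windspeed = 0, ws_inv = 0,
                      ws_inv13 = 0, ws_inv14 = 0, temperature = 0,
                      s1 = 0, stability_class = 0L, blh = 0)
  hourly_kept <- NULL
  minimal <- params$calm
  for (ci in seq_len(ncol_fine)) {
    stack_ids <- grid$column_stacks[[ci]]
    gid <- stack_ids[1]
    base_blh <- if (minimal) 320 else 300 + 1150 * smooth_field(xc[gid], yc[gid], domain, phases[5:8])[1]
    blh_h <- pmin(pmax(base_blh * (1 + 0.4 * diurnal + 0.1 * stats::rnorm(n_hours, sd = 0.5)), 50), 1500)
    spd_col <- if (minimal) 1e-3 else max(spd[gid], 0.5)
    ws_h <- pmax(spd_col * (1 + 0.45 * stats::rnorm(n_hours)), 0.2)
    hfx_h <- if (minimal) rep(-5, n_hours) else 120 * pmax(diurnal, 0) - 20 + 10 * stats::rnorm(n_hours)
    met <- data.frame(blh = blh_h,
                      ustar = pmax(0.05, 0.1 * ws_h),
                      hfx = hfx_h,
                      temperature = 288 + 8 * seasonal + 4 * diurnal,
                      rho = rep(1.2, n_hours))
    mix <- average_mixing_coefficients(met, grid$layer_tops)
    if (minimal) {
      mix$M2u <- 0; mix$M2d[] <- 0
      mix$Kzz <- pmin(mix$Kzz, 0.3); mix$Kxx <- mix$Kyy <- 0.5
    }
    layers_here <- cells$layer[stack_ids] + 1L
    f$M2u[gid] <- mix$M2u
    f$M2d[stack_ids] <- mix$M2d[layers_here]
    f$Kzz[stack_ids] <- mix$Kzz[layers_here]
    f$Kxx[stack_ids] <- mix$Kxx
    f$Kyy[stack_ids] <- mix$Kyy
    f$blh[stack_ids] <- mix$blh

    ho_h <- pmax(2e6 * pmax(diurnal, 0) + 1e5 + 2e5 * abs(stats::rnorm(n_hours)), 0)
    cloud_h <- pmin(pmax(0.3 + 0.25 * stats::rnorm(n_hours), 0), 1)
    lwc_h <- 3e-4 * cloud_h
    f$kS[stack_ids] <- average_rate_constant(met$temperature, ho_h, cloud_h, lwc_h)

    # partitioning: relax gas/particle masses toward a column equilibrium
    for (sp in c("fp_NO3", "fp_NH4", "fp_org")) {
      phi <- switch(sp,
                    fp_NO3 = 0.15 + 0.5 * smooth_field(xc[gid], yc[gid], domain, phases[c(2, 4, 6, 8)])[1],
                    fp_NH4 = 0.3 + 0.4 * smooth_field(xc[gid], yc[gid], domain, phases[c(1, 3, 5, 7)])[1],
                    fp_org = 0.1 + 0.3 * smooth_field(xc[gid], yc[gid], domain, phases[c(3, 1, 7, 5)])[1])
      tot_m <- 50 + 10 * diurnal + 5 * seasonal + stats::rnorm(n_hours, sd = 0.5)
      mp <- phi * tot_m + 0.05 * stats::rnorm(n_hours)
      f[stack_ids, sp] <- partitioning_fraction(tot_m - mp, mp)
    }

    precip_h <- pmax(stats::rexp(n_hours, rate = 1 / 3e-8) - 2.5e-8, 0)
    rates <- wet_scavenging_rates(precip_h, cloud_h)  # vectorised over hours
    f$rwd_particle[stack_ids] <- mean(rates$particle)
    f$rwd_SO2[stack_ids] <- mean(rates$SO2)
    f$rwd_othergas[stack_ids] <- mean(rates$othergas)

    plume$windspeed[ci] <- mean(ws_h)
    plume$ws_inv[ci] <- mean(1 / ws_h)
    plume$ws_inv13[ci] <- mean(ws_h^(-1 / 3))
    plume$ws_inv14[ci] <- mean(ws_h^(-1.4))
    plume$temperature[ci] <- mean(met$temperature)
    plume$s1[ci] <- 9.81 / mean(met$temperature) * 0.005  # g/T * dtheta/dz
    plume$stability_class[ci] <- as.integer(mean(hfx_h) <= 0)  # 1 = stable
    plume$blh[ci] <- mean(blh_h)

    if (keep_hourly && ci == 1L) {
      hourly_kept <- list(met = met, HO = ho_h, cloud = cloud_h, lwc = lwc_h,
                          windspeed = ws_h, precip = precip_h)
    }
  }
  # fields for above-cap cells: inherit the area-weighted mean of fine
  # columns below (coarse cells above the boundary layer: no convection)
  above <- which(!(grid$below_cap[cells$layer + 1L]))
  if (length(above)) {
    f$Kzz[above] <- 0.3
    f$Kxx[above] <- f$Kyy[above] <- mean(f$Kxx[-above])
    f$kS[above] <- mean(f$kS[-above])
    f$fp_NO3[above] <- mean(f$fp_NO3[-above])
    f$fp_NH4[above] <- mean(f$fp_NH4[-above])
    f$fp_org[above] <- mean(f$fp_org[-above])
    f$rwd_particle[above] <- mean(f$rwd_particle[-above])
    f$rwd_SO2[above] <- mean(f$rwd_SO2[-above])
    f$rwd_othergas[above] <- mean(f$rwd_othergas[-above])
    f$blh[above] <- mean(f$blh[-above])
  }
  # wind deviations: deviation advection acts horizontally; keep face winds
  # for above-cap cells too (already set from spd which covers all cells)

  # dry deposition resistances: ground layer only (s m^-1)
  f$ra <- f$rb <- f$rc_gas <- f$rc_particle <- NA_real_
  gids <- cells$id[cells$is_ground]
  ustar_g <- pmax(0.05, 0.1 * pmax(spd[gids], if (minimal) 0.5 else 1))
  f$ra[gids] <- log(10 / 0.1) / (0.4 * ustar_g)
  f$rb[gids] <- 5 / ustar_g
  f$rc_gas[gids] <- 60 + 80 * smooth_field(xc[gids], yc[gids], domain, phases[c(4, 2, 8, 6)])
  f$rc_particle[gids] <- 1 / (ustar_g * 2e-3)

  structure(list(fields = f, plume = plume, grid_ref = list(n_cells = n),
                 meta = list(seed = seed, params = params),
                 hourly = hourly_kept),
            class = "cell_fields")
}

#' Validate a field archive against its physical invariants
#'
#' All rates, resistances, deviations and mixing coefficients must be
#' non-negative; partitioning fractions in `[0, 1]`; boundary-layer height
#' positive.
#'
#' @param fields A `cell_fields` object.
#' @return Invisibly `TRUE`; stops otherwise.
#' @export
validate_fields <- function(fields) {
  f <- fields$fields
  nonneg <- c("Udev", "Vdev", "Kxx", "Kyy", "Kzz", "M2u", "M2d", "kS",
              "rwd_particle", "rwd_SO2", "rwd_othergas")
  for (v in nonneg) {
    if (any(f[[v]] < 0, na.rm = TRUE)) stop("negative field: ", v, call. = FALSE)
  }
  for (v in c("fp_NO3", "fp_NH4", "fp_org")) {
    if (any(f[[v]] < 0 | f[[v]] > 1)) stop("partitioning fraction outside [0,1]: ", v, call. = FALSE)
  }
  if (any(f$blh <= 0)) stop("non-positive boundary layer height", call. = FALSE)
  res <- c("ra", "rb", "rc_gas", "rc_particle")
  for (v in res) {
    if (any(f[[v]] <= 0, na.rm = TRUE)) stop("non-positive resistance: ", v, call. = FALSE)
  }
  invisible(TRUE)
}
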