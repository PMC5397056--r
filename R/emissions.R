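# Emission-change scenarios: GeoJSON ingestion, Briggs plume rise for
# elevated sources, and conversion of annual totals into per-cell
# volumetric source terms.  Amounts may be negative: the model evaluates
# marginal emission *changes*.

EMITTED_SPECIES <- c("VOC", "NOx", "NH3", "SOx", "PM2_5")
SECONDS_PER_YEAR <- 3.15576e7  # Julian year

# mass per unit: micrograms
UNIT_UG <- c(short_ton = 907.18474e9, tonne = 1e12, kg = 1e9)

# emitted species -> tracked model species and molar mass scaling to the
# particle-forming moiety (gases are tracked as the mass of the particle
# they can form, so chemistry and partitioning conserve tracked mass)
EMISSION_MAP <- data.frame(
  emitted = EMITTED_SPECIES,
  tracked = c("VOC", "NOx", "NH3", "SOx", "pPM25"),
  scale = c(1,            # VOC tracked as SOA-potential mass
            62.00 / 46.01, # NOx (as NO2) -> NO3-equivalent
            18.04 / 17.03, # NH3 -> NH4-equivalent
            96.06 / 64.06, # SOx (as SO2) -> SO4-equivalent
            1))

#' Create an emission record
#'
#' @param geom A [geometry()] (point, line or polygon).
#' @param amounts Named numeric vector of annual emission changes for any of
#'   `VOC`, `NOx`, `NH3`, `SOx`, `PM2_5` (matched case-insensitively);
#'   missing species are 0.  Negative amounts represent reductions.
#' @param stack Optional stack attributes: named list/vector with `height`
#'   (m), `diam` (m), `temp` (exit temperature, K), `velocity` (m s^-1).
#'   All four must be present or all absent.
#' @param units Base unit of the amounts.
#' @return An object of class `emission_record`.
#' @export
emission_record <- function(geom, amounts, stack = NULL,
                            units = c("short_ton", "tonne", "kg")) {
  units <- match.arg(units)
  full <- stats::setNames(numeric(length(EMITTED_SPECIES)), EMITTED_SPECIES)
  if (length(amounts)) {
    idx <- match(toupper(names(amounts)), toupper(EMITTED_SPECIES))
    if (anyNA(idx)) {
      stop("input error: unknown species attribute(s): ",
           paste(names(amounts)[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    full[idx] <- as.numeric(amounts)
  }
  if (any(!is.finite(full))) stop("input error: non-finite emission amount", call. = FALSE)
  if (!is.null(stack)) {
    stack <- as.list(stack)
    need <- c("height", "diam", "temp", "velocity")
    if (!all(need %in% names(stack))) {
      stop("input error: stack attributes must all be present (height, diam, temp, velocity)",
           call. = FALSE)
    }
    stack <- lapply(stack[need], as.numeric)
    if (stack$diam <= 0 || stack$velocity < 0) {
      stop("input error: non-positive stack diameter or negative exit velocity",
           call. = FALSE)
    }
  }
  structure(list(geometry = geom, amounts = full, stack = stack, units = units),
            class = "emission_record")
}

# ---------------------------------------------------------------------------
# GeoJSON I/O

geojson_geometry <- function(g) {
  ty <- g$type
  cm <- function(x) do.call(rbind, lapply(x, function(p) unlist(p)))
  switch(ty,
    Point = geometry("point", matrix(unlist(g$coordinates), ncol = 2, byrow = TRUE)),
    MultiPoint = geometry("multipoint", cm(g$coordinates)),
    LineString = geometry("line", cm(g$coordinates)),
    Polygon = geometry("polygon", cm(g$coordinates[[1]])),
    stop("input error: unsupported geometry type: ", ty, call. = FALSE))
}

#' Read emission records from GeoJSON files
#'
#' One record per feature.  Species attributes `VOC`, `NOx`, `NH3`, `SOx`,
#' `PM2_5` are matched case-insensitively; missing attributes default to 0.
#' Stack attributes `height`, `diam`, `temp`, `velocity` (all four, or
#' none) mark an elevated source.
#'
#' @param paths Character vector of GeoJSON file paths.
#' @param units Base unit of the annual amounts.
#' @return List of `emission_record`s.
#' @export
read_emissions <- function(paths, units = "short_ton") {
  records <- list()
  for (p in paths) {
    if (!file.exists(p)) stop("I/O error: no such file: ", p, call. = FALSE)
    gj <- tryCatch(jsonlite::read_json(p),
                   error = function(e) stop("I/O error: cannot parse ", p, ": ",
                                            conditionMessage(e), call. = FALSE))
    feats <- if (identical(gj$type, "FeatureCollection")) gj$features
             else if (identical(gj$type, "Feature")) list(gj)
             else stop("I/O error: not a GeoJSON feature file: ", p, call. = FALSE)
    for (ft in feats) {
      props <- ft$properties
      nm <- names(props)
      sp_idx <- match(toupper(EMITTED_SPECIES), toupper(nm))
      amounts <- stats::setNames(
        vapply(sp_idx, function(i) if (is.na(i)) 0 else as.numeric(props[[i]]),
               numeric(1)),
        EMITTED_SPECIES)
      stack_idx <- match(c("height", "diam", "temp", "velocity"), tolower(nm))
      stack <- if (all(!is.na(stack_idx))) {
        stats::setNames(lapply(stack_idx, function(i) as.numeric(props[[i]])),
                        c("height", "diam", "temp", "velocity"))
      } else NULL
      records[[length(records) + 1L]] <-
        emission_record(geojson_geometry(ft$geometry), amounts, stack, units)
    }
  }
  records
}

#' Write emission records to a GeoJSON file
#'
#' @param records List of `emission_record`s.
#' @param file Output path.
#' @export
write_emissions <- function(records, file) {
  feats <- lapply(records, function(r) {
    cc <- r$geometry$coords
    geom <- switch(r$geometry$type,
      point = list(type = "Point", coordinates = as.numeric(cc[1, ])),
      multipoint = list(type = "MultiPoint",
                        coordinates = lapply(seq_len(nrow(cc)), function(i) as.numeric(cc[i, ]))),
      line = list(type = "LineString",
                  coordinates = lapply(seq_len(nrow(cc)), function(i) as.numeric(cc[i, ]))),
      polygon = list(type = "Polygon",
                     coordinates = list(lapply(c(seq_len(nrow(cc)), 1L),
                                               function(i) as.numeric(cc[i, ])))))
    props <- as.list(r$amounts)
    if (!is.null(r$stack)) props <- c(props, r$stack)
    list(type = "Feature", geometry = geom, properties = props)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

# ---------------------------------------------------------------------------
# Plume rise

#' Briggs plume rise: injection layer for an emission record
#'
#' Computes the Briggs final plume rise from stack buoyancy and momentum
#' fluxes using the pre-averaged inverse windspeed powers stored in the
#' field archive, taking the larger of the buoyant and momentum rises, and
#' returns the vertical layer containing the effective source height
#' (stack height + rise), capped at the top layer.  Records without stack
#' attributes inject at ground level (layer 0).  For line and polygon
#' sources the column at the geometry centroid is used.
#'
#' @param record An `emission_record`.
#' @param grid A `vr_grid`.
#' @param fields A `cell_fields` archive for the grid.
#' @return Integer layer index (0 = ground).
#' @export
plume_rise <- function(record, grid, fields) {
  if (is.null(record$stack)) return(0L)
  st <- record$stack
  if (st$diam <= 0 || st$velocity < 0) {
    stop("input error: invalid stack diameter or exit velocity", call. = FALSE)
  }
  ctr <- geometry_centroid(record$geometry)
  cols <- grid$fine_columns
  ci <- which(ctr[1] >= cols$xmin & ctr[1] < cols$xmax &
              ctr[2] >= cols$ymin & ctr[2] < cols$ymax)
  if (!length(ci)) stop("input error: stack location outside domain", call. = FALSE)
  pl <- fields$plume[fields$plume$col == ci[1], ]
  rise <- briggs_rise(stack_height = st$height, diam = st$diam,
                      exit_temp = st$temp, exit_vel = st$velocity,
                      ambient_temp = pl$temperature, ws_inv = pl$ws_inv,
                      ws_inv13 = pl$ws_inv13, s1 = pl$s1,
                      stable = pl$stability_class == 1L)
  h_eff <- st$height + rise
  layer <- findInterval(h_eff, grid$layer_tops)  # 0 when below first top
  min(layer, length(grid$layer_tops) - 1L)
}

#' Briggs final plume rise (m)
#'
#' Buoyancy flux `Fb = g vs (d/2)^2 (Ts - Ta)/Ts` and momentum flux
#' `Fm = vs^2 (d/2)^2 Ta/Ts`.  Neutral/unstable buoyant rise uses the
#' 21.425/38.71 final-rise forms with the pre-averaged inverse windspeed;
#' stable branches use the 2.6 and 1.5 coefficient forms with the
#' pre-averaged windspeed^(-1/3).  The larger of the buoyant and momentum
#' rises is returned.
#'
#' @param stack_height Stack height (m, unused in the rise itself).
#' @param diam,exit_temp,exit_vel Stack exit diameter (m), temperature (K),
#'   velocity (m s^-1).
#' @param ambient_temp Annual-mean ambient temperature (K).
#' @param ws_inv Annual mean of windspeed^-1 (s m^-1).
#' @param ws_inv13 Annual mean of windspeed^(-1/3).
#' @param s1 Stability parameter g/T * d(theta)/dz (s^-2).
#' @param stable Logical stability-class flag.
#' @return Plume rise above stack top (m).
#' @export
briggs_rise <- function(stack_height, diam, exit_temp, exit_vel,
                        ambient_temp, ws_inv, ws_inv13, s1, stable) {
  r <- diam / 2
  fb <- max(9.81 * exit_vel * r^2 * (exit_temp - ambient_temp) / max(exit_temp, 1), 0)
  fm <- exit_vel^2 * r^2 * ambient_temp / max(exit_temp, 1)
  if (stable) {
    s <- max(s1, 1e-6)
    dh_b <- if (fb > 0) 2.6 * (fb / s)^(1 / 3) * ws_inv13 else 0
    dh_m <- 1.5 * (fm / sqrt(s))^(1 / 3) * ws_inv13
  } else {
    dh_b <- if (fb <= 0) 0
            else if (fb < 55) 21.425 * fb^0.75 * ws_inv
            else 38.71 * fb^0.6 * ws_inv
    dh_m <- 3 * diam * exit_vel * ws_inv
  }
  max(dh_b, dh_m, 0)
}

# ---------------------------------------------------------------------------
# Gridding

#' Allocate emission records onto the grid as volumetric source terms
#'
#' Each record's annual amounts are area-weighted over the footprint cells
#' of its injection layer (plume rise per record when stack attributes are
#' present), converted to the tracked moiety mass and to micrograms per
#' cubic metre per second by dividing by cell volume and seconds per year.
#' The total gridded mass rate equals the summed in-domain record rate.
#'
#' @param records List of `emission_record`s.
#' @param grid A `vr_grid`.
#' @param fields A `cell_fields` archive (needed for plume rise).
#' @return A cells x 9 species matrix of source rates (ug m^-3 s^-1),
#'   class `source_field`.
#' @export
grid_emissions <- function(records, grid, fields) {
  cells <- grid$cells
  S <- matrix(0, nrow(cells), length(SPECIES),
              dimnames = list(NULL, SPECIES))
  for (r in records) {
    if (!inherits(r, "emission_record")) stop("not an emission_record", call. = FALSE)
    layer <- plume_rise(r, grid, fields)
    w <- area_weights(r$geometry, grid, layer = layer)
    if (!nrow(w)) next
    u <- UNIT_UG[[r$units]]
    for (k in seq_len(nrow(EMISSION_MAP))) {
      amt <- r$amounts[[EMISSION_MAP$emitted[k]]]
      if (amt == 0) next
      rate <- amt * u * EMISSION_MAP$scale[k] / SECONDS_PER_YEAR  # ug s^-1
      sp <- EMISSION_MAP$tracked[k]
      S[w$id, sp] <- S[w$id, sp] + rate * w$weight / cells$volume[w$id]
    }
  }
  structure(S, class = c("source_field", "matrix"))
}
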