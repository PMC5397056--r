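# Paired model-comparison statistics and the area-/population-weighted
# aggregation used in all evaluations.

#' Paired comparison statistics
#'
#' Mean bias `MB = mean(Y - X)`, mean error `ME = mean(|Y - X|)`, mean
#' fractional bias `MFB = mean(2 (Y - X)/(Y + X))`, mean fractional error
#' `MFE = mean(2 |Y - X|/(Y + X))`, model ratio `MR = mean(Y / X)`, plus
#' least-squares regression slope `S`, intercept `I` and the squared
#' Pearson correlation `R2` of Y on X.  When weights are supplied all
#' means are weighted and the regression/correlation are weighted too.
#'
#' Pairs with `Y + X = 0` are excluded from the fractional metrics, and
#' pairs with `X = 0` from MR; the exclusion counts are reported.
#' MFB/MFE are returned as fractions (multiply by 100 for percent).
#'
#' @param X Reference values (e.g. the comprehensive model).
#' @param Y Values under evaluation.
#' @param weights Optional non-negative weights.
#' @return An object of class `comparison_stats`: list with MB, ME, MFB,
#'   MFE, MR, S, I, R2, n, and the exclusion tallies.
#' @export
compare <- function(X, Y, weights = NULL) {
  n <- length(X)
  if (length(Y) != n || n < 1) stop("input error: X and Y must have equal length >= 1", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0)) {
    stop("input error: weights must be non-negative and match the data length", call. = FALSE)
  }
  wmean <- function(v, w) sum(w * v) / sum(w)
  d <- Y - X
  MB <- wmean(d, weights)
  ME <- wmean(abs(d), weights)
  fr_keep <- (Y + X) != 0
  MFB <- wmean(2 * d[fr_keep] / (Y + X)[fr_keep], weights[fr_keep])
  MFE <- wmean(2 * abs(d)[fr_keep] / (Y + X)[fr_keep], weights[fr_keep])
  mr_keep <- X != 0
  MR <- wmean((Y / X)[mr_keep], weights[mr_keep])
  if (n >= 2) {
    fit <- stats::lm(Y ~ X, weights = weights)
    S <- unname(stats::coef(fit)[2])
    I <- unname(stats::coef(fit)[1])
    w <- weights / sum(weights)
    mx <- sum(w * X); my <- sum(w * Y)
    cxy <- sum(w * (X - mx) * (Y - my))
    vx <- sum(w * (X - mx)^2); vy <- sum(w * (Y - my)^2)
    R2 <- if (vx > 0 && vy > 0) (cxy^2) / (vx * vy) else NA_real_
    R2_unweighted <- stats::cor(X, Y)^2
  } else {
    S <- I <- R2 <- R2_unweighted <- NA_real_
  }
  structure(list(MB = MB, ME = ME, MFB = MFB, MFE = MFE, MR = MR,
                 S = S, I = I, R2 = R2, R2_unweighted = R2_unweighted,
                 n = n,
                 excluded_fractional = sum(!fr_keep),
                 excluded_ratio = sum(!mr_keep)),
            class = "comparison_stats")
}

#' @export
print.comparison_stats <- function(x, ...) {
  cat(sprintf("n = %d pairs\n", x$n))
  cat(sprintf("MB  = %.4g   ME  = %.4g\n", x$MB, x$ME))
  cat(sprintf("MFB = %.1f%%   MFE = %.1f%%   MR = %.3g\n",
              100 * x$MFB, 100 * x$MFE, x$MR))
  if (!is.na(x$S)) {
    cat(sprintf("S = %.3g   I = %.3g   R2 = %.3g\n", x$S, x$I, x$R2))
  }
  if (x$excluded_fractional || x$excluded_ratio) {
    cat(sprintf("(excluded: %d pairs from MFB/MFE, %d from MR)\n",
                x$excluded_fractional, x$excluded_ratio))
  }
  invisible(x)
}

#' Area- or population-weighted mean over ground-layer cells
#'
#' @param values Numeric vector, one value per ground-layer cell (or per
#'   grid cell — non-ground entries are ignored when the length matches the
#'   full cell table).
#' @param grid A `vr_grid`.
#' @param mode `"area"` (cell footprint area) or `"population"`.
#' @return Weighted mean (scalar).
#' @export
weighted_mean_ground <- function(values, grid, mode = c("area", "population")) {
  mode <- match.arg(mode)
  cells <- grid$cells
  g <- cells[cells$is_ground, ]
  v <- if (length(values) == nrow(cells)) values[g$id] else values
  if (length(v) != nrow(g)) stop("input error: values do not match ground cells", call. = FALSE)
  w <- if (mode == "area") g$dx * g$dy else g$population
  keep <- !is.na(v)
  if (sum(w[keep]) <= 0) stop("input error: all weights are zero", call. = FALSE)
  sum(w[keep] * v[keep]) / sum(w[keep])
}

#' Normalise values so the largest magnitude equals one
#'
#' @param values Numeric vector with at least one nonzero entry.
#' @return `values / max(abs(values))`; idempotent.
#' @export
normalize_for_comparison <- function(values) {
  m <- max(abs(values))
  if (m == 0) stop("input error: all values are zero", call. = FALSE)
  values / m
}

#' Write a comparison-statistics table, optionally by region
#'
#' @param X,Y Paired per-cell values on the grid's ground layer.
#' @param grid A `vr_grid`.
#' @param file CSV output path.
#' @param regions Optional named list of polygon coordinate matrices; a row
#'   of statistics is produced per region (cells assigned by footprint
#'   centre).
#' @param weights Optional weights (e.g. cell population).
#' @return Invisibly the statistics data frame.
#' @export
stats_table <- function(X, Y, grid, file = NULL, regions = NULL, weights = NULL) {
  rows <- list(all = compare(X, Y, weights))
  if (!is.null(regions)) {
    g <- grid$cells[grid$cells$is_ground, ]
    cx <- (g$xmin + g$xmax) / 2; cy <- (g$ymin + g$ymax) / 2
    for (nm in names(regions)) {
      poly <- regions[[nm]]
      inside <- vapply(seq_along(cx), function(i) {
        polygon_rect_area(poly, c(cx[i] - 1, cx[i] + 1, cy[i] - 1, cy[i] + 1)) > 0
      }, logical(1))
      if (sum(inside) >= 1) {
        rows[[nm]] <- compare(X[inside], Y[inside],
                              if (is.null(weights)) NULL else weights[inside])
      }
    }
  }
  df <- do.call(rbind, lapply(names(rows), function(nm) {
    s <- rows[[nm]]
    data.frame(region = nm, n = s$n, MB = s$MB, ME = s$ME,
               MFB_pct = 100 * s$MFB, MFE_pct = 100 * s$MFE, MR = s$MR,
               S = s$S, I = s$I, R2 = s$R2)
  }))
  if (!is.null(file)) utils::write.csv(df, file, row.names = FALSE)
  invisible(df)
}
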