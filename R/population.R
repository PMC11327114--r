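#' @title Population projection
#' @description Bias correction of decadal population projections against
#'   a reference series and shape-preserving (PCHIP) interpolation to
#'   annual layers.
#' @name population_projection
NULL

check_population <- function(pop, arg = "population") {
  if (!is.data.frame(pop) || !all(c("year", "cell", "density") %in% names(pop))) {
    abort_invalid(sprintf("`%s` must have columns year, cell, density.", arg))
  }
  if (any(pop$density < 0)) abort_invalid(sprintf("`%s` has negative densities.", arg))
  invisible(pop)
}

#' Cellwise population bias-correction factor
#'
#' The mean, over the overlapping years, of the observed-to-predicted
#' density quotient, computed per cell.  Cells where the predicted
#' density falls below `guard` persons per square km take the study-area
#' mean factor instead of an unstable quotient.
#'
#' @param observed,predicted Population tibbles (`year`, `cell`,
#'   `density`) with at least one overlapping year.
#' @param guard Minimum predicted density for a cellwise quotient
#'   (default 0.5).
#' @return A tibble `cell`, `factor`.
#' @export
population_bias_factor <- function(observed, predicted, guard = 0.5) {
  check_population(observed, "observed")
  check_population(predicted, "predicted")
  d <- dplyr::inner_join(observed, predicted, by = c("year", "cell"),
                         suffix = c("_obs", "_pred"))
  if (nrow(d) == 0) abort_invalid("no overlapping years between the series.")
  d |>
    dplyr::mutate(ok = .data$density_pred >= guard,
                  q = ifelse(.data$ok, .data$density_obs / pmax(.data$density_pred, guard), NA_real_)) |>
    dplyr::group_by(.data$cell) |>
    dplyr::summarise(factor = mean(.data$q, na.rm = TRUE), .groups = "drop") |>
    dplyr::mutate(factor = ifelse(is.finite(.data$factor), .data$factor,
                                  mean(.data$factor, na.rm = TRUE)))
}

# Shape-preserving piecewise-cubic Hermite slopes (Fritsch-Carlson).
# y: n_series x n_knots matrix, x: knot positions.  Returns slope matrix.
pchip_slopes <- function(x, y) {
  n <- length(x)
  h <- diff(x)
  delta <- sweep(y[, -1, drop = FALSE] - y[, -n, drop = FALSE], 2L, h, `/`)
  d <- matrix(0, nrow(y), n)
  if (n == 2) {
    d[, 1] <- delta[, 1]; d[, 2] <- delta[, 1]
    return(d)
  }
  for (k in 2:(n - 1)) {
    d1 <- delta[, k - 1]; d2 <- delta[, k]
    w1 <- 2 * h[k] + h[k - 1]; w2 <- h[k] + 2 * h[k - 1]
    harm <- (w1 + w2) / (w1 / d1 + w2 / d2)
    d[, k] <- ifelse(d1 * d2 > 0, harm, 0)
  }
  d[, 1] <- pchip_end_slope(h[1], h[2], delta[, 1], delta[, 2])
  d[, n] <- pchip_end_slope(h[n - 1], h[n - 2], delta[, n - 1], delta[, n - 2])
  d
}

# one-sided three-point end slope with the standard shape-preserving clips
pchip_end_slope <- function(h1, h2, del1, del2) {
  d <- ((2 * h1 + h2) * del1 - h1 * del2) / (h1 + h2)
  d <- ifelse(sign(d) != sign(del1), 0, d)
  ifelse(sign(del1) != sign(del2) & abs(d) > 3 * abs(del1), 3 * del1, d)
}

#' Shape-preserving annual interpolation of a decadal series
#'
#' Per-cell monotone piecewise-cubic Hermite interpolation (PCHIP)
#' through the decadal knots: the interpolant passes through every knot
#' exactly, introduces no new local extrema between knots, and therefore
#' keeps non-negative knot series non-negative.  Extrapolation outside
#' the knot span is refused.
#'
#' @param decadal Population tibble with the knot years (e.g. 2010, 2020,
#'   ..., 2050).
#' @param years Integer years to interpolate at (within the knot span).
#' @return A population tibble `year`, `cell`, `density` over `years`.
#' @export
hermite_annual <- function(decadal, years) {
  check_population(decadal, "decadal")
  knots <- sort(unique(decadal$year))
  if (length(knots) < 2) abort_invalid("need at least 2 knot years.")
  years <- as.integer(years)
  if (any(years < min(knots)) || any(years > max(knots))) {
    abort_invalid("extrapolation outside the knot span is not supported.")
  }
  wide <- decadal |>
    dplyr::arrange(.data$year, .data$cell) |>
    tidyr::pivot_wider(names_from = "year", values_from = "density")
  y <- as.matrix(wide[, as.character(knots)])
  d <- pchip_slopes(knots, y)
  h <- diff(knots)
  out <- purrr::map(years, function(yr) {
    k <- findInterval(yr, knots, rightmost.closed = TRUE)
    t <- (yr - knots[k]) / h[k]
    h00 <- (1 + 2 * t) * (1 - t)^2
    h10 <- t * (1 - t)^2
    h01 <- t^2 * (3 - 2 * t)
    h11 <- t^2 * (t - 1)
    val <- h00 * y[, k] + h10 * h[k] * d[, k] +
      h01 * y[, k + 1] + h11 * h[k] * d[, k + 1]
    tibble::tibble(year = yr, cell = wide$cell, density = unname(val))
  })
  dplyr::bind_rows(out) |> dplyr::arrange(.data$year, .data$cell)
}

#' Bias-correct and interpolate a decadal population projection
#'
#' Applies the cellwise bias factor to every decadal layer, then
#' interpolates annually with [hermite_annual()].
#'
#' @param decadal_raw Population tibble at the decadal knots.
#' @param factor Tibble `cell`, `factor` from [population_bias_factor()]
#'   (or any finite per-cell factor).
#' @param years Years to interpolate at.
#' @return A population tibble `year`, `cell`, `density`.
#' @export
project_population <- function(decadal_raw, factor, years) {
  check_population(decadal_raw, "decadal_raw")
  if (!all(c("cell", "factor") %in% names(factor)) || any(!is.finite(factor$factor))) {
    abort_invalid("`factor` must be a finite per-cell factor tibble.")
  }
  corrected <- decadal_raw |>
    dplyr::inner_join(factor, by = "cell") |>
    dplyr::mutate(density = .data$density * .data$factor) |>
    dplyr::select("year", "cell", "density")
  hermite_annual(corrected, years)
}
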