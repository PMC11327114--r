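#' @title Climate processing
#' @description Delta-method bias correction of modelled climate against
#'   an observed climatology, downscale validation statistics,
#'   bioclimatic summaries, rolling multi-year climate means and the
#'   climate-window selection re-analysis.
#' @name climate_processing
NULL

climate_vars <- c("tmin", "tmax", "rain")

check_climate <- function(stack, arg = "climate") {
  need <- c("year", "month", "cell", climate_vars)
  if (!is.data.frame(stack) || !all(need %in% names(stack))) {
    abort_invalid(sprintf("`%s` must be a climate tibble with columns %s.",
                          arg, paste(need, collapse = ", ")))
  }
  invisible(stack)
}

#' Multi-year monthly climatology
#'
#' Per-cell, per-month mean of each climate variable over the given
#' reference years.
#'
#' @param stack Climate tibble (`year`, `month`, `cell`, `tmin`, `tmax`,
#'   `rain`).
#' @param years Years to average over (default: all years present).
#' @return A tibble `month`, `cell`, `tmin`, `tmax`, `rain`.
#' @export
climatology <- function(stack, years = NULL) {
  check_climate(stack)
  if (!is.null(years)) stack <- dplyr::filter(stack, .data$year %in% years)
  if (nrow(stack) == 0) abort_invalid("no data in the requested reference years.")
  stack |>
    dplyr::group_by(.data$month, .data$cell) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(climate_vars), mean),
                     .groups = "drop")
}

#' Difference bias-correction field (used for temperature)
#'
#' Cellwise, per calendar month: observed minus modelled reference
#' climatology.
#'
#' @param observed_ref,modelled_ref Climate tibbles over the same lattice
#'   and reference period.
#' @param variables Which variables get a difference correction (default
#'   the two temperatures).
#' @return A correction tibble `month`, `cell`, `variable`, `correction`
#'   with attribute `kind = "difference"`.
#' @export
difference_correction <- function(observed_ref, modelled_ref,
                                  variables = c("tmin", "tmax")) {
  obs <- climatology(observed_ref)
  mod <- climatology(modelled_ref)
  check_same_support(obs, mod)
  out <- dplyr::inner_join(
    tidyr::pivot_longer(obs, dplyr::all_of(variables),
                        names_to = "variable", values_to = "obs"),
    tidyr::pivot_longer(mod, dplyr::all_of(variables),
                        names_to = "variable", values_to = "mod"),
    by = c("month", "cell", "variable")
  ) |>
    dplyr::transmute(.data$month, .data$cell, .data$variable,
                     correction = .data$obs - .data$mod)
  attr(out, "kind") <- "difference"
  out
}

#' Ratio bias-correction field (used for rainfall and other ratio-scaled
#' variables)
#'
#' Cellwise, per calendar month: observed divided by modelled reference
#' climatology, with the denominator floored to avoid blow-ups in dry
#' cells.
#'
#' @inheritParams difference_correction
#' @param variables Variables corrected multiplicatively (default rain).
#' @param floor Small positive denominator guard (variable units).
#' @return A correction tibble with attribute `kind = "ratio"`; strictly
#'   positive values.
#' @export
ratio_correction <- function(observed_ref, modelled_ref,
                             variables = "rain", floor = 0.01) {
  if (floor <= 0) abort_invalid("`floor` must be positive.")
  obs <- climatology(observed_ref)
  mod <- climatology(modelled_ref)
  check_same_support(obs, mod)
  out <- dplyr::inner_join(
    tidyr::pivot_longer(obs, dplyr::all_of(variables),
                        names_to = "variable", values_to = "obs"),
    tidyr::pivot_longer(mod, dplyr::all_of(variables),
                        names_to = "variable", values_to = "mod"),
    by = c("month", "cell", "variable")
  ) |>
    dplyr::transmute(.data$month, .data$cell, .data$variable,
                     correction = pmax(.data$obs, 0) / pmax(.data$mod, floor))
  attr(out, "kind") <- "ratio"
  out
}

check_same_support <- function(a, b) {
  if (nrow(a) != nrow(b) ||
      !identical(sort(unique(a$cell)), sort(unique(b$cell))) ||
      !identical(sort(unique(a$month)), sort(unique(b$month)))) {
    abort_invalid("observed and modelled references do not share lattice/months.")
  }
}

#' Apply delta corrections to a modelled climate stack
#'
#' Difference corrections add; ratio corrections multiply.  Applying the
#' corrections computed on a reference period back onto the modelled
#' reference reproduces the observed reference climatology (exactly for
#' differences, up to the denominator floor for ratios).  After applying
#' temperature corrections, `tmin` is capped at `tmax` to preserve the
#' stack invariant.
#'
#' @param modelled_future Climate tibble to correct.
#' @param correction A correction tibble from [difference_correction()] or
#'   [ratio_correction()] (or several row-bound together provided each
#'   carries one `kind`; pass them in sequence otherwise).
#' @return The corrected climate tibble.
#' @export
apply_delta <- function(modelled_future, correction) {
  check_climate(modelled_future, "modelled_future")
  kind <- attr(correction, "kind")
  if (is.null(kind) || !kind %in% c("difference", "ratio")) {
    abort_invalid("`correction` must carry a kind attribute (difference/ratio).")
  }
  vars <- unique(correction$variable)
  if (!all(vars %in% climate_vars)) abort_invalid("unknown variable in correction.")
  wide <- tidyr::pivot_wider(correction, names_from = "variable",
                             values_from = "correction", names_prefix = ".corr_")
  out <- dplyr::left_join(modelled_future, wide, by = c("month", "cell"))
  for (v in vars) {
    cv <- paste0(".corr_", v)
    if (any(is.na(out[[cv]]))) {
      abort_invalid("correction does not cover all months/cells of the stack.")
    }
    out[[v]] <- if (kind == "difference") out[[v]] + out[[cv]] else out[[v]] * out[[cv]]
    out[[cv]] <- NULL
  }
  out$tmin <- pmin(out$tmin, out$tmax)
  out
}

#' Validate a downscale against observations
#'
#' Pooled over cells and years: Pearson correlation, the OLS slope and
#' intercept of observed on backcast, and the root mean squared error.
#'
#' @param observed,backcast Tibbles with columns `cell`, `year`, `value`
#'   on the same support (at least 3 years).
#' @return A one-row tibble `r`, `slope`, `intercept`, `rmse`, `n`.
#' @export
validate_downscale <- function(observed, backcast) {
  for (nm in c("cell", "year", "value")) {
    if (!nm %in% names(observed) || !nm %in% names(backcast)) {
      abort_invalid("`observed` and `backcast` need columns cell, year, value.")
    }
  }
  d <- dplyr::inner_join(observed, backcast, by = c("cell", "year"),
                         suffix = c("_obs", "_mod"))
  if (length(unique(d$year)) < 3) abort_invalid("need at least 3 overlapping years.")
  if (stats::sd(d$value_mod) == 0) {
    rlang::abort("backcast is constant: correlation undefined.",
                 class = "envenomr_undefined_correlation")
  }
  fit <- stats::lm(value_obs ~ value_mod, data = d)
  tibble::tibble(
    r = stats::cor(d$value_obs, d$value_mod),
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    rmse = sqrt(mean((d$value_obs - d$value_mod)^2)),
    n = nrow(d)
  )
}

#' Annual bioclimatic summaries
#'
#' Per-cell annual means of monthly minimum and maximum temperature and
#' the annual total rainfall for one year.
#'
#' @param stack Climate tibble.
#' @param year Calendar year (must have all 12 months in the stack).
#' @return A tibble `cell`, `tmin_mean`, `tmax_mean`, `rain_total`.
#' @export
bioclim_summaries <- function(stack, year) {
  check_climate(stack)
  d <- dplyr::filter(stack, .data$year == !!year)
  if (length(unique(d$month)) != 12L) {
    abort_invalid(sprintf("year %s does not have 12 months in the stack.", year))
  }
  d |>
    dplyr::group_by(.data$cell) |>
    dplyr::summarise(tmin_mean = mean(.data$tmin),
                     tmax_mean = mean(.data$tmax),
                     rain_total = sum(.data$rain), .groups = "drop")
}

#' Rolling multi-year mean of bioclimatic summaries
#'
#' Mean of [bioclim_summaries()] over `window` consecutive years ending at
#' `year`.  The default window of 3 — the year plus its two predecessors —
#' is the averaging span used when projecting the snake abundance models.
#'
#' @param stack Climate tibble.
#' @param year Final year of the window.
#' @param window Number of years averaged (default 3).
#' @return A tibble `cell`, `tmin_mean`, `tmax_mean`, `rain_total`.
#' @export
rolling_climate_mean <- function(stack, year, window = 3L) {
  check_climate(stack)
  if (window < 1) abort_invalid("`window` must be >= 1.")
  yrs <- (year - window + 1L):year
  have <- unique(stack$year)
  if (!all(yrs %in% have)) {
    abort_invalid(sprintf("insufficient climate history: need years %d-%d.",
                          min(yrs), max(yrs)))
  }
  purrr::map(yrs, \(y) bioclim_summaries(stack, y)) |>
    dplyr::bind_rows() |>
    dplyr::group_by(.data$cell) |>
    dplyr::summarise(dplyr::across(dplyr::everything(), mean), .groups = "drop")
}

#' Select the climate averaging window that best explains incidence
#'
#' For each candidate window length, the observed envenoming counts are
#' regressed (Poisson, log link, log-population offset) on the three
#' bioclimatic summaries averaged over that window, and the window
#' minimising the AIC is returned.  Ties break toward the smaller window.
#'
#' @param incidence Tibble `cell`, `y` (counts), `H` (population).
#' @param stack Climate tibble with enough history before `year`.
#' @param year Survey year (final year of every candidate window).
#' @param candidate_windows Integer vector of window lengths (default
#'   1:10).
#' @return An object of class `window_selection`: list with `best`
#'   (integer) and `table` (tibble `window`, `aic`).
#' @export
select_climate_window <- function(incidence, stack, year,
                                  candidate_windows = 1:10) {
  if (length(candidate_windows) == 0) abort_invalid("no candidate windows.")
  if (!all(c("cell", "y", "H") %in% names(incidence))) {
    abort_invalid("`incidence` needs columns cell, y, H.")
  }
  res <- purrr::map_dfr(sort(unique(as.integer(candidate_windows))), function(w) {
    bio <- rolling_climate_mean(stack, year, w)
    d <- dplyr::inner_join(incidence, bio, by = "cell")
    fit <- stats::glm(y ~ tmin_mean + tmax_mean + rain_total,
                      offset = log(pmax(H, 1e-8)),
                      family = stats::poisson(), data = d)
    tibble::tibble(window = w, aic = stats::AIC(fit))
  })
  best <- res$window[order(res$aic, res$window)][1]
  structure(list(best = best, table = res), class = "window_selection")
}

#' @export
print.window_selection <- function(x, ...) {
  cat(sprintf("<window_selection> best window: %d years\n", x$best))
  print(x$table)
  invisible(x)
}

#' @rdname select_climate_window
#' @param x A `window_selection` object.
#' @param ... Unused.
#' @export
autoplot.window_selection <- function(x, ...) {
  ggplot2::ggplot(x$table, ggplot2::aes(.data$window, .data$aic)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = dplyr::filter(x$table, .data$window == x$best),
                        colour = "red", size = 3) +
    ggplot2::labs(x = "Climate averaging window (years)", y = "AIC") +
    ggplot2::theme_minimal()
}
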