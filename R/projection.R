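#' @title Scenario projection engine
#' @description Drives annual scenario projections 2010-2050 (delta-
#'   corrected climate, CLUE-style land cover, interpolated population,
#'   projected snake abundance, sum / majority upscaling, expected
#'   incidence under fixed fitted parameters) and computes the change
#'   statistics: per-pixel trends, percentage change, national
#'   accumulated change with standard errors, RCM consensus, dominant
#'   species and land-cover-transition summaries.
#' @name projection_engine
NULL

#' Block-sum upscaling of a quantity layer
#'
#' Aggregates `factor` x `factor` blocks of fine cells by summation (the
#' aggregation used for snake point intensity and population); the grand
#' total is conserved exactly.
#'
#' @param layer Tibble `cell` plus a value column.
#' @param lattice Fine [make_lattice()] geometry; both dimensions must be
#'   divisible by `factor`.
#' @param factor Block edge length in cells (default 5).
#' @param value Name of the value column (default `"value"`).
#' @return A list with `layer` (coarse tibble `cell`, value column) and
#'   `lattice` (the coarse geometry).
#' @export
upscale_sum <- function(layer, lattice, factor = 5L, value = "value") {
  up_core(layer, lattice, factor, value, function(block) sum(block))
}

#' Block-mean upscaling of a quantity layer
#'
#' As [upscale_sum()] but averaging, used for intensive quantities (e.g.
#' a spatial random effect held fixed during projection).
#'
#' @inheritParams upscale_sum
#' @export
upscale_mean <- function(layer, lattice, factor = 5L, value = "value") {
  up_core(layer, lattice, factor, value, function(block) mean(block))
}

up_core <- function(layer, lattice, factor, value, fun) {
  stopifnot(inherits(lattice, "env_lattice"))
  factor <- as.integer(factor)
  if (lattice$n_rows %% factor != 0 || lattice$n_cols %% factor != 0) {
    abort_invalid("lattice dimensions are not divisible by the factor (no partial blocks).")
  }
  v <- layer_values_any(layer, value, lattice$n_cells)
  nr <- lattice$n_rows %/% factor; nc <- lattice$n_cols %/% factor
  if (nr < 3L || nc < 3L) {
    abort_invalid("coarse grid smaller than 3x3; use a larger fine lattice.")
  }
  cell <- seq_len(lattice$n_cells)
  brow <- (((cell - 1L) %/% lattice$n_cols) %/% factor) + 1L
  bcol <- (((cell - 1L) %% lattice$n_cols) %/% factor) + 1L
  bid <- (brow - 1L) * nc + bcol
  agg <- vapply(split(v, bid), fun, numeric(1))
  coarse <- make_lattice(nr, nc, lattice$cell_size * factor, lattice$origin,
                         lattice$crs_label)
  tbl <- tibble::tibble(cell = as.integer(names(agg)), !!value := unname(agg)) |>
    dplyr::arrange(.data$cell)
  list(layer = tbl, lattice = coarse)
}

#' Majority-vote upscaling of a land cover map
#'
#' Each coarse cell takes the class covering the largest area of its
#' `factor` x `factor` block; ties go to the lowest legend index.
#'
#' @param landcover Tibble `cell`, `class`.
#' @param lattice Fine [make_lattice()] geometry.
#' @param factor Block edge length (default 5).
#' @return A list with `layer` (coarse `cell`, `class`) and `lattice`.
#' @export
upscale_majority <- function(landcover, lattice, factor = 5L) {
  stopifnot(inherits(lattice, "env_lattice"))
  factor <- as.integer(factor)
  if (lattice$n_rows %% factor != 0 || lattice$n_cols %% factor != 0) {
    abort_invalid("lattice dimensions are not divisible by the factor (no partial blocks).")
  }
  cls <- match(as.character(layer_values_any(landcover, "class", lattice$n_cells)),
               landcover_classes())
  nr <- lattice$n_rows %/% factor; nc <- lattice$n_cols %/% factor
  if (nr < 3L || nc < 3L) abort_invalid("coarse grid smaller than 3x3.")
  cell <- seq_len(lattice$n_cells)
  brow <- (((cell - 1L) %/% lattice$n_cols) %/% factor) + 1L
  bcol <- (((cell - 1L) %% lattice$n_cols) %/% factor) + 1L
  bid <- (brow - 1L) * nc + bcol
  maj <- vapply(split(cls, bid), function(b) which.max(tabulate(b, 5L)), integer(1))
  coarse <- make_lattice(nr, nc, lattice$cell_size * factor, lattice$origin,
                         lattice$crs_label)
  list(layer = tibble::tibble(cell = as.integer(names(maj)),
                              class = factor(landcover_classes()[unname(maj)],
                                             levels = landcover_classes())) |>
         dplyr::arrange(.data$cell),
       lattice = coarse)
}

#' Define a global-change scenario
#'
#' Pairings follow the scenario design: the sustainability pathway
#' (SSP1) uses no further emissions and the historical climate trend;
#' the middle-of-the-road pathway (SSP2) pairs with RCP4.5; the
#' fossil-fuelled pathway (SSP5) with RCP8.5.  RCP scenarios nest one of
#' three regional circulation models whose synthetic stand-ins differ in
#' bias and trend strength.
#'
#' @param ssp_id One of "SSP1", "SSP2", "SSP5".
#' @param rcm_id For SSP1 must be "historical-trend"; otherwise one of
#'   "CNRM-CM5", "GFDL-CM3", "MPI-ESM-LR".
#' @param trend Optional [climate_trend()] override; the default depends
#'   on the RCP (historical +0.1 C/decade; RCP4.5 +0.25; RCP8.5 +0.5,
#'   with mild drying) scaled by a per-RCM factor (CNRM 0.8, GFDL 1.2,
#'   MPI 1.0).
#' @param growth Optional per-decade population multipliers; defaults
#'   give the highest growth to SSP2, then SSP1, lowest to SSP5.
#' @param demand_2050 Optional named class shares targeted linearly by
#'   2050 (default: SSP1 reforests mildly; SSP2 moderate
#'   anthropisation; SSP5 strong agricultural/urban expansion).
#' @param rcm_bias Additive temperature / multiplicative rainfall bias of
#'   the synthetic RCM (corrected away by the delta method).
#' @return A list of class `scenario`.
#' @export
scenario <- function(ssp_id = c("SSP1", "SSP2", "SSP5"),
                     rcm_id = NULL, trend = NULL, growth = NULL,
                     demand_2050 = NULL, rcm_bias = NULL) {
  ssp_id <- match.arg(ssp_id)
  rcp_id <- switch(ssp_id, SSP1 = "none", SSP2 = "RCP4.5", SSP5 = "RCP8.5")
  if (is.null(rcm_id)) {
    rcm_id <- if (ssp_id == "SSP1") "historical-trend" else "CNRM-CM5"
  }
  if (ssp_id == "SSP1" && rcm_id != "historical-trend") {
    abort_invalid("SSP1 pairs with the historical-trend climate only.")
  }
  if (ssp_id != "SSP1" &&
      !rcm_id %in% c("CNRM-CM5", "GFDL-CM3", "MPI-ESM-LR")) {
    abort_invalid("RCP scenarios need one of the three RCMs.")
  }
  rcm_scale <- c("historical-trend" = 1, "CNRM-CM5" = 0.8,
                 "GFDL-CM3" = 1.2, "MPI-ESM-LR" = 1.0)[[rcm_id]]
  if (is.null(trend)) {
    base <- switch(rcp_id,
                   none = c(0.1, 1.0),
                   "RCP4.5" = c(0.25, 0.99),
                   "RCP8.5" = c(0.5, 0.97))
    trend <- climate_trend(base[1] * rcm_scale,
                           1 - (1 - base[2]) * rcm_scale)
  }
  if (is.null(growth)) {
    growth <- switch(ssp_id,
                     SSP1 = c(1.06, 1.05, 1.05, 1.04),
                     SSP2 = c(1.08, 1.07, 1.06, 1.06),
                     SSP5 = c(1.04, 1.03, 1.02, 1.02))
  }
  if (is.null(demand_2050)) {
    demand_2050 <- switch(ssp_id,
      SSP1 = c(forest = 0.40, degraded_forest = 0.12, agriculture = 0.27,
               urban = 0.12, tea = 0.09),
      SSP2 = c(forest = 0.31, degraded_forest = 0.16, agriculture = 0.32,
               urban = 0.13, tea = 0.08),
      SSP5 = c(forest = 0.26, degraded_forest = 0.18, agriculture = 0.36,
               urban = 0.14, tea = 0.06))
  }
  if (is.null(rcm_bias)) {
    rcm_bias <- switch(rcm_id,
                       "historical-trend" = list(temp = 0, rain = 1),
                       "CNRM-CM5" = list(temp = 1.2, rain = 0.85),
                       "GFDL-CM3" = list(temp = -0.8, rain = 1.2),
                       "MPI-ESM-LR" = list(temp = 0.5, rain = 0.9))
  }
  structure(list(ssp_id = ssp_id, rcp_id = rcp_id, rcm_id = rcm_id,
                 trend = trend, growth = growth, demand_2050 = demand_2050,
                 rcm_bias = rcm_bias),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario> %s / %s / %s: +%.2f C per decade, rain x%.3f per decade\n",
              x$ssp_id, x$rcp_id, x$rcm_id,
              x$trend$warming_per_decade, x$trend$rain_multiplier_per_decade))
  invisible(x)
}

# linear demand trajectory from the current class counts to the 2050 shares
demand_trajectory <- function(start_counts, shares_2050, years, n_free) {
  target <- round(shares_2050 * n_free)
  target[1] <- target[1] + (n_free - sum(target))   # rounding residue
  purrr::map_dfr(years, function(y) {
    w <- (y - years[1]) / (max(years) - years[1])
    cnt <- round((1 - w) * start_counts + w * target)
    cnt[1] <- cnt[1] + (n_free - sum(cnt))
    tibble::tibble(year = y, class = factor(landcover_classes(),
                                            levels = landcover_classes()),
                   cells = as.integer(cnt))
  })
}

#' Run one scenario projection
#'
#' The full annual pipeline on the synthetic study system: (1) a
#' synthetic RCM climate is generated with the scenario's bias and
#' trend, delta-corrected against the observed reference climatology
#' (difference for temperatures, ratio for rainfall) — the
#' historical-trend climate skips correction; (2) land cover is
#' allocated annually along the scenario demand trajectory with logistic
#' location factors refreshed from dynamic climate and population
#' drivers; (3) decadal population under the scenario growth is
#' bias-corrected against the 2010 reference and PCHIP-interpolated
#' annually; (4) species abundance indices are projected from the
#' 3-year rolling climate mean and the year's land cover covariates;
#' (5) everything is upscaled (sums for abundance and population,
#' majority vote for land cover, block means for the CAR field) and the
#' expected incidence evaluated with the fitted parameters held
#' constant.
#'
#' @param scen A [scenario()].
#' @param params Fitted [envenoming_params()] (held constant).
#' @param truth The [make_synthetic_truth()] baseline study system.
#' @param years Projection years (default 2010:2050).
#' @param upscale_factor Block size for the coarse grid (default 5).
#' @param seed Integer seed for the scenario-specific generators.
#' @return An object of class `scenario_run`: annual coarse incidence
#'   (`incidence`: tibble `year`, `cell`, `incidence`), coarse
#'   population (`population`), fine annual land cover (`landcover`),
#'   coarse land cover (`landcover_coarse`), coarse species layers for
#'   first and last year (`species_first`, `species_last`), the coarse
#'   lattice, and the scenario.
#' @export
run_scenario <- function(scen, params, truth, years = 2010:2050,
                         upscale_factor = 5L, seed = 1L) {
  stopifnot(inherits(scen, "scenario"), inherits(truth, "synthetic_truth"),
            inherits(params, "envenoming_params"))
  lat <- truth$lattice
  n <- lat$n_cells
  all_years <- (min(years) - 2):max(years)

  ## --- climate -----------------------------------------------------------
  if (scen$rcm_id == "historical-trend") {
    clim <- gen_climate(lat, all_years, scen$trend,
                        seed = derive_seed(seed, 21L))
  } else {
    ref_years <- intersect(unique(truth$climate$year), all_years[1:5])
    modelled <- gen_climate(lat, all_years, scen$trend,
                            seed = derive_seed(seed, 22L),
                            base_tmax = 30 + scen$rcm_bias$temp,
                            base_rain = 150 * scen$rcm_bias$rain)
    obs_ref <- dplyr::filter(truth$climate, .data$year %in% ref_years)
    mod_ref <- dplyr::filter(modelled, .data$year %in% ref_years)
    corr_t <- difference_correction(obs_ref, mod_ref)
    corr_r <- ratio_correction(obs_ref, mod_ref)
    clim <- modelled |> apply_delta(corr_t) |> apply_delta(corr_r)
  }

  ## --- population --------------------------------------------------------
  predicted <- gen_population(lat, base_density = 250, growth = scen$growth,
                              urban_bias = 1, landcover = truth$landcover,
                              seed = derive_seed(seed, 23L))
  observed <- dplyr::filter(truth$population, .data$year == 2010)
  fac <- population_bias_factor(observed, predicted)
  pop_annual <- project_population(predicted, fac, years)
  H2010_fine <- dplyr::filter(pop_annual, .data$year == years[1]) |>
    dplyr::select("cell", "density")

  ## --- land cover --------------------------------------------------------
  tree_prop <- categories_to_proportion(truth$treecover,
                                        default_tree_reference_mean())
  drivers_for <- function(y) {
    bio <- rolling_climate_mean(clim, y, 3L)
    hy <- dplyr::filter(pop_annual, .data$year == max(min(y), years[1]))
    tibble::tibble(cell = bio$cell,
                   tmax_mean = bio$tmax_mean,
                   rain_total = bio$rain_total,
                   log_pop = log1p(hy$density[order(hy$cell)]))
  }
  factors <- fit_location_factors(truth$landcover, drivers_for(years[1]))
  start_counts <- tabulate(match(as.character(truth$landcover$class),
                                 landcover_classes()), 5L)
  demand <- demand_trajectory(start_counts, scen$demand_2050[landcover_classes()],
                              years, n)
  rules <- transition_rules(n_cells = n)
  lc_series <- simulate_landcover(truth$landcover, demand, factors,
                                  drivers_for, rules)

  ## --- abundance model (fitted once at baseline) -------------------------
  base_bio <- rolling_climate_mean(truth$climate, years[1], 3L)
  base_cov0 <- derived_covariates(truth$landcover, tree_prop, lat)
  sp_fits <- list(); sp_niche <- list()
  for (sp in default_species()) {
    occ <- dplyr::filter(truth$species$occurrences, .data$species == sp)
    niche <- estimate_niche(occ, base_bio, lat)
    counts <- tibble::tibble(cell = seq_len(n),
                             count = tabulate(coords_to_cell(lat, occ$x, occ$y), n))
    cov <- dplyr::left_join(base_bio, base_cov0, by = "cell")
    cov$niche_dist <- niche_distance(niche, base_bio)$distance
    cov$forest_dist[!is.finite(cov$forest_dist)] <- 0
    sp_fits[[sp]] <- fit_abundance_model(counts, cov)
    sp_niche[[sp]] <- niche
  }
  weights <- stats::setNames(truth$species$spec$expert_weight,
                             truth$species$spec$species)

  ## --- annual loop -------------------------------------------------------
  rho_coarse <- upscale_mean(layer_tbl(lat, truth$rho), lat, upscale_factor)
  coarse <- rho_coarse$lattice
  H2010_coarse <- upscale_sum(H2010_fine, lat, upscale_factor,
                              value = "density")$layer
  inc <- list(); popc <- list(); lcc <- list()
  S_first <- NULL; S_last <- NULL
  for (y in years) {
    bio <- rolling_climate_mean(clim, y, 3L)
    lc_y <- dplyr::filter(lc_series, .data$year == y) |>
      dplyr::select("cell", "class")
    cov <- dplyr::left_join(bio, derived_covariates(lc_y, tree_prop, lat),
                            by = "cell")
    cov$forest_dist[!is.finite(cov$forest_dist)] <- 0
    ab <- purrr::imap_dfr(sp_fits, function(f, sp) {
      dplyr::mutate(project_abundance(f, cov, sp_niche[[sp]]), species = sp)
    })
    ab <- apply_expert_weights(ab, weights)
    # aggregate by block sums, then divide by the block area so the layers
    # feeding the per-km^2 fitted coefficients keep the fitted scale
    S_coarse <- ab |>
      dplyr::group_by(.data$species) |>
      dplyr::group_modify(~ upscale_sum(.x, lat, upscale_factor)$layer) |>
      dplyr::ungroup() |>
      dplyr::mutate(value = .data$value / upscale_factor^2)
    hy <- dplyr::filter(pop_annual, .data$year == y) |>
      dplyr::select("cell", "density")
    H_coarse <- upscale_sum(hy, lat, upscale_factor, value = "density")$layer
    lc_coarse <- upscale_majority(lc_y, lat, upscale_factor)$layer
    cls_idx <- match(as.character(lc_coarse$class), landcover_classes())
    mu <- forward_mu(cls_idx, log1p(H2010_coarse$density / upscale_factor^2),
                     H_coarse$density,
                     species_matrix(S_coarse, coarse$n_cells),
                     rho_coarse$layer$value, params)
    inc[[as.character(y)]] <- tibble::tibble(year = y,
                                             cell = seq_len(coarse$n_cells),
                                             incidence = mu)
    popc[[as.character(y)]] <- tibble::tibble(year = y, cell = H_coarse$cell,
                                              H = H_coarse$density)
    lcc[[as.character(y)]] <- dplyr::mutate(lc_coarse, year = y, .before = 1)
    if (y == years[1]) S_first <- S_coarse
    if (y == max(years)) S_last <- S_coarse
  }
  structure(list(
    incidence = dplyr::bind_rows(inc),
    population = dplyr::bind_rows(popc),
    landcover = lc_series,
    landcover_coarse = dplyr::bind_rows(lcc),
    species_first = S_first, species_last = S_last,
    lattice = coarse, fine_lattice = lat, scenario = scen,
    years = years, seed = seed
  ), class = "scenario_run")
}

#' @export
print.scenario_run <- function(x, ...) {
  cat(sprintf("<scenario_run> %s/%s/%s, %d-%d on %dx%d coarse grid\n",
              x$scenario$ssp_id, x$scenario$rcp_id, x$scenario$rcm_id,
              min(x$years), max(x$years), x$lattice$n_rows, x$lattice$n_cols))
  invisible(x)
}

#' Per-pixel incidence trend
#'
#' Closed-form per-cell OLS slope of annual incidence on calendar year.
#'
#' @param series Tibble `year`, `cell` and a value column.
#' @param value Value column name (default `"incidence"`).
#' @return A tibble `cell`, `slope`.
#' @export
pixel_trend <- function(series, value = "incidence") {
  if (length(unique(series$year)) < 3) abort_invalid("need at least 3 years.")
  series |>
    dplyr::group_by(.data$cell) |>
    dplyr::summarise(slope = {
      x <- .data$year - mean(.data$year)
      sum(x * (.data[[value]] - mean(.data[[value]]))) / sum(x^2)
    }, .groups = "drop")
}

#' Percentage change between two years
#'
#' `100 * (end - start) / start` per cell; cells with a zero start value
#' are masked (`NA`).
#'
#' @param start_layer,end_layer Tibbles `cell` plus the value column.
#' @param value Value column name (default `"incidence"`).
#' @return A tibble `cell`, `pct_change`.
#' @export
pct_change <- function(start_layer, end_layer, value = "incidence") {
  n <- nrow(start_layer)
  a <- layer_values_any(start_layer, value, n)
  b <- layer_values_any(end_layer, value, n)
  tibble::tibble(cell = seq_len(n),
                 pct_change = ifelse(a > 0, 100 * (b - a) / a, NA_real_))
}

#' National accumulated percentage change with standard error
#'
#' The national incidence rate (total incidence over total population on
#' the coarse grid) is regressed on year; the accumulated percentage
#' change of the fitted line relative to its 2010 value is reported per
#' year with the standard error propagated from the slope's OLS standard
#' error.
#'
#' @param series Incidence tibble `year`, `cell`, `incidence`.
#' @param H Population tibble `year`, `cell`, `H`.
#' @return A tibble `year`, `rate`, `accum_pct`, `se`.
#' @export
national_series <- function(series, H) {
  if (length(unique(series$year)) < 3) abort_invalid("need at least 3 years.")
  d <- dplyr::inner_join(
    dplyr::summarise(dplyr::group_by(series, .data$year),
                     inc = sum(.data$incidence), .groups = "drop"),
    dplyr::summarise(dplyr::group_by(H, .data$year),
                     pop = sum(.data$H), .groups = "drop"),
    by = "year") |>
    dplyr::mutate(rate = .data$inc / .data$pop)
  fit <- stats::lm(rate ~ year, data = d)
  sl <- summary(fit)$coefficients["year", ]
  base <- unname(stats::predict(fit, newdata = data.frame(year = min(d$year))))
  tibble::tibble(
    year = d$year, rate = d$rate,
    accum_pct = 100 * unname(sl["Estimate"]) * (d$year - min(d$year)) / base,
    se = 100 * unname(sl["Std. Error"]) * (d$year - min(d$year)) / abs(base)
  )
}

#' RCM consensus on decreasing incidence
#'
#' Counts, per cell, how many RCM slope layers are strictly negative
#' (a slope of exactly zero counts as not decreasing), and the fraction
#' of total area in each agreement count.
#'
#' @param slope_layers List of 1-3 tibbles `cell`, `slope`.
#' @return A list with `consensus` (tibble `cell`, `n_decreasing`) and
#'   `fractions` (tibble `n_decreasing`, `fraction`; sums to 1).
#' @export
rcm_consensus <- function(slope_layers) {
  if (length(slope_layers) < 1) abort_invalid("need at least one slope layer.")
  if (length(slope_layers) > 3) abort_invalid("at most three RCM layers.")
  n <- nrow(slope_layers[[1]])
  cnt <- rep(0L, n)
  for (sl in slope_layers) {
    cnt <- cnt + as.integer(layer_values_any(sl, "slope", n) < 0)
  }
  fractions <- tibble::tibble(n_decreasing = 0:3) |>
    dplyr::mutate(fraction = vapply(.data$n_decreasing,
                                    function(k) mean(cnt == k), numeric(1)))
  list(consensus = tibble::tibble(cell = seq_len(n), n_decreasing = cnt),
       fractions = fractions)
}

#' Most abundant (model-weighted) species per cell
#'
#' Per cell, the species maximising the weighted index
#' `c_s * S_s * exp(b_s)` (default) or `c_s * S_s`; ties go to the
#' species with the lower index.
#'
#' @param S Abundance tibble `species`, `cell`, `value`.
#' @param params Fitted [envenoming_params()].
#' @param weighting `"full"` (both coefficient families) or `"contact"`
#'   (`c_s` only).
#' @return A tibble `cell`, `species` (factor in species order).
#' @export
dominant_species <- function(S, params, weighting = c("full", "contact")) {
  weighting <- match.arg(weighting)
  if (nrow(S) == 0) abort_invalid("empty abundance set.")
  n <- max(S$cell)
  m <- species_matrix(S, n)
  w <- if (weighting == "full") params$c * exp(params$b) else params$c
  wm <- sweep(m, 2, w, `*`)
  idx <- max.col(wm, ties.method = "first")
  tibble::tibble(cell = seq_len(n),
                 species = factor(default_species()[idx],
                                  levels = default_species()))
}

#' Percentage-change summary by land cover transition
#'
#' For every (from, to) class pair observed between the two coarse maps:
#' the number of cells and the median, quartiles and 2.5/97.5 percentiles
#' of the per-cell percentage change.  Unobserved transitions are
#' omitted; masked (`NA`) percentage changes are dropped.
#'
#' @param lc_start,lc_end Coarse land cover tibbles `cell`, `class`.
#' @param pct Tibble `cell`, `pct_change`.
#' @return A tibble `from`, `to`, `n`, `median`, `q25`, `q75`, `q2.5`,
#'   `q97.5`.
#' @export
transition_change_summary <- function(lc_start, lc_end, pct) {
  n <- nrow(lc_start)
  d <- tibble::tibble(
    from = layer_values_any(lc_start, "class", n),
    to = layer_values_any(lc_end, "class", n),
    pct = layer_values_any(pct, "pct_change", n)
  )
  d |>
    dplyr::filter(!is.na(.data$pct)) |>
    dplyr::group_by(.data$from, .data$to) |>
    dplyr::summarise(
      n = dplyr::n(),
      median = stats::median(.data$pct),
      q25 = stats::quantile(.data$pct, 0.25),
      q75 = stats::quantile(.data$pct, 0.75),
      `q2.5` = stats::quantile(.data$pct, 0.025),
      `q97.5` = stats::quantile(.data$pct, 0.975),
      .groups = "drop"
    )
}

#' @rdname run_scenario
#' @param object A `scenario_run`.
#' @param ... Unused.
#' @export
autoplot.scenario_run <- function(object, ...) {
  ns <- national_series(object$incidence, object$population)
  ggplot2::ggplot(ns, ggplot2::aes(.data$year, .data$accum_pct)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$accum_pct - .data$se,
                                      ymax = .data$accum_pct + .data$se),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "Year",
                  y = "Accumulated change in national incidence (%)",
                  title = sprintf("%s / %s / %s", object$scenario$ssp_id,
                                  object$scenario$rcp_id,
                                  object$scenario$rcm_id)) +
    ggplot2::theme_minimal()
}
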