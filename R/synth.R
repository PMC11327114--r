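#' @title Synthetic landscape generation
#' @description Generators for the raster inputs of the envenoming
#'   pipeline: spatially autocorrelated monthly climate with
#'   scenario-dependent trends, a five-class land cover mosaic, tree
#'   cover, decadal population grids, species abundance truth with
#'   occurrence points, and forward-simulated envenoming counts.  All
#'   randomness flows from one master seed via [derive_seed()].
#' @name landscape_synth
NULL

#' Derive a sub-stream seed from a master seed
#'
#' Deterministic splitting of one master seed into per-stage streams so
#' that every generated fixture is exactly regenerable.  The mapping is a
#' fixed affine hash modulo 2^31 - 1.
#'
#' @param seed Master seed (integer).
#' @param stream Stream index (small integer; each generator uses a fixed
#'   one, see the individual generators).
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stream) {
  as.integer((abs(as.numeric(seed)) * 7919 + as.numeric(stream) * 104729 + 1) %% 2147483647)
}

# Moving-average smoothing of a per-cell field on the lattice grid; `width`
# is the half-width of the square window (cells).  Edges use the available
# neighbourhood (normalised by the count actually summed).
smooth_field <- function(lattice, values, width = 2L) {
  m <- matrix(values, nrow = lattice$n_rows, ncol = lattice$n_cols, byrow = TRUE)
  acc <- matrix(0, lattice$n_rows, lattice$n_cols)
  cnt <- matrix(0, lattice$n_rows, lattice$n_cols)
  for (dr in -width:width) {
    rs <- max(1, 1 + dr):min(lattice$n_rows, lattice$n_rows + dr)
    rt <- rs - dr
    for (dc in -width:width) {
      cs <- max(1, 1 + dc):min(lattice$n_cols, lattice$n_cols + dc)
      ct <- cs - dc
      acc[rt, ct] <- acc[rt, ct] + m[rs, cs]
      cnt[rt, ct] <- cnt[rt, ct] + 1
    }
  }
  as.numeric(t(acc / cnt))
}

#' Climate trend specification
#'
#' @param warming_per_decade Added to monthly temperatures, degrees C per
#'   decade (applied linearly in time).
#' @param rain_multiplier_per_decade Multiplies monthly rainfall once per
#'   decade (compounding; 1 = no change).
#' @return A list of class `climate_trend`.
#' @export
climate_trend <- function(warming_per_decade = 0, rain_multiplier_per_decade = 1) {
  if (rain_multiplier_per_decade <= 0) {
    abort_invalid("`rain_multiplier_per_decade` must be positive.")
  }
  structure(list(warming_per_decade = warming_per_decade,
                 rain_multiplier_per_decade = rain_multiplier_per_decade),
            class = "climate_trend")
}

#' Generate a synthetic monthly climate stack
#'
#' Monthly minimum / maximum temperature (degrees C) and total rainfall
#' (mm) per cell and year.  The surface is the sum of a fixed
#' elevation-like gradient, a smoothed (moving-average) Gaussian random
#' field per year, a seasonal cycle, national interannual anomalies, and
#' the linear trend requested by `trend`.  Rainfall is log-normal so it is
#' strictly positive; minimum temperature is maximum minus a positive
#' diurnal-to-monthly range, so `tmin <= tmax` holds everywhere by
#' construction.
#'
#' @param lattice An [make_lattice()] geometry.
#' @param years Integer vector of calendar years (non-empty).
#' @param trend A [climate_trend()].
#' @param seed Master seed; the generator uses stream 1.
#' @param base_tmax Spatial mean of annual-mean maximum temperature (30 C).
#' @param gradient_range Total drop of the elevation-like temperature
#'   gradient across the grid (degrees C; default 5).
#' @param base_rain Mean monthly rainfall at the reference year (mm;
#'   default 150).
#' @param spatial_sd Standard deviation of the (pre-smoothing) spatial
#'   climatology field, drawn once per stack: the spatial pattern is a
#'   fixed climatology, as for real terrain.
#' @param interannual_sd Standard deviation (degrees C) of the national
#'   annual temperature anomaly (default 0.01; the synthetic system is
#'   deliberately climate-sensitive, so its null climatology is kept
#'   correspondingly smooth).
#' @param rain_interannual_sd Standard deviation of the national annual
#'   log-rainfall anomaly (relative).
#' @param annual_field_sd Standard deviation (degrees C) of an additional
#'   spatially structured (smoothed) anomaly field drawn independently
#'   each year, with a proportional log-rain counterpart.  Default 0:
#'   interannual variability is purely national.  Used by experiments
#'   that need year-to-year spatial climate contrast (e.g. the climate
#'   window re-analysis).
#' @param smooth_width Moving-average half-width (cells) of the random
#'   field.
#' @return A tibble with columns `year`, `month`, `cell`, `tmin`, `tmax`,
#'   `rain`; one row per year-month-cell.
#' @export
gen_climate <- function(lattice, years, trend = climate_trend(), seed = 1L,
                        base_tmax = 30, gradient_range = 5, base_rain = 150,
                        spatial_sd = 0.8, interannual_sd = 0.01,
                        rain_interannual_sd = 0.005, annual_field_sd = 0,
                        smooth_width = 2L) {
  stopifnot(inherits(lattice, "env_lattice"))
  if (length(years) == 0) abort_invalid("`years` must be non-empty.")
  if (!inherits(trend, "climate_trend")) abort_invalid("`trend` must be a climate_trend().")
  years <- sort(unique(as.integer(years)))
  set.seed(derive_seed(seed, 1L))
  n <- lattice$n_cells
  year0 <- years[1]

  cells <- lattice_cells(lattice)
  # fixed elevation-like gradient: cooler and wetter towards the grid top
  grad <- -gradient_range * (cells$y - min(cells$y)) / max(diff(range(cells$y)), 1)
  rain_grad <- 0.3 * (cells$y - mean(cells$y)) / max(diff(range(cells$y)), 1)

  seas_t <- 1.5 * cos(2 * pi * (1:12 - 4) / 12)          # warm peak ~April
  seas_r <- 1 + 0.6 * cos(2 * pi * (1:12 - 10) / 12)     # wet peak ~October

  # fixed spatial climatology (one realisation per stack)
  field_t <- smooth_field(lattice, stats::rnorm(n, 0, spatial_sd * 3), smooth_width)
  field_r <- smooth_field(lattice, stats::rnorm(n, 0, 0.25 * 3), smooth_width)
  rng <- pmax(8 + smooth_field(lattice, stats::rnorm(n, 0, 1.5), smooth_width), 2)

  out <- vector("list", length(years))
  for (k in seq_along(years)) {
    yr <- years[k]
    dy <- (yr - year0) / 10
    anom <- stats::rnorm(1, 0, interannual_sd)
    rain_anom <- stats::rnorm(1, 0, rain_interannual_sd)
    af <- 0; arf <- 0
    if (annual_field_sd > 0) {
      af <- smooth_field(lattice, stats::rnorm(n, 0, annual_field_sd * 3),
                         smooth_width)
      arf <- smooth_field(lattice, stats::rnorm(n, 0, annual_field_sd * 0.9),
                          smooth_width)
    }
    warm <- trend$warming_per_decade * dy
    rmul <- trend$rain_multiplier_per_decade^dy
    tmax <- outer(grad + field_t + base_tmax + anom + warm + af, seas_t, `+`)
    tmin <- tmax - rng
    month_noise <- matrix(stats::rnorm(n * 12, 0, 0.15), n, 12)
    rain <- base_rain * rmul * exp(field_r + rain_grad + rain_anom + arf +
                                     month_noise * 0.1) %*% diag(seas_r)
    out[[k]] <- tibble::tibble(
      year = yr,
      month = rep(1:12, each = n),
      cell = rep(seq_len(n), times = 12),
      tmin = as.numeric(tmin + month_noise * 0.5),
      tmax = as.numeric(tmax + month_noise * 0.5),
      rain = as.numeric(rain)
    )
  }
  dplyr::bind_rows(out)
}

#' Five-class land cover legend
#'
#' @return Character vector of the five land cover classes, in legend
#'   order (1 = forest, ..., 5 = tea).
#' @export
landcover_classes <- function() {
  c("forest", "degraded_forest", "agriculture", "urban", "tea")
}

#' Generate a synthetic five-class land cover mosaic
#'
#' A single smoothed Gaussian field is cut at the empirical quantiles that
#' produce the requested class counts, giving spatially clumped classes
#' whose realised shares match `class_fractions` up to integer rounding.
#'
#' @param lattice An [make_lattice()] geometry.
#' @param class_fractions Numeric length-5 vector of target shares, in
#'   legend order ([landcover_classes()]); must sum to 1.
#' @param smoothness Moving-average half-width of the field (cells).
#' @param seed Master seed; stream 2.
#' @return A tibble `cell`, `class` (factor with the five-class legend).
#' @export
gen_landcover <- function(lattice, class_fractions = c(0.35, 0.15, 0.3, 0.1, 0.1),
                          smoothness = 2L, seed = 1L) {
  stopifnot(inherits(lattice, "env_lattice"))
  if (length(class_fractions) != 5L) {
    abort_invalid("`class_fractions` must have length 5 (one share per legend class).")
  }
  if (abs(sum(class_fractions) - 1) > 1e-9 || any(class_fractions < 0)) {
    abort_invalid("`class_fractions` must be non-negative and sum to 1.")
  }
  set.seed(derive_seed(seed, 2L))
  n <- lattice$n_cells
  field <- smooth_field(lattice, stats::rnorm(n), smoothness)
  counts <- floor(class_fractions * n)
  rem <- n - sum(counts)
  if (rem > 0) {  # distribute remainder to the largest fractional parts
    fr <- class_fractions * n - counts
    counts[order(fr, decreasing = TRUE)[seq_len(rem)]] <-
      counts[order(fr, decreasing = TRUE)[seq_len(rem)]] + 1L
  }
  cls <- integer(n)
  cls[order(field)] <- rep.int(seq_len(5L), counts)
  tibble::tibble(cell = seq_len(n),
                 class = factor(landcover_classes()[cls],
                                levels = landcover_classes()))
}

#' Generate a synthetic tree cover field
#'
#' Tree cover categories 1..5 correspond to the bands 0-20, 21-40, 41-60,
#' 61-80 and 81-100 percent of land covered by trees.  Categories are
#' drawn conditionally on the land cover class (forest high, urban low)
#' with mild noise.
#'
#' @param lattice An [make_lattice()] geometry.
#' @param landcover A land cover tibble from [gen_landcover()].
#' @param seed Master seed; stream 3.
#' @return A tibble `cell`, `category` (integer 1..5).
#' @export
gen_treecover <- function(lattice, landcover, seed = 1L) {
  set.seed(derive_seed(seed, 3L))
  cls <- layer_values(landcover, lattice, "class", allow_na = FALSE)
  centre <- c(forest = 4.5, degraded_forest = 3.5, agriculture = 2,
              urban = 1.2, tea = 2.5)[as.character(cls)]
  cat <- pmin(5L, pmax(1L, as.integer(round(centre + stats::rnorm(length(cls), 0, 0.6)))))
  tibble::tibble(cell = seq_len(lattice$n_cells), category = cat)
}

#' Generate decadal synthetic population density grids
#'
#' A smoothed log-normal base surface for 2010 is propagated to 2020,
#' 2030, 2040 and 2050 with per-decade growth multipliers.  When
#' `urban_bias > 0` and a land cover map is supplied, growth concentrates
#' near urban cells while the national total still follows the
#' multipliers exactly.
#'
#' @param lattice An [make_lattice()] geometry.
#' @param base_density Mean density in 2010 (persons per square km).
#' @param growth Numeric length-4 vector of per-decade multipliers
#'   (2010-20, ..., 2040-50); all positive.
#' @param urban_bias Non-negative scalar; 0 gives spatially uniform
#'   growth.
#' @param landcover Optional land cover tibble (needed when
#'   `urban_bias > 0`).
#' @param seed Master seed; stream 4.
#' @return A tibble `year`, `cell`, `density` for the five decadal years.
#' @export
gen_population <- function(lattice, base_density = 250,
                           growth = c(1.07, 1.06, 1.05, 1.04),
                           urban_bias = 0, landcover = NULL, seed = 1L) {
  stopifnot(inherits(lattice, "env_lattice"))
  if (base_density < 0) abort_invalid("`base_density` must be non-negative.")
  if (length(growth) != 4L || any(growth <= 0)) {
    abort_invalid("`growth` must be 4 positive per-decade multipliers.")
  }
  set.seed(derive_seed(seed, 4L))
  n <- lattice$n_cells
  field <- smooth_field(lattice, stats::rnorm(n, 0, 2), 2L)
  d <- base_density * exp(field - mean(field))
  w <- rep(1, n)
  if (urban_bias > 0) {
    if (is.null(landcover)) abort_invalid("`landcover` is required when `urban_bias` > 0.")
    cls <- layer_values(landcover, lattice, "class")
    dist_urb <- distance_to_class(lattice, cls == "urban")
    w <- 1 + urban_bias * exp(-dist_urb / (2 * lattice$cell_size))
  }
  years <- seq(2010, 2050, by = 10)
  out <- vector("list", 5L)
  out[[1]] <- tibble::tibble(year = 2010L, cell = seq_len(n), density = d)
  for (k in 1:4) {
    # only the growth increment is redistributed towards w, so growth = 1
    # leaves the layer untouched and totals follow `growth` exactly
    d <- d + (growth[k] - 1) * sum(d) * (d * w) / sum(d * w)
    out[[k + 1]] <- tibble::tibble(year = years[k + 1], cell = seq_len(n), density = d)
  }
  dplyr::bind_rows(out)
}

# Euclidean distance (km) from every cell centre to the nearest TRUE cell.
# Returns Inf everywhere if no cell is TRUE.
distance_to_class <- function(lattice, is_target) {
  cells <- lattice_cells(lattice)
  idx <- which(is_target)
  if (length(idx) == 0) return(rep(Inf, lattice$n_cells))
  tx <- cells$x[idx]; ty <- cells$y[idx]
  out <- numeric(lattice$n_cells)
  for (i in seq_len(lattice$n_cells)) {
    if (is_target[i]) next
    out[i] <- sqrt(min((cells$x[i] - tx)^2 + (cells$y[i] - ty)^2))
  }
  out
}

#' Default snake taxa
#'
#' The seven medically relevant venomous land snakes of the study system.
#'
#' @return Character vector of length 7.
#' @export
default_species <- function() {
  c("Bungarus caeruleus", "Bungarus ceylonicus", "Daboia russelii",
    "Echis carinatus", "Hypnale spp", "Naja naja",
    "Trimeresurus trigonocephalus")
}

#' Default per-species abundance coefficient table
#'
#' Coefficients of the log-linear abundance index on standardised
#' bioclimatic summaries (annual mean tmin/tmax, total rain), land cover
#' derived covariates (proportion agriculture, distance to forest in km,
#' tree cover proportion) and niche-centroid distance, plus the
#' standardised niche centroid offsets of each species and its expert
#' relative-abundance weight.  All niche-distance coefficients are
#' negative: abundance peaks at the species' climatic optimum.
#'
#' @return A tibble with one row per taxon.
#' @export
default_species_spec <- function() {
  sp <- default_species()
  tibble::tibble(
    species = sp,
    intercept      = c(0.2, -0.3, 0.3, -0.5, 0.5, 0.1, -0.2),
    b_tmax         = c(0.30, -0.25, 0.20, 0.35, -0.20, 0.15, -0.30),
    b_rain         = c(-0.25, 0.30, -0.15, -0.35, 0.30, 0.00, 0.25),
    b_agric        = c(0.4, -0.2, 0.5, 0.3, 0.2, 0.4, -0.3),
    b_forest_dist  = c(0.02, -0.06, 0.03, 0.04, -0.05, 0.01, -0.06),
    b_tree         = c(-0.3, 0.5, -0.4, -0.5, 0.4, -0.2, 0.6),
    b_niche        = c(-0.6, -0.8, -0.5, -0.7, -0.6, -0.5, -0.8),
    centroid_tmax  = c(0.2, -0.8, 0.0, 0.4, -0.5, -0.2, -0.9),
    centroid_rain  = c(-0.6, 0.8, -0.2, -0.9, 0.6, 0.0, 0.8),
    expert_weight  = rep(1, length(sp))
  )
}

#' Generate species abundance truth and occurrence points
#'
#' Builds per-species abundance index surfaces `S_s >= 0` from a
#' log-linear intensity in standardised bioclimatic summaries, land cover
#' derived covariates and the distance to each species' climatic niche
#' centroid, then samples occurrence points multinomially with
#' probability proportional to intensity (fixed `n_occurrences` per
#' species, jittered uniformly within cells).
#'
#' @param lattice An [make_lattice()] geometry.
#' @param climate A climate stack from [gen_climate()].
#' @param landcover A land cover tibble.
#' @param treecover A tree cover tibble ([gen_treecover()]).
#' @param spec Coefficient table covering all seven default taxa
#'   ([default_species_spec()]).
#' @param year Reference year for the bioclimatic summary (3-year rolling
#'   mean ending that year).
#' @param n_occurrences Occurrence points per species (default 150).
#' @param seed Master seed; stream 5.
#' @return A list with `abundance` (tibble `species`, `cell`, `value`),
#'   `occurrences` (tibble `species`, `x`, `y`), `covariates` (per-cell
#'   covariate tibble incl. per-species niche distances) and `spec`.
#' @export
gen_species_truth <- function(lattice, climate, landcover, treecover,
                              spec = default_species_spec(),
                              year = NULL, n_occurrences = 150, seed = 1L) {
  missing_sp <- setdiff(default_species(), spec$species)
  if (length(missing_sp) > 0) {
    abort_invalid(paste0("species missing from `spec`: ",
                         paste(missing_sp, collapse = ", ")))
  }
  set.seed(derive_seed(seed, 5L))
  yrs <- sort(unique(climate$year))
  if (is.null(year)) year <- yrs[min(3L, length(yrs))]
  bio <- rolling_climate_mean(climate, year = year,
                              window = min(3L, match(year, yrs)))
  tree_prop <- categories_to_proportion(treecover,
                                        reference_mean = default_tree_reference_mean())
  cov <- derived_covariates(landcover, tree_prop, lattice)
  std <- function(v) (v - mean(v)) / stats::sd(v)
  X <- tibble::tibble(
    cell = bio$cell,
    tmax_s = std(bio$tmax_mean),
    rain_s = std(bio$rain_total),
    tmin_s = std(bio$tmin_mean),
    prop_agric = cov$prop_agric,
    forest_dist = ifelse(is.finite(cov$forest_dist), cov$forest_dist,
                         max(cov$forest_dist[is.finite(cov$forest_dist)], 0)),
    tree_prop = cov$tree_prop
  )
  n <- lattice$n_cells
  cells <- lattice_cells(lattice)
  ab <- vector("list", nrow(spec)); occ <- vector("list", nrow(spec))
  nd <- vector("list", nrow(spec))
  for (k in seq_len(nrow(spec))) {
    p <- spec[k, ]
    dist <- sqrt((X$tmax_s - p$centroid_tmax)^2 + (X$rain_s - p$centroid_rain)^2)
    lin <- p$intercept + p$b_tmax * X$tmax_s + p$b_rain * X$rain_s +
      p$b_agric * X$prop_agric + p$b_forest_dist * X$forest_dist +
      p$b_tree * X$tree_prop + p$b_niche * dist
    S <- exp(lin)
    ab[[k]] <- tibble::tibble(species = p$species, cell = seq_len(n), value = S)
    nd[[k]] <- tibble::tibble(species = p$species, cell = seq_len(n),
                              niche_dist = dist)
    counts <- as.integer(stats::rmultinom(1, n_occurrences, prob = S))
    ci <- rep.int(seq_len(n), counts)
    occ[[k]] <- tibble::tibble(
      species = p$species,
      x = cells$x[ci] + stats::runif(length(ci), -0.5, 0.5) * lattice$cell_size,
      y = cells$y[ci] + stats::runif(length(ci), -0.5, 0.5) * lattice$cell_size
    )
  }
  list(abundance = dplyr::bind_rows(ab),
       occurrences = dplyr::bind_rows(occ),
       niche_distance = dplyr::bind_rows(nd),
       covariates = X, spec = spec)
}

#' Default study-area mean tree cover proportion
#' @return Scalar used to rescale tree cover categories to proportions.
#' @export
default_tree_reference_mean <- function() 0.45
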