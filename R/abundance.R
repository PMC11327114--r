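#' @title Snake abundance surfaces
#' @description Per-species abundance index layers from climate and land
#'   cover covariates and niche-centroid distance: a log-linear intensity
#'   model (count regression with a cell-area offset) standing in for the
#'   study-scale point-process fits, plus expert relative-abundance
#'   weighting.
#' @name snake_abundance
NULL

#' Estimate a climatic niche model from occurrence points
#'
#' Climate covariates are standardised over the whole study area; the
#' niche centroid is the mean of the standardised climate at the cells
#' containing occurrence points (the mean conditions where the species
#' has been observed).
#'
#' @param occurrences Tibble `x`, `y` (projected km; one species).
#' @param climate_summary Tibble `cell` plus numeric climate covariate
#'   columns (e.g. from [bioclim_summaries()]).
#' @param lattice The [make_lattice()] geometry.
#' @param variables Covariate columns to use (default: all numeric
#'   columns except `cell`).
#' @return An object of class `niche_model`: variables, per-variable mean
#'   and sd, and the standardised centroid.
#' @export
estimate_niche <- function(occurrences, climate_summary, lattice,
                           variables = NULL) {
  if (nrow(occurrences) < 5) abort_invalid("need at least 5 occurrence points.")
  if (is.null(variables)) {
    variables <- setdiff(names(climate_summary), "cell")
  }
  cells <- coords_to_cell(lattice, occurrences$x, occurrences$y)
  if (any(is.na(cells))) abort_invalid("occurrences fall outside the lattice.")
  X <- as.matrix(climate_summary[order(climate_summary$cell), variables])
  mu <- colMeans(X)
  sd_ <- apply(X, 2, stats::sd)
  if (any(sd_ <= 0)) abort_invalid("constant climate covariate: cannot standardise.")
  Z <- sweep(sweep(X, 2, mu), 2, sd_, `/`)
  centroid <- colMeans(Z[cells, , drop = FALSE])
  structure(list(variables = variables, mean = mu, sd = sd_,
                 centroid = centroid),
            class = "niche_model")
}

#' @export
print.niche_model <- function(x, ...) {
  cat("<niche_model> centroid (standardised):\n")
  print(round(x$centroid, 3))
  invisible(x)
}

#' Niche-centroid distance surface
#'
#' Per-cell Euclidean distance, in standardised climate space, from the
#' cell's conditions to the species' niche centroid.
#'
#' @param niche A [estimate_niche()] model.
#' @param climate_summary Tibble `cell` plus the same covariate columns.
#' @return A tibble `cell`, `distance` (>= 0; 0 iff the cell sits at the
#'   centroid).
#' @export
niche_distance <- function(niche, climate_summary) {
  stopifnot(inherits(niche, "niche_model"))
  miss <- setdiff(niche$variables, names(climate_summary))
  if (length(miss) > 0) {
    abort_invalid(paste0("missing niche variables: ", paste(miss, collapse = ", ")))
  }
  X <- as.matrix(climate_summary[, niche$variables])
  Z <- sweep(sweep(X, 2, niche$mean), 2, niche$sd, `/`)
  D <- sweep(Z, 2, niche$centroid)
  tibble::tibble(cell = climate_summary$cell, distance = sqrt(rowSums(D^2)))
}

#' Fit a log-linear abundance intensity model
#'
#' Maximum-likelihood Poisson regression of gridded occurrence counts on
#' the covariate layers with a log cell-area offset.  This is the
#' intensity surface behind the abundance index: with an intercept, the
#' fitted intensity integrates to the total observed count.
#'
#' @param gridded_counts Tibble `cell`, `count` (non-negative integers).
#' @param covariates Tibble `cell` plus numeric covariate columns
#'   (typically bioclim summaries, land-cover covariates and the niche
#'   distance).
#' @param cell_area Cell area (km^2) for the offset (default 1).
#' @return An object of class `abundance_fit` wrapping the glm; supports
#'   [generics::tidy()] and [generics::glance()].
#' @export
fit_abundance_model <- function(gridded_counts, covariates, cell_area = 1) {
  if (!all(c("cell", "count") %in% names(gridded_counts))) {
    abort_invalid("`gridded_counts` needs columns cell, count.")
  }
  if (all(gridded_counts$count == 0)) {
    rlang::abort("all counts are zero: intensity not estimable.",
                 class = "envenomr_degenerate_data")
  }
  vars <- setdiff(names(covariates), "cell")
  d <- dplyr::inner_join(gridded_counts, covariates, by = "cell")
  keep <- vars[purrr::map_lgl(vars, \(v) stats::sd(d[[v]]) > 0)]
  dropped <- setdiff(vars, keep)
  if (length(dropped) > 0) {
    rlang::warn(paste0("dropping constant covariates: ",
                       paste(dropped, collapse = ", ")))
  }
  if (length(keep) == 0) abort_invalid("no usable (non-constant) covariates.")
  f <- stats::reformulate(keep, response = "count")
  fit <- stats::glm(f, family = stats::poisson(), data = d,
                    offset = rep(log(cell_area), nrow(d)))
  if (!fit$converged) {
    rlang::abort("abundance model did not converge.",
                 class = "envenomr_convergence_error")
  }
  structure(list(fit = fit, variables = keep, cell_area = cell_area),
            class = "abundance_fit")
}

#' @export
print.abundance_fit <- function(x, ...) {
  cat("<abundance_fit> log-linear intensity on:",
      paste(x$variables, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname fit_abundance_model
#' @param x An `abundance_fit` object.
#' @param ... Unused.
#' @export
tidy.abundance_fit <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(co), estimate = co[, 1],
                 std.error = co[, 2], statistic = co[, 3], p.value = co[, 4])
}

#' @rdname fit_abundance_model
#' @export
glance.abundance_fit <- function(x, ...) {
  tibble::tibble(null.deviance = x$fit$null.deviance,
                 deviance = x$fit$deviance,
                 AIC = stats::AIC(x$fit),
                 nobs = stats::nobs(x$fit))
}

#' Project an abundance index surface
#'
#' Evaluates `S_s = exp(linear predictor)` per cell from a fitted
#' intensity model, a covariate table for the target year (built from the
#' 3-year rolling climate mean and that year's land cover), and the
#' species' niche model (used to refresh the niche-distance covariate).
#'
#' @param fit An [fit_abundance_model()] object.
#' @param covariates Tibble `cell` plus the model's covariates; if a
#'   `niche` is given and the table has the niche variables, the
#'   `niche_dist` column is recomputed from them.
#' @param niche Optional [estimate_niche()] model.
#' @return A tibble `cell`, `value` with `value = S_s >= 0` finite.
#' @export
project_abundance <- function(fit, covariates, niche = NULL) {
  stopifnot(inherits(fit, "abundance_fit"))
  if (!is.null(niche) && all(niche$variables %in% names(covariates))) {
    covariates$niche_dist <- niche_distance(niche, covariates)$distance
  }
  miss <- setdiff(fit$variables, names(covariates))
  if (length(miss) > 0) {
    abort_invalid(paste0("missing covariates: ", paste(miss, collapse = ", ")))
  }
  eta <- as.numeric(stats::predict(fit$fit, newdata = covariates, type = "link"))
  val <- exp(eta)
  if (any(!is.finite(val))) abort_invalid("non-finite projected abundance.")
  tibble::tibble(cell = covariates$cell, value = val)
}

#' Apply expert relative-abundance weights
#'
#' Multiplies each species' abundance index layer by its expert weight
#' `w_s > 0`.
#'
#' @param abundance Tibble `species`, `cell`, `value`.
#' @param weights Named numeric vector of positive weights (names =
#'   species); species without a name keep weight 1.
#' @return The reweighted abundance tibble.
#' @export
apply_expert_weights <- function(abundance, weights) {
  if (any(weights <= 0)) abort_invalid("expert weights must be positive.")
  w <- weights[abundance$species]
  w[is.na(w)] <- 1
  dplyr::mutate(abundance, value = .data$value * as.numeric(w))
}
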