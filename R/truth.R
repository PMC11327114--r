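#' Assemble a complete synthetic study system
#'
#' Builds every layer the pipeline needs on one lattice: monthly climate
#' with an optional trend, the five-class land cover mosaic, tree cover,
#' decadal population, the seven species abundance truth with occurrence
#' points, a CAR field drawn at the true precision, and the true
#' envenoming parameters.  The master seed is recorded so any fixture is
#' exactly regenerable.
#'
#' @param n_rows,n_cols Lattice dimensions (default 20 x 20 at 1 km so a
#'   5x upscaling gives a 4 x 4 coarse grid).
#' @param years Calendar years of the climate stack (default 2008-2050,
#'   so the 3-year rolling window exists at 2010).
#' @param seed Master seed.
#' @param params True [envenoming_params()].
#' @param trend A [climate_trend()].
#' @param class_fractions,base_density,growth,urban_bias Passed to the
#'   land cover / population generators.
#' @return An object of class `synthetic_truth`.
#' @export
make_synthetic_truth <- function(n_rows = 20, n_cols = 20,
                                 years = 2008:2050, seed = 1L,
                                 params = default_params(),
                                 trend = climate_trend(),
                                 class_fractions = c(0.35, 0.15, 0.3, 0.1, 0.1),
                                 base_density = 250,
                                 growth = c(1.07, 1.06, 1.05, 1.04),
                                 urban_bias = 1) {
  lattice <- make_lattice(n_rows, n_cols)
  climate <- gen_climate(lattice, years, trend, seed)
  landcover <- gen_landcover(lattice, class_fractions, seed = seed)
  treecover <- gen_treecover(lattice, landcover, seed = seed)
  population <- gen_population(lattice, base_density, growth, urban_bias,
                               landcover, seed = seed)
  species <- gen_species_truth(lattice, climate, landcover, treecover,
                               seed = seed)
  rho <- rcar_field(lattice, params$tau, seed)
  structure(list(
    lattice = lattice, climate = climate, landcover = landcover,
    treecover = treecover, population = population,
    species = species, rho = rho, params = params, trend = trend,
    seed = as.integer(seed)
  ), class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> %dx%d lattice, years %d-%d, seed %d\n",
              x$lattice$n_rows, x$lattice$n_cols,
              min(x$climate$year), max(x$climate$year), x$seed))
  invisible(x)
}

#' Forward-simulate observed envenoming counts
#'
#' Computes the expected incidence `Delta He` from the truth layers and
#' true parameters for the given year and draws per-cell Poisson counts
#' around it (capped at the population so `y <= H` always holds).
#'
#' @param truth A [make_synthetic_truth()] object.
#' @param year Year within the truth's population span.
#' @param seed Integer seed (stream 8).
#' @return A tibble `cell`, `y` (counts), `H` (population), `mu` (the
#'   true expected incidence).
#' @export
simulate_incidence <- function(truth, year = 2010, seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  yrs <- range(truth$population$year)
  if (year < yrs[1] || year > yrs[2]) {
    abort_invalid(sprintf("year %s outside the truth population span.", year))
  }
  set.seed(derive_seed(seed, 8L))
  H <- hermite_annual(truth$population, year)$density
  cls_idx <- match(as.character(layer_values(truth$landcover, truth$lattice, "class")),
                   landcover_classes())
  H2010 <- truth$population |> dplyr::filter(.data$year == 2010)
  Smat <- species_matrix(truth$species$abundance, truth$lattice$n_cells)
  mu <- forward_mu(cls_idx, log1p(H2010$density[order(H2010$cell)]), H,
                   Smat, truth$rho, truth$params)
  y <- pmin(stats::rpois(length(mu), mu), floor(H))
  tibble::tibble(cell = seq_along(mu), y = y, H = H, mu = mu)
}

# write a data frame as CSV with 17-significant-digit numerics so doubles
# round-trip exactly
write_csv17 <- function(df, path) {
  out <- df
  for (nm in names(out)) {
    if (is.double(out[[nm]])) out[[nm]] <- sprintf("%.17g", out[[nm]])
    if (is.factor(out[[nm]])) out[[nm]] <- as.character(out[[nm]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

#' Write a synthetic truth fixture to disk
#'
#' Rasters and tables as plain CSV, parameters and lattice geometry as
#' JSON, plus a manifest recording the master seed and the md5 checksum
#' of every file.
#'
#' @param truth A [make_synthetic_truth()] object.
#' @param dir Directory (created if needed).
#' @return The manifest, invisibly.
#' @export
write_fixture <- function(truth, dir) {
  stopifnot(inherits(truth, "synthetic_truth"))
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(dir, 2) != 0) abort_io("fixture directory is not writable.")
  files <- list(
    climate = "climate.csv", landcover = "landcover.csv",
    treecover = "treecover.csv", population = "population.csv",
    abundance = "abundance.csv", occurrences = "occurrences.csv",
    rho = "rho.csv", species_spec = "species_spec.csv"
  )
  write_csv17(truth$climate, file.path(dir, files$climate))
  write_csv17(truth$landcover, file.path(dir, files$landcover))
  write_csv17(truth$treecover, file.path(dir, files$treecover))
  write_csv17(truth$population, file.path(dir, files$population))
  write_csv17(truth$species$abundance, file.path(dir, files$abundance))
  write_csv17(truth$species$occurrences, file.path(dir, files$occurrences))
  write_csv17(tibble::tibble(cell = seq_along(truth$rho),
                             rho = sprintf_num(truth$rho)),
              file.path(dir, files$rho))
  write_csv17(truth$species$spec, file.path(dir, files$species_spec))
  jsonlite::write_json(
    list(lattice = truth$lattice[c("n_rows", "n_cols", "cell_size", "origin",
                                   "crs_label")],
         params = unclass(truth$params),
         trend = unclass(truth$trend)),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  paths <- c(unlist(files), "meta.json")
  sums <- tools::md5sum(file.path(dir, paths))
  manifest <- list(seed = truth$seed,
                   checksums = as.list(stats::setNames(unname(sums), paths)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

sprintf_num <- function(x) as.numeric(sprintf("%.17g", x))

#' Read a synthetic truth fixture back from disk
#'
#' Verifies every file against the manifest checksums before loading;
#' a mismatch (tampered or truncated file) is an error.
#'
#' @param dir Fixture directory written by [write_fixture()].
#' @return A `synthetic_truth` object.
#' @export
read_fixture <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) abort_io("no manifest.json in fixture directory.")
  manifest <- jsonlite::read_json(mpath)
  for (f in names(manifest$checksums)) {
    got <- unname(tools::md5sum(file.path(dir, f)))
    if (is.na(got) || got != manifest$checksums[[f]]) {
      rlang::abort(sprintf("checksum mismatch for fixture file '%s'.", f),
                   class = "envenomr_validation_error")
    }
  }
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  lattice <- make_lattice(meta$lattice$n_rows, meta$lattice$n_cols,
                          meta$lattice$cell_size, meta$lattice$origin,
                          meta$lattice$crs_label)
  params <- envenoming_params(meta$params$beta0, meta$params$beta1,
                              meta$params$c, meta$params$B0, meta$params$B,
                              meta$params$b, meta$params$tau)
  rd <- function(f) tibble::as_tibble(utils::read.csv(file.path(dir, f)))
  landcover <- rd("landcover.csv") |>
    dplyr::mutate(class = factor(.data$class, levels = landcover_classes()))
  structure(list(
    lattice = lattice, climate = rd("climate.csv"), landcover = landcover,
    treecover = rd("treecover.csv"), population = rd("population.csv"),
    species = list(abundance = rd("abundance.csv"),
                   occurrences = rd("occurrences.csv"),
                   spec = rd("species_spec.csv")),
    rho = rd("rho.csv")$rho,
    params = params,
    trend = climate_trend(meta$trend$warming_per_decade,
                          meta$trend$rain_multiplier_per_decade),
    seed = as.integer(manifest$seed)
  ), class = "synthetic_truth")
}
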