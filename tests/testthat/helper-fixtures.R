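# shared fixtures, built once per test run and cached
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# small synthetic study system (20x20, short climate record)
small_truth <- function() {
  cached("small_truth", function() {
    make_synthetic_truth(n_rows = 20, n_cols = 20, years = 2008:2015, seed = 42)
  })
}

# full-length study system for scenario runs
long_truth <- function() {
  cached("long_truth", function() {
    make_synthetic_truth(n_rows = 20, n_cols = 20, years = 2008:2050, seed = 42)
  })
}

# a small random climate stack for oracle tests
random_stack <- function(lattice, years, seed = 7) {
  set.seed(seed)
  rows <- expand.grid(cell = seq_len(lattice$n_cells), month = 1:12,
                      year = years)
  tmax <- 25 + rnorm(nrow(rows), 0, 3)
  tibble::tibble(
    year = rows$year, month = rows$month, cell = rows$cell,
    tmin = tmax - runif(nrow(rows), 2, 10), tmax = tmax,
    rain = rexp(nrow(rows), 1 / 100)
  )
}

# brute-force per-month climatology by explicit loops (independent oracle)
loop_climatology <- function(stack, var) {
  cells <- sort(unique(stack$cell))
  months <- sort(unique(stack$month))
  out <- matrix(NA_real_, length(cells), length(months))
  for (i in seq_along(cells)) {
    for (m in seq_along(months)) {
      v <- stack[[var]][stack$cell == cells[i] & stack$month == months[m]]
      out[i, m] <- mean(v)
    }
  }
  out
}

expect_deterministic <- function(expr1, expr2) {
  expect_identical(expr1, expr2)
}

# random-but-valid parameter sets and layer stacks for forward-model tests
rand_params <- function(seed) {
  set.seed(seed)
  envenoming_params(
    beta0 = rnorm(5, -3, 1), beta1 = rnorm(5, 0.1, 0.1),
    c = abs(rnorm(7, 1, 1)), B0 = rnorm(1),
    B = rnorm(5, 0, 0.5), b = rnorm(7, 0, 0.2), tau = rexp(1) + 0.5
  )
}

rand_layers <- function(lattice, seed) {
  set.seed(seed)
  n <- lattice$n_cells
  list(
    landcover = tibble::tibble(cell = seq_len(n),
                               class = factor(sample(landcover_classes(), n, TRUE),
                                              levels = landcover_classes())),
    H = tibble::tibble(cell = seq_len(n), density = runif(n, 10, 1000)),
    S = tidyr::expand_grid(species = default_species(), cell = seq_len(n)) |>
      dplyr::mutate(value = stats::rexp(dplyr::n(), 1)),
    rho = rnorm(n, 0, 0.3)
  )
}

# a short two-chain fit on the small study system
small_fit <- function(n_iter = 1200, seed = 3) {
  truth <- small_truth()
  obs <- simulate_incidence(truth, 2010, seed = 1)
  H2010 <- truth$population |>
    dplyr::filter(year == 2010) |>
    dplyr::select(cell, density)
  fit_mcmc(obs, truth$species$abundance, truth$landcover, H2010,
           truth$lattice, n_chains = 2, n_iter = n_iter, seed = seed)
}
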