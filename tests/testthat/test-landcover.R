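drivers_tbl <- function(lattice, seed = 1) {
  set.seed(seed)
  tibble::tibble(cell = seq_len(lattice$n_cells),
                 x1 = rnorm(lattice$n_cells),
                 x2 = rnorm(lattice$n_cells))
}

test_that("logistic location factors recover generating coefficients", {
  lat <- make_lattice(20, 20)
  set.seed(31)
  x <- rnorm(400)
  p <- plogis(0.5 + 2 * x)
  pres <- rbinom(400, 1, p)
  # embed the generated class inside a 5-class map (others from leftovers)
  other <- sample(2:5, 400, replace = TRUE)
  lc <- tibble::tibble(cell = 1:400,
                       class = factor(ifelse(pres == 1, landcover_classes()[1],
                                             landcover_classes()[other]),
                                      levels = landcover_classes()))
  drv <- tibble::tibble(cell = 1:400, x1 = x)
  fac <- fit_location_factors(lc, drv)
  co <- tidy(fac)
  sl <- co[co$class == "forest" & co$term == "x1", ]
  expect_lt(abs(sl$estimate - 2), 1.96 * sl$std.error + 0.2)

  # single-class map is degenerate
  mono <- tibble::tibble(cell = 1:400,
                         class = factor("forest", levels = landcover_classes()))
  expect_error(fit_location_factors(mono, drv),
               class = "envenomr_invalid_argument")
})

test_that("null drivers are not spuriously significant", {
  lat <- make_lattice(20, 20)
  covered <- 0L
  for (s in 1:100) {
    lc <- gen_landcover(lat, seed = s)
    drv <- drivers_tbl(lat, seed = 1000 + s)     # independent of the map
    fac <- fit_location_factors(lc, drv)
    co <- tidy(fac)
    sl <- co[co$class == "forest" & co$term == "x1", ]
    covered <- covered + (abs(sl$estimate) <= 1.96 * sl$std.error)
  }
  expect_gte(covered, 90L)
})

test_that("suitability is the inverse-logit of the fitted linear predictor", {
  lat <- make_lattice(10, 10)
  lc <- gen_landcover(lat, seed = 2)
  drv <- drivers_tbl(lat, 2)
  fac <- fit_location_factors(lc, drv)
  su <- suitability(fac, drv)
  expect_true(all(su$p > 0 & su$p < 1))
  # oracle: manual inverse-logit from the coefficients
  co <- coef(fac$fits[["urban"]])
  eta <- co[1] + co[2] * drv$x1 + co[3] * drv$x2
  expect_equal(su$p[su$class == "urban"], unname(plogis(eta)),
               tolerance = 1e-10)
  # zero coefficients give probability one half everywhere
  fac0 <- fac
  fac0$fits[["forest"]]$coefficients[] <- 0
  su0 <- suitability(fac0, drv)
  expect_true(all(su0$p[su0$class == "forest"] == 0.5))
  expect_error(suitability(fac, drv[, "cell", drop = FALSE]),
               class = "envenomr_invalid_argument")
})

random_suit <- function(n, seed) {
  set.seed(seed)
  tidyr::expand_grid(cell = seq_len(n), class = landcover_classes()) |>
    dplyr::mutate(p = runif(dplyr::n(), 0.05, 0.95))
}

test_that("allocation is a fixed point when demand equals the current map", {
  lat <- make_lattice(8, 8)
  lc <- gen_landcover(lat, c(0.3, 0.2, 0.2, 0.15, 0.15), seed = 3)
  dem <- table(factor(lc$class, levels = landcover_classes()))
  uni <- tidyr::expand_grid(cell = seq_len(64), class = landcover_classes()) |>
    dplyr::mutate(p = 0.5)
  out <- allocate_year(lc, uni, as.integer(dem),
                       transition_rules(n_cells = 64), elasticity = 0.5,
                       tol = 0)
  expect_identical(as.character(out$class), as.character(lc$class))
})

test_that("demanded conversions flow to the highest-suitability cells", {
  lat <- make_lattice(8, 8)
  lc <- tibble::tibble(cell = 1:64,
                       class = factor(rep(c("forest", "agriculture"),
                                          c(40, 24)),
                                      levels = landcover_classes()))
  set.seed(4)
  ag_p <- runif(64, 0.05, 0.90)
  ag_p[41:64] <- runif(24, 0.95, 0.99)   # existing agriculture stays attractive
  suit <- tidyr::expand_grid(cell = 1:64, class = landcover_classes()) |>
    dplyr::mutate(p = 0.2)
  suit$p[suit$class == "agriculture"] <- ag_p[suit$cell[suit$class == "agriculture"]]
  dem <- c(forest = 30, degraded_forest = 0, agriculture = 34, urban = 0, tea = 0)
  out <- allocate_year(lc, suit, dem, transition_rules(n_cells = 64),
                       elasticity = 0, tol = 0)
  converted <- which(lc$class == "forest" & out$class == "agriculture")
  expect_length(converted, 10L)
  # exactly the 10 forest cells with the highest agriculture suitability
  forest_cells <- which(lc$class == "forest")
  best10 <- forest_cells[order(ag_p[forest_cells], decreasing = TRUE)][1:10]
  expect_setequal(converted, best10)
})

test_that("infeasible demand under forbidden transitions raises a non-convergence error", {
  lat <- make_lattice(3, 3)
  lc <- tibble::tibble(cell = 1:9,
                       class = factor("urban", levels = landcover_classes()))
  allowed <- diag(5) == 1          # nothing may change class
  dem <- c(forest = 5, degraded_forest = 0, agriculture = 0, urban = 4, tea = 0)
  expect_error(
    allocate_year(lc, random_suit(9, 5), dem,
                  transition_rules(allowed, n_cells = 9), tol = 0),
    class = "envenomr_nonconvergence_error")
})

test_that("allocation matches exhaustive search on tiny maps", {
  lat <- make_lattice(3, 3)
  classes <- landcover_classes()
  for (seed in 1:5) {
    set.seed(seed)
    cur <- sample(1:3, 9, replace = TRUE)
    lc <- tibble::tibble(cell = 1:9, class = factor(classes[cur],
                                                    levels = classes))
    suit <- random_suit(9, 100 + seed)
    dem <- c(tabulate(sample(1:3, 9, replace = TRUE), 3), 0, 0)
    names(dem) <- classes
    el <- 0.3
    out <- allocate_year(lc, suit, dem, transition_rules(n_cells = 9),
                         elasticity = el, tol = 0)
    # score of the returned assignment
    sm <- matrix(qlogis(suit$p[order(match(suit$class, classes), suit$cell)]),
                 9, 5)
    score_of <- function(a) {
      sum(sm[cbind(1:9, a)]) + el * sum(a == cur)
    }
    got <- score_of(match(as.character(out$class), classes))
    # exhaustive search over all assignments meeting the demand
    grid <- as.matrix(expand.grid(rep(list(1:3), 9)))
    ok <- apply(grid, 1, function(a) all(tabulate(a, 5) == dem))
    best <- max(apply(grid[ok, , drop = FALSE], 1, score_of))
    expect_equal(got, best, tolerance = 1e-9)
  }
})

test_that("multi-year simulation respects demand, legality and restrictions", {
  lat <- make_lattice(10, 10)
  lc <- gen_landcover(lat, seed = 6)
  drv <- drivers_tbl(lat, 6)
  fac <- fit_location_factors(lc, drv)
  counts0 <- tabulate(match(as.character(lc$class), landcover_classes()), 5)

  # urban never reverts to forest; first 5 cells frozen
  allowed <- matrix(TRUE, 5, 5)
  allowed[4, 1] <- FALSE
  restricted <- rep(FALSE, 100); restricted[1:5] <- TRUE
  rules <- transition_rules(allowed, restricted)

  years <- 2010:2020
  # urban demand grows monotonically at forest's expense
  demand <- purrr::map_dfr(seq_along(years), function(i) {
    d <- counts0 + c(-(i - 1), 0, 0, i - 1, 0)
    tibble::tibble(year = years[i],
                   class = factor(landcover_classes(),
                                  levels = landcover_classes()),
                   cells = as.integer(d))
  })
  sim <- simulate_landcover(lc, demand, fac, drv, rules, tol = 1)

  urban_counts <- sim |>
    dplyr::filter(class == "urban") |>
    dplyr::count(year)
  expect_true(all(diff(urban_counts$n) >= 0))

  # demand met within tolerance every year
  for (y in years) {
    cy <- sim |> dplyr::filter(year == y)
    got <- tabulate(match(as.character(cy$class), landcover_classes()), 5)
    want <- demand$cells[demand$year == y]
    expect_true(all(abs(got - want) <= 1))
  }
  # no illegal transition anywhere in the run; restricted cells frozen
  wide <- tidyr::pivot_wider(sim, names_from = "year", values_from = "class")
  for (i in seq_along(years)[-1]) {
    from <- match(as.character(wide[[as.character(years[i - 1])]]),
                  landcover_classes())
    to <- match(as.character(wide[[as.character(years[i])]]),
                landcover_classes())
    expect_true(all(allowed[cbind(from, to)]))
  }
  expect_true(all(as.character(wide$`2010`[1:5]) ==
                    as.character(wide$`2020`[1:5])))
  # reproducible
  sim2 <- simulate_landcover(lc, demand, fac, drv, rules, tol = 1)
  expect_identical(sim, sim2)
})

test_that("tree cover bands rescale to the requested study-area mean", {
  tree1 <- tibble::tibble(cell = 1:10, category = 1L)
  p1 <- categories_to_proportion(tree1, 0.10)
  expect_true(all(abs(p1$proportion - 0.10) < 1e-12))

  set.seed(7)
  tree <- tibble::tibble(cell = 1:100, category = sample(1:5, 100, TRUE))
  p <- categories_to_proportion(tree, 0.37)
  expect_equal(mean(p$proportion), 0.37, tolerance = 1e-9)

  tree5 <- tibble::tibble(cell = 1:10, category = c(rep(1L, 9), 5L))
  p5 <- categories_to_proportion(tree5, 0.6)
  expect_lte(max(p5$proportion), 0.99)
  expect_error(categories_to_proportion(tree, 1.2),
               class = "envenomr_invalid_argument")
})

test_that("derived covariates match brute-force computations", {
  lat <- make_lattice(12, 12)
  set.seed(8)
  lc <- gen_landcover(lat, seed = 8)
  tree <- categories_to_proportion(gen_treecover(lat, lc, seed = 8), 0.45)
  cov <- derived_covariates(lc, tree, lat, neighbourhood = 1)

  cells <- lattice_cells(lat)
  cls <- as.character(lc$class[order(lc$cell)])
  fidx <- which(cls == "forest")
  for (i in c(1, 40, 77, 144)) {
    # O(n^2) all-pairs forest distance
    d_or <- if (length(fidx)) {
      if (cls[i] == "forest") 0 else
        sqrt(min((cells$x[i] - cells$x[fidx])^2 +
                   (cells$y[i] - cells$y[fidx])^2))
    } else Inf
    expect_equal(cov$forest_dist[i], d_or, tolerance = 1e-12)
    # neighbourhood proportion by explicit scan
    nb <- which(abs(cells$row - cells$row[i]) <= 1 &
                  abs(cells$col - cells$col[i]) <= 1)
    expect_equal(cov$prop_agric[i], mean(cls[nb] == "agriculture"),
                 tolerance = 1e-12)
  }
  expect_true(all(cov$forest_dist[fidx] == 0))

  all_ag <- tibble::tibble(cell = 1:144,
                           class = factor("agriculture",
                                          levels = landcover_classes()))
  expect_warning(cov2 <- derived_covariates(all_ag, tree, lat),
                 "no forest")
  expect_true(all(cov2$prop_agric == 1))
  expect_true(all(is.infinite(cov2$forest_dist)))
})
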