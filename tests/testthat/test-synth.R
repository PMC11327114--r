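test_that("climate stacks respect physical invariants and determinism", {
  lat <- make_lattice(10, 10)
  clim <- gen_climate(lat, 2010:2012, climate_trend(0, 1), seed = 3)
  expect_true(all(clim$tmin <= clim$tmax))
  expect_true(all(clim$rain >= 0))
  expect_equal(nrow(clim), 100 * 12 * 3)
  clim2 <- gen_climate(lat, 2010:2012, climate_trend(0, 1), seed = 3)
  expect_identical(clim, clim2)
  expect_error(gen_climate(lat, integer(0)), class = "envenomr_invalid_argument")
})

test_that("null and warming trends are recovered from generated series", {
  lat <- make_lattice(10, 10)
  # no trend: decadal change in national mean tmax is ~0
  clim0 <- gen_climate(lat, 2010:2030, climate_trend(0, 1), seed = 5)
  nat0 <- dplyr::summarise(dplyr::group_by(clim0, year),
                           tmax = mean(tmax), .groups = "drop")
  expect_lt(abs(mean(nat0$tmax[nat0$year >= 2025]) -
                  mean(nat0$tmax[nat0$year <= 2015])), 0.15)
  # +0.3 C/decade: fitted OLS slope within 20% of 0.03 C/yr across seeds
  slopes <- vapply(1:10, function(sd) {
    cl <- gen_climate(lat, 2010:2050, climate_trend(0.3, 1), seed = sd)
    nat <- dplyr::summarise(dplyr::group_by(cl, year),
                            tmax = mean(tmax), .groups = "drop")
    unname(coef(lm(tmax ~ year, nat))[2])
  }, numeric(1))
  expect_true(all(abs(slopes - 0.03) < 0.2 * 0.03))
})

test_that("land cover generator hits requested class shares", {
  lat <- make_lattice(20, 20)
  lc <- gen_landcover(lat, c(1, 0, 0, 0, 0), seed = 1)
  expect_true(all(lc$class == "forest"))

  fr <- c(0.4, 0.2, 0.25, 0.1, 0.05)
  lc2 <- gen_landcover(lat, fr, seed = 2)
  shares <- as.numeric(table(lc2$class)[landcover_classes()]) / 400
  expect_true(all(abs(shares - fr) <= 0.05))
  expect_identical(lc2, gen_landcover(lat, fr, seed = 2))
  expect_error(gen_landcover(lat, c(0.5, 0.5, 0.5, 0, 0)),
               class = "envenomr_invalid_argument")
})

test_that("population layers follow growth multipliers and stay put at growth 1", {
  lat <- make_lattice(10, 10)
  flat <- gen_population(lat, 100, rep(1, 4), seed = 4)
  p10 <- flat$density[flat$year == 2010]
  p50 <- flat$density[flat$year == 2050]
  expect_equal(p50, p10)

  lc <- gen_landcover(lat, seed = 4)
  flat_b <- gen_population(lat, 100, rep(1, 4), urban_bias = 2,
                           landcover = lc, seed = 4)
  expect_equal(flat_b$density[flat_b$year == 2050],
               flat_b$density[flat_b$year == 2010])

  grow <- gen_population(lat, 100, rep(1.1, 4), seed = 4)
  ratio <- sum(grow$density[grow$year == 2050]) /
    sum(grow$density[grow$year == 2010])
  expect_equal(ratio, 1.1^4, tolerance = 1e-9)
  expect_identical(grow, gen_population(lat, 100, rep(1.1, 4), seed = 4))
  expect_error(gen_population(lat, -1), class = "envenomr_invalid_argument")
})

test_that("species truth responds to niche distance and is reproducible", {
  truth <- small_truth()
  expect_error(
    gen_species_truth(truth$lattice, truth$climate, truth$landcover,
                      truth$treecover, spec = default_species_spec()[1:3, ]),
    class = "envenomr_invalid_argument")

  # strong negative niche coefficient: abundance anti-correlates with distance
  sp <- default_species_spec()
  d <- dplyr::inner_join(truth$species$abundance, truth$species$niche_distance,
                         by = c("species", "cell"))
  d1 <- dplyr::filter(d, species == sp$species[2])   # b_niche = -0.8
  expect_lt(cor(d1$value, d1$niche_dist, method = "spearman"), 0)

  again <- gen_species_truth(truth$lattice, truth$climate, truth$landcover,
                             truth$treecover, seed = truth$seed)
  expect_identical(again$abundance, truth$species$abundance)
  expect_identical(again$occurrences, truth$species$occurrences)
})

test_that("flat coefficient spec gives flat abundance surfaces", {
  truth <- small_truth()
  sp0 <- default_species_spec()
  sp0[, c("intercept", "b_tmax", "b_rain", "b_agric", "b_forest_dist",
          "b_tree", "b_niche")] <- 0
  flat <- gen_species_truth(truth$lattice, truth$climate, truth$landcover,
                            truth$treecover, sp0, seed = 9)
  expect_true(all(flat$abundance$value == 1))
})

test_that("simulated counts are centred on the model mean", {
  truth <- small_truth()
  obs <- simulate_incidence(truth, 2010, seed = 1)
  expect_true(all(obs$y <= obs$H))
  expect_identical(obs, simulate_incidence(truth, 2010, seed = 1))
  expect_error(simulate_incidence(truth, 1999),
               class = "envenomr_invalid_argument")

  # zero snake abundance and no spatial effect: hazard 0, all counts 0
  t0 <- truth
  t0$species$abundance$value <- 0
  t0$rho <- rep(0, truth$lattice$n_cells)
  expect_true(all(simulate_incidence(t0, 2010, seed = 2)$y == 0))

  # Monte Carlo mean of replicate draws matches Delta-He within 3 SE
  reps <- vapply(1:200, function(s) simulate_incidence(truth, 2010, seed = s)$y,
                 numeric(truth$lattice$n_cells))
  mc_mean <- rowMeans(reps)
  mc_se <- sqrt(pmax(obs$mu, 1e-9) / 200)   # Poisson variance = mean
  in3 <- abs(mc_mean - obs$mu) <= 3 * mc_se + 1e-9
  expect_gt(mean(in3), 0.98)
})

test_that("fixtures round-trip exactly and detect tampering", {
  truth <- small_truth()
  dir <- withr::local_tempdir()
  man <- write_fixture(truth, dir)
  expect_equal(man$seed, truth$seed)

  back <- read_fixture(dir)
  expect_equal(back$climate$tmax, truth$climate$tmax, tolerance = 1e-12)
  expect_equal(back$population$density, truth$population$density,
               tolerance = 1e-12)
  expect_identical(as.character(back$landcover$class),
                   as.character(truth$landcover$class))
  expect_equal(back$rho, truth$rho, tolerance = 1e-12)
  expect_equal(back$params$c, truth$params$c)

  # tampering breaks the checksum validation
  f <- file.path(dir, "rho.csv")
  writeLines(c(readLines(f)[1], "1,999"), f)
  expect_error(read_fixture(dir), class = "envenomr_validation_error")
})
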