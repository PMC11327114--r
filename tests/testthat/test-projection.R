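test_that("block-sum upscaling conserves totals and matches a block loop", {
  lat <- make_lattice(20, 20)
  ones <- tibble::tibble(cell = 1:400, value = 1)
  up <- upscale_sum(ones, lat, 5)
  expect_true(all(up$layer$value == 25))
  expect_equal(up$lattice$n_cells, 16L)

  set.seed(71)
  rl <- tibble::tibble(cell = 1:400, value = rnorm(400))
  upr <- upscale_sum(rl, lat, 5)
  expect_equal(sum(upr$layer$value), sum(rl$value), tolerance = 1e-12)
  # naive block loop oracle
  m <- matrix(rl$value[order(rl$cell)], 20, 20, byrow = TRUE)
  for (bc in 1:16) {
    br <- (bc - 1) %/% 4 + 1; bl <- (bc - 1) %% 4 + 1
    want <- sum(m[((br - 1) * 5 + 1):(br * 5), ((bl - 1) * 5 + 1):(bl * 5)])
    expect_equal(upr$layer$value[bc], want, tolerance = 1e-12)
  }
  lat18 <- make_lattice(18, 20)
  expect_error(upscale_sum(tibble::tibble(cell = 1:360, value = 1), lat18, 5),
               class = "envenomr_invalid_argument")
})

test_that("majority-vote upscaling picks the modal class with low-index ties", {
  lat <- make_lattice(20, 20)
  cls <- rep("tea", 400)
  m <- matrix(cls, 20, 20, byrow = TRUE)
  # first block: 13 forest / 12 urban -> forest
  blk <- c(rep("forest", 13), rep("urban", 12))
  m[1:5, 1:5] <- matrix(blk, 5, 5)
  # second block: 12 forest / 12 urban / 1 tea -> tie at 12 -> forest
  blk2 <- c(rep("forest", 12), rep("urban", 12), "tea")
  m[1:5, 6:10] <- matrix(blk2, 5, 5)
  lc <- tibble::tibble(cell = 1:400,
                       class = factor(as.character(t(m)),
                                      levels = landcover_classes()))
  up <- upscale_majority(lc, lat, 5)
  expect_equal(as.character(up$layer$class[1]), "forest")
  expect_equal(as.character(up$layer$class[2]), "forest")
  expect_equal(as.character(up$layer$class[16]), "tea")

  # brute-force counting oracle on a random map
  set.seed(72)
  lcr <- tibble::tibble(cell = 1:400,
                        class = factor(sample(landcover_classes(), 400, TRUE),
                                       levels = landcover_classes()))
  upr <- upscale_majority(lcr, lat, 5)
  mm <- matrix(match(as.character(lcr$class), landcover_classes()),
               20, 20, byrow = TRUE)
  for (bc in c(1, 7, 16)) {
    br <- (bc - 1) %/% 4 + 1; bl <- (bc - 1) %% 4 + 1
    cnt <- tabulate(mm[((br - 1) * 5 + 1):(br * 5), ((bl - 1) * 5 + 1):(bl * 5)], 5)
    expect_equal(as.character(upr$layer$class[bc]),
                 landcover_classes()[which.max(cnt)])
  }
})

test_that("pixel trends equal closed-form OLS slopes", {
  flat <- tidyr::expand_grid(year = 2010:2014, cell = 1:9) |>
    dplyr::mutate(incidence = 7)
  expect_true(all(pixel_trend(flat)$slope == 0))

  lin <- tidyr::expand_grid(year = 2010:2012, cell = 1:4) |>
    dplyr::mutate(incidence = year - 2009)
  expect_equal(pixel_trend(lin)$slope, rep(1, 4))

  set.seed(73)
  rnd <- tidyr::expand_grid(year = 2010:2020, cell = 1:9) |>
    dplyr::mutate(incidence = rnorm(dplyr::n()))
  tr <- pixel_trend(rnd)
  for (cl in c(1, 5, 9)) {
    d <- rnd[rnd$cell == cl, ]
    expect_equal(tr$slope[tr$cell == cl],
                 unname(coef(lm(incidence ~ year, d))[2]), tolerance = 1e-10)
  }
  expect_error(pixel_trend(dplyr::filter(lin, year < 2012)),
               class = "envenomr_invalid_argument")
})

test_that("percentage change follows the paper formula with zero-base masking", {
  a <- tibble::tibble(cell = 1:3, incidence = c(10, 5, 0))
  b <- tibble::tibble(cell = 1:3, incidence = c(8, 5, 2))
  pc <- pct_change(a, b)
  expect_equal(pc$pct_change[1], -20)
  expect_equal(pc$pct_change[2], 0)
  expect_true(is.na(pc$pct_change[3]))
})

test_that("national accumulated change and its standard error are exact OLS", {
  yrs <- 2010:2050
  # exactly linear decline of 0.5% of baseline per year: -20% by 2050
  rate <- 0.1 * (1 - 0.005 * (yrs - 2010))
  series <- tidyr::expand_grid(year = yrs, cell = 1:4) |>
    dplyr::mutate(incidence = rate[match(year, yrs)] * 250)
  H <- tidyr::expand_grid(year = yrs, cell = 1:4) |>
    dplyr::mutate(H = 1000)
  ns <- national_series(series, H)
  expect_equal(tail(ns$accum_pct, 1), -20, tolerance = 1e-9)
  expect_equal(tail(ns$se, 1), 0, tolerance = 1e-9)

  # noisy series: slope SE equals the textbook OLS formula
  set.seed(74)
  noisy <- dplyr::mutate(series,
                         incidence = incidence + rnorm(dplyr::n(), 0, 2))
  nn <- national_series(noisy, H)
  agg <- noisy |>
    dplyr::group_by(year) |>
    dplyr::summarise(rate = sum(incidence) / 4000)
  fit <- lm(rate ~ year, agg)
  se <- summary(fit)$coefficients["year", "Std. Error"]
  base <- unname(predict(fit, newdata = data.frame(year = 2010)))
  expect_equal(tail(nn$se, 1), 100 * se * 40 / abs(base), tolerance = 1e-9)
  expect_error(national_series(dplyr::filter(series, year < 2012), H),
               class = "envenomr_invalid_argument")
})

test_that("RCM consensus counts strictly negative slopes", {
  neg <- tibble::tibble(cell = 1:9, slope = -1)
  cons3 <- rcm_consensus(list(neg, neg, neg))
  expect_true(all(cons3$consensus$n_decreasing == 3))
  expect_equal(cons3$fractions$fraction[cons3$fractions$n_decreasing == 3], 1)

  zero <- tibble::tibble(cell = 1:9, slope = 0)
  expect_true(all(rcm_consensus(list(zero))$consensus$n_decreasing == 0))

  set.seed(75)
  sls <- purrr::map(1:3, ~ tibble::tibble(cell = 1:9, slope = rnorm(9)))
  out <- rcm_consensus(sls)
  want <- rowSums(vapply(sls, function(s) s$slope < 0, logical(9)))
  expect_equal(out$consensus$n_decreasing, unname(want))
  expect_equal(sum(out$fractions$fraction), 1)
  expect_error(rcm_consensus(list()), class = "envenomr_invalid_argument")
})

test_that("dominant species maximises the coefficient-weighted index", {
  p <- envenoming_params(rep(0, 5), rep(0, 5), c(2, 1, rep(1, 5)), 0,
                         rep(0, 5), rep(0, 7))
  S <- tidyr::expand_grid(species = default_species(), cell = 1:4) |>
    dplyr::mutate(value = ifelse(species %in% default_species()[1:2], 1, 0))
  d <- dominant_species(S, p)
  expect_true(all(d$species == default_species()[1]))

  set.seed(76)
  Sr <- tidyr::expand_grid(species = default_species(), cell = 1:9) |>
    dplyr::mutate(value = rexp(dplyr::n()))
  pr <- rand_params(77)
  dr <- dominant_species(Sr, pr, weighting = "full")
  Sm <- matrix(0, 9, 7)
  for (k in 1:7) Sm[, k] <- Sr$value[Sr$species == default_species()[k]]
  w <- pr$c * exp(pr$b)
  expect_equal(as.integer(dr$species), unname(max.col(sweep(Sm, 2, w, `*`),
                                                      ties.method = "first")))
})

test_that("transition summaries aggregate percentage change by class pair", {
  lcA <- tibble::tibble(cell = 1:9, class = factor("forest",
                                                   levels = landcover_classes()))
  pct0 <- tibble::tibble(cell = 1:9, pct_change = 0)
  t1 <- transition_change_summary(lcA, lcA, pct0)
  expect_equal(nrow(t1), 1L)
  expect_equal(as.character(t1$from), "forest")
  expect_equal(t1$median, 0)

  # hand-built toy with three transitions
  lcB <- tibble::tibble(
    cell = 1:9,
    class = factor(c(rep("forest", 3), rep("agriculture", 3), rep("urban", 3)),
                   levels = landcover_classes()))
  pct <- tibble::tibble(cell = 1:9, pct_change = c(10, 20, 30, -10, -20, -30,
                                                   5, 5, 8))
  t2 <- transition_change_summary(lcA, lcB, pct)
  expect_equal(nrow(t2), 3L)
  f2a <- t2[t2$to == "agriculture", ]
  expect_equal(f2a$n, 3L)
  expect_equal(f2a$median, -20)
  expect_equal(t2$median[t2$to == "urban"], 5)
  expect_lte(nrow(t2), 25L)
})

test_that("scenario pairings enforce the SSP-RCP-RCM design", {
  expect_error(scenario("SSP1", "GFDL-CM3"), class = "envenomr_invalid_argument")
  expect_error(scenario("SSP2", "historical-trend"),
               class = "envenomr_invalid_argument")
  s1 <- scenario("SSP1")
  expect_equal(s1$rcp_id, "none")
  expect_equal(s1$rcm_id, "historical-trend")
  s5 <- scenario("SSP5", "MPI-ESM-LR")
  expect_equal(s5$rcp_id, "RCP8.5")
  expect_gt(s5$trend$warming_per_decade, scenario("SSP2", "MPI-ESM-LR")$trend$warming_per_decade)
})
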