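test_that("parameter counts match the five-class seven-species design", {
  p <- default_params()
  expect_equal(n_bite_parameters(p), 17L)
  expect_equal(n_envenoming_parameters(p), 13L)
  expect_error(envenoming_params(rep(0, 4), rep(0, 5), rep(0, 7), 0,
                                 rep(0, 5), rep(0, 7)),
               class = "envenomr_invalid_argument")
  expect_error(envenoming_params(rep(0, 5), rep(0, 5), rep(-1, 7), 0,
                                 rep(0, 5), rep(0, 7)),
               class = "envenomr_invalid_argument")
  expect_error(envenoming_params(rep(0, 5), rep(0, 5), rep(1, 7), 0,
                                 rep(0, 5), rep(0, 7), tau = 0),
               class = "envenomr_invalid_argument")
})

test_that("contact rate is log-linear in log population with class terms", {
  lat <- make_lattice(5, 5)
  ly <- rand_layers(lat, 51)
  p0 <- envenoming_params(rep(0, 5), rep(0, 5), rep(1, 7), 0, rep(0, 5),
                          rep(0, 7))
  expect_true(all(contact_rate(ly$landcover, ly$H, p0)$beta == 1))

  p <- rand_params(52)
  beta <- contact_rate(ly$landcover, ly$H, p)$beta
  cls <- as.character(ly$landcover$class)
  # naive loop oracle
  for (i in c(1, 10, 25)) {
    expect_equal(beta[i],
                 unname(exp(p$beta0[cls[i]] +
                              p$beta1[cls[i]] * log1p(ly$H$density[i]))),
                 tolerance = 1e-12)
  }
  # negative slope: beta decreases in population within a class
  pneg <- envenoming_params(rep(0, 5), rep(-0.5, 5), rep(1, 7), 0, rep(0, 5),
                            rep(0, 7))
  bn <- contact_rate(ly$landcover, ly$H, pneg)$beta
  for (cl in landcover_classes()) {
    idx <- which(cls == cl)
    if (length(idx) > 2) {
      ord <- idx[order(ly$H$density[idx])]
      expect_true(all(diff(bn[ord]) <= 0))
    }
  }
})

test_that("hazard, bite and envenoming probabilities follow the closed forms", {
  lat <- make_lattice(5, 5)
  ly <- rand_layers(lat, 53)
  n <- lat$n_cells

  # beta = 1, one species with c = 2 and S = 3: hazard 6
  p1 <- envenoming_params(rep(0, 5), rep(0, 5), c(2, rep(0, 6)), 0,
                          rep(0, 5), rep(0, 7))
  S3 <- dplyr::mutate(ly$S, value = ifelse(species == default_species()[1], 3, 0))
  beta1 <- tibble::tibble(cell = seq_len(n), beta = 1)
  h <- bite_hazard(beta1, p1, S3, rho = rep(0, n))
  expect_true(all(h$hazard == 6))

  # zero abundance and rho: hazard 0; large negative rho floors at 0
  S0 <- dplyr::mutate(ly$S, value = 0)
  expect_true(all(bite_hazard(beta1, p1, S0, rep(0, n))$hazard == 0))
  expect_true(all(bite_hazard(beta1, p1, S0, rep(-10, n))$hazard == 0))

  # bite probability closed forms and limits
  expect_equal(bite_probability(tibble::tibble(cell = 1, hazard = 0))$p_bite, 0)
  expect_equal(bite_probability(tibble::tibble(cell = 1, hazard = log(2)))$p_bite,
               0.5, tolerance = 1e-12)
  expect_lt(bite_probability(tibble::tibble(cell = 1, hazard = 20))$p_bite, 1)
  expect_error(bite_probability(tibble::tibble(cell = 1, hazard = -1)),
               class = "envenomr_invalid_argument")

  # envenoming probability: logit-linear closed forms
  pe0 <- envenoming_probability(ly$landcover, S0, p1)
  expect_true(all(pe0$p_env == 0.5))
  p8 <- envenoming_params(rep(0, 5), rep(0, 5), rep(1, 7), qlogis(0.8),
                          rep(0, 5), rep(0, 7))
  expect_equal(envenoming_probability(ly$landcover, S0, p8)$p_env,
               rep(0.8, n), tolerance = 1e-12)
  # naive loop oracle on random inputs
  pr <- rand_params(54)
  pe <- envenoming_probability(ly$landcover, ly$S, pr)$p_env
  Sm <- matrix(0, n, 7)
  for (k in 1:7) {
    Sm[, k] <- ly$S$value[ly$S$species == default_species()[k]]
  }
  cls <- as.character(ly$landcover$class)
  for (i in c(2, 13, 25)) {
    eta <- pr$B0 + pr$B[cls[i]] + sum(pr$b * Sm[i, ])
    expect_equal(pe[i], unname(plogis(eta)), tolerance = 1e-12)
  }
})

test_that("expected incidence is the mass-action product and never exceeds H", {
  H <- tibble::tibble(cell = 1:3, density = c(1000, 10, 0))
  pb <- tibble::tibble(cell = 1:3, p_bite = c(0.1, 0, 0.9))
  pe <- tibble::tibble(cell = 1:3, p_env = c(0.5, 0.5, 0.99))
  inc <- expected_incidence(H, pb, pe)
  expect_equal(inc$incidence, c(50, 0, 0))
  expect_true(all(inc$incidence <= H$density))
  bad <- dplyr::mutate(pb, p_bite = 1.2)
  expect_error(expected_incidence(H, bad, pe),
               class = "envenomr_invalid_argument")
})

test_that("incidence is monotone in each species abundance", {
  lat <- make_lattice(5, 5)
  for (s in 1:10) {
    ly <- rand_layers(lat, 500 + s)
    p <- rand_params(600 + s)
    p$b <- abs(p$b)             # b >= 0 for the monotonicity property
    beta <- contact_rate(ly$landcover, ly$H, p)
    base <- expected_incidence(
      ly$H,
      bite_probability(bite_hazard(beta, p, ly$S, ly$rho)),
      envenoming_probability(ly$landcover, ly$S, p))
    k <- (s %% 7) + 1
    S_up <- dplyr::mutate(ly$S, value = value +
                            0.5 * (species == default_species()[k]))
    up <- expected_incidence(
      ly$H,
      bite_probability(bite_hazard(beta, p, S_up, ly$rho)),
      envenoming_probability(ly$landcover, S_up, p))
    expect_true(all(up$incidence >= base$incidence - 1e-12))
  }
})

test_that("CAR log-density matches hand sums and the dense Gaussian oracle", {
  lat <- make_lattice(3, 3)
  expect_equal(car_log_density(rep(0, 9), lat, 2), (9 - 1) / 2 * log(2))

  # hand computation of the pairwise quadratic form on the rook edges
  rho <- c(0.3, -0.1, 0.2, 0, -0.2, 0.1, -0.3, 0.05, -0.05)
  rho <- rho - mean(rho)
  edges <- rbind(c(1, 2), c(2, 3), c(4, 5), c(5, 6), c(7, 8), c(8, 9),
                 c(1, 4), c(4, 7), c(2, 5), c(5, 8), c(3, 6), c(6, 9))
  Q_hand <- sum((rho[edges[, 1]] - rho[edges[, 2]])^2)
  tau <- 1.7
  expect_equal(car_log_density(rho, lat, tau),
               (9 - 1) / 2 * log(tau) - tau / 2 * Q_hand, tolerance = 1e-12)

  # density ratios equal the dense pseudo-inverse multivariate normal oracle
  A <- as.matrix(lattice_adjacency_matrix(lat))
  L <- diag(rowSums(A)) - A
  set.seed(55)
  for (k in 1:5) {
    r1 <- rnorm(9); r1 <- r1 - mean(r1)
    r2 <- rnorm(9); r2 <- r2 - mean(r2)
    ours <- car_log_density(r1, lat, tau) - car_log_density(r2, lat, tau)
    oracle <- -tau / 2 * (drop(t(r1) %*% L %*% r1) - drop(t(r2) %*% L %*% r2))
    expect_equal(ours, oracle, tolerance = 1e-8)
  }

  expect_error(car_log_density(rep(1, 9), lat, 1),
               class = "envenomr_invalid_argument")  # not sum-to-zero
  expect_error(car_log_density(rho, lat, -1),
               class = "envenomr_invalid_argument")
})

test_that("CAR field sampler honours the constraint and the precision scale", {
  lat <- make_lattice(6, 6)
  r <- rcar_field(lat, tau = 4, seed = 5)
  expect_equal(sum(r), 0, tolerance = 1e-10)
  expect_identical(r, rcar_field(lat, tau = 4, seed = 5))
  r_small_tau <- vapply(1:30, function(s) sd(rcar_field(lat, 1, s)), numeric(1))
  r_big_tau <- vapply(1:30, function(s) sd(rcar_field(lat, 100, s)), numeric(1))
  expect_gt(mean(r_small_tau), 5 * mean(r_big_tau))
})

test_that("Poisson likelihood matches the scalar pmf and its edge cases", {
  expect_equal(log_likelihood(rep(0, 4), rep(1, 4)), -4)
  set.seed(56)
  y <- rpois(50, 5); mu <- rexp(50, 1 / 5)
  expect_equal(log_likelihood(y, mu), sum(dpois(y, mu, log = TRUE)),
               tolerance = 1e-12)
  # the likelihood at y = mu beats nearby means (mode property)
  expect_gt(log_likelihood(rep(4, 10), rep(4, 10)),
            log_likelihood(rep(4, 10), rep(5, 10)))
  expect_identical(log_likelihood(c(0, 2), c(1, 0)), -Inf)
  expect_error(log_likelihood(c(-1), c(1)), class = "envenomr_invalid_argument")
})
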