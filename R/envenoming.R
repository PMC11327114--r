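#' @title Mechanistic envenoming model
#' @description The snakebite envenoming incidence model: a mass-action
#'   bite process with land-cover- and population-dependent contact
#'   rates, species-specific contact and envenoming coefficients, an
#'   intrinsic CAR spatial effect, Poisson observation of counts,
#'   adaptive MCMC fitting, DIC, and spatially corrected posterior
#'   predictive checks.
#'
#' @details The expected incidence in cell `i` is
#'   \deqn{\Delta He_i = H_i \, (1 - e^{-h_i}) \, P_{env,i}}
#'   with hazard \eqn{h_i = \max(0,\; \beta_i \sum_s c_s S_{s,i} + \rho_i)},
#'   contact rate \eqn{\beta_i = \exp(\beta_{0,L_i} + \beta_{1,L_i}
#'   \log(1 + H^{2010}_i))} and envenoming probability
#'   \eqn{\mathrm{logit}(P_{env,i}) = B_0 + B_{L_i} + \sum_s b_s S_{s,i}}.
#'   With 5 land cover classes and 7 species the bite submodel has
#'   \eqn{2\cdot 5 + 7 = 17} free parameters and the envenoming submodel
#'   \eqn{1 + 5 + 7 = 13}.
#' @name envenoming_model
NULL

#' Envenoming model parameters
#'
#' @param beta0,beta1 Numeric length-5 (per land cover class, legend
#'   order): log contact-rate intercepts and slopes on `log(1 + H2010)`.
#' @param c Numeric length-7 (per species): non-negative species contact
#'   rates.
#' @param B0 Scalar envenoming intercept (logit scale).
#' @param B Numeric length-5: land-cover envenoming coefficients.
#' @param b Numeric length-7: species envenoming slopes.
#' @param tau Positive CAR precision.
#' @return An object of class `envenoming_params`.
#' @export
envenoming_params <- function(beta0, beta1, c, B0, B, b, tau = 1) {
  if (length(beta0) != 5L || length(beta1) != 5L || length(B) != 5L) {
    abort_invalid("`beta0`, `beta1`, `B` must have length 5 (one per class).")
  }
  if (length(c) != 7L || length(b) != 7L) {
    abort_invalid("`c` and `b` must have length 7 (one per species).")
  }
  if (any(c < 0)) abort_invalid("species contact rates `c` must be >= 0.")
  if (tau <= 0) abort_invalid("`tau` must be positive.")
  structure(list(
    beta0 = stats::setNames(as.numeric(beta0), landcover_classes()),
    beta1 = stats::setNames(as.numeric(beta1), landcover_classes()),
    c = stats::setNames(as.numeric(c), default_species()),
    B0 = as.numeric(B0),
    B = stats::setNames(as.numeric(B), landcover_classes()),
    b = stats::setNames(as.numeric(b), default_species()),
    tau = as.numeric(tau)
  ), class = "envenoming_params")
}

#' @export
print.envenoming_params <- function(x, ...) {
  cat(sprintf("<envenoming_params> bite submodel: %d parameters; envenoming submodel: %d parameters; tau = %.3g\n",
              n_bite_parameters(x), n_envenoming_parameters(x), x$tau))
  invisible(x)
}

#' Free parameter counts of the two submodels
#'
#' The bite submodel (class intercepts, class slopes, species contact
#' rates) has `2 |L| + |s|` free parameters; the envenoming submodel
#' (global intercept, class coefficients, species slopes) has
#' `1 + |L| + |s|`.
#'
#' @param params An [envenoming_params()] object.
#' @return Integer count.
#' @export
n_bite_parameters <- function(params) {
  length(params$beta0) + length(params$beta1) + length(params$c)
}

#' @rdname n_bite_parameters
#' @export
n_envenoming_parameters <- function(params) {
  1L + length(params$B) + length(params$b)
}

#' Default ("true") parameters of the synthetic study system
#'
#' Used by the synthetic-truth generator to forward-simulate envenoming
#' counts; also the target of the parameter-recovery experiments.
#'
#' @return An [envenoming_params()] object.
#' @export
default_params <- function() {
  envenoming_params(
    beta0 = c(-4.0, -3.8, -3.5, -4.2, -3.7),
    beta1 = c(0.10, 0.08, 0.15, 0.04, 0.12),
    c = c(2.0, 0.8, 2.5, 0.6, 3.0, 1.5, 0.8),
    B0 = -0.8,
    B = c(0.5, 0.3, -0.2, -0.6, 0.1),
    b = c(0.25, -0.15, 0.20, -0.10, 0.15, 0.10, -0.20),
    tau = 25
  )
}

# species abundance tibble -> n_cells x 7 matrix in default_species() order
species_matrix <- function(S, n_cells) {
  sp <- default_species()
  m <- matrix(NA_real_, n_cells, length(sp))
  si <- match(S$species, sp)
  if (any(is.na(si))) abort_invalid("unknown species in abundance set.")
  m[cbind(S$cell, si)] <- S$value
  if (any(is.na(m))) abort_invalid("abundance set does not cover all cells/species.")
  if (any(m < 0)) abort_invalid("abundance indices must be >= 0.")
  m
}

#' Human-snake contact rate surface
#'
#' `beta_i = exp(beta0[L_i] + beta1[L_i] * log(1 + H2010_i))`: a
#' log-linear contact rate in baseline (2010) population density with
#' class-specific intercept and slope.
#'
#' @param landcover Tibble `cell`, `class`.
#' @param H2010 Tibble `cell`, `density` (baseline population density).
#' @param params An [envenoming_params()] object.
#' @return A tibble `cell`, `beta` (> 0).
#' @export
contact_rate <- function(landcover, H2010, params) {
  cls <- as.character(layer_values_any(landcover, "class", nrow(landcover)))
  if (!all(cls %in% landcover_classes())) abort_invalid("unknown land cover class.")
  H <- layer_values_any(H2010, "density", nrow(landcover))
  if (any(H < 0)) abort_invalid("negative population density.")
  beta <- exp(params$beta0[cls] + params$beta1[cls] * log1p(H))
  tibble::tibble(cell = sort(landcover$cell), beta = unname(beta))
}

#' Bite hazard surface
#'
#' `h_i = max(0, beta_i * sum_s c_s S_si + rho_i)`: the mass-action
#' hazard, floored at zero so that the CAR effect cannot produce a
#' negative hazard.
#'
#' @param beta Tibble `cell`, `beta` from [contact_rate()].
#' @param params An [envenoming_params()] object.
#' @param S Abundance tibble `species`, `cell`, `value`.
#' @param rho Per-cell CAR effect: tibble `cell`, `rho`, or a numeric
#'   vector, or NULL for zero.
#' @return A tibble `cell`, `hazard` (>= 0).
#' @export
bite_hazard <- function(beta, params, S, rho = NULL) {
  n <- nrow(beta)
  bv <- layer_values_any(beta, "beta", n)
  Sm <- species_matrix(S, n)
  rv <- if (is.null(rho)) rep(0, n)
        else if (is.data.frame(rho)) layer_values_any(rho, "rho", n)
        else as.numeric(rho)
  if (length(rv) != n) abort_invalid("`rho` does not match the lattice.")
  h <- pmax(0, bv * as.numeric(Sm %*% params$c) + rv)
  tibble::tibble(cell = seq_len(n), hazard = h)
}

#' Bite probability from hazard
#'
#' `p = 1 - exp(-h)`, the mass-action probability that a person in the
#' cell is bitten during the period; strictly below 1 and monotone in the
#' hazard.
#'
#' @param h Tibble `cell`, `hazard` (all >= 0).
#' @return A tibble `cell`, `p_bite` in [0, 1).
#' @export
bite_probability <- function(h) {
  hv <- layer_values_any(h, "hazard", nrow(h))
  if (any(hv < 0)) abort_invalid("hazard must be >= 0.")
  # clamp so saturation at huge hazards keeps p strictly below 1
  tibble::tibble(cell = seq_len(nrow(h)),
                 p_bite = pmin(-expm1(-hv), 1 - 1e-12))
}

#' Envenoming probability surface
#'
#' `logit(P_env,i) = B0 + B[L_i] + sum_s b_s S_si`: the conditional
#' probability that a bite results in envenoming.
#'
#' @param landcover Tibble `cell`, `class`.
#' @param S Abundance tibble `species`, `cell`, `value`.
#' @param params An [envenoming_params()] object.
#' @return A tibble `cell`, `p_env` in (0, 1).
#' @export
envenoming_probability <- function(landcover, S, params) {
  n <- nrow(landcover)
  cls <- as.character(layer_values_any(landcover, "class", n))
  if (!all(cls %in% landcover_classes())) abort_invalid("unknown land cover class.")
  Sm <- species_matrix(S, n)
  eta <- params$B0 + params$B[cls] + as.numeric(Sm %*% params$b)
  # clamp to the open interval: plogis saturates at |eta| beyond ~37
  tibble::tibble(cell = seq_len(n),
                 p_env = pmin(pmax(stats::plogis(unname(eta)), 1e-12),
                              1 - 1e-12))
}

#' Expected envenoming incidence
#'
#' `Delta He_i = H_i * p_bite_i * P_env_i`: new envenoming cases per cell
#' per period, never exceeding the susceptible population.
#'
#' @param H Tibble `cell`, `density` (susceptible population).
#' @param p_bite Tibble `cell`, `p_bite`.
#' @param p_env Tibble `cell`, `p_env`.
#' @return A tibble `cell`, `incidence` with `0 <= incidence <= H`.
#' @export
expected_incidence <- function(H, p_bite, p_env) {
  n <- nrow(H)
  Hv <- layer_values_any(H, "density", n)
  pb <- layer_values_any(p_bite, "p_bite", n)
  pe <- layer_values_any(p_env, "p_env", n)
  if (any(Hv < 0)) abort_invalid("population must be >= 0.")
  if (any(pb < 0 | pb >= 1) || any(pe <= 0 | pe >= 1)) {
    abort_invalid("probabilities out of range.")
  }
  tibble::tibble(cell = seq_len(n), incidence = Hv * pb * pe)
}

# all-in-one forward evaluation on plain vectors (used by the sampler and
# the simulators); returns the per-cell expected incidence
forward_mu <- function(cls_idx, logH2010, Hsus, Smat, rho, p) {
  beta <- exp(p$beta0[cls_idx] + p$beta1[cls_idx] * logH2010)
  haz <- pmax(0, beta * as.numeric(Smat %*% p$c) + rho)
  penv <- stats::plogis(p$B0 + unname(p$B[cls_idx]) + as.numeric(Smat %*% p$b))
  Hsus * (-expm1(-haz)) * penv
}

#' Intrinsic CAR log-density
#'
#' Log-density of the sum-to-zero intrinsic CAR field up to an additive
#' constant: `((n-1)/2) log(tau) - (tau/2) * sum_(i~j) (rho_i - rho_j)^2`
#' over the unique rook edges (rank-deficient normaliser, hence `n - 1`).
#'
#' @param rho Numeric per-cell field summing to zero (tolerance 1e-6 of
#'   its scale).
#' @param lattice The [make_lattice()] geometry (connected).
#' @param tau Positive precision.
#' @return Scalar log-density (up to a constant).
#' @export
car_log_density <- function(rho, lattice, tau) {
  stopifnot(inherits(lattice, "env_lattice"))
  if (tau <= 0) abort_invalid("`tau` must be positive.")
  if (length(rho) != lattice$n_cells) abort_invalid("`rho` does not match lattice.")
  if (!lattice_connected(lattice)) abort_invalid("adjacency is disconnected.")
  if (abs(sum(rho)) > 1e-6 * max(1, max(abs(rho)))) {
    abort_invalid("`rho` must sum to zero (identifiability constraint).")
  }
  e <- lattice$edges
  Q <- sum((rho[e[, 1]] - rho[e[, 2]])^2)
  (lattice$n_cells - 1) / 2 * log(tau) - tau / 2 * Q
}

lattice_connected <- function(lattice) {
  n <- lattice$n_cells
  seen <- logical(n); seen[1] <- TRUE; frontier <- 1L
  while (length(frontier) > 0) {
    nxt <- unique(unlist(lattice$adjacency[frontier]))
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

#' Sample an intrinsic CAR field
#'
#' Draws one sum-to-zero field from the intrinsic CAR with precision
#' `tau` on the lattice, via the eigendecomposition of the graph
#' Laplacian (the zero eigenvalue / constant eigenvector is dropped).
#'
#' @param lattice The [make_lattice()] geometry.
#' @param tau Positive precision.
#' @param seed Integer seed.
#' @return Numeric per-cell field with `sum(rho) == 0`.
#' @export
rcar_field <- function(lattice, tau, seed = 1L) {
  set.seed(derive_seed(seed, 6L))
  A <- as.matrix(lattice_adjacency_matrix(lattice))
  L <- diag(rowSums(A)) - A
  ev <- eigen(L, symmetric = TRUE)
  n <- lattice$n_cells
  keep <- seq_len(n - 1)          # drop the null (constant) eigenvector
  z <- stats::rnorm(n - 1)
  rho <- ev$vectors[, keep, drop = FALSE] %*% (z / sqrt(tau * ev$values[keep]))
  as.numeric(rho - mean(rho))
}

#' Poisson log-likelihood of observed envenoming counts
#'
#' @param y Non-negative integer counts per cell.
#' @param mu Expected incidence per cell (`Delta He`); a zero mean with a
#'   positive count yields `-Inf`.
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(y, mu) {
  if (length(y) != length(mu)) abort_invalid("`y` and `mu` differ in length.")
  if (any(y < 0) || any(mu < 0)) abort_invalid("negative counts or means.")
  sum(pois_ll(y, mu, lgamma(y + 1)))
}

# elementwise poisson log-pmf with precomputed lgamma(y+1)
pois_ll <- function(y, mu, lg) {
  ll <- y * log(mu) - mu - lg
  bad <- mu <= 0
  if (any(bad)) ll[bad] <- ifelse(y[bad] == 0, 0, -Inf)
  ll
}

#' Default priors for the envenoming model
#'
#' Normal(0, 10^2) on all fixed effects on their linear scales,
#' half-Normal(0, 5) on the species contact rates `c_s`, Gamma(1, 0.01)
#' on the CAR precision `tau`.
#'
#' @param fixed_sd,c_sd,tau_shape,tau_rate Prior hyperparameters.
#' @return A list of class `prior_spec`.
#' @export
default_priors <- function(fixed_sd = 10, c_sd = 5, tau_shape = 1,
                           tau_rate = 0.01) {
  structure(list(fixed_sd = fixed_sd, c_sd = c_sd,
                 tau_shape = tau_shape, tau_rate = tau_rate),
            class = "prior_spec")
}
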