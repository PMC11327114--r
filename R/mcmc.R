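#' Fit the envenoming model by adaptive MCMC
#'
#' Adaptive random-walk Metropolis-within-Gibbs over the 30 fixed effects
#' (`beta0`, `beta1`, `c`, `B0`, `B`, `b`), with: a Gibbs update of the
#' CAR precision `tau`; single-site random-walk updates of the CAR field
#' `rho` performed in the two colour classes of the bipartite rook
#' lattice (sites within a colour are conditionally independent, so the
#' colour block is updated in one vectorised sweep with per-site
#' accept/reject) and re-centred to sum to zero after every scan; and two
#' low-cost "ridge" moves along the weakly identified directions (a
#' joint shift of `B0` against all `B[l]`, and a joint rescaling of all
#' `c_s` against the `beta0` intercepts) that leave the likelihood
#' invariant and are accepted on the prior ratio alone.  Step sizes adapt
#' during warmup towards an acceptance rate of 0.35.
#'
#' @param obs Tibble `cell`, `y` (counts), `H` (susceptible population).
#' @param S Abundance tibble `species`, `cell`, `value`.
#' @param landcover Tibble `cell`, `class`.
#' @param H2010 Tibble `cell`, `density` (baseline density entering the
#'   contact rate).
#' @param lattice The [make_lattice()] geometry.
#' @param priors A [default_priors()] object.
#' @param n_chains Number of chains (>= 2).
#' @param n_iter Iterations per chain; the first half is warmup.
#' @param seed Master seed (chain `k` uses stream `10 + k`).
#' @param init Optional named list overriding the default initial values.
#' @return An object of class `envenoming_fit` with posterior draws,
#'   summaries (median, 90% interval, split-Rhat, effective sample
#'   size), DIC, the posterior mean CAR field, and the posterior median
#'   expected incidence per cell.  Supports [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @export
fit_mcmc <- function(obs, S, landcover, H2010, lattice,
                     priors = default_priors(), n_chains = 3L,
                     n_iter = 20000L, seed = 1L, init = NULL) {
  stopifnot(inherits(lattice, "env_lattice"))
  if (n_chains < 2) abort_invalid("need at least 2 chains.")
  if (n_iter < 200) abort_invalid("`n_iter` too small.")
  n <- lattice$n_cells
  y <- layer_values_any(obs, "y", n)
  Hsus <- layer_values_any(obs, "H", n)
  if (any(y < 0) || any(y > Hsus)) abort_invalid("need 0 <= y <= H.")
  cls <- as.character(layer_values_any(landcover, "class", n))
  cls_idx <- match(cls, landcover_classes())
  logH <- log1p(layer_values_any(H2010, "density", n))
  Smat <- species_matrix(S, n)
  lg <- lgamma(y + 1)

  # colour classes of the rook lattice (checkerboard)
  cellrow <- ((seq_len(n) - 1L) %/% lattice$n_cols) + 1L
  cellcol <- ((seq_len(n) - 1L) %% lattice$n_cols) + 1L
  colour <- (cellrow + cellcol) %% 2L
  colour_idx <- list(which(colour == 0L), which(colour == 1L))
  A <- lattice_adjacency_matrix(lattice)
  deg <- as.numeric(Matrix::rowSums(A))
  class_idx <- lapply(seq_len(5L), function(l) which(cls_idx == l))

  par_names <- c(paste0("beta0[", landcover_classes(), "]"),
                 paste0("beta1[", landcover_classes(), "]"),
                 paste0("c[", default_species(), "]"),
                 "B0",
                 paste0("B[", landcover_classes(), "]"),
                 paste0("b[", default_species(), "]"),
                 "tau")
  warmup <- n_iter %/% 2L
  n_save <- n_iter - warmup
  mu_thin <- max(1L, n_save %/% 300L)

  chains <- vector("list", n_chains)
  for (ch in seq_len(n_chains)) {
    chains[[ch]] <- run_chain(
      y = y, Hsus = Hsus, cls_idx = cls_idx, logH = logH, Smat = Smat,
      lg = lg, class_idx = class_idx, colour_idx = colour_idx, A = A,
      deg = deg, edges = lattice$edges, priors = priors,
      n_iter = n_iter, warmup = warmup, mu_thin = mu_thin,
      seed = derive_seed(seed, 10L + ch), init = init, jitter = (ch - 1) * 0.1
    )
  }

  draws <- lapply(chains, `[[`, "draws")
  for (k in seq_along(draws)) colnames(draws[[k]]) <- par_names
  rhat <- vapply(seq_along(par_names), function(j)
    split_rhat(lapply(draws, function(m) m[, j])), numeric(1))
  ess <- vapply(seq_along(par_names), function(j)
    sum(vapply(draws, function(m) ess_chain(m[, j]), numeric(1))), numeric(1))
  all_draws <- do.call(rbind, draws)
  summ <- tibble::tibble(
    term = par_names,
    median = apply(all_draws, 2, stats::median),
    q5 = apply(all_draws, 2, stats::quantile, 0.05),
    q95 = apply(all_draws, 2, stats::quantile, 0.95),
    rhat = rhat, ess = ess
  )

  # DIC focused on the expected incidence: pD = Dbar - D(posterior mean of
  # mu).  Evaluating D at the posterior-mean parameters instead can hit the
  # hazard floor (mu = 0 with y > 0, infinite deviance); the mean-mu focus
  # is the standard Poisson-mean parameterisation and is always finite.
  dev_all <- unlist(lapply(chains, `[[`, "deviance"))
  dbar <- mean(dev_all)
  rho_mean <- Reduce(`+`, lapply(chains, `[[`, "rho_sum")) / (n_save * n_chains)
  mu_mean <- Reduce(`+`, lapply(chains, `[[`, "mu_sum")) / (n_save * n_chains)
  d_hat <- -2 * sum(pois_ll(y, mu_mean, lg))
  p_d <- dbar - d_hat
  mu_draws <- do.call(rbind, lapply(chains, `[[`, "mu_draws"))
  mu_median <- apply(mu_draws, 2, stats::median)

  structure(list(
    draws = draws, par_names = par_names, summary = summ,
    dic = dbar + p_d, p_d = p_d, dbar = dbar,
    rho_mean = rho_mean, mu_median = mu_median,
    accept = lapply(chains, `[[`, "accept"),
    data = list(y = y, H = Hsus, cls_idx = cls_idx, logH = logH, Smat = Smat),
    lattice = lattice, n_iter = n_iter, warmup = warmup,
    n_chains = n_chains, seed = seed
  ), class = "envenoming_fit")
}

# one MCMC chain; see fit_mcmc for the scheme
run_chain <- function(y, Hsus, cls_idx, logH, Smat, lg, class_idx,
                      colour_idx, A, deg, edges, priors, n_iter, warmup,
                      mu_thin, seed, init, jitter = 0) {
  set.seed(seed)
  n <- length(y)
  st <- list(beta0 = rep(-1, 5) + stats::rnorm(5, 0, 0.1 + jitter),
             beta1 = rep(0.05, 5) + stats::rnorm(5, 0, 0.02),
             c = pmax(rep(0.05, 7) + stats::rnorm(7, 0, 0.01), 1e-4),
             B0 = stats::rnorm(1, 0, 0.2), B = stats::rnorm(5, 0, 0.2),
             b = stats::rnorm(7, 0, 0.05), tau = 1)
  if (!is.null(init)) for (nm in names(init)) st[[nm]] <- init[[nm]]
  rho <- rep(0, n)

  fsd <- priors$fixed_sd; csd <- priors$c_sd

  # caches
  beta <- exp(st$beta0[cls_idx] + st$beta1[cls_idx] * logH)
  M <- as.numeric(Smat %*% st$c)
  eta <- st$B0 + st$B[cls_idx] + as.numeric(Smat %*% st$b)
  haz <- pmax(0, beta * M + rho)
  mu <- Hsus * (-expm1(-haz)) * stats::plogis(eta)
  ll <- pois_ll(y, mu, lg)
  if (!all(is.finite(ll))) {
    rlang::abort("non-finite initial posterior (zero mean with positive count).",
                 class = "envenomr_initialization_error")
  }

  n_scalar <- 30L
  ls <- rep(log(0.1), n_scalar)      # log step sizes, adapted in warmup
  ls_rho <- log(0.5)
  ls_ridge <- c(log(0.3), log(0.3))
  ls_pair <- rep(log(0.05), 5L)
  mean_logH <- vapply(class_idx, function(ii)
    if (length(ii)) mean(logH[ii]) else 0, numeric(1))
  acc_count <- numeric(n_scalar + 3L)

  n_save <- n_iter - warmup
  draws <- matrix(NA_real_, n_save, 31L)
  deviance <- numeric(n_save)
  rho_sum <- numeric(n)
  mu_sum <- numeric(n)
  mu_draws <- matrix(NA_real_, length(seq(1L, n_save, by = mu_thin)), n)
  mu_row <- 0L

  # scalar parameter metadata: family, index-within, prior sd
  fam <- c(rep("beta0", 5), rep("beta1", 5), rep("c", 7), "B0",
           rep("B", 5), rep("b", 7))
  wit <- c(1:5, 1:5, 1:7, 1L, 1:5, 1:7)

  for (it in seq_len(n_iter)) {
    adapt <- it <= warmup
    gamma <- if (adapt) min(0.5, 3 / sqrt(it)) else 0

    for (j in seq_len(n_scalar)) {
      f <- fam[j]; k <- wit[j]
      old <- st[[f]][k]
      prop <- old + stats::rnorm(1, 0, exp(ls[j]))
      if (f == "c" && prop < 0) {       # reject outside half-normal support
        if (adapt) ls[j] <- ls[j] - gamma * 0.35
        next
      }
      if (f %in% c("beta0", "beta1")) {
        idx <- class_idx[[k]]
        if (length(idx) == 0) {       # class absent: posterior = prior
          a <- min(1, exp((old^2 - prop^2) / (2 * fsd^2)))
          if (stats::runif(1) < a) st[[f]][k] <- prop
          if (adapt) ls[j] <- ls[j] + gamma * (a - 0.35)
          next
        }
        b_new <- if (f == "beta0") exp(prop + st$beta1[k] * logH[idx])
                 else exp(st$beta0[k] + prop * logH[idx])
        haz_new <- pmax(0, b_new * M[idx] + rho[idx])
        mu_new <- Hsus[idx] * (-expm1(-haz_new)) * stats::plogis(eta[idx])
        ll_new <- pois_ll(y[idx], mu_new, lg[idx])
        dlp <- sum(ll_new) - sum(ll[idx]) + (old^2 - prop^2) / (2 * fsd^2)
        a <- accept_prob(dlp)
        if (stats::runif(1) < a) {
          st[[f]][k] <- prop
          beta[idx] <- b_new; haz[idx] <- haz_new; mu[idx] <- mu_new
          ll[idx] <- ll_new
          acc_count[j] <- acc_count[j] + 1
        }
      } else if (f == "c") {
        M_new <- M + (prop - old) * Smat[, k]
        haz_new <- pmax(0, beta * M_new + rho)
        mu_new <- Hsus * (-expm1(-haz_new)) * stats::plogis(eta)
        ll_new <- pois_ll(y, mu_new, lg)
        dlp <- sum(ll_new) - sum(ll) + (old^2 - prop^2) / (2 * csd^2)
        a <- accept_prob(dlp)
        if (stats::runif(1) < a) {
          st$c[k] <- prop
          M <- M_new; haz <- haz_new; mu <- mu_new; ll <- ll_new
          acc_count[j] <- acc_count[j] + 1
        }
      } else {                          # B0 / B / b: only eta changes
        if (f == "B0") { idx <- seq_len(n); eta_new <- eta + (prop - old) }
        else if (f == "B") {
          idx <- class_idx[[k]]
          if (length(idx) == 0) {
            a <- min(1, exp((old^2 - prop^2) / (2 * fsd^2)))
            if (stats::runif(1) < a) st$B[k] <- prop
            if (adapt) ls[j] <- ls[j] + gamma * (a - 0.35)
            next
          }
          eta_new <- eta[idx] + (prop - old)
        } else { idx <- seq_len(n); eta_new <- eta + (prop - old) * Smat[, k] }
        mu_new <- Hsus[idx] * (-expm1(-haz[idx])) * stats::plogis(eta_new)
        ll_new <- pois_ll(y[idx], mu_new, lg[idx])
        dlp <- sum(ll_new) - sum(ll[idx]) + (old^2 - prop^2) / (2 * fsd^2)
        a <- accept_prob(dlp)
        if (stats::runif(1) < a) {
          st[[f]][k] <- prop
          eta[idx] <- eta_new; mu[idx] <- mu_new; ll[idx] <- ll_new
          acc_count[j] <- acc_count[j] + 1
        }
      }
      if (adapt) ls[j] <- ls[j] + gamma * (a - 0.35)
      a <- 0
    }

    # per-class joint (beta0, beta1) move along their correlation direction:
    # beta1 += d, beta0 -= d * mean(logH) keeps the class-mean contact rate
    for (l in 1:5) {
      idx <- class_idx[[l]]
      if (length(idx) == 0) next
      d <- stats::rnorm(1, 0, exp(ls_pair[l]))
      b0_new <- st$beta0[l] - d * mean_logH[l]
      b1_new <- st$beta1[l] + d
      b_new <- exp(b0_new + b1_new * logH[idx])
      haz_new <- pmax(0, b_new * M[idx] + rho[idx])
      mu_new <- Hsus[idx] * (-expm1(-haz_new)) * stats::plogis(eta[idx])
      ll_new <- pois_ll(y[idx], mu_new, lg[idx])
      dlp <- sum(ll_new) - sum(ll[idx]) +
        (st$beta0[l]^2 - b0_new^2 + st$beta1[l]^2 - b1_new^2) / (2 * fsd^2)
      a <- accept_prob(dlp)
      if (stats::runif(1) < a) {
        st$beta0[l] <- b0_new; st$beta1[l] <- b1_new
        beta[idx] <- b_new; haz[idx] <- haz_new; mu[idx] <- mu_new
        ll[idx] <- ll_new
      }
      if (adapt) ls_pair[l] <- ls_pair[l] + gamma * (a - 0.35)
    }

    # ridge move 1: B0 + d, B - d  (eta invariant; prior ratio only)
    d <- stats::rnorm(1, 0, exp(ls_ridge[1]))
    dlp <- (st$B0^2 - (st$B0 + d)^2) / (2 * fsd^2) +
      sum(st$B^2 - (st$B - d)^2) / (2 * fsd^2)
    a <- min(1, exp(dlp))
    if (stats::runif(1) < a) {
      st$B0 <- st$B0 + d; st$B <- st$B - d
      acc_count[n_scalar + 1] <- acc_count[n_scalar + 1] + 1
    }
    if (adapt) ls_ridge[1] <- ls_ridge[1] + gamma * (a - 0.35)

    # ridge move 2: c * e^d, beta0 - d  (beta*M invariant; prior + Jacobian)
    d <- stats::rnorm(1, 0, exp(ls_ridge[2]))
    c_new <- st$c * exp(d)
    dlp <- sum(st$c^2 - c_new^2) / (2 * csd^2) +
      sum(st$beta0^2 - (st$beta0 - d)^2) / (2 * fsd^2) + 7 * d
    a <- min(1, exp(dlp))
    if (stats::runif(1) < a) {
      st$c <- c_new; st$beta0 <- st$beta0 - d
      beta <- beta * exp(-d); M <- M * exp(d)
      acc_count[n_scalar + 2] <- acc_count[n_scalar + 2] + 1
    }
    if (adapt) ls_ridge[2] <- ls_ridge[2] + gamma * (a - 0.35)

    # rho: vectorised single-site updates per checkerboard colour
    for (colr in 1:2) {
      idx <- colour_idx[[colr]]
      nbsum <- as.numeric(A %*% rho)[idx]
      r_old <- rho[idx]
      r_new <- r_old + stats::rnorm(length(idx), 0, exp(ls_rho))
      haz_new <- pmax(0, beta[idx] * M[idx] + r_new)
      mu_new <- Hsus[idx] * (-expm1(-haz_new)) * stats::plogis(eta[idx])
      ll_new <- pois_ll(y[idx], mu_new, lg[idx])
      dprior <- -st$tau / 2 * (deg[idx] * (r_new^2 - r_old^2) -
                                 2 * (r_new - r_old) * nbsum)
      dl <- ll_new - ll[idx] + dprior
      dl[is.na(dl)] <- -Inf
      acc <- log(stats::runif(length(idx))) < dl
      if (any(acc)) {
        ii <- idx[acc]
        rho[ii] <- r_new[acc]; haz[ii] <- haz_new[acc]
        mu[ii] <- mu_new[acc]; ll[ii] <- ll_new[acc]
      }
      mean_a <- mean(pmin(1, exp(dl)))
      if (adapt) ls_rho <- ls_rho + gamma * (mean_a - 0.35)
      acc_count[n_scalar + 3] <- acc_count[n_scalar + 3] + mean(acc) / 2
    }
    # re-centre to the sum-to-zero constraint, refresh caches
    m_rho <- mean(rho)
    if (abs(m_rho) > 1e-12) {
      rho_c <- rho - m_rho
      haz_c <- pmax(0, beta * M + rho_c)
      mu_c <- Hsus * (-expm1(-haz_c)) * stats::plogis(eta)
      ll_c <- pois_ll(y, mu_c, lg)
      if (all(is.finite(ll_c))) {   # never re-centre into a zero-density state
        rho <- rho_c; haz <- haz_c; mu <- mu_c; ll <- ll_c
      }
    }

    # Gibbs update of tau given rho
    Q <- sum((rho[edges[, 1]] - rho[edges[, 2]])^2)
    st$tau <- stats::rgamma(1, shape = priors$tau_shape + (n - 1) / 2,
                            rate = priors$tau_rate + Q / 2)

    if (it > warmup) {
      s <- it - warmup
      draws[s, ] <- c(st$beta0, st$beta1, st$c, st$B0, st$B, st$b, st$tau)
      deviance[s] <- -2 * sum(ll)
      rho_sum <- rho_sum + rho
      mu_sum <- mu_sum + mu
      if ((s - 1L) %% mu_thin == 0L) {
        mu_row <- mu_row + 1L
        mu_draws[mu_row, ] <- mu
      }
    }
  }
  list(draws = draws, deviance = deviance, rho_sum = rho_sum,
       mu_sum = mu_sum,
       mu_draws = mu_draws[seq_len(mu_row), , drop = FALSE],
       accept = acc_count / n_iter)
}

# NaN-safe Metropolis acceptance probability
accept_prob <- function(dlp) {
  if (is.na(dlp)) return(0)
  min(1, exp(dlp))
}

# split-Rhat over chains (each split in half)
split_rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(x) {
    h <- length(x) %/% 2
    list(x[seq_len(h)], x[(h + 1):(2 * h)])
  }), recursive = FALSE)
  m <- length(halves); nn <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- nn * stats::var(means)
  if (W <= 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

# effective sample size (Geyer initial positive sequence)
ess_chain <- function(x) {
  nn <- length(x)
  if (stats::var(x) == 0) return(0)
  ac <- stats::acf(x, lag.max = min(nn - 1, 200), plot = FALSE)$acf[, 1, 1]
  s <- 0
  k <- 2
  while (k < length(ac)) {
    pair <- ac[k] + ac[k + 1]
    if (is.na(pair) || pair < 0) break
    s <- s + pair
    k <- k + 2
  }
  nn / (1 + 2 * s)
}

#' @export
print.envenoming_fit <- function(x, ...) {
  cat(sprintf("<envenoming_fit> %d chains x %d iterations (%d warmup)\n",
              x$n_chains, x$n_iter, x$warmup))
  cat(sprintf("  DIC %.1f (pD %.1f); median split-Rhat %.3f\n",
              x$dic, x$p_d, stats::median(x$summary$rhat)))
  invisible(x)
}

#' @rdname fit_mcmc
#' @param x An `envenoming_fit` object.
#' @param ... Unused.
#' @export
tidy.envenoming_fit <- function(x, ...) x$summary

#' @rdname fit_mcmc
#' @export
glance.envenoming_fit <- function(x, ...) {
  tibble::tibble(dic = x$dic, p_d = x$p_d, dbar = x$dbar,
                 median_rhat = stats::median(x$summary$rhat),
                 min_ess = min(x$summary$ess),
                 n_draws = x$n_chains * (x$n_iter - x$warmup))
}

#' @rdname fit_mcmc
#' @param object An `envenoming_fit` object.
#' @param pars Parameters to plot (default: the first six).
#' @export
autoplot.envenoming_fit <- function(object, pars = NULL, ...) {
  if (is.null(pars)) pars <- object$par_names[c(1, 6, 11, 18, 19, 31)]
  df <- purrr::imap_dfr(object$draws, function(m, ch) {
    tibble::as_tibble(m[, pars, drop = FALSE]) |>
      dplyr::mutate(chain = factor(ch), .iter = dplyr::row_number()) |>
      tidyr::pivot_longer(dplyr::all_of(pars), names_to = "term")
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$.iter, .data$value,
                                   colour = .data$chain)) +
    ggplot2::geom_line(alpha = 0.7, linewidth = 0.2) +
    ggplot2::facet_wrap(~term, scales = "free_y") +
    ggplot2::labs(x = "post-warmup iteration", y = NULL) +
    ggplot2::theme_minimal()
}

#' Deviance information criterion of a fit
#'
#' `DIC = Dbar + pD` with `pD = Dbar - D(posterior mean)`, deviance
#' being minus twice the Poisson log-likelihood.
#'
#' @param fit An [fit_mcmc()] result.
#' @return Scalar DIC.
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "envenoming_fit"))
  fit$dic
}

#' Spatially corrected posterior predictive check
#'
#' Pearson correlation between observed counts and the posterior median
#' expected incidence, with a Monte Carlo p-value from a null that
#' preserves the spatial autocorrelation of the observed field: the
#' observed counts are rotated by random row/column shifts on the lattice
#' torus and the correlation recomputed for each rotation.
#'
#' @param fit An [fit_mcmc()] result.
#' @param n_mc Number of torus rotations (>= 99).
#' @param seed Integer seed.
#' @return A list with `r` and `p_mc`.
#' @export
posterior_predictive_check <- function(fit, n_mc = 999L, seed = 1L) {
  stopifnot(inherits(fit, "envenoming_fit"))
  if (n_mc < 99) abort_invalid("`n_mc` must be >= 99.")
  y <- fit$data$y
  mu <- fit$mu_median
  if (stats::sd(y) == 0 || stats::sd(mu) == 0) {
    rlang::abort("constant field: correlation undefined.",
                 class = "envenomr_undefined_correlation")
  }
  r <- stats::cor(y, mu)
  set.seed(derive_seed(seed, 7L))
  nr <- fit$lattice$n_rows; nc <- fit$lattice$n_cols
  ym <- matrix(y, nr, nc, byrow = TRUE)
  r_null <- numeric(n_mc)
  for (k in seq_len(n_mc)) {
    dr <- sample.int(nr, 1) - 1L; dc <- sample.int(nc, 1) - 1L
    if (dr == 0 && dc == 0) dr <- sample.int(nr - 1, 1)
    ys <- ym[c((dr + 1):nr, seq_len(dr))[seq_len(nr)],
             c((dc + 1):nc, seq_len(dc))[seq_len(nc)], drop = FALSE]
    r_null[k] <- stats::cor(as.numeric(t(ys)), mu)
  }
  list(r = r, p_mc = (1 + sum(r_null >= r)) / (n_mc + 1))
}

#' Residual summary of a fit
#'
#' Raw residuals: observed counts minus the posterior median expected
#' incidence, and their mean.
#'
#' @param fit An [fit_mcmc()] result.
#' @return A list with `mean` and a tibble `residuals` (`cell`, `resid`).
#' @export
residual_summary <- function(fit) {
  stopifnot(inherits(fit, "envenoming_fit"))
  resid <- fit$data$y - fit$mu_median
  list(mean = mean(resid),
       residuals = tibble::tibble(cell = seq_along(resid), resid = resid))
}
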