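#' @title Land cover change
#' @description A documented CLUE-style annual land cover allocator built
#'   from five inputs: class transition rules, optional annual pairwise
#'   change caps, logistic-regression location factors, per-class demand,
#'   and spatial restrictions.  Also provides the tree-cover category to
#'   proportion reclassification and the land-cover-derived covariates of
#'   the snake abundance models.
#' @name landcover_change
NULL

#' Transition rules for the land cover allocator
#'
#' @param allowed 5x5 logical matrix, `allowed[from, to]`, in legend order
#'   ([landcover_classes()]).  The diagonal (staying put) is always
#'   allowed and is forced `TRUE`.
#' @param restricted Logical vector over cells: restricted cells never
#'   change class.  Default: none.
#' @param n_cells Number of cells (needed when `restricted` is not
#'   given).
#' @return A list of class `transition_rules`.
#' @export
transition_rules <- function(allowed = NULL, restricted = NULL, n_cells = NULL) {
  k <- 5L
  if (is.null(allowed)) allowed <- matrix(TRUE, k, k)
  if (!is.matrix(allowed) || !all(dim(allowed) == k) || !is.logical(allowed)) {
    abort_invalid("`allowed` must be a 5x5 logical matrix.")
  }
  diag(allowed) <- TRUE
  if (is.null(restricted)) {
    if (is.null(n_cells)) abort_invalid("give `restricted` or `n_cells`.")
    restricted <- rep(FALSE, n_cells)
  }
  dimnames(allowed) <- list(landcover_classes(), landcover_classes())
  structure(list(allowed = allowed, restricted = restricted),
            class = "transition_rules")
}

#' Fit logistic-regression location factors
#'
#' For each land cover class, the probability of presence is modelled by
#' a maximum-likelihood logistic regression of the 0/1 presence of the
#' class on the driver layers.
#'
#' @param landcover Tibble `cell`, `class`.
#' @param drivers Tibble with `cell` plus one numeric column per driver.
#' @return An object of class `location_factors` holding the per-class
#'   coefficient vectors; supports [generics::tidy()].
#' @export
fit_location_factors <- function(landcover, drivers) {
  if (!all(c("cell", "class") %in% names(landcover))) {
    abort_invalid("`landcover` needs columns cell, class.")
  }
  dn <- setdiff(names(drivers), "cell")
  if (length(dn) < 1) abort_invalid("need at least one driver layer.")
  d <- dplyr::inner_join(landcover, drivers, by = "cell")
  tab <- table(factor(d$class, levels = landcover_classes()))
  if (any(tab < 10)) {
    abort_invalid(paste0("each class needs >= 10 cells; too few: ",
                         paste(names(tab)[tab < 10], collapse = ", ")))
  }
  fits <- purrr::map(landcover_classes(), function(cl) {
    d$.pres <- as.integer(d$class == cl)
    f <- stats::reformulate(dn, response = ".pres")
    fit <- withCallingHandlers(
      stats::glm(f, family = stats::binomial(), data = d,
                 control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
      warning = function(w) invokeRestart("muffleWarning")
    )
    # perfect separation: the deviance collapses to zero and the MLE
    # diverges; quasi-separation (saturated fitted values but positive
    # deviance) is kept, as usual for suitability regressions
    if (fit$deviance < 1e-6 || any(abs(stats::coef(fit)) > 1e3)) {
      rlang::abort(sprintf("perfect separation fitting class '%s'.", cl),
                   class = "envenomr_separation_error")
    }
    if (!fit$converged) {
      rlang::abort(sprintf("logistic fit for class '%s' did not converge.", cl),
                   class = "envenomr_convergence_error")
    }
    fit
  })
  names(fits) <- landcover_classes()
  structure(list(fits = fits, drivers = dn), class = "location_factors")
}

#' @export
print.location_factors <- function(x, ...) {
  cat("<location_factors> logistic suitability models for 5 classes on drivers:",
      paste(x$drivers, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname fit_location_factors
#' @param x A `location_factors` object.
#' @param ... Unused.
#' @export
tidy.location_factors <- function(x, ...) {
  purrr::imap_dfr(x$fits, function(fit, cl) {
    co <- summary(fit)$coefficients
    tibble::tibble(class = cl, term = rownames(co),
                   estimate = co[, 1], std.error = co[, 2])
  })
}

#' Per-class suitability probabilities
#'
#' Inverse-logit of each class's fitted linear predictor on the supplied
#' drivers.
#'
#' @param factors A [fit_location_factors()] object.
#' @param drivers Tibble `cell` plus the same driver columns used in the
#'   fit.
#' @return A tibble `cell`, `class`, `p` with `p` in (0, 1).
#' @export
suitability <- function(factors, drivers) {
  stopifnot(inherits(factors, "location_factors"))
  miss <- setdiff(factors$drivers, names(drivers))
  if (length(miss) > 0) {
    abort_invalid(paste0("missing driver columns: ", paste(miss, collapse = ", ")))
  }
  purrr::imap_dfr(factors$fits, function(fit, cl) {
    tibble::tibble(cell = drivers$cell, class = cl,
                   p = as.numeric(stats::predict(fit, newdata = drivers,
                                                 type = "response")))
  })
}

# suitability tibble -> n_cells x 5 logit matrix in legend order
suit_matrix <- function(suit, n_cells) {
  m <- matrix(NA_real_, n_cells, 5L)
  ci <- match(suit$class, landcover_classes())
  m[cbind(suit$cell, ci)] <- stats::qlogis(pmin(pmax(suit$p, 1e-12), 1 - 1e-12))
  if (any(is.na(m))) abort_invalid("suitability does not cover all cells/classes.")
  m
}

#' Allocate one year of land cover change
#'
#' Iterative competitive allocation in the CLUE-S style: each cell scores
#' every legal class as logit-suitability plus a conversion-elasticity
#' bonus for keeping its current class plus a per-class offset; cells take
#' their best-scoring class, and offsets are adjusted until allocated
#' counts match demand within `tol` cells.  A final exact repair pass
#' (cheapest legal reassignments, followed by profitable swap polishing)
#' enforces the demand exactly when `tol = 0`.
#'
#' @param current Tibble `cell`, `class` (the map being updated).
#' @param suit Suitability tibble from [suitability()].
#' @param demand Named integer vector (legend order or named by class) of
#'   target cell counts; must sum to the number of allocatable cells.
#' @param rules A [transition_rules()] object.
#' @param elasticity Per-class conversion resistance added to the score of
#'   staying in the current class (length 5 or scalar; default 0.5).
#' @param tol Allowed absolute deviation from demand, in cells (default 1).
#' @param max_iter Offset-adjustment iteration cap (default 1000).
#' @return A tibble `cell`, `class`.
#' @export
allocate_year <- function(current, suit, demand, rules,
                          elasticity = 0.5, tol = 1L, max_iter = 1000L) {
  classes <- landcover_classes()
  n <- nrow(current)
  cur <- match(layer_values_any(current, "class", n), classes)
  if (!is.null(names(demand))) demand <- demand[classes]
  demand <- as.integer(round(demand))
  if (length(demand) != 5L || any(is.na(demand))) {
    abort_invalid("`demand` must give a count for each of the 5 classes.")
  }
  if (length(elasticity) == 1L) elasticity <- rep(elasticity, 5L)
  restricted <- rules$restricted
  if (length(restricted) != n) abort_invalid("restriction mask does not match lattice.")
  free <- which(!restricted)
  # restricted cells keep their class and consume demand
  demand_free <- demand - tabulate(cur[restricted], 5L)
  if (any(demand_free < 0)) {
    abort_invalid("demand below the count fixed by restricted cells.")
  }
  if (sum(demand_free) != length(free)) {
    abort_invalid("demand must sum to the number of allocatable cells.")
  }

  score <- suit_matrix(suit, n)[free, , drop = FALSE]
  curf <- cur[free]
  score[cbind(seq_along(free), curf)] <-
    score[cbind(seq_along(free), curf)] + elasticity[curf]
  legal <- rules$allowed[curf, , drop = FALSE]       # nf x 5 logical
  score[!legal] <- -Inf
  if (any(demand_free > 0 & colSums(legal) == 0)) {
    rlang::abort("demand cannot be met: no legal source cells for a class.",
                 class = "envenomr_nonconvergence_error")
  }

  # iterative competitive allocation: adjust per-class offsets until the
  # allocated counts match demand; steps shrink on oscillation
  offset <- rep(0, 5L)
  step <- 0.5
  last_gap <- rep(0L, 5L)
  alloc <- max.col(score, ties.method = "first")
  for (it in seq_len(max_iter)) {
    sc <- sweep(score, 2L, offset, `+`)
    alloc <- max.col(sc, ties.method = "first")      # lowest index wins ties
    counts <- tabulate(alloc, 5L)
    gap <- demand_free - counts
    if (max(abs(gap)) <= tol) break
    if (any(gap * last_gap < 0)) step <- step * 0.8 else step <- min(step * 1.1, 5)
    last_gap <- gap
    offset <- offset + step * gap / pmax(1, demand_free)
  }
  # exact repair meets the demand precisely (and raises a non-convergence
  # error when the transition rules make it infeasible)
  alloc <- repair_allocation(alloc, score, demand_free)
  out_class <- cur
  out_class[free] <- alloc
  tibble::tibble(cell = seq_len(n), class = factor(classes[out_class],
                                                   levels = classes))
}

# Exact repair to meet demand, then 2-swap / 3-cycle polish towards the
# maximum-total-score legal assignment.
repair_allocation <- function(alloc, score, demand) {
  counts <- tabulate(alloc, 5L)
  # move cheapest cells from surplus classes to deficit classes
  while (any(counts != demand)) {
    over <- which(counts > demand)
    under <- which(counts < demand)
    best <- NULL; best_loss <- Inf
    for (a in over) {
      idx <- which(alloc == a)
      for (b in under) {
        loss <- score[idx, a] - score[idx, b]
        ok <- is.finite(loss)
        if (!any(ok)) next
        j <- idx[ok][which.min(loss[ok])]
        l <- min(loss[ok])
        if (l < best_loss) { best_loss <- l; best <- c(j, b) }
      }
    }
    if (is.null(best)) {
      rlang::abort("demand cannot be met under the transition rules.",
                   class = "envenomr_nonconvergence_error")
    }
    counts[alloc[best[1]]] <- counts[alloc[best[1]]] - 1L
    alloc[best[1]] <- best[2]
    counts[best[2]] <- counts[best[2]] + 1L
  }
  # pairwise swap polish (keeps counts; only improves total score)
  repeat {
    improved <- FALSE
    for (a in 1:4) for (b in (a + 1):5) {
      ia <- which(alloc == a); ib <- which(alloc == b)
      if (length(ia) == 0 || length(ib) == 0) next
      # gain of moving i: a->b and j: b->a
      ga <- score[ia, b] - score[ia, a]
      gb <- score[ib, a] - score[ib, b]
      i <- ia[which.max(ga)]; j <- ib[which.max(gb)]
      if (is.finite(max(ga)) && is.finite(max(gb)) &&
          max(ga) + max(gb) > 1e-12) {
        alloc[i] <- b; alloc[j] <- a
        improved <- TRUE
      }
    }
    # 3-cycle polish a->b->c->a
    for (a in 1:5) for (b in 1:5) for (cc in 1:5) {
      if (length(unique(c(a, b, cc))) != 3) next
      ia <- which(alloc == a); ib <- which(alloc == b); ic <- which(alloc == cc)
      if (!length(ia) || !length(ib) || !length(ic)) next
      ga <- score[ia, b] - score[ia, a]
      gb <- score[ib, cc] - score[ib, b]
      gc <- score[ic, a] - score[ic, cc]
      if (is.finite(max(ga)) && is.finite(max(gb)) && is.finite(max(gc)) &&
          max(ga) + max(gb) + max(gc) > 1e-12) {
        alloc[ia[which.max(ga)]] <- b
        alloc[ib[which.max(gb)]] <- cc
        alloc[ic[which.max(gc)]] <- a
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  alloc
}

layer_values_any <- function(layer, col, n) {
  if (!is.data.frame(layer) || !all(c("cell", col) %in% names(layer)) ||
      nrow(layer) != n) {
    abort_invalid(sprintf("expected a tibble with columns cell, %s over %d cells.",
                          col, n))
  }
  layer[[col]][order(layer$cell)]
}

#' Simulate annual land cover change
#'
#' Year-by-year application of [allocate_year()] along a demand
#' trajectory, refreshing suitability from dynamic drivers each year when
#' a `drivers_by_year` function is supplied.
#'
#' @param start Tibble `cell`, `class` for the first year.
#' @param demand Tibble `year`, `class`, `cells` (target counts per class
#'   per year); each year must sum to the allocatable cell count.
#' @param factors A [fit_location_factors()] object.
#' @param drivers_by_year Either a tibble of static drivers (`cell` +
#'   driver columns) or a function `year -> drivers tibble`.
#' @param rules A [transition_rules()] object.
#' @param elasticity,tol,max_iter Passed to [allocate_year()].
#' @return A tibble `year`, `cell`, `class` (including the start year).
#' @export
simulate_landcover <- function(start, demand, factors, drivers_by_year, rules,
                               elasticity = 0.5, tol = 1L, max_iter = 1000L) {
  years <- sort(unique(demand$year))
  cur <- start
  out <- list(dplyr::mutate(cur, year = years[1], .before = 1))
  get_drivers <- if (is.function(drivers_by_year)) drivers_by_year else function(y) drivers_by_year
  for (y in years[-1]) {
    dem <- demand |> dplyr::filter(.data$year == y)
    dv <- setNames(dem$cells, as.character(dem$class))
    su <- suitability(factors, get_drivers(y))
    cur <- allocate_year(cur, su, dv, rules, elasticity, tol, max_iter)
    out[[length(out) + 1]] <- dplyr::mutate(cur, year = y, .before = 1)
  }
  dplyr::bind_rows(out)
}

#' Reclassify tree cover categories to proportions
#'
#' The five 20%-band categories are mapped to their band midpoints (0.10,
#' 0.30, 0.50, 0.70, 0.90) and rescaled by one factor so that the
#' study-area mean equals `reference_mean`, then clamped to [0, 0.99].
#'
#' @param tree Tibble `cell`, `category` (integers 1..5).
#' @param reference_mean Target study-area mean proportion, in (0, 0.99).
#' @return A tibble `cell`, `category`, `proportion`.
#' @export
categories_to_proportion <- function(tree, reference_mean) {
  if (!all(c("cell", "category") %in% names(tree))) {
    abort_invalid("`tree` needs columns cell, category.")
  }
  if (!all(tree$category %in% 1:5)) abort_invalid("categories must be in 1..5.")
  if (reference_mean <= 0 || reference_mean >= 0.99) {
    abort_invalid("`reference_mean` must lie in (0, 0.99).")
  }
  mid <- c(0.10, 0.30, 0.50, 0.70, 0.90)[tree$category]
  k <- reference_mean / mean(mid)
  tibble::tibble(cell = tree$cell, category = tree$category,
                 proportion = pmin(pmax(mid * k, 0), 0.99))
}

#' Land-cover-derived covariates
#'
#' The covariates feeding the snake abundance models: the proportion of
#' agriculture within a square neighbourhood, the Euclidean distance (km)
#' to the nearest forest cell (0 on forest cells), and the tree-cover
#' proportion pass-through.
#'
#' @param landcover Tibble `cell`, `class`.
#' @param tree Tibble `cell`, `proportion` (from
#'   [categories_to_proportion()]).
#' @param lattice The [make_lattice()] geometry.
#' @param neighbourhood Neighbourhood radius in cells (>= 1); the window
#'   is the (2r+1) x (2r+1) square, truncated at edges.
#' @return A tibble `cell`, `prop_agric`, `forest_dist`, `tree_prop`.
#'   When no forest exists anywhere, `forest_dist` is `Inf` with a
#'   warning.
#' @export
derived_covariates <- function(landcover, tree, lattice, neighbourhood = 1L) {
  if (neighbourhood < 1) abort_invalid("`neighbourhood` must be >= 1.")
  cls <- layer_values(landcover, lattice, "class")
  is_ag <- as.numeric(cls == "agriculture")
  m <- matrix(is_ag, lattice$n_rows, lattice$n_cols, byrow = TRUE)
  acc <- matrix(0, lattice$n_rows, lattice$n_cols)
  cnt <- matrix(0, lattice$n_rows, lattice$n_cols)
  for (dr in -neighbourhood:neighbourhood) {
    rs <- max(1, 1 + dr):min(lattice$n_rows, lattice$n_rows + dr); rt <- rs - dr
    for (dc in -neighbourhood:neighbourhood) {
      cs <- max(1, 1 + dc):min(lattice$n_cols, lattice$n_cols + dc); ct <- cs - dc
      acc[rt, ct] <- acc[rt, ct] + m[rs, cs]
      cnt[rt, ct] <- cnt[rt, ct] + 1
    }
  }
  prop_ag <- as.numeric(t(acc / cnt))
  is_forest <- cls == "forest"
  if (!any(is_forest)) {
    rlang::warn("no forest cells anywhere: forest_dist is Inf.")
  }
  fdist <- distance_to_class(lattice, is_forest)
  tp <- layer_values_any(tree, "proportion", lattice$n_cells)
  tibble::tibble(cell = seq_len(lattice$n_cells),
                 prop_agric = prop_ag, forest_dist = fdist, tree_prop = tp)
}
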