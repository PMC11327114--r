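#' @title Configuration and pipeline orchestration
#' @description YAML-driven configuration with schema validation, and a
#'   run_pipeline() orchestrator binding the synth, fit, project and
#'   summarize stages with a JSON manifest (seeds, checksums, timing)
#'   for reproducibility.
#' @name cli_config
NULL

config_schema <- function() {
  list(
    seed = "integer",
    lattice = list(n_rows = "integer", n_cols = "integer", cell_size = "number"),
    years = list(from = "integer", to = "integer"),
    scenarios = "list",
    model = list(n_chains = "integer", n_iter = "integer",
                 priors = list(fixed_sd = "number", c_sd = "number",
                               tau_shape = "number", tau_rate = "number")),
    stages = list(synth = "logical", fit = "logical", project = "logical",
                  summarize = "logical")
  )
}

default_config <- function() {
  list(
    seed = 1L,
    lattice = list(n_rows = 20L, n_cols = 20L, cell_size = 1),
    years = list(from = 2010L, to = 2050L),
    scenarios = list(list(ssp = "SSP1", rcm = "historical-trend")),
    model = list(n_chains = 2L, n_iter = 2000L,
                 priors = list(fixed_sd = 10, c_sd = 5,
                               tau_shape = 1, tau_rate = 0.01)),
    stages = list(synth = TRUE, fit = TRUE, project = TRUE, summarize = TRUE)
  )
}

check_keys <- function(cfg, schema, path = "") {
  bad <- setdiff(names(cfg), names(schema))
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown config key(s): ",
                        paste0(path, bad, collapse = ", ")),
                 class = "envenomr_config_error")
  }
  for (nm in names(cfg)) {
    if (is.list(schema[[nm]]) && nm != "scenarios") {
      if (!is.list(cfg[[nm]])) {
        rlang::abort(sprintf("config key '%s%s' must be a mapping.", path, nm),
                     class = "envenomr_config_error")
      }
      check_keys(cfg[[nm]], schema[[nm]], paste0(path, nm, "."))
    }
  }
  invisible(TRUE)
}

merge_config <- function(defaults, cfg) {
  for (nm in names(cfg)) {
    defaults[[nm]] <- if (is.list(cfg[[nm]]) && is.list(defaults[[nm]]) &&
                          nm != "scenarios") {
      merge_config(defaults[[nm]], cfg[[nm]])
    } else cfg[[nm]]
  }
  defaults
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file, rejects unknown keys, fills defaults, and attaches
#' a provenance block (package version and master seed).
#'
#' @param path YAML file path.
#' @return A validated config list of class `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("config file '%s' not found.", path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  check_keys(cfg, config_schema())
  cfg <- merge_config(default_config(), cfg)
  cfg$provenance <- list(
    package = "envenomr",
    version = as.character(utils::packageVersion("envenomr")),
    seed = cfg$seed
  )
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("<run_config> seed %d, %dx%d lattice, years %d-%d, %d scenario(s)\n",
              x$seed, x$lattice$n_rows, x$lattice$n_cols,
              x$years$from, x$years$to, length(x$scenarios)))
  invisible(x)
}

#' Run the full pipeline
#'
#' Executes the toggled stages in order — synth (generate and write the
#' synthetic study system), fit (simulate baseline incidence and fit the
#' envenoming model), project (run every configured scenario) and
#' summarize (national series and percentage-change tables) — and writes
#' a JSON manifest with per-stage status, seeds, timing and output file
#' checksums.  Stages whose outputs already exist are skipped
#' (resumable) unless `overwrite = TRUE`.
#'
#' @param config A [load_config()] object (or a path to a YAML file).
#' @param out_dir Output directory.
#' @param overwrite Re-run stages whose outputs exist (default FALSE).
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config, out_dir, overwrite = FALSE) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed, provenance = config$provenance,
                   stages = list())
  mpath <- file.path(out_dir, "manifest.json")
  truth <- NULL; fit <- NULL

  run_stage <- function(name, outputs, fun) {
    t0 <- Sys.time()
    done <- all(file.exists(file.path(out_dir, outputs)))
    status <- if (done && !overwrite) "skipped" else {
      tryCatch({ fun(); "ok" },
               error = function(e) {
                 manifest$stages[[name]] <<- list(
                   status = "failed", error = conditionMessage(e))
                 jsonlite::write_json(manifest, mpath, auto_unbox = TRUE)
                 rlang::abort(sprintf("stage '%s' failed: %s", name,
                                      conditionMessage(e)),
                              class = "envenomr_stage_error", parent = e)
               })
    }
    sums <- tools::md5sum(file.path(out_dir, outputs))
    manifest$stages[[name]] <<- list(
      status = status,
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")),
      outputs = as.list(stats::setNames(unname(sums), outputs))
    )
  }

  make_truth <- function() {
    make_synthetic_truth(
      n_rows = config$lattice$n_rows, n_cols = config$lattice$n_cols,
      years = (config$years$from - 2):config$years$to, seed = config$seed)
  }

  ## synth
  if (isTRUE(config$stages$synth)) {
    run_stage("synth", file.path("synth", "manifest.json"), function() {
      truth <<- make_truth()
      write_fixture(truth, file.path(out_dir, "synth"))
    })
  }
  if (is.null(truth)) truth <- make_truth()

  ## fit
  fit_out <- c(file.path("fit", "chains.csv"),
               file.path("fit", "diagnostics.json"),
               file.path("fit", "params.json"))
  if (isTRUE(config$stages$fit)) {
    run_stage("fit", fit_out, function() {
      obs <- simulate_incidence(truth, config$years$from, config$seed)
      pri <- do.call(default_priors, config$model$priors)
      fit <<- fit_mcmc(obs, truth$species$abundance, truth$landcover,
                       dplyr::filter(truth$population, .data$year == 2010) |>
                         dplyr::select("cell", "density"),
                       truth$lattice, priors = pri,
                       n_chains = config$model$n_chains,
                       n_iter = config$model$n_iter, seed = config$seed)
      dir.create(file.path(out_dir, "fit"), showWarnings = FALSE)
      chains <- purrr::imap_dfr(fit$draws, function(m, ch)
        dplyr::mutate(tibble::as_tibble(m), chain = ch,
                      iteration = dplyr::row_number()))
      utils::write.csv(chains, file.path(out_dir, "fit", "chains.csv"),
                       row.names = FALSE)
      jsonlite::write_json(
        list(dic = fit$dic, p_d = fit$p_d,
             median_rhat = stats::median(fit$summary$rhat),
             summary = fit$summary),
        file.path(out_dir, "fit", "diagnostics.json"),
        auto_unbox = TRUE, digits = NA)
      med <- fit$summary$median
      jsonlite::write_json(
        list(beta0 = med[1:5], beta1 = med[6:10], c = med[11:17],
             B0 = med[18], B = med[19:23], b = med[24:30], tau = med[31]),
        file.path(out_dir, "fit", "params.json"), digits = NA)
    })
  }

  fitted_params <- function() {
    pj <- file.path(out_dir, "fit", "params.json")
    if (file.exists(pj)) {
      p <- jsonlite::read_json(pj, simplifyVector = TRUE)
      envenoming_params(p$beta0, p$beta1, pmax(p$c, 0), p$B0, p$B, p$b,
                        max(p$tau, 1e-6))
    } else if (isTRUE(config$stages$fit)) {
      rlang::abort("no fitted parameters available.",
                   class = "envenomr_dependency_error")
    } else {
      rlang::abort("project stage needs fitted parameters: enable the fit stage or provide fit/params.json.",
                   class = "envenomr_dependency_error")
    }
  }

  ## project
  scen_name <- function(s) paste0(s$ssp, "_", gsub("[^A-Za-z0-9]", "-", s$rcm))
  if (isTRUE(config$stages$project)) {
    params <- fitted_params()
    for (s in config$scenarios) {
      nm <- scen_name(s)
      run_stage(paste0("project_", nm),
                file.path("project", paste0(nm, "_incidence.csv")), function() {
        scen <- scenario(s$ssp, s$rcm)
        run <- run_scenario(scen, params, truth,
                            years = config$years$from:config$years$to,
                            seed = config$seed)
        dir.create(file.path(out_dir, "project"), showWarnings = FALSE)
        utils::write.csv(run$incidence,
                         file.path(out_dir, "project",
                                   paste0(nm, "_incidence.csv")),
                         row.names = FALSE)
        utils::write.csv(run$population,
                         file.path(out_dir, "project",
                                   paste0(nm, "_population.csv")),
                         row.names = FALSE)
      })
    }
  }

  ## summarize
  if (isTRUE(config$stages$summarize)) {
    run_stage("summarize", "national_change.csv", function() {
      rows <- purrr::map_dfr(config$scenarios, function(s) {
        nm <- scen_name(s)
        inc <- tibble::as_tibble(utils::read.csv(
          file.path(out_dir, "project", paste0(nm, "_incidence.csv"))))
        pop <- tibble::as_tibble(utils::read.csv(
          file.path(out_dir, "project", paste0(nm, "_population.csv"))))
        dplyr::mutate(national_series(inc, pop), scenario = nm, .before = 1)
      })
      utils::write.csv(rows, file.path(out_dir, "national_change.csv"),
                       row.names = FALSE)
    })
  }

  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
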