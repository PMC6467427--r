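#' Default run configuration
#'
#' Fills a configuration list with defaults; every piece of randomness
#' in a run is traceable to the seeds recorded here.
#'
#' @param ... named overrides (see Details).
#' @details Recognized fields: `n_species`, `model` ("glv"/"saturable"),
#'   `seed` (parameter draw), `data_seed` (noise), `prior`
#'   ("L2"/"L1"/"none"), `prior_sd`, `cvar_beta` (NULL disables CVaR),
#'   `n_samples` (rMAP draws), `noise_scale`, `noise_floor`,
#'   `initial_abundance`, `max_iterations`, `n_starts`, `output`,
#'   `measurements` (CSV path; when absent, synthetic data are
#'   generated), `design` (JSON path), `species_set` (scale-study
#'   sizes).
#' @return a `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(n_species = 3L, model = "glv", seed = 1L, data_seed = 2L,
              prior = "L2", prior_sd = 1 / 50, cvar_beta = NULL,
              n_samples = 100L, noise_scale = 0.05, noise_floor = 0.1,
              initial_abundance = 0.01, max_iterations = 500L,
              n_starts = 1L, output = ".",
              measurements = NULL, design = NULL,
              species_set = c(12L, 24L, 36L, 48L))
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1L]]) && is.null(names(over)))
    over <- over[[1L]]
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    stopf("unknown configuration field(s): %s", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    obj <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stopf("the 'yaml' package is required for YAML configs")
      yaml::read_yaml(config)
    } else jsonlite::read_json(config, simplifyVector = TRUE)
    return(run_config(obj))
  }
  if (inherits(config, "run_config")) return(config)
  run_config(config)
}

cfg_inputs <- function(cfg) {
  design <- if (!is.null(cfg$design)) read_design(cfg$design)
  else build_design(cfg$n_species,
                    initial_abundance = cfg$initial_abundance)
  params <- draw_parameters(length(design$species_labels), cfg$seed,
                            model_form = cfg$model,
                            species_labels = design$species_labels)
  data <- if (!is.null(cfg$measurements))
    read_measurements_csv(cfg$measurements)
  else generate_dataset(params, design,
                        noise_model(cfg$noise_scale, cfg$noise_floor),
                        seed = cfg$data_seed, model_form = cfg$model)
  list(design = design, params = params, data = data)
}

cfg_fit <- function(cfg, inp, prior_form = cfg$prior) {
  map_estimate(
    inp$design, inp$data, model_form = cfg$model,
    prior = prior_spec(prior_form, sd = cfg$prior_sd),
    cvar = if (!is.null(cfg$cvar_beta)) cvar_spec(cfg$cvar_beta),
    options = solver_options(max_iterations = cfg$max_iterations),
    n_starts = cfg$n_starts)
}

#' Run a workbench command
#'
#' End-to-end scenario driver writing plain-text artifacts (and the
#' exact configuration used) into the output directory.
#'
#' * `simulate`: design JSON, generating-parameter CSVs, measurement CSV.
#' * `estimate`: MAP fit; estimates CSV + result JSON + fitted values.
#' * `observability`: no-prior fit, inertia report JSON.
#' * `uq`: MAP fit + rMAP samples CSV + posterior summary JSON.
#' * `diagnose`: MAP fit + per-point/series error CSVs + tail means.
#' * `scale-study`: design-size table over `species_set`.
#'
#' @param command one of the commands above.
#' @param config a [run_config()], plain list, or path to a JSON/YAML
#'   configuration file.
#' @return invisibly, a list of artifact paths (plus key results).
#' @export
run_command <- function(command = c("simulate", "estimate",
                                    "observability", "uq", "diagnose",
                                    "scale-study"),
                        config = run_config()) {
  command <- match.arg(command)
  cfg <- load_config(config)
  dir.create(cfg$output, showWarnings = FALSE, recursive = TRUE)
  art <- list()
  save_cfg <- function() {
    path <- file.path(cfg$output, "config.json")
    jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
    art$config <<- path
  }
  log_stage <- function(stage)
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), stage))

  if (command == "scale-study") {
    log_stage("scale-study: summarizing designs")
    tab <- do.call(rbind, lapply(cfg$species_set, function(s) {
      sm <- summarize_design(build_design(s), model_form = cfg$model)
      data.frame(n_species = sm$n_species, n_parameters = sm$n_parameters,
                 n_differential_equations = sm$n_differential_equations,
                 n_experiments = sm$n_experiments,
                 n_data_points = sm$n_data_points)
    }))
    path <- file.path(cfg$output, "scale_study.csv")
    utils::write.csv(tab, path, row.names = FALSE)
    art$table <- path
    save_cfg()
    art$summary <- tab
    return(invisible(art))
  }

  log_stage("preparing inputs")
  inp <- cfg_inputs(cfg)
  if (command == "simulate") {
    art$design <- write_design(inp$design,
                               file.path(cfg$output, "design.json"))
    art$params <- write_parameters_csv(
      inp$params, file.path(cfg$output, "true_params"))
    art$measurements <- write_measurements_csv(
      inp$data, file.path(cfg$output, "measurements.csv"))
    save_cfg()
    return(invisible(art))
  }

  log_stage(sprintf("fitting (%s prior%s)", cfg$prior,
                    if (!is.null(cfg$cvar_beta))
                      sprintf(", CVaR beta=%.2f", cfg$cvar_beta) else ""))
  if (command == "observability") {
    fit <- cfg_fit(cfg, inp, prior_form = "none")
    obs <- observability_test(fit$nlp, fit$result)
    rep <- obs$report
    path <- file.path(cfg$output, "observability.json")
    jsonlite::write_json(
      list(verdict = rep$verdict,
           inertia = c(rep$n_plus, rep$n_minus, rep$n_zero),
           expected = unname(rep$expected),
           schur_inertia = unname(rep$schur_inertia),
           n_active_bounds = length(obs$active_bounds)),
      path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    art$report <- path
    if (!is.null(obs$covariance)) {
      cpath <- file.path(cfg$output, "covariance.csv")
      utils::write.csv(as.data.frame(obs$covariance), cpath)
      art$covariance <- cpath
    }
    save_cfg()
    art$verdict <- rep$verdict
    return(invisible(art))
  }

  fit <- cfg_fit(cfg, inp)
  est <- data.frame(parameter = names(fit$theta),
                    estimate = unname(fit$theta))
  path <- file.path(cfg$output, "estimates.csv")
  utils::write.csv(est, path, row.names = FALSE)
  art$estimates <- path
  rpath <- file.path(cfg$output, "result.json")
  jsonlite::write_json(
    list(status = fit$status, objective = fit$objective,
         iterations = fit$iterations,
         constraint_violation = fit$result$constraint_violation),
    rpath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  art$result <- rpath

  if (command == "estimate") {
    fpath <- file.path(cfg$output, "fitted.csv")
    utils::write.csv(fitted_measurements(fit), fpath, row.names = FALSE)
    art$fitted <- fpath
    truth <- theta_pack(inp$params)
    if (length(truth) == length(fit$theta)) {
      rec <- data.frame(parameter = names(truth), truth = unname(truth),
                        estimate = unname(fit$theta))
      rec$error <- rec$estimate - rec$truth
      tpath <- file.path(cfg$output, "recovery.csv")
      utils::write.csv(rec, tpath, row.names = FALSE)
      art$recovery <- tpath
      art$rmse <- sqrt(mean(rec$error^2))
    }
  } else if (command == "uq") {
    log_stage(sprintf("rMAP sampling (%d draws)", cfg$n_samples))
    samp <- rmap_sample(fit, n_samples = cfg$n_samples,
                        spec = perturbation_spec(seed = cfg$data_seed))
    spath <- file.path(cfg$output, "rmap_samples.csv")
    utils::write.csv(as.data.frame(samp$samples), spath, row.names = FALSE)
    art$samples <- spath
    sm <- summarize_posterior(samp)
    jpath <- file.path(cfg$output, "posterior_summary.json")
    jsonlite::write_json(
      list(mean = as.list(sm$mean), std = as.list(sm$std),
           moment3 = as.list(sm$moment3), moment4 = as.list(sm$moment4),
           n_samples = sm$n_samples),
      jpath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    art$summary <- jpath
  } else if (command == "diagnose") {
    tab <- fitting_errors(inp$data, fit)
    p1 <- file.path(cfg$output, "errors_points.csv")
    p2 <- file.path(cfg$output, "errors_series.csv")
    utils::write.csv(tab$points, p1, row.names = FALSE)
    utils::write.csv(tab$series, p2, row.names = FALSE)
    tm <- tail_mean(tab, 0.1)
    p3 <- file.path(cfg$output, "tail_means.json")
    jsonlite::write_json(tm, p3, auto_unbox = TRUE, digits = NA)
    art$points <- p1; art$series <- p2; art$tails <- p3
    art$tail_mean <- tm$tail_mean
  }
  save_cfg()
  invisible(art)
}
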