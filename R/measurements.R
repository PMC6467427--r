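#' Multiplicative-with-floor measurement noise model
#'
#' The standard deviation attached to an observation with value `eta` is
#' `scale * max(floor, eta)`: 5% relative noise with an absolute floor
#' that keeps weights finite near extinction.
#'
#' @param scale relative noise level (default 0.05).
#' @param floor abundance floor (default 0.1).
#' @return a `noise_model` object.
#' @export
noise_model <- function(scale = 0.05, floor = 0.1) {
  if (scale <= 0 || floor <= 0) stopf("'scale' and 'floor' must be positive")
  structure(list(scale = scale, floor = floor), class = "noise_model")
}

#' Noise standard deviation for a given output level
#'
#' @param noise a [noise_model()].
#' @param eta output abundance value(s).
#' @return numeric vector of standard deviations.
#' @export
noise_std <- function(noise, eta) noise$scale * pmax(noise$floor, eta)

validate_measurements <- function(data) {
  need <- c("experiment_id", "species", "time_h", "abundance", "std")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stopf("measurement table lacks column(s): %s", paste(miss, collapse = ", "))
  key <- paste(data$experiment_id, data$species, data$time_h)
  if (anyDuplicated(key))
    stopf("duplicate (experiment, species, time) measurement records")
  if (any(!is.finite(data$std)) || any(data$std <= 0))
    stopf("all measurement standard deviations must be positive")
  invisible(data)
}

#' Generate a noisy synthetic measurement set
#'
#' Simulates every experiment of the design with the reference
#' integrator, evaluates the true outputs at the sampling times
#' (pre-dilution values at dilution instants), attaches standard
#' deviations via the noise rule `sigma = scale * max(floor, eta_true)`,
#' and adds independent Gaussian noise N(0, sigma^2).  Negative noisy
#' observations are clipped at zero by default (abundances are
#' physical).
#'
#' @param params generating [community_parameters()].
#' @param design an [build_design()] design.
#' @param noise a [noise_model()].
#' @param seed integer seed.
#' @param model_form `"glv"` or `"saturable"`.
#' @param sigma_from whether the noise rule is applied to the noiseless
#'   simulated output (`"true"`, default) or re-applied to the noisy
#'   observation (`"observed"`).
#' @param clip_negative clip negative observations at 0 (default TRUE).
#' @param rel_tol,abs_tol integrator tolerances.
#' @return a data frame with columns `experiment_id`, `species`,
#'   `time_h`, `abundance`, `std`; the noiseless outputs are kept in the
#'   `"truth"` attribute.
#' @export
generate_dataset <- function(params, design, noise = noise_model(), seed,
                             model_form = c("glv", "saturable"),
                             sigma_from = c("true", "observed"),
                             clip_negative = TRUE,
                             rel_tol = 1e-8, abs_tol = 1e-10) {
  model_form <- match.arg(model_form)
  sigma_from <- match.arg(sigma_from)
  recs <- lapply(design$experiments, function(ex) {
    traj <- tryCatch(
      simulate_experiment(params, ex, model_form, rel_tol, abs_tol),
      error = function(e)
        stopf("simulation failed for experiment '%s': %s",
              ex$experiment_id, conditionMessage(e)))
    truth <- trajectory_at(traj, ex$sampling_times_h)
    data.frame(
      experiment_id = ex$experiment_id,
      species = rep(ex$member_species,
                    each = length(ex$sampling_times_h)),
      time_h = rep(ex$sampling_times_h, length(ex$member_species)),
      truth = as.vector(truth),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out <- with_seed(seed, {
    sigma <- noise_std(noise, out$truth)
    obs <- out$truth + stats::rnorm(nrow(out), sd = sigma)
    if (clip_negative) obs <- pmax(obs, 0)
    if (sigma_from == "observed") sigma <- noise_std(noise, obs)
    out$abundance <- obs
    out$std <- sigma
    out
  })
  truth <- out$truth
  out$truth <- NULL
  attr(out, "truth") <- truth
  validate_measurements(out)
  out
}

#' Replicate a design for data augmentation
#'
#' Returns the design extended with `n_replicates` copies of every
#' experiment under new ids (`<id>__rep<j>`), as used to build enlarged
#' estimation problems from replicated synthetic data.
#'
#' @param design an experiment design.
#' @param n_replicates number of additional copies (>= 0).
#' @return an `experiment_design` with `(n_replicates + 1) * K` experiments.
#' @export
replicate_design <- function(design, n_replicates) {
  if (n_replicates < 0) stopf("'n_replicates' must be >= 0")
  if (n_replicates == 0) return(design)
  extra <- list()
  for (j in seq_len(n_replicates)) {
    extra <- c(extra, lapply(design$experiments, function(ex) {
      ex$experiment_id <- sprintf("%s__rep%d", ex$experiment_id, j)
      ex
    }))
  }
  structure(list(species_labels = design$species_labels,
                 experiments = c(design$experiments, extra)),
            class = "experiment_design")
}

#' Augment a measurement set with perturbed replicates
#'
#' Appends `n_replicates` copies of the base records in which each
#' observation is freshly re-perturbed (`eta + e`, `e ~ N(0, std^2)`),
#' filed under new experiment ids matching [replicate_design()].
#'
#' @param base measurement data frame.
#' @param n_replicates number of replicate copies (>= 0).
#' @param seed integer seed.
#' @param clip_negative clip negative perturbed observations at 0.
#' @return augmented measurement data frame.
#' @export
augment_with_replicates <- function(base, n_replicates, seed,
                                    clip_negative = TRUE) {
  validate_measurements(base)
  if (n_replicates < 0) stopf("'n_replicates' must be >= 0")
  if (n_replicates == 0) return(base)
  out <- with_seed(seed, {
    copies <- lapply(seq_len(n_replicates), function(j) {
      cp <- base
      cp$experiment_id <- sprintf("%s__rep%d", cp$experiment_id, j)
      cp$abundance <- cp$abundance + stats::rnorm(nrow(cp), sd = cp$std)
      if (clip_negative) cp$abundance <- pmax(cp$abundance, 0)
      cp
    })
    do.call(rbind, c(list(base), copies))
  })
  rownames(out) <- NULL
  validate_measurements(out)
  out
}

#' Write / read measurement CSV
#'
#' Columns: `experiment_id`, `species`, `time_h`, `abundance`, `std`.
#'
#' @param data measurement data frame.
#' @param path file path.
#' @return `write_measurements_csv` returns `path` invisibly;
#'   `read_measurements_csv` returns the validated data frame.
#' @export
write_measurements_csv <- function(data, path) {
  validate_measurements(data)
  utils::write.csv(
    data[, c("experiment_id", "species", "time_h", "abundance", "std")],
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_measurements_csv
#' @export
read_measurements_csv <- function(path) {
  validate_measurements(utils::read.csv(path, stringsAsFactors = FALSE))
}
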