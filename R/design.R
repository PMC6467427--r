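#' Define a single culture experiment
#'
#' @param experiment_id unique identifier.
#' @param member_species character vector of cultured species labels
#'   (length 1 for mono-species, 2 for pairwise co-culture).
#' @param duration_h experiment duration T (hours).
#' @param sampling_times_h strictly increasing sampling times in
#'   (0, duration].
#' @param initial_abundances nonnegative initial abundance per member.
#' @param dilution_times_h times of serial dilutions, in (0, duration).
#' @param dilution_factor multiplicative dilution factor in (0, 1].
#' @return an object of class `experiment`.
#' @export
experiment <- function(experiment_id, member_species, duration_h,
                       sampling_times_h, initial_abundances,
                       dilution_times_h = numeric(0),
                       dilution_factor = 1) {
  member_species <- as.character(member_species)
  sampling_times_h <- as.numeric(sampling_times_h)
  dilution_times_h <- as.numeric(dilution_times_h)
  initial_abundances <- as.numeric(initial_abundances)
  if (length(initial_abundances) == 1L)
    initial_abundances <- rep(initial_abundances, length(member_species))
  if (anyDuplicated(member_species)) stopf("member species must be unique")
  if (duration_h <= 0) stopf("duration must be positive")
  if (is.unsorted(sampling_times_h, strictly = TRUE))
    stopf("sampling times must be strictly increasing")
  if (any(sampling_times_h <= 0) || any(sampling_times_h > duration_h))
    stopf("sampling times must lie in (0, duration]")
  if (length(dilution_times_h)) {
    if (is.unsorted(dilution_times_h, strictly = TRUE))
      stopf("dilution times must be strictly increasing")
    if (any(dilution_times_h <= 0) || any(dilution_times_h >= duration_h))
      stopf("dilution times must lie in (0, duration)")
  }
  if (dilution_factor <= 0 || dilution_factor > 1)
    stopf("dilution factor must be in (0, 1]")
  if (length(initial_abundances) != length(member_species))
    stopf("one initial abundance per member species is required")
  if (any(initial_abundances < 0))
    stopf("initial abundances must be nonnegative")
  structure(
    list(experiment_id = as.character(experiment_id),
         member_species = member_species,
         duration_h = duration_h,
         sampling_times_h = sampling_times_h,
         initial_abundances = initial_abundances,
         dilution_times_h = dilution_times_h,
         dilution_factor = dilution_factor),
    class = "experiment")
}

#' Build the full mono + pairwise experimental design
#'
#' For S species the design comprises one mono-species experiment per
#' species (sampled every `mono_sampling_interval_h` over
#' `mono_duration_h`; 0.5 h over 24 h by default, giving 48 samples) and
#' one pairwise co-culture per unordered pair (`pairwise_n_samples`
#' samples at `pairwise_sampling_interval_h` spacing, serial 1/20
#' dilutions every `dilution_period_h`).  Both cultured species are
#' observed at every pairwise sampling time.
#'
#' @param n_species number of species S (>= 1).
#' @param mono_sampling_interval_h mono sampling interval (h).
#' @param mono_duration_h mono experiment duration (h).
#' @param pairwise_n_samples number of pairwise sampling times.
#' @param pairwise_sampling_interval_h pairwise sampling spacing (h).
#' @param dilution_period_h period between dilutions in pairwise
#'   experiments (h).
#' @param dilution_factor dilution factor.
#' @param initial_abundance initial abundance per cultured species.
#' @param species_labels optional labels; defaults to `sp1..spS`.
#' @return an object of class `experiment_design`: list with
#'   `species_labels` and `experiments`.
#' @export
build_design <- function(n_species,
                         mono_sampling_interval_h = 0.5,
                         mono_duration_h = 24,
                         pairwise_n_samples = 8,
                         pairwise_sampling_interval_h = 12,
                         dilution_period_h = 24,
                         dilution_factor = 1 / 20,
                         initial_abundance = 0.01,
                         species_labels = NULL) {
  s <- as.integer(n_species)
  if (s < 1L) stopf("'n_species' must be >= 1")
  if (mono_sampling_interval_h <= 0 || pairwise_sampling_interval_h <= 0 ||
      dilution_period_h <= 0)
    stopf("sampling and dilution intervals must be positive")
  if (is.null(species_labels)) species_labels <- paste0("sp", seq_len(s))
  species_labels <- as.character(species_labels)

  exps <- vector("list", s + s * (s - 1L) / 2L)
  j <- 0L
  mono_times <- seq(mono_sampling_interval_h, mono_duration_h,
                    by = mono_sampling_interval_h)
  for (i in seq_len(s)) {
    j <- j + 1L
    exps[[j]] <- experiment(
      experiment_id = sprintf("mono_%s", species_labels[i]),
      member_species = species_labels[i],
      duration_h = mono_duration_h,
      sampling_times_h = mono_times,
      initial_abundances = initial_abundance)
  }
  if (s >= 2L) {
    pair_times <- pairwise_sampling_interval_h * seq_len(pairwise_n_samples)
    pair_dur <- max(pair_times)
    dil_times <- seq(dilution_period_h, pair_dur, by = dilution_period_h)
    dil_times <- dil_times[dil_times < pair_dur]
    for (a in seq_len(s - 1L)) for (b in seq((a + 1L), s)) {
      j <- j + 1L
      exps[[j]] <- experiment(
        experiment_id = sprintf("pair_%s_%s", species_labels[a],
                                species_labels[b]),
        member_species = species_labels[c(a, b)],
        duration_h = pair_dur,
        sampling_times_h = pair_times,
        initial_abundances = initial_abundance,
        dilution_times_h = dil_times,
        dilution_factor = dilution_factor)
    }
  }
  ids <- vapply(exps, `[[`, character(1), "experiment_id")
  if (anyDuplicated(ids)) stopf("experiment ids must be unique")
  structure(list(species_labels = species_labels, experiments = exps),
            class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  nm <- sum(vapply(x$experiments, function(e)
    length(e$member_species) == 1L, logical(1)))
  cat(sprintf("Experimental design: %d species, %d experiments (%d mono, %d multi)\n",
              length(x$species_labels), length(x$experiments), nm,
              length(x$experiments) - nm))
  invisible(x)
}

#' Summarize the size of an estimation problem
#'
#' Counts species, parameters, differential equations (one per cultured
#' species per experiment), experiments, and scalar data points (one per
#' cultured species per sampling time).
#'
#' @param design an [build_design()] design.
#' @param model_form `"glv"` or `"saturable"`.
#' @return a `design_summary` (named list of counts).
#' @export
summarize_design <- function(design, model_form = c("glv", "saturable")) {
  model_form <- match.arg(model_form)
  s <- length(design$species_labels)
  sizes <- vapply(design$experiments, function(e)
    length(e$member_species), integer(1))
  npts <- vapply(design$experiments, function(e)
    length(e$member_species) * length(e$sampling_times_h), integer(1))
  structure(
    list(n_species = s,
         n_parameters = n_parameters(s, model_form),
         n_differential_equations = sum(sizes),
         n_experiments = length(design$experiments),
         n_data_points = sum(npts)),
    class = "design_summary")
}

#' @export
print.design_summary <- function(x, ...) {
  cat(sprintf(
    "species %d | parameters %d | ODEs %d | experiments %d | data points %d\n",
    x$n_species, x$n_parameters, x$n_differential_equations,
    x$n_experiments, x$n_data_points))
  invisible(x)
}

#' Serialize a design to JSON (or YAML)
#'
#' @param design an experiment design.
#' @param path output file; format chosen by extension (`.json` or
#'   `.yaml`/`.yml`, the latter requiring the yaml package).
#' @return invisibly, `path`.
#' @export
write_design <- function(design, path) {
  obj <- list(species_labels = design$species_labels,
              experiments = lapply(design$experiments, unclass))
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stopf("the 'yaml' package is required for YAML output")
    yaml::write_yaml(obj, path)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Read a design written by [write_design()]
#'
#' @param path file path.
#' @return an `experiment_design`.
#' @export
read_design <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stopf("the 'yaml' package is required for YAML input")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  exps <- lapply(seq_len(length(obj$experiments$experiment_id %||%
                                  obj$experiments)), identity)
  # jsonlite may simplify the experiment list to a data frame; normalize
  raw <- obj$experiments
  if (is.data.frame(raw)) raw <- split(raw, seq_len(nrow(raw)))
  exps <- lapply(raw, function(e)
    experiment(e$experiment_id[[1]],
               unlist(e$member_species),
               e$duration_h[[1]],
               unlist(e$sampling_times_h),
               unlist(e$initial_abundances),
               unlist(e$dilution_times_h) %||% numeric(0),
               e$dilution_factor[[1]]))
  names(exps) <- NULL
  structure(list(species_labels = unlist(obj$species_labels),
                 experiments = exps),
            class = "experiment_design")
}
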