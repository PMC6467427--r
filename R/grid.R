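## Discretization grids for implicit Euler transcription.
##
## A grid is the ordered list of time nodes of one experiment.  Node 1
## carries the initial condition; every later node carries exactly one
## constraint: either an implicit Euler step from the previous node or an
## instantaneous dilution jump (in which case the node time duplicates
## the previous node's time; pre- and post-dilution states are separate
## variables).

make_grid <- function(base_times, dilution_times, dilution_factor,
                      sample_times, experiment_id) {
  bt <- sort(unique(round(base_times, 10)))
  if (bt[1] != 0) stopf("grid must start at time 0")
  if (length(dilution_times) &&
      !all(round(dilution_times, 10) %in% bt))
    stopf("dilution times must lie on the grid")
  if (!all(round(sample_times, 10) %in% bt))
    stopf("sampling times must lie on the grid")
  times <- numeric(0); kind <- character(0)
  for (t in bt) {
    times <- c(times, t)
    kind <- c(kind, if (length(times) == 1L) "init" else "step")
    if (t %in% round(dilution_times, 10)) {
      times <- c(times, t)
      kind <- c(kind, "dilution")
    }
  }
  sample_node <- vapply(round(sample_times, 10), function(t)
    which(round(times, 10) == t)[1L], integer(1))
  structure(list(times = times, kind = kind,
                 dilution_factor = dilution_factor,
                 sample_times = sample_times, sample_node = sample_node,
                 experiment_id = experiment_id),
            class = "glv_grid")
}

#' Build the implicit-Euler time grid of one experiment
#'
#' Mono-species experiments refine the sampling grid `mono_substeps`-fold
#' (the sampling times themselves are always nodes).  Multi-species
#' experiments use `pairwise_n_intervals` equal Euler intervals over the
#' whole duration, with the sampling and dilution times merged into the
#' node set; each dilution time appears as a doubled node carrying the
#' pre- and post-dilution states.  The defaults give a uniform 0.1-h
#' step (five points per mono sampling interval, 120 per pairwise
#' sampling interval), which passes the discretization-sufficiency
#' check on the synthetic designs; see the package vignette.
#'
#' @param experiment an [experiment()] object.
#' @param mono_substeps refinement factor for mono-species grids
#'   (default 5, i.e. five Euler steps per 0.5-h sampling interval,
#'   h = 0.1 h).
#' @param pairwise_n_intervals number of equal Euler intervals for
#'   multi-species grids (default 960 over the 96-h design, i.e. 120
#'   per 12-h sampling interval, h = 0.1 h).
#' @return a `glv_grid` object.
#' @export
build_grid <- function(experiment, mono_substeps = 5,
                       pairwise_n_intervals = 960) {
  ex <- experiment
  if (mono_substeps < 1 || pairwise_n_intervals < 1)
    stopf("grid refinement settings must be positive integers")
  if (length(ex$member_species) == 1L) {
    base <- c(0, ex$sampling_times_h, ex$dilution_times_h)
    grid0 <- sort(unique(round(base, 10)))
    base <- subdivide(grid0, mono_substeps)
  } else {
    base <- c(seq(0, ex$duration_h, length.out = pairwise_n_intervals + 1L),
              ex$sampling_times_h, ex$dilution_times_h)
  }
  make_grid(base, ex$dilution_times_h, ex$dilution_factor,
            ex$sampling_times_h, ex$experiment_id)
}

subdivide <- function(times, factor) {
  if (factor == 1) return(times)
  out <- times[1]
  for (i in seq_len(length(times) - 1L)) {
    seg <- seq(times[i], times[i + 1L], length.out = factor + 1L)
    out <- c(out, seg[-1L])
  }
  out
}

#' Refine a grid by an integer factor
#'
#' Every implicit Euler interval is subdivided `factor`-fold; dilution
#' jumps are preserved.  Used by the discretization-sufficiency check.
#'
#' @param grid a `glv_grid`.
#' @param factor integer refinement factor (>= 1).
#' @return a refined `glv_grid`.
#' @export
refine_grid <- function(grid, factor = 2) {
  if (factor == 1) return(grid)
  step_nodes <- grid$times[grid$kind != "dilution"]
  dil_times <- grid$times[grid$kind == "dilution"]
  make_grid(subdivide(step_nodes, factor), dil_times,
            grid$dilution_factor, grid$sample_times, grid$experiment_id)
}

#' Build grids for every experiment of a design
#'
#' @param design an experiment design.
#' @param mono_substeps,pairwise_n_intervals see [build_grid()].
#' @return named list of `glv_grid` objects (by experiment id).
#' @export
build_grids <- function(design, mono_substeps = 5,
                        pairwise_n_intervals = 960) {
  g <- lapply(design$experiments, build_grid,
              mono_substeps = mono_substeps,
              pairwise_n_intervals = pairwise_n_intervals)
  stats::setNames(g, vapply(design$experiments, `[[`, character(1),
                            "experiment_id"))
}

#' Refine every grid of a grids list
#'
#' @param grids named list of `glv_grid` objects.
#' @param factor integer refinement factor.
#' @return refined grids list.
#' @export
refine_grids <- function(grids, factor = 2)
  lapply(grids, refine_grid, factor = factor)
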