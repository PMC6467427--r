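## Model right-hand sides.
##
## gLV:        dx_s/dt = (mu_s + sum_{s'} a_{ss'} x_{s'}) x_s
## saturable:  dx_s/dt = (mu_s + sum_{s'} a_{ss'} x_{s'} / (K_{ss'} + x_{s'})) x_s
##
## All internal kernels work on the "local" parameters of an experiment,
## i.e. the rows/columns of mu, alpha, K restricted to the cultured
## species; species absent from an experiment have zero abundance and do
## not enter the dynamics.

local_params <- function(params, members, model_form) {
  idx <- match(members, params$species_labels)
  if (anyNA(idx))
    stopf("unknown species label(s): %s",
          paste(members[is.na(idx)], collapse = ", "))
  lp <- list(mu = unname(params$growth_rates[idx]),
             alpha = unname(params$interactions[idx, idx, drop = FALSE]))
  if (model_form == "saturable") {
    if (is.null(params$saturations))
      stopf("saturable model requires saturation constants")
    lp$K <- unname(params$saturations[idx, idx, drop = FALSE])
  }
  lp
}

glv_f <- function(x, lp) as.vector((lp$mu + lp$alpha %*% x) * x)

sat_f <- function(x, lp) {
  g <- matrix(x, nrow(lp$K), length(x), byrow = TRUE)
  g <- g / (lp$K + g)
  as.vector((lp$mu + rowSums(lp$alpha * g)) * x)
}

model_f <- function(x, lp, model_form) {
  if (model_form == "glv") glv_f(x, lp) else sat_f(x, lp)
}

# Jacobian of f with respect to the state vector
model_fx <- function(x, lp, model_form) {
  n <- length(x)
  if (model_form == "glv") {
    percap <- as.vector(lp$mu + lp$alpha %*% x)
    jac <- lp$alpha * x            # x_s * a_{ss'}
    diag(jac) <- diag(jac) + percap
    jac
  } else {
    xm <- matrix(x, n, n, byrow = TRUE)
    g <- xm / (lp$K + xm)
    gx <- lp$K / (lp$K + xm)^2
    percap <- lp$mu + rowSums(lp$alpha * g)
    jac <- (lp$alpha * gx) * x
    diag(jac) <- diag(jac) + percap
    jac
  }
}

#' gLV model right-hand side
#'
#' Evaluates the generalized Lotka-Volterra abundance rates
#' for the species cultured in an experiment; species outside `members`
#' are treated as absent.
#'
#' @param state numeric abundance vector over `members` (same order).
#' @param params a [community_parameters()] object.
#' @param members character vector of cultured species labels.
#' @return numeric vector of abundance rates (abundance/h).
#' @export
glv_rhs <- function(state, params, members = params$species_labels) {
  if (length(state) != length(members))
    stopf("'state' must have one entry per member species")
  glv_f(as.numeric(state), local_params(params, members, "glv"))
}

#' Saturable gLV model right-hand side
#'
#' Like [glv_rhs()] but each interaction saturates in the donor
#' abundance, `x'/(K + x')`, halving at `x' = K`.
#'
#' @inheritParams glv_rhs
#' @return numeric vector of abundance rates (abundance/h).
#' @export
saturable_rhs <- function(state, params, members = params$species_labels) {
  if (length(state) != length(members))
    stopf("'state' must have one entry per member species")
  sat_f(as.numeric(state), local_params(params, members, "saturable"))
}

#' Simulate one experiment with a stiff reference integrator
#'
#' Integrates the chosen community model over the experiment duration
#' with `deSolve::lsoda`.  Serial dilutions are instantaneous jumps: at
#' each dilution time the state is multiplied by the dilution factor and
#' integration restarts, and both the pre- and post-dilution states are
#' stored (duplicated time point).
#'
#' @param params a [community_parameters()] object.
#' @param experiment an [experiment()] design object.
#' @param model_form `"glv"` or `"saturable"`.
#' @param rel_tol,abs_tol integrator tolerances.
#' @param times optional output times; defaults to the union of 0, the
#'   sampling times, the dilution times and the duration.
#' @return a `trajectory` object: list with `times` (duplicated at
#'   dilutions), `states` (matrix, one column per member species) and
#'   `post_dilution` (logical flags).
#' @export
simulate_experiment <- function(params, experiment,
                                model_form = c("glv", "saturable"),
                                rel_tol = 1e-8, abs_tol = 1e-10,
                                times = NULL) {
  model_form <- match.arg(model_form)
  if (rel_tol <= 0 || abs_tol <= 0) stopf("tolerances must be positive")
  ex <- experiment
  lp <- local_params(params, ex$member_species, model_form)
  n <- length(ex$member_species)
  if (is.null(times))
    times <- sort(unique(c(0, ex$sampling_times_h, ex$dilution_times_h,
                           ex$duration_h)))
  times <- times[times >= 0 & times <= ex$duration_h]
  if (!0 %in% times) times <- c(0, times)

  deriv <- function(t, y, p) list(model_f(y, lp, model_form))
  segments <- sort(unique(c(0, ex$dilution_times_h, ex$duration_h)))
  out_t <- numeric(0); out_x <- NULL; post <- logical(0)
  x <- as.numeric(ex$initial_abundances)
  for (i in seq_len(length(segments) - 1L)) {
    a <- segments[i]; b <- segments[i + 1L]
    seg_times <- sort(unique(c(a, times[times > a & times < b], b)))
    sol <- deSolve::lsoda(y = x, times = seg_times, func = deriv,
                          rtol = rel_tol, atol = abs_tol)
    if (attr(sol, "istate")[1L] < 0)
      stopf("integration failed in experiment '%s' near t = %.3f h",
            ex$experiment_id, utils::tail(sol[, 1L], 1L))
    keep <- if (i == 1L) seq_len(nrow(sol)) else seq_len(nrow(sol))[-1L]
    out_t <- c(out_t, sol[keep, 1L])
    out_x <- rbind(out_x, sol[keep, -1L, drop = FALSE])
    post <- c(post, rep(FALSE, length(keep)))
    x <- as.numeric(sol[nrow(sol), -1L])
    if (b %in% ex$dilution_times_h) {   # instantaneous dilution jump
      x <- ex$dilution_factor * x
      out_t <- c(out_t, b)
      out_x <- rbind(out_x, x)
      post <- c(post, TRUE)
    }
  }
  colnames(out_x) <- ex$member_species
  rownames(out_x) <- NULL
  structure(list(times = out_t, states = out_x, post_dilution = post,
                 experiment_id = ex$experiment_id),
            class = "trajectory")
}

#' Trajectory values at sampling times
#'
#' Extracts the simulated state at given times; at a dilution time the
#' pre-dilution value is returned (samples are taken before passaging).
#'
#' @param traj a `trajectory` from [simulate_experiment()].
#' @param at numeric vector of times.
#' @return matrix (length(at) x n_members).
#' @export
trajectory_at <- function(traj, at) {
  idx <- vapply(at, function(t) {
    j <- which(abs(traj$times - t) < 1e-9 & !traj$post_dilution)
    if (length(j) == 0L) j <- which(abs(traj$times - t) < 1e-9)
    if (length(j) == 0L)
      stopf("time %.4f h is not on the trajectory grid", t)
    j[1L]
  }, integer(1))
  traj$states[idx, , drop = FALSE]
}
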