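#' Community model parameters
#'
#' Container for the parameters of a generalized Lotka-Volterra (gLV)
#' community model or its saturable variant.  `growth_rates[s]` is the
#' intrinsic growth rate of species `s` (1/h); `interactions[s, sp]` is
#' the effect of donor species `sp` on the per-capita growth rate of
#' recipient species `s` (1/(abundance h)); `saturations[s, sp]`, when
#' present, is the half-saturation abundance of that interaction
#' (saturable model only, strictly positive).
#'
#' @param species_labels character vector of S species identifiers.
#' @param growth_rates numeric vector of length S.
#' @param interactions numeric S x S matrix (rows = recipient, columns =
#'   donor).
#' @param saturations optional numeric S x S matrix of strictly positive
#'   half-saturation constants.
#' @return an object of class `community_parameters`.
#' @export
community_parameters <- function(species_labels, growth_rates, interactions,
                                 saturations = NULL) {
  species_labels <- as.character(species_labels)
  s <- length(species_labels)
  if (s < 1L) stopf("at least one species is required")
  if (anyDuplicated(species_labels))
    stopf("species labels must be unique")
  growth_rates <- as.numeric(growth_rates)
  interactions <- as.matrix(interactions)
  if (length(growth_rates) != s)
    stopf("'growth_rates' must have length %d", s)
  if (!all(dim(interactions) == c(s, s)))
    stopf("'interactions' must be a %d x %d matrix", s, s)
  if (!all(is.finite(growth_rates)) || !all(is.finite(interactions)))
    stopf("all parameter values must be finite")
  dimnames(interactions) <- list(species_labels, species_labels)
  names(growth_rates) <- species_labels
  if (!is.null(saturations)) {
    saturations <- as.matrix(saturations)
    if (!all(dim(saturations) == c(s, s)))
      stopf("'saturations' must be a %d x %d matrix", s, s)
    if (!all(is.finite(saturations)) || any(saturations <= 0))
      stopf("'saturations' must be strictly positive and finite")
    dimnames(saturations) <- list(species_labels, species_labels)
  }
  structure(
    list(species_labels = species_labels, growth_rates = growth_rates,
         interactions = interactions, saturations = saturations),
    class = "community_parameters")
}

#' @export
print.community_parameters <- function(x, ...) {
  cat(sprintf("Community parameters: %d species (%s model)\n",
              length(x$species_labels),
              if (is.null(x$saturations)) "gLV" else "saturable gLV"))
  cat("  growth rates:", signif(unname(x$growth_rates), 3), "\n")
  invisible(x)
}

#' Number of free parameters of a community model
#'
#' S^2 + S for the gLV model and 2 S^2 + S when saturation constants are
#' included.
#'
#' @param n_species number of species S.
#' @param model_form `"glv"` or `"saturable"`.
#' @return integer parameter count.
#' @export
n_parameters <- function(n_species, model_form = c("glv", "saturable")) {
  model_form <- match.arg(model_form)
  s <- as.integer(n_species)
  if (model_form == "glv") s^2 + s else 2L * s^2 + s
}

#' Flatten community parameters to a named vector
#'
#' The ordering is per recipient species: growth rate first, then its row
#' of interaction coefficients, i.e. (mu_1, a_11..a_1S, ..., mu_S,
#' a_S1..a_SS); saturation constants, when present, follow in the same
#' row-major order.
#'
#' @param params a [community_parameters()] object.
#' @return named numeric vector of length S^2+S (gLV) or 2S^2+S.
#' @export
theta_pack <- function(params) {
  lbl <- params$species_labels
  s <- length(lbl)
  out <- numeric(0)
  nm <- character(0)
  for (i in seq_len(s)) {
    out <- c(out, params$growth_rates[i], params$interactions[i, ])
    nm <- c(nm, sprintf("mu[%s]", lbl[i]),
            sprintf("alpha[%s,%s]", lbl[i], lbl))
  }
  if (!is.null(params$saturations)) {
    for (i in seq_len(s)) {
      out <- c(out, params$saturations[i, ])
      nm <- c(nm, sprintf("K[%s,%s]", lbl[i], lbl))
    }
  }
  stats::setNames(out, nm)
}

#' Rebuild community parameters from a flat vector
#'
#' Inverse of [theta_pack()].
#'
#' @param theta numeric vector in [theta_pack()] ordering.
#' @param species_labels species identifiers.
#' @param model_form `"glv"` or `"saturable"`.
#' @return a [community_parameters()] object.
#' @export
theta_unpack <- function(theta, species_labels,
                         model_form = c("glv", "saturable")) {
  model_form <- match.arg(model_form)
  s <- length(species_labels)
  need <- n_parameters(s, model_form)
  if (length(theta) != need)
    stopf("'theta' must have length %d for %d species (%s)", need, s,
          model_form)
  mu <- numeric(s)
  alpha <- matrix(0, s, s)
  for (i in seq_len(s)) {
    off <- (i - 1L) * (s + 1L)
    mu[i] <- theta[off + 1L]
    alpha[i, ] <- theta[off + 1L + seq_len(s)]
  }
  ksat <- NULL
  if (model_form == "saturable") {
    kv <- theta[(s^2 + s) + seq_len(s^2)]
    ksat <- matrix(kv, s, s, byrow = TRUE)
  }
  community_parameters(species_labels, mu, alpha, ksat)
}

#' Draw random community parameters
#'
#' Growth rates are drawn from N(0.3, 0.1^2), self-interactions from
#' N(-1, 0.1^2) and cross-interactions from N(0, 0.1^2); these are the
#' generating distributions used throughout the synthetic scalability
#' designs.  For the saturable model form, half-saturation constants are
#' drawn log-normally around 1 (median 1, sdlog 0.25), a scale comparable
#' to the community carrying capacities.
#'
#' @param n_species number of species.
#' @param seed integer seed (required; draws are deterministic given it).
#' @param model_form `"glv"` or `"saturable"`.
#' @param species_labels optional labels; defaults to `sp1..spS`.
#' @return a [community_parameters()] object.
#' @export
draw_parameters <- function(n_species, seed,
                            model_form = c("glv", "saturable"),
                            species_labels = NULL) {
  model_form <- match.arg(model_form)
  s <- as.integer(n_species)
  if (is.null(species_labels)) species_labels <- paste0("sp", seq_len(s))
  with_seed(seed, {
    mu <- stats::rnorm(s, mean = 0.3, sd = 0.1)
    alpha <- matrix(stats::rnorm(s * s, mean = 0, sd = 0.1), s, s)
    diag(alpha) <- stats::rnorm(s, mean = -1, sd = 0.1)
    ksat <- if (model_form == "saturable")
      matrix(stats::rlnorm(s * s, meanlog = 0, sdlog = 0.25), s, s)
    else NULL
    community_parameters(species_labels, mu, alpha, ksat)
  })
}

#' Write community parameters to CSV tables
#'
#' Produces `<stem>_growth.csv` (columns `species`, `mu`) and
#' `<stem>_interactions.csv` (columns `recipient`, `donor`, `alpha` and,
#' for the saturable form, `K`).
#'
#' @param params a [community_parameters()] object.
#' @param stem file path stem.
#' @return invisibly, the two file paths.
#' @export
write_parameters_csv <- function(params, stem) {
  growth <- data.frame(species = params$species_labels,
                       mu = unname(params$growth_rates))
  lbl <- params$species_labels
  inter <- expand.grid(donor = lbl, recipient = lbl,
                       stringsAsFactors = FALSE)[, 2:1]
  inter$alpha <- as.vector(t(params$interactions))
  if (!is.null(params$saturations))
    inter$K <- as.vector(t(params$saturations))
  f1 <- paste0(stem, "_growth.csv")
  f2 <- paste0(stem, "_interactions.csv")
  utils::write.csv(growth, f1, row.names = FALSE)
  utils::write.csv(inter, f2, row.names = FALSE)
  invisible(c(f1, f2))
}

#' Read community parameters from CSV tables
#'
#' @param stem file path stem used by [write_parameters_csv()].
#' @return a [community_parameters()] object.
#' @export
read_parameters_csv <- function(stem) {
  growth <- utils::read.csv(paste0(stem, "_growth.csv"),
                            stringsAsFactors = FALSE)
  inter <- utils::read.csv(paste0(stem, "_interactions.csv"),
                           stringsAsFactors = FALSE)
  lbl <- growth$species
  s <- length(lbl)
  alpha <- matrix(NA_real_, s, s, dimnames = list(lbl, lbl))
  alpha[cbind(match(inter$recipient, lbl), match(inter$donor, lbl))] <-
    inter$alpha
  ksat <- NULL
  if ("K" %in% names(inter)) {
    ksat <- matrix(NA_real_, s, s, dimnames = list(lbl, lbl))
    ksat[cbind(match(inter$recipient, lbl), match(inter$donor, lbl))] <-
      inter$K
  }
  community_parameters(lbl, growth$mu, alpha, ksat)
}
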