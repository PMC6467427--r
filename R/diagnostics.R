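#' Model predictions at the measurement records
#'
#' Extracts the fitted outputs (discretized states at the sampling
#' nodes) from a MAP fit, one row per measurement record.
#'
#' @param fit a `glv_fit`.
#' @return data frame with columns `experiment_id`, `species`,
#'   `time_h`, `predicted`.
#' @export
fitted_measurements <- function(fit) {
  nlp <- fit$nlp
  w <- fit$result$w_star
  out <- lapply(nlp$exps, function(ex)
    data.frame(experiment_id = ex$id,
               species = ex$members[ex$obs$sp],
               time_h = ex$grid$times[ex$obs$node],
               predicted = w[ex$obs$var],
               stringsAsFactors = FALSE))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Weighted squared fitting errors
#'
#' Per-point errors `0.5 * ((eta - pred)/sigma)^2`, per-series totals
#' (grouped by experiment and species, mirroring one trajectory panel
#' each), and the overall total.
#'
#' @param data measurement data frame (`experiment_id`, `species`,
#'   `time_h`, `abundance`, `std`).
#' @param predictions either a `glv_fit` or a data frame with columns
#'   `experiment_id`, `species`, `time_h`, `predicted`.
#' @return an `error_table`: `points` (per-record data frame with
#'   `value`), `series` (per experiment-species totals), `overall`.
#' @export
fitting_errors <- function(data, predictions) {
  validate_measurements(data)
  if (inherits(predictions, "glv_fit"))
    predictions <- fitted_measurements(predictions)
  key <- function(d) paste(d$experiment_id, d$species,
                           round(d$time_h, 9))
  idx <- match(key(data), key(predictions))
  if (anyNA(idx)) {
    miss <- data[which(is.na(idx))[1L], ]
    stopf("no prediction for record (%s, %s, %.3f h)",
          miss$experiment_id, miss$species, miss$time_h)
  }
  pts <- data[, c("experiment_id", "species", "time_h")]
  pts$value <- 0.5 * ((data$abundance - predictions$predicted[idx]) /
                        data$std)^2
  agg <- stats::aggregate(value ~ experiment_id + species, data = pts,
                          FUN = sum)
  agg <- agg[order(agg$experiment_id, agg$species), ]
  rownames(agg) <- NULL
  structure(list(points = pts, series = agg, overall = sum(pts$value)),
            class = "error_table")
}

#' @export
print.error_table <- function(x, ...) {
  cat(sprintf("Fitting errors: %d points, %d series, overall %.4g\n",
              nrow(x$points), nrow(x$series), x$overall))
  invisible(x)
}

#' Largest fitting errors
#'
#' The `k` largest entries of an error table at point or series
#' granularity, sorted by decreasing value with ties broken by
#' (experiment, species, time) lexicographic order.
#'
#' @param table an `error_table` from [fitting_errors()].
#' @param k number of entries (>= 1).
#' @param granularity `"point"` or `"series"`.
#' @return data frame of the top entries; if `k` exceeds the table size
#'   the whole table is returned with attribute `truncated = FALSE` set
#'   to note the short supply.
#' @export
top_k_errors <- function(table, k = 10, granularity = c("point", "series")) {
  granularity <- match.arg(granularity)
  if (k < 1) stopf("'k' must be >= 1")
  d <- if (granularity == "point") table$points else table$series
  ord <- if (granularity == "point")
    order(-d$value, d$experiment_id, d$species, d$time_h)
  else order(-d$value, d$experiment_id, d$species)
  out <- d[ord, , drop = FALSE]
  flag <- k > nrow(out)
  out <- utils::head(out, k)
  rownames(out) <- NULL
  attr(out, "short_supply") <- flag
  out
}

#' Mean of the largest fraction of errors
#'
#' The tail size is `ceiling(fraction * length(errors))`; the overall
#' mean is returned alongside to expose the robust-fitting trade-off
#' (smaller tail mean, larger overall mean).
#'
#' @param errors numeric vector of errors (or an `error_table`, whose
#'   point values are used).
#' @param fraction tail fraction in (0, 1].
#' @return list with `tail_mean` and `overall_mean`.
#' @export
tail_mean <- function(errors, fraction = 0.1) {
  if (inherits(errors, "error_table")) errors <- errors$points$value
  if (!length(errors)) stopf("'errors' must be non-empty")
  if (fraction <= 0 || fraction > 1)
    stopf("'fraction' must lie in (0, 1]")
  m <- ceiling(fraction * length(errors))
  srt <- sort(errors, decreasing = TRUE)
  list(tail_mean = mean(srt[seq_len(m)]), overall_mean = mean(errors))
}

#' Histogram bin counts of fitting errors (for export)
#'
#' @param table an `error_table`.
#' @param breaks number of bins or break vector (see [graphics::hist]).
#' @return data frame with `lower`, `upper`, `count`.
#' @export
error_histogram <- function(table, breaks = 30) {
  h <- graphics::hist(table$points$value, breaks = breaks, plot = FALSE)
  data.frame(lower = utils::head(h$breaks, -1L),
             upper = h$breaks[-1L], count = h$counts)
}
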