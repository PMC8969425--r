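# Prediction-corrected visual predictive checks.

#' Assign observations to time bins
#'
#' @param times numeric vector of times after first dose (h).
#' @param n_bins requested number of bins.
#' @param strategy `"quantile"` (near-equal occupancy, default) or
#'   `"fixed"` (equal-width edges, or user-supplied `edges`).
#' @param edges optional explicit bin edges for the fixed strategy.
#' @return Integer vector of bin indices (1-based). A time lying exactly on
#'   an interior edge goes to the lower bin. If fewer distinct times than
#'   bins are available, bins are merged with a warning.
#' @export
assign_bins <- function(times, n_bins = 8, strategy = c("quantile", "fixed"),
                        edges = NULL) {
  strategy <- match.arg(strategy)
  if (n_bins < 1) abort_pk("n_bins must be >= 1")
  if (n_bins == 1 && is.null(edges)) return(rep(1L, length(times)))
  if (is.null(edges)) {
    if (strategy == "quantile") {
      edges <- unique(stats::quantile(times, probs = seq(0, 1, length.out = n_bins + 1),
                                      names = FALSE, type = 7))
    } else {
      edges <- seq(min(times), max(times), length.out = n_bins + 1)
    }
  }
  edges <- unique(edges)
  if (length(edges) - 1 < n_bins) {
    warn_pk("only %d distinct bin(s) supported by the data; bins merged",
            max(length(edges) - 1, 1))
  }
  if (length(edges) < 2) return(rep(1L, length(times)))
  as.integer(cut(times, breaks = edges, include.lowest = TRUE, right = TRUE))
}

#' Prediction correction
#'
#' Rescales each value by the ratio of its bin's median population
#' prediction to the record's own population prediction, so observations
#' (and simulated values) taken under different doses and covariates become
#' comparable within a bin. Applied identically to observed and simulated
#' values.
#'
#' @param value numeric vector (or matrix with one column per record) of
#'   concentrations.
#' @param pred strictly positive population predictions, one per record.
#' @param bin bin index per record (see [assign_bins()]).
#' @return Corrected values, same shape as `value`.
#' @export
prediction_correct <- function(value, pred, bin) {
  if (any(!is.finite(pred)) || any(pred <= 0)) {
    abort_pk("prediction correction needs strictly positive PRED for every record")
  }
  med <- tapply(pred, bin, stats::median)
  ratio <- as.numeric(med[as.character(bin)]) / pred
  if (is.matrix(value)) sweep(value, 2, ratio, `*`) else value * ratio
}

#' Percentage of points outside the prediction interval
#'
#' Count-to-percentage arithmetic used in outside-band reporting: one
#' decimal, halves rounded away from zero.
#'
#' @param count number of observations outside the band.
#' @param total total number of observations.
#' @return Percentage rounded to one decimal.
#' @export
#' @examples
#' outside_percentage(5, 103)
outside_percentage <- function(count, total) {
  if (any(count > total)) abort_pk("count cannot exceed total")
  round_half_away(100 * count / total, 1)
}

#' Prediction-corrected visual predictive check
#'
#' Bins observations on time after first dose, prediction-corrects observed
#' and simulated values identically, and per bin compares the observed
#' 5th/50th/95th percentiles to the band spanned by the pooled corrected
#' simulated values (by default the 2.5th-97.5th percentiles, i.e. a 95%
#' prediction interval for the concentrations). Each observation is flagged
#' as outside if its corrected value falls strictly outside its bin's band;
#' the outside percentage is reported to one decimal.
#'
#' @param data study dataset tibble (quantifiable observations only).
#' @param ensemble a `pk_ensemble` from [simulate_ensemble()] aligned to
#'   `data`.
#' @param model the [pk_model()] (used for the population predictions that
#'   drive the correction); not needed if `data` already has a `pred`
#'   column.
#' @param n_bins number of time bins (quantile binning).
#' @param pi width of the prediction interval (default 0.95).
#' @param correct apply prediction correction (set `FALSE` for a plain VPC).
#' @param log_scale perform the comparison on log-transformed values.
#' @param max_time drop records observed later than this time (h) from the
#'   check (default `Inf`: all records are counted).
#' @return An object of class `pk_vpc`: list with `bands` (per analyte x
#'   bin: band and observed percentiles), `records` (per observation:
#'   corrected value, band, outside flag) and `summary` (per analyte:
#'   `n`, `outside`, `pct_outside`).
#' @export
vpc_bands <- function(data, ensemble, model = NULL, n_bins = 8, pi = 0.95,
                      correct = TRUE, log_scale = FALSE, max_time = Inf) {
  stopifnot(inherits(ensemble, "pk_ensemble"))
  if (ensemble$nsim < 2) abort_pk("a VPC needs nsim >= 2 simulation replicates")
  if (!"pred" %in% names(data)) {
    if (is.null(model)) abort_pk("either a pred column or a model is required")
    data <- population_prediction(data, model)
  }
  obs <- data[data$evid == 0, , drop = FALSE]
  if (nrow(obs) != ncol(ensemble$sim)) {
    abort_pk("ensemble (%d records) is not aligned to the dataset (%d observations)",
             ncol(ensemble$sim), nrow(obs))
  }
  keep <- obs$time <= max_time
  obs <- obs[keep, , drop = FALSE]
  sim <- ensemble$sim[, keep, drop = FALSE]
  if (correct) {
    # the prediction correction is undefined where PRED is not positive
    # (e.g. samples inside an absorption lag window); such records cannot
    # enter a prediction-corrected VPC
    bad <- !is.finite(obs$pred) | obs$pred <= 0
    if (any(bad)) {
      warn_pk("%d record(s) with non-positive PRED excluded from the prediction-corrected VPC",
              sum(bad))
      obs <- obs[!bad, , drop = FALSE]
      sim <- sim[, !bad, drop = FALSE]
    }
  }

  records <- vector("list", 0)
  bands <- vector("list", 0)
  summary <- vector("list", 0)
  lo_q <- (1 - pi) / 2
  hi_q <- 1 - lo_q

  for (an in unique(obs$analyte)) {
    sel <- obs$analyte == an
    o <- obs[sel, , drop = FALSE]
    s <- sim[, sel, drop = FALSE]
    bin <- assign_bins(o$time, n_bins)
    if (correct) {
      oc <- prediction_correct(o$dv, o$pred, bin)
      sc <- prediction_correct(s, o$pred, bin)
    } else {
      oc <- o$dv
      sc <- s
    }
    if (log_scale) {
      oc <- log(oc)
      sc <- log(pmax(sc, 1e-300))
    }
    ub <- sort(unique(bin))
    bb <- lapply(ub, function(b) {
      i <- bin == b
      if (!any(i)) abort_pk("empty bin in VPC")
      pool <- as.numeric(sc[, i, drop = FALSE])
      qs <- stats::quantile(pool, c(lo_q, hi_q), names = FALSE)
      op <- stats::quantile(oc[i], c(0.05, 0.5, 0.95), names = FALSE)
      tibble::tibble(analyte = an, bin = b,
                     t_lo = min(o$time[i]), t_hi = max(o$time[i]),
                     t_mid = stats::median(o$time[i]),
                     band_lo = qs[1], band_hi = qs[2],
                     obs_p5 = op[1], obs_p50 = op[2], obs_p95 = op[3],
                     n_obs = sum(i))
    })
    bb <- dplyr::bind_rows(bb)
    lo <- bb$band_lo[match(bin, bb$bin)]
    hi <- bb$band_hi[match(bin, bb$bin)]
    outside <- oc < lo | oc > hi
    records[[an]] <- tibble::tibble(
      analyte = an, id = o$id, time = o$time, bin = bin,
      value_corrected = oc, band_lo = lo, band_hi = hi, outside = outside
    )
    bands[[an]] <- bb
    summary[[an]] <- tibble::tibble(
      analyte = an, n = length(oc), outside = sum(outside),
      pct_outside = outside_percentage(sum(outside), length(oc))
    )
  }

  structure(
    list(bands = dplyr::bind_rows(bands), records = dplyr::bind_rows(records),
         summary = dplyr::bind_rows(summary), nsim = ensemble$nsim,
         pi = pi, corrected = correct, log_scale = log_scale),
    class = "pk_vpc"
  )
}

#' @export
print.pk_vpc <- function(x, ...) {
  cat(sprintf("<pk_vpc> %s, %d replicates, %.0f%% prediction interval\n",
              if (x$corrected) "prediction-corrected" else "uncorrected",
              x$nsim, 100 * x$pi))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.pk_vpc <- function(x, ...) x$bands

#' @export
glance.pk_vpc <- function(x, ...) x$summary

#' Plot a (prediction-corrected) VPC
#'
#' Band as a shaded ribbon over time, observed percentiles as lines, and the
#' individual (corrected) observations as points, faceted by analyte.
#'
#' @param object a `pk_vpc` object.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.pk_vpc <- function(object, ...) {
  b <- object$bands
  r <- object$records
  ggplot2::ggplot(b, ggplot2::aes(x = .data$t_mid)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$band_lo, ymax = .data$band_hi),
                         fill = "grey70", alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$obs_p50), linetype = 2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$obs_p5), linetype = 3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$obs_p95), linetype = 3) +
    ggplot2::geom_point(data = r,
                        ggplot2::aes(x = .data$time, y = .data$value_corrected,
                                     colour = .data$outside), size = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black", `TRUE` = "red"),
                                 guide = "none") +
    ggplot2::facet_wrap(~analyte, scales = "free") +
    ggplot2::labs(x = "time after first dose (h)",
                  y = if (object$corrected) "prediction-corrected concentration (nmol/mL)"
                      else "concentration (nmol/mL)")
}
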