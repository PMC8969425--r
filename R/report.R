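# End-to-end external-evaluation pipeline.

#' Run the full external evaluation of one or more models
#'
#' For every model: population predictions and the prediction-based metrics
#' (PE, RMSE, MPE, MAPE per analyte), empirical-Bayes fits and conditional
#' weighted residuals, a K-replicate simulation ensemble, the
#' prediction-corrected VPC with outside-band counts, and the NPDE with
#' their hypothesis tests. Failure of one model's branch is caught and
#' reported without aborting the whole run. A cross-model comparison table
#' ranks models by RMSE and |MPE| per analyte.
#'
#' @param data study dataset tibble (internal units). BQL records are
#'   excluded automatically (with a reported count) before evaluation.
#' @param models a [pk_model()] or (named) list of them.
#' @param nsim simulation replicates per model (K).
#' @param seed master seed; each model's simulation uses the same master
#'   seed, so two identical model configurations yield identical reports.
#' @param n_bins VPC time bins.
#' @param mixture_pred PRED convention for mixture models (see
#'   [population_prediction()]).
#' @param ebe compute EBE fits and CWRES (the slowest stage; set `FALSE` to
#'   skip).
#' @return An object of class `pk_evaluation`: per-model results
#'   (`$models`), the comparison table (`$comparison`) and the BQL exclusion
#'   counts (`$bql_excluded`).
#' @export
run_evaluation <- function(data, models, nsim = 1000, seed = 1, n_bins = 8,
                           mixture_pred = "weighted", ebe = TRUE) {
  if (inherits(models, "pk_model")) models <- list(models)
  if (is.null(names(models)) || any(names(models) == "")) {
    names(models) <- vapply(models, function(m) m$label, character(1))
  }
  if (length(models) < 1) abort_pk("at least one model is required")
  data <- bql_filter(data)
  excluded <- attr(data, "bql_excluded")

  results <- lapply(names(models), function(nm) {
    model <- models[[nm]]
    tryCatch({
      keep <- data$evid == 1 | data$analyte %in% analyte_names(model)
      d <- data[keep, , drop = FALSE]
      d <- population_prediction(d, model, mixture_pred = mixture_pred)
      # bias/precision metrics stay on the natural concentration scale for
      # every model so PE/RMSE are comparable in nmol/mL across models;
      # prediction_metrics(log_scale = TRUE) remains available separately
      metrics <- prediction_metrics(d, "dv", "pred", .data$analyte)
      ens <- simulate_ensemble(d, model, nsim = nsim, seed = seed)
      vpc <- tryCatch(
        vpc_bands(d, ens, n_bins = n_bins, log_scale = model$scale == "log"),
        error = function(e) {
          warn_pk("pcVPC for model %s not computed: %s", nm, conditionMessage(e))
          NULL
        })
      npde <- tryCatch(
        compute_npde(d, ens),
        error = function(e) {
          warn_pk("NPDE for model %s not computed: %s", nm, conditionMessage(e))
          NULL
        })
      fits <- NULL
      gof <- d
      if (ebe) {
        fits <- ebe_estimate(d, model)
        gof <- compute_cwres(d, model, fits)
      }
      list(model = model, data = gof, metrics = metrics, ensemble_seed = seed,
           vpc = vpc, npde = npde, ebe = fits, error = NULL)
    }, error = function(e) {
      warn_pk("evaluation of model %s failed: %s", nm, conditionMessage(e))
      list(model = model, error = conditionMessage(e))
    })
  })
  names(results) <- names(models)

  metrics_all <- dplyr::bind_rows(lapply(names(results), function(nm) {
    r <- results[[nm]]
    if (is.null(r$error)) dplyr::mutate(r$metrics, model = nm, .before = 1) else NULL
  }))
  comparison <- NULL
  if (nrow(metrics_all %||% tibble::tibble())) {
    comparison <- metrics_all |>
      dplyr::group_by(.data$analyte) |>
      dplyr::mutate(rank_rmse = rank(.data$rmse, ties.method = "min"),
                    rank_abs_mpe = rank(abs(.data$mpe), ties.method = "min")) |>
      dplyr::ungroup() |>
      dplyr::arrange(.data$analyte, .data$rank_rmse)
  }

  structure(list(models = results, comparison = comparison,
                 bql_excluded = excluded, nsim = nsim, seed = seed),
            class = "pk_evaluation")
}

#' @export
print.pk_evaluation <- function(x, ...) {
  cat(sprintf("<pk_evaluation> %d model(s), %d replicates (seed %d)\n",
              length(x$models), x$nsim, x$seed))
  if (!is.null(x$comparison)) {
    print(x$comparison[, c("model", "analyte", "n", "pe", "rmse", "mpe", "mape")])
  }
  for (nm in names(x$models)) {
    r <- x$models[[nm]]
    if (!is.null(r$error)) {
      cat(sprintf("  model %s FAILED: %s\n", nm, r$error))
    } else if (!is.null(r$vpc)) {
      s <- r$vpc$summary
      cat(sprintf("  model %s pcVPC outside: %s\n", nm,
                  paste(sprintf("%s %.1f%% (%d/%d)", s$analyte, s$pct_outside,
                                s$outside, s$n), collapse = "; ")))
    }
  }
  invisible(x)
}

#' Tidy an evaluation report
#'
#' @param x a `pk_evaluation`.
#' @param ... unused.
#' @return Long tibble of per-model, per-analyte metrics, pcVPC outside
#'   percentages and NPDE test p-values.
#' @export
tidy.pk_evaluation <- function(x, ...) {
  dplyr::bind_rows(lapply(names(x$models), function(nm) {
    r <- x$models[[nm]]
    if (!is.null(r$error)) return(NULL)
    m <- dplyr::mutate(r$metrics, model = nm, .before = 1)
    v <- if (is.null(r$vpc)) {
      tibble::tibble(analyte = character(), pct_outside = numeric())
    } else {
      r$vpc$summary[, c("analyte", "pct_outside")]
    }
    npde_mean <- if (is.null(r$npde)) {
      tibble::tibble(analyte = character(), npde_mean = numeric(), npde_var = numeric())
    } else {
      r$npde$records |>
        dplyr::group_by(.data$analyte) |>
        dplyr::summarise(npde_mean = mean(.data$npde), npde_var = stats::var(.data$npde),
                         .groups = "drop")
    }
    m |>
      dplyr::left_join(v, by = "analyte") |>
      dplyr::left_join(npde_mean, by = "analyte")
  }))
}

#' One-row-per-model summary of an evaluation
#'
#' @param x a `pk_evaluation`.
#' @param ... unused.
#' @return Tibble with one row per model x analyte including the global
#'   NPDE verdict.
#' @export
glance.pk_evaluation <- function(x, ...) {
  dplyr::bind_rows(lapply(names(x$models), function(nm) {
    r <- x$models[[nm]]
    if (!is.null(r$error)) {
      return(tibble::tibble(model = nm, failed = TRUE))
    }
    verdict <- if (is.null(r$npde)) {
      tibble::tibble(analyte = character(), npde_min_p = numeric(), npde_reject = logical())
    } else {
      r$npde$tests |>
        dplyr::group_by(.data$analyte) |>
        dplyr::summarise(npde_min_p = min(.data$p_value),
                         npde_reject = min(.data$p_value) < 0.05 / 3, .groups = "drop")
    }
    tidy_row <- tidy.pk_evaluation(structure(list(models = x$models[nm]),
                                             class = "pk_evaluation"))
    dplyr::left_join(tidy_row, verdict, by = "analyte") |>
      dplyr::mutate(failed = FALSE)
  }))
}

#' Observed-versus-predicted goodness-of-fit plot
#'
#' @param data tibble with `dv` and `pred` columns (e.g. a model's `$data`
#'   slot of a [run_evaluation()] result).
#' @param log_scale plot on log-log axes.
#' @return A ggplot object faceted by analyte, with the identity line.
#' @export
plot_gof <- function(data, log_scale = TRUE) {
  d <- data[data$evid == 0 & !is.na(data$dv), , drop = FALSE]
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$pred, y = .data$dv)) +
    ggplot2::geom_point(size = 1, alpha = 0.7) +
    ggplot2::geom_abline(linetype = 2) +
    ggplot2::facet_wrap(~analyte, scales = "free") +
    ggplot2::labs(x = "population prediction (nmol/mL)", y = "observation (nmol/mL)")
  if (log_scale) p <- p + ggplot2::scale_x_log10() + ggplot2::scale_y_log10()
  p
}
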