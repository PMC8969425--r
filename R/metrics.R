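# Prediction-based bias and precision metrics.

#' Prediction error metrics (PE, RMSE, MPE, MAPE)
#'
#' Compares observations to population predictions, pooling all observation
#' records (optionally per group):
#' PE = mean(pred - obs), RMSE = sqrt(mean((pred - obs)^2)),
#' MPE = 100 * mean((pred - obs) / obs), MAPE = 100 * mean(|pred - obs| / obs).
#' With the pred - obs orientation a model that systematically over-predicts
#' has positive PE and MPE. PE and RMSE carry the concentration unit
#' (nmol/mL); MPE and MAPE are percentages.
#'
#' @param data tibble holding observations and predictions (e.g. output of
#'   [population_prediction()]); dose rows (`evid == 1`) are ignored.
#' @param obs,pred column names (tidy-eval) of the observed and predicted
#'   concentrations; defaults `dv` and `pred`.
#' @param ... optional grouping columns (tidy-eval), e.g. `analyte`.
#' @param log_scale compute the metrics on log-transformed concentrations
#'   (for models fitted on the log scale).
#' @return Tibble with one row per group: `n`, `pe`, `rmse`, `mpe`, `mape`.
#' @export
#' @examples
#' prediction_metrics(
#'   tibble::tibble(dv = c(1, 1), pred = c(1.2, 0.8), evid = 0)
#' )
prediction_metrics <- function(data, obs = "dv", pred = "pred", ...,
                               log_scale = FALSE) {
  if ("evid" %in% names(data)) data <- data[data$evid == 0, , drop = FALSE]
  o <- data[[obs]]
  p <- data[[pred]]
  if (is.null(o) || is.null(p)) abort_pk("columns '%s' and '%s' are required", obs, pred)
  bad <- which(!is.na(o) & o <= 0)
  if (length(bad)) {
    abort_pk("non-positive observation(s) at record(s) %s; exclude BQL data first",
             paste(utils::head(bad, 5), collapse = ", "))
  }
  data <- data[!is.na(o) & !is.na(p), , drop = FALSE]
  if (log_scale) {
    data[[obs]] <- log(data[[obs]])
    data[[pred]] <- log(data[[pred]])
  }
  data |>
    dplyr::group_by(...) |>
    dplyr::summarise(
      n = sum(!is.na(.data[[obs]])),
      pe = mean(.data[[pred]] - .data[[obs]]),
      rmse = sqrt(mean((.data[[pred]] - .data[[obs]])^2)),
      mpe = 100 * mean((.data[[pred]] - .data[[obs]]) / .data[[obs]]),
      mape = 100 * mean(abs(.data[[pred]] - .data[[obs]]) / .data[[obs]]),
      .groups = "drop"
    )
}
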