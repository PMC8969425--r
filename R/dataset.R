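# Longitudinal event datasets.
#
# A study dataset is an ordinary tibble in long event format, one row per
# dose or observation:
#   id      subject identifier
#   time    hours after the subject's first recorded dose (>= 0)
#   evid    1 = dose, 0 = observation
#   amt     dose amount in nmol (dose rows)
#   analyte analyte name (observation rows)
#   dv      observed concentration in nmol/mL (observation rows; NA if BQL)
#   bql     TRUE if the observation was below the quantification limit
#   wt, age covariates (kg, years); further covariate columns are allowed
# Being a plain tibble keeps the whole pipeline pipeable.

dataset_columns <- c("id", "time", "evid", "amt", "analyte", "dv", "bql", "wt", "age")

check_dataset <- function(data, require_obs = TRUE) {
  missing <- setdiff(c("id", "time", "evid"), names(data))
  if (length(missing)) abort_pk("dataset is missing columns: %s", paste(missing, collapse = ", "))
  if (any(data$time < 0, na.rm = TRUE)) abort_pk("negative times in dataset")
  doses <- data[data$evid == 1, ]
  if (nrow(doses) && (!"amt" %in% names(data) || any(!is.finite(doses$amt) | doses$amt <= 0))) {
    abort_pk("every dose row needs a positive amt")
  }
  obs <- data[data$evid == 0, ]
  if (require_obs && nrow(obs) == 0) abort_pk("dataset has no observation records")
  if (nrow(obs) && !"analyte" %in% names(data)) abort_pk("observation rows need an analyte column")
  unsorted <- data |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(bad = is.unsorted(.data$time), .groups = "drop")
  if (any(unsorted$bad)) {
    abort_pk("times are not non-decreasing within subject(s): %s",
             paste(unsorted$id[unsorted$bad], collapse = ", "))
  }
  invisible(data)
}

subject_covariates <- function(data) {
  covs <- intersect(setdiff(names(data), c("id", "time", "evid", "amt", "analyte", "dv", "bql")),
                    names(data))
  data |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(covs), dplyr::first), .groups = "drop")
}

# split into per-subject design pieces; obs rows carry .row, their position
# in the observation table (the column order of simulation ensembles)
split_design <- function(data, model) {
  obs <- data |>
    dplyr::filter(.data$evid == 0) |>
    dplyr::mutate(.row = dplyr::row_number(),
                  role = analyte_roles(model, .data$analyte))
  doses <- data |> dplyr::filter(.data$evid == 1)
  ids <- unique(data$id)
  covs <- subject_covariates(data)
  lapply(ids, function(i) {
    list(
      id = i,
      covs = as.list(covs[covs$id == i, , drop = FALSE]),
      doses = doses[doses$id == i, c("time", "amt")],
      obs = obs[obs$id == i, ]
    )
  })
}

analyte_roles <- function(model, analyte) {
  nms <- analyte_names(model)
  roles <- vapply(model$analytes, function(a) a$role, character(1))
  bad <- setdiff(unique(analyte), nms)
  if (length(bad)) {
    abort_pk("dataset analyte(s) %s not in model %s (expects %s)",
             paste(bad, collapse = ", "), model$label, paste(nms, collapse = ", "))
  }
  roles[match(analyte, nms)]
}

#' Drop below-quantification-limit records
#'
#' None of the evaluation diagnostics can use censored records unless the
#' model itself handles censoring, so BQL observations are excluded up front
#' and the exclusion is reported per analyte.
#'
#' @param data a study dataset tibble with a logical `bql` column.
#' @return The dataset without BQL observation rows. The per-analyte counts
#'   of excluded records are attached as attribute `"bql_excluded"` (a
#'   tibble) and reported via a message.
#' @export
bql_filter <- function(data) {
  if (!"bql" %in% names(data)) abort_pk("dataset has no bql column")
  drop <- data$evid == 0 & !is.na(data$bql) & data$bql
  excluded <- data[drop, ] |>
    dplyr::count(.data$analyte, name = "n_excluded")
  out <- data[!drop, , drop = FALSE]
  if (any(drop)) {
    msg <- paste(sprintf("%s: %d", excluded$analyte, excluded$n_excluded), collapse = ", ")
    message("Excluded BQL records - ", msg)
  }
  if (sum(data$evid == 0) > 0 && sum(out$evid == 0) == 0) {
    warn_pk("all observation records were BQL; the filtered dataset has no observations")
  }
  attr(out, "bql_excluded") <- excluded
  out
}
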