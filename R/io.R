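# Dataset readers/writers.
#
# CSV dialect: comma separated, header required, "." as missing marker.
# Canonical column names are lowercase (id, time, evid, amt, analyte, dv,
# bql, wt, age) but the common NONMEM-style uppercase aliases (ID, TIME,
# EVID, AMT, DV, MDV, WT, AGE) are accepted. External units are ng/mL for
# concentrations and mg for dose amounts; internal units are nmol/mL and
# nmol (conversion through the analyte molecular weights).

DATASET_ALIASES <- c(
  ID = "id", TIME = "time", EVID = "evid", AMT = "amt", DV = "dv",
  ANALYTE = "analyte", CMT = "analyte", BQL = "bql", BLQ = "bql",
  WT = "wt", WEIGHT = "wt", AGE = "age", MDV = "mdv"
)

#' Read a study dataset from CSV
#'
#' @param path CSV file path.
#' @param model a [pk_model()] whose analytes supply the molecular weights
#'   used for unit conversion (required when `units = "external"`).
#' @param units `"external"` (file in ng/mL and mg; converted to internal
#'   molar units on read) or `"internal"` (file already in nmol/mL, nmol).
#' @return A validated study dataset tibble in internal units. Observations
#'   recorded before any dose of their subject are accepted with a warning
#'   (pre-dose samples).
#' @export
read_dataset <- function(path, model = NULL, units = c("external", "internal")) {
  units <- match.arg(units)
  if (!file.exists(path)) abort_pk("file not found: %s", path)
  raw <- utils::read.csv(path, na.strings = c("NA", "."), stringsAsFactors = FALSE)
  hit <- names(raw) %in% names(DATASET_ALIASES)
  names(raw)[hit] <- DATASET_ALIASES[names(raw)[hit]]
  data <- tibble::as_tibble(raw)
  if ("mdv" %in% names(data) && !"evid" %in% names(data)) {
    data$evid <- as.integer(data$mdv != 0)
  }
  data$evid <- as.integer(data$evid)
  if (!"bql" %in% names(data)) data$bql <- ifelse(data$evid == 0, FALSE, NA)
  data$bql <- as.logical(data$bql)
  obs <- data$evid == 0
  if (any(obs & is.na(data$analyte))) {
    abort_pk("observation rows without an analyte: rows %s",
             paste(utils::head(which(obs & is.na(data$analyte)), 5), collapse = ", "))
  }
  if (any(data$time < 0, na.rm = TRUE)) {
    abort_pk("negative time at rows %s",
             paste(utils::head(which(data$time < 0), 5), collapse = ", "))
  }

  if (units == "external") {
    if (is.null(model)) abort_pk("a model is required to convert external units")
    parent <- model_analyte(model, "parent")
    dose <- data$evid == 1
    data$amt[dose] <- mass_to_molar(data$amt[dose], parent, "amount")
    for (a in model$analytes) {
      sel <- obs & data$analyte == a$name & !is.na(data$dv)
      data$dv[sel] <- mass_to_molar(data$dv[sel], a)
    }
  }

  check_dataset(data, require_obs = FALSE)
  pre <- data |>
    dplyr::group_by(.data$id) |>
    dplyr::mutate(.first_dose = suppressWarnings(min(.data$time[.data$evid == 1]))) |>
    dplyr::ungroup()
  n_pre <- sum(pre$evid == 0 & pre$time < pre$.first_dose, na.rm = TRUE)
  if (n_pre > 0) warn_pk("%d observation(s) recorded before any dose (pre-dose samples)", n_pre)
  data
}

#' Write a study dataset to CSV
#'
#' @param data study dataset tibble in internal molar units.
#' @param path output path.
#' @param model a [pk_model()] (needed to convert back to external units).
#' @param units write `"internal"` molar units (default, lossless round
#'   trip) or `"external"` mass units.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path, model = NULL, units = c("internal", "external")) {
  units <- match.arg(units)
  out <- as.data.frame(data)
  if (units == "external") {
    if (is.null(model)) abort_pk("a model is required to convert to external units")
    parent <- model_analyte(model, "parent")
    dose <- out$evid == 1
    out$amt[dose] <- molar_to_mass(out$amt[dose], parent, "amount")
    for (a in model$analytes) {
      sel <- out$evid == 0 & out$analyte == a$name & !is.na(out$dv)
      out$dv[sel] <- molar_to_mass(out$dv[sel], a)
    }
  }
  utils::write.csv(out, path, row.names = FALSE, na = ".")
  invisible(path)
}
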