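#' Analyte specification
#'
#' Describes one measured compound: its name, molecular weight and its role
#' in a parent-metabolite model. Concentrations are handled internally in
#' nmol/mL and amounts in nmol; the molecular weight converts between the
#' external mass units (ng/mL, mg) and the internal molar units.
#'
#' @param name character label, e.g. `"risperidone"`.
#' @param molecular_weight molecular weight in g/mol; must be positive.
#' @param role `"parent"` or `"metabolite"`.
#' @return An object of class `pk_analyte`.
#' @export
#' @examples
#' risp <- pk_analyte("risperidone", 410.485, "parent")
#' mass_to_molar(0.100, risp) # the 0.100 ng/mL assay LLOQ in nmol/mL
pk_analyte <- function(name, molecular_weight, role = c("parent", "metabolite")) {
  role <- match.arg(role)
  if (!is.numeric(molecular_weight) || length(molecular_weight) != 1 ||
      !is.finite(molecular_weight) || molecular_weight <= 0) {
    abort_pk("molecular_weight must be a single positive number")
  }
  structure(
    list(name = as.character(name), molecular_weight = molecular_weight, role = role),
    class = "pk_analyte"
  )
}

#' @export
print.pk_analyte <- function(x, ...) {
  cat(sprintf("<pk_analyte> %s (%s), MW %.3f g/mol\n", x$name, x$role, x$molecular_weight))
  invisible(x)
}

#' Convert mass units to molar units
#'
#' Divides a concentration in ng/mL (or an amount in mg) by the analyte's
#' molecular weight, yielding nmol/mL (or nmol). The numerical factor is the
#' same for both conversions: 1 mg = 1e6 ng, and 1 nmol = MW ng, so
#' mg / MW * 1e3 umol = ... reduces to `value / MW` for ng/mL -> nmol/mL and
#' `value * 1e6 / MW` for mg -> nmol.
#'
#' @param value non-negative numeric vector.
#' @param analyte a [pk_analyte()].
#' @param what `"concentration"` (ng/mL -> nmol/mL) or `"amount"` (mg -> nmol).
#' @return numeric vector in molar units.
#' @export
mass_to_molar <- function(value, analyte, what = c("concentration", "amount")) {
  what <- match.arg(what)
  stopifnot(inherits(analyte, "pk_analyte"))
  if (any(value < 0, na.rm = TRUE)) abort_pk("negative mass values cannot be converted")
  if (what == "concentration") value / analyte$molecular_weight
  else value * 1e6 / analyte$molecular_weight
}

#' Convert molar units back to mass units
#'
#' Inverse of [mass_to_molar()].
#' @inheritParams mass_to_molar
#' @return numeric vector in ng/mL or mg.
#' @export
molar_to_mass <- function(value, analyte, what = c("concentration", "amount")) {
  what <- match.arg(what)
  stopifnot(inherits(analyte, "pk_analyte"))
  if (what == "concentration") value * analyte$molecular_weight
  else value * analyte$molecular_weight / 1e6
}
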