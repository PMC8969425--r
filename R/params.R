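# Individual parameter resolution: theta -> mixture override -> covariate
# terms -> multiplicative exp(eta).

# Vectorised resolver used by the simulation engine: eta is a K x p matrix
# (columns named), subpop a length-K character vector (NA when no mixture).
# covs is a named list of scalar covariate values for one subject.
# Returns a named list of length-K parameter vectors.
indiv_pars_matrix <- function(model, covs, eta = NULL, subpop = NULL) {
  K <- if (!is.null(eta)) nrow(eta) else if (!is.null(subpop)) length(subpop) else 1L
  pars <- lapply(model$theta, function(v) rep.int(as.numeric(v), K))

  if (!is.null(model$mixture)) {
    if (is.null(subpop)) abort_pk("model %s has a mixture: a subpopulation label is required", model$label)
    labels <- names(model$mixture$proportions)
    bad <- setdiff(unique(subpop), labels)
    if (length(bad)) abort_pk("unknown subpopulation label(s): %s", paste(bad, collapse = ", "))
    for (sp in labels) {
      idx <- subpop == sp
      if (!any(idx)) next
      ov <- model$mixture$overrides[[sp]]
      for (nm in names(ov)) pars[[nm]][idx] <- as.numeric(ov[[nm]])
    }
  }

  for (term in model$covariates) {
    x <- covs[[term$covariate]]
    if (is.null(x) || is.na(x)) {
      abort_pk("covariate '%s' required by model %s is missing from the subject",
               term$covariate, model$label)
    }
    fac <- switch(term$form,
      power = (x / term$reference)^term$exponent,
      linear = 1 + term$slope * (x - term$reference)
    )
    pars[[term$parameter]] <- pars[[term$parameter]] * fac
  }

  if (!is.null(eta) && ncol(eta) > 0) {
    for (j in seq_len(ncol(eta))) {
      nm <- colnames(eta)[j]
      pars[[nm]] <- pars[[nm]] * exp(eta[, j])
    }
  }
  pars
}

#' Resolve individual parameters
#'
#' Applies, in order: the subpopulation's mixture overrides (if the model has
#' a mixture), the covariate terms (e.g. allometric weight scaling), and the
#' multiplicative `exp(eta)` inter-individual random effects. With `eta = 0`,
#' reference covariates and no mixture this returns theta unchanged.
#'
#' @param model a [pk_model()].
#' @param covariates named list or one-row data frame of covariate values
#'   (e.g. `list(wt = 18.7)`).
#' @param eta named numeric vector of random effects (names matching
#'   `rownames(model$omega)`); `NULL` means all zero.
#' @param subpop subpopulation label; required for mixture models, ignored
#'   otherwise.
#' @return Named list of individual parameter values.
#' @export
#' @examples
#' m <- model_library("b")
#' individual_parameters(m, list(wt = 35), subpop = "normal")
individual_parameters <- function(model, covariates = list(), eta = NULL, subpop = NULL) {
  stopifnot(inherits(model, "pk_model"))
  covariates <- as.list(covariates)
  en <- eta_names(model)
  if (is.null(eta)) {
    eta <- stats::setNames(rep(0, length(en)), en)
  } else {
    if (!all(names(eta) %in% en)) abort_pk("eta names must match rownames(model$omega)")
    full <- stats::setNames(rep(0, length(en)), en)
    full[names(eta)] <- eta
    eta <- full
  }
  em <- matrix(eta, nrow = 1, dimnames = list(NULL, names(eta)))
  pars <- indiv_pars_matrix(model, covariates, eta = em,
                            subpop = if (!is.null(model$mixture)) subpop)
  lapply(pars, function(v) unname(v[1]))
}
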