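# Population model representation.
#
# A pk_model bundles everything needed to simulate or predict for one
# published model: the analytes, the compartmental structure, typical-value
# parameters (theta), the log-normal inter-individual covariance (omega),
# an optional finite mixture of metabolizer subpopulations, covariate terms,
# and per-analyte residual error. All internal units are molar: clearances
# L/h, volumes L, amounts nmol, concentrations nmol/mL.

PK_PAR_NAMES <- c("CL", "V", "ka", "ALAG", "Q", "Vp", "fm", "CLm", "Vm", "F")

#' Compartmental structure of a parent-metabolite model
#'
#' @param parent_compartments 1 or 2 disposition compartments for the parent.
#' @param has_metabolite does the model also describe a 1-compartment
#'   metabolite formed from the parent?
#' @param lag is an absorption lag time (`ALAG`) part of the model?
#' @return a `pk_structure` list.
#' @export
pk_structure <- function(parent_compartments = 1, has_metabolite = FALSE, lag = FALSE) {
  if (!parent_compartments %in% c(1, 2)) abort_pk("parent_compartments must be 1 or 2")
  structure(
    list(parent_compartments = as.integer(parent_compartments),
         has_metabolite = isTRUE(has_metabolite), lag = isTRUE(lag)),
    class = "pk_structure"
  )
}

required_pars <- function(structure) {
  p <- c("CL", "V", "ka")
  if (structure$parent_compartments == 2) p <- c(p, "Q", "Vp")
  if (structure$has_metabolite) p <- c(p, "fm", "CLm", "Vm")
  p
}

#' Allometric covariate preset
#'
#' Body-weight power terms with the conventional fixed exponents: 0.75 on
#' clearances and 1 on volumes, referenced to 70 kg.
#'
#' @param clearances,volumes character vectors of parameter names to scale.
#' @param reference reference weight in kg.
#' @return a list of covariate terms usable as the `covariates` argument of
#'   [pk_model()].
#' @export
allometric_terms <- function(clearances = c("CL", "Q", "CLm"),
                             volumes = c("V", "Vp", "Vm"),
                             reference = 70) {
  c(
    lapply(clearances, function(p)
      list(parameter = p, covariate = "wt", form = "power",
           reference = reference, exponent = 0.75)),
    lapply(volumes, function(p)
      list(parameter = p, covariate = "wt", form = "power",
           reference = reference, exponent = 1))
  )
}

#' Define a population pharmacokinetic model
#'
#' @param label short model label ("A".."E" for the shipped examples, or any
#'   user label).
#' @param analytes list of one or two [pk_analyte()] objects (at most one
#'   parent and one metabolite).
#' @param structure a [pk_structure()].
#' @param theta named list/vector of typical values. Recognised names:
#'   `CL`, `V`, `ka` (always); `Q`, `Vp` (2-compartment parent); `fm`, `CLm`,
#'   `Vm` (metabolite); `ALAG` (lag, h); `F` (bioavailability, default 1).
#' @param omega covariance matrix of the log-normal inter-individual random
#'   effects; row/column names must be parameter names. May be `NULL` (no
#'   IIV). Must be symmetric positive semidefinite.
#' @param mixture optional subpopulation mixture: a list with `proportions`
#'   (named numeric, summing to 1) and `overrides` (named list per
#'   subpopulation of theta entries, typically `CL` and/or `fm`).
#' @param covariates list of covariate terms, each a list with `parameter`,
#'   `covariate`, `form` (`"power"` or `"linear"`), `reference` and
#'   `exponent` (power) or `slope` (linear). See [allometric_terms()].
#' @param error per-analyte residual error: a named list (by analyte name) of
#'   lists with `additive` (sd, nmol/mL on natural scale; sd of log
#'   concentration on log scale) and `proportional` (fractional sd).
#' @param scale `"natural"` or `"log"`: the scale on which residual error acts
#'   and on which the model was fitted.
#' @return an object of class `pk_model`.
#' @export
#' @examples
#' m <- pk_model(
#'   label = "demo",
#'   analytes = list(pk_analyte("risperidone", 410.485, "parent")),
#'   structure = pk_structure(1),
#'   theta = list(CL = 20, V = 100, ka = 1),
#'   omega = diag(c(CL = 0.2, V = 0.1)),
#'   error = list(risperidone = list(additive = 1e-4, proportional = 0.2))
#' )
pk_model <- function(label, analytes, structure, theta, omega = NULL,
                     mixture = NULL, covariates = list(),
                     error, scale = c("natural", "log")) {
  scale <- match.arg(scale)
  stopifnot(inherits(structure, "pk_structure"))
  if (inherits(analytes, "pk_analyte")) analytes <- list(analytes)
  roles <- vapply(analytes, function(a) a$role, character(1))
  if (sum(roles == "parent") != 1 || sum(roles == "metabolite") > 1) {
    abort_pk("analytes must contain exactly one parent and at most one metabolite")
  }
  if (structure$has_metabolite != any(roles == "metabolite")) {
    abort_pk("structure$has_metabolite must match the analyte list")
  }

  theta <- as.list(theta)
  if (is.null(theta$F)) theta$F <- 1
  if (structure$lag && is.null(theta$ALAG)) abort_pk("structure has a lag but theta$ALAG is missing")
  unknown <- setdiff(names(theta), PK_PAR_NAMES)
  if (length(unknown)) abort_pk("unknown theta entries: %s", paste(unknown, collapse = ", "))
  missing <- setdiff(required_pars(structure), names(theta))
  if (length(missing)) abort_pk("theta is missing: %s", paste(missing, collapse = ", "))
  pos <- setdiff(names(theta), "ALAG")
  bad <- pos[vapply(theta[pos], function(v) !is.finite(v) || v <= 0, logical(1))]
  if (length(bad)) abort_pk("theta entries must be strictly positive: %s", paste(bad, collapse = ", "))
  if (theta$fm %||% 0.5 > 1) abort_pk("fm must be <= 1")

  if (!is.null(omega)) {
    omega <- as.matrix(omega)
    if (is.null(rownames(omega))) abort_pk("omega must have parameter names as dimnames")
    colnames(omega) <- rownames(omega)
    if (max(abs(omega - t(omega))) > 1e-10) abort_pk("omega must be symmetric")
    ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-10 * max(abs(ev), 1)) abort_pk("omega must be positive semidefinite")
    bad <- setdiff(rownames(omega), names(theta))
    if (length(bad)) abort_pk("omega names not in theta: %s", paste(bad, collapse = ", "))
  }

  if (!is.null(mixture)) {
    p <- unlist(mixture$proportions)
    if (is.null(names(p)) || length(p) < 2) abort_pk("mixture$proportions must be a named vector of >= 2 probabilities")
    if (abs(sum(p) - 1) > 1e-12) abort_pk("mixture proportions must sum to 1 (got %.15f)", sum(p))
    if (any(p < 0)) abort_pk("mixture proportions must be non-negative")
    if (!setequal(names(mixture$overrides), names(p))) {
      abort_pk("mixture$overrides must have one entry per subpopulation")
    }
    for (sp in names(mixture$overrides)) {
      bad <- setdiff(names(mixture$overrides[[sp]]), names(theta))
      if (length(bad)) abort_pk("mixture override refers to unknown parameter: %s", paste(bad, collapse = ", "))
    }
    mixture$proportions <- p
  }

  for (term in covariates) {
    if (!term$parameter %in% names(theta)) {
      abort_pk("covariate term targets unknown parameter '%s'", term$parameter)
    }
    if (!term$form %in% c("power", "linear")) abort_pk("covariate form must be 'power' or 'linear'")
  }

  err_names <- names(error)
  an_names <- vapply(analytes, function(a) a$name, character(1))
  if (!all(an_names %in% err_names)) {
    abort_pk("error must name every analyte: missing %s",
             paste(setdiff(an_names, err_names), collapse = ", "))
  }
  for (nm in an_names) {
    e <- error[[nm]]
    e$additive <- e$additive %||% 0
    e$proportional <- e$proportional %||% 0
    if (e$additive <= 0 && e$proportional <= 0) {
      abort_pk("analyte '%s' needs a positive additive or proportional error", nm)
    }
    error[[nm]] <- e
  }

  structure(
    list(label = as.character(label), analytes = analytes, structure = structure,
         theta = theta, omega = omega, mixture = mixture,
         covariates = covariates, error = error, scale = scale),
    class = "pk_model"
  )
}

#' @export
print.pk_model <- function(x, ...) {
  st <- x$structure
  cat(sprintf("<pk_model> %s: %d-cpt parent%s%s, %s-scale error\n",
              x$label, st$parent_compartments,
              if (st$has_metabolite) " + 1-cpt metabolite" else " only",
              if (st$lag) ", lagged absorption" else "", x$scale))
  cat("  analytes:", paste(vapply(x$analytes, function(a) a$name, character(1)), collapse = ", "), "\n")
  cat("  theta:", paste(sprintf("%s=%.4g", names(x$theta), unlist(x$theta)), collapse = ", "), "\n")
  if (!is.null(x$mixture)) {
    cat("  mixture:", paste(sprintf("%s=%.3g", names(x$mixture$proportions), x$mixture$proportions),
                            collapse = ", "), "\n")
  }
  if (length(x$covariates)) cat("  covariate terms:", length(x$covariates), "\n")
  invisible(x)
}

model_analyte <- function(model, role) {
  for (a in model$analytes) if (a$role == role) return(a)
  NULL
}

analyte_names <- function(model) vapply(model$analytes, function(a) a$name, character(1))

analyte_by_name <- function(model, name) {
  for (a in model$analytes) if (a$name == name) return(a)
  abort_pk("analyte '%s' is not part of model %s", name, model$label)
}

subpop_labels <- function(model) {
  if (is.null(model$mixture)) NA_character_ else names(model$mixture$proportions)
}

eta_names <- function(model) if (is.null(model$omega)) character(0) else rownames(model$omega)

# --- configuration files -----------------------------------------------------

#' Read a model configuration file
#'
#' Model configurations are YAML files with keys `label`, `analytes`,
#' `structure`, `theta`, `omega` (lower triangle rows, named), `mixture`,
#' `covariates`, `error` and `scale`. See the files shipped under
#' `system.file("extdata/models", package = "pkeval")` for the format.
#'
#' @param path path to a YAML model configuration.
#' @return a [pk_model()].
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  analytes <- lapply(cfg$analytes, function(a) pk_analyte(a$name, a$molecular_weight, a$role))
  st <- pk_structure(cfg$structure$parent_compartments,
                     isTRUE(cfg$structure$has_metabolite),
                     isTRUE(cfg$structure$lag))
  omega <- NULL
  if (!is.null(cfg$omega)) {
    nms <- names(cfg$omega)
    p <- length(nms)
    omega <- matrix(0, p, p, dimnames = list(nms, nms))
    for (i in seq_len(p)) {
      row <- as.numeric(cfg$omega[[i]])
      if (length(row) != i) abort_pk("omega row '%s' must have %d entries (lower triangle)", nms[i], i)
      omega[i, seq_len(i)] <- row
      omega[seq_len(i), i] <- row
    }
  }
  mixture <- cfg$mixture
  if (!is.null(mixture)) mixture$proportions <- unlist(mixture$proportions)
  pk_model(
    label = cfg$label, analytes = analytes, structure = st,
    theta = cfg$theta, omega = omega, mixture = mixture,
    covariates = cfg$covariates %||% list(),
    error = cfg$error, scale = cfg$scale %||% "natural"
  )
}

#' Write a model configuration file
#'
#' @param model a [pk_model()].
#' @param path output path (YAML).
#' @return `path`, invisibly.
#' @export
write_model_config <- function(model, path) {
  omega <- NULL
  if (!is.null(model$omega)) {
    nms <- rownames(model$omega)
    omega <- stats::setNames(
      lapply(seq_along(nms), function(i) as.numeric(model$omega[i, seq_len(i)])), nms)
  }
  mixture <- model$mixture
  if (!is.null(mixture)) mixture$proportions <- as.list(mixture$proportions)
  cfg <- list(
    label = model$label,
    analytes = lapply(model$analytes, function(a)
      list(name = a$name, molecular_weight = a$molecular_weight, role = a$role)),
    structure = unclass(model$structure),
    theta = model$theta,
    omega = omega,
    mixture = mixture,
    covariates = model$covariates,
    error = model$error,
    scale = model$scale
  )
  yaml::write_yaml(cfg[!vapply(cfg, is.null, logical(1))], path)
  invisible(path)
}

#' The shipped example model library
#'
#' Five models spanning the structural families commonly used for
#' risperidone and its active metabolite: "a" (2-compartment parent +
#' 1-compartment metabolite, lagged absorption, allometric scaling), "b"
#' (pediatric 1-compartment joint model with a three-subpopulation clearance
#' mixture and allometric scaling), "c" (adult 1-compartment joint mixture
#' model, no size covariate), "d" ("c" plus allometric scaling) and "e"
#' (2-compartment parent-only mixture model with two subpopulations, lagged
#' absorption, log-scale residual error). The numeric values are
#' *representative* fixture values chosen to produce realistic pediatric
#' concentration ranges; they are not the published estimates of any study.
#'
#' @param label optional single label ("a".."e"); if omitted, a named list of
#'   all five models is returned.
#' @return a [pk_model()] or a named list of them.
#' @export
#' @examples
#' model_library("b")
model_library <- function(label = NULL) {
  dir <- system.file("extdata", "models", package = "pkeval")
  if (!is.null(label)) {
    return(read_model_config(file.path(dir, paste0("model_", tolower(label), ".yaml"))))
  }
  files <- list.files(dir, pattern = "^model_[a-z]\\.yaml$", full.names = TRUE)
  models <- lapply(files, read_model_config)
  stats::setNames(models, vapply(models, function(m) tolower(m$label), character(1)))
}
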