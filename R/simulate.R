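# Simulation engine: population replicates of a study design.

# symmetric square root of a PSD covariance matrix (handles singular omegas)
omega_sqrt <- function(omega) {
  if (is.null(omega) || nrow(omega) == 0) return(NULL)
  e <- eigen(omega, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(omega)) %*% t(e$vectors)
}

#' Draw individuals from the population model
#'
#' Samples subpopulation membership from the mixing proportions and the
#' random-effect vector from the multivariate normal with covariance
#' `model$omega`, using the current RNG state.
#'
#' @param model a [pk_model()].
#' @param n number of individuals to draw.
#' @return A tibble with a `subpop` column (NA when the model has no
#'   mixture) and one `eta_<name>` column per random effect.
#' @export
sample_individual <- function(model, n = 1) {
  stopifnot(inherits(model, "pk_model"))
  subpop <- if (is.null(model$mixture)) {
    rep(NA_character_, n)
  } else {
    p <- model$mixture$proportions
    names(p)[sample.int(length(p), n, replace = TRUE, prob = p)]
  }
  en <- eta_names(model)
  eta <- matrix(0, n, length(en), dimnames = list(NULL, en))
  if (length(en)) {
    z <- matrix(stats::rnorm(n * length(en)), n, length(en))
    eta[, ] <- z %*% omega_sqrt(model$omega)
  }
  out <- tibble::tibble(subpop = subpop)
  for (j in seq_along(en)) out[[paste0("eta_", en[j])]] <- eta[, j]
  out
}

apply_residual_error <- function(f, model, analyte, eps1, eps2,
                                 truncate_negative = FALSE) {
  e <- model$error[[analyte]]
  if (model$scale == "log") {
    y <- ifelse(f > 0, f * exp(e$additive * eps1), 0)
  } else {
    y <- f * (1 + e$proportional * eps1) + e$additive * eps2
    if (truncate_negative) y <- pmax(y, 0)
  }
  y
}

#' Simulate a replicate ensemble over a study design
#'
#' Repeats the whole study `nsim` times under the model: for every replicate
#' and subject a fresh subpopulation and random-effect vector are drawn, the
#' noise-free profile is solved over the subject's dosing history, and the
#' model's residual error is applied at each observation record. The result
#' is the replicate-by-observation matrix that the simulation-based
#' diagnostics (pcVPC, NPDE) consume.
#'
#' Reproducibility: each replicate has its own RNG stream derived from the
#' master seed, so replicate r is identical whatever `nsim` is, and the same
#' seed always yields a bit-identical ensemble. Within a replicate the draw
#' order is: subpopulations (all subjects), random effects (all subjects),
#' then two residual-error normals per observation record (both are drawn
#' whatever the error model, to keep streams aligned across error models).
#'
#' Negative concentrations arising under a natural-scale additive error are
#' kept by default (they are legitimate draws of the error model);
#' `truncate_negative = TRUE` clips them at zero.
#'
#' @param data study dataset tibble (see `bql_filter()`; BQL records should
#'   already be excluded).
#' @param model a [pk_model()].
#' @param nsim number of replicates (K).
#' @param seed integer master seed.
#' @param truncate_negative clip negative simulated concentrations at zero.
#' @return An object of class `pk_ensemble`: list with `sim` (nsim x n_obs
#'   matrix, nmol/mL), `obs` (the observation records, in `sim` column
#'   order), `nsim`, `seed` and the model label.
#' @export
simulate_ensemble <- function(data, model, nsim = 1000, seed = 1,
                              truncate_negative = FALSE) {
  stopifnot(inherits(model, "pk_model"))
  if (nsim < 1) abort_pk("nsim must be >= 1")
  check_dataset(data)
  design <- split_design(data, model)
  n_sub <- length(design)
  n_obs <- sum(vapply(design, function(s) nrow(s$obs), integer(1)))
  if (n_obs == 0) abort_pk("dataset has no observation records")

  en <- eta_names(model)
  p <- length(en)
  sq <- omega_sqrt(model$omega)
  mix <- model$mixture
  seeds <- replicate_seeds(seed, nsim)

  subpop <- matrix(NA_character_, nsim, n_sub)
  eta <- array(0, c(nsim, n_sub, p))
  eps1 <- matrix(0, nsim, n_obs)
  eps2 <- matrix(0, nsim, n_obs)
  for (r in seq_len(nsim)) {
    set.seed(seeds[r])
    if (!is.null(mix)) {
      pr <- mix$proportions
      subpop[r, ] <- names(pr)[sample.int(length(pr), n_sub, replace = TRUE, prob = pr)]
    }
    if (p > 0) {
      z <- matrix(stats::rnorm(n_sub * p), n_sub, p)
      eta[r, , ] <- z %*% sq
    }
    eps1[r, ] <- stats::rnorm(n_obs)
    eps2[r, ] <- stats::rnorm(n_obs)
  }

  sim <- matrix(NA_real_, nsim, n_obs)
  for (s in seq_len(n_sub)) {
    sub <- design[[s]]
    if (nrow(sub$obs) == 0) next
    if (nrow(sub$doses) == 0) {
      sim[, sub$obs$.row] <- 0
      next
    }
    em <- matrix(eta[, s, ], nrow = nsim, ncol = p, dimnames = list(NULL, en))
    pars <- indiv_pars_matrix(model, sub$covs, eta = em,
                              subpop = if (!is.null(mix)) subpop[, s])
    ut <- unique(sub$obs$time)
    cm <- conc_matrix(pars, model$structure, sub$doses, ut)
    for (k in seq_len(nrow(sub$obs))) {
      o <- sub$obs[k, ]
      f <- cm[[o$role]][, match(o$time, ut)]
      sim[, o$.row] <- apply_residual_error(
        f, model, o$analyte, eps1[, o$.row], eps2[, o$.row], truncate_negative)
    }
  }

  obs <- dplyr::bind_rows(lapply(design, function(s) s$obs))
  obs <- obs[order(obs$.row), , drop = FALSE]
  structure(
    list(sim = sim, obs = obs, nsim = nsim, seed = seed, model = model$label,
         scale = model$scale),
    class = "pk_ensemble"
  )
}

#' @export
print.pk_ensemble <- function(x, ...) {
  cat(sprintf("<pk_ensemble> model %s: %d replicates x %d observations (seed %d)\n",
              x$model, x$nsim, ncol(x$sim), x$seed))
  invisible(x)
}

#' Tidy a simulation ensemble into long format
#'
#' @param x a `pk_ensemble`.
#' @param ... unused.
#' @return Tibble with columns `replicate`, `id`, `time`, `analyte`, `value`.
#' @export
tidy.pk_ensemble <- function(x, ...) {
  n <- ncol(x$sim)
  tibble::tibble(
    replicate = rep(seq_len(x$nsim), times = n),
    id = rep(x$obs$id, each = x$nsim),
    time = rep(x$obs$time, each = x$nsim),
    analyte = rep(x$obs$analyte, each = x$nsim),
    value = as.numeric(x$sim)
  )
}
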