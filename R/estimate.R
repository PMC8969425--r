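# Individual-level inference with the population parameters held fixed:
# population predictions, empirical-Bayes (MAP) random effects, mixture-class
# posteriors, and FOCE-style conditional weighted residuals.

#' Population predictions (PRED)
#'
#' Adds the population prediction at each observation record: the noise-free
#' profile with all random effects at zero. For mixture models the default is
#' the mixing-proportion-weighted average of the per-subpopulation eta = 0
#' profiles (the marginal mean at eta = 0); `mixture_pred =
#' "most_probable"` instead uses the single a-priori most probable
#' subpopulation. PRED depends only on the design (doses, times, covariates),
#' never on the observed values.
#'
#' @param data study dataset tibble.
#' @param model a [pk_model()].
#' @param mixture_pred `"weighted"` or `"most_probable"`.
#' @return `data` with a `pred` column added (nmol/mL; `NA` on dose rows).
#' @export
population_prediction <- function(data, model,
                                  mixture_pred = c("weighted", "most_probable")) {
  mixture_pred <- match.arg(mixture_pred)
  stopifnot(inherits(model, "pk_model"))
  check_dataset(data, require_obs = FALSE)
  design <- split_design(data, model)
  pred_obs <- rep(NA_real_, sum(data$evid == 0))
  for (sub in design) {
    if (nrow(sub$obs) == 0) next
    ut <- unique(sub$obs$time)
    f <- pred_profile(model, sub$covs, sub$doses, ut, mixture_pred)
    for (k in seq_len(nrow(sub$obs))) {
      o <- sub$obs[k, ]
      pred_obs[o$.row] <- f[[o$role]][match(o$time, ut)]
    }
  }
  out <- data
  out$pred <- NA_real_
  out$pred[out$evid == 0] <- pred_obs
  out
}

# noise-free eta = 0 profile with mixture handling; returns list by role
pred_profile <- function(model, covs, doses, times, mixture_pred = "weighted") {
  if (nrow(doses) == 0) {
    zero <- rep(0, length(times))
    return(list(parent = zero, metabolite = zero))
  }
  if (is.null(model$mixture)) {
    cm <- conc_matrix(indiv_pars_matrix(model, covs), model$structure, doses, times)
    return(lapply(cm, function(m) m[1, ]))
  }
  pr <- model$mixture$proportions
  if (mixture_pred == "most_probable") {
    sp <- names(pr)[which.max(pr)]
    cm <- conc_matrix(indiv_pars_matrix(model, covs, subpop = sp),
                      model$structure, doses, times)
    return(lapply(cm, function(m) m[1, ]))
  }
  cm <- conc_matrix(indiv_pars_matrix(model, covs, subpop = names(pr)),
                    model$structure, doses, times)
  lapply(cm, function(m) as.numeric(pr %*% m))
}

#' Mixture-class posterior probabilities
#'
#' Bayes' rule over subpopulations, computed stably through log-sum-exp:
#' posterior_j proportional to prior_j * exp(log_lik_j).
#'
#' @param log_lik numeric vector of per-subpopulation observation
#'   log-likelihoods (any common additive constant cancels).
#' @param prior prior (mixing) probabilities, summing to 1.
#' @return Numeric vector of posterior probabilities (sums to 1).
#' @export
#' @examples
#' mixture_posterior(log(c(1, 4)), prior = c(0.8, 0.2))
mixture_posterior <- function(log_lik, prior) {
  if (length(log_lik) != length(prior)) abort_pk("log_lik and prior lengths differ")
  if (abs(sum(prior) - 1) > 1e-8) abort_pk("prior must sum to 1")
  if (all(log_lik == -Inf)) abort_pk("all class log-likelihoods are -Inf: no data support")
  lw <- log(prior) + log_lik
  w <- exp(lw - logsumexp(lw))
  w / sum(w)
}

# residual sd at a predicted concentration (natural scale) or the log-sd
obs_sd <- function(model, analyte, f) {
  e <- model$error[[analyte]]
  if (model$scale == "log") rep(e$additive, length(f))
  else sqrt(e$additive^2 + (e$proportional * f)^2)
}

# log-likelihood of one subject's observations at a given eta / subpop
subject_loglik <- function(model, sub, eta, subpop) {
  obs <- sub$obs
  en <- eta_names(model)
  em <- matrix(eta, nrow = 1, dimnames = list(NULL, en))
  pars <- indiv_pars_matrix(model, sub$covs, eta = em, subpop = subpop)
  ut <- unique(obs$time)
  cm <- conc_matrix(pars, model$structure, sub$doses, ut)
  ll <- 0
  for (k in seq_len(nrow(obs))) {
    o <- obs[k, ]
    f <- cm[[o$role]][1, match(o$time, ut)]
    sd <- obs_sd(model, o$analyte, f)
    if (model$scale == "log") {
      f <- max(f, 1e-12)
      ll <- ll + stats::dnorm(log(o$dv), log(f), sd, log = TRUE)
    } else {
      ll <- ll + stats::dnorm(o$dv, f, sd, log = TRUE)
    }
  }
  ll
}

#' Empirical-Bayes individual estimates
#'
#' For every subject, and for every candidate subpopulation when the model
#' has a mixture, maximises the joint posterior log p(y | eta, subpop) +
#' log p(eta) over the random effects with the population parameters held
#' fixed. The per-subpopulation maxima, combined with the mixing proportions
#' through Bayes' rule, give each subject's class posterior; the reported
#' MAP eta is that of the a-posteriori most probable class. Subjects with no
#' quantifiable observations get eta = 0 and the prior class probabilities.
#'
#' The eta search is a quasi-Newton (`nlminb`) run from three deterministic
#' starts (0 and +/- 0.5 prior SD on each coordinate) to guard against local
#' optima; non-convergence of all starts is flagged in the `converged`
#' column, never silently ignored.
#'
#' @param data study dataset tibble (BQL records excluded).
#' @param model a [pk_model()].
#' @return A tibble of class `pk_ebe` with one row per subject: `id`,
#'   `subpop` (posterior-mode class), one `post_<class>` column per class,
#'   one `eta_<name>` column per random effect, `loglik` and `converged`.
#' @export
ebe_estimate <- function(data, model) {
  stopifnot(inherits(model, "pk_model"))
  check_dataset(data, require_obs = FALSE)
  design <- split_design(data, model)
  en <- eta_names(model)
  p <- length(en)
  omega <- model$omega
  oinv <- if (p > 0) solve(omega + diag(1e-10, p)) else NULL
  classes <- if (is.null(model$mixture)) NA_character_ else names(model$mixture$proportions)
  prior <- if (is.null(model$mixture)) 1 else model$mixture$proportions

  fit_one <- function(sub) {
    n_obs <- nrow(sub$obs)
    if (n_obs == 0 || p == 0) {
      eta0 <- rep(0, p)
      obj <- vapply(classes, function(cl) {
        if (n_obs == 0) 0 else subject_loglik(model, sub, eta0, if (!is.na(cl)) cl)
      }, numeric(1))
      post <- as.numeric(mixture_posterior(obj, prior))
      best <- which.max(post)
      return(list(eta = eta0, post = post, subpop = classes[best],
                  loglik = obj[best], converged = TRUE))
    }
    sds <- sqrt(diag(omega))
    starts <- list(rep(0, p), 0.5 * sds, -0.5 * sds)
    res <- lapply(classes, function(cl) {
      neg <- function(eta) {
        ll <- subject_loglik(model, sub, eta, if (!is.na(cl)) cl)
        -(ll - 0.5 * drop(eta %*% oinv %*% eta))
      }
      fits <- lapply(starts, function(s0) {
        tryCatch(stats::nlminb(s0, neg), error = function(e) list(objective = Inf, convergence = 1))
      })
      best <- fits[[which.min(vapply(fits, function(f) f$objective, numeric(1)))]]
      best
    })
    obj <- -vapply(res, function(f) f$objective, numeric(1))
    post <- as.numeric(mixture_posterior(obj, prior))
    best <- which.max(post)
    list(eta = res[[best]]$par, post = post, subpop = classes[best],
         loglik = obj[best],
         converged = any(vapply(res, function(f) isTRUE(f$convergence == 0), logical(1))))
  }

  fits <- lapply(design, fit_one)
  out <- tibble::tibble(id = vapply(design, function(s) s$id, data$id[[1]]))
  out$subpop <- vapply(fits, function(f) f$subpop, character(1))
  if (!is.null(model$mixture)) {
    for (j in seq_along(classes)) {
      out[[paste0("post_", classes[j])]] <- vapply(fits, function(f) f$post[j], numeric(1))
    }
  }
  for (j in seq_len(p)) {
    out[[paste0("eta_", en[j])]] <- vapply(fits, function(f) f$eta[j], numeric(1))
  }
  out$loglik <- vapply(fits, function(f) f$loglik, numeric(1))
  out$converged <- vapply(fits, function(f) f$converged, logical(1))
  if (any(!out$converged)) {
    warn_pk("EBE optimisation did not converge for subject(s): %s",
            paste(out$id[!out$converged], collapse = ", "))
  }
  class(out) <- c("pk_ebe", class(out))
  attr(out, "model") <- model$label
  out
}

#' Conditional weighted residuals
#'
#' FOCE-style residuals: the individual prediction is linearised around the
#' subject's MAP eta with finite differences (gradient G, relative step
#' 1e-4); the marginal covariance of the subject's observation vector is
#' approximated by G Omega G' plus the residual covariance at the individual
#' prediction, and the residual y - f(eta_hat) + G eta_hat is whitened with
#' the inverse Cholesky factor. Under the true model CWRES are approximately
#' standard normal. A singular covariance is ridge-regularised with a
#' warning. For log-scale models residuals are formed on the log scale.
#'
#' @param data study dataset tibble with observations.
#' @param model a [pk_model()].
#' @param fits result of [ebe_estimate()] for the same data and model; if
#'   `NULL` it is computed.
#' @return `data` with columns `ipred` (individual prediction, nmol/mL) and
#'   `cwres` added (`NA` on dose rows).
#' @export
compute_cwres <- function(data, model, fits = NULL) {
  stopifnot(inherits(model, "pk_model"))
  if (is.null(fits)) fits <- ebe_estimate(data, model)
  design <- split_design(data, model)
  en <- eta_names(model)
  p <- length(en)
  n_obs_total <- sum(data$evid == 0)
  ipred <- cwres <- rep(NA_real_, n_obs_total)

  for (sub in design) {
    n <- nrow(sub$obs)
    if (n == 0) next
    row <- which(fits$id == sub$id)
    if (length(row) != 1) abort_pk("no EBE fit for subject %s", as.character(sub$id))
    eta_hat <- if (p > 0) as.numeric(fits[row, paste0("eta_", en)]) else numeric(0)
    sp <- fits$subpop[row]
    if (is.na(sp)) sp <- NULL

    f_at <- function(eta) {
      em <- matrix(eta, nrow = 1, dimnames = list(NULL, en))
      pars <- indiv_pars_matrix(model, sub$covs, eta = em, subpop = sp)
      ut <- unique(sub$obs$time)
      cm <- conc_matrix(pars, model$structure, sub$doses, ut)
      vapply(seq_len(n), function(k) {
        cm[[sub$obs$role[k]]][1, match(sub$obs$time[k], ut)]
      }, numeric(1))
    }

    f_hat <- f_at(eta_hat)
    y <- sub$obs$dv
    if (model$scale == "log") {
      fl <- log(pmax(f_hat, 1e-12))
      yl <- log(y)
    }

    G <- matrix(0, n, p)
    for (j in seq_len(p)) {
      h <- 1e-4 * max(1, abs(eta_hat[j]))
      up <- dn <- eta_hat
      up[j] <- up[j] + h; dn[j] <- dn[j] - h
      fu <- f_at(up); fd <- f_at(dn)
      if (model$scale == "log") {
        G[, j] <- (log(pmax(fu, 1e-12)) - log(pmax(fd, 1e-12))) / (2 * h)
      } else {
        G[, j] <- (fu - fd) / (2 * h)
      }
    }

    sdv <- vapply(seq_len(n), function(k) obs_sd(model, sub$obs$analyte[k], f_hat[k]), numeric(1))
    V <- diag(sdv^2, n)
    if (p > 0) V <- V + G %*% model$omega %*% t(G)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) {
      warn_pk("singular residual covariance for subject %s; ridge-regularised", as.character(sub$id))
      ch <- chol(V + diag(1e-8 * mean(diag(V)), n))
    }
    resid <- if (model$scale == "log") yl - fl else y - f_hat
    if (p > 0) resid <- resid + as.numeric(G %*% eta_hat)
    w <- forwardsolve(t(ch), resid)
    ipred[sub$obs$.row] <- f_hat
    cwres[sub$obs$.row] <- w
  }

  out <- data
  out$ipred <- out$cwres <- NA_real_
  out$ipred[out$evid == 0] <- ipred
  out$cwres[out$evid == 0] <- cwres
  out
}
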