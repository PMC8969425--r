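# Normalized prediction distribution errors.

#' Compute normalized prediction distribution errors
#'
#' For each subject (and analyte), the observed vector and every simulated
#' replicate are centred on the simulated mean and whitened with the inverse
#' lower-triangular Cholesky factor of the empirical simulation covariance
#' (decorrelation in record order). The prediction distribution error of a
#' record is the rank of the whitened observation among the whitened
#' replicates divided by K, with ties counted as one half and the result
#' clamped to [1/(2K), 1 - 1/(2K)]; the npde is its standard-normal
#' quantile. Under the data-generating model the npde are approximately
#' iid standard normal. Subjects with a single observation use the scalar
#' standardization path (no matrix factorisation). A singular empirical
#' covariance is ridge-regularised with a warning.
#'
#' @param data study dataset tibble (quantifiable observations only).
#' @param ensemble a `pk_ensemble` from [simulate_ensemble()] aligned to
#'   `data`.
#' @return An object of class `pk_npde`: a list with `records` (tibble with
#'   per-observation `pde` and `npde`) and `tests` (see [npde_tests()],
#'   computed per analyte and overall).
#' @export
compute_npde <- function(data, ensemble) {
  stopifnot(inherits(ensemble, "pk_ensemble"))
  K <- ensemble$nsim
  if (K < 2) abort_pk("NPDE needs nsim >= 2 replicates (>= 100 recommended)")
  obs <- data[data$evid == 0, , drop = FALSE]
  if (nrow(obs) != ncol(ensemble$sim)) {
    abort_pk("ensemble (%d records) is not aligned to the dataset (%d observations)",
             ncol(ensemble$sim), nrow(obs))
  }
  sim <- ensemble$sim
  pde <- rep(NA_real_, nrow(obs))
  grp <- interaction(obs$id, obs$analyte, drop = TRUE)

  for (g in levels(grp)) {
    idx <- which(grp == g)
    n <- length(idx)
    S <- sim[, idx, drop = FALSE]
    y <- obs$dv[idx]
    mu <- colMeans(S)
    Sc <- sweep(S, 2, mu)
    yc <- y - mu
    if (n == 1) {
      sdev <- stats::sd(as.numeric(S))
      if (sdev <= 0) {
        warn_pk("degenerate simulation spread for subject %s; ridge-regularised",
                as.character(obs$id[idx[1]]))
        sdev <- sdev + 1e-12
      }
      ys <- yc / sdev
      Ss <- Sc / sdev
    } else {
      V <- stats::cov(Sc)
      ch <- tryCatch(chol(V), error = function(e) NULL)
      if (is.null(ch)) {
        warn_pk("singular simulation covariance for subject %s; ridge-regularised",
                as.character(obs$id[idx[1]]))
        ch <- chol(V + diag(1e-8 * max(mean(diag(V)), 1e-12), n))
      }
      L <- t(ch)
      ys <- forwardsolve(L, yc)
      Ss <- t(forwardsolve(L, t(Sc)))
    }
    below <- colSums(Ss < rep(ys, each = K))
    ties <- colSums(Ss == rep(ys, each = K))
    pde[idx] <- (below + 0.5 * ties) / K
  }

  pde <- pmin(pmax(pde, 1 / (2 * K)), 1 - 1 / (2 * K))
  records <- tibble::tibble(
    id = obs$id, time = obs$time, analyte = obs$analyte,
    dv = obs$dv, pde = pde, npde = stats::qnorm(pde)
  )
  safe_tests <- function(x) {
    tryCatch(npde_tests(x)$tests, error = function(e) {
      tibble::tibble(test = c("t_mean_zero", "var_one", "shapiro_normality"),
                     statistic = NA_real_, p_value = NA_real_)
    })
  }
  tests <- records |>
    dplyr::group_by(.data$analyte) |>
    dplyr::group_modify(~ safe_tests(.x$npde)) |>
    dplyr::ungroup()
  structure(list(records = records, tests = tests, nsim = K),
            class = "pk_npde")
}

#' Hypothesis tests on npde values
#'
#' The standard battery: a t-test of mean 0, a chi-squared (Fisher) test of
#' variance 1, and a Shapiro-Wilk test of normality. The global verdict
#' applies a Bonferroni correction over the three tests: the model is
#' rejected when the smallest p-value is below `alpha / 3`.
#'
#' @param npde numeric vector of npde values (length >= 3).
#' @param alpha global significance level (default 0.05).
#' @return A list with `tests` (tibble: test, statistic, p_value), `reject`
#'   (logical global verdict) and `alpha`.
#' @export
npde_tests <- function(npde, alpha = 0.05) {
  npde <- npde[is.finite(npde)]
  n <- length(npde)
  if (n < 3) abort_pk("npde tests need at least 3 values")
  if (stats::sd(npde) == 0) abort_pk("constant npde vector: normality test undefined")

  t_p <- stats::t.test(npde, mu = 0)$p.value
  # two-sided chi-squared test of Var = 1
  stat <- (n - 1) * stats::var(npde)
  v_p <- 2 * min(stats::pchisq(stat, n - 1), stats::pchisq(stat, n - 1, lower.tail = FALSE))
  v_p <- min(v_p, 1)
  x <- npde
  if (n > 5000) x <- x[round(seq(1, n, length.out = 5000))]
  s_p <- stats::shapiro.test(x)$p.value

  tests <- tibble::tibble(
    test = c("t_mean_zero", "var_one", "shapiro_normality"),
    statistic = c(mean(npde), stats::var(npde), NA_real_),
    p_value = c(t_p, v_p, s_p)
  )
  list(tests = tests, reject = min(tests$p_value) < alpha / 3, alpha = alpha)
}

#' @export
print.pk_npde <- function(x, ...) {
  cat(sprintf("<pk_npde> %d observations, %d replicates\n", nrow(x$records), x$nsim))
  print(x$tests)
  invisible(x)
}

#' @export
tidy.pk_npde <- function(x, ...) x$records

#' @export
glance.pk_npde <- function(x, ...) {
  x$records |>
    dplyr::group_by(.data$analyte) |>
    dplyr::summarise(n = dplyr::n(), mean_npde = mean(.data$npde),
                     var_npde = stats::var(.data$npde), .groups = "drop")
}

#' Plot npde diagnostics
#'
#' @param object a `pk_npde` object.
#' @param type `"qq"` (normal quantile-quantile plot) or `"hist"`.
#' @param ... unused.
#' @return A ggplot object faceted by analyte.
#' @export
autoplot.pk_npde <- function(object, type = c("qq", "hist"), ...) {
  type <- match.arg(type)
  r <- object$records
  if (type == "qq") {
    ggplot2::ggplot(r, ggplot2::aes(sample = .data$npde)) +
      ggplot2::stat_qq(size = 1) +
      ggplot2::stat_qq_line(linetype = 2) +
      ggplot2::facet_wrap(~analyte) +
      ggplot2::labs(x = "theoretical quantiles", y = "npde")
  } else {
    ggplot2::ggplot(r, ggplot2::aes(x = .data$npde)) +
      ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                              bins = 20, fill = "grey70", colour = "grey30") +
      ggplot2::stat_function(fun = stats::dnorm, linetype = 2) +
      ggplot2::facet_wrap(~analyte) +
      ggplot2::labs(x = "npde", y = "density")
  }
}
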