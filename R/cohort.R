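# Synthetic opportunistic pediatric cohorts.
#
# Emulates the structure of a standard-of-care ("opportunistic") pediatric
# PK study: a wide age range with the matching body weights, irregular
# maintenance dosing, very sparse sampling clustered around clinical blood
# draws, and assay censoring at the quantification limit. Observations are
# simulated from a user-supplied generating model and the generating truth
# (class, random effects, noise-free concentrations) is retained so recovery
# tests can score themselves.

# median weight (kg) as a function of age (y): log-linear interpolation
# through typical growth-curve anchor points
default_weight_anchors <- function() {
  data.frame(age = c(0.08, 0.5, 1, 2, 5, 10, 14, 17),
             wt = c(4.0, 7.5, 10, 12.5, 18, 32, 50, 62))
}

median_weight <- function(age, anchors = default_weight_anchors()) {
  exp(stats::approx(log(anchors$age), log(anchors$wt), xout = log(age), rule = 2)$y)
}

#' Configuration of a synthetic opportunistic cohort
#'
#' Defaults reproduce the structure of a 62-subject pediatric
#' standard-of-care study: ages 0.16-16.8 y, weights 3.64-129 kg, a median of
#' 9 recorded doses per subject (range 1-43), a median of 1 PK sample per
#' subject (range 1-7), median dose 0.017 mg/kg rounded to 0.05 mg
#' increments, and a 0.100 ng/mL lower limit of quantitation.
#'
#' @param n number of subjects.
#' @param age_range truncation bounds for age (years).
#' @param age_median,age_sdlog log-normal age distribution (median, sdlog).
#' @param weight_sdlog log-normal spread of weight around the age-specific
#'   median growth curve.
#' @param weight_range truncation bounds for weight (kg).
#' @param dose_per_kg list: `median` (mg/kg), `sdlog`, `range`.
#' @param doses_per_subject list: `median`, `sdlog`, `range`.
#' @param samples_per_subject list: `p` (geometric success probability) and
#'   `max`; the truncated geometric gives a median of 1 sample.
#' @param interval_choices,interval_probs candidate dosing intervals (h) and
#'   their probabilities.
#' @param interval_jitter_sdlog log-normal jitter on successive dose
#'   intervals (missed/irregular doses).
#' @param trough_fraction fraction of samples drawn trough-like (just before
#'   the next dose); the rest are uniform within the interval, with a small
#'   heavy-tailed fraction of late washout draws.
#' @param late_fraction fraction of samples drawn long after the last dose.
#' @param dose_increment dose rounding increment (mg).
#' @param lloq lower limit of quantitation in ng/mL (0 disables censoring).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n = 62,
                          age_range = c(0.16, 16.8),
                          age_median = 4.67, age_sdlog = 1.1,
                          weight_sdlog = 0.25, weight_range = c(3.64, 129),
                          dose_per_kg = list(median = 0.017, sdlog = 0.8,
                                             range = c(0.003, 0.068)),
                          doses_per_subject = list(median = 9, sdlog = 0.9,
                                                   range = c(1, 43)),
                          samples_per_subject = list(p = 0.55, max = 7),
                          interval_choices = c(12, 24),
                          interval_probs = c(0.5, 0.5),
                          interval_jitter_sdlog = 0.15,
                          trough_fraction = 0.5,
                          late_fraction = 0.05,
                          dose_increment = 0.05,
                          lloq = 0.100) {
  stopifnot(n >= 1, all(age_range > 0), all(weight_range > 0), lloq >= 0)
  structure(as.list(environment()), class = "cohort_config")
}

rlnorm_trunc <- function(n, median, sdlog, range) {
  x <- stats::rlnorm(n, log(median), sdlog)
  pmin(pmax(x, range[1]), range[2])
}

#' Generate a synthetic opportunistic study dataset
#'
#' Draws a cohort per `config`, simulates one observation set from
#' `generating_model` (one subpopulation + random-effect draw per subject,
#' residual error per record) and censors records below the LLOQ. Times are
#' hours after each subject's first dose; the first dose is at t = 0.
#'
#' @param config a [cohort_config()].
#' @param generating_model the [pk_model()] the observations are simulated
#'   from.
#' @param seed integer seed; the same seed always reproduces the dataset
#'   exactly.
#' @return A list of class `pk_cohort` with `data` (study dataset tibble,
#'   internal molar units) and `truth` (per-subject tibble: true subpop,
#'   true etas) plus `truth_obs` (per-observation noise-free concentration).
#' @export
generate_cohort <- function(config = cohort_config(), generating_model, seed = 1) {
  stopifnot(inherits(config, "cohort_config"), inherits(generating_model, "pk_model"))
  set.seed(seed)
  n <- config$n
  parent <- model_analyte(generating_model, "parent")

  age <- rlnorm_trunc(n, config$age_median, config$age_sdlog, config$age_range)
  wt <- median_weight(age) * stats::rlnorm(n, 0, config$weight_sdlog)
  wt <- pmin(pmax(wt, config$weight_range[1]), config$weight_range[2])

  nd <- round(rlnorm_trunc(n, config$doses_per_subject$median,
                           config$doses_per_subject$sdlog,
                           config$doses_per_subject$range))
  ns <- pmin(stats::rgeom(n, config$samples_per_subject$p) + 1L,
             config$samples_per_subject$max)
  dose_mgkg <- rlnorm_trunc(n, config$dose_per_kg$median, config$dose_per_kg$sdlog,
                            config$dose_per_kg$range)
  dose_mg <- pmax(round(dose_mgkg * wt / config$dose_increment) * config$dose_increment,
                  config$dose_increment)
  interval <- sample(config$interval_choices, n, replace = TRUE,
                     prob = config$interval_probs)

  draws <- sample_individual(generating_model, n)
  en <- eta_names(generating_model)
  lloq_nmol <- vapply(generating_model$analytes, function(a)
    mass_to_molar(config$lloq, a), numeric(1))
  names(lloq_nmol) <- analyte_names(generating_model)

  rows <- vector("list", n)
  truth_obs <- vector("list", n)
  for (i in seq_len(n)) {
    gaps <- interval[i] * stats::rlnorm(nd[i], 0, config$interval_jitter_sdlog)
    dose_times <- c(0, cumsum(gaps))[seq_len(nd[i])]
    amt_nmol <- mass_to_molar(dose_mg[i], parent, "amount")

    kind <- sample(c("trough", "uniform", "late"), ns[i], replace = TRUE,
                   prob = c(config$trough_fraction,
                            1 - config$trough_fraction - config$late_fraction,
                            config$late_fraction))
    u <- stats::runif(ns[i])
    after <- sample.int(nd[i], ns[i], replace = TRUE)
    t_obs <- ifelse(
      kind == "trough", dose_times[after] + interval[i] * (0.85 + 0.15 * u),
      ifelse(kind == "uniform", dose_times[after] + interval[i] * u,
             max(dose_times) + interval[i] * (1 + 3 * abs(stats::rt(ns[i], df = 3)))))
    t_obs <- sort(round(t_obs, 2))

    eta <- if (length(en)) {
      matrix(as.numeric(draws[i, paste0("eta_", en)]), nrow = 1,
             dimnames = list(NULL, en))
    }
    pars <- indiv_pars_matrix(generating_model, list(wt = wt[i], age = age[i]),
                              eta = eta, subpop = draws$subpop[i])
    doses <- data.frame(time = dose_times, amt = amt_nmol)
    cm <- conc_matrix(pars, generating_model$structure, doses, t_obs)

    obs_list <- list()
    for (a in generating_model$analytes) {
      f <- cm[[a$role]][1, ]
      eps1 <- stats::rnorm(ns[i]); eps2 <- stats::rnorm(ns[i])
      y <- apply_residual_error(f, generating_model, a$name, eps1, eps2)
      bql <- if (config$lloq > 0) y < lloq_nmol[a$name] else rep(FALSE, ns[i])
      obs_list[[a$name]] <- tibble::tibble(
        id = i, time = t_obs, evid = 0L, amt = NA_real_, analyte = a$name,
        dv = ifelse(bql, NA_real_, y), bql = bql,
        wt = wt[i], age = age[i]
      )
      truth_obs[[length(truth_obs) + 1]] <- tibble::tibble(
        id = i, time = t_obs, analyte = a$name, conc_true = f
      )
    }
    dose_rows <- tibble::tibble(
      id = i, time = dose_times, evid = 1L, amt = amt_nmol,
      analyte = NA_character_, dv = NA_real_, bql = NA,
      wt = wt[i], age = age[i]
    )
    rows[[i]] <- dplyr::bind_rows(dose_rows, dplyr::bind_rows(obs_list)) |>
      dplyr::arrange(.data$time, .data$evid)
  }

  data <- dplyr::bind_rows(rows)
  if (sum(data$evid == 0) == 0) abort_pk("configuration produced zero observations")
  truth <- dplyr::bind_cols(tibble::tibble(id = seq_len(n), age = age, wt = wt), draws)
  structure(list(data = data, truth = truth,
                 truth_obs = dplyr::bind_rows(truth_obs), seed = seed,
                 model = generating_model$label),
            class = "pk_cohort")
}

#' @export
print.pk_cohort <- function(x, ...) {
  n_obs <- sum(x$data$evid == 0)
  cat(sprintf("<pk_cohort> %d subjects, %d observation records (%d BQL), generated from model %s (seed %d)\n",
              length(unique(x$data$id)), n_obs,
              sum(x$data$bql, na.rm = TRUE), x$model, x$seed))
  invisible(x)
}
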