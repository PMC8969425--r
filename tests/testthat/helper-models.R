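# Small in-code fixtures shared across the suite.

named_diag <- function(x) {
  m <- diag(x, length(x))
  dimnames(m) <- list(names(x), names(x))
  m
}

# 1-compartment parent-only model, no mixture, no covariates
toy_parent_model <- function(omega = named_diag(c(CL = 0.09, V = 0.04)),
                             prop = 0.10, add = 0, scale = "natural",
                             cl = 5, v = 50, ka = 1.5) {
  pk_model(
    label = "toy1", analytes = list(pk_analyte("drug", 400, "parent")),
    structure = pk_structure(1),
    theta = list(CL = cl, V = v, ka = ka),
    omega = omega, error = list(drug = list(additive = add, proportional = prop)),
    scale = scale
  )
}

# 1-compartment parent + metabolite, no mixture
toy_joint_model <- function(omega = named_diag(c(CL = 0.09, CLm = 0.09)),
                            prop = 0.10) {
  pk_model(
    label = "toyJ",
    analytes = list(pk_analyte("drug", 400, "parent"),
                    pk_analyte("drug-M1", 420, "metabolite")),
    structure = pk_structure(1, has_metabolite = TRUE),
    theta = list(CL = 5, V = 50, ka = 1.5, fm = 0.4, CLm = 3, Vm = 80),
    omega = omega,
    error = list(drug = list(additive = 0, proportional = prop),
                 `drug-M1` = list(additive = 0, proportional = prop))
  )
}

# two-subpopulation mixture with 5-fold separated clearances
toy_mixture_model <- function(cl_lo = 2, cl_hi = 10, p_lo = 0.5, prop = 0.10,
                              omega = named_diag(c(CL = 0.04, V = 0.04))) {
  pk_model(
    label = "toyMix", analytes = list(pk_analyte("drug", 400, "parent")),
    structure = pk_structure(1),
    theta = list(CL = cl_hi, V = 50, ka = 1.5),
    omega = omega,
    mixture = list(
      proportions = c(slow = p_lo, fast = 1 - p_lo),
      overrides = list(slow = list(CL = cl_lo), fast = list(CL = cl_hi))
    ),
    error = list(drug = list(additive = 0, proportional = prop))
  )
}

# regular study design: each subject doses q12h and is observed at obs_times
design_data <- function(n_subjects = 1, obs_times = c(2, 11),
                        dose_times = seq(0, 36, by = 12), amt = 2000,
                        analytes = "drug", wt = 70, age = 8, dv = NA_real_) {
  one <- function(i) {
    doses <- tibble::tibble(id = i, time = dose_times, evid = 1L, amt = amt,
                            analyte = NA_character_, dv = NA_real_, bql = NA,
                            wt = wt, age = age)
    obs <- tidyr::expand_grid(time = obs_times, analyte = analytes)
    obs <- tibble::tibble(id = i, time = obs$time, evid = 0L, amt = NA_real_,
                          analyte = obs$analyte, dv = dv, bql = FALSE,
                          wt = wt, age = age)
    dplyr::arrange(dplyr::bind_rows(doses, obs), time, evid)
  }
  dplyr::bind_rows(lapply(seq_len(n_subjects), one))
}

# fill dv by drawing one replicate from the model (data "generated by" model)
simulate_observations <- function(data, model, seed = 1) {
  ens <- simulate_ensemble(data, model, nsim = 1, seed = seed)
  out <- data
  out$dv[out$evid == 0] <- as.numeric(ens$sim[1, ])
  out
}

# fake ensemble wrapper for handcrafted simulation matrices
fake_ensemble <- function(sim, data, seed = 0) {
  obs <- data[data$evid == 0, , drop = FALSE]
  obs$.row <- seq_len(nrow(obs))
  structure(list(sim = sim, obs = obs, nsim = nrow(sim), seed = seed,
                 model = "fake", scale = "natural"),
            class = "pk_ensemble")
}
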