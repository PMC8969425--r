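test_that("degenerate randomness collapses replicates onto the prediction", {
  m <- toy_parent_model(omega = named_diag(c(CL = 0, V = 0)))
  m$error$drug$proportional <- 0 # degenerate on purpose; constructor forbids it
  d <- design_data(n_subjects = 3)
  ens <- simulate_ensemble(d, m, nsim = 20, seed = 1)
  pred <- population_prediction(d, m)
  pred_obs <- pred$pred[pred$evid == 0]
  for (r in 1:20) expect_equal(as.numeric(ens$sim[r, ]), pred_obs)
})

test_that("omega = 0 gives eta = 0 draws; mixing proportions are respected", {
  m0 <- toy_parent_model(omega = named_diag(c(CL = 0, V = 0)))
  set.seed(1)
  dr <- sample_individual(m0, 50)
  expect_true(all(dr$eta_CL == 0) && all(dr$eta_V == 0))

  mm <- toy_mixture_model(p_lo = 0.5)
  set.seed(42)
  dr <- sample_individual(mm, 10000)
  f_slow <- mean(dr$subpop == "slow")
  expect_lt(abs(f_slow - 0.5), 3 * sqrt(0.25 / 10000))

  m3 <- model_library("b")
  set.seed(7)
  dr3 <- sample_individual(m3, 20000)
  for (sp in names(m3$mixture$proportions)) {
    p <- m3$mixture$proportions[[sp]]
    expect_lt(abs(mean(dr3$subpop == sp) - p), 3 * sqrt(p * (1 - p) / 20000))
  }
})

test_that("a 10% proportional error yields a ~10% replicate CV", {
  m <- toy_parent_model(omega = named_diag(c(CL = 0, V = 0)), prop = 0.10)
  d <- design_data(obs_times = 6)
  ens <- simulate_ensemble(d, m, nsim = 1e5, seed = 3)
  cv <- stats::sd(ens$sim[, 1]) / mean(ens$sim[, 1])
  expect_equal(cv, 0.10, tolerance = 0.02)
})

test_that("ensembles are reproducible and replicate-prefix-stable", {
  m <- toy_joint_model()
  d <- design_data(n_subjects = 4, analytes = c("drug", "drug-M1"))
  e1 <- simulate_ensemble(d, m, nsim = 60, seed = 11)
  e2 <- simulate_ensemble(d, m, nsim = 60, seed = 11)
  expect_identical(e1$sim, e2$sim)
  # replicate r does not depend on the total replicate count
  e_small <- simulate_ensemble(d, m, nsim = 25, seed = 11)
  expect_identical(e_small$sim, e1$sim[1:25, ])
  # different seed, different draws
  expect_false(identical(e1$sim, simulate_ensemble(d, m, nsim = 60, seed = 12)$sim))
})

test_that("log-scale simulation equals a log-normal multiplicative error", {
  m_log <- toy_parent_model(prop = 0, add = 0.3, scale = "log",
                            omega = named_diag(c(CL = 0, V = 0)))
  d <- design_data(obs_times = 6)
  ens <- simulate_ensemble(d, m_log, nsim = 2e4, seed = 5)
  f <- population_prediction(d, m_log)$pred
  f <- f[!is.na(f)]
  qs <- stats::quantile(ens$sim[, 1], c(0.1, 0.5, 0.9), names = FALSE)
  theo <- f * exp(0.3 * stats::qnorm(c(0.1, 0.5, 0.9)))
  expect_equal(qs, theo, tolerance = 0.03)
})

test_that("permuting replicates leaves downstream diagnostics unchanged", {
  m <- toy_parent_model()
  d <- simulate_observations(design_data(n_subjects = 8), m, seed = 2)
  ens <- simulate_ensemble(d, m, nsim = 150, seed = 9)
  ens_perm <- ens
  set.seed(1)
  ens_perm$sim <- ens$sim[sample(150), ]
  expect_equal(compute_npde(d, ens)$records, compute_npde(d, ens_perm)$records)
  dp <- population_prediction(d, m)
  expect_equal(vpc_bands(dp, ens, n_bins = 2)$summary,
               vpc_bands(dp, ens_perm, n_bins = 2)$summary)
})

test_that("simulation guards: empty designs and nsim", {
  m <- toy_parent_model()
  d <- design_data()
  expect_error(simulate_ensemble(d[d$evid == 1, ], m, nsim = 5), "observation")
  expect_error(simulate_ensemble(d, m, nsim = 0), "nsim")
})
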