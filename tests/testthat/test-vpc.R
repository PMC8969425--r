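test_that("bin assignment: single bin, equal occupancy, tie rule, merging", {
  expect_identical(assign_bins(c(1, 5, 9), 1), rep(1L, 3))

  # 8 bins over 16 equally spaced times: exactly 2 per bin
  b <- assign_bins(1:16, 8)
  expect_identical(as.integer(table(b)), rep(2L, 8))

  # a time exactly on an interior edge goes to the lower bin
  b2 <- assign_bins(c(1, 2, 2.5, 3), n_bins = 2, strategy = "fixed", edges = c(1, 2, 3))
  expect_identical(b2, c(1L, 1L, 2L, 2L))

  # fewer distinct times than bins: merged with a warning
  expect_warning(b3 <- assign_bins(rep(c(1, 2), 5), 4), "merged")
  expect_lte(length(unique(b3)), 2)
})

test_that("prediction correction rescales by the bin-median PRED", {
  # constant PRED within the bin: identity
  expect_equal(prediction_correct(c(1, 2, 3), pred = c(2, 2, 2), bin = c(1, 1, 1)),
               c(1, 2, 3))
  # value 4.0, PRED 2.0 in a bin whose median PRED is 1.0 -> corrected 2.0
  expect_equal(prediction_correct(c(4, 5, 6), pred = c(2, 1, 1), bin = c(1, 1, 1))[1], 2)
  # positive scaling preserves replicate ordering within a record
  sims <- matrix(c(1, 3, 2, 5, 4, 6), nrow = 3)
  cor <- prediction_correct(sims, pred = c(2, 0.5), bin = c(1, 1))
  expect_identical(apply(cor, 2, order), apply(sims, 2, order))
  expect_error(prediction_correct(1, pred = 0, bin = 1), "positive")
})

test_that("outside percentages use one-decimal half-away-from-zero rounding", {
  expect_equal(outside_percentage(5, 103), 4.9)
  expect_equal(outside_percentage(23, 112), 20.5)
  expect_equal(outside_percentage(12, 103), 11.7) # 11.650... rounds up
  expect_equal(round_half_away(11.65, 1), 11.7)
  expect_equal(round_half_away(-11.65, 1), -11.7)
  expect_error(outside_percentage(5, 4), "exceed")
})

test_that("a degenerate ensemble collapses the band onto PRED", {
  m <- toy_parent_model(omega = named_diag(c(CL = 0, V = 0)))
  m$error$drug$proportional <- 0
  d <- design_data(n_subjects = 6, obs_times = c(3, 10))
  pred <- population_prediction(d, m)
  ens <- simulate_ensemble(d, m, nsim = 30, seed = 2)
  dd <- pred
  dd$dv[dd$evid == 0] <- pred$pred[pred$evid == 0] * 1.01 # all off-PRED
  v <- vpc_bands(dd, ens, n_bins = 2)
  expect_equal(v$bands$band_lo, v$bands$band_hi)
  expect_identical(v$summary$outside, v$summary$n)
})

test_that("correction is a no-op when each bin holds one design point", {
  # homogeneous subjects observed at the same time per bin: the bin median
  # PRED equals every record's PRED, so pcVPC and plain VPC coincide
  m <- toy_parent_model()
  d <- simulate_observations(design_data(n_subjects = 12, obs_times = c(4, 16)), m, 6)
  pred <- population_prediction(d, m)
  ens <- simulate_ensemble(d, m, nsim = 80, seed = 3)
  v_pc <- vpc_bands(pred, ens, n_bins = 2, correct = TRUE)
  v_plain <- vpc_bands(pred, ens, n_bins = 2, correct = FALSE)
  expect_equal(v_pc$bands, v_plain$bands)
  expect_equal(v_pc$summary, v_plain$summary)
})

test_that("late samples can be excluded from the outside counts", {
  m <- toy_parent_model()
  d <- simulate_observations(design_data(n_subjects = 10, obs_times = c(4, 16, 1100)),
                             m, 13)
  pred <- population_prediction(d, m)
  ens <- simulate_ensemble(d, m, nsim = 50, seed = 4)
  v_all <- vpc_bands(pred, ens, n_bins = 2)
  v_trim <- vpc_bands(pred, ens, n_bins = 2, max_time = 1000)
  expect_identical(sum(v_trim$summary$n), sum(v_all$summary$n) - 10L)
})

test_that("VPC guards: misalignment and tiny ensembles", {
  m <- toy_parent_model()
  d <- simulate_observations(design_data(n_subjects = 3), m, 1)
  pred <- population_prediction(d, m)
  ens <- simulate_ensemble(d, m, nsim = 10, seed = 1)
  expect_error(vpc_bands(pred[pred$evid == 0, ][-1, ], ens), "aligned")
  ens1 <- simulate_ensemble(d, m, nsim = 1, seed = 1)
  expect_error(vpc_bands(pred, ens1), "nsim")
})
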