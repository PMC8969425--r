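test_that("no drug appears before the first dose plus lag", {
  st <- pk_structure(2, has_metabolite = TRUE, lag = TRUE)
  p <- list(CL = 20, V = 100, ka = 1, ALAG = 2, Q = 8, Vp = 90,
            fm = 0.4, CLm = 6, Vm = 150)
  prof <- solve_profile(p, st, doses = data.frame(time = 5, amt = 1000),
                        times = c(0, 3, 6.9))
  expect_true(all(prof$conc == 0))
  after <- solve_profile(p, st, doses = data.frame(time = 5, amt = 1000),
                         times = 7.5)
  expect_true(all(after$conc > 0))
})

test_that("linear superposition: repeated doses equal shifted single doses", {
  st <- pk_structure(1, has_metabolite = TRUE)
  p <- list(CL = 5, V = 50, ka = 1.5, fm = 0.4, CLm = 3, Vm = 80)
  tt <- seq(0, 48, by = 1.5)
  both <- solve_profile(p, st, data.frame(time = c(0, 12), amt = 800), tt)
  d1 <- solve_profile(p, st, data.frame(time = 0, amt = 800), tt)
  d2 <- solve_profile(p, st, data.frame(time = 12, amt = 800), tt)
  expect_equal(both$conc, d1$conc + d2$conc, tolerance = 1e-12)
})

test_that("single oral dose matches the hand-coded Bateman solution", {
  CL <- 5; V <- 50; ka <- 1.5; D <- 1000; Fb <- 0.8
  k <- CL / V
  tt <- seq(0.25, 48, by = 0.25)
  bateman <- Fb * D * ka / (V * 1000 * (ka - k)) * (exp(-k * tt) - exp(-ka * tt))
  prof <- solve_profile(list(CL = CL, V = V, ka = ka, F = Fb), pk_structure(1),
                        data.frame(time = 0, amt = D), tt)
  expect_lt(max(abs(prof$conc - bateman) / bateman), 1e-6)
})

test_that("doubling all doses doubles every noise-free concentration", {
  st <- pk_structure(2, has_metabolite = TRUE, lag = TRUE)
  p <- list(CL = 20, V = 100, ka = 1, ALAG = 0.5, Q = 8, Vp = 90,
            fm = 0.4, CLm = 6, Vm = 150)
  tt <- seq(0.5, 36, by = 0.5)
  doses <- data.frame(time = c(0, 10, 24), amt = c(500, 700, 300))
  doses2 <- transform(doses, amt = 2 * amt)
  a <- solve_profile(p, st, doses, tt)
  b <- solve_profile(p, st, doses2, tt)
  expect_equal(b$conc, 2 * a$conc, tolerance = 1e-14)
})

test_that("mass is conserved when all elimination is switched off", {
  # with CL = CLm = 0 and F = 1 the compartment amounts must always sum to
  # the cumulative administered dose (checked on the ODE engine's states)
  st <- pk_structure(2, has_metabolite = TRUE, lag = FALSE)
  p <- list(CL = 0, V = 100, ka = 1, Q = 8, Vp = 90,
            fm = 0.4, CLm = 0, Vm = 150, F = 1)
  doses <- data.frame(time = c(0, 12), amt = c(600, 400))
  tt <- c(1, 6, 11.99, 12.5, 24, 48)
  sol <- pkeval:::solve_profile_ode(p, st, doses, tt)
  total <- rowSums(sol$amounts)
  cumdose <- ifelse(tt >= 12, 1000, 600)
  expect_equal(total, cumdose, tolerance = 1e-8)
})

test_that("near-coincident rate constants do not destabilise the solver", {
  # ka == CL/V is the classic degenerate Bateman case
  p <- list(CL = 5, V = 50, ka = 0.1)
  tt <- seq(0.5, 24, by = 0.5)
  a <- solve_profile(p, pk_structure(1), data.frame(time = 0, amt = 1000), tt)
  o <- solve_profile(p, pk_structure(1), data.frame(time = 0, amt = 1000), tt,
                     engine = "ode")
  expect_lt(max(abs(a$conc - o$conc) / pmax(o$conc, 1e-12)), 1e-6)
})

test_that("invalid inputs are rejected", {
  p <- list(CL = 5, V = 50, ka = 1.5)
  expect_error(solve_profile(p, pk_structure(1), data.frame(time = 0, amt = -5), 1),
               "positive")
  expect_error(solve_profile(p, pk_structure(1), data.frame(time = c(5, 0), amt = 1), 1),
               "sorted")
  expect_error(solve_profile(p, pk_structure(1), data.frame(time = 0, amt = 1), -1),
               "non-negative")
})
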