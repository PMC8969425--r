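test_that("mass/molar conversions follow the molecular weights", {
  risp <- pk_analyte("risperidone", 410.485, "parent")
  expect_identical(mass_to_molar(0, risp), 0)
  # assay LLOQ of 0.100 ng/mL in nmol/mL
  expect_equal(mass_to_molar(0.100, risp), 0.100 / 410.485)
  expect_equal(mass_to_molar(0.100, risp), 2.4361e-4, tolerance = 1e-4)
  # a 1 mg dose in nmol
  expect_equal(mass_to_molar(1, risp, "amount"), 1e6 / 410.485)
  expect_equal(mass_to_molar(1, risp, "amount"), 2436.1, tolerance = 1e-4)
  # round trip and error handling
  expect_equal(molar_to_mass(mass_to_molar(3.7, risp), risp), 3.7)
  expect_error(mass_to_molar(-1, risp), "negative")
  expect_error(pk_analyte("x", -5, "parent"), "positive")
})

test_that("individual parameters: identity, allometry, mixture overrides", {
  m <- toy_parent_model()
  # eta = 0, no covariates, no mixture: theta comes back exactly
  expect_equal(individual_parameters(m, list(wt = 70)), m$theta)

  # allometric preset at 35 kg multiplies CL by (35/70)^0.75
  ma <- pk_model("allo", list(pk_analyte("drug", 400, "parent")), pk_structure(1),
                 theta = list(CL = 5, V = 50, ka = 1.5),
                 covariates = allometric_terms("CL", "V"),
                 error = list(drug = list(proportional = 0.1)))
  p <- individual_parameters(ma, list(wt = 35))
  expect_equal(p$CL / 5, (35 / 70)^0.75)
  expect_equal(p$CL / 5, 0.59460, tolerance = 1e-5)
  expect_equal(p$V / 50, 0.5)

  # covariate at its reference value changes nothing
  expect_equal(individual_parameters(ma, list(wt = 70)), ma$theta)

  # mixture override replaces only the listed entries
  mb <- model_library("b")
  p_poor <- individual_parameters(mb, list(wt = 70), subpop = "poor")
  expect_equal(p_poor$CL, mb$mixture$overrides$poor$CL)
  expect_equal(p_poor$fm, mb$mixture$overrides$poor$fm)
  expect_equal(p_poor$V, mb$theta$V)

  expect_error(individual_parameters(mb, list(wt = 70), subpop = "ultrarapid"),
               "subpopulation")
  expect_error(individual_parameters(mb, list(), subpop = "poor"), "wt")
})

test_that("eta acts multiplicatively through exp()", {
  m <- toy_parent_model()
  p <- individual_parameters(m, list(), eta = c(CL = 0.3, V = -0.2))
  expect_equal(p$CL, m$theta$CL * exp(0.3))
  expect_equal(p$V, m$theta$V * exp(-0.2))
  expect_equal(p$ka, m$theta$ka)
})

test_that("model validation rejects inconsistent specifications", {
  an <- list(pk_analyte("drug", 400, "parent"))
  err <- list(drug = list(proportional = 0.1))
  expect_error(pk_model("x", an, pk_structure(1), list(CL = -1, V = 50, ka = 1),
                        error = err), "positive")
  expect_error(pk_model("x", an, pk_structure(2), list(CL = 1, V = 50, ka = 1),
                        error = err), "Q")
  om <- matrix(c(1, 2, 2, 1), 2, 2, dimnames = list(c("CL", "V"), c("CL", "V")))
  expect_error(pk_model("x", an, pk_structure(1), list(CL = 1, V = 50, ka = 1),
                        omega = om, error = err), "semidefinite")
  expect_error(pk_model("x", an, pk_structure(1), list(CL = 1, V = 50, ka = 1),
                        mixture = list(proportions = c(a = 0.6, b = 0.5),
                                       overrides = list(a = list(CL = 1), b = list(CL = 2))),
                        error = err), "sum to 1")
  expect_error(pk_model("x", an, pk_structure(1), list(CL = 1, V = 50, ka = 1),
                        error = list(drug = list(additive = 0, proportional = 0))),
               "error")
})

test_that("model configurations survive a write/read round trip", {
  for (lab in c("a", "b", "e")) {
    m <- model_library(lab)
    path <- withr::local_tempfile(fileext = ".yaml")
    write_model_config(m, path)
    m2 <- read_model_config(path)
    expect_equal(m2$theta, m$theta)
    expect_equal(m2$omega, m$omega)
    expect_equal(m2$mixture$proportions, m$mixture$proportions)
    expect_equal(m2$covariates, m$covariates)
    expect_equal(m2$error, m$error)
    expect_identical(m2$scale, m$scale)
  }
})
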