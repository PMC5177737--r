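base_pop <- function(covariates = list(), omega2 = c(CL = 0.09, V = 0.04)) {
  population_model(pk_model(1), c(CL = 2, V = 3), omega = omega2,
                   error = error_model("combined", sigma_add = 5,
                                       sigma_prop = 0.1),
                   covariates = covariates)
}

test_that("typical values apply each covariate functional form", {
  # no effects: identity
  expect_equal(typical_value(base_pop(), list(AGE = 30)),
               c(CL = 2, V = 3))
  # each form at its centering value returns the raw TV
  for (form in c("linear", "power", "exponential")) {
    p <- base_pop(list(covariate_effect("CL", "BW", form, theta = 0.75,
                                        center = 70)))
    expect_equal(typical_value(p, list(BW = 70))[["CL"]], 2)
  }
  # power form doubling the covariate: TV * 2^theta
  p <- base_pop(list(covariate_effect("CL", "BW", "power", theta = 0.75,
                                      center = 70)))
  expect_equal(typical_value(p, list(BW = 140))[["CL"]], 2 * 2^0.75,
               tolerance = 1e-12)
  expect_equal(2 * 2^0.75, 3.3636, tolerance = 1e-4)
  # linear and exponential forms
  p2 <- base_pop(list(covariate_effect("V", "AGE", "linear", theta = 0.01,
                                       center = 30)))
  expect_equal(typical_value(p2, list(AGE = 40))[["V"]], 3 * 1.1)
  p3 <- base_pop(list(covariate_effect("CL", "AGE", "exponential",
                                       theta = -0.02, center = 30)))
  expect_equal(typical_value(p3, list(AGE = 35))[["CL"]],
               2 * exp(-0.1))
  # categorical effect applies only on the coded level
  p4 <- base_pop(list(covariate_effect("CL", "BTYPE", "categorical",
                                       theta = 0.3, level = 4)))
  expect_equal(typical_value(p4, list(BTYPE = 4))[["CL"]], 2.6)
  expect_equal(typical_value(p4, list(BTYPE = 1))[["CL"]], 2)
  # multiple effects compose multiplicatively
  p5 <- base_pop(list(
    covariate_effect("CL", "BW", "power", theta = 0.75, center = 70),
    covariate_effect("CL", "AGE", "exponential", theta = -0.02,
                     center = 30)))
  expect_equal(typical_value(p5, list(BW = 140, AGE = 35))[["CL"]],
               2 * 2^0.75 * exp(-0.1))
})

test_that("a missing required covariate raises a typed condition", {
  p <- base_pop(list(covariate_effect("CL", "VWF", "power", theta = 0.2,
                                      center = 100)))
  expect_error(typical_value(p, list(AGE = 30)),
               class = "hemopk_covariate_unavailable")
})

test_that("individual parameters follow the log-normal law", {
  p <- base_pop()
  expect_equal(individual_parameters(p, list(), c(0, 0)),
               c(CL = 2, V = 3))
  th <- individual_parameters(p, list(), c(log(2), 0))
  expect_equal(th[["CL"]], 4)
  expect_error(individual_parameters(p, list(), 0.1), "length")
  # monotone in each eta component
  e1 <- individual_parameters(p, list(), c(0.5, -0.2))
  e2 <- individual_parameters(p, list(), c(0.6, -0.2))
  expect_gt(e2[["CL"]], e1[["CL"]])
})

test_that("simulated etas reproduce omega: variance and independence", {
  set.seed(77)
  n <- 1e5
  om <- matrix(c(0.09, 0, 0, 0.04), 2)
  eta <- hemopk:::rmvnorm_chol(n, c(0, 0), om)
  # var(log CL_i) = omega^2_CL within 3 standard errors
  se_var <- 0.09 * sqrt(2 / (n - 1))
  expect_lt(abs(var(eta[, 1]) - 0.09), 3 * se_var)
  # diagonal omega: components uncorrelated
  expect_lt(abs(cor(eta[, 1], eta[, 2])), 0.02)
})

test_that("residual SD follows each error form", {
  em <- error_model("combined", sigma_add = 5, sigma_prop = 0.1)
  expect_equal(residual_sd(0, em), 5)            # proportional part vanishes
  expect_equal(residual_sd(100, em), sqrt(125))  # ~11.1803
  expect_equal(sqrt(125), 11.1803, tolerance = 1e-4)
  emp <- error_model("proportional", sigma_prop = 0.15)
  expect_equal(residual_sd(c(10, 20), emp), c(1.5, 3))  # linear in f
  expect_error(residual_sd(-1, em), "non-negative")
  expect_error(error_model("additive", sigma_add = -1))
})

test_that("model YAML serialization round trips", {
  p <- base_pop(list(covariate_effect("CL", "BW", "power", theta = 0.75,
                                      center = 70)))
  f <- tempfile(fileext = ".yaml")
  write_model_yaml(p, f)
  p2 <- read_model_yaml(f)
  expect_equal(p2$theta, p$theta)
  expect_equal(p2$omega, p$omega)
  expect_equal(p2$error$form, p$error$form)
  expect_equal(p2$covariates[[1]]$theta, 0.75)
  expect_equal(typical_value(p2, list(BW = 100)),
               typical_value(p, list(BW = 100)))
})
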