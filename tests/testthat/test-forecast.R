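# Bayesian individual forecasting: MAP, credibility bands, threshold
# reporting.

test_that("with no observations the band matches the prior predictive", {
  sim <- small_cohort(n = 2, seed = 201)
  priors <- prior_set(prop_truth(), "truth")
  s <- subject_data(sim$dataset, 1)
  s0 <- s[s$EVID == 1, ]  # dose records only
  g <- c(6, 24, 48)
  fc <- posterior_band(s0, priors, time_grid = g, n_draws = 4000,
                       seed = 9)
  expect_equal(fc$ess, 4000, tolerance = 1)  # uniform weights
  # oracle: direct eta draws from the prior
  set.seed(4242)
  eta <- hemopk:::rmvnorm_chol(4e4, c(0, 0), priors$pop$omega)
  typ <- typical_value(priors$pop, list(AGE = s$AGE[1], BW = s$BW[1]))
  fr <- hemopk:::frame_one(s0)
  th <- matrix(rep(typ, each = 4e4), 4e4,
               dimnames = list(NULL, names(typ)))
  th[, priors$pop$eta_on] <- th[, priors$pop$eta_on] * exp(eta)
  cc <- hemopk:::cpp_conc_draws(1, th, fr$reg_start, fr$reg_dur,
                                fr$reg_rate, fr$baseline, fr$resid_conc, g)
  oracle <- apply(cc, 2, quantile, c(0.025, 0.5, 0.975))
  expect_equal(fc$band$median, oracle[2, ], tolerance = 0.05)
  expect_equal(fc$band$lower, oracle[1, ], tolerance = 0.10)
  expect_equal(fc$band$upper, oracle[3, ], tolerance = 0.10)
})

test_that("band ordering holds pointwise for every seed", {
  sim <- small_cohort(n = 3, seed = 211)
  priors <- prior_set(prop_truth(), "truth")
  for (sd_ in 1:3) {
    s <- subject_data(sparsify(sim$dataset, c(24, 48)), sd_)
    fc <- posterior_band(s, priors, n_draws = 400, seed = sd_)
    expect_true(all(fc$band$lower <= fc$band$median + 1e-9))
    expect_true(all(fc$band$median <= fc$band$upper + 1e-9))
  }
})

test_that("threshold times are ordered and lower-bound leads the median", {
  sim <- small_cohort(n = 3, seed = 221)
  priors <- prior_set(prop_truth(), "truth")
  s <- subject_data(sparsify(sim$dataset, c(3, 24, 48)), 1)
  fc <- posterior_band(s, priors, n_draws = 800, seed = 3)
  rep_ <- report_thresholds(fc)
  tt <- rep_$thresholds$time_h
  expect_true(all(diff(tt) > 0))  # t(0.05) < t(0.02) < t(0.01)
  # the lower bound crosses each threshold before the median curve does
  med_fun <- hemopk:::forecast_quantile_fun(fc, 0.5)
  for (i in seq_len(nrow(rep_$thresholds))) {
    lvl <- rep_$thresholds$threshold_iu_ml[i] * 1000
    expect_gt(med_fun(rep_$thresholds$time_h[i]), lvl)
  }
  # fixed-time concentrations carry ordered intervals
  cc <- rep_$concentrations
  expect_true(all(cc$lower_iu_ml <= cc$median_iu_ml &
                  cc$median_iu_ml <= cc$upper_iu_ml))
})

test_that("the deterministic limit matches the closed-form inversion", {
  # omega -> 0 with rich data: the band collapses onto the typical curve
  tight <- fviii_reference_model(
    error = error_model("proportional", sigma_prop = 0.05),
    omega2 = c(CL = 1e-8, V = 1e-8))
  sim <- small_cohort(n = 2, seed = 231, model = tight)
  priors <- prior_set(tight, "tight")
  s <- subject_data(sim$dataset, 1)
  fc <- posterior_band(s, priors, n_draws = 500, seed = 7)
  rep_ <- report_thresholds(fc, thresholds_iu_ml = 0.01)
  fr <- hemopk:::frame_one(s)
  reg <- dose_regimen(fr$reg_start, fr$reg_dur, fr$reg_rate * fr$reg_dur)
  t_oracle <- time_to_level(pk_model(1),
                            typical_value(tight, fr$covs), reg, 10,
                            initial_state(fr$baseline, fr$resid_conc))
  expect_lt(abs(rep_$thresholds$time_h[1] - t_oracle), 0.1)
})

test_that("MAP recovers simulated individual parameters from rich profiles", {
  sim <- small_cohort(n = 20, seed = 241)
  priors <- prior_set(prop_truth(), "truth")
  rel_err <- vapply(1:20, function(cid) {
    m <- map_individual(subject_data(sim$dataset, cid), priors)
    truth_cl <- sim$truth$subjects$CL[cid]
    abs(m$theta[["CL"]] - truth_cl) / truth_cl
  }, numeric(1))
  expect_lt(median(rel_err), 0.10)
})

test_that("duplicating the data pulls eta away from the prior mode", {
  sim <- small_cohort(n = 3, seed = 251)
  priors <- prior_set(prop_truth(), "truth")
  for (cid in 1:3) {
    s <- subject_data(sparsify(sim$dataset, c(6, 24)), cid)
    m1 <- map_individual(s, priors)
    obs <- s[s$EVID != 1, ]
    s2 <- rbind(s, obs)  # every observation twice
    m2 <- map_individual(s2, priors)
    expect_true(all(abs(m2$eta) >= abs(m1$eta) - 1e-6))
  }
})

test_that("credibility bands contract as observations accumulate", {
  sim <- small_cohort(n = 6, seed = 261)
  priors <- prior_set(prop_truth(), "truth")
  g <- seq(0, 72, by = 2)
  narrower <- vapply(1:6, function(cid) {
    s <- subject_data(sim$dataset, cid)
    s2 <- sparsify(pk_dataset(s), c(24, 48))
    s6 <- sparsify(pk_dataset(s), c(1, 6, 9, 24, 32, 48))
    f2 <- posterior_band(s2, priors, time_grid = g, n_draws = 500,
                         seed = 100 + cid)
    f6 <- posterior_band(s6, priors, time_grid = g, n_draws = 500,
                         seed = 100 + cid)
    mean(f6$band$upper - f6$band$lower) <
      mean(f2$band$upper - f2$band$lower)
  }, logical(1))
  expect_true(all(narrower))
})

test_that("forecast reproducibility and prior immutability", {
  sim <- small_cohort(n = 2, seed = 271)
  priors <- prior_set(prop_truth(), "brand-A")
  s <- subject_data(sim$dataset, 1)
  f1 <- posterior_band(s, priors, n_draws = 300, seed = 5)
  f2 <- posterior_band(s, priors, n_draws = 300, seed = 5)
  expect_identical(f1$band, f2$band)
  expect_equal(priors$provenance, "brand-A")
  expect_error(prior_set(population_model(
    pk_model(1), c(CL = 0.2, V = 3),
    omega = c(CL = 0), error = error_model("additive", 1))),
    "positive-definite")
})
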