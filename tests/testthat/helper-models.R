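# Shared fixtures: small truth models and cohorts built in code.

prop_truth <- function(sigma_prop = 0.1, omega2 = c(CL = 0.09, V = 0.09)) {
  fviii_reference_model(error = error_model("proportional",
                                            sigma_prop = sigma_prop),
                        omega2 = omega2)
}

small_cohort <- function(n = 8, seed = 1, model = prop_truth(), ...) {
  simulate_cohort(simulation_spec(n_subjects = n, seed = seed,
                                  model = model, ...))
}

# exclusion of BLQ rows (the naive alternative to M3); subjects whose
# observations are all BLQ are dropped entirely
drop_blq_rows <- function(ds) {
  d <- ds[ds$EVID != 3, , drop = FALSE]
  keep <- vapply(unique(d$CID),
                 function(cc) any(d$EVID[d$CID == cc] == 0), logical(1))
  pk_dataset(d[d$CID %in% unique(d$CID)[keep], , drop = FALSE],
             provenance = "blq-excluded")
}

# one assembled subject with exact (noise-free) 1-cpt observations
exact_subject <- function(cid = 1, CL = 0.2, V = 3, amount = 2000,
                          duration = 0.25, times = c(1, 3, 6, 12, 24),
                          baseline = 5, bw = 70, age = 30,
                          loq = DEFAULT_LOQ_IUL) {
  f <- pk_concentration(pk_model(1), c(CL = CL, V = V),
                        dose_regimen(0, duration, amount), times,
                        initial_state(baseline, 0))
  assemble_subject(cid, dose = list(amount_iu = amount,
                                    duration_h = duration),
                   observations = data.frame(time_h = times, conc_iul = f),
                   demographics = list(age = age, bw = bw),
                   baseline_iul = baseline, loq_iul = loq)
}
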