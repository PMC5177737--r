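## Synthetic cohort simulator: rich and sparse factor-level datasets with
## known ground truth, standing in for proprietary dense PK study cohorts.

#' Reference FVIII-like truth model (simulator default)
#'
#' A 1-compartment model with terminal half-life about 12 h (CL 0.17 L/h,
#' V 3 L), log-normal between-subject variability (omega^2 = 0.09 on CL
#' and V) and combined additive-proportional residual error. These are
#' implementation defaults chosen as plausible for a recombinant FVIII
#' concentrate, not estimates from any real brand.
#'
#' @param error an [error_model()] overriding the default combined form.
#' @param omega2 named vector of eta variances.
#' @param covariates covariate effects for the truth (default none).
#' @export
fviii_reference_model <- function(error = error_model("combined",
                                                      sigma_add = 2,
                                                      sigma_prop = 0.1),
                                  omega2 = c(CL = 0.09, V = 0.09),
                                  covariates = list()) {
  population_model(pk_model(1), theta = c(CL = 0.17, V = 3),
                   omega = omega2, error = error,
                   covariates = covariates)
}

#' Simulation specification
#'
#' Defines the cohort generator: truth model, subject count, covariate
#' ranges (ages 12-65 years and weights in the 42-130 kg span typical of
#' adolescent/adult dense PK studies), an 11-sample rich schedule (4
#' points in the first hour, 7 through 48 h), 50 IU/kg dosed over 10
#' minutes, and censoring at the 0.01 IU/mL LOQ.
#'
#' @param n_subjects cohort size.
#' @param model truth [population_model()].
#' @param age_range years (uniform draw).
#' @param dose_iu_kg dose per kg.
#' @param infusion_duration_h infusion duration (0.1666 = 10 min).
#' @param schedule_h sampling times, hours after dose start.
#' @param loq_iul assay LOQ, IU/L.
#' @param baseline_iul endogenous baseline given to every subject.
#' @param seed mandatory RNG seed.
#' @export
simulation_spec <- function(n_subjects = 24,
                            model = fviii_reference_model(),
                            age_range = c(12, 65),
                            dose_iu_kg = 50,
                            infusion_duration_h = 0.1666,
                            schedule_h = c(0.25, 0.5, 0.75, 1, 3, 6, 9,
                                           24, 28, 32, 48),
                            loq_iul = DEFAULT_LOQ_IUL,
                            baseline_iul = DEFAULT_BASELINE_IUL,
                            seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(length(schedule_h) > 0, loq_iul > 0, n_subjects >= 1)
  structure(list(n_subjects = n_subjects, model = model,
                 age_range = age_range, dose_iu_kg = dose_iu_kg,
                 infusion_duration_h = infusion_duration_h,
                 schedule_h = sort(schedule_h), loq_iul = loq_iul,
                 baseline_iul = baseline_iul, seed = seed),
            class = "simulation_spec")
}

## weight conditional on age: linear growth to 18 y, adult plateau,
## log-normal spread (a simulator choice mimicking pediatric-to-adult
## dense-study ranges)
simulate_weight <- function(age) {
  mu <- ifelse(age < 18, 10 + 3.5 * age, 73)
  pmin(pmax(mu * rlnorm(length(age), 0, 0.15), 15), 190)
}

#' Simulate a cohort with known ground truth
#'
#' Draws covariates, eta ~ N(0, Omega), computes individual parameters,
#' simulates concentrations at the schedule with residual error, censors
#' values below the LOQ into BLQ rows, and assembles the records through
#' [assemble_subject()]. Fully reproducible from the spec's seed.
#'
#' @param spec a [simulation_spec()].
#' @return list: `dataset` (a [pk_dataset()]) and `truth` (list with
#'   `subjects` and `observations` data frames).
#' @export
simulate_cohort <- function(spec) {
  set.seed(spec$seed)
  pop <- spec$model
  model <- pop$structural
  q <- length(pop$eta_on)
  n <- spec$n_subjects
  age <- round(runif(n, spec$age_range[1], spec$age_range[2]), 1)
  bw <- round(simulate_weight(age), 1)
  eta <- if (q && any(pop$omega != 0))
    rmvnorm_chol(n, rep(0, q), pop$omega)
  else matrix(0, n, q)
  blocks <- list()
  subj_rows <- list()
  obs_rows <- list()
  for (i in seq_len(n)) {
    covs <- list(AGE = age[i], BW = bw[i])
    theta <- individual_parameters(pop, covs, eta[i, ])
    if (any(theta <= 0)) stop("spec yields non-positive parameters")
    amt <- spec$dose_iu_kg * bw[i]
    reg <- dose_regimen(0, trunc4(spec$infusion_duration_h), amt)
    f <- pk_concentration(model, theta, reg, spec$schedule_h,
                          initial_state(spec$baseline_iul, 0))
    em <- pop$error
    g <- residual_sd(f, em)
    y <- if (em$form == "exponential") f * exp(g * rnorm(length(f)))
         else pmax(f + g * rnorm(length(f)), 0)
    blocks[[i]] <- assemble_subject(
      cid = i, dose = list(amount_iu = amt,
                           duration_h = spec$infusion_duration_h),
      observations = data.frame(time_h = spec$schedule_h, conc_iul = y),
      demographics = list(age = age[i], bw = bw[i]),
      baseline_iul = spec$baseline_iul, loq_iul = spec$loq_iul)
    srow <- data.frame(cid = i, age = age[i], bw = bw[i])
    for (k in seq_len(q)) srow[[paste0("eta_", pop$eta_on[k])]] <- eta[i, k]
    for (p in names(theta)) srow[[p]] <- theta[[p]]
    subj_rows[[i]] <- srow
    obs_rows[[i]] <- data.frame(cid = i, time_h = spec$schedule_h,
                                f_iul = f, y_iul = y,
                                blq = y < spec$loq_iul)
  }
  ds <- pk_dataset(do.call(rbind, blocks),
                   provenance = sprintf("simulated (seed %d)", spec$seed))
  list(dataset = ds,
       truth = list(subjects = do.call(rbind, subj_rows),
                    observations = do.call(rbind, obs_rows),
                    spec = spec))
}

#' Reduce a rich dataset to a sparse sampling design
#'
#' Keeps only observation/BLQ rows at the given times (the 3-4 levels per
#' patient a clinical site would submit); dose and first records are kept
#' intact.
#'
#' @param ds a [pk_dataset()].
#' @param keep_times hours to retain.
#' @export
sparsify <- function(ds, keep_times) {
  if (!length(keep_times)) stop("keep_times must be non-empty")
  kt <- trunc4(keep_times)
  keep <- ds$EVID == 1 | trunc4(ds$TIMEH) %in% kt
  pk_dataset(ds[keep, , drop = FALSE],
             provenance = paste0(attr(ds, "provenance"), " [sparsified]"))
}

#' Plant detectable errors in a dataset
#'
#' Used to exercise the validation rules: plants rising-concentration
#' rows, duplicates, covariate outliers and missing values, returning the
#' modified dataset and a ledger of what was planted where.
#'
#' @param ds a [pk_dataset()].
#' @param error_menu named list of counts:
#'   `rising`, `duplicate`, `covariate_outlier`, `missing`.
#' @param seed RNG seed.
#' @return list: `dataset`, `planted` (ledger data frame).
#' @export
inject_errors <- function(ds, error_menu = list(), seed = 1) {
  set.seed(seed)
  menu <- modifyList(list(rising = 0, duplicate = 0,
                          covariate_outlier = 0, missing = 0), error_menu)
  out <- as.data.frame(ds)
  planted <- list()
  note <- function(cid, row, category)
    planted[[length(planted) + 1]] <<-
      data.frame(cid = cid, row = row, category = category)
  obs_idx <- which(out$EVID == 0)
  if (menu$rising > 0) {
    ## pick observations with a valid predecessor and raise them above it
    cand <- obs_idx[vapply(obs_idx, function(r) {
      prev <- which(out$CID == out$CID[r] & out$EVID == 0 &
                    out$TIMEH < out$TIMEH[r])
      length(prev) > 0
    }, logical(1))]
    pick <- sample(cand, min(menu$rising, length(cand)))
    for (r in pick) {
      prev <- which(out$CID == out$CID[r] & out$EVID == 0 &
                    out$TIMEH < out$TIMEH[r])
      out$DV[r] <- max(out$DV[prev]) * 2
      note(out$CID[r], r, "rising-concentration")
    }
  }
  if (menu$covariate_outlier > 0) {
    pick <- sample(unique(out$CID), min(menu$covariate_outlier,
                                        length(unique(out$CID))))
    for (cid in pick) {
      rows <- which(out$CID == cid)
      out$AGE[rows] <- 250
      note(cid, rows[1], "covariate-outlier")
    }
  }
  if (menu$missing > 0) {
    pick <- sample(obs_idx, min(menu$missing, length(obs_idx)))
    for (r in pick) {
      out$DV[r] <- NA
      note(out$CID[r], r, "missing-value")
    }
  }
  if (menu$duplicate > 0) {
    pick <- sample(seq_len(nrow(out)), min(menu$duplicate, nrow(out)))
    dup <- out[pick, , drop = FALSE]
    for (j in seq_along(pick))
      note(dup$CID[j], NA_integer_, "duplicate-record")
    out <- rbind(out, dup)
    out <- out[order(match(out$CID, unique(out$CID))), , drop = FALSE]
  }
  rownames(out) <- NULL
  list(dataset = pk_dataset(out, provenance =
                              paste0(attr(ds, "provenance"),
                                     " [errors planted]")),
       planted = if (length(planted)) do.call(rbind, planted)
                 else data.frame(cid = numeric(), row = integer(),
                                 category = character()))
}
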