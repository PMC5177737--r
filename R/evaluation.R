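## Model evaluation: goodness-of-fit diagnostics (CWRES, IWRES,
## shrinkage, collinearity), bootstrap stability, cross-validation with
## mean error / mean squared error, and sparse-subset validation.

#' Goodness-of-fit diagnostics
#'
#' Plot-ready tables (no rendering): observed vs population/individual
#' predictions, conditional weighted residuals (CWRES, via the FOCE
#' first-order expansion about the conditional eta mode), individual
#' weighted residuals, QQ-plot data, eta histograms, eta- and
#' epsilon-shrinkage, the condition number of the estimation covariance
#' (when available) and variance inflation factors across covariates.
#' CWRES/IWRES are computed only for valid observations (`MDV5 = 0`); BLQ
#' rows are excluded.
#'
#' @param fit a converged `pk_fit`.
#' @param ds the fitted dataset (unused; the fit carries its frame).
#' @return list of class `pk_diagnostics`: `residuals` (per observation),
#'   `eta` (per subject), `shrinkage`, `condition_number`, `vif`,
#'   `qq` (theoretical vs sample CWRES quantiles).
#' @export
compute_diagnostics <- function(fit, ds = NULL) {
  if (!isTRUE(fit$converged))
    stop("diagnostics require a converged fit")
  pop <- fit$pop
  ncpt <- pop$structural$n_compartments
  q <- length(pop$eta_on)
  oi <- omega_inv(pop$omega)
  rows <- list()
  for (i in seq_along(fit$frame)) {
    fr <- fit$frame[[i]]
    keep <- fr$mdv5 == 0 & fr$is_blq == 0
    if (!any(keep)) next
    typ <- as.numeric(typical_matrix(pop, fit$cov_df[i, , drop = FALSE]))
    names(typ) <- names(pop$theta)
    eh <- fit$eta_hat[i, ]
    ipar <- typ
    ipar[pop$eta_on] <- ipar[pop$eta_on] * exp(eh)
    f_eta <- function(eta) {
      p <- typ
      p[pop$eta_on] <- p[pop$eta_on] * exp(eta)
      as.numeric(cpp_conc(ncpt, p, fr$reg_start, fr$reg_dur, fr$reg_rate,
                          fr$baseline, fr$resid_conc, fr$t_obs))[keep]
    }
    fhat <- f_eta(eh)
    y <- fr$dv[keep]
    g <- residual_sd(fhat, pop$error)
    ## FOCE linearization about the conditional mode
    Fm <- vapply(seq_len(q), function(k) {
      h <- 1e-4
      ep <- eh; em <- eh
      ep[k] <- ep[k] + h; em[k] <- em[k] - h
      (f_eta(ep) - f_eta(em)) / (2 * h)
    }, numeric(length(fhat)))
    Fm <- matrix(Fm, ncol = q)
    Ey <- fhat - as.numeric(Fm %*% eh)
    V <- Fm %*% pop$omega %*% t(Fm) + diag(g^2, length(g))
    L <- t(chol((V + t(V)) / 2))
    cwres <- as.numeric(forwardsolve(L, y - Ey))
    iwres <- (y - fhat) / g
    pred0 <- as.numeric(cpp_conc(ncpt, typ, fr$reg_start, fr$reg_dur,
                                 fr$reg_rate, fr$baseline, fr$resid_conc,
                                 fr$t_obs))[keep]
    rows[[length(rows) + 1]] <- data.frame(
      cid = fr$cid, time = fr$t_obs[keep], dv = y, pred = pred0,
      ipred = fhat, cwres = cwres, iwres = iwres)
  }
  res <- do.call(rbind, rows)
  omega_sd <- sqrt(diag(pop$omega))
  eta_shrink <- (1 - apply(fit$eta_hat, 2, sd) / omega_sd) * 100
  eps_shrink <- (1 - sd(res$iwres)) * 100
  vif <- covariate_vif(fit$cov_df)
  srt <- sort(res$cwres)
  qq <- data.frame(theoretical = qnorm(stats::ppoints(length(srt))),
                   sample = srt)
  structure(list(residuals = res,
                 eta = data.frame(cid = rownames(fit$eta_hat),
                                  fit$eta_hat),
                 shrinkage = list(eta_pct = eta_shrink,
                                  eps_pct = eps_shrink),
                 condition_number = fit$condition_number %||% NA_real_,
                 vif = vif, qq = qq),
            class = "pk_diagnostics")
}

covariate_vif <- function(cov_df) {
  num <- cov_df[, vapply(cov_df, function(x)
    is.numeric(x) && length(unique(x[!is.na(x)])) > 1, logical(1)),
    drop = FALSE]
  if (ncol(num) < 2) return(setNames(rep(NA_real_, ncol(num)), names(num)))
  vapply(names(num), function(cn) {
    r2 <- summary(lm(num[[cn]] ~ ., data = num[setdiff(names(num),
                                                       cn)]))$r.squared
    1 / max(1 - r2, 1e-12)
  }, numeric(1))
}

#' Bootstrap the population fit
#'
#' Subject-level resampling with replacement (same number of subjects),
#' refit on each resample, percentile 2.5/50/97.5 intervals per parameter.
#' Non-converged resamples are counted and excluded from the percentiles;
#' a success rate below 50% flags the model unstable.
#'
#' @param ds a [pk_dataset()].
#' @param pop the model to refit (e.g. `fit$pop`).
#' @param n_resamples number of bootstrap resamples.
#' @param seed RNG seed (recorded in the result).
#' @param options fitting options.
#' @return list of class `pk_bootstrap`: `percentiles` (matrix),
#'   `estimates` (matrix of per-resample natural parameters),
#'   `success_rate`, `unstable`, `seed`.
#' @export
bootstrap_fit <- function(ds, pop, n_resamples = 200, seed = 1,
                          options = list()) {
  stopifnot(n_resamples >= 1)
  set.seed(seed)
  cids <- unique(ds$CID)
  n <- length(cids)
  est <- list()
  ok <- logical(n_resamples)
  for (b in seq_len(n_resamples)) {
    pick <- sample(cids, n, replace = TRUE)
    res <- do.call(rbind, lapply(seq_along(pick), function(j) {
      s <- ds[ds$CID == pick[j], , drop = FALSE]
      s$CID <- j
      s
    }))
    dsb <- pk_dataset(res, provenance = paste0("bootstrap-", b))
    fb <- tryCatch(fit_population(dsb, pop, options),
                   error = function(e) NULL)
    ok[b] <- !is.null(fb) && fb$converged
    if (!is.null(fb)) est[[b]] <- natural_params(fb$pop)
  }
  kept <- do.call(rbind, est[ok])
  pct <- if (!is.null(kept) && nrow(kept))
    apply(kept, 2, quantile, probs = c(0.025, 0.5, 0.975))
  else NULL
  rate <- mean(ok)
  structure(list(percentiles = pct, estimates = kept,
                 n_resamples = n_resamples, success_rate = rate,
                 unstable = rate < 0.5, seed = seed),
            class = "pk_bootstrap")
}

#' Cross-validation with mean error and mean squared error
#'
#' Subjects (never observations within a subject) are partitioned into
#' folds (`k`-fold) or a single holdout set. The model is refitted on the
#' training subjects and held-out subjects are predicted at the population
#' level (`eta = 0`, own covariates and regimen). Bias and accuracy are
#' the mean error `ME = mean(pred - obs)` and mean squared error of the
#' valid (non-BLQ) held-out observations, per fold and pooled
#' (observation-count weighted).
#'
#' @param ds a [pk_dataset()].
#' @param pop model skeleton to refit per fold.
#' @param scheme `"kfold"` or `"holdout"`.
#' @param k number of folds.
#' @param holdout_fraction fraction of subjects held out.
#' @param seed RNG seed for the partition.
#' @param options fitting options.
#' @param log_scale compute ME/MSE on log-concentrations.
#' @param refit refit the model on each training set (default); with
#'   `FALSE` the supplied model is evaluated as-is on the held-out
#'   subjects (external evaluation of a fixed model).
#' @return list of class `pk_crossval`: `folds` (per-fold table), `me`,
#'   `mse` (pooled), `scheme`, `seed`.
#' @export
cross_validate <- function(ds, pop, scheme = c("kfold", "holdout"),
                           k = 5, holdout_fraction = 0.2, seed = 1,
                           options = list(), log_scale = FALSE,
                           refit = TRUE) {
  scheme <- match.arg(scheme)
  set.seed(seed)
  cids <- unique(ds$CID)
  n <- length(cids)
  if (scheme == "kfold") {
    if (k > n) stop("k cannot exceed the number of subjects")
    fold_of <- sample(rep(seq_len(k), length.out = n))
    folds <- split(cids, fold_of)
  } else {
    nh <- max(1, round(holdout_fraction * n))
    folds <- list(sample(cids, nh))
  }
  rows <- list()
  for (fi in seq_along(folds)) {
    test_cids <- folds[[fi]]
    if (refit) {
      train <- pk_dataset(ds[!ds$CID %in% test_cids, , drop = FALSE],
                          provenance = "cv-train")
      fitf <- fit_population(train, pop, options)
    } else {
      fitf <- list(pop = pop) # evaluate the supplied model as-is
    }
    frame_t <- est_frame(pk_dataset(ds[ds$CID %in% test_cids, ,
                                       drop = FALSE],
                                    provenance = "cv-test"))
    err <- unlist(lapply(frame_t, function(fr) {
      keep <- fr$is_blq == 0
      if (!any(keep)) return(numeric(0))
      typ <- typical_value(fitf$pop, fr$covs)
      pred <- as.numeric(cpp_conc(pop$structural$n_compartments,
                                  as.numeric(typ), fr$reg_start,
                                  fr$reg_dur, fr$reg_rate, fr$baseline,
                                  fr$resid_conc, fr$t_obs))[keep]
      obs <- fr$dv[keep]
      if (log_scale) log(pred) - log(obs) else pred - obs
    }))
    if (!length(err)) stop("fold ", fi, " has zero valid observations")
    rows[[fi]] <- data.frame(fold = fi, n_obs = length(err),
                             me = mean(err), mse = mean(err^2))
  }
  tab <- do.call(rbind, rows)
  w <- tab$n_obs / sum(tab$n_obs)
  structure(list(folds = tab, me = sum(w * tab$me),
                 mse = sum(w * tab$mse), scheme = scheme, seed = seed,
                 log_scale = log_scale),
            class = "pk_crossval")
}

#' Sparse-subset validation
#'
#' Compares individual forecasts derived from a sparse subset of each
#' subject's samples (the 3-4 levels a clinical site would submit) with
#' forecasts from the full rich profile: MAP estimation on both, then the
#' terminal half-life and the times to 50/20/10 IU/L (0.05/0.02/0.01
#' IU/mL) from the individual curves, with relative differences.
#'
#' @param ds_rich rich dataset.
#' @param priors a [prior_set()] (or `population_model`) supplying the
#'   population priors.
#' @param subset_times times (hours) to keep; subjects missing any of them
#'   are skipped with a warning.
#' @return list of class `pk_sparse_validation`: per-subject `table` and
#'   `summary` (median absolute relative differences).
#' @export
sparse_subset_validation <- function(ds_rich, priors, subset_times) {
  pop <- as_population_model(priors)
  rows <- list()
  skipped <- character(0)
  for (cid in unique(ds_rich$CID)) {
    s <- subject_data(ds_rich, cid)
    obs_t <- s$TIMEH[s$EVID %in% c(0, 3)]
    if (!all(trunc4(subset_times) %in% trunc4(obs_t))) {
      skipped <- c(skipped, as.character(cid))
      next
    }
    keep <- s$EVID == 1 | trunc4(s$TIMEH) %in% trunc4(subset_times)
    ssub <- s[keep, , drop = FALSE]
    q_full <- forecast_quantities(s, pop)
    q_sub <- forecast_quantities(ssub, pop)
    rel <- (q_sub - q_full) / q_full
    rows[[length(rows) + 1]] <- data.frame(
      cid = cid, quantity = names(q_full), full = q_full, sparse = q_sub,
      rel_diff = rel, row.names = NULL)
  }
  if (length(skipped))
    warning("skipped subjects missing subset times: ",
            paste(skipped, collapse = ", "))
  tab <- do.call(rbind, rows)
  summ <- tapply(abs(tab$rel_diff), tab$quantity,
                 function(x) median(x, na.rm = TRUE))
  structure(list(table = tab, summary = summ, subset_times = subset_times),
            class = "pk_sparse_validation")
}

## deterministic per-subject forecast quantities from the MAP curve
forecast_quantities <- function(subject, pop) {
  m <- conditional_eta_mode(subject, pop)
  fr <- frame_one(subject)
  theta <- individual_parameters(pop, fr$covs, m$eta)
  model <- pop$structural
  reg <- data.frame(start_h = fr$reg_start, duration_h = fr$reg_dur,
                    amount_iu = fr$reg_rate * fr$reg_dur)
  init <- initial_state(fr$baseline, fr$resid_conc)
  tt <- function(level) {
    v <- time_to_level(model, theta, reg, level, init)
    if (is.na(v)) NA_real_ else v
  }
  c(t_half = terminal_halflife(model, theta),
    t50 = tt(50), t20 = tt(20), t10 = tt(10))
}
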