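## Maximum-likelihood estimation of the population model by a
## Laplace/FOCE-with-interaction class approximation: inner Newton search
## for each subject's conditional eta mode, curvature correction, outer
## quasi-Newton optimization of fixed effects, omega (log-Cholesky) and
## sigma.  BLQ records enter the likelihood through the M3 censored terms.

omega_inv <- function(omega) {
  ch <- tryCatch(chol(omega), error = function(e) NULL)
  if (is.null(ch)) stop("omega is singular or not positive definite")
  list(Oinv = chol2inv(ch), logdet = 2 * sum(log(diag(ch))))
}

frame_one <- function(subject) {
  if (!is.data.frame(subject)) return(subject) # already a frame entry
  fr <- est_frame(subject)
  if (length(fr) != 1) stop("expected a single subject's records")
  fr[[1]]
}

eta_idx0 <- function(pop) {
  as.integer(match(pop$eta_on, pop$structural$param_names) - 1L)
}

#' Joint -2 log-likelihood of one subject's data and eta
#'
#' `-2 [ sum_valid log phi((y - f)/g) + sum_BLQ log Phi((LOQ - f)/g) ] +
#' eta' Omega^-1 eta + log |2 pi Omega|`, with `f` the individual
#' prediction and `g` the residual SD at `f`. BLQ rows contribute the M3
#' censored-likelihood terms. Under the exponential error form the
#' residual terms act on the log scale and the LOQ bound is transformed
#' accordingly.
#'
#' @param subject one subject's records (rows of a [pk_dataset()]).
#' @param pop a [population_model()].
#' @param eta numeric vector, one entry per eta-bearing parameter.
#' @return scalar.
#' @export
individual_joint_neg2ll <- function(subject, pop, eta) {
  fr <- frame_one(subject)
  typ <- typical_value(pop, fr$covs)
  oi <- omega_inv(pop$omega)
  cpp_joint_neg2ll(eta, as.numeric(typ), eta_idx0(pop),
                   pop$structural$n_compartments, fr,
                   err_code(pop$error), sigma_vec(pop$error),
                   oi$Oinv, oi$logdet, TRUE)
}

#' Conditional eta mode (empirical Bayes estimate)
#'
#' Minimizes [individual_joint_neg2ll()] over eta by a Newton search
#' started at `eta = 0` (deterministic). A subject with no observations
#' returns the prior mode, 0.
#'
#' @inheritParams individual_joint_neg2ll
#' @return list: `eta` (named), `value` (joint -2LL at the mode),
#'   `hessian` (of the joint in eta), `grad_norm`, `converged`.
#' @export
conditional_eta_mode <- function(subject, pop) {
  fr <- frame_one(subject)
  typ <- typical_value(pop, fr$covs)
  oi <- omega_inv(pop$omega)
  m <- cpp_eta_mode(as.numeric(typ), eta_idx0(pop),
                    pop$structural$n_compartments, fr,
                    err_code(pop$error), sigma_vec(pop$error),
                    oi$Oinv, oi$logdet)
  m$eta <- setNames(as.numeric(m$eta), pop$eta_on)
  m
}

## ---- parameter packing -----------------------------------------------------

pack_params <- function(pop, estimate_omega = TRUE, estimate_sigma = TRUE) {
  par <- log(pop$theta)
  names(par) <- paste0("lTV_", names(pop$theta))
  for (i in seq_along(pop$covariates)) {
    ce <- pop$covariates[[i]]
    par[paste0("beta_", ce$param, ".", ce$covariate, i)] <- ce$theta
  }
  if (estimate_omega) {
    q <- length(pop$eta_on)
    if (pop$omega_structure == "diagonal") {
      v <- log(sqrt(diag(pop$omega)))
      names(v) <- paste0("lom_", pop$eta_on)
      par <- c(par, v)
    } else {
      L <- t(chol(pop$omega))
      v <- numeric(0)
      for (j in seq_len(q)) for (i in j:q)
        v[paste0("och_", i, ".", j)] <-
          if (i == j) log(L[i, j]) else L[i, j]
      par <- c(par, v)
    }
  }
  if (estimate_sigma) {
    em <- pop$error
    s <- switch(em$form,
      additive = c(lsig_add = log(em$sigma_add)),
      proportional = c(lsig_prop = log(em$sigma_prop)),
      exponential = c(lsig_add = log(em$sigma_add)),
      combined = c(lsig_add = log(max(em$sigma_add, 1e-4)),
                   lsig_prop = log(max(em$sigma_prop, 1e-4))))
    par <- c(par, s)
  }
  par
}

unpack_params <- function(par, skel, estimate_omega = TRUE,
                          estimate_sigma = TRUE) {
  pop <- skel
  pn <- names(pop$theta)
  pop$theta <- setNames(exp(par[paste0("lTV_", pn)]), pn)
  for (i in seq_along(pop$covariates)) {
    ce <- pop$covariates[[i]]
    pop$covariates[[i]]$theta <-
      as.numeric(par[paste0("beta_", ce$param, ".", ce$covariate, i)])
  }
  if (estimate_omega) {
    q <- length(pop$eta_on)
    if (pop$omega_structure == "diagonal") {
      om <- diag(exp(par[paste0("lom_", pop$eta_on)])^2, q)
    } else {
      L <- matrix(0, q, q)
      for (j in seq_len(q)) for (i in j:q) {
        v <- par[paste0("och_", i, ".", j)]
        L[i, j] <- if (i == j) exp(v) else v
      }
      om <- L %*% t(L)
    }
    dimnames(om) <- list(pop$eta_on, pop$eta_on)
    pop$omega <- om
  }
  if (estimate_sigma) {
    em <- pop$error
    if ("lsig_add" %in% names(par)) em$sigma_add <- exp(par[["lsig_add"]])
    if ("lsig_prop" %in% names(par)) em$sigma_prop <- exp(par[["lsig_prop"]])
    pop$error <- em
  }
  pop
}

## natural-scale parameter vector (for SEs and bootstrap summaries)
natural_params <- function(pop) {
  out <- pop$theta
  names(out) <- paste0("TV", names(pop$theta))
  for (i in seq_along(pop$covariates)) {
    ce <- pop$covariates[[i]]
    out[paste0("theta_", ce$param, ".", ce$covariate)] <- ce$theta
  }
  q <- length(pop$eta_on)
  for (i in seq_len(q)) {
    out[paste0("omega2_", pop$eta_on[i])] <- pop$omega[i, i]
    if (pop$omega_structure == "unstructured" && i < q)
      for (j in (i + 1):q)
        out[paste0("omega_", pop$eta_on[i], ".", pop$eta_on[j])] <-
          pop$omega[i, j]
  }
  em <- pop$error
  if (em$form %in% c("additive", "exponential", "combined"))
    out["sigma_add"] <- em$sigma_add
  if (em$form %in% c("proportional", "combined"))
    out["sigma_prop"] <- em$sigma_prop
  out
}

## ---- population fit --------------------------------------------------------

make_cpp_subjects <- function(frame) {
  lapply(frame, function(fr) fr[c("reg_start", "reg_dur", "reg_rate",
                                  "t_obs", "dv", "is_blq", "loq",
                                  "baseline", "resid_conc")])
}

frame_cov_df <- function(frame) {
  cn <- unique(unlist(lapply(frame, function(fr) names(fr$covs))))
  as.data.frame(lapply(setNames(cn, cn), function(nm)
    vapply(frame, function(fr) fr$covs[[nm]] %||% NA_real_, numeric(1))))
}

#' Fit the population model (Laplace/FOCEI-class)
#'
#' Minimizes the Laplace approximation to the marginal -2 log-likelihood,
#' `sum_i [ joint_i(eta_hat_i) + log det(H_i / (4 pi)) ]`, over typical
#' values (log scale), covariate coefficients, omega (log-Cholesky) and
#' sigma (log scale). The inner eta search restarts at 0 on every outer
#' evaluation, so the fit is deterministic.
#'
#' @param ds a [pk_dataset()].
#' @param pop a [population_model()] skeleton holding initial values.
#' @param options list: `estimate_omega`, `estimate_sigma` (logical,
#'   default TRUE), `se` (compute standard errors; default FALSE),
#'   `init_pooled` (initialize typical values from a naive pooled fit;
#'   default FALSE, i.e. the skeleton's values are the initials),
#'   `maxit` (outer iteration cap).
#' @return object of class `pk_fit`: the fitted model (`$pop`), `$ofv`,
#'   per-subject `$eta_hat`, `$predictions` (population and individual),
#'   convergence flags, and (with `se`) `$se`, `$covariance`,
#'   `$condition_number`.
#' @export
fit_population <- function(ds, pop, options = list()) {
  opt <- modifyList(list(estimate_omega = TRUE, estimate_sigma = TRUE,
                         se = FALSE, init_pooled = FALSE, maxit = 400),
                    options)
  frame <- est_frame(ds)
  if (length(frame) < 2) stop("need at least 2 subjects")
  subs <- make_cpp_subjects(frame)
  cov_df <- frame_cov_df(frame)
  if (opt$init_pooled) {
    np <- tryCatch(naive_pooled_fit(ds, pop$structural, pop$error),
                   error = function(e) NULL)
    if (!is.null(np) && np$converged) {
      pop$theta <- np$theta
      if (opt$estimate_sigma) pop$error <- np$error
    }
  }
  skel <- pop
  ncpt <- pop$structural$n_compartments
  eidx <- eta_idx0(pop)
  ecode <- err_code(pop$error)
  obj <- function(par) {
    p2 <- tryCatch(unpack_params(par, skel, opt$estimate_omega,
                                 opt$estimate_sigma),
                   error = function(e) NULL)
    if (is.null(p2)) return(1e10)
    typ <- tryCatch(typical_matrix(p2, cov_df), error = function(e) NULL)
    if (is.null(typ) || any(!is.finite(typ)) || any(typ <= 0))
      return(1e10)
    r <- tryCatch(cpp_laplace_ofv(typ, eidx, ncpt, subs, ecode,
                                  sigma_vec(p2$error), p2$omega),
                  error = function(e) NULL)
    if (is.null(r) || !is.finite(r$ofv)) return(1e10)
    r$ofv
  }
  start <- pack_params(pop, opt$estimate_omega, opt$estimate_sigma)
  ctrl <- list(iter.max = opt$maxit, eval.max = 4L * opt$maxit,
               rel.tol = 1e-10, x.tol = 1e-8)
  fit <- nlminb(start, obj, control = ctrl, lower = -20, upper = 20)
  ## polish restarts: guard against premature stops. nlminb can report
  ## "false convergence" at an optimum of an objective with slight
  ## inner-optimization noise, so the fit counts as converged when any
  ## run reports success or a restart finds no material improvement.
  outer_ok <- fit$convergence == 0
  for (r in 1:3) {
    fit2 <- nlminb(fit$par, obj, control = ctrl, lower = -20, upper = 20)
    gain <- fit$objective - fit2$objective
    if (fit2$objective <= fit$objective) fit <- fit2
    if (fit2$convergence == 0 || gain < 1e-3) {
      outer_ok <- TRUE
      break
    }
  }
  par <- setNames(fit$par, names(start))
  pop_hat <- unpack_params(par, skel, opt$estimate_omega,
                           opt$estimate_sigma)
  typ <- typical_matrix(pop_hat, cov_df)
  final <- cpp_laplace_ofv(typ, eidx, ncpt, subs, ecode,
                           sigma_vec(pop_hat$error), pop_hat$omega)
  eta_hat <- final$eta_hat
  rownames(eta_hat) <- vapply(frame, `[[`, numeric(1), "cid")
  colnames(eta_hat) <- pop_hat$eta_on
  preds <- fit_predictions(pop_hat, frame, typ, eta_hat)
  out <- structure(list(
    pop = pop_hat, ofv = final$ofv, par = par,
    eta_hat = eta_hat, inner_converged = as.logical(final$converged),
    converged = outer_ok && all(final$converged),
    message = fit$message, iterations = fit$iterations,
    n_par = length(par), n_subjects = length(frame),
    n_obs = sum(vapply(frame, function(f) length(f$t_obs), numeric(1))),
    predictions = preds, frame = frame, cov_df = cov_df,
    fingerprint = dataset_fingerprint(ds),
    options = opt), class = "pk_fit")
  if (opt$se) out <- add_fit_se(out, obj)
  out
}

fit_predictions <- function(pop, frame, typ, eta_hat) {
  ncpt <- pop$structural$n_compartments
  do.call(rbind, lapply(seq_along(frame), function(i) {
    fr <- frame[[i]]
    if (!length(fr$t_obs)) return(NULL)
    ppar <- typ[i, ]
    ipar <- ppar
    ipar[pop$eta_on] <- ipar[pop$eta_on] * exp(eta_hat[i, ])
    pred <- cpp_conc(ncpt, ppar, fr$reg_start, fr$reg_dur, fr$reg_rate,
                     fr$baseline, fr$resid_conc, fr$t_obs)
    ipred <- cpp_conc(ncpt, ipar, fr$reg_start, fr$reg_dur, fr$reg_rate,
                      fr$baseline, fr$resid_conc, fr$t_obs)
    data.frame(cid = fr$cid, time = fr$t_obs, dv = fr$dv,
               blq = fr$is_blq == 1, mdv5 = fr$mdv5,
               pred = as.numeric(pred), ipred = as.numeric(ipred))
  }))
}

add_fit_se <- function(fit, obj) {
  H <- fd_hessian(obj, fit$par, h = 1e-4)
  cov_packed <- tryCatch(2 * solve(H), error = function(e) NULL)
  if (is.null(cov_packed)) {
    fit$se <- NULL; fit$condition_number <- NA_real_
    fit$se_note <- "information matrix singular"
    return(fit)
  }
  nat <- function(par) natural_params(
    unpack_params(setNames(par, names(fit$par)), fit$pop,
                  fit$options$estimate_omega, fit$options$estimate_sigma))
  nat0 <- nat(fit$par)
  J <- t(vapply(seq_along(nat0), function(k) {
    fd_grad(function(p) nat(p)[k], fit$par)
  }, numeric(length(fit$par))))
  cov_nat <- J %*% cov_packed %*% t(J)
  dimnames(cov_nat) <- list(names(nat0), names(nat0))
  se <- sqrt(pmax(diag(cov_nat), 0))
  dsc <- sqrt(pmax(diag(cov_nat), 1e-300))
  corr <- cov_nat / outer(dsc, dsc)
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  fit$covariance <- cov_nat
  fit$se <- se
  fit$estimates <- nat0
  fit$condition_number <- max(ev) / max(min(ev), 1e-300)
  fit
}

#' @export
print.pk_fit <- function(x, ...) {
  cat(sprintf("Population PK fit: OFV %.3f, %d subjects, %d observations\n",
              x$ofv, x$n_subjects, x$n_obs))
  cat("converged:", x$converged, "\n")
  print(natural_params(x$pop))
  invisible(x)
}

## ---- naive pooled fit ------------------------------------------------------

pooled_init <- function(frame, structural) {
  ## crude initials from peaks and terminal slopes
  v1 <- stats::median(vapply(frame, function(fr) {
    amt <- sum(fr$reg_rate * fr$reg_dur)
    pk <- max(fr$dv[fr$is_blq == 0] - fr$baseline, 1)
    amt / pk
  }, numeric(1)))
  lam <- stats::median(vapply(frame, function(fr) {
    ok <- fr$is_blq == 0 & fr$dv > fr$baseline
    t <- fr$t_obs[ok]; y <- log(fr$dv[ok] - fr$baseline[1] + 0.1)
    if (length(t) < 3) return(0.1)
    k <- max(length(t) - 3, 1):length(t)
    s <- -coef(lm(y[k] ~ t[k]))[2]
    if (!is.finite(s) || s <= 0) 0.1 else s
  }, numeric(1)))
  cl <- lam * v1
  th <- switch(structural$n_compartments,
               c(CL = cl, V = v1),
               c(CL = cl, V1 = v1 * 0.8, Q = cl, V2 = v1 * 0.5),
               c(CL = cl, V1 = v1 * 0.7, Q2 = cl, V2 = v1 * 0.5,
                 Q3 = cl / 2, V3 = v1))
  pmax(th, 1e-4)
}

#' Naive pooled analysis
#'
#' Fits a single parameter vector to all subjects' data, ignoring
#' between-subject variability; the first step of model development, used
#' to explore compartment count and to initialize the population fit.
#'
#' @param ds a [pk_dataset()].
#' @param structural a [pk_model()].
#' @param error an [error_model()]; its sigmas are initial values.
#' @param init optional named vector of initial structural parameters.
#' @return list: `theta`, `error`, `ofv`, `converged`.
#' @export
naive_pooled_fit <- function(ds, structural, error, init = NULL) {
  frame <- est_frame(ds)
  subs <- make_cpp_subjects(frame)
  ncpt <- structural$n_compartments
  ecode <- err_code(error)
  th0 <- init %||% pooled_init(frame, structural)
  th0 <- th0[structural$param_names]
  em0 <- error
  if (em0$sigma_add == 0 && em0$form %in% c("additive", "exponential",
                                            "combined"))
    em0$sigma_add <- if (em0$form == "exponential") 0.2 else 1
  if (em0$sigma_prop == 0 && em0$form %in% c("proportional", "combined"))
    em0$sigma_prop <- 0.2
  skel <- list(theta = th0, error = em0)
  npar_th <- length(th0)
  pack <- function(th, em) {
    p <- log(th)
    if (em$form %in% c("additive", "exponential", "combined"))
      p <- c(p, lsa = log(em$sigma_add))
    if (em$form %in% c("proportional", "combined"))
      p <- c(p, lsp = log(em$sigma_prop))
    p
  }
  obj <- function(par) {
    th <- exp(par[seq_len(npar_th)])
    sig <- c(0, 0)
    i <- npar_th
    if (em0$form %in% c("additive", "exponential", "combined"))
      { i <- i + 1; sig[1] <- exp(par[i]) }
    if (em0$form %in% c("proportional", "combined"))
      { i <- i + 1; sig[2] <- exp(par[i]) }
    tot <- 0
    for (s in subs) {
      v <- cpp_joint_neg2ll(numeric(0), th, integer(0), ncpt, s, ecode,
                            sig, matrix(0, 0, 0), 0, FALSE)
      if (!is.finite(v)) return(1e10)
      tot <- tot + v
    }
    tot
  }
  fit <- nlminb(pack(th0, em0), obj,
                control = list(iter.max = 400, rel.tol = 1e-10),
                lower = -15, upper = 15)
  th <- setNames(exp(fit$par[seq_len(npar_th)]), structural$param_names)
  em <- em0
  i <- npar_th
  if (em0$form %in% c("additive", "exponential", "combined"))
    { i <- i + 1; em$sigma_add <- exp(fit$par[i]) }
  if (em0$form %in% c("proportional", "combined"))
    { i <- i + 1; em$sigma_prop <- exp(fit$par[i]) }
  list(theta = th, error = em, ofv = fit$objective,
       converged = fit$convergence == 0)
}

## ---- model comparison ------------------------------------------------------

#' Compare nested models by objective function value
#'
#' The larger model is superior when the OFV decreases by at least the
#' 0.95 chi-squared quantile for the added degrees of freedom (3.84 for a
#' single added parameter). Fits on different datasets are refused.
#'
#' @param reduced,full `pk_fit` objects (or lists with `ofv`,
#'   `fingerprint`, `n_par`).
#' @param added_df degrees of freedom added by the full model; default
#'   inferred from the parameter counts.
#' @return object of class `model_comparison`: `ofv_reduced`, `ofv_full`,
#'   `delta_ofv`, `added_df`, `threshold`, `superior`.
#' @export
compare_models <- function(reduced, full, added_df = NULL) {
  if (!is.null(reduced$fingerprint) && !is.null(full$fingerprint) &&
      !identical(reduced$fingerprint, full$fingerprint))
    stop("models were fitted on different datasets")
  if (is.null(added_df)) {
    added_df <- (full$n_par %||% NA) - (reduced$n_par %||% NA)
    if (is.na(added_df) || added_df < 1)
      stop("supply added_df for models without parameter counts")
  }
  delta <- reduced$ofv - full$ofv
  thr <- lrt_threshold(added_df)
  structure(list(ofv_reduced = reduced$ofv, ofv_full = full$ofv,
                 delta_ofv = delta, added_df = added_df, threshold = thr,
                 superior = delta >= thr),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf(
    "dOFV = %.3f on %d df (threshold %.2f): full model %s\n",
    x$delta_ofv, x$added_df, x$threshold,
    if (x$superior) "superior" else "not superior"))
  invisible(x)
}

#' Test the omega structure (diagonal vs unstructured)
#'
#' Fits the model with a diagonal and with an unstructured eta
#' variance-covariance matrix and compares them with `q(q-1)/2` added
#' degrees of freedom, testing for correlation between random effects.
#'
#' @inheritParams fit_population
#' @return list: `diagonal` and `unstructured` fits plus the
#'   `comparison` ([compare_models()] result).
#' @export
test_omega_structure <- function(ds, pop, options = list()) {
  q <- length(pop$eta_on)
  if (q < 2) stop("need at least 2 eta-bearing parameters")
  pop_d <- pop
  pop_d$omega <- diag(diag(pop$omega), q) |>
    (\(m) { dimnames(m) <- list(pop$eta_on, pop$eta_on); m })()
  pop_d$omega_structure <- "diagonal"
  fit_d <- fit_population(ds, pop_d, options)
  pop_u <- fit_d$pop
  pop_u$omega_structure <- "unstructured"
  ## nudge off-diagonals so the Cholesky start is interior
  pop_u$omega <- pop_u$omega + diag(1e-8, q)
  fit_u <- fit_population(ds, pop_u, options)
  cmp <- compare_models(fit_d, fit_u, added_df = q * (q - 1) / 2)
  list(diagonal = fit_d, unstructured = fit_u, comparison = cmp)
}

## ---- covariate selection ---------------------------------------------------

candidate_label <- function(ce)
  sprintf("%s~%s(%s)", ce$param, ce$covariate, ce$form)

fill_center <- function(ce, ds) {
  if (is.null(ce$center) && ce$form != "categorical") {
    x <- ds[[ce$covariate]]
    if (is.null(x)) stop("covariate not in dataset: ", ce$covariate)
    ce$center <- median(x[!duplicated(ds$CID)], na.rm = TRUE)
  }
  ce
}

#' Stepwise forward covariate selection
#'
#' At each round every remaining candidate effect is added to the current
#' model (coefficient initialized at 0) and refitted; the candidate with
#' the largest OFV drop of at least 3.84 is examined for precision (95%
#' Wald CI of its coefficient excluding zero) and, if precise, retained.
#' Candidates failing the precision criterion are dropped from the pool.
#' An optional stricter backward pass (default threshold 6.63, alpha 0.01)
#' is off by default.
#'
#' @param ds dataset used for the base fit.
#' @param base_fit a `pk_fit` of the base model on `ds`.
#' @param candidates list of [covariate_effect()]s; continuous centers
#'   default to the dataset median across subjects.
#' @param threshold OFV drop required for inclusion.
#' @param backward run the backward pass.
#' @param backward_threshold OFV rise required to retain an effect in the
#'   backward pass.
#' @param options fitting options passed to [fit_population()].
#' @return list: final `model`, final `fit`, and a `trace` data frame with
#'   one row per tested model.
#' @export
stepwise_covariates <- function(ds, base_fit, candidates,
                                threshold = lrt_threshold(1),
                                backward = FALSE,
                                backward_threshold = qchisq(0.99, 1),
                                options = list()) {
  candidates <- lapply(candidates, fill_center, ds = ds)
  current <- base_fit
  pool <- candidates
  trace <- list()
  round <- 0L
  repeat {
    round <- round + 1L
    if (!length(pool)) break
    fits <- vector("list", length(pool))
    for (k in seq_along(pool)) {
      ce <- pool[[k]]
      popc <- current$pop
      popc$covariates <- c(popc$covariates, list(ce))
      popc$covariates[[length(popc$covariates)]]$theta <- 0
      fits[[k]] <- fit_population(ds, popc, options)
      trace[[length(trace) + 1]] <- data.frame(
        round = round, candidate = candidate_label(ce),
        ofv = fits[[k]]$ofv, delta_ofv = current$ofv - fits[[k]]$ofv,
        action = "tested")
    }
    deltas <- current$ofv - vapply(fits, `[[`, numeric(1), "ofv")
    ord <- order(deltas, decreasing = TRUE)
    accepted <- FALSE
    drop_k <- integer()
    for (k in ord) {
      if (deltas[k] < threshold) break
      fk <- fits[[k]]
      if (is.null(fk$se)) fk <- refit_with_se(ds, fk, options)
      ce <- fk$pop$covariates[[length(fk$pop$covariates)]]
      nm <- paste0("theta_", ce$param, ".", ce$covariate)
      est <- fk$estimates[nm]; se <- fk$se[nm]
      ci <- est + c(-1.96, 1.96) * se
      if (is.na(se) || (ci[1] < 0 && ci[2] > 0)) {
        trace[[length(trace) + 1]] <- data.frame(
          round = round, candidate = candidate_label(ce), ofv = fk$ofv,
          delta_ofv = deltas[k], action = "rejected-precision")
        drop_k <- c(drop_k, k)
        next
      }
      current <- fk
      trace[[length(trace) + 1]] <- data.frame(
        round = round, candidate = candidate_label(ce), ofv = fk$ofv,
        delta_ofv = deltas[k], action = "selected")
      drop_k <- c(drop_k, k)
      accepted <- TRUE
      break
    }
    pool <- pool[setdiff(seq_along(pool), drop_k)]
    if (!accepted) break
  }
  if (backward && length(current$pop$covariates)) {
    repeat {
      removed <- FALSE
      for (k in seq_along(current$pop$covariates)) {
        popr <- current$pop
        ce <- popr$covariates[[k]]
        popr$covariates <- popr$covariates[-k]
        fr <- fit_population(ds, popr, options)
        rise <- fr$ofv - current$ofv
        act <- if (rise < backward_threshold) "backward-removed"
               else "backward-retained"
        trace[[length(trace) + 1]] <- data.frame(
          round = round, candidate = candidate_label(ce), ofv = fr$ofv,
          delta_ofv = -rise, action = act)
        if (rise < backward_threshold) { current <- fr; removed <- TRUE
                                         break }
      }
      if (!removed || !length(current$pop$covariates)) break
    }
  }
  list(model = current$pop, fit = current,
       trace = do.call(rbind, trace))
}

refit_with_se <- function(ds, fit, options) {
  o <- modifyList(options, list(se = TRUE))
  f2 <- fit_population(ds, fit$pop, o)
  f2
}

#' Screen eta estimates against covariates
#'
#' Associations between the post-hoc eta estimates and each covariate:
#' Pearson correlation for continuous covariates, Kruskal-Wallis for
#' categorical codes (`RACE`, `BTYPE`), ranked by p-value. Constant
#' covariates are reported as undefined.
#'
#' @param fit a `pk_fit` (with `eta_hat`).
#' @param ds the fitted dataset (only used if the fit lacks covariates).
#' @return data frame: `eta`, `covariate`, `type`, `statistic`, `p`,
#'   `note`, ranked by `p`.
#' @export
screen_eta_covariates <- function(fit, ds = NULL) {
  cov_df <- fit$cov_df
  eh <- fit$eta_hat
  cats <- c("RACE", "BTYPE")
  rows <- list()
  for (e in colnames(eh)) for (cn in names(cov_df)) {
    x <- cov_df[[cn]]
    if (all(is.na(x))) next
    if (length(unique(x[!is.na(x)])) < 2) {
      rows[[length(rows) + 1]] <- data.frame(
        eta = e, covariate = cn, type = "constant",
        statistic = NA_real_, p = NA_real_,
        note = "association undefined (constant covariate)")
      next
    }
    if (cn %in% cats) {
      k <- kruskal.test(eh[, e], factor(x))
      rows[[length(rows) + 1]] <- data.frame(
        eta = e, covariate = cn, type = "categorical",
        statistic = unname(k$statistic), p = k$p.value, note = "")
    } else {
      ct <- cor.test(eh[, e], x)
      rows[[length(rows) + 1]] <- data.frame(
        eta = e, covariate = cn, type = "continuous",
        statistic = unname(ct$estimate), p = ct$p.value, note = "")
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$p), ]
}

## ---- model variant registry ------------------------------------------------

#' Registry of model variants and covariate-driven selection
#'
#' When a significant covariate may be unavailable at the clinical site,
#' several model variants are kept per molecule; the most-preferred variant
#' whose required covariates are all available is selected. Age and weight
#' are always available, so the registry must contain a variant requiring
#' at most those (enforced at construction).
#'
#' @param variants list of lists with `name`, `model` (a
#'   [population_model()]), `requires` (character vector of covariate
#'   names), `rank` (1 = most preferred, e.g. most precise).
#' @export
model_registry <- function(variants) {
  for (v in variants)
    stopifnot(!is.null(v$name), inherits(v$model, "population_model"),
              is.numeric(v$rank))
  ok <- any(vapply(variants, function(v)
    all(toupper(v$requires) %in% c("AGE", "BW")), logical(1)))
  if (!ok)
    stop("registry must include an age/weight-only fallback variant")
  structure(list(variants = variants), class = "model_registry")
}

#' @rdname model_registry
#' @param available_covariates covariate names available for the subject.
#' @param registry a [model_registry()].
#' @return the selected variant's `model`, with attributes `variant` (its
#'   name) and `rank`.
#' @export
select_model_variant <- function(available_covariates, registry) {
  avail <- unique(c(toupper(available_covariates), "AGE", "BW"))
  ok <- Filter(function(v) all(toupper(v$requires) %in% avail),
               registry$variants)
  if (!length(ok)) stop("no model variant satisfiable")
  best <- ok[[which.min(vapply(ok, `[[`, numeric(1), "rank"))]]
  out <- best$model
  attr(out, "variant") <- best$name
  attr(out, "rank") <- best$rank
  out
}
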