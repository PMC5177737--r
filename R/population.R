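## The hierarchical population model: typical values with covariate
## effects, exponential (log-normal) between-subject variability, and
## residual unexplained variability.

#' Residual unexplained variability model
#'
#' The observation-level error. Forms: `additive` (constant SD),
#' `proportional` (SD proportional to the prediction), `exponential`
#' (additive error on the log scale, i.e. log-normal), and the `combined`
#' additive-proportional form `sqrt(f^2 sigma_prop^2 + sigma_add^2)`, the
#' most commonly used in PK modeling.
#'
#' @param form one of `"additive"`, `"proportional"`, `"exponential"`,
#'   `"combined"`.
#' @param sigma_add additive SD (IU/L), or the log-scale SD for the
#'   exponential form.
#' @param sigma_prop proportional SD (fraction).
#' @export
error_model <- function(form = c("combined", "additive", "proportional",
                                 "exponential"),
                        sigma_add = 0, sigma_prop = 0) {
  form <- match.arg(form)
  if (sigma_add < 0 || sigma_prop < 0) stop("sigma values must be >= 0")
  structure(list(form = form, sigma_add = sigma_add,
                 sigma_prop = sigma_prop),
            class = "error_model")
}

err_code <- function(em) {
  match(em$form, c("additive", "proportional", "exponential", "combined"))
}

#' Residual standard deviation at a prediction
#'
#' For the exponential form the returned value is the log-scale SD
#' (the error acts multiplicatively as `f * exp(sigma * z)`).
#'
#' @param f predicted concentration(s), IU/L (>= 0).
#' @param em an [error_model()].
#' @export
residual_sd <- function(f, em) {
  if (any(f < 0)) stop("predictions must be non-negative")
  switch(em$form,
         additive = rep(em$sigma_add, length(f)),
         proportional = f * em$sigma_prop,
         exponential = rep(em$sigma_add, length(f)),
         combined = sqrt(f^2 * em$sigma_prop^2 + em$sigma_add^2))
}

#' Covariate effect on a structural parameter
#'
#' Functional forms relating a covariate `x` with centering value `c` to
#' the typical value: `linear` `TV (1 + theta (x - c))`, `power`
#' `TV (x/c)^theta`, `exponential` `TV exp(theta (x - c))`, and
#' `categorical` `TV (1 + theta 1{x == level})`. Multiple effects on one
#' parameter compose multiplicatively.
#'
#' @param param target structural parameter name (e.g. `"CL"`).
#' @param covariate dataset covariate name (e.g. `"BW"`).
#' @param form functional form.
#' @param theta coefficient (magnitude and direction of the association).
#' @param center centering value (dataset mean or median; frozen into the
#'   model object). Must be positive for the power form. `NULL` allowed for
#'   categorical effects and for candidates whose center is filled in from
#'   the data at selection time.
#' @param level category code for the categorical form.
#' @export
covariate_effect <- function(param, covariate,
                             form = c("power", "linear", "exponential",
                                      "categorical"),
                             theta = 0, center = NULL, level = NULL) {
  form <- match.arg(form)
  if (form == "power" && !is.null(center) && center <= 0)
    stop("centering value must be positive for the power form")
  if (form == "categorical" && is.null(level))
    stop("categorical effect needs a level")
  structure(list(param = param, covariate = covariate, form = form,
                 theta = theta, center = center, level = level),
            class = "covariate_effect")
}

#' Population pharmacokinetic model
#'
#' Combines a structural model, fixed effects (typical values and covariate
#' coefficients), the between-subject variability matrix `omega` (variances
#' of the log-normal `eta` terms), and a residual error model.
#'
#' @param structural a [pk_model()].
#' @param theta named vector of typical values, one per structural
#'   parameter, all positive.
#' @param omega named vector of `eta` variances (diagonal structure), or a
#'   full symmetric positive-definite matrix (unstructured) with
#'   dimnames naming the eta-bearing parameters.
#' @param error an [error_model()].
#' @param covariates list of [covariate_effect()]s; applied
#'   multiplicatively in the declared order.
#' @return object of class `population_model`.
#' @export
population_model <- function(structural, theta, omega, error,
                             covariates = list()) {
  theta <- theta[structural$param_names]
  if (anyNA(theta)) stop("theta must name every structural parameter")
  if (any(theta <= 0)) stop("typical values must be positive")
  if (is.matrix(omega)) {
    if (is.null(rownames(omega))) stop("omega matrix needs dimnames")
    struct <- "unstructured"
    eta_on <- rownames(omega)
  } else {
    if (is.null(names(omega))) stop("omega vector needs names")
    struct <- "diagonal"
    eta_on <- names(omega)
    omega <- diag(omega, nrow = length(omega)) |>
      (\(m) { dimnames(m) <- list(eta_on, eta_on); m })()
  }
  if (!all(eta_on %in% structural$param_names))
    stop("omega names must be structural parameters")
  ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-10)) stop("omega must be positive semi-definite")
  for (ce in covariates)
    if (!ce$param %in% structural$param_names)
      stop("covariate effect targets unknown parameter: ", ce$param)
  structure(list(structural = structural, theta = theta, omega = omega,
                 omega_structure = struct, eta_on = eta_on,
                 error = error, covariates = covariates),
            class = "population_model")
}

#' @export
print.population_model <- function(x, ...) {
  cat(sprintf("Population PK model: %d-compartment, %s omega, %s error\n",
              x$structural$n_compartments, x$omega_structure,
              x$error$form))
  cat("typical values:\n")
  print(x$theta)
  cat("eta on:", paste(x$eta_on, collapse = ", "), "\n")
  if (length(x$covariates))
    for (ce in x$covariates)
      cat(sprintf("  %s ~ %s (%s, theta=%g, center=%s)\n", ce$param,
                  ce$covariate, ce$form, ce$theta,
                  if (is.null(ce$center)) "-" else format(ce$center)))
  invisible(x)
}

cov_value <- function(covariates, name) {
  v <- covariates[[name]]
  if (is.null(v) || is.na(v)) {
    cond <- structure(class = c("hemopk_covariate_unavailable", "error",
                                "condition"),
                      list(message = paste("covariate unavailable:", name),
                           call = sys.call(-1)))
    stop(cond)
  }
  v
}

apply_effect <- function(tv, ce, x) {
  switch(ce$form,
         linear = tv * (1 + ce$theta * (x - ce$center)),
         power = tv * (x / ce$center)^ce$theta,
         exponential = tv * exp(ce$theta * (x - ce$center)),
         categorical = tv * (1 + ce$theta * as.numeric(x == ce$level)))
}

#' Covariate-adjusted typical values
#'
#' Applies the model's covariate effects, multiplicatively in declared
#' order, to the population typical values.
#'
#' @param pop a [population_model()].
#' @param covariates named list (or one-row data frame) of this subject's
#'   covariate values.
#' @return named vector of typical parameter values.
#' @export
typical_value <- function(pop, covariates = list()) {
  tv <- pop$theta
  for (ce in pop$covariates) {
    x <- cov_value(covariates, ce$covariate)
    tv[ce$param] <- apply_effect(tv[ce$param], ce, x)
  }
  tv
}

## vectorized typical values: one row per subject of cov_df
typical_matrix <- function(pop, cov_df) {
  n <- nrow(cov_df)
  tv <- matrix(rep(pop$theta, each = n), n,
               dimnames = list(NULL, names(pop$theta)))
  for (ce in pop$covariates) {
    x <- cov_df[[ce$covariate]]
    if (is.null(x) || anyNA(x))
      stop("covariate unavailable: ", ce$covariate)
    tv[, ce$param] <- apply_effect(tv[, ce$param], ce, x)
  }
  tv
}

#' Individual parameters from typical values and eta
#'
#' PK parameters are taken log-normally distributed across subjects:
#' `theta_i = TV * exp(eta_i)` on eta-bearing parameters, the typical value
#' otherwise.
#'
#' @inheritParams typical_value
#' @param eta numeric vector, one entry per eta-bearing parameter (in
#'   `pop$eta_on` order).
#' @return named vector of individual parameters (all positive).
#' @export
individual_parameters <- function(pop, covariates = list(), eta) {
  if (length(eta) != length(pop$eta_on))
    stop("eta must have length ", length(pop$eta_on))
  tv <- typical_value(pop, covariates)
  tv[pop$eta_on] <- tv[pop$eta_on] * exp(eta)
  tv
}

sigma_vec <- function(em) c(em$sigma_add, em$sigma_prop)

## ---- serialization ---------------------------------------------------------

#' Serialize / load a population model (YAML)
#'
#' The YAML form is the versioned "brand model" artifact consumed by the
#' forecasting stage.
#'
#' @param pop a [population_model()].
#' @param path file path.
#' @export
write_model_yaml <- function(pop, path) {
  obj <- list(
    schema = "hemopk-model/1",
    n_compartments = pop$structural$n_compartments,
    theta = as.list(pop$theta),
    omega = list(structure = pop$omega_structure,
                 names = pop$eta_on,
                 values = as.numeric(pop$omega)),
    error = list(form = pop$error$form, sigma_add = pop$error$sigma_add,
                 sigma_prop = pop$error$sigma_prop),
    covariates = lapply(pop$covariates, function(ce)
      list(param = ce$param, covariate = ce$covariate, form = ce$form,
           theta = ce$theta, center = ce$center, level = ce$level)))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_model_yaml
#' @export
read_model_yaml <- function(path) {
  o <- yaml::read_yaml(path)
  if (!identical(o$schema, "hemopk-model/1"))
    stop("unrecognized model schema")
  q <- length(o$omega$names)
  om <- matrix(o$omega$values, q, q,
               dimnames = list(o$omega$names, o$omega$names))
  if (identical(o$omega$structure, "diagonal"))
    om <- setNames(diag(om), o$omega$names)
  population_model(
    pk_model(o$n_compartments),
    theta = unlist(o$theta),
    omega = om,
    error = error_model(o$error$form, o$error$sigma_add,
                        o$error$sigma_prop),
    covariates = lapply(o$covariates, function(ce)
      covariate_effect(ce$param, ce$covariate, ce$form, ce$theta,
                       ce$center, ce$level)))
}
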