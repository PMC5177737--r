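#' Structural disposition models for IV infusion
#'
#' Linear 1-, 2- and 3-compartment mammillary models with constant-rate
#' intravenous infusion, in the clearance parameterizations used for factor
#' concentrates: `CL, V` (1-cpt), `CL, V1, Q, V2` (2-cpt) and
#' `CL, V1, Q2, V2, Q3, V3` (3-cpt). The disposition is evaluated in closed
#' form as a sum of exponentials with rate constants obtained by
#' eigen-decomposition of the micro-constant matrix.
#'
#' @param n_compartments 1, 2 or 3.
#' @return an object of class `pk_model` holding the compartment count and
#'   parameter names.
#' @examples
#' m <- pk_model(1)
#' pk_concentration(m, c(CL = 0.2, V = 3), dose_regimen(0, 0.1666, 2000),
#'                  times = c(1, 12, 24))
#' @export
pk_model <- function(n_compartments) {
  stopifnot(n_compartments %in% 1:3)
  nm <- switch(n_compartments,
               c("CL", "V"),
               c("CL", "V1", "Q", "V2"),
               c("CL", "V1", "Q2", "V2", "Q3", "V3"))
  structure(list(n_compartments = as.integer(n_compartments),
                 param_names = nm),
            class = "pk_model")
}

#' @export
print.pk_model <- function(x, ...) {
  cat(sprintf("%d-compartment IV infusion model (%s)\n",
              x$n_compartments, paste(x$param_names, collapse = ", ")))
  invisible(x)
}

check_params <- function(model, params) {
  params <- params[model$param_names]
  if (anyNA(params))
    stop("parameters must be named and include: ",
         paste(model$param_names, collapse = ", "))
  if (any(params <= 0)) stop("all PK parameters must be strictly positive")
  as.numeric(params)
}

#' Dosing regimen of constant-rate infusions
#'
#' @param start_h infusion start times (hours), non-decreasing.
#' @param duration_h infusion durations (hours), strictly positive.
#' @param amount_iu doses (IU), non-negative.
#' @return data frame of class `dose_regimen`.
#' @export
dose_regimen <- function(start_h, duration_h, amount_iu) {
  d <- data.frame(start_h = start_h, duration_h = duration_h,
                  amount_iu = amount_iu)
  if (any(d$duration_h <= 0)) stop("infusion duration must be positive")
  if (any(d$amount_iu < 0)) stop("dose amounts must be non-negative")
  if (is.unsorted(d$start_h)) stop("infusion starts must be non-decreasing")
  class(d) <- c("dose_regimen", "data.frame")
  d
}

#' Initial state of the subject at the time reference
#'
#' `baseline_iul` is the endogenous factor level, treated as an additive
#' constant. `residual_iul` is residual factor from a previous dose
#' (measured pre-dose level minus baseline); it is represented as an initial
#' central-compartment amount `residual_iul * V1` that decays according to
#' the disposition model.
#'
#' @param baseline_iul endogenous level, IU/L (>= 0).
#' @param residual_iul pre-dose excess over baseline, IU/L (>= 0).
#' @export
initial_state <- function(baseline_iul = 0, residual_iul = 0) {
  stopifnot(baseline_iul >= 0, residual_iul >= 0)
  structure(list(baseline_iul = baseline_iul, residual_iul = residual_iul),
            class = "initial_state")
}

#' Concentration-time profile
#'
#' Closed-form central concentration under superposed constant-rate
#' infusions: baseline plus the decaying residual pre-dose amount plus, for
#' each infusion of rate R, `sum_i (R A_i / lambda_i) (1 - exp(-lambda_i
#' (t - t0)))` during the infusion and the standard cessation superposition
#' afterwards.
#'
#' @param model a [pk_model()].
#' @param params named positive parameter vector (see [pk_model()]).
#' @param regimen a [dose_regimen()]; may have zero rows.
#' @param times hours (>= 0).
#' @param init an [initial_state()].
#' @return concentrations, IU/L.
#' @export
pk_concentration <- function(model, params, regimen, times,
                             init = initial_state()) {
  p <- check_params(model, params)
  if (any(times < 0)) stop("times must be non-negative")
  if (is.null(regimen) || nrow(regimen) == 0)
    regimen <- data.frame(start_h = numeric(), duration_h = numeric(),
                          amount_iu = numeric())
  as.numeric(cpp_conc(model$n_compartments, p,
                      regimen$start_h, regimen$duration_h,
                      regimen$amount_iu / regimen$duration_h,
                      init$baseline_iul, init$residual_iul, times))
}

#' Disposition exponentials
#'
#' Rate constants and unit-bolus central-concentration coefficients, from
#' eigen-decomposition of the micro-constant matrix.
#'
#' @inheritParams pk_concentration
#' @return list with `lambda` (1/h) and `A` (per L), such that a unit bolus
#'   gives `sum(A * exp(-lambda * t))`.
#' @export
pk_disposition <- function(model, params) {
  p <- check_params(model, params)
  d <- cpp_disposition(model$n_compartments, p)
  list(lambda = as.numeric(d$lambda), A = as.numeric(d$A))
}

#' Terminal half-life
#'
#' `ln 2` divided by the smallest disposition rate constant.
#'
#' @inheritParams pk_concentration
#' @return hours.
#' @export
terminal_halflife <- function(model, params) {
  d <- pk_disposition(model, params)
  log(2) / min(d$lambda)
}

#' Time to reach a factor level
#'
#' First time after the end of the final infusion at which the concentration
#' falls to `level_iul` or below. After the last infusion the profile is a
#' sum of positive decaying exponentials plus baseline, hence strictly
#' decreasing; the crossing is bracketed and refined to better than 0.01 h.
#'
#' @inheritParams pk_concentration
#' @param level_iul target level, IU/L; must exceed the baseline asymptote.
#' @param search_window optional upper limit (hours) for the search; default
#'   extends to 40 terminal half-lives past the last infusion.
#' @return hours since the time reference, or `NA` with attribute
#'   `reason = "never-reached"` when `level_iul <= baseline`, or
#'   `reason = "beyond-window"` when no crossing occurs in the window.
#' @export
time_to_level <- function(model, params, regimen, level_iul,
                          init = initial_state(), search_window = NULL) {
  if (level_iul <= init$baseline_iul) {
    out <- NA_real_
    attr(out, "reason") <- "never-reached"
    return(out)
  }
  t_end <- if (nrow(regimen)) max(regimen$start_h + regimen$duration_h) else 0
  cfun <- function(t) pk_concentration(model, params, regimen, t, init)
  if (cfun(t_end) <= level_iul) return(t_end)
  thalf <- terminal_halflife(model, params)
  upper <- if (is.null(search_window)) t_end + 40 * thalf
           else max(search_window)
  if (cfun(upper) > level_iul) {
    out <- NA_real_
    attr(out, "reason") <- "beyond-window"
    return(out)
  }
  r <- uniroot(function(t) cfun(t) - level_iul, c(t_end, upper),
               tol = 1e-4)
  r$root
}

#' Steady-state trough and the dose/interval/trough solver
#'
#' For a regimen of identical infusions (dose, infusion duration, interval)
#' repeated indefinitely, the trough is the concentration at the end of the
#' dosing interval at steady state, by geometric superposition of the
#' disposition exponentials. Given any two of dose per kg, interval and
#' target trough, the third is solved for: dose is linear in
#' (trough - baseline), interval by monotone root finding.
#'
#' @param model,params structural model and individual parameters.
#' @param bw body weight, kg.
#' @param dose_iu_kg dose, IU/kg (supply two of the three).
#' @param interval_h dosing interval, hours.
#' @param trough_iu_ml target/resulting trough, IU/mL.
#' @param duration_h infusion duration, hours.
#' @param baseline_iul endogenous baseline, IU/L.
#' @return list with all three quantities, the name of the solved one, and a
#'   `note` ("achieved without dosing" when the target trough does not
#'   exceed baseline, "infeasible" when no interval longer than the infusion
#'   achieves it).
#' @export
solve_regimen <- function(model, params, bw,
                          dose_iu_kg = NULL, interval_h = NULL,
                          trough_iu_ml = NULL,
                          duration_h = 0.1666, baseline_iul = 5) {
  known <- c(dose = !is.null(dose_iu_kg), interval = !is.null(interval_h),
             trough = !is.null(trough_iu_ml))
  if (sum(known) != 2)
    stop("supply exactly two of dose_iu_kg, interval_h, trough_iu_ml")
  d <- pk_disposition(model, params)
  ## steady-state trough above baseline per IU administered
  unit_trough <- function(tau) {
    sum((d$A / (d$lambda * duration_h)) *
        (1 - exp(-d$lambda * duration_h)) *
        exp(-d$lambda * (tau - duration_h)) /
        (1 - exp(-d$lambda * tau)))
  }
  solved <- names(known)[!known]
  note <- ""
  if (solved == "trough") {
    tr <- baseline_iul + dose_iu_kg * bw * unit_trough(interval_h)
    trough_iu_ml <- iu_l_to_iu_ml(tr)
  } else if (solved == "dose") {
    target <- iu_ml_to_iu_l(trough_iu_ml) - baseline_iul
    if (target <= 0) {
      dose_iu_kg <- 0
      note <- "achieved without dosing"
    } else {
      dose_iu_kg <- target / unit_trough(interval_h) / bw
    }
  } else {
    target <- iu_ml_to_iu_l(trough_iu_ml) - baseline_iul
    if (target <= 0) {
      interval_h <- Inf
      note <- "achieved without dosing"
    } else {
      amt <- dose_iu_kg * bw
      f <- function(tau) amt * unit_trough(tau) - target
      lo <- duration_h * (1 + 1e-6)
      if (f(lo) < 0) {
        interval_h <- NA_real_
        note <- "infeasible"
      } else {
        hi <- lo * 2
        while (f(hi) > 0 && hi < 1e6) hi <- hi * 2
        interval_h <- uniroot(f, c(lo, hi), tol = 1e-6)$root
      }
    }
  }
  list(dose_iu_kg = dose_iu_kg, interval_h = interval_h,
       trough_iu_ml = trough_iu_ml, solved = solved, note = note)
}
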