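## Pipeline orchestration (simulate -> validate -> fit -> evaluate ->
## forecast) with a hashed artifact manifest, and the structured PopPK
## report skeleton.

default_pipeline_config <- function() {
  list(stages = c("simulate", "validate", "fit", "evaluate", "forecast"),
       seed = 1,
       out_dir = "hemopk-run",
       n_subjects = 20,
       rise_tolerance = 0.5,
       sparse_times = c(3, 24, 48),
       cv_k = 4,
       n_draws = 500,
       force = FALSE)
}

#' Run the modeling pipeline
#'
#' Executes the requested stages in order, writing versioned artifacts
#' (cohort CSV, validation flags TSV, fit JSON, evaluation JSON, forecast
#' JSON) and a manifest with MD5 hashes and the seeds used. Re-runs skip
#' stages whose outputs already exist unless `force` is set, so a rerun
#' without changes reproduces the manifest hashes byte for byte.
#'
#' @param config list (or path to a YAML file) overriding
#'   `stages`, `seed`, `out_dir`, `n_subjects`, `sparse_times`, `cv_k`,
#'   `n_draws`, `force`.
#' @return the manifest (invisibly written as `manifest.json`).
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- modifyList(default_pipeline_config(), config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  art <- function(f) file.path(cfg$out_dir, f)
  manifest <- list(schema = "hemopk-manifest/1", seed = cfg$seed,
                   stages = cfg$stages, artifacts = list())
  stage_err <- function(stage, e)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  done <- function(f) file.exists(art(f)) && !cfg$force

  if ("simulate" %in% cfg$stages && !done("cohort.csv")) {
    tryCatch({
      sim <- simulate_cohort(simulation_spec(n_subjects = cfg$n_subjects,
                                             seed = cfg$seed))
      write_pk_dataset(sim$dataset, art("cohort.csv"))
      utils::write.table(sim$truth$subjects, art("truth.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
    }, error = function(e) stage_err("simulate", e))
  }
  if ("validate" %in% cfg$stages && !done("flags.tsv")) {
    tryCatch({
      ds <- read_pk_dataset(art("cohort.csv"))
      flags <- validate_pk_dataset(ds,
                                   rise_tolerance = cfg$rise_tolerance)
      utils::write.table(flags, art("flags.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
    }, error = function(e) stage_err("validate", e))
  }
  if ("fit" %in% cfg$stages && !done("fit.json")) {
    tryCatch({
      ds <- read_pk_dataset(art("cohort.csv"))
      skel <- fviii_reference_model()
      fit <- fit_population(ds, skel)
      write_fit_json(fit, art("fit.json"))
      write_model_yaml(fit$pop, art("model.yaml"))
    }, error = function(e) stage_err("fit", e))
  }
  if ("evaluate" %in% cfg$stages && !done("evaluation.json")) {
    tryCatch({
      ds <- read_pk_dataset(art("cohort.csv"))
      fit <- fit_population(ds, read_model_yaml(art("model.yaml")))
      diag <- compute_diagnostics(fit)
      cv <- cross_validate(ds, fit$pop, "kfold", k = cfg$cv_k,
                           seed = cfg$seed)
      obj <- list(
        cwres_mean = mean(diag$residuals$cwres),
        cwres_sd = sd(diag$residuals$cwres),
        eta_shrinkage_pct = as.list(diag$shrinkage$eta_pct),
        eps_shrinkage_pct = diag$shrinkage$eps_pct,
        cv_me = cv$me, cv_mse = cv$mse, cv_scheme = cv$scheme)
      jsonlite::write_json(obj, art("evaluation.json"), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
    }, error = function(e) stage_err("evaluate", e))
  }
  if ("forecast" %in% cfg$stages && !done("forecasts.json")) {
    tryCatch({
      ds <- read_pk_dataset(art("cohort.csv"))
      pop <- read_model_yaml(art("model.yaml"))
      priors <- prior_set(pop, provenance = "pipeline fit")
      sparse <- sparsify(ds, cfg$sparse_times)
      fcs <- lapply(unique(sparse$CID), function(cid) {
        fc <- posterior_band(subject_data(sparse, cid), priors,
                             n_draws = cfg$n_draws, seed = cfg$seed + cid)
        rep <- report_thresholds(fc)
        list(cid = cid,
             theta = as.list(fc$theta_map),
             thresholds = rep$thresholds,
             concentrations = rep$concentrations)
      })
      jsonlite::write_json(fcs, art("forecasts.json"), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
    }, error = function(e) stage_err("forecast", e))
  }
  files <- setdiff(list.files(cfg$out_dir), "manifest.json")
  manifest$artifacts <- lapply(setNames(files, files), function(f)
    list(md5 = unname(tools::md5sum(art(f))),
         bytes = file.size(art(f))))
  jsonlite::write_json(manifest, art("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

write_fit_json <- function(fit, path) {
  obj <- list(schema = "hemopk-fit/1",
              ofv = fit$ofv, converged = fit$converged,
              n_subjects = fit$n_subjects, n_obs = fit$n_obs,
              estimates = as.list(natural_params(fit$pop)),
              eta_hat = as.data.frame(fit$eta_hat))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

BOX3_SECTIONS <- c("Summary", "Introduction",
                   "Objectives, Hypotheses and Assumptions",
                   "Materials and Methods", "Results", "Discussion",
                   "Application of Results", "Appendix")

#' Assemble the structured PopPK report
#'
#' Populates the standard report skeleton (the eight top-level sections
#' recommended for comprehensive PopPK reports, with Materials and
#' Methods subdivided into Assay, Data and Data Analysis Methods) from fit
#' and evaluation artifacts. Sections without artifacts are populated
#' with an explicit "not run" rather than omitted, and the JSON and text
#' renderings carry the same numbers (single source).
#'
#' @param fit a `pk_fit`.
#' @param evaluation optional list with `diagnostics` ([compute_diagnostics()]),
#'   `bootstrap` ([bootstrap_fit()]), `crossval` ([cross_validate()]).
#' @param cfg optional list: `title`, `brand`, `assay`.
#' @return object of class `poppk_report` (a named list of sections).
#' @export
render_report <- function(fit, evaluation = NULL, cfg = list()) {
  if (!isTRUE(fit$converged)) stop("report requires a converged fit")
  est <- natural_params(fit$pop)
  par_tab <- data.frame(parameter = names(est), estimate = unname(est))
  if (!is.null(fit$se))
    par_tab$se <- unname(fit$se[par_tab$parameter])
  bs <- evaluation$bootstrap
  if (!is.null(bs) && !is.null(bs$percentiles)) {
    pc <- bs$percentiles
    par_tab$boot_lower <- unname(pc["2.5%", par_tab$parameter])
    par_tab$boot_median <- unname(pc["50%", par_tab$parameter])
    par_tab$boot_upper <- unname(pc["97.5%", par_tab$parameter])
  } else {
    par_tab$boot_lower <- par_tab$boot_median <- par_tab$boot_upper <-
      "not run"
  }
  dg <- evaluation$diagnostics
  cv <- evaluation$crossval
  sections <- list(
    "Summary" = sprintf(
      "%d-compartment population PK model, %d subjects, %d observations, OFV %.3f.",
      fit$pop$structural$n_compartments, fit$n_subjects, fit$n_obs,
      fit$ofv),
    "Introduction" = cfg$title %||%
      "Population PK model for a clotting factor concentrate.",
    "Objectives, Hypotheses and Assumptions" = paste(
      "Characterize the population PK of the concentrate;",
      "log-normal between-subject variability;",
      fit$pop$error$form, "residual error; M3 handling of BLQ data."),
    "Materials and Methods" = list(
      Assay = cfg$assay %||% "One-stage clotting assay (LOQ 0.01 IU/mL).",
      Data = sprintf("%d subjects, %d observations (dataset %s).",
                     fit$n_subjects, fit$n_obs, fit$fingerprint),
      "Data Analysis Methods" = paste(
        "Laplace/FOCE-with-interaction estimation; nested models compared",
        "at a 3.84 OFV drop per added parameter.")),
    "Results" = list(parameter_table = par_tab,
                     condition_number = fit$condition_number %||% "not run",
                     shrinkage = if (!is.null(dg)) dg$shrinkage
                                 else "not run",
                     crossval = if (!is.null(cv))
                       list(me = cv$me, mse = cv$mse) else "not run"),
    "Discussion" = "See diagnostics and evaluation artifacts.",
    "Application of Results" = paste(
      "Population estimates serve as informative priors for Bayesian",
      "individual forecasts from sparse sampling."),
    "Appendix" = list(eta_shrinkage = if (!is.null(dg))
      as.list(dg$shrinkage$eta_pct) else "not run"))
  structure(sections, class = "poppk_report")
}

#' @export
print.poppk_report <- function(x, ...) {
  for (nm in names(x)) {
    cat("==", nm, "==\n")
    sec <- x[[nm]]
    if (is.character(sec)) cat(sec, "\n")
    else utils::str(sec, max.level = 2, give.attr = FALSE)
    cat("\n")
  }
  invisible(x)
}

#' @rdname render_report
#' @param report a `poppk_report`.
#' @param path output JSON path.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(path)
}
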