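## Dataset assembly, reading/writing and validation in the NONMEM-dialect
## CSV layout used for factor concentrate PopPK modeling.

REQUIRED_COLS <- c("CID", "OCC", "TIMEH", "AMT", "RATE", "DV", "AGE", "BW",
                   "EVID", "DOSE", "PREDOSE", "MDV5", "BASELINE", "BLQ",
                   "MDV3")
OPTIONAL_COLS <- c("HT", "VWF", "RACE", "BTYPE", "HCT")
## columns where -1 is the "not measured" sentinel
SENTINEL_COLS <- c("PREDOSE", "BASELINE")

#' Default imputed endogenous baseline, IU/L
#'
#' When no baseline factor level was measured, 0.005 IU/mL (0.5% of normal
#' activity, i.e. 5 IU/L) is assumed.
#' @export
DEFAULT_BASELINE_IUL <- 5

#' Default assay limit of quantification, IU/L
#'
#' 0.01 IU/mL (10 IU/L), the commonly cited LOQ of clotting activity assays
#' and the defining level of severe hemophilia.
#' @export
DEFAULT_LOQ_IUL <- 10

#' Construct a PK dataset from event-record rows
#'
#' @param records data frame with at least the required columns (`CID`,
#'   `OCC`, `TIMEH`, `AMT`, `RATE`, `DV`, `AGE`, `BW`, `EVID`, `DOSE`,
#'   `PREDOSE`, `MDV5`, `BASELINE`, `BLQ`, `MDV3`); optional covariates
#'   `HT`, `VWF`, `RACE`, `BTYPE`, `HCT` are carried along when present.
#' @param provenance free-text source label.
#' @return object of class `pk_dataset` (a data frame).
#' @export
pk_dataset <- function(records, provenance = "unspecified") {
  miss <- setdiff(REQUIRED_COLS, names(records))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(records$EVID), c(0, 1, 3))
  if (length(bad))
    stop("unexpected EVID code: ", paste(bad, collapse = ", "))
  for (cid in unique(records$CID)) {
    s <- records[records$CID == cid, ]
    if (!any(s$EVID == 1 & s$AMT > 0))
      stop("subject ", cid, " has no dose record")
    if (!any(s$EVID %in% c(0, 3)))
      stop("subject ", cid, " has no observation or BLQ record")
  }
  keep <- c(REQUIRED_COLS, intersect(OPTIONAL_COLS, names(records)))
  records <- as.data.frame(records)[, keep]
  for (cn in keep) records[[cn]] <- as.numeric(records[[cn]])
  rownames(records) <- NULL
  structure(records, class = c("pk_dataset", "data.frame"),
            provenance = provenance)
}

#' @export
print.pk_dataset <- function(x, ...) {
  cat(sprintf("PK dataset: %d subjects, %d records (%d observations, %d BLQ)\n",
              length(unique(x$CID)), nrow(x), sum(x$EVID == 0),
              sum(x$EVID == 3)))
  cat("provenance:", attr(x, "provenance"), "\n")
  NextMethod()
}

subject_ids <- function(ds) unique(ds$CID)

#' Extract one subject's records
#' @param ds a [pk_dataset()].
#' @param cid subject id.
#' @export
subject_data <- function(ds, cid) {
  s <- ds[ds$CID == cid, , drop = FALSE]
  if (!nrow(s)) stop("no such subject: ", cid)
  s
}

#' Read a PK dataset from NONMEM-dialect CSV
#'
#' Case-insensitive header; `-1` sentinels in `PREDOSE`/`BASELINE` and `.`
#' entries are mapped to `NA`; `EVID` codes other than 0 (valid
#' observation), 1 (dose) and 3 (BLQ observation) are rejected.
#'
#' @param file path, connection, or literal CSV text (contains a newline).
#' @param provenance source label; defaults to the file name.
#' @return a [pk_dataset()].
#' @export
read_pk_dataset <- function(file, provenance = NULL) {
  if (is.character(file) && length(file) == 1 && grepl("\n", file))
    file <- textConnection(file)
  raw <- read.csv(file, colClasses = "character", check.names = FALSE,
                  strip.white = TRUE)
  names(raw) <- toupper(names(raw))
  miss <- setdiff(REQUIRED_COLS, names(raw))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  keep <- c(REQUIRED_COLS, intersect(OPTIONAL_COLS, names(raw)))
  out <- raw[, keep]
  for (cn in keep) {
    v <- out[[cn]]
    v[v %in% c(".", "")] <- NA
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' in column %s at data row %d",
                   v[bad[1]], cn, bad[1]))
    if (cn %in% SENTINEL_COLS) num[!is.na(num) & num == -1] <- NA
    out[[cn]] <- num
  }
  ## order by appearance of CID, then original row order within subject
  out <- out[order(match(out$CID, unique(out$CID))), , drop = FALSE]
  pk_dataset(out, provenance = provenance %||%
               if (is.character(file)) file else "connection")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a PK dataset to NONMEM-dialect CSV
#'
#' Numeric values are written with full (17 significant digit) precision so
#' that a read/write round trip is exact. `NA` in `PREDOSE`/`BASELINE`
#' becomes the `-1` sentinel; other missing values become `.`.
#'
#' @param ds a [pk_dataset()].
#' @param path output file.
#' @export
write_pk_dataset <- function(ds, path) {
  out <- as.data.frame(ds)
  for (cn in names(out)) {
    v <- out[[cn]]
    s <- sprintf("%.17g", v)
    s[is.na(v)] <- if (cn %in% SENTINEL_COLS) "-1" else "."
    out[[cn]] <- s
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble one subject's record block
#'
#' Builds the standard record layout: the first record (time 0) carries the
#' pre-dose level and the baseline (measured value, or the imputed
#' 0.005 IU/mL = 5 IU/L); the second record carries the dose with `TIMEH`
#' equal to the infusion duration truncated to 4 decimal places and
#' `RATE = AMT/TIMEH`; subsequent records are the observations in time
#' order, with concentrations below the LOQ encoded as EVID=3 BLQ rows
#' (`BLQ` = LOQ, `MDV3 = 0`, `MDV5 = 1`).
#'
#' @param cid subject id (positive integer).
#' @param dose list with `amount_iu` and `duration_h` (> 0); optional
#'   `start_h` (default 0) for later occasions.
#' @param observations data frame with `time_h` and `conc_iul`.
#' @param demographics list with required `age` (years) and `bw` (kg);
#'   optional `ht`, `vwf`, `race`, `btype`, `hct`.
#' @param baseline_iul measured endogenous level (IU/L) or `NULL`.
#' @param predose_iul measured pre-dose level (IU/L) or `NULL`.
#' @param loq_iul assay limit of quantification, IU/L.
#' @param occ dose occasion number.
#' @return data frame of event-record rows for this subject.
#' @export
assemble_subject <- function(cid, dose, observations, demographics,
                             baseline_iul = NULL, predose_iul = NULL,
                             loq_iul = DEFAULT_LOQ_IUL, occ = 1) {
  if (dose$duration_h <= 0) stop("invalid dose: duration must be positive")
  if (any(observations$time_h < 0))
    stop("ordering error: observation before time 0")
  if (is.null(demographics$age) || is.null(demographics$bw))
    stop("demographics must include age and bw")
  start <- dose$start_h %||% 0
  dur <- trunc4(dose$duration_h)
  base <- baseline_iul %||% DEFAULT_BASELINE_IUL
  obs <- observations[order(observations$time_h), , drop = FALSE]
  nobs <- nrow(obs)
  blq <- obs$conc_iul < loq_iul
  n <- nobs + if (occ == 1) 2L else 1L
  row0 <- function(timeh, amt, rate, dv, evid, mdv5, blqv, mdv3) {
    data.frame(CID = cid, OCC = occ, TIMEH = timeh, AMT = amt, RATE = rate,
               DV = dv, AGE = demographics$age, BW = demographics$bw,
               EVID = evid, DOSE = amt / demographics$bw,
               PREDOSE = predose_iul %||% NA_real_, MDV5 = mdv5,
               BASELINE = base, BLQ = blqv, MDV3 = mdv3)
  }
  rows <- list()
  if (occ == 1)
    rows[[1]] <- row0(0, 0, 0, 0, 1, 1, 0, 1)
  rows[[length(rows) + 1]] <-
    row0(trunc4(start + dur), dose$amount_iu, dose$amount_iu / dur, 0,
         1, 1, 0, 1)
  if (nobs) {
    orows <- row0(trunc4(obs$time_h), 0, 0,
                  ifelse(blq, loq_iul, obs$conc_iul),
                  ifelse(blq, 3, 0), ifelse(blq, 1, 0),
                  ifelse(blq, loq_iul, 0), 0)
    rows[[length(rows) + 1]] <- orows
  }
  out <- do.call(rbind, rows)
  for (oc in intersect(c("ht", "vwf", "race", "btype", "hct"),
                       names(demographics)))
    out[[toupper(oc)]] <- demographics[[oc]]
  rownames(out) <- NULL
  out
}

default_covariate_bounds <- function() {
  list(AGE = c(0, 120), BW = c(2, 250), HT = c(40, 230),
       VWF = c(0, 600), HCT = c(10, 70))
}

default_categorical_codes <- function() {
  list(BTYPE = 1:4, RACE = 1:9)
}

#' Validate a PK dataset
#'
#' Pure report (the dataset is unchanged): flags rising post-infusion
#' concentrations within an occasion, missing required values, continuous
#' covariates outside plausible bounds, unexpected categorical codes, and
#' duplicate records within a subject.
#'
#' @param ds a [pk_dataset()].
#' @param covariate_bounds named list of `c(lower, upper)` plausible ranges.
#' @param categorical_codes named list of allowed code sets.
#' @param rise_tolerance fractional rise tolerated before flagging: a
#'   post-infusion observation is flagged when it exceeds the previous
#'   valid observation by more than this fraction. The default 0 flags
#'   any rise (every flagged row is then reviewed and resolved); when
#'   screening data whose assay noise is known, a positive tolerance
#'   (e.g. 0.5) suppresses flags that pure measurement error explains.
#' @return data frame of flags: `cid`, `row` (row index in `ds`),
#'   `category`, `message`, `resolution` (all `"unresolved"`).
#' @export
validate_pk_dataset <- function(ds,
                                covariate_bounds = default_covariate_bounds(),
                                categorical_codes = default_categorical_codes(),
                                rise_tolerance = 0) {
  flags <- list()
  add <- function(cid, row, category, message)
    flags[[length(flags) + 1]] <<-
      data.frame(cid = cid, row = row, category = category,
                 message = message, resolution = "unresolved")
  for (cid in subject_ids(ds)) {
    idx <- which(ds$CID == cid)
    s <- ds[idx, ]
    ## duplicates (byte-identical rows within the subject)
    dup <- which(duplicated(s))
    for (d in dup)
      add(cid, idx[d], "duplicate-record", "duplicate of an earlier record")
    for (occ in unique(s$OCC)) {
      so <- s[s$OCC == occ, ]
      oidx <- idx[s$OCC == occ]
      dose_end <- suppressWarnings(
        max(so$TIMEH[so$EVID == 1 & so$AMT > 0]))
      ## rising concentrations among valid observations after infusion end
      oo <- which(so$EVID == 0 & so$TIMEH >= dose_end)
      if (length(oo) > 1) {
        for (k in 2:length(oo)) {
          if (isTRUE(so$DV[oo[k]] >
                     so$DV[oo[k - 1]] * (1 + rise_tolerance)))
            add(cid, oidx[oo[k]], "rising-concentration",
                sprintf("concentration %g at t=%g exceeds %g at t=%g",
                        so$DV[oo[k]], so$TIMEH[oo[k]],
                        so$DV[oo[k - 1]], so$TIMEH[oo[k - 1]]))
        }
      }
    }
    ## missing required values (sentinel columns may be NA = not measured)
    for (cn in setdiff(REQUIRED_COLS, SENTINEL_COLS)) {
      for (r in which(is.na(s[[cn]])))
        add(cid, idx[r], "missing-value", paste("missing", cn))
    }
    ## covariate plausibility (continuous)
    for (cn in intersect(names(covariate_bounds), names(s))) {
      b <- covariate_bounds[[cn]]
      v <- s[[cn]]
      for (r in which(!is.na(v) & (v < b[1] | v > b[2])))
        add(cid, idx[r], "covariate-outlier",
            sprintf("%s = %g outside (%g, %g)", cn, v[r], b[1], b[2]))
    }
    ## categorical codes
    for (cn in intersect(names(categorical_codes), names(s))) {
      v <- s[[cn]]
      for (r in which(!is.na(v) & !(v %in% categorical_codes[[cn]])))
        add(cid, idx[r], "unexpected-category",
            sprintf("%s code %g not in declared set", cn, v[r]))
    }
  }
  if (!length(flags))
    return(data.frame(cid = numeric(), row = integer(),
                      category = character(), message = character(),
                      resolution = character()))
  out <- do.call(rbind, flags)
  rownames(out) <- NULL
  out
}

#' Apply documented resolutions to flagged records
#'
#' Every flag must carry a resolution: `"corrected"` (with `field` and
#' `new_value` columns giving the replacement) or `"excluded"` (the row is
#' removed). A subject left without any observation or BLQ record is
#' dropped entirely, with a warning. Flagged data are never silently kept.
#'
#' @param ds a [pk_dataset()].
#' @param flags flag table from [validate_pk_dataset()] with filled
#'   `resolution` (and `field`/`new_value` for corrections).
#' @return list with the resolved `dataset` and an `audit` log data frame.
#' @export
apply_resolutions <- function(ds, flags) {
  if (nrow(flags) == 0)
    return(list(dataset = ds, audit = data.frame()))
  if (any(flags$resolution == "unresolved"))
    stop("unresolved flags present; every flag must be corrected or excluded")
  audit <- list()
  drop_rows <- integer()
  for (i in seq_len(nrow(flags))) {
    f <- flags[i, ]
    if (f$resolution == "excluded") {
      drop_rows <- c(drop_rows, f$row)
      audit[[length(audit) + 1]] <- data.frame(
        cid = f$cid, row = f$row, action = "excluded", detail = f$message)
    } else if (f$resolution == "corrected") {
      if (is.null(f$field) || is.na(f$field))
        stop("corrected flag needs 'field' and 'new_value'")
      old <- ds[[f$field]][f$row]
      ds[[f$field]][f$row] <- f$new_value
      audit[[length(audit) + 1]] <- data.frame(
        cid = f$cid, row = f$row, action = "corrected",
        detail = sprintf("%s: %g -> %g", f$field, old, f$new_value))
    } else stop("unknown resolution: ", f$resolution)
  }
  if (length(drop_rows)) ds <- ds[-unique(drop_rows), , drop = FALSE]
  ## enforce the dataset invariant: a subject needs >= 1 observation/BLQ row
  for (cid in unique(ds$CID)) {
    s <- ds[ds$CID == cid, ]
    if (!any(s$EVID %in% c(0, 3))) {
      warning("subject ", cid,
              " left without observations after exclusions; dropped")
      ds <- ds[ds$CID != cid, , drop = FALSE]
      audit[[length(audit) + 1]] <- data.frame(
        cid = cid, row = NA_integer_, action = "subject-dropped",
        detail = "no observations remain")
    }
  }
  rownames(ds) <- NULL
  list(dataset = pk_dataset(ds, provenance = attr(ds, "provenance") %||%
                              "resolved"),
       audit = do.call(rbind, audit))
}

## ---- estimation frame ------------------------------------------------------
## Internal per-subject view used by the likelihood code: regimen (each dose
## record's TIMEH is the absolute end-of-infusion time, duration AMT/RATE),
## baseline (imputed 5 IU/L when absent), residual pre-dose concentration,
## observation times/values/BLQ indicators (rows with MDV3 == 0).
est_frame <- function(ds) {
  lapply(subject_ids(ds), function(cid) {
    s <- ds[ds$CID == cid, , drop = FALSE]
    dr <- s[s$EVID == 1 & s$AMT > 0, , drop = FALSE]
    dur <- dr$AMT / dr$RATE
    base <- s$BASELINE[1]
    if (is.na(base)) base <- DEFAULT_BASELINE_IUL
    pre <- s$PREDOSE[1]
    resid <- if (is.na(pre)) 0 else max(pre - base, 0)
    o <- s[s$MDV3 == 0 & s$EVID %in% c(0, 3), , drop = FALSE]
    covs <- list(AGE = s$AGE[1], BW = s$BW[1])
    for (cn in intersect(OPTIONAL_COLS, names(s)))
      covs[[cn]] <- s[[cn]][1]
    list(cid = cid,
         reg_start = dr$TIMEH - dur, reg_dur = dur,
         reg_rate = dr$RATE,
         baseline = base, resid_conc = resid,
         t_obs = o$TIMEH, dv = o$DV,
         is_blq = as.integer(o$EVID == 3),
         loq = ifelse(o$EVID == 3, o$BLQ, 0),
         mdv5 = o$MDV5,
         covs = covs)
  })
}

## cheap fingerprint used to refuse comparing fits on different data
dataset_fingerprint <- function(ds) {
  paste(nrow(ds), length(unique(ds$CID)),
        format(sum(ds$TIMEH) + sum(ds$DV, na.rm = TRUE), digits = 15),
        sep = ":")
}
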