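test_that("a minimal three-record file parses into one subject", {
  txt <- paste(
    "CID,OCC,TIMEH,AMT,RATE,DV,AGE,BW,EVID,DOSE,PREDOSE,MDV5,BASELINE,BLQ,MDV3",
    "1,1,0,0,0,0,30,70,1,0,-1,1,5,0,1",
    "1,1,0.1666,3500,21008.4,0,30,70,1,50,-1,1,5,0,1",
    "1,1,24,0,0,250,30,70,0,0,-1,0,5,0,0",
    sep = "\n")
  ds <- read_pk_dataset(txt)
  expect_s3_class(ds, "pk_dataset")
  expect_equal(length(unique(ds$CID)), 1)
  expect_equal(sum(ds$EVID == 0), 1)
  expect_true(is.na(ds$PREDOSE[1]))  # -1 sentinel mapped to absent
})

test_that("unexpected EVID codes and malformed cells are rejected", {
  txt <- paste(
    "CID,OCC,TIMEH,AMT,RATE,DV,AGE,BW,EVID,DOSE,PREDOSE,MDV5,BASELINE,BLQ,MDV3",
    "1,1,0,0,0,0,30,70,1,0,-1,1,5,0,1",
    "1,1,0.1666,3500,21008.4,0,30,70,1,50,-1,1,5,0,1",
    "1,1,24,0,0,250,30,70,2,0,-1,0,5,0,0",
    sep = "\n")
  expect_error(read_pk_dataset(txt), "unexpected EVID code")
  txt2 <- sub("24,0,0,250", "24,0,0,abc", txt)
  txt2 <- sub(",2,0,-1,0", ",0,0,-1,0", txt2)
  expect_error(read_pk_dataset(txt2), "non-numeric.*DV")
  expect_error(read_pk_dataset(sub(",MDV3", ",XX", txt)),
               "missing required column")
})

test_that("write/read round trip reproduces every numeric field exactly", {
  ds <- small_cohort(n = 5, seed = 11)$dataset
  f <- tempfile(fileext = ".csv")
  write_pk_dataset(ds, f)
  ds2 <- read_pk_dataset(f)
  for (cn in names(ds))
    expect_identical(ds2[[cn]], ds[[cn]], label = cn)
})

test_that("assembled records follow the standard layout", {
  s <- assemble_subject(
    1, dose = list(amount_iu = 3000, duration_h = 10 / 60),
    observations = data.frame(time_h = c(24, 1, 48),
                              conc_iul = c(80, 900, 4)),
    demographics = list(age = 30, bw = 60))
  # 10-minute administration encodes as 0.1666 (truncated, not rounded)
  expect_identical(s$TIMEH[2], 0.1666)
  expect_equal(s$RATE[2], 3000 / 0.1666)
  expect_equal(s$DOSE[2], 50)
  # unmeasured baseline imputed at 0.005 IU/mL = 5 IU/L
  expect_identical(s$BASELINE[1], 5)
  expect_true(is.na(s$PREDOSE[1]))
  # observations sorted; the 4 IU/L sample is below LOQ -> BLQ row
  expect_equal(s$TIMEH[3:5], c(1, 24, 48))
  blq <- s[s$TIMEH == 48, ]
  expect_equal(blq$EVID, 3)
  expect_equal(blq$BLQ, DEFAULT_LOQ_IUL)
  expect_equal(blq$MDV3, 0)  # enters the M3 likelihood
  expect_equal(blq$MDV5, 1)  # excluded from residual diagnostics
  # RATE x TIMEH returns AMT for a clean duration
  s2 <- assemble_subject(1, dose = list(amount_iu = 3000,
                                        duration_h = 0.25),
                         observations = data.frame(time_h = 2,
                                                   conc_iul = 500),
                         demographics = list(age = 30, bw = 60))
  expect_equal(s2$RATE[2], 12000)
  expect_equal(s2$RATE[2] * s2$TIMEH[2], 3000)
})

test_that("assembly rejects invalid doses and negative times", {
  expect_error(assemble_subject(1, list(amount_iu = 100, duration_h = 0),
                                data.frame(time_h = 1, conc_iul = 10),
                                list(age = 30, bw = 60)),
               "invalid dose")
  expect_error(assemble_subject(1, list(amount_iu = 100, duration_h = 1),
                                data.frame(time_h = -1, conc_iul = 10),
                                list(age = 30, bw = 60)),
               "ordering error")
})

test_that("validation flags rising concentrations, outliers and duplicates", {
  s <- assemble_subject(
    1, dose = list(amount_iu = 3000, duration_h = 0.25),
    observations = data.frame(time_h = c(1, 6, 24),
                              conc_iul = c(900, 600, 700)),
    demographics = list(age = 30, bw = 60))
  ds <- pk_dataset(s)
  fl <- validate_pk_dataset(ds)
  rising <- fl[fl$category == "rising-concentration", ]
  expect_equal(nrow(rising), 1)
  expect_equal(ds$TIMEH[rising$row], 24)

  dup <- pk_dataset(rbind(s, s[4, ]))
  fl2 <- validate_pk_dataset(dup)
  expect_equal(sum(fl2$category == "duplicate-record"), 1)

  s3 <- s; s3$AGE <- 250
  fl3 <- validate_pk_dataset(pk_dataset(s3))
  expect_true(any(fl3$category == "covariate-outlier"))

  s4 <- s; s4$DV[4] <- NA
  fl4 <- validate_pk_dataset(pk_dataset(s4))
  expect_true(any(fl4$category == "missing-value"))

  s5 <- s; s5$BTYPE <- 7
  fl5 <- validate_pk_dataset(pk_dataset(s5))
  expect_true(any(fl5$category == "unexpected-category"))
})

test_that("a clean simulated cohort validates with zero flags", {
  ds <- small_cohort(n = 6, seed = 3)$dataset
  # the rise tolerance matched to assay noise suppresses spurious flags
  expect_equal(nrow(validate_pk_dataset(ds, rise_tolerance = 0.5)), 0)
})

test_that("resolutions are applied and audited; nothing kept silently", {
  s <- assemble_subject(
    1, dose = list(amount_iu = 3000, duration_h = 0.25),
    observations = data.frame(time_h = c(1, 6, 24),
                              conc_iul = c(900, 600, 700)),
    demographics = list(age = 30, bw = 60))
  ds <- pk_dataset(s)
  fl <- validate_pk_dataset(ds)
  expect_error(apply_resolutions(ds, fl), "unresolved")

  # corrected with the identical value: dataset unchanged, audit non-empty
  flc <- fl; flc$resolution <- "corrected"
  flc$field <- "DV"; flc$new_value <- ds$DV[flc$row]
  rc <- apply_resolutions(ds, flc)
  expect_equal(as.data.frame(rc$dataset), as.data.frame(ds))
  expect_gt(nrow(rc$audit), 0)

  # exclusion removes exactly the flagged row
  fle <- fl; fle$resolution <- "excluded"
  re <- apply_resolutions(ds, fle)
  expect_equal(nrow(re$dataset), nrow(ds) - 1)

  # excluding a subject's only observation drops the subject with warning
  s1 <- assemble_subject(2, dose = list(amount_iu = 1000,
                                        duration_h = 0.25),
                         observations = data.frame(time_h = 6,
                                                   conc_iul = 200),
                         demographics = list(age = 20, bw = 50))
  ds2 <- pk_dataset(rbind(s, s1))
  only <- which(ds2$CID == 2 & ds2$EVID == 0)
  fx <- data.frame(cid = 2, row = only, category = "rising-concentration",
                   message = "x", resolution = "excluded")
  expect_warning(r2 <- apply_resolutions(ds2, fx), "dropped")
  expect_false(2 %in% r2$dataset$CID)
})

test_that("multi-occasion dose records encode start and duration consistently", {
  s1 <- assemble_subject(1, dose = list(amount_iu = 2000, duration_h = 0.25),
                         observations = data.frame(time_h = c(6, 24),
                                                   conc_iul = c(400, 100)),
                         demographics = list(age = 30, bw = 70))
  s2 <- assemble_subject(1, occ = 2,
                         dose = list(amount_iu = 2000, duration_h = 0.25,
                                     start_h = 48),
                         observations = data.frame(time_h = c(54, 72),
                                                   conc_iul = c(400, 100)),
                         demographics = list(age = 30, bw = 70))
  ds <- pk_dataset(rbind(s1, s2))
  fr <- hemopk:::est_frame(ds)[[1]]
  expect_equal(fr$reg_start, c(0, 48))
  expect_equal(fr$reg_dur, c(0.25, 0.25))
})
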