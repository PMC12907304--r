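test_that("demographics follow the truncated cohort distributions", {
  expect_equal(nrow(generate_demographics(0)), 0)
  demo <- generate_demographics(1e4, seed = 31)
  expect_equal(mean(demo$age), 72.95, tolerance = 0.2 / 72.95)
  expect_true(all(demo$age >= 67 & demo$age <= 82))
  expect_equal(mean(demo$wt), 65.63, tolerance = 0.05)
  expect_true(all(demo$wt >= 49 & demo$wt <= 80))
  expect_equal(mean(demo$sex), 0.55, tolerance = 0.05)
  # deterministic under a fixed seed
  expect_identical(generate_demographics(20, seed = 5),
                   generate_demographics(20, seed = 5))
  expect_error(generate_demographics(-1), "non-negative")
})

test_that("the protocol schedule has 19 nominal samples per subject", {
  des <- study_design()
  st <- pk_sample_times(des, infusion_end = 125)
  expect_length(st, 19)
  expect_false(is.unsorted(st))
  expect_equal(st[1:4], c(0, 1, 3, 5))          # around the 1-min bolus
  expect_true(all(c(10, 15, 20, 35, 50, 65) %in% st)) # during maintenance
  expect_equal(max(st), 125 + 360)              # 6 h after cessation
  ds <- generate_study(des, default_population_model(), seed = 12)
  expect_equal(sum(ds$EVID == 0 & ds$CMT == 1), 20 * 19)
  expect_equal(sum(ds$EVID == 0 & ds$CMT == 4), 20 * 19)
  expect_equal(sum(ds$EVID == 1), 20 * 2)
})

test_that("noise-free generation reproduces the structural model exactly", {
  pop0 <- noiseless_population()
  des <- study_design(n_subjects = 3)
  ds <- generate_study(des, pop0, seed = 8)
  for (id in unique(ds$ID)) {
    sub <- ds[ds$ID == id, ]
    dose <- sub[sub$EVID == 1, ]
    reg <- regimen(lapply(seq_len(nrow(dose)), function(i)
      dose_event(dose$TIME[i], dose$RATE[i], dose$AMT[i] / dose$RATE[i])))
    obs <- sub[sub$EVID == 0 & sub$CMT == 1, ]
    tr <- simulate_profile(pk_parameters(CL = individual_cl(
      1.01, covariate_model(), obs$WT[1], obs$AGE[1])),
      table3_pd(), reg, obs$TIME)
    expect_equal(obs$DV, tr$Cp, tolerance = 1e-12)
    bis <- sub[sub$EVID == 0 & sub$CMT == 4, ]
    expect_equal(bis$DV, tr$BIS, tolerance = 1e-12)
  }
})

test_that("BLQ flagging follows the quantification limit", {
  ds <- generate_study(study_design(), seed = 44)
  pre <- ds$EVID == 0 & ds$CMT == 1 & ds$TIME == 0
  expect_true(all(ds$BLQ[pre] == 1)) # pre-dose concentration is 0 < LLOQ
  obs <- ds$EVID == 0 & ds$CMT == 1
  expect_equal(ds$BLQ[obs] == 1, ds$DV[obs] < 5)
  expect_true(all(ds$BLQ[ds$CMT == 4] == 0))
  # reproducibility: the dataset is a pure function of (design, pop, seed)
  expect_identical(as.data.frame(ds),
                   as.data.frame(generate_study(study_design(), seed = 44)))
})

test_that("BLQ fraction grows as the maintenance dose shrinks", {
  des_lo <- study_design(maintenance_mgkg_h = 0.1)
  des_hi <- study_design(maintenance_mgkg_h = 1.2)
  frac <- function(ds) {
    obs <- ds$EVID == 0 & ds$CMT == 1 & ds$TIME > 0
    mean(ds$BLQ[obs])
  }
  expect_gt(frac(generate_study(des_lo, seed = 3)),
            frac(generate_study(des_hi, seed = 3)))
})

test_that("event datasets round-trip through CSV", {
  ds <- generate_study(study_design(n_subjects = 4), seed = 17)
  path <- tempfile(fileext = ".csv")
  write_dataset(ds, path)
  ds2 <- read_dataset(path)
  for (cl in names(ds))
    expect_equal(ds2[[cl]], ds[[cl]], tolerance = 1e-12, label = cl)

  # header validation
  bad <- as.data.frame(ds)[, setdiff(names(ds), "DV")]
  path_bad <- tempfile(fileext = ".csv")
  write.csv(bad, path_bad, row.names = FALSE)
  expect_error(read_dataset(path_bad), "DV")
  expect_error(write_dataset(bad, tempfile()), "DV")

  # unsorted times are rejected with the offending row
  shuffled <- as.data.frame(ds)
  shuffled[c(2, 10), "TIME"] <- shuffled[c(10, 2), "TIME"]
  path_shuf <- tempfile(fileext = ".csv")
  write.csv(shuffled, path_shuf, row.names = FALSE, na = ".")
  expect_error(read_dataset(path_shuf), "not sorted within subject")
})

test_that("a hand-written two-row fixture parses as specified", {
  path <- tempfile(fileext = ".csv")
  writeLines(c(
    "ID,TIME,EVID,AMT,RATE,DV,MDV,BLQ,CMT,WT,AGE,SEX",
    "1,0,1,26.4,26.4,.,1,0,1,66,72.5,1",
    "1,3,0,.,.,2481.5,0,0,1,66,72.5,1"), path)
  ds <- read_dataset(path)
  expect_s3_class(ds, "study_dataset")
  expect_equal(nrow(ds), 2)
  expect_equal(ds$AMT[1] / ds$RATE[1], 1)  # 1-min bolus of 0.4 mg/kg x 66 kg
  expect_equal(ds$DV[2], 2481.5)
  expect_true(is.na(ds$DV[1]))
})
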