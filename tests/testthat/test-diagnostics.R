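test_that("CWRES reduces to the plain weighted residual without IIV", {
  # pooled evaluation (no random effects): CWRES = (DV - PRED)/sd
  ds <- generate_study(study_design(n_subjects = 4), seed = 91)
  fit <- evaluate_pk_model(ds, table2_pk(), omega2 = c(V1 = 0),
                          sigma2 = 0.26, covariates = final_cl_covariates())
  rt <- residual_table(fit)
  expect_equal(rt$CWRES, (rt$DV - rt$PRED) / (sqrt(0.26) * rt$PRED),
               tolerance = 1e-10)
  expect_equal(rt$CWRES, rt$IWRES, tolerance = 1e-10)
  expect_equal(nrow(rt), sum(ds$EVID == 0 & ds$CMT == 1 & ds$BLQ == 0))
})

test_that("CWRES is standardized under the true model", {
  fit <- shared_eval_fit() # published model evaluated on its own simulation
  rt <- residual_table(fit)
  expect_gt(mean(rt$CWRES), -0.15)
  expect_lt(mean(rt$CWRES), 0.15)
  expect_gt(sd(rt$CWRES), 0.85)
  expect_lt(sd(rt$CWRES), 1.15)
  expect_true(all(is.finite(rt$CWRES)))
  expect_true(all(rt$TAD >= 0 & rt$TAD <= rt$TIME))
})

test_that("a misspecified clearance leaves a visible CWRES trend", {
  bad <- evaluate_pk_model(shared_study(),
                           pk_parameters(CL = 1.01 / 2),
                           covariates = final_cl_covariates())
  rt <- residual_table(bad)
  expect_gt(abs(mean(rt$CWRES)), 0.5)
})

test_that("bootstrap resampling is reproducible and brackets the estimates", {
  ds <- generate_study(study_design(n_subjects = 8),
                       population_model(omega2 = c(V1 = 0.06, CL = 0.03),
                                        res = residual_model(0.09, 4)),
                       seed = 92)
  set <- fit_settings(outer_tol = 1e-5, outer_maxit = 120)
  fit <- fit_pk(ds, omega2_init = c(V1 = 0.06, CL = 0.03),
                sigma2_init = 0.09, settings = set)
  b1 <- bootstrap(ds, fit, n_reps = 8, seed = 17, settings = set)
  b2 <- bootstrap(ds, fit, n_reps = 8, seed = 17, settings = set)
  expect_identical(b1$estimates, b2$estimates)
  expect_gte(b1$convergence_fraction, 0.5)
  sm <- b1$summary
  expect_true(all(sm$lo <= sm$median & sm$median <= sm$hi))
  # medians should sit near the original point estimates
  expect_equal(sm$median[sm$parameter == "CL"], fit$theta[["CL"]],
               tolerance = 0.15)
  expect_equal(sm$median[sm$parameter == "V1"], fit$theta[["V1"]],
               tolerance = 0.15)
  b3 <- bootstrap(ds, fit, n_reps = 1, seed = 1, settings = set)
  expect_equal(nrow(b3$estimates), 1)
})

test_that("prediction correction is the identity when PRED is constant", {
  # identical dosing, covariates and sampling time across subjects: every
  # PRED in the (single) bin is equal, so pcY = Y * med(PRED)/PRED = Y
  pop <- default_population_model()
  dv <- c(520, 610, 480, 700, 655, 590)
  one <- function(id, dvi) data.frame(
    ID = id, TIME = c(0, 5, 35), EVID = c(1, 1, 0),
    AMT = c(26.4, 101.2, NA), RATE = c(26.4, 0.88, NA),
    DV = c(NA, NA, dvi), MDV = c(1, 1, 0), BLQ = 0, CMT = 1,
    WT = 66, AGE = 72.5, SEX = 1)
  ds <- structure(do.call(rbind, Map(one, seq_along(dv), dv)),
                  class = c("study_dataset", "data.frame"))
  v <- pc_vpc(ds, pop, type = "pk", n_sim = 40, n_bins = 3, seed = 5)
  expect_equal(nrow(v$bins), 1)
  expect_equal(as.numeric(v$bins[1, c("obs_p5", "obs_p50", "obs_p95")]),
               as.numeric(quantile(dv, c(0.05, 0.5, 0.95))),
               tolerance = 1e-9)
})

test_that("percentile curves are ordered and coverage is reported", {
  ds <- shared_study()
  pop <- default_population_model()
  v <- pc_vpc(ds, pop, type = "pk", n_sim = 60, seed = 9)
  expect_true(all(v$bins$obs_p5 <= v$bins$obs_p50 &
                    v$bins$obs_p50 <= v$bins$obs_p95))
  expect_true(v$coverage >= 0 && v$coverage <= 1)
  vb <- pc_vpc(ds, pop, type = "pd", n_sim = 60, seed = 9)
  expect_true(all(vb$bins$obs_p5 <= vb$bins$obs_p50 &
                    vb$bins$obs_p50 <= vb$bins$obs_p95))
})

test_that("a grossly biased model fails the predictive check", {
  ds <- shared_study()
  biased <- population_model(pk = pk_parameters(CL = 2 * 1.01))
  v <- pc_vpc(ds, biased, type = "pk", n_sim = 80, seed = 11)
  good <- pc_vpc(ds, default_population_model(), type = "pk", n_sim = 80,
                 seed = 11)
  expect_lt(v$coverage, good$coverage)
  # the elimination-phase median must fall outside the biased band somewhere
  expect_lt(min(v$bins$cover_p50), 1)
})

test_that("fitted stages assemble into a population model", {
  fit <- shared_eval_fit()
  pop <- as_population_model(fit)
  expect_s3_class(pop, "population_model")
  expect_equal(pop$pk$V1, 2.95)
  expect_equal(pop$cov$theta_wt, 0.74)
  expect_equal(pop$res$pk_sigma2, 0.26)
})
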