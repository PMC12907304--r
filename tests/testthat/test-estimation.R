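# --- the generic FOCE-I engine -------------------------------------------

test_that("FOCE-I equals the exact marginal likelihood on a linear model", {
  # random-intercept model with additive error: the Laplace approximation is
  # exact, so the OFV must match the closed-form multivariate-normal -2LL
  set.seed(5)
  mu <- 10; om2 <- 4; s2 <- 2.25; n_i <- 6; N <- 12
  subs <- lapply(seq_len(N), function(i) {
    y <- mu + rnorm(1, 0, sqrt(om2)) + rnorm(n_i, 0, sqrt(s2))
    list(dv = y,
         predict = function(eta) list(f = rep(mu, n_i) + eta[1],
                                      F = matrix(1, n_i, 1)))
  })
  got <- ofv_focei_generic(subs, omega = matrix(om2, 1, 1), sigma2 = s2,
                           error = "additive")
  exact <- sum(vapply(subs, function(s) {
    S <- s2 * diag(n_i) + om2
    r <- s$dv - mu
    determinant(2 * pi * S, logarithm = TRUE)$modulus[1] +
      drop(r %*% solve(S, r))
  }, numeric(1)))
  expect_equal(got$ofv, exact, tolerance = 1e-4 / abs(exact))
  # conditional modes are the known ridge-shrunken subject means
  shrink <- om2 / (om2 + s2 / n_i)
  means <- vapply(subs, function(s) mean(s$dv) - mu, numeric(1))
  expect_equal(as.numeric(got$eta), shrink * means, tolerance = 1e-6)
})

test_that("a single Gaussian observation matches the hand-written density", {
  # one observation, no random-effect information -> ofv is the scalar
  # normal -2 log density marginalised over eta (here eta has no effect)
  y <- 3.7; mu <- 3.0; s2 <- 0.49
  subs <- list(list(dv = y,
                    predict = function(eta) list(f = mu, F = matrix(0, 1, 1))))
  got <- ofv_focei_generic(subs, omega = matrix(1e-8, 1, 1), sigma2 = s2,
                           error = "additive")
  expect_equal(got$ofv, log(2 * pi * s2) + (y - mu)^2 / s2, tolerance = 1e-6)
})

# --- the PK-specific compiled path ---------------------------------------

test_that("compiled inner solver agrees with the R reference objective", {
  ds <- shared_study()
  omega2 <- c(V1 = 0.06, V2 = 0.11, V3 = 0.11, CL = 0.03, Q2 = 0.03,
              Q3 = 0.02)
  fit <- shared_eval_fit()
  # at the conditional mode, the compiled conditional -2 log density must
  # equal inner_objective evaluated in plain R
  for (id in c(1, 7, 20)) {
    s <- fit$subjects[[id]]
    r <- cipropkpd:::.focei_pk_subject_cpp(
      fit$theta * cipropkpd:::.subject_factors(
        s, fit$covariates, c(0.74, -0.21)),
      match(names(omega2), c("V1", "V2", "V3", "CL", "Q2", "Q3")) - 1L,
      s$events, s$times, s$dv, diag(omega2), 0.26, numeric(6), 100, 1e-9)
    ref <- inner_objective(ds, id, table2_pk(), omega2, 0.26,
                           eta = as.numeric(r$eta),
                           covariates = final_cl_covariates())
    expect_equal(r$cond2ll, ref, tolerance = 1e-8)
    # the mode is a minimum of the R-side objective too
    for (k in 1:6) {
      bump <- numeric(6); bump[k] <- 0.05
      expect_gt(inner_objective(ds, id, table2_pk(), omega2, 0.26,
                                as.numeric(r$eta) + bump,
                                covariates = final_cl_covariates()), ref)
    }
  }
})

test_that("vanishing prior reduces the inner objective to the residual term", {
  ds <- shared_study()
  omega_big <- c(V1 = 1e6, V2 = 1e6, V3 = 1e6, CL = 1e6, Q2 = 1e6, Q3 = 1e6)
  v <- inner_objective(ds, 1, table2_pk(), omega_big, 0.26, eta = rep(0, 6),
                       covariates = final_cl_covariates())
  s <- cipropkpd:::.split_subjects(ds, 1)[[1]]
  th <- unlist(table2_pk())
  th["CL"] <- individual_cl(1.01, covariate_model(), s$wt, s$age)
  f <- cipropkpd:::.sim_cp(th, 1, s$events, s$times)
  g <- 0.26 * f^2
  resid_term <- sum(log(2 * pi * g) + (s$dv - f)^2 / g)
  prior_term <- 6 * log(2 * pi) + sum(log(omega_big))
  expect_equal(v - prior_term, resid_term, tolerance = 1e-8)
})

test_that("doubling sigma2 shifts the conditional objective algebraically", {
  # for fixed eta: sum log g doubles -> + n log 2, residual quadratic halves
  ds <- shared_study()
  eta <- rep(0.01, 6)
  omega2 <- c(V1 = 0.06, V2 = 0.11, V3 = 0.11, CL = 0.03, Q2 = 0.03,
              Q3 = 0.02)
  v1 <- inner_objective(ds, 2, table2_pk(), omega2, 0.26, eta)
  v2 <- inner_objective(ds, 2, table2_pk(), omega2, 0.52, eta)
  s <- cipropkpd:::.split_subjects(ds, 1)[[2]]
  f <- cipropkpd:::.sim_cp(unlist(table2_pk()), 1, s$events, s$times)
  # recompute the two pieces directly
  th <- unlist(table2_pk()); th[names(omega2)] <- th[names(omega2)] * exp(eta)
  fi <- cipropkpd:::.sim_cp(th, 1, s$events, s$times)
  quad <- sum((s$dv - fi)^2 / (0.26 * fi^2))
  n <- length(s$dv)
  expect_equal(v2 - v1, n * log(2) - quad / 2, tolerance = 1e-8)
})

test_that("OFV is invariant to subject relabeling and row order", {
  ds <- generate_study(study_design(n_subjects = 6), seed = 61)
  base <- ofv_focei(ds, omega2 = c(V1 = 0.06, CL = 0.03), sigma2 = 0.26)
  perm <- as.data.frame(ds)
  perm$ID <- c(4, 5, 6, 1, 2, 3)[perm$ID]
  perm <- perm[order(perm$ID, perm$TIME, perm$EVID), ]
  relab <- ofv_focei(structure(perm, class = c("study_dataset", "data.frame")),
                     omega2 = c(V1 = 0.06, CL = 0.03), sigma2 = 0.26)
  expect_equal(as.numeric(base), as.numeric(relab), tolerance = 1e-8)
})

test_that("degenerate random effects reduce the OFV to pooled least squares", {
  ds <- generate_study(study_design(n_subjects = 5), seed = 62)
  tiny <- ofv_focei(ds, omega2 = c(V1 = 1e-10, CL = 1e-10), sigma2 = 0.26)
  pooled <- 0
  for (s in cipropkpd:::.split_subjects(ds, 1)) {
    if (!length(s$dv)) next
    f <- cipropkpd:::.sim_cp(unlist(table2_pk()), 1, s$events, s$times)
    g <- 0.26 * f^2
    pooled <- pooled + sum(log(2 * pi * g) + (s$dv - f)^2 / g)
  }
  expect_equal(as.numeric(tiny), pooled, tolerance = 1e-4)
})

# --- outer optimisation ---------------------------------------------------

test_that("noise-free data are recovered to the exact-fit limit", {
  ds <- generate_study(study_design(n_subjects = 3), noiseless_population(),
                       seed = 3)
  init <- pk_parameters(V1 = 3.3, V2 = 41, V3 = 70, CL = 1.1, Q2 = 0.68,
                        Q3 = 0.73)
  fit <- fit_pk(ds, init = init, covariates = final_cl_covariates(),
                omega2_init = c(V1 = 0), sigma2_init = 1e-6,
                estimate_omega = FALSE, estimate_sigma = FALSE,
                settings = fit_settings(outer_tol = 1e-12,
                                        outer_maxit = 2000,
                                        outer_maxeval = 20000))
  truth <- unlist(table2_pk())
  expect_true(all(abs(fit$theta - truth) / truth < 1e-3))
  phis <- vapply(fit$covariates, `[[`, numeric(1), "estimate")
  expect_equal(phis, c(0.74, -0.21), tolerance = 2e-3,
               ignore_attr = TRUE)
})

test_that("the true model beats a x1.5 perturbation in OFV", {
  ds <- shared_study()
  at_truth <- ofv_focei(ds, table2_pk(), covariates = final_cl_covariates())
  perturbed <- ofv_focei(
    ds, pk_parameters(V1 = 2.95 * 1.5, V2 = 45.15 * 1.5, V3 = 76.79 * 1.5,
                      CL = 1.01 * 1.5, Q2 = 0.76 * 1.5, Q3 = 0.66 * 1.5),
    covariates = final_cl_covariates())
  expect_lt(as.numeric(at_truth), as.numeric(perturbed))
})

test_that("different starting points reach the same optimum", {
  ds <- generate_study(study_design(n_subjects = 8),
                       population_model(omega2 = c(V1 = 0.06, CL = 0.03),
                                        res = residual_model(0.09, 4)),
                       seed = 64)
  inits <- list(pk_parameters(),
                pk_parameters(V1 = 4.2, V2 = 30, V3 = 110, CL = 1.45,
                              Q2 = 0.5, Q3 = 0.95))
  fits <- lapply(inits, function(ini)
    fit_pk(ds, init = ini, omega2_init = c(V1 = 0.06, CL = 0.03),
           sigma2_init = 0.09))
  expect_equal(fits[[1]]$ofv, fits[[2]]$ofv, tolerance = 1e-4)
  # the peripheral branch lies on a likelihood ridge; compare the
  # identified parameters
  for (p in c("V1", "CL"))
    expect_equal(fits[[1]]$theta[[p]], fits[[2]]$theta[[p]],
                 tolerance = 0.02)
})

# --- sequential PD --------------------------------------------------------

test_that("noise-free BIS data recover the PD parameters", {
  pop0 <- noiseless_population()
  ds <- generate_study(study_design(n_subjects = 6), pop0, seed = 71)
  ipk <- attr(ds, "truth")[, c("ID", "V1", "V2", "V3", "CL", "Q2", "Q3")]
  fit <- fit_pd_sequential(ds, ipk,
                           init = pd_parameters(ke0 = 0.8, E0 = 90,
                                                Emax = 50, EC50 = 260,
                                                gamma = 2.5),
                           omega2_init = c(EC50 = 0), sigma2_init = 1e-6,
                           estimate_omega = FALSE, estimate_sigma = FALSE,
                           settings = fit_settings(outer_tol = 1e-12,
                                                   outer_maxit = 2000,
                                                   outer_maxeval = 20000))
  truth <- c(KE0 = 1.09, E0 = 93.40, EMAX = 45.77, EC50 = 233.91,
             GAMMA = 3.00)
  expect_true(all(abs(fit$theta - truth) / truth < 5e-3))
})

test_that("freeing the variance components never worsens the OFV", {
  ds <- generate_study(study_design(n_subjects = 8), seed = 72)
  ipk <- attr(ds, "truth")[, c("ID", "V1", "V2", "V3", "CL", "Q2", "Q3")]
  fixed <- fit_pd_sequential(ds, ipk, omega2_init = c(EC50 = 0.02,
                                                      GAMMA = 0.05),
                             sigma2_init = 12, estimate_omega = FALSE,
                             estimate_sigma = FALSE)
  free <- fit_pd_sequential(ds, ipk, omega2_init = c(EC50 = 0.02,
                                                     GAMMA = 0.05),
                            sigma2_init = 12)
  expect_lte(free$ofv, fixed$ofv + 1e-6) # nested models
})

test_that("shrinkage behaves at its limits", {
  fit <- shared_eval_fit()
  sh <- shrinkage(fit)
  expect_true(all(sh$eta > -20 & sh$eta < 100))
  expect_true(sh$eps > -20 && sh$eps < 100)
  # near-degenerate omega pins the modes at zero: shrinkage towards 100%
  tiny <- evaluate_pk_model(shared_study(), table2_pk(),
                            omega2 = c(V1 = 1e-8, V2 = 1e-8, V3 = 1e-8,
                                       CL = 1e-8, Q2 = 1e-8, Q3 = 1e-8),
                            sigma2 = 0.26,
                            covariates = final_cl_covariates())
  expect_true(all(shrinkage(tiny)$eta > 90))
})

test_that("fit serialization carries the estimates", {
  fit <- shared_eval_fit()
  path <- tempfile(fileext = ".json")
  write_fit_json(fit, path)
  rt <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(rt$theta$V1, 2.95)
  expect_equal(rt$ofv, fit$ofv, tolerance = 1e-10)
  expect_equal(nrow(as.data.frame(rt$individual)), 20)
})
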