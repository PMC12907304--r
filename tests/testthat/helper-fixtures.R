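# Shared fixtures. Everything is generated in code at test time; the one
# full-size study simulated under the published final model is cached and
# reused across test files.

table2_pk <- function() pk_parameters(V1 = 2.95, V2 = 45.15, V3 = 76.79,
                                      CL = 1.01, Q2 = 0.76, Q3 = 0.66)
table3_pd <- function() pd_parameters(ke0 = 1.09, E0 = 93.40, Emax = 45.77,
                                      EC50 = 233.91, gamma = 3.00)

# deterministic population (no IIV, no residual noise)
noiseless_population <- function() {
  population_model(omega2 = c(V1 = 0), res = residual_model(0, 0))
}

# null covariate population with reduced IIV, used by covariate-search tests
null_cov_population <- function(omega2 = c(CL = 0.03),
                                res = residual_model(0.09, 4)) {
  population_model(cov = covariate_model(theta_wt = 0, theta_age = 0),
                   omega2 = omega2, res = res)
}

.fixture_env <- new.env(parent = emptyenv())

# one full-size study under the published final model, shared by the
# estimation and diagnostics tests
shared_study <- function() {
  if (is.null(.fixture_env$study))
    .fixture_env$study <- generate_study(study_design(),
                                         default_population_model(),
                                         seed = 20260901)
  .fixture_env$study
}

# the published model evaluated (not re-estimated) on the shared study
shared_eval_fit <- function() {
  if (is.null(.fixture_env$eval_fit))
    .fixture_env$eval_fit <- evaluate_pk_model(
      shared_study(), pk = table2_pk(), covariates = final_cl_covariates())
  .fixture_env$eval_fit
}

# random admissible PK parameter draws for property-style tests
random_pk <- function() {
  pk_parameters(V1 = runif(1, 1, 10), V2 = runif(1, 10, 80),
                V3 = runif(1, 20, 150), CL = runif(1, 0.3, 2),
                Q2 = runif(1, 0.2, 2), Q3 = runif(1, 0.2, 2))
}

random_regimen <- function(wt = 66) {
  study_regimen(wt, maintenance_duration = runif(1, 60, 180))
}
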