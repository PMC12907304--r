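#' Covariate model for clearance
#'
#' Power-function covariate model on elimination clearance, centred at the
#' cohort reference values embedded in the published equation:
#' `CL = theta_CL * (WT/66)^0.74 * (AGE/72.5)^(-0.21)`.
#'
#' @param ref_wt reference body weight (kg).
#' @param ref_age reference age (years).
#' @param theta_wt weight exponent on CL.
#' @param theta_age age exponent on CL.
#' @return a `covariate_model` object.
#' @export
covariate_model <- function(ref_wt = 66, ref_age = 72.5,
                            theta_wt = 0.74, theta_age = -0.21) {
  .assert_scalar_pos(ref_wt, "ref_wt")
  .assert_scalar_pos(ref_age, "ref_age")
  structure(list(ref_wt = ref_wt, ref_age = ref_age,
                 theta_wt = theta_wt, theta_age = theta_age),
            class = "covariate_model")
}

#' Individual clearance from the covariate model
#'
#' `CL_i = theta_cl * (wt/ref_wt)^theta_wt * (age/ref_age)^theta_age *
#' exp(eta_cl)`. Monotone increasing in weight and decreasing in age for the
#' published exponent signs.
#'
#' @param theta_cl population typical clearance (L/min).
#' @param cov a [covariate_model()].
#' @param wt body weight (kg), > 0.
#' @param age age (years), > 0.
#' @param eta_cl individual log-scale random effect (default 0).
#' @return clearance in L/min.
#' @examples
#' individual_cl(1.01, covariate_model(), wt = 66, age = 72.5) # typical value
#' @export
individual_cl <- function(theta_cl, cov, wt, age, eta_cl = 0) {
  .assert_scalar_pos(theta_cl, "theta_cl")
  if (!inherits(cov, "covariate_model"))
    stop("`cov` must be a `covariate_model`", call. = FALSE)
  if (any(wt <= 0) || any(age <= 0))
    stop("covariates `wt` and `age` must be strictly positive", call. = FALSE)
  theta_cl * (wt / cov$ref_wt)^cov$theta_wt *
    (age / cov$ref_age)^cov$theta_age * exp(eta_cl)
}

#' Residual-error model
#'
#' Proportional error for plasma concentrations,
#' `C_obs = C_pred * (1 + eps)`, and additive error for BIS,
#' `BIS_obs = BIS_pred + eps`, with `eps ~ N(0, sigma^2)`. Published residual
#' magnitudes are interpreted as variances by default (`convention =
#' "variance"`); set `convention = "sd"` to read them as standard deviations.
#'
#' @param pk_sigma2 proportional-error magnitude for concentrations.
#' @param pd_sigma2 additive-error magnitude for BIS.
#' @param convention how the supplied magnitudes are interpreted.
#' @return a `residual_model` with elements `pk_sigma2`, `pd_sigma2` stored as
#'   variances.
#' @export
residual_model <- function(pk_sigma2 = 0.26, pd_sigma2 = 7.70,
                           convention = c("variance", "sd")) {
  convention <- match.arg(convention)
  .assert_scalar_pos(pk_sigma2, "pk_sigma2", strict = FALSE)
  .assert_scalar_pos(pd_sigma2, "pd_sigma2", strict = FALSE)
  if (convention == "sd") {
    pk_sigma2 <- pk_sigma2^2
    pd_sigma2 <- pd_sigma2^2
  }
  structure(list(pk_sigma2 = pk_sigma2, pd_sigma2 = pd_sigma2,
                 convention = convention),
            class = "residual_model")
}

#' Variance of an observation under the residual model
#'
#' The variance function consumed by the FOCE-I estimator: proportional error
#' gives `sigma2_pk * pred^2`, additive error gives `sigma2_pd`.
#'
#' @param pred model prediction(s).
#' @param kind `"pk"` (proportional) or `"pd"` (additive).
#' @param res a [residual_model()].
#' @return variance(s), same length as `pred`.
#' @export
residual_variance <- function(pred, kind = c("pk", "pd"), res = residual_model()) {
  kind <- match.arg(kind)
  if (!inherits(res, "residual_model"))
    stop("`res` must be a `residual_model`", call. = FALSE)
  if (any(!is.finite(pred))) stop("`pred` must be finite", call. = FALSE)
  if (kind == "pk") {
    if (any(pred < 0)) stop("PK predictions must be non-negative", call. = FALSE)
    res$pk_sigma2 * pred^2
  } else {
    rep(res$pd_sigma2, length(pred))
  }
}

#' Add residual error to predictions
#'
#' @param pred model prediction(s).
#' @param kind `"pk"` or `"pd"`.
#' @param res a [residual_model()].
#' @return noisy observation(s); draws come from the current RNG stream.
#' @rdname residual_variance
#' @export
apply_residual <- function(pred, kind = c("pk", "pd"), res = residual_model()) {
  kind <- match.arg(kind)
  if (!inherits(res, "residual_model"))
    stop("`res` must be a `residual_model`", call. = FALSE)
  if (any(!is.finite(pred))) stop("`pred` must be finite", call. = FALSE)
  n <- length(pred)
  if (kind == "pk") {
    if (any(pred < 0)) stop("PK predictions must be non-negative", call. = FALSE)
    pred * (1 + rnorm(n, 0, sqrt(res$pk_sigma2)))
  } else {
    pred + rnorm(n, 0, sqrt(res$pd_sigma2))
  }
}

# parameters that may carry inter-individual variability
.OMEGA_PARAMS <- c("V1", "V2", "V3", "CL", "Q2", "Q3", "EC50", "GAMMA")

#' Population PK/PD model
#'
#' Bundles the fixed-effect structural parameters, the covariate model on CL,
#' the diagonal log-normal inter-individual variance matrix and the residual
#' error models into one object used by the study generator, the estimator
#' initialisation, the predictive checks and the dose simulations. Defaults
#' are the published final-model estimates for elderly patients.
#'
#' IIV is carried on the six PK parameters and, for PD, on EC50 and gamma only
#' (baseline, Emax and ke0 have no reported between-subject variability).
#'
#' @param pk a [pk_parameters()].
#' @param pd a [pd_parameters()].
#' @param cov a [covariate_model()].
#' @param omega2 named vector of log-scale variances; names among
#'   `r paste(.OMEGA_PARAMS, collapse = ", ")`. Entries may be 0 (no IIV).
#' @param res a [residual_model()].
#' @return a `population_model` object.
#' @examples
#' pop <- default_population_model()
#' sample_individual(pop, wt = 70, age = 75, seed = 1)
#' @export
population_model <- function(pk = pk_parameters(), pd = pd_parameters(),
                             cov = covariate_model(),
                             omega2 = c(V1 = 0.06, V2 = 0.11, V3 = 0.11,
                                        CL = 0.03, Q2 = 0.03, Q3 = 0.02,
                                        EC50 = 0.09, GAMMA = 0.02),
                             res = residual_model()) {
  stopifnot(inherits(pk, "pk_parameters"), inherits(pd, "pd_parameters"),
            inherits(cov, "covariate_model"), inherits(res, "residual_model"))
  if (is.null(names(omega2)) || !all(names(omega2) %in% .OMEGA_PARAMS))
    stop("`omega2` must be named with parameters among: ",
         paste(.OMEGA_PARAMS, collapse = ", "), call. = FALSE)
  if (any(omega2 < 0))
    stop("`omega2` entries must be non-negative variances", call. = FALSE)
  full <- setNames(numeric(length(.OMEGA_PARAMS)), .OMEGA_PARAMS)
  full[names(omega2)] <- omega2
  structure(list(pk = pk, pd = pd, cov = cov, omega2 = full, res = res),
            class = "population_model")
}

#' @rdname population_model
#' @export
default_population_model <- function() population_model()

#' Sample an individual from the population model
#'
#' Draws the log-normal random effects `eta ~ N(0, omega2)` (independent
#' across parameters, matching the diagonal variance structure) and applies
#' the covariate model, giving `theta_i = theta_pop * covariate factor *
#' exp(eta_i)`. All sampled parameters are strictly positive by construction.
#' The median (not the mean) of sampled parameters equals the typical value at
#' the reference covariates.
#'
#' @param pop a [population_model()].
#' @param wt body weight (kg).
#' @param age age (years).
#' @param seed optional seed for a reproducible draw; `NULL` uses the current
#'   RNG stream.
#' @return a list with elements `pk` ([pk_parameters()]), `pd`
#'   ([pd_parameters()]) and `eta` (named vector of the realized random
#'   effects).
#' @export
sample_individual <- function(pop, wt, age, seed = NULL) {
  if (!inherits(pop, "population_model"))
    stop("`pop` must be a `population_model`", call. = FALSE)
  if (wt <= 0 || age <= 0)
    stop("covariates `wt` and `age` must be strictly positive", call. = FALSE)
  with_seed(seed, {
    eta <- rnorm(length(pop$omega2), 0, sqrt(pop$omega2))
    names(eta) <- names(pop$omega2)
    cl_typ <- individual_cl(pop$pk$CL, pop$cov, wt, age)
    pk_i <- pk_parameters(
      V1 = pop$pk$V1 * exp(eta[["V1"]]),
      V2 = pop$pk$V2 * exp(eta[["V2"]]),
      V3 = pop$pk$V3 * exp(eta[["V3"]]),
      CL = cl_typ * exp(eta[["CL"]]),
      Q2 = pop$pk$Q2 * exp(eta[["Q2"]]),
      Q3 = pop$pk$Q3 * exp(eta[["Q3"]]))
    pd_i <- pd_parameters(
      ke0 = pop$pd$ke0, E0 = pop$pd$E0, Emax = pop$pd$Emax,
      EC50 = pop$pd$EC50 * exp(eta[["EC50"]]),
      gamma = pop$pd$gamma * exp(eta[["GAMMA"]]))
    list(pk = pk_i, pd = pd_i, eta = eta)
  })
}

#' Read and write population-model configuration files
#'
#' The model is serialized to a flat YAML mapping with keys `V1, V2, V3, CL,
#' Q2, Q3, THETA_WT_CL, THETA_AGE_CL, REF_WT, REF_AGE, KE0, E0, EMAX, EC50,
#' GAMMA, OMEGA_<param>, SIGMA_PK, SIGMA_PD, SIGMA_CONVENTION`.
#'
#' @param pop a [population_model()].
#' @param path file path.
#' @return `read_population_config()` returns a [population_model()];
#'   `write_population_config()` returns `path` invisibly.
#' @export
write_population_config <- function(pop, path) {
  stopifnot(inherits(pop, "population_model"))
  om <- as.list(pop$omega2)
  names(om) <- paste0("OMEGA_", names(om))
  cfg <- c(list(V1 = pop$pk$V1, V2 = pop$pk$V2, V3 = pop$pk$V3,
                CL = pop$pk$CL, Q2 = pop$pk$Q2, Q3 = pop$pk$Q3,
                THETA_WT_CL = pop$cov$theta_wt, THETA_AGE_CL = pop$cov$theta_age,
                REF_WT = pop$cov$ref_wt, REF_AGE = pop$cov$ref_age,
                KE0 = pop$pd$ke0, E0 = pop$pd$E0, EMAX = pop$pd$Emax,
                EC50 = pop$pd$EC50, GAMMA = pop$pd$gamma),
           om,
           list(SIGMA_PK = pop$res$pk_sigma2, SIGMA_PD = pop$res$pd_sigma2,
                SIGMA_CONVENTION = "variance"))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_population_config
#' @export
read_population_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("V1", "V2", "V3", "CL", "Q2", "Q3", "KE0", "E0", "EMAX", "EC50",
            "GAMMA", "SIGMA_PK", "SIGMA_PD")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("population config is missing keys: ", paste(miss, collapse = ", "),
         call. = FALSE)
  om_keys <- grep("^OMEGA_", names(cfg), value = TRUE)
  omega2 <- setNames(vapply(cfg[om_keys], as.numeric, numeric(1)),
                     sub("^OMEGA_", "", om_keys))
  population_model(
    pk = pk_parameters(cfg$V1, cfg$V2, cfg$V3, cfg$CL, cfg$Q2, cfg$Q3),
    pd = pd_parameters(cfg$KE0, cfg$E0, cfg$EMAX, cfg$EC50, cfg$GAMMA),
    cov = covariate_model(
      ref_wt = if (is.null(cfg$REF_WT)) 66 else cfg$REF_WT,
      ref_age = if (is.null(cfg$REF_AGE)) 72.5 else cfg$REF_AGE,
      theta_wt = if (is.null(cfg$THETA_WT_CL)) 0 else cfg$THETA_WT_CL,
      theta_age = if (is.null(cfg$THETA_AGE_CL)) 0 else cfg$THETA_AGE_CL),
    omega2 = omega2,
    res = residual_model(cfg$SIGMA_PK, cfg$SIGMA_PD,
                         convention = if (is.null(cfg$SIGMA_CONVENTION))
                           "variance" else cfg$SIGMA_CONVENTION))
}
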