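#' Estimation settings
#'
#' Tolerances and iteration limits for the nested FOCE-I optimisation: the
#' outer quasi-Newton minimisation over the fixed effects and variance
#' components (on log scale) and the inner Newton-type minimisation of each
#' subject's conditional objective over its random effects.
#'
#' @param outer_tol relative tolerance of the outer optimiser.
#' @param outer_maxit maximum outer iterations.
#' @param outer_maxeval maximum outer objective evaluations.
#' @param inner_tol convergence tolerance of the inner eta search.
#' @param inner_maxit maximum inner iterations per subject.
#' @return a `fit_settings` object.
#' @export
fit_settings <- function(outer_tol = 1e-6, outer_maxit = 600,
                         outer_maxeval = 20000, inner_tol = 1e-9,
                         inner_maxit = 100) {
  stopifnot(outer_tol > 0, inner_tol > 0, outer_maxit >= 1, inner_maxit >= 1)
  structure(list(outer_tol = outer_tol, outer_maxit = outer_maxit,
                 outer_maxeval = outer_maxeval, inner_tol = inner_tol,
                 inner_maxit = inner_maxit),
            class = "fit_settings")
}

.PK_THETA <- c("V1", "V2", "V3", "CL", "Q2", "Q3")
.PD_THETA <- c("KE0", "E0", "EMAX", "EC50", "GAMMA")

#' Covariate term for the structural PK model
#'
#' Continuous covariates enter as power functions centred at a reference
#' value, `theta * (cov/ref)^phi`; categorical (0/1) covariates as fractional
#' shifts, `theta * (1 + phi * cov)`. With `ref = NULL` the reference is the
#' cohort median, computed from the dataset at fit time.
#'
#' @param param structural parameter the covariate acts on (e.g. `"CL"`).
#' @param covariate dataset column name (e.g. `"WT"`, `"AGE"`, `"SEX"`).
#' @param ref reference (centering) value for power terms.
#' @param init initial exponent / shift; also the fixed value when the term is
#'   not estimated.
#' @param form `"power"` or `"fractional"`.
#' @return a `covariate_term` object.
#' @examples
#' # the published final-model covariates: weight and age on clearance
#' final_cl_covariates()
#' @export
covariate_term <- function(param, covariate, ref = NULL, init = 0,
                           form = c("power", "fractional")) {
  form <- match.arg(form)
  if (!param %in% .PK_THETA)
    stop("`param` must be one of: ", paste(.PK_THETA, collapse = ", "),
         call. = FALSE)
  structure(list(param = param, covariate = covariate, ref = ref,
                 init = init, form = form,
                 name = paste0(covariate, "_on_", param)),
            class = "covariate_term")
}

#' @rdname covariate_term
#' @export
final_cl_covariates <- function() {
  list(covariate_term("CL", "WT", ref = 66, init = 0.74),
       covariate_term("CL", "AGE", ref = 72.5, init = -0.21))
}

# resolve NULL refs to cohort medians; returns the term list
.resolve_cov_refs <- function(terms, subs) {
  lapply(terms, function(tm) {
    if (tm$form == "power" && is.null(tm$ref)) {
      vals <- vapply(subs, function(s) .cov_value(s, tm$covariate), numeric(1))
      tm$ref <- median(vals)
    }
    tm
  })
}

.cov_value <- function(subj, name) {
  v <- switch(name, WT = subj$wt, AGE = subj$age,
              subj$covariates[[name]])
  if (is.null(v) || is.na(v))
    stop("covariate `", name, "` not available for subject ", subj$id,
         call. = FALSE)
  as.numeric(v)
}

# multiplicative covariate factors for one subject, named by PK parameter
.subject_factors <- function(subj, terms, phis) {
  fac <- setNames(rep(1, length(.PK_THETA)), .PK_THETA)
  for (k in seq_along(terms)) {
    tm <- terms[[k]]
    v <- .cov_value(subj, tm$covariate)
    fac[tm$param] <- fac[tm$param] *
      if (tm$form == "power") (v / tm$ref)^phis[k] else 1 + phis[k] * v
  }
  fac
}

# ---------------------------------------------------------------------------
# generic FOCE-I machinery (R implementation)
# ---------------------------------------------------------------------------

# Inner Newton-type minimisation of the conditional -2 log joint density for
# one subject, with a Fisher-type (Gauss-Newton) curvature approximation and
# backtracking line search. predict_fn(eta) must return list(f, F) with F the
# n x d Jacobian df/deta. Mirrors the compiled PK-specific path.
.focei_subject_generic <- function(predict_fn, dv, omega, sigma2,
                                   error = c("additive", "proportional"),
                                   eta0 = NULL, maxit = 100, tol = 1e-8) {
  error <- match.arg(error)
  d <- nrow(omega)
  if (is.null(eta0)) eta0 <- numeric(d)
  Oinv <- solve(omega)
  ldO <- determinant(omega, logarithm = TRUE)$modulus[1]
  gfun <- function(f) {
    if (error == "proportional") pmax(sigma2 * f^2, 1e-12)
    else rep(sigma2, length(f))
  }
  obj <- function(eta, f) {
    g <- gfun(f)
    sum(log(2 * pi * g) + (dv - f)^2 / g) +
      drop(eta %*% Oinv %*% eta) + d * log(2 * pi) + ldO
  }
  eta <- eta0
  pr <- predict_fn(eta)
  val <- obj(eta, pr$f)
  conv <- FALSE
  for (it in seq_len(maxit)) {
    f <- pr$f; F <- pr$F
    g <- gfun(f); r <- dv - f
    Gd <- if (error == "proportional") 2 * sigma2 * f * F else 0 * F
    grad <- drop(crossprod(Gd, (1 - r^2 / g) / g)) -
      2 * drop(crossprod(F, r / g)) + 2 * drop(Oinv %*% eta)
    H2 <- 2 * crossprod(F, F / g) + crossprod(Gd, Gd / g^2) + 2 * Oinv
    delta <- tryCatch(solve(H2, grad), error = function(e) NULL)
    if (is.null(delta)) break
    alpha <- 1; ok <- FALSE
    for (ls in 1:30) {
      enew <- eta - alpha * delta
      pnew <- predict_fn(enew)
      vnew <- obj(enew, pnew$f)
      if (is.finite(vnew) && vnew <= val + 1e-12) { ok <- TRUE; break }
      alpha <- alpha / 2
    }
    if (!ok) { conv <- TRUE; break }
    step <- alpha * max(abs(delta)); dec <- val - vnew
    eta <- enew; pr <- pnew; val <- vnew
    if (step < tol || dec < 1e-12) { conv <- TRUE; break }
  }
  f <- pr$f; F <- pr$F; g <- gfun(f)
  Gd <- if (error == "proportional") 2 * sigma2 * f * F else 0 * F
  H2 <- 2 * crossprod(F, F / g) + crossprod(Gd, Gd / g^2) + 2 * Oinv
  ldH <- determinant(H2, logarithm = TRUE)$modulus[1]
  list(eta = eta, ofv = val - d * log(2 * pi) + ldH - d * log(2),
       cond2ll = val, pred = f, jac = F, gvec = g, converged = conv)
}

#' FOCE-I objective for a user-supplied structural model
#'
#' Computes the FOCE-I approximation to -2 log marginal likelihood for a list
#' of subjects, each described by a prediction function of the random effects.
#' This is the estimation engine stripped of the built-in PK/PD structure; it
#' is used internally for the BIS model and is exposed so that simple models
#' with a known exact marginal likelihood can be checked against it.
#'
#' @param subjects list; each element a list with `dv` (observations) and
#'   `predict`, a function of `eta` returning `list(f, F)` (prediction vector
#'   and its Jacobian with respect to `eta`).
#' @param omega random-effect covariance matrix (d x d).
#' @param sigma2 residual variance parameter.
#' @param error `"additive"` or `"proportional"`.
#' @param settings a [fit_settings()] (inner controls are used).
#' @return list with `ofv` (total), `eta` (matrix of conditional modes) and
#'   `subjects` (per-subject detail lists).
#' @export
ofv_focei_generic <- function(subjects, omega, sigma2,
                              error = c("additive", "proportional"),
                              settings = fit_settings()) {
  error <- match.arg(error)
  omega <- as.matrix(omega)
  res <- lapply(subjects, function(s)
    .focei_subject_generic(s$predict, s$dv, omega, sigma2, error,
                           eta0 = s$eta0, maxit = settings$inner_maxit,
                           tol = settings$inner_tol))
  list(ofv = sum(vapply(res, `[[`, numeric(1), "ofv")),
       eta = do.call(rbind, lapply(res, `[[`, "eta")),
       subjects = res)
}

# ---------------------------------------------------------------------------
# PK model objective
# ---------------------------------------------------------------------------

# Subject-typical parameter matrix (n_subjects x 6) with covariate factors
.theta_matrix <- function(subs, theta, terms, phis) {
  t(vapply(subs, function(s) theta * .subject_factors(s, terms, phis),
           numeric(6)))
}

# Subject-level OFV contributions for the three-compartment model with
# proportional error; compiled inner loop, warm-started from `cache`. The
# non-detail path goes through a single batched C++ call per evaluation.
.pk_ofv_eval <- function(subs, theta, phis, terms, omega2, sigma2, settings,
                         cache = NULL, detail = FALSE) {
  eta_params <- names(omega2)
  d <- length(eta_params)
  eta_idx <- match(eta_params, .PK_THETA) - 1L
  omega <- diag(omega2, nrow = d)
  n <- length(subs)

  if (!detail && d > 0) {
    if (!is.null(cache) && is.null(cache$packed))
      cache$packed <- list(events = lapply(subs, `[[`, "events"),
                           times = lapply(subs, `[[`, "times"),
                           dv = lapply(subs, `[[`, "dv"))
    pk <- if (!is.null(cache)) cache$packed else
      list(events = lapply(subs, `[[`, "events"),
           times = lapply(subs, `[[`, "times"),
           dv = lapply(subs, `[[`, "dv"))
    warm <- if (!is.null(cache) && !is.null(cache$eta_mat)) cache$eta_mat
            else matrix(0, n, d)
    r <- .focei_pk_all_cpp(.theta_matrix(subs, theta, terms, phis), eta_idx,
                           pk$events, pk$times, pk$dv, omega, sigma2, warm,
                           settings$inner_maxit, settings$inner_tol)
    if (!is.null(cache)) cache$eta_mat <- r$eta
    return(r$ofv)
  }

  total <- 0
  out <- if (detail) vector("list", n)
  for (i in seq_len(n)) {
    s <- subs[[i]]
    th <- theta * .subject_factors(s, terms, phis)
    if (d > 0) {
      eta0 <- if (!is.null(cache) && !is.null(cache$eta_mat))
        cache$eta_mat[i, ] else numeric(d)
      r <- .focei_pk_subject_cpp(th, eta_idx, s$events, s$times, s$dv,
                                 omega, sigma2, eta0,
                                 settings$inner_maxit, settings$inner_tol)
    } else { # no random effects: pooled extended least squares
      f <- .sim_cp(th, 1, s$events, s$times)
      g <- pmax(sigma2 * f^2, 1e-12)
      r <- list(eta = numeric(0),
                ofv = sum(log(2 * pi * g) + (s$dv - f)^2 / g),
                cond2ll = NA_real_, pred = f,
                jac = matrix(0, length(f), 0), gvec = g, converged = TRUE)
    }
    total <- total + r$ofv
    if (detail) out[[i]] <- r
  }
  if (detail) list(ofv = total, subjects = out) else total
}

#' FOCE-I objective function value for the PK model
#'
#' Evaluates (without optimising the fixed effects) the FOCE-I approximation
#' to -2 log marginal likelihood of the concentration data under the
#' three-compartment model: for each subject the conditional objective is
#' minimised over its random effects and the Laplace-type curvature correction
#' is added. Deterministic given the data. Subjects whose inner search fails
#' to converge are reported in the `unreliable` attribute.
#'
#' @param dataset a `study_dataset` (or any event-format data.frame).
#' @param pk a [pk_parameters()] object with the fixed effects.
#' @param omega2 named vector of log-normal IIV variances (subset of
#'   `V1, V2, V3, CL, Q2, Q3`); entries must be > 0.
#' @param sigma2 proportional residual variance.
#' @param covariates list of [covariate_term()]s; their `init` values are used
#'   as fixed exponents.
#' @param settings a [fit_settings()].
#' @return the OFV (scalar) with attribute `unreliable` (integer vector of
#'   subject ids whose inner optimisation did not converge).
#' @export
ofv_focei <- function(dataset, pk = pk_parameters(),
                      omega2 = c(V1 = 0.06, V2 = 0.11, V3 = 0.11, CL = 0.03,
                                 Q2 = 0.03, Q3 = 0.02),
                      sigma2 = 0.26, covariates = list(),
                      settings = fit_settings()) {
  stopifnot(inherits(pk, "pk_parameters"))
  subs <- .split_subjects(dataset, cmt = 1)
  subs <- subs[vapply(subs, function(s) length(s$dv) > 0, logical(1))]
  if (!length(subs))
    stop("no quantifiable concentration observations in `dataset`",
         call. = FALSE)
  covariates <- .resolve_cov_refs(covariates, subs)
  phis <- vapply(covariates, `[[`, numeric(1), "init")
  theta <- setNames(unlist(pk[.PK_THETA]), .PK_THETA)
  det <- .pk_ofv_eval(subs, theta, phis, covariates,
                      omega2[omega2 > 0], sigma2, settings, detail = TRUE)
  bad <- vapply(det$subjects, function(r) !isTRUE(r$converged), logical(1))
  structure(det$ofv,
            unreliable = vapply(subs[bad], `[[`, numeric(1), "id"))
}

#' Conditional objective of one subject at a given eta
#'
#' The quantity minimised by the inner FOCE-I step: -2 log of the joint
#' density of the subject's residuals (with the residual variance evaluated at
#' the eta-dependent prediction, i.e. with interaction) plus the random-effect
#' prior term `eta' Omega^-1 eta + log|2 pi Omega|`. Implemented directly in R
#' and therefore usable as an independent check on the compiled inner solver.
#'
#' @param dataset event-format dataset.
#' @param id subject identifier within `dataset`.
#' @param pk fixed effects ([pk_parameters()]).
#' @param omega2 named IIV variances (> 0).
#' @param sigma2 proportional residual variance.
#' @param eta random-effect vector, ordered as `names(omega2)`.
#' @param covariates list of [covariate_term()]s (fixed at their `init`).
#' @return scalar objective value.
#' @export
inner_objective <- function(dataset, id, pk, omega2, sigma2, eta,
                            covariates = list()) {
  subs <- .split_subjects(dataset, cmt = 1)
  s <- subs[[match(id, vapply(subs, `[[`, numeric(1), "id"))]]
  covariates <- .resolve_cov_refs(covariates, subs)
  phis <- vapply(covariates, `[[`, numeric(1), "init")
  theta <- setNames(unlist(pk[.PK_THETA]), .PK_THETA) *
    .subject_factors(s, covariates, phis)
  eta_params <- names(omega2)
  if (length(eta) != length(eta_params))
    stop("`eta` must have one element per `omega2` entry", call. = FALSE)
  omega <- diag(omega2, nrow = length(omega2))
  if (any(omega2 <= 0)) stop("`omega2` entries must be > 0", call. = FALSE)
  th <- theta
  th[eta_params] <- th[eta_params] * exp(eta)
  f <- .sim_cp(th, 1, s$events, s$times)
  g <- pmax(sigma2 * f^2, 1e-12)
  sum(log(2 * pi * g) + (s$dv - f)^2 / g) +
    drop(eta %*% solve(omega) %*% eta) +
    length(eta) * log(2 * pi) +
    determinant(omega, logarithm = TRUE)$modulus[1]
}

# Central finite-difference gradient with a step wide enough to dominate the
# truncation noise of the nested inner optimisation (the default internal
# forward differences of the PORT routines are too narrow and stall the outer
# search with spurious "false convergence").
.central_gradient <- function(objective, lower, upper, h = 1e-4) {
  function(par) {
    vapply(seq_along(par), function(k) {
      e <- h * max(1, abs(par[k]))
      up <- pmin(par[k] + e, upper[k])
      dn <- pmax(par[k] - e, lower[k])
      pp <- par
      pp[k] <- up; f1 <- objective(pp)
      pp[k] <- dn; f2 <- objective(pp)
      if (up == dn) 0 else (f1 - f2) / (up - dn)
    }, numeric(1))
  }
}

# ---------------------------------------------------------------------------
# outer optimisation: PK
# ---------------------------------------------------------------------------

#' Fit the population PK model by FOCE-I
#'
#' Quasi-Newton (PORT) minimisation of the FOCE-I objective over the log fixed
#' effects, the covariate exponents, and the log variance components. The
#' inner per-subject eta search is warm-started across outer iterations.
#'
#' @param dataset event-format dataset with concentration observations
#'   (`EVID == 0`, `CMT == 1`); BLQ-flagged rows are excluded from estimation.
#' @param init initial fixed effects ([pk_parameters()]).
#' @param covariates list of [covariate_term()]s whose exponents are estimated
#'   (e.g. [final_cl_covariates()]).
#' @param omega2_init named initial IIV variances; parameters with a zero (or
#'   absent) entry carry no random effect.
#' @param sigma2_init initial proportional residual variance.
#' @param estimate_omega,estimate_sigma set to `FALSE` to fix the variance
#'   components at their initial values.
#' @param settings a [fit_settings()].
#' @return a `pkpd_fit` object: list with `theta`, `covariates` (terms with
#'   estimated exponents), `omega2`, `sigma2`, `ofv`, `eta` (conditional
#'   modes), `shrinkage`, `subjects` (per-subject detail), `converged`,
#'   `trace`.
#' @export
fit_pk <- function(dataset, init = pk_parameters(), covariates = list(),
                   omega2_init = c(V1 = 0.06, V2 = 0.11, V3 = 0.11, CL = 0.03,
                                   Q2 = 0.03, Q3 = 0.02),
                   sigma2_init = 0.26, estimate_omega = TRUE,
                   estimate_sigma = TRUE, settings = fit_settings()) {
  stopifnot(inherits(init, "pk_parameters"), inherits(settings, "fit_settings"))
  subs <- .split_subjects(dataset, cmt = 1)
  subs <- subs[vapply(subs, function(s) length(s$dv) > 0, logical(1))]
  if (length(subs) == 0)
    stop("no quantifiable concentration observations in `dataset`",
         call. = FALSE)
  covariates <- .resolve_cov_refs(covariates, subs)
  omega2_init <- omega2_init[omega2_init > 0]
  eta_params <- names(omega2_init)
  if (!all(eta_params %in% .PK_THETA))
    stop("`omega2_init` names must be among: ",
         paste(.PK_THETA, collapse = ", "), call. = FALSE)
  nphi <- length(covariates)
  d <- length(eta_params)

  start <- c(log(unlist(init[.PK_THETA])),
             vapply(covariates, `[[`, numeric(1), "init"),
             if (estimate_omega && d) log(omega2_init),
             if (estimate_sigma) log(sigma2_init))
  lower <- c(rep(-7, 6), rep(-5, nphi),
             if (estimate_omega && d) rep(log(1e-5), d),
             if (estimate_sigma) log(1e-6))
  upper <- c(rep(12, 6), rep(5, nphi),
             if (estimate_omega && d) rep(log(5), d),
             if (estimate_sigma) log(10))
  frac <- vapply(covariates, function(tm) tm$form == "fractional", logical(1))
  if (any(frac)) lower[6 + which(frac)] <- -0.9

  decode <- function(par) {
    k <- 0
    theta <- setNames(exp(par[1:6]), .PK_THETA); k <- 6
    phis <- if (nphi) par[k + seq_len(nphi)] else numeric(0); k <- k + nphi
    om <- if (estimate_omega && d) {
      o <- exp(par[k + seq_len(d)]); k <- k + d
      setNames(o, eta_params)
    } else omega2_init
    s2 <- if (estimate_sigma) exp(par[k + 1]) else sigma2_init
    list(theta = theta, phis = phis, omega2 = om, sigma2 = s2)
  }

  cache <- new.env(parent = emptyenv())
  cache$eta <- vector("list", length(subs))
  trace <- new.env(parent = emptyenv())
  trace$n <- 0L; trace$best <- Inf; trace$log <- list()
  objective <- function(par) {
    p <- decode(par)
    v <- .pk_ofv_eval(subs, p$theta, p$phis, covariates, p$omega2, p$sigma2,
                      settings, cache = cache)
    trace$n <- trace$n + 1L
    if (is.finite(v) && v < trace$best) {
      trace$best <- v
      trace$log[[length(trace$log) + 1L]] <- c(eval = trace$n, ofv = v)
    }
    if (!is.finite(v)) 1e10 else v
  }
  gradient <- .central_gradient(objective, lower, upper)

  opt <- nlminb(start, objective, gradient = gradient,
                lower = lower, upper = upper,
                control = list(iter.max = settings$outer_maxit,
                               eval.max = settings$outer_maxeval,
                               rel.tol = settings$outer_tol))
  p <- decode(opt$par)
  det <- .pk_ofv_eval(subs, p$theta, p$phis, covariates, p$omega2, p$sigma2,
                      settings, cache = cache, detail = TRUE)

  for (k in seq_along(covariates)) covariates[[k]]$estimate <- p$phis[k]
  eta <- if (d) do.call(rbind, lapply(det$subjects, function(r)
    as.numeric(r$eta))) else matrix(0, length(subs), 0)
  if (d) colnames(eta) <- eta_params
  # population predictions (eta = 0) per subject
  pred0 <- lapply(subs, function(s)
    .sim_cp(p$theta * .subject_factors(s, covariates, p$phis), 1,
            s$events, s$times))
  subj_detail <- Map(function(s, r, p0) {
    list(id = s$id, times = s$times, dv = s$dv, events = s$events,
         wt = s$wt, age = s$age, covariates = s$covariates,
         eta = as.numeric(r$eta), ipred = as.numeric(r$pred), pred = p0,
         jac = r$jac, gvec = as.numeric(r$gvec),
         inner_converged = r$converged)
  }, subs, det$subjects, pred0)

  fit <- structure(list(
    type = "pk", theta = p$theta, covariates = covariates,
    omega2 = p$omega2, sigma2 = p$sigma2, ofv = det$ofv, eta = eta,
    eta_params = eta_params, subjects = subj_detail,
    converged = opt$convergence == 0, message = opt$message,
    n_obs = sum(lengths(lapply(subs, `[[`, "dv"))),
    n_subjects = length(subs), n_eval = trace$n,
    trace = do.call(rbind, trace$log), settings = settings,
    error = "proportional"),
    class = c("pk_fit", "pkpd_fit"))
  fit$shrinkage <- shrinkage(fit)
  fit
}

#' Evaluate the PK model at fixed estimates
#'
#' Builds a `pk_fit` object (conditional modes, predictions, OFV, shrinkage)
#' at a given set of parameter values without optimising the fixed effects --
#' the estimation-free counterpart of [fit_pk()], useful for diagnosing a
#' known or published model against a dataset.
#'
#' @inheritParams fit_pk
#' @param pk fixed effects to evaluate at.
#' @param omega2 named IIV variances (> 0 entries carry random effects).
#' @param sigma2 proportional residual variance.
#' @return a `pkpd_fit` of type `"pk"` (with `converged = NA`).
#' @export
evaluate_pk_model <- function(dataset, pk = pk_parameters(),
                              omega2 = c(V1 = 0.06, V2 = 0.11, V3 = 0.11,
                                         CL = 0.03, Q2 = 0.03, Q3 = 0.02),
                              sigma2 = 0.26, covariates = list(),
                              settings = fit_settings()) {
  stopifnot(inherits(pk, "pk_parameters"))
  subs <- .split_subjects(dataset, cmt = 1)
  subs <- subs[vapply(subs, function(s) length(s$dv) > 0, logical(1))]
  if (!length(subs))
    stop("no quantifiable concentration observations in `dataset`",
         call. = FALSE)
  covariates <- .resolve_cov_refs(covariates, subs)
  phis <- vapply(covariates, `[[`, numeric(1), "init")
  theta <- setNames(unlist(pk[.PK_THETA]), .PK_THETA)
  omega2 <- omega2[omega2 > 0]
  eta_params <- names(omega2)
  d <- length(eta_params)
  det <- .pk_ofv_eval(subs, theta, phis, covariates, omega2, sigma2, settings,
                      detail = TRUE)
  for (k in seq_along(covariates)) covariates[[k]]$estimate <- phis[k]
  eta <- if (d) do.call(rbind, lapply(det$subjects, function(r)
    as.numeric(r$eta))) else matrix(0, length(subs), 0)
  if (d) colnames(eta) <- eta_params
  pred0 <- lapply(subs, function(s)
    .sim_cp(theta * .subject_factors(s, covariates, phis), 1,
            s$events, s$times))
  subj_detail <- Map(function(s, r, p0) {
    list(id = s$id, times = s$times, dv = s$dv, events = s$events,
         wt = s$wt, age = s$age, covariates = s$covariates,
         eta = as.numeric(r$eta), ipred = as.numeric(r$pred), pred = p0,
         jac = r$jac, gvec = as.numeric(r$gvec),
         inner_converged = r$converged)
  }, subs, det$subjects, pred0)
  fit <- structure(list(
    type = "pk", theta = theta, covariates = covariates, omega2 = omega2,
    sigma2 = sigma2, ofv = det$ofv, eta = eta, eta_params = eta_params,
    subjects = subj_detail, converged = NA, message = "evaluation only",
    n_obs = sum(lengths(lapply(subs, `[[`, "dv"))),
    n_subjects = length(subs), n_eval = 1L, trace = NULL,
    settings = settings, error = "proportional"),
    class = c("pk_fit", "pkpd_fit"))
  fit$shrinkage <- shrinkage(fit)
  fit
}

#' Individual (empirical Bayes) parameters from a PK fit
#'
#' @param fit a `pk_fit`.
#' @return data.frame of per-subject PK parameters at the conditional modes.
#' @export
individual_parameters <- function(fit) {
  stopifnot(inherits(fit, "pk_fit"))
  phis <- vapply(fit$covariates, `[[`, numeric(1), "estimate")
  out <- lapply(fit$subjects, function(s) {
    th <- fit$theta * .subject_factors(s, fit$covariates, phis)
    th[fit$eta_params] <- th[fit$eta_params] * exp(s$eta)
    data.frame(ID = s$id, WT = s$wt, AGE = s$age, t(th))
  })
  do.call(rbind, out)
}

# ---------------------------------------------------------------------------
# outer optimisation: PD (sequential, individual PK parameters fixed)
# ---------------------------------------------------------------------------

# analytic prediction + Jacobian of the sigmoid Emax model in the two
# random effects (log EC50 shift, log gamma shift)
.pd_predict <- function(ce, E0, Emax, EC50, gamma) {
  function(eta) {
    ec <- EC50 * exp(eta[1])
    ga <- gamma * exp(eta[2])
    pos <- ce > 0
    lr <- ifelse(pos, log(ce / ec), 0)
    u <- ifelse(pos, exp(ga * lr), 0)
    den <- (1 + u)^2
    dEdu <- -Emax / den
    F <- cbind(dEdu * (-ga * u), dEdu * (ga * lr * u))
    list(f = E0 - Emax * u / (1 + u), F = F)
  }
}

#' Fit the BIS model sequentially by FOCE-I
#'
#' Sequential (IPP) PK/PD estimation: each subject's PK parameters are fixed
#' at the empirical Bayes estimates of a previous PK fit; the effect-site
#' concentration is computed exactly from the individual PK model for the
#' current `ke0`; and the PD fixed effects (`ke0, E0, Emax, EC50, gamma`),
#' the IIV variances on EC50 and gamma, and the additive residual variance are
#' estimated by FOCE-I on the BIS rows.
#'
#' @param dataset event-format dataset with BIS observations (`CMT == 4`).
#' @param pk_fit a converged `pk_fit` on the same dataset (or a data.frame of
#'   individual PK parameters with columns `ID, V1, V2, V3, CL, Q2, Q3`).
#' @param init initial PD fixed effects ([pd_parameters()]).
#' @param omega2_init named initial IIV variances for `EC50` and `GAMMA`.
#' @param sigma2_init initial additive residual variance (BIS^2 units).
#' @param estimate_omega,estimate_sigma fix variance components when `FALSE`.
#' @param settings a [fit_settings()].
#' @return a `pkpd_fit` of type `"pd"`.
#' @export
fit_pd_sequential <- function(dataset, pk_fit, init = pd_parameters(),
                              omega2_init = c(EC50 = 0.09, GAMMA = 0.02),
                              sigma2_init = 7.70, estimate_omega = TRUE,
                              estimate_sigma = TRUE,
                              settings = fit_settings()) {
  stopifnot(inherits(init, "pd_parameters"))
  ipk <- if (is.data.frame(pk_fit)) pk_fit else individual_parameters(pk_fit)
  subs <- .split_subjects(dataset, cmt = 4)
  subs <- subs[vapply(subs, function(s) length(s$dv) > 0, logical(1))]
  if (!length(subs))
    stop("no BIS observations (CMT == 4) in `dataset`", call. = FALSE)
  omega2_init <- omega2_init[omega2_init > 0]
  eta_params <- names(omega2_init)
  if (!all(eta_params %in% c("EC50", "GAMMA")))
    stop("PD random effects are supported on EC50 and GAMMA only",
         call. = FALSE)
  d <- length(eta_params)
  pkpars <- lapply(subs, function(s) {
    row <- ipk[ipk$ID == s$id, , drop = FALSE]
    if (nrow(row) != 1)
      stop("no individual PK parameters for subject ", s$id, call. = FALSE)
    unlist(row[1, .PK_THETA])
  })

  start <- c(log(unlist(init[c("ke0", "E0", "Emax", "EC50", "gamma")])),
             if (estimate_omega && d) log(omega2_init),
             if (estimate_sigma) log(sigma2_init))
  lower <- c(log(c(1e-3, 40, 1, 5, 0.2)),
             if (estimate_omega && d) rep(log(1e-5), d),
             if (estimate_sigma) log(1e-4))
  upper <- c(log(c(50, 100, 100, 5000, 20)),
             if (estimate_omega && d) rep(log(5), d),
             if (estimate_sigma) log(1000))

  decode <- function(par) {
    th <- setNames(exp(par[1:5]), .PD_THETA); k <- 5
    om <- if (estimate_omega && d) {
      o <- exp(par[k + seq_len(d)]); k <- k + d
      setNames(o, eta_params)
    } else omega2_init
    s2 <- if (estimate_sigma) exp(par[k + 1]) else sigma2_init
    list(theta = th, omega2 = om, sigma2 = s2)
  }

  # map (EC50, GAMMA) onto the 2-d eta of .pd_predict; absent effects pinned
  expand_omega <- function(om) {
    o2 <- c(EC50 = 1e-10, GAMMA = 1e-10)
    o2[names(om)] <- om
    diag(o2, nrow = 2)
  }

  cache <- new.env(parent = emptyenv())
  cache$eta_mat <- matrix(0, length(subs), 2)
  dv_list <- lapply(subs, `[[`, "dv")
  trace <- new.env(parent = emptyenv()); trace$n <- 0L
  ce_for <- function(ke0) lapply(seq_along(subs), function(i)
    pmax(.sim_amounts_cpp(c(pkpars[[i]], ke0), subs[[i]]$events,
                          subs[[i]]$times)[, 4], 0))
  # hot path: batched compiled inner solves; the detail pass below re-derives
  # every subject through the generic R engine (same mathematics)
  eval_all <- function(p, detail = FALSE) {
    omega <- expand_omega(p$omega2)
    ce_list <- ce_for(p$theta[["KE0"]])
    if (!detail) {
      r <- .focei_pd_all_cpp(ce_list, dv_list, p$theta[["E0"]],
                             p$theta[["EMAX"]], p$theta[["EC50"]],
                             p$theta[["GAMMA"]], omega, p$sigma2,
                             cache$eta_mat, settings$inner_maxit,
                             settings$inner_tol)
      cache$eta_mat <- r$eta
      return(r$ofv)
    }
    total <- 0
    out <- vector("list", length(subs))
    for (i in seq_along(subs)) {
      s <- subs[[i]]
      pf <- .pd_predict(ce_list[[i]], p$theta["E0"], p$theta["EMAX"],
                        p$theta["EC50"], p$theta["GAMMA"])
      r <- .focei_subject_generic(pf, s$dv, omega, p$sigma2, "additive",
                                  eta0 = cache$eta_mat[i, ],
                                  maxit = settings$inner_maxit,
                                  tol = settings$inner_tol)
      total <- total + r$ofv
      r$ce <- ce_list[[i]]
      out[[i]] <- r
    }
    list(ofv = total, subjects = out)
  }
  objective <- function(par) {
    trace$n <- trace$n + 1L
    v <- eval_all(decode(par))
    if (!is.finite(v)) 1e10 else v
  }
  gradient <- .central_gradient(objective, lower, upper)

  opt <- nlminb(start, objective, gradient = gradient,
                lower = lower, upper = upper,
                control = list(iter.max = settings$outer_maxit,
                               eval.max = settings$outer_maxeval,
                               rel.tol = settings$outer_tol))
  p <- decode(opt$par)
  det <- eval_all(p, detail = TRUE)
  eta <- do.call(rbind, lapply(det$subjects, function(r)
    r$eta[match(eta_params, c("EC50", "GAMMA"))]))
  if (d) colnames(eta) <- eta_params

  subj_detail <- Map(function(s, r, pk_i) {
    pred0 <- .pd_predict(r$ce, p$theta["E0"], p$theta["EMAX"],
                         p$theta["EC50"], p$theta["GAMMA"])(c(0, 0))$f
    list(id = s$id, times = s$times, dv = s$dv, events = s$events,
         wt = s$wt, age = s$age, covariates = s$covariates, ce = r$ce,
         eta = r$eta[match(eta_params, c("EC50", "GAMMA"))],
         ipred = r$pred, pred = pred0,
         jac = r$jac[, match(eta_params, c("EC50", "GAMMA")), drop = FALSE],
         gvec = r$gvec, inner_converged = r$converged, pk = pk_i)
  }, subs, det$subjects, pkpars)

  fit <- structure(list(
    type = "pd", theta = p$theta, covariates = list(), omega2 = p$omega2,
    sigma2 = p$sigma2, ofv = det$ofv, eta = eta, eta_params = eta_params,
    subjects = subj_detail, converged = opt$convergence == 0,
    message = opt$message,
    n_obs = sum(lengths(lapply(subs, `[[`, "dv"))),
    n_subjects = length(subs), n_eval = trace$n, trace = NULL,
    settings = settings, error = "additive"),
    class = c("pd_fit", "pkpd_fit"))
  fit$shrinkage <- shrinkage(fit)
  fit
}

# ---------------------------------------------------------------------------

#' Eta- and epsilon-shrinkage of a fit
#'
#' `eta-shrinkage = 100 * (1 - sd(eta_hat) / omega)` per random effect, and
#' `epsilon-shrinkage = 100 * (1 - sd(IWRES))` with
#' `IWRES = (DV - IPRED) / sqrt(var)`. Values near 100% signal that the data
#' carry little individual information and conditional diagnostics are
#' untrustworthy.
#'
#' @param fit a `pkpd_fit`.
#' @return list with `eta` (named percentages) and `eps` (scalar percentage).
#' @export
shrinkage <- function(fit) {
  stopifnot(inherits(fit, "pkpd_fit"))
  eta_sh <- if (length(fit$eta_params)) {
    om <- sqrt(fit$omega2[fit$eta_params])
    100 * (1 - apply(fit$eta, 2, sd) / om)
  } else setNames(numeric(0), character(0))
  iwres <- unlist(lapply(fit$subjects, function(s)
    (s$dv - s$ipred) / sqrt(s$gvec)))
  list(eta = eta_sh, eps = 100 * (1 - sd(iwres)))
}

#' @export
print.pkpd_fit <- function(x, ...) {
  cat(sprintf("FOCE-I %s fit: %d subjects, %d observations\n",
              toupper(x$type), x$n_subjects, x$n_obs))
  cat(sprintf("  OFV %.3f  (%s, %d objective evaluations)\n", x$ofv,
              if (x$converged) "converged" else "NOT converged", x$n_eval))
  cat("  theta:\n")
  print(round(x$theta, 4))
  if (length(x$covariates)) {
    cat("  covariate exponents:\n")
    for (tm in x$covariates)
      cat(sprintf("    %s = %.4f (ref %.4g)\n", tm$name, tm$estimate,
                  if (is.null(tm$ref)) NA else tm$ref))
  }
  cat("  omega2:\n")
  print(round(x$omega2, 4))
  cat(sprintf("  sigma2: %.4f\n", x$sigma2))
  if (!is.null(x$shrinkage)) {
    cat(sprintf("  eta-shrinkage (%%): %s\n",
                paste(sprintf("%s %.1f", names(x$shrinkage$eta),
                              x$shrinkage$eta), collapse = ", ")))
    cat(sprintf("  eps-shrinkage (%%): %.1f\n", x$shrinkage$eps))
  }
  invisible(x)
}

#' Serialize a fit to JSON
#'
#' Writes estimates, OFV, convergence status, shrinkage and the per-subject
#' conditional modes (plus individual parameters for PK fits) to a JSON
#' report.
#'
#' @param fit a `pkpd_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "pkpd_fit"))
  phis <- if (length(fit$covariates))
    setNames(vapply(fit$covariates, `[[`, numeric(1), "estimate"),
             vapply(fit$covariates, `[[`, character(1), "name"))
  else NULL
  obj <- list(type = fit$type, theta = as.list(fit$theta),
              covariate_exponents = as.list(phis),
              omega2 = as.list(fit$omega2), sigma2 = fit$sigma2,
              ofv = fit$ofv, converged = fit$converged,
              shrinkage = fit$shrinkage,
              eta = as.data.frame(fit$eta),
              individual = if (fit$type == "pk")
                individual_parameters(fit) else NULL)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(path)
}
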