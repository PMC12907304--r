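#' Residual diagnostics table
#'
#' One row per (non-BLQ) observation with the observed value (DV), the
#' population prediction (PRED, random effects at zero), the individual
#' prediction (IPRED, at the conditional modes), the individual weighted
#' residual (IWRES) and the conditional weighted residual (CWRES). CWRES uses
#' the FOCE linearization: the model is expanded to first order in eta around
#' the conditional mode, giving observation mean `f(eta_hat) - F eta_hat` and
#' covariance `F Omega F' + diag(g(eta_hat))`; the residual vector is
#' standardized by the Cholesky factor of that covariance. TAD is the time
#' after the most recent dose-event start.
#'
#' @param fit a `pkpd_fit` (PK or PD).
#' @return a data.frame with columns `ID, TIME, TAD, DV, PRED, IPRED, IWRES,
#'   CWRES`.
#' @export
residual_table <- function(fit) {
  stopifnot(inherits(fit, "pkpd_fit"))
  d <- length(fit$eta_params)
  omega <- diag(fit$omega2[fit$eta_params], nrow = d)
  out <- lapply(fit$subjects, function(s) {
    F <- s$jac
    covm <- diag(s$gvec, nrow = length(s$gvec))
    if (d) covm <- covm + F %*% omega %*% t(F)
    L <- tryCatch(chol(covm), error = function(e)
      stop("singular observation covariance for subject ", s$id,
           call. = FALSE))
    r <- s$dv - s$ipred + if (d) drop(F %*% s$eta) else 0
    tad <- vapply(s$times, function(t) {
      st <- s$events[, 1][s$events[, 1] <= t + 1e-9]
      if (length(st)) t - max(st) else t
    }, numeric(1))
    data.frame(ID = s$id, TIME = s$times, TAD = tad, DV = s$dv,
               PRED = s$pred, IPRED = s$ipred,
               IWRES = (s$dv - s$ipred) / sqrt(s$gvec),
               CWRES = drop(backsolve(L, r, transpose = TRUE)))
  })
  do.call(rbind, out)
}

#' Nonparametric bootstrap of the PK fit
#'
#' Resamples subjects (the exchangeable unit) with replacement, refits the
#' model on each replicate (warm-started at the original estimates), and
#' summarizes the replicate estimates by their median and 2.5th/97.5th
#' percentiles. Replicates whose outer optimisation fails are excluded and
#' counted.
#'
#' @param dataset the original event-format dataset.
#' @param fit the original `pk_fit` whose configuration is bootstrapped.
#' @param n_reps number of bootstrap replicates (>= 1).
#' @param seed optional seed; the replicate resampling is fully reproducible.
#' @param settings optional [fit_settings()] override for the refits.
#' @return a `bootstrap_result`: list with `estimates` (replicate x parameter
#'   matrix), `summary` (median, lo, hi per parameter), `n_failed`,
#'   `convergence_fraction`.
#' @export
bootstrap <- function(dataset, fit, n_reps = 1000, seed = NULL,
                      settings = NULL) {
  stopifnot(inherits(fit, "pk_fit"), n_reps >= 1)
  if (is.null(settings)) settings <- fit$settings
  ids <- unique(dataset$ID)
  phis <- vapply(fit$covariates, `[[`, numeric(1), "estimate")
  terms <- fit$covariates
  for (k in seq_along(terms)) terms[[k]]$init <- phis[k]
  init <- do.call(pk_parameters, as.list(fit$theta))
  with_seed(seed, {
    reps <- vector("list", n_reps)
    for (b in seq_len(n_reps)) {
      take <- sample(ids, length(ids), replace = TRUE)
      pieces <- lapply(seq_along(take), function(j) {
        sub <- dataset[dataset$ID == take[j], , drop = FALSE]
        sub$ID <- j
        sub
      })
      bds <- do.call(rbind, pieces)
      reps[[b]] <- tryCatch({
        bf <- fit_pk(bds, init = init, covariates = terms,
                     omega2_init = fit$omega2, sigma2_init = fit$sigma2,
                     settings = settings)
        if (!bf$converged) NULL else
          c(bf$theta,
            setNames(vapply(bf$covariates, `[[`, numeric(1), "estimate"),
                     vapply(bf$covariates, `[[`, character(1), "name")),
            setNames(bf$omega2, paste0("omega2_", names(bf$omega2))),
            sigma2 = bf$sigma2)
      }, error = function(e) NULL)
    }
  })
  ok <- !vapply(reps, is.null, logical(1))
  if (!any(ok)) stop("all bootstrap replicates failed", call. = FALSE)
  est <- do.call(rbind, reps[ok])
  qs <- t(apply(est, 2, quantile, probs = c(0.5, 0.025, 0.975)))
  colnames(qs) <- c("median", "lo", "hi")
  structure(list(estimates = est,
                 summary = data.frame(parameter = rownames(qs), qs,
                                      row.names = NULL),
                 n_reps = n_reps, n_failed = sum(!ok),
                 convergence_fraction = mean(ok)),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("Bootstrap: %d replicates, %.0f%% converged\n",
              x$n_reps, 100 * x$convergence_fraction))
  print(x$summary, digits = 4)
  invisible(x)
}

# population prediction (eta = 0) for every observation row of one type
.pred_table <- function(dataset, pop, type = c("pk", "pd")) {
  type <- match.arg(type)
  cmt <- if (type == "pk") 1 else 4
  subs <- .split_subjects(dataset, cmt = cmt)
  subs <- subs[vapply(subs, function(s) length(s$dv) > 0, logical(1))]
  lapply(subs, function(s) {
    cl <- individual_cl(pop$pk$CL, pop$cov, s$wt, s$age)
    p6 <- c(pop$pk$V1, pop$pk$V2, pop$pk$V3, cl, pop$pk$Q2, pop$pk$Q3)
    am <- .sim_amounts_cpp(c(p6, pop$pd$ke0), s$events, s$times)
    pred <- if (type == "pk") .MGL_TO_NGML * am[, 1] / p6[1]
            else bis_from_ce(pop$pd, pmax(am[, 4], 0))
    tad <- vapply(s$times, function(t) {
      st <- s$events[, 1][s$events[, 1] <= t + 1e-9]
      if (length(st)) t - max(st) else t
    }, numeric(1))
    list(sub = s, p6 = p6, pred = pred, tad = tad)
  })
}

#' Prediction-corrected visual predictive check
#'
#' Observations and simulations are normalized within time bins by the
#' population prediction: concentrations (proportional error) by the ratio
#' form `pcY = Y * median(PRED_bin) / PRED`, BIS (additive error, bounded
#' scale) by the additive form `pcY = Y + (median(PRED_bin) - PRED)`. The
#' observed 5th/50th/95th percentiles per bin are compared with 95% confidence
#' bands obtained from `n_sim` datasets simulated under the model (new random
#' effects and residual noise on the original design). Bins are quantile bins
#' of time after dose; empty or degenerate bins are merged automatically by
#' the quantile construction.
#'
#' @param dataset event-format dataset.
#' @param pop a [population_model()] (e.g. the fitted model via
#'   [as_population_model()]).
#' @param type `"pk"` (concentrations) or `"pd"` (BIS).
#' @param n_sim number of simulated replicate datasets (>= 100 recommended).
#' @param n_bins target number of time bins.
#' @param seed optional seed.
#' @return a `vpc_result`: list with `bins` (per-bin observed percentiles and
#'   simulated bands with coverage flags), `coverage` (fraction of bin x
#'   percentile combinations whose observed value falls inside its band),
#'   `type`, `n_sim`.
#' @export
pc_vpc <- function(dataset, pop, type = c("pk", "pd"), n_sim = 200,
                   n_bins = 8, seed = NULL) {
  type <- match.arg(type)
  stopifnot(inherits(pop, "population_model"), n_sim >= 1)
  pt <- .pred_table(dataset, pop, type)
  if (!length(pt)) stop("no observations of the requested type", call. = FALSE)
  tad <- unlist(lapply(pt, `[[`, "tad"))
  pred <- unlist(lapply(pt, `[[`, "pred"))
  dv <- unlist(lapply(pt, function(x) x$sub$dv))

  brk <- unique(quantile(tad, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(brk) < 2) brk <- range(tad) + c(-1, 1)
  bin <- cut(tad, breaks = brk, include.lowest = TRUE)

  pc <- function(y, p, b) {
    med <- tapply(p, b, median)[b]
    if (type == "pk") y * as.numeric(med) / pmax(p, 1e-12)
    else y + (as.numeric(med) - p)
  }
  probs <- c(0.05, 0.5, 0.95)
  obs_pc <- pc(dv, pred, bin)
  obs_q <- do.call(rbind, tapply(obs_pc, bin, quantile, probs = probs,
                                 simplify = FALSE))

  sims <- with_seed(seed, {
    replicate(n_sim, {
      y <- unlist(lapply(pt, function(x) {
        s <- x$sub
        ind <- sample_individual(pop, s$wt, s$age)
        am <- .sim_amounts_cpp(
          c(ind$pk$V1, ind$pk$V2, ind$pk$V3, ind$pk$CL, ind$pk$Q2, ind$pk$Q3,
            ind$pd$ke0), s$events, s$times)
        if (type == "pk")
          apply_residual(.MGL_TO_NGML * am[, 1] / ind$pk$V1, "pk", pop$res)
        else
          apply_residual(bis_from_ce(ind$pd, pmax(am[, 4], 0)), "pd",
                         pop$res)
      }))
      ypc <- pc(y, pred, bin)
      do.call(rbind, tapply(ypc, bin, quantile, probs = probs,
                            simplify = FALSE))
    })
  }) # dims: bins x 3 x n_sim
  lo <- apply(sims, c(1, 2), quantile, probs = 0.025)
  hi <- apply(sims, c(1, 2), quantile, probs = 0.975)

  lev <- levels(bin)
  bins <- data.frame(
    bin = lev,
    tad_lo = brk[-length(brk)], tad_hi = brk[-1],
    n = as.integer(table(bin)),
    obs_p5 = obs_q[, 1], obs_p50 = obs_q[, 2], obs_p95 = obs_q[, 3],
    p5_lo = lo[, 1], p5_hi = hi[, 1],
    p50_lo = lo[, 2], p50_hi = hi[, 2],
    p95_lo = lo[, 3], p95_hi = hi[, 3], row.names = NULL)
  bins$cover_p5 <- bins$obs_p5 >= bins$p5_lo & bins$obs_p5 <= bins$p5_hi
  bins$cover_p50 <- bins$obs_p50 >= bins$p50_lo & bins$obs_p50 <= bins$p50_hi
  bins$cover_p95 <- bins$obs_p95 >= bins$p95_lo & bins$obs_p95 <= bins$p95_hi
  structure(list(bins = bins,
                 coverage = mean(unlist(bins[c("cover_p5", "cover_p50",
                                               "cover_p95")])),
                 type = type, n_sim = n_sim),
            class = "vpc_result")
}

#' @export
print.vpc_result <- function(x, ...) {
  cat(sprintf("pc-VPC (%s): %d bins, %d simulations, coverage %.0f%%\n",
              x$type, nrow(x$bins), x$n_sim, 100 * x$coverage))
  print(x$bins[, c("bin", "n", "obs_p5", "obs_p50", "obs_p95",
                   "cover_p5", "cover_p50", "cover_p95")], digits = 4)
  invisible(x)
}

#' Population model from fitted stages
#'
#' Assembles a [population_model()] from a PK fit and (optionally) a PD fit so
#' that predictive checks and dose simulations can be run under the estimated
#' model. Without a PD fit the published PD parameters are carried over.
#'
#' @param pk_fit a `pk_fit`.
#' @param pd_fit optional `pd_fit`.
#' @return a [population_model()].
#' @export
as_population_model <- function(pk_fit, pd_fit = NULL) {
  stopifnot(inherits(pk_fit, "pk_fit"))
  cov <- covariate_model(theta_wt = 0, theta_age = 0)
  for (tm in pk_fit$covariates) {
    if (tm$param == "CL" && tm$covariate == "WT") {
      cov$theta_wt <- tm$estimate; cov$ref_wt <- tm$ref
    } else if (tm$param == "CL" && tm$covariate == "AGE") {
      cov$theta_age <- tm$estimate; cov$ref_age <- tm$ref
    } else if (!is.null(tm$estimate) && abs(tm$estimate) > 1e-8)
      warning("covariate term ", tm$name,
              " is not representable in `covariate_model` and was dropped")
  }
  pd <- if (is.null(pd_fit)) pd_parameters() else
    pd_parameters(ke0 = pd_fit$theta[["KE0"]], E0 = pd_fit$theta[["E0"]],
                  Emax = pd_fit$theta[["EMAX"]], EC50 = pd_fit$theta[["EC50"]],
                  gamma = pd_fit$theta[["GAMMA"]])
  om <- c(pk_fit$omega2,
          if (!is.null(pd_fit)) pd_fit$omega2 else
            c(EC50 = 0.09, GAMMA = 0.02))
  population_model(
    pk = do.call(pk_parameters, as.list(pk_fit$theta)),
    pd = pd, cov = cov, omega2 = om,
    res = residual_model(pk_fit$sigma2,
                         if (is.null(pd_fit)) 7.70 else pd_fit$sigma2))
}
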