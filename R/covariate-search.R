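#' Chi-squared threshold for nested-model OFV comparisons
#'
#' The change in OFV between nested models is referenced against a chi-squared
#' distribution; the forward-inclusion gate uses the upper 5% point for one
#' degree of freedom (3.84) and backward elimination the upper 0.1% point
#' (10.83).
#'
#' @param alpha significance level in (0, 1).
#' @param df degrees of freedom (>= 1).
#' @return the critical OFV change.
#' @examples
#' chi2_threshold(0.05, 1) # 3.84
#' @export
chi2_threshold <- function(alpha, df = 1) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1)
    stop("`alpha` must lie strictly between 0 and 1", call. = FALSE)
  if (df < 1) stop("`df` must be >= 1", call. = FALSE)
  qchisq(1 - alpha, df)
}

#' Default covariate candidate set
#'
#' Continuous candidates (weight, age, BMI, creatinine, albumin, ALT, AST,
#' total bilirubin, total protein) enter as power functions centred at the
#' cohort median; sex enters as a fractional shift. Candidates are generated
#' for each target parameter (clearance and central volume by default).
#'
#' @param params structural parameters to test covariates on.
#' @param continuous continuous covariate column names.
#' @param categorical categorical (0/1) covariate column names.
#' @return list of [covariate_term()]s.
#' @export
default_candidates <- function(params = c("CL", "V1"),
                               continuous = c("WT", "AGE", "BMI", "CREAT",
                                              "ALB", "ALT", "AST", "TBIL",
                                              "TP"),
                               categorical = "SEX") {
  out <- list()
  for (p in params) {
    for (cv in continuous)
      out[[length(out) + 1L]] <- covariate_term(p, cv, form = "power")
    for (cv in categorical)
      out[[length(out) + 1L]] <- covariate_term(p, cv, form = "fractional")
  }
  out
}

# refit with a given term list, warm-started at a previous fit's estimates
.refit_with_terms <- function(dataset, fit, terms, settings) {
  fit_pk(dataset, init = do.call(pk_parameters, as.list(fit$theta)),
         covariates = terms, omega2_init = fit$omega2,
         sigma2_init = fit$sigma2, settings = settings)
}

.warm_terms <- function(fit) {
  lapply(fit$covariates, function(tm) { tm$init <- tm$estimate; tm })
}

#' Forward inclusion step of the stepwise covariate search
#'
#' Fits each remaining candidate singly on top of the current model and
#' selects the one with the largest OFV reduction, provided the reduction
#' reaches the inclusion gate (default `chi2_threshold(0.05, 1)` = 3.84). Ties
#' are broken by the larger reduction, then by lexical candidate name.
#' Candidates whose fit fails are skipped with a warning.
#'
#' @param dataset event-format dataset.
#' @param current_fit the current `pk_fit` (its covariates stay in the model).
#' @param candidates list of [covariate_term()]s still to be tested.
#' @param settings [fit_settings()] for the candidate refits.
#' @param threshold inclusion gate on the OFV reduction.
#' @return list with `selected` (term name or `NULL`), `fit` (updated or
#'   unchanged), and `log` (one row per candidate tested).
#' @export
forward_step <- function(dataset, current_fit, candidates,
                         settings = fit_settings(),
                         threshold = chi2_threshold(0.05, 1)) {
  stopifnot(inherits(current_fit, "pk_fit"))
  have <- vapply(current_fit$covariates, `[[`, character(1), "name")
  candidates <- candidates[!vapply(candidates, `[[`, character(1), "name")
                           %in% have]
  if (!length(candidates))
    return(list(selected = NULL, fit = current_fit,
                log = data.frame(candidate = character(0),
                                 ofv_before = numeric(0),
                                 ofv_after = numeric(0),
                                 delta_ofv = numeric(0),
                                 decision = character(0))))
  base_terms <- .warm_terms(current_fit)
  rows <- list(); fits <- list()
  for (cand in candidates) {
    cf <- tryCatch(
      .refit_with_terms(dataset, current_fit, c(base_terms, list(cand)),
                        settings),
      error = function(e) {
        warning("candidate ", cand$name, " skipped: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    drop_ofv <- if (is.null(cf)) NA_real_ else current_fit$ofv - cf$ofv
    rows[[length(rows) + 1L]] <- data.frame(
      candidate = cand$name, ofv_before = current_fit$ofv,
      ofv_after = if (is.null(cf)) NA_real_ else cf$ofv,
      delta_ofv = drop_ofv,
      decision = if (is.null(cf)) "failed"
                 else if (drop_ofv >= threshold) "eligible" else "rejected")
    fits[[cand$name]] <- cf
  }
  log <- do.call(rbind, rows)
  elig <- log[!is.na(log$delta_ofv) & log$delta_ofv >= threshold, ]
  if (!nrow(elig))
    return(list(selected = NULL, fit = current_fit, log = log))
  elig <- elig[order(-elig$delta_ofv, elig$candidate), ]
  sel <- elig$candidate[1]
  log$decision[log$candidate == sel] <- "selected"
  list(selected = sel, fit = fits[[sel]], log = log)
}

#' Backward elimination of the stepwise covariate search
#'
#' Removes each included covariate singly; if the smallest resulting OFV
#' increase is below the elimination gate (default `chi2_threshold(0.001, 1)`
#' = 10.83, i.e. the covariate does not defend its place at alpha = 0.001)
#' the covariate is dropped and the step repeats until a fixed point.
#'
#' @param dataset event-format dataset.
#' @param full_fit the `pk_fit` containing all forward-selected covariates.
#' @param settings [fit_settings()].
#' @param threshold elimination gate on the OFV increase.
#' @return list with `fit` (reduced model), `retained` (character vector of
#'   term names), and `log`.
#' @export
backward_step <- function(dataset, full_fit, settings = fit_settings(),
                          threshold = chi2_threshold(0.001, 1)) {
  stopifnot(inherits(full_fit, "pk_fit"))
  fit <- full_fit
  rows <- list()
  repeat {
    terms <- .warm_terms(fit)
    if (!length(terms)) break
    inc <- rep(NA_real_, length(terms))
    red_fits <- vector("list", length(terms))
    for (k in seq_along(terms)) {
      rf <- tryCatch(.refit_with_terms(dataset, fit, terms[-k], settings),
                     error = function(e) {
                       warning("removal of ", terms[[k]]$name, " failed: ",
                               conditionMessage(e), call. = FALSE)
                       NULL
                     })
      if (!is.null(rf)) { inc[k] <- rf$ofv - fit$ofv; red_fits[[k]] <- rf }
      rows[[length(rows) + 1L]] <- data.frame(
        candidate = terms[[k]]$name, ofv_before = fit$ofv,
        ofv_after = if (is.null(rf)) NA_real_ else rf$ofv,
        delta_ofv = inc[k], decision = "tested")
    }
    if (all(is.na(inc))) break
    k_min <- which.min(inc)
    if (inc[k_min] < threshold) {
      rows[[length(rows)]]$decision <- rows[[length(rows)]]$decision # no-op
      rows[[length(rows) + 1L]] <- data.frame(
        candidate = terms[[k_min]]$name, ofv_before = fit$ofv,
        ofv_after = red_fits[[k_min]]$ofv, delta_ofv = inc[k_min],
        decision = "removed")
      fit <- red_fits[[k_min]]
    } else break
  }
  list(fit = fit,
       retained = vapply(fit$covariates, `[[`, character(1), "name"),
       log = if (length(rows)) do.call(rbind, rows) else
         data.frame(candidate = character(0), ofv_before = numeric(0),
                    ofv_after = numeric(0), delta_ofv = numeric(0),
                    decision = character(0)))
}

#' Stepwise covariate model building
#'
#' Greedy forward inclusion (one covariate per step, OFV reduction >= 3.84)
#' followed by backward elimination (OFV increase on removal >= 10.83 to be
#' retained). The search log is a deterministic function of the dataset,
#' candidate list and settings.
#'
#' @param dataset event-format dataset.
#' @param candidates list of [covariate_term()]s (default
#'   [default_candidates()] restricted to columns present in `dataset`).
#' @param base_fit optional starting `pk_fit` (default: covariate-free fit).
#' @param settings [fit_settings()].
#' @param forward_threshold,backward_threshold the two OFV gates.
#' @param ... further arguments passed to [fit_pk()] for the base fit.
#' @return an `scm_result`: list with `final_fit`, `retained`, `log` (tidy
#'   step log), `base_ofv`, `final_ofv`.
#' @export
run_scm <- function(dataset, candidates = NULL, base_fit = NULL,
                    settings = fit_settings(),
                    forward_threshold = chi2_threshold(0.05, 1),
                    backward_threshold = chi2_threshold(0.001, 1), ...) {
  if (is.null(candidates)) {
    cand <- default_candidates()
    candidates <- cand[vapply(cand, function(tm)
      tm$covariate %in% names(dataset), logical(1))]
  }
  if (is.null(base_fit))
    base_fit <- fit_pk(dataset, settings = settings, ...)
  fit <- base_fit
  logs <- list(); step <- 0L
  repeat {
    step <- step + 1L
    fs <- forward_step(dataset, fit, candidates, settings, forward_threshold)
    if (nrow(fs$log)) {
      fs$log$phase <- "forward"; fs$log$step <- step
      logs[[length(logs) + 1L]] <- fs$log
    }
    if (is.null(fs$selected)) break
    fit <- fs$fit
  }
  bs <- backward_step(dataset, fit, settings, backward_threshold)
  if (nrow(bs$log)) {
    bs$log$phase <- "backward"; bs$log$step <- step + 1L
    logs[[length(logs) + 1L]] <- bs$log
  }
  structure(list(final_fit = bs$fit, retained = bs$retained,
                 log = if (length(logs)) do.call(rbind, logs) else NULL,
                 base_ofv = base_fit$ofv, final_ofv = bs$fit$ofv),
            class = "scm_result")
}

#' @export
print.scm_result <- function(x, ...) {
  cat(sprintf("Stepwise covariate search: OFV %.2f -> %.2f\n",
              x$base_ofv, x$final_ofv))
  cat("  retained:", if (length(x$retained)) paste(x$retained, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}
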