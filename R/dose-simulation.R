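#' Candidate dosing regimen for simulation
#'
#' A weight-based loading dose followed by a continuous maintenance infusion;
#' in simulation mode the maintenance infusion starts at the end of the
#' loading dose. Per-subject absolute rates scale with body weight.
#'
#' @param maintenance_mgkg_h maintenance infusion rate (mg/kg/h).
#' @param loading_mgkg loading dose (mg/kg).
#' @param loading_duration loading-dose duration (min).
#' @param maintenance_duration maintenance duration (min).
#' @param maintenance_start maintenance start (min); defaults to the end of
#'   the loading dose.
#' @return a `regimen_spec` object.
#' @export
regimen_spec <- function(maintenance_mgkg_h, loading_mgkg = 0.4,
                         loading_duration = 1, maintenance_duration = 120,
                         maintenance_start = NULL) {
  .assert_scalar_pos(maintenance_mgkg_h, "maintenance_mgkg_h", strict = FALSE)
  .assert_scalar_pos(loading_mgkg, "loading_mgkg")
  .assert_scalar_pos(loading_duration, "loading_duration")
  .assert_scalar_pos(maintenance_duration, "maintenance_duration")
  if (is.null(maintenance_start)) maintenance_start <- loading_duration
  structure(list(maintenance_mgkg_h = maintenance_mgkg_h,
                 loading_mgkg = loading_mgkg,
                 loading_duration = loading_duration,
                 maintenance_duration = maintenance_duration,
                 maintenance_start = maintenance_start),
            class = "regimen_spec")
}

.spec_regimen <- function(spec, wt) {
  ev <- list(dose_event(0, spec$loading_mgkg * wt / spec$loading_duration,
                        spec$loading_duration))
  if (spec$maintenance_mgkg_h > 0)
    ev[[2]] <- dose_event(spec$maintenance_start,
                          spec$maintenance_mgkg_h * wt / 60,
                          spec$maintenance_duration)
  regimen(ev)
}

#' Monte Carlo simulation of a dosing regimen
#'
#' Draws `n_subjects` virtual elderly patients (cohort demographic
#' distributions), samples their individual PK/PD parameters from the
#' population model, and simulates the structural BIS time course on a 1-min
#' grid. BIS percentile curves describe the structural (noise-free) sedation
#' state; residual BIS noise is observation error and is excluded by default.
#'
#' @param pop a [population_model()].
#' @param spec a [regimen_spec()].
#' @param n_subjects number of virtual subjects.
#' @param seed optional seed.
#' @param times simulation grid (min).
#' @param band,window target BIS band and evaluation window (min) used for
#'   the attainment summaries.
#' @param include_residual add residual noise to the BIS samples before
#'   summarizing (off by default).
#' @param demographics optional data.frame with columns `wt` and `age` to use
#'   instead of drawing a fresh virtual cohort (e.g. to compare regimens or
#'   models on identical subjects).
#' @return a `regimen_summary`: list with `spec`, `times`, `median`, `p5`,
#'   `p95` (pointwise BIS percentile curves), `time_in_band` (of the median
#'   curve over the window), `subject_time_in_band` (per-subject fractions),
#'   `fraction_median_in_band` (fraction of subjects whose median BIS over
#'   the window lies in the band) and `n_subjects`.
#' @export
simulate_regimen <- function(pop, spec, n_subjects = 1000, seed = NULL,
                             times = seq(0, 150, by = 1), band = c(40, 60),
                             window = c(30, 120), include_residual = FALSE,
                             demographics = NULL) {
  stopifnot(inherits(pop, "population_model"), inherits(spec, "regimen_spec"))
  with_seed(seed, {
    demo <- if (is.null(demographics))
      generate_demographics(n_subjects, include_labs = FALSE)
    else {
      stopifnot(all(c("wt", "age") %in% names(demographics)))
      n_subjects <- nrow(demographics)
      demographics
    }
    bis <- matrix(NA_real_, n_subjects, length(times))
    for (i in seq_len(n_subjects)) {
      ind <- sample_individual(pop, demo$wt[i], demo$age[i])
      tr <- simulate_profile(ind$pk, ind$pd, .spec_regimen(spec, demo$wt[i]),
                             times)
      bis[i, ] <- if (include_residual)
        apply_residual(tr$BIS, "pd", pop$res) else tr$BIS
    }
    med <- apply(bis, 2, median)
    win <- times >= window[1] & times <= window[2]
    in_band <- function(x) x >= band[1] & x <= band[2]
    structure(list(
      spec = spec, times = times, median = med,
      p5 = apply(bis, 2, quantile, probs = 0.05),
      p95 = apply(bis, 2, quantile, probs = 0.95),
      time_in_band = mean(in_band(med[win])),
      subject_time_in_band = rowMeans(in_band(bis[, win, drop = FALSE])),
      fraction_median_in_band =
        mean(in_band(apply(bis[, win, drop = FALSE], 1, median))),
      band = band, window = window, n_subjects = n_subjects),
      class = "regimen_summary")
  })
}

#' @export
print.regimen_summary <- function(x, ...) {
  win <- x$times >= x$window[1] & x$times <= x$window[2]
  cat(sprintf("Regimen %.1f mg/kg over %g min + %.1f mg/kg/h for %g min (n = %d)\n",
              x$spec$loading_mgkg, x$spec$loading_duration,
              x$spec$maintenance_mgkg_h, x$spec$maintenance_duration,
              x$n_subjects))
  cat(sprintf("  median BIS over %g-%g min: %.1f-%.1f; time in [%g, %g]: %.0f%%\n",
              x$window[1], x$window[2], min(x$median[win]), max(x$median[win]),
              x$band[1], x$band[2], 100 * x$time_in_band))
  invisible(x)
}

#' Evaluate a grid of maintenance rates
#'
#' Runs [simulate_regimen()] for each maintenance rate of the candidate grid
#' (default 0.4-1.4 mg/kg/h in 0.2 steps) with a common loading dose.
#'
#' @param pop a [population_model()].
#' @param rates maintenance rates (mg/kg/h).
#' @param n_subjects virtual subjects per regimen.
#' @param seed optional seed; each regimen uses an offset sub-seed so the
#'   whole grid is reproducible.
#' @param ... passed to [simulate_regimen()] / [regimen_spec()].
#' @return list of `regimen_summary` objects, named by rate.
#' @export
simulate_regimen_grid <- function(pop, rates = c(0.4, 0.6, 0.8, 1.0, 1.2, 1.4),
                                  n_subjects = 1000, seed = NULL, ...) {
  out <- lapply(seq_along(rates), function(k)
    simulate_regimen(pop, regimen_spec(rates[k]), n_subjects = n_subjects,
                     seed = if (is.null(seed)) NULL else seed + k - 1L, ...))
  names(out) <- sprintf("%.1f", rates)
  out
}

#' Select the optimal maintenance regimen
#'
#' Ranks candidate regimens by the fraction of the evaluation window during
#' which the median simulated BIS lies within the target band; ties are
#' broken toward the lower maintenance rate (minimum-effective-dose
#' principle).
#'
#' @param summaries list of `regimen_summary` objects.
#' @param band target BIS band.
#' @param window evaluation window (min).
#' @return the winning `regimen_spec`, with attributes `time_in_band` and
#'   `rate`.
#' @export
select_optimal <- function(summaries, band = c(40, 60), window = c(30, 120)) {
  if (!length(summaries)) stop("no regimen summaries supplied", call. = FALSE)
  stopifnot(all(vapply(summaries, inherits, logical(1), "regimen_summary")))
  score <- vapply(summaries, function(s) {
    win <- s$times >= window[1] & s$times <= window[2]
    mean(s$median[win] >= band[1] & s$median[win] <= band[2])
  }, numeric(1))
  rate <- vapply(summaries, function(s) s$spec$maintenance_mgkg_h, numeric(1))
  ord <- order(-score, rate)
  best <- summaries[[ord[1]]]$spec
  attr(best, "time_in_band") <- score[ord[1]]
  attr(best, "rate") <- rate[ord[1]]
  best
}
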