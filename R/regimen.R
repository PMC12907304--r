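#' Zero-order dose events and infusion regimens
#'
#' A dose event is a constant-rate (zero-order) infusion: `rate` mg/min for
#' `duration` minutes starting at `start` minutes. Protocol boluses are
#' represented as 1-minute infusions, so there is no separate instantaneous
#' bolus branch.
#'
#' @param start start time (min, >= 0).
#' @param rate infusion rate (mg/min, >= 0).
#' @param duration infusion duration (min, > 0).
#' @return a `dose_event` (named list).
#' @export
dose_event <- function(start, rate, duration) {
  if (!is.numeric(start) || length(start) != 1 || !is.finite(start) || start < 0)
    stop("`start` must be a non-negative time in minutes", call. = FALSE)
  .assert_scalar_pos(rate, "rate", strict = FALSE)
  .assert_scalar_pos(duration, "duration")
  structure(list(start = start, rate = rate, duration = duration),
            class = "dose_event")
}

#' @param ... `dose_event` objects (or a single list of them).
#' @return `regimen()` returns a `regimen`: a list of events sorted by start
#'   time.
#' @rdname dose_event
#' @export
regimen <- function(...) {
  ev <- list(...)
  if (length(ev) == 1 && is.list(ev[[1]]) && !inherits(ev[[1]], "dose_event"))
    ev <- ev[[1]]
  if (!all(vapply(ev, inherits, logical(1), "dose_event")))
    stop("all regimen elements must be `dose_event` objects", call. = FALSE)
  ev <- ev[order(vapply(ev, `[[`, numeric(1), "start"))]
  structure(list(events = ev), class = "regimen")
}

#' Total administered dose of a regimen
#'
#' @param x a `regimen`.
#' @return total dose in mg (`sum(rate * duration)`).
#' @export
total_dose <- function(x) {
  stopifnot(inherits(x, "regimen"))
  sum(vapply(x$events, function(e) e$rate * e$duration, numeric(1)))
}

# regimen -> events matrix (start, rate, duration) consumed by the C++ solver
.events_matrix <- function(reg) {
  if (inherits(reg, "regimen")) reg <- reg$events
  if (length(reg) == 0) return(matrix(numeric(0), ncol = 3))
  t(vapply(reg, function(e) c(e$start, e$rate, e$duration), numeric(3)))
}

#' Protocol dosing regimens
#'
#' `study_regimen()` builds the clinical-study regimen: a weight-based bolus
#' (default 0.4 mg/kg over 1 min at time 0) followed by a maintenance infusion
#' (default 0.8 mg/kg/h) starting 5 min after the bolus. `simulation_regimen()`
#' builds the regimen evaluated in dose-finding simulations, where the
#' maintenance infusion starts immediately at the end of the loading dose.
#'
#' @param wt body weight (kg).
#' @param bolus_mgkg loading dose (mg/kg).
#' @param bolus_duration loading-dose infusion duration (min).
#' @param maintenance_mgkg_h maintenance rate (mg/kg/h).
#' @param maintenance_start maintenance start time (min).
#' @param maintenance_duration maintenance duration (min).
#' @return a `regimen`.
#' @examples
#' study_regimen(66, maintenance_duration = 120)
#' @export
study_regimen <- function(wt, bolus_mgkg = 0.4, bolus_duration = 1,
                          maintenance_mgkg_h = 0.8, maintenance_start = 5,
                          maintenance_duration = 115) {
  .assert_scalar_pos(wt, "wt")
  regimen(
    dose_event(0, bolus_mgkg * wt / bolus_duration, bolus_duration),
    dose_event(maintenance_start, maintenance_mgkg_h * wt / 60,
               maintenance_duration)
  )
}

#' @rdname study_regimen
#' @export
simulation_regimen <- function(wt, bolus_mgkg = 0.4, bolus_duration = 1,
                               maintenance_mgkg_h = 0.6,
                               maintenance_duration = 120) {
  .assert_scalar_pos(wt, "wt")
  regimen(
    dose_event(0, bolus_mgkg * wt / bolus_duration, bolus_duration),
    dose_event(bolus_duration, maintenance_mgkg_h * wt / 60,
               maintenance_duration)
  )
}

#' @export
print.regimen <- function(x, ...) {
  cat(sprintf("Infusion regimen: %d event(s), total dose %.2f mg\n",
              length(x$events), total_dose(x)))
  for (e in x$events)
    cat(sprintf("  t = %g min: %.3f mg/min for %g min (%.2f mg)\n",
                e$start, e$rate, e$duration, e$rate * e$duration))
  invisible(x)
}
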