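#' System matrix of the PK/effect-site model
#'
#' Builds the 4x4 constant-coefficient matrix of the linear system in state
#' order (A1, A2, A3, Ce): the mammillary three-compartment disposition block
#' with micro-rate constants `k12 = Q2/V1`, `k21 = Q2/V2`, `k13 = Q3/V1`,
#' `k31 = Q3/V3`, `k10 = CL/V1`, plus the effect-site row implementing
#' `dCe/dt = ke0 * (1000 * A1/V1 - Ce)` (Ce carried in ng/mL while amounts are
#' in mg). The eigenvalues of the 3x3 disposition block are real and strictly
#' negative for any admissible parameter set.
#'
#' @param pk a [pk_parameters()] object.
#' @param ke0 effect-site equilibration rate (1/min).
#' @return a 4x4 numeric matrix with dimnames `A1, A2, A3, Ce`.
#' @examples
#' eigen(build_system_matrix(pk_parameters(), 1.09)[1:3, 1:3])$values
#' @export
build_system_matrix <- function(pk, ke0) {
  if (!inherits(pk, "pk_parameters"))
    stop("`pk` must be a `pk_parameters` object", call. = FALSE)
  .assert_scalar_pos(ke0, "ke0")
  A <- matrix(0, 4, 4, dimnames = list(c("A1", "A2", "A3", "Ce"),
                                       c("A1", "A2", "A3", "Ce")))
  A[1, 1] <- -(pk$CL + pk$Q2 + pk$Q3) / pk$V1
  A[1, 2] <- pk$Q2 / pk$V2
  A[1, 3] <- pk$Q3 / pk$V3
  A[2, 1] <- pk$Q2 / pk$V1
  A[2, 2] <- -pk$Q2 / pk$V2
  A[3, 1] <- pk$Q3 / pk$V1
  A[3, 3] <- -pk$Q3 / pk$V3
  A[4, 1] <- ke0 * .MGL_TO_NGML / pk$V1
  A[4, 4] <- -ke0
  A
}

#' BIS predicted from effect-site concentration
#'
#' Inhibitory sigmoid Emax (Hill) model:
#' `BIS(Ce) = E0 - Emax * Ce^gamma / (EC50^gamma + Ce^gamma)`. Strictly
#' decreasing in `Ce`, bounded in `(E0 - Emax, E0]`.
#'
#' @param pd a [pd_parameters()] object.
#' @param ce effect-site concentration(s), ng/mL, >= 0.
#' @return BIS value(s), same length as `ce`.
#' @export
bis_from_ce <- function(pd, ce) {
  if (!inherits(pd, "pd_parameters"))
    stop("`pd` must be a `pd_parameters` object", call. = FALSE)
  if (!is.numeric(ce) || any(!is.finite(ce)) || any(ce < 0))
    stop("`ce` must be non-negative and finite", call. = FALSE)
  # (ce/EC50)^gamma parameterization is stable for large ce
  u <- (ce / pd$EC50)^pd$gamma
  pd$E0 - pd$Emax * u / (1 + u)
}

#' Simulate the concentration and BIS time course
#'
#' Exact solution of the linear three-compartment + effect-site system under a
#' piecewise-constant infusion regimen, evaluated on an arbitrary time grid.
#' Propagation is segment-by-segment through the eigendecomposition of the
#' system matrix (matrix-exponential fallback on degeneracy), so accuracy is
#' limited only by floating point, not by a step size.
#'
#' @param pk a [pk_parameters()] object.
#' @param pd a [pd_parameters()] object (used for `ke0` and the BIS column).
#' @param regimen a [regimen()].
#' @param times sorted, non-negative time grid (min).
#' @return a data.frame with columns `time`, `A1`, `A2`, `A3` (amounts, mg),
#'   `Cp` (plasma concentration, ng/mL), `Ce` (effect-site concentration,
#'   ng/mL) and `BIS`.
#' @examples
#' tr <- simulate_profile(pk_parameters(), pd_parameters(),
#'                        simulation_regimen(66), times = 0:150)
#' tr[tr$time %in% c(1, 30, 120), c("time", "Cp", "Ce", "BIS")]
#' @export
simulate_profile <- function(pk, pd, regimen, times) {
  if (!inherits(pk, "pk_parameters"))
    stop("`pk` must be a `pk_parameters` object", call. = FALSE)
  if (!inherits(pd, "pd_parameters"))
    stop("`pd` must be a `pd_parameters` object", call. = FALSE)
  if (!inherits(regimen, "regimen"))
    stop("`regimen` must be a `regimen` object", call. = FALSE)
  if (!is.numeric(times) || any(!is.finite(times)))
    stop("`times` must be finite numeric", call. = FALSE)
  if (any(times < 0)) stop("`times` must be non-negative", call. = FALSE)
  if (is.unsorted(times)) stop("`times` must be sorted", call. = FALSE)

  am <- .sim_amounts_cpp(
    c(pk$V1, pk$V2, pk$V3, pk$CL, pk$Q2, pk$Q3, pd$ke0),
    .events_matrix(regimen), as.numeric(times))
  cp <- .MGL_TO_NGML * am[, 1] / pk$V1
  ce <- pmax(am[, 4], 0) # exact solver can leave sub-epsilon negatives
  data.frame(time = times, A1 = am[, 1], A2 = am[, 2], A3 = am[, 3],
             Cp = cp, Ce = ce, BIS = bis_from_ce(pd, ce))
}

# Plasma concentrations only (internal fast path used by the estimator;
# symmetric-eigendecomposition solver for the disposition block).
.sim_cp <- function(pars6, ke0, events, times) {
  .MGL_TO_NGML * .sim_a1_cpp(pars6, events, times) / pars6[1]
}
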