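#' Structural pharmacokinetic parameters
#'
#' Fixed-effect parameters of the linear three-compartment disposition model:
#' central, shallow-peripheral and deep-peripheral volumes, elimination
#' clearance from the central compartment, and the two intercompartmental
#' clearances. Internal units are L and L/min.
#'
#' @param V1 central volume of distribution (L).
#' @param V2 shallow peripheral volume (L).
#' @param V3 deep peripheral volume (L).
#' @param CL elimination clearance (L/min).
#' @param Q2 intercompartmental clearance, central <-> shallow (L/min).
#' @param Q3 intercompartmental clearance, central <-> deep (L/min).
#' @return an object of class `pk_parameters` (named list).
#' @examples
#' pk_parameters() # published typical values for elderly patients
#' @export
pk_parameters <- function(V1 = 2.95, V2 = 45.15, V3 = 76.79,
                          CL = 1.01, Q2 = 0.76, Q3 = 0.66) {
  for (nm in c("V1", "V2", "V3", "CL", "Q2", "Q3"))
    .assert_scalar_pos(get(nm), nm)
  structure(list(V1 = V1, V2 = V2, V3 = V3, CL = CL, Q2 = Q2, Q3 = Q3),
            class = "pk_parameters")
}

#' Pharmacodynamic (BIS) parameters
#'
#' Parameters of the effect-site link and the inhibitory sigmoid Emax model
#' mapping effect-site concentration to the bispectral index:
#' `BIS(Ce) = E0 - Emax * Ce^gamma / (EC50^gamma + Ce^gamma)`.
#'
#' @param ke0 effect-site equilibration rate constant (1/min).
#' @param E0 baseline BIS (0-100 scale).
#' @param Emax maximum BIS suppression (BIS units); must not exceed `E0`.
#' @param EC50 effect-site concentration at half-maximal suppression (ng/mL).
#' @param gamma Hill coefficient (dimensionless steepness).
#' @return an object of class `pd_parameters` (named list).
#' @examples
#' pd <- pd_parameters()
#' bis_from_ce(pd, pd$EC50) # E0 - Emax/2 by construction
#' @export
pd_parameters <- function(ke0 = 1.09, E0 = 93.40, Emax = 45.77,
                          EC50 = 233.91, gamma = 3.00) {
  .assert_scalar_pos(ke0, "ke0")
  .assert_scalar_pos(E0, "E0")
  .assert_scalar_pos(Emax, "Emax")
  .assert_scalar_pos(EC50, "EC50")
  .assert_scalar_pos(gamma, "gamma")
  if (E0 > 100) stop("`E0` must lie on the 0-100 BIS scale", call. = FALSE)
  if (Emax > E0)
    stop("`Emax` must not exceed the baseline `E0`", call. = FALSE)
  structure(list(ke0 = ke0, E0 = E0, Emax = Emax, EC50 = EC50, gamma = gamma),
            class = "pd_parameters")
}

#' @export
print.pk_parameters <- function(x, ...) {
  cat("Three-compartment PK parameters\n")
  cat(sprintf("  V1 %.3g L  V2 %.4g L  V3 %.4g L\n", x$V1, x$V2, x$V3))
  cat(sprintf("  CL %.3g L/min  Q2 %.3g L/min  Q3 %.3g L/min\n",
              x$CL, x$Q2, x$Q3))
  invisible(x)
}

#' @export
print.pd_parameters <- function(x, ...) {
  cat("Effect-site sigmoid Emax (BIS) parameters\n")
  cat(sprintf("  ke0 %.3g /min  E0 %.4g  Emax %.4g  EC50 %.4g ng/mL  gamma %.3g\n",
              x$ke0, x$E0, x$Emax, x$EC50, x$gamma))
  invisible(x)
}
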