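---
title: "Population PK/PD of ciprofol in elderly patients: models, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population PK/PD of ciprofol in elderly patients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
structural and statistical models, the estimation machinery, what the
synthetic-study generator does and does not emulate, and the numerical and
design decisions that were genuinely open. The README shows the workflow;
here we explain the choices.

## The problem

Ciprofol is an intravenous GABA~A~-agonist anaesthetic. In elderly surgical
patients, reduced clearance and altered body composition shift both its
disposition and its concentration–effect relationship, so dosing rules
derived from younger adults over- or under-shoot the target depth of
anaesthesia. The package implements a population PK/PD analysis for this
setting: a mechanistic disposition model for plasma concentration, an
effect-site link to the bispectral index (BIS, a processed-EEG sedation
score: ~100 awake, 40–60 surgical anaesthesia), nonlinear mixed-effects
estimation, model qualification, and Monte Carlo evaluation of candidate
infusion regimens against the BIS 40–60 band.

## Structural model

Disposition is a linear mammillary three-compartment model, parameterized by
volumes `V1, V2, V3` (L; central, shallow-peripheral, deep-peripheral) and
clearances `CL, Q2, Q3` (L/min; elimination and the two intercompartmental
clearances). With amounts `A = (A1, A2, A3)` (mg) and zero-order infusion
rate `r(t)` (mg/min),

$$
\dot A_1 = r(t) - \Bigl(\tfrac{CL + Q_2 + Q_3}{V_1}\Bigr)A_1
          + \tfrac{Q_2}{V_2}A_2 + \tfrac{Q_3}{V_3}A_3,\qquad
\dot A_2 = \tfrac{Q_2}{V_1}A_1 - \tfrac{Q_2}{V_2}A_2,\qquad
\dot A_3 = \tfrac{Q_3}{V_1}A_1 - \tfrac{Q_3}{V_3}A_3 .
$$

The effect site is a hypothetical compartment whose concentration `Ce`
equilibrates with plasma at first-order rate `ke0` (1/min),
$\dot C_e = k_{e0}(C_p - C_e)$, removing the hysteresis between plasma
concentration and effect. BIS follows the inhibitory sigmoid Emax (Hill)
model

$$
\mathrm{BIS}(C_e) = E_0 - E_{\max}\,
  \frac{C_e^{\gamma}}{EC_{50}^{\gamma} + C_e^{\gamma}} ,
$$

strictly decreasing in `Ce` and bounded below by `E0 − Emax`.

Units: time in minutes, amounts in mg, volumes in L; concentrations are
carried as mg/L internally and exposed as ng/mL through a single ×1000
conversion constant, with `EC50` handled in ng/mL. Having exactly one
conversion point avoids silent unit errors between the L·min⁻¹ and ng·mL⁻¹
scales in which the parameters are reported.

Default parameter values are the published elderly-population estimates:
`V1 = 2.95`, `V2 = 45.15`, `V3 = 76.79` L, `CL = 1.01`, `Q2 = 0.76`,
`Q3 = 0.66` L/min, and `ke0 = 1.09` /min, `E0 = 93.40`, `Emax = 45.77`,
`EC50 = 233.91` ng/mL, `γ = 3.00`.

### Exact simulation

Because the system is linear with piecewise-constant input, it is solved
exactly segment by segment: on a segment with constant rate, $x(t_0+\Delta)
= e^{A\Delta}(x_0 + A^{-1}b) - A^{-1}b$. Two compiled solvers implement
this:

* the full 4-state system (amounts + `Ce`) through the eigendecomposition of
  the block-triangular system matrix, with a matrix-exponential fallback if
  the eigenvector matrix is ill-conditioned (the measure-zero
  repeated-eigenvalue case);
* a fast 3-state path for estimation, exploiting that the mammillary block
  is similar to a symmetric matrix under the volume scaling
  $S=\mathrm{diag}(V^{-1/2})$, so a symmetric eigendecomposition (real,
  orthonormal, robust to degeneracy by construction) gives the propagator.

Accuracy is limited only by floating point: the test suite checks agreement
with an adaptive ODE integrator at 1e−6 relative, mass balance through a
state-integral identity at 1e−8 relative, and superposition at 1e−10.
Sub-epsilon negative amounts from cancellation are truncated at zero.
Protocol boluses are modelled as 1-minute zero-order infusions, as
administered; no instantaneous-bolus branch exists. The effect site is
carried as a fourth state of the same linear system rather than convolved
separately, preserving exactness with one code path.

## Statistical model

Inter-individual variability (IIV) is log-normal, `θ_i = θ_pop·exp(η_i)`
with `η ~ N(0, ω²)`, independent across parameters (diagonal Ω, matching the
reported structure). IIV is carried on the six PK parameters and, on the PD
side, on `EC50` and `γ` only; `ke0`, `E0` and `Emax` have no reported
between-subject variance. Residual error is proportional for concentrations,
`y = f·(1+ε)`, and additive for BIS, `y = f + ε`.

**Magnitude convention.** The source analysis prints single numbers labelled
`ω` and `σ` while writing the distributions as `N(0, ω²)` and `N(0, σ²)`;
whether the printed values are variances or standard deviations is genuinely
ambiguous (the prose suggests standard deviations, while the usual NLME
reporting convention and the implied coefficients of variation suggest
variances). The package treats the printed values as **variances by
default** and exposes the choice as configuration
(`residual_model(convention = "sd")`). Under the default, the proportional
concentration error has a ~51% CV — a harsh noise regime whose consequences
for identifiability are discussed below.

Clearance carries the published covariate model,
`CL = θ_CL·(WT/66)^0.74·(AGE/72.5)^(−0.21)`, centred at the cohort medians
embedded in the printed equation (66 kg, 72.5 y); the centering constants
are fixed, not recomputed from data, except in the covariate search where
candidate terms centre at the current cohort's median.

## Estimation: FOCE-I

The objective is the first-order-conditional-estimation-with-interaction
approximation to −2 log marginal likelihood. For subject *i* with residual
variance function `g_j(η)` (`σ²f_j²(η)` proportional, `σ²` additive — the
η-dependence of `g` is the "interaction"), the inner problem minimises the
conditional objective

$$
2h(\eta) = \sum_j\Bigl[\log\bigl(2\pi g_j(\eta)\bigr)
 + \frac{(y_j - f_j(\eta))^2}{g_j(\eta)}\Bigr]
 + \eta^\top\Omega^{-1}\eta + \log\lvert 2\pi\Omega\rvert
$$

over `η`, by Newton iterations with a Fisher-type (Gauss–Newton) curvature
approximation, backtracking line search, and warm starts from the previous
outer iteration. The subject's contribution is the Laplace-type value

$$
\mathrm{OFV}_i = 2h(\hat\eta) - d\log 2\pi + \log\det\bigl(H/2\pi\cdot 2\pi\bigr),
\qquad H = \tfrac12\nabla^2\,2h(\hat\eta),
$$

with the same Fisher-type `H` (the common FOCE practice; it is exact for
models linear in `η` with additive error, which the tests exploit: on a
linear random-intercept model the OFV matches the closed-form marginal
multivariate-normal −2LL to ~1e−13).

The outer problem minimises the summed OFV over log-transformed structural
parameters, covariate exponents, and log variance components, using the PORT
quasi-Newton code (`nlminb`) with box bounds. One numerical point matters:
the outer gradient is computed by **central differences with step 1e−4** on
the transformed scale. The inner optimisation is itself iterative, so the
objective carries truncation noise of order the inner tolerance;
the PORT code's internal forward differences use a much narrower step and
drown in that noise, stalling with spurious "false convergence". The wide
central-difference gradient restores clean convergence (verified by the
noise-free exact-fit tests, which recover the generating parameters to
<0.1%).

Conditional modes give empirical-Bayes individual parameters;
`η`- and `ε`-shrinkage are reported as `100·(1 − sd(η̂)/ω)` and
`100·(1 − sd(IWRES))`.

**Sequential PD.** PD is estimated sequentially with individual PK
parameters fixed at their empirical-Bayes values (the "IPP" approach): `Ce`
is computed exactly from each subject's PK curve for the current `ke0`, and
`ke0, E0, Emax, EC50, γ`, the two PD IIV variances and the additive residual
variance are estimated by FOCE-I on the BIS rows, with analytic
η-derivatives of the Hill model. The source analysis does not state whether
PK and PD were fit simultaneously; sequential fitting is standard, far
cheaper, and documented here as a limitation for exact equivalence.

**Multi-start.** Displaced starting points were probed during development;
the outer optimiser reaches the same optimum from starts ±50% away (the
suite tests this), so no multi-start machinery is included.

**BLQ.** Observations below the 5 ng/mL quantification limit are flagged and
excluded from estimation (M1). The likelihood-based M3 treatment is out of
scope.

## Covariate search

Stepwise covariate modelling on the PK model: greedy forward inclusion (one
candidate per step; an OFV reduction of at least `qchisq(0.95, 1) = 3.84` is
required; ties broken by the larger drop, then lexical name) followed by
backward elimination (a covariate is retained only if its removal raises the
OFV by at least `qchisq(0.999, 1) = 10.83`). Continuous candidates enter as
power functions centred at the cohort median; binary candidates as
fractional shifts. The default candidate set — weight, age, sex, BMI,
creatinine, albumin, ALT, AST, total bilirubin, total protein, on CL and V1 —
mirrors the covariates screened in the source analysis, which does not
enumerate exact covariate–parameter pairs; the set is configurable. The
suite checks the gate's type-I calibration directly: on studies simulated
with no covariate effects, the per-candidate false-inclusion rate over 500
single-covariate tests must sit at 5% ± 2%.

## Diagnostics

* **CWRES** uses the FOCE linearization around the conditional mode:
  mean `f(η̂) − Fη̂`, covariance `FΩFᵀ + diag(g(η̂))`, standardized by the
  Cholesky factor. Under the true model on its own simulated data the suite
  requires sample mean in (−0.15, 0.15) and SD in (0.85, 1.15).
* **Bootstrap** resamples subjects — the only exchangeable unit — with
  replacement, refits warm-started from the original estimates, and reports
  medians with 2.5–97.5 percentile intervals; failed replicates are excluded
  and counted. It is implemented for the PK stage; a full sequential PD
  bootstrap would refit both stages per replicate and is omitted for cost.
* **pc-VPC**: observations and simulations are prediction-corrected within
  time-after-dose bins — ratio form `pcY = Y·med(PRED_bin)/PRED` for
  concentrations (proportional error), additive form
  `pcY = Y + (med(PRED_bin) − PRED)` for BIS (additive error on a bounded
  scale); the correction forms follow the error models since the source does
  not print its formula. Bins are quantile bins of time after dose (default
  8; empty bins merge automatically through the quantile construction).
  Observed 5th/50th/95th percentiles are compared with 95% bands from
  simulated replicates; self-consistency (a model checked against data
  simulated from itself) must cover ≥90% of bin × percentile checks.

## The synthetic-study generator

No public dataset exists, so the generator emulates the study design and is
itself first-class, tested code: 20 elderly subjects with ages from
N(72.95, 4.47²) truncated to 67–82 y and weights from N(65.63, 9.34²)
truncated to 49–80 kg (the parent location is re-centred so the *truncated*
mean matches the reported cohort mean — asymmetric truncation would
otherwise shift the ages by ~+0.6 y); 55% male; a 0.4 mg/kg bolus over
1 min; 0.8 mg/kg/h maintenance from 5 min for a per-subject surgery
duration drawn Uniform(60, 180) min (surgery length is never reported; the
range brackets the 2-h simulation horizon and is configurable); the 19
nominal arterial samples per subject (pre-dose and 1, 3, 5 min around the
bolus; 5–60 min offsets into maintenance; 3 min–6 h after cessation) with
BIS recorded synchronously at the same clock times; proportional
concentration noise and additive BIS noise; BLQ flagging at 5 ng/mL. Baseline
laboratory covariates (BMI, creatinine, albumin, ALT, AST, bilirubin, total
protein) are drawn from the cohort's reported distributions and carry no
effect in the generating model — they exist as honest null candidates for
covariate screening.

What the generator does **not** emulate: the ~6 unscheduled extra samples
(386 reported vs 380 nominal — unexplained in the source and not modelled),
rescue midazolam and remifentanil co-administration, hemodynamic drift,
dropout, and assay error structure beyond the residual model. Passing
recovery tests therefore demonstrates internal consistency of the
estimator under the stated design — not robustness to the protocol
deviations of a real theatre.

Every dataset is reconstructible from `(design, population config, seed)`;
nothing binary is stored.

## Dose-regimen simulation

Candidate regimens are a 0.4 mg/kg loading dose over 1 min followed by
maintenance at 0.4–1.4 mg/kg/h (0.2 steps) for 2 h. In simulation mode the
maintenance infusion starts at the end of the loading dose (the protocol
description of the simulations), versus 5 min in study-emulation mode; both
are configuration. Each regimen is evaluated in 1,000 virtual subjects drawn
from the demographic and IIV distributions, on a 1-min grid over 0–150 min.
Percentile curves summarize the *structural* BIS — residual BIS noise is
observation error, not sedation state — with an option to include it.

"Stably maintains BIS 40–60" is operationalized as the fraction of the
30–120 min window in which the pointwise median BIS lies inside the band;
the window excludes the induction transient and is reported with results.
The optimal regimen maximises this time-in-band with ties broken toward the
lower rate (minimum-effective-dose principle). Because `E0 − Emax ≈ 47.6`
bounds the structural BIS from below, rates above the minimum effective one
also hold the band — the tie-break, not the band alone, is what selects the
lowest adequate rate.

## Problem sizes and runtime choices

The test suite exercises full-size studies (20 subjects × 19 samples) for
the recovery and diagnostics checks, and reduced configurations chosen for
statistical adequacy at tractable cost elsewhere: the false-inclusion
calibration uses 25 null studies of 8 subjects with IIV on CL only (500
candidate tests, enough for a ±2% check of a 5% rate); bootstrap and
multi-start tests use 8-subject studies. The acceptance script refits 5
replicate full-size studies and runs the 1,000-subject regimen grid.

## Known limitations

* **Deep-compartment identifiability.** Under the default
  variance-convention residual noise (~51% CV) with 20 subjects, the
  likelihood in the (`V2`,`Q2`,`V3`,`Q3`) directions is nearly flat along a
  ridge, and the `V3` maximum-likelihood estimate is strongly dispersed
  across simulated replicates (and skews high), while `V1`, `CL` and all PD
  parameters recover tightly. This is a property of the design and noise
  level, not of the optimiser: displaced starts reach the same optimum, the
  noise-free limit recovers `V3` to <0.1%, and the OFV matches the exact
  marginal likelihood where one exists. Median-of-5-replicates summaries of
  `V3` inherit that dispersion.
* Sequential (IPP) PD estimation; simultaneous PK/PD fitting is not
  implemented.
* No asymptotic standard errors: uncertainty is bootstrap-based, as in the
  source analysis. RSE% values are therefore not reproduced.
* No inter-occasion variability, no off-diagonal Ω, no M3 BLQ likelihood,
  no covariate-stratified VPC, no TCI/closed-loop control, no co-medication
  interaction surfaces.
* The observed-data OFVs of the source analysis are not reproducible: the
  clinical dataset is private, so all data-dependent checks run on
  synthetic studies generated under the published model.
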