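#' Clinical study design
#'
#' Encodes the emulated study protocol: 20 elderly subjects; a 0.4 mg/kg
#' bolus infused over 1 min at time 0; a 0.8 mg/kg/h maintenance infusion
#' starting at 5 min and running for a per-subject surgery duration; arterial
#' PK samples at protocol offsets (pre-dose and 1, 3, 5 min around the bolus;
#' 5, 10, 15, 30, 45, 60 min after the start of maintenance; 3, 5, 10, 30, 60,
#' 90, 120, 240, 360 min after infusion cessation -- 19 nominal samples per
#' subject) with BIS recorded synchronously at the same clock times; and a
#' 5 ng/mL lower limit of quantification.
#'
#' The per-subject infusion duration is drawn uniformly on
#' `infusion_duration_range` (surgery length varies between patients).
#'
#' @param n_subjects number of subjects.
#' @param bolus_mgkg,bolus_duration loading dose (mg/kg) and its duration (min).
#' @param maintenance_mgkg_h maintenance infusion rate (mg/kg/h).
#' @param maintenance_start maintenance start time (min after bolus start).
#' @param infusion_duration_range range (min) for the uniform per-subject
#'   maintenance duration.
#' @param lloq lower limit of quantification (ng/mL).
#' @param include_labs add baseline laboratory covariate columns (BMI,
#'   creatinine, albumin, AST, ALT, total bilirubin, total protein) drawn from
#'   the cohort distributions; these are not part of the data-generating model
#'   and serve as null candidates for covariate screening.
#' @return a `study_design` object.
#' @export
study_design <- function(n_subjects = 20, bolus_mgkg = 0.4, bolus_duration = 1,
                         maintenance_mgkg_h = 0.8, maintenance_start = 5,
                         infusion_duration_range = c(60, 180), lloq = 5,
                         include_labs = TRUE) {
  if (n_subjects < 0) stop("`n_subjects` must be >= 0", call. = FALSE)
  if (length(infusion_duration_range) != 2 ||
      any(infusion_duration_range <= 0) || diff(infusion_duration_range) < 0)
    stop("`infusion_duration_range` must be an increasing positive pair",
         call. = FALSE)
  structure(list(n_subjects = as.integer(n_subjects), bolus_mgkg = bolus_mgkg,
                 bolus_duration = bolus_duration,
                 maintenance_mgkg_h = maintenance_mgkg_h,
                 maintenance_start = maintenance_start,
                 infusion_duration_range = infusion_duration_range,
                 lloq = lloq, include_labs = isTRUE(include_labs)),
            class = "study_design")
}

#' Nominal PK sampling times for one subject
#'
#' @param design a [study_design()].
#' @param infusion_end clock time (min) at which the maintenance infusion
#'   stops.
#' @return sorted vector of 19 sampling times (min).
#' @export
pk_sample_times <- function(design, infusion_end) {
  stopifnot(inherits(design, "study_design"))
  sort(c(0, 1, 3, 5,
         design$maintenance_start + c(5, 10, 15, 30, 45, 60),
         infusion_end + c(3, 5, 10, 30, 60, 90, 120, 240, 360)))
}

.rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  # Rejection sampler for a truncated normal whose *truncated* mean equals
  # the requested cohort mean: asymmetric truncation shifts the mean of a
  # plainly truncated normal (by ~+0.6 y for the age window), so the parent
  # location is re-centred first.
  mu <- .trunc_parent_mean(mean, sd, lo, hi)
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- rnorm(length(need), mu, sd)
    ok <- draw >= lo & draw <= hi
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

# parent location mu such that E[X | lo <= X <= hi], X ~ N(mu, sd^2),
# equals `target`
.trunc_parent_mean <- function(target, sd, lo, hi) {
  tmean <- function(mu) {
    a <- (lo - mu) / sd; b <- (hi - mu) / sd
    z <- pnorm(b) - pnorm(a)
    mu + sd * (dnorm(a) - dnorm(b)) / z
  }
  stats::uniroot(function(mu) tmean(mu) - target,
                 lower = lo, upper = hi, tol = 1e-10)$root
}

# cohort moments (mean, sd, low, high) for baseline covariates
.COHORT_LABS <- list(
  BMI   = c(24.70, 2.31, 21.20, 29.38),
  CREAT = c(64.65, 18.43, 37, 107),
  ALB   = c(40.40, 3.02, 36.7, 44.7),
  AST   = c(21.25, 3.57, 16, 28),
  ALT   = c(23.85, 13.62, 8, 73),
  TBIL  = c(11.38, 5.70, 5, 28.3),
  TP    = c(69.30, 4.60, 61.6, 81.6)
)

#' Generate a virtual elderly cohort
#'
#' Ages are drawn from Normal(72.95, 4.47^2) truncated to the enrolled range
#' 67-82 years; weights from Normal(65.63, 9.34^2) truncated to 49-80 kg; sex
#' is Bernoulli with 55% male. Optional laboratory covariates are drawn from
#' the corresponding cohort distributions (truncated normals on the observed
#' ranges).
#'
#' @param n number of subjects (>= 0).
#' @param seed optional seed.
#' @param include_labs include baseline laboratory columns.
#' @return a data.frame with columns `id`, `age`, `wt`, `sex` (1 = male) and,
#'   optionally, the laboratory covariates.
#' @export
generate_demographics <- function(n, seed = NULL, include_labs = TRUE) {
  if (!is.numeric(n) || length(n) != 1 || n < 0)
    stop("`n` must be a non-negative count", call. = FALSE)
  n <- as.integer(n)
  with_seed(seed, {
    out <- data.frame(
      id = seq_len(n),
      age = if (n) .rtruncnorm1(n, 72.95, 4.47, 67, 82) else numeric(0),
      wt = if (n) .rtruncnorm1(n, 65.63, 9.34, 49, 80) else numeric(0),
      sex = if (n) rbinom(n, 1, 0.55) else integer(0))
    if (include_labs && n) {
      for (nm in names(.COHORT_LABS)) {
        m <- .COHORT_LABS[[nm]]
        out[[nm]] <- .rtruncnorm1(n, m[1], m[2], m[3], m[4])
      }
    }
    out
  })
}

#' Generate a synthetic PK/PD study
#'
#' Simulates the full study: demographics, per-subject weight-scaled dosing,
#' individual parameters sampled from the population model, noisy plasma
#' concentrations at the 19 protocol sampling times (proportional error) and
#' synchronous noisy BIS readings (additive error). Observations below the
#' limit of quantification are flagged (`BLQ = 1`), not deleted; the pre-dose
#' sample is always BLQ because the true concentration is zero.
#'
#' The returned dataset is in event format, one row per dose event or
#' observation, with columns `ID, TIME, EVID, AMT, RATE, DV, MDV, BLQ, CMT,
#' WT, AGE, SEX` (+ laboratory covariates when requested). `CMT` is 1 for
#' doses and plasma observations and 4 for BIS rows. The true (noise-free)
#' individual parameters are attached as `attr(x, "truth")` for recovery
#' testing, and the design/population as `attr(x, "design")` /
#' `attr(x, "population")`.
#'
#' @param design a [study_design()].
#' @param pop a [population_model()].
#' @param seed optional seed; the whole study is reproducible from
#'   `(design, pop, seed)`.
#' @return a `study_dataset` data.frame as described above.
#' @examples
#' ds <- generate_study(study_design(n_subjects = 2), seed = 42)
#' head(ds)
#' @export
generate_study <- function(design = study_design(),
                           pop = default_population_model(), seed = NULL) {
  stopifnot(inherits(design, "study_design"), inherits(pop, "population_model"))
  with_seed(seed, {
    demo <- generate_demographics(design$n_subjects,
                                  include_labs = design$include_labs)
    rows <- vector("list", design$n_subjects)
    truth <- vector("list", design$n_subjects)
    for (i in seq_len(design$n_subjects)) {
      dur <- runif(1, design$infusion_duration_range[1],
                   design$infusion_duration_range[2])
      if (dur <= 0) stop("infusion duration must be positive", call. = FALSE)
      wt <- demo$wt[i]; age <- demo$age[i]
      reg <- study_regimen(wt, design$bolus_mgkg, design$bolus_duration,
                           design$maintenance_mgkg_h, design$maintenance_start,
                           maintenance_duration = dur)
      ind <- sample_individual(pop, wt, age)
      st <- pk_sample_times(design, design$maintenance_start + dur)
      tr <- simulate_profile(ind$pk, ind$pd, reg, st)
      cp_obs <- apply_residual(tr$Cp, "pk", pop$res)
      bis_obs <- apply_residual(tr$BIS, "pd", pop$res)

      ev <- .events_matrix(reg)
      dose <- data.frame(ID = i, TIME = ev[, 1], EVID = 1,
                         AMT = ev[, 2] * ev[, 3], RATE = ev[, 2],
                         DV = NA_real_, MDV = 1, BLQ = 0, CMT = 1,
                         WT = wt, AGE = age, SEX = demo$sex[i])
      pk <- data.frame(ID = i, TIME = st, EVID = 0, AMT = NA_real_,
                       RATE = NA_real_, DV = cp_obs, MDV = 0,
                       BLQ = as.integer(cp_obs < design$lloq), CMT = 1,
                       WT = wt, AGE = age, SEX = demo$sex[i])
      pd <- data.frame(ID = i, TIME = st, EVID = 0, AMT = NA_real_,
                       RATE = NA_real_, DV = bis_obs, MDV = 0, BLQ = 0,
                       CMT = 4, WT = wt, AGE = age, SEX = demo$sex[i])
      sub <- rbind(dose, pk, pd)
      if (design$include_labs)
        for (nm in names(.COHORT_LABS)) sub[[nm]] <- demo[[nm]][i]
      sub <- sub[order(sub$TIME, sub$EVID, sub$CMT), ]
      rows[[i]] <- sub
      truth[[i]] <- data.frame(
        ID = i, WT = wt, AGE = age, DUR = dur,
        V1 = ind$pk$V1, V2 = ind$pk$V2, V3 = ind$pk$V3, CL = ind$pk$CL,
        Q2 = ind$pk$Q2, Q3 = ind$pk$Q3, KE0 = ind$pd$ke0, E0 = ind$pd$E0,
        EMAX = ind$pd$Emax, EC50 = ind$pd$EC50, GAMMA = ind$pd$gamma,
        t(setNames(ind$eta, paste0("ETA_", names(ind$eta)))))
    }
    ds <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    if (is.null(ds)) ds <- .empty_dataset(design$include_labs)
    structure(ds, truth = do.call(rbind, truth), design = design,
              population = pop, class = c("study_dataset", "data.frame"))
  })
}

.DATASET_COLS <- c("ID", "TIME", "EVID", "AMT", "RATE", "DV", "MDV", "BLQ",
                   "CMT", "WT", "AGE", "SEX")

.empty_dataset <- function(include_labs = FALSE) {
  ds <- as.data.frame(setNames(rep(list(numeric(0)), length(.DATASET_COLS)),
                               .DATASET_COLS))
  if (include_labs)
    for (nm in names(.COHORT_LABS)) ds[[nm]] <- numeric(0)
  ds
}

#' Read and write event-format study datasets
#'
#' Plain CSV round trip of the event-format table produced by
#' [generate_study()]. `read_dataset()` validates the header (all required
#' columns present) and that times are sorted within each subject, naming the
#' offending row on failure. Extra columns (e.g. laboratory covariates) are
#' preserved.
#'
#' @param ds a `study_dataset` data.frame.
#' @param path file path (CSV).
#' @return `read_dataset()` returns a `study_dataset`; `write_dataset()`
#'   returns `path` invisibly.
#' @export
write_dataset <- function(ds, path) {
  if (!is.data.frame(ds)) stop("`ds` must be a data.frame", call. = FALSE)
  miss <- setdiff(.DATASET_COLS, names(ds))
  if (length(miss))
    stop("dataset is missing required columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  write.csv(as.data.frame(ds)[, c(.DATASET_COLS,
                                  setdiff(names(ds), .DATASET_COLS))],
            path, row.names = FALSE, quote = FALSE, na = ".")
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ds <- read.csv(path, na.strings = c(".", "NA", ""))
  miss <- setdiff(.DATASET_COLS, names(ds))
  if (length(miss))
    stop("dataset file is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (id in unique(ds$ID)) {
    tt <- ds$TIME[ds$ID == id]
    if (is.unsorted(tt)) {
      bad <- which(ds$ID == id)[which(diff(tt) < 0)[1] + 1]
      stop(sprintf("times are not sorted within subject %s (file row %d)",
                   id, bad + 1L), call. = FALSE)
    }
  }
  obs <- ds$EVID == 0
  if (any(obs & is.na(ds$DV)))
    stop(sprintf("observation row without a DV value (file row %d)",
                 which(obs & is.na(ds$DV))[1] + 1L), call. = FALSE)
  dose <- ds$EVID == 1
  if (any(dose & (is.na(ds$AMT) | ds$AMT <= 0)))
    stop(sprintf("dose row with missing or non-positive AMT (file row %d)",
                 which(dose & (is.na(ds$AMT) | ds$AMT <= 0))[1] + 1L),
         call. = FALSE)
  structure(ds, class = c("study_dataset", "data.frame"))
}

# split a dataset into per-subject pieces used by the estimator
.split_subjects <- function(ds, cmt = 1) {
  ids <- unique(ds$ID)
  lapply(ids, function(id) {
    sub <- ds[ds$ID == id, , drop = FALSE]
    dose <- sub[sub$EVID == 1, , drop = FALSE]
    obs <- sub[sub$EVID == 0 & sub$CMT == cmt & sub$BLQ == 0, , drop = FALSE]
    ev <- if (nrow(dose))
      cbind(dose$TIME, dose$RATE, dose$AMT / dose$RATE)
    else matrix(numeric(0), ncol = 3)
    cov1 <- sub[1, setdiff(names(sub), c(.DATASET_COLS[1:9])), drop = FALSE]
    list(id = id, times = obs$TIME, dv = obs$DV, events = ev,
         wt = sub$WT[1], age = sub$AGE[1], covariates = cov1)
  })
}
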