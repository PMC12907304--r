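test_that("system matrix carries the mammillary rate constants", {
  pk <- table2_pk()
  A <- build_system_matrix(pk, ke0 = 1.09)
  expect_equal(A[2, 1], pk$Q2 / pk$V1)
  expect_equal(A[2, 2], -pk$Q2 / pk$V2)
  expect_equal(A[3, 1], pk$Q3 / pk$V1)
  expect_equal(A[1, 1], -(pk$CL + pk$Q2 + pk$Q3) / pk$V1)
  expect_equal(A[4, 1], 1.09 * 1000 / pk$V1)
  expect_equal(A[4, 4], -1.09)
  # decoupled peripheral compartments: central amount decays at CL/V1
  pk0 <- pk_parameters(Q2 = 1e-12, Q3 = 1e-12)
  A0 <- build_system_matrix(pk0, 1)
  expect_equal(A0[1, 1], -(pk0$CL + 2e-12) / pk0$V1, tolerance = 1e-10)
  expect_lt(max(abs(A0[1, 2:3])), 1e-10)
  expect_error(build_system_matrix(pk, -1), "ke0")
  expect_error(pk_parameters(V1 = -2), "V1")
})

test_that("disposition eigenvalues are real, negative, distinct (eigen oracle)", {
  A <- build_system_matrix(table2_pk(), 1.09)[1:3, 1:3]
  ev <- eigen(A)$values
  expect_true(all(Im(ev) == 0))
  expect_true(all(Re(ev) < 0))
  expect_equal(length(unique(round(Re(ev), 10))), 3)
  # property: random admissible parameter sets give real negative spectra
  withr_seed <- 421
  set.seed(withr_seed)
  for (i in 1:10) {
    ev <- eigen(build_system_matrix(random_pk(), runif(1, 0.1, 5))[1:3, 1:3],
                only.values = TRUE)$values
    expect_true(all(abs(Im(ev)) < 1e-12) && all(Re(ev) < 0))
  }
})

test_that("BIS model reproduces its anchor points and is monotone", {
  pd <- table3_pd()
  expect_equal(bis_from_ce(pd, 0), 93.40)
  expect_equal(bis_from_ce(pd, pd$EC50), 93.40 - 45.77 / 2) # 70.515
  # far above EC50 the curve approaches E0 - Emax from above
  hi <- bis_from_ce(pd, 100 * pd$EC50)
  expect_gt(hi, 93.40 - 45.77)
  expect_lt(hi, 93.40 - 45.77 + 0.01)
  ce <- seq(0, 2000, by = 5)
  expect_true(all(diff(bis_from_ce(pd, ce)) < 0))
  expect_error(bis_from_ce(pd, -1), "non-negative")
  expect_error(pd_parameters(Emax = 95, E0 = 93.4), "Emax")
})

test_that("empty regimen gives zero drug and baseline BIS", {
  tr <- simulate_profile(table2_pk(), table3_pd(), regimen(list()), 0:60)
  expect_true(all(tr$Cp == 0) && all(tr$Ce == 0))
  expect_true(all(tr$BIS == 93.40))
})

test_that("constant infusion reaches rate/clearance steady state", {
  # R = 0.66 mg/min, CL = 1.01 L/min -> Cp_ss = 1000 R / CL = 653.5 ng/mL
  tr <- simulate_profile(table2_pk(), table3_pd(),
                         regimen(dose_event(0, 0.66, 2e5)), c(1.9e5))
  expect_equal(tr$Cp, 1000 * 0.66 / 1.01, tolerance = 1e-8)
})

test_that("closed-form trajectories match an adaptive ODE integrator", {
  skip_if_not_installed("deSolve")
  ode_oracle <- function(pk, ke0, events, times) {
    rate_fn <- function(t) {
      r <- 0
      for (i in seq_len(nrow(events)))
        if (t >= events[i, 1] && t < events[i, 1] + events[i, 3])
          r <- r + events[i, 2]
      r
    }
    deriv <- function(t, y, p) {
      with(pk, {
        dA1 <- rate_fn(t) - (CL + Q2 + Q3) / V1 * y[1] + Q2 / V2 * y[2] +
          Q3 / V3 * y[3]
        dA2 <- Q2 / V1 * y[1] - Q2 / V2 * y[2]
        dA3 <- Q3 / V1 * y[1] - Q3 / V3 * y[3]
        dCe <- ke0 * (1000 * y[1] / V1 - y[4])
        list(c(dA1, dA2, dA3, dCe))
      })
    }
    # integrate piecewise so the integrator never smooths over a rate jump
    bks <- sort(unique(c(0, events[, 1], events[, 1] + events[, 3], times)))
    out <- deSolve::ode(c(0, 0, 0, 0), bks, deriv, NULL, method = "lsoda",
                        rtol = 1e-11, atol = 1e-12)
    out[match(times, bks), -1, drop = FALSE]
  }

  # the typical 66-kg protocol regimen, checked at interior times
  pk <- table2_pk(); pd <- table3_pd()
  reg <- regimen(dose_event(0, 26.4, 1), dose_event(1, 0.66, 119))
  times <- c(10, 30, 120)
  tr <- simulate_profile(pk, pd, reg, times)
  orc <- ode_oracle(pk, pd$ke0, cipropkpd:::.events_matrix(reg), times)
  expect_equal(tr$Cp, 1000 * orc[, 1] / pk$V1, tolerance = 1e-6)
  expect_equal(tr$Ce, orc[, 4], tolerance = 1e-6)

  # property: random parameters and regimens agree everywhere
  set.seed(99)
  for (rep in 1:5) {
    pk <- random_pk()
    ke0 <- runif(1, 0.2, 3)
    pdx <- pd_parameters(ke0 = ke0)
    reg <- random_regimen(wt = runif(1, 49, 80))
    times <- sort(runif(8, 0.5, 400))
    tr <- simulate_profile(pk, pdx, reg, times)
    orc <- ode_oracle(pk, ke0, cipropkpd:::.events_matrix(reg), times)
    expect_equal(tr$A1, orc[, 1], tolerance = 1e-6)
    expect_equal(tr$A2, orc[, 2], tolerance = 1e-6)
    expect_equal(tr$A3, orc[, 3], tolerance = 1e-6)
    expect_equal(tr$Ce, orc[, 4], tolerance = 1e-6)
  }
})

test_that("mass balance holds to solver accuracy", {
  # eliminated mass recovered from the state integral identity
  # int_x over a segment = A^{-1} (x(t1) - x(t0) - b dt)
  set.seed(7)
  for (rep in 1:4) {
    pk <- if (rep == 1) table2_pk() else random_pk()
    reg <- random_regimen()
    ev <- cipropkpd:::.events_matrix(reg)
    A <- build_system_matrix(pk, 1)[1:3, 1:3]
    k10 <- pk$CL / pk$V1
    bks <- sort(unique(c(0, ev[, 1], ev[, 1] + ev[, 3], 250, 480)))
    tr <- simulate_profile(pk, table3_pd(), reg, bks)
    x <- t(as.matrix(tr[, c("A1", "A2", "A3")]))
    eliminated <- 0
    for (s in seq_len(length(bks) - 1)) {
      rate <- sum(ev[, 2][ev[, 1] <= bks[s] + 1e-9 &
                          ev[, 1] + ev[, 3] > bks[s] + 1e-9])
      b <- c(rate, 0, 0)
      intx <- solve(A, x[, s + 1] - x[, s] - b * (bks[s + 1] - bks[s]))
      eliminated <- eliminated + k10 * intx[1]
    }
    infused <- sum(ev[, 2] * pmin(ev[, 3], pmax(0, 480 - ev[, 1])))
    remaining <- sum(x[, length(bks)])
    expect_equal(infused - remaining, as.numeric(eliminated),
                 tolerance = 1e-8)
  }
})

test_that("the linear system superposes", {
  pk <- table2_pk(); pd <- table3_pd()
  regA <- regimen(dose_event(0, 26.4, 1))
  regB <- regimen(dose_event(5, 0.88, 100))
  regAB <- regimen(dose_event(0, 26.4, 1), dose_event(5, 0.88, 100))
  tt <- c(0.5, 2, 7, 30, 90, 150, 300)
  trA <- simulate_profile(pk, pd, regA, tt)
  trB <- simulate_profile(pk, pd, regB, tt)
  trAB <- simulate_profile(pk, pd, regAB, tt)
  for (col in c("A1", "A2", "A3", "Cp", "Ce"))
    expect_equal(trAB[[col]], trA[[col]] + trB[[col]],
                 tolerance = 1e-10)
})

test_that("effect-site concentration peaks after plasma", {
  tt <- seq(0, 30, by = 0.05)
  tr <- simulate_profile(table2_pk(), table3_pd(),
                         regimen(dose_event(0, 26.4, 1)), tt)
  expect_gt(tt[which.max(tr$Ce)], tt[which.max(tr$Cp)])
})

test_that("regimen bookkeeping and input validation hold", {
  reg <- study_regimen(66, maintenance_duration = 115)
  expect_equal(total_dose(reg), 0.4 * 66 + 0.8 * 66 / 60 * 115)
  expect_error(simulate_profile(table2_pk(), table3_pd(), reg, c(3, 1)),
               "sorted")
  expect_error(simulate_profile(table2_pk(), table3_pd(), reg, c(-2, 1)),
               "non-negative")
  expect_error(dose_event(0, -1, 10), "rate")
  expect_error(dose_event(0, 1, 0), "duration")
})
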