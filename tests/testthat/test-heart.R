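# Time-varying elastance chambers and dynamic valves.

test_that("elastance hits its configured extrema over one cycle", {
  T <- 0.857
  cases <- list(
    patient_heart$atrium,
    patient_heart$ventricle,
    elastance_params(E_min = 0.05, E_max = 2.5, tau1 = 0.12, tau2 = 0.4,
                     m1 = 2, m2 = 25, t_onset = 0.3, V0 = 8, Ks = 0))
  for (p in cases) {
    tt <- seq(0, T, length.out = 200001)
    E <- evaluate_elastance(tt, p, T)
    expect_equal(min(E), p$E_min, tolerance = 1e-6)
    expect_equal(max(E), p$E_max, tolerance = 1e-6)
  }
})

test_that("elastance is E_min at contraction onset and periodic", {
  p <- patient_heart$ventricle
  T <- 0.857
  expect_equal(evaluate_elastance(p$t_onset, p, T), p$E_min)
  tt <- c(0.1, 0.33, 0.61)
  expect_equal(evaluate_elastance(tt, p, T),
               evaluate_elastance(tt + 3 * T, p, T))
})

test_that("atrial activation shape matches direct evaluation at tau1", {
  # at one systolic time constant past onset the unscaled shape is
  # 0.5 / (1 + (tau1/tau2)^m2), here 0.5/(1 + 0.4^30)
  p <- patient_heart$atrium
  T <- 0.857
  shape_expected <- 0.5 / (1 + (p$tau1 / p$tau2)^p$m2)
  k <- elastance_k_reference(p, T)
  E_expected <- k * shape_expected + p$E_min
  expect_equal(evaluate_elastance(p$t_onset + p$tau1, p, T), E_expected,
               tolerance = 1e-9)
})

test_that("elastance rejects invalid parameters", {
  expect_error(elastance_params(0.2, 0.4, -0.1, 0.2, 20, 30, 0, 5, 0),
               "tau")
  expect_error(elastance_params(0.4, 0.2, 0.1, 0.2, 20, 30, 0, 5, 0),
               "E_max")
  expect_error(evaluate_elastance(0, patient_heart$atrium, T = -1),
               "invalid")
})

test_that("chamber pressure follows the source-resistance elastance relation", {
  p <- patient_heart$ventricle
  # V = V0 gives zero pressure regardless of outflow
  expect_equal(chamber_pressure(p$V0, 123, 1.5, p), 0)
  # Ks = 0 degenerates to E (V - V0)
  p0 <- elastance_params(p$E_min, p$E_max, p$tau1, p$tau2, p$m1, p$m2,
                         p$t_onset, p$V0, Ks = 0)
  expect_equal(chamber_pressure(80, 500, 1.2, p0), 1.2 * (80 - p0$V0))
  # end-diastolic ventricle of the fixture patient: E = 0.065, V = 74.4
  expect_equal(chamber_pressure(74.4, 0, 0.065, p), 0.065 * (74.4 - 10.5))
  expect_equal(chamber_pressure(74.4, 0, 0.065, p), 4.1535)
})

test_that("valve state dynamics saturate at the fully open/closed limits", {
  avv <- patient_heart$avv
  expect_equal(valve_state_derivative(1, 10, avv), 0)
  expect_equal(valve_state_derivative(0, -10, avv), 0)
  expect_equal(valve_state_derivative(0.5, 10, avv), 0.5 * 8 * 10)
  # closing branch uses K_vc
  aov <- patient_heart$aov
  expect_equal(valve_state_derivative(0.5, -10, aov), 0.5 * 2 * (-10))
})

test_that("valve flow derivative: equilibrium, odd drag, unit-checked inertance", {
  aov <- patient_heart$aov
  expect_equal(valve_flow_derivative(0, 50, 50, 1, aov, rho_blood), 0)
  # Bernoulli drag is odd in Q: the drag-induced part changes sign
  base <- valve_flow_derivative(0, 60, 50, 0.7, aov, rho_blood)
  fp <- valve_flow_derivative(150, 60, 50, 0.7, aov, rho_blood)
  fm <- valve_flow_derivative(-150, 60, 50, 0.7, aov, rho_blood)
  expect_equal(fp - base, -(fm - base), tolerance = 1e-12)
  # fully open aortic valve, dP = 1 mmHg: dQ/dt = dP A_eff / (rho l_eff),
  # cross-checked by independent SI arithmetic (133.322 Pa, m^3/s^2 -> ml/s^2)
  expected_si <- 133.322 * 1.68e-4 / (1060 * 0.08) * 1e6
  expect_equal(valve_flow_derivative(0, 51, 50, 1, aov, rho_blood),
               expected_si, tolerance = 1e-6)
})

test_that("closed heart conserves chamber volumes", {
  # adverse gradients across both valves at any phase: atrium at its
  # reference volume (zero pressure) and aortic pressure above anything
  # the ventricle can develop
  s <- heart_state(V_A = 5.5, V_V = 74.4, Q_AVV = 0, Q_AAo = 0,
                   xi_AVV = 0, xi_AoV = 0, t = 0.3)
  out <- step_heart(s, Q_PA_in = 0, P_AAo = 300, dt = 1e-3,
                    params = patient_heart)
  # with zero inflow and both valves closed nothing moves
  expect_equal(out[["V_A"]], 5.5)
  expect_equal(out[["V_V"]], 74.4)
  expect_equal(out[["Q_AVV"]], 0)
  expect_equal(out[["Q_AAo"]], 0)
})

test_that("chamber volume changes equal the integrated interface fluxes", {
  # mid-diastole, atrioventricular valve open and filling
  s <- heart_state(V_A = 40, V_V = 50, Q_AVV = 50, Q_AAo = 0,
                   xi_AVV = 0.8, xi_AoV = 0, t = 0.55 * 0.857)
  dt <- 2e-4
  Q_PA <- 30
  tot0 <- s[["V_A"]] + s[["V_V"]]
  vol_in <- 0; out_flux <- 0
  for (i in 1:500) {
    s <- step_heart(s, Q_PA_in = Q_PA, P_AAo = 55, dt = dt,
                    params = patient_heart)
    vol_in <- vol_in + dt * Q_PA
    out_flux <- out_flux + dt * attr(s, "Q_AAo_bar")
  }
  expect_equal(s[["V_A"]] + s[["V_V"]], tot0 + vol_in - out_flux,
               tolerance = 1e-12)
})

test_that("valve states remain in [0, 1] under arbitrary pressure forcing", {
  set.seed(42)
  avv <- patient_heart$avv
  xi <- 0.5
  dt <- 1e-3
  for (i in 1:5000) {
    dP <- rnorm(1, 0, 40)
    xi <- xi + dt * valve_state_derivative(xi, dP, avv)
    xi <- min(max(xi, 0), 1)
    expect_true(xi >= 0 && xi <= 1)
  }
})

test_that("heart RK4 matches a reference integrator and converges at order 4", {
  skip_if_not_installed("deSolve")
  hp <- patient_heart
  t0 <- 0.55 * hp$T  # diastole: AVV open, AoV closed, no branch switching
  y0 <- c(V_A = 40, V_V = 50, Q_AVV = 50, Q_AAo = 0, xi_AVV = 0.8,
          xi_AoV = 0)
  parms <- list(hp = hp, Q_PA = 30, P_AAo = 55, rho = rho_blood,
                kA = elastance_k_reference(hp$atrium, hp$T),
                kV = elastance_k_reference(hp$ventricle, hp$T))
  t_end <- t0 + 0.02
  ref <- deSolve::lsoda(y0, c(t0, t_end), heart_rhs_reference, parms,
                        rtol = 1e-13, atol = 1e-13)
  y_ref <- ref[2, 2:7]

  run_rk4 <- function(n) {
    s <- heart_state(y0[1], y0[2], y0[3], y0[4], y0[5], y0[6], t = t0)
    dt <- (t_end - t0) / n
    for (i in seq_len(n)) s <- step_heart(s, 30, 55, dt, hp)
    unname(unclass(s)[1:6])
  }
  err <- function(n) max(abs(run_rk4(n) - unname(y_ref)) /
                           pmax(abs(unname(y_ref)), 1))
  # tight agreement at moderate resolution
  expect_lt(err(200), 1e-8)
  # observed convergence order of the one-step integrator
  e1 <- err(10); e2 <- err(20); e3 <- err(40)
  order21 <- log2(e1 / e2); order32 <- log2(e2 / e3)
  expect_gt(order21, 3.8)
  expect_gt(order32, 3.8)
})

test_that("heart stepper reports numerical blowup with the offending variable", {
  s <- heart_state(V_A = 35, V_V = 74, Q_AVV = 1e308, Q_AAo = 0,
                   xi_AVV = 1, xi_AoV = 0, t = 0)
  expect_error(step_heart(s, 0, 50, 1e-3, patient_heart), "non-finite")
})
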