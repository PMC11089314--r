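# 1-D compliant-vessel mechanics and the pulse-wave solver.

test_that("stiffness from PWV inverts to the reference wave speed", {
  A0 <- 4.9087
  beta <- beta_from_pwv(535, A0, rho_blood)
  expect_equal(wave_speed(A0, A0, beta, rho_blood), 535, tolerance = 1e-14)
  # quadrupling the density at fixed beta halves the wave speed
  expect_equal(wave_speed(A0, A0, beta, 4 * rho_blood), 535 / 2,
               tolerance = 1e-14)
  # ascending-aorta inlet value, cross-checked by independent SI arithmetic:
  # beta = 2 rho c^2 sqrt(A0) = 2*1060*5.35^2*sqrt(4.9087e-4) Pa m
  beta_si <- 2 * 1060 * 5.35^2 * sqrt(4.9087e-4)          # Pa m
  beta_internal <- beta_si / 133.322 * 100                # mmHg cm
  expect_equal(beta, beta_internal, tolerance = 1e-4)
})

test_that("tube law is anchored at the reference state and monotone", {
  A0 <- 2.5; beta <- beta_from_pwv(300, A0, rho_blood); P0 <- 10
  expect_equal(tube_law_pressure(A0, A0, beta, P0), P0)
  A <- seq(0.5 * A0, 2 * A0, length.out = 200)
  expect_true(all(diff(tube_law_pressure(A, A0, beta, P0)) > 0))
  expect_error(tube_law_pressure(-1, A0, beta, P0), "positive")
  # pressure rise at 10% distension matches direct evaluation, and the
  # finite-difference c^2 = (A/rho) dP/dA at A0 recovers the wave speed
  dP <- tube_law_pressure(1.1 * A0, A0, beta, P0) - P0
  expect_equal(dP, (beta / A0) * (sqrt(1.1) - 1) * sqrt(A0), tolerance = 1e-12)
  h <- 1e-6
  dPdA <- (tube_law_pressure(A0 + h, A0, beta, P0) -
             tube_law_pressure(A0 - h, A0, beta, P0)) / (2 * h)
  expect_equal(sqrt(A0 / rho_blood * dPdA), 300, tolerance = 1e-6)
})

test_that("vessel meshing tapers linearly and covers the full length", {
  row <- patient$config$vessels[[1]]  # ascending aorta
  seg <- vessel_segment(row$name, row$L, row$D_in, row$D_out, row$PWV, 40,
                        row$node_in, row$node_out)
  mesh <- build_vessel_mesh(seg, 1, rho_blood)   # 1 mm cells
  expect_equal(mesh$L, 2.90)
  expect_equal(mesh$N * mesh$dx, mesh$L)
  # midpoint diameter (25.0 + 15.5)/2 = 20.25 mm
  A_mid <- stats::approx(mesh$x_cell, mesh$A0_cell, xout = mesh$L / 2)$y
  expect_equal(sqrt(4 * A_mid / pi) * 10, 20.25, tolerance = 1e-6)
  # untapered vessel gives a uniform reference area
  mesh_u <- uniform_vessel(50, 10, 3, 10, 5)
  expect_equal(length(unique(round(mesh_u$A0_cell, 12))), 1L)
})

test_that("uniform reference state is a fixed point of the solver", {
  mesh <- build_vessel_mesh(vessel_segment("taper", 60, 18, 9, 4, 25, 1, 2),
                            5, rho_blood)
  st <- vessel_state_uniform(mesh)
  bnd <- list(A_in = mesh$A0_face[1], U_in = 0,
              A_out = mesh$A0_face[mesh$N + 1], U_out = 0)
  for (i in 1:50) st <- advance_1d(st, mesh, 1e-4, bnd, mu_blood)
  expect_equal(st$A, mesh$A0_cell, tolerance = 1e-13)
  expect_equal(st$U, numeric(mesh$N), tolerance = 1e-13)
})

test_that("discrete volume change equals the recorded boundary fluxes exactly", {
  mesh <- uniform_vessel(100, 15, 4, 20, 5)
  st <- vessel_state_uniform(mesh)
  # perturb smoothly and drive with a pulsed inflow against a resistor
  st$A <- st$A * (1 + 0.02 * sin(seq(0, pi, length.out = mesh$N)))
  dt <- 2e-4
  V0 <- vessel_volume(st, mesh)
  net <- 0
  for (i in 1:400) {
    fin <- couple_1d_0d(st, mesh, "in",
                        list(type = "flux", F = 40 * sin(2 * pi * i * dt / 0.1)))
    fout <- couple_1d_0d(st, mesh, "out",
                         list(type = "resistor", R = 1.2, P_ext = 5))
    st <- advance_1d(st, mesh, dt,
                     list(A_in = fin$A, U_in = fin$U,
                          A_out = fout$A, U_out = fout$U), mu_blood)
    bf <- attr(st, "boundary_flux")
    net <- net + dt * (bf[["in"]] - bf[["out"]])
  }
  expect_equal(vessel_volume(st, mesh) - V0, net, tolerance = 1e-12)
})

test_that("small pulses propagate at the configured wave speed", {
  # long uniform vessel, closed ends; a small Gaussian area pulse splits
  # into two characteristics travelling at +-c0
  for (pwv in c(5.35, 2.81)) {
    mesh <- uniform_vessel(400, 20, pwv, 20, 5)
    c0 <- pwv * 100
    st <- vessel_state_uniform(mesh)
    x0 <- mesh$L / 2
    amp <- 0.005
    st$A <- st$A * (1 + amp * exp(-((mesh$x_cell - x0) / 2)^2))
    dt <- 0.3 * mesh$dx / c0
    wall <- list(type = "resistor", R = Inf, P_ext = 0)
    travel <- 12  # cm
    n <- round(travel / c0 / dt)
    res <- run_vessel(mesh, st, dt, n, wall, wall)
    # the right-going half of the pulse peaks at x0 + travel
    right <- mesh$x_cell > x0 + travel / 2
    x_peak <- peak_location(mesh$x_cell[right],
                            res$state$A[right] / mesh$A0_cell[right])
    measured_c <- (x_peak - x0) / (n * dt)
    expect_lt(abs(measured_c - c0) / c0, 0.02)
  }
})

test_that("solver enforces its CFL bound when asked", {
  mesh <- uniform_vessel(100, 15, 4, 20, 5)
  st <- vessel_state_uniform(mesh)
  bnd <- list(A_in = mesh$A0_face[1], U_in = 0,
              A_out = mesh$A0_face[mesh$N + 1], U_out = 0)
  expect_error(advance_1d(st, mesh, 1, bnd, mu_blood, check_cfl = TRUE),
               "CFL")
})
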