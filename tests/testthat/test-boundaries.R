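# Characteristic boundary coupling: terminal elements and junctions.

test_that("terminal resistor coupling satisfies Ohm's law at the face", {
  mesh <- uniform_vessel(100, 15, 4, 20, 5)
  st <- vessel_state_uniform(mesh, P = 24)   # distended, will discharge
  f <- couple_1d_0d(st, mesh, "out", list(type = "resistor", R = 1.5,
                                          P_ext = 6))
  expect_equal(f$Q, (f$P - 6) / 1.5, tolerance = 1e-8)
  # at a node_in face the flux is signed into the element as well
  g <- couple_1d_0d(st, mesh, "in", list(type = "resistor", R = 1.5,
                                         P_ext = 40))
  expect_equal(g$Q, (g$P - 40) / 1.5, tolerance = 1e-8)
  expect_lt(g$Q, 0)  # higher external pressure feeds the vessel
})

test_that("steady flow through a terminal resistor is Ohmic end to end", {
  mesh <- uniform_vessel(60, 12, 3, 20, 5)
  st <- vessel_state_uniform(mesh)
  dt <- 1e-4
  res <- run_vessel(mesh, st, dt, 12000,
                    el_in = list(type = "flux", F = 20),
                    el_out = list(type = "resistor", R = 1.1, P_ext = 5))
  st <- res$state
  fout <- couple_1d_0d(st, mesh, "out", list(type = "resistor", R = 1.1,
                                             P_ext = 5))
  expect_equal(fout$Q, 20, tolerance = 1e-4)          # steady throughput
  expect_equal(fout$Q, (fout$P - 5) / 1.1, tolerance = 1e-8)
})

test_that("a blocked end reflects an incident pulse positively", {
  mesh <- uniform_vessel(300, 20, 3, 10, 5)
  c0 <- 300
  st <- vessel_state_uniform(mesh)
  amp <- 0.004
  x0 <- 10
  # right-travelling characteristic pulse: dU = c dA/A ~ matched signs
  bump <- amp * exp(-((mesh$x_cell - x0) / 2)^2)
  st$A <- mesh$A0_cell * (1 + bump)
  st$U <- c0 * bump        # right-going characteristic: dU = c dA/A
  dt <- 0.3 * mesh$dx / c0
  wall <- list(type = "resistor", R = Inf, P_ext = 0)
  P_amp_in <- max(vessel_pressure(st, mesh)) - 10
  # run until the pulse has hit the far wall and returned 12 cm
  n <- round(((mesh$L - x0) + 12) / c0 / dt)
  res <- run_vessel(mesh, st, dt, n, wall, wall)
  P_back <- vessel_pressure(res$state, mesh)
  # the reflected pulse has the same (positive) pressure sign
  expect_gt(max(P_back) - 10, 0.5 * P_amp_in)
  i_peak <- which.max(P_back)
  expect_lt(mesh$x_cell[i_peak], mesh$L - 6)  # travelling back, not stuck
})

test_that("a characteristic-impedance termination is nearly reflectionless", {
  mesh <- uniform_vessel(300, 20, 3, 10, 5)
  c0 <- 300
  Z0 <- rho_blood * c0 / mesh$A0_cell[1]
  st <- vessel_state_uniform(mesh)
  amp <- 0.004
  x0 <- 10
  bump <- amp * exp(-((mesh$x_cell - x0) / 2)^2)
  st$A <- mesh$A0_cell * (1 + bump)
  st$U <- c0 * bump
  P_amp_in <- max(vessel_pressure(st, mesh)) - 10
  dt <- 0.3 * mesh$dx / c0
  # run until the pulse has fully left through the matched outlet
  n <- round(((mesh$L - x0) + 15) / c0 / dt)
  res <- run_vessel(mesh, st, dt, n,
                    el_in = list(type = "resistor", R = Inf, P_ext = 0),
                    el_out = list(type = "resistor", R = Z0, P_ext = 10))
  P_back <- vessel_pressure(res$state, mesh)
  # linear theory: reflection coefficient (R - Z0)/(R + Z0) = 0
  expect_lt(max(abs(P_back - 10)) / P_amp_in, 0.02)
})

test_that("junctions conserve mass and total pressure to tight residuals", {
  mesh_p <- uniform_vessel(60, 14, 3, 8, 5)
  mesh_d <- uniform_vessel(60, 10, 3, 8, 5)
  st_p <- vessel_state_uniform(mesh_p, P = 9)
  st_p$U <- st_p$U + 30
  st_d1 <- vessel_state_uniform(mesh_d, P = 8.2)
  st_d2 <- vessel_state_uniform(mesh_d, P = 8.4)
  sol <- junction_solve(list(
    list(state = st_p, mesh = mesh_p, side = "out"),
    list(state = st_d1, mesh = mesh_d, side = "in"),
    list(state = st_d2, mesh = mesh_d, side = "in")), node = 99)
  r <- attr(sol, "residual")
  expect_lt(abs(r[1]), 1e-10)
  expect_true(all(abs(r[-1]) < 1e-10))
  # verify against an independent brute-force solve of the same system
  fi <- lapply(list(list(st_p, mesh_p, "out"), list(st_d1, mesh_d, "in"),
                    list(st_d2, mesh_d, "in")),
               function(x) fontansim:::.face_info(x[[1]], x[[2]], x[[3]]))
  s <- sapply(fi, `[[`, "s"); kc <- sapply(fi, `[[`, "kc")
  W <- sapply(fi, `[[`, "W"); A0 <- sapply(fi, `[[`, "A0")
  beta <- sapply(fi, `[[`, "beta"); P0 <- sapply(fi, `[[`, "P0")
  resid <- function(A) {
    U <- W - s * 4 * kc * A^0.25
    P <- P0 + beta / A0 * (sqrt(A) - sqrt(A0))
    Pt <- P + 0.5 * rho_blood * U^2
    c(sum(s * A * U), Pt[-1] - Pt[1])
  }
  # dense Newton with a finite-difference Jacobian, independent of the
  # package's analytic implementation
  A <- sapply(fi, `[[`, "A_init")
  for (it in 1:60) {
    r0 <- resid(A)
    J <- vapply(seq_along(A), function(j) {
      h <- 1e-8 * A[j]; Ah <- A; Ah[j] <- Ah[j] + h
      (resid(Ah) - r0) / h
    }, numeric(length(A)))
    A <- A - solve(J, r0)
  }
  expect_equal(sapply(sol, `[[`, "A"), A, tolerance = 1e-8)
})

test_that("two identical daughters split the parent flow symmetrically", {
  mesh_p <- uniform_vessel(60, 14, 3, 8, 5)
  mesh_d <- uniform_vessel(60, 10, 3, 8, 5)
  st_p <- vessel_state_uniform(mesh_p, P = 9); st_p$U <- st_p$U + 25
  st_d <- vessel_state_uniform(mesh_d, P = 8)
  sol <- junction_solve(list(
    list(state = st_p, mesh = mesh_p, side = "out"),
    list(state = st_d, mesh = mesh_d, side = "in"),
    list(state = st_d, mesh = mesh_d, side = "in")), node = 1)
  expect_equal(sol[[2]]$A, sol[[3]]$A, tolerance = 1e-14)
  expect_equal(sol[[2]]$U, sol[[3]]$U, tolerance = 1e-14)
  expect_equal(sol[[1]]$A * sol[[1]]$U, 2 * sol[[2]]$A * sol[[2]]$U,
               tolerance = 1e-9)
})

test_that("a vessel split by a junction matches the unsplit vessel", {
  # same tube, solved as one domain vs two sub-domains joined at a node
  whole <- uniform_vessel(200, 15, 3, 10, 5)
  half <- uniform_vessel(100, 15, 3, 10, 5)
  inflow <- function(t) 25 * sin(2 * pi * t / 0.4)^2
  dt <- 0.3 * whole$dx / 320
  n <- round(0.4 / dt)

  st_w <- vessel_state_uniform(whole)
  for (i in seq_len(n)) {
    t <- (i - 1) * dt
    fin <- couple_1d_0d(st_w, whole, "in", list(type = "flux", F = inflow(t)))
    fout <- couple_1d_0d(st_w, whole, "out",
                         list(type = "resistor", R = 0.8, P_ext = 5))
    st_w <- advance_1d(st_w, whole, dt,
                       list(A_in = fin$A, U_in = fin$U,
                            A_out = fout$A, U_out = fout$U), mu_blood)
  }

  st_a <- vessel_state_uniform(half); st_b <- vessel_state_uniform(half)
  for (i in seq_len(n)) {
    t <- (i - 1) * dt
    fin <- couple_1d_0d(st_a, half, "in", list(type = "flux", F = inflow(t)))
    jn <- junction_solve(list(list(state = st_a, mesh = half, side = "out"),
                              list(state = st_b, mesh = half, side = "in")),
                         node = 1)
    fout <- couple_1d_0d(st_b, half, "out",
                         list(type = "resistor", R = 0.8, P_ext = 5))
    st_a <- advance_1d(st_a, half, dt,
                       list(A_in = fin$A, U_in = fin$U,
                            A_out = jn[[1]]$A, U_out = jn[[1]]$U), mu_blood)
    st_b <- advance_1d(st_b, half, dt,
                       list(A_in = jn[[2]]$A, U_in = jn[[2]]$U,
                            A_out = fout$A, U_out = fout$U), mu_blood)
  }
  P_whole <- vessel_pressure(st_w, whole)
  P_split <- c(vessel_pressure(st_a, half), vessel_pressure(st_b, half))
  amp <- max(abs(P_whole - 10))
  expect_gt(amp, 0.5)  # the wave actually reached the probes
  expect_lt(max(abs(P_whole - P_split)) / amp, 0.05)
})
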