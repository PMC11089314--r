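# Shared fixtures and small independent oracles used across test files.

rho_blood <- fontansim:::rho_internal(1060)
mu_blood <- fontansim:::mu_internal(0.0035)

patient <- fixture_patient()

# heart parameter bundle of the built-in patient (absolute time constants)
patient_heart <- local({
  hc <- patient$config$heart
  T <- patient$config$settings$T
  heart_params(
    atrium = elastance_params(hc$atrium$E_min, hc$atrium$E_max,
                              hc$atrium$tau1_frac * T, hc$atrium$tau2_frac * T,
                              hc$atrium$m1, hc$atrium$m2,
                              hc$atrium$t_onset_frac * T, hc$atrium$V0,
                              hc$atrium$K_s),
    ventricle = elastance_params(hc$ventricle$E_min, hc$ventricle$E_max,
                                 hc$ventricle$tau1_frac * T,
                                 hc$ventricle$tau2_frac * T,
                                 hc$ventricle$m1, hc$ventricle$m2,
                                 hc$ventricle$t_onset_frac * T,
                                 hc$ventricle$V0, hc$ventricle$K_s),
    avv = valve_params(hc$avv$A_ann, hc$avv$l_eff, hc$avv$K_vo, hc$avv$K_vc),
    aov = valve_params(hc$aov$A_ann, hc$aov$l_eff, hc$aov$K_vo, hc$aov$K_vc),
    T = T, rho = rho_blood)
})

# Independent right-hand side of the heart equations, written directly from
# their definitions (elastance pressure relation, Bernoulli valve, valve
# state rates) for use with a reference integrator.  Assumes both valve
# branches stay away from switching points over the test interval.
elastance_shape_reference <- function(u, p) {
  g1 <- (u / p$tau1)^p$m1; g2 <- (u / p$tau2)^p$m2
  (g1 / (1 + g1)) / (1 + g2)
}

# scaling factor located on a dense grid (>= 1e5 points per cycle)
elastance_k_reference <- function(p, T) {
  u <- seq(0, T, length.out = 200001)
  (p$E_max - p$E_min) / max(elastance_shape_reference(u, p))
}

heart_rhs_reference <- function(t, y, parms) {
  hp <- parms$hp; Q_PA <- parms$Q_PA; P_AAo <- parms$P_AAo
  eA <- hp$atrium; eV <- hp$ventricle
  shape <- elastance_shape_reference
  E_A <- parms$kA * shape((t - eA$t_onset) %% hp$T, eA) + eA$E_min
  E_V <- parms$kV * shape((t - eV$t_onset) %% hp$T, eV) + eV$E_min
  P_A <- E_A * (y[1] - eA$V0) * (1 - eA$Ks * y[3])
  P_V <- E_V * (y[2] - eV$V0) * (1 - eV$Ks * y[4])
  bern <- function(Q, dP, xi, vp) {
    if (xi <= 1e-6 && dP < 0) return(0)  # valve held closed
    A_eff <- vp$A_ann * max(xi, 1e-6)
    B <- parms$rho / (2 * A_eff^2)
    L <- parms$rho * vp$l_eff / A_eff
    (dP - B * abs(Q) * Q) / L
  }
  gate <- function(xi, dP, vp)
    if (dP >= 0) (1 - xi) * vp$K_vo * dP else xi * vp$K_vc * dP
  list(c(Q_PA - y[3],
         y[3] - y[4],
         bern(y[3], P_A - P_V, y[5], hp$avv),
         bern(y[4], P_V - P_AAo, y[6], hp$aov),
         gate(y[5], P_A - P_V, hp$avv),
         gate(y[6], P_V - P_AAo, hp$aov)))
}

# half-sine single-cycle flow waveform with a given per-cycle volume
half_sine_flow <- function(volume, T, systole_frac = 0.35) {
  ts <- T * systole_frac
  amp <- volume * pi / (2 * ts)
  function(t) {
    u <- t %% T
    ifelse(u < ts, amp * sin(pi * u / ts), 0)
  }
}

# sub-cell peak location by three-point parabolic interpolation
peak_location <- function(x, y) {
  i <- which.max(y)
  if (i == 1L || i == length(y)) return(x[i])
  d <- 0.5 * (y[i - 1L] - y[i + 1L]) /
    (y[i - 1L] - 2 * y[i] + y[i + 1L])
  x[i] + d * (x[2L] - x[1L])
}

# build a single uniform test vessel + mesh
uniform_vessel <- function(L_mm = 200, D_mm = 20, pwv = 5.35, P0 = 40,
                           h_mm = 5, rho = rho_blood) {
  seg <- vessel_segment("test", L_mm, D_mm, D_mm, pwv, P0, 1, 2)
  build_vessel_mesh(seg, h_mm, rho)
}

# advance a stand-alone vessel with given boundary elements for n steps;
# elements as in couple_1d_0d; returns final state and cumulative boundary
# volume influx
run_vessel <- function(mesh, state, dt, n, el_in, el_out, mu = mu_blood) {
  vol_in <- 0
  for (i in seq_len(n)) {
    fin <- couple_1d_0d(state, mesh, "in", el_in)
    fout <- couple_1d_0d(state, mesh, "out", el_out)
    state <- advance_1d(state, mesh, dt,
                        list(A_in = fin$A, U_in = fin$U,
                             A_out = fout$A, U_out = fout$U), mu)
    bf <- attr(state, "boundary_flux")
    vol_in <- vol_in + dt * (bf[["in"]] - bf[["out"]])
  }
  list(state = state, vol_in = vol_in)
}
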