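# Waveform error metrics and cardiovascular indices.

make_wave <- function(values, kind = "pressure", site = "", T = 0.857) {
  n <- length(values)
  waveform_series((seq_len(n) - 1) * T / n, values, kind = kind, site = site)
}

test_that("identical waveforms give zero errors", {
  tt <- seq(0, 0.856, by = 1e-3)
  y <- 50 + 10 * sin(2 * pi * tt / 0.857)
  w <- waveform_series(tt, y, "pressure", "AAo")
  e <- rppe_and_mean_errors(w, w)
  expect_equal(e$rppe, 0)
  expect_equal(e$mean_error, 0)
})

test_that("a constant offset gives the closed-form mean error", {
  tt <- seq(0, 0.856, by = 1e-3)
  y <- 50 + 10 * sin(2 * pi * tt / 0.857)
  d <- 2.5
  sim <- waveform_series(tt, y + d, "pressure", "AAo")
  meas <- waveform_series(tt, y, "pressure", "AAo")
  e <- rppe_and_mean_errors(sim, meas, align = "none")
  expect_equal(e$mean_error, d / mean(y), tolerance = 1e-12)
})

test_that("point-wise pressure error matches hand evaluation", {
  # two samples: errors |0|/10 and |2|/10 -> RPPE = 10%
  sim <- make_wave(c(10, 12))
  meas <- make_wave(c(10, 10))
  e <- rppe_and_mean_errors(sim, meas, rate = 2 / 0.857, align = "none")
  expect_equal(e$rppe, 0.1, tolerance = 1e-12)
})

test_that("ventricular pressure and flow use max-normalisation", {
  tt <- seq(0, 0.856, by = 1e-3)
  y <- 40 + 30 * sin(2 * pi * tt / 0.857)^2
  d <- 3
  sim_v <- waveform_series(tt, y + d, "pressure", "ventricle")
  meas_v <- waveform_series(tt, y, "pressure", "ventricle")
  e_v <- rppe_and_mean_errors(sim_v, meas_v, align = "none")
  expect_equal(e_v$rppe, d / max(y), tolerance = 1e-10)
  # the same signals treated as vascular pressure normalise point-wise
  sim_p <- waveform_series(tt, y + d, "pressure", "AAo")
  meas_p <- waveform_series(tt, y, "pressure", "AAo")
  e_p <- rppe_and_mean_errors(sim_p, meas_p, align = "none")
  expect_equal(e_p$rppe, mean(d / y), tolerance = 1e-10)
  expect_gt(e_p$rppe, e_v$rppe)  # the two conventions genuinely differ here
  # flows always normalise by the cycle maximum of the measurement
  sim_q <- waveform_series(tt, y + d, "flow", "AAo")
  meas_q <- waveform_series(tt, y, "flow", "AAo")
  expect_equal(rppe_and_mean_errors(sim_q, meas_q, align = "none")$rppe,
               d / max(y), tolerance = 1e-10)
})

test_that("RPPE is invariant to a common shift but not a relative one", {
  tt <- seq(0, 0.856, by = 1e-3)
  base <- 50 + 10 * sin(2 * pi * tt / 0.857) + 3 * cos(4 * pi * tt / 0.857)
  shift <- function(y, k) c(y[(k + 1):length(y)], y[1:k])
  sim <- waveform_series(tt, base * 1.03, "pressure", "AAo")
  meas <- waveform_series(tt, base, "pressure", "AAo")
  e0 <- rppe_and_mean_errors(sim, meas, align = "foot")$rppe
  sim_s <- waveform_series(tt, shift(base * 1.03, 100), "pressure", "AAo")
  meas_s <- waveform_series(tt, shift(base, 100), "pressure", "AAo")
  e_both <- rppe_and_mean_errors(sim_s, meas_s, align = "foot")$rppe
  expect_equal(e_both, e0, tolerance = 1e-6)
  # foot alignment also absorbs a shift of only one signal
  e_one <- rppe_and_mean_errors(sim_s, meas, align = "foot")$rppe
  expect_equal(e_one, e0, tolerance = 1e-6)
  # without alignment, shifting one signal changes the error
  e_none <- rppe_and_mean_errors(sim_s, meas, align = "none")$rppe
  expect_gt(e_none, 2 * e0)
})

test_that("zero denominators are reported as metric errors", {
  sim <- make_wave(c(1, 2, 3))
  meas <- make_wave(c(1, 0, 3))
  expect_error(rppe_and_mean_errors(sim, meas, rate = 3 / 0.857,
                                    align = "none"),
               "zero denominator")
})

test_that("cardiac indices reproduce the printed baseline arithmetic", {
  # synthetic one-cycle waveforms with the published cycle means
  T <- 0.857
  n <- 857
  tt <- (seq_len(n) - 1) / 1000
  pulse <- sin(pi * tt / T)^2
  wf <- data.frame(
    time = tt,
    Q_AAo = 35.72 / T + 30 * cos(2 * pi * tt / T),  # mean SV/T
    P_AAo = 50.66 + 14 * (pulse - mean(pulse)),
    P_RPA = 8.25 + 0.4 * (pulse - mean(pulse)),
    P_LPA = 8.25 - 0.2 * (pulse - mean(pulse)),
    P_A = 4.11 + 0.5 * (pulse - mean(pulse)),
    P_V = 40 + 32.74 * (pulse - mean(pulse)),
    V_V = 59.2 + 18 * (pulse - mean(pulse)),
    Q_RPA = 25.98 + 2 * (pulse - mean(pulse)),
    Q_LPA = 15.68 + 1 * (pulse - mean(pulse)),
    P_SVC = 8.9 + 0 * tt, P_IVC = 8.5 + 0 * tt)
  idx <- cardiac_indices(wf, T)
  expect_equal(idx$SV, 35.72, tolerance = 1e-6)
  expect_equal(idx$HR, 60 / T)
  expect_equal(idx$CO, 35.72 * (60 / T) / 1000, tolerance = 1e-6)
  expect_equal(round(idx$CO, 2), 2.50)
  expect_equal(round(idx$SVR, 2), 18.62, tolerance = 1e-3)
  expect_equal(round(idx$PVR, 2), 1.66, tolerance = 1e-3)
  # identity: CO recomputed from SV and HR matches the integral route
  expect_equal(idx$CO, idx$SV * idx$HR / 1000, tolerance = 1e-10)
  # degenerate site equality gives zero SVR
  wf0 <- wf; wf0$P_AAo <- wf$P_A
  expect_equal(cardiac_indices(wf0, T)$SVR, 0, tolerance = 1e-12)
})

test_that("waveform containers validate their grids", {
  expect_error(waveform_series(c(0, 0.1, 0.1), c(1, 2, 3), "flow"),
               "strictly increasing")
  expect_error(waveform_series(c(0, 0.1), c(1, 2, 3), "flow"), "lengths")
  tt <- seq(0, 0.99, by = 0.01)       # one 1-second cycle, 100 samples
  w <- waveform_series(tt, sin(2 * pi * tt), "flow")
  r <- resample_waveform(w, 1000)
  expect_equal(length(r$values), 1000)
  expect_equal(r$values[1], w$values[1])
})
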