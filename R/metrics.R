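# Waveform error metrics and cardiovascular indices.
#
# Two normalisation conventions apply to the relative point-to-point error
# (RPPE) over one cardiac cycle of N samples:
#   vascular pressure:      mean over i of |P_sim_i - P_meas_i| / |P_meas_i|
#   flow (any site):        mean over i of |Q_sim_i - Q_meas_i| / max(Q_meas)
#   ventricular pressure:   mean over i of |P_sim_i - P_meas_i| / max(P_meas)
#   ventricular volume:     mean over i of |V_sim_i - V_meas_i| / |V_meas_i|
# Mean-value errors are signed and use the same denominators (the cycle
# mean of the measurement for point-wise-normalised quantities, the cycle
# maximum for max-normalised ones).

#' Waveform series container
#'
#' A uniformly sampled signal over one cardiac cycle.
#'
#' @param time strictly increasing, uniform time grid (s)
#' @param values signal samples
#' @param kind one of `"pressure"`, `"flow"`, `"volume"`
#' @param site site label; `"ventricle"` selects the ventricular
#'   (max-normalised) error convention for pressure
#' @return an object of class `waveform_series`
#' @export
waveform_series <- function(time, values, kind = c("pressure", "flow", "volume"),
                            site = "") {
  kind <- match.arg(kind)
  if (length(time) != length(values)) stop("time and values lengths differ")
  if (any(diff(time) <= 0)) stop("time grid must be strictly increasing")
  structure(list(time = as.numeric(time), values = as.numeric(values),
                 kind = kind, site = site),
            class = "waveform_series")
}

#' Resample a waveform series to a target rate
#'
#' Linear interpolation onto a uniform grid covering the same cycle.  The
#' cycle period is inferred as the grid span plus one sampling interval
#' (a uniform grid over one period omits the final, wrap-around sample),
#' and interpolation extends the series periodically.
#'
#' @param w a [waveform_series()]
#' @param rate samples per second (default 1000)
#' @return a resampled `waveform_series`
#' @export
resample_waveform <- function(w, rate = 1000) {
  t0 <- w$time[1L]
  n_in <- length(w$time)
  period <- (w$time[n_in] - t0) + stats::median(diff(w$time))
  n <- max(2L, as.integer(round(period * rate)))
  t_out <- t0 + (seq_len(n) - 1L) * period / n
  tt <- c(w$time, t0 + period)
  yy <- c(w$values, w$values[1L])
  waveform_series(t_out, stats::approx(tt, yy, xout = t_out)$y,
                  w$kind, w$site)
}

# circularly shift a vector so that its "foot" (minimum preceding the main
# upstroke) moves to index 1
.foot_index <- function(y) {
  # the foot is the cycle minimum; for multi-minima signals take the global one
  which.min(y)
}

.align_cycle <- function(sim, meas, align) {
  if (identical(align, "none")) return(list(sim = sim, meas = meas))
  shift_to <- function(y, i) if (i > 1L) c(y[i:length(y)], y[seq_len(i - 1L)]) else y
  if (is.numeric(align)) {
    # fixed offset in samples applied to the simulated signal
    i <- (as.integer(align) %% length(sim)) + 1L
    return(list(sim = shift_to(sim, i), meas = meas))
  }
  list(sim = shift_to(sim, .foot_index(sim)),
       meas = shift_to(meas, .foot_index(meas)))
}

#' Relative point-to-point and mean-value errors between two waveforms
#'
#' Both series are resampled to a common rate, aligned (by default at the
#' waveform foot, to compensate for asynchronous acquisition), and compared
#' with the normalisation convention matching the quantity kind and site.
#'
#' @param sim,meas [waveform_series()] objects of the same kind, one cycle
#'   each
#' @param rate common sampling rate (default 1000 samples/s)
#' @param align `"foot"` (default), `"none"`, or an integer sample offset
#'   applied to the simulated series
#' @return list with `rppe` (>= 0) and `mean_error` (signed), both
#'   dimensionless fractions
#' @export
rppe_and_mean_errors <- function(sim, meas, rate = 1000, align = "foot") {
  if (sim$kind != meas$kind) stop("cannot compare different quantity kinds")
  s <- resample_waveform(sim, rate)$values
  m <- resample_waveform(meas, rate)$values
  n <- min(length(s), length(m))
  s <- s[seq_len(n)]; m <- m[seq_len(n)]
  al <- .align_cycle(s, m, align)
  s <- al$sim; m <- al$meas

  ventricular <- identical(sim$site, "ventricle") || identical(meas$site, "ventricle")
  max_norm <- sim$kind == "flow" || (sim$kind == "pressure" && ventricular)
  if (max_norm) {
    denom <- max(m)
    if (denom == 0) stop("metric error: zero cycle maximum in measurement")
    rppe <- mean(abs(s - m) / denom)
    mean_error <- (mean(s) - mean(m)) / denom
  } else {
    if (any(m == 0))
      stop(sprintf("metric error: zero denominator sample at index %d",
                   which(m == 0)[1L]))
    rppe <- mean(abs((s - m) / m))
    mean_error <- (mean(s) - mean(m)) / mean(m)
  }
  list(rppe = rppe, mean_error = mean_error)
}

#' Cardiovascular indices from one converged cycle
#'
#' Stroke volume is the time integral of aortic (valve) flow over one
#' cycle; heart rate is 60/T; cardiac output follows as SV * HR / 1000.
#' Systemic vascular resistance is (mean arterial - mean atrial pressure) /
#' CO and pulmonary vascular resistance (mean pulmonary arterial - mean
#' atrial pressure) / CO, with the mean arterial pressure read at the
#' ascending aorta and the mean pulmonary arterial pressure the unweighted
#' average of the two pulmonary branch means.
#'
#' @param wf data frame of probe waveforms over exactly one cycle on a
#'   uniform grid (as produced by [run_to_periodic()]); columns used:
#'   `Q_AAo`, `P_AAo`, `P_RPA`, `P_LPA`, `P_A`, `P_V`, `V_V`, `Q_RPA`,
#'   `Q_LPA`, `P_SVC`, `P_IVC`
#' @param T cardiac period (s)
#' @return an object of class `cardiac_indices` (named list)
#' @export
cardiac_indices <- function(wf, T) {
  SV <- mean(wf$Q_AAo) * T
  HR <- 60 / T
  CO <- SV * HR / 1000
  if (CO == 0) stop("index error: zero cardiac output")
  map <- mean(wf$P_AAo)
  mpap <- (mean(wf$P_RPA) + mean(wf$P_LPA)) / 2
  m_atr <- mean(wf$P_A)
  out <- list(
    SV = SV, HR = HR, CO = CO,
    systolic_arterial_pressure = max(wf$P_AAo),
    mean_arterial_pressure = map,
    mean_pulmonary_arterial_pressure = mpap,
    mean_atrial_pressure = m_atr,
    ventricular_end_diastolic_pressure = wf$P_V[1L],
    ventricular_peak_pressure = max(wf$P_V),
    mean_tcpc_pressure = mean(c(mean(wf$P_SVC), mean(wf$P_IVC),
                                mean(wf$P_RPA), mean(wf$P_LPA))),
    SVR = (map - m_atr) / CO,
    PVR = (mpap - m_atr) / CO,
    mean_rpa_flow = mean(wf$Q_RPA),
    mean_lpa_flow = mean(wf$Q_LPA),
    ventricular_volume_mean = mean(wf$V_V),
    ventricular_volume_min = min(wf$V_V),
    ventricular_volume_max = max(wf$V_V))
  class(out) <- "cardiac_indices"
  out
}

#' @export
print.cardiac_indices <- function(x, ...) {
  cat(sprintf("  SV %.2f ml/cycle | HR %.1f /min | CO %.2f l/min\n",
              x$SV, x$HR, x$CO))
  cat(sprintf("  arterial P %.2f mmHg (sys %.2f) | PA P %.2f | atrial P %.2f\n",
              x$mean_arterial_pressure, x$systolic_arterial_pressure,
              x$mean_pulmonary_arterial_pressure, x$mean_atrial_pressure))
  cat(sprintf("  ventricular P peak %.2f, EDP %.2f mmHg | V %.1f [%.1f, %.1f] ml\n",
              x$ventricular_peak_pressure, x$ventricular_end_diastolic_pressure,
              x$ventricular_volume_mean, x$ventricular_volume_min,
              x$ventricular_volume_max))
  cat(sprintf("  SVR %.2f, PVR %.2f mmHg.min/l | Q RPA %.2f, LPA %.2f ml/s\n",
              x$SVR, x$PVR, x$mean_rpa_flow, x$mean_lpa_flow))
  invisible(x)
}
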