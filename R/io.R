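# Waveform CSV I/O and results serialisation.

#' Read a two-column waveform CSV
#'
#' Expects a header row `time_s,value`, comma separation, strictly
#' increasing time.
#'
#' @param path CSV file
#' @param kind quantity kind passed to [waveform_series()]
#' @param site site label
#' @return a [waveform_series()]
#' @export
read_waveform_csv <- function(path, kind = "flow", site = "") {
  if (!file.exists(path)) stop("waveform file not found: ", path)
  df <- utils::read.csv(path, header = TRUE)
  if (ncol(df) < 2L) stop("waveform CSV needs two columns (time_s, value)")
  bad <- which(!is.finite(df[[1L]]) | !is.finite(df[[2L]]))
  if (length(bad))
    stop(sprintf("parse error in %s: non-numeric row %d", path, bad[1L] + 1L))
  if (any(diff(df[[1L]]) <= 0)) {
    i <- which(diff(df[[1L]]) <= 0)[1L]
    stop(sprintf("parse error in %s: non-monotone time at row %d", path, i + 2L))
  }
  waveform_series(df[[1L]], df[[2L]], kind = kind, site = site)
}

#' Write a waveform series to CSV
#'
#' @param w a [waveform_series()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_waveform_csv <- function(w, path) {
  df <- data.frame(time_s = w$time, value = w$values)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Evaluate a periodically extended waveform
#'
#' Interpolates the series at arbitrary times, wrapping modulo its span
#' (so a one-cycle waveform drives a simulation of any length).
#'
#' @param w a [waveform_series()]
#' @return a function of time `f(t)` returning the value
#' @export
periodic_waveform_fun <- function(w) {
  t0 <- w$time[1L]
  n <- length(w$time)
  span <- (w$time[n] - t0) + stats::median(diff(w$time))
  tt <- c(w$time - t0, span)
  yy <- c(w$values, w$values[1L])
  function(t) stats::approx(tt, yy, xout = (t - t0) %% span)$y
}

#' Write a simulation results bundle to a directory
#'
#' Per-probe waveform CSVs (`<signal>.csv`), cardiovascular indices and
#' convergence history as JSON, and a run log with the solver settings.
#'
#' @param sol a `periodic_solution` from [run_to_periodic()]
#' @param out_dir output directory (created if needed)
#' @return `out_dir`, invisibly
#' @export
write_results <- function(sol, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wf <- sol$waveforms
  for (nm in setdiff(names(wf), "time")) {
    utils::write.csv(data.frame(time_s = wf$time, value = wf[[nm]]),
                     file.path(out_dir, paste0(nm, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(
    list(indices = unclass(sol$indices),
         convergence = list(cycles = sol$cycles, converged = sol$converged,
                            cycle_means = as.data.frame(sol$means),
                            volume_drift = sol$volume_drift)),
    file.path(out_dir, "indices.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(c(
    sprintf("scenario: %s", sol$scenario),
    sprintf("dt: %.6e s", sol$dt),
    sprintf("T: %.6f s", sol$T),
    sprintf("cycles: %d (converged: %s)", sol$cycles, sol$converged),
    "deterministic: yes (no random number use anywhere in the solver)"),
    file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
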