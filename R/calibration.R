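# Physics-based calibration helpers: the Ohmic resistance primitive used by
# the stepwise estimation of resistive elements from cycle-mean pressures
# and flows, and provenance bookkeeping separating data-derived from
# manually adjusted parameters.

#' Ohmic resistance estimate from cycle means
#'
#' R = mean pressure drop / mean flow, the estimation primitive for purely
#' resistive elements.
#'
#' @param dP_mean mean pressure drop across the element (mmHg)
#' @param Q_mean mean flow through it (ml/s)
#' @return resistance (mmHg s/ml)
#' @export
ohmic_resistance <- function(dP_mean, Q_mean) {
  if (any(Q_mean == 0)) stop("estimation error: zero mean flow")
  dP_mean / Q_mean
}

#' Convert a per-beat volume to a mean flow
#'
#' @param volume_per_beat ml/beat
#' @param T cardiac period (s)
#' @return mean flow (ml/s)
#' @export
mean_flow_from_beat_volume <- function(volume_per_beat, T) {
  if (!(T > 0)) stop("cardiac period must be positive")
  volume_per_beat / T
}

# every model parameter with its provenance class; the heart elastance and
# valve parameters (and nothing else except the noted exceptions) required
# manual adjustment against the measured aortic flow and ventricular
# pressure/volume
.provenance_table <- function(config) {
  h <- config$heart
  rows <- list()
  add <- function(name, value, source)
    rows[[length(rows) + 1L]] <<- data.frame(parameter = name, value = value,
                                             source = source,
                                             stringsAsFactors = FALSE)
  man <- "manually-adjusted"; dat <- "data-derived"
  # atrium: all manually adjusted
  a <- h$atrium
  add("K_s,A", a$K_s, man); add("E_min,A", a$E_min, man)
  add("E_max,A", a$E_max, man); add("V_0,A", a$V0, man)
  add("m_1,A", a$m1, man); add("m_2,A", a$m2, man)
  add("tau_1,A/T", a$tau1_frac, man); add("tau_2,A/T", a$tau2_frac, man)
  add("t_onset,A/T", a$t_onset_frac, man)
  # atrioventricular valve: all manually adjusted
  v <- h$avv
  add("l_eff,AVV", v$l_eff, man); add("A_ann,AVV", v$A_ann, man)
  add("K_vo,AVV", v$K_vo, man); add("K_vc,AVV", v$K_vc, man)
  # ventricle: all manually adjusted except the source resistance
  ve <- h$ventricle
  add("K_s,V", ve$K_s, dat); add("E_min,V", ve$E_min, man)
  add("E_max,V", ve$E_max, man); add("V_0,V", ve$V0, man)
  add("m_1,V", ve$m1, man); add("m_2,V", ve$m2, man)
  add("tau_1,V/T", ve$tau1_frac, man); add("tau_2,V/T", ve$tau2_frac, man)
  add("t_onset,V/T", ve$t_onset_frac, man)
  # aortic valve: all manually adjusted
  av <- h$aov
  add("l_eff,AoV", av$l_eff, man); add("A_ann,AoV", av$A_ann, man)
  add("K_vo,AoV", av$K_vo, man); add("K_vc,AoV", av$K_vc, man)
  # peripheral compartments and lungs: data-derived
  up <- config$compartments$upper; lo <- config$compartments$lower
  add("R_a1", up$R_a1, dat); add("R_a2", up$R_a2, dat)
  add("R_c1", up$R_c1, dat); add("R_v1", up$R_v1, dat)
  add("C_a1", up$C_a1, dat); add("C_v1", up$C_v1, dat)
  add("R_a4", lo$R_a4, dat); add("R_c2", lo$R_c2, dat)
  add("R_v2", lo$R_v2, dat); add("C_a2", lo$C_a2, dat)
  add("C_v2", lo$C_v2, dat)
  add("R_RPA", config$lungs$R_RPA, dat)
  add("R_LPA", config$lungs$R_LPA, dat)
  # global settings
  add("T", config$settings$T, dat)
  add("V_blood", config$settings$V_blood, dat)
  add("c_Ao", 5.35, dat); add("c_TCPC", 2.81, dat)
  # 1-D geometry: all measured from imaging
  for (row in config$vessels) {
    add(paste0("L,", row$name), row$L, dat)
    add(paste0("D_in,", row$name), row$D_in, dat)
    add(paste0("D_out,", row$name), row$D_out, dat)
  }
  do.call(rbind, rows)
}

#' Parameter provenance report
#'
#' Classifies every model parameter as data-derived (estimated directly
#' from the patient's examination) or manually adjusted (tuned to match the
#' measured aortic flow wave and ventricular pressure/volume), and reports
#' the counts.
#'
#' @param config a validated `fontan_config`
#' @return list with `table` (data frame: parameter, value, source) and
#'   `counts` (named vector: total, data_derived, manually_adjusted)
#' @export
provenance_report <- function(config) {
  config <- validate_config(config)
  tab <- .provenance_table(config)
  # the PWV entries of the vessel table duplicate c_Ao/c_TCPC; they are not
  # counted twice
  counts <- c(total = nrow(tab),
              data_derived = sum(tab$source == "data-derived"),
              manually_adjusted = sum(tab$source == "manually-adjusted"))
  list(table = tab, counts = counts)
}
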