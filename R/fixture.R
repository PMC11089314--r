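# Built-in patient fixture: the 10-year-old Fontan patient whose
# haemodynamic examination (combined catheterisation + CMR) calibrated the
# model.  Every model parameter and every measurement summary ships here so
# the baseline simulation needs no external data.

#' Built-in patient model configuration and measurement summaries
#'
#' Returns the complete baseline configuration of the reference patient —
#' heart chamber/valve parameters, the nine 1-D vessel segments of the aorta
#' and cavopulmonary connection, peripheral compartments, lung resistances,
#' global settings — together with the measured haemodynamic summaries
#' (cycle volumes per beat, invasive mean/extreme pressures) used for
#' calibration checks and error metrics.
#'
#' This patient lacks the left subclavian artery (no `R_a3`; only two
#' supra-aortic vessels) and has the left pulmonary artery split into two
#' segments describing an external compression of its calibre.
#'
#' @return a list with elements `config` (a validated `fontan_config`) and
#'   `measurements` (a data frame of site/quantity/value rows)
#' @export
fixture_patient <- function() {
  config <- list(
    settings = list(
      T = 0.857, V_blood = 556.69,
      rho = 1060, mu = 0.0035,          # SI; converted internally
      dt = "auto", element_size = 5,
      max_cycles = 30, periodicity_tol = 1e-3,
      output_rate = 1000,
      P_init = 6,                        # diastolic pressure from LPCW
      P0_aorta = 40, P0_tcpc = 6),
    heart = list(
      atrium = list(K_s = 7.5e-4, E_min = 0.2, E_max = 0.4, V0 = 5.5,
                    m1 = 20, m2 = 30, tau1_frac = 0.1, tau2_frac = 0.25,
                    t_onset_frac = 0.7),
      ventricle = list(K_s = 1.4e-4, E_min = 0.065, E_max = 1.97, V0 = 10.5,
                       m1 = 1.3, m2 = 30, tau1_frac = 0.18, tau2_frac = 0.45,
                       t_onset_frac = 0),
      avv = list(l_eff = 4, A_ann = 4.5, K_vo = 8, K_vc = 8),
      aov = list(l_eff = 8, A_ann = 1.68, K_vo = 4, K_vc = 2)),
    vessels = list(
      list(name = "AAo",    node_in = 1, node_out = 2,  L = 29, D_in = 25,   D_out = 15.5, PWV = 5.35),
      list(name = "DAo",    node_in = 2, node_out = 3,  L = 90, D_in = 15.5, D_out = 10.5, PWV = 5.35),
      list(name = "BCA",    node_in = 2, node_out = 4,  L = 25, D_in = 9,    D_out = 10.5, PWV = 5.35),
      list(name = "LCCA",   node_in = 2, node_out = 5,  L = 30, D_in = 6.5,  D_out = 5,    PWV = 5.35),
      list(name = "IVC",    node_in = 6, node_out = 7,  L = 55, D_in = 31,   D_out = 22,   PWV = 2.81),
      list(name = "RPA",    node_in = 7, node_out = 10, L = 12, D_in = 13,   D_out = 13,   PWV = 2.81),
      list(name = "LPA_i",  node_in = 7, node_out = 8,  L = 22, D_in = 10.5, D_out = 6,    PWV = 2.81),
      list(name = "LPA_ii", node_in = 8, node_out = 11, L = 14, D_in = 6,    D_out = 8,    PWV = 2.81),
      list(name = "SVC",    node_in = 7, node_out = 9,  L = 15, D_in = 22,   D_out = 14.5, PWV = 2.81)),
    compartments = list(
      upper = list(R_a1 = 0.5086, R_a2 = 2.2430, R_c1 = 1.3305,
                   R_v1 = 0.0054, C_a1 = 2.4563, C_v1 = 23.3356),
      lower = list(R_a4 = 0.2646, R_c2 = 0.5767, R_v2 = 1.4841,
                   C_a2 = 2.4921, C_v2 = 0.1897)),
    lungs = list(R_RPA = 0.1720, R_LPA = 0.2474),
    scenario = list(kind = "baseline",
                    vasodilation_fraction = 0.25,
                    fenestration = list(length_cm = 3, diameter_mm = 4,
                                        R = 0.5, inertance = FALSE))
  )
  config <- validate_config(config)

  measurements <- data.frame(
    site = c("heart", "ventricle", "ventricle", "ventricle", "heart", "ventricle",
             "AAo", "DAo", "RPA", "LPA", "SVC", "IVC",
             "ventricle", "ventricle",
             "AAo", "AAo", "AAo", "arch", "arch", "arch",
             "DAo", "DAo", "DAo",
             "IVC", "SVC", "LPA", "RPA", "LPCW", "lungs"),
    quantity = c("heart_rate_bpm", "end_diastolic_volume_ml",
                 "end_systolic_volume_ml", "stroke_volume_ml",
                 "cardiac_output_l_min", "ejection_fraction_pct",
                 "flow_ml_per_beat", "flow_ml_per_beat", "flow_ml_per_beat",
                 "flow_ml_per_beat", "flow_ml_per_beat", "flow_ml_per_beat",
                 "end_diastolic_pressure_mmHg", "peak_pressure_mmHg",
                 "systolic_pressure_mmHg", "diastolic_pressure_mmHg", "mean_pressure_mmHg",
                 "systolic_pressure_mmHg", "diastolic_pressure_mmHg", "mean_pressure_mmHg",
                 "systolic_pressure_mmHg", "diastolic_pressure_mmHg", "mean_pressure_mmHg",
                 "mean_pressure_mmHg", "mean_pressure_mmHg",
                 "mean_pressure_mmHg", "mean_pressure_mmHg", "mean_pressure_mmHg",
                 "measured_PVR_mmHg_min_l"),
    value = c(70, 74.4, 37.6, 36.8, 2.51, 48,
              36, 16, 21, 14, 18, 17,
              7, 73,
              69, 40, 50, 71, 41, 52,
              68, 42, 53,
              8.5, 8.9, 8.4, 8.4, 6, 1.2),
    stringsAsFactors = FALSE)

  list(config = config, measurements = measurements)
}
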