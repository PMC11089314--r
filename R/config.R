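# Model configuration document: schema validation, YAML/JSON round trip.
# Keys follow the clinical parameter naming of the patient tables verbatim
# (R_a1 ... C_v2, R_RPA, R_LPA; vessel rows name/node_in/node_out/L/D_in/
# D_out/PWV in mm and m/s).

.settings_keys <- c("T", "V_blood", "rho", "mu", "dt", "element_size",
                    "max_cycles", "periodicity_tol", "output_rate",
                    "P_init", "P0_aorta", "P0_tcpc")
.chamber_keys <- c("K_s", "E_min", "E_max", "V0", "m1", "m2",
                   "tau1_frac", "tau2_frac", "t_onset_frac")
.valve_keys <- c("l_eff", "A_ann", "K_vo", "K_vc")
.vessel_keys <- c("name", "node_in", "node_out", "L", "D_in", "D_out", "PWV")
.upper_keys <- c("R_a1", "R_a2", "R_c1", "R_v1", "C_a1", "C_v1")
.lower_keys <- c("R_a4", "R_c2", "R_v2", "C_a2", "C_v2")
.lung_keys <- c("R_RPA", "R_LPA")

.check_keys <- function(x, required, where, optional = character()) {
  if (is.null(x)) stop(sprintf("config section '%s' is missing", where))
  missing <- setdiff(required, names(x))
  if (length(missing))
    stop(sprintf("config '%s': missing key(s) %s", where,
                 paste(missing, collapse = ", ")))
  extra <- setdiff(names(x), c(required, optional))
  if (length(extra))
    stop(sprintf("config '%s': unknown key(s) %s", where,
                 paste(extra, collapse = ", ")))
  invisible(x)
}

.check_positive <- function(x, keys, where) {
  for (k in keys) {
    v <- x[[k]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("config '%s': '%s' must be a positive number", where, k))
  }
}

#' Validate a model configuration document
#'
#' Checks schema completeness (missing and unknown keys are both errors),
#' units-bearing invariants (positivity of resistances, compliances,
#' geometry), and cross-field constraints.
#'
#' @param cfg a nested list as produced by [load_config()] or
#'   [fixture_patient()]
#' @return the validated config, invisibly classed as `fontan_config`
#' @export
validate_config <- function(cfg) {
  .check_keys(cfg, c("settings", "heart", "vessels", "compartments",
                     "lungs", "scenario"),
              "top level", optional = c("probes", "submodel_wk3"))
  s <- .check_keys(cfg$settings, .settings_keys, "settings")
  .check_positive(s, c("T", "V_blood", "rho", "mu", "element_size",
                       "output_rate"), "settings")
  if (!identical(s$dt, "auto")) .check_positive(s, "dt", "settings")

  h <- .check_keys(cfg$heart, c("atrium", "ventricle", "avv", "aov"), "heart")
  for (ch in c("atrium", "ventricle")) {
    x <- .check_keys(h[[ch]], .chamber_keys, paste0("heart$", ch))
    .check_positive(x, c("E_min", "E_max", "m1", "m2", "tau1_frac",
                         "tau2_frac"), paste0("heart$", ch))
    if (x$E_max < x$E_min)
      stop(sprintf("heart$%s: E_max must be >= E_min", ch))
    if (x$t_onset_frac < 0 || x$t_onset_frac >= 1)
      stop(sprintf("heart$%s: t_onset_frac must lie in [0, 1)", ch))
    if (x$K_s < 0 || x$V0 < 0)
      stop(sprintf("heart$%s: K_s and V0 must be >= 0", ch))
  }
  for (vl in c("avv", "aov")) {
    x <- .check_keys(h[[vl]], .valve_keys, paste0("heart$", vl))
    .check_positive(x, .valve_keys, paste0("heart$", vl))
  }

  if (!length(cfg$vessels)) stop("config 'vessels': at least one vessel row required")
  for (row in cfg$vessels) {
    .check_keys(row, .vessel_keys, "vessels row")
    .check_positive(row, c("L", "D_in", "D_out", "PWV"),
                    paste0("vessels$", row$name))
    if (row$node_in == row$node_out)
      stop(sprintf("vessels$%s: node_in and node_out must differ", row$name))
  }

  cmp <- .check_keys(cfg$compartments, c("upper", "lower"), "compartments")
  up <- .check_keys(cmp$upper, .upper_keys, "compartments$upper",
                    optional = "R_a3")
  .check_positive(up, .upper_keys, "compartments$upper")
  if (!is.null(up$R_a3)) .check_positive(up, "R_a3", "compartments$upper")
  lo <- .check_keys(cmp$lower, .lower_keys, "compartments$lower")
  .check_positive(lo, .lower_keys, "compartments$lower")

  lg <- .check_keys(cfg$lungs, .lung_keys, "lungs")
  .check_positive(lg, .lung_keys, "lungs")

  sc <- .check_keys(cfg$scenario, "kind", "scenario",
                    optional = c("vasodilation_fraction", "fenestration"))
  if (!sc$kind %in% c("baseline", "vasodilation", "fenestration"))
    stop("scenario$kind must be baseline, vasodilation or fenestration")
  if (!is.null(sc$vasodilation_fraction)) {
    fr <- sc$vasodilation_fraction
    if (!is.numeric(fr) || fr < 0 || fr >= 1)
      stop("scenario$vasodilation_fraction must lie in [0, 1)")
  }
  if (!is.null(sc$fenestration)) {
    fe <- .check_keys(sc$fenestration, c("length_cm", "diameter_mm", "R"),
                      "scenario$fenestration", optional = "inertance")
    .check_positive(fe, c("length_cm", "diameter_mm", "R"),
                    "scenario$fenestration")
  }
  class(cfg) <- "fontan_config"
  invisible(cfg)
}

#' Load a model configuration from YAML or JSON
#'
#' @param path file path; `.json` files are parsed as JSON, anything else as
#'   YAML (JSON being a YAML subset, both work through the YAML reader too)
#' @return a validated `fontan_config`
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  else yaml::read_yaml(path)
  validate_config(cfg)
}

#' Write a model configuration to YAML
#'
#' @param cfg a `fontan_config`
#' @param path output file path
#' @return `path`, invisibly
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 15L)
  invisible(path)
}
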