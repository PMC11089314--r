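# Internal unit system: pressure in mmHg, volume in ml (= cm^3), time in s,
# length in cm, area in cm^2, flow in ml/s.  Density and viscosity are
# converted from SI once, here, so the rest of the code never converts.

# 1 mmHg = 133.322 Pa = 1333.22 dyn/cm^2
.MMHG_DYN <- 1333.22

#' Convert a density from SI to internal units
#'
#' @param rho_si density in kg/m^3
#' @return density in mmHg s^2 / cm^2
#' @keywords internal
rho_internal <- function(rho_si) (rho_si * 1e-3) / .MMHG_DYN

#' Convert a dynamic viscosity from SI to internal units
#'
#' @param mu_si viscosity in Pa s
#' @return viscosity in mmHg s
#' @keywords internal
mu_internal <- function(mu_si) (mu_si * 10) / .MMHG_DYN
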