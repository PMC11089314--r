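# Lumped (0-D) vascular models: the upper/lower body compartments
# (arterial resistances feeding an arterial compliance node, capillary
# resistance, venous compliance node, venous resistance), the purely
# resistive lung model, and the three-element Windkessel used as a terminal
# by the open-loop calibration submodels.

#' Body compartment parameters
#'
#' One peripheral vascular bed: a set of arterial inlet resistances (one per
#' feeding artery) into a common arterial node, a capillary resistance to a
#' venous node, and a venous resistance draining to the attached vein.
#'
#' @param Ra_list numeric vector of arterial inlet resistances (mmHg s/ml),
#'   one per feeding artery
#' @param Rc capillary resistance (mmHg s/ml)
#' @param Rv venous resistance (mmHg s/ml)
#' @param Ca arterial compliance (ml/mmHg)
#' @param Cv venous compliance (ml/mmHg)
#' @return an object of class `body_compartment_params`
#' @export
body_compartment_params <- function(Ra_list, Rc, Rv, Ca, Cv) {
  if (length(Ra_list) < 1L) stop("Ra_list must have at least one entry")
  if (any(c(Ra_list, Rc, Rv, Ca, Cv) <= 0))
    stop("all resistances and compliances must be positive")
  structure(list(Ra_list = Ra_list, Rc = Rc, Rv = Rv, Ca = Ca, Cv = Cv),
            class = "body_compartment_params")
}

#' Body compartment pressure derivatives and flows
#'
#' @param state numeric `c(Pa, Pv)`: arterial and venous node pressures
#'   (mmHg)
#' @param feed_P feeding artery pressures (mmHg), one per entry of `Ra_list`
#' @param outlet_P pressure of the attached vein (mmHg)
#' @param params a [body_compartment_params()]
#' @return list with `deriv = c(dPa, dPv)` (mmHg/s) and the instantaneous
#'   flows `Qa` (vector), `Qc`, `Qv` (ml/s)
#' @export
body_compartment_derivatives <- function(state, feed_P, outlet_P, params) {
  if (length(feed_P) != length(params$Ra_list))
    stop("need one feeding pressure per arterial resistance")
  Pa <- state[1L]; Pv <- state[2L]
  Qa <- (feed_P - Pa) / params$Ra_list
  Qc <- (Pa - Pv) / params$Rc
  Qv <- (Pv - outlet_P) / params$Rv
  list(deriv = c((sum(Qa) - Qc) / params$Ca, (Qc - Qv) / params$Cv),
       Qa = Qa, Qc = Qc, Qv = Qv)
}

#' Advance a body compartment by one RK4 step
#'
#' Boundary conditions are held constant over the step, in one of two
#' modes.  With `feed_P`/`outlet_P`, the feeding and outlet pressures are
#' frozen and the boundary flows follow Ohm's law at every stage (the
#' stand-alone compartment of the calibration submodels).  With
#' `feed_Q`/`outlet_Q`, the boundary flows themselves are frozen — the mode
#' used inside the coupled network, where the interface fluxes have already
#' been solved implicitly at the 1-D boundary faces and the same numbers
#' must move volume on both sides.  Only the capillary exchange flow varies
#' within the step in that mode.
#'
#' @inheritParams body_compartment_derivatives
#' @param dt time step (s)
#' @param feed_Q total frozen arterial inflow (ml/s); overrides `feed_P`
#' @param outlet_Q frozen venous outflow (ml/s); overrides `outlet_P`
#' @return list with the advanced `state` and the stage-weighted mean flows
#'   `Qa_bar` (vector, or total in flux mode) and `Qv_bar`
#' @export
step_body_compartment <- function(state, feed_P = NULL, outlet_P = NULL,
                                  params, dt, feed_Q = NULL, outlet_Q = NULL) {
  flux_mode <- !is.null(feed_Q)
  if (flux_mode) {
    f <- function(s) {
      Qc <- (s[1L] - s[2L]) / params$Rc
      c((feed_Q - Qc) / params$Ca, (Qc - outlet_Q) / params$Cv)
    }
    k1 <- f(state); k2 <- f(state + 0.5 * dt * k1)
    k3 <- f(state + 0.5 * dt * k2); k4 <- f(state + dt * k3)
    new <- state + (dt / 6) * (k1 + 2 * k2 + 2 * k3 + k4)
    return(list(state = new, Qa_bar = feed_Q, Qv_bar = outlet_Q))
  }
  f <- function(s) body_compartment_derivatives(s, feed_P, outlet_P, params)
  d1 <- f(state)
  s2 <- state + 0.5 * dt * d1$deriv
  d2 <- f(s2)
  s3 <- state + 0.5 * dt * d2$deriv
  d3 <- f(s3)
  s4 <- state + dt * d3$deriv
  d4 <- f(s4)
  w <- c(1, 2, 2, 1) / 6
  new <- state + dt * (w[1] * d1$deriv + w[2] * d2$deriv +
                         w[3] * d3$deriv + w[4] * d4$deriv)
  Qa_bar <- w[1] * d1$Qa + w[2] * d2$Qa + w[3] * d3$Qa + w[4] * d4$Qa
  Qv_bar <- sum(w * c(d1$Qv, d2$Qv, d3$Qv, d4$Qv))
  list(state = new, Qa_bar = Qa_bar, Qv_bar = Qv_bar)
}

#' Lung parameters
#'
#' @param R_RPA,R_LPA pulmonary branch resistances (mmHg s/ml)
#' @return an object of class `lung_params`
#' @export
lung_params <- function(R_RPA, R_LPA) {
  if (R_RPA <= 0 || R_LPA <= 0) stop("pulmonary resistances must be positive")
  structure(list(R_RPA = R_RPA, R_LPA = R_LPA), class = "lung_params")
}

#' Ohmic pulmonary branch flows
#'
#' @param P_RPA,P_LPA distal pulmonary artery pressures (mmHg)
#' @param P_A atrial pressure (mmHg)
#' @param params a [lung_params()]
#' @return named vector `c(Q_RPA, Q_LPA)` (ml/s); the atrial inflow is their
#'   sum
#' @export
lung_flows <- function(P_RPA, P_LPA, P_A, params) {
  c(Q_RPA = (P_RPA - P_A) / params$R_RPA,
    Q_LPA = (P_LPA - P_A) / params$R_LPA)
}

#' Three-element Windkessel parameters
#'
#' @param R1 proximal (characteristic) resistance (mmHg s/ml)
#' @param R2 distal resistance (mmHg s/ml)
#' @param C compliance (ml/mmHg)
#' @param P_out outflow pressure (mmHg)
#' @return an object of class `wk3_params`
#' @export
wk3_params <- function(R1, R2, C, P_out = 0) {
  if (any(c(R1, R2, C) <= 0)) stop("R1, R2 and C must be positive")
  structure(list(R1 = R1, R2 = R2, C = C, P_out = P_out), class = "wk3_params")
}

#' Advance a three-element Windkessel by one RK4 step
#'
#' State is the compliance-node pressure `P_c`, with
#' `C dP_c/dt = Q_in - (P_c - P_out)/R2` and the interface relation
#' `P_proximal = P_c + Q_in R1`.  `Q_in` is held constant over the step.
#'
#' @param Q_in inflow (ml/s)
#' @param P_c compliance-node pressure (mmHg)
#' @param params a [wk3_params()]
#' @param dt time step (s)
#' @return list with advanced `P_c` and the interface pressure `P_proximal`
#'   at the new state
#' @export
wk3_step <- function(Q_in, P_c, params, dt) {
  if (!(dt > 0)) stop("dt must be positive")
  f <- function(p) (Q_in - (p - params$P_out) / params$R2) / params$C
  k1 <- f(P_c)
  k2 <- f(P_c + 0.5 * dt * k1)
  k3 <- f(P_c + 0.5 * dt * k2)
  k4 <- f(P_c + dt * k3)
  P_new <- P_c + (dt / 6) * (k1 + 2 * k2 + 2 * k3 + k4)
  list(P_c = P_new, P_proximal = P_new + Q_in * params$R1)
}
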