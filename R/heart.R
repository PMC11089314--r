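# Univentricular heart: two time-varying elastance chambers (atrium,
# ventricle) in series with two dynamic valves (atrioventricular, aortic).
# Chamber pressure P = E(t) (V - V0) (1 - Ks Q_out); valve flow follows a
# Bernoulli pressure-flow law with inertance, and the valve state xi in [0,1]
# opens/closes at a rate proportional to the transvalvular pressure
# difference.

# Relative floor on the valve state used to regularise the effective area
# A_eff = A_ann * xi, which otherwise vanishes for a closed valve.
.XI_FLOOR <- 1e-6

#' Elastance chamber parameters
#'
#' Parameter container for a time-varying elastance chamber.  Time constants
#' and the contraction onset are absolute (seconds), not fractions of the
#' cardiac period.
#'
#' @param E_min,E_max minimum and maximum elastance over the cycle (mmHg/ml)
#' @param tau1,tau2 contraction and relaxation time constants (s)
#' @param m1,m2 contraction and relaxation rate exponents (dimensionless)
#' @param t_onset contraction onset within one period (s)
#' @param V0 reference (zero-pressure) volume (ml)
#' @param Ks source-resistance coefficient (s/ml)
#' @return an object of class `elastance_params`
#' @export
elastance_params <- function(E_min, E_max, tau1, tau2, m1, m2, t_onset, V0, Ks) {
  if (!(E_min > 0) || !(E_max >= E_min))
    stop("invalid elastance parameters: need E_max >= E_min > 0")
  if (!(tau1 > 0) || !(tau2 > 0) || !(m1 > 0) || !(m2 > 0))
    stop("invalid elastance parameters: tau1, tau2, m1, m2 must be > 0")
  if (t_onset < 0) stop("invalid elastance parameters: t_onset must be >= 0")
  if (V0 < 0 || Ks < 0) stop("invalid elastance parameters: V0, Ks must be >= 0")
  structure(list(E_min = E_min, E_max = E_max, tau1 = tau1, tau2 = tau2,
                 m1 = m1, m2 = m2, t_onset = t_onset, V0 = V0, Ks = Ks),
            class = "elastance_params")
}

#' Valve parameters
#'
#' @param A_ann annulus area (cm^2)
#' @param l_eff effective length (cm)
#' @param K_vo,K_vc opening and closing rate coefficients (1/(mmHg s))
#' @return an object of class `valve_params`
#' @export
valve_params <- function(A_ann, l_eff, K_vo, K_vc) {
  vals <- c(A_ann = A_ann, l_eff = l_eff, K_vo = K_vo, K_vc = K_vc)
  if (any(!(vals > 0))) stop("valve parameters must all be strictly positive")
  structure(as.list(vals), class = "valve_params")
}

# Unscaled activation shape s(u) = g1/(1+g1) * 1/(1+g2) at phase u >= 0.
.elastance_shape <- function(u, p) {
  g1 <- (u / p$tau1)^p$m1
  g2 <- (u / p$tau2)^p$m2
  (g1 / (1 + g1)) / (1 + g2)
}

# Scaling factor k = (E_max - E_min) / max s, with the maximum located on a
# dense phase grid (the shape has a single interior maximum).
.elastance_k <- function(p, T, n_grid = 2048L) {
  u <- seq(0, T, length.out = n_grid)
  smax <- max(.elastance_shape(u, p))
  # refine around the grid maximum with a golden-section polish
  i <- which.max(.elastance_shape(u, p))
  lo <- u[max(1L, i - 1L)]; hi <- u[min(n_grid, i + 1L)]
  opt <- stats::optimize(function(x) .elastance_shape(x, p),
                         interval = c(lo, hi), maximum = TRUE,
                         tol = .Machine$double.eps^0.5)
  smax <- max(smax, opt$objective)
  (p$E_max - p$E_min) / smax
}

#' Evaluate a time-varying elastance
#'
#' Computes E(t) for an elastance chamber.  Time is interpreted modulo the
#' cardiac period `T` relative to the contraction onset, so activations that
#' span the cycle boundary (e.g. atrial contraction with onset late in the
#' cycle) wrap around.  The activation shape is scaled so that its maximum
#' over one cycle equals `E_max` exactly and its baseline is `E_min`.
#'
#' @param t time (s); may be a vector
#' @param p an [elastance_params()] object
#' @param T cardiac period (s)
#' @return elastance E(t) in mmHg/ml
#' @export
evaluate_elastance <- function(t, p, T) {
  if (!(T > 0)) stop("invalid parameter: cardiac period T must be > 0")
  if (!inherits(p, "elastance_params")) stop("p must be an elastance_params object")
  k <- .elastance_k(p, T)
  u <- (t - p$t_onset) %% T
  k * .elastance_shape(u, p) + p$E_min
}

#' Chamber pressure from the elastance relation
#'
#' P = E (V - V0) (1 - Ks Q_out): the source-resistance term lowers the
#' developed pressure in proportion to the outflow.
#'
#' @param V chamber volume (ml)
#' @param Q_out outflow through the downstream valve (ml/s)
#' @param E instantaneous elastance (mmHg/ml)
#' @param p an [elastance_params()] object (V0, Ks are used)
#' @return pressure (mmHg)
#' @export
chamber_pressure <- function(V, Q_out, E, p) {
  E * (V - p$V0) * (1 - p$Ks * Q_out)
}

#' Valve state rate of change
#'
#' The valve state xi (0 = closed, 1 = open) opens at rate (1-xi) K_vo dP for
#' a favourable pressure difference and closes at rate xi K_vc dP for an
#' adverse one.
#'
#' @param xi valve state in \[0, 1\]
#' @param dP upstream-minus-downstream pressure difference (mmHg)
#' @param p a [valve_params()] object
#' @return d(xi)/dt (1/s)
#' @export
valve_state_derivative <- function(xi, dP, p) {
  ifelse(dP >= 0, (1 - xi) * p$K_vo * dP, xi * p$K_vc * dP)
}

#' Valve flow rate of change
#'
#' Bernoulli valve: dQ/dt = (dP - B |Q| Q) / L with B = rho / (2 A_eff^2) and
#' L = rho l_eff / A_eff, where A_eff = A_ann * xi.  The effective area is
#' floored at a small fraction of the annulus area so the coefficients stay
#' finite; flow through a valve held closed is managed by the integrator, not
#' here.
#'
#' @param Q valve flow (ml/s)
#' @param P_up,P_down upstream and downstream pressures (mmHg)
#' @param xi valve state
#' @param p a [valve_params()] object
#' @param rho blood density in internal units (mmHg s^2/cm^2); see
#'   [rho_internal()]
#' @return dQ/dt (ml/s^2)
#' @export
valve_flow_derivative <- function(Q, P_up, P_down, xi, p, rho) {
  A_eff <- p$A_ann * max(xi, .XI_FLOOR)
  B <- rho / (2 * A_eff^2)
  L <- rho * p$l_eff / A_eff
  (P_up - P_down - B * abs(Q) * Q) / L
}

#' Heart state constructor
#'
#' @param V_A,V_V atrial and ventricular volumes (ml)
#' @param Q_AVV,Q_AAo atrioventricular and aortic valve flows (ml/s)
#' @param xi_AVV,xi_AoV valve states in \[0, 1\]
#' @param t phase time within the cycle (s)
#' @return a named numeric vector of class `heart_state`
#' @export
heart_state <- function(V_A, V_V, Q_AVV = 0, Q_AAo = 0,
                        xi_AVV = 0, xi_AoV = 0, t = 0) {
  if (V_A <= 0 || V_V <= 0) stop("chamber volumes must be positive")
  if (xi_AVV < 0 || xi_AVV > 1 || xi_AoV < 0 || xi_AoV > 1)
    stop("valve states must lie in [0, 1]")
  structure(c(V_A = V_A, V_V = V_V, Q_AVV = Q_AVV, Q_AAo = Q_AAo,
              xi_AVV = xi_AVV, xi_AoV = xi_AoV, t = t),
            class = "heart_state")
}

#' Parameter bundle for the whole heart
#'
#' @param atrium,ventricle [elastance_params()] objects
#' @param avv,aov [valve_params()] objects for the atrioventricular and aortic
#'   valves
#' @param T cardiac period (s)
#' @param rho blood density in internal units
#' @return a list of class `heart_params` with precomputed elastance scaling
#'   factors
#' @export
heart_params <- function(atrium, ventricle, avv, aov, T, rho) {
  structure(list(atrium = atrium, ventricle = ventricle, avv = avv, aov = aov,
                 T = T, rho = rho,
                 k_A = .elastance_k(atrium, T),
                 k_V = .elastance_k(ventricle, T)),
            class = "heart_params")
}

# Fast scalar elastance evaluation with precomputed k (hot path).
.elastance_at <- function(t, p, k, T) {
  u <- (t - p$t_onset) %% T
  k * .elastance_shape(u, p) + p$E_min
}

# Heart state derivative.  Boundary couplings: Q_PA_in is the (constant over
# the step) inflow into the atrium; P_AAo is the (constant) aortic root
# pressure.  A valve at its floor with an adverse pressure gradient carries
# zero flow; the flow ODE is skipped and Q is pinned at zero.
.heart_deriv <- function(s, hp, Q_PA_in, P_AAo) {
  t <- s[7L]
  E_A <- .elastance_at(t, hp$atrium, hp$k_A, hp$T)
  E_V <- .elastance_at(t, hp$ventricle, hp$k_V, hp$T)
  P_A <- E_A * (s[1L] - hp$atrium$V0) * (1 - hp$atrium$Ks * s[3L])
  P_V <- E_V * (s[2L] - hp$ventricle$V0) * (1 - hp$ventricle$Ks * s[4L])

  dP_avv <- P_A - P_V
  dP_aov <- P_V - P_AAo
  avv_closed <- s[5L] <= .XI_FLOOR && dP_avv < 0
  aov_closed <- s[6L] <= .XI_FLOOR && dP_aov < 0

  Q_AVV <- if (avv_closed) 0 else s[3L]
  Q_AAo <- if (aov_closed) 0 else s[4L]

  dQ_AVV <- if (avv_closed) 0 else
    valve_flow_derivative(Q_AVV, P_A, P_V, s[5L], hp$avv, hp$rho)
  dQ_AAo <- if (aov_closed) 0 else
    valve_flow_derivative(Q_AAo, P_V, P_AAo, s[6L], hp$aov, hp$rho)

  dxi_AVV <- if (dP_avv >= 0) (1 - s[5L]) * hp$avv$K_vo * dP_avv
             else s[5L] * hp$avv$K_vc * dP_avv
  dxi_AoV <- if (dP_aov >= 0) (1 - s[6L]) * hp$aov$K_vo * dP_aov
             else s[6L] * hp$aov$K_vc * dP_aov

  c(Q_PA_in - Q_AVV,    # dV_A
    Q_AVV - Q_AAo,      # dV_V
    dQ_AVV, dQ_AAo, dxi_AVV, dxi_AoV, 1)
}

#' Advance the heart by one RK4 step
#'
#' Boundary couplings (atrial inflow `Q_PA_in` and aortic root pressure
#' `P_AAo`) are held constant over the step.  Valve states are clamped to
#' \[0, 1\] after the step; a valve at its closed floor under an adverse
#' pressure gradient carries exactly zero flow.
#'
#' @param state a [heart_state()] vector
#' @param Q_PA_in pulmonary (atrial) inflow held over the step (ml/s)
#' @param P_AAo aortic root pressure held over the step (mmHg)
#' @param dt time step (s)
#' @param params a [heart_params()] bundle
#' @return the advanced `heart_state`, with attributes `Q_AAo_bar` and
#'   `Q_AVV_bar`: the RK4 stage-weighted mean valve flows over the step (the
#'   exact discrete fluxes that moved volume between chambers and into the
#'   aorta)
#' @export
step_heart <- function(state, Q_PA_in, P_AAo, dt, params) {
  if (!(dt > 0)) stop("dt must be positive")
  nm <- names(state)
  s <- unname(unclass(state))
  k1 <- .heart_deriv(s, params, Q_PA_in, P_AAo)
  s2 <- s + 0.5 * dt * k1
  k2 <- .heart_deriv(s2, params, Q_PA_in, P_AAo)
  s3 <- s + 0.5 * dt * k2
  k3 <- .heart_deriv(s3, params, Q_PA_in, P_AAo)
  s4 <- s + dt * k3
  k4 <- .heart_deriv(s4, params, Q_PA_in, P_AAo)
  out <- s + (dt / 6) * (k1 + 2 * k2 + 2 * k3 + k4)

  # stage-weighted mean valve flows: exactly the discrete fluxes that the
  # RK4 volume update integrated, reused by the caller as interface fluxes
  # so chamber/vessel volume bookkeeping is consistent
  if (any(!is.finite(out))) {
    bad <- nm[which(!is.finite(out))[1L]]
    stop(sprintf("heart integration blew up: non-finite '%s' at t = %.6f s",
                 bad, s[7L]))
  }

  w <- c(1, 2, 2, 1) / 6
  Q_AVV_bar <- Q_PA_in - sum(w * c(k1[1L], k2[1L], k3[1L], k4[1L]))
  Q_AAo_bar <- Q_AVV_bar - sum(w * c(k1[2L], k2[2L], k3[2L], k4[2L]))

  # clamp valve states; a valve at the closed floor carries no flow
  out[5L] <- min(max(out[5L], 0), 1)
  out[6L] <- min(max(out[6L], 0), 1)
  if (out[5L] <= .XI_FLOOR) out[3L] <- 0
  if (out[6L] <= .XI_FLOOR) out[4L] <- 0
  names(out) <- nm
  structure(out, class = "heart_state",
            Q_AAo_bar = Q_AAo_bar, Q_AVV_bar = Q_AVV_bar)
}

#' Atrial and ventricular pressures for a heart state
#'
#' @inheritParams step_heart
#' @return named vector with `P_A`, `P_V`, `E_A`, `E_V`
#' @export
heart_pressures <- function(state, params) {
  s <- unname(unclass(state))
  E_A <- .elastance_at(s[7L], params$atrium, params$k_A, params$T)
  E_V <- .elastance_at(s[7L], params$ventricle, params$k_V, params$T)
  c(P_A = E_A * (s[1L] - params$atrium$V0) * (1 - params$atrium$Ks * s[3L]),
    P_V = E_V * (s[2L] - params$ventricle$V0) * (1 - params$ventricle$Ks * s[4L]),
    E_A = E_A, E_V = E_V)
}
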