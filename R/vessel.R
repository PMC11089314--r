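# 1-D pulse-wave solver for a tapered compliant vessel.
#
# Governing equations (area A, cross-sectionally averaged velocity U):
#   dA/dt + d(AU)/dx           = 0
#   dU/dt + d(U^2/2 + P/rho)/dx = -22 pi mu U / (rho A)
# closed by the tube law P = P0 + (beta/A0(x)) (sqrt(A) - sqrt(A0(x))),
# giving the wave speed c^2 = beta sqrt(A) / (2 rho A0).
#
# Discretisation: cell-centred finite volume with two-step Richtmyer
# (Lax-Wendroff) fluxes.  Area updates are in conservation form, so the
# discrete vessel volume changes exactly by the boundary-face fluxes.
# Boundary faces are supplied by the characteristic-based coupling solvers
# (see boundaries.R).

#' Wall stiffness from a reference pulse wave velocity
#'
#' beta = 2 rho c0^2 sqrt(A0), chosen so that the tube-law wave speed at
#' A = A0 equals c0.
#'
#' @param c0 reference pulse wave velocity (cm/s in internal units)
#' @param A0 reference area (cm^2)
#' @param rho blood density (internal units)
#' @return stiffness beta (mmHg cm)
#' @export
beta_from_pwv <- function(c0, A0, rho) {
  if (any(c(c0, A0, rho) <= 0)) stop("c0, A0 and rho must be positive")
  2 * rho * c0^2 * sqrt(A0)
}

#' Tube-law transmural pressure
#'
#' @param A luminal area (cm^2)
#' @param A0 reference area (cm^2)
#' @param beta wall stiffness (mmHg cm)
#' @param P0 reference (diastolic) pressure (mmHg)
#' @return pressure (mmHg)
#' @export
tube_law_pressure <- function(A, A0, beta, P0) {
  if (any(A <= 0) || any(A0 <= 0)) stop("areas must be positive")
  P0 + (beta / A0) * (sqrt(A) - sqrt(A0))
}

#' Tube-law wave speed
#'
#' c^2 = beta sqrt(A) / (2 rho A0).
#'
#' @inheritParams tube_law_pressure
#' @param rho blood density (internal units)
#' @return wave speed (cm/s)
#' @export
wave_speed <- function(A, A0, beta, rho) {
  sqrt(beta * sqrt(A) / (2 * rho * A0))
}

#' 1-D vessel segment description
#'
#' Geometry and wave speed of one vessel, in the clinical units of the input
#' tables (mm and m/s); converted to internal units when meshed.
#'
#' @param name vessel label
#' @param length vessel length (mm)
#' @param D_in,D_out inlet and outlet diameters (mm)
#' @param pwv reference pulse wave velocity (m/s)
#' @param P0 reference diastolic pressure (mmHg)
#' @param node_in,node_out topology node ids
#' @return an object of class `vessel_segment`
#' @export
vessel_segment <- function(name, length, D_in, D_out, pwv, P0,
                           node_in, node_out) {
  if (any(c(length, D_in, D_out, pwv) <= 0))
    stop(sprintf("vessel '%s': length, diameters and pwv must be positive", name))
  if (node_in == node_out)
    stop(sprintf("vessel '%s': node_in and node_out must differ", name))
  structure(list(name = name, length = length, D_in = D_in, D_out = D_out,
                 pwv = pwv, P0 = P0, node_in = node_in, node_out = node_out),
            class = "vessel_segment")
}

#' Build a computational mesh for a vessel segment
#'
#' Cell-centred mesh with `N = max(2, round(L / h))` equal cells.  The
#' diameter tapers linearly in x between the segment end values; the cell
#' reference areas follow from the local diameter, face reference areas are
#' the arithmetic means of the adjacent cells (end faces are one-sided), a
#' choice that preserves the uniform-pressure steady state exactly.
#'
#' @param spec a [vessel_segment()]
#' @param target_element_size target cell size (mm)
#' @param rho blood density (internal units)
#' @return an object of class `vessel_mesh` (all lengths in cm)
#' @export
build_vessel_mesh <- function(spec, target_element_size = 5, rho) {
  L_cm <- spec$length / 10
  N <- max(2L, as.integer(round(spec$length / target_element_size)))
  dx <- L_cm / N
  x_cell <- (seq_len(N) - 0.5) * dx
  x_face <- (0:N) * dx
  D_cm <- function(x) (spec$D_in + (spec$D_out - spec$D_in) * x / L_cm) / 10
  A0_cell <- pi * D_cm(x_cell)^2 / 4
  A0_face <- c(A0_cell[1L],
               (A0_cell[-N] + A0_cell[-1L]) / 2,
               A0_cell[N])
  c0 <- spec$pwv * 100  # m/s -> cm/s
  # constant PWV along the (possibly tapered) vessel => beta varies with x
  beta_cell <- beta_from_pwv(c0, A0_cell, rho)
  beta_face <- beta_from_pwv(c0, A0_face, rho)
  # precomputed constants for the hot paths
  bA0_cell <- beta_cell / A0_cell; sA0_cell <- sqrt(A0_cell)
  bA0_face <- beta_face / A0_face; sA0_face <- sqrt(A0_face)
  fc <- list(
    "in" = list(i = 1L, f = 1L, s = -1,
                A0 = A0_face[1L], beta = beta_face[1L],
                kc = sqrt(beta_face[1L] / (2 * rho * A0_face[1L]))),
    "out" = list(i = N, f = N + 1L, s = 1,
                 A0 = A0_face[N + 1L], beta = beta_face[N + 1L],
                 kc = sqrt(beta_face[N + 1L] / (2 * rho * A0_face[N + 1L]))))
  structure(list(name = spec$name, N = N, dx = dx, L = L_cm,
                 x_cell = x_cell, x_face = x_face,
                 A0_cell = A0_cell, A0_face = A0_face,
                 beta_cell = beta_cell, beta_face = beta_face,
                 bA0_cell = bA0_cell, sA0_cell = sA0_cell,
                 bA0_face = bA0_face, sA0_face = sA0_face,
                 fc = fc,
                 P0 = spec$P0, c0 = c0, rho = rho,
                 node_in = spec$node_in, node_out = spec$node_out),
            class = "vessel_mesh")
}

#' Initial state for a vessel
#'
#' @param mesh a [build_vessel_mesh()] mesh
#' @param P initial uniform pressure (mmHg)
#' @return list of class `vessel_state` with cell vectors `A` and `U`
#' @export
vessel_state_uniform <- function(mesh, P = mesh$P0) {
  s <- sqrt(mesh$A0_cell) + (P - mesh$P0) * mesh$A0_cell / mesh$beta_cell
  if (any(s <= 0)) stop("initial pressure collapses the vessel")
  structure(list(A = s^2, U = numeric(mesh$N)), class = "vessel_state")
}

#' Tube-law pressure of every cell of a vessel state
#'
#' @param state a `vessel_state`
#' @param mesh the matching `vessel_mesh`
#' @return pressure at the cell centres (mmHg)
#' @export
vessel_pressure <- function(state, mesh) {
  tube_law_pressure(state$A, mesh$A0_cell, mesh$beta_cell, mesh$P0)
}

# one right-hand-side evaluation of the semi-discrete MUSCL-Rusanov scheme
# (compiled kernel); returns d/dt of (A, U) given frozen boundary-face
# states.  Minmod-limited reconstruction of (P, U) at interior faces: the
# area at a face follows from the face reference geometry, so a spatially
# uniform pressure is an exact steady state on any taper.
.muscl_rhs <- function(A, U, mesh, bnd, mu) {
  N <- mesh$N
  .muscl_rhs_cpp(A, U, mesh$bA0_cell, mesh$sA0_cell, mesh$A0_face,
                 mesh$P0, mesh$c0, mesh$rho, mesh$dx,
                 bnd$A_in, bnd$U_in, bnd$A_out, bnd$U_out,
                 mesh$bA0_face[1L], mesh$sA0_face[1L],
                 mesh$bA0_face[N + 1L], mesh$sA0_face[N + 1L],
                 mu)
}

#' Advance a 1-D vessel state by one time step
#'
#' MUSCL (minmod-limited) reconstruction of pressure and velocity with
#' Rusanov fluxes, advanced with a two-stage strong-stability-preserving
#' Runge-Kutta step: formally second-order accurate in space and time on
#' smooth solutions and oscillation-free at steep fronts.  `bnd` carries
#' the boundary-face states `(A_in, U_in, A_out, U_out)` computed by the
#' coupling layer and held over the step; these define the boundary fluxes,
#' so the discrete vessel volume change equals
#' `dt * (A_in U_in - A_out U_out)` to machine precision.
#'
#' @param state a `vessel_state`
#' @param mesh a `vessel_mesh`
#' @param dt time step (s); must satisfy the CFL bound 0.5 dx / max(|U| + c)
#'   used by the driver
#' @param bnd named list with `A_in`, `U_in`, `A_out`, `U_out`
#' @param mu blood viscosity (internal units)
#' @param check_cfl if TRUE, abort with a configuration error when the CFL
#'   bound is violated
#' @return advanced `vessel_state`, with attribute `boundary_flux`:
#'   c(in = A_in U_in, out = A_out U_out)
#' @export
advance_1d <- function(state, mesh, dt, bnd, mu, check_cfl = FALSE) {
  A <- state$A; U <- state$U
  if (check_cfl) {
    cmax <- max(wave_speed(A, mesh$A0_cell, mesh$beta_cell, mesh$rho) + abs(U))
    if (dt > 0.5 * mesh$dx / cmax)
      stop(sprintf("CFL violation in '%s': dt = %.3g > admissible %.3g",
                   mesh$name, dt, 0.5 * mesh$dx / cmax))
  }
  k1 <- .muscl_rhs(A, U, mesh, bnd, mu)
  A1 <- A + dt * k1$dA; U1 <- U + dt * k1$dU
  if (any(A1 <= 0))
    stop(sprintf("solver blowup: negative area in '%s' at cell %d",
                 mesh$name, which(A1 <= 0)[1L]))
  k2 <- .muscl_rhs(A1, U1, mesh, bnd, mu)
  A_new <- 0.5 * (A + A1 + dt * k2$dA)
  U_new <- 0.5 * (U + U1 + dt * k2$dU)
  if (any(A_new <= 0))
    stop(sprintf("solver blowup: negative area in '%s' at cell %d",
                 mesh$name, which(A_new <= 0)[1L]))
  structure(list(A = A_new, U = U_new), class = "vessel_state",
            boundary_flux = c("in" = k1$F_in, "out" = k1$F_out))
}

#' Discrete volume of a vessel state
#'
#' @param state a `vessel_state`
#' @param mesh the matching `vessel_mesh`
#' @return volume (ml)
#' @export
vessel_volume <- function(state, mesh) sum(state$A) * mesh$dx
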