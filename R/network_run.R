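# Closed-loop time stepping and periodic convergence.
#
# Staggered explicit coupling per global step dt:
#   1. junction faces are solved from the current 1-D states (the atrial
#      fenestration, when present, enters one junction's mass balance);
#   2. the heart advances by RK4 with the atrial inflow (lung flows + shunt
#      flow) and aortic root pressure held constant over the step;
#   3. the body compartments advance by RK4 with the 1-D terminal pressures
#      held constant;
#   4. every 1-D terminal face is solved for the stage-averaged 0-D flux,
#      so each interface moves exactly the same volume on both of its
#      sides, making total blood volume conservative to round-off;
#   5. all vessels advance one Richtmyer step with those boundary faces.

.probe_names <- c("P_AAo", "Q_AAo_1d", "P_arch", "P_DAo", "Q_DAo",
                  "P_SVC", "Q_SVC", "P_IVC", "Q_IVC",
                  "P_RPA", "Q_RPA", "P_LPA", "Q_LPA",
                  "P_A", "P_V", "V_A", "V_V",
                  "Q_AVV", "Q_AAo", "xi_AVV", "xi_AoV",
                  "Pa1", "Pv1", "Pa2", "Pv2", "Q_fen")

# index of the probe cell (mid-vessel) per vessel
.mid_cell <- function(mesh) max(1L, as.integer(ceiling(mesh$N / 2)))

.record_probes <- function(m) {
  st <- m$states; ms <- m$meshes
  g <- function(nm) {
    i <- .mid_cell(ms[[nm]])
    c(tube_law_pressure(st[[nm]]$A[i], ms[[nm]]$A0_cell[i],
                        ms[[nm]]$beta_cell[i], ms[[nm]]$P0),
      st[[nm]]$A[i] * st[[nm]]$U[i])
  }
  aao <- g("AAo"); dao <- g("DAo"); svc <- g("SVC"); ivc <- g("IVC")
  rpa <- g("RPA"); lpa <- g("LPA_i")
  arch <- {
    n <- ms$AAo$N
    tube_law_pressure(st$AAo$A[n], ms$AAo$A0_cell[n], ms$AAo$beta_cell[n],
                      ms$AAo$P0)
  }
  hp <- heart_pressures(m$hstate, m$heart)
  h <- unclass(m$hstate)
  c(aao[1L], aao[2L], arch, dao[1L], dao[2L],
    svc[1L], -svc[2L],            # SVC re-signed to physiological direction
    ivc[1L], ivc[2L],
    rpa[1L], rpa[2L], lpa[1L], lpa[2L],
    hp[["P_A"]], hp[["P_V"]], h[1L], h[2L], h[3L], h[4L], h[5L], h[6L],
    m$cu[1L], m$cu[2L], m$cl[1L], m$cl[2L], m$Q_fen)
}

# one global step of the closed loop; mutates the model environment
.step_closed_loop <- function(m, dt) {
  hp <- heart_pressures(m$hstate, m$heart)
  P_A <- hp[["P_A"]]

  # 1. junctions (records max residual for diagnostics)
  jfaces <- vector("list", length(m$junctions))
  Q_fen_now <- 0
  for (j in seq_along(m$junctions)) {
    jn <- m$junctions[[j]]
    jc <- m$jc[[j]]
    n_e <- length(jc$s)
    A_cell <- numeric(n_e); U_cell <- numeric(n_e)
    for (e in seq_len(n_e)) {
      st <- m$states[[jn$ends[[e]]$vessel]]
      A_cell[e] <- st$A[jc$i[e]]
      U_cell[e] <- st$U[jc$i[e]]
    }
    W <- U_cell + jc$s * 4 * jc$kc * sqrt(sqrt(A_cell))
    sink <- NULL
    if (!is.null(jn$sink)) {
      sink <- if (jn$sink$L_in > 0) list(Q = m$Q_fen)
      else list(R = jn$sink$R, P_ext = P_A)
    }
    sol <- .junction_core(jc, W, if (is.null(m$jA[[j]])) A_cell else m$jA[[j]],
                          sink = sink, node = jn$node)
    m$jA[[j]] <- vapply(sol, function(f) f$A, 0)
    jfaces[[j]] <- sol
    if (!is.null(jn$sink)) {
      Q_fen_now <- attr(sol, "Q_sink")
      m$fen_P_node <- sol[[1L]]$P
      if (jn$sink$L_in == 0) m$Q_fen <- Q_fen_now
    }
  }

  # 2. terminal faces: solved implicitly against their resistor relations
  #    with the 0-D node pressures frozen at step start (implicit in the
  #    face state, so small attachment resistances stay stable)
  res <- list(
    "BCA:out"    = list(R = m$comp_upper$Ra_list[1L], P_ext = m$cu[1L]),
    "LCCA:out"   = list(R = m$comp_upper$Ra_list[2L], P_ext = m$cu[1L]),
    "DAo:out"    = list(R = m$comp_lower$Ra_list[1L], P_ext = m$cl[1L]),
    "SVC:out"    = list(R = m$comp_upper$Rv, P_ext = m$cu[2L]),
    "IVC:in"     = list(R = m$comp_lower$Rv, P_ext = m$cl[2L]),
    "RPA:out"    = list(R = m$lungs$R_RPA, P_ext = P_A),
    "LPA_ii:out" = list(R = m$lungs$R_LPA, P_ext = P_A))
  tfaces <- list()
  for (key in names(res)) {
    parts <- strsplit(key, ":", fixed = TRUE)[[1L]]
    con <- m$tc[[key]]
    st <- m$states[[parts[1L]]]
    W <- st$U[con$i] + con$s * 4 * con$kc * sqrt(sqrt(st$A[con$i]))
    tfaces[[key]] <- .terminal_solve(con, W,
                                     m$faces[[parts[1L]]][[parts[2L]]]$A,
                                     c(list(type = "resistor"), res[[key]]))
  }

  # 3. heart (atrial inflow and aortic root pressure frozen over the step);
  #    the atrial inflow is exactly the flux the pulmonary faces deliver
  Q_PA_in <- tfaces[["RPA:out"]]$Q + tfaces[["LPA_ii:out"]]$Q + Q_fen_now
  hs_new <- step_heart(m$hstate, Q_PA_in, m$faces$AAo[["in"]]$P, dt, m$heart)
  Q_AAo_bar <- attr(hs_new, "Q_AAo_bar")
  con <- m$tc[["AAo:in"]]
  st <- m$states$AAo
  W <- st$U[con$i] + con$s * 4 * con$kc * sqrt(sqrt(st$A[con$i]))
  tfaces[["AAo:in"]] <- .terminal_solve(con, W, m$faces$AAo[["in"]]$A,
                                        list(type = "flux", F = Q_AAo_bar))

  # 4. body compartments advance with the same frozen interface fluxes
  up <- step_body_compartment(m$cu, params = m$comp_upper, dt = dt,
                              feed_Q = tfaces[["BCA:out"]]$Q +
                                tfaces[["LCCA:out"]]$Q,
                              outlet_Q = -tfaces[["SVC:out"]]$Q)
  lo <- step_body_compartment(m$cl, params = m$comp_lower, dt = dt,
                              feed_Q = tfaces[["DAo:out"]]$Q,
                              outlet_Q = -tfaces[["IVC:in"]]$Q)

  # 5. advance all vessels
  faces_new <- m$faces
  # collect per-vessel boundary data
  bnd <- lapply(m$meshes, function(mesh) list())
  for (j in seq_along(m$junctions)) {
    jn <- m$junctions[[j]]
    for (e in seq_along(jn$ends)) {
      v <- jn$ends[[e]]$vessel; side <- jn$ends[[e]]$side
      bnd[[v]][[side]] <- jfaces[[j]][[e]]
    }
  }
  for (key in names(tfaces)) {
    parts <- strsplit(key, ":", fixed = TRUE)[[1L]]
    bnd[[parts[1L]]][[parts[2L]]] <- tfaces[[key]]
  }
  for (nm in names(m$meshes)) {
    b <- bnd[[nm]]
    m$states[[nm]] <- advance_1d(m$states[[nm]], m$meshes[[nm]], dt,
                                 list(A_in = b[["in"]]$A, U_in = b[["in"]]$U,
                                      A_out = b[["out"]]$A, U_out = b[["out"]]$U),
                                 m$mu)
    faces_new[[nm]][["in"]] <- b[["in"]]
    faces_new[[nm]][["out"]] <- b[["out"]]
  }
  m$faces <- faces_new

  # 6. fenestration inertance update (when enabled)
  for (jn in m$junctions) {
    if (!is.null(jn$sink) && jn$sink$L_in > 0) {
      dQ <- (m$fen_P_node - P_A - jn$sink$R * m$Q_fen) / jn$sink$L_in
      m$Q_fen <- m$Q_fen + dt * dQ
    }
  }

  m$hstate <- hs_new
  m$cu <- up$state
  m$cl <- lo$state
  m$t <- m$t + dt
  invisible(m)
}

# automatic time step from the CFL bound (0.5) with a velocity headroom
.auto_dt <- function(m) {
  dts <- vapply(m$meshes, function(mesh) {
    head_U <- 150  # cm/s velocity headroom
    0.5 * mesh$dx / (1.15 * mesh$c0 + head_U)
  }, 0)
  min(dts)
}

#' Run a circulation model to its periodic state
#'
#' Advances whole cardiac cycles until the cycle means of all probe signals
#' change by less than `periodicity_tol` (relative) between consecutive
#' cycles, or until `max_cycles`.  The final cycle's waveforms are returned
#' resampled to the configured output rate (default 1 kHz).
#'
#' @param model an initialized `circulation_model`
#' @param max_cycles,periodicity_tol override the configured settings
#' @param verbose print per-cycle convergence diagnostics
#' @return an object of class `periodic_solution`: list with `waveforms`
#'   (data frame, `time` plus one column per probe signal, one cycle at the
#'   output rate), `means` (cycle-mean history matrix), `converged`,
#'   `cycles`, `dt`, `T`, `volume_drift` (per-cycle relative change of total
#'   stored volume), `indices` (see [cardiac_indices()])
#' @export
run_to_periodic <- function(model, max_cycles = NULL, periodicity_tol = NULL,
                            verbose = FALSE) {
  if (!isTRUE(model$initialized)) stop("initialize the model first")
  s <- model$settings
  if (is.null(max_cycles)) max_cycles <- s$max_cycles
  if (is.null(periodicity_tol)) periodicity_tol <- s$periodicity_tol
  dt0 <- if (identical(s$dt, "auto")) .auto_dt(model) else s$dt
  n_steps <- as.integer(ceiling(model$T / dt0))
  dt <- model$T / n_steps

  np <- length(.probe_names)
  rec <- matrix(0, n_steps, np)
  colnames(rec) <- .probe_names
  means_hist <- NULL
  drift_hist <- numeric(0)
  converged <- FALSE
  V_prev <- total_blood_volume(model)

  for (cyc in seq_len(max_cycles)) {
    for (i in seq_len(n_steps)) {
      rec[i, ] <- .record_probes(model)
      .step_closed_loop(model, dt)
    }
    model$cycle <- model$cycle + 1L
    mu_cyc <- colMeans(rec)
    V_now <- total_blood_volume(model)
    drift_hist <- c(drift_hist, (V_now - V_prev) / s$V_blood)
    V_prev <- V_now
    if (!is.null(means_hist)) {
      prev <- means_hist[nrow(means_hist), ]
      rel <- abs(mu_cyc - prev) / pmax(abs(mu_cyc), 0.1)
      if (verbose)
        message(sprintf("cycle %d: max rel change %.2e, volume %.4f ml",
                        cyc, max(rel), V_now))
      if (max(rel) < periodicity_tol) {
        means_hist <- rbind(means_hist, mu_cyc)
        converged <- TRUE
        break
      }
    }
    means_hist <- rbind(means_hist, mu_cyc)
  }
  if (!converged)
    warning(sprintf("not periodic after %d cycles (tol %.1e); returning partial result",
                    max_cycles, periodicity_tol))

  # resample the final cycle to the output rate (periodic extension)
  t_step <- (seq_len(n_steps) - 1L) * dt
  n_out <- as.integer(round(model$T * s$output_rate))
  t_out <- (seq_len(n_out) - 1L) / s$output_rate
  wf <- data.frame(time = t_out)
  for (k in seq_len(np)) {
    y <- rec[, k]
    wf[[.probe_names[k]]] <- stats::approx(c(t_step, model$T), c(y, y[1L]),
                                           xout = t_out)$y
  }

  sol <- list(waveforms = wf, rec = rec, dt = dt, T = model$T,
              means = means_hist, volume_drift = drift_hist,
              converged = converged, cycles = model$cycle,
              scenario = model$scenario$kind)
  sol$indices <- cardiac_indices(wf, model$T)
  class(sol) <- "periodic_solution"
  sol
}

#' @export
print.periodic_solution <- function(x, ...) {
  cat(sprintf("Periodic solution (%s): %d cycles, dt = %.2e s, %s\n",
              x$scenario, x$cycles, x$dt,
              if (x$converged) "converged" else "NOT converged"))
  if (!is.null(x$indices)) print(x$indices)
  invisible(x)
}
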