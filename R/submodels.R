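# Open-loop calibration submodels.  The closed loop decomposes into four
# simpler assemblies used by the stepwise parameter estimation:
#   1  0-D heart + three-element Windkessel (3WK) for the whole systemic
#      circulation, driven by a prescribed pulmonary (atrial) inflow;
#   2  1-D aorta + supra-aortic vessels with 3WK terminals, driven by a
#      prescribed aortic root flow;
#   3  1-D cavopulmonary connection with the lung resistances draining to a
#      constant atrial pressure, driven by prescribed caval flows;
#   4  the aorta and TCPC of 2 and 3 coupled through the body compartments
#      into one open loop, driven by a prescribed aortic root flow.

# equivalent series/parallel resistance of the systemic periphery
.systemic_resistance <- function(config) {
  up <- config$compartments$upper; lo <- config$compartments$lower
  R_up <- 1 / (1 / up$R_a1 + 1 / up$R_a2) + up$R_c1 + up$R_v1
  R_lo <- lo$R_a4 + lo$R_c2 + lo$R_v2
  1 / (1 / R_up + 1 / R_lo)
}

# characteristic impedance rho c0 / A0 of a configured vessel end
.char_impedance <- function(config, name, side) {
  row <- NULL
  for (r in config$vessels) if (r$name == name) row <- r
  if (is.null(row)) stop("no vessel named ", name)
  D <- if (side == "in") row$D_in else row$D_out
  A0 <- pi * (D / 10)^2 / 4
  rho_internal(config$settings$rho) * (row$PWV * 100) / A0
}

# default 3WK parameter sets derived from the configured periphery
.default_wk3 <- function(config) {
  P_out <- config$settings$P_init
  up <- config$compartments$upper; lo <- config$compartments$lower
  R_paths <- c(BCA = up$R_a1 + up$R_c1 + up$R_v1,
               LCCA = up$R_a2 + up$R_c1 + up$R_v1,
               DAo = lo$R_a4 + lo$R_c2 + lo$R_v2)
  C_tot <- up$C_a1 + lo$C_a2
  G <- 1 / R_paths
  Cs <- C_tot * G / sum(G)
  Z0 <- .char_impedance(config, "AAo", "in")
  sys <- list(systemic = wk3_params(Z0,
                                    max(.systemic_resistance(config) - Z0, 1e-3),
                                    C_tot, P_out))
  for (nm in c("BCA", "LCCA", "DAo")) {
    Zt <- .char_impedance(config, nm, "out")
    sys[[nm]] <- wk3_params(Zt, max(R_paths[[nm]] - Zt, 1e-3),
                            Cs[[nm]], P_out)
  }
  sys
}

.as_wave_fun <- function(w) {
  if (is.function(w)) return(w)
  if (inherits(w, "waveform_series")) return(periodic_waveform_fun(w))
  stop("prescribed waveforms must be waveform_series objects or functions of time")
}

#' Build an open-loop calibration submodel
#'
#' @param which submodel number, 1-4
#' @param config a validated `fontan_config`
#' @param waveforms named list of prescribed flow waveforms
#'   ([waveform_series()] or functions of time, ml/s): submodel 1 needs
#'   `Q_PA`; submodels 2 and 4 need `Q_AAo`; submodel 3 needs `Q_IVC` and
#'   `Q_SVC` (both positive toward the TCPC)
#' @param wk3 optional named list of [wk3_params()] overriding the defaults
#'   derived from the configured periphery (`systemic` for submodel 1;
#'   `BCA`, `LCCA`, `DAo` for submodel 2)
#' @param P_atrium constant atrial pressure for submodels 3 and 4 (mmHg);
#'   default the configured initial pressure
#' @return an (uninitialized) open-loop model environment of class
#'   `circulation_model`
#' @export
build_submodel <- function(which, config, waveforms = list(), wk3 = NULL,
                           P_atrium = NULL) {
  config <- validate_config(config)
  s <- config$settings
  rho <- rho_internal(s$rho); mu <- mu_internal(s$mu)
  if (is.null(P_atrium)) P_atrium <- s$P_init
  need <- switch(as.character(which),
                 "1" = "Q_PA", "2" = "Q_AAo",
                 "3" = c("Q_IVC", "Q_SVC"), "4" = "Q_AAo",
                 stop("submodel number must be 1, 2, 3 or 4"))
  missing <- setdiff(need, names(waveforms))
  if (length(missing))
    stop("configuration error: missing prescribed waveform(s): ",
         paste(missing, collapse = ", "))
  wfun <- lapply(waveforms, .as_wave_fun)

  aorta_set <- c("AAo", "DAo", "BCA", "LCCA")
  tcpc_set <- c("IVC", "RPA", "LPA_i", "LPA_ii", "SVC")
  keep <- switch(as.character(which),
                 "1" = character(), "2" = aorta_set, "3" = tcpc_set,
                 "4" = c(aorta_set, tcpc_set))

  T <- s$T
  m <- new.env(parent = emptyenv())
  m$kind <- paste0("submodel", which)
  m$which <- as.integer(which)
  m$config <- config; m$settings <- s
  m$rho <- rho; m$mu <- mu; m$T <- T
  m$wfun <- wfun
  m$P_atrium <- P_atrium
  m$initialized <- FALSE

  # submodel 2 references the DAo diastolic pressure; others the LPCW value
  P_init <- if (which == 2) 42 else s$P_init
  m$P_init <- P_init

  meshes <- list()
  for (row in config$vessels) {
    if (!(row$name %in% keep)) next
    P0 <- if (row$name %in% .aorta_names) {
      if (which == 2) 42 else s$P0_aorta
    } else s$P0_tcpc
    seg <- vessel_segment(row$name, row$L, row$D_in, row$D_out, row$PWV,
                          P0, row$node_in, row$node_out)
    meshes[[row$name]] <- build_vessel_mesh(seg, s$element_size, rho)
  }
  m$meshes <- meshes

  # junctions among the retained vessels
  node_ends <- list()
  for (nm in names(meshes)) {
    mm <- meshes[[nm]]
    for (side in c("in", "out")) {
      node <- if (side == "in") mm$node_in else mm$node_out
      key <- as.character(node)
      node_ends[[key]] <- c(node_ends[[key]],
                            list(list(vessel = nm, side = side)))
    }
  }
  m$junctions <- list()
  for (key in names(node_ends))
    if (length(node_ends[[key]]) > 1L)
      m$junctions[[length(m$junctions) + 1L]] <-
        list(node = as.integer(key), ends = node_ends[[key]], sink = NULL)

  wk3_all <- .default_wk3(config)
  if (!is.null(wk3)) wk3_all[names(wk3)] <- wk3

  # heart (submodel 1 only)
  if (which == 1) {
    hc <- config$heart
    atr <- elastance_params(hc$atrium$E_min, hc$atrium$E_max,
                            hc$atrium$tau1_frac * T, hc$atrium$tau2_frac * T,
                            hc$atrium$m1, hc$atrium$m2,
                            hc$atrium$t_onset_frac * T, hc$atrium$V0,
                            hc$atrium$K_s)
    ven <- elastance_params(hc$ventricle$E_min, hc$ventricle$E_max,
                            hc$ventricle$tau1_frac * T, hc$ventricle$tau2_frac * T,
                            hc$ventricle$m1, hc$ventricle$m2,
                            hc$ventricle$t_onset_frac * T, hc$ventricle$V0,
                            hc$ventricle$K_s)
    avv <- valve_params(hc$avv$A_ann, hc$avv$l_eff, hc$avv$K_vo, hc$avv$K_vc)
    aov <- valve_params(hc$aov$A_ann, hc$aov$l_eff, hc$aov$K_vo, hc$aov$K_vc)
    m$heart <- heart_params(atr, ven, avv, aov, T, rho)
    m$wk3_systemic <- wk3_all$systemic
  }

  # terminal wiring
  terminals <- list()
  if (which == 2) {
    terminals[["AAo:in"]] <- list(kind = "prescribed_flux", fun = wfun$Q_AAo)
    for (nm in c("BCA", "LCCA", "DAo"))
      terminals[[paste0(nm, ":out")]] <- list(kind = "wk3", params = wk3_all[[nm]])
  } else if (which == 3) {
    terminals[["IVC:in"]] <- list(kind = "prescribed_flux", fun = wfun$Q_IVC)
    # positive Q_SVC toward the TCPC enters the SVC at its node_out face
    terminals[["SVC:out"]] <- list(kind = "prescribed_flux",
                                   fun = function(t) -wfun$Q_SVC(t))
    terminals[["RPA:out"]] <- list(kind = "resistor", R = config$lungs$R_RPA,
                                   P_ext = P_atrium)
    terminals[["LPA_ii:out"]] <- list(kind = "resistor", R = config$lungs$R_LPA,
                                      P_ext = P_atrium)
  } else if (which == 4) {
    terminals[["AAo:in"]] <- list(kind = "prescribed_flux", fun = wfun$Q_AAo)
    terminals[["BCA:out"]] <- list(kind = "body_feed", compartment = "upper", slot = 1L)
    terminals[["LCCA:out"]] <- list(kind = "body_feed", compartment = "upper", slot = 2L)
    terminals[["DAo:out"]] <- list(kind = "body_feed", compartment = "lower", slot = 1L)
    terminals[["SVC:out"]] <- list(kind = "venous_return", compartment = "upper")
    terminals[["IVC:in"]] <- list(kind = "venous_return", compartment = "lower")
    terminals[["RPA:out"]] <- list(kind = "resistor", R = config$lungs$R_RPA,
                                   P_ext = P_atrium)
    terminals[["LPA_ii:out"]] <- list(kind = "resistor", R = config$lungs$R_LPA,
                                      P_ext = P_atrium)
  }
  m$terminals <- terminals

  if (which == 4) {
    up <- config$compartments$upper; lo <- config$compartments$lower
    m$comp_upper <- body_compartment_params(c(up$R_a1, up$R_a2), up$R_c1,
                                            up$R_v1, up$C_a1, up$C_v1)
    m$comp_lower <- body_compartment_params(lo$R_a4, lo$R_c2, lo$R_v2,
                                            lo$C_a2, lo$C_v2)
  }
  class(m) <- "circulation_model"
  m
}

#' Initialize an open-loop submodel
#'
#' Zero velocity, uniform pressure at the submodel's reference diastolic
#' value; Windkessel compliance nodes and body compartments start at the
#' same pressure.
#'
#' @param m a submodel from [build_submodel()]
#' @return the model, initialized in place
#' @export
initialize_submodel <- function(m) {
  P <- m$P_init
  m$states <- lapply(m$meshes, function(mesh) vessel_state_uniform(mesh, P))
  m$faces <- lapply(m$meshes, function(mesh) {
    sL <- sqrt(mesh$A0_face[1L]) +
      (P - mesh$P0) * mesh$A0_face[1L] / mesh$beta_face[1L]
    sR <- sqrt(mesh$A0_face[mesh$N + 1L]) +
      (P - mesh$P0) * mesh$A0_face[mesh$N + 1L] / mesh$beta_face[mesh$N + 1L]
    list("in" = list(A = sL^2, U = 0, P = P),
         "out" = list(A = sR^2, U = 0, P = P))
  })
  names(m$faces) <- names(m$meshes)
  for (key in names(m$terminals))
    if (m$terminals[[key]]$kind == "wk3") m$terminals[[key]]$P_c <- P
  if (m$which == 1) {
    E_A0 <- evaluate_elastance(0, m$heart$atrium, m$T)
    m$hstate <- heart_state(V_A = m$heart$atrium$V0 + P / E_A0, V_V = 74.4,
                            t = 0)
    m$P_c <- P          # systemic 3WK compliance-node pressure
    m$P_AAo <- P
  }
  if (!is.null(m$comp_upper)) {
    m$cu <- c(Pa = P, Pv = P)
    m$cl <- c(Pa = P, Pv = P)
  }
  m$t <- 0
  m$cycle <- 0L
  m$jA <- vector("list", length(m$junctions))
  m$initialized <- TRUE
  invisible(m)
}

# one step of submodel 1 (pure 0-D)
.step_submodel1 <- function(m, dt) {
  Q_PA <- m$wfun$Q_PA(m$t)
  hs_new <- step_heart(m$hstate, Q_PA, m$P_AAo, dt, m$heart)
  w <- wk3_step(attr(hs_new, "Q_AAo_bar"), m$P_c, m$wk3_systemic, dt)
  m$P_c <- w$P_c
  m$P_AAo <- m$P_c + unclass(hs_new)[4L] * m$wk3_systemic$R1
  m$hstate <- hs_new
  m$t <- m$t + dt
  invisible(m)
}

# one step of an open 1-D submodel (2, 3 or 4)
.step_open_1d <- function(m, dt) {
  jfaces <- vector("list", length(m$junctions))
  for (j in seq_along(m$junctions)) {
    jn <- m$junctions[[j]]
    ends <- lapply(jn$ends, function(e)
      list(state = m$states[[e$vessel]], mesh = m$meshes[[e$vessel]],
           side = e$side))
    jfaces[[j]] <- junction_solve(ends, node = jn$node, A_init = m$jA[[j]])
    m$jA[[j]] <- vapply(jfaces[[j]], function(f) f$A, 0)
  }

  tfaces <- list()
  for (key in names(m$terminals)) {
    tm <- m$terminals[[key]]
    parts <- strsplit(key, ":", fixed = TRUE)[[1L]]
    nm <- parts[1L]; side <- parts[2L]
    st <- m$states[[nm]]; mesh <- m$meshes[[nm]]
    if (tm$kind == "prescribed_flux") {
      tfaces[[key]] <- couple_1d_0d(st, mesh, side,
                                    list(type = "flux", F = tm$fun(m$t)))
    } else if (tm$kind == "resistor") {
      tfaces[[key]] <- couple_1d_0d(st, mesh, side,
                                    list(type = "resistor", R = tm$R,
                                         P_ext = tm$P_ext))
    } else if (tm$kind == "wk3") {
      f <- couple_1d_0d(st, mesh, side,
                        list(type = "resistor", R = tm$params$R1,
                             P_ext = tm$P_c))
      w <- wk3_step(f$Q, tm$P_c, tm$params, dt)
      m$terminals[[key]]$P_c <- w$P_c
      tfaces[[key]] <- f
    } else {
      # body_feed / venous_return: implicit resistor coupling against the
      # compartment node pressure frozen at step start
      el <- switch(tm$kind,
        body_feed = if (tm$compartment == "upper")
          list(R = m$comp_upper$Ra_list[tm$slot], P_ext = m$cu[1L])
        else list(R = m$comp_lower$Ra_list[tm$slot], P_ext = m$cl[1L]),
        venous_return = if (tm$compartment == "upper")
          list(R = m$comp_upper$Rv, P_ext = m$cu[2L])
        else list(R = m$comp_lower$Rv, P_ext = m$cl[2L]))
      tfaces[[key]] <- couple_1d_0d(st, mesh, side,
                                    c(list(type = "resistor"), el))
    }
  }

  # compartments advance with the frozen interface fluxes
  if (!is.null(m$comp_upper)) {
    up <- step_body_compartment(m$cu, params = m$comp_upper, dt = dt,
                                feed_Q = tfaces[["BCA:out"]]$Q +
                                  tfaces[["LCCA:out"]]$Q,
                                outlet_Q = -tfaces[["SVC:out"]]$Q)
    lo <- step_body_compartment(m$cl, params = m$comp_lower, dt = dt,
                                feed_Q = tfaces[["DAo:out"]]$Q,
                                outlet_Q = -tfaces[["IVC:in"]]$Q)
    m$cu_next <- up$state; m$cl_next <- lo$state
  }

  bnd <- lapply(m$meshes, function(mesh) list())
  for (j in seq_along(m$junctions)) {
    jn <- m$junctions[[j]]
    for (e in seq_along(jn$ends)) {
      bnd[[jn$ends[[e]]$vessel]][[jn$ends[[e]]$side]] <- jfaces[[j]][[e]]
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
    m$faces[[nm]][["in"]] <- b[["in"]]
    m$faces[[nm]][["out"]] <- b[["out"]]
  }
  if (!is.null(m$comp_upper)) {
    m$cu <- m$cu_next; m$cl <- m$cl_next
  }
  m$t <- m$t + dt
  invisible(m)
}

.submodel_probes <- function(m) {
  if (m$which == 1) {
    hp <- heart_pressures(m$hstate, m$heart)
    h <- unclass(m$hstate)
    v <- c(hp[["P_A"]], hp[["P_V"]], h[1L], h[2L], h[3L], h[4L], h[5L], h[6L],
           m$P_AAo, m$P_c)
    names(v) <- c("P_A", "P_V", "V_A", "V_V", "Q_AVV", "Q_AAo",
                  "xi_AVV", "xi_AoV", "P_AAo", "P_c")
    return(v)
  }
  out <- numeric(0)
  for (nm in names(m$meshes)) {
    mesh <- m$meshes[[nm]]; st <- m$states[[nm]]
    i <- .mid_cell(mesh)
    P <- tube_law_pressure(st$A[i], mesh$A0_cell[i], mesh$beta_cell[i], mesh$P0)
    Q <- st$A[i] * st$U[i]
    if (nm == "SVC") Q <- -Q
    v <- c(P, Q); names(v) <- paste0(c("P_", "Q_"), nm)
    out <- c(out, v)
  }
  if (!is.null(m$comp_upper)) {
    v <- c(m$cu, m$cl); names(v) <- c("Pa1", "Pv1", "Pa2", "Pv2")
    out <- c(out, v)
  }
  out
}

#' Run an open-loop submodel to its periodic state
#'
#' Same periodicity criterion as [run_to_periodic()]; prescribed waveforms
#' are extended periodically.
#'
#' @param m an initialized submodel
#' @param max_cycles,periodicity_tol overrides of the configured settings
#' @param verbose print per-cycle diagnostics
#' @return a `periodic_solution`-like list (no cardiac indices for the
#'   vessel-only submodels; submodel 1 reports heart signals)
#' @export
run_submodel <- function(m, max_cycles = NULL, periodicity_tol = NULL,
                         verbose = FALSE) {
  if (!isTRUE(m$initialized)) stop("initialize the submodel first")
  s <- m$settings
  if (is.null(max_cycles)) max_cycles <- s$max_cycles
  if (is.null(periodicity_tol)) periodicity_tol <- s$periodicity_tol
  dt0 <- if (m$which == 1) m$T / 4000 else
    if (identical(s$dt, "auto")) .auto_dt(m) else s$dt
  n_steps <- as.integer(ceiling(m$T / dt0))
  dt <- m$T / n_steps

  p0 <- .submodel_probes(m)
  rec <- matrix(0, n_steps, length(p0))
  colnames(rec) <- names(p0)
  means_hist <- NULL
  converged <- FALSE
  stepper <- if (m$which == 1) .step_submodel1 else .step_open_1d

  for (cyc in seq_len(max_cycles)) {
    for (i in seq_len(n_steps)) {
      rec[i, ] <- .submodel_probes(m)
      stepper(m, dt)
    }
    m$cycle <- m$cycle + 1L
    mu_cyc <- colMeans(rec)
    if (!is.null(means_hist)) {
      prev <- means_hist[nrow(means_hist), ]
      rel <- abs(mu_cyc - prev) / pmax(abs(mu_cyc), 0.1)
      if (verbose) message(sprintf("cycle %d: max rel change %.2e", cyc, max(rel)))
      if (max(rel) < periodicity_tol) {
        means_hist <- rbind(means_hist, mu_cyc)
        converged <- TRUE
        break
      }
    }
    means_hist <- rbind(means_hist, mu_cyc)
  }
  if (!converged)
    warning(sprintf("submodel not periodic after %d cycles", max_cycles))

  t_step <- (seq_len(n_steps) - 1L) * dt
  n_out <- as.integer(round(m$T * s$output_rate))
  t_out <- (seq_len(n_out) - 1L) / s$output_rate
  wf <- data.frame(time = t_out)
  for (k in seq_len(ncol(rec)))
    wf[[colnames(rec)[k]]] <- stats::approx(c(t_step, m$T),
                                            c(rec[, k], rec[1L, k]),
                                            xout = t_out)$y
  structure(list(waveforms = wf, rec = rec, dt = dt, T = m$T,
                 means = means_hist, converged = converged,
                 cycles = m$cycle, scenario = m$kind),
            class = "periodic_solution")
}
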