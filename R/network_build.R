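# Closed-loop network assembly: wire the 1-D vessel domains, the 0-D heart,
# body compartments and lungs into one model object, allocate initial
# volumes, and apply intervention scenarios.
#
# The model object is an environment (the stepper mutates state in place):
#   meshes      named list of vessel_mesh
#   states      named list of vessel_state
#   junctions   list of junction descriptors (node id + member ends)
#   terminals   named list of terminal attachments per vessel end
#   heart       heart_params; hstate: heart_state
#   comp_upper/comp_lower: body_compartment_params; cu/cl: c(Pa, Pv)
#   lungs       lung_params
#   faces       per-vessel cached boundary-face states
#   settings, scenario, fen (fenestration descriptor or NULL)

.aorta_names <- c("AAo", "DAo", "BCA", "LCCA")

#' Build the closed-loop patient circulation model
#'
#' Meshes the nine 1-D vessel domains, derives junctions from the node ids
#' (a node shared by two or more vessel ends becomes a junction; a node with
#' a single end must carry a terminal attachment), and wires the terminal
#' ends: brachiocephalic and carotid outlets feed the upper-body
#' compartment, the descending aorta feeds the lower body, the venous sides
#' return into the venae cavae, the pulmonary artery outlets drain through
#' the lung resistances into the atrium, and the heart pumps from the atrium
#' into the ascending aorta.
#'
#' @param config a validated `fontan_config` (see [fixture_patient()],
#'   [load_config()])
#' @return a circulation model object of class `circulation_model`
#' @export
build_closed_loop <- function(config) {
  config <- validate_config(config)
  s <- config$settings
  rho <- rho_internal(s$rho)
  mu <- mu_internal(s$mu)

  meshes <- list()
  for (row in config$vessels) {
    P0 <- if (row$name %in% .aorta_names) s$P0_aorta else s$P0_tcpc
    seg <- vessel_segment(row$name, row$L, row$D_in, row$D_out, row$PWV,
                          P0, row$node_in, row$node_out)
    meshes[[row$name]] <- build_vessel_mesh(seg, s$element_size, rho)
  }

  # collect vessel ends per node
  node_ends <- list()
  for (nm in names(meshes)) {
    m <- meshes[[nm]]
    for (side in c("in", "out")) {
      node <- if (side == "in") m$node_in else m$node_out
      key <- as.character(node)
      node_ends[[key]] <- c(node_ends[[key]],
                            list(list(vessel = nm, side = side)))
    }
  }

  # expected terminal attachments, keyed by "<vessel>:<side>"
  terminal_spec <- list(
    "AAo:in"    = list(kind = "heart_outflow"),
    "BCA:out"   = list(kind = "body_feed", compartment = "upper", slot = 1L),
    "LCCA:out"  = list(kind = "body_feed", compartment = "upper", slot = 2L),
    "DAo:out"   = list(kind = "body_feed", compartment = "lower", slot = 1L),
    "SVC:out"   = list(kind = "venous_return", compartment = "upper"),
    "IVC:in"    = list(kind = "venous_return", compartment = "lower"),
    "RPA:out"   = list(kind = "lung", branch = "R_RPA"),
    "LPA_ii:out" = list(kind = "lung", branch = "R_LPA"))

  junctions <- list(); terminals <- list()
  for (key in names(node_ends)) {
    ends <- node_ends[[key]]
    if (length(ends) == 1L) {
      ekey <- paste0(ends[[1L]]$vessel, ":", ends[[1L]]$side)
      att <- terminal_spec[[ekey]]
      if (is.null(att))
        stop(sprintf("topology error: dangling vessel end %s at node %s",
                     ekey, key))
      terminals[[ekey]] <- c(att, list(node = as.integer(key)))
    } else if (length(ends) <= 4L) {
      junctions[[length(junctions) + 1L]] <-
        list(node = as.integer(key), ends = ends)
    } else {
      stop(sprintf("topology error: node %s joins %d vessel ends", key,
                   length(ends)))
    }
  }
  needed <- setdiff(names(terminal_spec), names(terminals))
  if (length(needed))
    stop(sprintf("topology error: missing terminal attachment(s): %s",
                 paste(needed, collapse = ", ")))

  T <- s$T
  hc <- config$heart
  atr <- elastance_params(hc$atrium$E_min, hc$atrium$E_max,
                          hc$atrium$tau1_frac * T, hc$atrium$tau2_frac * T,
                          hc$atrium$m1, hc$atrium$m2,
                          hc$atrium$t_onset_frac * T,
                          hc$atrium$V0, hc$atrium$K_s)
  ven <- elastance_params(hc$ventricle$E_min, hc$ventricle$E_max,
                          hc$ventricle$tau1_frac * T, hc$ventricle$tau2_frac * T,
                          hc$ventricle$m1, hc$ventricle$m2,
                          hc$ventricle$t_onset_frac * T,
                          hc$ventricle$V0, hc$ventricle$K_s)
  avv <- valve_params(hc$avv$A_ann, hc$avv$l_eff, hc$avv$K_vo, hc$avv$K_vc)
  aov <- valve_params(hc$aov$A_ann, hc$aov$l_eff, hc$aov$K_vo, hc$aov$K_vc)

  up <- config$compartments$upper
  lo <- config$compartments$lower
  upper_Ra <- c(up$R_a1, up$R_a2)
  if (!is.null(up$R_a3)) upper_Ra <- c(upper_Ra, up$R_a3)

  m <- new.env(parent = emptyenv())
  m$config <- config
  m$settings <- s
  m$rho <- rho; m$mu <- mu; m$T <- T
  m$meshes <- meshes
  m$junctions <- junctions
  m$terminals <- terminals
  m$heart <- heart_params(atr, ven, avv, aov, T, rho)
  m$comp_upper <- body_compartment_params(upper_Ra, up$R_c1, up$R_v1,
                                          up$C_a1, up$C_v1)
  m$comp_lower <- body_compartment_params(lo$R_a4, lo$R_c2, lo$R_v2,
                                          lo$C_a2, lo$C_v2)
  m$lungs <- lung_params(config$lungs$R_RPA, config$lungs$R_LPA)
  m$scenario <- config$scenario
  m$fen <- NULL
  m$initialized <- FALSE
  class(m) <- "circulation_model"
  m
}

#' @export
print.circulation_model <- function(x, ...) {
  if (!is.null(x$kind) && x$kind != "closed_loop") {
    cat(sprintf("Open-loop Fontan circulation %s", x$kind))
    cat(sprintf(" (%d 1-D domains)\n", length(x$meshes)))
    return(invisible(x))
  }
  cat("Closed-loop 1-D/0-D Fontan circulation model\n")
  cat(sprintf("  1-D domains: %d (%s)\n", length(x$meshes),
              paste(names(x$meshes), collapse = ", ")))
  cat(sprintf("  junctions at nodes: %s\n",
              paste(vapply(x$junctions, function(j) j$node, 0L),
                    collapse = ", ")))
  cat(sprintf("  T = %.3f s, V_blood = %.2f ml\n", x$T,
              x$settings$V_blood))
  cat(sprintf("  scenario: %s%s\n", x$scenario$kind,
              if (!is.null(x$fen)) " (fenestration active)" else ""))
  invisible(x)
}

#' Initialize the circulation model state
#'
#' Zero velocity everywhere; vessels start at their reference area (i.e. at
#' their regional diastolic pressure), compartment nodes at the configured
#' uniform initial pressure, the ventricle at the measured end-diastolic
#' volume and the atrium at the volume matching the initial pressure.  The
#' remaining blood volume (total minus everything allocated so far) is
#' stored in the venous compartments in proportion to their compliance, so
#' the model's total stored volume equals `V_blood` exactly; the closed-loop
#' dynamics then conserve it.
#'
#' @param model a `circulation_model` from [build_closed_loop()]
#' @param V_V_init initial ventricular volume (ml); default the patient's
#'   end-diastolic volume
#' @return the model, initialized in place
#' @export
initialize_circulation <- function(model, V_V_init = 74.4) {
  s <- model$settings

  E_A0 <- evaluate_elastance(0, model$heart$atrium, model$T)
  V_A_init <- model$heart$atrium$V0 + s$P_init / E_A0
  model$hstate <- heart_state(V_A = V_A_init, V_V = V_V_init, t = 0)

  model$cu <- c(Pa = s$P_init, Pv = s$P_init)
  model$cl <- c(Pa = s$P_init, Pv = s$P_init)

  # Volume allocation: aortic vessels at A0, arterial compartment nodes at
  # the initial pressure, chambers as above; the remaining blood volume is
  # stored on the venous side -- in the venous compliances (proportional to
  # compliance) and, self-consistently, in the cavopulmonary vessels, which
  # sit at the venous pressure because the venous resistances are near
  # zero.  The common venous pressure is found so the total equals V_blood
  # exactly.
  aortic <- names(model$meshes) %in% .aorta_names
  Cv_tot <- model$comp_upper$Cv + model$comp_lower$Cv
  fixed_V <- V_A_init + V_V_init +
    (model$comp_upper$Ca + model$comp_lower$Ca) * s$P_init +
    sum(vapply(names(model$meshes)[aortic], function(nm)
      vessel_volume(vessel_state_uniform(model$meshes[[nm]]),
                    model$meshes[[nm]]), 0))
  tcpc_V <- function(P) sum(vapply(names(model$meshes)[!aortic], function(nm)
    vessel_volume(vessel_state_uniform(model$meshes[[nm]], P),
                  model$meshes[[nm]]), 0))
  vol_err <- function(P) fixed_V + Cv_tot * P + tcpc_V(P) - s$V_blood
  if (vol_err(0.5) > 0)
    stop(sprintf(paste0("configuration error: V_blood = %.1f ml is smaller ",
                        "than the minimum volume the model can hold"),
                 s$V_blood))
  P_ven <- stats::uniroot(vol_err, c(0.5, 200), tol = 1e-12)$root
  model$cu[2L] <- P_ven
  model$cl[2L] <- P_ven

  model$states <- lapply(names(model$meshes), function(nm)
    vessel_state_uniform(model$meshes[[nm]],
                         if (nm %in% .aorta_names) model$meshes[[nm]]$P0
                         else P_ven))
  names(model$states) <- names(model$meshes)

  # cached boundary-face states (A, U, P) per vessel end
  model$faces <- lapply(names(model$meshes), function(nm) {
    mesh <- model$meshes[[nm]]
    P <- if (nm %in% .aorta_names) mesh$P0 else P_ven
    sL <- sqrt(mesh$A0_face[1L]) +
      (P - mesh$P0) * mesh$A0_face[1L] / mesh$beta_face[1L]
    sR <- sqrt(mesh$A0_face[mesh$N + 1L]) +
      (P - mesh$P0) * mesh$A0_face[mesh$N + 1L] / mesh$beta_face[mesh$N + 1L]
    list("in" = list(A = sL^2, U = 0, P = P),
         "out" = list(A = sR^2, U = 0, P = P))
  })
  names(model$faces) <- names(model$meshes)

  model$t <- 0
  model$cycle <- 0L
  model$Q_fen <- 0
  model$jA <- vector("list", length(model$junctions))
  # precomputed boundary-face constants for the stepper
  model$jc <- lapply(model$junctions, function(jn) {
    con <- lapply(jn$ends, function(e)
      .face_const(model$meshes[[e$vessel]], e$side))
    list(s = vapply(con, `[[`, 0, "s"),
         kc = vapply(con, `[[`, 0, "kc"),
         bA0 = vapply(con, `[[`, 0, "bA0"),
         r0 = vapply(con, `[[`, 0, "r0"),
         P0 = vapply(con, `[[`, 0, "P0"),
         rho = con[[1L]]$rho,
         i = vapply(con, `[[`, 0L, "i"))
  })
  model$tc <- list()
  for (key in c("AAo:in", "BCA:out", "LCCA:out", "DAo:out", "SVC:out",
                "IVC:in", "RPA:out", "LPA_ii:out")) {
    parts <- strsplit(key, ":", fixed = TRUE)[[1L]]
    model$tc[[key]] <- .face_const(model$meshes[[parts[1L]]], parts[2L])
  }
  model$initialized <- TRUE
  invisible(model)
}

#' Total stored blood volume of the model state
#'
#' Chambers + 1-D vessel content + compartment stored volume (C times node
#' pressure, plus the allocation constant fixed at initialization).
#'
#' @param model an initialized `circulation_model`
#' @return volume (ml)
#' @export
total_blood_volume <- function(model) {
  vessel_V <- sum(vapply(names(model$meshes), function(nm)
    vessel_volume(model$states[[nm]], model$meshes[[nm]]), 0))
  comp_V <- model$comp_upper$Ca * model$cu[1L] + model$comp_upper$Cv * model$cu[2L] +
    model$comp_lower$Ca * model$cl[1L] + model$comp_lower$Cv * model$cl[2L]
  unname(model$hstate[1L] + model$hstate[2L] + vessel_V + comp_V)
}

#' Apply pulmonary vasodilation to a model
#'
#' Scales both pulmonary branch resistances by `(1 - fraction)`; nothing
#' else changes.
#'
#' @param model a `circulation_model`
#' @param fraction resistance reduction in \[0, 1); default 0.25
#' @return the model, modified in place
#' @export
apply_vasodilation <- function(model, fraction = 0.25) {
  if (!is.numeric(fraction) || fraction < 0 || fraction >= 1)
    stop("configuration error: vasodilation fraction must lie in [0, 1)")
  model$lungs <- lung_params(model$lungs$R_RPA * (1 - fraction),
                             model$lungs$R_LPA * (1 - fraction))
  invisible(model)
}

#' Open an atrial fenestration
#'
#' Adds a shunt from the axial midpoint of the inferior vena cava to the
#' atrium: a short tube of the given dimensions with Ohmic resistance `R`.
#' The IVC is split into two equal sub-segments joined at a junction whose
#' mass balance includes the shunt flow.  By default the shunt is a pure
#' resistor; `inertance = TRUE` adds the tube inertance rho l / A.
#'
#' @param model a `circulation_model` (not yet initialized)
#' @param R shunt resistance (mmHg s/ml)
#' @param length_cm,diameter_mm tube dimensions (used for the inertance)
#' @param inertance logical; include the tube inertance term
#' @return the model, modified in place
#' @export
apply_fenestration <- function(model, R = 0.5, length_cm = 3,
                               diameter_mm = 4, inertance = FALSE) {
  if (model$initialized)
    stop("apply the fenestration before initializing the model")
  ivc <- model$meshes$IVC
  if (is.null(ivc)) stop("model has no IVC vessel to fenestrate")

  # split the IVC at its midpoint into two sub-segments sharing a new node
  new_node <- max(vapply(model$meshes, function(m)
    max(m$node_in, m$node_out), 0)) + 1L
  row <- NULL
  for (r in model$config$vessels) if (r$name == "IVC") row <- r
  D_mid <- (row$D_in + row$D_out) / 2
  rho <- model$rho
  seg_lo <- vessel_segment("IVC", row$L / 2, row$D_in, D_mid, row$PWV,
                           ivc$P0, row$node_in, new_node)
  seg_hi <- vessel_segment("IVC_up", row$L / 2, D_mid, row$D_out, row$PWV,
                           ivc$P0, new_node, row$node_out)
  h <- model$settings$element_size
  meshes <- model$meshes
  meshes$IVC <- build_vessel_mesh(seg_lo, h, rho)
  meshes$IVC_up <- build_vessel_mesh(seg_hi, h, rho)
  model$meshes <- meshes

  # rewire: IVC_up now owns the old IVC:out junction membership
  for (j in seq_along(model$junctions)) {
    for (e in seq_along(model$junctions[[j]]$ends)) {
      end <- model$junctions[[j]]$ends[[e]]
      if (end$vessel == "IVC" && end$side == "out")
        model$junctions[[j]]$ends[[e]]$vessel <- "IVC_up"
    }
  }
  A_fen <- pi * (diameter_mm / 10 / 2)^2
  model$junctions[[length(model$junctions) + 1L]] <- list(
    node = new_node,
    ends = list(list(vessel = "IVC", side = "out"),
                list(vessel = "IVC_up", side = "in")),
    sink = list(R = R, L_in = if (inertance) rho * length_cm / A_fen else 0))
  model$scenario$kind <- "fenestration"
  invisible(model)
}
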