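# Model compilation and integration: morphology x parameter set -> a
# segment-level compiled model handed to the C++ Crank-Nicolson tree solver.

#' Compile a morphology and parameter set into a simulatable model
#'
#' Evaluates every channel's somatodendritic density rule at each segment
#' centre, computes segment membrane areas (tapered frusta) and axial
#' coupling conductances, and packs everything for the integrator. Somatic
#' segments receive the somatic densities; dendritic segments receive
#' `density_at(rule, g_soma, x)` with x the path distance of the segment
#' centre from the soma.
#'
#' @param morph a discretized [generate_surrogate()] / [read_swc()] morphology
#' @param params a [parameter_set()]
#' @param channels character vector of enabled mechanisms, subset of
#'   `c("na","kdr","cat","cal","h","ahp","can","pas")`; defaults to all.
#'   Disabling `"pas"` removes the leak (used by the Ih-only clamp model).
#' @return object of class `compiled_model`
#' @export
compile_model <- function(morph, params,
                          channels = c("na", "kdr", "cat", "cal", "h",
                                       "ahp", "can", "pas")) {
  validate_morphology(morph)
  validate_parameter_set(params)
  s <- morph$sections
  ns <- nrow(s)
  seg_parent <- integer(0); seg_area <- numeric(0); seg_x <- numeric(0)
  seg_rhalf <- numeric(0); seg_section <- integer(0)
  last_seg_of_section <- integer(ns)
  idx <- 0L
  for (i in seq_len(ns)) {
    k <- s$nseg[i]
    dp <- s$diam_prox[i]; dd <- s$diam_dist[i]
    Lseg <- s$length[i] / k
    x0 <- if (s$kind[i] == "soma") 0 else path_distance(morph, s$id[i], 0)
    parent_sec <- s$parent_id[i]
    for (j in seq_len(k)) {
      idx <- idx + 1L
      f0 <- (j - 1) / k; f1 <- j / k; fc <- (j - 0.5) / k
      d0 <- dp + (dd - dp) * f0
      d1 <- dp + (dd - dp) * f1
      dc <- dp + (dd - dp) * fc
      seg_area[idx] <- section_lateral_area(Lseg, d0, d1) * 1e-8  # cm^2
      seg_x[idx] <- if (s$kind[i] == "soma") 0 else x0 + fc * s$length[i]
      # half-segment axial resistance, Ohm (lengths um -> cm)
      seg_rhalf[idx] <- params$R_a * (Lseg * 1e-4 / 2) /
        (pi * (dc * 1e-4 / 2)^2)
      seg_section[idx] <- i
      seg_parent[idx] <- if (j > 1L) idx - 1L
        else if (is.na(parent_sec)) 0L             # root
        else last_seg_of_section[match(parent_sec, s$id)]
    }
    last_seg_of_section[i] <- idx
  }
  nseg <- idx
  ax_g <- numeric(nseg)
  for (i in seq_len(nseg)) {
    p <- seg_parent[i]
    if (p > 0L) ax_g[i] <- 1 / (seg_rhalf[i] + seg_rhalf[p])
  }
  is_soma <- s$kind[seg_section] == "soma"
  dens <- function(tag, gname) {
    if (!(tag %in% channels)) return(rep(0, nseg))
    g <- params[[gname]]
    out <- numeric(nseg)
    out[is_soma] <- g
    out[!is_soma] <- density_at(params$rules[[tag]], g, seg_x[!is_soma])
    out
  }
  g_pas <- if ("pas" %in% channels)
    rep(1e-3 / params$R_m, nseg) else rep(0, nseg)   # S/cm^2 (R_m kOhm cm^2)

  cpp <- list(parent = as.integer(seg_parent - 1L),
              area = seg_area, ax_g = ax_g,
              g_na = dens("na", "g_Na"), g_kdr = dens("kdr", "g_Kdr"),
              p_cat = ghk_permeability(dens("cat", "g_CaT"),
                                       ca_o = params$Ca_o,
                                       temp = params$temperature + 273.15),
              p_cal = ghk_permeability(dens("cal", "g_CaL"),
                                       ca_o = params$Ca_o,
                                       temp = params$temperature + 273.15),
              g_h = dens("h", "g_h"), g_ahp = dens("ahp", "g_AHP"),
              g_can = dens("can", "g_CAN"), g_pas = g_pas,
              e_pas = params$E_pas, c_m = params$C_m,
              e_na = params$E_Na, e_k = params$E_K,
              e_h = params$ih$e_rev, e_can = params$E_CAN,
              v_traub = params$v_traub,
              sh_na = params$Sh_Na, sh_kdr = params$Sh_Kdr,
              ih = unclass(params$ih), ca_o = params$Ca_o,
              temp_k = params$temperature + 273.15,
              calcium = unclass(params$calcium),
              ahp_ca_half = params$ahp_ca_half, ahp_tau = params$ahp_tau,
              ahp_gate_exp = params$ahp_gate_exp %||% 2,
              ahp_hill = params$ahp_hill %||% 2,
              can_ca_half = params$can_ca_half, can_tau = params$can_tau,
              cat_v50m = params$cat_v50m, cat_km = params$cat_km,
              cat_v50h = params$cat_v50h, cat_kh = params$cat_kh,
              v_init = params$V_rest)
  model <- list(morph_name = morph$name, params = params, cpp = cpp,
                n_seg = nseg, seg_x = seg_x, seg_section = seg_section,
                is_soma = is_soma, channels = channels,
                cache = new.env(parent = emptyenv()))
  class(model) <- "compiled_model"
  model
}

#' @export
print.compiled_model <- function(x, ...) {
  cat("Compiled interneuron model:", x$params$name, "on", x$morph_name, "\n")
  cat(sprintf("  %d segments, total area %.1f um^2, mechanisms: %s\n",
              x$n_seg, sum(x$cpp$area) * 1e8,
              paste(x$channels, collapse = " ")))
  invisible(x)
}

#' Low-level integration of a compiled model
#'
#' Advances the model with the Crank-Nicolson branched-cable scheme
#' (staggered exact-exponential gating updates, linear-time tree solve).
#' Most users should call the protocol runners instead.
#'
#' @param model a [compile_model()] result
#' @param stim stimulus list with optional elements `steps`
#'   (data.frame seg/amp/on/off; seg 1-based, amp nA, times ms), `vclamp`
#'   (seg, t, v) and `syn` (see [run_synaptic_barrage()])
#' @param t_stop duration, ms
#' @param dt time step, ms (<= 0.05)
#' @param init state list from a previous run's `final` element; if NULL the
#'   model starts at `V_rest` with gates at steady state
#' @param record segment indices (1-based) to record; default soma
#' @param stride record every `stride`-th step
#' @return list with `t`, `v`, `ca`, `iclamp`, `final`
#' @export
integrate_model <- function(model, stim = list(), t_stop, dt = 0.025,
                            init = NULL, record = 1L, stride = 1L) {
  stopifnot(inherits(model, "compiled_model"), dt > 0, dt <= 0.05)
  cstim <- list()
  if (!is.null(stim$steps)) {
    st <- stim$steps
    cstim$steps <- list(seg = as.integer(st$seg) - 1L, amp = st$amp,
                        on = st$on, off = st$off)
  }
  if (!is.null(stim$vclamp)) {
    vc <- stim$vclamp
    cstim$vclamp <- list(seg = as.integer(vc$seg) - 1L, t = vc$t, v = vc$v)
  }
  if (!is.null(stim$syn)) {
    sy <- stim$syn
    cstim$syn <- list(seg = as.integer(sy$seg) - 1L, gmax = sy$gmax,
                      e_rev = sy$e_rev, tau_rise = sy$tau_rise,
                      tau_decay = sy$tau_decay, ev_t = sy$ev_t,
                      ev_syn = as.integer(sy$ev_syn) - 1L)
  }
  cpp_integrate(model$cpp, cstim, dt, t_stop,
                if (is.null(init)) list() else init,
                as.integer(record) - 1L, as.integer(stride))
}

# Memoized resting state of a model: long relaxation with no input.
rest_state <- function(model, dt = 0.025, t_relax = 2000) {
  key <- sprintf("rest_%g", dt)
  if (!is.null(model$cache[[key]])) return(model$cache[[key]])
  out <- integrate_model(model, t_stop = t_relax, dt = dt,
                         stride = max(1L, as.integer(50 / dt)))
  nt <- length(out$t)
  drift <- abs(out$v[nt, 1] - out$v[nt - 1, 1]) /
    (out$t[nt] - out$t[nt - 1])
  if (drift > 2e-4)
    warning(sprintf("resting state still drifting at %.2g mV/ms", drift))
  st <- list(state = out$final, v_rest = out$v[nt, 1], drift = drift)
  model$cache[[key]] <- st
  st
}

#' Resting potential of the compiled model
#'
#' Locates the somatic steady state by a long (2 s) relaxation with all
#' mechanisms active and no stimulus.
#'
#' @param model a [compile_model()] result
#' @param dt time step, ms
#' @return somatic resting potential, mV
#' @export
find_rest <- function(model, dt = 0.025) {
  st <- rest_state(model, dt = dt)
  if (st$drift > 1e-3)
    stop(sprintf("resting state did not converge (drift %.3g mV/ms)",
                 st$drift))
  st$v_rest
}

#' Calibrate the leak reversal potential
#'
#' The leak reversal E_pas differs from the resting potential because
#' several active conductances (Ih, Ca_T, I_CAN) are open around rest.
#' This adjusts E_pas by a secant iteration until the somatic resting
#' potential of the full model equals `target` within `tol`.
#'
#' @param model a [compile_model()] result
#' @param target desired resting potential, mV (defaults to the parameter
#'   set's V_rest)
#' @param tol tolerance, mV
#' @param max_iter iteration cap
#' @return the model, with calibrated `E_pas` in place (and in
#'   `model$params$E_pas`)
#' @export
calibrate_epas <- function(model, target = model$params$V_rest, tol = 0.05,
                           max_iter = 12L) {
  eval_rest <- function(epas) {
    model$cpp$e_pas <- epas
    model$cache <- new.env(parent = emptyenv())
    rest_state(model)$v_rest
  }
  e0 <- model$cpp$e_pas
  v0 <- eval_rest(e0)
  if (abs(v0 - target) < tol) return(model)
  e1 <- e0 + (target - v0)        # unit-slope first guess
  v1 <- eval_rest(e1)
  for (it in seq_len(max_iter)) {
    if (abs(v1 - target) < tol) break
    slope <- (v1 - v0) / (e1 - e0)
    e2 <- e1 + (target - v1) / slope
    e0 <- e1; v0 <- v1
    e1 <- e2; v1 <- eval_rest(e2)
  }
  if (abs(v1 - target) >= tol)
    stop(sprintf("E_pas calibration did not converge: rest %.3f mV vs target %.3f mV",
                 v1, target))
  model$cpp$e_pas <- e1
  model$params$E_pas <- e1
  model$params$E_pas_provenance <- "calibrated"
  model$cache <- new.env(parent = emptyenv())
  model
}

#' Somatic input resistance
#'
#' Injects a small, long current step at the soma from rest and reports the
#' steady-state voltage deflection divided by the current.
#'
#' @param model a [compile_model()] result
#' @param probe_pA probe amplitude, pA (small and hyperpolarizing by default)
#' @param t_step step duration, ms (long enough to reach steady state)
#' @param dt time step, ms
#' @return input resistance, MOhm
#' @export
input_resistance <- function(model, probe_pA = -10, t_step = 1500,
                             dt = 0.025) {
  rs <- rest_state(model, dt = dt)
  stim <- list(steps = data.frame(seg = 1L, amp = probe_pA * 1e-3,
                                  on = 0, off = t_step))
  out <- integrate_model(model, stim, t_stop = t_step, dt = dt,
                         init = rs$state, stride = max(1L, as.integer(20 / dt)))
  nt <- length(out$t)
  dv <- out$v[nt, 1] - rs$v_rest
  dv / (probe_pA * 1e-3)   # mV / nA = MOhm
}

# ---------------------------------------------------------------------------
# Simulation result container

new_in_sim <- function(t, v, ca = NULL, iclamp = NULL, dt, protocol = NULL,
                       rec_names = "soma", stim_window = NULL, seed = NULL) {
  colnames(v) <- rec_names
  r <- list(t = t, v = v, ca = ca, iclamp = iclamp, dt = dt,
            protocol = protocol, stim_window = stim_window, seed = seed)
  class(r) <- "in_sim"
  r
}

#' @export
print.in_sim <- function(x, ...) {
  cat("Simulation result:", length(x$t), "samples over",
      sprintf("%.1f ms (dt = %g ms)", max(x$t), x$dt), "\n")
  if (!is.null(x$protocol))
    cat("  protocol:", format_protocol(x$protocol), "\n")
  cat(sprintf("  somatic V range [%.1f, %.1f] mV\n",
              min(x$v[, 1]), max(x$v[, 1])))
  invisible(x)
}

#' @export
as.data.frame.in_sim <- function(x, ...) {
  df <- data.frame(t = x$t)
  for (j in seq_len(ncol(x$v))) df[[paste0("v_", colnames(x$v)[j])]] <- x$v[, j]
  if (!is.null(x$ca))
    for (j in seq_len(ncol(x$ca))) df[[paste0("ca_", colnames(x$v)[j])]] <- x$ca[, j]
  df
}

#' @export
plot.in_sim <- function(x, which = 1L, ...) {
  graphics::plot(x$t, x$v[, which], type = "l", xlab = "time (ms)",
                 ylab = "membrane potential (mV)", ...)
  if (!is.null(x$stim_window))
    graphics::abline(v = x$stim_window, lty = 3, col = "grey50")
  invisible(x)
}

#' Write a simulation result to CSV (+ JSON metadata sidecar)
#'
#' @param x an `in_sim`
#' @param path CSV output path; metadata goes to `<path>.json`
#' @return `path` invisibly
#' @export
write_sim_result <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  meta <- list(dt = x$dt, protocol = x$protocol, seed = x$seed,
               stim_window = x$stim_window)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

format_protocol <- function(p) {
  if (is.null(p)) return("none")
  paste0(p$kind, if (!is.null(p$amplitude_pA))
    sprintf(" %g pA", p$amplitude_pA[1]) else "",
    if (!is.null(p$holding_mV)) sprintf(" from %g mV", p$holding_mV) else "")
}
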