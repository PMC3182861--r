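# Stimulation/recording protocols: somatic current steps (with optional
# holding potential), ideal somatic voltage-clamp series, and the GABAergic
# synaptic barrage. All runners settle the model at rest (or at the holding
# potential) before the recorded window.

#' GABA-A synaptic barrage specification
#'
#' A population of inhibitory synapses distributed at random (seeded) over
#' the dendritic segments. Each synapse produces a difference-of-exponentials
#' conductance normalized to peak `gmax_nS`. In the default synchronous mode
#' all synapses are activated together every `interval_ms` over
#' `duration_ms`; in the staggered mode each synapse keeps the same rhythm
#' but with a random phase within the interval.
#'
#' @param n_synapses number of synapses
#' @param gmax_nS peak conductance per synapse, nS
#' @param e_rev reversal potential, mV
#' @param tau_rise,tau_decay conductance time constants, ms
#' @param interval_ms inter-activation interval, ms
#' @param duration_ms barrage duration, ms
#' @param seed placement (and phase) seed
#' @param mode `"synchronous"` or `"staggered"`
#' @return list of class `synapse_spec`
#' @export
synapse_spec <- function(n_synapses = 50, gmax_nS = 1, e_rev = -82,
                         tau_rise = 0.5, tau_decay = 5, interval_ms = 10,
                         duration_ms = 300, seed = 7L,
                         mode = c("synchronous", "staggered")) {
  stopifnot(tau_rise < tau_decay, gmax_nS >= 0, interval_ms > 0,
            duration_ms > 0)
  s <- list(n_synapses = as.integer(n_synapses), gmax_nS = gmax_nS,
            e_rev = e_rev, tau_rise = tau_rise, tau_decay = tau_decay,
            interval_ms = interval_ms, duration_ms = duration_ms,
            seed = as.integer(seed), mode = match.arg(mode))
  class(s) <- "synapse_spec"
  s
}

#' Constant current required to hold the soma at a target potential
#'
#' Secant iteration on the steady-state somatic potential under a constant
#' somatic current injection.
#'
#' @param model a [compile_model()] result
#' @param target_mV target potential, within +/- 15 mV of rest
#' @param tol tolerance on the steady-state potential, mV
#' @param dt time step, ms
#' @return holding current, pA
#' @export
find_holding_current <- function(model, target_mV, tol = 0.1, dt = 0.025) {
  rs <- rest_state(model, dt = dt)
  if (abs(target_mV - rs$v_rest) > 15)
    stop("holding target more than 15 mV from rest", call. = FALSE)
  eval_v <- function(i_nA) {
    out <- integrate_model(model,
      list(steps = data.frame(seg = 1L, amp = i_nA, on = 0, off = 1e9)),
      t_stop = 1200, dt = dt, init = rs$state,
      stride = max(1L, as.integer(20 / dt)))
    v <- out$v[, 1]
    if (max(v[out$t > 300]) > -20)
      stop("holding target unreachable without spiking", call. = FALSE)
    v[length(v)]
  }
  if (abs(target_mV - rs$v_rest) < tol) return(0)
  r_est <- model$params$R_m * 1e3 / sum(model$cpp$area) / 1e6  # MOhm, lumped
  i0 <- 0; v0 <- rs$v_rest
  i1 <- (target_mV - rs$v_rest) / r_est                        # nA
  v1 <- eval_v(i1)
  for (it in 1:8) {
    if (abs(v1 - target_mV) < tol) break
    sl <- (v1 - v0) / (i1 - i0)
    i2 <- i1 + (target_mV - v1) / sl
    i0 <- i1; v0 <- v1
    i1 <- i2; v1 <- eval_v(i2)
  }
  if (abs(v1 - target_mV) >= tol)
    stop(sprintf("holding-current search did not converge (V = %.2f mV)", v1),
         call. = FALSE)
  i1 * 1e3   # pA
}

# Settled state at a holding current (memoized per model+current).
held_state <- function(model, i_hold_pA, dt = 0.025, t_settle = 1000) {
  rs <- rest_state(model, dt = dt)
  if (abs(i_hold_pA) < 1e-12) return(rs$state)
  key <- sprintf("held_%.6g_%g", i_hold_pA, dt)
  if (!is.null(model$cache[[key]])) return(model$cache[[key]])
  out <- integrate_model(model,
    list(steps = data.frame(seg = 1L, amp = i_hold_pA * 1e-3, on = 0,
                            off = 1e9)),
    t_stop = t_settle, dt = dt, init = rs$state,
    stride = max(1L, as.integer(20 / dt)))
  model$cache[[key]] <- out$final
  out$final
}

#' Run a somatic current-step protocol
#'
#' A 900 ms (by default) somatic current step, optionally from a steady
#' holding potential maintained by a constant compensatory current, with a
#' post-stimulus window long enough to capture rebound responses.
#'
#' @param model a [compile_model()] result
#' @param amplitude_pA step amplitude, pA (in [-300, 300])
#' @param holding_mV optional holding potential; a holding current is
#'   determined with [find_holding_current()] and applied throughout
#' @param duration step duration, ms
#' @param pre pre-stimulus recorded baseline, ms
#' @param post post-stimulus window, ms (>= 300 recommended for rebounds)
#' @param dt time step, ms
#' @param record segment indices to record (1 = soma)
#' @return an `in_sim` with `stim_window = c(pre, pre + duration)`
#' @export
run_current_step <- function(model, amplitude_pA, holding_mV = NULL,
                             duration = 900, pre = 100, post = 300,
                             dt = 0.025, record = 1L) {
  stopifnot(abs(amplitude_pA) <= 300)
  i_hold <- if (is.null(holding_mV)) 0 else
    find_holding_current(model, holding_mV, dt = dt)
  st <- held_state(model, i_hold, dt = dt)
  t_stop <- pre + duration + post
  steps <- data.frame(seg = 1L, amp = amplitude_pA * 1e-3,
                      on = pre, off = pre + duration)
  if (i_hold != 0)
    steps <- rbind(steps, data.frame(seg = 1L, amp = i_hold * 1e-3,
                                     on = 0, off = 1e9))
  out <- integrate_model(model, list(steps = steps), t_stop = t_stop,
                         dt = dt, init = st, record = record)
  new_in_sim(out$t, out$v, ca = out$ca, dt = dt,
             protocol = list(kind = "current_step",
                             amplitude_pA = amplitude_pA,
                             holding_mV = holding_mV,
                             holding_pA = i_hold, duration = duration),
             rec_names = ifelse(record == 1L, "soma",
                                paste0("seg", record)),
             stim_window = c(pre, pre + duration))
}

#' Run an ideal somatic voltage-clamp series
#'
#' Clamps the soma (infinite-gain, no series resistance) at a holding
#' potential, then steps to each command potential for `t_step` ms,
#' recording the clamp current. Used with an Ih-only model this reproduces
#' the current families of the Ih characterization experiments.
#'
#' @param model a [compile_model()] result (typically built with
#'   `channels = "h"`; see [ih_clamp_model()])
#' @param commands command potentials, mV
#' @param holding holding potential between steps, mV
#' @param t_step step duration, ms
#' @param pre settling time at holding before each step, ms
#' @param dt time step, ms
#' @return object of class `vclamp_series`: list with `t` (ms, 0 at step
#'   onset), `i` (nA, one column per command), `commands`, `holding`
#' @export
run_voltage_clamp_series <- function(model, commands = seq(-130, -65, by = 5),
                                     holding = -40, t_step = 1000, pre = 300,
                                     dt = 0.025) {
  imat <- NULL
  tt <- NULL
  for (cmd in commands) {
    stim <- list(vclamp = list(seg = 1L, t = c(0, pre), v = c(holding, cmd)))
    out <- integrate_model(model, stim, t_stop = pre + t_step, dt = dt)
    sel <- out$t >= pre
    if (is.null(tt)) tt <- out$t[sel] - pre
    imat <- cbind(imat, out$iclamp[sel])
  }
  colnames(imat) <- sprintf("%g", commands)
  r <- list(t = tt, i = imat, commands = commands, holding = holding,
            dt = dt)
  class(r) <- "vclamp_series"
  r
}

#' @export
print.vclamp_series <- function(x, ...) {
  cat("Voltage-clamp series:", length(x$commands), "commands",
      sprintf("(%g..%g mV) from holding %g mV\n", min(x$commands),
              max(x$commands), x$holding))
  invisible(x)
}

#' @export
plot.vclamp_series <- function(x, ...) {
  graphics::matplot(x$t, x$i * 1e3, type = "l", lty = 1,
                    xlab = "time from step onset (ms)",
                    ylab = "clamp current (pA)", ...)
  invisible(x)
}

#' Single-compartment Ih-only clamp model
#'
#' A soma-only model containing just the Ih mechanism (no leak), used by the
#' Ih activation/time-constant fitting pipeline.
#'
#' @param params a [parameter_set()] providing g_h and the Ih kinetics
#' @param area_um2 membrane area, um^2
#' @return a `compiled_model`
#' @export
ih_clamp_model <- function(params = parameter_set("P1"), area_um2 = 10000) {
  d <- sqrt(area_um2 / pi)   # cylinder with L = D
  secs <- data.frame(id = 1L, parent_id = NA_integer_, kind = "soma",
                     length = d, diam_prox = d, diam_dist = d, nseg = 1L,
                     stringsAsFactors = FALSE)
  m <- new_morphology(secs, name = sprintf("clamp-soma-%g", area_um2))
  compile_model(m, params, channels = "h")
}

#' Run a GABAergic synaptic barrage
#'
#' Places `spec$n_synapses` inhibitory synapses at seeded-random dendritic
#' segments and activates them rhythmically for the barrage duration,
#' recording through a post-barrage window to capture rebound responses.
#'
#' @param model a [compile_model()] result
#' @param spec a [synapse_spec()]
#' @param holding_mV optional holding potential before/throughout
#' @param pre pre-barrage baseline, ms
#' @param post post-barrage window, ms
#' @param dt time step, ms
#' @return an `in_sim` with `stim_window = c(pre, pre + duration)`
#' @export
run_synaptic_barrage <- function(model, spec = synapse_spec(),
                                 holding_mV = NULL, pre = 100, post = 400,
                                 dt = 0.025) {
  i_hold <- if (is.null(holding_mV)) 0 else
    find_holding_current(model, holding_mV, dt = dt)
  st <- held_state(model, i_hold, dt = dt)
  dend <- which(!model$is_soma)
  rng <- local_rng(spec$seed)
  segs <- if (length(dend))
    dend[floor(rng(spec$n_synapses) * length(dend)) + 1L] else
    rep(1L, spec$n_synapses)
  times0 <- seq(0, spec$duration_ms - spec$interval_ms,
                by = spec$interval_ms)
  if (spec$mode == "synchronous") {
    ev_t <- rep(pre + times0, each = spec$n_synapses)
    ev_syn <- rep(seq_len(spec$n_synapses), times = length(times0))
  } else {
    phase <- rng(spec$n_synapses) * spec$interval_ms
    ev_t <- as.vector(outer(seq_len(spec$n_synapses), times0,
                            function(s, t0) pre + t0 + phase[s]))
    ev_syn <- rep(seq_len(spec$n_synapses), times = length(times0))
  }
  ord <- order(ev_t)
  stim <- list(syn = list(seg = segs, gmax = spec$gmax_nS * 1e-3,
                          e_rev = spec$e_rev, tau_rise = spec$tau_rise,
                          tau_decay = spec$tau_decay,
                          ev_t = ev_t[ord], ev_syn = ev_syn[ord]))
  if (i_hold != 0)
    stim$steps <- data.frame(seg = 1L, amp = i_hold * 1e-3, on = 0, off = 1e9)
  t_stop <- pre + spec$duration_ms + post
  out <- integrate_model(model, stim, t_stop = t_stop, dt = dt, init = st)
  new_in_sim(out$t, out$v, ca = out$ca, dt = dt,
             protocol = list(kind = "synaptic_barrage",
                             holding_mV = holding_mV, holding_pA = i_hold,
                             n_synapses = spec$n_synapses,
                             seed = spec$seed, mode = spec$mode),
             stim_window = c(pre, pre + spec$duration_ms),
             seed = spec$seed)
}
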