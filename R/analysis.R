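# Feature extraction and fitting: spikes, AP width, I/O curves, sag,
# burst/rebound classification, and the Ih activation / time-constant
# fitting pipeline.

#' Detect action potentials by threshold crossing
#'
#' Upward crossings of `threshold` (default 0 mV, which all simulated APs
#' overshoot), with a refractory guard so each AP is counted once.
#'
#' @param x an `in_sim` or a numeric voltage vector
#' @param t time grid, ms (taken from `x` when it is an `in_sim`)
#' @param threshold detection threshold, mV
#' @param refractory minimal separation between spikes, ms
#' @return object of class `spike_train`: list with `times` (ms), `peaks`
#'   (mV), `n`
#' @export
detect_spikes <- function(x, t = NULL, threshold = 0, refractory = 1) {
  if (inherits(x, "in_sim")) { t <- x$t; v <- x$v[, 1] } else v <- x
  stopifnot(length(t) == length(v))
  up <- which(v[-1] > threshold & v[-length(v)] <= threshold)
  times <- numeric(0); peaks <- numeric(0)
  last <- -Inf
  for (i in up) {
    # linear interpolation of the crossing time
    tc <- t[i] + (threshold - v[i]) / (v[i + 1] - v[i]) * (t[i + 1] - t[i])
    if (tc - last < refractory) next
    j1 <- min(length(v), i + which(v[(i + 1):min(length(v), i + 200)] <
                                     threshold)[1])
    if (is.na(j1)) j1 <- length(v)
    peaks <- c(peaks, max(v[i:j1]))
    times <- c(times, tc)
    last <- tc
  }
  st <- list(times = times, peaks = peaks, n = length(times))
  class(st) <- "spike_train"
  st
}

#' @export
print.spike_train <- function(x, ...) {
  cat("Spike train:", x$n, "spikes")
  if (x$n) cat(sprintf(" (first %.1f ms, last %.1f ms)", x$times[1],
                       x$times[x$n]))
  cat("\n")
  invisible(x)
}

#' Action-potential width at half-maximal amplitude
#'
#' Width of one AP at half of its peak-minus-baseline amplitude, with linear
#' interpolation between samples. The baseline is the spike take-off
#' potential: the voltage where dV/dt first exceeds `dvdt_on` (mV/ms) in the
#' 5 ms before the peak.
#'
#' @param x an `in_sim`
#' @param spike_index which spike (per [detect_spikes()])
#' @param dvdt_on take-off criterion, mV/ms
#' @return half width, ms
#' @export
ap_half_width <- function(x, spike_index = 1L, dvdt_on = 20) {
  st <- detect_spikes(x)
  if (st$n < spike_index) stop("spike ", spike_index, " not found",
                               call. = FALSE)
  t <- x$t; v <- x$v[, 1]
  tc <- st$times[spike_index]
  i0 <- max(1L, which(t >= tc - 5)[1])
  i1 <- which(t >= tc + 5)[1]
  if (is.na(i1)) stop("spike truncated by end of trace", call. = FALSE)
  tt <- t[i0:i1]; vv <- v[i0:i1]
  ip <- which.max(vv)
  dvdt <- c(0, diff(vv) / diff(tt))
  ion <- which(dvdt[seq_len(ip)] > dvdt_on)[1]
  if (is.na(ion)) stop("no spike take-off found", call. = FALSE)
  base <- vv[ion]
  half <- base + (vv[ip] - base) / 2
  iu <- max(which(vv[seq_len(ip)] <= half))        # last sub-half before peak
  t_up <- tt[iu] + (half - vv[iu]) / (vv[iu + 1] - vv[iu]) *
    (tt[iu + 1] - tt[iu])
  after <- vv[ip:length(vv)]
  idn <- ip - 1L + which(after <= half)[1]
  if (is.na(idn)) stop("spike truncated by end of trace", call. = FALSE)
  t_dn <- tt[idn - 1] + (half - vv[idn - 1]) / (vv[idn] - vv[idn - 1]) *
    (tt[idn] - tt[idn - 1])
  t_dn - t_up
}

#' Simulate an I/O curve (spike count vs injected current)
#'
#' Runs a 900 ms somatic current step per amplitude and counts the spikes
#' elicited throughout the stimulus period.
#'
#' @param model a [compile_model()] result
#' @param amplitudes_pA strictly increasing step amplitudes, pA
#' @param holding_mV optional holding potential (compensatory current)
#' @param duration stimulus duration, ms
#' @param dt time step, ms
#' @return object of class `io_curve`: data.frame with `amp` and `n`
#' @export
io_curve <- function(model, amplitudes_pA, holding_mV = NULL,
                     duration = 900, dt = 0.025) {
  stopifnot(length(amplitudes_pA) >= 3, !is.unsorted(amplitudes_pA,
                                                     strictly = TRUE))
  n <- integer(length(amplitudes_pA))
  for (k in seq_along(amplitudes_pA)) {
    sim <- run_current_step(model, amplitudes_pA[k], holding_mV = holding_mV,
                            duration = duration, post = 100, dt = dt)
    st <- detect_spikes(sim)
    n[k] <- sum(st$times >= sim$stim_window[1] &
                  st$times <= sim$stim_window[2])
  }
  out <- data.frame(amp = amplitudes_pA, n = n)
  class(out) <- c("io_curve", "data.frame")
  out
}

#' Slope of an I/O curve over the 2-15 spike range
#'
#' Ordinary least-squares slope of spike count against current amplitude,
#' restricted to the points with between 2 and 15 elicited spikes.
#'
#' @param curve an [io_curve()]
#' @return slope, spikes/pA
#' @export
io_slope <- function(curve) {
  sel <- curve$n >= 2 & curve$n <= 15
  if (sum(sel) < 2)
    stop("fewer than 2 I/O points in the 2-15 spike range", call. = FALSE)
  unname(coef(stats::lm(n ~ amp, data = curve[sel, ]))[2])
}

#' @export
plot.io_curve <- function(x, ...) {
  graphics::plot(x$amp, x$n, type = "b", pch = 16,
                 xlab = "injected current (pA)",
                 ylab = "spikes per stimulus", ...)
  invisible(x)
}

#' Sag ratio of a hyperpolarizing step response
#'
#' `(V_peak - V_plateau) / (V_peak - V_baseline)` where V_peak is the early
#' hyperpolarized extremum during the step, V_plateau the mean over the last
#' 100 ms of the step, and V_baseline the pre-stimulus potential. Zero for a
#' passive response; positive when Ih relaxes the initial hyperpolarization.
#'
#' @param x an `in_sim` from a hyperpolarizing [run_current_step()]
#' @return dimensionless sag ratio
#' @export
sag_ratio <- function(x) {
  w <- x$stim_window
  if (is.null(w)) stop("trace has no stimulus window", call. = FALSE)
  t <- x$t; v <- x$v[, 1]
  base <- mean(v[t >= w[1] - 50 & t < w[1]])
  vin <- v[t >= w[1] & t <= w[2]]
  vpeak <- min(vin)
  if (vpeak >= base - 1)
    stop("no hyperpolarization detected", call. = FALSE)
  vplat <- mean(v[t >= w[2] - 100 & t <= w[2]])
  (vpeak - vplat) / (vpeak - base)
}

#' Count rebound spikes after stimulus offset
#' @param x an `in_sim`
#' @param window ms after stimulus offset to count spikes in
#' @return integer spike count
#' @export
rebound_spikes <- function(x, window = 200) {
  st <- detect_spikes(x)
  off <- x$stim_window[2]
  sum(st$times > off & st$times <= off + window)
}

#' Classify a firing response
#'
#' Rule-based classification of a spike train relative to a stimulus
#' window:
#' \itemize{
#'   \item `silent`: no spikes;
#'   \item `rebound_burst`: >= 2 spikes within `rebound_window` ms after
#'     stimulus offset (with no spiking during the stimulus);
#'   \item `initial_burst_then_tonic`: the leading inter-spike intervals
#'     form a cluster shorter than half the median of the later intervals;
#'   \item `periodic_bursting`: clearly bimodal ISIs (max > 3x min, split
#'     at the midpoint between shortest and longest interval) with at
#'     least two burst-separating gaps recurring through the stimulus and
#'     at least two short-ISI clusters;
#'   \item `tonic`: anything else with spikes during the stimulus.
#' }
#'
#' @param train a [detect_spikes()] result
#' @param stim_window `c(on, off)` of the stimulus, ms
#' @param rebound_window ms after offset within which rebound spikes count
#' @return a classification string
#' @export
classify_response <- function(train, stim_window, rebound_window = 200) {
  times <- train$times
  n_in <- sum(times >= stim_window[1] & times <= stim_window[2])
  n_post <- sum(times > stim_window[2] &
                  times <= stim_window[2] + rebound_window)
  if (n_in == 0) {
    if (n_post >= 2) return("rebound_burst")
    return("silent")
  }
  tin <- times[times >= stim_window[1] & times <= stim_window[2]]
  if (length(tin) < 4) return("tonic")
  isi <- diff(tin)
  # split ISIs at the midpoint between the shortest and longest interval:
  # "short" intervals are intra-burst, "long" ones separate bursts
  thr <- (min(isi) + max(isi)) / 2
  short <- isi < thr
  # periodic bursting: clearly bimodal ISIs with several burst-separating
  # gaps that recur through the stimulus (not just an onset burst)
  gap_pos <- which(!short)
  if (max(isi) > 3 * min(isi) && length(gap_pos) >= 2 &&
      sum(short) >= 2 && max(gap_pos) > length(isi) / 2 &&
      sum(rle(short)$values) >= 2) {  # >= 2 short-ISI clusters
    return("periodic_bursting")
  }
  # initial burst: greedy prefix of ISIs each < 50% of the median of the rest
  k <- 0L
  while (k < length(isi) - 2 && isi[k + 1] <
         0.5 * stats::median(isi[(k + 2):length(isi)])) k <- k + 1L
  if (k >= 1) return("initial_burst_then_tonic")
  "tonic"
}

# ---------------------------------------------------------------------------
# Ih fitting pipeline

#' Least-squares Boltzmann fit of activation ratios
#'
#' Fits `ratio = (1 + exp((V - shift)/stp))^-1` by Nelder-Mead least
#' squares, with data-driven initialization.
#'
#' @param v command potentials, mV
#' @param ratio activation ratios
#' @return list with `shift`, `stp`, `residuals`
#' @export
fit_boltzmann <- function(v, ratio) {
  if (diff(range(ratio)) < 1e-6)
    stop("degenerate activation series: all ratios equal", call. = FALSE)
  # inits: half-crossing by interpolation, slope from the 25-75% span
  o <- order(v)
  vs <- v[o]; rs <- ratio[o]
  shift0 <- tryCatch(stats::approx(rs, vs, xout = 0.5, ties = mean)$y,
                     error = function(e) NA_real_)
  if (is.na(shift0)) shift0 <- stats::median(vs)
  stp0 <- 8
  obj <- function(p) sum((ratio - 1 / (1 + exp((v - p[1]) / p[2])))^2)
  fit <- stats::optim(c(shift0, stp0), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  list(shift = fit$par[1], stp = fit$par[2],
       residuals = ratio - 1 / (1 + exp((v - fit$par[1]) / fit$par[2])))
}

#' Fit the Ih activation curve from a voltage-clamp series
#'
#' Reproduces the experimental activation-fitting procedure: the
#' steady-state current of each command step is normalized by the maximum
#' amplitude over the trial and the resulting ratios are fitted by a
#' Boltzmann curve. With `driving_force_correction` (default) each
#' steady-state current is first divided by its driving force `(V - E_h)`,
#' so the fitted quantity estimates the conductance activation itself.
#'
#' @param series a [run_voltage_clamp_series()] result from an Ih-only model
#' @param e_rev Ih reversal potential used in the correction, mV
#' @param driving_force_correction divide by (V - E_h) before normalizing
#' @return object of class `ih_fit`: `shift`, `stp`, `ratios`, `commands`
#' @export
fit_ih_activation <- function(series, e_rev = -44,
                              driving_force_correction = TRUE) {
  nt <- length(series$t)
  tail_idx <- which(series$t >= max(series$t) * 0.98)
  i_inf <- colMeans(series$i[tail_idx, , drop = FALSE])     # nA
  if (driving_force_correction) {
    g <- i_inf / (series$commands - e_rev)
    ratio <- g / max(g)
  } else {
    ratio <- i_inf / i_inf[which.max(abs(i_inf))]
  }
  fb <- fit_boltzmann(series$commands, ratio)
  out <- list(shift = fb$shift, stp = fb$stp, ratios = ratio,
              commands = series$commands, residuals = fb$residuals)
  class(out) <- "ih_fit"
  out
}

#' @export
print.ih_fit <- function(x, ...) {
  cat(sprintf("Ih Boltzmann fit: shift = %.2f mV, stp = %.2f mV (rms %.2g)\n",
              x$shift, x$stp, sqrt(mean(x$residuals^2))))
  invisible(x)
}

#' Fit Ih activation time constants and their bell-shaped voltage dependence
#'
#' Each command step's current trace (0-1000 ms from onset) is fitted by a
#' single-exponential activation curve `I = (1 - exp(-t/tau)) * I_inf`,
#' giving tau per command potential; the tau values are then fitted across
#' commands by the four-parameter bell curve
#' `tau(V) = exp((V+a1)/a2) / (1 + exp((V+a3)/a4))`.
#'
#' @param series a [run_voltage_clamp_series()] result from an Ih-only model
#' @param fit_window ms from step onset used for the exponential fits
#' @return list with `tau` (per command, ms), `commands`, `a` (a1..a4),
#'   `tau_fun` (fitted curve as a function of mV)
#' @export
fit_ih_tau <- function(series, fit_window = c(0, 1000)) {
  cmds <- series$commands
  sel <- series$t >= fit_window[1] & series$t <= fit_window[2]
  tt <- series$t[sel]
  tau <- rep(NA_real_, length(cmds))
  for (k in seq_along(cmds)) {
    y <- series$i[sel, k]
    # measure relative to the instantaneous current just after the step so
    # that only the time-dependent activation remains
    y <- y - y[2]
    y <- y[-1]
    ttk <- tt[-1] - tt[2]
    if (diff(range(y)) < 1e-9)
      stop("constant current trace at command ", cmds[k], " mV",
           call. = FALSE)
    df <- data.frame(t = ttk, y = y)
    i_inf0 <- y[length(y)]
    tau0 <- ttk[which.min(abs(y - (1 - exp(-1)) * i_inf0))]
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ iinf * (1 - exp(-t / tau)), data = df,
                        start = list(iinf = i_inf0, tau = max(tau0, 1)),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit))
      warning("exponential fit failed at command ", cmds[k], " mV")
    else tau[k] <- coef(fit)[["tau"]]
  }
  ok <- !is.na(tau)
  if (sum(ok) >= 5) {
    a <- fit_tau_bell(cmds[ok], tau[ok])
    list(tau = tau, commands = cmds, a = a,
         tau_fun = function(v) exp((v + a[1]) / a[2]) /
           (1 + exp((v + a[3]) / a[4])))
  } else {
    list(tau = tau, commands = cmds, a = NULL, tau_fun = NULL)
  }
}

# Four-parameter bell-curve fit with data-driven initialization: the
# hyperpolarized limb of log(tau) is linear with slope 1/a2, the peak
# location ties a3 to the maximum.
fit_tau_bell <- function(v, tau) {
  stopifnot(length(v) >= 5)
  lt <- log(tau)
  nlow <- max(3L, floor(length(v) / 3))
  o <- order(v)
  vlow <- v[o][seq_len(nlow)]; ltlow <- lt[o][seq_len(nlow)]
  cf <- coef(stats::lm(ltlow ~ vlow))
  a2 <- 1 / cf[2]
  a1 <- cf[1] * a2
  vpk <- v[which.max(tau)]
  a3 <- -vpk + 8
  a4 <- 6
  obj <- function(p) {
    th <- exp((v + p[1]) / p[2]) / (1 + exp((v + p[3]) / p[4]))
    sum((tau - th)^2)
  }
  fit <- stats::optim(c(a1, a2, a3, a4), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 5000))
  fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 5000))
  unname(fit$par)
}
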