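# Feature extraction on constructed traces with known answers, plus the Ih
# fitting pipeline on synthetic and simulated data.

# synthetic trace: baseline with triangular spikes of given peak/width
make_spike_trace <- function(spike_times, dt = 0.025, t_stop = 500,
                             baseline = -63, peak = 40, half_base = 1) {
  t <- seq(0, t_stop, by = dt)
  v <- rep(baseline, length(t))
  for (ts in spike_times) {
    sel <- abs(t - ts) <= half_base
    v[sel] <- pmax(v[sel], baseline +
                     (peak - baseline) * (1 - abs(t[sel] - ts) / half_base))
  }
  dlgnIN:::new_in_sim(t, matrix(v, ncol = 1), dt = dt,
                      stim_window = c(0, t_stop))
}

test_that("spike detection finds exactly the injected spikes", {
  tr <- make_spike_trace(c(100, 200, 300))
  st <- detect_spikes(tr)
  expect_identical(st$n, 3L)
  expect_equal(st$times, c(100, 200, 300), tolerance = 0.05)
  expect_equal(st$peaks, rep(40, 3), tolerance = 1e-6)
  flat <- make_spike_trace(numeric(0))
  expect_identical(detect_spikes(flat)$n, 0L)
})

test_that("refractory guard merges crossings closer than 1 ms", {
  tr <- make_spike_trace(c(100, 100.6, 200))
  st <- detect_spikes(tr)
  expect_identical(st$n, 2L)
})

test_that("triangular spike has its analytic half width", {
  # peak 40, baseline -63: take-off essentially at the triangle base, so
  # half-max sits at the midpoint of each flank: width = half_base
  tr <- make_spike_trace(150, half_base = 1.2)
  w <- ap_half_width(tr, 1)
  # take-off detection trims the very bottom of the flank; width is within
  # a few percent of the ideal 1.2 ms
  expect_equal(w, 1.2, tolerance = 0.05)
  # refinement invariance: halving dt changes the width < 2%
  tr2 <- make_spike_trace(150, half_base = 1.2, dt = 0.0125)
  expect_equal(ap_half_width(tr2, 1), w, tolerance = 0.02)
})

test_that("response classification follows its ISI rules", {
  w <- c(100, 1000)
  empty <- list(times = numeric(0), n = 0L)
  expect_identical(classify_response(empty, w), "silent")
  tonic <- list(times = seq(150, 950, by = 80), n = 11L)
  expect_identical(classify_response(tonic, w), "tonic")
  ib <- list(times = c(110, 118, 126, 200, 280, 360, 440, 520, 600, 680),
             n = 10L)
  expect_identical(classify_response(ib, w), "initial_burst_then_tonic")
  pb <- list(times = c(110, 118, 126, 250, 258, 266, 390, 398, 406,
                       530, 538, 546, 670, 678, 686), n = 15L)
  expect_identical(classify_response(pb, w), "periodic_bursting")
  reb <- list(times = c(1030, 1045, 1060), n = 3L)
  expect_identical(classify_response(reb, w), "rebound_burst")
  late <- list(times = c(1500), n = 1L)
  expect_identical(classify_response(late, w), "silent")
})

test_that("io_slope uses only the 2-15 spike band", {
  cv <- structure(data.frame(amp = c(40, 50, 60, 70, 80),
                             n = c(0, 2, 6, 10, 30)),
                  class = c("io_curve", "data.frame"))
  # 80 pA (30 spikes) and 40 pA (0) excluded: slope from (50,2),(60,6),(70,10)
  expect_equal(io_slope(cv), 0.4, tolerance = 1e-12)
  cv2 <- structure(data.frame(amp = c(40, 50), n = c(0, 1)),
                   class = c("io_curve", "data.frame"))
  expect_error(io_slope(cv2), "2-15")
})

test_that("Boltzmann fit recovers generating parameters from clean ratios", {
  v <- seq(-130, -65, by = 5)
  truth <- 1 / (1 + exp((v + 80) / 7.4))
  fit <- fit_boltzmann(v, truth)
  expect_equal(fit$shift, -80, tolerance = 1e-4)
  expect_equal(fit$stp, 7.4, tolerance = 1e-4)
  expect_error(fit_boltzmann(v, rep(0.5, length(v))), "degenerate")
})

test_that("Ih activation fit round-trips through the simulated clamp series", {
  mod <- ih_clamp_model()
  ser <- run_voltage_clamp_series(mod)
  fit <- fit_ih_activation(ser)
  expect_equal(fit$shift, -96, tolerance = 0.015)
  expect_equal(fit$stp, 10, tolerance = 0.08)
})

test_that("clamp series currents are monotone with largest amplitude at -130 mV", {
  mod <- ih_clamp_model()
  ser <- run_voltage_clamp_series(mod)
  i_inf <- ser$i[nrow(ser$i), ]
  expect_true(all(i_inf <= 0))            # inward
  expect_identical(unname(which.max(abs(i_inf))), 1L)
  expect_true(all(diff(abs(i_inf)) < 0))  # decreasing magnitude with depol.
})

test_that("zeroed Ih conductance gives zero clamp current deviation", {
  p <- modify_conductances(parameter_set("P1"), scale = list(g_h = 0))
  mod <- ih_clamp_model(p)
  ser <- run_voltage_clamp_series(mod, commands = c(-120, -90))
  expect_lt(max(abs(ser$i)), 1e-9)
})

test_that("tau fitting recovers the generating time constants and bell curve", {
  mod <- ih_clamp_model()
  ser <- run_voltage_clamp_series(mod)
  ft <- fit_ih_tau(ser)
  k <- which(ser$commands == -80)
  expect_equal(ft$tau[k], ih_tau(-80), tolerance = 0.01)
  vg <- seq(-130, -65, by = 5)
  expect_lt(max(abs(ft$tau_fun(vg) - ih_tau(vg)) / ih_tau(vg)), 0.05)
  # synthetic single-exponential trace with tau = 132 ms
  t <- seq(0, 1000, by = 0.025)
  fake <- list(t = t,
               i = cbind(`-80` = -0.1 * (1 - exp(-t / 132))),
               commands = -80, holding = -40, dt = 0.025)
  class(fake) <- "vclamp_series"
  ft2 <- fit_ih_tau(fake)
  expect_equal(ft2$tau[1], 132, tolerance = 0.01)
})

test_that("constant clamp trace is rejected by the tau fit", {
  t <- seq(0, 1000, by = 0.025)
  fake <- list(t = t, i = cbind(`-80` = rep(-0.5, length(t))),
               commands = -80, holding = -40, dt = 0.025)
  class(fake) <- "vclamp_series"
  expect_error(fit_ih_tau(fake), "constant")
})
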