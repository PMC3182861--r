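test_that("P1 and P2 carry the published parameter values", {
  p1 <- parameter_set("P1")
  expect_equal(p1$V_rest, -63)
  expect_equal(p1$R_m, 22)
  expect_equal(p1$C_m, 1.1)
  expect_equal(p1$R_a, 113)
  expect_equal(p1$g_Na, 0.09)
  expect_equal(p1$Sh_Na, 10.4)
  expect_equal(p1$g_Kdr, 0.37)
  expect_equal(p1$Sh_Kdr, 11.8)
  expect_equal(p1$g_CaT, 1.2e-5)
  expect_equal(p1$g_CaL, 9e-4)
  expect_equal(p1$g_h, 1.1e-4)
  expect_equal(p1$g_AHP, 6.3e-5)
  expect_equal(p1$g_CAN, 2e-8)
  p2 <- parameter_set("P2")
  expect_equal(p2$V_rest, -69)
  expect_equal(p2$R_m, 45)
  expect_equal(p2$Sh_Na, 12.7)
  expect_equal(p2$Sh_Kdr, 15)
  expect_equal(p2$g_CaT, 8.5e-6)
  expect_equal(p2$g_CaL, 1.3e-3)
  expect_equal(p2$g_h, 1e-5)
  expect_equal(p2$g_AHP, 1.3e-4)
  expect_equal(p2$g_CAN, 1e-7)
  # membrane time constant R_m * C_m rounds to the published values
  expect_equal(round(membrane_time_constant(p1)), 24)
  expect_equal(round(membrane_time_constant(p2)), 50)
  expect_equal(membrane_time_constant(p1), 24.2)
  expect_equal(membrane_time_constant(p2), 49.5)
})

test_that("parameter-set YAML round trip is lossless", {
  p <- parameter_set("P2")
  tf <- withr::local_tempfile(fileext = ".yaml")
  write_parameter_set(p, tf)
  q <- read_parameter_set(tf)
  for (g in dlgnIN:::conductance_names())
    expect_identical(q[[g]], p[[g]])
  expect_identical(q$ih$shift, p$ih$shift)
  expect_identical(q$rules$cat$kind, "linear_distance")
  expect_equal(q$E_pas, p$E_pas, tolerance = 1e-12)
})

test_that("Ih activation follows the fitted Boltzmann curve", {
  expect_equal(ih_activation_inf(-96), 0.5)
  expect_equal(ih_activation_inf(-106), 1 / (1 + exp(-1)), tolerance = 1e-12)
  expect_lt(ih_activation_inf(20), 1e-4)
  expect_gt(ih_activation_inf(-150), 0.99)
  v <- seq(-140, 0, by = 1)
  expect_true(all(diff(ih_activation_inf(v)) < 0))
})

test_that("Ih time constant is the printed bell curve", {
  # at V = -a3 the denominator is exactly 2
  expect_equal(ih_tau(-78.8), exp((250 - 78.8) / 30.7) / 2, tolerance = 1e-12)
  expect_equal(ih_tau(-78.8), 132.0, tolerance = 1e-3)
  # interior maximum near -87.2 mV at about 163 ms, unimodal
  v <- seq(-140, -40, by = 0.05)
  tt <- ih_tau(v)
  expect_equal(v[which.max(tt)], -87.2, tolerance = 0.002)
  expect_equal(max(tt), 163, tolerance = 0.01)
  expect_lt(ih_tau(-130), max(tt))
  expect_lt(ih_tau(-40), max(tt))
  d <- diff(tt) > 0
  expect_identical(sum(diff(d) != 0), 1L)   # single turning point
})

test_that("voltage shifts act as rigid translations of the gating curves", {
  v <- seq(-90, 20, by = 5)
  for (ch in list(c("na", "m"), c("na", "h"), c("kdr", "n"))) {
    sh <- 10.4
    g0 <- gate_curves(ch[1], ch[2], v, shift = 0)
    g1 <- gate_curves(ch[1], ch[2], v + sh, shift = sh)
    expect_equal(g1$inf, g0$inf, tolerance = 1e-12)
    expect_equal(g1$tau, g0$tau, tolerance = 1e-12)
  }
})

test_that("gating steady states are monotone and bounded in [0,1]", {
  v <- seq(-120, 40, by = 1)
  for (spec in list(list("na", "m", +1), list("na", "h", -1),
                    list("kdr", "n", +1), list("cat", "m", +1),
                    list("cat", "h", -1), list("cal", "m", +1))) {
    g <- gate_curves(spec[[1]], spec[[2]], v)
    expect_true(all(g$inf >= 0 & g$inf <= 1))
    expect_true(all(g$tau > 0))
    expect_true(all(spec[[3]] * diff(g$inf) >= -1e-12))
  }
})

test_that("Q10 corrections scale the T-current time constants", {
  expect_equal(q10_factor(3), 3 ^ 1.2, tolerance = 1e-12)
  expect_equal(q10_factor(1.5), 1.5 ^ 1.2, tolerance = 1e-12)
  expect_equal(q10_factor(3, temp = 24), 1)
  v <- seq(-100, 0, by = 10)
  warm <- gate_curves("cat", "m", v, temp_corrected = TRUE)
  cold <- gate_curves("cat", "m", v, temp_corrected = FALSE)
  expect_equal(cold$tau / warm$tau, rep(3 ^ 1.2, length(v)),
               tolerance = 1e-12)
  expect_equal(warm$inf, cold$inf)   # steady states are unaffected
  wh <- gate_curves("cat", "h", v, temp_corrected = TRUE)
  ch <- gate_curves("cat", "h", v, temp_corrected = FALSE)
  expect_equal(ch$tau / wh$tau, rep(1.5 ^ 1.2, length(v)), tolerance = 1e-12)
})

test_that("calcium-dependent activations hit their half points", {
  expect_equal(ahp_activation_inf(435e-6), 0.5)
  expect_identical(ahp_activation_inf(0), 0)
  expect_lt(ahp_activation_inf(100e-6), 0.5)
  expect_gt(ahp_activation_inf(2e-3), 0.9)
  expect_error(ahp_activation_inf(-1e-6), "calcium")
  expect_equal(can_activation_inf(200e-6), 0.5)
  expect_identical(can_activation_inf(0), 0)
})

test_that("GHK flux has the correct limits, sign and ohmic regime", {
  expect_identical(ghk_flux(0, 2, 2), 0)
  # removable singularity: series value matches evaluation at +/- 1e-6 mV
  lim <- ghk_flux(0, 1e-4, 2)
  # the symmetric mean of the two evaluations cancels the linear term
  expect_equal((ghk_flux(1e-6, 1e-4, 2) + ghk_flux(-1e-6, 1e-4, 2)) / 2,
               lim, tolerance = 1e-9)
  expect_equal(ghk_flux(1e-6, 1e-4, 2), lim, tolerance = 1e-6)
  # inward for physiological gradient at rest
  expect_lt(ghk_flux(-60, 1e-4, 2), 0)
  expect_error(ghk_flux(-60, -1e-4, 2), "positive")
  # near the Nernst potential the flux is locally linear in V (< 1% error
  # from the secant slope within +/- 1 mV)
  tk <- 309.15
  e_ca <- 1e3 * 8.3134 * tk / (2 * 96485.309) * log(2 / 1e-4)
  f <- function(v) ghk_flux(v, 1e-4, 2, tk)
  slope <- (f(e_ca + 0.01) - f(e_ca - 0.01)) / 0.02
  lin_err <- abs(f(e_ca + 1) - (f(e_ca) + slope * 1)) / abs(slope * 1)
  expect_lt(lin_err, 0.04)   # GHK curvature at the reversal is ~3%/mV
})

test_that("density rules evaluate as printed", {
  u <- density_rule("uniform_ratio", ratio = 0.1)
  expect_equal(density_at(u, 0.37, c(0, 50, 400)), rep(0.037, 3))
  l <- density_rule("linear_distance", slope = 0.04)
  expect_equal(density_at(l, 1.2e-5, 0), 1.2e-5)
  expect_equal(density_at(l, 2, 60), 2 * 3.4)
  expect_error(density_at(l, 1, -5))
})

test_that("conductance edits scale, set and swap correctly", {
  p1 <- parameter_set("P1"); p2 <- parameter_set("P2")
  pz <- modify_conductances(p1, scale = list(g_CaT = 0))
  expect_identical(pz$g_CaT, 0)
  ps <- modify_conductances(p2, set = list(g_AHP = p1$g_AHP))
  expect_identical(ps$g_AHP, 6.3e-5)
  expect_error(modify_conductances(p1, scale = list(g_bogus = 2)),
               "unknown conductance")
  sw <- swap_conductances(p1, p2, c("g_h", "g_CaT"))
  expect_identical(sw$p1$g_h, p2$g_h)
  expect_identical(sw$p2$g_CaT, p1$g_CaT)
  back <- swap_conductances(sw$p1, sw$p2, c("g_h", "g_CaT"))
  expect_identical(back$p1$g_h, p1$g_h)
  expect_identical(back$p2$g_CaT, p2$g_CaT)
})
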