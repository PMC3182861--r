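test_that("passive single compartment follows the analytic RC response", {
  p <- passive_params(-70)
  mod <- compile_model(soma_only_morph(), p, channels = "pas")
  A <- mod$cpp$area
  r_in <- p$R_m * 1e3 / A / 1e6         # MOhm, lumped
  tau <- p$R_m * p$C_m
  i <- -0.001                            # nA (1 pA probe)
  out <- integrate_model(mod,
    list(steps = data.frame(seg = 1, amp = i, on = 0, off = 500)),
    t_stop = 500, dt = 0.025)
  v_an <- -70 + i * r_in * (1 - exp(-out$t / tau))
  expect_lt(max(abs(out$v[, 1] - v_an)), 0.1)
  expect_equal(out$v[length(out$t), 1] + 70, i * r_in, tolerance = 1e-4)
})

test_that("charge balance holds for the passive step (0.5%)", {
  p <- passive_params(-70)
  mod <- compile_model(soma_only_morph(), p, channels = "pas")
  A <- mod$cpp$area
  i <- -0.001
  out <- integrate_model(mod,
    list(steps = data.frame(seg = 1, amp = i, on = 0, off = 400)),
    t_stop = 400, dt = 0.025)
  t <- out$t; v <- out$v[, 1]
  dt <- diff(t)
  q_inj <- abs(i * 1e-6 * max(t))                      # mA*ms
  g <- 1e-3 / p$R_m
  q_leak <- sum(abs(g * ((v[-1] + v[-length(v)]) / 2 + 70)) * dt) * A
  q_cap <- abs(1e-3 * p$C_m * (v[length(v)] - v[1])) * A
  expect_equal(q_leak + q_cap, q_inj, tolerance = 5e-3)
})

test_that("two-compartment passive steady state matches the resistive network", {
  p <- passive_params(-70)
  m2 <- two_comp_morph()
  mod <- compile_model(m2, p, channels = "pas")
  out <- integrate_model(mod,
    list(steps = data.frame(seg = 1, amp = -0.002, on = 0, off = 2000)),
    t_stop = 2000, dt = 0.025, record = c(1, 2))
  a <- mod$cpp$area
  g1 <- a[1] / (p$R_m * 1e3); g2 <- a[2] / (p$R_m * 1e3)
  gax <- mod$cpp$ax_g[2]
  amat <- matrix(c(g1 + gax, -gax, -gax, g2 + gax), 2, 2, byrow = TRUE)
  vs <- solve(amat, c(-0.002 * 1e-6, 0))
  nt <- length(out$t)
  expect_equal(out$v[nt, 1] + 70, vs[1], tolerance = 1e-3)
  expect_equal(out$v[nt, 2] + 70, vs[2], tolerance = 1e-3)
})

test_that("compilation evaluates density rules at segment centres", {
  m <- default_morph()
  p1 <- parameter_set("P1")
  mod <- compile_model(m, p1)
  soma <- mod$is_soma
  expect_equal(mod$cpp$g_na[soma], p1$g_Na)
  expect_equal(unique(mod$cpp$g_na[!soma]), 0.1 * p1$g_Na)
  x <- mod$seg_x[!soma]
  pf <- ghk_permeability(1)
  expect_equal(mod$cpp$p_cat[!soma], p1$g_CaT * (1 + 0.04 * x) * pf)
  expect_equal(mod$cpp$g_h[!soma], rep(p1$g_h, sum(!soma)))
  # soma-only compile gets pure somatic densities
  mods <- compile_model(soma_only_morph(), p1)
  expect_equal(mods$cpp$g_kdr, p1$g_Kdr)
  # P1 vs P2 differ only through the parameter set on the same morphology
  mod2 <- compile_model(m, parameter_set("P2"))
  expect_identical(mod$cpp$parent, mod2$cpp$parent)
  expect_identical(mod$cpp$area, mod2$cpp$area)
})

test_that("disabling all active channels rests the model exactly at E_pas", {
  p <- passive_params(-66)
  mod <- compile_model(two_comp_morph(), p, channels = "pas")
  expect_equal(find_rest(mod), -66, tolerance = 1e-6)
})

test_that("calibrated models rest at their target potentials", {
  for (nm in c("P1", "P2")) {
    mod <- default_model(nm)
    expect_equal(find_rest(mod), parameter_set(nm)$V_rest, tolerance = 0.1)
  }
})

test_that("identical inputs give bit-identical simulation results", {
  mod <- default_model("P1")
  s1 <- run_current_step(mod, 70, post = 50)
  s2 <- run_current_step(mod, 70, post = 50)
  expect_identical(s1$v, s2$v)
  expect_identical(s1$ca, s2$ca)
})

test_that("no NaN and finite voltages across a protocol battery", {
  mod <- default_model("P2")
  for (amp in c(-150, 0, 80)) {
    sim <- run_current_step(mod, amp, post = 150)
    expect_true(all(is.finite(sim$v)))
    expect_true(all(is.finite(sim$ca)))
    expect_true(all(diff(sim$t) > 0))
  }
})

test_that("spike pattern converges under dt refinement", {
  mod <- default_model("P1")
  s1 <- run_current_step(mod, 70, post = 50, dt = 0.025)
  s2 <- run_current_step(mod, 70, post = 50, dt = 0.0125)
  t1 <- detect_spikes(s1)$times
  t2 <- detect_spikes(s2)$times
  # a marginal final spike may appear or vanish under refinement
  expect_lte(abs(length(t1) - length(t2)), 1)
  expect_lt(abs(t1[1] - t2[1]), 0.1)          # onset converged
  expect_lt(abs(median(diff(t1)) / median(diff(t2)) - 1), 0.005)
})

test_that("voltage refinement: 330 vs 660 segments differ < 0.5 mV on a subthreshold step", {
  # spike-free membrane (leak + Ih) isolates the spatial discretization
  m660 <- discretize(default_morph(), n_total = 660)
  p <- passive_params(-70)
  mod330 <- compile_model(default_morph(), p, channels = c("pas", "h"))
  mod660 <- compile_model(m660, p, channels = c("pas", "h"))
  s330 <- run_current_step(mod330, -150, post = 100)
  s660 <- run_current_step(mod660, -150, post = 100)
  expect_lt(max(abs(s330$v[, 1] - s660$v[, 1])), 0.5)
})

test_that("the integrator reports instability rather than clipping", {
  p <- passive_params(-70)
  mod <- compile_model(soma_only_morph(), p, channels = "pas")
  expect_error(integrate_model(mod,
    list(steps = data.frame(seg = 1, amp = 1, on = 0, off = 500)),
    t_stop = 500, dt = 0.025), "unstable")
})
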