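test_that("holding current search reproduces the target potential", {
  mod <- default_model("P1")
  expect_equal(find_holding_current(mod, parameter_set("P1")$V_rest), 0,
               tolerance = 0.5)
  i57 <- find_holding_current(mod, -57)
  expect_gt(i57, 0)
  sim <- run_current_step(mod, 0, holding_mV = -57, duration = 300,
                          post = 0)
  expect_equal(unname(sim$v[length(sim$t), 1]), -57, tolerance = 0.2)
  expect_error(find_holding_current(mod, -30), "15 mV")
})

test_that("zero-amplitude step stays flat at rest", {
  mod <- default_model("P1")
  sim <- run_current_step(mod, 0, duration = 300, post = 0)
  expect_lt(diff(range(sim$v[, 1])), 0.1)
  expect_equal(mean(sim$v[, 1]), parameter_set("P1")$V_rest, tolerance = 0.2)
})

test_that("synaptic barrage: zero conductance leaves the trace unchanged", {
  mod <- default_model("P2")
  s0 <- run_current_step(mod, 0, duration = 300, post = 100)
  sz <- run_synaptic_barrage(mod, synapse_spec(gmax_nS = 0), post = 100)
  expect_lt(max(abs(sz$v[, 1] - mean(s0$v[, 1]))), 0.1)
})

test_that("barrage hyperpolarization respects the synaptic reversal bound", {
  mod <- default_model("P2")
  sim <- run_synaptic_barrage(mod, synapse_spec())
  expect_gt(min(sim$v[, 1]), -82 - 1)
})

test_that("barrage placement and response are reproducible by seed", {
  mod <- default_model("P1")
  s1 <- run_synaptic_barrage(mod, synapse_spec(seed = 7))
  s2 <- run_synaptic_barrage(mod, synapse_spec(seed = 7))
  expect_identical(s1$v, s2$v)
  s3 <- run_synaptic_barrage(mod, synapse_spec(seed = 8))
  expect_false(identical(s1$v, s3$v))
})

test_that("staggered barrage mode differs from synchronous but stays bounded", {
  mod <- default_model("P2")
  sy <- run_synaptic_barrage(mod, synapse_spec(mode = "staggered"))
  expect_gt(min(sy$v[, 1]), -83)
  expect_true(all(is.finite(sy$v)))
})

test_that("run_config executes a reference config end to end", {
  cfg <- system.file("configs", "fig_step_P1_70pA.yaml", package = "dlgnIN")
  out_dir <- withr::local_tempdir()
  res <- run_config(cfg, out_dir)
  expect_true(file.exists(file.path(out_dir, "trace.csv")))
  expect_true(file.exists(file.path(out_dir, "features.csv")))
  expect_true(file.exists(file.path(out_dir, "provenance.json")))
  feat <- read.csv(file.path(out_dir, "features.csv"))
  expect_gt(feat$n_stim, 2)
  # determinism: running the same config twice gives identical traces
  out2 <- withr::local_tempdir()
  run_config(cfg, out2)
  expect_identical(readLines(file.path(out_dir, "trace.csv")),
                   readLines(file.path(out2, "trace.csv")))
})

test_that("run_config validates its schema before any compute", {
  out_dir <- withr::local_tempdir()
  expect_error(run_config(list(params = "P1"), out_dir), "protocol")
  expect_error(run_config(list(params = "P1", dt = -1,
                               protocol = list(kind = "current_step")),
                          out_dir), "dt")
  expect_error(run_config(list(params = "P1",
                               protocol = list(kind = "nope")), out_dir),
               "unknown protocol")
})
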