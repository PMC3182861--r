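test_that("surrogate generator hits the configured morphometrics", {
  m <- default_morph()
  expect_equal(surface_area(m), 9864, tolerance = 0.01)
  expect_equal(dendrite_length(m), 5771, tolerance = 0.01)
  expect_equal(longest_path(m), 673, tolerance = 0.01)
  expect_identical(nrow(m$sections), 104L)
  expect_identical(n_segments(m), 330L)
  # length-weighted mean dendritic diameter is implied by area and length
  s <- summary(m)
  expect_equal(s$mean_diameter, 0.5, tolerance = 0.15)
})

test_that("surrogate generation is deterministic in the seed", {
  m1 <- generate_surrogate(morpho_config(seed = 42))
  m2 <- generate_surrogate(morpho_config(seed = 42))
  expect_identical(m1$sections, m2$sections)
  m3 <- generate_surrogate(morpho_config(seed = 43))
  expect_false(identical(m1$sections$length, m3$sections$length))
})

test_that("area variant configs reproduce their target areas", {
  for (w in c("a", "b", "c")) {
    target <- c(a = 9566, b = 7071, c = 14336)[[w]]
    m <- generate_surrogate(morpho_variant(w))
    expect_equal(surface_area(m), target, tolerance = 0.01)
  }
})

test_that("soma-only config gives the bare soma area", {
  m <- soma_only_morph()
  expect_equal(surface_area(m), pi * 16 * 16, tolerance = 1e-12)
})

test_that("surface area is additive and exact for cylinders", {
  m2 <- two_comp_morph(dend_len = 10, dend_diam = 1)
  # soma cylinder + single 10 um x 1 um dendrite
  expect_equal(surface_area(m2), pi * 100 + 10 * pi, tolerance = 1e-12)
  m3 <- two_comp_morph(dend_len = 20, dend_diam = 1)
  expect_equal(surface_area(m3) - pi * 100,
               2 * (surface_area(m2) - pi * 100), tolerance = 1e-12)
})

test_that("infeasible generator configs raise constraint errors", {
  expect_error(generate_surrogate(morpho_config(target_area = 200)),
               "target_area")
  expect_error(generate_surrogate(
    morpho_config(target_dendrite_length = 40000)), "mean diameter")
})

test_that("path distance is zero in the soma and additive along chains", {
  m <- two_comp_morph(dend_len = 60)
  expect_identical(path_distance(m, 1, 0.5), 0)
  expect_equal(path_distance(m, 2, 1), 60)
  secs <- rbind(m$sections,
                data.frame(id = 3L, parent_id = 2L, kind = "dend",
                           length = 50, diam_prox = 2, diam_dist = 2,
                           nseg = 1L, stringsAsFactors = FALSE))
  m3 <- dlgnIN:::new_morphology(secs, "chain")
  expect_equal(path_distance(m3, 3, 1), 110)
  expect_error(path_distance(m, 99), "unknown section")
})

test_that("discretization rules behave as specified", {
  m <- default_morph()
  expect_identical(n_segments(discretize(m, n_total = 330)), 330L)
  expect_identical(n_segments(discretize(m, n_total = 660)), 660L)
  m1 <- discretize(m, max_seg_length = 40)
  m2 <- discretize(m, max_seg_length = 20)
  long <- m$sections$length > 40 & m$sections$kind != "soma"
  expect_true(all(m2$sections$nseg[long] >= 2 * m1$sections$nseg[long] - 1))
  ms <- discretize(two_comp_morph(), n_total = 2)
  expect_identical(ms$sections$nseg, c(1L, 1L))
})

test_that("SWC round trip preserves geometry to high precision", {
  m <- default_morph()
  tf <- withr::local_tempfile(fileext = ".swc")
  write_swc(m, tf)
  m2 <- read_swc(tf)
  expect_identical(nrow(m2$sections), nrow(m$sections))
  expect_equal(surface_area(m2), surface_area(m), tolerance = 1e-6)
  expect_equal(dendrite_length(m2), dendrite_length(m), tolerance = 1e-6)
  expect_equal(longest_path(m2), longest_path(m), tolerance = 1e-6)
  expect_equal(sort(m2$sections$length[m2$sections$kind != "soma"]),
               sort(m$sections$length[m$sections$kind != "soma"]),
               tolerance = 1e-6)
})

test_that("SWC parser reports malformed input with context", {
  tf <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("1 1 0 0 0 5 -1", "2 3 10 0 0 1 7"), tf)
  expect_error(read_swc(tf), "parent id 7")
  writeLines(c("1 1 0 0 0 5 -1", "2 1 0 0 0 5 -1"), tf)
  expect_error(read_swc(tf), "one root")
  writeLines(c("1 1 0 0 0 5 -1", "2 3 10 0 0"), tf)
  expect_error(read_swc(tf), "malformed SWC line 2")
})

test_that("three-point soma plus single neurite reads as two sections", {
  tf <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("1 1 0 0 0 5 -1",
               "2 1 0 -5 0 5 1",
               "3 1 0 5 0 5 1",
               "4 3 20 0 0 1 1"), tf)
  m <- read_swc(tf)
  expect_identical(nrow(m$sections), 2L)
  expect_identical(m$sections$kind, c("soma", "dend"))
  expect_equal(m$sections$length[2], 20)
  expect_equal(m$sections$diam_dist[2], 2)
})
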