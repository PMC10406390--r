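test_that("phantom generation is bit-reproducible under a fixed seed", {
  p <- small_phantom(theta = 20, noise_sigma = 0.01, seed = 42L)
  mm1 <- generate_phantom_mm(p)
  mm2 <- generate_phantom_mm(p)
  expect_identical(mm1$elements, mm2$elements)
  p2 <- small_phantom(theta = 20, noise_sigma = 0.01, seed = 43L)
  expect_false(identical(generate_phantom_mm(p2)$elements, mm1$elements))
})

test_that("undistorted phantom obeys the element taxonomy exactly", {
  p <- small_phantom(theta = 0)
  az <- 0:359
  expect_equal(azimuthal_element_model("m12", az, p),
               azimuthal_element_model("m21", az, p), tolerance = 1e-12)
  expect_equal(azimuthal_element_model("m13", az, p),
               azimuthal_element_model("m31", az, p), tolerance = 1e-12)
  # four-periodic closed forms
  expect_equal(azimuthal_element_model("m22", az, p),
               0.35 + 0.15 * cos(4 * pi / 180 * az), tolerance = 1e-12)
  expect_equal(azimuthal_element_model("m33", az, p),
               0.35 - 0.15 * cos(4 * pi / 180 * az), tolerance = 1e-12)
  # diagonals constant
  expect_equal(diff(range(azimuthal_element_model("m44", az, p))), 0)
  expect_equal(azimuthal_element_model("m11", az, p), rep(1, 360))
  expect_error(azimuthal_element_model("m55", az, p), "unknown")
  expect_error(azimuthal_element_model(c(0, 2), az, p), "unknown")
})

test_that("generated elements stay bounded and noise respects the seed", {
  for (th in c(0, 25, 50, 70)) {
    mm <- generate_phantom_mm(small_phantom(theta = th))
    expect_lte(max(abs(mm$elements)), 1)
  }
  expect_error(phantom_params(ring_radius = -1), "positive")
  expect_error(phantom_params(incidence_theta = 95), "\\[0, 90\\)")
  expect_error(phantom_params(image_size = c(150L, 150L), ring_radius = 80,
                              ring_half_width = 3), "does not fit")
})

test_that("symmetry breaking and baseline shift separate the M12/M21 pair", {
  p <- small_phantom(theta = 30)
  az <- 0:359
  d <- distortion_profile(p)
  expect_gt(d$symmetry_breaking, 0)
  m12 <- azimuthal_element_model("m12", az, p)
  m21 <- azimuthal_element_model("m21", az, p)
  expect_gt(max(abs(m12 - m21)), 0.1)
  # amplitude gain on m12, loss on m21; opposite-sign baselines
  expect_equal(mean(m12), d$baseline_shift, tolerance = 1e-12)
  expect_equal(mean(m21), -d$baseline_shift, tolerance = 1e-12)
})

test_that("two-periodic pairs transpose above the threshold angle", {
  # isolate the swap: disable the other prominent-incidence effects
  p_swap <- small_phantom(theta = 60, phase_retardance_max = 0,
                          prominent_baseline_drop = 0)
  p_ref <- small_phantom(theta = 60, phase_retardance_max = 0,
                         prominent_baseline_drop = 0,
                         transposition_threshold = 80)
  az <- 0:359
  expect_true(distortion_profile(p_swap)$transposed)
  expect_false(distortion_profile(p_ref)$transposed)
  expect_equal(azimuthal_element_model("m12", az, p_swap),
               azimuthal_element_model("m21", az, p_ref), tolerance = 1e-12)
  expect_equal(azimuthal_element_model("m31", az, p_swap),
               azimuthal_element_model("m13", az, p_ref), tolerance = 1e-12)
})

test_that("deep collapse drives the M33 curve to the square-wave limit", {
  az <- 0:359
  cs_at <- function(theta) {
    p <- small_phantom(theta = theta)
    spec <- harmonic_amplitudes(azimuthal_element_model("m33", az, p))
    cs_from_spectrum(spec, index_map = 4L * c(1L, 3L, 5L, 7L))
  }
  expect_lt(cs_at(75), 0.1 * cs_at(0))
})

test_that("phantom parameters round-trip through YAML and JSON configs", {
  p <- small_phantom(theta = 35, noise_sigma = 0.02, seed = 9L)
  for (ext in c(".yaml", ".json")) {
    path <- file.path(withr::local_tempdir(), paste0("cfg", ext))
    write_phantom_config(p, path)
    back <- read_phantom_config(path)
    expect_equal(unclass(back), unclass(p), tolerance = 1e-12)
  }
})

test_that("ground-truth curve table covers all 16 elements", {
  p <- small_phantom()
  tab <- phantom_truth_curves(p, azimuths = seq(0, 350, by = 10))
  expect_identical(names(tab), c("azimuth_deg", mm_element_names()))
  expect_identical(nrow(tab), 36L)
  expect_equal(tab$m22, azimuthal_element_model("m22", tab$azimuth_deg, p))
})
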