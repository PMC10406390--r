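test_that("measurement row reproduces brute-force Mueller-chain intensities", {
  cfg <- acquisition_config()
  set.seed(11)
  for (rep in 1:20) {
    m <- matrix(runif(16, -1, 1), 4, 4)
    r1 <- runif(1, 0, 360); r2 <- runif(1, 0, 360)
    w <- measurement_row(r1, r2, cfg)
    expect_equal(sum(w * as.vector(t(m))), oracle_intensity(m, r1, r2),
                 tolerance = 1e-12)
  }
  # aligned elements: generator and analyzer both 0.5*(1,1,0,0), so the
  # Kronecker weights are 0.25 on the top-left 2x2 block
  w0 <- measurement_row(0, 0, cfg)
  expected <- rep(0, 16)
  expected[c(1, 2, 5, 6)] <- 0.25
  expect_equal(w0, expected, tolerance = 1e-12)
})

test_that("DRR design is full rank at quarter-wave, degenerate at zero retardance", {
  expect_identical(qr(drr_design_matrix(acquisition_config()))$rank, 16L)
  w0 <- drr_design_matrix(acquisition_config(retardance = 0))
  expect_lte(qr(w0)$rank, 4L)
  expect_error(render_frames(mm_image(random_mm_array(2, 2, 1)),
                             acquisition_config(retardance = 0)),
               "rank-deficient")
})

test_that("reconstruct after render is the identity on noiseless input", {
  cfg <- acquisition_config()
  for (seed in 1:10) {
    a <- random_mm_array(3, 3, seed)
    rec <- suppressWarnings(reconstruct_mm(render_frames(mm_image(a), cfg)))
    expect_lt(max(abs(rec$elements - a)), 1e-10)
  }
  # identity everywhere round-trips and matches the closed-form air signal
  id <- array(0, c(2, 2, 16))
  for (k in c(1, 6, 11, 16)) id[, , k] <- 1
  fs <- render_frames(mm_image(id), cfg)
  analytic <- vapply(seq_len(cfg$n_frames), function(k) {
    oracle_intensity(diag(4), cfg$r1_angles[k], cfg$r2_angles[k])
  }, numeric(1))
  expect_equal(as.numeric(fs$frames[1, 1, ]), analytic, tolerance = 1e-12)
  rec <- reconstruct_mm(fs)
  expect_lt(max(abs(rec$elements - id)), 1e-10)
  expect_lt(max(attr(rec, "residual")), 1e-12)
})

test_that("rendering is linear in the Mueller matrix", {
  cfg <- acquisition_config()
  a1 <- random_mm_array(2, 2, 21); a2 <- random_mm_array(2, 2, 22)
  f1 <- render_frames(mm_image(a1), cfg)$frames
  f2 <- render_frames(mm_image(a2), cfg)$frames
  f12 <- render_frames(mm_image(0.3 * a1 + 1.7 * a2), cfg)$frames
  expect_equal(f12, 0.3 * f1 + 1.7 * f2, tolerance = 1e-12)
})

test_that("Fourier fit recovers trivial series and matches a dense DFT oracle", {
  phase <- 2 * 6 * (0:29)
  fit_c <- fit_fourier_coefficients(rep(4.2, 30), phase)
  expect_equal(fit_c$alpha0, 4.2, tolerance = 1e-12)
  expect_lt(max(abs(c(fit_c$alpha, fit_c$beta))), 1e-12)

  x3 <- cos(3 * pi / 180 * phase)
  fit3 <- fit_fourier_coefficients(x3, phase)
  expect_equal(fit3$alpha[3], 1, tolerance = 1e-10)
  expect_lt(max(abs(fit3$alpha[-3])), 1e-10)
  expect_lt(max(abs(fit3$beta)), 1e-10)

  # random-MM signal: 30-sample fit vs DFT of the continuous signal on a
  # 3600-point grid
  cfg <- acquisition_config()
  set.seed(5)
  m <- matrix(runif(16, -1, 1), 4, 4)
  i30 <- vapply(seq_len(30), function(k) {
    oracle_intensity(m, cfg$r1_angles[k], cfg$r2_angles[k])
  }, numeric(1))
  fit <- fit_fourier_coefficients(i30, phase)
  r1_dense <- 180 * (0:3599) / 3600
  i_dense <- vapply(seq_along(r1_dense), function(k) {
    oracle_intensity(m, r1_dense[k], 5 * r1_dense[k])
  }, numeric(1))
  xf <- fft(i_dense) / 3600
  expect_equal(fit$alpha0, Re(xf[1]), tolerance = 1e-10)
  expect_equal(fit$alpha, 2 * Re(xf[2:13]), tolerance = 1e-9)
  expect_equal(fit$beta, -2 * Im(xf[2:13]), tolerance = 1e-9)
  expect_equal(fit$fitted, i30, tolerance = 1e-10)
  expect_error(fit_fourier_coefficients(i30[1:20], phase[1:20], n_max = 12),
               "at least")
})

test_that("normalization by M11 divides channels and masks degenerate pixels", {
  a <- array(0, c(2, 2, 16))
  for (k in c(1, 6, 11, 16)) a[, , k] <- 3
  norm <- normalize_by_m11(mm_image(a))
  expect_true(norm$normalized)
  expect_equal(norm$elements[, , 1], matrix(1, 2, 2))
  expect_equal(norm$elements[, , 6], matrix(1, 2, 2))
  a[1, 1, 1] <- 0
  expect_message(norm2 <- normalize_by_m11(mm_image(a)), "masked 1 pixels")
  expect_true(norm2$mask[1, 1])
  expect_false(any(norm2$mask[-1]))
})

test_that("frame stacks and MM images survive the TIFF + sidecar round trip", {
  cfg <- acquisition_config()
  a <- random_mm_array(4, 4, 31)
  mm <- mm_image(a, normalized = TRUE, incidence_theta = 25)
  p1 <- file.path(withr::local_tempdir(), "mm.tif")
  write_mm_tiff(mm, p1)
  back <- read_mm_tiff(p1)
  expect_lt(max(abs(back$elements - a)), 1e-6)
  expect_equal(back$incidence_theta, 25)
  expect_true(back$normalized)

  fs <- render_frames(mm_image(a), cfg)
  p2 <- file.path(withr::local_tempdir(), "frames.tif")
  write_frames_tiff(fs, p2)
  fs2 <- read_frames_tiff(p2)
  expect_lt(max(abs(fs2$frames - fs$frames)), 1e-6)
  expect_equal(fs2$r1_angles, fs$r1_angles)
  rec <- suppressWarnings(reconstruct_mm(fs2))
  expect_lt(max(abs(rec$elements - a)), 1e-4)
})
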