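test_that("mean and kurtosis reproduce their defining formulas", {
  expect_equal(curve_mean(c(1, 1, 1)), 1)
  expect_equal(curve_mean(c(0, 2)), 1)
  expect_error(curve_mean(numeric()), "no finite values")
  # two-point symmetric distribution
  expect_equal(curve_kurtosis(rep(c(-1, 1), 50)), 1)
  expect_error(curve_kurtosis(rep(2, 10)), "constant")
  # dense single period of a sinusoid: fourth/second moment ratio 3/2,
  # confirmed by an independent quadrature oracle
  phi <- 2 * pi * (0:9999) / 10000
  num <- integrate(function(t) cos(t)^4, 0, 2 * pi)$value / (2 * pi)
  den <- (integrate(function(t) cos(t)^2, 0, 2 * pi)$value / (2 * pi))^2
  expect_equal(num / den, 1.5, tolerance = 1e-8)
  expect_equal(curve_kurtosis(cos(phi)), 1.5, tolerance = 1e-3)
})

test_that("kurtosis is near 3 for normal samples and affine invariant", {
  set.seed(101)
  x <- rnorm(2e5)
  expect_equal(curve_kurtosis(x), 3, tolerance = 0.05)
  for (i in 1:10) {
    a <- runif(1, -5, 5); b <- runif(1, -5, 5)
    if (abs(a) < 0.1) a <- 1
    expect_equal(curve_kurtosis(a * x[1:1000] + b),
                 curve_kurtosis(x[1:1000]), tolerance = 1e-10)
  }
})

test_that("peak detection on a pure four-periodic cosine", {
  az <- 0:359
  a_amp <- 0.3
  cv <- azimuthal_curve("m22", az, 0.1 + a_amp * cos(4 * pi / 180 * az))
  pk <- find_peaks_valleys(cv)
  expect_identical(nrow(pk$peaks), 4L)
  expect_identical(nrow(pk$valleys), 4L)
  expect_equal(sort(pk$peaks$azimuth), c(0, 90, 180, 270))
  expect_lt(max(pk$pp_values), 1e-10)
  expect_equal(pk$pv_values, rep(2 * a_amp, 4), tolerance = 1e-3)
  expect_equal(pk$pp_gap, 0.5)  # twin peaks at 0 and 90 in the 180 window
})

test_that("peaks and valleys interleave on the circular domain", {
  set.seed(7)
  for (i in 1:10) {
    az <- 0:359
    v <- 0.3 * cos(2 * pi / 180 * az + runif(1, 0, 6)) +
      0.2 * cos(4 * pi / 180 * az + runif(1, 0, 6)) +
      0.05 * rnorm(360)
    pk <- suppressWarnings(find_peaks_valleys(azimuthal_curve("x", az, v)))
    a <- c(pk$peaks$azimuth, pk$valleys$azimuth)
    t <- rep(c("p", "v"), c(nrow(pk$peaks), nrow(pk$valleys)))
    t <- t[order(a)]
    if (length(t) >= 2) {
      types <- c(t, t[1])  # wrap: alternation implies equal counts
      expect_true(all(types[-1] != types[-length(types)]))
      expect_identical(nrow(pk$peaks), nrow(pk$valleys))
    } else {
      expect_lte(length(t), 1L)
    }
  }
})

test_that("unequal twin peaks give the height difference as the P-P value", {
  az <- 0:359
  # two peaks per 180-degree period with different heights
  v <- sin(2 * pi / 180 * az) + 0.35 * sin(4 * pi / 180 * az)
  pk <- find_peaks_valleys(azimuthal_curve("x", az, v))
  # independent enumeration oracle on a dense grid
  f <- function(a) sin(2 * pi / 180 * a) + 0.35 * sin(4 * pi / 180 * a)
  dense <- seq(0, 360, by = 0.01)
  fv <- f(dense)
  loc_max <- which(diff(sign(diff(fv))) == -2) + 1
  heights <- sort(fv[loc_max], decreasing = TRUE)[1:2]
  expect_identical(nrow(pk$peaks), 2L)
  expect_equal(sort(pk$peaks$value, decreasing = TRUE), heights,
               tolerance = 1e-3)
  expect_equal(pk$pp_values, abs(diff(heights)), tolerance = 1e-3)
})

test_that("a flat noisy curve yields an empty peak set with a warning", {
  set.seed(3)
  v <- rep(1, 360)
  expect_warning(pk <- find_peaks_valleys(azimuthal_curve("x", 0:359, v)),
                 "no extrema")
  expect_identical(nrow(pk$peaks), 0L)
  expect_true(is.na(pk$pp_gap))
})

test_that("FDH conserves counts and localizes constants", {
  el <- array(0, c(40, 40, 16))
  el[, , 6] <- 0.25
  mm <- mm_image(el)
  fdh <- compute_fdh(mm, "m22")
  expect_identical(sum(fdh$counts > 0), 1L)
  expect_identical(sum(fdh$counts), 1600L)
  # two half-planes with distinct values -> two equally filled bins
  el[, , 6] <- cbind(matrix(-0.5, 40, 20), matrix(0.5, 40, 20))
  fdh2 <- compute_fdh(mm_image(el), "m22")
  expect_identical(sum(fdh2$counts > 0), 2L)
  expect_true(all(fdh2$counts[fdh2$counts > 0] == 800L))
  expect_identical(fdh2$n_pixels, 1600L)
  expect_error(compute_fdh(mm_image(el), "m22",
                           roi_mask = matrix(FALSE, 40, 40)),
               "empty region")
})

test_that("a baseline shift moves the FDH centroid by the applied shift", {
  p0 <- small_phantom(theta = 0)
  p1 <- small_phantom(theta = 0, two_periodic = list(amplitude = 0.12,
                                                     baseline = 0.2,
                                                     phase = 0))
  roi <- matrix(FALSE, 150, 150)
  ctr <- (150 + 1) / 2
  for (r in 1:150) for (cc in 1:150) {
    roi[r, cc] <- abs(sqrt((r - ctr)^2 + (cc - ctr)^2) - 60) <= 3
  }
  f0 <- compute_fdh(generate_phantom_mm(p0), "m12", roi_mask = roi)
  f1 <- compute_fdh(generate_phantom_mm(p1), "m12", roi_mask = roi)
  expect_equal(fdh_centroid(f1) - fdh_centroid(f0), 0.2, tolerance = 0.01)
})
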