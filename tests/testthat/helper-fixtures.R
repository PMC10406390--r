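# shared fixtures: small, fast phantom geometries and oracle helpers

small_phantom <- function(theta = 0, ...) {
  phantom_params(image_size = c(150L, 150L), ring_radius = 60,
                 ring_half_width = 3, incidence_theta = theta, ...)
}

small_ring <- list(radius = 60, half_width = 3)

# paint an arbitrary azimuthal profile f (degrees -> value) onto the m12
# channel of an otherwise empty normalized image
paint_azimuthal <- function(f, h = 150L, radius = 60, half_width = 5) {
  ctr <- (h + 1) / 2
  row <- matrix(seq_len(h), h, h)
  col <- t(row)
  dx <- col - ctr; dy <- -(row - ctr)
  r <- sqrt(dx^2 + dy^2)
  phi <- (atan2(dy, dx) * 180 / pi) %% 360
  inside <- r >= radius - half_width & r <= radius + half_width
  img <- matrix(0, h, h)
  img[inside] <- f(phi[inside])
  el <- array(0, c(h, h, 16))
  el[, , 1] <- 1
  el[, , 2] <- img
  mm_image(el, normalized = TRUE, provenance = "painted")
}

# rotate the imaged scene counterclockwise by 90 degrees (square matrix)
rotate_scene_90 <- function(m) t(m)[nrow(m):1, ]

# independent brute-force oracle: intensity through the full optical chain
# P2 . R2 . M . R1 . P1 acting on unit unpolarized light
oracle_intensity <- function(m, r1, r2, retardance = 90) {
  s <- mueller_polarizer(0) %*% mueller_retarder(retardance, r2) %*% m %*%
    mueller_retarder(retardance, r1) %*% mueller_polarizer(0) %*%
    c(1, 0, 0, 0)
  s[1]
}

# O(N^2) direct DFT-summation oracle for harmonic amplitudes
oracle_spectrum <- function(x, n_max) {
  n <- length(x)
  t <- 2 * pi * (seq_len(n) - 1) / n
  amps <- vapply(seq_len(n_max), function(k) {
    a <- sum(x * cos(k * t)) * 2 / n
    b <- sum(x * sin(k * t)) * 2 / n
    sqrt(a^2 + b^2)
  }, numeric(1))
  list(alpha0 = mean(x), amplitude = amps)
}

random_mm_array <- function(h, w, seed) {
  set.seed(seed)
  a <- array(stats::runif(h * w * 16, -1, 1), c(h, w, 16))
  a[, , 1] <- 1
  a
}
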