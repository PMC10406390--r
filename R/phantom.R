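#' Parameters of the synthetic concentric-fiber phantom
#'
#' Describes a backscattering Mueller-matrix (MM) image of a phantom made of
#' concentrically aligned anisotropic fibers, together with the distortions
#' that an oblique incidence angle `theta` between the illumination and
#' detection arms imprints on it. With all distortions off the normalized
#' elements follow the classic azimuthal taxonomy: constant diagonals
#' (M11, M44), two-periodic off-diagonals (M12, M21, M13, M31) and
#' four-periodic central-block elements (M22, M33, M23, M32).
#'
#' Each distortion knob is the maximum of a smooth monotone profile in
#' `theta` (evaluated by [distortion_profile()]):
#' \describe{
#'   \item{baseline_shift_max}{`b(theta) = b_max * sin(theta)`, opposite-sign
#'     baseline offsets of the M12/M21 (and, halved, M13/M31) pairs.}
#'   \item{symmetry_breaking_max}{`s(theta) = s_max * sin(theta)`,
#'     differential amplitude gain `(1 + s)` vs `(1 - s)` across the
#'     M12/M21 pair (40% as strong across M13/M31).}
#'   \item{collapse_max}{`c(theta) = c_max * sin(theta)`, depth of period
#'     degeneracy of the central block: M22 collapses towards an impulse
#'     train at 0/180 deg (single-peak collapse), M33 towards a square wave
#'     high on (45, 135) deg (double-peak collapse with converging twin
#'     peaks).}
#'   \item{diag_modulation_max}{`d(theta) = d_max * sin(theta)`, azimuthal
#'     modulation of M44 enhancing vertical fibers (90/270 deg).}
#'   \item{diag_decay}{fractional reduction of the M44 baseline,
#'     `1 - decay * sin(theta)`.}
#'   \item{phase_retardance_max, prominent_baseline_drop,
#'     transposition_threshold}{effects of prominent oblique incidence:
#'     above the threshold (degrees) the two-periodic pairs transpose their
#'     values, and the central block acquires an azimuthal phase shift
#'     `psi(theta)` and an extra baseline drop, both ramping in smoothly as
#'     `1 - exp(-(theta - threshold)/5)`.}
#' }
#'
#' @param image_size integer `c(H, W)` in pixels.
#' @param center ring center `c(row, col)` in pixels; default image center.
#' @param ring_radius nominal sampling-ring radius in pixels.
#' @param ring_half_width annulus half-width in pixels.
#' @param incidence_theta oblique incidence angle theta in degrees, in
#'   `[0, 90)`.
#' @param two_periodic,four_periodic lists with `amplitude`, `baseline`,
#'   `phase` (degrees) for the respective element groups (dimensionless,
#'   M11-normalized units).
#' @param m44_baseline undistorted M44 level.
#' @param baseline_shift_max,symmetry_breaking_max,collapse_max,
#'   diag_modulation_max,diag_decay,phase_retardance_max,
#'   prominent_baseline_drop,transposition_threshold distortion knobs, see
#'   Details.
#' @param noise_sigma standard deviation of additive Gaussian noise applied
#'   to every channel.
#' @param seed integer RNG seed; identical parameters and seed reproduce the
#'   phantom bit-identically.
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(image_size = c(420L, 420L),
                           center = (image_size + 1) / 2,
                           ring_radius = 200,
                           ring_half_width = 5,
                           incidence_theta = 0,
                           two_periodic = list(amplitude = 0.12,
                                               baseline = 0, phase = 0),
                           four_periodic = list(amplitude = 0.15,
                                                baseline = 0.35, phase = 0),
                           m44_baseline = 0.55,
                           baseline_shift_max = 0.08,
                           symmetry_breaking_max = 0.6,
                           collapse_max = 1,
                           diag_modulation_max = 0.12,
                           diag_decay = 0.4,
                           phase_retardance_max = 20,
                           prominent_baseline_drop = 0.15,
                           transposition_threshold = 50,
                           noise_sigma = 0,
                           seed = 1L) {
  if (ring_radius <= 0) stop("ring_radius must be positive", call. = FALSE)
  if (incidence_theta < 0 || incidence_theta >= 90) {
    stop("incidence_theta must lie in [0, 90) degrees", call. = FALSE)
  }
  edge <- min(center[1] - 1, image_size[1] - center[1],
              center[2] - 1, image_size[2] - center[2])
  if (ring_radius + ring_half_width + 2 >= edge) {
    stop("ring annulus (radius + half_width = ",
         ring_radius + ring_half_width,
         " px) does not fit inside the image", call. = FALSE)
  }
  structure(list(image_size = as.integer(image_size), center = center,
                 ring_radius = ring_radius, ring_half_width = ring_half_width,
                 incidence_theta = incidence_theta,
                 two_periodic = two_periodic, four_periodic = four_periodic,
                 m44_baseline = m44_baseline,
                 baseline_shift_max = baseline_shift_max,
                 symmetry_breaking_max = symmetry_breaking_max,
                 collapse_max = collapse_max,
                 diag_modulation_max = diag_modulation_max,
                 diag_decay = diag_decay,
                 phase_retardance_max = phase_retardance_max,
                 prominent_baseline_drop = prominent_baseline_drop,
                 transposition_threshold = transposition_threshold,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "phantom_params")
}

#' Evaluate the distortion knobs at the configured incidence angle
#'
#' @param params a [phantom_params] object.
#' @return A list with components `baseline_shift`, `symmetry_breaking`,
#'   `collapse_depth`, `diag_modulation`, `phase_retardance` (degrees),
#'   `baseline_drop`, and logical `transposed`.
#' @export
distortion_profile <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  th <- params$incidence_theta
  s <- sin(deg2rad(th))
  gate <- if (th > params$transposition_threshold) {
    1 - exp(-(th - params$transposition_threshold) / 5)
  } else 0
  list(baseline_shift = params$baseline_shift_max * s,
       symmetry_breaking = params$symmetry_breaking_max * s,
       collapse_depth = params$collapse_max * s,
       diag_modulation = params$diag_modulation_max * s,
       phase_retardance = params$phase_retardance_max * gate,
       baseline_drop = params$prominent_baseline_drop * gate,
       transposed = th > params$transposition_threshold)
}

#' Ground-truth azimuthal model of one phantom element
#'
#' Analytic value of a normalized Mueller element of the concentric-fiber
#' phantom as a function of the azimuth around the ring, under the
#' distortions configured in `params`. This is the curve that ring sampling
#' of the rasterized phantom recovers, and the reference for parameter
#' recovery tests.
#'
#' Undistorted forms (azimuth `phi` in degrees):
#' `M12 = M21 = B2 + A2 cos(2 phi)`, `M13 = M31 = B2 + A2 sin(2 phi)`,
#' `M22 = B4 + A4 cos(4 phi)`, `M33 = B4 - A4 cos(4 phi)`,
#' `M23 = -M32 = A4 sin(4 phi)`, `M11 = 1`, `M44` constant, remaining
#' elements 0 (they carry little signal in backscattering from fibrous
#' samples). Period degeneracy mixes the four-periodic carrier with an
#' impulse train (M22) or a saturated square-like wave (M33), with mixing
#' weight equal to the collapse depth.
#'
#' @param element element name (`"m22"`) or `(i, j)` pair.
#' @param azimuth azimuth(s) in degrees, taken modulo 360.
#' @param params a [phantom_params].
#' @return Numeric vector of element values, one per azimuth.
#' @export
azimuthal_element_model <- function(element, azimuth, params) {
  stopifnot(inherits(params, "phantom_params"))
  k <- mm_element_index(element)
  dst <- distortion_profile(params)
  if (dst$transposed) {
    # prominent oblique incidence: two-periodic pairs swap values
    swap <- c(2L, 5L, 3L, 9L)            # m12, m21, m13, m31
    names(swap) <- c(5L, 2L, 9L, 3L)
    if (k %in% names(swap)) k <- swap[[as.character(k)]] else
    if (k %in% swap) k <- as.integer(names(swap)[match(k, swap)])
  }
  phi <- (azimuth %% 360)
  p2 <- params$two_periodic; p4 <- params$four_periodic
  b <- dst$baseline_shift; s <- dst$symmetry_breaking
  cc <- dst$collapse_depth
  r2 <- deg2rad(2 * (phi - p2$phase))
  phic <- phi - p4$phase - dst$phase_retardance
  r4 <- deg2rad(phic)
  b4 <- p4$baseline - dst$baseline_drop
  kap <- 2 + 8 * cc
  val <- switch(as.character(k),
    "1"  = rep(1, length(phi)),
    "16" = params$m44_baseline * (1 - params$diag_decay *
             sin(deg2rad(params$incidence_theta))) +
           dst$diag_modulation * cos(2 * deg2rad(phi - 90)),
    "2"  = p2$baseline + b + (1 + s) * p2$amplitude * cos(r2),
    "5"  = p2$baseline - b + (1 - s) * p2$amplitude * cos(r2),
    "3"  = p2$baseline + 0.5 * b + (1 + 0.4 * s) * p2$amplitude * sin(r2),
    "9"  = p2$baseline - 0.5 * b + (1 - 0.4 * s) * p2$amplitude * sin(r2),
    "6"  = b4 + p4$amplitude * ((1 - cc) * cos(4 * r4) +
             cc * (2 * exp(kap * (cos(2 * r4) - 1)) - 1)),
    "11" = b4 + p4$amplitude * ((1 - cc) * (-cos(4 * r4)) +
             cc * tanh(kap * (-cos(2 * r4))) / tanh(kap)),
    "7"  = (1 - 0.5 * cc) * p4$amplitude * sin(4 * r4),
    "10" = -(1 - 0.5 * cc) * p4$amplitude * sin(4 * r4),
    rep(0, length(phi)))
  val
}

#' Rasterize the synthetic phantom into a Mueller-matrix image
#'
#' Paints every pixel of the ring annulus with the value of
#' [azimuthal_element_model()] at that pixel's azimuth (counterclockwise
#' from the +x image axis; the fiber there runs along the tangent of the
#' concentric circle through the pixel). Pixels outside the annulus take the
#' background value (1 for M11, 0 otherwise). Additive Gaussian noise of
#' standard deviation `noise_sigma` is then applied to every channel using
#' the configured seed, so the result is bit-reproducible.
#'
#' @param params a [phantom_params].
#' @return A normalized [mm_image] (M11 is identically 1 inside the annulus
#'   before noise).
#' @export
generate_phantom_mm <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  h <- params$image_size[1]; w <- params$image_size[2]
  row <- matrix(seq_len(h), h, w)
  col <- matrix(seq_len(w), h, w, byrow = TRUE)
  dx <- col - params$center[2]
  dy <- -(row - params$center[1])        # +y up so azimuth is CCW from +x
  r <- sqrt(dx^2 + dy^2)
  phi <- (atan2(dy, dx) * 180 / pi) %% 360
  # paint a 2 px guard band beyond the nominal half-width so that bilinear
  # interpolation at the nominal sampling extent never mixes in background
  guard <- 2
  inside <- r >= params$ring_radius - params$ring_half_width - guard &
            r <= params$ring_radius + params$ring_half_width + guard
  el <- array(0, c(h, w, 16))
  el[, , 1] <- 1
  phi_in <- phi[inside]
  for (k in 1:16) {
    ch <- el[, , k]
    ch[inside] <- azimuthal_element_model(mm_element_names()[k], phi_in,
                                          params)
    el[, , k] <- ch
  }
  if (params$noise_sigma > 0) {
    el <- el + local_rnorm(params$seed, length(el),
                           sd = params$noise_sigma)
  }
  mm_image(el, normalized = TRUE, incidence_theta = params$incidence_theta,
           provenance = sprintf("phantom(seed=%d,theta=%g)", params$seed,
                                params$incidence_theta))
}

# draw n Gaussian deviates from a private RNG stream, leaving the global
# RNG state untouched
local_rnorm <- function(seed, n, sd = 1) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  stats::rnorm(n, sd = sd)
}

#' Ground-truth azimuthal curves of the phantom as a table
#'
#' @param params a [phantom_params].
#' @param azimuths sampling grid in degrees.
#' @return A data.frame with column `azimuth_deg` followed by `m11 ... m44`.
#' @export
phantom_truth_curves <- function(params, azimuths = 0:359) {
  out <- data.frame(azimuth_deg = azimuths)
  for (nm in mm_element_names()) {
    out[[nm]] <- azimuthal_element_model(nm, azimuths, params)
  }
  out
}

#' Save / load phantom parameters as YAML or JSON config
#'
#' @param params a [phantom_params].
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @return `write_phantom_config()` returns `path` invisibly;
#'   `read_phantom_config()` a [phantom_params].
#' @export
write_phantom_config <- function(params, path) {
  stopifnot(inherits(params, "phantom_params"))
  x <- unclass(params)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname write_phantom_config
#' @export
read_phantom_config <- function(path) {
  x <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(phantom_params, x)
}
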