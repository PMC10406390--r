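#' Dual-rotating-retarder acquisition configuration
#'
#' The DRR scheme measures a full Mueller matrix from a sequence of
#' intensity frames recorded while two quarter-wave plates rotate at a
#' fixed 1:5 rate ratio, sandwiched between fixed horizontal polarizers:
#' polarizer P1 and retarder R1 form the polarization state generator, and
#' retarder R2 followed by polarizer P2 the analyzer. Thirty frames with an
#' R1 step of 6 degrees per frame give a full-rank 30 x 16 design at
#' quarter-wave retardance.
#'
#' @param n_frames number of intensity frames (default 30).
#' @param r1_step R1 rotation step in degrees per frame (default 6).
#' @param rate_ratio R2 step as a multiple of the R1 step (fixed ratio 5 in
#'   the classic scheme).
#' @param retardance retardance of both wave plates in degrees (nominal 90).
#' @param polarizer_angle orientation of both fixed polarizers in degrees
#'   (0 = horizontal).
#' @param intensity_scale source intensity in arbitrary camera units.
#' @return An object of class `acquisition_config`.
#' @export
acquisition_config <- function(n_frames = 30L, r1_step = 6, rate_ratio = 5,
                               retardance = 90, polarizer_angle = 0,
                               intensity_scale = 1) {
  if (n_frames < 16) stop("n_frames must be at least 16", call. = FALSE)
  r1 <- r1_step * (seq_len(n_frames) - 1)
  structure(list(n_frames = as.integer(n_frames), r1_step = r1_step,
                 rate_ratio = rate_ratio, retardance = retardance,
                 polarizer_angle = polarizer_angle,
                 intensity_scale = intensity_scale,
                 r1_angles = r1, r2_angles = (rate_ratio * r1) %% 360),
            class = "acquisition_config")
}

#' Polarimetric measurement row for one retarder position
#'
#' Builds the 16-vector of weights `w` such that the detected intensity is
#' `w . vec(M)` (row-major `m11, m12, ..., m44`), from the Kronecker product
#' of the analyzer's intensity row with the generator Stokes vector:
#' generator = rotated retarder applied to the polarizer output of unit
#' unpolarized light; analyzer row = first row of polarizer x rotated
#' retarder.
#'
#' @param r1_angle,r2_angle fast-axis angles of R1 and R2 in degrees.
#' @param config an [acquisition_config].
#' @return Numeric 16-vector of weights.
#' @export
measurement_row <- function(r1_angle, r2_angle, config = acquisition_config()) {
  s_gen <- mueller_retarder(config$retardance, r1_angle) %*%
    mueller_polarizer(config$polarizer_angle) %*% c(1, 0, 0, 0)
  a_row <- (mueller_polarizer(config$polarizer_angle) %*%
              mueller_retarder(config$retardance, r2_angle))[1, ]
  as.numeric(kronecker(a_row, as.numeric(s_gen)))
}

#' Stacked DRR design matrix
#'
#' @param config an [acquisition_config].
#' @return `n_frames x 16` matrix whose k-th row is the measurement row at
#'   the k-th retarder position.
#' @export
drr_design_matrix <- function(config = acquisition_config()) {
  t(vapply(seq_len(config$n_frames), function(k) {
    measurement_row(config$r1_angles[k], config$r2_angles[k], config)
  }, numeric(16)))
}

design_rank <- function(w) qr(w, tol = 1e-10)$rank

#' Forward-render a DRR frame stack from a Mueller-matrix image
#'
#' Frame `k` at each pixel is `measurement_row(k) . vec(M(pixel))`, scaled
#' by the source intensity; optional additive Gaussian camera noise is
#' seeded for reproducibility.
#'
#' @param mm an [mm_image] (unnormalized values are used as-is).
#' @param config an [acquisition_config]; must give a full-rank design.
#' @param noise_sigma standard deviation of additive frame noise, in the
#'   same arbitrary units as the frames (applied after intensity scaling).
#' @param seed RNG seed for the noise stream.
#' @return An object of class `frame_set`: list with `frames`
#'   (`H x W x n_frames` array), `r1_angles`, `r2_angles`, `config`.
#' @export
render_frames <- function(mm, config = acquisition_config(),
                          noise_sigma = 0, seed = 1L) {
  stopifnot(inherits(mm, "mm_image"))
  w <- drr_design_matrix(config)
  if (design_rank(w) < 16) {
    stop("DRR design matrix is rank-deficient; choose a different r1_step",
         call. = FALSE)
  }
  d <- dim(mm$elements)
  e <- matrix(mm$elements, d[1] * d[2], 16)     # pixels x 16
  f <- e %*% t(w) * config$intensity_scale      # pixels x n_frames
  if (noise_sigma > 0) {
    f <- f + local_rnorm(seed, length(f), sd = noise_sigma)
  }
  structure(list(frames = array(f, c(d[1], d[2], config$n_frames)),
                 r1_angles = config$r1_angles, r2_angles = config$r2_angles,
                 config = config),
            class = "frame_set")
}

#' Reconstruct a Mueller-matrix image from DRR frames
#'
#' Solves the per-pixel `n_frames x 16` linear system by Moore-Penrose
#' pseudoinverse of the design matrix (least squares for noisy frames,
#' exact round trip on noiseless rendered frames).
#'
#' @param frames a [render_frames()] `frame_set`.
#' @param config acquisition configuration; defaults to the one stored in
#'   `frames`.
#' @return An unnormalized [mm_image] with attribute `residual` holding the
#'   per-pixel root-mean-square intensity misfit (`H x W` matrix).
#' @export
reconstruct_mm <- function(frames, config = frames$config) {
  stopifnot(inherits(frames, "frame_set"))
  w <- drr_design_matrix(config) * config$intensity_scale
  if (design_rank(w) < 16) {
    stop("DRR design matrix is rank-deficient; choose a different r1_step",
         call. = FALSE)
  }
  if (min(frames$frames) < 0) {
    warning("negative intensities in input frames (",
            sum(frames$frames < 0), " samples); proceeding")
  }
  d <- dim(frames$frames)
  f <- matrix(frames$frames, d[1] * d[2], d[3])   # pixels x n_frames
  e <- f %*% t(pinv(w))                            # pixels x 16
  resid <- sqrt(rowMeans((f - e %*% t(w))^2))
  out <- mm_image(array(e, c(d[1], d[2], 16)), normalized = FALSE,
                  provenance = "drr-reconstruction")
  attr(out, "residual") <- matrix(resid, d[1], d[2])
  out
}

# Moore-Penrose pseudoinverse via SVD
pinv <- function(a, tol = 1e-12) {
  s <- svd(a)
  keep <- s$d > tol * s$d[1]
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Fit the truncated Fourier series of a DRR intensity signal
#'
#' Least-squares fit of
#' `I(t) = a0 + sum_{n=1}^{n_max} (a_n cos(n t) + b_n sin(n t))`
#' to an intensity series sampled at the given phases. In the DRR scheme
#' the effective phase advances at twice the R1 mechanical angle, so the
#' 30-frame, 6-degree-step acquisition samples one full phase cycle and
#' supports harmonics up to `n_max = 12`.
#'
#' @param intensity numeric intensity series.
#' @param phase_deg sampling phases in degrees (default: the effective
#'   phase `2 * r1` of the standard 30-frame scheme).
#' @param n_max highest harmonic fitted (default 12).
#' @return List of class `fourier_coefficients`: `alpha0`, `alpha`, `beta`
#'   (length `n_max`), `fitted`, `residual` (RMS misfit).
#' @export
fit_fourier_coefficients <- function(intensity,
                                     phase_deg = 2 * 6 *
                                       (seq_along(intensity) - 1),
                                     n_max = 12L) {
  n <- length(intensity)
  if (n < 2 * n_max + 1) {
    stop("need at least 2*n_max + 1 = ", 2 * n_max + 1,
         " samples for the Fourier fit, got ", n, call. = FALSE)
  }
  t <- deg2rad(phase_deg)
  x <- cbind(1, do.call(cbind, lapply(seq_len(n_max), function(k) {
    cbind(cos(k * t), sin(k * t))
  })))
  fit <- stats::lsfit(x, intensity, intercept = FALSE)
  cf <- fit$coefficients
  structure(list(alpha0 = unname(cf[1]),
                 alpha = unname(cf[seq(2, 2 * n_max, by = 2)]),
                 beta = unname(cf[seq(3, 2 * n_max + 1, by = 2)]),
                 fitted = as.numeric(x %*% cf),
                 residual = sqrt(mean(fit$residuals^2))),
            class = "fourier_coefficients")
}

#' Read and write DRR frame stacks as multi-page TIFF
#'
#' One TIFF page per frame, affinely rescaled to `[0, 1]`; the scale,
#' retarder angles and acquisition configuration go to a JSON sidecar.
#'
#' @param frames a `frame_set`.
#' @param path output TIFF path.
#' @return `write_frames_tiff()` returns `path` invisibly;
#'   `read_frames_tiff()` a `frame_set`.
#' @export
write_frames_tiff <- function(frames, path) {
  stopifnot(inherits(frames, "frame_set"))
  lo <- min(frames$frames); hi <- max(frames$frames)
  if (hi <= lo) hi <- lo + 1
  n <- dim(frames$frames)[3]
  pages <- lapply(seq_len(n),
                  function(k) (frames$frames[, , k] - lo) / (hi - lo))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(format = "mmoblique-frame-set", value_offset = lo,
               value_scale = hi - lo, r1_angles = frames$r1_angles,
               r2_angles = frames$r2_angles,
               config = unclass(frames$config))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_frames_tiff
#' @export
read_frames_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  f <- array(0, c(h, w, length(pages)))
  for (k in seq_along(pages)) {
    f[, , k] <- pages[[k]] * meta$value_scale + meta$value_offset
  }
  cfg <- meta$config
  config <- acquisition_config(n_frames = cfg$n_frames, r1_step = cfg$r1_step,
                               rate_ratio = cfg$rate_ratio,
                               retardance = cfg$retardance,
                               polarizer_angle = cfg$polarizer_angle,
                               intensity_scale = cfg$intensity_scale)
  structure(list(frames = f, r1_angles = meta$r1_angles,
                 r2_angles = meta$r2_angles, config = config),
            class = "frame_set")
}
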