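#' Mean and kurtosis of azimuthal curves and pixel samples
#'
#' The two descriptive statistics used to summarize non-periodic element
#' curves: the arithmetic mean
#' `mu = (1/n) sum(p_i)` and the population (non-excess) kurtosis
#' `k = (1/n) sum((p_i - mu)^4) / ((1/n) sum((p_i - mu)^2))^2`,
#' for which a normal distribution gives 3, a single period of a sinusoid
#' 1.5, and any non-constant sample at least 1. No small-sample bias
#' correction and no subtraction of 3 is applied.
#'
#' @param values numeric vector or an [azimuthal_curve] (NA values, i.e.
#'   masked samples, are dropped).
#' @param flat_tolerance range below which the sample counts as constant
#'   (degenerate for the kurtosis); default `1e-8`.
#' @return `curve_mean()` and `curve_kurtosis()` return a single number.
#' @export
curve_mean <- function(values) {
  p <- curve_values(values)
  if (length(p) == 0) stop("no finite values to average", call. = FALSE)
  mean(p)
}

#' @rdname curve_mean
#' @export
curve_kurtosis <- function(values, flat_tolerance = 1e-8) {
  p <- curve_values(values)
  if (length(p) < 2 || diff(range(p)) < flat_tolerance) {
    stop("kurtosis is undefined for a constant (zero-variance) sample",
         call. = FALSE)
  }
  mu <- mean(p)
  m2 <- mean((p - mu)^2)
  mean((p - mu)^4) / m2^2
}

curve_values <- function(x) {
  v <- if (inherits(x, "azimuthal_curve")) x$values else as.numeric(x)
  v[is.finite(v)]
}

# keep only alternating extrema on the circular domain: runs of same-type
# extrema (including across the wrap) collapse to their most extreme member
enforce_alternation <- function(ext_idx, ext_type, sm) {
  repeat {
    m <- length(ext_idx)
    if (m < 2) return(list(idx = ext_idx, type = ext_type))
    nxt <- c(2:m, 1)
    dup <- which(ext_type == ext_type[nxt])  # q and q+1 share a type
    if (!length(dup)) return(list(idx = ext_idx, type = ext_type))
    q <- dup[1]; q2 <- if (q == m) 1 else q + 1
    drop <- if (ext_type[q] == "peak") {
      if (sm[ext_idx[q]] >= sm[ext_idx[q2]]) q2 else q
    } else {
      if (sm[ext_idx[q]] <= sm[ext_idx[q2]]) q2 else q
    }
    ext_idx <- ext_idx[-drop]; ext_type <- ext_type[-drop]
  }
}

# circular moving average with odd window
circular_smooth <- function(v, window) {
  if (window <= 1) return(v)
  half <- (window - 1) %/% 2
  n <- length(v)
  ext <- c(v[(n - half + 1):n], v, v[1:half])
  stats::filter(ext, rep(1 / window, window), sides = 2)[(half + 1):(half + n)]
}

#' Peak and valley analysis of an azimuthal curve
#'
#' Detects local maxima (P) and minima (V) on the circular azimuth domain
#' (wrapping at 360 degrees) after light circular moving-average smoothing,
#' keeps extrema whose prominence exceeds `prominence_fraction` of the
#' curve's full range, and reports the raw curve values at the detected
#' azimuths. From the azimuth-ordered extrema it derives:
#' \describe{
#'   \item{pp_values}{absolute differences between consecutive peak
#'     values.}
#'   \item{pv_values}{absolute differences between each peak and the
#'     following valley.}
#'   \item{pp_gap}{azimuthal distance between the twin peaks falling in one
#'     nominal period (default the first 0-180 degree window), in units of
#'     the period; 0 once the twins have merged into a single peak, NA if
#'     no peak lies in the window.}
#' }
#'
#' @param curve an [azimuthal_curve] (or plain numeric vector, assumed on a
#'   uniform grid over 360 degrees).
#' @param prominence_fraction minimum prominence as a fraction of
#'   `max - min` (default 0.05).
#' @param smooth_window circular moving-average window in samples
#'   (default 5) applied before extremum detection.
#' @param nominal_period period (degrees) defining the twin-peak window for
#'   `pp_gap` (default 180).
#' @param flat_tolerance absolute range below which the curve counts as
#'   flat and the peak set is empty (default `1e-8`, i.e. numerically
#'   constant on the M11-normalized scale).
#' @return An object of class `peak_set`: lists `peaks` and `valleys` (each
#'   a data.frame of `azimuth`, `value`), plus `pp_values`, `pv_values`,
#'   `pp_gap`.
#' @export
find_peaks_valleys <- function(curve, prominence_fraction = 0.05,
                               smooth_window = 5L, nominal_period = 180,
                               flat_tolerance = 1e-8) {
  if (inherits(curve, "azimuthal_curve")) {
    az <- curve$azimuths; raw <- curve$values
  } else {
    raw <- as.numeric(curve)
    az <- 360 * (seq_along(raw) - 1) / length(raw)
  }
  if (length(raw) < 8) stop("need at least 8 samples", call. = FALSE)
  ok <- is.finite(raw)
  v <- raw
  v[!ok] <- stats::approx(az[ok], raw[ok], xout = az[!ok], rule = 2)$y
  sm <- circular_smooth(v, smooth_window)
  n <- length(sm)
  if (max(sm) - min(sm) < flat_tolerance) {
    warning("no extrema above the prominence threshold (flat curve)")
    return(structure(list(peaks = data.frame(azimuth = numeric(),
                                             value = numeric()),
                          valleys = data.frame(azimuth = numeric(),
                                               value = numeric()),
                          pp_values = numeric(), pv_values = numeric(),
                          pp_gap = NA_real_), class = "peak_set"))
  }
  nxt <- c(2:n, 1); prv <- c(n, 1:(n - 1))
  is_max <- sm > sm[prv] & sm >= sm[nxt]
  is_min <- sm < sm[prv] & sm <= sm[nxt]
  ext_idx <- which(is_max | is_min)
  ext_type <- ifelse(is_max[ext_idx], "peak", "valley")
  alt <- enforce_alternation(ext_idx, ext_type, sm)
  ext_idx <- alt$idx; ext_type <- alt$type
  # prominence against adjacent opposite extrema (circular)
  thr <- prominence_fraction * (max(sm) - min(sm))
  m <- length(ext_idx)
  prom <- numeric(m)
  if (m >= 2) {
    for (q in seq_len(m)) {
      left <- ext_idx[if (q == 1) m else q - 1]
      right <- ext_idx[if (q == m) 1 else q + 1]
      prom[q] <- if (ext_type[q] == "peak") {
        sm[ext_idx[q]] - max(sm[left], sm[right])
      } else min(sm[left], sm[right]) - sm[ext_idx[q]]
    }
  }
  sel <- prom >= thr
  ext_idx <- ext_idx[sel]; ext_type <- ext_type[sel]
  if (!length(ext_idx)) {
    warning("no extrema above the prominence threshold")
    return(structure(list(peaks = data.frame(azimuth = numeric(),
                                             value = numeric()),
                          valleys = data.frame(azimuth = numeric(),
                                               value = numeric()),
                          pp_values = numeric(), pv_values = numeric(),
                          pp_gap = NA_real_), class = "peak_set"))
  }
  # re-enforce alternation after the prominence filter
  alt <- enforce_alternation(ext_idx, ext_type, sm)
  ext_idx <- alt$idx; ext_type <- alt$type
  peaks <- data.frame(azimuth = az[ext_idx[ext_type == "peak"]],
                      value = raw[ext_idx[ext_type == "peak"]])
  valleys <- data.frame(azimuth = az[ext_idx[ext_type == "valley"]],
                        value = raw[ext_idx[ext_type == "valley"]])
  pp <- if (nrow(peaks) >= 2) abs(diff(peaks$value)) else numeric()
  pv <- numeric()
  if (nrow(peaks) && nrow(valleys)) {
    for (q in seq_len(nrow(peaks))) {
      following <- valleys$azimuth[valleys$azimuth > peaks$azimuth[q]]
      vq <- if (length(following)) {
        valleys$value[valleys$azimuth == min(following)][1]
      } else valleys$value[which.min(valleys$azimuth)][1]
      pv <- c(pv, abs(peaks$value[q] - vq))
    }
  }
  twin <- peaks$azimuth[peaks$azimuth < nominal_period]
  gap <- if (length(twin) >= 2) {
    (max(twin) - min(twin)) / nominal_period
  } else if (length(twin) == 1) 0 else NA_real_
  structure(list(peaks = peaks, valleys = valleys, pp_values = pp,
                 pv_values = pv, pp_gap = gap), class = "peak_set")
}

#' Frequency distribution histogram (FDH) of an element image
#'
#' Transforms the 2D image of one Mueller element into a 1D histogram of
#' its pixel values over a region of interest; a horizontal shift of the
#' FDH reflects an overall change of the element's level, a shape change a
#' change of its distribution. Values outside `value_range` are clamped
#' into the end bins so that counts conserve the pixel total.
#'
#' @param mm an [mm_image].
#' @inheritParams mm_element_index
#' @param roi_mask optional logical `H x W` matrix selecting the region of
#'   interest (`TRUE` = use pixel); default all unmasked pixels.
#' @param n_bins number of bins (default 256).
#' @param value_range histogram support (default `c(-1, 1)`, matching
#'   M11-normalized elements).
#' @return An object of class `fdh`: `bin_edges`, `bin_centers`, `counts`,
#'   `n_pixels`.
#' @export
compute_fdh <- function(mm, element, roi_mask = NULL, n_bins = 256L,
                        value_range = c(-1, 1)) {
  stopifnot(inherits(mm, "mm_image"))
  img <- mm_element(mm, element)
  use <- !mm$mask
  if (!is.null(roi_mask)) use <- use & roi_mask
  vals <- img[use]
  vals <- vals[is.finite(vals)]
  if (!length(vals)) stop("empty region of interest", call. = FALSE)
  edges <- seq(value_range[1], value_range[2], length.out = n_bins + 1)
  clamped <- pmin(pmax(vals, value_range[1]), value_range[2])
  idx <- pmin(pmax(findInterval(clamped, edges, rightmost.closed = TRUE),
                   1L), n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  structure(list(bin_edges = edges,
                 bin_centers = (edges[-1] + edges[-(n_bins + 1)]) / 2,
                 counts = counts, n_pixels = length(vals)),
            class = "fdh")
}

#' Centroid (mean value) of an FDH
#'
#' @param fdh an [compute_fdh()] result.
#' @return Count-weighted mean of the bin centers.
#' @export
fdh_centroid <- function(fdh) {
  stopifnot(inherits(fdh, "fdh"))
  sum(fdh$bin_centers * fdh$counts) / sum(fdh$counts)
}

#' Write an FDH to CSV (`bin_center, count`)
#'
#' @param fdh an [compute_fdh()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_fdh_csv <- function(fdh, path) {
  utils::write.csv(data.frame(bin_center = fdh$bin_centers,
                              count = fdh$counts),
                   path, row.names = FALSE)
  invisible(path)
}
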