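#' Azimuthal dependent curve container
#'
#' Value of one Mueller element sampled on a uniform azimuth grid over
#' `[0, 360)` degrees along a ring of the image.
#'
#' @param element element name (e.g. `"m22"`).
#' @param azimuths uniform, strictly increasing grid in `[0, 360)` degrees.
#' @param values one value per azimuth (NA where every contributing pixel
#'   was masked).
#' @param provenance free-form description of source image and ring
#'   geometry.
#' @return An object of class `azimuthal_curve`.
#' @export
azimuthal_curve <- function(element, azimuths, values,
                            provenance = "unspecified") {
  stopifnot(length(azimuths) == length(values),
            !is.unsorted(azimuths, strictly = TRUE))
  step <- diff(azimuths)
  if (length(step) && diff(range(step)) > 1e-9 * mean(step)) {
    stop("azimuth grid must be uniform", call. = FALSE)
  }
  structure(list(element = element, azimuths = azimuths, values = values,
                 n_samples = length(values), provenance = provenance),
            class = "azimuthal_curve")
}

#' @export
print.azimuthal_curve <- function(x, ...) {
  cat(sprintf("<azimuthal_curve> %s: %d samples over [%g, %g) deg (%s)\n",
              x$element, x$n_samples, min(x$azimuths),
              max(x$azimuths) + diff(x$azimuths[1:2]), x$provenance))
  invisible(x)
}

# bilinear interpolation of matrix `img` at fractional (row, col) positions;
# masked pixels poison the sub-sample (returns NA there)
bilinear_interp <- function(img, row, col, mask = NULL) {
  h <- nrow(img); w <- ncol(img)
  r0 <- pmin(pmax(floor(row), 1L), h - 1L)
  c0 <- pmin(pmax(floor(col), 1L), w - 1L)
  fr <- row - r0; fc <- col - c0
  i00 <- cbind(r0, c0); i01 <- cbind(r0, c0 + 1L)
  i10 <- cbind(r0 + 1L, c0); i11 <- cbind(r0 + 1L, c0 + 1L)
  v <- (1 - fr) * (1 - fc) * img[i00] + (1 - fr) * fc * img[i01] +
    fr * (1 - fc) * img[i10] + fr * fc * img[i11]
  if (!is.null(mask)) {
    bad <- mask[i00] | mask[i01] | mask[i10] | mask[i11]
    v[bad] <- NA_real_
  }
  v
}

#' Extract the azimuthal dependent curve of a Mueller element
#'
#' For each azimuth on a uniform grid, averages bilinearly interpolated
#' pixel values along the radial extent `[radius - half_width,
#' radius + half_width]` of the ray from the ring center at that azimuth
#' (azimuth counterclockwise from the +x image axis). Sub-samples touching
#' masked pixels are excluded from the average; an azimuth whose sub-samples
#' are all masked yields `NA`.
#'
#' @param mm an [mm_image].
#' @inheritParams mm_element_index
#' @param center ring center `c(row, col)`; default image center.
#' @param radius ring radius in pixels (default 200).
#' @param half_width annulus half-width in pixels (default 5).
#' @param n_samples azimuth samples over 360 degrees (default 360, i.e.
#'   1-degree resolution).
#' @param n_radial radial sub-samples averaged per azimuth (default 11).
#' @return An [azimuthal_curve].
#' @export
extract_azimuthal_curve <- function(mm, element, center = NULL, radius = 200,
                                    half_width = 5, n_samples = 360L,
                                    n_radial = 11L) {
  stopifnot(inherits(mm, "mm_image"), n_samples >= 8)
  d <- dim(mm$elements)
  if (is.null(center)) center <- (d[1:2] + 1) / 2
  edge <- min(center[1] - 1, d[1] - center[1],
              center[2] - 1, d[2] - center[2])
  if (radius + half_width > edge) {
    stop("ring (radius + half_width = ", radius + half_width,
         " px) extends outside the image", call. = FALSE)
  }
  img <- mm_element(mm, element)
  phi <- 360 * (seq_len(n_samples) - 1) / n_samples
  radii <- if (n_radial > 1) {
    seq(radius - half_width, radius + half_width, length.out = n_radial)
  } else radius
  grid <- expand.grid(r = radii, phi = phi)
  a <- deg2rad(grid$phi)
  rows <- center[1] - grid$r * sin(a)
  cols <- center[2] + grid$r * cos(a)
  v <- bilinear_interp(img, rows, cols,
                       mask = if (any(mm$mask)) mm$mask else NULL)
  vals <- colMeans(matrix(v, nrow = length(radii)), na.rm = TRUE)
  vals[is.nan(vals)] <- NA_real_
  elname <- if (is.character(element)) element else
    mm_element_names()[mm_element_index(element)]
  azimuthal_curve(elname, phi, vals,
                  provenance = sprintf("%s ring r=%g+/-%g", mm$provenance,
                                       radius, half_width))
}

#' Write azimuthal curves to CSV
#'
#' One file per curve with columns `azimuth_deg, value`, or a single wide
#' table for a full set of 16 curves (columns `azimuth_deg, m11 ... m44`).
#'
#' @param curves a single [azimuthal_curve] or a named list of 16 of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_curves_csv <- function(curves, path) {
  if (inherits(curves, "azimuthal_curve")) {
    utils::write.csv(data.frame(azimuth_deg = curves$azimuths,
                                value = curves$values),
                     path, row.names = FALSE)
  } else {
    out <- data.frame(azimuth_deg = curves[[1]]$azimuths)
    for (cv in curves) out[[cv$element]] <- cv$values
    utils::write.csv(out, path, row.names = FALSE)
  }
  invisible(path)
}

#' Extract curves for all 16 Mueller elements
#'
#' @inheritParams extract_azimuthal_curve
#' @param ... passed to [extract_azimuthal_curve()].
#' @return Named list of 16 [azimuthal_curve]s (`m11 ... m44`).
#' @export
extract_all_curves <- function(mm, ...) {
  stats::setNames(lapply(mm_element_names(), function(nm) {
    extract_azimuthal_curve(mm, nm, ...)
  }), mm_element_names())
}
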