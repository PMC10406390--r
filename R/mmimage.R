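#' Mueller-matrix image container
#'
#' An `mm_image` holds the 16 spatial channels of a Mueller matrix measured
#' or simulated over an image plane, as an `H x W x 16` array with channels
#' in row-major element order `m11, m12, ..., m44`. A logical mask marks
#' pixels excluded from analysis (e.g. where normalization by M11 is
#' undefined).
#'
#' @param elements numeric `H x W x 16` array, channel order `m11 ... m44`.
#' @param normalized logical; `TRUE` if all channels have been divided
#'   pixelwise by M11 (channel 1 is then identically 1 where unmasked).
#' @param incidence_theta oblique incidence angle theta in degrees between
#'   the illumination (PSG) and detection (PSA) arms, if known.
#' @param provenance free-form tag recording how the image was produced.
#' @param mask optional logical `H x W` matrix, `TRUE` = excluded pixel.
#' @return An object of class `mm_image`.
#' @export
mm_image <- function(elements, normalized = FALSE, incidence_theta = NA_real_,
                     provenance = "unspecified", mask = NULL) {
  stopifnot(is.array(elements), length(dim(elements)) == 3L,
            dim(elements)[3] == 16L)
  if (is.null(mask)) {
    mask <- matrix(FALSE, dim(elements)[1], dim(elements)[2])
  }
  stopifnot(identical(dim(mask), dim(elements)[1:2]))
  structure(list(elements = elements, normalized = normalized,
                 incidence_theta = incidence_theta,
                 provenance = provenance, mask = mask),
            class = "mm_image")
}

#' Channel names and indexing for Mueller elements
#'
#' Elements are addressed either by name (`"m23"`), by `(i, j)` pair, or by
#' the row-major channel index `4 * (i - 1) + j`.
#'
#' @param element element name such as `"m23"`, or an integer pair `c(i, j)`.
#' @return `mm_element_index()` returns the channel index in `1:16`;
#'   `mm_element_names()` the 16 channel names in storage order.
#' @export
mm_element_index <- function(element) {
  if (is.character(element)) {
    idx <- match(tolower(element), mm_element_names())
    if (is.na(idx)) {
      stop("unknown Mueller element name: '", element, "'", call. = FALSE)
    }
    return(idx)
  }
  if (is.numeric(element) && length(element) == 2L) {
    i <- element[1]; j <- element[2]
    if (!all(c(i, j) %in% 1:4)) {
      stop("unknown Mueller element index: (", i, ", ", j, ")", call. = FALSE)
    }
    return(4L * (i - 1L) + j)
  }
  stop("element must be a name like 'm23' or an (i, j) pair", call. = FALSE)
}

#' @rdname mm_element_index
#' @export
mm_element_names <- function() {
  as.vector(t(outer(1:4, 1:4, function(i, j) paste0("m", i, j))))
}

#' Extract one element channel as a matrix
#'
#' @param mm an [mm_image].
#' @inheritParams mm_element_index
#' @return numeric `H x W` matrix.
#' @export
mm_element <- function(mm, element) {
  stopifnot(inherits(mm, "mm_image"))
  mm$elements[, , mm_element_index(element)]
}

#' @export
print.mm_image <- function(x, ...) {
  d <- dim(x$elements)
  cat(sprintf("<mm_image> %d x %d px, 16 channels, %s\n", d[1], d[2],
              if (x$normalized) "normalized by M11" else "unnormalized"))
  cat(sprintf("  incidence theta: %s deg; provenance: %s; masked px: %d\n",
              format(x$incidence_theta), x$provenance, sum(x$mask)))
  invisible(x)
}

#' Normalize a Mueller-matrix image by its M11 channel
#'
#' Divides every channel pixelwise by M11, the unpolarized backscattering
#' intensity. Pixels with |M11| below `eps_fraction * max(|M11|)` cannot be
#' normalized; they are masked and excluded from downstream statistics
#' rather than producing infinities.
#'
#' @param mm an unnormalized [mm_image].
#' @param eps_fraction relative threshold on |M11| below which a pixel is
#'   masked (default `1e-6`).
#' @return A normalized [mm_image]; the number of newly masked pixels is
#'   reported via `message()` when nonzero.
#' @export
normalize_by_m11 <- function(mm, eps_fraction = 1e-6) {
  stopifnot(inherits(mm, "mm_image"))
  m11 <- mm$elements[, , 1]
  eps <- eps_fraction * max(abs(m11), 0)
  bad <- !is.finite(m11) | abs(m11) <= eps
  n_new <- sum(bad & !mm$mask)
  if (n_new > 0) {
    message("normalize_by_m11: masked ", n_new, " pixels with |M11| <= ",
            format(eps))
  }
  safe <- ifelse(bad, 1, m11)
  el <- mm$elements
  for (k in 1:16) el[, , k] <- el[, , k] / safe
  el[, , 1][!bad] <- 1
  mm_image(el, normalized = TRUE, incidence_theta = mm$incidence_theta,
           provenance = paste0(mm$provenance, "+norm"),
           mask = mm$mask | bad)
}

#' Read and write Mueller-matrix images as multi-page TIFF
#'
#' The 16 channels are written as a 16-page 32-bit float TIFF in row-major
#' element order (`m11` first). Because baseline TIFF readers clamp to
#' `[0, 1]`, each page is stored affinely rescaled to that range; the per-file
#' scale and offset, together with the image metadata, go to a JSON sidecar
#' (`<path>.json`) so that `read_mm_tiff()` restores the original values.
#'
#' @param mm an [mm_image].
#' @param path output TIFF path; the sidecar is written at `<path>.json`.
#' @return `write_mm_tiff()` returns `path` invisibly; `read_mm_tiff()`
#'   returns an [mm_image].
#' @export
write_mm_tiff <- function(mm, path) {
  stopifnot(inherits(mm, "mm_image"))
  lo <- min(mm$elements); hi <- max(mm$elements)
  if (hi <= lo) hi <- lo + 1
  pages <- lapply(1:16, function(k) (mm$elements[, , k] - lo) / (hi - lo))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(format = "mmoblique-mm-image", value_offset = lo,
               value_scale = hi - lo, normalized = mm$normalized,
               incidence_theta = mm$incidence_theta,
               provenance = mm$provenance,
               channels = mm_element_names(),
               masked_pixels = which(mm$mask) - 1L)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_mm_tiff
#' @export
read_mm_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != 16L) {
    stop("expected a 16-page Mueller TIFF, found ", length(pages), " pages",
         call. = FALSE)
  }
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  lo <- meta$value_offset %||% 0
  sc <- meta$value_scale %||% 1
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  el <- array(0, c(h, w, 16))
  for (k in 1:16) el[, , k] <- pages[[k]] * sc + lo
  mask <- matrix(FALSE, h, w)
  if (length(meta$masked_pixels)) {
    mask[unlist(meta$masked_pixels) + 1L] <- TRUE
  }
  mm_image(el,
           normalized = isTRUE(meta$normalized),
           incidence_theta = as.numeric(meta$incidence_theta %||% NA_real_),
           provenance = as.character(meta$provenance %||% basename(path)),
           mask = mask)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
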