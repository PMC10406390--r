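#' Pipeline configuration
#'
#' Declares a full analysis run: where the Mueller-matrix images come from
#' (synthesized phantom, DRR frame stacks to reconstruct, or ready MM
#' images), the incidence-angle sweep, and the geometry/statistics settings
#' applied at every angle.
#'
#' @param mode `"synthetic"` (generate the phantom at each theta),
#'   `"from-frames"` (reconstruct each input frame stack) or `"from-mm"`
#'   (analyze supplied MM images).
#' @param thetas incidence angles in degrees, each in `[0, 90)`; in
#'   non-synthetic modes used to label the corresponding inputs.
#' @param inputs for the non-synthetic modes: a list, one entry per theta,
#'   each either a file path (TIFF written by [write_frames_tiff()] /
#'   [write_mm_tiff()]) or an in-memory `frame_set` / [mm_image].
#' @param phantom named list of [phantom_params()] overrides.
#' @param acquisition named list of [acquisition_config()] overrides.
#' @param ring named list of ring-sampling settings (`radius`,
#'   `half_width`, `n_samples`, `n_radial`).
#' @param stats named list of statistics settings (`prominence_fraction`,
#'   `smooth_window`, `n_bins`, `value_range`).
#' @param output_dir optional directory for the report bundle; `NULL`
#'   keeps results in memory only.
#' @param seed integer seed controlling every stochastic stage.
#' @param verbose echo every effective default at run start.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "from-frames", "from-mm"),
                            thetas = c(5, 10, 15, 20, 30, 40, 50),
                            inputs = NULL,
                            phantom = list(), acquisition = list(),
                            ring = list(), stats = list(),
                            output_dir = NULL, seed = 1L, verbose = FALSE) {
  mode <- match.arg(mode)
  if (any(thetas < 0 | thetas >= 90)) {
    stop("all thetas must lie in [0, 90) degrees", call. = FALSE)
  }
  if (mode != "synthetic") {
    if (is.null(inputs) || length(inputs) != length(thetas)) {
      stop("mode '", mode, "' needs one input per theta", call. = FALSE)
    }
    for (inp in inputs) {
      if (is.character(inp) && !file.exists(inp)) {
        stop("input path does not exist: ", inp, call. = FALSE)
      }
    }
  }
  ring <- utils::modifyList(list(radius = 200, half_width = 5,
                                 n_samples = 360L, n_radial = 11L), ring)
  stats <- utils::modifyList(list(prominence_fraction = 0.05,
                                  smooth_window = 5L, n_bins = 256L,
                                  value_range = c(-1, 1)), stats)
  structure(list(mode = mode, thetas = thetas, inputs = inputs,
                 phantom = phantom, acquisition = acquisition, ring = ring,
                 stats = stats, output_dir = output_dir,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

#' Analyze one Mueller-matrix image
#'
#' Runs the per-image analysis surface: ring-samples all 16 azimuthal
#' curves, computes mean and kurtosis, peak/valley metrics, the harmonic
#' spectrum with periodicity classification, the square-wave coefficient
#' Cs (odd harmonics designated at multiples of the element's undistorted
#' fundamental: 2 for the off-diagonal pairs, 4 for the central block),
#' and the FDH of every element.
#'
#' @param mm a normalized [mm_image].
#' @param ring,stats settings lists as in [pipeline_config()].
#' @return A list with `curves`, `spectra`, `peaks`, `fdhs` (per-element
#'   lists) and `summary`, a data.frame with one row per element
#'   (`element`, `class`, `mean`, `kurtosis`, `A1`, `A3`, `A5`, `A7`,
#'   `Cs`, `pp_mean`, `pv_mean`, `pp_gap`).
#' @export
analyze_mm_image <- function(mm, ring = list(), stats = list()) {
  cfg <- pipeline_config(mode = "synthetic", thetas = 0, ring = ring,
                         stats = stats)
  ring <- cfg$ring; stats <- cfg$stats
  curves <- extract_all_curves(mm, radius = ring$radius,
                               half_width = ring$half_width,
                               n_samples = ring$n_samples,
                               n_radial = ring$n_radial)
  fundamental <- c(m12 = 2, m21 = 2, m13 = 2, m31 = 2,
                   m22 = 4, m33 = 4, m23 = 4, m32 = 4)
  rows <- list(); spectra <- list(); peaks <- list(); fdhs <- list()
  for (nm in mm_element_names()) {
    cv <- curves[[nm]]
    spec <- harmonic_amplitudes(cv)
    spectra[[nm]] <- spec
    pk <- suppressWarnings(
      find_peaks_valleys(cv, prominence_fraction = stats$prominence_fraction,
                         smooth_window = stats$smooth_window))
    peaks[[nm]] <- pk
    fdhs[[nm]] <- compute_fdh(mm, nm, n_bins = stats$n_bins,
                              value_range = stats$value_range)
    kur <- tryCatch(curve_kurtosis(cv), error = function(e) NA_real_)
    n0 <- fundamental[nm]
    odd <- if (!is.na(n0)) spec$amplitude[n0 * c(1, 3, 5, 7)] else
      rep(NA_real_, 4)
    cs <- if (!is.na(n0)) {
      square_wave_coefficient(odd[1], odd[2], odd[3], odd[4])
    } else NA_real_
    rows[[nm]] <- data.frame(
      element = nm,
      class = classify_periodicity(spec,
                                   expected = element_expected_class(nm)),
      mean = curve_mean(cv), kurtosis = kur,
      A1 = odd[1], A3 = odd[2], A5 = odd[3], A7 = odd[4], Cs = cs,
      pp_mean = if (length(pk$pp_values)) mean(pk$pp_values) else NA_real_,
      pv_mean = if (length(pk$pv_values)) mean(pk$pv_values) else NA_real_,
      pp_gap = pk$pp_gap)
  }
  list(curves = curves, spectra = spectra, peaks = peaks, fdhs = fdhs,
       summary = do.call(rbind, c(rows, list(make.row.names = FALSE))))
}

resolve_input <- function(inp, mode) {
  if (is.character(inp)) {
    if (mode == "from-frames") read_frames_tiff(inp) else read_mm_tiff(inp)
  } else inp
}

#' Run the full oblique-incidence analysis pipeline
#'
#' For every incidence angle of the sweep, obtains a normalized MM image
#' (generated, reconstructed from frames, or supplied), analyzes it with
#' [analyze_mm_image()], and assembles a long summary table (element x
#' theta). With `output_dir` set, writes per-theta subdirectories (MM
#' TIFF + sidecar, curve CSV, spectrum CSV) plus `summary.csv` and a
#' `run_metadata.json` capturing every effective setting.
#'
#' @param config a [pipeline_config].
#' @return A list of class `pipeline_result`: `summary` (data.frame with a
#'   leading `theta_deg` column), `per_theta` (named list of
#'   [analyze_mm_image()] results), `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (config$verbose) {
    message("pipeline settings: ",
            jsonlite::toJSON(list(mode = config$mode, thetas = config$thetas,
                                  ring = config$ring, stats = config$stats,
                                  phantom = config$phantom,
                                  acquisition = config$acquisition,
                                  seed = config$seed),
                             auto_unbox = TRUE, digits = 6))
  }
  out_dir <- config$output_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  per_theta <- list(); summaries <- list()
  for (i in seq_along(config$thetas)) {
    th <- config$thetas[i]
    stage <- "input"
    mm <- tryCatch({
      if (config$mode == "synthetic") {
        pars <- do.call(phantom_params,
                        utils::modifyList(config$phantom,
                                          list(incidence_theta = th,
                                               seed = config$seed + i - 1L)))
        generate_phantom_mm(pars)
      } else {
        obj <- resolve_input(config$inputs[[i]], config$mode)
        if (config$mode == "from-frames") {
          stage <- "reconstruction"
          normalize_by_m11(reconstruct_mm(obj))
        } else {
          if (obj$normalized) obj else normalize_by_m11(obj)
        }
      }
    }, error = function(e) {
      stop("pipeline stage '", stage, "' failed at theta = ", th, " deg (",
           config$mode, "): ", conditionMessage(e), call. = FALSE)
    })
    stage <- "analysis"
    res <- tryCatch(
      analyze_mm_image(mm, ring = config$ring, stats = config$stats),
      error = function(e) {
        stop("pipeline stage 'analysis' failed at theta = ", th, " deg: ",
             conditionMessage(e), call. = FALSE)
      })
    key <- sprintf("theta_%g", th)
    per_theta[[key]] <- res
    summaries[[key]] <- cbind(theta_deg = th, res$summary)
    if (!is.null(out_dir)) {
      sub <- file.path(out_dir, key)
      dir.create(sub, showWarnings = FALSE)
      write_mm_tiff(mm, file.path(sub, "mm_image.tif"))
      write_curves_csv(res$curves, file.path(sub, "curves.csv"))
      spec_tab <- do.call(rbind, lapply(names(res$spectra), function(nm) {
        cbind(element = nm, spectrum_table(res$spectra[[nm]]))
      }))
      utils::write.csv(spec_tab, file.path(sub, "spectra.csv"),
                       row.names = FALSE)
    }
  }
  summary <- do.call(rbind, c(summaries, list(make.row.names = FALSE)))
  if (!is.null(out_dir)) {
    utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(mode = config$mode, thetas = config$thetas,
                              ring = config$ring, stats = config$stats,
                              phantom = config$phantom,
                              acquisition = config$acquisition,
                              seed = config$seed,
                              timestamp = format(Sys.time())),
                         file.path(out_dir, "run_metadata.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  structure(list(summary = summary, per_theta = per_theta, config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> mode=%s, %d thetas, %d summary rows\n",
              x$config$mode, length(x$config$thetas), nrow(x$summary)))
  invisible(x)
}
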