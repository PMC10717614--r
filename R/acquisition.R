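#' TCSPC acquisition configuration
#'
#' Describes the time-correlated single photon counting (TCSPC) acquisition
#' geometry: laser repetition rate, the measurement window it implies, the
#' number of time bins per pixel, image dimensions, detection channels and the
#' photon-count quality-control floor. The default profile is an 80 MHz
#' two-photon system recording 512 x 512 pixel images with 256 time bins over
#' the 12.5 ns inter-pulse window, NAD(P)H excited at 760 nm and FAD at
#' 800 nm, and a minimum of 1e6 photons per region of interest.
#'
#' @param repetition_rate_mhz Laser repetition rate in MHz. The measurement
#'   window is `1000 / repetition_rate_mhz` nanoseconds.
#' @param n_bins Number of time bins spanning the window (>= 2).
#' @param image_shape Integer vector `c(rows, cols)` of the image raster.
#' @param channels Character vector of detection channels.
#' @param excitation_nm Named numeric vector of excitation wavelengths (nm),
#'   one per channel.
#' @param min_peak_photons Photon-count floor used by quality control. Applied
#'   to the total ROI photon count by default (see [extract_features()]); the
#'   per-bin peak count is also reported so either reading of a "peak photon"
#'   requirement can be checked.
#'
#' @return An object of class `acquisition_config` with fields
#'   `repetition_rate_mhz`, `window` (ns), `n_bins`, `bin_width` (ns),
#'   `image_shape`, `channels`, `excitation_nm`, `min_peak_photons`.
#' @examples
#' cfg <- acquisition_config()
#' cfg$window     # 12.5 ns
#' cfg$bin_width  # 12.5 / 256 ns
#' @export
acquisition_config <- function(repetition_rate_mhz = 80,
                               n_bins = 256L,
                               image_shape = c(512L, 512L),
                               channels = c("NADPH", "FAD"),
                               excitation_nm = c(NADPH = 760, FAD = 800),
                               min_peak_photons = 1e6) {
  stopifnot(is.numeric(repetition_rate_mhz), length(repetition_rate_mhz) == 1,
            repetition_rate_mhz > 0)
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 2L) {
    stop("`n_bins` must be an integer >= 2", call. = FALSE)
  }
  image_shape <- as.integer(image_shape)
  stopifnot(length(image_shape) == 2, all(image_shape >= 1))
  window <- 1000 / repetition_rate_mhz
  structure(
    list(
      repetition_rate_mhz = repetition_rate_mhz,
      window = window,
      n_bins = n_bins,
      bin_width = window / n_bins,
      image_shape = image_shape,
      channels = channels,
      excitation_nm = excitation_nm,
      min_peak_photons = min_peak_photons
    ),
    class = "acquisition_config"
  )
}

#' @export
print.acquisition_config <- function(x, ...) {
  cat("TCSPC acquisition configuration\n")
  cat(sprintf("  repetition rate: %g MHz (window %g ns)\n",
              x$repetition_rate_mhz, x$window))
  cat(sprintf("  time bins: %d (bin width %.5f ns)\n", x$n_bins, x$bin_width))
  cat(sprintf("  image: %d x %d pixels\n", x$image_shape[1], x$image_shape[2]))
  cat(sprintf("  channels: %s\n", paste(x$channels, collapse = ", ")))
  cat(sprintf("  photon QC floor: %g\n", x$min_peak_photons))
  invisible(x)
}

#' Bin edges and centres for a configuration
#'
#' @param config An [acquisition_config()].
#' @return For `bin_edges`, a numeric vector of length `n_bins + 1` spanning
#'   `[0, window]`; for `bin_centres`, the `n_bins` midpoints.
#' @keywords internal
bin_edges <- function(config) {
  seq(0, config$window, length.out = config$n_bins + 1L)
}

#' @rdname bin_edges
#' @keywords internal
bin_centres <- function(config) {
  e <- bin_edges(config)
  (e[-1] + e[-length(e)]) / 2
}

#' Ground truth for a simulated fluorescence decay
#'
#' Parameters of the bi-exponential decay model
#' \deqn{I(t) = I(0)[\alpha_1 e^{-t/\tau_1} + \alpha_2 e^{-t/\tau_2}] + C}
#' used as the simulation ground truth. By convention `tau1` is the long
#' (protein-bound NAD(P)H) component and `tau2` the short (free) component.
#' `alpha1_frac` is the normalised amplitude fraction
#' \eqn{\alpha_1 / (\alpha_1 + \alpha_2)}; amplitudes are kept as fractions
#' summing to one, with the overall photon budget carried separately by
#' `total_photons`, so the scale degeneracy of the raw amplitudes never
#' enters.
#'
#' @param tau1 Long lifetime component (ns); must exceed `tau2`.
#' @param tau2 Short lifetime component (ns); must be positive.
#' @param alpha1_frac Amplitude fraction of the long component, in `[0, 1]`.
#' @param background_rate Expected background counts per bin (the additive
#'   constant `C` of the model). Default 0.
#' @param total_photons Expected number of signal photons (excluding
#'   background) before truncation to the measurement window.
#'
#' @return An object of class `decay_truth`.
#' @examples
#' decay_truth(tau1 = 3.0, tau2 = 0.4, alpha1_frac = 0.3, total_photons = 1e5)
#' @export
decay_truth <- function(tau1, tau2, alpha1_frac,
                        background_rate = 0, total_photons) {
  stopifnot(is.numeric(tau1), is.numeric(tau2), is.numeric(alpha1_frac))
  if (!(tau2 > 0) || !(tau1 > tau2)) {
    stop("require tau1 > tau2 > 0 (tau1 is the long, protein-bound component)",
         call. = FALSE)
  }
  if (alpha1_frac < 0 || alpha1_frac > 1) {
    stop("`alpha1_frac` must lie in [0, 1]", call. = FALSE)
  }
  if (background_rate < 0) {
    stop("`background_rate` must be non-negative", call. = FALSE)
  }
  if (!(total_photons > 0)) {
    stop("`total_photons` must be positive", call. = FALSE)
  }
  structure(
    list(tau1 = tau1, tau2 = tau2, alpha1_frac = alpha1_frac,
         background_rate = background_rate, total_photons = total_photons),
    class = "decay_truth"
  )
}

#' @export
print.decay_truth <- function(x, ...) {
  cat(sprintf(
    "decay ground truth: tau1 = %g ns, tau2 = %g ns, alpha1 = %g, C = %g/bin, N = %g photons\n",
    x$tau1, x$tau2, x$alpha1_frac, x$background_rate, x$total_photons))
  invisible(x)
}

#' Construct a decay histogram
#'
#' A decay histogram holds non-negative photon counts per time bin for one
#' ROI, pixel or channel, together with the bin centres in nanoseconds.
#'
#' @param counts Non-negative integer counts, one per bin.
#' @param bin_centres Bin centres in ns, same length as `counts`.
#' @param channel Detection channel label.
#' @param roi_id Optional ROI identifier.
#' @param truth Optional [decay_truth()] the histogram was generated from.
#' @return An object of class `decay_histogram` with `total_photons ==
#'   sum(counts)`.
#' @export
decay_histogram <- function(counts, bin_centres, channel = "NADPH",
                            roi_id = NA_character_, truth = NULL) {
  counts <- as.numeric(counts)
  if (length(counts) != length(bin_centres)) {
    stop("`counts` and `bin_centres` must have the same length", call. = FALSE)
  }
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop("counts must be finite and non-negative", call. = FALSE)
  }
  structure(
    list(counts = counts, bin_centres = as.numeric(bin_centres),
         channel = channel, roi_id = roi_id,
         total_photons = sum(counts), truth = truth),
    class = "decay_histogram"
  )
}

#' @export
print.decay_histogram <- function(x, ...) {
  cat(sprintf("decay histogram: %d bins over [%.3f, %.3f] ns, %g photons (%s)\n",
              length(x$counts), min(x$bin_centres), max(x$bin_centres),
              x$total_photons, x$channel))
  invisible(x)
}
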