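# ROI segmentation, decay aggregation, optical redox ratio and per-image
# photonic feature assembly. Pixel indices are row-major throughout; masks
# are logical matrices with the same shape as the image.

#' Segment a cellular region of interest from an intensity image
#'
#' Thresholds the intensity image to separate cells from background, removing
#' background pixels before ROI-level decay fitting. Methods: `"otsu"`
#' (Otsu's threshold via EBImage, the default), `"percentile"` (threshold at
#' an intensity quantile, `params$p`, default 0.5) and `"fixed"`
#' (`params$threshold`). All methods are deterministic; pixels strictly above
#' the threshold form the mask.
#'
#' @param image Numeric intensity matrix.
#' @param method One of `"otsu"`, `"percentile"`, `"fixed"`.
#' @param params List of method parameters.
#' @return An object of class `roi_mask`: list with the logical `mask`, the
#'   `threshold` used, and `method`/`params` provenance.
#' @export
segment_roi <- function(image, method = c("otsu", "percentile", "fixed"),
                        params = list()) {
  method <- match.arg(method)
  if (length(image) == 0) stop("empty image", call. = FALSE)
  rng <- range(image)
  if (rng[1] == rng[2]) {
    stop("no ROI found: image is uniform", call. = FALSE)
  }
  threshold <- switch(method,
    otsu = {
      scaled <- (image - rng[1]) / (rng[2] - rng[1])
      EBImage::otsu(EBImage::Image(scaled), range = c(0, 1)) *
        (rng[2] - rng[1]) + rng[1]
    },
    percentile = {
      p <- if (is.null(params$p)) 0.5 else params$p
      as.numeric(stats::quantile(image, p))
    },
    fixed = {
      if (is.null(params$threshold)) {
        stop("fixed-threshold segmentation needs `params$threshold`",
             call. = FALSE)
      }
      params$threshold
    })
  mask <- image > threshold
  if (!any(mask)) stop("no ROI found: empty foreground", call. = FALSE)
  structure(list(mask = mask, threshold = threshold,
                 method = method, params = params),
            class = "roi_mask")
}

as_mask <- function(mask) {
  if (inherits(mask, "roi_mask")) mask$mask else mask
}

#' Aggregate a decay stack over a region of interest
#'
#' Bin-wise sum of the per-pixel decays of all masked pixels, yielding the
#' ROI-level decay histogram that is the primary fit target. The histogram's
#' total photon count equals the masked intensity sum exactly, and the
#' operation is additive over disjoint masks.
#'
#' @param x A `flim_image` (from [simulate_flim_image()]), or a 3-d counts
#'   array `[rows, cols, bins]` (then `config` is required).
#' @param mask Logical matrix or `roi_mask`.
#' @param config [acquisition_config()] giving the time axis when `x` is a
#'   bare array.
#' @return A [decay_histogram()].
#' @export
aggregate_decay <- function(x, mask, config = NULL) {
  if (inherits(x, "flim_image")) {
    config <- x$config
    stack <- x$stack
    channel <- x$channel
    truth <- x$truth
  } else {
    stack <- x
    channel <- "NADPH"
    truth <- NULL
    if (is.null(config)) {
      stop("`config` is required when `x` is a bare array", call. = FALSE)
    }
  }
  mask <- as_mask(mask)
  if (!identical(dim(mask), dim(stack)[1:2])) {
    stop("mask shape does not match the decay stack", call. = FALSE)
  }
  if (!any(mask)) stop("empty mask", call. = FALSE)
  flat <- matrix(stack, nrow = prod(dim(stack)[1:2]), ncol = dim(stack)[3])
  counts <- colSums(flat[as.vector(mask), , drop = FALSE])
  decay_histogram(counts, bin_centres(config), channel = channel,
                  truth = truth)
}

#' Optical redox ratio of a FAD / NAD(P)H image pair
#'
#' `ORR = FAD / NAD(P)H`, computed as the ratio of the summed masked FAD
#' intensity to the summed masked NAD(P)H intensity (ratio of sums, not mean
#' of pixel-wise ratios: robust to zero-count pixels; the two differ and the
#' choice is recorded here). A lower ORR reads as a higher NAD(P)H pool. The
#' ratio is invariant under scaling both channels by the same constant.
#'
#' @param fad,nadph Intensity matrices of the same shape.
#' @param mask Optional logical matrix or `roi_mask`; default uses all
#'   pixels.
#' @return The ORR (unitless).
#' @examples
#' optical_redox_ratio(matrix(2, 4, 4), matrix(4, 4, 4))  # 0.5
#' @export
optical_redox_ratio <- function(fad, nadph, mask = NULL) {
  if (!identical(dim(fad), dim(nadph))) {
    stop("FAD and NAD(P)H images must have the same shape", call. = FALSE)
  }
  if (is.null(mask)) mask <- matrix(TRUE, nrow(fad), ncol(fad))
  mask <- as_mask(mask)
  denom <- sum(nadph[mask])
  if (denom <= 0) {
    stop("masked NAD(P)H intensity sum is zero; ORR undefined", call. = FALSE)
  }
  sum(fad[mask]) / denom
}

#' Extract per-image photonic feature vectors
#'
#' Runs the full ROI pipeline on each image record: segment the NAD(P)H
#' intensity image, aggregate the masked decay stack, fit the bi-exponential
#' model, derive the amplitude-weighted mean lifetime, and compute the
#' optical redox ratio with the same mask applied to the FAD channel. Images
#' whose ROI photon total falls below the QC floor or whose fit fails the
#' chi-squared acceptance are flagged (`qc_pass = FALSE` with a reason) and
#' meant to be excluded from downstream clustering; they never crash the
#' extraction.
#'
#' @param images List of records, each a list with elements `nadph` (a
#'   `flim_image`), `fad` (FAD intensity matrix), and optional `condition`
#'   and `day` labels.
#' @param segmentation Segmentation method passed to [segment_roi()].
#' @param qc_floor Minimum ROI photon total; defaults to each image's
#'   configured `min_peak_photons`.
#' @param threshold Chi-squared acceptance threshold for the decay fit.
#' @param fit_args Extra arguments passed to [fit_biexponential()].
#' @return Data frame with one row per image: `condition`, `day`, `tau_avg`,
#'   `tau1`, `tau2`, `alpha1_frac`, `nadph_intensity`, `fad_intensity`,
#'   `orr`, `chi2_reduced`, `roi_pixels`, `qc_pass`, `flag`.
#' @export
extract_features <- function(images, segmentation = "otsu", qc_floor = NULL,
                             threshold = 1.3, fit_args = list()) {
  rows <- lapply(seq_along(images), function(i) {
    rec <- images[[i]]
    out <- data.frame(
      condition = if (is.null(rec$condition)) NA_character_ else rec$condition,
      day = if (is.null(rec$day)) NA_real_ else rec$day,
      tau_avg = NA_real_, tau1 = NA_real_, tau2 = NA_real_,
      alpha1_frac = NA_real_, nadph_intensity = NA_real_,
      fad_intensity = NA_real_, orr = NA_real_, chi2_reduced = NA_real_,
      roi_pixels = NA_integer_, qc_pass = FALSE, flag = "",
      stringsAsFactors = FALSE)
    roi <- tryCatch(segment_roi(rec$nadph$intensity, method = segmentation),
                    error = function(e) e)
    if (inherits(roi, "error")) {
      out$flag <- conditionMessage(roi)
      return(out)
    }
    out$roi_pixels <- sum(roi$mask)
    hist <- aggregate_decay(rec$nadph, roi)
    out$nadph_intensity <- hist$total_photons
    out$fad_intensity <- sum(rec$fad[roi$mask])
    out$orr <- optical_redox_ratio(rec$fad, rec$nadph$intensity, roi)
    floor_i <- if (is.null(qc_floor)) rec$nadph$config$min_peak_photons
               else qc_floor
    if (hist$total_photons < floor_i) {
      out$flag <- sprintf("ROI photon total %g below QC floor %g",
                          hist$total_photons, floor_i)
      return(out)
    }
    fit <- tryCatch(
      do.call(fit_biexponential,
              c(list(hist = hist, threshold = threshold), fit_args)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      out$flag <- conditionMessage(fit)
      return(out)
    }
    out$tau1 <- fit$tau1; out$tau2 <- fit$tau2
    out$alpha1_frac <- fit$alpha1
    out$chi2_reduced <- fit$chi2_reduced
    out$tau_avg <- tau_avg(fit)
    if (!fit$accepted) {
      out$flag <- sprintf("fit rejected (chi2_red = %.3f, converged = %s)",
                          fit$chi2_reduced, fit$converged)
      return(out)
    }
    out$qc_pass <- TRUE
    out
  })
  do.call(rbind, rows)
}
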