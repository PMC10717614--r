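# Forward models for every input the pipeline consumes: TCSPC decay
# histograms and images, intensity-image pairs, microplate absorbance tables,
# qPCR Ct tables and grouped photonic feature tables. All generators take an
# integer seed and are bit-reproducible; randomness is scoped with
# withr::with_seed so the caller's RNG state is never disturbed.

#' Derive a reproducible sub-stream seed
#'
#' Mixes a global seed with an object index through a 32-bit linear
#' congruential step, so collections of objects can be generated in any order
#' (or in parallel) while each object's stream depends only on `(seed, index)`.
#'
#' @param seed Global integer seed.
#' @param index Non-negative object index.
#' @return An integer in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, index) {
  s <- (as.double(seed) %% 2147483647) + 1
  x <- (s * 48271 + as.double(index) * 69621) %% 2147483647
  as.integer(x)
}

# Photon mass per bin of the window-truncated bi-exponential mixture.
# Amplitude fractions a1, (1 - a1) weight the *intensity* amplitudes of the
# two exponentials; the photon-number weight of component i is proportional
# to alpha_i * tau_i, and the mass in bin [a, b] of a unit-mean exponential
# is exp(-a/tau) - exp(-b/tau) (exact integration, no midpoint sampling).
decay_bin_mass <- function(edges, tau1, tau2, alpha1_frac) {
  w1 <- alpha1_frac * tau1
  w2 <- (1 - alpha1_frac) * tau2
  lo <- edges[-length(edges)]
  hi <- edges[-1]
  m1 <- exp(-lo / tau1) - exp(-hi / tau1)
  m2 <- if (w2 > 0) exp(-lo / tau2) - exp(-hi / tau2) else 0
  (w1 * m1 + w2 * m2) / (w1 + w2)
}

#' Expected bin counts under the bi-exponential forward model
#'
#' The noise-free expectation of each time bin: `total_photons` distributed
#' over bins according to the exact per-bin integral of the amplitude-weighted
#' bi-exponential mixture, plus the uniform background rate. Photons falling
#' beyond the measurement window are lost, so the expected in-window signal
#' total is `total_photons` times the window mass of the mixture.
#'
#' @param truth A [decay_truth()].
#' @param config An [acquisition_config()].
#' @return Numeric vector of expected counts, one per bin.
#' @export
expected_decay_counts <- function(truth, config) {
  stopifnot(inherits(truth, "decay_truth"), inherits(config, "acquisition_config"))
  truth$total_photons *
    decay_bin_mass(bin_edges(config), truth$tau1, truth$tau2, truth$alpha1_frac) +
    truth$background_rate
}

#' Simulate a TCSPC decay histogram
#'
#' Draws independent Poisson counts per time bin with expectation given by
#' [expected_decay_counts()]: the bi-exponential mixture integrated exactly
#' over each bin plus a uniform background. The decay starts at t = 0 (the
#' peak bin); no instrument response function is convolved, so the forward
#' model is exactly the model the fitter assumes.
#'
#' @param truth A [decay_truth()].
#' @param config An [acquisition_config()]; default is the 80 MHz / 256-bin
#'   profile.
#' @param seed Integer seed; identical `(truth, config, seed)` give
#'   bit-identical histograms.
#' @param channel Channel label attached to the histogram.
#' @return A [decay_histogram()] carrying its generating `truth`.
#' @examples
#' h <- simulate_decay(decay_truth(3, 0.4, 0.3, total_photons = 1e4),
#'                     acquisition_config(), seed = 1)
#' length(h$counts)  # 256
#' @export
simulate_decay <- function(truth, config = acquisition_config(), seed = 1L,
                           channel = "NADPH") {
  stopifnot(inherits(truth, "decay_truth"), inherits(config, "acquisition_config"))
  mu <- expected_decay_counts(truth, config)
  counts <- withr::with_seed(seed, stats::rpois(config$n_bins, mu))
  decay_histogram(counts, bin_centres(config), channel = channel, truth = truth)
}

#' Simulate a FLIM image with per-pixel decay stacks
#'
#' Generates a full decay stack `counts[rows, cols, bins]` where foreground
#' (cell) pixels follow the bi-exponential `truth` at `truth$total_photons`
#' expected photons per pixel, and background pixels follow the same kinetic
#' shape at `bg_fraction` of the cell brightness. The intensity image is the
#' time-sum of the stack, so summing the stack over bins reproduces it
#' exactly, always.
#'
#' @param truth A [decay_truth()]; `total_photons` is the expected photon
#'   count per foreground pixel.
#' @param config An [acquisition_config()] whose `image_shape` sets the
#'   raster size.
#' @param seed Integer seed.
#' @param mask Logical matrix of foreground pixels matching
#'   `config$image_shape`. Default: all pixels foreground.
#' @param bg_fraction Background pixel brightness as a fraction of foreground
#'   brightness (default 0.01).
#' @param channel Channel label.
#' @return An object of class `flim_image`: list with `stack` (3-d array),
#'   `intensity` (matrix), `mask_truth`, `truth`, `config`, `channel`, `seed`.
#' @export
simulate_flim_image <- function(truth, config, seed = 1L, mask = NULL,
                                bg_fraction = 0.01, channel = "NADPH") {
  stopifnot(inherits(truth, "decay_truth"), inherits(config, "acquisition_config"))
  shp <- config$image_shape
  if (is.null(mask)) mask <- matrix(TRUE, shp[1], shp[2])
  if (!identical(dim(mask), as.integer(shp))) {
    stop(sprintf("mask shape (%s) does not match config image_shape (%s)",
                 paste(dim(mask), collapse = "x"), paste(shp, collapse = "x")),
         call. = FALSE)
  }
  mass <- decay_bin_mass(bin_edges(config), truth$tau1, truth$tau2,
                         truth$alpha1_frac)
  per_pixel <- ifelse(mask, truth$total_photons, truth$total_photons * bg_fraction)
  mu <- outer(as.vector(per_pixel), mass) +
    truth$background_rate / length(per_pixel)
  counts <- withr::with_seed(seed, stats::rpois(length(mu), mu))
  stack <- array(counts, dim = c(shp[1], shp[2], config$n_bins))
  intensity <- rowSums(stack, dims = 2)
  structure(
    list(stack = stack, intensity = intensity, mask_truth = mask,
         truth = truth, config = config, channel = channel, seed = seed),
    class = "flim_image"
  )
}

#' @export
print.flim_image <- function(x, ...) {
  cat(sprintf("FLIM image (%s): %d x %d pixels x %d bins, %g photons total\n",
              x$channel, dim(x$stack)[1], dim(x$stack)[2], dim(x$stack)[3],
              sum(x$intensity)))
  invisible(x)
}

#' Simulate a paired NAD(P)H / FAD intensity image
#'
#' Forward model of the optical redox ratio: inside the ROI, NAD(P)H pixel
#' counts are Poisson with mean `nadh_mean` and FAD pixel counts Poisson with
#' mean `orr_true * nadh_mean`, so the ratio of summed masked intensities
#' estimates `orr_true`. Pixels outside the mask are dark (zero mean).
#'
#' @param orr_true True FAD/NAD(P)H intensity ratio (>= 0).
#' @param nadh_mean Expected NAD(P)H counts per ROI pixel (> 0).
#' @param shape Integer vector `c(rows, cols)`.
#' @param seed Integer seed.
#' @param mask Logical ROI matrix; default all `TRUE`.
#' @return List with matrices `nadh`, `fad`, the `mask`, and `orr_true`.
#' @export
simulate_intensity_pair <- function(orr_true, nadh_mean, shape = c(128L, 128L),
                                    seed = 1L, mask = NULL) {
  if (orr_true < 0) stop("`orr_true` must be non-negative", call. = FALSE)
  if (!(nadh_mean > 0)) stop("`nadh_mean` must be positive", call. = FALSE)
  shape <- as.integer(shape)
  if (is.null(mask)) mask <- matrix(TRUE, shape[1], shape[2])
  n <- prod(shape)
  imgs <- withr::with_seed(seed, {
    nadh <- stats::rpois(n, ifelse(mask, nadh_mean, 0))
    fad <- stats::rpois(n, ifelse(mask, orr_true * nadh_mean, 0))
    list(nadh, fad)
  })
  list(nadh = matrix(imgs[[1]], shape[1], shape[2]),
       fad = matrix(imgs[[2]], shape[1], shape[2]),
       mask = mask, orr_true = orr_true)
}

#' Simulate a colorimetric microplate read-out with standards
#'
#' Standards and samples are generated from the same affine absorbance model
#' `reading = intercept + slope * (concentration / dilution) + noise`, with
#' i.i.d. Gaussian noise. Standards are read neat (dilution 1) at the stated
#' concentrations; each sample's dilution factor is recorded in its well row
#' so inverse regression can undo it.
#'
#' @param true_concs Numeric vector of true sample concentrations.
#' @param slope,intercept Affine absorbance response (truth).
#' @param noise_sd Gaussian reading noise SD (0 gives exact readings).
#' @param dilution Dilution factor applied to samples before reading
#'   (scalar or per-sample vector).
#' @param standards Numeric vector of standard concentrations (>= 3 values
#'   spanning the assay range).
#' @param analyte Analyte label stored per well.
#' @param seed Integer seed.
#' @return A data frame with columns `well`, `role` (`"standard"`/`"sample"`),
#'   `analyte`, `true_conc`, `dilution`, `reading`.
#' @export
simulate_assay_plate <- function(true_concs, slope, intercept, noise_sd = 0,
                                 dilution = 1,
                                 standards = seq(0, 300, length.out = 7),
                                 analyte = "glucose", seed = 1L) {
  if (length(standards) < 3) {
    stop("at least 3 standard concentrations are required", call. = FALSE)
  }
  true_concs <- as.numeric(true_concs)
  dilution <- rep_len(dilution, length(true_concs))
  conc_read <- c(standards, true_concs / dilution)
  n <- length(conc_read)
  readings <- withr::with_seed(seed,
    intercept + slope * conc_read + stats::rnorm(n, 0, noise_sd))
  data.frame(
    well = sprintf("W%02d", seq_len(n)),
    role = rep(c("standard", "sample"), c(length(standards), length(true_concs))),
    analyte = analyte,
    true_conc = c(standards, true_concs),
    dilution = c(rep(1, length(standards)), dilution),
    reading = readings,
    stringsAsFactors = FALSE
  )
}

#' Simulate a qPCR Ct table with known fold changes
#'
#' Constructs a long-format Ct table such that exact 2^-ddCt analysis of the
#' noise-free table, normalised to the reference gene and calibrated to the
#' calibrator condition, returns exactly the requested fold changes:
#' the sample condition's delta-Ct for each gene is set to
#' `calibrator_dct - log2(fold)`.
#'
#' @param fold_changes Named positive numeric vector: requested fold change
#'   per gene in `condition` relative to `calibrator`.
#' @param ref_gene_ct Ct of the reference gene (same in both conditions before
#'   noise).
#' @param calibrator_dcts Delta-Ct (gene minus reference) per gene in the
#'   calibrator condition; scalar or named vector aligned with
#'   `fold_changes`.
#' @param replicate_sd Gaussian technical-replicate noise SD on every Ct.
#' @param n_replicates Technical replicates per gene and condition.
#' @param condition,calibrator Condition labels.
#' @param ref_gene Reference gene symbol (default beta-actin).
#' @param seed Integer seed.
#' @return Long data frame with columns `sample`, `condition`, `gene`, `ct`,
#'   `replicate`, ready for [delta_delta_ct()].
#' @export
simulate_ct_table <- function(fold_changes, ref_gene_ct = 20,
                              calibrator_dcts = 6, replicate_sd = 0,
                              n_replicates = 1L, condition = "Osteo",
                              calibrator = "Xpan", ref_gene = "ACTB",
                              seed = 1L) {
  if (is.null(names(fold_changes))) {
    stop("`fold_changes` must be a named vector (one entry per gene)",
         call. = FALSE)
  }
  if (any(fold_changes <= 0)) {
    stop("fold changes must be positive", call. = FALSE)
  }
  genes <- names(fold_changes)
  calibrator_dcts <- rep_len(calibrator_dcts, length(genes))
  sample_dcts <- calibrator_dcts - log2(fold_changes)
  grid <- expand.grid(replicate = seq_len(n_replicates),
                      gene = c(ref_gene, genes),
                      condition = c(calibrator, condition),
                      stringsAsFactors = FALSE)
  ct0 <- mapply(function(g, cond) {
    if (g == ref_gene) return(ref_gene_ct)
    d <- if (cond == calibrator) calibrator_dcts[match(g, genes)]
         else sample_dcts[match(g, genes)]
    ref_gene_ct + d
  }, grid$gene, grid$condition)
  ct <- withr::with_seed(seed, ct0 + stats::rnorm(nrow(grid), 0, replicate_sd))
  data.frame(
    sample = paste0(grid$condition, "_1"),
    condition = grid$condition,
    gene = grid$gene,
    ct = ct,
    replicate = grid$replicate,
    stringsAsFactors = FALSE
  )
}

#' Study operating points for the osteogenic 2P-FLIM time course
#'
#' Per-condition, per-day means and standard deviations of the NAD(P)H
#' photonic variables (amplitude-weighted mean lifetime, protein-bound
#' lifetime, free lifetime, optical redox ratio) used as the default
#' operating points of the grouped feature simulator. Expansion-medium (Xpan)
#' cells hold a constant glycolytic profile across the two-week course;
#' osteogenic-medium (Osteo) cells shift toward oxidative phosphorylation
#' (rising tau_avg and tau1, falling ORR); lactate-supplemented osteogenic
#' medium (OsteoLact) sits between the two at day 14 with the lowest ORR. At
#' day 0 the conditions are indistinguishable.
#'
#' @return Data frame with columns `condition`, `day`, `tau_avg_mean`,
#'   `tau_avg_sd`, `tau1_mean`, `tau1_sd`, `tau2_mean`, `tau2_sd`,
#'   `orr_mean`, `orr_sd`.
#' @export
flim_study_conditions <- function() {
  df <- rbind(
    data.frame(condition = "Xpan", day = c(0, 3, 7, 14),
               tau_avg_mean = 1.097, tau_avg_sd = 0.040,
               tau1_mean = 2.683, tau1_sd = 0.027,
               orr_mean = 0.724, orr_sd = 0.020),
    data.frame(condition = "Osteo", day = c(0, 3, 7, 14),
               tau_avg_mean = c(1.097, 1.167, 1.236, 1.316),
               tau_avg_sd   = c(0.040, 0.004, 0.010, 0.011),
               tau1_mean    = c(2.683, 2.800, 2.979, 3.146),
               tau1_sd      = c(0.027, 0.039, 0.053, 0.015),
               orr_mean     = c(0.724, 0.615, 0.534, 0.585),
               orr_sd       = c(0.020, 0.021, 0.029, 0.012)),
    data.frame(condition = "OsteoLact", day = 14,
               tau_avg_mean = 1.148, tau_avg_sd = 0.005,
               tau1_mean = 3.000, tau1_sd = 0.050,
               orr_mean = 0.547, orr_sd = 0.016)
  )
  df$tau2_mean <- 0.400
  df$tau2_sd <- 0.010
  df[, c("condition", "day", "tau_avg_mean", "tau_avg_sd", "tau1_mean",
         "tau1_sd", "tau2_mean", "tau2_sd", "orr_mean", "orr_sd")]
}

#' Simulate a grouped per-image photonic feature table
#'
#' Draws per-image photonic feature vectors for each requested
#' condition-by-day operating point: `tau_avg`, `tau1`, `tau2` and `orr` are
#' Gaussian around the group means, `alpha1_frac` is derived so the
#' amplitude-weighted mean lifetime identity holds, and the FAD intensity is
#' `orr` times the NAD(P)H intensity exactly.
#'
#' @param conditions Data frame in the format of [flim_study_conditions()]
#'   (the default), optionally subset to the conditions and days wanted.
#' @param n_images Images per condition-by-day group.
#' @param nadph_mean,nadph_sd Per-image total NAD(P)H ROI intensity
#'   distribution (counts).
#' @param seed Integer seed; each group's draw uses a derived sub-stream.
#' @return Data frame with one row per image: `condition`, `day`, `image`,
#'   `tau_avg`, `tau1`, `tau2`, `alpha1_frac`, `nadph_intensity`,
#'   `fad_intensity`, `orr`.
#' @export
simulate_feature_table <- function(conditions = flim_study_conditions(),
                                   n_images = 10L,
                                   nadph_mean = 1.2e6, nadph_sd = 5e4,
                                   seed = 1L) {
  rows <- lapply(seq_len(nrow(conditions)), function(i) {
    g <- conditions[i, ]
    withr::with_seed(derive_seed(seed, i), {
      tau1 <- stats::rnorm(n_images, g$tau1_mean, g$tau1_sd)
      tau2 <- pmax(stats::rnorm(n_images, g$tau2_mean, g$tau2_sd), 0.05)
      tau_avg <- stats::rnorm(n_images, g$tau_avg_mean, g$tau_avg_sd)
      tau_avg <- pmin(pmax(tau_avg, tau2 + 1e-3), tau1 - 1e-3)
      orr <- pmax(stats::rnorm(n_images, g$orr_mean, g$orr_sd), 0)
      nadph <- pmax(stats::rnorm(n_images, nadph_mean, nadph_sd), 1)
      data.frame(
        condition = g$condition, day = g$day, image = seq_len(n_images),
        tau_avg = tau_avg, tau1 = tau1, tau2 = tau2,
        alpha1_frac = (tau_avg - tau2) / (tau1 - tau2),
        nadph_intensity = nadph, fad_intensity = orr * nadph, orr = orr,
        stringsAsFactors = FALSE
      )
    })
  })
  do.call(rbind, rows)
}
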