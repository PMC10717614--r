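# Forward-model generators: Poisson decay histograms, FLIM images,
# intensity pairs, assay plates and Ct tables.

test_that("default acquisition profile encodes the 80 MHz / 256-bin geometry", {
  cfg <- acquisition_config()
  expect_equal(cfg$window, 12.5)
  expect_equal(cfg$n_bins, 256L)
  expect_equal(cfg$bin_width, 12.5 / 256)
  expect_equal(cfg$image_shape, c(512L, 512L))
  expect_equal(cfg$min_peak_photons, 1e6)
  h <- simulate_decay(decay_truth(3, 0.4, 0.3, total_photons = 1e4),
                      cfg, seed = 1)
  expect_length(h$counts, 256)
  expect_equal(max(h$bin_centres) + cfg$bin_width / 2, 12.5)
})

test_that("ground-truth validation rejects invalid decays", {
  expect_error(decay_truth(0.4, 3, 0.3, total_photons = 1e4), "tau1 > tau2")
  expect_error(decay_truth(3, 0.4, 1.2, total_photons = 1e4), "alpha1_frac")
  expect_error(decay_truth(3, 0.4, 0.3, total_photons = 0), "positive")
  expect_error(decay_truth(3, 0.4, 0.3, background_rate = -1,
                           total_photons = 10), "non-negative")
})

test_that("empirical mean arrival time matches the analytic binned mean", {
  cfg <- acquisition_config()
  truth <- decay_truth(3.0, 0.4, 0.3, total_photons = 1e6)
  h <- simulate_decay(truth, cfg, seed = 11)
  emp_mean <- sum(h$bin_centres * h$counts) / sum(h$counts)
  ana_mean <- binned_mean_arrival(truth, cfg)
  # SE of the mean arrival time from the same histogram
  emp_var <- sum(h$counts * (h$bin_centres - emp_mean)^2) / sum(h$counts)
  se <- sqrt(emp_var / sum(h$counts))
  expect_lt(abs(emp_mean - ana_mean), 3 * se)
})

test_that("mono-exponential limit: log expected counts affine in t", {
  cfg <- toy_config()
  truth <- decay_truth(2.5, 0.4, 1, total_photons = 1e5)
  mu <- expected_decay_counts(truth, cfg)
  ctr <- (seq(0, cfg$window, length.out = cfg$n_bins + 1)[-1] -
          cfg$bin_width / 2)
  slope <- stats::coef(stats::lm(log(mu) ~ ctr))[2]
  expect_equal(unname(slope), -1 / 2.5, tolerance = 1e-10)
})

test_that("expected in-window total equals photons times truncated mass", {
  cfg <- acquisition_config()
  truth <- decay_truth(3.0, 0.4, 0.3, total_photons = 1e6)
  mu <- expected_decay_counts(truth, cfg)
  w1 <- 0.3 * 3.0; w2 <- 0.7 * 0.4
  in_window <- (w1 * (1 - exp(-12.5 / 3)) + w2 * (1 - exp(-12.5 / 0.4))) /
    (w1 + w2)
  expect_equal(sum(mu), 1e6 * in_window, tolerance = 1e-12)
})

test_that("simulators are bit-reproducible and leave the global RNG alone", {
  cfg <- toy_config()
  truth <- decay_truth(3, 0.4, 0.3, total_photons = 1e4)
  set.seed(99)
  before <- .Random.seed
  h1 <- simulate_decay(truth, cfg, seed = 7)
  expect_identical(before, .Random.seed)
  h2 <- simulate_decay(truth, cfg, seed = 7)
  expect_identical(h1$counts, h2$counts)
  i1 <- simulate_flim_image(truth, cfg, seed = 7)
  i2 <- simulate_flim_image(truth, cfg, seed = 7)
  expect_identical(i1$stack, i2$stack)
  expect_false(identical(h1$counts,
                         simulate_decay(truth, cfg, seed = 8)$counts))
})

test_that("Poisson forward model has unit index of dispersion", {
  cfg <- toy_config(n_bins = 8L)
  truth <- decay_truth(3, 0.4, 0.3, total_photons = 500)
  reps <- sapply(1:600, function(i) {
    simulate_decay(truth, cfg, seed = derive_seed(5, i))$counts
  })
  disp <- apply(reps, 1, stats::var) / rowMeans(reps)
  # each bin's dispersion ~ 1 +/- sqrt(2/599); test the average across bins
  expect_equal(mean(disp), 1, tolerance = 0.05)
})

test_that("decay stack time-sum reproduces the intensity image exactly", {
  cfg <- toy_config()
  truth <- decay_truth(3, 0.4, 0.3, total_photons = 200)
  mask <- matrix(FALSE, 16, 16); mask[5:12, 5:12] <- TRUE
  img <- simulate_flim_image(truth, cfg, seed = 3, mask = mask)
  expect_identical(rowSums(img$stack, dims = 2), img$intensity)
  # background pixels are ~1% of cell brightness
  expect_lt(mean(img$intensity[!mask]), 0.1 * mean(img$intensity[mask]))
  expect_error(simulate_flim_image(truth, cfg, mask = matrix(TRUE, 4, 4)),
               "shape")
})

test_that("intensity pair encodes the requested redox ratio", {
  pair <- simulate_intensity_pair(1, 200, shape = c(64, 64), seed = 2)
  expect_equal(sum(pair$fad) / sum(pair$nadh), 1, tolerance = 0.02)
  expect_error(simulate_intensity_pair(-1, 100), "non-negative")
  expect_error(simulate_intensity_pair(1, 0), "positive")
})

test_that("assay plate forward model inverts exactly at zero noise", {
  plate <- simulate_assay_plate(c(50, 120, 250), slope = 0.002,
                                intercept = 0.01, noise_sd = 0,
                                dilution = 1, seed = 1)
  res <- analyse_plate(plate)
  expect_equal(res$conc, c(50, 120, 250), tolerance = 1e-9)
  expect_equal(attr(res, "curve")$slope, 0.002, tolerance = 1e-12)
  expect_error(simulate_assay_plate(1, 1, 0, standards = c(0, 1)),
               "standard")
})

test_that("all-blank plate recovers concentrations near zero", {
  plate <- simulate_assay_plate(rep(0, 4), slope = 0.002, intercept = 0.01,
                                noise_sd = 1e-4, seed = 6)
  res <- analyse_plate(plate)
  expect_true(all(abs(res$conc) < 1))  # < 1 unit on a 0-300 range
})

test_that("fitted standard-curve slope is unbiased under reading noise", {
  slopes <- sapply(1:200, function(i) {
    plate <- simulate_assay_plate(numeric(0), slope = 0.002,
                                  intercept = 0.01, noise_sd = 0.005,
                                  standards = seq(0, 300, length.out = 8),
                                  seed = derive_seed(21, i))
    suppressWarnings(
      fit_standard_curve(plate$true_conc, plate$reading)$slope)
  })
  se <- stats::sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - 0.002), 3 * se)
})

test_that("Ct table round trips requested fold changes at zero noise", {
  tab <- simulate_ct_table(c(ALPL = 2.3, SPP1 = 15.47, RUNX2 = 1),
                           replicate_sd = 0, seed = 1)
  fc <- delta_delta_ct(tab)
  osteo <- fc[fc$condition == "Osteo", ]
  expect_equal(osteo$fold[osteo$gene == "ALPL"], 2.3, tolerance = 1e-9)
  expect_equal(osteo$fold[osteo$gene == "SPP1"], 15.47, tolerance = 1e-9)
  expect_equal(osteo$fold[osteo$gene == "RUNX2"], 1, tolerance = 1e-9)
  expect_error(simulate_ct_table(c(A = -2)), "positive")
  expect_error(simulate_ct_table(2), "named")
})

test_that("feature table respects its internal identities", {
  tab <- simulate_feature_table(n_images = 5, seed = 3)
  expect_equal(tab$orr, tab$fad_intensity / tab$nadph_intensity,
               tolerance = 1e-9)
  expect_equal(tab$tau_avg,
               tab$alpha1_frac * tab$tau1 + (1 - tab$alpha1_frac) * tab$tau2,
               tolerance = 1e-9)
  expect_true(all(tab$tau_avg >= tab$tau2 & tab$tau_avg <= tab$tau1))
  # group means track the requested operating points
  day14 <- tab[tab$day == 14 & tab$condition == "Osteo", ]
  expect_equal(mean(day14$tau_avg), 1.316, tolerance = 0.02)
})

test_that("decay container and intensity TIFF round trip", {
  cfg <- toy_config()
  truth <- decay_truth(3, 0.4, 0.3, total_photons = 100)
  img <- simulate_flim_image(truth, cfg, seed = 4)
  tmp <- withr::local_tempfile(fileext = ".rds")
  write_decay_container(img, tmp)
  back <- read_decay_container(tmp)
  expect_identical(back$stack, img$stack)
  expect_equal(back$truth$tau1, 3)
  tmp2 <- withr::local_tempfile(fileext = ".tif")
  write_intensity_tiff(img$intensity, tmp2)
  expect_equal(read_intensity_tiff(tmp2), img$intensity,
               ignore_attr = TRUE, tolerance = 1e-3)
})
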