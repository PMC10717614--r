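# flimredox

Metabolic profiling of differentiating mesenchymal stem cells from
two-photon fluorescence lifetime imaging (2P-FLIM) data — as a tested,
fully synthetic-data-driven analysis pipeline.

During osteogenic differentiation, stem cells shift from glycolysis toward
oxidative phosphorylation. 2P-FLIM reads that shift out label-free: the
autofluorescence decay of NAD(P)H, recorded per pixel by time-correlated
single photon counting (TCSPC), is bi-exponential,

    I(t) = I(0) [ α₁ e^(−t/τ₁) + α₂ e^(−t/τ₂) ] + C

with τ₁ the long (protein-bound) and τ₂ the short (free) NAD(P)H lifetime.
The amplitude-weighted mean lifetime

    τ_avg = (τ₁α₁ + τ₂α₂) / (α₁ + α₂)

rises with oxidative metabolism, and the optical redox ratio
ORR = FAD / NAD(P)H (intensity ratio) falls as the NAD(P)H pool grows.
This package provides, for users analysing or simulating such experiments:

- **Simulation with known ground truth**: Poisson TCSPC decay histograms
  and images (80 MHz, 12.5 ns window, 256 bins by default), intensity
  pairs with a known ORR, microplate absorbance tables, qPCR Ct tables,
  and grouped per-image feature tables at the study's printed operating
  points.
- **Decay fitting**: bounded bi-exponential fits (variable-projection
  weighted least squares seeding a Poisson maximum-likelihood refinement),
  Neyman-weighted reduced χ² with the field's χ²_red < 1.3 acceptance
  rule, and τ_avg.
- **Image metrics**: Otsu/percentile/fixed ROI segmentation, ROI decay
  aggregation, ratio-of-sums ORR, and per-image photonic feature vectors
  with QC flags.
- **Assay & expression arithmetic**: standard-curve inverse regression,
  metabolite consumption (Δ = initial − final), exogenous-lactate
  correction, alizarin-red-per-DNA, 2^−ΔΔCt fold changes normalised to
  β-actin, z-score matrices, RNA purity checks.
- **Cluster separation**: PCA with 99% covariance error ellipses,
  pooled-covariance Mahalanobis distance, two-sample Hotelling's T² with
  F-value, critical F and p-value, pairwise group reports, and a seeded
  UMAP wrapper.

## Worked example

Simulate a decay at the day-14 osteogenic operating point, fit it, and
derive the lifetime metrics:

```r
library(flimredox)

cfg   <- acquisition_config()                      # 80 MHz, 256 bins, 12.5 ns
truth <- decay_truth(tau1 = 3.146, tau2 = 0.400,
                     alpha1_frac = 0.3336, total_photons = 1e5)
fit <- fit_biexponential(simulate_decay(truth, cfg, seed = 1))
fit
#> bi-exponential fit: tau1 = 3.121 ns, tau2 = 0.391 ns, alpha1 = 0.334, C = 0.34
#>   tau_avg = 1.302 ns; chi2_red = 0.944; accepted
```

The fit recovers the generating lifetimes (τ₁ = 3.121 vs 3.146 ns true;
τ_avg = 1.302 vs 1.316 ns) from a single 10⁵-photon histogram, and its
reduced χ² of 0.944 clears the 1.3 acceptance threshold. The redox ratio
and consumption arithmetic work the same way:

```r
pair <- simulate_intensity_pair(orr_true = 0.547, nadh_mean = 100,
                                shape = c(128, 128), seed = 3)
optical_redox_ratio(pair$fad, pair$nadh)
#> [1] 0.546
metabolite_delta(2.0, 0.583)    # glutamine, mM: initial − final
#> [1] 1.417
```

Group separation on simulated day-14 feature tables (10 images per
condition; expansion medium, osteogenic medium, lactate-supplemented
osteogenic medium):

```r
feats <- simulate_feature_table(n_images = 10, seed = 1)
day14 <- feats[feats$day == 14, ]
vars  <- c("tau_avg", "tau1", "tau2", "alpha1_frac",
           "nadph_intensity", "fad_intensity", "orr")
pairwise_group_report(as.matrix(day14[, vars]), day14$condition)
#>   group1    group2 n1 n2 p mahalanobis  t2 f_value f_critical  p_value significant
#> 1   Xpan     Osteo 10 10 2        9.00 405     191       3.59 2.21e-12        TRUE
#> 2   Xpan OsteoLact 10 10 2        9.74 474     224       3.59 6.12e-13        TRUE
#> 3  Osteo OsteoLact 10 10 2        6.77 229     108       3.59 2.15e-10        TRUE
```

All three condition pairs are significantly separated (F ≫ critical F,
p < 0.05) on the first two PCA scores — at day 0 the same report returns
non-significant, reproducing the time-dependence of the metabolic shift.
The methods vignette (`vignettes/flim-metabolic-profiling.Rmd`) documents
the models, defaults and design choices in detail.

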