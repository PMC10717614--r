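Package: flimredox
Title: Metabolic Profiling of Differentiating Stem Cells from Two-Photon FLIM Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of two-photon fluorescence lifetime imaging
    (2P-FLIM) metabolic-profiling experiments on differentiating mesenchymal
    stem cells. Provides a Poisson forward model for time-correlated single
    photon counting (TCSPC) decay histograms and images, bounded weighted
    least-squares bi-exponential lifetime fitting with reduced chi-squared
    acceptance, amplitude-weighted mean lifetime and NAD(P)H/FAD optical redox
    ratio metrics, ROI segmentation and per-image photonic feature extraction,
    microplate standard-curve inverse regression with metabolite consumption
    accounting, qPCR relative quantification by the 2^-ddCt method with z-score
    matrices, and multivariate cluster-separation statistics (PCA with 99%
    covariance error ellipses, Mahalanobis distance, two-sample Hotelling's T2
    with F-value, critical F and p-value, and a UMAP embedding wrapper).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    EBImage,
    uwot,
    withr,
    tiff,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
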