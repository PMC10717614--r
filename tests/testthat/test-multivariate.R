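# PCA, confidence ellipses, Mahalanobis / Hotelling statistics, UMAP wrapper
# and the pairwise separation report.

gauss_group <- function(n, mu, sd = 1, seed = 1) {
  withr::with_seed(seed,
    matrix(stats::rnorm(n * length(mu), rep(mu, each = n), sd), nrow = n))
}

test_that("PCA concentrates collinear data on the first component", {
  set.seed(2)
  t <- rnorm(50)
  x <- cbind(t, t) + rnorm(100, sd = 1e-6)
  pc <- fit_pca(x, standardize = FALSE)
  expect_gt(pc$explained_var[1], 0.999)
})

test_that("PCA spectrum is rotation- and permutation-invariant", {
  set.seed(3)
  x <- matrix(rnorm(200), 50, 4) %*% diag(c(3, 2, 1, 0.5))
  theta <- 0.7
  R <- diag(4); R[1:2, 1:2] <- matrix(c(cos(theta), sin(theta),
                                        -sin(theta), cos(theta)), 2)
  expect_equal(fit_pca(x %*% R, standardize = FALSE)$explained_var,
               fit_pca(x, standardize = FALSE)$explained_var,
               tolerance = 1e-9)
  perm <- sample(nrow(x))
  expect_equal(fit_pca(x[perm, ], standardize = FALSE)$explained_var,
               fit_pca(x, standardize = FALSE)$explained_var,
               tolerance = 1e-12)
  expect_error(fit_pca(cbind(x, 1)), "constant")
  expect_error(fit_pca(x[1:2, ]), "3 observations")
})

test_that("separated groups separate in PCA score space", {
  x <- rbind(gauss_group(20, c(0, 0, 0, 0), seed = 4),
             gauss_group(20, c(4, 4, 0, 0), seed = 5))
  pc <- fit_pca(x, n_components = 2, standardize = FALSE)
  d <- sqrt(sum((colMeans(pc$scores[1:20, ]) -
                 colMeans(pc$scores[21:40, ]))^2))
  within <- mean(apply(pc$scores[1:20, ], 2, sd))
  expect_gt(d, 2 * within)
})

test_that("99% ellipse semi-axes approach sqrt(qchisq(.99, 2)) for unit isotropic data", {
  x <- gauss_group(20000, c(0, 0), sd = 1, seed = 6)
  el <- covariance_ellipse(x, level = 0.99)
  expect_equal(unname(el$semi_axes), rep(sqrt(qchisq(0.99, 2)), 2),
               tolerance = 0.03)
  expect_false(el$degenerate)
})

test_that("ellipse is rotation-equivariant and flags collinear input", {
  x <- gauss_group(500, c(1, 2), sd = 1, seed = 7) %*% diag(c(3, 1))
  th <- pi / 6
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  e1 <- covariance_ellipse(x)
  e2 <- covariance_ellipse(x %*% t(R))
  expect_equal(e2$semi_axes, e1$semi_axes, tolerance = 1e-9)
  ang <- (e2$angle - e1$angle) %% pi
  expect_equal(min(ang, pi - ang), th, tolerance = 1e-6)
  line <- cbind(1:10, 2 * (1:10))
  expect_true(covariance_ellipse(line)$degenerate)
  expect_error(covariance_ellipse(x[1:2, ]), "3 points")
  expect_error(covariance_ellipse(x, level = 1), "level")
})

test_that("empirical coverage of the 99% ellipse is calibrated", {
  x <- gauss_group(10000, c(0, 0), sd = 1, seed = 8) %*%
    matrix(c(2, 0.5, 0.5, 1), 2)
  el <- covariance_ellipse(x, level = 0.99)
  S <- stats::cov(x)
  d2 <- stats::mahalanobis(x, colMeans(x), S)
  coverage <- mean(d2 <= stats::qchisq(0.99, 2))
  expect_gte(coverage, 0.985)
  expect_lte(coverage, 0.995)
  # the ellipse outline itself sits at that quantile
  pts <- ellipse_outline(el, 64)
  expect_equal(unname(stats::mahalanobis(pts, el$centre, S)),
               rep(stats::qchisq(0.99, 2), 64), tolerance = 0.01)
})

test_that("Mahalanobis distance: closed forms and affine invariance", {
  g <- gauss_group(30, c(0, 0, 0), seed = 9)
  expect_equal(mahalanobis_distance(g, g), 0, tolerance = 1e-12)
  # identity covariance: equals Euclidean distance of means
  mu <- c(2, -1)
  n <- 4000
  g1 <- gauss_group(n, c(0, 0), seed = 10)
  g2 <- gauss_group(n, mu, seed = 11)
  expect_equal(mahalanobis_distance(g1, g2),
               sqrt(sum((colMeans(g1) - colMeans(g2))^2)), tolerance = 0.03)
  expect_equal(mahalanobis_distance(g1, g2), mahalanobis_distance(g2, g1))
  # affine invariance under a shared invertible map
  A <- matrix(c(2, 0.3, -0.5, 1.4), 2)
  b <- c(5, -2)
  t1 <- sweep(g1 %*% t(A), 2, b, `+`)
  t2 <- sweep(g2 %*% t(A), 2, b, `+`)
  expect_equal(mahalanobis_distance(t1, t2), mahalanobis_distance(g1, g2),
               tolerance = 1e-8)
  expect_error(mahalanobis_distance(g1[1:2, 1, drop = FALSE], g1),
               "same features")
  expect_error(mahalanobis_distance(gauss_group(2, c(0, 0, 0), seed = 1),
                                    gauss_group(2, c(0, 0, 0), seed = 2)),
               "invertible")
})

test_that("Hotelling T2: identities, t-test reduction and affine invariance", {
  g1 <- gauss_group(12, c(0, 0, 0, 0), seed = 12)
  same <- hotelling_t2(g1, g1)
  expect_equal(same$t2, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1)
  expect_false(same$significant)
  # exact relation between T2 and the Mahalanobis distance
  g2 <- gauss_group(9, c(1, 0.5, 0, -0.5), seed = 13)
  h <- hotelling_t2(g1, g2)
  expect_equal(h$t2, (12 * 9 / 21) * h$mahalanobis^2, tolerance = 1e-12)
  expect_equal(h$significant, h$p_value < 0.05)
  expect_equal(h$significant, h$f_value > h$f_critical)
  # p = 1 reduces to the squared equal-variance two-sample t statistic
  a <- matrix(c(1.2, 2.1, 0.7), ncol = 1)
  b <- matrix(c(3.4, 2.8, 3.9), ncol = 1)
  hu <- hotelling_t2(a, b)
  tt <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(hu$t2, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(hu$p_value, tt$p.value, tolerance = 1e-10)
  # identical F under a shared affine transformation
  A <- matrix(rnorm(16), 4); A <- A + 4 * diag(4)
  b0 <- rnorm(4)
  h2 <- hotelling_t2(sweep(g1 %*% A, 2, b0, `+`),
                     sweep(g2 %*% A, 2, b0, `+`))
  expect_equal(h2$f_value, h$f_value, tolerance = 1e-8)
  expect_error(hotelling_t2(g1[1:2, ], g2[1:2, ]), "insufficient|invertible")
})

test_that("UMAP wrapper is seeded-deterministic and separates clear groups", {
  x <- rbind(gauss_group(25, c(0, 0, 0, 0), sd = 0.5, seed = 14),
             gauss_group(25, c(8, 8, 8, 8), sd = 0.5, seed = 15))
  e1 <- umap_embed(x, seed = 42)
  e2 <- umap_embed(x, seed = 42)
  expect_identical(e1, e2)
  labels <- rep(1:2, each = 25)
  sil <- cluster::silhouette(labels, stats::dist(e1))
  expect_gt(mean(sil[, "sil_width"]), 0.5)
  expect_error(umap_embed(x[1:10, ], n_neighbors = 15), "observations")
})

test_that("pairwise report enumerates pairs and respects small-group rule", {
  x <- rbind(gauss_group(8, c(0, 0), seed = 16),
             gauss_group(8, c(5, 0), seed = 17),
             gauss_group(8, c(0, 5), seed = 18),
             gauss_group(2, c(9, 9), seed = 19))
  groups <- rep(c("A", "B", "C", "tiny"), c(8, 8, 8, 2))
  expect_message(rep_tab <- pairwise_group_report(x, groups, space = "raw"),
                 "tiny")
  expect_equal(nrow(rep_tab), 3)   # 3 usable groups -> 3 pairs
  expect_true(all(rep_tab$significant))
  expect_equal(rep_tab$t2,
               rep_tab$n1 * rep_tab$n2 / (rep_tab$n1 + rep_tab$n2) *
                 rep_tab$mahalanobis^2, tolerance = 1e-12)
})

test_that("pairwise report has power against a 3-sigma mean shift", {
  hits <- sapply(1:100, function(i) {
    x <- rbind(gauss_group(10, c(0, 0, 0, 0), seed = derive_seed(500, i)),
               gauss_group(10, c(3, 0, 0, 0), seed = derive_seed(501, i)))
    pairwise_group_report(x, rep(c("a", "b"), each = 10),
                          space = "raw")$significant
  })
  expect_gte(mean(hits), 0.9)
})

test_that("duplicated group under two labels is usually non-significant", {
  hits <- sapply(1:200, function(i) {
    x <- rbind(gauss_group(10, c(0, 0, 0, 0), seed = derive_seed(600, i)),
               gauss_group(10, c(0, 0, 0, 0), seed = derive_seed(601, i)))
    pairwise_group_report(x, rep(c("a", "b"), each = 10),
                          space = "raw")$significant
  })
  expect_gte(mean(!hits), 0.94)
})
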