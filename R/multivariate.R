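# Multivariate cluster-separation statistics for per-image photonic feature
# vectors and per-sample gene panels: PCA with covariance error ellipses,
# Mahalanobis distance between group centroids, the two-sample Hotelling T2
# test with its F conversion, and a thin UMAP wrapper.

#' Principal component analysis of a feature matrix
#'
#' Centred (and by default standardised) PCA via the singular value
#' decomposition. Features such as lifetimes (ns) and intensities (counts)
#' are on incommensurate scales, so standardisation is on by default.
#' Component signs are fixed by convention (the largest-magnitude loading of
#' each component is positive) so results are fully deterministic.
#'
#' @param x Numeric matrix or data frame, observations in rows (>= 3, no
#'   missing values).
#' @param n_components Number of components to keep (default: all).
#' @param standardize Scale features to unit variance before PCA (default
#'   `TRUE`).
#' @return An object of class `pca_model`: `means`, `sds`, `loadings`
#'   (orthonormal columns), `scores`, `explained_var` (fractions of total
#'   variance, over all components), `standardize`.
#' @export
fit_pca <- function(x, n_components = NULL, standardize = TRUE) {
  x <- as.matrix(x)
  if (nrow(x) < 3) stop("PCA needs at least 3 observations", call. = FALSE)
  if (anyNA(x)) stop("missing values in feature matrix", call. = FALSE)
  if (standardize && any(apply(x, 2, stats::sd) == 0)) {
    bad <- colnames(x)[apply(x, 2, stats::sd) == 0]
    stop(sprintf("constant feature(s) cannot be standardised: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = standardize)
  # sign convention: largest-magnitude loading of each component positive
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  pc$rotation <- sweep(pc$rotation, 2, flip, `*`)
  pc$x <- sweep(pc$x, 2, flip, `*`)
  k <- if (is.null(n_components)) ncol(pc$rotation)
       else min(n_components, ncol(pc$rotation))
  structure(
    list(means = pc$center,
         sds = if (standardize) pc$scale else rep(1, ncol(x)),
         loadings = pc$rotation[, seq_len(k), drop = FALSE],
         scores = pc$x[, seq_len(k), drop = FALSE],
         explained_var = pc$sdev^2 / sum(pc$sdev^2),
         standardize = standardize),
    class = "pca_model"
  )
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("PCA model: %d components kept of %d\n",
              ncol(x$scores), length(x$explained_var)))
  cat("  explained variance:",
      paste0(sprintf("%.1f%%", 100 * x$explained_var[seq_len(ncol(x$scores))]),
             collapse = ", "), "\n")
  invisible(x)
}

#' Covariance error ellipse of a 2-d point cloud
#'
#' The confidence ellipse of a bivariate Gaussian estimated from the group's
#' scores: semi-axes are `sqrt(eigenvalue * qchisq(level, df = 2))` along the
#' covariance eigenvectors, centred on the group mean. At the default 99%
#' level the isotropic unit-variance semi-axis is `sqrt(9.2103) ~ 3.035`.
#'
#' @param scores Two-column matrix of group scores (>= 3 points).
#' @param level Confidence level in (0, 1), default 0.99.
#' @return An object of class `confidence_ellipse`: `centre`, `semi_axes`
#'   (major, minor), `angle` (radians, orientation of the major axis),
#'   `level`, `degenerate` flag (collinear scores).
#' @export
covariance_ellipse <- function(scores, level = 0.99) {
  scores <- as.matrix(scores)
  if (ncol(scores) != 2) stop("`scores` must have 2 columns", call. = FALSE)
  if (nrow(scores) < 3) stop("need at least 3 points", call. = FALSE)
  if (level <= 0 || level >= 1) stop("`level` must be in (0, 1)", call. = FALSE)
  ctr <- colMeans(scores)
  S <- stats::cov(scores)
  eg <- eigen(S, symmetric = TRUE)
  degenerate <- eg$values[2] <= .Machine$double.eps * max(eg$values[1], 1)
  q <- stats::qchisq(level, df = 2)
  structure(
    list(centre = ctr,
         semi_axes = sqrt(pmax(eg$values, 0) * q),
         angle = atan2(eg$vectors[2, 1], eg$vectors[1, 1]),
         level = level, degenerate = degenerate),
    class = "confidence_ellipse"
  )
}

#' Points of a confidence ellipse outline
#'
#' @param ellipse A [covariance_ellipse()] result.
#' @param n Number of outline points.
#' @return An `n x 2` matrix tracing the ellipse, for plotting over PCA
#'   scores.
#' @export
ellipse_outline <- function(ellipse, n = 100) {
  stopifnot(inherits(ellipse, "confidence_ellipse"))
  t <- seq(0, 2 * pi, length.out = n)
  circ <- cbind(ellipse$semi_axes[1] * cos(t), ellipse$semi_axes[2] * sin(t))
  rot <- matrix(c(cos(ellipse$angle), sin(ellipse$angle),
                  -sin(ellipse$angle), cos(ellipse$angle)), 2, 2)
  sweep(circ %*% t(rot), 2, ellipse$centre, `+`)
}

pooled_covariance <- function(g1, g2) {
  n1 <- nrow(g1); n2 <- nrow(g2)
  ((n1 - 1) * stats::cov(g1) + (n2 - 1) * stats::cov(g2)) / (n1 + n2 - 2)
}

#' Mahalanobis distance between two group centroids
#'
#' `sqrt((m1 - m2)' S^-1 (m1 - m2))` with `S` the pooled within-group
#' covariance (equal-covariance assumption of the classical two-sample
#' Hotelling formulation). Symmetric in the groups and invariant under any
#' common invertible affine map of both groups.
#'
#' @param group1,group2 Numeric matrices with the same columns, observations
#'   in rows; `n1 + n2 - 2` must exceed the dimension.
#' @return The Mahalanobis distance (>= 0).
#' @export
mahalanobis_distance <- function(group1, group2) {
  g1 <- as.matrix(group1); g2 <- as.matrix(group2)
  if (ncol(g1) != ncol(g2)) {
    stop("groups must share the same features", call. = FALSE)
  }
  p <- ncol(g1)
  if (nrow(g1) + nrow(g2) - 2 <= p) {
    stop("pooled covariance is not invertible: n1 + n2 - 2 must exceed p",
         call. = FALSE)
  }
  S <- pooled_covariance(g1, g2)
  Sinv <- tryCatch(solve(S), error = function(e) {
    v <- diag(S)
    stop(sprintf(
      "singular pooled covariance; near-constant or collinear feature(s): %s",
      paste(colnames(g1)[v <= .Machine$double.eps * max(v)], collapse = ", ")),
      call. = FALSE)
  })
  d <- colMeans(g1) - colMeans(g2)
  sqrt(drop(t(d) %*% Sinv %*% d))
}

#' Two-sample Hotelling T2 test
#'
#' `T2 = (n1 n2 / (n1 + n2)) * D^2` with `D` the pooled-covariance
#' Mahalanobis distance between centroids, converted to
#' `F = T2 (n1 + n2 - p - 1) / (p (n1 + n2 - 2))` on `(p, n1 + n2 - p - 1)`
#' degrees of freedom. The group pair is declared significantly separated
#' when the F-value exceeds the critical F at `alpha` (equivalently p-value
#' < alpha).
#'
#' @param group1,group2 Numeric matrices, observations in rows.
#' @param alpha Significance level (default 0.05).
#' @return An object of class `cluster_separation`: `n1`, `n2`, `p`,
#'   `mahalanobis`, `t2`, `f_value`, `f_critical`, `p_value`, `significant`.
#' @export
hotelling_t2 <- function(group1, group2, alpha = 0.05) {
  g1 <- as.matrix(group1); g2 <- as.matrix(group2)
  n1 <- nrow(g1); n2 <- nrow(g2); p <- ncol(g1)
  if (n1 + n2 - p - 1 < 1) {
    stop("insufficient observations for the Hotelling F conversion",
         call. = FALSE)
  }
  D <- mahalanobis_distance(g1, g2)
  t2 <- (n1 * n2 / (n1 + n2)) * D^2
  df2 <- n1 + n2 - p - 1
  f_value <- t2 * df2 / (p * (n1 + n2 - 2))
  f_critical <- stats::qf(1 - alpha, p, df2)
  p_value <- stats::pf(f_value, p, df2, lower.tail = FALSE)
  structure(
    list(n1 = n1, n2 = n2, p = p, mahalanobis = D, t2 = t2,
         f_value = f_value, f_critical = f_critical, p_value = p_value,
         alpha = alpha, significant = f_value > f_critical),
    class = "cluster_separation"
  )
}

#' @export
print.cluster_separation <- function(x, ...) {
  cat(sprintf(
    "Hotelling T2: D = %.3f, T2 = %.3f, F(%d, %d) = %.3f (crit %.3f), p = %.3g -> %s\n",
    x$mahalanobis, x$t2, x$p, x$n1 + x$n2 - x$p - 1, x$f_value, x$f_critical,
    x$p_value, if (x$significant) "separated" else "not separated"))
  invisible(x)
}

#' UMAP embedding of a feature matrix
#'
#' Thin, seeded wrapper around `uwot::umap` for 2-d visualisation of the
#' photonic feature space. Single-threaded so a fixed seed gives an
#' identical embedding across runs. No geometry guarantee is claimed for a
#' single homogeneous group.
#'
#' @param x Feature matrix (>= `n_neighbors + 1` observations).
#' @param n_neighbors,min_dist Standard UMAP controls (defaults 15, 0.1).
#' @param seed Integer seed (default 42).
#' @return `n x 2` matrix of embedding coordinates.
#' @export
umap_embed <- function(x, n_neighbors = 15, min_dist = 0.1, seed = 42L) {
  x <- as.matrix(x)
  if (nrow(x) < n_neighbors + 1) {
    stop("need at least n_neighbors + 1 observations", call. = FALSE)
  }
  withr::with_seed(seed,
    uwot::umap(x, n_neighbors = n_neighbors, min_dist = min_dist,
               n_threads = 1, n_sgd_threads = 1, batch = TRUE))
}

#' Pairwise cluster-separation report
#'
#' Runs the two-sample Hotelling T2 test for every unordered pair of groups,
#' by default on the first two PCA scores of the standardised feature matrix
#' (matching the plotted error ellipses); `space = "raw"` tests the raw
#' features. Groups with fewer than 3 observations are skipped with a
#' message. No multiple-testing correction is applied by default (raw
#' p-values are reported); `bonferroni = TRUE` adjusts the significance
#' threshold by the number of pairs.
#'
#' @param x Feature matrix, observations in rows.
#' @param groups Group label per observation.
#' @param alpha Significance level (default 0.05).
#' @param space `"pca"` (default) or `"raw"`.
#' @param n_components PCA components used when `space = "pca"` (default 2).
#' @param bonferroni Divide `alpha` by the number of pairs (default `FALSE`).
#' @return Data frame with one row per pair: `group1`, `group2`, `n1`, `n2`,
#'   `p`, `mahalanobis`, `t2`, `f_value`, `f_critical`, `p_value`,
#'   `significant`.
#' @export
pairwise_group_report <- function(x, groups, alpha = 0.05,
                                  space = c("pca", "raw"), n_components = 2,
                                  bonferroni = FALSE) {
  space <- match.arg(space)
  x <- as.matrix(x)
  groups <- as.character(groups)
  stopifnot(nrow(x) == length(groups))
  lev <- unique(groups)
  sizes <- table(groups)
  small <- names(sizes)[sizes < 3]
  if (length(small) > 0) {
    message("skipping group(s) with n < 3: ", paste(small, collapse = ", "))
    lev <- setdiff(lev, small)
  }
  if (length(lev) < 2) stop("need at least 2 usable groups", call. = FALSE)
  feat <- if (space == "pca") {
    fit_pca(x, n_components = n_components, standardize = TRUE)$scores
  } else x
  pairs <- utils::combn(lev, 2)
  a <- if (bonferroni) alpha / ncol(pairs) else alpha
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    g1 <- feat[groups == pairs[1, j], , drop = FALSE]
    g2 <- feat[groups == pairs[2, j], , drop = FALSE]
    h <- hotelling_t2(g1, g2, alpha = a)
    data.frame(group1 = pairs[1, j], group2 = pairs[2, j],
               n1 = h$n1, n2 = h$n2, p = h$p,
               mahalanobis = h$mahalanobis, t2 = h$t2,
               f_value = h$f_value, f_critical = h$f_critical,
               p_value = h$p_value, significant = h$significant,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
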