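# Independent oracles used across the suite. These deliberately avoid the
# package's optimisation path: the grid-search oracle profiles the linear
# parameters in closed form and scans the nonlinear ones on a grid before a
# Nelder-Mead polish, and the arrival-time oracle evaluates the binned
# mixture mean analytically.

# Small acquisition profile for fast tests.
toy_config <- function(n_bins = 64L, shape = c(16L, 16L)) {
  acquisition_config(n_bins = n_bins, image_shape = shape,
                     min_peak_photons = 1)
}

# Analytic mean photon arrival time of the *binned* truncated mixture:
# sum(centre * mass) / sum(mass) over the window. Matches what the empirical
# mean of simulated bin centres estimates.
binned_mean_arrival <- function(truth, config) {
  e <- seq(0, config$window, length.out = config$n_bins + 1)
  ctr <- (e[-1] + e[-length(e)]) / 2
  w1 <- truth$alpha1_frac * truth$tau1
  w2 <- (1 - truth$alpha1_frac) * truth$tau2
  m <- w1 * (exp(-e[-length(e)] / truth$tau1) - exp(-e[-1] / truth$tau1)) +
       w2 * (exp(-e[-length(e)] / truth$tau2) - exp(-e[-1] / truth$tau2))
  sum(ctr * m) / sum(m)
}

# Weighted SSE of a candidate (tau1, tau2, a1) with the linear parameters
# (N, C) profiled out by weighted linear least squares.
profiled_wsse <- function(counts, edges, tau1, tau2, a1) {
  m1 <- exp(-edges[-length(edges)] / tau1) - exp(-edges[-1] / tau1)
  m2 <- exp(-edges[-length(edges)] / tau2) - exp(-edges[-1] / tau2)
  w1 <- a1 * tau1; w2 <- (1 - a1) * tau2
  mass <- (w1 * m1 + w2 * m2) / (w1 + w2)
  w <- 1 / pmax(counts, 1)
  X <- cbind(mass, 1)
  beta <- stats::lm.wfit(X, counts, w)$coefficients
  beta[is.na(beta)] <- 0
  # respect N >= 0, C >= 0: re-solve on the boundary when a constraint binds
  if (beta[2] < 0) {
    beta[2] <- 0
    beta[1] <- max(sum(w * mass * counts) / sum(w * mass^2), 0)
  } else if (beta[1] < 0) {
    beta[1] <- 0
    beta[2] <- max(sum(w * counts) / sum(w), 0)
  }
  resid <- counts - X %*% beta
  list(wsse = sum(w * resid^2), N = beta[1], C = beta[2])
}

# Grid search over (tau1, tau2, a1) with profiled linear parameters,
# followed by a Nelder-Mead refinement. Independent of minpack.lm.
grid_search_fit <- function(hist) {
  counts <- hist$counts
  peak <- which.max(counts)
  obs <- counts[peak:length(counts)]
  width <- diff(hist$bin_centres[1:2])
  edges <- (seq_len(length(obs) + 1) - 1) * width
  grid <- expand.grid(tau1 = seq(1.2, 5.5, by = 0.25),
                      tau2 = seq(0.12, 0.95, by = 0.08),
                      a1 = seq(0.05, 0.95, by = 0.1))
  wsse <- mapply(function(t1, t2, a1) {
    profiled_wsse(obs, edges, t1, t2, a1)$wsse
  }, grid$tau1, grid$tau2, grid$a1)
  best <- grid[which.min(wsse), ]
  obj <- function(p) {
    if (p[1] <= p[2] || p[2] <= 0.05 || p[3] < 0 || p[3] > 1) return(1e12)
    profiled_wsse(obs, edges, p[1], p[2], p[3])$wsse
  }
  opt <- stats::optim(c(best$tau1, best$tau2, best$a1), obj,
                      control = list(maxit = 2000, reltol = 1e-12))
  lin <- profiled_wsse(obs, edges, opt$par[1], opt$par[2], opt$par[3])
  list(tau1 = opt$par[1], tau2 = opt$par[2], alpha1 = opt$par[3],
       N = lin$N, C = lin$C, wsse = opt$value)
}

# Weighted SSE of a package fit on its own fit range, for oracle comparison.
package_fit_wsse <- function(fit) {
  sum((fit$observed - fit$expected)^2 / pmax(fit$observed, 1))
}
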