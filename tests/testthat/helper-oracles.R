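# Independent oracles and small fixture builders shared across tests.

# Truncated power series for the modified Bessel function I0, independent of
# the package's log-domain evaluation path.
bessel_i0_series <- function(x, terms = 60) {
  k <- 0:terms
  sum((x / 2)^(2 * k) / factorial(k)^2)
}

# Draw measured distances for a true separation r with per-axis error sigma
# (definition of the Rice distribution, independent of the package).
draw_rice <- function(n, r, sigma) {
  sqrt((r + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2)
}

# Build a list of separation measurements from measured distances.
make_measurements <- function(d, sigma, r_max = 60, grid_n = 1200) {
  sigma <- rep_len(sigma, length(d))
  lapply(seq_along(d), function(i) {
    separation_posterior(d[i], sigma[i], r_max = r_max, grid_n = grid_n,
                         complex_id = i)
  })
}

# Pooled distribution of a synthetic species mixture observed with
# localization error sigma (measurement-level closed loop, no imaging).
make_mixture_dist <- function(separations, weights, n, sigma = 1.5,
                              max_ci_width = 10, seed = 1) {
  set.seed(seed)
  k <- sample.int(length(weights), n, replace = TRUE, prob = weights)
  d <- vapply(k, function(j) draw_rice(1, separations[j], sigma), numeric(1))
  dist <- compile_distribution(make_measurements(d, sigma), max_ci_width)
  attr(dist, "species") <- k
  dist
}

# Ground-truth two-emitter complex at a given separation with randomized
# orientation and sub-pixel placement, default acquisition settings.
random_pair_truth <- function(separation_nm, photons = 10000,
                              bleach_frames = c(9, 17), fwhm = 300) {
  theta <- runif(1, 0, 2 * pi)
  ctr <- c(700, 700) + runif(2, -50, 50)
  half <- separation_nm / 2 * c(cos(theta), sin(theta))
  emitter_pair_truth(rbind(ctr + half, ctr - half), photons, bleach_frames,
                     fwhm)
}

# Brute-force conditioning oracle for the separation posterior: sample true
# separations uniformly, push them through the Rice measurement model, and
# keep those measured within +/- eps of d.  Returns bin probabilities on
# `breaks`.
brute_force_posterior <- function(d, sigma, breaks, r_max = 60,
                                  n_draws = 4e6, eps = 0.15, chunks = 3) {
  counts <- numeric(length(breaks) - 1)
  for (ch in seq_len(chunks)) {
    r <- runif(n_draws, 0, r_max)
    d_meas <- sqrt((r + rnorm(n_draws, 0, sigma))^2 +
                     rnorm(n_draws, 0, sigma)^2)
    keep <- abs(d_meas - d) < eps
    counts <- counts + hist(r[keep], breaks = breaks, plot = FALSE)$counts
  }
  counts / sum(counts)
}

# Bin a normalized posterior onto the same breaks (trapezoid-free: fine grid
# sums are adequate at 1200 points).
bin_posterior <- function(m, breaks) {
  w <- diff(m$r[1:2])
  p <- m$posterior * w
  idx <- cut(m$r, breaks = breaks, include.lowest = TRUE)
  v <- tapply(p, idx, sum, default = 0)
  v <- as.numeric(v)
  v[is.na(v)] <- 0
  v / sum(v)
}
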