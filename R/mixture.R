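# Pooled separation distributions: compilation, Rician mixture decomposition
# with BIC model selection, bias-region reporting and population fractions.

#' Compile a pooled distribution of filtered separation measurements
#'
#' Retains the measurements whose 69% interval width passes the resolution
#' filter and sums their unit-normalized posteriors on the common grid.  The
#' summed curve integrates to the number of retained measurements; it is the
#' display form of the pooled distribution, while the mixture decomposition
#' operates on the point estimates `(d_i, sigma_i)`.
#'
#' @param measurements List of `separation_measurement` objects sharing one
#'   posterior grid.
#' @param max_ci_width_nm Resolution threshold, nm (strict `<`).
#' @return An object of class `flimp_distribution` with `measurements`,
#'   `d_nm`, `sigma_nm`, `grid`, `curve` and `n`.
#' @export
compile_distribution <- function(measurements, max_ci_width_nm) {
  stopifnot(length(measurements) >= 1, max_ci_width_nm >= 0)
  pass <- vapply(measurements, passes_resolution_filter, logical(1),
                 max_ci_width_nm = max_ci_width_nm)
  if (!any(pass)) {
    stop(sprintf("no measurement passes the resolution filter: 0 of %d below %.2f nm",
                 length(measurements), max_ci_width_nm))
  }
  kept <- measurements[pass]
  grid <- kept[[1]]$r
  for (m in kept) {
    if (!isTRUE(all.equal(m$r, grid))) {
      stop("measurements must share a common posterior grid")
    }
  }
  curve <- Reduce(`+`, lapply(kept, `[[`, "posterior"))
  structure(list(
    measurements = kept,
    d_nm = vapply(kept, `[[`, numeric(1), "d_nm"),
    sigma_nm = vapply(kept, `[[`, numeric(1), "sigma_nm"),
    ci = t(vapply(kept, `[[`, numeric(2), "ci69")),
    grid = grid, curve = curve, n = length(kept),
    max_ci_width_nm = max_ci_width_nm
  ), class = "flimp_distribution")
}

#' @export
print.flimp_distribution <- function(x, ...) {
  cat(sprintf("pooled separation distribution: %d measurements (CI width < %.2f nm)\n",
              x$n, x$max_ci_width_nm))
  invisible(x)
}

# log-sum-exp over matrix rows
row_logsumexp <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

# log Rice density matrix: rows = measurements, cols = component positions
rice_logf_matrix <- function(d, sigma, positions) {
  vapply(positions, function(r) rice_likelihood(d, r, sigma, log = TRUE),
         numeric(length(d)))
}

# ratio I1/I0 with scaled Bessels; matched asymptotic expansions for x > 100
# (relative error ~1e-11, far cheaper than besselI)
bessel_ratio_10 <- function(x) {
  out <- numeric(length(x))
  big <- x > 100
  mid <- x > 0 & !big
  if (any(mid)) {
    out[mid] <- besselI(x[mid], 1, expon.scaled = TRUE) /
      besselI(x[mid], 0, expon.scaled = TRUE)
  }
  if (any(big)) {
    u <- 1 / (8 * x[big])
    num <- 1 + u * (-3 + u * (-7.5 + u * (-52.5 + u * -590.625)))
    den <- 1 + u * (1 + u * (4.5 + u * (37.5 + u * 459.375)))
    out[big] <- num / den
  }
  out
}

# One EM pass at fixed K from given initial positions/weights; per-component
# Rice scale is the measurement's own sigma_i (measurement-error mixture).
em_rician <- function(d, sigma, positions, weights, r_max, max_iter = 300,
                      tol = 1e-7) {
  n <- length(d)
  K <- length(positions)
  logf <- rice_logf_matrix(d, sigma, positions)
  ll <- sum(row_logsumexp(sweep(logf, 2, log(weights), `+`)))
  ll_trace <- ll
  prec <- 1 / sigma^2
  for (iter in seq_len(max_iter)) {
    lw <- sweep(logf, 2, log(weights), `+`)
    gamma <- exp(lw - row_logsumexp(lw))
    w_new <- pmax(colMeans(gamma), 1e-12)
    w_new <- w_new / sum(w_new)
    # weighted Rician ML fixed point for each position
    pos_new <- positions
    for (k in seq_len(K)) {
      b <- bessel_ratio_10(d * positions[k] * prec)
      pos_new[k] <- sum(gamma[, k] * d * b * prec) / sum(gamma[, k] * prec)
    }
    logf_new <- rice_logf_matrix(d, sigma, pos_new)
    ll_new <- sum(row_logsumexp(sweep(logf_new, 2, log(w_new), `+`)))
    if (ll_new < ll - 1e-10) {
      # fixed point overshoot: exact M-step by 1D maximization (monotone EM)
      for (k in seq_len(K)) {
        qk <- function(r) sum(gamma[, k] * rice_likelihood(d, r, sigma, log = TRUE))
        pos_new[k] <- stats::optimize(qk, c(0, r_max), maximum = TRUE,
                                      tol = 1e-6)$maximum
      }
      logf_new <- rice_logf_matrix(d, sigma, pos_new)
      ll_new <- sum(row_logsumexp(sweep(logf_new, 2, log(w_new), `+`)))
    }
    converged <- abs(ll_new - ll) < tol * (1 + abs(ll))
    positions <- pos_new
    weights <- w_new
    logf <- logf_new
    ll <- ll_new
    ll_trace <- c(ll_trace, ll)
    if (converged) break
  }
  list(positions = positions, weights = weights, logL = ll,
       converged = iter < max_iter || converged, n_iter = iter,
       logL_trace = ll_trace)
}

#' Fit a Rician mixture to a pooled separation distribution
#'
#' Maximizes `sum_i log sum_k w_k Rice(d_i | r_k, sigma_i)` over component
#' positions and weights by expectation-maximization.  Each measurement
#' contributes with its own localization error `sigma_i` as the Rice scale
#' (the component widths are measurement-limited; no extra per-component
#' width parameter).  EM is restarted from `n_starts` initializations
#' (positions at jittered quantiles of the measured separations) and the
#' best log-likelihood is kept.
#'
#' @param dist A [compile_distribution()] result.
#' @param K Number of components (`>= 1`, with `n >= 2 K`).
#' @param n_starts Number of EM multi-starts.  Default 20.
#' @param max_iter,tol EM stopping parameters.
#' @param seed Integer seed for the initialization jitter.
#' @return An object of class `rician_mixture`: `K`, ascending `positions`,
#'   matching `weights`, `logL`, `bic` (`(2K-1) ln n - 2 logL`), `converged`,
#'   and the per-iteration `logL_trace` of the winning start.
#' @export
fit_rician_mixture <- function(dist, K, n_starts = 20, max_iter = 300,
                               tol = 1e-8, seed = 1) {
  stopifnot(inherits(dist, "flimp_distribution"), K >= 1)
  n <- dist$n
  if (n < 2 * K) stop("need n >= 2 K measurements to fit K components")
  d <- dist$d_nm
  sigma <- dist$sigma_nm
  r_max <- max(dist$grid)
  qs <- stats::quantile(d, probs = (seq_len(K) - 0.5) / K, names = FALSE)
  jitter_sd <- max(diff(range(d)) / (4 * K), 0.1)
  best <- NULL
  with_seed(seed, {
    for (s in seq_len(n_starts)) {
      pos0 <- qs
      if (s > 1) pos0 <- pmax(qs + stats::rnorm(K, 0, jitter_sd), 0.01)
      fit <- em_rician(d, sigma, pos0, rep(1 / K, K), r_max,
                       max_iter = max_iter, tol = tol)
      if (is.null(best) || fit$logL > best$logL) best <- fit
    }
  })
  ord <- order(best$positions)
  structure(list(
    K = K,
    positions = best$positions[ord],
    weights = best$weights[ord],
    logL = best$logL,
    bic = (2 * K - 1) * log(n) - 2 * best$logL,
    converged = best$converged,
    n_iter = best$n_iter,
    logL_trace = best$logL_trace,
    n = n
  ), class = "rician_mixture")
}

#' @export
print.rician_mixture <- function(x, ...) {
  cat(sprintf("Rician mixture: K = %d, logL = %.2f, BIC = %.2f\n",
              x$K, x$logL, x$bic))
  for (k in seq_len(x$K)) {
    cat(sprintf("  component %d: position %.2f nm, weight %.3f\n",
                k, x$positions[k], x$weights[k]))
  }
  invisible(x)
}

#' Select the number of Rician components by BIC
#'
#' Fits mixtures with `K = 1 .. K_max` (capped at `n / 2`) and returns the
#' model minimizing `BIC = (2K - 1) ln n - 2 logL` (K positions and K - 1
#' free weights).  Ties are broken toward smaller K.
#'
#' @inheritParams fit_rician_mixture
#' @param K_max Largest K considered.  Default 8.
#' @return The minimum-BIC `rician_mixture`, with the full BIC table in
#'   `$bic_table`.
#' @export
select_K_by_bic <- function(dist, K_max = 8, n_starts = 20, seed = 1, ...) {
  stopifnot(inherits(dist, "flimp_distribution"))
  if (dist$n < 4) stop("need at least 4 measurements for model selection")
  K_hi <- min(K_max, floor(dist$n / 2))
  fits <- lapply(seq_len(K_hi), function(K) {
    fit_rician_mixture(dist, K, n_starts = n_starts, seed = seed + K, ...)
  })
  bics <- vapply(fits, `[[`, numeric(1), "bic")
  best_k <- which(bics <= min(bics) + 1e-9)[1]  # ties toward smaller K
  out <- fits[[best_k]]
  out$bic_table <- data.frame(K = seq_len(K_hi), bic = bics,
                              logL = vapply(fits, `[[`, numeric(1), "logL"))
  out
}

#' Bootstrap confidence intervals for mixture component positions
#'
#' Nonparametric bootstrap: measurements are resampled with replacement and
#' the mixture refitted at fixed K; component identity is matched by
#' ascending position order.  Percentile intervals are reported at the 69%
#' level by default, matching the per-measurement precision convention, and
#' are asymmetric like the underlying Rice posteriors.
#'
#' @inheritParams fit_rician_mixture
#' @param model The fitted `rician_mixture` whose components are bootstrapped.
#' @param B Bootstrap resamples.  Default 250.
#' @param level Central percentile level.  Default 0.69.
#' @param n_starts EM multi-starts per resample (fewer than the main fit;
#'   each refit starts near the full-data solution).
#' @return Matrix `K x 2` of interval bounds (nm).
#' @export
bootstrap_mixture_positions <- function(dist, model, B = 250, level = 0.69,
                                        n_starts = 3, seed = 1) {
  stopifnot(inherits(dist, "flimp_distribution"),
            inherits(model, "rician_mixture"))
  K <- model$K
  d <- dist$d_nm
  sigma <- dist$sigma_nm
  r_max <- max(dist$grid)
  pos_mat <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(length(d), replace = TRUE)
      best <- NULL
      for (s in seq_len(n_starts)) {
        pos0 <- model$positions
        if (s > 1) pos0 <- pmax(pos0 + stats::rnorm(K, 0, 0.5), 0.01)
        fit <- em_rician(d[idx], sigma[idx], pos0, model$weights, r_max,
                         max_iter = 200)
        if (is.null(best) || fit$logL > best$logL) best <- fit
      }
      sort(best$positions)
    }, numeric(K))
  })
  pos_mat <- matrix(pos_mat, nrow = K)
  lo <- (1 - level) / 2
  t(apply(pos_mat, 1, stats::quantile, probs = c(lo, 1 - lo), names = FALSE))
}

#' Report mixture components with the bias-region rule
#'
#' Separations comparable to or below the measurement resolution (the 0-6.5
#' nm bias region by default) have best-fit peak positions subject to the
#' upward small-separation bias of the Rice distribution; for components
#' whose position confidence interval intersects that region only the
#' interval is quoted, never the best-fit position.  Other components are
#' reported with their position and asymmetric bootstrap interval.  Setting
#' `bias_limit_nm = 0` disables suppression.
#'
#' @param model A fitted `rician_mixture`.
#' @param dist The distribution it was fitted to; required for bootstrap
#'   intervals (omit to report without intervals).
#' @param bias_limit_nm Upper edge of the bias region, nm.  Default 6.5.
#' @param resolution_nm Nominal measurement resolution, nm (annotation only).
#' @param B,level,seed Bootstrap parameters, see
#'   [bootstrap_mixture_positions()].
#' @return A data frame with one row per component: `component`, `weight`,
#'   `position_nm` (`NA` where suppressed), `ci_low_nm`, `ci_high_nm`,
#'   `interval_only`.
#' @export
bias_region_report <- function(model, dist = NULL, bias_limit_nm = 6.5,
                               resolution_nm = 4.8, B = 250, level = 0.69,
                               seed = 1) {
  stopifnot(inherits(model, "rician_mixture"))
  if (!is.null(dist)) {
    ci <- bootstrap_mixture_positions(dist, model, B = B, level = level,
                                      seed = seed)
  } else {
    ci <- cbind(model$positions, model$positions)
  }
  suppress <- if (bias_limit_nm <= 0) {
    rep(FALSE, model$K)
  } else {
    ci[, 1] <= bias_limit_nm  # CI intersects [0, bias_limit]
  }
  out <- data.frame(
    component = seq_len(model$K),
    weight = model$weights,
    position_nm = ifelse(suppress, NA_real_, model$positions),
    ci_low_nm = ci[, 1],
    ci_high_nm = ci[, 2],
    interval_only = suppress
  )
  attr(out, "bias_limit_nm") <- bias_limit_nm
  attr(out, "resolution_nm") <- resolution_nm
  out
}

interval_overlaps <- function(ci, low, high) ci[, 1] <= high & ci[, 2] >= low

fraction_estimate <- function(label, fraction, n_num, n_den,
                              bootstrap_sd = NA_real_, B = 0L) {
  structure(list(label = label, fraction = fraction, n_numerator = n_num,
                 n_denominator = n_den, bootstrap_sd = bootstrap_sd, B = B),
            class = "fraction_estimate")
}

#' @export
print.fraction_estimate <- function(x, ...) {
  cat(sprintf("fraction '%s': %.3f (%d / %d)%s\n", x$label, x$fraction,
              x$n_numerator, x$n_denominator,
              if (x$B > 0) sprintf(", bootstrap sd %.3f (B = %d)",
                                   x$bootstrap_sd, x$B) else ""))
  invisible(x)
}

#' Population fraction of a species by the integral-area rule
#'
#' Each retained measurement contributes one unit of integral area.  The
#' species fraction is the ratio of the area of measurements whose 69%
#' interval overlaps the target species interval to the area of measurements
#' whose interval overlaps the reference region (the 0-20.1 nm dimer-tetramer
#' region by convention).  Overlap means non-empty intersection of closed
#' intervals, so one measurement may contribute to several species
#' numerators.
#'
#' @param dist A [compile_distribution()] result.
#' @param target Target [species_interval()] (e.g. `expected_interval("dimer")`).
#' @param region Reference [species_interval()] for the denominator.
#' @return A `fraction_estimate` (no bootstrap error; see
#'   [bootstrap_fraction()]).
#' @export
species_fraction <- function(dist, target, region) {
  stopifnot(inherits(dist, "flimp_distribution"),
            inherits(target, "species_interval"),
            inherits(region, "species_interval"))
  num <- interval_overlaps(dist$ci, target$low_nm, target$high_nm)
  den <- interval_overlaps(dist$ci, region$low_nm, region$high_nm)
  if (sum(den) == 0) {
    warning("no measurement overlaps the reference region; fraction undefined")
    return(fraction_estimate(target$label, NaN, sum(num), 0L))
  }
  fraction_estimate(target$label, sum(num) / sum(den), sum(num), sum(den))
}

#' Bootstrap error of a species fraction
#'
#' Resamples the retained measurements with replacement `B` times (1,000 by
#' convention), recomputes the fraction in each replicate, and reports the
#' standard deviation of the replicates as the error.
#'
#' @inheritParams species_fraction
#' @param B Bootstrap resamples.  Default 1000.
#' @param seed Integer seed.
#' @return A `fraction_estimate` with `bootstrap_sd` filled in.
#' @export
bootstrap_fraction <- function(dist, target, region, B = 1000, seed = 1) {
  stopifnot(B >= 100)
  est <- species_fraction(dist, target, region)
  num <- interval_overlaps(dist$ci, target$low_nm, target$high_nm)
  den <- interval_overlaps(dist$ci, region$low_nm, region$high_nm)
  fracs <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(dist$n, replace = TRUE)
      nd <- sum(den[idx])
      if (nd == 0) NA_real_ else sum(num[idx]) / nd
    }, numeric(1))
  })
  est$bootstrap_sd <- stats::sd(fracs, na.rm = TRUE)
  est$B <- as.integer(B)
  est
}

#' Fractions below and above a separation cut
#'
#' Splits the retained measurements by whether their 69% interval overlaps
#' the range below the cut (`[0, cut]`, the dimer/tetramer range for the
#' 20.1 nm convention) or above it (`[cut, r_max]`), relative to all retained
#' measurements.  A measurement straddling the cut contributes to both
#' numerators, so the two fractions may sum to more than 1.
#'
#' @param dist A [compile_distribution()] result.
#' @param cut_nm The separation cut, nm.  Default 20.1.
#' @return A list with `fraction_estimate`s `below` and `above`.
#' @export
tail_fraction <- function(dist, cut_nm = 20.1) {
  stopifnot(inherits(dist, "flimp_distribution"), cut_nm > 0)
  r_max <- max(dist$grid)
  below <- interval_overlaps(dist$ci, 0, cut_nm)
  above <- interval_overlaps(dist$ci, cut_nm, r_max)
  list(
    below = fraction_estimate(sprintf("below %.1f nm", cut_nm),
                              mean(below), sum(below), dist$n),
    above = fraction_estimate(sprintf("above %.1f nm", cut_nm),
                              mean(above), sum(above), dist$n)
  )
}
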