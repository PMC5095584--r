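# Two-emitter localization: spot detection, intensity traces, bleaching-step
# segmentation and the global seven-parameter PSF fit.

# Separable Gaussian blur with replicate edge padding.
gaussian_blur <- function(img, sigma) {
  radius <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-radius:radius, 0, sigma)
  k <- k / sum(k)
  conv_axis <- function(m) {
    padded <- m[c(rep(1L, radius), seq_len(nrow(m)), rep(nrow(m), radius)), ,
                drop = FALSE]
    out <- apply(padded, 2, function(col) stats::filter(col, k, sides = 2))
    out[radius + seq_len(nrow(m)), , drop = FALSE]
  }
  t(conv_axis(t(conv_axis(img))))
}

#' Detect diffraction-limited spot candidates in a frame
#'
#' Band-pass filters the image (difference of Gaussians), then keeps local
#' maxima whose filtered amplitude exceeds `min_snr` times a robust noise
#' scale, applying greedy non-maximum suppression at radius `min_sep_px`.
#'
#' @param frame Numeric matrix (one image frame).
#' @param min_snr Minimum peak amplitude in units of the robust noise level
#'   of the band-passed image.
#' @param min_sep_px Minimum centre-to-centre candidate distance, pixels.
#' @param sigma_small,sigma_large Band-pass Gaussian widths, pixels.
#' @return A data frame with 0-based pixel coordinates `x_px`, `y_px` (column
#'   and row of the candidate maximum) and its band-passed amplitude `value`,
#'   ordered by decreasing amplitude.  Empty for a blank frame.
#' @export
detect_spots <- function(frame, min_snr = 5, min_sep_px = 5,
                         sigma_small = 1, sigma_large = 3) {
  stopifnot(is.matrix(frame))
  if (!all(is.finite(frame))) stop("frame must be finite-valued")
  bp <- gaussian_blur(frame, sigma_small) - gaussian_blur(frame, sigma_large)
  noise <- stats::mad(bp)
  thr <- max(min_snr * noise, .Machine$double.eps)
  ny <- nrow(bp); nx <- ncol(bp)
  empty <- data.frame(x_px = numeric(0), y_px = numeric(0),
                      value = numeric(0))
  if (ny < 3 || nx < 3) return(empty)
  core <- bp[2:(ny - 1), 2:(nx - 1)]
  is_max <- core > thr
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    is_max <- is_max & (core >= bp[2:(ny - 1) + dy, 2:(nx - 1) + dx])
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0) return(empty)
  cand <- data.frame(x_px = idx[, 2], y_px = idx[, 1],  # back to full-image,
                     value = core[idx])                 # 0-based coordinates
  cand <- cand[order(-cand$value), , drop = FALSE]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (i == 1) { keep[1] <- TRUE; next }
    d2 <- (cand$x_px[keep] - cand$x_px[i])^2 + (cand$y_px[keep] - cand$y_px[i])^2
    keep[i] <- all(d2 >= min_sep_px^2)
  }
  rownames(cand) <- NULL
  cand[keep, , drop = FALSE]
}

#' Extract an intensity time course for one spot
#'
#' Per frame, sums the background-subtracted counts within a disc of
#' `radius_px` around the spot and records the intensity-weighted centroid of
#' the (non-negative) background-subtracted counts in that disc.  The
#' per-frame background level is the median of the pixels outside the disc.
#'
#' @param stack Numeric array `ny x nx x n_frames`.
#' @param spot List or one-row data frame with 0-based `x_px`, `y_px`.
#' @param radius_px Integration radius, pixels.
#' @param complex_id Optional identifier.
#' @return An object of class `intensity_trace` with `frames`, `intensities`
#'   and an `n_frames x 2` matrix `centroids` (0-based pixel coordinates).
#' @export
extract_trace <- function(stack, spot, radius_px = 4, complex_id = NA) {
  stopifnot(length(dim(stack)) == 3)
  ny <- dim(stack)[1]; nx <- dim(stack)[2]; nt <- dim(stack)[3]
  cx <- spot$x_px; cy <- spot$y_px
  if (cx - radius_px < 0 || cx + radius_px > nx - 1 ||
      cy - radius_px < 0 || cy + radius_px > ny - 1) {
    stop("spot too close to the image edge for the requested radius")
  }
  xs <- matrix(rep(0:(nx - 1), each = ny), ny, nx)
  ys <- matrix(rep(0:(ny - 1), nx), ny, nx)
  disc <- (xs - cx)^2 + (ys - cy)^2 <= radius_px^2
  n_in <- sum(disc)
  intens <- numeric(nt)
  cents <- matrix(NA_real_, nt, 2)
  for (t in seq_len(nt)) {
    f <- stack[, , t]
    bg <- stats::median(f[!disc])
    sub <- f - bg
    intens[t] <- sum(sub[disc])
    pos <- pmax(sub, 0) * disc
    tot <- sum(pos)
    if (tot > 0) cents[t, ] <- c(sum(pos * xs), sum(pos * ys)) / tot
  }
  structure(list(complex_id = complex_id, frames = seq_len(nt),
                 intensities = intens, centroids = cents, n_px = n_in,
                 spot = c(x_px = cx, y_px = cy), radius_px = radius_px),
            class = "intensity_trace")
}

# Best single split of x[a:b] by squared-error cost; returns the split point
# (last index of the left segment) and the cost reduction.
best_split <- function(x, a, b) {
  n <- b - a + 1
  if (n < 2) return(list(gain = -Inf, split = NA))
  seg <- x[a:b]
  cs <- cumsum(seg)
  cs2 <- cumsum(seg^2)
  tot <- cs2[n] - cs[n]^2 / n
  i <- seq_len(n - 1)
  left <- cs2[i] - cs[i]^2 / i
  right <- (cs2[n] - cs2[i]) - (cs[n] - cs[i])^2 / (n - i)
  gain <- tot - (left + right)
  k <- which.max(gain)
  list(gain = gain[k], split = a + k - 1)
}

#' Segment an intensity trace into photobleaching steps
#'
#' Piecewise-constant segmentation by binary least-squares change-point
#' detection with penalty `2 ln(n) sigma^2` per change point (`sigma` is a
#' robust noise estimate from first differences).  A usable two-emitter trace
#' must decay to zero; if more than two downward steps occur, only the lowest
#' two non-zero levels are analysed, mapping to the two-emitter and
#' one-emitter segments of the seven-parameter fit.  Traces with fewer than
#' two resolvable bleaching steps are rejected (flagged, not an error):
#' they signal single fluorophores or incomplete bleaching.
#'
#' @param trace An [extract_trace()] result (needs `>= 10` frames).
#' @param penalty Optional penalty override.
#' @return An object of class `step_segmentation`: `change_points` (last
#'   frame of each segment but the final), `levels`, `n_steps` (number of
#'   downward bleaching steps to zero), `accepted`, `reason`, and the frame
#'   ranges `two_seg` / `one_seg` of the retained segments.
#' @export
detect_steps <- function(trace, penalty = NULL) {
  x <- trace$intensities
  n <- length(x)
  if (n < 10) stop("trace must have at least 10 frames")
  # photon noise is heteroscedastic (variance grows with the level), so the
  # change-point search runs on the variance-stabilizing square root
  y <- sqrt(pmax(x, 0))
  dy <- diff(y)
  sigma_y <- stats::mad(dy) / sqrt(2)
  if (sigma_y == 0) sigma_y <- stats::sd(dy) / sqrt(2)
  if (is.na(sigma_y) || sigma_y == 0) sigma_y <- 1e-8
  if (is.null(penalty)) penalty <- 2 * log(n) * sigma_y^2
  bounds <- c(0L, n)  # segment boundaries (index of last point per segment)
  repeat {
    found <- FALSE
    segs <- cbind(utils::head(bounds, -1) + 1L, utils::tail(bounds, -1))
    for (s in seq_len(nrow(segs))) {
      bs <- best_split(y, segs[s, 1], segs[s, 2])
      if (is.finite(bs$gain) && bs$gain > penalty) {
        bounds <- sort(unique(c(bounds, bs$split)))
        found <- TRUE
        break
      }
    }
    if (!found) break
  }
  starts <- utils::head(bounds, -1) + 1L
  ends <- utils::tail(bounds, -1)
  # merge adjacent segments whose raw-scale means are statistically
  # indistinguishable (spurious splits from the greedy search)
  repeat {
    if (length(starts) == 1) break
    means <- mapply(function(a, b) mean(x[a:b]), starts, ends)
    lens <- ends - starts + 1
    vars <- mapply(function(a, b) {
      if (b > a) stats::var(x[a:b]) else NA_real_
    }, starts, ends)
    vars[is.na(vars)] <- max(vars, 1, na.rm = TRUE)
    se <- sqrt(vars[-length(vars)] / lens[-length(lens)] +
                 vars[-1] / lens[-1])
    z <- abs(diff(means)) / pmax(se, 1e-12)
    j <- which.min(z)
    if (z[j] >= 4) break
    starts <- starts[-(j + 1)]
    ends <- ends[-j]
  }
  levels <- mapply(function(a, b) mean(x[a:b]), starts, ends)
  sigma <- stats::mad(diff(x)) / sqrt(2)  # raw-scale noise, for thresholds
  if (is.na(sigma) || sigma == 0) sigma <- 1e-8
  change_points <- utils::head(ends, -1)
  zero_thr <- max(3 * sigma, 0.05 * max(levels, 0))
  nonzero <- which(levels > zero_thr)
  out <- list(change_points = change_points, levels = levels,
              starts = starts, ends = ends, noise_sd = sigma,
              zero_threshold = zero_thr, n_steps = NA_integer_,
              accepted = FALSE, reason = NULL, two_seg = NULL, one_seg = NULL)
  class(out) <- "step_segmentation"
  if (length(levels) == 1 || length(nonzero) == 0) {
    out$reason <- "no bleaching step found"
    return(out)
  }
  if (levels[length(levels)] > zero_thr) {
    out$reason <- "trace does not decay to zero"
    return(out)
  }
  if (length(nonzero) < 2) {
    out$reason <- "only one non-zero level (single emitter)"
    return(out)
  }
  # lowest two non-zero levels = the last two non-zero segments
  one_i <- nonzero[length(nonzero)]
  two_i <- nonzero[length(nonzero) - 1]
  if (levels[two_i] <= levels[one_i]) {
    out$reason <- "retained levels not decreasing"
    return(out)
  }
  # two similar-brightness fluorophores: the two-emitter level must be about
  # twice the one-emitter level, or the segmentation is inconsistent with a
  # single-fluorophore bleaching step
  ratio <- levels[two_i] / levels[one_i]
  if (ratio < 4 / 3 || ratio > 4) {
    out$reason <- "level ratio inconsistent with a single-fluorophore step"
    return(out)
  }
  out$n_steps <- length(nonzero)
  out$accepted <- TRUE
  out$two_seg <- c(starts[two_i], ends[two_i])
  out$one_seg <- c(starts[one_i], ends[one_i])
  out
}

# Integrated-Gaussian spot image in pixel units (pixel size 1, centres at
# 0 .. n-1); used by the fit objective.
spot_image_px <- function(x, y, photons, sigma, nx, ny) {
  px <- stats::pnorm(seq(-0.5, nx - 0.5), mean = x, sd = sigma)
  py <- stats::pnorm(seq(-0.5, ny - 0.5), mean = y, sd = sigma)
  photons * tcrossprod(py[-1] - py[-(ny + 1)], px[-1] - px[-(nx + 1)])
}

# Background estimate: median of the border pixels of an image.
border_median <- function(img) {
  ny <- nrow(img); nx <- ncol(img)
  stats::median(c(img[1, ], img[ny, ], img[, 1], img[, nx]))
}

# Intensity-weighted centroid of a (background-subtracted) image, 0-based px.
image_centroid <- function(img) {
  pos <- pmax(img, 0)
  tot <- sum(pos)
  xs <- rep(0:(ncol(img) - 1), each = nrow(img))
  ys <- rep(0:(nrow(img) - 1), ncol(img))
  c(sum(pos * xs), sum(pos * ys)) / tot
}

# Core least-squares fit of the segment-mean images A (two emitters) and B
# (surviving emitter) with shared FWHM and shared I2; returns parameters in
# pixel units.
fit_two_emitter_images <- function(A, B, init) {
  ny <- nrow(A); nx <- ncol(A)
  resid <- function(p) {
    sig <- fwhm_to_sigma(p[7])
    g2 <- spot_image_px(p[4], p[5], 1, sig, nx, ny)
    mA <- p[3] * spot_image_px(p[1], p[2], 1, sig, nx, ny) + p[6] * g2
    c(A - mA, B - p[6] * g2)
  }
  lower <- c(-2, -2, 1e-6, -2, -2, 1e-6, 0.8)
  upper <- c(nx + 1, ny + 1, Inf, nx + 1, ny + 1, Inf, max(nx, ny))
  fit <- minpack.lm::nls.lm(init, lower = lower, upper = upper, fn = resid,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ptol = 1e-10, ftol = 1e-10))
  list(par = unname(fit$par), value = fit$deviance,
       converged = fit$info %in% 1:4)
}

# Full estimation path from raw segment-mean images: border-median
# background subtraction, moment-based initialization, then the joint
# seven-parameter least-squares fit.  Shared by the main fit and the
# parametric bootstrap so the error estimate reflects the whole path.
fit_two_emitter_raw <- function(A_raw, B_raw) {
  bgA <- border_median(A_raw); bgB <- border_median(B_raw)
  A <- A_raw - bgA; B <- B_raw - bgB
  ny <- nrow(A); nx <- ncol(A)
  c2 <- image_centroid(B)
  I2_0 <- max(sum(B), 1e-3)
  xs <- rep(0:(nx - 1), each = ny); ys <- rep(0:(ny - 1), nx)
  posB <- pmax(B, 0)
  varB <- sum(posB * ((xs - c2[1])^2 + (ys - c2[2])^2)) / (2 * sum(posB))
  fwhm0 <- 2 * sqrt(2 * log(2)) * sqrt(max(varB, 0.4))
  resid <- pmax(A - spot_image_px(c2[1], c2[2], I2_0,
                                  fwhm_to_sigma(fwhm0), nx, ny), 0)
  c1 <- if (sum(resid) > 0) image_centroid(resid) else c2 + 0.5
  I1_0 <- max(sum(A) - I2_0, 1e-3)
  init <- c(c1[1], c1[2], I1_0, c2[1], c2[2], I2_0, fwhm0)
  fit <- fit_two_emitter_images(A, B, init)
  fit$bgA <- bgA
  fit$bgB <- bgB
  fit
}

#' Global seven-parameter two-emitter fit
#'
#' Jointly fits the mean image of the two-emitter segment (sum of two
#' integrated Gaussians) and the mean image of the one-emitter segment (a
#' single Gaussian at the surviving emitter's position) by least squares,
#' with seven free parameters: `x1, y1, I1, x2, y2, I2` and a shared FWHM.
#' The surviving emitter is emitter 2 by construction -- its identity is
#' fixed by the one-emitter segment, following the centroid-shift logic of
#' stepwise photobleaching, not by intensity ordering.  Per-emitter
#' localization errors are estimated by parametric bootstrap: the fitted
#' model images are re-noised according to the camera model (scaled for the
#' number of averaged frames) and refitted `n_boot` times.
#'
#' @param stack Image stack (counts), as from [render_spot_stack()].
#' @param segmentation An accepted [detect_steps()] result.
#' @param camera The [camera_model()].
#' @param n_boot Bootstrap refits for the localization errors (`>= 100`
#'   recommended; `0` skips the error estimate).
#' @param seed Optional integer seed for the bootstrap.
#' @return An object of class `two_emitter_fit` with positions and FWHM in
#'   nm, intensities in counts per frame, per-emitter per-axis localization
#'   errors `sigma1_nm`, `sigma2_nm`, and `converged` / `degenerate` flags.
#'   Degenerate fits (separation below 0.1 px) are flagged for exclusion.
#' @export
fit_two_emitters <- function(stack, segmentation, camera, n_boot = 100,
                             seed = NULL) {
  stopifnot(inherits(segmentation, "step_segmentation"),
            inherits(camera, "camera_model"))
  if (!segmentation$accepted) {
    stop("segmentation was rejected: ", segmentation$reason)
  }
  two_f <- segmentation$two_seg[1]:segmentation$two_seg[2]
  one_f <- segmentation$one_seg[1]:segmentation$one_seg[2]
  A_raw <- apply(stack[, , two_f, drop = FALSE], c(1, 2), mean)
  B_raw <- apply(stack[, , one_f, drop = FALSE], c(1, 2), mean)
  fit <- fit_two_emitter_raw(A_raw, B_raw)
  p <- fit$par
  bgA <- fit$bgA; bgB <- fit$bgB
  ny <- nrow(A_raw); nx <- ncol(A_raw)
  sep_px <- sqrt((p[1] - p[4])^2 + (p[2] - p[5])^2)
  degenerate <- sep_px < 0.1
  sigma1 <- sigma2 <- NA_real_
  if (n_boot > 0 && fit$converged && !degenerate) {
    sig <- fwhm_to_sigma(p[7])
    g1 <- spot_image_px(p[1], p[2], p[3], sig, nx, ny)
    g2 <- spot_image_px(p[4], p[5], p[6], sig, nx, ny)
    A_hat <- g1 + g2; B_hat <- g2
    # per-pixel noise sd of an n-frame mean image under the camera model
    noise_sd <- function(model, bg, n) {
      mu <- pmax(model + bg, 0) / camera$gain  # photons
      shot_var <- mu * camera$gain^2 * (1 + camera$excess_noise)
      sqrt((shot_var + camera$read_noise_e^2) / n)
    }
    sdA <- noise_sd(A_hat, bgA, length(two_f))
    sdB <- noise_sd(B_hat, bgB, length(one_f))
    # replay the full estimation path (background estimate, moment
    # initialization, fit) on re-noised raw model images
    boot <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        Ab <- A_hat + bgA + stats::rnorm(length(A_hat), 0, sdA)
        Bb <- B_hat + bgB + stats::rnorm(length(B_hat), 0, sdB)
        fb <- fit_two_emitter_raw(Ab, Bb)
        fb$par[c(1, 2, 4, 5)]
      }, numeric(4))
    })
    v1 <- (stats::var(boot[1, ]) + stats::var(boot[2, ])) / 2
    v2 <- (stats::var(boot[3, ]) + stats::var(boot[4, ])) / 2
    # the joint fit anti-correlates the two position estimates; absorb the
    # covariance so that sigma1^2 + sigma2^2 equals the per-axis variance of
    # the separation vector (the Rice scale propagated downstream)
    cv <- (stats::cov(boot[1, ], boot[3, ]) +
             stats::cov(boot[2, ], boot[4, ])) / 2
    sigma1 <- sqrt(max(v1 - cv, 1e-12))
    sigma2 <- sqrt(max(v2 - cv, 1e-12))
  }
  px <- camera$pixel_size_nm
  structure(list(
    x1_nm = p[1] * px, y1_nm = p[2] * px, I1 = p[3],
    x2_nm = p[4] * px, y2_nm = p[5] * px, I2 = p[6],
    fwhm_nm = p[7] * px,
    sigma1_nm = sigma1 * px, sigma2_nm = sigma2 * px,
    converged = fit$converged, degenerate = degenerate,
    rss = fit$value, separation_px = sep_px
  ), class = "two_emitter_fit")
}

#' Measured separation and combined localization error
#'
#' @param fit A converged, non-degenerate [fit_two_emitters()] result.
#' @return Named numeric `c(d_nm, sigma_pair_nm)` where
#'   `d = sqrt((x1-x2)^2 + (y1-y2)^2)` and
#'   `sigma_pair = sqrt(sigma1^2 + sigma2^2)`.
#' @export
measured_separation <- function(fit) {
  stopifnot(inherits(fit, "two_emitter_fit"))
  if (!fit$converged || fit$degenerate) {
    stop("fit is degenerate or did not converge")
  }
  d <- sqrt((fit$x1_nm - fit$x2_nm)^2 + (fit$y1_nm - fit$y2_nm)^2)
  c(d_nm = d, sigma_pair_nm = sqrt(fit$sigma1_nm^2 + fit$sigma2_nm^2))
}

#' Localize one complex from its image stack
#'
#' Convenience wrapper chaining spot detection on the time-averaged image,
#' trace extraction, step detection and the two-emitter fit.
#'
#' @param stack Image stack of one complex.
#' @param camera The [camera_model()].
#' @param radius_px Trace integration radius.
#' @param n_boot Bootstrap refits for localization errors.
#' @param seed Optional seed.
#' @param complex_id Identifier carried through.
#' @return A list with elements `trace`, `segmentation`, `fit` (NULL when
#'   rejected) and `status` (`"ok"` or the rejection reason).
#' @export
localize_stack <- function(stack, camera, radius_px = 4, n_boot = 100,
                           seed = NULL, complex_id = NA) {
  mean_img <- apply(stack, c(1, 2), mean)
  spots <- detect_spots(mean_img, min_snr = 3, min_sep_px = 5)
  if (nrow(spots) == 0) {
    return(list(trace = NULL, segmentation = NULL, fit = NULL,
                status = "no spot detected"))
  }
  spot <- spots[1, ]
  radius_px <- min(radius_px,
                   floor(min(spot$x_px, spot$y_px,
                             ncol(mean_img) - 1 - spot$x_px,
                             nrow(mean_img) - 1 - spot$y_px)))
  trace <- extract_trace(stack, spot, radius_px = radius_px,
                         complex_id = complex_id)
  seg <- detect_steps(trace)
  if (!seg$accepted) {
    return(list(trace = trace, segmentation = seg, fit = NULL,
                status = seg$reason))
  }
  fit <- fit_two_emitters(stack, seg, camera, n_boot = n_boot, seed = seed)
  status <- if (!fit$converged) {
    "fit did not converge"
  } else if (fit$degenerate) {
    "degenerate fit (emitters unresolved)"
  } else {
    "ok"
  }
  list(trace = trace, segmentation = seg, fit = fit, status = status)
}

#' Measure pair separations for a set of synthetic complexes
#'
#' Renders each ground-truth complex, runs the localization chain and
#' collects one row per complex: the measured separation, the combined
#' localization error, step diagnostics and the ground truth for closed-loop
#' comparison.
#'
#' @param truths List of [emitter_pair_truth()] (e.g. from
#'   [sample_species_mixture()]).
#' @param camera The [camera_model()].
#' @param n_boot Bootstrap refits per complex for localization errors (0
#'   skips them; see [fit_two_emitters()]).
#' @param seed Integer seed; per-complex seeds are derived from it.
#' @param extra_frames Frames appended after the last bleach so the zero
#'   level is well sampled.
#' @return A data frame with one row per complex (`complex_id`, `label`,
#'   `d_nm`, `sigma_nm`, `n_steps`, `status`, `true_separation_nm`);
#'   rejected complexes carry `NA` measurements.
#' @export
flimp_measure <- function(truths, camera, n_boot = 0, seed = 1,
                          extra_frames = 6) {
  rows <- lapply(seq_along(truths), function(i) {
    truth <- truths[[i]]
    n_frames <- max(max(truth$bleach_frames) + extra_frames, 12L)
    stack <- render_spot_stack(truth, camera, n_frames, seed = seed + 2L * i)
    res <- localize_stack(stack, camera, n_boot = n_boot,
                          seed = seed + 2L * i + 1L, complex_id = i)
    d <- sig <- NA_real_
    if (identical(res$status, "ok")) {
      ms <- measured_separation(res$fit)
      d <- ms[["d_nm"]]
      sig <- ms[["sigma_pair_nm"]]
    }
    data.frame(complex_id = i,
               label = attr(truth, "label") %||% NA_character_,
               d_nm = d, sigma_nm = sig,
               n_steps = if (is.null(res$segmentation)) NA_integer_ else
                 res$segmentation$n_steps,
               status = res$status,
               true_separation_nm = truth$separation_nm)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
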