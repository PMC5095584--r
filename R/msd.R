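# Mean squared displacement analysis of single-particle tracks.

# Split a track table into per-track lists of (t, x, y) matrices, keyed by
# dataset and track.
split_tracks <- function(tracks) {
  stopifnot(is.data.frame(tracks),
            all(c("track_id", "x_nm", "y_nm") %in% names(tracks)))
  if (!"dataset_id" %in% names(tracks)) tracks$dataset_id <- "default"
  key <- interaction(tracks$dataset_id, tracks$track_id, drop = TRUE)
  lapply(split(tracks, key), function(tr) {
    tr <- tr[order(tr$t_s %||% tr$frame), ]
    list(dataset = tr$dataset_id[1], x = tr$x_nm, y = tr$y_nm,
         t = if ("t_s" %in% names(tr)) tr$t_s else tr$frame)
  })
}

# All squared displacements of one track at a given frame lag (overlapping
# pairs).
sq_disp <- function(tr, lag) {
  n <- length(tr$x)
  if (lag >= n) return(numeric(0))
  i <- seq_len(n - lag)
  (tr$x[i + lag] - tr$x[i])^2 + (tr$y[i + lag] - tr$y[i])^2
}

#' Mean squared displacement curve of a set of tracks
#'
#' `MSD(dT) = < |r_i(T + dT) - r_i(T)|^2 >`, averaged over all pairs of
#' points separated by `dT` within each track (overlapping pairs) and over
#' all tracks.  Time lags are taken in whole frames; tracks must share a
#' uniform frame interval.
#'
#' @param tracks Data frame with columns `track_id`, `x_nm`, `y_nm`, `t_s`
#'   (and optionally `dataset_id`), e.g. from [simulate_tracks()].
#' @param max_lag Largest lag, frames.
#' @return An object of class `msd_curve`: a data frame with `lag_frames`,
#'   `lag_s`, `msd_nm2`, `n_pairs`, and (after [bootstrap_msd()])
#'   `se_nm2`.
#' @export
msd_curve <- function(tracks, max_lag = 10) {
  trs <- split_tracks(tracks)
  if (length(trs) == 0) stop("no tracks")
  dts <- unlist(lapply(trs, function(tr) diff(tr$t)))
  dt <- stats::median(dts)
  if (any(abs(dts - dt) > 1e-9 * max(dt, 1))) {
    stop("tracks must have a uniform time spacing")
  }
  lens <- vapply(trs, function(tr) length(tr$x), integer(1))
  if (max_lag >= max(lens)) {
    stop("`max_lag` exceeds the length of every track")
  }
  rows <- lapply(seq_len(max_lag), function(lag) {
    sq <- unlist(lapply(trs, sq_disp, lag = lag))
    data.frame(lag_frames = lag, lag_s = lag * dt,
               msd_nm2 = mean(sq), n_pairs = length(sq))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("msd_curve", "data.frame")
  attr(out, "dt_s") <- dt
  out
}

#' Instantaneous diffusion coefficient from an MSD curve
#'
#' Fits a straight line through the first two points of the MSD curve and
#' returns `D = m / 4` from its gradient `m` (2D diffusion).  By default the
#' line is unconstrained (exact interpolation of the two points); with
#' `through_origin = TRUE` it is the least-squares line through the origin.
#' Units follow the curve: with nm and seconds, `D` is in nm^2/s.
#'
#' @param curve An [msd_curve()] result (`>= 2` lags).
#' @param through_origin Constrain the fit through the origin.
#' @return A list with `D`, `m` (slope), `intercept`, and `negative_slope`
#'   flag (a negative first gradient is reported as-is and flagged).
#' @export
diffusion_coefficient <- function(curve, through_origin = FALSE) {
  stopifnot(nrow(curve) >= 2)
  t2 <- curve$lag_s[1:2]
  y2 <- curve$msd_nm2[1:2]
  if (t2[1] == t2[2]) stop("identical lags")
  if (through_origin) {
    m <- sum(t2 * y2) / sum(t2^2)
    b <- 0
  } else {
    m <- (y2[2] - y2[1]) / (t2[2] - t2[1])
    b <- y2[1] - m * t2[1]
  }
  list(D = m / 4, m = m, intercept = b, negative_slope = m < 0)
}

#' Triple-bootstrap errors for MSD and diffusion coefficient
#'
#' Repeats the MSD calculation `B` times (200 by convention), each time on a
#' synthetic data set built by resampling with replacement at three levels:
#' the data sets present, the tracks within each data set, and the
#' time points within each track.  Time-point resampling is implemented as
#' resampling, per track and lag, the squared displacements of that track
#' with replacement (resampling raw time points would destroy the lag
#' structure; this preserves it while bootstrapping the per-track sampling
#' noise).  Per-lag standard deviations over replicates become the MSD error
#' bars, and the standard deviation of the per-replicate `D` is `sigma_D`.
#'
#' @param tracks Track table (`>= 2` tracks); see [msd_curve()].
#' @param max_lag Largest lag, frames.
#' @param B Bootstrap replicates (`>= 10`).  Default 200.
#' @param seed Integer seed.
#' @param resample_datasets,resample_tracks,resample_pairs Toggles for the
#'   three resampling levels.
#' @param through_origin Passed to [diffusion_coefficient()].
#' @return The [msd_curve()] of the original tracks with a `se_nm2` column,
#'   plus attributes `D`, `sigma_D`, and `B`.
#' @export
bootstrap_msd <- function(tracks, max_lag = 10, B = 200, seed = 1,
                          resample_datasets = TRUE, resample_tracks = TRUE,
                          resample_pairs = TRUE, through_origin = FALSE) {
  if (B < 10) stop("`B` must be >= 10")
  trs <- split_tracks(tracks)
  if (length(trs) < 2) stop("need at least 2 tracks")
  base <- msd_curve(tracks, max_lag = max_lag)
  datasets <- vapply(trs, `[[`, character(1), "dataset")
  ds_levels <- unique(datasets)
  by_ds <- lapply(ds_levels, function(d) which(datasets == d))
  names(by_ds) <- ds_levels
  # precompute per-track, per-lag squared displacements
  sq <- lapply(trs, function(tr) {
    lapply(seq_len(max_lag), function(lag) sq_disp(tr, lag))
  })
  lag_s <- base$lag_s
  reps <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      ds_idx <- if (resample_datasets) {
        sample(ds_levels, length(ds_levels), replace = TRUE)
      } else {
        ds_levels
      }
      track_idx <- unlist(lapply(ds_idx, function(d) {
        ids <- by_ds[[d]]
        if (resample_tracks) sample(ids, length(ids), replace = TRUE) else ids
      }))
      vapply(seq_len(max_lag), function(lag) {
        vals <- unlist(lapply(track_idx, function(i) {
          v <- sq[[i]][[lag]]
          if (resample_pairs && length(v) > 0) {
            v[sample.int(length(v), replace = TRUE)]
          } else {
            v
          }
        }))
        mean(vals)
      }, numeric(1))
    }, numeric(max_lag))
  })
  reps <- matrix(reps, nrow = max_lag)
  base$se_nm2 <- apply(reps, 1, stats::sd)
  d_reps <- apply(reps, 2, function(msd) {
    fake <- data.frame(lag_s = lag_s, msd_nm2 = msd)
    diffusion_coefficient(fake, through_origin = through_origin)$D
  })
  attr(base, "D") <- diffusion_coefficient(base,
                                           through_origin = through_origin)$D
  attr(base, "sigma_D") <- stats::sd(d_reps)
  attr(base, "B") <- as.integer(B)
  base
}
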