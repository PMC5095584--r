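#' Camera and acquisition model
#'
#' Describes the detector and acquisition settings used both to render
#' synthetic image stacks and to interpret pixel coordinates.  The noise
#' model is photon shot noise (Poisson), optionally doubled in variance to
#' approximate electron-multiplying excess noise, followed by a multiplicative
#' gain and additive Gaussian read noise.  Pixel coordinates place the origin
#' at the centre of the first pixel; physical positions are
#' `pixel_index * pixel_size_nm`.
#'
#' @param pixel_size_nm Pixel pitch in the sample plane, nm.  Default 100.
#' @param read_noise_e Read noise standard deviation, counts.  Default 1.
#' @param gain Multiplicative gain, counts per photon.  Default 1.
#' @param background_photons_per_px Mean background photons per pixel per
#'   frame.  Default 5.
#' @param frame_interval_s Time between frames, seconds.  Default 0.28.
#' @param excess_noise If `TRUE`, approximate electron-multiplying excess
#'   noise by doubling the shot-noise variance.  Default `FALSE`.
#' @param shot_noise If `FALSE`, photon shot noise and background sampling
#'   are disabled (deterministic expected image); used for noiseless checks.
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(pixel_size_nm = 100, read_noise_e = 1, gain = 1,
                         background_photons_per_px = 5,
                         frame_interval_s = 0.28, excess_noise = FALSE,
                         shot_noise = TRUE) {
  stopifnot(pixel_size_nm > 0, frame_interval_s > 0, read_noise_e >= 0,
            gain > 0, background_photons_per_px >= 0)
  structure(list(pixel_size_nm = pixel_size_nm, read_noise_e = read_noise_e,
                 gain = gain,
                 background_photons_per_px = background_photons_per_px,
                 frame_interval_s = frame_interval_s,
                 excess_noise = isTRUE(excess_noise),
                 shot_noise = isTRUE(shot_noise)),
            class = "camera_model")
}

#' Ground truth for one two-emitter complex
#'
#' @param positions 2x2 matrix of emitter positions in nm (rows = emitters,
#'   columns = x, y).
#' @param photons_per_frame Mean detected photons per frame per emitter.
#' @param bleach_frames Integer vector of length 2: the first frame in which
#'   each emitter is dark (it emits in frames `1 .. bleach_frame - 1`).
#' @param psf_fwhm_nm Full width at half maximum of the point spread
#'   function, nm.
#' @return An object of class `emitter_pair_truth` carrying the true
#'   separation in `$separation_nm`.
#' @export
emitter_pair_truth <- function(positions, photons_per_frame, bleach_frames,
                               psf_fwhm_nm) {
  positions <- as.matrix(positions)
  stopifnot(all(dim(positions) == c(2, 2)), photons_per_frame > 0,
            length(bleach_frames) == 2, all(bleach_frames >= 1),
            all(bleach_frames == round(bleach_frames)), psf_fwhm_nm > 0)
  structure(list(
    positions = positions,
    separation_nm = sqrt(sum((positions[1, ] - positions[2, ])^2)),
    photons_per_frame = photons_per_frame,
    bleach_frames = as.integer(bleach_frames),
    psf_fwhm_nm = psf_fwhm_nm
  ), class = "emitter_pair_truth")
}

#' Specification of a mixture of fluorophore-pair species
#'
#' @param labels Character vector of species names.
#' @param separations_nm True dye-to-dye separation of each species, nm.
#' @param weights Mixture weights; non-negative, summing to 1.
#' @param n_complexes Number of complexes to draw.
#' @param seed Integer seed.
#' @return An object of class `species_mixture_spec`.
#' @export
species_mixture_spec <- function(labels, separations_nm, weights,
                                 n_complexes, seed) {
  stopifnot(length(labels) == length(separations_nm),
            length(labels) == length(weights), length(labels) >= 1,
            all(weights >= 0), abs(sum(weights) - 1) < 1e-9,
            all(separations_nm >= 0), n_complexes >= 1)
  structure(list(labels = as.character(labels),
                 separations_nm = separations_nm, weights = weights,
                 n_complexes = as.integer(n_complexes),
                 seed = seed),
            class = "species_mixture_spec")
}

#' Default five-species synthetic mixture
#'
#' Dye-corrected separations of the dimer plus the chain model's tetramer
#' through decamer predictions: 12.5, 19.6, 27.1, 34.6, 42.1 nm.  Weights
#' decay with oligomer order, mimicking a population dominated by dimers and
#' tetramers with rarer long chains.
#'
#' @param n_complexes Number of complexes.
#' @param seed Integer seed.
#' @param weights Optional override of the five weights.
#' @return A [species_mixture_spec()].
#' @export
default_species_mixture <- function(n_complexes = 150, seed = 1,
                                    weights = c(0.35, 0.3, 0.15, 0.12, 0.08)) {
  m <- oligomer_chain_model()
  seps <- c(12.5, dye_corrected_separation(m, predict_ligand_separation(m, 2:5)))
  species_mixture_spec(
    labels = c("dimer", "tetramer", "hexamer", "octamer", "decamer"),
    separations_nm = seps, weights = weights,
    n_complexes = n_complexes, seed = seed
  )
}

# Mean of ceiling(Exponential(rate = 1/mean_frames)): closed form used as the
# oracle for bleach-frame sampling.
mean_ceiling_exp <- function(mean_frames) 1 / (1 - exp(-1 / mean_frames))

#' Sample single-step photobleaching frames
#'
#' Bleaching is memoryless: survival times are exponential with mean
#' `mean_frames` (in frame units) and the bleach frame is the first dark
#' frame, `ceiling` of the survival time (always `>= 1`).
#'
#' @param n Number of draws.
#' @param mean_frames Mean exponential survival time in frames.
#' @param seed Optional integer seed.
#' @return Integer vector of bleach frames.
#' @export
sample_bleach_frames <- function(n, mean_frames, seed = NULL) {
  stopifnot(n >= 1, mean_frames > 0)
  with_seed(seed, as.integer(ceiling(stats::rexp(n, rate = 1 / mean_frames))))
}

#' Draw a mixture of two-emitter complexes with known ground truth
#'
#' Species are sampled i.i.d. by the mixture weights; each complex is placed
#' near `centre_nm` (uniform jitter of half-width `centre_jitter_nm` per
#' axis) with its two emitters at the species separation in a uniformly
#' random orientation.  Bleach frames are drawn per emitter from
#' [sample_bleach_frames()].
#'
#' @param spec A [species_mixture_spec()].
#' @param photons_per_frame Mean photons per frame per emitter.
#' @param mean_bleach_frames Mean bleach survival time, frames.
#' @param psf_fwhm_nm PSF full width at half maximum, nm.
#' @param centre_nm Length-2 centre of the field, nm.
#' @param centre_jitter_nm Half-width of the uniform placement jitter, nm.
#' @return A list of [emitter_pair_truth()] objects; each carries its
#'   species label in attribute `"label"`.
#' @export
sample_species_mixture <- function(spec, photons_per_frame = 10000,
                                   mean_bleach_frames = 8,
                                   psf_fwhm_nm = 300,
                                   centre_nm = c(700, 700),
                                   centre_jitter_nm = 50) {
  stopifnot(inherits(spec, "species_mixture_spec"))
  with_seed(spec$seed, {
    k <- sample.int(length(spec$weights), spec$n_complexes, replace = TRUE,
                    prob = spec$weights)
    lapply(seq_len(spec$n_complexes), function(i) {
      r <- spec$separations_nm[k[i]]
      theta <- stats::runif(1, 0, 2 * pi)
      centre <- centre_nm + stats::runif(2, -centre_jitter_nm, centre_jitter_nm)
      half <- r / 2 * c(cos(theta), sin(theta))
      truth <- emitter_pair_truth(
        positions = rbind(centre + half, centre - half),
        photons_per_frame = photons_per_frame,
        bleach_frames = sample_bleach_frames(2, mean_bleach_frames),
        psf_fwhm_nm = psf_fwhm_nm
      )
      attr(truth, "label") <- spec$labels[k[i]]
      truth
    })
  })
}

# Expected photon image of one emitter: integrated (pixel-averaged) symmetric
# 2D Gaussian.  Pixel (i, j) (1-based row = y, column = x) has its centre at
# ((j - 1) * px, (i - 1) * px) nm and unit area; returns the matrix of photon
# fractions times `photons`.
integrated_gaussian_image <- function(x_nm, y_nm, photons, sigma_nm,
                                      nx, ny, pixel_size_nm) {
  xe <- (seq_len(nx + 1) - 1.5) * pixel_size_nm  # pixel edges, x
  ye <- (seq_len(ny + 1) - 1.5) * pixel_size_nm
  fx <- diff(stats::pnorm(xe, mean = x_nm, sd = sigma_nm))
  fy <- diff(stats::pnorm(ye, mean = y_nm, sd = sigma_nm))
  photons * outer(fy, fx)
}

#' Render a two-emitter photobleaching image stack
#'
#' Per frame, each emitter that has not yet bleached contributes an
#' integrated 2D Gaussian of FWHM `truth$psf_fwhm_nm` scaled to its mean
#' photon rate, on top of a uniform background.  Shot noise (Poisson,
#' optionally with doubled variance for electron-multiplying excess noise),
#' gain and Gaussian read noise are applied per the camera model.  A spot
#' image with two live emitters therefore shows two intensity levels and
#' decays to zero in two bleaching steps, the centroid shifting when the
#' first fluorophore bleaches.
#'
#' @param truth An [emitter_pair_truth()].
#' @param camera A [camera_model()].
#' @param n_frames Number of frames; must cover the latest bleach frame.
#' @param seed Optional integer seed.
#' @param nx,ny Image size in pixels.
#' @return A numeric array `ny x nx x n_frames` of counts, with the truth
#'   record attached as attribute `"truth"`.
#' @export
render_spot_stack <- function(truth, camera, n_frames, seed = NULL,
                              nx = 15, ny = 15) {
  stopifnot(inherits(truth, "emitter_pair_truth"),
            inherits(camera, "camera_model"))
  if (truth$photons_per_frame <= 0) stop("zero photon rate")
  if (n_frames < max(truth$bleach_frames)) {
    stop("`n_frames` must cover the latest bleach frame")
  }
  sigma <- fwhm_to_sigma(truth$psf_fwhm_nm)
  spots <- lapply(1:2, function(e) {
    integrated_gaussian_image(truth$positions[e, 1], truth$positions[e, 2],
                              truth$photons_per_frame, sigma,
                              nx, ny, camera$pixel_size_nm)
  })
  with_seed(seed, {
    stack <- array(0, dim = c(ny, nx, n_frames))
    for (t in seq_len(n_frames)) {
      mu <- matrix(camera$background_photons_per_px, ny, nx)
      for (e in 1:2) if (t < truth$bleach_frames[e]) mu <- mu + spots[[e]]
      if (camera$shot_noise) {
        counts <- stats::rpois(length(mu), mu)
        if (camera$excess_noise) {
          counts <- counts + stats::rnorm(length(mu), 0, sqrt(mu))
        }
      } else {
        counts <- mu
      }
      frame <- counts * camera$gain
      if (camera$read_noise_e > 0) {
        frame <- frame + stats::rnorm(length(mu), 0, camera$read_noise_e)
      }
      stack[, , t] <- frame
    }
    attr(stack, "truth") <- truth
    stack
  })
}

#' Simulate 2D single-particle tracks
#'
#' Brownian tracks take independent Gaussian steps of variance `2 D dt` per
#' axis; confined tracks take the same steps but are reflected at the walls
#' of a square box of side `box_nm` (stationary distribution uniform in the
#' box, so the long-time MSD plateaus at `box_nm^2 / 3`).
#'
#' @param model `"brownian"` or `"confined"`.
#' @param D_um2_s Diffusion coefficient in um^2/s (`>= 0`).
#' @param n_tracks,n_steps Number of tracks and steps per track.
#' @param dt_s Frame interval, seconds.  Default 0.28.
#' @param box_nm Side of the confining box, nm (confined model only).
#' @param seed Optional integer seed.
#' @param dataset_id Dataset label attached to every row.
#' @return A data frame with columns `dataset_id`, `track_id`, `frame`,
#'   `t_s`, `x_nm`, `y_nm`.
#' @export
simulate_tracks <- function(model = c("brownian", "confined"), D_um2_s,
                            n_tracks, n_steps, dt_s = 0.28, box_nm = NULL,
                            seed = NULL, dataset_id = "sim") {
  model <- match.arg(model)
  stopifnot(D_um2_s >= 0, dt_s > 0, n_tracks >= 1, n_steps >= 1)
  if (model == "confined" && (is.null(box_nm) || box_nm <= 0)) {
    stop("confined model requires `box_nm` > 0")
  }
  step_sd_nm <- sqrt(2 * D_um2_s * dt_s) * 1000
  n_pts <- n_steps + 1
  with_seed(seed, {
    out <- lapply(seq_len(n_tracks), function(id) {
      dx <- stats::rnorm(n_steps, 0, step_sd_nm)
      dy <- stats::rnorm(n_steps, 0, step_sd_nm)
      if (model == "brownian") {
        x <- cumsum(c(0, dx))
        y <- cumsum(c(0, dy))
      } else {
        x <- reflect_walk(stats::runif(1, 0, box_nm), dx, box_nm)
        y <- reflect_walk(stats::runif(1, 0, box_nm), dy, box_nm)
      }
      data.frame(dataset_id = dataset_id, track_id = id,
                 frame = seq_len(n_pts) - 1L,
                 t_s = (seq_len(n_pts) - 1) * dt_s, x_nm = x, y_nm = y)
    })
    do.call(rbind, out)
  })
}

# Cumulative walk with reflecting boundaries at [0, box]: fold the free walk
# into the box (triangle-wave map), which is the exact reflected process.
reflect_walk <- function(x0, steps, box) {
  free <- x0 + cumsum(c(0, steps))
  m <- free %% (2 * box)
  ifelse(m > box, 2 * box - m, m)
}

#' Simulate plane-FRET lifetime records with known ground truth
#'
#' Each record carries a donor-only lifetime `tau_d_ns`, a donor+acceptor
#' lifetime consistent with the donor-above-acceptor-plane model at height
#' `h_over_R0` and the record's acceptor density, and the density itself.
#' The model efficiency at each density is the Monte Carlo mean of
#' [simulate_plane_fret()] (a fixed internal seed derived from `seed` makes
#' records reproducible); multiplicative Gaussian noise of coefficient of
#' variation `lifetime_noise_cv` is applied to the donor+acceptor lifetime.
#' With `lifetime_noise_cv = 0` the records are noiseless and a round trip
#' through [fit_doca()] recovers `h_over_R0`.
#'
#' @param h_over_R0 Donor height above the acceptor plane, in units of the
#'   Foerster radius; `> 0`.
#' @param densities Acceptor densities, acceptors per R0^2; `>= 0`.
#' @param n_donors_per_density Records per density.
#' @param lifetime_noise_cv Coefficient of variation of the multiplicative
#'   lifetime noise.
#' @param seed Integer seed.
#' @param tau_d_ns Donor-only lifetime, ns.
#' @param n_mc Monte Carlo realizations per density for the model mean.
#' @return A data frame of FRET records: `cell_id`, `tau_d_ns`, `tau_da_ns`,
#'   `density_per_R02`, plus the ground-truth efficiency `efficiency_true`.
#' @export
simulate_fret_dataset <- function(h_over_R0, densities,
                                  n_donors_per_density = 5,
                                  lifetime_noise_cv = 0, seed = 1,
                                  tau_d_ns = 2.5, n_mc = 4000) {
  stopifnot(h_over_R0 > 0, n_donors_per_density >= 1, lifetime_noise_cv >= 0)
  if (any(densities < 0)) stop("acceptor densities must be non-negative")
  e_model <- vapply(seq_along(densities), function(i) {
    simulate_plane_fret(h_over_R0, densities[i], n_mc = n_mc,
                        seed = seed + 7919 * i)
  }, numeric(1))
  with_seed(seed, {
    rows <- lapply(seq_along(densities), function(i) {
      e <- e_model[i]
      tau_da <- tau_d_ns * (1 - e)
      if (lifetime_noise_cv > 0) {
        tau_da <- tau_da *
          (1 + stats::rnorm(n_donors_per_density, 0, lifetime_noise_cv))
        tau_da <- pmin(pmax(tau_da, 1e-6), tau_d_ns)
      } else {
        tau_da <- rep(tau_da, n_donors_per_density)
      }
      data.frame(cell_id = paste0("d", i, "_", seq_len(n_donors_per_density)),
                 tau_d_ns = tau_d_ns, tau_da_ns = tau_da,
                 density_per_R02 = densities[i], efficiency_true = e)
    })
    do.call(rbind, rows)
  })
}
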