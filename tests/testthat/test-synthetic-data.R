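test_that("species mixtures sample by weight and respect the seed", {
  spec <- species_mixture_spec(c("dimer", "tetramer"), c(12.5, 19.6),
                               c(1, 0), n_complexes = 100, seed = 3)
  truths <- sample_species_mixture(spec)
  seps <- vapply(truths, `[[`, numeric(1), "separation_nm")
  expect_equal(seps, rep(12.5, 100), tolerance = 1e-9)

  spec2 <- species_mixture_spec(c("a", "b"), c(12.5, 19.6), c(0.5, 0.5),
                                n_complexes = 10000, seed = 4)
  truths2 <- sample_species_mixture(spec2)
  n_a <- sum(vapply(truths2, function(x) attr(x, "label"), "") == "a")
  # binomial oracle: within 3 sd of n p
  expect_lt(abs(n_a - 5000), 3 * sqrt(10000 * 0.25))

  expect_identical(
    vapply(sample_species_mixture(spec2), `[[`, numeric(1), "separation_nm"),
    vapply(sample_species_mixture(spec2), `[[`, numeric(1), "separation_nm"))
  expect_error(species_mixture_spec(character(0), numeric(0), numeric(0),
                                    10, 1))
})

test_that("bleach frames follow the discretized exponential survival law", {
  m <- 8
  draws <- sample_bleach_frames(10000, m, seed = 11)
  expect_true(all(draws >= 1))
  # closed-form mean of ceiling(Exp(1/m))
  expected <- 1 / (1 - exp(-1 / m))
  expect_lt(abs(mean(draws) - expected), 3 * sd(draws) / sqrt(10000))
})

test_that("noiseless renders conserve photons and centre the emitter exactly", {
  cam0 <- camera_model(read_noise_e = 0, background_photons_per_px = 0,
                       shot_noise = FALSE)
  # single live emitter at a pixel centre (second emitter already dark)
  tr <- emitter_pair_truth(rbind(c(700, 700), c(500, 500)), 2000,
                           c(15, 1), 300)
  st <- render_spot_stack(tr, cam0, 15)
  f <- st[, , 1]
  expect_equal(sum(f), 2000, tolerance = 1e-6)
  xs <- rep(0:14, each = 15) * 100
  ys <- rep(0:14, 15) * 100
  cx <- sum(f * matrix(xs, 15, 15, byrow = TRUE)) / sum(f)
  cy <- sum(f * matrix(ys, 15, 15)) / sum(f)
  expect_lt(abs(cx - 700), 1e-6 * 100)
  expect_lt(abs(cy - 700), 1e-6 * 100)
  # photon conservation in expectation per live emitter, with gain
  cam2 <- camera_model(read_noise_e = 0, background_photons_per_px = 0,
                       shot_noise = FALSE, gain = 3)
  tr2 <- emitter_pair_truth(rbind(c(700, 700), c(750, 700)), 1500,
                            c(10, 10), 300)
  st2 <- render_spot_stack(tr2, cam2, 12)
  expect_equal(sum(st2[, , 1]), 2 * 1500 * 3, tolerance = 1e-6)
  expect_error(render_spot_stack(tr2, cam2, 5), "bleach")
  tr_bad <- tr2
  tr_bad$photons_per_frame <- 0
  expect_error(render_spot_stack(tr_bad, cam2, 12), "photon")
})

test_that("localization spread scales as the inverse square root of photons", {
  cam <- camera_model(read_noise_e = 0, background_photons_per_px = 0)
  photons <- c(500, 1580, 5000)
  reps <- 300
  set.seed(21)
  sds <- vapply(photons, function(ph) {
    tr <- emitter_pair_truth(rbind(c(700, 700), c(500, 500)), ph,
                             c(2, 1), 300)
    cx <- vapply(seq_len(reps), function(i) {
      f <- render_spot_stack(tr, cam, 2, seed = 1000 * ph + i)[, , 1]
      sum(f * rep(0:14, each = 15) * 100) / sum(f)
    }, numeric(1))
    sd(cx)
  }, numeric(1))
  slope <- coef(lm(log(sds) ~ log(photons)))[2]
  expect_lt(abs(slope + 0.5), 0.05)
})

test_that("simulated tracks have the prescribed diffusion statistics", {
  still <- simulate_tracks("brownian", 0, n_tracks = 3, n_steps = 20,
                           seed = 1)
  expect_equal(var(still$x_nm), 0)
  tr <- simulate_tracks("brownian", 0.1, n_tracks = 100, n_steps = 100,
                        dt_s = 0.28, seed = 2)
  cv <- msd_curve(tr, max_lag = 5)
  D_hat <- diffusion_coefficient(cv)$D / 1e6  # nm^2/s -> um^2/s
  expect_lt(abs(D_hat - 0.1) / 0.1, 0.05)
  # confined: long-time plateau at box^2/3 (uniform stationary distribution)
  trc <- simulate_tracks("confined", 0.1, n_tracks = 20, n_steps = 1500,
                         box_nm = 300, seed = 3)
  cvc <- msd_curve(trc, max_lag = 30)
  plateau <- mean(cvc$msd_nm2[20:30])
  expect_lt(abs(plateau - 300^2 / 3) / (300^2 / 3), 0.1)
  expect_error(simulate_tracks("confined", 0.1, n_tracks = 2, n_steps = 10,
                               box_nm = 0), "box_nm")
})

test_that("synthetic FRET records follow the plane model with zero density inert", {
  rec0 <- simulate_fret_dataset(1.5, densities = c(0), 3, seed = 5)
  expect_equal(rec0$tau_da_ns, rec0$tau_d_ns)
  expect_equal(fret_efficiency(rec0$tau_da_ns, rec0$tau_d_ns), rep(0, 3))
  rec_a <- simulate_fret_dataset(1, c(0.5, 1), 2, seed = 6, n_mc = 500)
  rec_b <- simulate_fret_dataset(1, c(0.5, 1), 2, seed = 6, n_mc = 500)
  expect_identical(rec_a, rec_b)
  expect_error(simulate_fret_dataset(1, c(-0.5, 1), 2, seed = 1),
               "non-negative")
})
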