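cam_quiet <- camera_model(read_noise_e = 0, background_photons_per_px = 0,
                          shot_noise = FALSE)

test_that("spot detection finds isolated emitters and suppresses neighbours", {
  blank <- matrix(0, 40, 40)
  expect_equal(nrow(detect_spots(blank)), 0)
  expect_error(detect_spots(matrix(c(1, NA, 1, 1), 2, 2)), "finite")
  # five well-separated spots
  img <- matrix(0, 60, 60)
  pos <- cbind(x = c(10, 40, 25, 50, 10), y = c(10, 12, 35, 45, 50))
  sig <- flimpr:::fwhm_to_sigma(3)
  for (i in 1:5) {
    img <- img + flimpr:::spot_image_px(pos[i, 1], pos[i, 2], 1000, sig,
                                        60, 60)
  }
  set.seed(1)
  img <- img + rnorm(3600, 0, 1)
  found <- detect_spots(img, min_snr = 5, min_sep_px = 5)
  expect_equal(nrow(found), 5)
  for (i in 1:5) {
    dmin <- min(sqrt((found$x_px - pos[i, 1])^2 + (found$y_px - pos[i, 2])^2))
    expect_lt(dmin, 1.5)
  }
  # two spots one pixel apart collapse to one candidate
  img2 <- flimpr:::spot_image_px(20, 20, 1000, sig, 40, 40) +
    flimpr:::spot_image_px(21, 20, 1000, sig, 40, 40)
  expect_equal(nrow(detect_spots(img2, min_snr = 5, min_sep_px = 5)), 1)
})

test_that("traces integrate background-subtracted intensity and track bleaching", {
  tr <- emitter_pair_truth(rbind(c(700, 700), c(500, 500)), 2000,
                           c(8, 1), 300)
  st <- render_spot_stack(tr, cam_quiet, 14)
  trace <- extract_trace(st, list(x_px = 7, y_px = 7), radius_px = 5)
  expect_equal(trace$intensities[1:7], rep(2000, 7), tolerance = 1e-3)
  expect_equal(trace$intensities[8:14], rep(0, 7), tolerance = 1e-6)
  zero <- array(0, dim = c(15, 15, 12))
  tz <- extract_trace(zero, list(x_px = 7, y_px = 7), radius_px = 4)
  expect_equal(tz$intensities, rep(0, 12))
  expect_error(extract_trace(st, list(x_px = 1, y_px = 7), radius_px = 5),
               "edge")
})

test_that("step detection recovers noiseless change points and rejects bad traces", {
  mk_trace <- function(x) {
    structure(list(frames = seq_along(x), intensities = x),
              class = "intensity_trace")
  }
  seg <- detect_steps(mk_trace(c(rep(1000, 8), rep(500, 8), rep(0, 8))))
  expect_true(seg$accepted)
  expect_equal(seg$change_points, c(8, 16))
  expect_equal(seg$levels, c(1000, 500, 0))
  expect_equal(seg$two_seg, c(1, 8))
  expect_equal(seg$one_seg, c(9, 16))
  # three downward steps: only the lowest two non-zero levels are analysed
  seg3 <- detect_steps(mk_trace(c(rep(1500, 6), rep(1000, 6), rep(500, 6),
                                  rep(0, 6))))
  expect_true(seg3$accepted)
  expect_equal(seg3$n_steps, 3)
  expect_equal(seg3$two_seg, c(7, 12))
  expect_equal(seg3$one_seg, c(13, 18))
  # flat non-zero trace: no step
  set.seed(2)
  flat <- detect_steps(mk_trace(1000 + rnorm(30, 0, 5)))
  expect_false(flat$accepted)
  # single step to zero: one emitter only
  one <- detect_steps(mk_trace(c(rep(1000, 10), rep(0, 10))))
  expect_false(one$accepted)
  expect_error(detect_steps(mk_trace(rep(1, 5))), "at least 10")
})

test_that("noiseless seven-parameter fits are exact and flag degeneracy", {
  # separation 6 px, FWHM 3 px
  tr <- emitter_pair_truth(rbind(c(400, 700), c(1000, 700)), 2000,
                           c(9, 17), 300)
  st <- render_spot_stack(tr, cam_quiet, 22)
  seg <- detect_steps(extract_trace(st, list(x_px = 7, y_px = 7), 7))
  fit <- fit_two_emitters(st, seg, cam_quiet, n_boot = 0)
  expect_true(fit$converged)
  expect_false(fit$degenerate)
  expect_lt(abs(fit$x1_nm - 400), 0.1)   # < 1e-3 px
  expect_lt(abs(fit$y1_nm - 700), 0.1)
  expect_lt(abs(fit$x2_nm - 1000), 0.1)
  expect_lt(abs(fit$fwhm_nm - 300), 0.1)
  expect_equal(fit$I1, 2000, tolerance = 1e-3)
  # residuals numerically zero on noiseless input (infinity norm)
  A <- apply(st[, , seg$two_seg[1]:seg$two_seg[2]], c(1, 2), mean)
  sig <- flimpr:::fwhm_to_sigma(fit$fwhm_nm / 100)
  model <- flimpr:::spot_image_px(fit$x1_nm / 100, fit$y1_nm / 100, fit$I1,
                                  sig, 15, 15) +
    flimpr:::spot_image_px(fit$x2_nm / 100, fit$y2_nm / 100, fit$I2, sig,
                           15, 15)
  expect_lt(max(abs(A - model)), 1e-6 * max(st))
  # effectively coincident emitters -> degenerate flag
  tr2 <- emitter_pair_truth(rbind(c(697.5, 700), c(702.5, 700)), 2000,
                            c(9, 17), 300)
  st2 <- render_spot_stack(tr2, cam_quiet, 22)
  seg2 <- detect_steps(extract_trace(st2, list(x_px = 7, y_px = 7), 7))
  fit2 <- fit_two_emitters(st2, seg2, cam_quiet, n_boot = 0)
  expect_true(fit2$degenerate)
  expect_error(measured_separation(fit2), "degenerate")
})

test_that("measured separation follows the Euclidean and quadrature rules", {
  fit <- structure(list(x1_nm = 0, y1_nm = 0, x2_nm = 3, y2_nm = 4,
                        sigma1_nm = 1, sigma2_nm = 1, converged = TRUE,
                        degenerate = FALSE),
                   class = "two_emitter_fit")
  ms <- measured_separation(fit)
  expect_equal(ms[["d_nm"]], 5)
  expect_equal(ms[["sigma_pair_nm"]], sqrt(2))
})

test_that("the surviving emitter's fit matches the one-emitter segment centroid", {
  cam <- camera_model()
  set.seed(31)
  n <- 50
  hits <- 0
  total <- 0
  for (i in seq_len(n)) {
    truth <- random_pair_truth(19.6)
    st <- render_spot_stack(truth, cam, 22, seed = 400 + i)
    res <- localize_stack(st, cam, n_boot = 0)
    if (!identical(res$status, "ok")) next
    total <- total + 1
    one_f <- res$segmentation$one_seg[1]:res$segmentation$one_seg[2]
    B <- apply(st[, , one_f, drop = FALSE], c(1, 2), mean)
    cen <- flimpr:::image_centroid(B - flimpr:::border_median(B)) * 100
    err <- sqrt((cen[1] - res$fit$x2_nm)^2 + (cen[2] - res$fit$y2_nm)^2)
    if (err < 3) hits <- hits + 1  # within ~3x the localization error
  }
  expect_gt(total, 0.7 * n)
  expect_gt(hits / total, 0.95)
})

test_that("median measured separation is close to truth at tetramer scale", {
  cam <- camera_model()
  set.seed(32)
  truths <- lapply(1:150, function(i) random_pair_truth(19.6))
  tab <- flimp_measure(truths, cam, n_boot = 0, seed = 7)
  d <- tab$d_nm[tab$status == "ok"]
  expect_gt(length(d), 100)
  expect_lt(abs(median(d) - 19.6), 1)
})
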