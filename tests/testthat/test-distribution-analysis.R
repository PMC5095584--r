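test_that("compiled distributions count and sum unit posteriors", {
  set.seed(51)
  ms <- make_measurements(draw_rice(30, 19.6, 1.5), 1.5)
  dist <- compile_distribution(ms, 10)
  expect_equal(dist$n, 30)
  expect_equal(flimpr:::trapz(dist$grid, dist$curve), 30, tolerance = 1e-6)
  # duplicating a measurement adds exactly one unit of area
  dist2 <- compile_distribution(c(ms, ms[1]), 10)
  expect_equal(dist2$n, 31)
  expect_equal(flimpr:::trapz(dist2$grid, dist2$curve), 31, tolerance = 1e-6)
  expect_error(compile_distribution(ms, 0), "no measurement passes")
  bad <- c(ms[1], make_measurements(15, 1.5, r_max = 50))
  expect_error(compile_distribution(bad, 10), "common posterior grid")
})

test_that("single-component fits recover the species position and match direct logL", {
  dist <- make_mixture_dist(12.5, 1, n = 100, sigma = 1.5, seed = 52)
  fit <- fit_rician_mixture(dist, 1, seed = 1)
  expect_equal(fit$weights, 1)
  expect_lt(abs(fit$positions - 12.5), 0.5)
  direct <- sum(rice_likelihood(dist$d_nm, fit$positions, dist$sigma_nm,
                                log = TRUE))
  expect_equal(fit$logL, direct, tolerance = 1e-8)
  expect_equal(fit$bic, 1 * log(dist$n) - 2 * fit$logL)
})

test_that("two-species mixtures are recovered with monotone EM", {
  dist <- make_mixture_dist(c(12.5, 19.6), c(0.5, 0.5), n = 200,
                            sigma = 1.5, seed = 53)
  fit <- fit_rician_mixture(dist, 2, seed = 2)
  expect_lt(abs(fit$positions[1] - 12.5), 1)
  expect_lt(abs(fit$positions[2] - 19.6), 1)
  expect_lt(abs(fit$weights[1] - 0.5), 0.1)
  # EM never decreases the log-likelihood
  expect_true(all(diff(fit$logL_trace) >= -1e-6))
  expect_error(fit_rician_mixture(dist, 101), "n >= 2 K")
})

test_that("BIC selection avoids over-fitting and caps K by sample size", {
  dist1 <- make_mixture_dist(19.6, 1, n = 120, sigma = 1.5, seed = 54)
  sel1 <- select_K_by_bic(dist1, K_max = 4, seed = 3)
  expect_equal(sel1$K, 1)
  expect_equal(nrow(sel1$bic_table), 4)
  expect_equal(sel1$bic, min(sel1$bic_table$bic))
  tiny <- make_mixture_dist(c(12.5, 19.6), c(0.5, 0.5), n = 4,
                            sigma = 1.5, seed = 55)
  sel2 <- select_K_by_bic(tiny, K_max = 8, seed = 4)
  expect_lte(sel2$K, 2)
  expect_equal(nrow(sel2$bic_table), 2)  # n >= 2K caps the candidates
})

test_that("bias-region reporting suppresses positions near the resolution floor", {
  model <- structure(list(K = 2, positions = c(3, 11.9),
                          weights = c(0.3, 0.7), logL = 0, bic = 0, n = 50),
                     class = "rician_mixture")
  rep <- bias_region_report(model, bias_limit_nm = 6.5)
  expect_true(rep$interval_only[1])
  expect_true(is.na(rep$position_nm[1]))
  expect_false(rep$interval_only[2])
  expect_equal(rep$position_nm[2], 11.9)
  rep0 <- bias_region_report(model, bias_limit_nm = 0)
  expect_false(any(rep0$interval_only))
  expect_equal(rep0$position_nm, c(3, 11.9))
  # with a distribution attached, intervals come from the bootstrap
  dist <- make_mixture_dist(c(12.5, 19.6), c(0.5, 0.5), n = 60,
                            sigma = 1.5, seed = 56)
  fit <- fit_rician_mixture(dist, 2, seed = 5)
  repb <- bias_region_report(fit, dist, B = 50, seed = 6)
  expect_true(all(repb$ci_low_nm <= fit$positions + 1e-9))
  expect_true(all(repb$ci_high_nm >= fit$positions - 1e-9))
})

test_that("species fractions follow the interval-overlap counting rule", {
  # 6 measurements centred in the dimer window, 4 at the tetramer, tight
  # errors so each 69% interval stays within ~1 nm of its centre
  ms <- make_measurements(c(rep(12.5, 6), rep(19.6, 4)), 0.3)
  dist <- compile_distribution(ms, 5)
  fr <- species_fraction(dist, expected_interval("dimer"),
                         expected_interval("region"))
  expect_equal(fr$fraction, 0.6)
  expect_equal(fr$n_denominator, 10)
  # all measurements inside the target
  fr1 <- species_fraction(compile_distribution(ms[1:6], 5),
                          expected_interval("dimer"),
                          expected_interval("region"))
  expect_equal(fr1$fraction, 1)
  # invariant to duplication of the whole data set and to reordering
  fr2 <- species_fraction(compile_distribution(c(ms, ms), 5),
                          expected_interval("dimer"),
                          expected_interval("region"))
  expect_equal(fr2$fraction, fr$fraction)
  fr3 <- species_fraction(compile_distribution(rev(ms), 5),
                          expected_interval("dimer"),
                          expected_interval("region"))
  expect_equal(fr3$fraction, fr$fraction)
  # empty denominator signals an undefined fraction
  far <- compile_distribution(make_measurements(c(40, 45, 50), 0.3), 5)
  expect_warning(frna <- species_fraction(far, expected_interval("dimer"),
                                          expected_interval("region")),
                 "undefined")
  expect_true(is.nan(frna$fraction))
})

test_that("bootstrap fraction errors match the binomial scale on a Bernoulli toy", {
  # every measurement is wholly in or out of the dimer window; all are in
  # the region, so the fraction is a plain Bernoulli mean
  set.seed(57)
  n <- 100
  p <- 0.6
  lab <- runif(n) < p
  d <- ifelse(lab, 12.5, 18.5)
  dist <- compile_distribution(make_measurements(d, 0.3), 5)
  est <- bootstrap_fraction(dist, expected_interval("dimer"),
                            expected_interval("region"), B = 1000, seed = 7)
  p_hat <- mean(lab)
  expect_equal(est$fraction, p_hat)
  expect_lt(abs(est$bootstrap_sd - sqrt(p_hat * (1 - p_hat) / n)),
            0.2 * sqrt(p_hat * (1 - p_hat) / n))
  # identical measurements: zero bootstrap spread
  same <- compile_distribution(make_measurements(rep(12.5, 20), 0.3), 5)
  est0 <- bootstrap_fraction(same, expected_interval("dimer"),
                             expected_interval("region"), B = 200, seed = 8)
  expect_equal(est0$bootstrap_sd, 0)
  expect_error(bootstrap_fraction(dist, expected_interval("dimer"),
                                  expected_interval("region"), B = 50),
               "B")
})

test_that("species fraction of a 70/30 mixture matches its sampling expectation", {
  # The overlap index counts measurements whose 69% interval touches the
  # narrow species window, so a pure species overlaps its own window with
  # probability ~0.7-0.8, not 1; the estimator's expectation is computed
  # here by an independent large-sample oracle and the n = 200 estimate is
  # checked against it, while the dimer share of the two species indices
  # recovers the mixture weight (coverage factors cancel).
  dist <- make_mixture_dist(c(12.5, 19.6), c(0.7, 0.3), n = 200,
                            sigma = 1.5, seed = 58)
  est <- species_fraction(dist, expected_interval("dimer"),
                          expected_interval("region"))
  # oracle: overlap probabilities from direct Rice simulation with the
  # fixed 69% half-width of a sigma = 1.5 measurement
  set.seed(59)
  hw <- separation_posterior(12.5, 1.5)$ci_width_nm / 2
  overlap_prob <- function(r, lo, hi) {
    d <- draw_rice(40000, r, 1.5)
    mean(d - hw <= hi & d + hw >= lo)
  }
  p_num <- 0.7 * overlap_prob(12.5, 12.2, 12.8)
  p_den <- 0.7 * overlap_prob(12.5, 0, 20.1) +
    0.3 * overlap_prob(19.6, 0, 20.1)
  expect_lt(abs(est$fraction - p_num / p_den), 3 * sqrt(0.25 / 200))
  # calibrated dimer share across the two species indices
  tet <- species_fraction(dist, expected_interval("tetramer"),
                          expected_interval("region"))
  share <- est$fraction / (est$fraction + tet$fraction)
  expect_lt(abs(share - 0.7), 0.1)
})

test_that("tail fractions split measurements at the dimer-tetramer cut", {
  low <- compile_distribution(make_measurements(c(10, 12, 15), 0.3), 5)
  tf <- tail_fraction(low, 20.1)
  expect_equal(tf$below$fraction, 1)
  expect_equal(tf$above$fraction, 0)
  hex <- compile_distribution(make_measurements(rep(27.1, 5), 0.3), 5)
  tfh <- tail_fraction(hex, 20.1)
  expect_equal(tfh$above$fraction, 1)
  expect_equal(tfh$below$fraction, 0)
  # a measurement straddling the cut counts on both sides
  mix <- compile_distribution(make_measurements(c(10, 20.1, 30), 0.5), 6)
  tfm <- tail_fraction(mix, 20.1)
  expect_gt(tfm$below$fraction + tfm$above$fraction, 1)
})
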