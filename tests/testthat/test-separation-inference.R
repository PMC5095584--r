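test_that("Rice likelihood matches closed forms and an independent series", {
  # Rayleigh limit r = 0
  expect_equal(rice_likelihood(1, 0, 1), exp(-0.5), tolerance = 1e-12)
  # independent Bessel-series evaluation at d = 3, r = 2, sigma = 1
  expect_equal(rice_likelihood(3, 2, 1), 3 * exp(-6.5) * bessel_i0_series(6),
               tolerance = 1e-10)
  # the asymptotic large-argument branch agrees with direct evaluation
  # through the density at moderate arguments spanning the switch point
  d <- seq(18, 22, length.out = 50)
  direct <- (d / 1.5^2) * exp(-(d^2 + 20^2) / (2 * 1.5^2) + d * 20 / 1.5^2) *
    besselI(d * 20 / 1.5^2, 0, expon.scaled = TRUE)
  expect_equal(rice_likelihood(d, 20, 1.5), direct, tolerance = 1e-9)
  # density integrates to one over d
  f <- Vectorize(function(x) rice_likelihood(x, 5, 2))
  expect_equal(integrate(f, 0, Inf, rel.tol = 1e-10)$value, 1,
               tolerance = 1e-8)
  expect_error(rice_likelihood(1, 1, 0), "sigma")
  expect_error(rice_likelihood(-1, 1, 1))
})

test_that("separation posteriors are normalized with correct limits", {
  # vanishing-error limit: delta at the measurement
  m <- separation_posterior(12.5, 0.01)
  expect_lt(abs(m$r[which.max(m$posterior)] - 12.5), 0.05)
  expect_lt(m$ci_width_nm, 0.1)
  # posterior integrates to 1
  expect_equal(flimpr:::trapz(m$r, m$posterior), 1, tolerance = 1e-6)
  # small measured separation: mass piles against zero
  m2 <- separation_posterior(2, 2)
  expect_equal(m2$ci69[1], 0)
  expect_error(separation_posterior(10, 1, grid_n = 100), "grid")
  expect_error(separation_posterior(59, 2), "r_max")
})

test_that("posterior matches the brute-force conditioning oracle", {
  set.seed(41)
  d <- 12; sigma <- 2
  m <- separation_posterior(d, sigma)
  breaks <- seq(max(0, d - 6 * sigma), d + 6 * sigma, length.out = 30)
  p_brute <- brute_force_posterior(d, sigma, breaks, n_draws = 2e6,
                                   chunks = 2)
  p_grid <- bin_posterior(m, breaks)
  expect_lt(sum(abs(p_grid - p_brute)) / 2, 0.02)
})

test_that("credible intervals have the HPD and central properties", {
  m <- separation_posterior(25, 1.5)
  ci <- credible_interval(m, 0.69)
  mode <- m$r[which.max(m$posterior)]
  # narrow nearly-symmetric posterior: interval symmetric about the mode
  expect_lt(abs((ci[2] - mode) - (mode - ci[1])), 0.2)
  expect_equal(credible_interval(m, 1), range(m$r))
  cc <- credible_interval(m, 0.69, method = "central")
  expect_lt(abs(cc[1] - ci[1]), 0.3)
  expect_error(credible_interval(m, 0), "mass")
  expect_error(credible_interval(m, 1.5), "mass")
  # HPD is no wider than the central interval (up to grid resolution)
  skew <- separation_posterior(3, 2)
  hpd <- credible_interval(skew, 0.69)
  cen <- credible_interval(skew, 0.69, method = "central")
  expect_lte(hpd[2] - hpd[1], cen[2] - cen[1] + diff(skew$r[1:2]))
})

test_that("posterior mode and asymmetry reproduce Rice properties", {
  # for d >> sigma the mode approaches sqrt(d^2 - sigma^2)
  for (d in c(15, 25, 40)) {
    m <- separation_posterior(d, 2)
    expect_lt(abs(m$r[which.max(m$posterior)] - sqrt(d^2 - 4)),
              2 * diff(m$r[1:2]))
  }
  # low-separation skew: lower arm shorter than upper arm near the
  # resolution floor (d of order sigma)
  for (d in c(1, 2, 3)) {
    m <- separation_posterior(d, 2)
    mode <- m$r[which.max(m$posterior)]
    expect_lt(mode - m$ci69[1], m$ci69[2] - mode)
  }
})

test_that("resolution filtering is strict and monotone", {
  m <- separation_posterior(19.6, 1.5)
  w <- m$ci_width_nm
  expect_true(passes_resolution_filter(m, w + 0.1))
  expect_false(passes_resolution_filter(m, w))  # strict boundary
  expect_false(passes_resolution_filter(m, w - 0.1))
  # monotone: raising the threshold never drops a passing measurement
  set.seed(42)
  ms <- make_measurements(draw_rice(30, 19.6, 1.5), 1.5)
  pass5 <- vapply(ms, passes_resolution_filter, logical(1), 5)
  pass7 <- vapply(ms, passes_resolution_filter, logical(1), 7)
  expect_true(all(pass7[pass5]))
})
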