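test_that("distance density matches the Gaussian mixture and normalizes", {
  d <- distance_distribution(40, 3)
  expect_equal(distance_density(d, 40), 1 / (3 * sqrt(2 * pi)),
               tolerance = 1e-6)

  # numerical integral over (0, 200] is 1 for random valid distributions
  set.seed(7)
  for (i in 1:20) {
    f2 <- runif(1)
    d2 <- distance_distribution(runif(2, 15, 90), runif(2, 0.5, 12),
                                c(1 - f2, f2))
    integral <- stats::integrate(function(r) distance_density(d2, r),
                                 0, 200, rel.tol = 1e-10,
                                 subdivisions = 500L)$value
    expect_equal(integral, 1, tolerance = 1e-6)
  }

  # well-separated two-component density has local maxima at the means
  d3 <- distance_distribution(c(41.7, 28.8), c(2.3, 2.1), c(0.04, 0.96))
  rr <- seq(15, 60, by = 0.01)
  dens <- distance_density(d3, rr)
  peaks <- rr[which(diff(sign(diff(dens))) == -2) + 1L]
  expect_length(peaks, 2L)
  expect_equal(sort(peaks), c(28.8, 41.7), tolerance = 1e-2)
})

test_that("distance density rejects invalid input", {
  d <- distance_distribution(40, 3)
  expect_error(distance_density(d, -1), "distances")
  expect_error(distance_distribution(c(40, 30), c(3, 3), c(0.7, 0.7)),
               "sum to 1")
  expect_error(distance_distribution(-5, 3), "> 0")
  expect_error(distance_distribution(c(10, 20, 30), c(1, 1, 1)),
               "1 or 2")
})

test_that("single-acceptor intensity obeys its closed-form limits", {
  g <- small_grid()
  tc <- bin_centers(g)

  # pure donor: FRET term absent
  p <- fret_params(f_D = 1, A0 = 2)
  ref <- 2 * (0.87 * exp(-tc / 17.6) + 0.13 * exp(-tc / 4.73))
  expect_equal(fret_intensity_single(p, g), ref, tolerance = 1e-14)

  # point distance at R0 halves the lifetime
  p2 <- fret_params(f_D = 0, tau_D1 = 17.6, alpha_D1 = 1,
                    rbar_1 = 43.5, sigma_1 = 1e-3, f_A2 = 0)
  expect_equal(fret_intensity_single(p2, g), exp(-tc / 8.8),
               tolerance = 1e-6)

  # distant acceptor: transfer rate -> 0
  p3 <- fret_params(f_D = 0, rbar_1 = 200, sigma_1 = 3, f_A2 = 0, A0 = 1)
  donor <- 0.87 * exp(-tc / 17.6) + 0.13 * exp(-tc / 4.73)
  expect_lt(max(abs(fret_intensity_single(p3, g) - donor) / donor), 1e-3)

  expect_error(fret_params(R0 = -1), "R0")
})

test_that("single-acceptor intensity matches a dense quadrature oracle", {
  g <- small_grid(256L)
  tc <- bin_centers(g)
  p <- fret_params(f_D = 0.2, rbar_1 = 41.7, sigma_1 = 2.3, f_A2 = 0.5,
                   rbar_2 = 28.8, sigma_2 = 2.1, A0 = 3)
  got <- fret_intensity_single(p, g)
  ref <- oracle_intensity_single(tc, f_D = 0.2, alphas = c(0.87, 0.13),
                                 taus = c(17.6, 4.73), R0 = 43.5,
                                 means = c(41.7, 28.8), sds = c(2.3, 2.1),
                                 fracs = c(0.5, 0.5), A0 = 3)
  expect_lt(max(abs(got - ref) / ref), 1e-4)
})

test_that("two-acceptor factorization equals the direct double integral", {
  g <- time_grid(0.8, 64L)
  tc <- bin_centers(g)
  set.seed(11)
  for (i in 1:10) {
    f2 <- runif(1, 0.1, 0.9)
    m1 <- sort(runif(2, 25, 55), decreasing = TRUE)
    s1 <- runif(2, 1.5, 5)
    m2 <- sort(runif(2, 45, 65))
    s2 <- runif(2, 2, 6)
    p <- fret_params(f_D = 0, alpha_D1 = 0.87,
                     rbar_1 = m1[1], sigma_1 = s1[1], f_A2 = f2,
                     rbar_2 = m1[2], sigma_2 = s1[2],
                     rho2 = list(rbar = m2, sigma = s2))
    got <- fret_intensity_double(p, g)
    ref <- oracle_intensity_double(tc, alphas = c(0.87, 0.13),
                                   taus = c(17.6, 4.73), R0 = 43.5,
                                   means1 = m1, sds1 = s1,
                                   means2 = m2, sds2 = s2,
                                   fracs = c(1 - f2, f2))
    expect_lt(max(abs(got - ref) / ref), 1e-5)
  }
})

test_that("two-acceptor model decouples and compounds correctly", {
  g <- small_grid(256L)
  tc <- bin_centers(g)

  # far-away second acceptor: reduces to the single-acceptor model
  p <- fret_params(f_D = 0.1, rbar_1 = 41.7, sigma_1 = 2.3, f_A2 = 0.3,
                   rbar_2 = 28.8, sigma_2 = 2.1,
                   rho2 = list(rbar = c(500, 500), sigma = c(1, 1)))
  p1 <- fret_params(f_D = 0.1, rbar_1 = 41.7, sigma_1 = 2.3, f_A2 = 0.3,
                    rbar_2 = 28.8, sigma_2 = 2.1)
  dbl <- fret_intensity_double(p, g)
  sgl <- fret_intensity_single(p1, g)
  expect_lt(max(abs(dbl - sgl) / sgl), 1e-6)

  # both acceptors at R0: rates add, lifetime tau/3
  p3 <- fret_params(f_D = 0, tau_D1 = 17.6, alpha_D1 = 1,
                    rbar_1 = 43.5, sigma_1 = 1e-3, f_A2 = 0,
                    rho2 = list(rbar = c(43.5, 43.5), sigma = c(1e-3, 1e-3)))
  expect_equal(fret_intensity_double(p3, g), exp(-3 * tc / 17.6),
               tolerance = 1e-5)

  expect_error(fret_intensity_double(p1, g), "rho2")
  expect_error(fret_intensity_single(p, g), "rho2")
})

test_that("buffer intensity is the plain multi-exponential sum", {
  g <- time_grid(1, 16L, origin = 0)
  tc <- bin_centers(g)
  b <- buffer_model(100, 5)
  expect_equal(buffer_intensity(b, g)[1], 100)
  expect_equal(buffer_intensity(b, g)[6], 100 / exp(1))
  b0 <- buffer_model(c(0, 0), c(1, 6))
  expect_equal(buffer_intensity(b0, g), rep(0, 16L))
  expect_error(buffer_model(rep(1, 5), rep(1, 5)), "1 to 4")
})

test_that("reconvolution satisfies delta, background and shift identities", {
  g <- small_grid(256L)
  p <- fret_params(f_D = 1, A0 = 100)
  model <- fret_intensity_single(p, g)
  spike <- histogram(g, c(1, rep(0, 255)), role = "irf")

  out <- reconvolve(spike, model)
  expect_equal(out$counts, model, tolerance = 1e-12)

  out7 <- reconvolve(spike, model, bkgr_dec = 7)
  expect_equal(out7$counts, model + 7, tolerance = 1e-12)

  # whole-bin shift relocates the prediction exactly
  sh <- reconvolve(spike, model, shift_irf = g$bin_width * 1000)
  expect_equal(sh$counts[2:256], out$counts[1:255], tolerance = 1e-9)
  expect_equal(sh$counts[1], 0, tolerance = 1e-9)

  irf2 <- histogram(small_grid(128L), rep(1, 128L), role = "irf")
  expect_error(reconvolve(irf2, model), "grid")
  zero_irf <- histogram(g, rep(2, 256L), role = "irf")
  expect_error(reconvolve(zero_irf, model, bkgr_irf = 5), "all zero")
})

test_that("reconvolution matches direct convolution and conserves signal", {
  g <- small_grid(256L)
  irf <- test_irf(g)
  model <- fret_intensity_single(fret_params(f_D = 1, A0 = 50), g)
  buf <- buffer_intensity(test_buffer(), g)

  out <- reconvolve(irf, model, buf, f_B = 0.5, bkgr_dec = 2)
  h <- irf$counts / sum(irf$counts)
  ref <- oracle_convolve(h, model + 0.5 * buf) + 2
  expect_equal(out$counts, ref, tolerance = 1e-10)

  # conservation up to tail truncation: bounded by the IRF mass that falls
  # beyond the grid once convolved
  total_in <- sum(model + 0.5 * buf)
  total_out <- sum(out$counts - 2)
  expect_lt(total_out, total_in + 1e-8)
  expect_gt(total_out / total_in, 0.9)
})

test_that("tail slope of a reconvolved mono-exponential equals -1/tau", {
  g <- time_grid(0.05, 2048L)
  irf <- make_irf(g, center = 2, fwhm = 0.4, total_counts = 2e6,
                  background_rate = 0, seed = 5)
  model <- fret_intensity_single(fret_params(f_D = 1, tau_D1 = 17.6,
                                             alpha_D1 = 1, A0 = 1), g)
  out <- reconvolve(irf, model)
  tc <- bin_centers(g)
  idx <- tc > 7 & tc < 60
  slope <- coef(lm(log(out$counts[idx]) ~ tc[idx]))[2]
  expect_equal(unname(slope), -1 / 17.6, tolerance = 5e-3)
})

test_that("mean arrival time decreases strictly with the mean distance", {
  g <- small_grid(512L)
  mat <- vapply(c(45, 40, 35, 30), function(rb) {
    p <- fret_params(f_D = 0, rbar_1 = rb, sigma_1 = 3, f_A2 = 0.3,
                     rbar_2 = rb - 8, sigma_2 = 3)
    mean_arrival_time(fret_intensity_single(p, g), g)
  }, numeric(1))
  expect_true(all(diff(mat) < 0))
})
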