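# Shared small synthetic setup: coarse grid keeps the fits fast while the
# photon budget stays realistic.
fit_grid <- time_grid(0.05, 2048L)

test_that("Poisson-weighted chi-square follows its definition", {
  g <- time_grid(1, 4L, origin = 0)
  a <- histogram(g, c(100, 50, 20, 5), role = "decay")
  expect_equal(weighted_chi_square(a, a), 0)
  b <- histogram(g, c(110, 50, 20, 5), role = "decay")
  expect_equal(weighted_chi_square(a, b, window = c(1, 2)), 1.0)
  # variance floor of 1 for empty bins
  z <- histogram(g, c(0, 0, 0, 0), role = "decay")
  p <- histogram(g, c(2, 0, 0, 0), role = "decay")
  expect_equal(weighted_chi_square(z, p), 4)
  expect_error(weighted_chi_square(a, histogram(time_grid(2, 4), rep(1, 4),
                                                "decay")), "grids")
  expect_error(weighted_chi_square(a, b, window = c(3, 2)), "window")
})

test_that("chi-square per bin is near 1 for Poisson data at the truth", {
  set.seed(99)
  pred <- 50 + 5000 * exp(-seq(0, 8, length.out = 4000))
  obs <- rpois(4000, pred)
  g <- time_grid(0.01, 4000L)
  chi2 <- weighted_chi_square(histogram(g, obs, "decay"),
                              histogram(g, pred, "decay"))
  expect_gt(chi2 / 4000, 0.9)
  expect_lt(chi2 / 4000, 1.1)
})

test_that("buffer fitting recovers a two-component model and flags degeneracy", {
  irf <- test_irf(fit_grid, seed = 8)
  truth <- buffer_model(c(25000, 3500), c(1, 6), acquisition_duration = 300)
  bh <- simulate_buffer(truth, irf, bkgr_dec = 0.5, seed = 21)
  expect_gt(sum(bh$counts), 5e5)  # ample photons for a 5% recovery check

  bf <- fit_buffer(bh, irf, n_components = 2L)
  taus <- sort(bf$model$lifetimes)
  expect_equal(taus[1], 1, tolerance = 0.05)
  expect_equal(taus[2], 6, tolerance = 0.05)
  expect_true(bf$fit$converged)
  expect_equal(bf$model$acquisition_duration, 300)

  # noise-free input: the objective collapses to ~0
  exact <- reconvolve(irf, buffer_intensity(truth, fit_grid),
                      bkgr_dec = 0.5)
  bh0 <- histogram(fit_grid, exact$counts, role = "buffer",
                   acquisition_duration = 300)
  bf0 <- fit_buffer(bh0, irf, n_components = 2L)
  expect_lt(bf0$fit$reduced_chi2, 1e-3)

  # flat counts: no decaying component to find; flagged, not an error
  flat <- histogram(fit_grid, rep(3, fit_grid$n_bins), role = "buffer",
                    acquisition_duration = 300)
  bfd <- fit_buffer(flat, irf, n_components = 2L)
  expect_true(bfd$fit$status$degenerate)

  expect_error(fit_buffer(bh, irf, n_components = 5L), "1 and 4")
})

test_that("donor-only protocol recovers the double-exponential donor", {
  scen <- make_scenario("donor_only", seed = 31,
                        overrides = list(grid = fit_grid))
  buf <- scen$buffer$model
  fit <- fit_donor_only(scen$datasets[[1]]$decay, scen$irf, buf)
  expect_true(fit$converged)
  expect_equal(fit$estimates[["tau_D1"]], 17.6, tolerance = 0.3 / 17.6)
  expect_equal(fit$estimates[["alpha_D1"]], 0.87, tolerance = 0.03 / 0.87)
  expect_gt(fit$reduced_chi2, 0.85)
  expect_lt(fit$reduced_chi2, 1.15)

  # protocol violations need the explicit override
  expect_error(fit_donor_only(scen$datasets[[1]]$decay, scen$irf, buf,
                              free = c("f_D", "tau_D1")), "protocol")

  # mono-exponential truth fit with two components converges anyway, with
  # the spare component degenerate (vanishing fraction or equal lifetimes)
  p1 <- fret_params(f_D = 1, tau_D1 = 10, alpha_D1 = 1, shift_irf = 0,
                    f_B = 0, bkgr_dec = 0.2)
  mono <- simulate_histogram(p1, scen$irf, NULL, total_counts = 2e6,
                             seed = 5)
  fm <- fit_donor_only(mono, scen$irf, NULL)
  e <- fm$estimates
  degenerate <- e[["alpha_D1"]] > 0.98 || e[["alpha_D1"]] < 0.02 ||
    abs(e[["tau_D1"]] - e[["tau_D2"]]) < 1
  expect_true(degenerate)
  expect_gt(fm$reduced_chi2, 0.85)
  expect_lt(fm$reduced_chi2, 1.15)

  # noise-free input at the generating parameters: chi-square ~ 0
  truth <- attr(scen$datasets[[1]]$decay, "truth")
  exact <- predict_decay(truth, scen$irf, buf)
  h0 <- histogram(fit_grid, exact$counts, role = "decay",
                  acquisition_duration = 300)
  f0 <- fit_donor_only(h0, scen$irf, buf, params = truth)
  expect_lt(f0$reduced_chi2, 1e-4)
})

test_that("single-state decay fits recover the generating Gaussian", {
  irf <- test_irf(fit_grid, seed = 12)
  buf <- test_buffer()
  for (cfg in list(list(fix = 0, rbar = 41.7, sigma = 2.3),
                   list(fix = 1, rbar = 28.8, sigma = 2.1))) {
    pt <- fret_params(f_D = 0.15, rbar_1 = 41.7, sigma_1 = 2.3,
                      f_A2 = cfg$fix, rbar_2 = 28.8, sigma_2 = 2.1,
                      shift_irf = 25, f_B = 1, bkgr_dec = 0.5, A0 = 1)
    dec <- simulate_histogram(pt, irf, buf, total_counts = 5e6,
                              seed = 40 + cfg$fix)
    fit <- fit_decay(dec, irf, buf,
                     params = fret_params(f_B = 1, f_A2 = cfg$fix,
                                          fixed = c(f_A2 = TRUE)))
    nm <- if (cfg$fix == 0) c("rbar_1", "sigma_1") else
      c("rbar_2", "sigma_2")
    expect_equal(fit$estimates[[nm[1]]], cfg$rbar, tolerance = 1 / cfg$rbar)
    expect_equal(fit$estimates[[nm[2]]], cfg$sigma, tolerance = 0.5)
    expect_gt(fit$reduced_chi2, 0.9)
    expect_lt(fit$reduced_chi2, 1.1)
  }
})

test_that("the fixing rules of the standard protocol are enforced", {
  irf <- test_irf(fit_grid, seed = 12)
  buf <- test_buffer()
  pt <- fret_params(f_D = 0.15, rbar_1 = 41.7, sigma_1 = 2.3, f_A2 = 0.5,
                    rbar_2 = 28.8, sigma_2 = 2.1, shift_irf = 25, f_B = 1,
                    bkgr_dec = 0.5, A0 = 1)
  dec <- simulate_histogram(pt, irf, buf, total_counts = 1e6, seed = 3,
                            acquisition_duration = 300)
  fit <- fit_decay(dec, irf, buf, params = fret_params(f_B = 2))
  # R0, donor parameters, f_B, bkgr_irf never appear among the free set
  expect_false(any(c("R0", "tau_D1", "alpha_D1", "tau_D2", "f_B",
                     "bkgr_irf") %in% names(fit$estimates)))
  v <- fit$dataset_values[[1]]
  expect_equal(v[["R0"]], 43.5)
  expect_equal(v[["bkgr_irf"]], 0)
  # f_B comes from the acquisition-time ratio, overriding the passed value
  expect_equal(v[["f_B"]], 300 / 300)
  # protocol violation is a misuse error unless explicitly overridden
  expect_error(fit_decay(dec, irf, buf, params = fret_params(f_B = 1),
                         free = c("rbar_1", "R0")), "protocol")

  # the optimizer's accepted objective trace never increases
  expect_true(all(diff(fit$rsstrace) <= 1e-8))

  # degrees of freedom bookkeeping
  expect_equal(fit$degrees_of_freedom,
               fit$n_obs - length(fit$estimates))
})

test_that("global fits reduce to single fits and validate sharing", {
  irf <- test_irf(fit_grid, seed = 17)
  buf <- test_buffer()
  pt <- fret_params(f_D = 0.15, rbar_1 = 41.7, sigma_1 = 2.3, f_A2 = 0.5,
                    rbar_2 = 28.8, sigma_2 = 2.1, shift_irf = 25, f_B = 1,
                    bkgr_dec = 0.5, A0 = 1)
  dec <- simulate_histogram(pt, irf, buf, total_counts = 2e6, seed = 50)

  single <- fit_decay(dec, irf, buf, params = fret_params(f_B = 1))
  p0 <- single$dataset_values[[1]]
  pars <- fret_params(f_B = 1)
  pars <- do.call(fret_params, c(as.list(p0), list(rho2 = NULL)))
  # two identical replicates, every free parameter shared
  ds <- fit_dataset(dec, irf, buf, tdfret:::.protocol_params(
    pars, tdfret:::.STANDARD_FREE_DECAY, tdfret:::.STANDARD_FREE_DECAY,
    c(f_B = 1, bkgr_irf = 0), FALSE))
  spec <- fit_spec(list(ds, ds), sharing = tdfret:::.STANDARD_FREE_DECAY)
  glob <- fit_global(spec)
  for (nm in c("rbar_1", "rbar_2", "f_A2", "f_D"))
    expect_equal(glob$estimates[[nm]], single$estimates[[nm]],
                 tolerance = 1e-2)

  # sharing a parameter that is fixed in one dataset is a validation error
  ds2 <- ds
  ds2$params <- tdfret:::.set_fixed(ds2$params, "f_A2", TRUE)
  expect_error(fit_spec(list(ds, ds2), sharing = c("f_A2")),
               "inconsistent sharing")
  expect_error(fit_global(fit_spec(list(ds))), "at least two")
})

test_that("titration global fit recovers per-condition fractions", {
  irf <- test_irf(fit_grid, seed = 23)
  buf <- test_buffer()
  f2s <- c(0.08, 0.5, 0.8, 0.96)
  decs <- lapply(seq_along(f2s), function(i) {
    pt <- fret_params(f_D = 0.15, rbar_1 = 41.7, sigma_1 = 2.3,
                      f_A2 = f2s[i], rbar_2 = 28.8, sigma_2 = 2.1,
                      shift_irf = 25, f_B = 1, bkgr_dec = 0.5, A0 = 1)
    simulate_histogram(pt, irf, buf, total_counts = 5e6, seed = 60 + i,
                       condition = sprintf("c%d", i))
  })
  spec <- prepare_global_spec(decs, irf, buf, fret_params(f_B = 1))
  fit <- fit_global(spec)
  est <- fit$estimates[sprintf("f_A2@%d", seq_along(f2s))]
  expect_true(all(abs(est - f2s) < 0.05))
  expect_equal(fit$estimates[["rbar_1"]], 41.7, tolerance = 1 / 41.7)
  expect_equal(fit$estimates[["rbar_2"]], 28.8, tolerance = 1 / 28.8)
})
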