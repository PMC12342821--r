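test_that("simulated IRFs are reproducible, well-budgeted and collapsible", {
  g <- small_grid()
  a <- make_irf(g, seed = 77)
  b <- make_irf(g, seed = 77)
  expect_identical(a$counts, b$counts)
  expect_false(identical(a$counts, make_irf(g, seed = 78)$counts))

  big <- make_irf(g, total_counts = 1e6, background_rate = 0, seed = 5)
  expect_lt(abs(sum(big$counts) - 1e6), 4 * sqrt(1e6))

  spike <- make_irf(g, center = 2.1, fwhm = 1e-6, total_counts = 1e4,
                    background_rate = 0, seed = 9)
  expect_equal(sum(spike$counts > 0), 1L)

  expect_error(make_irf(g, center = 1e4), "outside")
})

test_that("simulated decays embed their truth and order by FRET", {
  g <- small_grid()
  irf <- test_irf(g)
  buf <- test_buffer()
  # f_D = 0 isolates the FRET population: at a fixed photon budget a
  # donor-only admixture gains photon share as FRET strengthens and can
  # invert the naive mean-arrival ordering
  p_rest <- fret_params(f_D = 0, rbar_1 = 41.7, sigma_1 = 2.3, f_A2 = 0,
                        rbar_2 = 28.8, sigma_2 = 2.1, f_B = 1,
                        bkgr_dec = 0.5, A0 = 1)
  p_act <- tdfret:::.set_values(p_rest, c(f_A2 = 1))
  d_rest <- simulate_histogram(p_rest, irf, buf, 1e6, seed = 4)
  d_act <- simulate_histogram(p_act, irf, buf, 1e6, seed = 4)
  expect_identical(d_rest$counts,
                   simulate_histogram(p_rest, irf, buf, 1e6, seed = 4)$counts)
  # rbar_2 < rbar_1: the all-active decay arrives earlier
  expect_lt(mean_arrival_time(d_act), mean_arrival_time(d_rest))

  tr <- attr(d_rest, "truth")
  expect_s3_class(tr, "fret_params")
  expect_equal(tr$values[["rbar_1"]], 41.7)
  expect_gt(tr$values[["A0"]], 0)
  expect_lt(abs(sum(d_rest$counts) - 1e6), 4 * sqrt(1e6))
})

test_that("scenario presets carry the right structure and monotonicity", {
  expect_error(make_scenario("nonsense"), "unknown scenario")
  expect_setequal(scenario_names(),
                  c("donor_only", "intrasubunit", "intersubunit",
                    "homotetramer", "full_length"))

  g <- small_grid(1024L)
  scen <- make_scenario("homotetramer", seed = 5,
                        overrides = list(grid = g, total_counts = 3e5))
  expect_false(is.null(scen$datasets[[1]]$truth$rho2))
  expect_equal(scen$datasets[[1]]$truth$rho2$rbar, c(54.1, 58.0))
  expect_equal(scen$conditions$f_A2, c(0.25, 0.60, 0.94))

  fl <- make_scenario("full_length", seed = 6,
                      overrides = list(grid = g, total_counts = 3e5,
                                       f_D = 0))
  # conditions derive from the quadratic binding model (K_D = 0.53 uM)
  expect_equal(fl$conditions$f_A2[1], 0.41)
  expect_equal(fl$conditions$f_A2[nrow(fl$conditions)], 0.99,
               tolerance = 1e-3)
  # saturating cAMP decays faster than apo
  expect_lt(mean_arrival_time(fl$datasets[[nrow(fl$conditions)]]$decay),
            mean_arrival_time(fl$datasets[[1]]$decay))
  # same master seed, same bundle
  fl2 <- make_scenario("full_length", seed = 6,
                       overrides = list(grid = g, total_counts = 3e5,
                                        f_D = 0))
  expect_identical(fl$datasets[[1]]$decay$counts,
                   fl2$datasets[[1]]$decay$counts)
})

test_that("dose series respect the binding model and round-trip", {
  p <- dose_response_params(K_D = 0.53, P_total = 0.025, A = 0.99, B = 0.41)
  L <- c(0, 0.25, 0.5, 1, 2, 320)
  ser <- make_dose_series(p, L)
  expect_equal(ser$f_A2[1], 0.41)
  expect_true(all(diff(ser$f_A2) >= 0))
  fit <- fit_dose_response(ser$concentration, ser$f_A2)
  expect_equal(fit$estimates[["K_D"]], 0.53, tolerance = 0.01)
  expect_error(make_dose_series(p, c(-1, 2)), "negative")
})
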