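#' Simulate a measured instrument response function
#'
#' Stand-in for a scatter-based IRF measurement: a Gaussian pulse of the
#' requested full width at half maximum plus a uniform dark-count
#' background, Poisson-sampled per bin.  Bin masses are computed from the
#' Gaussian CDF so that widths below the bin width collapse to a single-bin
#' spike.
#'
#' @param grid A [time_grid()].
#' @param center Pulse center in ns; must lie inside the grid.
#' @param fwhm Full width at half maximum in ns, > 0.
#' @param total_counts Expected total counts in the pulse.
#' @param background_rate Expected uniform background, counts per bin.
#' @param seed RNG seed; the same seed reproduces the histogram exactly.
#' @return A `tcspc_histogram` with role `"irf"`.
#' @export
make_irf <- function(grid, center = 5, fwhm = 0.4, total_counts = 2e6,
                     background_rate = 0.01, seed = NULL) {
  stopifnot(inherits(grid, "time_grid"))
  if (fwhm <= 0) stop("fwhm must be > 0")
  tc <- bin_centers(grid)
  lo_edge <- tc[1] - grid$bin_width / 2
  hi_edge <- tc[grid$n_bins] + grid$bin_width / 2
  if (center < lo_edge || center > hi_edge)
    stop("IRF center (", center, " ns) lies outside the time grid")
  s <- fwhm / (2 * sqrt(2 * log(2)))
  edges <- c(tc - grid$bin_width / 2, hi_edge)
  mass <- diff(pnorm(edges, center, s))
  mass <- mass / sum(mass)
  expected <- total_counts * mass + background_rate
  counts <- .with_seed(seed, rpois(grid$n_bins, expected))
  h <- histogram(grid, counts, role = "irf")
  attr(h, "seed") <- seed
  h
}

#' Simulate a TCSPC decay with known ground truth
#'
#' Computes the noise-free reconvolved prediction for `params` (including
#' the `f_B`-scaled buffer and the constant background `bkgr_dec`), scales
#' the sample term so the total expected counts equal `total_counts`, and
#' draws independent Poisson counts per bin.  The generating parameters
#' (with the amplitude `A0` updated to the realized scale) are embedded in
#' the result as the `"truth"` attribute.
#'
#' @param params A [fret_params()] (with or without a `rho2` block).
#' @param irf IRF histogram defining the grid.
#' @param buffer Optional [buffer_model()].
#' @param total_counts Expected total photon count of the decay.
#' @param seed RNG seed.
#' @param acquisition_duration Acquisition time (s) recorded on the
#'   histogram.
#' @param condition Condition label recorded on the histogram.
#' @param n_quad Trapezoid points per Gaussian distance component.
#' @return A `tcspc_histogram` with role `"decay"` and attributes
#'   `"truth"` (a `fret_params`) and `"seed"`.
#' @export
simulate_histogram <- function(params, irf, buffer = NULL,
                               total_counts = 5e6, seed = NULL,
                               acquisition_duration = 300,
                               condition = NA_character_, n_quad = 501L) {
  stopifnot(inherits(params, "fret_params"),
            inherits(irf, "tcspc_histogram"))
  grid <- irf$grid
  v <- params$values
  model <- .fret_intensity_values(v, params$rho2, grid, n_quad = n_quad)
  sig <- reconvolve(irf, model, shift_irf = v[["shift_irf"]],
                    bkgr_irf = v[["bkgr_irf"]])$counts
  bufc <- 0
  if (!is.null(buffer) && v[["f_B"]] > 0)
    bufc <- reconvolve(irf, v[["f_B"]] * buffer_intensity(buffer, grid),
                       shift_irf = v[["shift_irf"]],
                       bkgr_irf = v[["bkgr_irf"]])$counts
  base <- v[["bkgr_dec"]] * grid$n_bins
  scale <- (total_counts - base - sum(bufc)) / sum(sig)
  if (!is.finite(scale) || scale <= 0)
    stop("total_counts too small for the requested background/buffer levels")
  expected <- scale * sig + bufc + v[["bkgr_dec"]]
  if (any(expected < 0)) {
    warning("negative expected counts clipped to 0")
    expected <- pmax(expected, 0)
  }
  counts <- .with_seed(seed, rpois(grid$n_bins, expected))
  h <- histogram(grid, counts, role = "decay",
                 acquisition_duration = acquisition_duration,
                 condition = condition)
  truth <- .set_values(params, c(A0 = scale * v[["A0"]]))
  attr(h, "truth") <- truth
  attr(h, "seed") <- seed
  h
}

#' Simulate a buffer-only decay
#'
#' The buffer model reconvolved with the IRF plus a constant background,
#' Poisson-sampled.  Amplitudes are taken from `buffer` as-is (counts).
#'
#' @inheritParams simulate_histogram
#' @param buffer A [buffer_model()].
#' @param bkgr_dec Constant background, counts per bin.
#' @export
simulate_buffer <- function(buffer, irf, bkgr_dec = 0.5, shift_irf = 0,
                            seed = NULL, acquisition_duration = 300) {
  stopifnot(inherits(buffer, "buffer_model"),
            inherits(irf, "tcspc_histogram"))
  grid <- irf$grid
  expected <- reconvolve(irf, buffer_intensity(buffer, grid),
                         shift_irf = shift_irf, bkgr_dec = bkgr_dec)$counts
  counts <- .with_seed(seed, rpois(grid$n_bins, pmax(expected, 0)))
  h <- histogram(grid, counts, role = "buffer",
                 acquisition_duration = acquisition_duration)
  attr(h, "seed") <- seed
  h
}

#' Ground-truth titration series from the quadratic binding model
#'
#' Forward-evaluates the tight-binding dose-response model at the given
#' total ligand concentrations, optionally adding Gaussian noise (clipped
#' to (0, 1)).
#'
#' @param dose_params A [dose_response_params()].
#' @param concentrations Total ligand concentrations (uM), >= 0.
#' @param noise_sd Additive Gaussian noise standard deviation (0 = exact).
#' @param seed RNG seed (used only when `noise_sd > 0`).
#' @return A data frame with columns `concentration` and `f_A2`.
#' @export
make_dose_series <- function(dose_params, concentrations, noise_sd = 0,
                             seed = NULL) {
  if (any(concentrations < 0)) stop("negative concentration")
  f <- dose_response_value(dose_params, concentrations)
  if (noise_sd > 0) {
    f <- .with_seed(seed, f + rnorm(length(f), 0, noise_sd))
    f <- pmin(pmax(f, 1e-4), 1 - 1e-4)
  }
  data.frame(concentration = concentrations, f_A2 = f)
}

## ---- scenario presets ----------------------------------------------------

## Distance parameters (Angstrom) for the experimental scenarios; donor and
## acceptor photophysics are common to all of them.
.scenario_presets <- function() {
  inter <- list(rbar = c(54.1, 58.0), sigma = c(3.0, 5.0))
  list(
    donor_only = list(
      f_D = 1, rho = NULL, rho2 = NULL,
      conditions = data.frame(label = "apo", f_A2 = 0)
    ),
    intrasubunit = list(
      f_D = 0.15,
      rho = list(rbar = c(41.7, 28.8), sigma = c(2.3, 2.1)),
      rho2 = NULL,
      dose = list(K_D = 0.22, P_total = 1.2, A = 0.96, B = 0.08,
                  concentrations = c(0, 0.5, 1, 2, 320))
    ),
    intersubunit = list(
      f_D = 0.15,
      rho = inter, rho2 = NULL,
      conditions = data.frame(label = c("apo", "cAMP_320uM"),
                              f_A2 = c(0.2, 0.8))
    ),
    homotetramer = list(
      f_D = 0.15,
      rho = list(rbar = c(41.6, 29.1), sigma = c(3.6, 4.1)),
      rho2 = inter,
      conditions = data.frame(label = c("apo", "cAMP_1uM", "cAMP_320uM"),
                              f_A2 = c(0.25, 0.60, 0.94))
    ),
    full_length = list(
      f_D = 0.15,
      rho = list(rbar = c(39.8, 31.0), sigma = c(4.1, 2.7)),
      rho2 = inter,
      dose = list(K_D = 0.53, P_total = 0.025, A = 0.99, B = 0.41,
                  concentrations = c(0, 0.25, 0.5, 1, 2, 320))
    )
  )
}

#' Names of the built-in synthetic scenarios
#' @export
scenario_names <- function() names(.scenario_presets())

#' Generate a complete synthetic TCSPC dataset bundle
#'
#' Builds a ground-truth dataset for one of the built-in experimental
#' scenarios: a simulated IRF, a buffer-only decay, and one FRET decay per
#' ligand condition, all carrying their generating parameters.  Scenarios
#' whose preset includes a dose-response block derive their per-condition
#' active-state fractions from the quadratic binding model; the others use
#' fixed condition tables.
#'
#' @param name One of [scenario_names()].
#' @param overrides Named list overriding preset configuration entries
#'   (e.g. `total_counts`, `grid`, `conditions`, `f_D`, `bkgr_dec`).
#' @param seed Master seed; all per-component seeds derive from it.
#' @param dir Optional directory; when given, the bundle is written to disk
#'   via [write_scenario_bundle()].
#' @return An object of class `fret_scenario` with elements `irf`,
#'   `buffer` (model + simulated histogram), `datasets` (per condition:
#'   decay histogram, label, true `f_A2`, true `fret_params`) and `config`.
#' @export
make_scenario <- function(name, overrides = list(), seed = 1, dir = NULL) {
  presets <- .scenario_presets()
  if (!name %in% names(presets))
    stop("unknown scenario '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  preset <- presets[[name]]

  config <- list(
    grid = time_grid(0.025, 4096L),
    total_counts = 5e6,
    donor = list(lifetimes = c(17.6, 4.73), fractions = c(0.87, 0.13)),
    R0 = 43.5,
    f_D = preset$f_D,
    shift_irf = 25,           # ps
    bkgr_dec = 0.5,           # counts / bin
    irf = list(center = 5, fwhm = 0.4, total_counts = 2e6,
               background_rate = 0.01),
    buffer = list(lifetimes = c(1, 6), fraction = 0.02),
    acquisition = list(decay = 300, buffer = 300),  # seconds
    rho = preset$rho,
    rho2 = preset$rho2,
    conditions = preset$conditions,
    dose = preset$dose
  )
  known <- c("grid", "total_counts", "donor", "R0", "f_D", "shift_irf",
             "bkgr_dec", "irf", "buffer", "acquisition", "rho", "rho2",
             "conditions", "dose")
  bad <- setdiff(names(overrides), known)
  if (length(bad))
    stop("unknown override(s): ", paste(bad, collapse = ", "))
  for (nm in names(overrides)) config[nm] <- list(overrides[[nm]])
  grid <- config$grid

  conditions <- config$conditions
  if (is.null(conditions)) {
    d <- config$dose
    dp <- dose_response_params(d$K_D, d$P_total, d$A, d$B)
    series <- make_dose_series(dp, d$concentrations)
    conditions <- data.frame(
      label = ifelse(series$concentration == 0, "apo",
                     sprintf("cAMP_%guM", series$concentration)),
      f_A2 = series$f_A2
    )
  }

  irf <- make_irf(grid, center = config$irf$center, fwhm = config$irf$fwhm,
                  total_counts = config$irf$total_counts,
                  background_rate = config$irf$background_rate,
                  seed = .child_seed(seed, 1L))

  # buffer amplitudes calibrated so the buffer-only measurement carries
  # `fraction` of the decay photon budget
  unit_buf <- buffer_model(rep(1, length(config$buffer$lifetimes)),
                           config$buffer$lifetimes)
  unit_counts <- sum(reconvolve(irf, buffer_intensity(unit_buf, grid))$counts)
  target_buf <- config$buffer$fraction * config$total_counts
  amp <- max(target_buf - config$bkgr_dec * grid$n_bins, 1) / unit_counts
  buffer <- buffer_model(rep(amp, length(config$buffer$lifetimes)),
                         config$buffer$lifetimes,
                         acquisition_duration = config$acquisition$buffer)
  buffer_hist <- simulate_buffer(buffer, irf, bkgr_dec = config$bkgr_dec,
                                 shift_irf = config$shift_irf,
                                 seed = .child_seed(seed, 2L),
                                 acquisition_duration = config$acquisition$buffer)

  f_B <- config$acquisition$decay / config$acquisition$buffer
  datasets <- vector("list", nrow(conditions))
  for (i in seq_len(nrow(conditions))) {
    f2 <- conditions$f_A2[i]
    if (is.null(config$rho)) {  # donor-only scenario
      p <- fret_params(
        f_D = 1, tau_D1 = config$donor$lifetimes[1],
        alpha_D1 = config$donor$fractions[1],
        tau_D2 = if (length(config$donor$lifetimes) > 1)
          config$donor$lifetimes[2] else 4.73,
        R0 = config$R0, shift_irf = config$shift_irf, f_B = f_B,
        bkgr_dec = config$bkgr_dec
      )
    } else {
      p <- fret_params(
        f_D = config$f_D, tau_D1 = config$donor$lifetimes[1],
        alpha_D1 = config$donor$fractions[1],
        tau_D2 = if (length(config$donor$lifetimes) > 1)
          config$donor$lifetimes[2] else 4.73,
        R0 = config$R0,
        rbar_1 = config$rho$rbar[1], sigma_1 = config$rho$sigma[1],
        f_A2 = f2,
        rbar_2 = config$rho$rbar[2], sigma_2 = config$rho$sigma[2],
        shift_irf = config$shift_irf, f_B = f_B,
        bkgr_dec = config$bkgr_dec, rho2 = config$rho2
      )
    }
    decay <- simulate_histogram(
      p, irf, buffer, total_counts = config$total_counts,
      seed = .child_seed(seed, 10L + i),
      acquisition_duration = config$acquisition$decay,
      condition = conditions$label[i]
    )
    datasets[[i]] <- list(decay = decay, condition = conditions$label[i],
                          f_A2_true = f2, truth = attr(decay, "truth"))
  }

  scen <- structure(
    list(name = name, seed = seed, grid = grid, irf = irf,
         buffer = list(model = buffer, histogram = buffer_hist),
         datasets = datasets, conditions = conditions, config = config),
    class = "fret_scenario"
  )
  if (!is.null(dir)) write_scenario_bundle(scen, dir)
  scen
}

#' @export
print.fret_scenario <- function(x, ...) {
  cat(sprintf("<fret_scenario> '%s'  seed=%d  %d condition(s), %g counts/decay\n",
              x$name, x$seed, length(x$datasets), x$config$total_counts))
  for (d in x$datasets)
    cat(sprintf("  %-12s f_A2 = %.3g\n", d$condition, d$f_A2_true))
  invisible(x)
}
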