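#' Poisson-weighted chi-square of a predicted decay
#'
#' TCSPC shot noise is Poisson, so each bin is weighted by an estimated
#' variance equal to the observed count, with a floor of one count so that
#' empty bins do not produce infinite weights:
#' `sum((obs - pred)^2 / max(obs, 1))` over the fit window.
#'
#' @param observed,predicted `tcspc_histogram`s on the same grid, or bare
#'   numeric count vectors of equal length.
#' @param window `c(first_bin, last_bin)` indices, or `NULL` for all bins.
#' @return The chi-square value (not reduced).
#' @export
weighted_chi_square <- function(observed, predicted, window = NULL) {
  if (inherits(observed, "tcspc_histogram") &&
      inherits(predicted, "tcspc_histogram")) {
    if (!.same_grid(observed$grid, predicted$grid))
      stop("observed and predicted histograms are on different grids")
    observed <- observed$counts
    predicted <- predicted$counts
  }
  if (length(observed) != length(predicted))
    stop("observed and predicted lengths differ")
  idx <- .window_index(window, length(observed))
  o <- observed[idx]
  p <- predicted[idx]
  sum((o - p)^2 / pmax(o, 1))
}

.window_index <- function(window, n) {
  if (is.null(window)) return(seq_len(n))
  stopifnot(length(window) == 2L)
  if (window[1] < 1 || window[2] > n || window[1] >= window[2])
    stop("invalid fit window [", window[1], ", ", window[2], "] for ", n,
         " bins")
  seq.int(window[1], window[2])
}

#' Default fit window for a decay
#'
#' From 5 bins before the IRF peak to the last bin with at least one
#' observed count.
#'
#' @param decay,irf `tcspc_histogram`s on the same grid.
#' @return Integer `c(first, last)`.
#' @export
default_fit_window <- function(decay, irf) {
  stopifnot(.same_grid(decay$grid, irf$grid))
  first <- max(1L, which.max(irf$counts) - 5L)
  nz <- which(decay$counts >= 1)
  last <- if (length(nz)) max(nz) else decay$grid$n_bins
  if (last <= first) stop("degenerate fit window: no counts after IRF peak")
  c(first, last)
}

#' Predicted decay histogram for a parameter vector
#'
#' Convenience wrapper: unconvolved FRET intensity (single- or two-acceptor
#' depending on the `rho2` block) reconvolved with the IRF and the
#' `f_B`-scaled buffer model.
#'
#' @param params A [fret_params()].
#' @param irf Measured IRF histogram.
#' @param buffer Optional [buffer_model()].
#' @param n_quad Trapezoid points per Gaussian distance component.
#' @return A `tcspc_histogram` of real-valued predicted counts.
#' @export
predict_decay <- function(params, irf, buffer = NULL, n_quad = 501L) {
  stopifnot(inherits(params, "fret_params"))
  v <- params$values
  model <- .fret_intensity_values(v, params$rho2, irf$grid, n_quad = n_quad)
  buf <- if (!is.null(buffer)) buffer_intensity(buffer, irf$grid)
  reconvolve(irf, model, buf, shift_irf = v[["shift_irf"]],
             bkgr_irf = v[["bkgr_irf"]], f_B = v[["f_B"]],
             bkgr_dec = v[["bkgr_dec"]])
}

## ---- fit specification ---------------------------------------------------

#' Assemble a (possibly global) fit specification
#'
#' @param datasets A list of datasets, each created by [fit_dataset()].
#' @param sharing Character vector of parameter names constrained equal
#'   across all datasets.  Every shared parameter must be free in every
#'   dataset.
#' @param n_quad Trapezoid points per Gaussian distance component.
#' @return An object of class `fret_fit_spec`.
#' @export
fit_spec <- function(datasets, sharing = character(), n_quad = 501L) {
  if (!length(datasets)) stop("at least one dataset is required")
  for (d in datasets) {
    if (!inherits(d, "fret_dataset"))
      stop("each dataset must be built with fit_dataset()")
  }
  .check_par_names(sharing)
  for (k in seq_along(datasets)) {
    d <- datasets[[k]]
    fixed_shared <- sharing[datasets[[k]]$params$fixed[sharing]]
    if (length(fixed_shared))
      stop("inconsistent sharing: parameter(s) ",
           paste(fixed_shared, collapse = ", "),
           " are fixed in dataset ", k, " but listed as shared-free")
  }
  total_free <- sum(vapply(datasets, function(d) sum(!d$params$fixed), 0L))
  for (d in datasets) {
    if (diff(d$window) + 1L <= total_free)
      stop("fit window shorter than the number of free parameters")
  }
  structure(list(datasets = datasets, sharing = sharing,
                 n_quad = as.integer(n_quad)),
            class = "fret_fit_spec")
}

#' @rdname fit_spec
#' @param decay,irf `tcspc_histogram`s on one grid.
#' @param buffer A [buffer_model()] (typically frozen from [fit_buffer()]),
#'   or `NULL` when the sample has no measurable buffer contribution.
#' @param params A [fret_params()] carrying starting values, fixed flags and
#'   bounds for this dataset.
#' @param window `c(first, last)` bin window; default from
#'   [default_fit_window()].
#' @export
fit_dataset <- function(decay, irf, buffer = NULL, params, window = NULL) {
  stopifnot(inherits(decay, "tcspc_histogram"),
            inherits(irf, "tcspc_histogram"),
            inherits(params, "fret_params"))
  if (!.same_grid(decay$grid, irf$grid))
    stop("decay and IRF histograms are on different grids")
  if (!is.null(buffer) && !inherits(buffer, "buffer_model"))
    stop("`buffer` must be a buffer_model (fit it first with fit_buffer())")
  if (is.null(window)) window <- default_fit_window(decay, irf)
  .window_index(window, decay$grid$n_bins)  # validates
  structure(list(decay = decay, irf = irf, buffer = buffer, params = params,
                 window = as.integer(window)),
            class = "fret_dataset")
}

## ---- core engine ---------------------------------------------------------

## Bounded Levenberg-Marquardt minimization of the summed Poisson-weighted
## chi-square over all datasets of a fret_fit_spec.  `starts` is a list of
## named start vectors over the free-parameter vector theta; the best
## (lowest deviance) solution wins.  Lazy multi-start: remaining starts are
## skipped once a fit reaches reduced chi-square <= lazy_threshold.
.fit_engine <- function(spec, starts = NULL, control = NULL,
                        lazy_threshold = 1.2, auto_jitter = FALSE) {
  ds <- spec$datasets
  nds <- length(ds)
  free_list <- lapply(ds, function(d) .PAR_NAMES[!d$params$fixed])
  shared <- spec$sharing
  for (s in shared) {
    ok <- vapply(free_list, function(f) s %in% f, TRUE)
    if (!all(ok))
      stop("inconsistent sharing: '", s, "' is not free in every dataset")
  }

  ## theta layout: shared parameters once, then per-dataset private ones
  theta_names <- shared
  maps <- vector("list", nds)  # per-ds: named theta-name per free param
  for (k in seq_len(nds)) {
    priv <- setdiff(free_list[[k]], shared)
    priv_theta <- if (nds == 1L) priv else paste0(priv, "@", k)
    theta_names <- c(theta_names, priv_theta)
    m <- c(stats::setNames(shared, shared),
           stats::setNames(priv_theta, priv))
    maps[[k]] <- m[free_list[[k]]]
  }
  if (!length(theta_names)) stop("no free parameters to fit")

  theta0 <- lower <- upper <- stats::setNames(numeric(length(theta_names)),
                                              theta_names)
  for (k in seq_len(nds)) {
    p <- ds[[k]]$params
    for (nm in free_list[[k]]) {
      tn <- maps[[k]][[nm]]
      theta0[tn] <- p$values[[nm]]
      lower[tn] <- p$lower[[nm]]
      upper[tn] <- p$upper[[nm]]
    }
  }

  ## per-dataset precomputations
  obs <- wts <- widx <- vector("list", nds)
  buf_int <- vector("list", nds)
  for (k in seq_len(nds)) {
    widx[[k]] <- .window_index(ds[[k]]$window, ds[[k]]$decay$grid$n_bins)
    obs[[k]] <- ds[[k]]$decay$counts[widx[[k]]]
    wts[[k]] <- 1 / sqrt(pmax(obs[[k]], 1))
    buf_int[k] <- list(if (!is.null(ds[[k]]$buffer))
      buffer_intensity(ds[[k]]$buffer, ds[[k]]$decay$grid))
  }
  cache <- new.env(parent = emptyenv())
  n_quad <- spec$n_quad

  predict_k <- function(k, theta) {
    v <- ds[[k]]$params$values
    v[free_list[[k]]] <- theta[maps[[k]]]
    model <- .fret_intensity_values(v, ds[[k]]$params$rho2,
                                    ds[[k]]$decay$grid, cache, n_quad)
    reconvolve(ds[[k]]$irf, model, buf_int[[k]],
               shift_irf = v[["shift_irf"]], bkgr_irf = v[["bkgr_irf"]],
               f_B = v[["f_B"]], bkgr_dec = v[["bkgr_dec"]])$counts
  }
  resid_fn <- function(theta) {
    theta <- stats::setNames(as.double(theta), theta_names)
    unlist(lapply(seq_len(nds), function(k)
      (obs[[k]] - predict_k(k, theta)[widx[[k]]]) * wts[[k]]), use.names = FALSE)
  }

  ctrl <- do.call(nls.lm.control,
                  modifyList(list(maxiter = 120, nprint = 0),
                             as.list(control %||% list())))
  n_obs <- sum(lengths(obs))
  dof <- n_obs - length(theta_names)
  if (dof <= 0) stop("fit window shorter than the number of free parameters")

  if (is.null(starts)) {
    starts <- list(theta0)
    if (auto_jitter) {
      # deterministic alternates: split distances the other way, nudge the
      # mixing fraction, and offset the IRF shift by half a bin (a shift
      # start of exactly zero can sit on a flat spot of the objective)
      half_bin_ps <- 500 * ds[[1]]$decay$grid$bin_width
      base_of <- sub("@.*$", "", theta_names)
      j1 <- j2 <- theta0
      j1[base_of == "rbar_1"] <- theta0[base_of == "rbar_1"] + 3
      j1[base_of == "rbar_2"] <- theta0[base_of == "rbar_2"] - 3
      j1[base_of == "f_A2"] <- 0.25
      j1[base_of == "shift_irf"] <- theta0[base_of == "shift_irf"] +
        half_bin_ps
      j2[base_of == "rbar_1"] <- theta0[base_of == "rbar_1"] - 3
      j2[base_of == "rbar_2"] <- theta0[base_of == "rbar_2"] + 3
      j2[base_of == "f_A2"] <- 0.75
      j2[base_of == "shift_irf"] <- theta0[base_of == "shift_irf"] -
        half_bin_ps
      starts <- list(theta0, j1, j2)
    }
  }
  best <- NULL
  n_starts_used <- 0L
  for (st in starts) {
    st <- pmin(pmax(stats::setNames(as.double(st[theta_names]), theta_names),
                    lower), upper)
    fit <- nls.lm(par = st, lower = lower, upper = upper, fn = resid_fn,
                  control = ctrl)
    n_starts_used <- n_starts_used + 1L
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
    if (best$deviance / dof <= lazy_threshold) break
  }
  fit <- best

  est <- stats::setNames(as.double(fit$par), theta_names)
  se <- rep(NA_real_, length(est))
  red_chi2 <- fit$deviance / dof
  cv <- tryCatch(solve(fit$hessian) * red_chi2, error = function(e) NULL)
  if (!is.null(cv)) se <- sqrt(pmax(diag(cv), 0))
  names(se) <- theta_names

  rng <- ifelse(is.finite(upper) & is.finite(lower), upper - lower,
                pmax(abs(est), 1))
  tol <- pmax(1e-8 * pmax(rng, 1), 1e-10)
  at_lo <- is.finite(lower) & (est - lower) < tol
  at_hi <- is.finite(upper) & (upper - est) < tol
  at_bounds <- theta_names[at_lo | at_hi]

  values <- predicted <- residuals <- vector("list", nds)
  for (k in seq_len(nds)) {
    v <- ds[[k]]$params$values
    v[free_list[[k]]] <- est[maps[[k]]]
    values[[k]] <- v
    pk <- predict_k(k, est)
    predicted[[k]] <- histogram(ds[[k]]$decay$grid, pmax(pk, 0),
                                role = "decay",
                                condition = ds[[k]]$decay$condition)
    residuals[[k]] <- (obs[[k]] - pk[widx[[k]]]) * wts[[k]]
  }

  structure(list(
    estimates = est, std_errors = se,
    reduced_chi2 = red_chi2, chi2 = fit$deviance,
    degrees_of_freedom = dof, n_obs = n_obs,
    converged = fit$info %in% 1:3,
    status = list(info = fit$info, message = fit$message,
                  at_bounds = at_bounds, n_starts_used = n_starts_used),
    at_bounds = at_bounds,
    rsstrace = fit$rsstrace,
    dataset_values = values,
    predicted = predicted,
    residuals = residuals,
    windows = lapply(ds, function(d) d$window),
    sharing = shared,
    free = free_list
  ), class = "fret_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fret_fit <- function(x, ...) {
  cat(sprintf("<fret_fit>  reduced chi^2 = %.4f  (chi^2 = %.4g, dof = %d)\n",
              x$reduced_chi2, x$chi2, x$degrees_of_freedom))
  cat(if (x$converged) "  converged" else
    paste0("  NOT converged (info = ", x$status$info, ")"), "\n")
  if (length(x$at_bounds))
    cat("  at bounds:", paste(x$at_bounds, collapse = ", "), "\n")
  est <- x$estimates
  se <- x$std_errors
  for (nm in names(est))
    cat(sprintf("  %-12s %12.6g +/- %.3g\n", nm, est[[nm]], se[[nm]]))
  invisible(x)
}

## ---- protocol fits -------------------------------------------------------

.STANDARD_FREE_DECAY <- c("f_D", "rbar_1", "sigma_1", "f_A2", "rbar_2",
                          "sigma_2", "shift_irf", "A0", "bkgr_dec")
.STANDARD_FREE_DONOR <- c("tau_D1", "alpha_D1", "tau_D2", "shift_irf", "A0",
                          "bkgr_dec")

## f_B fixed to the acquisition-time ratio of sample and buffer measurement.
.f_B_from_durations <- function(decay, buffer) {
  if (is.null(buffer)) return(0)
  if (!is.na(decay$acquisition_duration) &&
      !is.na(buffer$acquisition_duration) &&
      buffer$acquisition_duration > 0)
    return(decay$acquisition_duration / buffer$acquisition_duration)
  NA_real_
}

## Configure params for a protocol fit: fix everything outside `free`,
## force the protocol-fixed values, and error on protocol violations.
.protocol_params <- function(params, free, standard, protocol_values,
                             allow_nonstandard) {
  .check_par_names(free)
  off <- setdiff(free, standard)
  if (length(off) && !allow_nonstandard)
    stop("parameter(s) ", paste(off, collapse = ", "),
         " are fixed by the standard fitting protocol; ",
         "set allow_nonstandard = TRUE to override")
  params$fixed[] <- TRUE
  params$fixed[free] <- FALSE
  if (!allow_nonstandard && length(protocol_values))
    params <- .set_values(params, protocol_values)
  params
}

#' Fit a buffer-only decay with a multi-exponential reconvolution model
#'
#' Estimates up to four exponential components (amplitudes in counts,
#' lifetimes in ns) plus a constant background by Poisson-weighted
#' chi-square minimization of the reconvolved prediction.  The returned
#' model is typically frozen and passed to the sample fits.
#'
#' @param buffer_decay Measured buffer-only `tcspc_histogram`.
#' @param irf Measured IRF on the same grid.
#' @param n_components Number of exponential components (1-4).
#' @param window Fit window; default from [default_fit_window()].
#' @param control Optional [minpack.lm::nls.lm.control()] overrides.
#' @return A list with elements `model` (a [buffer_model()] carrying the
#'   buffer acquisition duration) and `fit` (estimates, reduced chi-square,
#'   residuals, convergence status).
#' @export
fit_buffer <- function(buffer_decay, irf, n_components = 2L, window = NULL,
                       control = NULL) {
  stopifnot(inherits(buffer_decay, "tcspc_histogram"),
            inherits(irf, "tcspc_histogram"))
  if (!.same_grid(buffer_decay$grid, irf$grid))
    stop("buffer decay and IRF are on different grids")
  if (n_components < 1L || n_components > 4L)
    stop("n_components must be between 1 and 4")
  k <- as.integer(n_components)
  if (is.null(window)) window <- default_fit_window(buffer_decay, irf)
  idx <- .window_index(window, buffer_decay$grid$n_bins)
  obs <- buffer_decay$counts[idx]
  w <- 1 / sqrt(pmax(obs, 1))
  grid <- buffer_decay$grid

  taus0 <- exp(seq(log(0.7), log(8), length.out = k))
  bkgr0 <- max(mean(utils::tail(buffer_decay$counts, 32L)), 1e-3)
  tot <- max(sum(buffer_decay$counts) - bkgr0 * grid$n_bins, 1)
  amps0 <- rep(tot * grid$bin_width / sum(taus0), k)
  theta0 <- c(amps0, taus0, bkgr0)
  nm <- c(paste0("alpha_B", seq_len(k)), paste0("tau_B", seq_len(k)),
          "bkgr_dec")
  names(theta0) <- nm
  lower <- c(rep(0, k), rep(0.05, k), 0)
  upper <- c(rep(Inf, k), rep(50, k), Inf)

  resid_fn <- function(theta) {
    buf <- buffer_model(pmax(theta[seq_len(k)], 0),
                        pmax(theta[k + seq_len(k)], 1e-6))
    pred <- reconvolve(irf, buffer_intensity(buf, grid),
                       bkgr_dec = theta[2L * k + 1L])$counts
    (obs - pred[idx]) * w
  }
  ctrl <- do.call(nls.lm.control,
                  modifyList(list(maxiter = 200, nprint = 0),
                             as.list(control %||% list())))
  fit <- nls.lm(par = theta0, lower = lower, upper = upper, fn = resid_fn,
                control = ctrl)
  est <- stats::setNames(as.double(fit$par), nm)
  dof <- length(obs) - length(est)
  red <- fit$deviance / dof

  amps <- est[seq_len(k)]
  taus <- est[k + seq_len(k)]
  total_amp <- sum(amps)
  at_bounds <- nm[(abs(est - lower) < 1e-8) |
                    (is.finite(upper) & abs(upper - est) < 1e-8)]
  degenerate <- total_amp <= 1e-6 ||
    any(amps < 1e-6 * max(total_amp, 1)) || length(at_bounds) > 0
  model <- buffer_model(amps, taus,
                        acquisition_duration = buffer_decay$acquisition_duration)
  pred <- reconvolve(irf, buffer_intensity(model, grid),
                     bkgr_dec = est[["bkgr_dec"]])$counts
  list(
    model = model,
    fit = structure(list(
      estimates = est, reduced_chi2 = red, chi2 = fit$deviance,
      degrees_of_freedom = dof, converged = fit$info %in% 1:3,
      status = list(info = fit$info, message = fit$message,
                    at_bounds = at_bounds, degenerate = degenerate),
      at_bounds = at_bounds, rsstrace = fit$rsstrace,
      residuals = list((obs - pred[idx]) * w),
      predicted = list(histogram(grid, pmax(pred, 0), role = "decay")),
      windows = list(as.integer(window))
    ), class = "fret_fit")
  )
}

#' Starting values for a sample decay fit
#'
#' Deterministic, documented initialization built on a coarse template
#' scan.  The predicted decay is linear in the donor-only amplitude
#' (`f_D * A0`), the FRET amplitude (`(1 - f_D) * A0`) and the constant
#' background `bkgr_dec`, so for each candidate single-Gaussian distance
#' template (mean 14-66 Angstrom in 4 Angstrom steps, width 2/4/8
#' Angstrom) those three coefficients are solved by weighted linear least
#' squares and the best-scoring template wins.  It seeds `f_D`, `A0`,
#' `bkgr_dec` and the distances: for a two-Gaussian fit the winning mean is
#' split by +/- 5 Angstrom into the two starting components with
#' `f_A2 = 0.5` and `sigma = 3` Angstrom; for single-component fits the
#' live component takes the winning template directly.
#'
#' @inheritParams fit_decay
#' @param stage1 Apply the two-component split seeding (kept for API
#'   stability; the scan itself always runs).
#' @return `params` with updated starting values for the free parameters.
#' @export
init_decay_params <- function(decay, irf, buffer = NULL, params,
                              n_quad = 501L, window = NULL, stage1 = TRUE,
                              control = NULL) {
  grid <- decay$grid
  free <- .PAR_NAMES[!params$fixed]
  v <- params$values
  tc <- bin_centers(grid)

  a <- c(v[["alpha_D1"]], 1 - v[["alpha_D1"]])
  tau <- c(v[["tau_D1"]], v[["tau_D2"]])
  donor_curve <- a[1] * exp(-tc / tau[1])
  if (a[2] > 0) donor_curve <- donor_curve + a[2] * exp(-tc / tau[2])
  ud <- reconvolve(irf, donor_curve)$counts
  bufc <- if (!is.null(buffer) && v[["f_B"]] > 0)
    v[["f_B"]] * reconvolve(irf, buffer_intensity(buffer, grid))$counts
  else 0
  y <- decay$counts - bufc
  w <- 1 / pmax(decay$counts, 1)

  cache <- new.env(parent = emptyenv())
  best <- NULL
  for (r in seq(14, 66, by = 4)) {
    for (s in c(2, 4, 8)) {
      v1 <- v
      v1[c("f_D", "rbar_1", "sigma_1", "f_A2", "A0", "bkgr_dec",
           "shift_irf", "bkgr_irf")] <- c(0, r, s, 0, 1, 0, 0, 0)
      uf <- reconvolve(irf, .fret_intensity_values(v1, params$rho2, grid,
                                                   cache, n_quad))$counts
      co <- .linear_three(y, ud, uf, w)
      if (is.null(co)) next
      if (is.null(best) || co$chi2 < best$chi2)
        best <- c(co, list(r = r, s = s))
    }
  }
  if (is.null(best)) return(params)

  # sub-bin IRF shift: re-score the winning template on a shift grid
  v1 <- v
  v1[c("f_D", "rbar_1", "sigma_1", "f_A2", "A0", "bkgr_dec",
       "shift_irf", "bkgr_irf")] <- c(0, best$r, best$s, 0, 1, 0, 0, 0)
  mf <- .fret_intensity_values(v1, params$rho2, grid, cache, n_quad)
  shift0 <- 0
  for (sh in seq(-0.6, 0.6, by = 0.15) * 1000 * grid$bin_width) {
    ud_s <- reconvolve(irf, donor_curve, shift_irf = sh)$counts
    uf_s <- reconvolve(irf, mf, shift_irf = sh)$counts
    y_s <- if (!is.null(buffer) && v[["f_B"]] > 0)
      decay$counts - v[["f_B"]] *
        reconvolve(irf, buffer_intensity(buffer, grid),
                   shift_irf = sh)$counts
    else decay$counts
    co <- .linear_three(y_s, ud_s, uf_s, w)
    if (is.null(co)) next
    if (co$chi2 < best$chi2) {
      best <- c(co, list(r = best$r, s = best$s))
      shift0 <- sh
    }
  }

  clamp <- function(x, nm) min(max(x, params$lower[[nm]] + 1e-6),
                               params$upper[[nm]] - 1e-6)
  upd <- c(
    f_D = min(max(best$a1 / max(best$a1 + best$a2, 1e-12), 1e-3), 0.999),
    A0 = max(best$a1 + best$a2, 1e-6),
    bkgr_dec = max(best$b, 0),
    shift_irf = shift0
  )
  f2_fixed <- params$fixed[["f_A2"]]
  f2 <- v[["f_A2"]]
  two_gauss <- stage1 && !f2_fixed &&
    all(!params$fixed[c("rbar_1", "rbar_2")])
  if (two_gauss) {
    upd <- c(upd, rbar_1 = clamp(best$r + 5, "rbar_1"), sigma_1 = 3,
             f_A2 = 0.5,
             rbar_2 = clamp(best$r - 5, "rbar_2"), sigma_2 = 3)
  } else if (f2_fixed && f2 >= 1 - 1e-12) {
    upd <- c(upd, rbar_2 = clamp(best$r, "rbar_2"), sigma_2 = best$s)
  } else if (f2_fixed && f2 <= 1e-12) {
    upd <- c(upd, rbar_1 = clamp(best$r, "rbar_1"), sigma_1 = best$s)
  } else {
    # both components live but f_A2 fixed at an intermediate value
    upd <- c(upd, rbar_1 = clamp(best$r + 5, "rbar_1"), sigma_1 = 3,
             rbar_2 = clamp(best$r - 5, "rbar_2"), sigma_2 = 3)
  }
  upd <- upd[intersect(names(upd), free)]
  if (length(upd)) params <- .set_values(params, upd)
  params
}

## Weighted least-squares solve of y ~ a1 * u1 + a2 * u2 + b, coefficients
## clipped at zero (with refits) so the seeds stay physical.
.linear_three <- function(y, u1, u2, w) {
  X <- cbind(u1, u2, 1)
  XtW <- t(X * w)
  co <- tryCatch(solve(XtW %*% X, XtW %*% y), error = function(e) NULL)
  if (is.null(co) || any(!is.finite(co))) return(NULL)
  co <- as.vector(co)
  if (co[3] < 0) {  # drop the background, refit the two amplitudes
    X2 <- X[, 1:2]
    XtW2 <- t(X2 * w)
    co2 <- tryCatch(solve(XtW2 %*% X2, XtW2 %*% y), error = function(e) NULL)
    if (is.null(co2) || any(!is.finite(co2))) return(NULL)
    co <- c(as.vector(co2), 0)
  }
  co[1:2] <- pmax(co[1:2], 0)
  if (co[1] + co[2] <= 0) return(NULL)
  r <- y - X %*% co
  list(a1 = co[1], a2 = co[2], b = co[3], chi2 = sum(w * r^2))
}

#' Fit a donor-only decay
#'
#' Standard protocol for the acceptor-free control sample: `f_D` is fixed at
#' 1, `f_B` is fixed to the acquisition-time ratio, `bkgr_irf` is fixed to
#' 0, and only the donor lifetimes/fraction, IRF shift, amplitude and decay
#' background vary.  The fitted donor parameters are then frozen for the
#' sample fits.
#'
#' @inheritParams fit_decay
#' @export
fit_donor_only <- function(decay, irf, buffer = NULL, params = NULL,
                           free = NULL, window = NULL, n_quad = 501L,
                           allow_nonstandard = FALSE, control = NULL) {
  if (is.null(params))
    params <- fret_params(f_D = 1, tau_D1 = 15, alpha_D1 = 0.8, tau_D2 = 4)
  if (is.null(free)) free <- .STANDARD_FREE_DONOR
  fB <- .f_B_from_durations(decay, buffer)
  if (is.na(fB)) fB <- params$values[["f_B"]]
  params <- .protocol_params(params, free, .STANDARD_FREE_DONOR,
                             c(f_D = 1, f_B = fB, bkgr_irf = 0),
                             allow_nonstandard)
  # amplitude / background starting values
  bkgr0 <- max(mean(utils::tail(decay$counts, 32L)), 1e-3)
  tau0 <- params$values[["tau_D1"]]
  a00 <- max((sum(decay$counts) - bkgr0 * decay$grid$n_bins) /
               max(tau0 / decay$grid$bin_width, 1), 1e-6) /
    max(params$values[["alpha_D1"]], 0.5)
  params <- .set_values(params, c(A0 = a00, bkgr_dec = bkgr0))
  spec <- fit_spec(list(fit_dataset(decay, irf, buffer, params, window)),
                   n_quad = n_quad)
  .fit_engine(spec, control = control)
}

#' Fit a donor + acceptor decay with the Gaussian distance-distribution model
#'
#' Standard protocol: the donor lifetimes/fraction are constrained to the
#' values previously determined from the donor-only sample, `R0` is fixed to
#' its spectroscopically determined value, `f_B` is fixed to the
#' acquisition-time ratio, and `bkgr_irf` is fixed to 0.  The free subset of
#' `f_D`, `rbar_1`, `sigma_1`, `f_A2`, `rbar_2`, `sigma_2`, `shift_irf`,
#' `A0`, `bkgr_dec` is estimated by bounded Poisson-weighted chi-square
#' minimization.  When `params` carries a `rho2` block, the two-acceptor
#' (intersubunit) model is used with the `rho2` component means/sds fixed
#' and its mixing fraction tied to `f_A2`.
#'
#' Two-Gaussian fits (free `f_A2`) are protected against local minima by up
#' to three deterministic jittered starts; later starts are only run when
#' the incumbent's reduced chi-square exceeds 1.2.
#'
#' @param decay,irf `tcspc_histogram`s on one grid.
#' @param buffer A frozen [buffer_model()] or `NULL`.
#' @param params A [fret_params()] with the donor parameters and `R0` set
#'   (e.g. from [fit_donor_only()]).  Parameters marked fixed in `params`
#'   (such as `f_A2` for single-state fits) are excluded from the default
#'   free set.
#' @param free Character vector of parameters to vary; defaults to the
#'   standard protocol subset minus any that `params` fixes.
#' @param window Fit window `c(first, last)`; default from
#'   [default_fit_window()].
#' @param init `"auto"` (default) seeds starting values with
#'   [init_decay_params()]; `"given"` uses the values in `params` as-is.
#' @param multistart Use jittered extra starts for two-Gaussian fits.
#' @param n_quad Trapezoid points per Gaussian distance component.
#' @param allow_nonstandard Permit a free set outside the standard protocol.
#' @param control Optional [minpack.lm::nls.lm.control()] overrides.
#' @return A `fret_fit`.
#' @export
fit_decay <- function(decay, irf, buffer = NULL, params, free = NULL,
                      window = NULL, init = c("auto", "given"),
                      multistart = TRUE, n_quad = 501L,
                      allow_nonstandard = FALSE, control = NULL) {
  init <- match.arg(init)
  stopifnot(inherits(params, "fret_params"))
  if (is.null(free))
    free <- setdiff(.STANDARD_FREE_DECAY, .PAR_NAMES[params$fixed])
  fB <- .f_B_from_durations(decay, buffer)
  if (is.na(fB)) fB <- params$values[["f_B"]]
  params <- .protocol_params(params, free, .STANDARD_FREE_DECAY,
                             c(f_B = fB, bkgr_irf = 0), allow_nonstandard)
  if (init == "auto")
    params <- init_decay_params(decay, irf, buffer, params, n_quad,
                                window = window, control = control)
  spec <- fit_spec(list(fit_dataset(decay, irf, buffer, params, window)),
                   n_quad = n_quad)
  .fit_engine(spec, control = control, auto_jitter = multistart)
}

#' Prepare a seeded global fit specification
#'
#' Builds a [fit_spec()] over several decays measured under different
#' conditions (e.g. a ligand titration), sharing the distance-distribution
#' shape parameters across datasets as in the standard protocol.  Each
#' dataset is seeded with [init_decay_params()]; the shared component means
#' are then re-seeded from the spread of the per-dataset template scans
#' (the least-quenched dataset pins the resting distance, the most-quenched
#' the active one) and each dataset's starting `f_A2` is placed by linear
#' interpolation between them.
#'
#' @param decays List of decay `tcspc_histogram`s (one per condition).
#' @param irf Shared IRF histogram.
#' @param buffer Frozen [buffer_model()] or `NULL`.
#' @param params Parameter template (donor values, `R0`, `rho2`, bounds).
#' @param sharing Parameters shared across datasets.
#' @param window Optional common fit window.
#' @param n_quad Trapezoid points per Gaussian component.
#' @return A `fret_fit_spec` ready for [fit_global()].
#' @export
prepare_global_spec <- function(decays, irf, buffer = NULL, params,
                                sharing = c("rbar_1", "sigma_1", "rbar_2",
                                            "sigma_2"),
                                window = NULL, n_quad = 501L) {
  stopifnot(length(decays) >= 1L, inherits(params, "fret_params"))
  pl <- lapply(decays, function(d) {
    p <- .protocol_params(params, setdiff(.STANDARD_FREE_DECAY,
                                          .PAR_NAMES[params$fixed]),
                          .STANDARD_FREE_DECAY,
                          c(f_B = {
                            fb <- .f_B_from_durations(d, buffer)
                            if (is.na(fb)) params$values[["f_B"]] else fb
                          }, bkgr_irf = 0), FALSE)
    init_decay_params(d, irf, buffer, p, n_quad = n_quad, window = window)
  })
  # per-dataset scan means (the split seeds are scan mean +/- 5)
  r_scan <- vapply(pl, function(p)
    (p$values[["rbar_1"]] + p$values[["rbar_2"]]) / 2, 0)
  r_hi <- max(r_scan)
  r_lo <- min(r_scan)
  if (r_hi - r_lo < 4) { r_hi <- r_hi + 2; r_lo <- r_lo - 2 }
  for (k in seq_along(pl)) {
    upd <- c(rbar_1 = r_hi + 2, rbar_2 = r_lo - 2)
    if (!pl[[k]]$fixed[["f_A2"]])
      upd <- c(upd, f_A2 = min(max((r_hi - r_scan[k]) / (r_hi - r_lo),
                                   0.05), 0.95))
    upd <- upd[intersect(names(upd), .PAR_NAMES[!pl[[k]]$fixed])]
    if (length(upd)) pl[[k]] <- .set_values(pl[[k]], upd)
  }
  datasets <- lapply(seq_along(decays), function(k)
    fit_dataset(decays[[k]], irf, buffer, pl[[k]], window))
  fit_spec(datasets, sharing = sharing, n_quad = n_quad)
}

#' Global fit over multiple decays with shared parameters
#'
#' Minimizes the summed Poisson-weighted chi-square over all datasets of a
#' [fit_spec()], with the parameters named in `spec$sharing` constrained
#' equal across datasets.  Starting values are taken from each dataset's
#' `params` (seed them with [init_decay_params()] or from single fits).
#'
#' @param spec A [fit_spec()] with at least two datasets.
#' @param control Optional [minpack.lm::nls.lm.control()] overrides.
#' @return A `fret_fit`; shared parameters appear once in `estimates`,
#'   dataset-private parameters as `name@k`.
#' @export
fit_global <- function(spec, control = NULL) {
  stopifnot(inherits(spec, "fret_fit_spec"))
  if (length(spec$datasets) < 2L)
    stop("global fitting requires at least two datasets")
  .fit_engine(spec, control = control, auto_jitter = TRUE)
}
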