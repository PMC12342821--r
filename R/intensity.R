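## ---- distance quadrature -------------------------------------------------
##
## Each Gaussian component is integrated by the trapezoid rule on its own
## uniform grid spanning rbar +/- 8 sigma, truncated below at r = 0.5
## Angstrom (where the transfer rate is astronomically fast and the density
## of any physical distribution is nil).  The truncated density is
## renormalized on that window, so components keep unit mass whatever the
## clipping.  501 points resolve any sigma, including the sigma -> 0
## single-distance limit, because the grid follows the component.

.R_MIN <- 0.5

.gauss_quad <- function(rbar, sigma, n_quad = 501L) {
  if (sigma <= 0) stop("sigma must be > 0")
  lo <- max(.R_MIN, rbar - 8 * sigma)
  hi <- max(rbar + 8 * sigma, lo + 16 * sigma)
  r <- seq(lo, hi, length.out = n_quad)
  h <- r[2L] - r[1L]
  w <- rep.int(h, n_quad)
  w[c(1L, n_quad)] <- h / 2
  d <- dnorm(r, rbar, sigma)
  z <- sum(w * d)
  if (z <= 0) stop("degenerate distance quadrature (no density mass)")
  list(r = r, p = w * d / z)
}

## FRET-quenched exponential kernel for one Gaussian distance component and
## one donor lifetime:
##   include_donor_rate = TRUE :  k(t) = int rho(r) exp(-t (1 + (R0/r)^6) / tau) dr
##   include_donor_rate = FALSE:  x(t) = int rho(r) exp(-t (R0/r)^6 / tau) dr
## The FALSE form is the extra-acceptor factor of the product-of-integrals
## two-acceptor model.
.fret_kernel <- function(tc, rbar, sigma, R0, tau, include_donor_rate = TRUE,
                         n_quad = 501L) {
  q <- .gauss_quad(rbar, sigma, n_quad)
  rate <- (R0 / q$r)^6 / tau
  if (include_donor_rate) rate <- rate + 1 / tau
  as.vector(q$p %*% exp(-outer(rate, tc)))
}

## Memoized kernel lookup.  `cache` is an environment (or NULL to disable);
## keys encode every input that the kernel depends on.  During numeric
## Jacobian evaluation most parameter perturbations leave the kernels
## untouched, so caching removes the dominant cost of refitting.
.cached_kernel <- function(cache, grid_key, tc, rbar, sigma, R0, tau,
                           include_donor_rate, n_quad) {
  if (is.null(cache))
    return(.fret_kernel(tc, rbar, sigma, R0, tau, include_donor_rate, n_quad))
  key <- sprintf("%s|%.12g|%.12g|%.12g|%.12g|%d|%d", grid_key, rbar, sigma,
                 R0, tau, as.integer(include_donor_rate), n_quad)
  val <- cache[[key]]
  if (is.null(val)) {
    val <- .fret_kernel(tc, rbar, sigma, R0, tau, include_donor_rate, n_quad)
    cache[[key]] <- val
  }
  val
}

## ---- model intensities ---------------------------------------------------

## Core unconvolved donor intensity for a 15-parameter vector `v` plus an
## optional intersubunit block `rho2`.  Returns per-bin counts at bin centers.
.fret_intensity_values <- function(v, rho2, grid, cache = NULL,
                                   n_quad = 501L) {
  .validate_fret_values(v)
  tc <- bin_centers(grid)
  gk <- .grid_id(grid)
  a <- c(v[["alpha_D1"]], 1 - v[["alpha_D1"]])
  tau <- c(v[["tau_D1"]], v[["tau_D2"]])
  donor <- a[1] * exp(-tc / tau[1])
  if (a[2] > 0) donor <- donor + a[2] * exp(-tc / tau[2])
  fD <- v[["f_D"]]
  if (fD >= 1 - 1e-15) return(v[["A0"]] * donor)

  f2 <- v[["f_A2"]]
  frac <- c(1 - f2, f2)
  rb1 <- c(v[["rbar_1"]], v[["rbar_2"]])
  sg1 <- c(v[["sigma_1"]], v[["sigma_2"]])
  R0 <- v[["R0"]]
  fret <- numeric(grid$n_bins)
  for (i in 1:2) {
    if (a[i] <= 0) next
    intra <- numeric(grid$n_bins)
    for (j in 1:2) {
      if (frac[j] <= 1e-12) next
      intra <- intra + frac[j] *
        .cached_kernel(cache, gk, tc, rb1[j], sg1[j], R0, tau[i], TRUE, n_quad)
    }
    comp <- intra
    if (!is.null(rho2)) {
      inter <- numeric(grid$n_bins)
      for (j in 1:2) {
        if (frac[j] <= 1e-12) next
        inter <- inter + frac[j] *
          .cached_kernel(cache, gk, tc, rho2$rbar[j], rho2$sigma[j], R0,
                         tau[i], FALSE, n_quad)
      }
      comp <- comp * inter
    }
    fret <- fret + a[i] * comp
  }
  v[["A0"]] * (fD * donor + (1 - fD) * fret)
}

#' Unconvolved donor intensity in the presence of one FRET acceptor
#'
#' Evaluates the single-acceptor FRET model for the donor fluorescence
#' intensity at the bin centers of `grid`: a donor-only term (weight `f_D`)
#' plus a term in which each donor lifetime component is quenched by a FRET
#' rate `(R0/r)^6 / tau` averaged over the Gaussian distance distribution.
#'
#' @param params A [fret_params()] *without* a `rho2` block.
#' @param grid A [time_grid()].
#' @param n_quad Number of trapezoid points per Gaussian component.
#' @return Numeric vector of per-bin intensities (counts).
#' @seealso [fret_intensity_double()] for the two-acceptor (intersubunit)
#'   model, [reconvolve()] to turn intensities into predicted histograms.
#' @export
fret_intensity_single <- function(params, grid, n_quad = 501L) {
  stopifnot(inherits(params, "fret_params"), inherits(grid, "time_grid"))
  if (!is.null(params$rho2))
    stop("params carry an intersubunit rho2 block; use fret_intensity_double()")
  .fret_intensity_values(params$values, NULL, grid, n_quad = n_quad)
}

#' Unconvolved donor intensity with two independent FRET acceptors
#'
#' Two-acceptor (intersubunit) extension of the FRET model: the second
#' acceptor contributes an additional distance-averaged quenching factor, and
#' because the two distance distributions are independent the double integral
#' factorizes into a product of one-dimensional integrals, evaluated here.
#' The intersubunit distribution's component means and sds come from
#' `params$rho2`; its mixing fraction is tied to the intrasubunit `f_A2`.
#'
#' @inheritParams fret_intensity_single
#' @param params A [fret_params()] *with* a `rho2` block.
#' @export
fret_intensity_double <- function(params, grid, n_quad = 501L) {
  stopifnot(inherits(params, "fret_params"), inherits(grid, "time_grid"))
  if (is.null(params$rho2))
    stop("params lack an intersubunit rho2 block; use fret_intensity_single()")
  .fret_intensity_values(params$values, params$rho2, grid, n_quad = n_quad)
}

#' Buffer-only model intensity
#'
#' Multi-exponential (up to four components) model of buffer background
#' fluorescence, evaluated at bin centers.  Amplitudes are in counts.
#'
#' @param buf A [buffer_model()].
#' @param grid A [time_grid()].
#' @export
buffer_intensity <- function(buf, grid) {
  stopifnot(inherits(buf, "buffer_model"), inherits(grid, "time_grid"))
  tc <- bin_centers(grid)
  out <- numeric(grid$n_bins)
  for (i in seq_along(buf$amplitudes))
    out <- out + buf$amplitudes[i] * exp(-tc / buf$lifetimes[i])
  out
}
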