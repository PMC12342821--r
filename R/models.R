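#' Donor-only fluorescence model
#'
#' One or two exponential components for the donor fluorophore in the absence
#' of acceptor.  Amplitude fractions are dimensionless and must sum to 1
#' (alpha_D1 + alpha_D2 = 1); lifetimes are in ns.
#'
#' @param lifetimes Numeric vector of 1 or 2 lifetimes (ns), all > 0.
#' @param fractions Amplitude fractions, same length, summing to 1.
#'   Defaults to a single component.
#' @export
donor_model <- function(lifetimes, fractions = NULL) {
  n <- length(lifetimes)
  if (n < 1L || n > 2L) stop("donor model must have 1 or 2 components")
  if (is.null(fractions)) fractions <- if (n == 1L) 1 else stop(
    "`fractions` required for a two-component donor")
  if (length(fractions) != n) stop("lifetimes/fractions length mismatch")
  if (any(lifetimes <= 0)) stop("donor lifetimes must be > 0")
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-8)
    stop("donor amplitude fractions must be >= 0 and sum to 1")
  structure(list(lifetimes = as.double(lifetimes),
                 fractions = as.double(fractions)),
            class = "donor_model")
}

#' Buffer fluorescence model
#'
#' Up to four exponential components describing the background fluorescence
#' of a buffer-only sample.  Unlike the donor model, amplitudes are in counts
#' and are not normalized.
#'
#' @param amplitudes Component amplitudes in counts, all >= 0 (1-4 values).
#' @param lifetimes Component lifetimes in ns, all > 0.
#' @param acquisition_duration Optional acquisition time (s) of the
#'   buffer-only measurement the model was fit to; used downstream to fix
#'   the `f_B` scaling of sample fits.
#' @export
buffer_model <- function(amplitudes, lifetimes,
                         acquisition_duration = NA_real_) {
  n <- length(amplitudes)
  if (n < 1L || n > 4L) stop("buffer model must have 1 to 4 components")
  if (length(lifetimes) != n) stop("amplitudes/lifetimes length mismatch")
  if (any(amplitudes < 0)) stop("buffer amplitudes must be >= 0")
  if (any(lifetimes <= 0)) stop("buffer lifetimes must be > 0")
  structure(list(amplitudes = as.double(amplitudes),
                 lifetimes = as.double(lifetimes),
                 acquisition_duration = as.double(acquisition_duration)),
            class = "buffer_model")
}

#' Gaussian donor-acceptor distance distribution
#'
#' The density of donor-acceptor distances is modeled as the sum of up to two
#' Gaussians, one per conformational state, truncated to positive distances
#' and renormalized.  Component fractions (f_A1 + f_A2 = 1) carry the state
#' occupancies that the energetics module converts to free energies.
#'
#' @param mean Component mean distances r-bar in Angstrom, all > 0 (1-2 values).
#' @param sd Component standard deviations sigma in Angstrom, all > 0.
#' @param fraction Component fractions summing to 1; defaults to 1 for a
#'   single component.
#' @export
distance_distribution <- function(mean, sd, fraction = NULL) {
  n <- length(mean)
  if (n < 1L || n > 2L)
    stop("distance distribution must have 1 or 2 Gaussian components")
  if (length(sd) != n) stop("mean/sd length mismatch")
  if (is.null(fraction)) {
    if (n != 1L) stop("`fraction` required for a two-component distribution")
    fraction <- 1
  }
  if (length(fraction) != n) stop("mean/fraction length mismatch")
  if (any(mean <= 0)) stop("mean distances must be > 0")
  if (any(sd <= 0)) stop("distance standard deviations must be > 0")
  if (any(fraction < 0) || abs(sum(fraction) - 1) > 1e-8)
    stop("component fractions must be >= 0 and sum to 1")
  structure(list(mean = as.double(mean), sd = as.double(sd),
                 fraction = as.double(fraction)),
            class = "distance_distribution")
}

#' Distance-distribution density
#'
#' Evaluates the (truncated, renormalized) Gaussian-mixture density of
#' donor-acceptor distances.  Each component is renormalized over r > 0, so
#' the mixture integrates to 1 on (0, Inf).
#'
#' @param dist A [distance_distribution()].
#' @param r Distances in Angstrom, all >= 0.
#' @return Density values in 1/Angstrom.
#' @examples
#' d <- distance_distribution(40, 3)
#' distance_density(d, 40)  # ~ 1 / (3 * sqrt(2 * pi))
#' @export
distance_density <- function(dist, r) {
  stopifnot(inherits(dist, "distance_distribution"))
  if (any(!is.finite(r)) || any(r < 0))
    stop("distances must be finite and >= 0")
  out <- numeric(length(r))
  for (j in seq_along(dist$mean)) {
    # mass of the untruncated Gaussian on r > 0
    z <- pnorm(0, dist$mean[j], dist$sd[j], lower.tail = FALSE)
    out <- out + dist$fraction[j] * dnorm(r, dist$mean[j], dist$sd[j]) / z
  }
  out
}
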