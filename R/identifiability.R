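#' Chi-square profile of one model parameter
#'
#' Classical profile-likelihood style identifiability diagnostic: for each
#' grid value the parameter is fixed and all remaining free parameters are
#' re-optimized, recording the reduced chi-square.  Well-determined
#' parameters give sharply convex profiles with the minimum at the
#' unconstrained estimate; shallow profiles (typical of the distribution
#' widths sigma) indicate poorly determined parameters.
#'
#' @param spec A [fit_spec()] in which `parameter` is free.
#' @param parameter Name of a free model parameter.
#' @param values Numeric grid of values to profile over (non-empty).
#' @param control Optional [minpack.lm::nls.lm.control()] overrides.
#' @return A data frame with columns `value` and `reduced_chi2`
#'   (class `chi2_profile`).
#' @export
chi2_profile <- function(spec, parameter, values, control = NULL) {
  stopifnot(inherits(spec, "fret_fit_spec"))
  .check_par_names(parameter)
  if (!length(values)) stop("`values` must be a non-empty numeric grid")
  free_anywhere <- any(vapply(spec$datasets,
                              function(d) !d$params$fixed[[parameter]], TRUE))
  if (!free_anywhere)
    stop("parameter '", parameter, "' is fixed in the fit specification; ",
         "profiling a fixed parameter is not meaningful")
  red <- vapply(values, function(v) {
    sp <- .fix_in_spec(spec, stats::setNames(v, parameter))
    .fit_engine(sp, control = control)$reduced_chi2
  }, numeric(1))
  structure(data.frame(value = values, reduced_chi2 = red),
            class = c("chi2_profile", "data.frame"),
            parameter = parameter)
}

#' Reduced chi-square surface over a pair of parameters
#'
#' Two-dimensional analogue of [chi2_profile()]: both parameters are fixed
#' on a grid and the remaining free parameters re-optimized at each node.
#' A tilted valley in the surface reveals correlation between the pair.
#'
#' @inheritParams chi2_profile
#' @param parameters Character vector of two free parameter names.
#' @param values1,values2 Grids for the first and second parameter.
#' @return A list (class `chi2_surface`) with `x`, `y` and the matrix
#'   `reduced_chi2` (rows index `values1`).
#' @export
chi2_surface <- function(spec, parameters, values1, values2,
                         control = NULL) {
  stopifnot(inherits(spec, "fret_fit_spec"), length(parameters) == 2L)
  .check_par_names(parameters)
  if (!length(values1) || !length(values2))
    stop("`values1` and `values2` must be non-empty")
  for (p in parameters) {
    free_anywhere <- any(vapply(spec$datasets,
                                function(d) !d$params$fixed[[p]], TRUE))
    if (!free_anywhere)
      stop("parameter '", p, "' is fixed in the fit specification")
  }
  z <- matrix(NA_real_, length(values1), length(values2))
  for (i in seq_along(values1)) {
    for (j in seq_along(values2)) {
      sp <- .fix_in_spec(spec, stats::setNames(c(values1[i], values2[j]),
                                               parameters))
      z[i, j] <- .fit_engine(sp, control = control)$reduced_chi2
    }
  }
  structure(list(x = values1, y = values2, reduced_chi2 = z,
                 parameters = parameters),
            class = "chi2_surface")
}

## Return a copy of `spec` with the named parameters set and fixed in every
## dataset (and dropped from the sharing set).
.fix_in_spec <- function(spec, values) {
  nms <- names(values)
  spec$sharing <- setdiff(spec$sharing, nms)
  spec$datasets <- lapply(spec$datasets, function(d) {
    d$params <- .set_values(d$params, values)
    d$params <- .set_fixed(d$params, nms, TRUE)
    d
  })
  spec
}

#' Curvature of a chi-square profile at its minimum
#'
#' Central second difference of the reduced chi-square around the profile
#' minimum, normalized by the grid step; used to compare how well different
#' parameters are determined.
#'
#' @param profile A `chi2_profile`.
#' @return Second difference per unit step squared.
#' @export
profile_curvature <- function(profile) {
  stopifnot(inherits(profile, "chi2_profile"))
  z <- profile$reduced_chi2
  i <- which.min(z)
  i <- min(max(i, 2L), length(z) - 1L)
  h <- profile$value[i + 1L] - profile$value[i]
  (z[i - 1L] - 2 * z[i] + z[i + 1L]) / h^2
}
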