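## Default box bounds for the 15 model parameters.  Distances in Angstrom,
## lifetimes in ns, shift in ps, amplitudes/backgrounds in counts.
.default_bounds <- function() {
  lower <- c(f_D = 0, tau_D1 = 0.1, alpha_D1 = 0, tau_D2 = 0.1, R0 = 1,
             rbar_1 = 10, sigma_1 = 0.1, f_A2 = 0, rbar_2 = 10, sigma_2 = 0.1,
             shift_irf = -1000, f_B = 0, A0 = 0, bkgr_dec = 0, bkgr_irf = 0)
  upper <- c(f_D = 1, tau_D1 = 50, alpha_D1 = 1, tau_D2 = 50, R0 = 100,
             rbar_1 = 100, sigma_1 = 20, f_A2 = 1, rbar_2 = 100, sigma_2 = 20,
             shift_irf = 1000, f_B = 100, A0 = Inf, bkgr_dec = Inf,
             bkgr_irf = Inf)
  list(lower = lower, upper = upper)
}

#' FRET model parameter vector
#'
#' The 15-parameter vector of the reconvolution FRET model, with
#' per-parameter fixed/varied flags and box bounds, plus an optional
#' intersubunit acceptor block (`rho2`).
#'
#' The 15 scalars are, in canonical order: `f_D` (fraction of donor-only
#' fluorescence), `tau_D1`, `alpha_D1`, `tau_D2` (donor-only lifetimes in ns
#' and first-component amplitude fraction, with `alpha_D2 = 1 - alpha_D1`),
#' `R0` (Forster distance, Angstrom), `rbar_1`, `sigma_1`, `f_A2`, `rbar_2`,
#' `sigma_2` (two-Gaussian donor-acceptor distance distribution, Angstrom;
#' `f_A2` is the fraction in the second, active-state component),
#' `shift_irf` (IRF/decay time shift, ps), `f_B` (buffer scaling), `A0`
#' (model amplitude, counts), `bkgr_dec` and `bkgr_irf` (time-independent
#' backgrounds, counts).
#'
#' When `rho2` is supplied the model gains a second, intersubunit FRET
#' acceptor whose distance distribution has fixed component means/sds and
#' whose mixing fraction is always tied to `f_A2` of the intrasubunit
#' distribution.
#'
#' @param f_D,tau_D1,alpha_D1,tau_D2,R0,rbar_1,sigma_1,f_A2,rbar_2,sigma_2,shift_irf,f_B,A0,bkgr_dec,bkgr_irf
#'   Model parameter values (see Description).
#' @param fixed Named logical vector of fixed flags to override the defaults
#'   (`R0`, `f_B` and `bkgr_irf` fixed; everything else free).
#' @param lower,upper Named numeric vectors overriding default box bounds.
#' @param rho2 Optional intersubunit acceptor block:
#'   `list(rbar = c(resting, active), sigma = c(resting, active))` in
#'   Angstrom.  Its mixing fraction is tied to `f_A2`.
#' @return An object of class `fret_params`.
#' @export
fret_params <- function(f_D = 0, tau_D1 = 17.6, alpha_D1 = 0.87,
                        tau_D2 = 4.73, R0 = 43.5,
                        rbar_1 = 45, sigma_1 = 3, f_A2 = 0,
                        rbar_2 = 30, sigma_2 = 3,
                        shift_irf = 0, f_B = 0, A0 = 1,
                        bkgr_dec = 0, bkgr_irf = 0,
                        fixed = NULL, lower = NULL, upper = NULL,
                        rho2 = NULL) {
  values <- c(f_D = f_D, tau_D1 = tau_D1, alpha_D1 = alpha_D1,
              tau_D2 = tau_D2, R0 = R0, rbar_1 = rbar_1, sigma_1 = sigma_1,
              f_A2 = f_A2, rbar_2 = rbar_2, sigma_2 = sigma_2,
              shift_irf = shift_irf, f_B = f_B, A0 = A0,
              bkgr_dec = bkgr_dec, bkgr_irf = bkgr_irf)
  stopifnot(identical(names(values), .PAR_NAMES))
  fixed_def <- stats::setNames(rep(FALSE, 15L), .PAR_NAMES)
  fixed_def[c("R0", "f_B", "bkgr_irf")] <- TRUE
  if (!is.null(fixed)) {
    .check_par_names(names(fixed))
    fixed_def[names(fixed)] <- as.logical(fixed)
  }
  b <- .default_bounds()
  if (!is.null(lower)) { .check_par_names(names(lower)); b$lower[names(lower)] <- lower }
  if (!is.null(upper)) { .check_par_names(names(upper)); b$upper[names(upper)] <- upper }
  if (!is.null(rho2)) {
    if (!is.list(rho2) || !all(c("rbar", "sigma") %in% names(rho2)) ||
        length(rho2$rbar) != 2L || length(rho2$sigma) != 2L)
      stop("`rho2` must be list(rbar = c(.,.), sigma = c(.,.))")
    if (any(rho2$rbar <= 0) || any(rho2$sigma <= 0))
      stop("rho2 means and sds must be > 0")
    rho2 <- list(rbar = as.double(rho2$rbar), sigma = as.double(rho2$sigma))
  }
  .validate_fret_values(values)
  structure(list(values = values, fixed = fixed_def,
                 lower = b$lower, upper = b$upper, rho2 = rho2),
            class = "fret_params")
}

.check_par_names <- function(nms) {
  bad <- setdiff(nms, .PAR_NAMES)
  if (length(bad))
    stop("unknown parameter name(s): ", paste(bad, collapse = ", "))
}

.validate_fret_values <- function(v) {
  if (v[["R0"]] <= 0) stop("R0 must be > 0")
  if (v[["tau_D1"]] <= 0 || v[["tau_D2"]] <= 0)
    stop("donor lifetimes must be > 0")
  if (v[["f_D"]] < 0 || v[["f_D"]] > 1) stop("f_D must be in [0, 1]")
  if (v[["f_A2"]] < 0 || v[["f_A2"]] > 1) stop("f_A2 must be in [0, 1]")
  if (v[["alpha_D1"]] < 0 || v[["alpha_D1"]] > 1)
    stop("alpha_D1 must be in [0, 1]")
  if (v[["f_B"]] < 0) stop("f_B must be >= 0")
  if (v[["bkgr_dec"]] < 0 || v[["bkgr_irf"]] < 0)
    stop("backgrounds must be >= 0")
  invisible(v)
}

#' @export
print.fret_params <- function(x, ...) {
  cat("<fret_params>", if (!is.null(x$rho2)) " + intersubunit acceptor (rho2)",
      "\n", sep = "")
  flag <- ifelse(x$fixed, "fixed", "free")
  for (nm in .PAR_NAMES)
    cat(sprintf("  %-10s %12.6g  (%s)\n", nm, x$values[[nm]], flag[[nm]]))
  if (!is.null(x$rho2))
    cat(sprintf("  rho2: rbar = %.3g/%.3g A, sigma = %.3g/%.3g A (tied to f_A2)\n",
                x$rho2$rbar[1], x$rho2$rbar[2],
                x$rho2$sigma[1], x$rho2$sigma[2]))
  invisible(x)
}

## Replace values (named) in a fret_params, revalidating.
.set_values <- function(params, values) {
  .check_par_names(names(values))
  params$values[names(values)] <- values
  .validate_fret_values(params$values)
  params
}

## Set fixed flags by name.
.set_fixed <- function(params, names, fixed = TRUE) {
  .check_par_names(names)
  params$fixed[names] <- fixed
  params
}

## Donor model implied by a parameter vector.
.donor_from_values <- function(v) {
  a1 <- v[["alpha_D1"]]
  if (a1 >= 1 - 1e-12) donor_model(v[["tau_D1"]])
  else donor_model(c(v[["tau_D1"]], v[["tau_D2"]]), c(a1, 1 - a1))
}

## Intrasubunit distance distribution implied by a parameter vector.
.rho1_from_values <- function(v) {
  f2 <- v[["f_A2"]]
  if (f2 <= 1e-12) distance_distribution(v[["rbar_1"]], v[["sigma_1"]])
  else if (f2 >= 1 - 1e-12)
    distance_distribution(v[["rbar_2"]], v[["sigma_2"]])
  else distance_distribution(c(v[["rbar_1"]], v[["rbar_2"]]),
                             c(v[["sigma_1"]], v[["sigma_2"]]),
                             c(1 - f2, f2))
}
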