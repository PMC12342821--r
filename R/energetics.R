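#' Energetics configuration
#'
#' Gas constant and absolute temperature used by the Boltzmann conversion
#' between state occupancies and free energies.  Energies are in kcal/mol
#' throughout.
#'
#' @param temperature Absolute temperature in K (default 298.15).
#' @param gas_constant Universal gas constant in kcal mol^-1 K^-1.
#' @export
energetics_config <- function(temperature = 298.15,
                              gas_constant = 1.9872e-3) {
  if (temperature <= 0) stop("temperature must be > 0 K")
  if (gas_constant <= 0) stop("gas constant must be > 0")
  structure(list(temperature = temperature, gas_constant = gas_constant),
            class = "energetics_config")
}

#' Conformational free energy from an active-state occupancy
#'
#' Boltzmann relation for a two-state equilibrium: the fraction of the
#' distance distribution in the active-state component, `f_A2`, maps to the
#' free energy of the resting-to-active transition as
#' `delta G = -RT * ln(f_A2 / (1 - f_A2))` (kcal/mol).
#'
#' @param f_A2 Active-state fraction(s), strictly inside (0, 1).
#' @param config An [energetics_config()].
#' @return Free energy in kcal/mol (vectorized over `f_A2`).
#' @examples
#' delta_g(0.5)            # 0: equal occupancy
#' delta_g(0.41)           # ~ +0.22 kcal/mol
#' @export
delta_g <- function(f_A2, config = energetics_config()) {
  stopifnot(inherits(config, "energetics_config"))
  if (any(!is.finite(f_A2)) || any(f_A2 <= 0) || any(f_A2 >= 1))
    stop("f_A2 must lie strictly inside (0, 1); occupancies of exactly ",
         "0 or 1 correspond to infinite free energy")
  -config$gas_constant * config$temperature * log(f_A2 / (1 - f_A2))
}

#' @rdname delta_g
#' @param dg Free energy in kcal/mol.
#' @details `f_A2_from_delta_g()` is the exact inverse,
#'   `1 / (1 + exp(dG / RT))`.
#' @export
f_A2_from_delta_g <- function(dg, config = energetics_config()) {
  stopifnot(inherits(config, "energetics_config"))
  1 / (1 + exp(dg / (config$gas_constant * config$temperature)))
}

#' Ligand-induced change in conformational free energy
#'
#' The energetic effect of the ligand on the two-state equilibrium:
#' `delta delta G = delta G(ligand) - delta G(apo)` (kcal/mol).
#'
#' @param dg_ligand,dg_apo Finite free energies in kcal/mol.
#' @export
delta_delta_g <- function(dg_ligand, dg_apo) {
  if (any(!is.finite(dg_ligand)) || any(!is.finite(dg_apo)))
    stop("free energies must be finite")
  dg_ligand - dg_apo
}

#' Quadratic tight-binding dose-response model
#'
#' Fractional response at total ligand concentration `L` for a receptor at
#' total concentration `P_total` with dissociation constant `K_D`, assuming
#' no binding cooperativity and accounting for ligand depletion:
#' `(A - B) * ((L + P + K) - sqrt((L + P + K)^2 - 4 P L)) / (2 P) + B`.
#' In the limit `P_total -> 0` this reduces to the hyperbola
#' `B + (A - B) * L / (L + K_D)`, which is used directly when `P_total`
#' is (numerically) zero.
#'
#' @param K_D Dissociation constant (uM), > 0.
#' @param P_total Total protein (binding-site) concentration (uM), >= 0.
#' @param A Saturating-ligand response (the `f_A2` plateau), in `[0, 1]`.
#' @param B Zero-ligand response, in `[0, 1]`.
#' @return For `dose_response_params()`, a parameter object; for
#'   [dose_response_value()], the fractional response.
#' @export
dose_response_params <- function(K_D, P_total, A, B) {
  if (K_D <= 0) stop("K_D must be > 0")
  if (P_total < 0) stop("P_total must be >= 0")
  if (A < 0 || A > 1 || B < 0 || B > 1)
    stop("A and B must lie in [0, 1]")
  structure(list(K_D = K_D, P_total = P_total, A = A, B = B),
            class = "dose_response_params")
}

#' @rdname dose_response_params
#' @param params A `dose_response_params`.
#' @param L_total Total ligand concentration(s) (uM), >= 0.
#' @export
dose_response_value <- function(params, L_total) {
  stopifnot(inherits(params, "dose_response_params"))
  if (any(L_total < 0)) stop("ligand concentrations must be >= 0")
  .dose_response(L_total, params$K_D, params$P_total, params$A, params$B)
}

.dose_response <- function(L, K, P, A, B) {
  if (P < 1e-9) return(B + (A - B) * L / (L + K))
  s <- L + P + K
  B + (A - B) * (s - sqrt(pmax(s^2 - 4 * P * L, 0))) / (2 * P)
}

#' Fit the quadratic dose-response model to titration data
#'
#' Least-squares estimation of `K_D`, `P_total`, `A` and `B` from
#' `(concentration, f_A2)` pairs.  Any subset can be held fixed via
#' `fixed`.  Degenerate inputs (no spread in the response) are flagged in
#' the returned status rather than raising an error.
#'
#' @param concentrations Total ligand concentrations (uM); should include 0
#'   and a saturating concentration.
#' @param f_A2_values Observed active-state fractions, same length.
#' @param fixed Optional named list of parameters to fix, e.g.
#'   `list(P_total = 1.2)`.
#' @param start Optional named list of starting values.
#' @return A list with `params` (a [dose_response_params()]), `estimates`,
#'   `residual_sd`, `converged` and `status`.
#' @export
fit_dose_response <- function(concentrations, f_A2_values, fixed = NULL,
                              start = NULL) {
  if (length(concentrations) != length(f_A2_values))
    stop("concentrations and f_A2_values lengths differ")
  if (any(concentrations < 0)) stop("negative concentration")
  all_names <- c("K_D", "P_total", "A", "B")
  fixed <- as.list(fixed %||% list())
  free <- setdiff(all_names, names(fixed))
  if (length(concentrations) < length(free))
    stop("fewer data points (", length(concentrations),
         ") than free parameters (", length(free), ")")
  if (length(concentrations) < 4L)
    stop("at least 4 (concentration, f_A2) pairs are required")

  flat <- stats::sd(f_A2_values) < 1e-10
  if (flat) {
    m <- mean(f_A2_values)
    return(list(params = dose_response_params(1, 0, m, m),
                estimates = c(K_D = NA_real_, P_total = 0, A = m, B = m),
                residual_sd = 0, converged = FALSE,
                status = "degenerate: responses carry no concentration dependence; K_D unidentifiable"))
  }

  st <- list(
    K_D = max(stats::median(concentrations[concentrations > 0]), 1e-3),
    P_total = 0.01,
    A = max(f_A2_values), B = min(f_A2_values)
  )
  st <- modifyList(st, as.list(start %||% list()))
  theta0 <- unlist(st[free])
  lower <- c(K_D = 1e-6, P_total = 0, A = 0, B = 0)[free]
  upper <- c(K_D = Inf, P_total = Inf, A = 1, B = 1)[free]

  resid_fn <- function(theta) {
    p <- modifyList(st, as.list(stats::setNames(theta, free)))
    p <- modifyList(p, fixed)
    f_A2_values - .dose_response(concentrations, p$K_D, p$P_total, p$A, p$B)
  }
  # the (K_D, P_total) pair sits on a shallow ridge when depletion is weak;
  # a small deterministic multi-start avoids stalling on it
  ctrl <- nls.lm.control(maxiter = 500, ftol = 1e-14, ptol = 1e-14)
  fit <- NULL
  for (P0 in unique(c(st$P_total, 1e-4, 0.01, 0.1, 1))) {
    for (K0 in unique(st$K_D * c(1, 0.2, 5))) {
      th <- theta0
      if ("P_total" %in% free) th[["P_total"]] <- P0
      if ("K_D" %in% free) th[["K_D"]] <- K0
      cand <- nls.lm(par = th, lower = lower, upper = upper, fn = resid_fn,
                     control = ctrl)
      if (is.null(fit) || cand$deviance < fit$deviance) fit <- cand
    }
  }
  est <- modifyList(st, as.list(stats::setNames(as.double(fit$par), free)))
  est <- modifyList(est, fixed)
  dof <- max(length(concentrations) - length(free), 1L)
  list(
    params = dose_response_params(est$K_D, est$P_total, est$A, est$B),
    estimates = unlist(est[all_names]),
    residual_sd = sqrt(fit$deviance / dof),
    converged = fit$info %in% 1:3,
    status = fit$message
  )
}

#' Per-condition free energies and ligand coupling energies
#'
#' Converts a table of fitted active-state fractions into free energies and,
#' when a zero-ligand (`apo`) condition is present, into per-condition
#' `delta delta G` values relative to it.
#'
#' @param conditions Character vector of condition labels.
#' @param f_A2 Fitted active-state fractions, strictly inside (0, 1).
#' @param config An [energetics_config()].
#' @param apo_label Label identifying the zero-ligand condition.
#' @return A data frame with columns `condition`, `f_A2`, `delta_g` and
#'   (when an apo row exists) `delta_delta_g`.
#' @export
energetics_table <- function(conditions, f_A2, config = energetics_config(),
                             apo_label = "apo") {
  if (length(conditions) != length(f_A2))
    stop("conditions and f_A2 lengths differ")
  dg <- delta_g(f_A2, config)
  out <- data.frame(condition = as.character(conditions), f_A2 = f_A2,
                    delta_g = dg, stringsAsFactors = FALSE)
  i_apo <- which(out$condition == apo_label)
  if (length(i_apo) == 1L)
    out$delta_delta_g <- delta_delta_g(dg, dg[i_apo])
  out
}
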