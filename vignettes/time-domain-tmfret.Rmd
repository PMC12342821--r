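---
title: "Time-domain tmFRET: model, fitting protocol and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-domain tmFRET: model, fitting protocol and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdfret)
```

# The measurement and the model

A TCSPC experiment histograms single-photon arrival times after pulsed
excitation.  With a transition metal ion acceptor (R0 ≈ 43.5 Å when paired
with the Acd donor), each donor–acceptor distance $r$ adds a transfer rate
$(R_0/r)^6/\tau_D$ to the donor decay rate, so the shape of the decay
encodes the distance *distribution* $\rho(r)$, not just a mean distance.
`tdfret` models $\rho(r)$ as the sum of up to two Gaussians — one per
conformational state of the protein (for the SthK cyclic
nucleotide-binding domain: resting and active positions of the C-helix) —
with mixing fraction $f_{A2}$ giving the active-state occupancy.

The predicted histogram is a linear reconvolution: the measured instrument
response function (IRF), background-subtracted, shifted by
$\mathit{shift}_{irf}$ and normalized to unit sum, convolved with the sum
of the sample intensity $I_{DA}(t)$ and a scaled buffer-fluorescence model
$f_B I_B(t)$, plus a constant dark-count background.  $I_{DA}(t)$ contains
a donor-only population of weight $f_D$ (incompletely labeled protein)
plus the FRET population, in which each of the (up to two) donor lifetime
components is quenched by the distance-averaged transfer factor.

For homotetramers in which every subunit carries both labels, a donor is
also quenched by acceptors on neighboring subunits.  This is modeled as a
single *independent* second acceptor with its own two-Gaussian
distribution $\rho_2(r_2)$: the survival factors multiply, and because the
two distributions are independent the double distance integral factorizes
into a product of one-dimensional integrals (verified in the test suite
against direct two-dimensional quadrature at $10^{-5}$ relative accuracy).
In the standard protocol $\rho_2$'s component means and widths are first
determined from a donor-only/acceptor-only mixing experiment and then held
fixed, with its mixing fraction tied to the intrasubunit $f_{A2}$.
Representing three neighboring acceptors by one effective Gaussian mostly
reflects the closest acceptor; it is an approximation inherited from the
experimental design, not a package limitation.

# The 15-parameter vector and the fixing rules

The model exposes exactly 15 named scalars: $f_D$, $\tau_{D1}$,
$\alpha_{D1}$, $\tau_{D2}$, $R_0$, $\bar r_1$, $\sigma_1$, $f_{A2}$,
$\bar r_2$, $\sigma_2$, $\mathit{shift}_{irf}$, $f_B$, $A_0$,
$\mathit{bkgr}_{dec}$, $\mathit{bkgr}_{irf}$.  The standard protocol,
enforced by `fit_donor_only()` and `fit_decay()` (override with
`allow_nonstandard = TRUE`), is:

* **donor-only control**: $f_D = 1$; only $\tau_{D1}, \alpha_{D1},
  \tau_{D2}, \mathit{shift}_{irf}, A_0, \mathit{bkgr}_{dec}$ vary;
* **sample fits**: donor parameters frozen at the control values; $R_0$
  fixed to its spectroscopically determined value; $f_B$ fixed to the
  sample/buffer acquisition-time ratio; $\mathit{bkgr}_{irf}$ fixed to 0;
* **global fits**: distance-shape parameters
  ($\bar r_1, \sigma_1, \bar r_2, \sigma_2$) shared across conditions,
  $f_{A2}$ (and the nuisance parameters) per condition.

Component identity carries no ordering constraint: state labels are
assigned by configuration, since intersubunit distances invert the
resting/active ordering (54.1 Å resting < 58.0 Å active).

Default bounds: $f_D, f_{A2}, \alpha_{D1} \in [0,1]$,
$\bar r \in [10, 100]$ Å, $\sigma \in [0.1, 20]$ Å,
$\tau \in [0.1, 50]$ ns, shift within ±1 ns.  All are per-parameter
configurable in `fret_params()`.

# Statistics

Shot noise in TCSPC is Poisson, so bins are weighted by an estimated
variance equal to the *observed* count, floored at one count so empty bins
stay finite: $\chi^2 = \sum (y - \hat y)^2 / \max(y, 1)$.  Using observed
rather than modeled counts is the conventional (Neyman) choice implied by
weighting with $\sqrt{Decay(t)}$; at very low counts it differs from the
Pearson choice, which is one reason the default fit window runs from 5
bins before the IRF peak to the last bin with at least one count rather
than over empty tail regions.  On correctly specified synthetic data the
reduced $\chi^2$ of the protocol fits averages within [0.9, 1.1] (tested
over 20 seeds at $5\times10^6$ counts).

Minimization is bounded Levenberg–Marquardt (`minpack.lm::nls.lm`).
Reported uncertainties come from the curvature (Gauss–Newton Hessian) at
the optimum scaled by the reduced $\chi^2$; `chi2_profile()` and
`chi2_surface()` provide profile-based intervals and pairwise-correlation
diagnostics.  On synthetic data the $\bar r$ profiles are sharply convex
while the $\sigma$ profiles are visibly shallower, and the
$(\sigma_1, f_D)$ surface shows a tilted valley — the widths are the least
well-determined parameters and should be interpreted with caution.

# Numerical choices

* **Distance quadrature.**  Each Gaussian component is integrated by the
  trapezoid rule on its own uniform 501-point grid spanning
  $\bar r \pm 8\sigma$, truncated below at $r = 0.5$ Å and renormalized on
  that window.  Letting the grid follow the component keeps the cost
  independent of $\sigma$ and resolves the $\sigma \to 0$ single-distance
  limit exactly (a fixed global grid cannot), while the trapezoid rule on
  a smooth Gaussian integrand converges far below the $10^{-6}$ level.
* **Convolution.**  Linear (non-circular) convolution via zero-padded FFT,
  truncated to the grid.  The IRF is background-subtracted, clipped at
  zero, shifted, then normalized to unit sum so that $A_0$ carries all
  amplitude.  Sub-bin shifts use linear interpolation; whole-bin shifts
  relocate the prediction exactly.
* **Initialization.**  The prediction is linear in
  $(f_D A_0,\ (1-f_D) A_0,\ \mathit{bkgr}_{dec})$, so starting values come
  from a deterministic template scan: single-Gaussian distance templates
  ($\bar r$ = 14–66 Å in 4 Å steps, $\sigma \in \{2, 4, 8\}$ Å) are scored
  by weighted linear least squares, followed by a sub-bin scan of the IRF
  shift on the winning template (a shift start of exactly zero can sit on
  a flat spot of the objective).  Two-Gaussian fits split the winning mean
  by ±5 Å with $f_{A2} = 0.5$ and $\sigma = 3$ Å; global fits place each
  condition's starting $f_{A2}$ by interpolating its scan mean between the
  least- and most-quenched conditions.
* **Multi-start.**  Two deterministic alternate starts (distances split
  the other way, $f_{A2} \to 0.25/0.75$, shift offset by half a bin) are
  run lazily — only when the incumbent's reduced $\chi^2$ exceeds 1.2.
* **Temperature.**  `energetics_config()` defaults to 298.15 K with
  $R = 1.9872\times10^{-3}$ kcal mol⁻¹ K⁻¹; this reproduces
  $\Delta G = +0.22$ kcal/mol from $f_{A2} = 0.41$.  Always configurable.
* **Degenerate inputs.**  Occupancies of exactly 0 or 1 are a domain error
  in `delta_g()` (infinite energy); a flat titration flags $K_D$ as
  unidentifiable instead of crashing; an all-background buffer fit is
  flagged degenerate in its convergence status; $P_{total} \to 0$
  evaluates the binding curve through its hyperbolic limit.

# The synthetic-data generator

`make_scenario()` builds complete, self-describing datasets for five
experimental designs — donor-only control, intrasubunit heterotetramer
(r̄ = 41.7/28.8 Å, σ = 2.3/2.1 Å), intersubunit-only heterotetramer
(54.1/3.0 and 58.0/5.0 Å), homotetramer (41.6/3.6, 29.1/4.1 Å with the
intersubunit second acceptor) and full-length channel (39.8/4.1,
31.0/2.7 Å) — using a double-exponential donor (17.6 ns/87%, 4.73 ns),
R0 = 43.5 Å, and, where a preset includes a titration, per-condition
occupancies derived from the quadratic binding model (K_D = 0.22 µM with
[P] = 1.2 µM for the fragment; K_D = 0.53 µM with [P] = 0.025 µM for the
full-length channel).

Where the experimental record does not state a quantity, the generator
uses fixed plausible defaults, all overridable: Gaussian IRF of 0.4 ns
FWHM centered at 5 ns, a two-component buffer (1 and 6 ns) carrying 2% of
the photon budget, dark counts of 0.5 counts/bin, an IRF/decay shift of
25 ps, a donor-only fraction $f_D = 0.15$, equal 300 s acquisitions
(so $f_B = 1$), and $5\times10^6$ photons per decay — enough for sub-Å
distance recovery while keeping simulation in seconds.  Every bundle
embeds its generating parameters and master seed; all randomness flows
through that seed.

What the generator deliberately does *not* emulate: detector afterpulsing,
pulse pile-up, repetition-rate wraparound, slow drifts of the IRF, and any
correlation between the states sampled by the intra- and intersubunit
distributions of one molecule (the factorized model assumes independence,
exactly as the fitting model does).  Passing recovery tests therefore
demonstrates correctness of the estimator under the model's own
assumptions, not robustness to instrument artifacts in real data.

One consequence of simulating at a *fixed photon budget* is worth noting:
because strong FRET compresses the FRET population's photons into early
times, a donor-only admixture ($f_D > 0$) gains photon share as FRET
strengthens, and summary statistics such as the mean arrival time need not
order monotonically with occupancy unless $f_D = 0$.

# Problem sizes used in the tests

The default grid is 4096 bins × 0.025 ns (102.4 ns window).  The test and
acceptance suites run the same window at 2048 bins × 0.05 ns — a binning
any TCSPC instrument would offer — which halves the cost per fit while
leaving recovery tolerances untouched; photon budgets stay at the
$5\times10^6$ counts used throughout.  Recovery checks use 20 independent
seeds per scenario; oracle-equivalence checks compare against dense
quadrature on 64-bin grids where only the integrand accuracy matters.

# Limitations

* $\kappa^2 = 2/3$ is folded into a fixed $R_0$; anisotropy effects are
  out of scope.
* At most two donor exponentials and two Gaussian distance components.
* The Neyman weighting biases estimates slightly at very low counts; fits
  of decays with peak counts below a few hundred should use larger bins.
* The intersubunit correction approximates three acceptors by one
  effective Gaussian; with donors/acceptors on more distant sites a
  shorter-R0 pair (or an explicit multi-acceptor model) would be needed.
* Printed $\Delta G$ values from rounded occupancies do not all recompute
  exactly at one temperature — the analysis here treats occupancies as the
  primary quantity and energies as derived, always reporting the
  temperature used.
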