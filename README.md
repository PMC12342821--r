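# tdfret

Time-domain analysis of transition metal ion FRET (tmFRET) experiments
recorded by time-correlated single photon counting (TCSPC).

Protein conformational equilibria can be read out by pairing a long-lived
donor fluorophore (such as the noncanonical amino acid Acd) with a
metal-complex acceptor whose small Förster distance (R0 ≈ 43.5 Å for
Acd/[Ru(bpy)2phenM]2+) makes transfer efficiency steeply distance-dependent
over 20–60 Å.  A TCSPC measurement of the donor decay then encodes the
*distribution* of donor–acceptor distances: each distance r quenches the
donor's intrinsic decay by an extra rate (R0/r)^6 / τ_D.  `tdfret`
implements the full analysis chain for such experiments — forward model,
fitting, energetics — together with a ground-truth synthetic data
generator, delimited-text I/O and a command-line interface.

## The model

The predicted photon-count time course is the reconvolution

    Decay(t) = [IRF(t − shift_irf) − bkgr_irf] ⊗ [I_DA(t) + f_B · I_B(t)] + bkgr_dec

where the donor-with-acceptor intensity for a two-exponential donor
(amplitude fractions α_Di, lifetimes τ_Di) and a Gaussian-mixture distance
density ρ(r) is

    I_DA(t) = A0 [ f_D Σᵢ α_Di e^(−t/τ_Di)
                 + (1 − f_D) ∫ ρ(r) Σᵢ α_Di e^(−t/τ_Di − (t/τ_Di)(R0/r)^6) dr ]

with ρ(r) the sum of up to two Gaussians (means r̄₁, r̄₂; widths σ₁, σ₂;
mixing fraction f_A2), one per conformational state.  For homomeric
proteins in which a donor sees acceptors on neighboring subunits, an
independent second acceptor with its own (fixed) distance distribution
multiplies each donor component by an additional distance-averaged
quenching factor; because the distributions are independent the double
integral factorizes into a product of one-dimensional integrals.
`I_B(t)` is a frozen multi-exponential buffer model and `f_B` is fixed to
the ratio of sample and buffer acquisition times.

Fits minimize the Poisson-weighted chi-square Σ (obs − pred)² / max(obs, 1)
with bounded Levenberg–Marquardt, singly or globally across conditions with
shared parameters.  Fitted state occupancies convert to free energies via
the Boltzmann relation ΔG = −RT ln(f_A2 / (1 − f_A2)), ligand effects via
ΔΔG = ΔG_ligand − ΔG_apo, and titrations are fit with the tight-binding
quadratic

    f(L) = (A − B) · ((L + P + K_D) − √((L + P + K_D)² − 4PL)) / (2P) + B.

## Worked example

Simulate an apo + saturating-cAMP experiment with known ground truth
(r̄ = 41.7/28.8 Å, σ = 2.3/2.1 Å, f_A2 = 0.08/0.96, 5×10⁶ photons per
decay), freeze the buffer model, fit both conditions globally with shared
distance parameters, and convert occupancies to free energies:

```r
library(tdfret)

scen <- make_scenario("intrasubunit", seed = 42,
                      overrides = list(
                        grid = time_grid(0.05, 2048),
                        conditions = data.frame(label = c("apo", "cAMP_320uM"),
                                                f_A2 = c(0.08, 0.96))))

bf <- fit_buffer(scen$buffer$histogram, scen$irf, n_components = 2)

decays <- lapply(scen$datasets, `[[`, "decay")
spec <- prepare_global_spec(decays, scen$irf, bf$model, fret_params(f_B = 1))
fit <- fit_global(spec)
print(fit)
#> <fret_fit>  reduced chi^2 = 1.0243  (chi^2 = 3987, dof = 3892)
#>   converged
#>   at bounds: bkgr_dec@1, bkgr_dec@2
#>   rbar_1            41.6766 +/- 0.0318
#>   sigma_1           2.14748 +/- 0.169
#>   rbar_2            28.7652 +/- 0.0236
#>   sigma_2           2.06789 +/- 0.0551
#>   f_D@1            0.151254 +/- 0.00175
#>   f_A2@1           0.085219 +/- 0.00647
#>   ...

energetics_table(c("apo", "cAMP_320uM"), fit$estimates[c("f_A2@1", "f_A2@2")])
#>         condition   f_A2 delta_g delta_delta_g
#> f_A2@1        apo 0.0852    1.41          0.00
#> f_A2@2 cAMP_320uM 0.9580   -1.85         -3.26
```

The shared distances come back within 0.1 Å of the generating values, the
per-condition occupancies within 0.01, and the fit sits at reduced χ² ≈ 1,
as expected for pure shot noise.  The final table reads: closing of the
C-helix is unfavorable without ligand (ΔG = +1.41 kcal/mol), favorable at
saturating cAMP (−1.85 kcal/mol), and the ligand contributes
ΔΔG ≈ −3.3 kcal/mol of coupling energy.

A command-line interface wraps the same pipeline
(`simulate`, `fit`, `fit-global`, `profile`, `surface`, `energetics`,
`dose-response`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "tdfret.R", package = "tdfret"))')" \
  simulate --scenario full_length --seed 7 --out bundle/
```

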