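# phlinkage

Thermodynamic linkage analysis of protonation ensembles from
constant-pH simulations.

`phlinkage` is for people who run constant-pH molecular dynamics (or
titration Monte Carlo) of a titratable protein in two oligomeric forms
and want to turn the resulting per-pH binary protonation trajectories
into biophysics: titration curves and Hill fits, protonation
correlation networks and correlation times, the pH-dependent *relative*
dimerization free energy, and the acidification-induced shift of the
monomer fraction. The motivating systems are pH-sensing membrane
proteins whose lumen-facing glutamates titrate between neutral and
acidified conditions, but nothing protein-specific is hard-coded: the
input is a table of 0/1 protonation states plus site metadata (label,
chain, lumenal/stromal compartment).

## The core identity

Wyman's linkage relation: the pH derivative of the dimerization free
energy is set by the difference in proton binding between the dimer and
two monomers,

    d(ΔG_dim)/d(pH) = ln(10)·kT·[Q_D(pH) − 2·Q_M(pH)]

Integrating the measured protonation-curve difference over pH (trapezoid
on the measured grid, anchored at a reference pH) gives the relative
dimerization free energy ΔΔG(pH). Because ΔQ is a sum of per-residue
terms, ΔΔG decomposes exactly into per-residue contributions, which can
be screened (default: |contribution| ≥ 1 kcal/mol anywhere on the grid)
to find the residues that carry the pH sensitivity. A downstream
2M⇌D mass-action step converts ΔΔG into monomer-fraction curves
parameterized by the monomer fraction at the reference pH (absolute
binding constants are not obtainable from linkage).

Because real constant-pH MD data are expensive and not bundled, the
package ships a synthetic generator with exact ground truth: an
Ising-like model of coupled titratable sites (`site_model()`), solved
exactly by component-factorized enumeration (`enumerate_equilibrium()`)
and sampled by a compiled Metropolis kernel (`sample_ensemble()`).
Every estimator in the package is validated against that oracle.

## Worked example

The bundled toy system has 16 titratable sites per monomer (10 lumenal,
6 stromal), planted pairwise couplings, and dimer-interface pKa shifts
of −1.0 on lumenal sites L01, L05 and L09:

```r
library(phlinkage)
mono <- toy_monomer_model(); dim <- toy_dimer_model()
grid <- seq(3, 8, 0.25)
em <- sample_ensemble(mono, grid, n_replicates = 5, n_frames = 2e4,
                      seed = 42, flip_attempt_prob = toy_flip_probs(mono),
                      system = "monomer")
ed <- sample_ensemble(dim, grid, n_replicates = 5, n_frames = 2e4,
                      seed = 43, flip_attempt_prob = toy_flip_probs(dim),
                      system = "dimer")

fit_hill(residue_curve(em, "L02"))
#> hill_fit [L02]: pKa = 5.200 (+/- 0.000), h = 0.999 (+/- 0.001)

fit_hill(residue_curve(em, "L03"))
#> hill_fit [L03]: pKa = 3.998 (+/- 0.050), h = 0.732 (+/- 0.036)
#>   [low confidence: curve does not cross 0.5 within the pH grid]
```

L02 is uncoupled and recovers its intrinsic pKa (5.2) with h = 1. L03
is anticooperatively coupled to L04 (+3 kcal/mol): its h < 1, and the
fit is flagged because the pair plateaus near half-protonation at the
acidic end of the grid, so the curve never crosses 0.5 — exactly the
kind of fit that should be read as indicative only.

```r
prof <- bootstrap_profile(em, ed, ref_pH = 3, compartment = "lumenal",
                          per_residue = TRUE, seed = 1)
screen_key_residues(prof)
#>   label max_abs_contribution
#> 1   L05             2.623807
#> 2   L01             2.571357
#> 3   L09             2.534570
```

The lumenal screen at 1 kcal/mol returns exactly the three residues
whose interface pKa was shifted — each contributes ~2.6 kcal/mol to the
pH dependence of dimerization — and nothing else.

```r
frac <- fraction_uncertainty(anchor_profile(prof$total, 7.5),
                             f_ref_grid = 0.5)
#>  f_ref   pH     f shift ci_lo ci_hi
#>    0.5 5.00 0.900 0.400 0.899 0.901
#>    0.5 5.75 0.609 0.109 0.605 0.612
#>    0.5 7.50 0.500 0.000 0.496 0.504
```

Starting from a 50/50 chain split at pH 7.5, acidifying to pH 5.75 (the
acid end of the physiological lumen range) raises the monomer fraction
to 0.61; at pH 5 the system is 90% monomeric. The 68% bands come from
replicate-level bootstrap propagated through the monotone mass-action
map.

A YAML-driven end-to-end run (`run_pipeline()`, or
`inst/cli/phlinkage.R` from a shell) writes occupancy tables, curves,
Hill fits, correlation maps/networks/times, free-energy profiles, the
key-residue screen, monomer fractions and a provenance record into an
output directory, bit-identically for a fixed seed.

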