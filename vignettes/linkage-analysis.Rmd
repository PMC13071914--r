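---
title: "pH-linkage analysis of protonation ensembles: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pH-linkage analysis of protonation ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phlinkage)
```

## The problem

Constant-pH simulations of a titratable membrane protein produce, for
every simulated pH and replicate, a time series of binary protonation
states - one 0/1 column per acidic residue. For a pH-sensing protein
that exists in a monomer-dimer equilibrium (the motivating case is a
thylakoid photoprotection sensor whose lumenal glutamates titrate in the
physiological window between roughly pH 7.5 and 5.7), those occupancy
series contain everything needed to ask three questions:

1. How does each residue titrate - where is its pK~a~, and does it bind
   protons cooperatively?
2. Which residues' protonation states are coupled, and on what time
   scale do they exchange protons?
3. How does acidification shift the dimerization equilibrium, and which
   residues carry that shift?

`phlinkage` answers all three from the occupancy tables alone. It never
touches coordinates, force fields or electrostatics solvers: the
simulation that produced the tables is upstream of this package.

## The linkage relation

The central identity is Wyman's linkage relation: the pH derivative of
a reaction free energy equals the difference in proton binding between
products and reactants,

$$\frac{\partial \Delta G_{dim}}{\partial pH} =
  \ln(10)\,k_BT\,\bigl[Q_D(pH) - 2\,Q_M(pH)\bigr]
  = \ln(10)\,k_BT\,\Delta Q(pH),$$

where $Q_D$ and $Q_M$ are the global protonation curves (total mean
number of bound protons) of dimer and monomer, and the factor 2 matches
the 2M $\rightleftharpoons$ D stoichiometry. Integrating $\Delta Q$
over pH from a reference pH gives the *relative* dimerization free
energy $\Delta\Delta G(pH)$; the absolute $\Delta G$ is not obtainable
this way, which is why every profile is anchored to zero at a reference
pH (default 3 for free-energy profiles, 7.5 for monomer-fraction work -
the neutral end of the physiological window).

Because $\Delta Q$ is a sum of per-residue terms
$\Delta q_i = \langle x_i\rangle_{D,A} + \langle x_i\rangle_{D,B} -
2\langle x_i\rangle_M$, the integral decomposes exactly: residue
profiles sum to the total at machine precision
(`residue_decomposition()`), and residues can be screened by the
maximum absolute contribution over the grid
(`screen_key_residues()`, default threshold 1 kcal/mol). A flat
per-residue profile means the residue does not modulate the *pH
sensitivity* of dimerization; it may still contribute arbitrarily much
to the absolute binding free energy.

Numerical choices:

* **Trapezoidal quadrature on the measured grid.** No interpolation or
  extrapolation is ever applied; the pH grid is the resolution. The
  quadrature error is quantifiable against the package's exact oracle
  and shrinks quadratically with the grid step (this is tested).
* **Temperature** defaults to 298.15 K and is configurable; $k_BT$ and
  $\ln(10)\,k_BT$ are always computed from the gas constant at run
  time.
* **Reference invariance.** Changing the reference pH rigidly shifts a
  profile (`anchor_profile()`), so profiles computed against different
  references are interconvertible without recomputation.

## The synthetic model and its exact oracle

Real constant-pH trajectories for this class of system are microseconds
of atomistic MD; no such data ships here. Instead the package includes
a generator whose statistics are *exactly solvable*, so every estimator
can be validated against ground truth rather than against another
simulation.

A `site_model()` assigns each titratable site an intrinsic pK~a~ and
couples pairs of protonated sites with energies $W_{ij}$ (kcal/mol):

$$E(s; pH) = \sum_i \ln(10)\,k_BT\,(pH - pK_{a,i})\,s_i
  + \sum_{i<j} W_{ij}\,s_i s_j .$$

This is the simplest (Ising-like, pairwise) model that produces the
phenomenology the analyses target: shifted apparent pK~a~ values, Hill
coefficients different from 1 (positive $W$ penalizes double
protonation, giving anticooperative binding and negative state
correlations; negative $W$ the opposite), correlation networks
including lumen-stroma pairs, and dimer-interface effects
(`build_dimer_model()` duplicates a monomer into chains A/B, applies
per-site interface pK~a~ shifts, and adds interchain couplings).

`enumerate_equilibrium()` computes the semi-grand partition function,
per-site means and the full covariance *exactly*. The sum factorizes
over connected components of the coupling graph, so a 32-site dimer
whose couplings form small clusters is solved exactly even though
$2^{32}$ states could never be enumerated; any single component larger
than 20 sites is refused with an explicit error.

`sample_ensemble()` is a single-site Metropolis sampler (one frame =
one full sweep; acceptance $\min(1, e^{-\Delta E/k_BT})$). Per-site
attempt probabilities below 1 emulate kinetically slow proton
exchangers. Initial states are drawn from the independent-site
Henderson-Hasselbalch probabilities and 100 burn-in sweeps are
discarded by default - a deliberately short equilibration, adequate
because the initial distribution is already close to stationary for
weak-to-moderate couplings. All randomness flows through R's RNG, so a
seed fixes the trajectories bit for bit.

What the generator does *not* emulate: conformational dynamics coupled
to protonation, tautomers, explicit electrostatics, or the heavy-tailed
trapping real membrane simulations show. Passing tests therefore
demonstrate the correctness of the estimators, not the sufficiency of
any particular amount of MD sampling.

## Titration analysis

Per-residue curves (`residue_curve()`) average the binary states over
frames and replicates; dimer residues are reported chain-averaged by
default (per-chain curves remain available as diagnostics). Global
curves (`global_curve()`) are sums over a site subset times a
stoichiometry factor - use 2 on the monomer to compare against the
dimer.

Hill fits (`fit_hill()`) use weighted nonlinear least squares of
$\langle x\rangle = 1/(1 + 10^{h(pH - pK_a)})$, with weights equal to
inverse squared CI half-widths (uniform when the band is degenerate)
and initialization at the grid point nearest half-protonation. Fits
are flagged `low_confidence` - never silently reported - when the
curve does not cross 0.5 inside the grid or the fitted pK~a~ leaves the
grid; such fits are merely indicative, as is typical for residues whose
titration the simulation barely brackets.

**Uncertainty.** All confidence bands are 68% percentile bootstrap
intervals (16th-84th percentile) over *replicates*, never frames:
frames are autocorrelated (protonation correlation times reach hundreds
of frames for slow sites), so the replicate is the only plausibly
independent unit. A single replicate yields a zero-width band plus a
warning rather than an error, keeping exploratory runs usable.

## Correlations and correlation times

`pairwise_correlation()` computes Pearson correlations between binary
state series - the phi coefficient. Sites with sample variance below
$10^{-6}$ at a pH (e.g. fully protonated there) are masked undefined,
not set to zero, and masked pairs can never form network edges. Pooled
correlation across replicates is the default; the per-replicate
alternative averages within-replicate maps and is insensitive to
replicates trapped in different protonation configurations - comparing
the two is itself diagnostic. `build_network()` keeps pairs with
$|c| \ge$ a threshold (default 0.3 - the notion of "substantial"
correlation is a tunable choice, not an estimate; sweep it) and flags
lumen-stroma edges.

`correlation_time()` integrates the replicate-averaged normalized
fluctuation autocorrelation up to the first nonpositive lag
(initial-positive-sequence truncation), giving
$\tau = \Delta t\,(1/2 + \sum_{t\ge1} C(t))$: 0.5 frames for white
noise, and the closed form $1/2 + \lambda/(1-\lambda)$,
$\lambda = 1 - 2p$, for a symmetric two-state chain with flip
probability $p$ - the case the sampler realizes exactly at
pH = pK~a~. Conversion to physical time requires the frame spacing of
the upstream simulation; outputs default to frame units.

## Monomer fraction under mass action

With only relative free energies available, the 2M $\rightleftharpoons$
D equilibrium is parameterized by the monomer fraction at the
reference pH instead of an absolute dimerization constant: for each
$f_{ref} \in (0,1)$, $\kappa_{ref} = (1-f_{ref})/(2 f_{ref}^2)$, then
$\kappa(pH) = \kappa_{ref}\, e^{-\Delta\Delta G(pH)/k_BT}$ and
$f(pH) = 2/(1 + \sqrt{1 + 8\kappa})$ - the cancellation-free root of
$2\kappa f^2 + f - 1 = 0$, exact at $\kappa = 0$. Fractions are
fractions of *chains* in monomeric form. CI bands propagate through
this map by evaluating it at the band edges, which is exact because the
map is monotone. By construction, the lumenal-only profile is the
default input: stromal pH is assumed buffered, so only lumen-facing
contributions should drive the physiological response.

## The toy benchmark system

`toy_monomer_model()` / `toy_dimer_model()` define the package's
standard benchmark: 16 sites (10 lumenal with pK~a~ 4.5-5.4, above the
aqueous glutamate reference of 4.25; 6 stromal at 4.0-4.8), planted
couplings L03-L04 (+3), S04-S05 (-2), the lumen-stroma pair L07-S02
(-2.5), dimer-interface shifts of -1.0 on the otherwise-uncoupled
lumenal sites L01/L05/L09, interchain couplings S01-S01 (+2.5) and
S03-S03 (-2.0), and slow exchangers L10 (attempt probability 0.1) and
S06 (0.05). The coupling graph's components never exceed two sites, so
the 32-site dimer remains exactly solvable. The planted interface
shifts produce per-residue contributions of ~2.5 kcal/mol - comfortably
above the 1 kcal/mol screening threshold - while every unshifted,
uncoupled-to-shifted residue contributes exactly zero, making
`screen_key_residues()` exactly checkable.

## Validation design and problem sizes

The test suite validates every estimator along two independent routes:
a hand-rolled brute-force sum over all microstates (tests only) against
`enumerate_equilibrium()`, and the exact oracle against the sampled
pipeline. The headline checks and the problem sizes the package uses
for them:

* **Oracle equivalence:** toy system, pH 3-8 step 0.25, 5 replicates
  of 10^5 sweeps: the sampled, bootstrap-banded $\Delta\Delta G$
  profile must agree with the exact partition-function profile within
  max(0.1 kcal/mol, 3 bootstrap SE) at every grid point.
* **Network recovery:** 20 regenerations; each planted coupling must
  appear as an edge ($|c| \ge 0.3$) at the pH where the *enumerated*
  correlation peaks, in at least 90% of regenerations, with uncoupled
  pairs exceeding the threshold in at most 5% of opportunities.
* **Bootstrap calibration:** 200 regenerations of a two-site
  monomer/four-site dimer system at 8 replicates x 3000 sweeps. The
  percentile bootstrap of a mean with $n$ replicates has expected
  coverage $2\,P(T_{n-1} \le z_{0.84}\sqrt{(n-1)/n}) - 1$: about 58%
  at $n = 5$ and 62% at $n = 8$ for a nominal 68% band. The
  calibration experiment uses 8 replicates so that the observed
  coverage tests the implementation rather than the small-sample bias
  of the percentile method itself; with very few replicates the method
  is expected to undercover, and users should read 5-replicate bands
  as slightly anticonservative.

## Known limitations

* Pairwise couplings only; no three-body terms. Real electrostatic
  networks can be higher-order, but pairwise terms already generate
  the cooperativity and correlation structure the estimators must
  detect.
* The Hill equation is the only pK~a~ estimator; strongly coupled
  sites are poorly summarized by (pK~a~, h), which is precisely what
  the correlation analysis is for.
* Replicate-level bootstrap cannot repair too-few replicates: bands
  from fewer than ~5 replicates are anticonservative (see above).
* The mass-action stage assumes a pure 2M $\rightleftharpoons$ D
  equilibrium at fixed total chain concentration; higher oligomers and
  association kinetics are out of scope.

## A worked example

```{r example, eval = FALSE}
library(phlinkage)

mono <- toy_monomer_model()
dim  <- toy_dimer_model()
grid <- seq(3, 8, 0.25)

em <- sample_ensemble(mono, grid, n_replicates = 5, n_frames = 2e4,
                      seed = 42, flip_attempt_prob = toy_flip_probs(mono),
                      system = "monomer")
ed <- sample_ensemble(dim, grid, n_replicates = 5, n_frames = 2e4,
                      seed = 43, flip_attempt_prob = toy_flip_probs(dim),
                      system = "dimer")

fit_hill(residue_curve(em, "L02"))        # ~ HH site: pKa 5.2, h = 1
prof <- bootstrap_profile(em, ed, ref_pH = 3, compartment = "lumenal",
                          per_residue = TRUE, seed = 1)
screen_key_residues(prof)                  # -> L01, L05, L09
frac <- fraction_uncertainty(anchor_profile(prof$total, 7.5))
head(frac)
```
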