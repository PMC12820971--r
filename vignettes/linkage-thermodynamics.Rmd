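---
title: "pH-dependent linkage thermodynamics: models, methods and design choices"
author: "protolink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pH-dependent linkage thermodynamics: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protolink)
```

## The model

A titratable species is a set of Q binary proton-binding sites with
intrinsic pKa values and pairwise couplings. A protonation microstate
x ∈ {0,1}^Q at pH has reduced energy

u(x; pH) = ln10 · Σᵢ xᵢ (pH − pKaᵢ) + Σ_{i<j} w_{ij} xᵢ xⱼ,

in units of RT, with w in RT as well. The binding polynomial
Z(pH) = Σₓ exp(−u) is the species' grand-canonical partition function
over protons; −RT ln Z is its proton-binding free energy, and every
derivative of the mean protonation n̄ = ⟨Σ xᵢ⟩ with respect to pH is a
fluctuation observable:

* dn̄/dpH = −ln10 · var(n)  (total curves; per site with cov(nᵢ, n)),
* d²n̄/dpH² = (ln10)² · μ₃(n), the third central moment.

An isolated site titrates exactly as a Hill curve with h = 1, which is
why the Hill equation f(pH) = [1 + 10^{h(pH−pKa)}]⁻¹ is both the
empirical fit model and the analytic single-site limit.

The linkage relation expresses a reaction's pH-dependent relative free
energy as ln10·RT times the integral over pH of the stoichiometric
difference in mean protonation between products and reactants. The same
quantity equals −RT·Δln Z differences, which is what the enumeration
oracle computes; agreement of the two routes is the package's central
correctness check and is enforced in the test suite over randomised
multi-site scenarios.

Assumptions worth stating plainly: sites are binary (no tautomers);
couplings are pairwise and pH-independent; protonation is decoupled
from conformation. Real constant-pH simulations couple protonation to
conformational dynamics — the synthetic model deliberately does not, so
passing tests demonstrate correctness of the *analysis machinery*, not
robustness to conformational heterogeneity in real data.

## The thermodynamically constrained spline

Constant-pH studies sample few, discrete pH values, so the integration
scheme matters. At every node the simulation provides the curve value
*and*, via the fluctuation relations above, its slope and curvature.
The package interpolates the protonation-difference curve with a
two-point Hermite spline constrained by all three:

* with values and slopes only, each segment is the classical cubic
  Hermite (error O(h⁴));
* with curvatures as well (`buildThermoSpline(x, y, m, c)`), each
  segment is the two-point quintic Hermite (error O(h⁶)).

The quintic form is the default throughout the pipeline. The decision
was quantitative: on unit-spaced pH nodes a cubic Hermite reproduces a
single-site titration curve only to about 5·10⁻³–7·10⁻³ in protonation
(verified against an independent spline implementation), which
propagates to tens of millikcal/mol in integrated profiles; the quintic
brings the same curve below 10⁻³ and integrated profiles on the
benchmark scenarios to a few millikcal/mol. Since the curvature is just
one more moment of the same protonation records — no new simulation
output is required — using it is squarely within the "constrain the
spline with what the simulation measures" philosophy. The original
thermodynamic-spline construction this emulates is not fully specified
in the literature it comes from (monotonicity treatment and end
conditions unknown); the Hermite family is our documented reading, with
linear extrapolation beyond the node span and closed-form per-segment
integrals (no quadrature anywhere).

The difference curve is splined once, with values, slopes and
curvatures combined stoichiometrically, rather than per species and
then subtracted — algebraically identical for Hermite interpolants,
cheaper, and it keeps bootstrap bands consistent.

The Hill-based alternative (`hillIntegration`) integrates each mapped
site pair in closed form via the exact antiderivative
F(pH) = pH − ln(1 + 10^{h(pH−pKa)})/(h ln10). It fits *per-site*
curves (not totals) so that the site decomposition remains available;
for uncoupled sites the two integration routes coincide.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| burn-in fraction | 0.15 | — | equilibration share of each trace discarded before averaging, mirroring the common practice of dropping the first sixth or so of a constant-pH run |
| pH grid | 3–8, step 1 | pH | the span where carboxylates and histidines titrate; step 1 is what such studies typically afford |
| replicates | 8 | — | independent repeats per pH; the replicate is the unit of uncertainty |
| sweeps per trace | 2·10⁴ | sweeps | one recorded state per sweep; enough for per-replicate standard errors well below the replicate scatter |
| ph_ref | 3 | pH | profiles are relative to the acidic end of the grid, where proteins are near-fully protonated |
| temperature | 300 | K | RT = 0.59616 kcal/mol; all free energies in kcal/mol |
| ligand curve | Hill h = 1, pKa 5.0 | — | the free fatty-acid ligand is represented by its calibrated experimental pKa rather than simulated |
| bootstrap B | 1000 | — | resamples of replicates; 68% central interval for protonation-derived quantities, ±1 SD selectable |
| Hill bounds | h ∈ (0, 10] | — | fits leaving the band are flagged non-converged rather than reported |
| pair-move threshold | 2.0 | pKa units | site pairs coupled at least this strongly also receive joint Metropolis flips |
| KDE bandwidth | σ_d (4/3N)^{1/5} | score units | per-dimension; basin cutoff 2 RT; mesh 0.5 by default |
| ion map | mesh 1 Å, bandwidth 2 Å | Å | triangular kernel; densities converted as 1 M = 6.022·10⁻⁴ Å⁻³ |

## What the synthetic generator emulates — and what it does not

`makeBenchmarkScenario` builds the five species of a
ligand-binding/dimerization cycle: monomer M with randomly drawn site
pKa values (3.5–7.5, mostly acids) and intra-chain couplings; a
one-site free ligand L (pKa 5.0); the complex ML as M with
binding-induced pKa shifts on the pocket-forming half of the sites plus
a bound-ligand site weakly coupled to the pocket; the dimer D as two
copies of M with inter-chain interface couplings; and DL2 analogously.
Because all four reaction free energies derive from the same five
partition functions, the thermodynamic cycle closes identically, which
pins down the sign conventions of every pipeline stage.

Couplings are drawn non-negative (0.25–1.0 pKa units). This is a
physical statement, not a convenience: in the binding-polynomial
convention, any purely electrostatic interaction between two titratable
sites — charged/charged repulsion between deprotonated acids or
protonated bases, attraction between an acid and a base — reduces, after
absorbing linear terms into the intrinsic pKa values, to a non-negative
coupling on the doubly-protonated indicator. Negative (cooperative)
couplings require a conformational intermediary, and this model is
protonation-only by design. Anticooperative couplings broaden titration
transitions (effective h ≤ 1), which is also what protein titration
data overwhelmingly show.

The Metropolis sampler performs q random-scan single-site flips per
sweep plus joint flips for strongly coupled pairs, using R's RNG for
reproducibility. One caveat it exposes honestly: exactly at pH = pKa an
uncoupled site's flip energy is zero and every attempt is accepted, so
the chain's exchange rate hits its ceiling there; diagnostics of "slow"
versus "fast" exchangers are therefore meaningful only relative to this
design, not to the physical proton-transfer kinetics the real method
has.

Not emulated: conformational coupling (pKa values never respond to
structure), tautomers, ionic-strength effects, and any Poisson–Boltzmann
energetics. Landscape fixtures are Gaussian mixtures in coordinate
space, not molecular ensembles.

## Numerical choices and degenerate inputs

* **Enumeration limit**: exact moments by full 2^Q enumeration up to
  Q = 20 sites, with an explicit error beyond; benchmark dimers stay
  well inside.
* **Hill fit initialisation**: pKa starts at the pH whose protonation is
  closest to 0.5, h at 1; Marquardt–Levenberg least squares with box
  constraints. Flat curves return `converged = FALSE` instead of
  erroring, and downstream Hill integration refuses non-converged fits.
* **Isoionic point**: the charge curve's spline (its slope is the total
  fluctuation slope, since the charge offsets are constants) is solved
  by bisection to 10⁻¹² after an exact-zero node check; no sign change
  on the grid means "no pI", reported as NA.
* **Zero-variance sites** are dropped from correlation tables rather
  than reported as NaN; self-pairs are excluded.
* **Bootstrap band** quantiles can, in skewed or degenerate resample
  sets, exclude the point estimate by a hair; bands are minimally
  widened to contain it so the containment invariant holds exactly.
* **Basin labels** are deterministic: connected components
  (8-neighbour) of the admissible set, numbered by the lowest linear
  cell index each contains. Cells whose density underflows to zero
  carry no finite energy and never join a basin. Sub-basins re-run the
  same rule inside one basin's mask at a caller-chosen lower cutoff —
  the original sub-basin definition in the landscape literature we
  mirror is not public, so this stand-in is the documented behaviour.
* **Superposition** enforces proper rotations (determinant guard);
  mirror-image frames keep a positive residual. Collinear fit
  selections are rejected.
* **Anchoring** is a rigid vertical shift (bands and resamples shift
  identically); anchors must lie inside the profile's pH span and are
  validated before any pipeline stage runs.
* **Profile uncertainty across the cycle** is combined on matched
  bootstrap resamples (same resample index in every leg) when
  available, preserving the correlations that naive quadrature
  destroys; quadrature of band half-widths is the fallback.

## Scale of the validation runs

The test suite exercises 20 randomised 4–8-site-per-monomer scenarios
for oracle equivalence (pH 3–8 at steps 1 and 0.25), fluctuation
identities on 10 of them, and one full sampled recovery at the study
design — 6 pH values × 8 replicates × 2·10⁴ sweeps for the four sampled
species, with B = 1000 bootstrap resamples per reaction. These sizes
keep the whole suite around a minute on one core while leaving the
statistical checks well-powered.

## Known limitations

* The spline's fidelity to the original (unpublished) construction is
  unknown; what is guaranteed is value/slope/curvature consistency with
  the simulation moments and closed-form integrals.
* Site decomposition requires a reaction written with a single product
  of unit stoichiometry (all cycle reactions are), and its meaning
  depends on the caller's site map.
* The bootstrap treats replicates as exchangeable and frames within a
  replicate as one block; no frame-level resampling is offered because
  frame autocorrelation would bias it.
* Binding cooperativity via a singly-occupied dimer is out of scope; the
  cycle is the four-species one.
* Ion maps use a separable triangular kernel; near grid edges the
  kernel mass is clipped, so concentrations are quantitative only in
  the grid interior.
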