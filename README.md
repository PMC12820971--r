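# protolink

pH-dependent linkage thermodynamics from protonation microstate traces.

## The problem

Constant-pH simulations record, at each simulated pH, the binary
protonation state of every titratable site over time. Wyman's linkage
relation turns those records into reaction thermodynamics: the
pH-derivative of a reaction free energy equals ln 10·RT times the
difference in proton binding between products and reactants, so

```
ΔΔG_bind(pH) = ln(10) RT ∫_{pH_ref}^{pH} ( n̄_complex − n̄_protein − n̄_ligand ) dpH′
```

with `n̄_X` the mean protonation of species X. Integrating the measured
titration-curve differences therefore yields relative binding and
dimerization free-energy profiles; per-site integrands give residue-level
contributions; and the four legs of the binding/dimerization cycle

```
ΔG_dim_holo = ΔG_dim_apo + ΔG_bind_D − 2 ΔG_bind_M
```

combine into a pH-dependent allosteric coupling
`ΔG_coupl = ΔG_dim_holo − ΔG_dim_apo = ΔG_bind_D − 2 ΔG_bind_M`
(positive = antagonistic: ligand binding disfavors dimerization).

protolink is for people analysing such simulations. It implements:

- **Titration analysis** — trace averaging with burn-in, replicate
  statistics, Hill fits `f(pH) = [1 + 10^{h(pH−pKa)}]^{-1}`, isoionic
  points, Pearson protonation correlations, proton-exchange diagnostics,
  and model-compound pKa calibration by pH shift.
- **Thermodynamically constrained spline integration** — the integrand
  is interpolated with a Hermite spline whose node slopes and curvatures
  are the fluctuation observables `dn̄/dpH = −ln10·var(n)` and
  `d²n̄/dpH² = ln10²·μ₃(n)`, then integrated in closed form; a
  closed-form Hill-based integration is available for comparison.
- **Cycle assembly** — profile anchoring to experimental values, cycle
  completion, closure checks, allosteric-coupling classification, and
  replicate-bootstrap uncertainty bands (matched resamples across the
  cycle).
- **Landscapes and structural metrics** — Kabsch superposition, PCA,
  KDE free-energy surfaces `E = −RT ln(P/P_max)` with the
  `σ(4/3N)^{1/5}` bandwidth rule, basin detection at a 2 RT cutoff,
  triangular-kernel ion concentration maps, contact areas, dihedrals,
  minimum contact distances.
- **An exactly solvable test bed** — coupled-site titration models whose
  binding polynomial is enumerated exactly (≤ 20 sites), a Metropolis
  sampler emitting constant-pH-style occupancy traces, and a benchmark
  monomer/ligand/dimer scenario whose true free-energy profiles are known,
  so every pipeline stage can be validated against closed forms.

## Worked example

Build the synthetic benchmark (4 titratable sites per monomer chain,
palmitate-like one-site ligand with pKa 5.0), integrate the four cycle
reactions from exact titration statistics, and complete the cycle:

```r
library(protolink)
scen <- makeBenchmarkScenario(n_sites = 4, seed = 42)
tabs <- lapply(scen$models, exactTitration, ph_grid = 3:8)
lig  <- ligandCurve(5.0)
profiles <- lapply(scen$reactions, integrateLinkage, tables = tabs,
                   ligand_curve = lig, ph_ref = 3)
profiles$bind_M
#> FreeEnergyProfile 'bind_M' (spline, relative to pH 3)
#>   pH 3 4 5 6 7 8
#>   ddG  0.000 -0.095 -0.431 -0.694 -0.870 -0.676 kcal/mol

holo <- completeCycle(profiles$dim_apo, profiles$bind_M, profiles$bind_D)
cyc  <- cycleProfiles(profiles$dim_apo, holo, profiles$bind_M, profiles$bind_D)
max(abs(cyc@closure))          # cycle closure residual
#> [1] 2.220446e-16
allostericCoupling(cyc)[, c("ph", "coupling", "classification")]
#>   ph    coupling classification
#> 1  3 0.000000000        neutral
#> 2  4 0.000843787   antagonistic
#> 3  5 0.008701656   antagonistic
#> 4  6 0.054744457   antagonistic
#> 5  7 0.069170618   antagonistic
#> 6  8 0.009510670   antagonistic
```

Binding is most favorable near neutral pH (the `bind_M` minimum of
−0.87 kcal/mol at pH 7 relative to pH 3), and for this scenario ligand
binding and dimerization antagonise each other at every pH — the
coupling profile is positive. The spline-integrated profile agrees with
the exact partition-function oracle to < 2e−3 kcal/mol on this grid.

Two self-contained worked values:

```r
completeCycle(-7.16, bind_M = -8.3, bind_D = -14.5)  # kcal/mol, at pH 7
#> [1] -5.06
ph <- seq(3, 7, 0.25)
calibrateModelPka(ph, 1/(1 + 10^(ph - 4.20)),
                  initial_model_pka = 4.19, experimental_pka = 5.0)$calibrated_pka
#> [1] 4.99
```

The first completes the dimerization/binding cycle from experimental
anchors (apo dimerization −7.16, monomer binding −8.3, dimer binding
−14.5 kcal/mol); the second calibrates a carboxylate model compound by
shifting its initial pKa (4.19) by the gap between the experimental
target (5.0) and the apparent pKa of its simulated titration curve
(4.20).

For the full trace-level pipeline (sample → average → integrate →
bootstrap → cycle) see `runPipeline()` and the methods vignette in
`vignettes/`.

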