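# gpcrbias

Quantification of ligand bias at G-protein-coupled receptors, plus a
desk-scale well-tempered metadynamics engine for linking binding-mode
energetics to coupling outcomes.

## The problem

Agonists of aminergic GPCRs (dopamine D2, serotonin 1A/2A, ...) can
preferentially activate some transducers (GoB, Gz, Gi2, Gq) over others
(β-arrestin 2). Quantifying that preference from concentration–response
data requires separating ligand-specific bias from assay-specific scale
differences between biosensors. This package implements the standard
analysis chain:

- **Variable-slope Hill fits** of concentration–response curves,
  `Y = basal + top / (1 + 10^(n(−pEC50 − log10 c)))`, with a
  deterministic multi-start optimizer (no fit-to-fit jitter).
- **AUC coupling ratios**: the area under each fitted curve over the
  assayed log-concentration window captures potency, efficacy and slope
  together; pairwise pathway ratios are divided by a reference agonist's
  ratios, which cancels biosensor scale and leaves pure coupling
  preference (the reference agonist's normalized matrix is exactly 1).
- **Operational (Black–Leff) bias factors**: a global fit of
  `E = Basal + (Em − Basal)·τⁿ[A]ⁿ / (([A]+KA)ⁿ + τⁿ[A]ⁿ)` per pathway
  with Em, Basal and n shared across agonists yields per-agonist
  transduction coefficients log R = log(τ/KA); reference-normalized
  differences between pathways give ΔΔlog(τ/KA) and the fold bias
  `10^ΔΔlog(τ/KA)`, with residual-resampling bootstrap CIs.
- **GIRK desensitization readouts**: peak normalization, terminal
  residual-current fractions, monoexponential decay fits, and one-way
  ANOVA with Bonferroni-adjusted pairwise comparisons.
- **Toy metadynamics**: overdamped Langevin dynamics on analytic 1D
  potentials with well-tempered, multiple-walker Gaussian deposition,
  hills-file I/O, free-energy reconstruction
  `F(s) = −γ/(γ−1)·V_bias(s)`, convergence monitoring, and automatic
  well/barrier detection.
- **Polar contact frequencies**: direct and water-bridged
  ligand–residue contacts per frame from plain coordinate tables.

Synthetic-data generators with known ground truth (Hill and operational
response surfaces, GIRK current traces at 156 Hz, Langevin/hills runs,
coordinate tables with planted contact rates) make every stage testable
end to end without any external data.

## Worked example

```r
library(gpcrbias)

truths <- list(
  bret_truth("dopamine",   "GoB",   7.5, 1.00),
  bret_truth("dopamine",   "barr2", 7.2, 0.80),
  bret_truth("p-tyramine", "GoB",   5.0, 0.55),
  bret_truth("p-tyramine", "barr2", 4.4, 0.10))
bret <- generate_bret_dataset(truths, n_rep = 3, seed = 1)

fit_hill(bret[bret$agonist == "dopamine" & bret$pathway == "GoB", ])
#> Variable-slope Hill fit
#>   pEC50 = 7.500 (SE NA)
#>   top   = 1.000 (SE NA)
#>   hill  = 1.000   basal = 0.000   RSS = 7.71e-21

prof <- auc_coupling_pipeline(bret, reference = "dopamine")
round(prof$normalized[["p-tyramine"]], 2)
#>       barr2  GoB
#> barr2  1.00 0.13
#> GoB    7.68 1.00
```

The normalized matrix reads: relative to dopamine, p-tyramine couples
~7.7-fold more strongly to GoB than to β-arrestin 2 (its arrestin
recruitment is weak in both potency and efficacy), the signature of a
G-protein-biased ligand. The noise-free fit recovers the generating
parameters to machine precision (RSS ≈ 8e-21), so parameter standard
errors are not defined and print as NA.

Binding-mode energetics on a toy double-well landscape (wells at the
direct- and water-mediated contact distances, 1.3 kcal/mol apart):

```r
pot <- toy_potential("double_well", wells = c(2.8, 5.5), barrier = 1.3)
run <- run_langevin_metadynamics(pot, metad_params(wall_position = 8, wall_lower = 1),
                                 n_steps = 2e6, seed = 42)
fes <- reconstruct_fes(run$hills, seq(1, 8, by = 0.02))
find_wells_and_barriers(fes)$barriers
#>   from   to barrier_kcal_mol
#> 1 5.66 2.76             1.30
#> 2 2.76 5.66             1.38
```

The recovered inter-well barrier (1.30 kcal/mol from the deeper well)
matches the constructed landscape within the engine's documented
0.3 kcal/mol tolerance. A desensitization readout:

```r
tau <- decay_tau_for_residual(0.30, 415, onset_tau = 5)
g <- generate_girk_trace(girk_truth(onset_tau = 5, decay_tau = tau))
residual_fraction(g, 415)
#> [1] 0.302
```

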