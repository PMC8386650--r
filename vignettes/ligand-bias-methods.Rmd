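---
title: "Quantifying GPCR ligand bias: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying GPCR ligand bias: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpcrbias)
```

This vignette documents the statistical models the package implements,
the assumptions behind them, the tunable parameters that matter, and
the design decisions taken where the methodology was genuinely open.

## Concentration–response model

All curve fitting uses the variable-slope sigmoid on the
log10-concentration axis,

$$Y(c) = \mathrm{basal} + \frac{\mathrm{top}}
  {1 + 10^{\,n\,(-\mathrm{pEC_{50}} - \log_{10} c)}},$$

so `top` is the span above basal (equal to Emax when basal is zero) and
$Y(\mathrm{EC_{50}}) = \mathrm{basal} + \mathrm{top}/2$. Responses are
abstract assay units (uBRET for biosensor recruitment, peak-normalized
current for GIRK); concentrations are molar throughout and potencies
are reported as pEC50, hence all logs are base 10. Zero-concentration
rows are excluded from the fit by construction — baseline handling is a
separate, explicit step (`subtract_baseline`), defaulting to the mean
response at each curve's lowest assayed concentration.

`fit_hill` minimizes unweighted least squares (no weighting is applied
anywhere in the chain; replicate-level rows and replicate means give
identical estimates for balanced designs). Two estimator choices remove
nondeterminism and degeneracy:

* **Deterministic multi-start.** The Levenberg–Marquardt optimizer is
  started from a fixed grid — seven pEC50 values spanning the assayed
  window crossed with Hill slopes 0.5, 1 and 2 — and the lowest residual
  sum of squares wins, ties going to the lowest pEC50 start. Identical
  data always give identical fits, and the suite verifies the result
  against an exhaustive (pEC50 × slope) grid search with the
  conditionally linear (basal, top) pair solved in closed form.
* **Slope bounds.** The Hill slope is constrained to (0.1, 10); outside
  that range the sigmoid degenerates into a step and the remaining
  parameters lose meaning.

A fit whose pEC50 lands more than one log unit outside the assayed
window is flagged `extrapolated`; a flat curve is returned as a flagged
non-converged fit rather than an error, so pipeline code can propagate
missingness.

## AUC coupling ratios

Coupling preference is summarized by the area under the *fitted*,
baseline-subtracted curve over the assayed log10-concentration window
(composite trapezoid, ≥ 1000 grid points; the unit-slope case is checked
against the closed-form log-domain softplus integral). Integrating the
fitted model rather than joining raw points makes the AUC a function of
potency, efficacy and slope jointly, and using one shared window for all
pathways of a ligand makes the window cancel in ratios.

For each agonist the pathway-by-pathway ratio matrix
$R_{ij} = \mathrm{AUC}_i/\mathrm{AUC}_j$ is divided element-wise by the
reference agonist's matrix. Different biosensors have arbitrary,
assay-specific response scales; any per-pathway rescaling multiplies
every agonist's $R_{ij}$ identically and cancels in the normalized
matrix (a property the test suite asserts). The reference agonist's own
normalized matrix is exactly 1, and $R_{ij} R_{ji} = 1$.

## Operational model and bias factors

Bias factors come from the Black–Leff operational model in its
τ-explicit form,

$$E = \mathrm{Basal} + (E_m - \mathrm{Basal})\,
  \frac{\tau^n [A]^n}{([A] + K_A)^n + \tau^n [A]^n},
  \qquad \tau = 10^{\log R + \log K_A},$$

fitted jointly per pathway with $E_m$, Basal and $n$ shared across
agonists; each agonist contributes one transduction coefficient
$\log R = \log(\tau/K_A)$. Full agonists have $\log K_A$ fixed at 0
(the full-agonist limit where $K_A$ and $\tau$ are not separately
identifiable and only their ratio matters); partial agonists have
$\log K_A$ estimated. By default all agonists are treated as full;
`full_agonists` makes the classification explicit. Starting values are
again deterministic: per-curve Hill fits seed the $\log R$ values (for a
full agonist the half-max sits at $[A] = 1/R$, so pEC50 is the natural
initializer), with a small multi-start over the transducer slope.

Normalization to the reference agonist within each pathway gives
$\Delta\log(\tau/K_A)$; the difference between two pathways gives
$\Delta\Delta\log(\tau/K_A)$ and the fold bias
$10^{\Delta\Delta\log(\tau/K_A)}$. The sign convention is pathway 1
minus pathway 2, reported alongside the ordered pathway pair, so
`bias > 1` means preference for the first pathway; reversing the pair
inverts the factor exactly.

Confidence intervals use a parametric bootstrap: responses are
resampled as fitted means plus residuals drawn with replacement, both
pathways are refitted, and the percentile interval of the bootstrap
fold-bias distribution is reported (default 95%, seed-controlled).
This replaces analytic SE propagation; it makes no covariance
assumptions and is exactly reproducible.

## GIRK desensitization

Traces are normalized to their own peak (after subtracting an
agonist-independent baseline when one is supplied). The residual
current after a long application is the mean normalized current over a
terminal averaging window; the window is 5 s wide because at 156 Hz a
single-sample readout would carry needless noise, and no narrower
window is dictated by the readout's meaning. `decay_tau_for_residual`
inverts the trace model so generators can plant exact residual
fractions; the suite checks the round trip to ±0.01 and that the
readout decreases strictly as the generator's decay accelerates.

Rate quantification fits `plateau + (1 − plateau)·exp(−(t − t_peak)/τ)`
to the post-peak segment; a trace with no measurable decay leaves τ
unidentifiable and is flagged rather than fitted. Group comparisons use
one-way ANOVA followed by pairwise two-sided pooled-SD t tests with
Bonferroni adjustment (raw p × number of pairs, capped at 1), the
standard conservative correction for small oocyte group counts.

## Toy metadynamics engine

The enhanced-sampling machinery operates on analytic one-dimensional
potentials standing in for the ligand–serine distance landscape: the
collective variable $s$ is a distance in Å, energies are kcal/mol. The
dynamics are overdamped (position) Langevin integrated with
Euler–Maruyama,

$$\mathrm{d}s = -\frac{U'(s) + V_\mathrm{bias}'(s) + V_\mathrm{wall}'(s)}
  {\gamma_f}\,\mathrm{d}t + \sqrt{2 k_B T\,\mathrm{d}t/\gamma_f}\,\eta,$$

because only the CV-space statistics matter at this scale — inertial
dynamics would add parameters without changing the stationary law. The
friction $\gamma_f$ (default 1 kcal mol⁻¹ ps Å⁻²) sets the diffusion
constant $D = k_BT/\gamma_f \approx 0.6$ Å²/ps at 300 K
($k_BT = 0.596$ kcal/mol), fast enough to traverse the accessible range
between depositions. The default timestep (0.002 ps) is validated
against the stiffest curvature of the potential plus wall
($\mathrm{d}t < \gamma_f/\max|U''|$); an unstable step is refused
outright since it would produce silently wrong sampling.

Deposition defaults are the production values used throughout:
0.1 kcal/mol hills of 0.1 Å spread every 4 ps, well-tempered bias
factor γ = 10, a one-sided harmonic wall with κ = 100 kcal/mol/Å²
beyond 12 Å (exponent 2, the common default for such restraints; a
matching lower wall confines the toy coordinate), six walkers sharing
one history-dependent bias with private buffers merged every 20 ps.
Hill heights follow
$h = w_0 \exp(-V_\mathrm{bias}(s)/((\gamma-1)k_BT))$ evaluated on the
walker's current view of the bias, so the first hill has height $w_0$
exactly and heights never exceed it.

The free energy is reconstructed with the standard rescaled-bias
estimator $F(s) = -\frac{\gamma}{\gamma-1} V_\mathrm{bias}(s)$, shifted
to $\min F = 0$ (energy plots are relative); time-averaged estimators
were not used. Convergence is monitored by recomputing the profile
every block of deposited Gaussians — 20 000 at production scale, 1 500
in the test runs, which deposit ~6 000–12 000 hills over 4–12 ns of
walker time (problem sizes chosen so a full suite runs on a laptop).
The **Boltzmann oracle** anchors correctness: for 1D overdamped
Langevin dynamics the free energy along the coordinate *is* the
potential, so $|F - (U - \min U)|$ is a true error, evaluated over the
thermally accessible region ($U - \min U \le 2$ kcal/mol, i.e. about
$3.4\,k_BT$ — beyond that, sampling is too sparse for the comparison to
be meaningful at these run lengths). The suite requires RMS ≤ 0.3
kcal/mol (≈ 0.5 $k_BT$) on harmonic, symmetric double-well and tilted
double-well landscapes, recovery of a constructed 1.3 kcal/mol
inter-well barrier to ±0.3 kcal/mol, and agreement between 1-walker and
6-walker runs at equal total hills.

Well detection reports local minima with a prominence above
0.5 kcal/mol (sub-$k_BT$ ripples are deposition noise, not binding
modes), including minima at the profile edge so a monotone profile
reports its single boundary well; barriers are the path maximum between
two wells minus the first well's depth, so they are asymmetric for
tilted landscapes.

## Contact analysis

Contacts are computed from plain per-frame coordinate tables (frame,
atom_id, role, x, y, z) — trajectory binary formats are out of scope. A
direct polar contact is a heavy-atom pair within 3.5 Å (closed
interval; the favorable-contact wells sit near 2.8 Å, and 3.5 Å is the
standard donor–acceptor criterion); a water-mediated contact requires
one water oxygen within the cutoff of *both* partners. A frame counts
at most once per pair — direct contact takes precedence — so direct and
bridged contacts are never double counted in a frequency. Frequencies
are invariant under rigid-body motion of each frame and monotone
non-decreasing in the cutoff; the water-bridge test is verified against
an exhaustive per-water oracle.

## Synthetic data: what it does and does not emulate

The generators produce exactly the response surfaces the estimators
assume: Hill or operational mean curves plus i.i.d. Gaussian noise,
GIRK traces as an activation×decay product sampled at 156 Hz over
415 s, Langevin/hills runs on known landscapes, and coordinate tables
with Bernoulli-planted contact rates. Defaults mirror the study
conditions: three replicates per point (three independent experiments),
a nine-point 1 pM–100 µM dilution series spanning every printed potency
(pEC50 4.06–7.94). Replicate-level noise SDs are fixture choices — the
source data report means ± SEM, not a replicate noise model — so
passing tests demonstrate estimator correctness under the stated model,
not robustness to heteroscedastic or correlated errors, plate effects,
receptor reserve differences or BRET photophysics, none of which are
modeled.

Two recovery suites quantify estimator accuracy at 5% noise: 200 Hill
curves (median |pEC50 error| < 0.05) and 50 multi-agonist operational
datasets (median |log R error| < 0.05). The Hill suite assays each
curve on a nine-point series bracketing its own EC50 (±4 logs), which
is how a dilution series is designed in practice; on a fixed panel grid
a pEC50-4 compound is half-observed at the top of the range and its
potency error reflects truncation, not the estimator. The fixed
1 pM–100 µM panel remains the default for multi-pathway comparisons,
where a shared window is what makes AUC ratios cancel.

## Known limitations

* Single-site, monotonic curves only: no biphasic models, no robust
  regression, no heteroscedastic weighting.
* Operational fits need ≥ 2 agonists per pathway (the shared system
  parameters are otherwise undefined), and an all-partial-agonist panel
  can leave $E_m$ weakly identified.
* The metadynamics engine is 1D and overdamped by design; it validates
  the bias/reconstruction machinery, not force fields or receptor
  dynamics.
* Bootstrap CIs reflect residual noise only, not between-batch
  variability.
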