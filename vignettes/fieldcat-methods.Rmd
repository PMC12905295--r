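---
title: "Electric fields, free-energy profiles, and transition-state diagnostics: methods"
author: "fieldcat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electric fields, free-energy profiles, and transition-state diagnostics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fieldcat)
```

`fieldcat` implements the analysis layer used to study how an enzyme's own
electrostatic field shapes the energetics of polyester (PET) hydrolysis:
projecting internal electric fields onto reaction axes, reconstructing
free-energy profiles from umbrella-sampling windows, converting barriers to
rates, decomposing field-induced barrier shifts, and validating transition
states by committor analysis. This vignette explains the models, the
defaults and their units, the numerical choices, and what the synthetic
fixtures do and do not demonstrate.

## Internal electric fields along reaction axes

The internal electric field (IEF) at a catalytic site is modelled as the
bare Coulomb field of the surrounding partial charges,

$$\vec F = K \sum_i \frac{q_i\,(\vec r_0 - \vec r_i)}{|\vec r_0 - \vec r_i|^3},$$

evaluated at the midpoint $\vec r_0$ of a *reaction axis* — an ordered atom
pair such as N1–H1 or O1–C1 — and projected onto the axis unit vector.
With charges in elementary units and distances in Å, the single conversion
constant $K = e/(4\pi\varepsilon_0 \cdot 10^{-20}\,\mathrm{m}^2) \cdot
10^{-8} = 1439.9645\ldots$ MV·cm⁻¹ maps the sum directly to MV/cm; it is
derived once from CODATA constants (`fc_constants`) and locked by a test
against an independent SI evaluation.

Conventions that had to be fixed:

* **Positive direction.** The unit vector runs tail→head in the order the
  axis is named ("O1–C1" means O1→C1). A negative axial component points
  head→tail.
* **Probe point.** $\vec r_0$ is the midpoint of the *instantaneous* axis
  atom positions, re-evaluated per frame, so the probe moves with the
  trajectory.
* **Environment.** The summation runs over a `selection`; the intended
  default for protein work is all protein atoms excluding the catalytic
  triad residues (165, 210, 242 in the cutinase numbering used by the toy
  generator), with substrate, solvent and ions excluded. Because
  solvent/substrate bookkeeping is a genuine modelling choice, it is left
  to the caller's `selection` rather than hard-coded. The two axis atoms
  are always removed from the sum.
* **No cutoffs, no periodic images.** A distance cutoff would silently
  change reported MV/cm values; the sum is exact over the selected atoms.

Per-window statistics (`window_field_statistics`) discard the first half of
each series by default, mirroring the common practice of analysing only
the equilibrated tail (e.g. the last 15 ps of 30-ps windows), and report
the mean and $n-1$ standard deviation. Cross-axis relationships are
summarised by a plain Pearson correlation matrix — deliberately simple and
interpretable.

## Umbrella sampling and WHAM

Windows are harmonically restrained,
$U_w(x) = k_f (x - x_w)^2$ by default. The force-constant convention
(no ½ factor) matches the restraint definition of the MD engine whose
force constants this package is meant to consume; a `half_k` flag switches
to the $\tfrac12 k$ convention, and a test pins the equivalence
($k$, full) ≡ ($2k$, half).

`wham_solve` iterates the standard self-consistency equations in log space:
unbiased bin probabilities $p_b \propto C_b / \sum_w N_w e^{(f_w -
U_w(x_b))/RT}$ and offsets $e^{-f_w/RT} = \sum_b p_b e^{-U_w(x_b)/RT}$,
until the largest offset change drops below the tolerance (default
$10^{-5}$ kcal/mol, with a $10^6$ iteration cap). The PMF is $-RT\ln p$ on
occupied bins, min-shifted to zero. Numerical choices:

* **Binning.** Uniform grid spanning the retained samples, padded by one
  bin; default width 0.02 Å suits bond-distance coordinates (0.1 Å is more
  appropriate for centre-of-mass distance profiles). Empty bins are
  masked, never interpolated — interpolation would fabricate barrier
  heights.
* **Equilibration discard.** The first `discard_fraction` (default 0.5) of
  each window is dropped before solving, the same rule for QM/MM-scale
  (15 of 30 ps) and classical (5 of 10 ns) windows.
* **Bootstrap.** Uncertainties come from resampling *points* within each
  window with replacement (window identities fixed), re-solving on the
  full-data grid, min-shifting each replicate, and taking per-bin standard
  deviations (default 100 replicates, seeded). Point resampling is the
  standard WHAM bootstrap; block or window resampling would only matter
  for autocorrelated input, which the exact sampler avoids by design.
* **Barrier extraction.** Among interior maxima the one with the largest
  prominence (height above the lower flanking basin) is taken; on clean
  profiles this is simply the highest interior maximum, but it ignores
  one-bin shot-noise spikes in sparse tails that would otherwise
  contaminate bootstrap replicates. Ties break toward the reactant side.
* **Diagnostics.** Adjacent-window histogram overlap
  ($\sum_b \min(\hat p_i, \hat p_j)$) and a first-half/second-half
  re-solve. The half-series comparison only uses bins holding ≥ 50 samples
  in both halves, because a bin with count $c$ carries shot noise of order
  $RT/\sqrt{c}$ (≈ 0.1 kcal/mol at the 50-sample floor at 343 K) and the
  sparse tail bins would dominate the reported maximum without measuring
  convergence at all.

Temperature defaults to 343.15 K, the operating temperature of
thermophilic PET hydrolases.

## Eyring conversions

`eyring_rate`/`eyring_barrier` implement
$k = \kappa \frac{k_B T}{h} e^{-\Delta G^\ddagger/RT}$ and its exact
inverse, with CODATA constants and $R = 1.987204\times10^{-3}$
kcal·mol⁻¹·K⁻¹. One documented quirk: the experimental PET-hydrolysis rate
window 0.3–1.6 s⁻¹ corresponds to 18.2–17.2 kcal/mol at **298.15 K** (at
343 K it would be 19.9–21.0), and a 10.7 kcal/mol barrier maps to ~10⁵ s⁻¹
at 298.15 K (~10⁶ at 343 K). Published numbers of this kind are therefore
reproduced at 298.15 K even when the surrounding text nominally refers to
the 343 K operating temperature; every function takes the temperature
explicitly so the choice is always visible.

## Stark models and the static/dynamic decomposition

Each reaction state (reactant complex, transition state, intermediates)
responds to an axial field $F$ (MV/cm) as

$$E(F) = E_0 - \mu c F - \tfrac12 \alpha c F^2,$$

with $\mu$ in debye, $\alpha$ in D·cm/MV, and $c = 0.048011$ kcal·mol⁻¹ per
(D·MV·cm⁻¹) derived from SI. The sign convention — a dipole parallel to a
positive field is stabilised — is locked by unit tests. Models are fitted
to field–energy scan tables by least squares (`fit_stark_model`, order 1
or 2), since the electronic-structure scans themselves are outside this
package's scope.

The barrier shift caused by the environment's field splits into

* a **static part**: the shift if both states felt the reactant-state
  field $F_\mathrm{RC}$, and
* a **dynamic extra**: the additional stabilisation the transition state
  gains because its own mean field $F_\mathrm{TS}$ differs,

with `total = static + dynamic_extra` holding identically by construction.
This mirrors the observation that the mean axial field can shift between a
reactant basin and a transition state (a reactant-state mean near −37
MV/cm moving to −52 MV/cm is the emulated magnitude), so the transition
state is preferentially stabilised beyond what a frozen field would give.
Whether a published decomposition of this kind used linear or quadratic
state response is generally not stated; both orders are supported and the
algebra is validated against a hand-evaluated SI oracle rather than
against any published value, whose underlying scan energies are not
tabulated.

## Committor validation

A configuration is transition-state-like when unbiased trajectories
started from it reach the product basin about half the time. The package
implements this on explicit 1-D model potentials (the stand-in for a
QM/MM surface): BAOAB Langevin dynamics, Maxwell–Boltzmann velocities
resampled per shot, position-only basin entry, default mass 12 amu,
friction 10 ps⁻¹, timestep 1 fs, 343.15 K. The default double well
$V(x) = h((x/w)^2-1)^2$ has its basins at the minima $x = \pm w$. Shots
hitting the step cap are excluded and counted separately; the committor
estimate carries a Wilson 95% interval (chosen over Wald for small-count
robustness). An ensemble passes when its median committor lies in
[0.4, 0.6] — a deliberately conventional window, labelled as this
package's choice since shot counts and acceptance windows for such
validations are rarely published.

## Synthetic data: what it does and does not show

The generators provide every input with known ground truth:

* `gen_point_charges` — random charge clouds with a brute-force companion
  field, so the Coulomb implementation is testable to 10⁻¹⁰ relative.
* `gen_prescribed_field_traj` — a ±q charge pair on the axis solved in
  closed form so the axial field equals the schedule *exactly*; optional
  decoy charges sit in the perpendicular plane and contribute zero axial
  field by symmetry. Feeding a Gaussian schedule with the reactant/TS
  means and spreads above emulates the statistical structure of a dynamic
  field shift.
* `sample_umbrella_windows` — exact inverse-CDF sampling from the biased
  Boltzmann density on a 10⁴-point grid. No Markov chain, hence no
  autocorrelation: WHAM accuracy is tested in isolation from sampling
  pathology.
* `gen_toy_active_site` — an 8-residue mini-protein with triad residue ids
  and an axis-bearing substrate fragment for parser/selection tests.

Passing tests on these fixtures demonstrates the *estimators* are correct:
they say nothing about force-field charge quality, sampling convergence of
real MD, solvent screening (the Coulomb sum has no dielectric), or the
validity of a 1-D reaction coordinate. The fixtures are statistical
stand-ins, not molecular models.

## Problem sizes and test design

The standard fixture is a 5 kcal/mol double well sampled with 21 windows
($k_f = 50$ kcal·mol⁻¹·Å⁻², centers −1.25…1.25 Å) at 10⁴ samples per
window, solved at 0.02 Å bins with 25–50 bootstrap replicates; the demo
analysis uses 5 × 10³ samples per window and 500 frames per field state.
These sizes resolve every feature the assertions test while keeping the
whole suite fast enough to run routinely. Statistical assertions are
calibrated from sampling theory (e.g. means within $3\sigma/\sqrt n$,
Stark parameters within the Student-$t$ 99.73% band of their fitted
standard errors given only 4 residual degrees of freedom), never tuned to
a particular draw.

## Known limitations

* No autocorrelation-aware effective-sample-size correction in the
  bootstrap; with real (correlated) window data the reported
  uncertainties would be optimistic.
* 1-D WHAM only; no 2-D surfaces, and MBAR is not used as the solver.
* The field model is vacuum Coulomb over fixed point charges: no induced
  polarisation, no reaction-field or continuum correction.
* Committor machinery runs on model potentials only — it validates the
  statistical procedure, not any real transition-state geometry.
* The multi-stage profile assembly offsets segments by explicit
  configuration numbers; it cannot reconstruct how mixed-level published
  profiles were referenced to a common zero.
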