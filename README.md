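# fieldcat

Analysis machinery for studying how an enzyme's built-in electric field
shapes the energetics of polyester (PET) depolymerization — written for
computational enzymologists who already have trajectories, umbrella-sampling
windows, and field–energy scans, and need the downstream statistics done
carefully and reproducibly.

The package covers five connected analyses:

1. **Internal electric fields (IEF).** The Coulomb field of the protein's
   partial charges, `F = K Σᵢ qᵢ(r₀−rᵢ)/|r₀−rᵢ|³`, evaluated at the
   midpoint of a *reaction axis* (an ordered atom pair such as N1–H1) and
   projected onto it, in MV/cm (`axial_field`). Per-window means ± s.d.
   after equilibration discard, and cross-axis Pearson correlations.
2. **Free-energy profiles by WHAM.** Self-consistent reconstruction of a
   1-D PMF from harmonically biased windows, with point-resampling
   bootstrap uncertainties, adjacent-window overlap and half-series
   convergence diagnostics, and barrier/reaction-energy extraction
   (`wham_solve`, `bootstrap_pmf`, `barrier_from_profile`).
3. **Eyring kinetics.** `k = κ(k_BT/h)·exp(−ΔG‡/RT)` and its exact inverse
   (`eyring_rate`, `eyring_barrier`).
4. **Stark analysis.** Per-state field response
   `E(F) = E₀ − μcF − ½αcF²` fitted to scan tables, and the decomposition
   of a field-induced barrier shift into a *static* part (both states feel
   the reactant-state field) and a *dynamic extra* (the transition state
   feels its own, shifted field) (`fit_stark_model`,
   `decompose_dynamic_shift`).
5. **Committor validation.** Langevin shooting on model potentials with
   Wilson confidence intervals and an ensemble pass/fail verdict
   (`committor_probability`, `validate_ts_ensemble`).

Seeded synthetic-data generators (`gen_point_charges`,
`gen_prescribed_field_traj`, `sample_umbrella_windows`,
`gen_toy_active_site`) produce every input with analytically known ground
truth, so the whole pipeline is testable end to end. The methods vignette
(`vignettes/fieldcat-methods.Rmd`) documents the models, conventions, and
numerical choices.

## Worked example

Convert the measured PET-hydrolysis rate window into activation free
energies, and recover a known barrier from synthetic umbrella windows:

```r
library(fieldcat)

eyring_barrier(1.6, 298.15)   # 17.1747  kcal/mol
eyring_barrier(0.3, 298.15)   # 18.16651 kcal/mol
log10(eyring_rate(10.7, 298.15))  # 4.95: a 10.7 kcal/mol barrier ~ 1e5 1/s

pot    <- model_potential("double_well", barrier_height = 5, half_separation = 1)
biases <- lapply(seq(-1.25, 1.25, length.out = 21), function(c0) bias_spec(c0, 50))
wins   <- sample_umbrella_windows(pot, biases, temperature = 343.15,
                                  n_samples = 10000, seed = 11)
cfg    <- wham_config(343.15, bin_width = 0.02, n_bootstrap = 25,
                      discard_fraction = 0, seed = 3)
prof   <- bootstrap_pmf(wins, cfg, reactant_side = "left")
barrier_from_profile(prof, "left")
#> $dg_barrier   5.008248      # generating potential: 5.0 kcal/mol
#> $dg_reaction  -0.03178724   # symmetric well: 0
```

The first two numbers bracket the barrier window implied by measured
PET-hydrolysis rates (17.1–18.1 kcal/mol); the WHAM barrier recovers the
planted 5 kcal/mol within its bootstrap uncertainty (±0.04 here).

## Analysis workflow

`analysis/` holds numbered drivers that run the whole study on synthetic
inputs and write their tables under `results/`:

```sh
Rscript analysis/01_synthetic_inputs.R   # windows, field states, scans, config.yaml
Rscript analysis/02_field_shift.R        # per-state IEF statistics -> field_statistics.csv
Rscript analysis/03_free_energy.R        # WHAM profile, barrier, diagnostics
Rscript analysis/04_kinetics_stark.R     # Eyring table + Stark decomposition
Rscript analysis/05_committor.R          # TS-ensemble committor verdict
Rscript analysis/06_full_pipeline.R      # everything from one YAML config
```

`run_pipeline()` drives the same stages programmatically from one
configuration and writes a deterministic JSON report.

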