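# lipidtools

Parameter-fitting and bilayer-analysis machinery for AMBER-family lipid
force fields, for force-field developers and membrane simulators who
need to (a) derive dihedral, angle and charge parameters from
quantum-mechanical reference data and (b) validate the resulting
bilayers against the standard structural observables — without carrying
a full MD or QM stack.

## What it computes

**Torsion fitting.** The AMBER dihedral potential is a cosine series

    E(θ) = Σ_n V_n · (1 + cos(nθ − γ_n))

with barrier heights `V_n` (kcal/mol), integer periodicities `n` and
phase shifts `γ_n`. Given conformer sets pairing the *zeroed* MM energy
(all fitted barriers set to zero) with a QM reference energy, a
real-coded genetic algorithm minimises the offset-aligned least-squares
objective

    F = Σ_i w_i (E_QM,i − E_zeroed,i − E_torsion,i − c)²

under the field's discrete constraint policies (phases restricted to
{0°, 180°} for hydrocarbon torsions or 60° increments for headgroups;
periodicities n = 1–5 for 1D scans, n = 1–3 for conformational
ensembles). An exhaustive grid-search oracle validates the GA on small
problems. Harmonic valence angles `E = K(θ − θ₀)²` are fitted to 1D
scans by linear regression in `(θ, θ²)`.

**Charges.** Per-conformer RESP charge sets are averaged into a final
fragment set (per-atom mean over the ensemble, typically 200
conformers) with any rounding residual redistributed uniformly so every
head/tail fragment carries its integer net charge exactly — the
modular-assembly bookkeeping that lets fragments combine into
zwitterionic or anionic lipids.

**Bilayer observables.** From trajectories (multi-model PDB or a
plain-text frames CSV, plus a metadata sidecar): area per lipid
`A = LxLy/(n/2)`; volume per lipid `(V_box − n_w·V_w)/n`; z-binned
number/electron density profiles and the head-to-head thickness `D_HH`
(peak-to-peak distance of the electron density); C–H order parameters
`S_CD = ⟨(3cos²θ − 1)/2⟩`; X-ray and neutron scattering form factors
`|F(q)| = |∫ Δρ(z)cos(qz) dz|`; cholesterol tilt-angle distributions;
midplane transit events (|z| < 2 Å runs, classified flip-flop vs
transient visit); and melting-point detection as the inflection of the
running-averaged APL(T) curve of a heating scan.

**Synthetic fixtures.** Every input class can be generated with known
ground truth (`make_fit_dataset`, `make_angle_scan`,
`make_charge_ensemble`, `make_bilayer_traj`, `make_heating_scan`,
`make_z_paths`), so the whole pipeline is testable without QM or MD.

## Worked example

Fit a two-term acyl-chain torsion from a noisy synthetic dataset, then
analyse a synthetic bilayer:

```r
library(lipidtools)

truth <- list(`cD-cD-cD-cD` = torsion_series(list(
  torsion_term(1, 1.5, 0), torsion_term(3, 0.8, 0)), "cD-cD-cD-cD"))
train <- make_fit_dataset(truth, n = 1000, sigma = 0.15, seed = 7)
test  <- make_fit_dataset(truth, n = 1000, sigma = 0.15, seed = 8)

fit <- run_ga_fit(train$dataset, phase_policy("binary_0_180"),
                  periodicity_policy("ensemble_1to3"),
                  ga_config(population_size = 200, generations = 300,
                            seed = 42),
                  test_set = test$dataset)
print(fit)
#> GA torsion fit (seed 42): fitness 21.9842, train RMSE 0.1483
#>   test RMSE 0.1506
#> Torsion series 'cD-cD-cD-cD' (3 terms)
#>   n = 1  V =   1.4895 kcal/mol  gamma =    0.0 deg
#>   n = 2  V =   0.0122 kcal/mol  gamma =    0.0 deg
#>   n = 3  V =   0.7973 kcal/mol  gamma =    0.0 deg
```

The fitted barriers recover the truth (1.5 and 0.8 kcal/mol) to ~0.01
kcal/mol; the train RMSE (0.148 kcal/mol) sits at the injected noise
level, and the matching test RMSE (0.151) shows no overfitting.

```r
g <- make_bilayer_traj(n_lipids = 128, n_frames = 8, d_hh = 38,
                       head_sd = 0.2,
                       scd_target = c(0.22, 0.2, 0.18, 0.15, 0.1, 0.05),
                       n_chol = 20, tilt_deg = 13, seed = 5)
area_per_lipid(g$traj, 128)$mean                       #> 64
dhh_from_profile(density_profile(g$traj, weighting = "electron"))
#> 38.25   (truth 38, bin width 0.25)
cholesterol_tilt(g$traj, g$o_atoms, g$c_atoms)$mode_deg #> 13.5

h <- make_heating_scan(midpoint = 319, sigma = 0.5, seed = 11)
melting_point(h$scan, 128)$tm                          #> 319.5 K
```

Each analyser recovers the generator's ground truth within its stated
tolerance (one bin for `D_HH` and tilt, ~1 K for the melting point).

A command-line interface wraps the same operations
(`lipidtools::main_cli()`, or the `inst/exec/lipidtools` Rscript
wrapper): subcommands `fit-torsion`, `fit-angle`, `avg-charges`,
`analyze`, `melt-scan`, `simulate-fixtures`; every run writes a
`.prov.json` provenance record.

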