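---
title: "Methods: torsion fitting, charge averaging and bilayer observables"
author: "lipidtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: torsion fitting, charge averaging and bilayer observables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidtools)
```

# Scope and scientific setting

Developing a lipid force field of the AMBER family involves three
computational stages that this package implements: fitting dihedral
(torsion) and valence-angle parameters to quantum-mechanical reference
energies, averaging per-conformer RESP partial charges into modular
head/tail fragments, and validating the resulting bilayers against the
structural observables measured by NMR and X-ray/neutron scattering.
The expensive upstream stages — QM single points and molecular-dynamics
sampling — are out of scope: their outputs (conformer energy tables,
charge sets, coordinate trajectories, heating scans) are the package's
*inputs*, and a synthetic-fixture module can generate each input class
with known ground truth.

# The torsion model and its fitness

The dihedral potential is the standard cosine series
$E(\theta) = \sum_n V_n\,(1 + \cos(n\theta - \gamma_n))$ with
non-negative barrier heights $V_n$ (kcal/mol), integer periodicities
$n \ge 1$ (no two terms of a series share one) and phases $\gamma_n$
in $[0^\circ, 360^\circ)$. Sign information is carried by the phase:
a term with $\gamma = 180^\circ$ is the sign-flipped cosine, which is
why the fitting constraint sets below never need negative barriers.

Each conformer record pairs the dihedral angles of the fitted torsions
with two energies: the *zeroed* MM energy (all fitted barriers set to
zero, so it contains every other force-field term) and the QM
reference. The objective is the weighted least-squares mismatch

$$F = \sum_i w_i \left(E_{QM,i} - E_{zeroed,i} - E_{torsion,i} - c\right)^2.$$

**Offset alignment.** QM and MM energies have unrelated zeros, so only
relative energies are comparable. The constant $c$ is fitted
analytically as the weighted mean residual (the optimum of a quadratic
in $c$), with a flag to disable. Consequences tested as invariants:
adding any constant to all QM energies leaves $F$ unchanged, and the
aligned $F$ never exceeds the unaligned one. One side effect is that
the constant part of a fitted series ($\sum_n V_n$) is not
identifiable; recovery is therefore always assessed on *centred*
energy curves.

**Weights** default to 1. The field exists for extensions (e.g.
Boltzmann weighting) but no weighting scheme is applied by default.

# The genetic algorithm

Phases are discrete by construction — $\{0^\circ, 180^\circ\}$ for
hydrocarbon torsions, $60^\circ$ increments for headgroup torsions
(stereochemistry), or user-fixed sets — and periodicity sets are
policy-driven ($n = 1\ldots5$ for 1D scans, $n = 1\ldots3$ for
conformational ensembles, or retained per-label sets). The chromosome
therefore mixes one continuous gene (barrier, clipped to
$[0, 10]$ kcal/mol by default) and one categorical gene (phase index)
per allowed periodicity per label; multi-label datasets are fitted
simultaneously on one concatenated chromosome.

Defaults: population 200, 500 generations, binary tournament
selection, uniform crossover at rate 0.8, per-gene mutation at rate
0.05, elitism 2. Barrier genes mutate by Gaussian steps whose width
*anneals geometrically from 0.3 to 0.01 kcal/mol* across generations;
phase genes mutate by uniform resampling from their policy set. The
annealing is a deliberate design choice: with a fixed step of
0.3 kcal/mol the population cannot settle below a ~0.1 kcal/mol noise
floor on the barriers, while the 0.05 kcal/mol curve-recovery
tolerance used in validation needs barrier precision of a few
hundredths. Annealing reaches it without adding any non-GA machinery
(gradient or least-squares polish steps are intentionally absent).

Determinism: all randomness flows from the single integer seed in
`ga_config`; the caller's RNG state is saved and restored, and
identical inputs reproduce bit-identical results. Elitism makes the
best-fitness history non-increasing, which is asserted. Equal-fitness
ties break toward the lowest total barrier (parsimony: the smoothest
torsion profile that explains the data).

**Validation oracle.** `ga_oracle_fit` enumerates every combination of
a barrier grid and the allowed phases (capped at $10^7$ candidates)
and returns the global minimum of the same fitness. Because the GA
optimises barriers continuously, it can legitimately *undercut* the
grid optimum; the meaningful checks, both tested, are (i) the GA comes
within 5% of the grid optimum and (ii) the oracle dominates the GA
candidate after snapping its barriers onto the oracle grid.

**Angle fitting.** $K(\theta-\theta_0)^2 + c$ (deviation in radians,
AMBER's convention for angle force constants) is a quadratic in
$\theta$, so the fit is an exact linear regression on
$(\theta, \theta^2)$; non-positive curvature or a vertex outside the
scan range raises an error rather than returning an extrapolated
minimum. The synthetic scan generator defaults to
$\theta_0 = 112^\circ$ over $90$–$150^\circ$ in $1^\circ$ steps, the
shape of a saturated-hydrocarbon C–C–C angle scan.

# Charge averaging

Final fragment charges are the per-atom arithmetic mean over a
conformer ensemble (200 members by default in the generator, matching
standard practice for implicitly polarised ensemble charges). The mean
total can drift from the integer fragment charge only at rounding
scale; the residual is removed by uniform redistribution over all
atoms. Uniform (rather than charge-weighted) redistribution is the
simplest scheme that cannot disproportionately flip small charges, and
the residuals are numerically tiny anyway. Printed tables are rounded
to 6 decimals with the redistribution re-applied after rounding, so
the printed column sums to the integer target exactly. Modular
assembly validation simply sums the integer fragment targets and
compares with the declared species charge (0 zwitterionic, −1
anionic).

# Bilayer observables

**Centring.** Every profile recentres each frame on the mass-weighted
centre of the lipid-role atoms; z = 0 is the bilayer midplane.
Coordinates are minimum-imaged in z against the per-frame box.

**Electron weighting.** An atom contributes $Z - q$ electrons (its
atomic number minus its partial charge), the convention that
distributes electrons according to the charge model; a pure-$Z$ mode
is exposed as a flag since analysis tools differ on this point.
Profiles use 0.25 Å bins by default and are symmetrised
($[\rho(z)+\rho(-z)]/2$) before form-factor transforms.

**$D_{HH}$** is the distance between the highest local maximum at
$z<0$ and at $z>0$ of the electron-density profile; monotone or
single-peaked profiles raise an error. Accuracy is limited by the bin
width, which is how the tests state their tolerance.

**Order parameters.** $S_{CD} = \langle(3\cos^2\theta - 1)/2\rangle$
over frames, molecules and equivalent hydrogens, with $\theta$ the
C–H angle to the z axis. The signed mean is exposed alongside
$|S_{CD}|$ (what NMR reports). Exact limits — axial 1, planar −0.5 —
and the isotropic null ($|S_{CD}| \to 0$) are asserted, as is
invariance under rigid rotations about z.

**Form factors.** $|F(q)| = |\int \Delta\rho(z)\cos(qz)\,dz|$ by
trapezoidal quadrature on the bin grid, against a solvent background
(0.333 e/Å$^3$ for X-ray water at ambient conditions, overridable).
The neutron route builds a scattering-length-density profile from
tabulated bound coherent scattering lengths, interpolating *water*
hydrogens between H and D by the D$_2$O fraction; lipid hydrogens are
treated as non-exchangeable. The default q grid (0–0.8 Å$^{-1}$, step
0.005) covers the experimentally reported range. Quadrature is checked
against closed forms (Gaussian and boxcar contrasts); discontinuous
test profiles need half-height edge samples for the trapezoid rule to
match the analytic transform, which is a property of the quadrature,
not an implementation artefact.

**Cholesterol tilt** uses the vector from the hydroxyl oxygen to the
chain-connecting sterol carbon, folded to $[0^\circ, 90^\circ]$
against the bilayer normal so both leaflets accumulate in one
histogram (1° bins); the mode bin centre is the "most probable tilt".

**Transit events.** With the molecule's z series centred on the
midplane, any maximal contiguous run of frames with $|z| < 2$ Å is one
event; it is a flip-flop if the leaflet sign after the run differs
from before, otherwise a transient visit. Runs touching the series
boundary cannot be resolved and count as transient visits. The
maximal-run rule is this package's declared convention (alternatives,
e.g. counting every band entry frame, would overcount contiguous
frames). Uniform temporal subsampling preserves counts exactly as long
as it does not skip an entire visit — a documented limitation asserted
on constructed fixtures.

**Melting point.** The area per lipid of a heating scan is smoothed by
a centred running mean over a 1 ns window (the conventional choice for
~0.5 K/ns heating ramps), and the transition temperature is the
maximum of the centrally differenced dAPL/dT. Two numerical choices
matter: the difference stencil spans ±2 windows and the slope is
smoothed with the same window — together they keep the derivative
above the smoothed noise floor without biasing the peak — and the
derivative is only evaluated where the running mean used a full
window, so an exactly linear scan yields an exactly constant slope and
triggers the "no distinct inflection" error instead of returning an
edge artefact.

# The synthetic world

The generators state the world the tests live in; their defaults are
not tuned to outcomes:

- `make_fit_dataset`: 1000 conformers (the scale of a conformer
  extraction from a bilayer run), uniform angles, a smooth two-cosine
  nuisance background as the zeroed MM energy, a constant offset
  (−97.3 kcal/mol) standing in for the unrelated absolute scales, and
  optional Gaussian noise.
- `make_angle_scan`: 90–150° in 1° steps, default minimum 112°,
  K = 120 kcal/mol/rad².
- `make_charge_ensemble`: 200 members, zero-sum Gaussian perturbations
  (σ = 0.05 e) around a base set that sums to the integer target.
- `make_bilayer_traj`: two leaflets of bead-chain lipids at 64 Å² per
  lipid, headgroups at ±D_HH/2 (default 38 Å) with 0.8 Å jitter, C–H
  orientations drawn from a two-point mixture on cos θ that realises
  any target S_CD in [−0.5, 1] exactly in expectation (the simplest
  exactly solvable scheme; axial with probability
  $p = (S_{CD}+\tfrac12)/\tfrac32$, planar otherwise), optional
  two-atom cholesterol probes with prescribed tilt. These lipids are
  deliberately non-physical — no sterics, no bonded structure beyond
  the C–H pairs — because they exist to carry exact statistical
  structure, not realism. A green analyser test therefore establishes
  correct *measurement*, not force-field quality.
- `make_heating_scan`: logistic APL(T) between 48 Å² (gel) and 62 Å²
  (fluid) plateaus with 2.5 K width, sampled at 0.5 K/ns and 0.05 ns
  intervals; presets at 319 K and 335 K midpoints mirror the melting
  temperatures a saturated-PC bilayer shows under 1–4 Lennard-Jones
  scalings of 0.167 (SCNB = 6) and 0.5 (SCNB = 2) respectively.
- `make_z_paths`: scripted approach/inside/exit segments with noise
  clipped so the trajectory is inside the band exactly during scripted
  visits and at |z| ≥ 2.6 Å otherwise — the truth sidecar is exact by
  construction.

All generators restore the caller's RNG state and are byte-identical
under a fixed seed.

# File formats and environment choices

Trajectories are read from multi-model PDB (CRYST1 boxes, fixed-column
records, element from columns 77–78 with a name-based fallback) plus a
CSV sidecar for atomic numbers, partial charges and roles, or from a
plain-text long-format frames CSV that round-trips at full double
precision. No NetCDF reader is included: no R NetCDF bindings are
available in the supported environment, and the frames CSV plays that
role as the text-based bulk-coordinate route. Parameters write to
AMBER frcmod DIHE/ANGLE sections with negative-periodicity
continuation rows for multi-term dihedrals. All writers are atomic
(temp file + rename).

# Known limitations

- No MM engine: zeroed energies are inputs, never computed; no SCEE
  electrostatic 1–4 pathway (only the Lennard-Jones SCNB divisor the
  melting analysis concerns).
- The GA is the only stochastic optimiser; no gradient or annealing
  alternatives.
- Form factors are the forward transform only; no fitting of scaling
  factors to experimental curves.
- The fixture bilayers cannot exercise headgroup-specific NMR
  signatures or any observable that requires genuine conformational
  ensembles.
- Order-parameter and tilt estimates inherit Monte-Carlo error from
  finite sampling; tests size their fixtures so the stated tolerances
  hold with wide margins.
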