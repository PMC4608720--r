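---
title: "Methods: kinase-domain state descriptors, collective modes and cryptic-pocket tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kinase-domain state descriptors, collective modes and cryptic-pocket tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Protein tyrosine kinase domains switch between active and inactive
conformations, and molecular-dynamics (MD) ensembles of different
biochemical states (inhibitor-bound, apo, singly or doubly phosphorylated
on the activation loop) differ in a small set of interpretable geometric
observables rather than in any single structure. `kindyn` implements the
trajectory-analysis side of such a study for the ZAP-70 kinase domain
convention of residue numbering: per-frame geometric descriptors, B-factor
flexibility and convergence profiles, quasi-harmonic collective-mode
analysis of concatenated multi-state ensembles, and grid-based transient
(cryptic) pocket detection. Because production MD ensembles are rarely
redistributable, the package also contains a first-class synthetic
generator that plants all of the relevant signals with known ground truth,
so every stage of the pipeline is testable end to end.

## Descriptors and their state logic

Four observables carry the state fingerprint:

* **DFG cyclization** — distance from the DFG aspartate (D479) side-chain
  carboxylate carbon to the glycine (G481) backbone amide hydrogen. Three
  conformations are distinguished: a hydrogen-bonded *closed* ring near
  3 Å, a *semi-closed* arrangement near 6 Å, and an *open*, extended loop
  near 8 Å. The classifier uses midpoint decision boundaries (4.5 and
  7.0 Å) between these reference levels; the levels are state centres, so
  midpoints are the least-committal boundary choice, and both are
  configurable (`fingerprint_thresholds()`). The partition of `[0, Inf)`
  is total and left-closed on the upper side, so boundary values classify
  upward deterministically.
* **alphaC positioning** — mass-weighted centre-of-mass distance between
  the alphaC helix (D379–Q392) and the C-lobe. Reported levels near
  13.5 Å (buried), 14.5–15 Å (intermediate) and 15.5 Å (displaced) give
  midpoint boundaries of 14.25 and 15.25 Å. The C-lobe selection defaults
  to the full C-lobe residue range of the role map with mass weighting;
  this choice is recorded in the series metadata because "centre of mass
  of the C-lobe" admits several atom selections.
* **K369–E386 salt bridge** — minimum heavy-atom distance between the
  lysine NZ and the glutamate carboxylate oxygens, scored as formed below
  4.0 Å. A geometric 4 Å heavy-atom cutoff is the common salt-bridge
  convention; occupancy is the fraction of frames strictly below it. No
  angular hydrogen-bond criterion is applied anywhere — occupancies are
  distance-only by design.
* **W505 gating** — minimum distance from the conserved tryptophan to the
  ATP site (bound ligand atoms when present, otherwise a configured
  anchor role, flagged in metadata). Side-chain gating is captured through
  distances only; no rotamer/dihedral analysis is attempted.

Amide hydrogens are frequently absent from crystal structures. When the
DFG glycine has no `H` atom the panel falls back to the amide nitrogen
with a nominal −1.0 Å N→H correction (floored at zero) and flags the
fallback in the metadata, rather than failing or silently measuring a
different quantity.

## Flexibility and convergence

Per-residue B-factors are computed as `B = (8π²/3)·RMSF²` from Cα
mean-square fluctuations after aligning all frames to the average
structure. The alignment reference is the iterated mean structure (two
passes), which is the standard RMSF practice; frame-1 referencing is
available by flag. For convergence diagnostics the trajectory is split
into `n_segments` (default 10) sequential parts of equal length, with
remainder frames going to the last segment; per-segment B-factors use the
segment's own mean position, and their across-segment variance per residue
measures whether local flexibility and the average structure are
stationary over the run.

Two numerical facts matter when validating against the closed form
`B = 8π²σ²` for isotropic jitter of per-axis σ: the estimator is exact to
machine precision against a direct variance computation, and the rigid-body
fit removes 6 of the 3N fitted degrees of freedom, lowering the expected
value by the factor `(1 − 6/(3N))` (≈ 0.8% for 240 residues). The test
suite asserts against the corrected expectation.

## Collective modes

"Normal modes" here are quasi-harmonic modes: eigenvectors of the
covariance matrix of aligned Cα coordinates (essential dynamics), computed
from the trajectories themselves rather than from a Hessian. Trajectories
of all states are concatenated in input order, aligned to the global mean
structure (first-frame bootstrap followed by two mean-structure passes —
the bootstrap makes the result exactly invariant to rigid motions
pre-applied to any input), and eigendecomposed without mass weighting
(a flag can enable Cα-only subsets other than the default). Rigid-body
motion is removed by the alignment, not by discarding six eigenmodes;
near-zero modes are reported, not dropped. Eigenvalue sums are checked
against the covariance trace on every run.

Per-(mode, state) statistics report mean, variance and RMS projection
amplitude. The **discrimination score** formalizes "mode amplitude
correlates with state": it is a one-way ANOVA F statistic computed over
states on the *squared* projections. Squaring matters: a mode planted as a
zero-mean oscillation active in one state only shifts the second moment,
not the mean, so an F on raw projections would be blind to exactly the
signal of interest; the squared-projection F responds to both mean shifts
and amplitude differences. Significance is assessed against a
label-permutation null (default 200 permutations), with the p-value
`(1 + #{null ≥ observed}) / (1 + n_perm)`, so the smallest attainable
p at 200 permutations is ≈ 0.005.

## Cavity detection and pocket tracking

The grid method follows the cited trajectory-cavity convention: voxels
(default 1.0 Å edge) are protein when their centre lies within
`vdw + probe` (probe 1.4 Å, the water radius) of an atom; an empty voxel
is a cavity candidate when protein blocks at least `min_blocked` of the 6
axis directions (default 6, fully buried); candidates group by
26-connectivity; components below 27 Å³ (one 3 Å cube) are noise and
discarded. None of these parameters are stated by the upstream method's
users, so all are config keys with these defaults. The grid margin exceeds
the largest atom reach plus two voxels, so no cavity can touch the box
boundary, and identical frames always produce identical voxel sets.

Pocket tracking seeds on the ten pocket-lining residues (R460, D461,
L462, A463, K500, W501, P502, W505, Y506, S524) and records, per frame,
the volume of the single largest component with at least one voxel within
5 Å of a seed atom — the largest-qualifying-component rule matches the
singular "the pocket" usage, as opposed to summing all nearby components.
The open/close boolean applies a volume threshold that is purely a
reporting convention. The shipped default is 200 Å³, a conservative level
above any discretization artefact; for the synthetic panel, whose planted
void is a 5×5×5 Å cube (125 Å³ analytic, ≈ 140–170 Å³ at 1 Å
discretization of the noisy walls), the tests and acceptance script pass
`open_threshold = 60` — above the 27 Å³ floor, below the planted volume —
because the default threshold would never classify a 125 Å³ pocket as
open. Both numbers are arguments, not constants.

## The synthetic generator

`simulate_panel()` produces the five canonical states with planted
signals:

| state | DFG (Å) | alphaC (Å) | bridge occ. | loop flex | modes | pocket |
|-------|---------|-----------|-------------|-----------|-------|--------|
| STA   | 3.0     | 15.0      | 1.0         | 1.0       | —     | off |
| Y0Y0  | 5.0     | 14.5      | 0.5         | 1.2       | 4     | gated |
| YP_Y0 | 5.0→8.0 at 0.4 | 13.5→14.5 at 1/3 | 0.1 | 2.0 | 1, 3 | off |
| Y0_YP | 5.0     | 15.5      | 0.0         | 2.5       | 1, 2  | off |
| YP_YP | 8.0     | 15.5      | 0.0         | 3.0       | 1, 2, 3 | off |

Distances follow exact AR(1) discretizations of Ornstein–Uhlenbeck
processes (relaxation time `ou_tau`, default 1 ns; stationary sd, default
0.3 Å — reference figures report no variances, so the sd is a free,
documented parameter). Scheduled transitions are step changes of the mean
at a stated fraction of the run: the mono-phosphorylated DFG opening at
0.4 of the trajectory and its alphaC shift at 1/3, mirroring transitions
observed around 600 ns and 500 ns of a 1.5 µs production run. Transitions
are scheduled, not spontaneous barrier crossings, so the acceptance
surface is reproducible.

The salt bridge is a two-state telegraph process over formed (3.0 Å) /
broken (8.0 Å) geometries with the profile's stationary occupancy and a
switching rate of 20 events/ns — fast enough that consecutive saved frames
(0.1 ns apart) are nearly independent and occupancy recovery follows the
binomial law. Planted collective modes are orthonormal random displacement
fields over the Cα atoms, with translation/rotation content projected out
(alignment would silently remove it and bias recovery tests) and helix
Cαs excluded (their positions are overwritten by the rigid helix
placement); amplitudes follow sinusoids with state-specific amplitude,
distinct periods and 10% amplitude noise, so the RMS projection of a mode
of amplitude A is A/√2. Pocket gating toggles the fat gate pseudo-atom
(a 3 Å sphere standing in for the whole tryptophan side chain) between an
"in" position that fills the planted wall-enclosed 5×5×5 Å void and an
"out" position that vacates it, with exponential dwell times of 6 ns open
/ 14 ns closed — an open fraction of 0.3 with several full cycles inside a
500 ns test-scale run. Real gating kinetics are slower; the dwell times
are deliberately scaled to the runs the package simulates.

Everything is a pure function of (profile, config): identical seeds give
bit-identical trajectories, and the five-state panel uses seeds
`seed + 0..4`.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: there is no force field, solvent or
thermostat; lobes are rigid atom clusters rather than folded protein;
transitions are scheduled rather than activated; descriptor fluctuations
are Gaussian and exactly mean-reverting; the cavity has analytic walls.
The generator validates the *analysis code*, not the physics: a pipeline
that recovers every planted signal here can still face sampling noise,
alignment ambiguity and force-field artefacts on real trajectories.

## Structure and trajectory I/O

PDB (v3 coordinate records, single- and multi-model) and DCD
(CHARMM/NAMD 32-bit) are supported for reading and writing, with
author residue numbering preserved end to end and all in-memory
coordinates in Å, times in ns. Altloc policy is keep-first-with-warning.
Van-der-Waals radii come from a bundled, overridable per-element table
(Bondi-style values). XTC is not in the supported set: no installed R
facility reads it, and its compressed coordinate codec is out of
proportion to its role as plumbing here; DCD or multi-model PDB cover the
same use. Empty (0-frame) writes are an error, never an empty file;
truncated DCD reads report the last complete frame.

## Pipeline

`run_pipeline()` composes simulate/load → descriptors → fingerprints →
B-factors → modes → pocket tracking → report, writing each stage under
deterministic file names with a JSON report (including seed and config
hash) and a plain-text summary. Exactly one input source — generator or
real trajectories — must be configured. Generator-path reruns with the
same config and seed are byte-identical, which the test suite asserts at
the file-hash level. Plots (descriptor traces, B-factor overlays, mode
amplitudes, pocket volumes) are optional and written as PDF by default.

## Problem sizes

The shipped defaults mirror a production setting: 15,000 frames per state
at 0.1 ns/frame, 240 residues. The test suite and acceptance script
exercise the same code paths at 200–5,000 frames per state (10,000 for
occupancy recovery, where binomial standard errors at three-sigma need
that depth), three generator seeds for the panel-level claims, and
1.0/0.5 Å grids for cavity work — sizes chosen so the full statistical
battery stays desk-fast while every tolerance below remains the binding
constraint rather than the sample size.

## Known limitations

* Occupancies are distance-cutoff only; no angular criteria.
* The DFG/alphaC decision boundaries are conventions over reported state
  centres, not fitted decision rules; hysteresis smoothing exists
  (0.5 Å option) but is off by default.
* Cavity volumes are voxel counts: discretization inflates a planted
  void by up to one surface shell, and rotations move volumes by several
  percent. Absolute pocket volumes from unknown grid parameters are not
  comparable across tools.
* The mode discrimination F is heuristic under temporal autocorrelation;
  the permutation null permutes frames freely and is therefore
  anti-conservative for slow modes. It ranks modes; it is not a
  publication-grade hypothesis test.
* `state_amplitude_stats()` requires at least two frames per state;
  single-frame states are an error, not a silent NA.
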