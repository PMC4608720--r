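# kindyn

Trajectory analysis for protein kinase domains: activation-state
descriptors, flexibility and convergence profiling, state-correlated
collective modes, and grid-based cryptic-pocket detection — plus a seeded
synthetic-trajectory generator that plants all of these signals with known
ground truth.

`kindyn` is aimed at computational structural biologists who run
molecular-dynamics (MD) simulations of kinase domains in several
biochemical states (inhibitor-bound, apo, phosphorylated variants) and
want a tested, reproducible pipeline from raw trajectories to a per-state
conformational fingerprint. Residue roles follow the ZAP-70 kinase-domain
numbering convention (DFG motif D479/F480/G481, catalytic salt bridge
K369–E386, alphaC helix D379–Q392, activation-loop tyrosines Y492/Y493,
gate residue W505), supplied as an overridable role map so the same code
drives any kinase.

## What it computes

* **Geometric descriptors** per frame: the DFG cyclization distance
  d(D479 Cγ → G481 H), the alphaC–C-lobe centre-of-mass distance, and
  minimum-distance contact series for the K369–E386 salt bridge and
  related interactions, with occupancies scored by a strict distance
  cutoff (default 4 Å).
* **State fingerprints**: each frame is classified as DFG closed /
  semi-closed / open (boundaries 4.5 and 7 Å, midpoints between the ~3,
  ~6 and ~8 Å reference conformations) and alphaC buried / intermediate /
  displaced (14.25 and 15.25 Å); occupancy fractions, dominant states and
  bridge occupancy summarize a trajectory.
* **B-factors and convergence**: per-residue B = (8π²/3)·RMSF² after
  iterated mean-structure alignment, plus per-segment B-factors over 10
  sequential splits and their across-segment variance.
* **Collective modes**: quasi-harmonic (essential-dynamics) modes of the
  concatenated multi-state Cα ensemble — eigenvectors of the aligned
  coordinate covariance — with per-(mode, state) projection statistics, an
  ANOVA-style discrimination score on squared projections, and a
  label-permutation null.
* **Cryptic pockets**: voxel-grid cavity detection (1 Å spacing, 1.4 Å
  probe, 6-direction buriedness, 26-connectivity flood fill) and per-frame
  volume tracking of the pocket seeded on its ten lining residues.

All results are tidy tibbles with `autoplot()`, `tidy()` and `glance()`
methods; trajectories read and write PDB (single- and multi-model) and
CHARMM/NAMD DCD.

## Worked example

Five synthetic state ensembles (2,000 frames each), then the fingerprint
and pocket track of the apo-like state:

```r
library(kindyn)

pan <- simulate_panel(generator_config(n_frames = 2000, seed = 1))
panel <- descriptor_panel(pan$trajectories$Y0Y0, pan$topology, pan$roles)
fp <- fingerprint_trajectory(panel)
fp
#> <kd_fingerprint> Y0Y0: DFG semi_closed (occ 0.96), alphaC intermediate, salt bridge 0.50, 2000 frames
glance(fp)
#>   state n_frames dominant_dfg dfg_closed dfg_semi_closed dfg_open dominant_alphaC saltbridge_occupancy mean_alphaC_distance
#> 1  Y0Y0     2000  semi_closed     0.0405            0.96        0    intermediate                0.499                 14.5
```

The apo-like state sits in the semi-closed DFG conformation 96% of the
time with the catalytic salt bridge formed in half the frames — the
planted profile for that state. The gated cryptic pocket opens only here:

```r
pt <- track_pocket(pan$trajectories$Y0Y0, pan$topology, pan$roles,
                   open_threshold = 60, stride = 10)
glance(pt)
#>   state n_frames max_volume_A3 argmax_frame open_fraction open_threshold
#> 1 Y0Y0       200           174         1541          0.42             60
```

The tracked volume (~170 Å³ when open; the planted void is a 5×5×5 Å cube
whose voxelized volume exceeds 125 Å³ by a surface shell) toggles with the
planted 6 ns/14 ns gate dwell times. Collective modes over all five
states, ranked by how sharply their projection amplitudes separate the
states:

```r
al <- concat_align(pan$trajectories, pan$topology)
m <- compute_modes(al, n_modes = 8)
st <- state_amplitude_stats(m)
st
#> <kd_modestats> 8 modes x 5 states; top discriminative mode 5 (F = 3250.6)
```

`autoplot(panel)`, `autoplot(st)` and `autoplot(pt)` give the standard
trace, amplitude and volume figures; `run_pipeline()` composes the whole
analysis (simulate/load → descriptors → fingerprints → B-factors → modes
→ pockets → JSON report) with deterministic outputs, and
`inst/cli/kindyn.R` wraps it for shell use.

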