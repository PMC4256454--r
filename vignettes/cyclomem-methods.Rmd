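---
title: "Models and methods behind cyclomem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cyclomem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclomem)
```

cyclomem is an analysis toolkit for coarse-grained (CG) simulations of the
cyclotide kalata B1 (kB1) interacting with a raft-mimicking membrane. It
covers the full computational pipeline around such simulations — model
construction, membrane generation, trajectory statistics, interaction-energy
decomposition and umbrella-sampling free energies — while the molecular
dynamics itself (thermostats, integrators, force-field tables) is out of
scope. Every analysis is exercised end-to-end on synthetic data with known
ground truth, so each stage's correctness can be demonstrated without
microsecond-scale MD. This vignette explains the models, the tunable
parameters and their defaults, and the choices made where the design was
genuinely open.

## The cyclic peptide model

kB1 is a 29-residue head-to-tail cyclic peptide with a cystine knot of three
disulfide bonds. Its sequence is divided into six loops by the six conserved
cysteines (positions 1, 5, 10, 15, 17, 22); `assign_loops()` labels the
inter-cysteine segments `loop1`–`loop5` in order and assigns the segment
that wraps across the cyclization junction to `loop6`, with cysteines in
their own `cys` group. For kB1 this puts Ser18–Val21 in loop 5 (including
the membrane-anchoring Trp19) and Thr23–Val29 in loop 6.

`build_cyclic_topology()` emits one backbone bead per residue plus the
standard CG protein side-chain beads (0 for Gly/Ala up to 4 for Trp), with
integer side-chain charges (Glu/Asp −1, Lys/Arg +1). At standard protonation
kB1's Glu3 and Arg24 cancel, giving net charge zero. Cyclization adds a
29th backbone bond between the last and first residues; since generic
parameter generators do not provide parameters for that junction, the
closure bond *copies* its length and force constant from a donor backbone
bond whose residue pair matches the junction chemistry (`copy_from_pair`
rule). For kB1 the junction is Val29–Cys1 and the automatic donor is the
Val21–Cys22 bond; other cyclic peptides can designate their donor
explicitly. Disulfide connectivity defaults to the cyclotide cystine-knot
pattern CysI–CysIV, CysII–CysV, CysIII–CysVI (1–15, 5–17, 10–22 for kB1) and
is a constructor argument, since knot topology is a family convention rather
than derivable from sequence. Angle and dihedral terms across the junction
are *not* emitted — only the closure bond — which is adequate for topology
accounting and synthetic-data purposes and is stated here as a limitation.

`map_atomistic_to_cg()` places the backbone bead at the centre of geometry
of the backbone atoms (N, CA, C, O) and, for residues with *k* side-chain
beads, partitions the side-chain heavy atoms in file order into *k*
contiguous chunks, one bead per chunk centre. The chunking is this package's
own convention: it preserves bead counts and centres-of-geometry contracts
exactly, but individual side-chain bead placements for multi-bead residues
will differ from mapping tools that assign named atoms to named beads.

## The raft-mimicking membrane

The membrane is a phase-separated bilayer of DUPC (unsaturated lipid), DPPC
(saturated) and cholesterol at mole ratio 0.07:0.62:0.31, hydrated with 6
water beads per lipid. `build_membrane()` places lipids on a hexagonal
lattice at an area per lipid of 0.64 nm² (the CG bilayer convention), with
DPPC plus a proportional share of cholesterol in a central lateral disc (the
liquid-ordered, lo, core) and DUPC plus the remaining cholesterol in the
surrounding annulus (liquid-disordered, ld). Species counts per leaflet are
apportioned by largest-remainder rounding so integer counts track the ratio
as closely as possible; cholesterol is split between core and annulus in
proportion to the DPPC:DUPC counts, since both regions contain cholesterol
and no finer rule is implied by the composition alone. Water is laid on a
cubic lattice above and below the bilayer, `round(6 × n_lipids)` beads
exactly.

The builder targets *geometric sanity, not equilibrium*: the real system
would relax the lateral structure over microseconds of MD. Downstream
analytics need species, leaflet and domain labels plus plausible geometry,
which is exactly what the builder provides deterministically from a seed.
The domain geometry is a central disc; "core surrounded by annulus" admits
other layouts (stripes), but a disc is the simplest shape satisfying the
description. Note a geometric consequence of the 7% DUPC fraction: at
desk-scale lipid counts the ld annulus is a thin ring, narrower than the
default 1.5 nm occupancy classification radius, so small synthetic membranes
cannot produce a neighbourhood that is majority-DUPC — the occupancy
classifier is therefore validated on constructed compositions instead.

## Synthetic data: the testing backbone

Three generators give every analysis a ground truth:

* `gen_binding_trajectory()` moves a rigid one-bead-per-residue peptide ring
  over a static membrane; each residue's height above the head-group plane
  follows a piecewise-linear target (approach, bound plateau, optional
  unbind/rebind breakpoints) plus Gaussian noise. Internal peptide dynamics
  are not emulated because no analysis in scope depends on them.
* `gen_tetramer_config()` builds a four-molecule frame in which a designated
  residue is within the contact cutoff minus a margin for exactly the listed
  molecule pairs and beyond cutoff plus margin for all others. Positions are
  found by a small least-squares layout and then *verified* by brute-force
  distance scan; infeasible margins raise a placement error.
* `sample_umbrella_windows()` draws window samples i.i.d. from the exact
  stationary density ∝ exp(−[U(z) + k/2 (z − c)²]/k~B~T) by inverse-CDF
  sampling on a fine grid, rather than by simulating Langevin dynamics. The
  free-energy estimator's contract concerns only the stationary density, so
  exact sampling is both faster and a stronger test. Defaults follow the
  simulated conditions: bias constant 1,500 kJ/(mol nm²), T = 310 K,
  k~B~ = 0.008314 kJ/(mol K).

All generators are pure functions of their specification and a seed. What
passing tests on these data do *not* show: kinetic realism, lipid diffusion,
correlated noise, or force-field accuracy — none of which the analyses
measure.

## Trajectory analytics

**Membrane surface.** The surface is the mean z of the head-group (PO4)
beads of the chosen leaflet. The choice of a head-group plane (rather than,
say, a density midpoint) matches the head-group/water interface picture of
amphipathic peptide binding; flat synthetic membranes recover the
construction height exactly.

**Distances and binding.** `residue_surface_distances()` reports the signed
z-distance of each residue's centre of geometry to that plane (minimum image
along z; negative = inserted below the head groups). A residue is *bound*
while its distance is ≤ 0 and *approaching* while ≤ 1.5 nm; both thresholds
are configurable, 0 being the natural insertion criterion for a head-group
plane. `binding_events()` reduces a distance profile to first-binding times
and bound intervals.

**Contact frequencies.** For `m` molecules of `n` residues, each frame
yields an `(mn) × (mn)` matrix of minimum bead–bead distances between
residue pairs (116 × 116 for the 4 × 29 tetramer). Two residues are in
contact for a molecule pair when their minimum distance is ≤ 1.2 nm, the
short-range interaction cutoff. Contacts are pooled over frames and the 6
unordered molecule pairs and reported as `100 · c/(c + n)` per residue pair,
reducing the matrix to 29 × 29. For an off-diagonal residue pair the two
orientations (i in A vs j in B, and j in A vs i in B) are OR-ed into a
single observation per molecule pair, so every entry shares the same
denominator (frames × molecule pairs); pooling frames-then-pairs or
pairs-then-frames is the same sum. A single frame in which Cys1–Cys1 is in
contact for 2 of the 6 pairs therefore scores 33%.

**Domain occupancy.** Per frame, lipids whose lateral minimum-image distance
from the peptide centre of mass is within 1.5 nm are tallied; a frame is
`lo` when the DPPC+CHOL fraction is ≥ 0.75, `ld` when ≤ 0.25, otherwise
`interface`. Radius and threshold are invented, configurable knobs (the
underlying notion of "located in a domain" admits many formalisations);
frames with no lipid in range classify as `interface` with a warning rather
than being dropped, so fractions always sum to 1.

## Interaction energies

Nonbonded energies use the standard CG force-shifted forms: Lennard-Jones
12-6 with the shift applied from 0.9 nm, and Coulomb with relative
permittivity 15 shifted from 0, both *exactly zero* at the 1.2 nm cutoff
with vanishing force and force-derivative there. The packaged bead-type pair
table carries compact, class-level well depths (polar/charged/nonpolar/apolar
levels, σ = 0.47 nm, small-bead pairs 0.43 nm at 75% ε); the exact published
force-field tables are deliberately not reproduced — analyses here depend on
the functional form and relative magnitudes, not on any specific published
ε. Group–group energies sum pair energies over inter-group bead pairs within
the cutoff, per frame, reporting mean ± sd; groups must be disjoint to
prevent double counting. `loop_decomposition()` computes the 21 unordered
loop-pair energies between *different* molecules and their percentages of
the summed total; cysteines form their own group and are excluded from the
loop partition by default (they are neither chemically nor visually part of
the loops), switchable with `include_cys`. Decomposition conservation — the
pair sums reproduce the undecomposed inter-molecular total — is enforced by
test.

## Free energies by WHAM

`wham()` bins every window's reaction-coordinate samples on a common grid
(bin width 0.02 nm by default) and iterates the standard self-consistent
equations: unbiased bin probabilities from bias-reweighted histogram counts,
window free-energy constants from the probabilities, until the largest
change in the constants falls below 10⁻⁶ kJ/mol (cap 100,000 iterations;
non-convergence is an error carrying the last residual, never a silent
result). The profile is −k~B~T ln p(z), shifted so the mean over z ∈ [1.8,
2.0] nm — the outermost 0.2 nm of the water side — is exactly zero, matching
the convention of quoting free energies relative to the peptide in water.
Bins no window visited are returned as `NA` and flagged. In the single
unbiased window limit the iteration terminates immediately and the profile
equals direct Boltzmann inversion of the histogram, a property the tests
assert exactly.

Window layouts follow `make_window_centers()`: an inclusive arithmetic
sequence (41 centres for 0.1 nm spacing over [−2, 2] nm) that refuses
non-integer spans rather than truncating silently; additional windows (2 for
the monomer layout, 45 total for the tetramer's) are passed as explicit
extra centres because their positions are a run-specific refinement of
histogram overlap.

Errors come from a complete-histogram bootstrap: each of 100 replicates
resamples every window's samples with replacement and re-runs WHAM
(warm-started from the full-data constants), and the per-bin standard
deviation across replicates is reported. Replicates that fail to converge
are dropped with a warning; more than 20% dropped is an error. Errors shrink
as 1/√n in the window sample count, which the test suite checks at n vs 4n.

## Problem sizes and numerical choices

The test suite and the reproduction script run WHAM at the full window
layout (41 windows × 5,000 samples × 100 bootstrap replicates, a few
minutes), membranes at up to 2,000 lipids, and oracle-equivalence checks
(brute-force distance scans and energy sums) on 20 randomised frames of
~100–500 beads — sizes chosen so every stage runs comfortably on a laptop
while leaving the statistical assertions well-powered. The WHAM iteration
works with the Boltzmann weight matrix exp(−bias/k~B~T) (entries in [0, 1],
no overflow) and re-centres the constants each sweep; histogram
inverse-CDF sampling is exact up to the 4,001-point grid resolution.
Degenerate inputs err early and specifically: empty files, particle-count
mismatches, non-cysteine disulfides, overlapping energy groups, boxes too
small to pack, infeasible contact geometries.

## Known limitations

* Only the closure *bond* crosses the cyclization junction; no junction
  angles/dihedrals.
* GRO is the only trajectory format (multi-frame GRO); XTC and binary
  topologies are not read.
* The membrane builder produces labelled starting geometry, not equilibrated
  structure; areas per lipid are uniform across species.
* LJ parameters are class-level stand-ins with the correct functional form,
  not a published force-field table.
* Bootstrap errors ignore sample autocorrelation — appropriate for the
  i.i.d. synthetic sampler, optimistic for real MD time series.
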