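---
title: "Methods: models, conventions and design choices in cypallo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, conventions and design choices in cypallo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cypallo)
```

`cypallo` post-processes molecular-dynamics data bearing on a superficial
allosteric site ("H1", among helices C, E and H) of membrane-anchored
drug-metabolizing cytochrome P450 enzymes. This vignette documents the
science behind each module: the model or procedure, its assumptions, the
parameters that matter, and the choices made where the design was
genuinely open. Units are fixed package-wide at the I/O boundary:
coordinates in Å, times in ps (readouts in ns where stated), energies in
kcal/mol.

## Atom roles and trajectories

All analyses run on four atom selections: protein α-carbons, the four
porphyrin nitrogens of the heme, the lipid C1 carbons that define the
leaflet reference plane, and ligand heavy atoms. `read_structure()`
assigns each atom exactly one role by residue/atom-name rules
(`default_role_rules()`); unmatched atoms become `OTHER`, so role counts
always partition the atom total. Residue numbers are taken verbatim from
the PDB (1-based, author numbering) — the conservation module maps sites
through an alignment, never by raw residue number, so no renumbering is
needed or done.

Trajectories are stored bio3d-style (one row per frame, 3N columns).
Multi-model PDB is the canonical text format; DCD is read when offered. A
truncated trajectory raises an error rather than returning a short read.
Frames are assumed to be whole-molecule (unwrapped) with respect to the
analyses performed; the geometric metrics use raw coordinates and no
minimum-image correction, which is appropriate for the centered, contiguous
systems the generator emits and is the documented expectation for imported
trajectories as well.

## Site conservation

The H1 site is defined by 18 residues in CYP2D6 numbering (`h1_site()`).
`map_site()` locates the alignment column of each ungapped reference
position, verifies the expected residue there (a mismatched reference
errors with the offending position), and extracts the same columns for all
sequences. Pair scoring is the three-level scheme: 1.0 identical, 0.5
different-but-same-group, 0 otherwise. Two open points are resolved as
follows and are configurable:

* **Grouping.** The default partition is aliphatic {A,V,L,I,M,C}, aromatic
  {F,W,Y}, polar {S,T,N,Q}, basic {K,R,H}, acidic {D,E}, special {G,P} — a
  standard physicochemical partition. Any alternative partition can be
  supplied; identity percentages are scheme-independent.
* **Aggregation.** The site value for a sequence pair is the mean pair
  score over the 18 mapped positions (per-pair site mean), reported as a
  symmetric matrix with unit diagonal, alongside percent identity over the
  site. The value is bounded by `identity/100 ≤ c ≤ identity/100 +
  0.5(1 − identity/100)`, which the tests enforce on randomized alignments.
* **Gaps** score 0 against everything, including another gap: a gap
  carries no conserved residue.

Alignment computation itself is delegated — the module consumes an aligned
FASTA (or character matrix) produced by any standard aligner.

## Membrane-model geometry

The membrane normal is the +z axis. The **heme tilt angle** is measured
between the best-fit plane of the four porphyrin nitrogens — the smallest
principal direction of the centered coordinates, exact for coplanar
atoms — and the z-axis: `90° − angle(normal, z)`, folded into [0°, 90°].
Under this convention a heme lying flat in the membrane plane reads 90°,
which is what makes the experimental 38–78° window meaningful; the
complementary normal-vs-normal convention is available via
`convention = "normal"`. Collinear nitrogens leave the plane undefined and
error.

The **burying depth** is the z-projection of the separation between the
unweighted Cα centroid and the lipid C1 centroid. The z-projection (not
the 3D centroid distance) is deliberate: the metric is defined relative to
the membrane plane, and a lateral offset of the leaflet centroid would
contaminate a 3D distance; `mode = "3d"` switches if desired. "Mass
center over α-carbons" is implemented as the unweighted Cα centroid (all
Cα masses equal), and the radius of gyration is likewise Cα-based and
unweighted.

RMSD uses least-squares rigid superposition (via bio3d) when requested;
RMSF superposes all frames onto the first over the same selection and
measures fluctuation about the superposed mean structure.
`validate_membrane_model()` gates the series means against inclusive
windows 38–78° (tilt) and 26–44 Å (depth, 35 ± 9).

## Hotspots

`association_scores()` implements the cumulative contact statistic: per
frame, the number of ligand heavy atoms within 5 Å of each α-carbon,
summed over frames and divided by the total number of ligand heavy atoms.
Multiple ligand copies are pooled into that total, matching a
normalization "to the total number of ligand heavy atoms". The score is
frame-order invariant, additive over trajectory concatenation, and
monotone in the cutoff — all property-tested.

`occupancy_zscore_grid()` voxelizes probe positions (default 1 Å voxels)
after superposing frames on the first frame's α-carbons, over the protein
bounding box plus a 5 Å margin. Because a "basal level of occupancy" is
not otherwise defined, the z-score normalization uses the mean and
standard deviation over *all* voxels of that box; an isolevel query such
as `occupancy_hotspots(grid, 15)` then returns voxels ≥ 15 σ. With
all-equal counts the z-scores are undefined and flagged rather than
silently zeroed. Grids export as OpenDX text for visualization.

## Tunnels

Per-frame bottleneck radii computed externally (CAVER-style CSV) are
parsed into per-tunnel series; frames without the tunnel are simply absent
(`n` counts found frames), and duplicated (frame, tunnel) rows error.
`compare_bottlenecks()` runs a two-sided Welch test from the series
summary statistics at α = 0.1 and reports `+` / `-` / `=`, or `n/a` when
a tunnel is absent in either condition. Swapping the conditions flips the
direction and preserves p.

`grid_bottleneck()` is an explicitly simplified stand-in for tunnel
geometry, not a Voronoi-based reimplementation (clustering parameters of
the external tool are metadata only). It runs a widest-path priority
search over 6-connected voxels of a clearance field, maximizing the
minimum clearance from a start voxel to the grid boundary. 6-connectivity
is chosen because face-adjacent moves give the conservative (narrowest)
bottleneck estimate. An isolated start returns a "no tunnel" value, not
an exception. The search is verified against two independent oracles:
exhaustive DFS path enumeration on small sparse corridor grids, and an
exhaustive threshold sweep with flood fill (the bottleneck is the largest
clearance level at which the start still reaches the boundary) on dense
random grids up to 6×6×4.

Egress pathways are assigned by the nearest tunnel anchor (Euclidean) to
the ligand center of mass at the first surface-crossing frame — the first
frame where the ligand COM is more than 5 Å from the nearest protein
atom, consistent with the dissociation criterion below. Ties break
lexicographically on the tunnel id, deterministically. Anchor coordinates
are configuration, not hard-coded structure-specific truth.

## Metadynamics readouts

The deposited bias is reconstructed from hills records as

$$V(s,t) = \sum_{t_i \le t} h_i \exp\!\left(-\frac{(s-s_i)^2}{2\sigma_i^2}\right)$$

with the width column read as σ (the PLUMED-style convention;
`width_is_fwhm = TRUE` converts from full width at half maximum).
Production defaults are h = 0.03 kcal/mol, σ = 0.05 Å on a
ligand-centroid-to-heme-iron distance CV with a 45 Å wall; the wall enters
only as the CV-grid upper bound (wall forces are simulation-side and out
of scope). No well-tempered rescaling is applied: heights are summed as
deposited. V is non-negative and non-decreasing in t at fixed s.

**Dissociation time (ΔT).** A visual "complete dissociation" call is
replaced by a reproducible criterion: the first frame opening a run of at
least `persistence` (default 10) frames whose ligand minimum distance
exceeds `threshold` (default 5 Å). Both parameters are exposed. Short
excursions are ignored; absence of egress is a value (`NA`), mirroring
replicas that never dissociate, and their maximal potential is then
evaluated at the final time and flagged.

**Maximal potential (P_max).** Defined here as the maximum of `V(s, ΔT)`
on a regular grid over [0, wall] with spacing ≤ σ/2 (no Gaussian can slip
between grid points; the coarse-grid error bound is h·(Δ/2)²/(2σ²) ≈ 3 %
of one hill height at the default spacing, and the tests verify agreement
with a 10× finer grid). An alternative reading — the maximum bias actually
experienced along the trajectory — is available by passing the CV trace
(`cv_trace`/`times`); it is bounded above by the grid maximum.

**Group comparison.** Per-metric two-sided Welch tests label each enzyme
by the group with the lower mean ("H1" = allosteric ligand bound, "WAT" =
none) at α = 0.1.

## Statistics and reporting

`welch_ttest_from_stats()` implements the summary-statistics Welch test
with Welch–Satterthwaite degrees of freedom and sample sd (ddof = 1),
matching the contract of summary-statistics t-test routines; it is
cross-checked in the tests against `stats::t.test` on raw draws. Both-zero
variances with equal means return p = 1 by convention; with unequal means
they error. In the outcome table, `Significance` is "yes" when *either*
egress metric falls below α — the either-metric rule, inferred from the
convention that a single sub-threshold metric suffices.
`plan_total_time()` and `cosolvent_plan()` account for the simulation
design (5415 ns per enzyme; 30 cosolvent runs and 600 ns per enzyme).

## The synthetic-data generator

The generator exists so that every analysis stage has inputs with exact,
independently known ground truth.

* `make_membrane_system()` builds a Cα-only bead protein (default 100
  residues within a 15 Å radius, centroid exactly at the origin), a
  4-atom porphyrin square (N–center 2.05 Å) rotated about x so its plane
  makes the target tilt with z, and a lipid C1 plane at exactly
  `bury_depth` above the protein centroid. Defaults (tilt 60°, depth
  37 Å) sit inside the experimental validation windows, at the level
  typical for equilibrated membrane-CYP models. Noise is isotropic
  Gaussian jitter per coordinate per frame — the simplest model whose
  effect on the metrics propagates analytically; at `noise_sd = 0` every
  metric is recovered exactly, and at 0.1 Å the empirical per-system
  spreads (tilt ≈ 2.0°, depth ≈ 0.017 Å, Rg ≈ 0.010 Å at the default
  sizes) set the ~3.5σ recovery tolerances used in the tests.
* `make_ligand_walk()` attaches a rigid ligand cluster that stays within
  contact of surface beads until a chosen frame, then leaves along the
  direction of a chosen exit anchor with strictly growing clearance —
  so the dissociation frame and exit pathway are known by construction.
  An optional single-frame excursion exercises persistence filtering.
* `make_alignment()` produces a reference plus identical variant
  sequences realizing a per-position plan (identical / same-group /
  different), with the expected conservation and identity matrices
  returned alongside.
* `make_tunnel_grid()` carves corridors with prescribed clearance
  profiles into a blocked grid and reports the known maximin bottleneck;
  corridor connectivity and boundary arrival are validated.
* `make_hills()` writes schedules that round-trip exactly through
  `read_hills()`.

All generators are deterministic under a fixed seed. What they do *not*
emulate is equally important for interpreting green tests: no realistic
lipid packing, solvent, energetics or docking poses; a bead protein with
no secondary structure; ligand kinematics, not dynamics. Passing the
recovery suite therefore demonstrates correctness of the *measurement*
pipeline — selections, geometry, statistics, bias reconstruction — not
realism of any simulation, and results on real trajectories inherit the
assumptions listed above (membrane normal along z, wrapped/unwrapped state,
role-labeling rules matching the force-field naming).

## Problem sizes and numerical choices

The test and acceptance workloads are deliberately desk-scale: membrane
systems of ~100 residues and 1–100 frames, 100-hill bias tables, grids up
to 6×6×4 for exhaustive cross-validation, 100-seed recovery families and
200-repeat power checks — sizes chosen so the full suite runs in well
under a minute while still exercising every code path and invariant.
Degenerate inputs are handled explicitly: collinear porphyrin nitrogens,
empty selections, zero-variance occupancy grids, both-zero-variance
t-tests, walled-in bottleneck starts, non-egressing replicas, and empty
hills files each have a defined value or a named error rather than
undefined behavior.

## Known limitations

* The physicochemical grouping is a documented default, not the (external,
  unpublished here) reference partition; group-level conservation values
  depend on it, identity values do not.
* The grid bottleneck finder is a geometric stand-in; it does not cluster
  tunnels across frames nor reproduce Voronoi-based radii.
* P_max is defined at the egress time over the full CV range; the
  along-trajectory variant is provided but not the default.
* Trajectory unwrapping beyond whole-molecule input is out of scope.
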