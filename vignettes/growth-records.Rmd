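---
title: "Growth records from voxel root time-series: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth records from voxel root time-series: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizotrack)
```

## The problem

Gel- and tomography-based imaging platforms deliver a *time-series of 3D
voxelized shapes* of one growing root system: sets $\mathbb{V}_0,
\dots, \mathbb{V}_T$ of unit cubes on an integer grid, one per
acquisition. Static tools measure each shape in isolation;
`rhizotrack` instead compresses the whole series into a single *growth
record* — the final shape equipped with a geodesic depth field, a branch
hierarchy, and a per-voxel creation-time field — from which structural
*and* dynamic traits of every individual branch can be read off.

Three modelling assumptions underpin the pipeline:

* **A1 (nested growth)** — a root system only elongates at tips and adds
  new branches at forks, so $\mathbb{V}_s \subseteq \mathbb{V}_t$ for
  $s \le t$ once the shapes share a coordinate frame;
* **A2 (tree topology)** — the system is connected and free of loops;
* **A3 (temporal density)** — acquisitions are frequent enough that a
  side branch, when first observed, is still shorter than its parent.

Real reconstructions violate all three mildly (touching branches create
loops; disconnected crowns appear); the pipeline tolerates mild
violations and reports the symptoms (loop candidates, switch counts,
alignment quality) rather than failing.

## Pipeline stages

### Voxel graph

Each shape becomes a weighted graph: nodes are voxels, arcs join
26-neighbours, and an arc weighs $1$, $\sqrt 2$ or $\sqrt 3$ voxel edges
for face/edge/corner adjacency, so that shortest paths approximate
physical path length in mm. (An `integer_weights` switch exposes the
cruder 1/2/3 weighting for comparison.) Disconnected inputs are reduced
to their largest component with a warning, since the downstream model
assumes connectivity.

### Rigid registration

All shapes are carried into the frame of $\mathbb{V}_0$ by motions
$M_{0t}$; any pair is then related by $M_{st} = M_{0s}^{-1} M_{0t}$.
When a shape already overlaps the reference well at the identity (the
common case for a fixed platform) ICP refines from there; otherwise a
4-point congruent sets (4PCS) search supplies the coarse motion: wide,
approximately coplanar 4-point bases are drawn from the source, and the
affine invariance of their two intersection ratios extracts congruent
candidates from the target by scanning point pairs of matching length.

Two pragmatic choices matter here and are deliberate:

* candidate motions are scored symmetrically — the fraction of target
  points landing within $\delta$ of the source *and* the fraction of the
  source covered by the moved target. Under nested growth the first
  component is bounded by $|\mathbb{V}_0|/|\mathbb{V}_t|$ while the
  second is near 1 for the correct motion, so the pair separates true
  alignments from partial overlays far better than either alone;
* candidates rotating by more than `max_rotation` (default 60°) are
  discarded. Successive acquisitions of a fixed platform differ by small
  repositioning motions; without the bound, near-symmetric shapes (a
  young root is almost a straight tube) lock onto 180° flips that score
  deceptively well.

ICP is plain point-to-point: correspondences are drawn from a fixed,
seeded sample of the *source* (earlier, smaller) side so growth voxels
in the target cannot bias the fit; the RMS residual is non-increasing by
construction and iteration stops when it improves by less than
`icp_tol` (default $10^{-3}$ mm). If the aligned residual still exceeds
one voxel edge the coarse search is retried with fresh bases (twice)
and the best result kept.

Quality control follows the platform convention: 10% of the first
shape's voxels are sampled and their mean distance to the closest voxel
of each aligned later shape is reported in voxel-edge units; a good
alignment stays below one edge, and shapes beyond `exclude_threshold`
(default 10.00 edges) are excluded from the growth record.

### Seed area and depth

Depth must be measured from a consistent origin. On the *last* shape,
principal component analysis of the voxels within Euclidean radius $R$
(in voxels) of each voxel finds locally spherical regions (three similar
covariance eigenvalues, smallest/largest $\ge$ `sphericity`, default
0.6); the largest such component, dilated by $R$, is the seed area. If
nothing qualifies — or the spherical set exceeds `max_fraction` of the
volume, as in blob-like shapes — the fall-back seed is the voxel nearest
the centroid of the topmost horizontal slice ($z$ points up, gravity is
$-z$). Among spherical components of comparable size the topmost wins:
a bare tube has two spherical end caps and the seed of a root system
sits at the top. What matters is not the biological truth of the region
but its *consistency* across the series, which is why the seed is
detected once (on $\mathbb{V}_T$) and propagated backwards: mapped seed
voxels claim their nearest voxels in each earlier shape.

Choose $R$ between one and two average branch radii. For the bundled
0.5 mm fixtures with a 1.5 mm primary we use $R = 4$ voxels (2 mm): at
$R = 3$ the neighbourhood ball fits inside the primary's tube, whose
core would then be labelled spherical and leak the seed down the trunk.

Depth $\varphi$ is multi-source Dijkstra from all seed voxels (weight-0
virtual source), computed with igraph; it is zero exactly on the seed
and 1-Lipschitz along arcs.

### Branch decomposition

Voxels are traversed in decreasing depth; an arc activates right after
its shallower endpoint. Every voxel starts as its own component carrying
a pointer to itself. When an arc $(u, v)$ merges two components with
tips $p$ (shallower) and $q$, either the overhang $\varphi(p) -
\varphi(u)$ is below `merge_threshold` and $p$'s whole piece is absorbed
into $q$'s branch, or $p$ is consolidated as a branch with fork $v$ and
parent $q$. The result partitions the voxels into branches
$(\mathrm{tip}, \mathrm{fork}, \mathrm{parent})$ linked into a tree
whose root branch holds the global depth maximum — a deepest-path
decomposition of the shape.

`merge_threshold` defaults to twice a crude average branch radius
$\hat r = \sqrt{V / (\pi\, \mathrm{depth}_{\max})}$: stubs shorter than
the branch thickness are surface noise, not laterals. Ties in depth are
broken lexicographically by voxel coordinate. Arcs whose endpoints are
already in one component are ignored (spanning-tree behaviour); those
that close no local triangle are counted as *loop candidates* — the
signature of touching branches (an A2 violation) — and reported, not
repaired: mistakes are local to the loop. Note that the assignment of
the junction voxels themselves depends on the order in which
simultaneously activated arcs are processed; any such assignment is
consistent with the traversal description, and the package fixes one by
its lexicographic arc order.

### Time function

The time field $\tau$ on $\mathbb{V} = \mathbb{V}_T$ starts at $T$
everywhere. Walking backwards over $t = T-1, \dots, 0$, every branch tip
of shape $t$ is mapped through the alignment to its nearest voxel $v$ of
$\mathbb{V}$ (matches farther than `tip_gate`, default 5 edges, are
skipped and counted); the branch of $\mathbb{V}$ containing $v$ has all
members $u$ with $\varphi(u) \le \varphi(v)$ stamped with $t$. Because
$t$ decreases, each voxel keeps the *earliest* time at which it was
observed. On noiseless series the sublevel sets $\{\tau \le t\}$
reproduce the aligned $\mathbb{V}_t$ up to a thin boundary band
(Jaccard $\ge 0.95$ in the bundled tests).

**Switch repair.** When a side branch out-grows its parent between
acquisitions, the depth decomposition of the final shape makes the
*younger* branch the through-going one at the fork. With the
earliest-observation semantics above this shows up as the side branch
being strictly *older* at the junction than the fork voxel itself:
fork $v$ of side branch $p$ has an arc-neighbour $u \in p$ with
$\tau(u) < \tau(v)$. Each conflict (processed in increasing fork depth)
is repaired by a *switch*: with $q$ the parent and $w$ its fork, the
part of $q$ between $v$ and $w$ moves to $p$, the fork/parent pointers
are exchanged so $p$ becomes through-going, children forking on the
moved segment re-parent, and $\tau$ on the segment is lowered to at most
$\tau(v)$. The scan repeats until clean or an iteration cap (10× the
fork count) is hit; repairs only ever lower $\tau$ and preserve the
tree. On clean simulations zero switches occur; a constructed
out-growth event yields exactly one, and the switch count is itself a
reported statistic — unusually high values flag acquisition problems
rather than biology.

### Traits

For branch $i$ at time $t$ the *sublevel branch*
$\mathbb{B}^i_t = \{u : \tau(u) \le t\}$ is measured: volume (voxel
count and mm³), depth and location of its tip (deepest member), length
(tip depth minus fork depth; full tip depth for the root branch),
tortuosity (length over the tip–fork Euclidean chord; tip to shallowest
member for the root branch), average radius $\sqrt{V / (\pi L)}$, angle
to gravity and to the parent (major PCA axes, folded into $[0°, 90°]$
since PCA axes carry no orientation; 0 for the root branch's parent
angle), switch-event indicator (is the branch longer than its parent at
$t$), and child count. Aggregates sum these per timepoint and
differences give growth increments. Seed volume, orientation, and
volume fraction are reported alongside, and a provisional, purely
geometric classification labels branches primary (topmost), seminal
(fork inside the seed area), crown (fork above the seed's bounding
box), or lateral — crown roots emerging above the reconstructed volume
cannot be identified geometrically, hence the "provisional" flag.

## The synthetic generator

Ground-truthed inputs are produced by sweeping balls along cubic-spline
curves (chord-length parameterized, densely sampled at a quarter voxel
edge): a voxel belongs to a branch if its center is within the sweep
radius of the curve truncated at the scheduled tip arc-length. Growth
schedules are non-decreasing, children attach on the parent's surface
and must be shorter than the parent when they first appear, and
non-adjacent curves may not approach closer than the sum of radii — so
A1–A3 hold by construction, and violations are rejected with errors.
Swept solids are capsules; the ground-truth volume is
$\pi r^2 L$ plus the free end-cap corrections (both caps for a
top-level branch, only the tip cap for a child, whose attach-end cap is
buried in its parent), and the ground-truth length is the curve arc
length. Optional per-timepoint rigid perturbations (re-voxelized on the
grid) exercise the registration, with the true motions returned.

The bundled fixtures define the validation conditions:

* `straight_root_spec()` — a 63.8 mm vertical branch of radius 1.5 mm
  at 0.5 mm voxels: tortuosity exactly 1, vertical orientation;
* `validation_root_system()` — a three-timepoint, seven-branch system
  (primary 63.8/71.1/95.2 mm, laterals of radii 1.0/0.885/0.685 mm
  appearing over the series, 4 mm seed ball) mirroring the
  hand-measured validation models;
* `curved_branch_specs()` — circular arcs (50–90°) and helices with
  generator-derived tortuosity;
* `small_root_system()` — a compact asymmetric 3-branch system used
  where many seeded registration replicates are run (10 series in the
  acceptance suite; ~3–6k voxels per shape keeps that under two
  minutes).

What the generator does *not* emulate: reconstruction blur, thickness
loss from image misalignment, touching branches, and disconnected
crowns. Passing its tests therefore demonstrates the correctness of the
algorithms under the stated assumptions, not robustness to every
artefact of a real imaging pipeline — the QC outputs (alignment
distances, loop candidates, switch counts) are the tools for spotting
those in real data.

## Numerical choices and limitations

* Geodesic length on the 26-neighbour graph systematically
  *over*-estimates Euclidean arc length by up to ~8% in unfavourable
  directions; on the bundled fixtures the net effect on total length
  stays within ~3%, and tortuosity errors stay under 2% because length
  and chord biases partially cancel.
* Depth ties and traversal ties are broken lexicographically; all
  randomized steps (base selection, subsampling, perturbations) take
  explicit seeds, so a run is reproducible bit-for-bit.
* The trait tables are only as good as the time field: branches whose
  early sublevel sets fall below the merge threshold of an early
  shape's own decomposition are first observed one acquisition late.
* Loop *removal* (separating touching branches) is out of scope; loops
  are detected heuristically (non-triangle intra-component arcs) and
  counted.
* Rigid registration only: the growth container fixes scale, and
  non-rigid deformation is not modelled.
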