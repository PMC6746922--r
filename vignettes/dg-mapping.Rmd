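---
title: "Directed graph mapping: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directed graph mapping: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dgmap)
```

## The problem

Catheter ablation of atrial and ventricular tachycardias requires the
operator to decide, from an electroanatomical activation map, whether
the arrhythmia is driven by reentry (an excitation wave circulating
around a functional phase singularity or an anatomical obstacle) or by a
focal source, and where the driver sits. Activation maps are sets of
local activation times (LATs) measured at discrete electrode positions,
and their interpretation is notoriously operator-dependent.

Directed graph (DG) mapping turns this interpretation into a
graph-theoretic computation. Excitation spreading from electrode to
electrode induces a directed network; reentry is then literally a
directed cycle in that network, and a focal source is a region whose
nodes have only outgoing edges. `dgmap()` implements the full pipeline
and returns a classed diagnosis object.

## The excitation network

**Neighbors.** Edges may only connect electrodes between which the wave
can travel directly. On regular grids a spherical neighborhood of
radius 1.5 x the lattice spacing gives up to 8 neighbors in 2D (26 in a
regular 3D grid); irregular clinical-style clouds are triangulated
(Delaunay), with an optional maximum-edge-length pruning for
concavities such as valve orifices (off by default). Non-planar clouds
are triangulated in their best-fit plane; true 3D tetrahedralization is
not implemented, which limits the Delaunay path to roughly 2-manifold
electrode clouds — the shape of single-chamber clinical maps.

**The conduction-velocity rule.** At a chosen time `t`, each electrode
contributes its first LAT after `t`. For a neighbor pair with positions
`x_u, x_v` and LATs `LAT_u < LAT_v`, a directed edge `u -> v` is drawn
iff

    cv_min  <  ||x_v - x_u|| / (LAT_v - LAT_u)  <  cv_max

with strict inequalities. Defaults follow tissue physiology:
`cv_min = 0.2`, `cv_max = 2.0` mm/ms for ventricular data, and
`cv_min = 0.08` mm/ms for atrial data (the slowest conduction measured
in human atria). The rule rejects apparent "conduction" that is too
fast (two electrodes activated by different wavefronts) or too slow
(successive beats).

**The dual-window merge.** Because edges always point from earlier to
later LAT, the single-window graph is acyclic by construction — reentry
cannot appear in it. A second graph is therefore built at `t + delta_t`
(default 40 ms; any `0 < delta_t < CL/2` works) and its edges are added
to the first **only when the origin node's LAT is unchanged**, i.e. the
origin has not yet re-fired. These are exactly the edges that close a
reentrant loop. By default a re-fired target electrode is identified
with its first-window node (one node per electrode, as a cycle must
revisit electrodes); `collapse = FALSE` keeps distinct (electrode, LAT)
nodes, in which case every stored edge satisfies the velocity rule
against its endpoints' stored LATs.

## Rotational activity

A cycle is a closed directed walk without node repetition. The smallest
cycle through a node `v` is found by breadth-first search: the shortest
path `v -> u` over all in-neighbors `u` of `v`, closed by `u -> v`
(compiled code; networks of a few hundred nodes are processed in
microseconds). Ties on edge count are broken by smaller geometric
perimeter, then by lexicographically smallest node sequence — over the
candidates induced by the deterministic BFS tree — so repeated runs are
identical. A brute-force enumeration of all simple cycles serves as the
oracle in the test suite.

Cycles are deduplicated by node set and **bundled**: single-linkage
clustering of their geometric centers (unweighted mean of node
positions) at a 1 cm threshold, followed by an optional pass (default
on) merging bundles that share nodes. Single-linkage makes the result
independent of cycle enumeration order. Each bundle is a reentry core
carrying the mean and the coordinate-wise median of its cycle centers
and its cycle count; the benchmark uses the median center and, per the
dominant-core rule, only the core with the most cycles (more cycles =
stronger evidence of sustained rotation).

## Focal activity

When the network contains no cycle (checked first — flowchart
precedence), LATs are bundled into 5 ms intervals (each LAT replaced by
its bin center, an idempotent operation) to suppress annotation
jitter, the network is rebuilt, and **source regions** — connected
components (over the neighbor relation) of nodes with in-degree 0 and
positive out-degree — are reported. The origin is the region centroid;
the earliest-activating electrode is reported alongside, since "the
middle of a region" admits both readings. Moving wavefront edges can
masquerade as sources at unlucky construction times; an optional
stability pass (default on in `dgmap()` for multi-beat recordings)
keeps only regions that recur at a second construction time one third
of a period later.

## Network features

- **Region of cycles**: per core, the electrodes on any of its cycles.
- **Region of influence**: each electrode is attributed to the core
  whose cycle-node set reaches it at the smallest network distance.
  "Arrival-time" distance (sum of per-edge LAT differences) is the
  default metric; hop count and path length in mm are options. Ties go
  to the core with more cycles, then the lower core index. Unreachable
  electrodes stay unassigned.
- **Wave averaging**: each directed arrow is split into four equal
  segments; with a surface mesh the segment endpoints are projected
  onto it (nearest point on the triangulated surface), in the planar
  case projection is the identity. Per node, all segments starting
  within 1 cm are averaged into one local propagation vector — a
  denoised flow map of the excitation.

## The phase-mapping baseline

The comparison method converts LATs to a sawtooth phase
`wrap(2*pi*(t - LAT)/CL)` in `[-pi, pi)` (using the activation nearest
in time to `t`) and searches for phase singularities. Design choices
that needed care:

- Phase is always differentiated **on the circle** (wrapped
  shortest-angle differences); naive differences produce spurious
  2*pi jumps at the sawtooth wrap line.
- The detector response is the **Sobel-filtered phase-gradient
  magnitude**: at a singularity all phase values meet, so spatial phase
  variation is maximal there. The response is deliberately not the
  quantized winding number: an integer-quantized response is nearly
  immune to LAT noise, which contradicts the well-documented noise
  fragility of phase mapping that the benchmark exists to quantify.
  The quantized plaquette charge is available separately
  (`phase_charge()`, and the `"nabla"` kernel) and carries the
  winding-number conservation test.
- A binary threshold at 95% of the maximal response defines detections,
  computed on the interior only (valid convolution, no padding), so
  frame edges cannot produce false positives.
- On a discrete grid one singularity's response is a **ring** of cells
  of diameter ~3 grid steps around the core (cells straddling the core
  wrap-cancel). Suprathreshold cells are therefore aggregated by
  single-linkage at 3.5 steps, positioned at their response-weighted
  centroid, and signed by the topological charge the cluster encloses.
- A smooth travelling wave has a spatially uniform response, and a
  purely relative threshold would flag it everywhere. A resolvable
  singularity forces phase steps toward the wrap scale near its core,
  so frames whose maximal response stays below `pi/6` rad per grid
  step are declared singularity-free. Waves undersampled to more than
  ~30 degrees of phase per electrode can still trigger the detector —
  a genuine ambiguity of phase data at that sampling.

## Synthetic activation fields

The generators produce the canonical stable-tachycardia patterns with
exact ground truth, so the whole pipeline is testable without an ionic
model:

- `make_rotor_field()`: an Archimedean-spiral rotor,
  `LAT = CL * (k + theta/2pi + r/lambda)` with
  `lambda = wave_speed * CL`. The radial term makes the wavefront
  propagate at `wave_speed` (default 0.7 mm/ms, the plane-wave
  conduction velocity of human ventricular tissue) away from the core,
  with apparent velocity dropping below `cv_min` only near the core —
  the structure of a real stable spiral. `wave_speed = 0` gives a
  rigidly rotating pure phase rotor. Default geometry: 16 x 16
  electrodes at 8 mm (a ~120 mm ventricular slab); the 64-electrode
  variant uses 16 mm spacing. Spacing is a configuration knob.
- `make_multi_rotor_field()`: counter-rotating phase rotors tiled into
  quadrants; the phase discontinuities at tile borders play the role
  of the wavebreak lines between spiral domains and keep each rotor's
  cycles confined to its own domain.
- `make_focal_field()` / `make_target_wave_field()`: centrifugal
  activation, `LAT = dist(electrode, nearest source)/CV + beat offset`.
- `make_anatomical_reentry_field()`: angular phase around an obstacle
  polygon; electrodes inside the obstacle carry no LATs (scar).
- `add_lat_noise()`: per-LAT independent Gaussian noise, or a
  lognormal alternative shifted to zero mean and rescaled to the same
  standard deviation so the two are comparable. Positions and truth
  are untouched; results are reproducible given a seed.

What the fixtures do **not** emulate: rotor meander, wavebreak and
fibrillatory conduction, curvature- and restitution-dependent velocity,
fibrosis, true electrogram morphology (but see the electrogram module),
and 3D ventricular anatomy. Passing tests therefore demonstrate
correctness of the algorithms under stable, stationary sources — not
clinical performance.

## From potentials to LATs

The electrogram module closes the loop from membrane potential to the
LATs everything else consumes. A unipolar electrogram at position `x`
is the midpoint-rule quadrature of `grad V . (r - x)/|r - x|^3` over
the tissue grid (central-difference gradients; a half-cell
minimum-distance guard keeps the electrode off the kernel
singularity). LATs are annotated at the steepest negative slope of the
electrogram, which coincides with the action-potential upstroke passing
beneath the electrode. Beats are separated by a blanking period of half
the estimated cycle length (estimated from the spacing of candidate
deflections). Synthetic potential fields advect a stereotyped
action-potential template (sigmoidal upstroke centred at the activation
time, plateau, sigmoidal repolarization) according to a known LAT map,
so annotation can be validated against exact truth.

## The noise-robustness benchmark

The study design: a periodic rotor recording is cut into 25 frames
(520 ms apart — two cycle lengths, so frame windows never overlap);
each frame receives independent per-LAT Gaussian noise at
`sigma = 0..30 ms`; DG mapping and phase mapping run on every noisy
replicate; each run is classified with a 1 cm correctness radius:

- **correct** — detections exist and all lie within 1 cm of the true
  core (a false core is a detection *outside* the radius);
- **error 1** — false core(s) in addition to the correct core;
- **error 2** — only false cores; **error 3** — no detection.

Confidence intervals use the cluster-robust sandwich standard error
with frames as clusters (replicates within a frame share the same
noiseless LATs and are correlated):
`SE^2 = G/(G-1) * sum_f (S_f - n_f p)^2 / N^2`, CI `p +/- 1.96 SE`.

The default desk-scale design is 25 frames x 40 replicates per noise
level (1,000 runs per method and sigma; the full-scale design of 25 x
1,000 is a flag away), with the rotor cycle length set to 260 ms —
chosen because the 520 ms frame separation is two such cycles and the
human-ventricular ionic model that motivates the fixture rotates at
about that period. The specificity study runs DG mapping on noisy
point-stimulation (target-wave) fields over the full sigma range: the
single-window graph is acyclic by construction and merged edges
originate only from nodes that have not re-fired, so on centrifugal
activation no directed cycle can arise and specificity is structural.

`scripts/acceptance.R` recomputes the headline accuracies of this
benchmark from scratch at the reduced design.

### What the desk-scale benchmark can and cannot show

The benchmark's qualitative claims are reproduced structurally: DG
accuracy is perfect without noise and at sigma = 5 ms, declines
monotonically with noise, never falls below phase mapping at the
benchmark noise levels, and specificity is exact. The *absolute*
accuracies depend on quantities the analytic fixture fixes by
assumption (rotor model, cycle length, electrode spacing): a DG edge
over distance `d` tolerates LAT-difference perturbations within a
window 4.5`d` ms wide, so per-edge survival at high sigma is governed
by `spacing/sigma`, while phase-mapping noise sensitivity is governed
by `sigma/CL` and the detector's ring footprint relative to the 1 cm
radius. No single geometry matches all of the published operating
points simultaneously, so mid-range accuracies should be read as
properties of this fixture, not as reproductions of the published
percentages.

## Numerical and degenerate-input choices

- Strict velocity inequalities; boundary-speed edges excluded.
- `delta_t = 0` merges to the single-window graph; `delta_t >= CL/2`
  warns.
- Cocircular Delaunay degeneracies follow the triangulator's
  tie-break; edge sets are canonicalized as sorted id pairs.
- Scar/no-signal electrodes (no LATs) are simply absent from the
  network; nothing is interpolated.
- Empty fields error; empty graphs and cycle-free networks are valid
  results.
- Sub-seeds for replicate `r` of frame `f` derive deterministically
  from the master seed, so any cell of the design can be reproduced in
  isolation.

## Limitations

Meandering or intermittent sources violate the stable-cycle assumption
(a full rotation must be recorded). Electrode clouds that are not
roughly 2-manifold need a neighbor relation supplied externally.
Phase-mapping absolute accuracy depends on grid resolution relative to
the 1 cm correctness radius, as analyzed above. Clinical export
parsing is out of scope: the CSV dialect documented in
`read_lat_table()` is the interchange format.
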