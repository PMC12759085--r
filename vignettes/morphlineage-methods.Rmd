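---
title: "Methods and design notes for morphlineage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for morphlineage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphlineage)
```

morphlineage implements four quantitative procedures used to characterize
self-organizing developmental systems — explants, embryoids, regenerating
tissues — that are profiled both by time-series single-cell RNA-seq and by
3D time-lapse cell tracking. This vignette explains each model, its
assumptions and tunable parameters, the synthetic study conditions the
package tests itself against, and the design choices made where the
procedures are conventionally underspecified.

## 1. KNN lineage coupling

### Model

Let two adjacent developmental stages share a low-dimensional embedding
(for instance, a joint batch-corrected PCA of the two samples). For each
later-stage cell, `assign_source_states()` finds its $k$ nearest
earlier-stage cells by Euclidean distance and assigns the modal cluster
among them as the cell's *source state* — the population it most likely
developed from. Cluster-level transition fractions, and a graph retaining
fractions strictly above a threshold $\tau$, follow in
`build_lineage_graph()`; `chain_timepoints()` unions the per-pair graphs
over a whole series.

The method assumes that (i) transcriptional change between adjacent stages
is small relative to between-cluster distances, so that a cell's nearest
earlier neighbors are its plausible ancestors, and (ii) the embedding
shared by the pair is free of stage-specific batch distortion (it consumes
whatever integrated embedding the user provides and deliberately does not
compute one).

### Parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `k` | 10 | cells | neighborhood large enough to vote stably, small enough to stay local |
| `threshold` | 0.20 | fraction | a later cluster keeps an ancestor only when more than 20% of its cells trace to it |

### Numerical conventions

* **Strict threshold.** "More than 20%" is implemented as $f > \tau$: a
  fraction of exactly 0.20 is *not* retained. All candidate fractions stay
  in the edge table for audit.
* **Frequency ties.** When two or more clusters are equally frequent among
  the $k$ neighbors, the cluster of the single nearest neighbor wins and
  the assignment is flagged `tie_broken`. The flag is honest: with $k=10$
  and few clusters, ties are common.
* **Distance ties.** Exact ties at the $k$-th neighbor are resolved by
  ascending cell-id order. With continuous embeddings these are measure-zero;
  the rule exists so that results are bit-reproducible on degenerate input.
* **Denominator.** Every later cell receives an assignment, so the fraction
  denominator is the full later-cluster size; there is no missingness term.
* **`k` larger than the earlier stage** falls back to using all earlier
  cells — "k nearest" semantics on degenerate input.
* The KNN search is a dense vectorised distance computation; at the method's
  natural scale (hundreds to a few thousand cells per stage) this is both
  the simplest and an entirely adequate approach, and it is verified against
  a naive $O(n^2)$ loop in the test suite.

## 2. Synthetic time-series generator

`simulate_timepoint_series()` emulates the input the lineage method
consumes: per-stage clusters as isotropic Gaussian blobs in an embedding,
with a known row-stochastic transition matrix $P$ (rows = later clusters,
columns = earlier clusters) describing what fraction of each later
cluster's cells descends from each earlier cluster.

Two design points deserve explanation:

* **Exact parent counts.** Parent populations are apportioned by
  largest-remainder rounding of $m \cdot P_{c'\cdot}$ ($m$ = cells per
  cluster) rather than i.i.d. draws, so the realized ground-truth fractions
  equal the matrix entries exactly whenever $mP$ is integral. This makes
  recovery tests crisp: the default conditions (100 cells/cluster, entries
  in steps of 0.1) admit no sampling slack.
* **Pair-local embeddings.** Each adjacent pair gets its own embedding
  space: the earlier stage's clusters sit at fresh well-separated centers
  (adjacent centers `cluster_separation` apart on a circle) and each later
  cell is drawn around the center of its assigned parent cluster with
  standard deviation `cluster_sd`. This mirrors pipelines that integrate
  adjacent stages pair by pair, and it is also a geometric necessity: in a
  single global embedding, any earlier cluster feeding two later clusters
  makes those two later clusters co-locate, so at the *next* stage the
  modal-neighbor vote would mix them and no generator could plant an
  arbitrary transition matrix recoverably. `chain_timepoints()` therefore
  accepts either a pair list (the generator's output) or a plain ordered
  slice list sharing one embedding (the user-data case).

The default conditions are 6 stages, 4 clusters of 100 cells,
`cluster_separation = 10` and `cluster_sd = 1` (separation 10× the blob
width), and a default transition matrix mixing merging, branching, a
terminal self-renewing population, and two entries at exactly 0.20 that
exercise the strict threshold. What these simulations do **not** emulate:
continuous differentiation trajectories (blobs are unimodal), embedding
distortion from imperfect integration, doublets, or cluster-size imbalance.
Passing recovery tests therefore shows the algorithm is implemented
correctly, not that $k = 10$ is optimal for any particular dataset.

## 3. Track decomposition

### Model

Tracked cells in an elongating tissue superimpose two motions: bulk tissue
elongation and their own migration. Anchor cells — an outer epithelial
layer joined by tight junctions that does not migrate — report the former.
With $\ge 3$ anchor tracks, the elongation trajectory is the per-frame
anchor centroid $\mathrm{ET}(t)$, and each cell's migration trajectory is

$$\mathrm{MT}(t) = \mathrm{OT}(t) - \left(\mathrm{ET}(t) -
\mathrm{ET}(t_0)\right),$$

with $t_0$ the first frame shared by the track and ET.

* **Offset convention.** Subtracting the ET *displacement* rather than the
  absolute ET anchors each migration trajectory at the cell's own observed
  starting position and makes the identity
  $\mathrm{OT} \equiv \mathrm{MT} + \Delta\mathrm{ET}$ exact; subtracting
  absolute ET would differ only by a constant per track, which matters for
  plotting but not for displacement statistics. The convention is recorded
  in the decomposition's attributes.
* **Gaps.** Trackers bridge short detection gaps; `resample_gaps()` fills
  gaps of up to `max_gap = 3` frames by linear interpolation (flagged) and
  splits tracks at longer gaps. Anchor tracks are gap-filled before the
  centroid since ET needs every anchor at every frame.
* **Directions.** `movement_directions()` projects displacements over a
  frame window onto a 2D plane, converts to angles measured
  counter-clockwise from the plane's first axis in $[0°, 360°)$, and bins
  them into 16 equal sectors by default (standard rose-plot granularity).
  The default plane is the top-two-principal-component plane of anchor
  displacements — the plane in which elongation unfolds — overridable to a
  literal axis pair (`"xy"`) or any 3×2 basis. Zero-length projections
  carry no angle; they are tallied separately so counts always conserve.
* **Rotation radius.** Circling migration is quantified by projecting the
  migration positions onto their principal plane and fitting a circle with
  the Kasa algebraic least-squares method — linear, deterministic, exact on
  noiseless circles, and adequate at the noise levels of positional
  tracking data.
* **Units.** Coordinates are treated as micrometres and frames as 3-minute
  intervals (the default `frame_interval` of the track simulator); both are
  conventions, not enforced — a 20-frame window spans about an hour.

### Synthetic tracks

`simulate_explant_tracks()` plants the decomposition's ground truth:
anchors follow `start + t · elongation_velocity + noise`; deep cells add a
circle of `rotation_radius` (default 10 μm, period 20 frames ≈ 1 h) in the
plane orthogonal to the elongation axis — mimicking the local rotational
movements of posterior progenitors relative to the elongation direction —
with random phase per cell. Isotropic Gaussian positional noise
(`noise_sd`, default 0.5 μm) is the simplest one-parameter model of
tracking jitter; ambient noise of real tracking data is not calibrated to
any particular instrument, so `noise_sd` is a free parameter. Not
emulated: cell division, track swaps, drift-field curvature, or
anchor-layer deformation.

## 4. Neighbor dynamics

Neighbors are cells within `radius = 15` μm, *inclusive* of the boundary —
one to two cell diameters, read as "within a 15 μm radius". Neighbor sets
are recomputed fresh at each timepoint from the cells present in that
frame; a cell absent at the later timepoint simply cannot be shared. The
retention rate of a cell present at both timepoints is
$|N_{t_1} \cap N_{t_2}| / |N_{t_1}|$. Cells with no initial neighbor have
an undefined rate: they are excluded from the table (not assigned 0) and
tallied in an attribute, so downstream means are not biased by a division
convention.

Rates grouped by interval length (e.g. frames 1–5 vs 1–10 vs 1–20 vs 1–44)
are compared with a one-way ANOVA; pairwise comparisons use Tukey HSD,
the standard post-hoc family when adjusted pairwise p-values accompany an
omnibus ANOVA. Under Brownian (purely dispersive) motion the mean rate
decreases with interval length — the package's test suite checks this
qualitative signature across seeds; collective motion keeps it near 1.

## 5. Pseudo-bulk similarity

Cluster profiles are per-cluster **means** of normalized expression —
chosen over the sum because it is invariant to cluster size (sum is
offered as an option); the scale convention is whatever normalization the
input matrices carry, recorded by the caller. Similarity is the Pearson
correlation over a shared marker-gene set: markers are an *input* (their
discovery by differential expression belongs to general-purpose toolkits),
the union of per-cluster marker lists intersected with both gene
universes, requiring at least 3 shared genes. Cross-dataset gene ids are
harmonized only through an explicit user-supplied mapping table — implicit
orthology guessing is a correctness hazard. Zero-variance profiles yield
an undefined (`NA`) correlation rather than 0, and `best_match()` excludes
them from the argmax; exact ties go to the first reference in column order
and are flagged.

`simulate_expression_pair()` plants disjoint marker blocks (effect 5 above
baseline 1, Gaussian noise clamped at zero) shared by a query and a
reference dataset with identity correspondence. It does not emulate count
overdispersion, dropout, or partially overlapping marker programs.

## 6. Pipeline and reproducibility

`run_pipeline()` drives all stages from one config (YAML or list) with a
single seed; without external inputs it runs end-to-end on the simulators,
which makes determinism checkable: two runs with the same config and seed
produce byte-identical analytic outputs (the manifest records md5 sums,
config, versions and timings, and is written atomically). Derived seeds
for the three simulators are small fixed offsets of the run seed.

## Problem sizes and known limitations

The test suite and the acceptance script run at the package's default
study conditions: 20-seed batches of 6-stage series (4 × 100 cells per
stage), tracks of 3 anchors + 6–10 deep cells over 60 frames, Brownian
batches of 50 cells × 30 frames, and 200-cell neighbor frames — sizes at
which the exhaustive oracles used for verification remain exact and fast.

Limitations worth knowing:

* Lineage coupling is only as good as the shared embedding; strong batch
  distortion between stages biases source assignment systematically, and
  the package deliberately has no opinion on how the embedding is made.
* The anchor-centroid ET estimates translation only; if the tissue rotates
  or shears, that motion leaks into every MT. Three anchors are the
  minimum, more are better.
* The neighbor rate is identity-based; it does not distinguish a neighbor
  that left the radius from one whose track ended.
* ANOVA on retention rates treats cells as independent observations, as is
  conventional for this analysis; spatial correlation between nearby cells
  is not modeled.
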