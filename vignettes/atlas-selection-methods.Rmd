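---
title: "Graph-based atlas selection and label fusion: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-based atlas selection and label fusion: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atlasfuse)
```

## The problem

Multi-atlas segmentation transfers expert label maps from a set of
atlases (labelled example scans) to a new subject scan through deformable
registration, then fuses the propagated candidate segmentations into a
consensus. Using many atlases averages out labelling and registration
errors, but it also averages out genuine minority anatomy: a subject whose
anatomy matches only a few atlases is pulled toward the population
majority. `atlasfuse` implements an atlas-selection scheme that addresses
this by modelling the atlas population as a directed cost graph, clustering
atlases along their shortest paths to the subject, and letting every
cluster contribute exactly one exemplar (its "neighboring template") to a
weighted majority vote.

## The cost graph

All atlases are pairwise co-registered with each other and registered to
the subject (ordered pairs: the graph is directed, and the subject needs no
outgoing edges because every path of interest terminates there). The edge
from image $i$ to image $j$ costs

$$e_{ij} = w_1\,\hat M_{ij} + w_2\,\hat H_{ij},
\qquad w_1 = 0.2,\ w_2 = 0.8,$$

with

* $M_{ij} = \frac1N \sum_m (i_m - j_m)^2$, the mean squared voxel-wise
  intensity difference between the target $i$... more precisely between the
  target image and the source image *after* warping it onto the target with
  the $i \to j$ field (intensity-squared units); and
* $H_{ij}$, the harmonic energy of that displacement field — the mean over
  voxels of the Frobenius norm of the Jacobian of the *displacement* (so
  the identity transform has energy exactly 0, and adding a constant
  translation changes nothing).

$M$ and $H$ are incommensurate (intensity² vs. dimensionless), so a fixed
weighted sum is only meaningful on a common scale: each term is min–max
normalised over all edges of the graph before weighting. This also places
every cost in $[0,1]$, which makes the later voting weight $1 - e$
well-defined. This normalisation is this package's choice; it is the
minimal assumption that makes the weighted combination and the voting
weight formula consistent.

Default weights put most of the decision on the shape term. That matters in
practice: the better the registration, the less residual intensity
difference survives warping, so with a very good registration $M$ measures
appearance differences (tissue contrast, calibration) rather than shape.
The package assumes intensity-calibrated, bias-corrected, skull-stripped,
co-aligned inputs — those corrections belong upstream.

## Selection: shortest-path clustering

Floyd–Warshall computes all-pairs shortest paths over the graph (path cost
= sum of edge costs; the aggregation is a design choice — additive is the
standard shortest-path semantics and penalises long chains). Each atlas's
shortest path to the subject is reconstructed; two atlases are clustered
together when their paths share at least one atlas vertex (subject
excluded), closed transitively by union–find. Atlases whose shortest route
is the direct edge and who appear on nobody else's path form singleton
clusters. "On the same shortest path" is ambiguous for partially
overlapping paths; shared-vertex closure is the weakest rule consistent
with per-cluster exemplar selection.

Per cluster, the exemplar is the member with the smallest *shortest-path*
cost to the subject (the clustering itself is path-based, so "closest" is
read the same way), with exact ties broken by the smallest node index. Its
voting weight, however, is $1 -$ the *direct* edge cost from the exemplar
to the subject, the quantity the fusion rule names explicitly. Because edge
costs depend on the subject, clustering is recomputed per subject; atlases
cannot be pre-clustered.

## Fusion

Each exemplar's label map is warped to the subject grid with the
exemplar-to-subject field using nearest-neighbour interpolation (labels are
categorical; no new values may be invented). Per voxel, label $L$ scores
the sum of the weights of the templates voting $L$; the highest score wins.
Two deliberate conventions: background (label 0) votes like any other label
— otherwise foreground bleeds into regions where most templates see
background — and ties go to the smallest label value, for determinism.
Weights are global per template; no local (per-voxel) weighting is
implemented.

## Registration backends

Registration is a contract, not a contribution: `register()` returns a
dense pull-back displacement field $u$ on the fixed grid such that
`warp(moving, u)` approximates the fixed image, with
$\mathrm{out}(x) = \mathrm{moving}(x + u(x))$, $u$ in voxel units, and
out-of-grid samples mapping to 0 (which is why phantoms place anatomy on a
zero background, like a skull-stripped scan). Three backends:

* **builtin** — a deterministic multi-resolution demons-style registrator:
  classic per-voxel force $-r\nabla I/(|\nabla I|^2 + r^2)$ on jointly
  rescaled intensities, Gaussian field regularisation ($\sigma = 1$ voxel)
  after every iteration, 3 pyramid levels with (30, 20, 10) iterations
  coarse-to-fine, best-iterate fallback so a non-converging run returns its
  best field rather than failing. Adequate for smooth phantom-scale
  deformations; it is not a topology-guaranteed diffeomorphic method, and
  production use on clinical data should inject fields from a dedicated
  tool via the **external** backend (`<moving>__to__<fixed>.nii.gz` files).
* **oracle** — returns a supplied known field; paired with the phantom
  generator, whose ground-truth deformations are known, it isolates
  selection/fusion behaviour from registration quality.

Both directions of a pair are computed independently; the graph is
directed, so mild asymmetry is tolerated rather than constrained away.

## The phantom generator

`make_phantom()` builds a base anatomy: four compact structures (one large
"thalamus-like" ellipsoid, one thin "ventricle-like" structure that
stresses the surface metrics, two smaller bodies) inside an outer head
ellipsoid, rendered with Gaussian partial-volume smoothing
($\sigma = 1.2$ voxels), an optional smooth multiplicative bias field
(random quadratic, default amplitude 0.02 — the residual left after the
upstream correction the pipeline assumes) and additive Gaussian noise
(default sd 0.02 on intensities spanning roughly 0.25–0.9). Everything is
deterministic given the seed.

`make_population()` organises members into modes that emulate anatomical
subtypes, and its design states explicitly what "controlled cluster
structure" means here:

* each mode draws a smooth random deformation axis $D_m$ with maximum
  displacement `between_mode_disp` (default 4 voxels on a $32^3$ grid);
* its members sit at evenly spaced severities along that axis — member $i$
  adds $(s_i - 1)D_m$ plus a small independent jitter field — with the
  member-specific displacement bounded by `within_mode_disp` (default 1
  voxel, i.e. a 4:1 between/within ratio) and only `jitter_frac = 0.1` of
  that budget spent on jitter;
* modes also differ in appearance: per-mode structure-intensity offsets
  (sd 0.08; background tissue at half that), plus per-member micro-offsets
  (sd 0.01);
* the subject is an independent noisy rendering of the undeformed base, so
  a member's distance to the subject grows with its severity;
* ground-truth base-to-member fields are returned, and
  `oracle_registrations()` turns them into exact pairwise fields by the
  fixed-point solve $U(x) = T_j(x) - T_i(x + U(x))$.

Two of these choices deserve their rationale. Severities are *evenly
spaced*, not i.i.d.: within a mode some members must be genuinely closer to
the subject than others, because with additive shortest-path costs a
two-hop route through a mode-mate only beats the direct edge when the
mode-mate's subject edge is cheaper by more than the within-mode edge
costs; i.i.d. isotropic member deformations make all members essentially
equidistant from the subject and every atlas degenerates into its own
singleton cluster. And modes differ in *appearance* as well as shape
because $M$ is computed after warping: under perfect (oracle) registration
a shape-only population leaves $M$ with no signal at all, and min–max
normalisation would amplify whatever noise remains into a fifth of every
edge cost. Real subtype populations differ in tissue appearance; the
generator makes that explicit and measurable.

What the phantoms do **not** emulate: MRI noise physics (no Rician model),
cortical folding, fine texture, partial-volume at clinical resolution, or
registration failure modes of real tools. Passing the phantom suite shows
the selection and fusion machinery does what it claims under known
conditions; it does not certify accuracy on clinical data.

## Evaluation metrics

Per structure: Dice similarity coefficient
$\mathrm{DSC} = 2|A \cap B|/(|A|+|B|) \times 100\%$ (both-empty pairs score
100 — perfect agreement on absence — and one-empty pairs 0); symmetric mean
absolute surface distance (MAD, mm); symmetric Hausdorff distance (mm, the
exact maximum, not a percentile variant). Surfaces are mask voxels with a
6-connected background neighbour (the outside of the grid counts as
background); distances run voxel-centre to voxel-centre through an exact
separable Euclidean distance transform that honours anisotropic spacing.
No sub-voxel meshing is attempted: at the 1 mm isotropic granularity these
metrics are usually reported with, voxel centres are the honest resolution.
Empty masks make the distance metrics undefined; they are reported as `NA`
with a warning rather than as an exception, so one missing structure does
not abort a batch evaluation.

## Numerical choices and degenerate inputs

* Interpolation: trilinear for intensities, nearest-neighbour (mandatory)
  for labels; out-of-grid samples are 0/background rather than clamped, to
  avoid smearing edge labels.
* Jacobians: central differences in the interior, one-sided at faces;
  single-slice fields are rejected as degenerate.
* Min–max normalisation maps an all-equal term matrix to 0 (such a term
  simply stops discriminating).
* Ties: smallest node index (exemplars), smallest label value (votes) —
  everywhere deterministic.
* An exemplar whose direct subject edge costs exactly 1 gets weight 0 and
  contributes nothing; this is logged as a warning instead of failing.
* The builtin registrator is seedless and deterministic; the whole
  pipeline is bit-reproducible given the config and seed.

## Problem sizes

The test suite and the acceptance script run on $32^3$ phantoms with 9
atlases (3 modes × 3 members), 100-graph shortest-path oracles on up to 7
nodes, 50 random vote stacks up to $8^3$, and 20 random $16^3$ mask pairs
for the metric oracles. These sizes were chosen so the full suite exercises
every pipeline stage end-to-end — including 81 pairwise builtin
registrations — in a few minutes on a single core, while remaining large
enough that surface metrics, partial-volume effects and cluster geometry
are non-trivial.

## Known limitations

* The builtin registrator is a stand-in: no topology guarantees, no
  cross-correlation metric, mean-squared-difference only.
* Global voting weights only; no STAPLE, joint fusion, or local weighting.
* All inputs must share one grid; resampling between geometries is out of
  scope (resample upstream).
* The phantom generator's appearance model is piecewise-constant with
  smooth corruption; it cannot stand in for validation on real scans.
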