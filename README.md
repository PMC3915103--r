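# atlasfuse

Multi-atlas segmentation for 3-D volumes (brain MRI and similar) with a
graph-based atlas selection step and weighted majority-vote label fusion.

## The problem

Segmenting subcortical structures by transferring expert labels from a
*single* atlas scan fails whenever the subject's anatomy deviates from that
atlas. Fusing labels from *many* atlases averages out labelling and
registration errors — but it also averages out genuine minority anatomy,
biasing results exactly for the atypical scans that matter most. The middle
ground implemented here: model the whole registered dataset as a directed
cost graph, cluster the atlases by their shortest paths to the subject, and
let every cluster contribute exactly one exemplar (its "neighboring
template") to the vote, so anatomical subgroups are each represented once
instead of being outvoted.

## The method

With all atlases pairwise co-registered and registered to the subject, the
edge from image *i* to image *j* costs

```
e_ij = w1 * M_ij + w2 * H_ij        (defaults w1 = 0.2, w2 = 0.8)
```

where `M_ij` is the mean squared voxel-wise intensity difference after
warping *i* onto *j* (Eq. form `M = 1/N * sum_m (i_m - j_m)^2`), `H_ij` is
the harmonic energy of the displacement field (mean Frobenius norm of the
displacement Jacobian), and both terms are min–max normalised over all
edges so the weighted sum and the voting weight `1 - e` are well defined.
Floyd–Warshall shortest paths cluster atlases that share path vertices en
route to the subject; per cluster the member with the smallest path cost is
selected, its voting weight is one minus its direct edge cost to the
subject, and the selected exemplars' labels are warped (nearest-neighbour)
onto the subject grid and fused per voxel by weighted majority, ties to the
smallest label. Evaluation reports Dice (%), symmetric mean absolute
surface distance (mm) and symmetric Hausdorff distance (mm) per structure.

Registration itself is pluggable (`builtin` demons-style stand-in,
`external` precomputed fields, `oracle` known fields for synthetic data);
the pipeline assumes bias-corrected, co-aligned, skull-stripped inputs.
A phantom generator produces labelled populations with known mode structure
and ground-truth deformations, so the whole pipeline is testable with no
clinical data.

## Worked example

```r
library(atlasfuse)

# a 9-atlas population: 3 anatomical modes x 3 members, 32^3 voxels,
# written in the directory layout the pipeline consumes
dir <- tempfile("pop")
paths <- simulate_population_dir(population_spec(seed = 3), dir)

res <- run_pipeline(paths$config)   # external backend, oracle fields
res$selection
#> <selection: 3 cluster(s)>
#>   {atlas01,atlas02,atlas03} -> exemplar atlas01 (weight 0.746)
#>   {atlas04,atlas05,atlas06} -> exemplar atlas04 (weight 0.546)
#>   {atlas07,atlas08,atlas09} -> exemplar atlas07 (weight 0.686)
res$metrics
#>   label dsc_percent     mad_mm hausdorff_mm note
#> 1     1    99.40688 0.02425167            1
#> 2     2    98.75519 0.02040816            1
#> 3     3    99.66102 0.01111111            1
#> 4     4    99.37888 0.01851852            1
#> 5    NA    99.30049 0.01857237            1 mean
```

The selection found the three planted modes (one cluster each) and picked
the member closest to the subject from every mode; each exemplar's weight
is one minus its direct edge cost to the subject. The metrics compare the
fused segmentation against the phantom's ground-truth labels: near-perfect
Dice and sub-voxel surface distances, as expected with oracle registration.
With the builtin registrator instead (`backend: builtin` in the config) the
same population fuses at ~87% mean Dice.

Artifacts land in the config's `output_dir`: pairwise fields, raw and
normalised cost matrices (CSV), the selection report (JSON, including
reconstructed shortest paths), the fused labels and a per-voxel confidence
map (NIfTI), and the metrics table (CSV). Re-runs reuse cached
registrations.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/atlasfuse.R simulate --out /tmp/pop --seed 3
Rscript inst/cli/atlasfuse.R run --config /tmp/pop/config.yaml
Rscript inst/cli/atlasfuse.R evaluate --auto fused.nii.gz --ref truth.nii.gz --out metrics.csv
```

## Layout

- `R/` — volumes & NIfTI I/O, registration backends, similarity terms,
  atlas graph & selection, fusion, metrics, phantom generator, pipeline
- `vignettes/atlas-selection-methods.Rmd` — the model, its assumptions,
  parameter defaults and design rationale
- `tests/testthat/` — unit, property and end-to-end acceptance tests
- `inst/cli/atlasfuse.R` — command-line entry point
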