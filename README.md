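# pcnaphase

Cell cycle phase discrimination from PCNA immunofluorescence images.

PCNA (proliferating cell nuclear antigen) is a DNA polymerase processivity
factor whose distribution inside the nucleus changes with cell cycle phase:
homogeneous in the G phases, many small scattered replication foci in early
S, foci at the nuclear periphery in mid S, and a few large central foci in
late S. `pcnaphase` assigns a phase to every nucleus in a single-time-point
fluorescence image — no live-cell time series needed — which makes
phase-resolved phenotype analysis possible with ordinary fixed-cell antibody
staining. It is aimed at bioimage analysts and cell biologists working with
confocal or widefield images of PCNA-labeled cells.

The pipeline:

1. **Segmentation** — minimum-cross-entropy (Li) thresholding: the
   threshold *t* minimizes
   `CE(t) = Σ_{g≤t} g·h(g)·log(g/μ₀) + Σ_{g>t} g·h(g)·log(g/μ₁)`,
   followed by connected-component labeling and size filtering.
2. **Cluster splitting** — touching nuclei are separated between concave
   contour points: split points are curvature maxima; chords must satisfy
   anti-parallel, non-intersection, convexity and size constraints; among
   admissible hypotheses with n = 2, 3, … parts the one minimizing
   `Σ_parts (1 − solidity) + λ · chord_length / perimeter` is accepted if it
   beats leaving the object unsplit. A distance-map watershed baseline is
   included for comparison.
3. **Features** — each nucleus is resampled to polar coordinates (radius on
   x, angle on y), which turns rotation into a cyclic shift; on top of that:
   basic histogram statistics + radial zone means, a 104-dimensional
   Haralick texture vector (13 GLCM statistics × 2 radius stripes × 2
   directions × 2 distances), a 64-bin intensity histogram, and a 64-bin
   histogram of intensity-surface principal curvatures.
4. **Classification** — z-score normalization, then an information-gain
   decision tree, a one-vs-all SVM with Hamming decoding, or multi-class
   AdaBoost over stumps; evaluated by seeded 10-fold cross-validation.
5. **Evaluation** — segmentation rates (correct / over- / under-segmented,
   which sum to 1 by definition) from point annotations, and per-class
   precision/recall with overall accuracy.

A synthetic scene generator (`generate_scene()`) renders all four PCNA
patterns, touching-cell clusters and confocal/widefield imaging with exact
ground truth, so the whole pipeline is testable without microscope data.

## Worked example

```r
library(pcnaphase)

# a synthetic confocal scene: 12 nuclei, half of them in touching pairs
sc <- generate_scene(scene_spec(n_nuclei = 12, cluster_fraction = 0.5,
                                rng_seed = 7))
sc
#> pcna_scene (confocal, seed 7): 448 x 448 px, 12 nuclei (6 clustered)

# segment, split clusters, and score against the exact ground truth
res <- segment_and_split(sc$image, pcna_config(presmooth_sigma = 1),
                         "geometric")
segmentation_rates(match_annotations(res$labels, sc$annotations))
#> segmentation: 12 nuclei | correct 1.000  over 0.000  under 0.000 (0 on background)

# per-nucleus feature vectors (6 basic stats + 8 zone means + 104 Haralick)
feats <- feature_table(sc$image$pixels, res$labels, "proposed")
dim(feats)
#> [1]  12 119

# phase classification on a 100-nucleus benchmark with known phases
bench <- phase_benchmark(25, "confocal", seed = 42)
tab <- benchmark_feature_table(bench, "proposed")
cross_validate(tab, bench$phases, k = 10, "decision_tree", seed = 42)
#> 10-fold cross-validation (decision_tree, seed 42): accuracy 0.890
#>          predicted
#> true       G EARLY_S MID_S LATE_S
#>   G       21       4     0      0
#>   EARLY_S  4      21     0      0
#>   MID_S    0       0    23      2
#>   LATE_S   0       0     1     24
```

All 12 nuclei are recovered (the three touching pairs are split correctly),
and the classifier separates the four phases at 89% pooled accuracy on this
small benchmark; the remaining confusion sits exactly where the biology puts
it, between G and early S, whose PCNA patterns are most alike. The full
400-nucleus benchmark (see below) is more precise.

A thin command-line front-end with `simulate`, `segment`, `split`,
`features`, `train`, `predict` and `evaluate` subcommands ships in
`inst/cli/pcna`.

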