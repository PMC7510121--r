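# beadmorph

Deep phenotyping of dendritic "beading" — bubble-like protrusions that form
along the dendrites of the *C. elegans* PVD neuron as it degenerates under
aging or acute cold-shock. Manual counting of beads in fluorescence images
is slow, biased, and discards almost everything an image contains. This
package implements the quantitative alternative: tiled instance
segmentation of beads, instance-level evaluation, a canonical 46-metric
morphological profile per image, and classifiers that predict an animal's
biological status (young / aged / cold-shocked) from that profile. A
synthetic fluorescence-scene simulator with exact ground truth makes every
stage of the pipeline testable without microscope data.

It is written for microscopists and computational biologists quantifying
neurodegeneration phenotypes in fluorescence projections, and for method
developers who need a harness (tiling, stitching, matching, metrics) around
any per-tile instance segmenter.

## The pipeline

1. **Tiling and stitching.** A 2048×2048 maximum-intensity projection is
   split into 9 overlapping 1024×1024 tiles (stride 512; symmetric mirror
   padding for non-conforming sizes). Any per-tile segmenter plugs in as a
   backend; predictions are stitched in raster order (top-left →
   bottom-right), keeping an instance only if its predicted foreground
   probability exceeds 0.7 and it overlaps no previously kept mask by more
   than 30% of its own area.
2. **Evaluation.** Predictions are matched one-to-one to ground truth by
   greedy IoU matching (IoU ≥ 0.3). With TP/FP/FN so defined,

   Precision = TP / (TP + FP),  Recall = TP / (TP + FN),

   and pixel-level accuracy is the per-bead Jaccard index |A ∩ B| / |A ∪ B|.
3. **Phenotypic profile.** Each image + mask set becomes a 46-slot feature
   vector `m01..m46`: bead count, total/mean/percentile bead areas, the
   fraction of beads under 100 px (`m16`), the mean pairwise inter-bead
   distance (`m17`) and its SEM (`m20`), the fractions of pairwise
   distances under 150/300 px (`m21`/`m22`), per-bead intensity statistics
   (`m32`, `m35`, `m37`, ...), and shape descriptors.
4. **Classification.** Subspace discriminant ensemble (majority vote over
   30 ridge-regularized LDA learners on random 23-dimensional feature
   subspaces), linear SVM, logistic regression, and KNN, evaluated by
   stratified 5-fold cross-validation with ROC/AUC; bidirectional stepwise
   logistic regression (AIC) identifies the discriminating metrics.

Backends shipped: a configurable noisy ground-truth **oracle** (controlled
false-negative/false-positive/boundary noise for validating the harness)
and a classical LoG **blob** baseline with an optional dendrite-proximity
filter. A Mask R-CNN-style CNN backend is supported through the same
per-tile contract; its training protocol is recorded as a configuration
schema (`cnn_backend_config()`), since network training happens on GPU
infrastructure outside this package.

## Worked example

```r
library(beadmorph)

profiles <- default_profiles()
scene <- generate_population(profiles$aged, 1, shape = c(512, 512), seed = 42)[[1]]
scene
#> <synthetic_scene> 81 beads (72 truth instances), 8 droplets, 512 x 512, seed 390758196

noise <- oracle_noise(drop_rate = 0.05, spurious_rate = 0.3,
                      score_mean = 0.9, score_sd = 0.05, seed = 42)
seg <- segment_image(scene$rendered, oracle_backend(scene$truth, noise),
                     tile = 256, stride = 128, backend_name = "oracle")
seg
#> <segmentation_result> 68 instances on 512 x 512 (backend: oracle)

score_matches(match_instances(seg, scene$truth, iou_min = 0.3))
#> <evaluation_scores> precision 1.000, recall 0.944, mean Jaccard 1.000 (TP 68 FP 0 FN 4)

round(feature_vector(bead_records(scene$rendered, seg))[
  c("m01", "m02", "m16", "m17", "m21", "m25", "m26")], 2)
#>     m01     m02     m16     m17     m21     m25     m26
#>   68.00 8055.00    0.32  197.75    0.35  115.00  327.00
```

The 81 placed beads merge into 72 disjoint ground-truth instances
(overlapping beads fuse); a 5% drop-rate oracle then recovers 68 of them
through the tiled stitcher — recall 0.944, no false positives (spurious
blobs and the 8 autofluorescent droplets are suppressed or fall below the
score threshold), and perfect per-bead masks (Jaccard 1). The profile of
the segmentation says this image has 68 beads covering 8055 px, 32% of
them under 100 px, with a mean inter-bead distance of 198 px. Per-metric
group comparisons use a Bonferroni-corrected significance level,
`bonferroni_alpha(0.05, 3)$alpha` = 0.016.

A full simulate → segment → evaluate → profile → classify run:

```r
cfg <- read_run_config(system.file("extdata", "demo_config.yaml",
                                   package = "beadmorph"))
manifest <- run_pipeline(cfg, "demo_run")
```

writes images, labeled masks + JSON sidecars, `features.csv`,
`evaluation.csv`, per-group `summary.csv`, a classifier `report.json`, and
a `manifest.json` with the config snapshot. A thin command-line wrapper
with `simulate` / `segment` / `evaluate` / `profile` / `summary` /
`classify` / `run-all` subcommands ships in `inst/cli/beadmorph.R`.

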