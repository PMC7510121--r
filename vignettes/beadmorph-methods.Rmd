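---
title: "Methods: quantifying dendritic beading with beadmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying dendritic beading with beadmorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The phenotype and the measurement problem

The PVD neuron of *C. elegans* is a multidendritic nociceptor whose
stereotyped, candelabra-shaped ("menorah") dendritic arbors degenerate with
age and after acute cold-shock. The degeneration manifests as *beading*:
bubble-like protrusions along the dendrites. Beads have roughly the same
fluorescence intensity as the dendrite itself and closely resemble
autofluorescent lipid droplets that overlap the arbor in maximum-intensity
projections, which is why plain intensity thresholding fails and why
counting by eye is slow and biased. beadmorph implements the downstream
quantitative machinery around any per-tile instance segmenter: tiling and
stitching, instance-level evaluation, a fixed 46-metric profile, and
status classification, together with a simulator that provides exact
ground truth for all of it.

## Tiled segmentation and the merge rules

Large projections (nominally 2048×2048) are segmented per tile. The grid
uses tiles of 1024 px and a stride of 512 px — the only regular grid that
produces exactly 9 overlapping tiles on a 2048-px frame with no padding.
For other sizes, the per-axis position count is
`n = max(1, ceiling((dim - tile)/stride) + 1)` and the frame is padded to
`stride*(n-1) + tile` by half-sample mirror reflection, split evenly with
the extra pixel to the bottom/right.

Stitching visits tiles in raster order and, within a tile, candidates in
descending score (ties by ascending label, for determinism). Two strict
boundary rules are applied exactly as worded in the field's convention:

* a candidate is kept only if its foreground probability is **greater
  than 0.7** (so a score of exactly 0.7 is dropped);
* a kept candidate must not overlap any previously kept mask **by more
  than 30%** (so exactly 30% survives), where the denominator is the
  *candidate's own* area — the rule suppresses a *newly* predicted
  duplicate of something already kept.

Duplicates are suppressed, never averaged: a bead seen by two overlapping
tiles keeps its first (raster-order) mask. Masks are mapped back to source
coordinates with the padding removed; a mask empty after clipping is
dropped.

## Evaluation

Matching is one-to-one greedy on IoU, accepting pairs with IoU ≥ 0.3.
No universal IoU threshold exists for "correctly identified"; 0.3 is
standard instance-detection practice and sits safely below the per-bead
Jaccard (≈ 0.7) that a good segmenter achieves, so the threshold does not
decide matches that a human would dispute. Ties in the greedy sweep break
by ascending (prediction label, truth label). On every fixture with ≤ 6
instances the greedy matching is verified in the test suite against an
exhaustive enumeration of injective assignments. Precision and recall
follow from the matched counts; with no predictions, precision is flagged
undefined (`NA`) rather than forced to a number. "True negatives" —
correctly ignored droplets — are only measurable on synthetic scenes,
where they are reported as a droplet-rejection rate (fraction of placed
droplets no prediction centroid lands in).

## The 46-metric profile

The profile is a fixed 46-slot vector per image. The slots named in the
field's numbering are pinned: `m16` (fraction of beads under 100 px),
`m17` (mean pairwise inter-bead distance), `m20` (its SEM), `m21`/`m22`
(fractions of pairwise distances under 150/300 px), `m25`/`m26`
(median/max bead area), `m32` (median bead intensity), `m35` (sd of mean
bead intensity), `m37` (90th-percentile bead intensity). The remaining
slots are filled with the same statistic families (count, area histogram
and percentiles, nearest-neighbor and pairwise distance statistics,
intensity percentiles, eccentricity/solidity, coefficients of variation);
this completion is this package's documented reconstruction, chosen so
that every slot is a plain, reproducible statistic.

Conventions pinned for reproducibility: "bead intensity" means the
distribution over beads of per-bead *mean* intensity, measured on the raw
(pre-normalization) image with no background subtraction; percentiles use
linear interpolation between order statistics (`quantile` type 7);
distances are Euclidean between mask centroids, in pixels (no micron
calibration is assumed anywhere); the 100/150/300-px thresholds are fixed
constants of the profile. Metrics whose statistic needs more beads than
the image has (any distance metric below 2 beads, any sd/SEM below 2
observations) are `NA` and flagged, not zero-filled; downstream models
impute them with training-set medians learned on training folds only.
Group summaries report mean ± SEM with undefined entries excluded, and
multiple-feature comparisons use a Bonferroni-corrected level
(`0.05 / 3` is displayed as `0.016` under the truncate-to-3-decimals
printing convention; the full-precision value is also returned).

## The simulator

The simulator's job is to emulate the features of PVD projections that the
pipeline's correctness depends on, with exact ground truth.

**Geometry.** One order-1 primary dendrite spans the frame horizontally;
order-2 stems branch from it alternately dorsally and ventrally (as PVD
menorahs reach toward both body-wall margins), each carrying two
horizontal order-3 arms ending in order-4 terminals that continue away
from the primary. Distal branches therefore occupy the vertical extremes
of the frame. All geometry is in pixels by design; frames of 512×512 with
8 menorahs are the default study size.

**Rendering.** Dendrites are soft tubes (Gaussian cross-section, width
1.5 px, amplitude 100), beads and droplets anti-aliased discs of their
radius (amplitude up to 400); the scene is blurred with a Gaussian PSF
(σ = 1.5 px), then Poisson noise on signal plus background (level 40) and
Gaussian read noise (σ = 4) are added. Ground-truth masks are the
noiseless per-bead profile thresholded at half its peak — a
parameter-free, reproducible definition whose area matches the nominal
disc area (π r²) within a few percent. Beads whose masks overlap are
merged into one truth instance, because instance masks must be disjoint
for unambiguous matching; droplets never enter the truth.

**Condition profiles.** The shipped defaults encode the qualitative
contrasts of the biology without claiming real-data values: young =
30 ± 10 beads of 150 ± 40 px, uniform over branch orders; aged = 100 ± 25
beads of 120 ± 35 px, uniform order weights; cold-shock = 70 ± 20 beads of
150 ± 40 px with order weights (0.05, 0.15, 0.40, 0.40) — cold-induced
protrusions form preferentially in distal order-3/4 branches, which in
this geometry sit at the dorsal/ventral extremes, so distally weighted
placement raises the mean inter-bead distance relative to uniform
placement at matched count.

The aged profile additionally sets a *regional nucleation* mechanism
(attraction probability 0.8 toward within 250 px of the first-placed
bead, with a 13-px center-spacing rule). This is a deliberate design
choice: the mean of all pairwise distances is invariant to how *many*
points are drawn from a fixed placement distribution, so a higher bead
count alone cannot reproduce the observed decrease of inter-bead distance
with age — some form of spatial concentration must be part of the
generative story. We model degeneration as nucleating around a focal
region and spreading locally; the spacing rule keeps clustered beads
distinct instances rather than letting them fuse (fusion would delete
exactly the short distances the mechanism is meant to create). Droplet
confounders (default 8 per scene) draw radii from the bead distribution
and are placed at least 10 px from every dendrite segment.

**Determinism.** Every stage draws from a seed derived deterministically
from a master seed (`derive_seed`), so populations, renders, oracle
corruption, folds and reports are all bit-reproducible.

## Segmentation backends

The **oracle** backend turns ground truth into controlled predictions:
each truth instance is dropped with probability `drop_rate`, survivors are
dilated/eroded by `dilate_px`, Poisson-many spurious discs are added at
least 5 px from all truth pixels (so FP/FN accounting is unambiguous), and
scores come from a clipped normal. Two design points matter. First, drop
decisions are made per truth *instance* (a hash of the noise seed and the
label), not per tile, so a bead visible in two overlapping tiles is
dropped consistently and the population recall converges to
`1 - drop_rate`. Second, the oracle emits only truth instances *fully
contained* in a tile: a clipped boundary fragment emitted first in raster
order can otherwise survive the 30% overlap rule alongside the complete
mask from the next tile, so emitting fragments would break the exactness
the zero-noise oracle is supposed to provide. With stride < tile, every
bead that fits in some tile is emitted by at least one.

The **blob** baseline is the classical approach the deep-learning route is
measured against: multi-scale difference-of-Gaussian detection, local
maxima above a response threshold, half-peak region growing, area
filtering, and optionally a dendrite-proximity filter (droplets sit off
the dendrite). When no dendrite mask is supplied, one is estimated by a
robust background threshold (median + 4·MAD) followed by selection of
elongated connected components — the arbor spans the frame, blobs do not.
The baseline's imperfect droplet rejection on synthetic scenes is the
expected behavior of intensity-based methods on this phenotype, not a
defect to be tuned away. A CNN backend is a configuration schema plus the
per-tile contract (`segment_tile`-style closures); training happens
outside this package.

## Classification

All 46 metrics enter every model. Features are standardized with
training-fold mean/sd for every family (uniformity makes the subspace
draws comparable), and undefined entries are imputed with training-fold
medians. The subspace discriminant ensemble follows the common convention
where the reference implementations leave hyperparameters unstated: B = 30
learners, each a linear discriminant on a random subspace of
d = ⌈46/2⌉ = 23 metrics, majority vote; a learner whose pooled
within-class covariance is singular in its subspace is ridge-regularized
(shrinkage toward a scaled identity, escalated until invertible), never
dropped. With B = 1 and the full feature space the ensemble reduces to
plain LDA, which the test suite verifies against an independent LDA
implementation. SVM is linear with C = 1; KNN uses k = 5 and Euclidean
distance; logistic regression drops aliased coefficients from the score.
Cross-validation is stratified 5-fold (per-class round-robin over a seeded
shuffle, so fold sizes differ by at most one per class); ROC curves come
from a threshold sweep and AUC from the trapezoidal rule, which equals the
Mann–Whitney statistic — asserted exactly in the tests. Stepwise selection
is bidirectional from the intercept-only logistic model, minimizing AIC —
a threshold-free, reproducible criterion — and reports metrics in entry
order; an empty selection is a valid result, not an error.

The binary tasks mirror the study designs this tooling serves: young
(≤ day 4) vs aged, cold-shocked vs control, cold-shocked vs aged, anterior
vs posterior.

## Numerical and interface conventions

* Coordinates are 1-based `(row, col)` with origin top-left, matching R's
  matrix convention; all distances in pixels.
* Contrast normalization is an imadjust-style quantile stretch with 1%
  saturation at each end by default (the conventional default where the
  exact fractions are unstated) mapping to `[0, 1]`; a constant image is
  returned unchanged.
* Masks serialize as a 16-bit labeled TIFF plus a JSON sidecar of scores;
  instances whose pixels collide in the label plane (overlaps up to 30%
  are legal after merging) carry run-length records in the sidecar, so the
  round trip is lossless and the files stay human-inspectable.
* All ties anywhere (stitching order, greedy matching, fold assignment)
  break deterministically, and every random draw descends from one master
  seed.

## Problem sizes and what the tests show

The test suite and the acceptance script exercise the pipeline at sizes
chosen to keep a full run in minutes on one CPU: 512×512 scenes with
256/128 tiling (the same 3×3 overlapping geometry as 2048 with 1024/512),
populations of 30 scenes per condition for directional contrasts, 60 per
class for classification, and ≥ 1000 beads for rate calibrations; the
2048-frame tile bookkeeping is exercised arithmetically. Monte-Carlo
checks use one-sided Wilcoxon tests at p < 0.01 or 3-SD binomial bands.

Passing these tests shows that the harness is correct — the merge rules,
matching, metrics and models do what they claim on scenes whose ground
truth is known exactly. It does not certify performance on real
micrographs: the simulator does not emulate three-dimensional structure,
uneven illumination, body autofluorescence beyond discrete droplets,
dendrite disorganization phenotypes, or the failure modes of a trained
CNN, and the condition profiles encode the direction and rough magnitude
of the biology, not measured effect sizes. Real-data accuracy claims
require real annotated data and live outside this package's scope.

## Known limitations

* The 46-slot completion beyond the pinned metrics is a reconstruction;
  analyses that depend on an unpinned slot's exact definition should cite
  this vignette's table rather than assume a universal convention.
* Whether inter-bead distances should be centroid- or boundary-based is
  convention; centroids are used.
* The blob baseline's dendrite-mask estimator assumes a single connected,
  frame-spanning arbor; heavily fragmented dendrites will defeat it.
* Classification assumes two classes; multi-class status prediction is out
  of scope.
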