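---
title: "Curating camera-trap datasets: similarity, splits, and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating camera-trap datasets: similarity, splits, and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trapcurate)
```

## The problem

Camera traps are motion-triggered, so one animal visit produces a burst of
near-identical frames. Datasets built from raw trap archives therefore
carry two linked pathologies: heavy redundancy (which wastes annotation
effort and biases training), and low intra-dataset variability (which makes
detectors fail at camera sites unseen during training). Web-sourced imagery
is far more varied but arrives with exact and near duplicates of its own,
and detectors trained on it still benefit from a small, well-chosen
*infusion* of real camera-trap frames before deployment.

`trapcurate` implements the curation and evaluation side of this workflow.
Training a detector is out of scope by design — the package prepares a
detector's inputs and scores its outputs.

## Structural similarity

Two grayscale images are compared window-by-window; per window

$$\mathrm{SSIM}(a,b) =
  \frac{(2\mu_a\mu_b + C_1)\,(2\sigma_{ab} + C_2)}
       {(\mu_a^2 + \mu_b^2 + C_1)\,(\sigma_a^2 + \sigma_b^2 + C_2)},$$

with the mean over all windows reported. The score lies in $[-1, 1]$;
identical images score exactly 1.

The published procedure fixes the two decision thresholds — delete above
0.8, cluster at or above 0.4 — but not the SSIM internals, so those are
package decisions, chosen from the standard SSIM literature and all
configurable through `ssim_params()`:

| parameter | default | why |
|---|---|---|
| $k_1, k_2$ | 0.01, 0.03 | canonical stabilization constants; $C_i = (k_i L)^2$ |
| dynamic range $L$ | 255 | 8-bit imagery |
| window | uniform 7×7, interior positions only | smallest common window; unbiased ($n-1$) covariance |
| comparison size | 256×256, bilinear | differently sized sources must be commensurable |
| grayscale | luminance conversion on decode | SSIM is defined on a single channel |

Threshold comparisons are deliberately asymmetric: deduplication uses a
strict `> 0.8` ("above"), clustering an inclusive `>= 0.4`; both are
arguments.

Two further decisions deserve emphasis because alternatives exist:

- **Clustering rule.** Only the pairwise threshold is specified upstream;
  this package uses single linkage (connected components of the thresholded
  similarity graph). A star comparison of one test image against all others
  generalizes naturally to transitive grouping, and a chain of
  pairwise-similar frames is one capture event even if its endpoints differ
  more. Complete linkage would split such chains; users wanting that
  behavior can post-process the similarity matrix themselves.
- **Deletion rule.** Read literally, "delete all images scoring above 0.8"
  would delete *both* members of each duplicate pair — a pool of exact
  duplicates would vanish entirely. `dedup()` instead keeps one
  seeded-random representative per duplicate component and removes the
  rest, which is the evident intent.

## Split and infusion arithmetic

All counts use round-half-up (`round_half_up()`, i.e. `floor(x + 0.5)` with
a `1e-9` epsilon so that decimal halves like $0.9 \times 1665 = 1498.5$
round up despite binary float representation). The published tables are
consistent with this rule in 15 of 16 train/validation rows; the one
exception (the rhino 15% infusion training count) sits on an exact .5
boundary that the source resolves inconsistently, and is therefore excluded
from the package's own regression fixtures.

- `base_split()` shuffles the positive pool with a seeded RNG and takes
  `round_half_up(0.9 n)` for training (the train count is clamped to
  $[1, n-1]$ so degenerate pools still yield both sets; the clamp cannot
  trigger at 0.9 for $n \ge 10$... with the exception of pools so small
  that a 10% share would vanish, which is precisely when you want it).
- `build_infusion_split()` selects $k = \mathrm{round\_half\_up}(p\,N)$
  camera-trap images and pools them with the base images **before**
  splitting — the published validation counts equal the 90/10 share of the
  combined pool, confirming infusion enters both sets rather than being
  appended to training.
- Infusion selection with a `cluster_set` visits clusters in ascending size
  order, drawing one seeded-random unused frame per cluster and cycling
  until $k$ frames are chosen. The upstream description ("SSIM sorted",
  one random frame per cluster) does not state the cluster ordering;
  ascending size is this package's default because it reaches rare,
  visually distinct events first, maximizing variability per added image.
  Omitting `clusters` gives plain seeded-random selection.
- `supplement_negatives()` appends negatives (images with no target object)
  *after* the split arithmetic — published table counts refer to positives
  only — and never assigns a negative to more than one subset. The
  conventional volumes are 800 training and 200 test negatives.
- Test sets are declared separately (out-of-sample by construction); the
  planner refuses overlap between negatives and existing split ids, and
  stratification (by site, time of day) is intentionally absent because the
  upstream split was a plain random shuffle.

Seeding: every randomized operation takes an explicit integer seed, runs
under a saved-and-restored RNG state, and `derive_seed(seed, stage)` maps a
global seed to per-stage seeds (MINSTD step plus a string hash, exact in
doubles, result < 2³¹) so pipeline stages reproduce identically when run
standalone.

## Evaluation

Boxes are 0-based half-open internally (`[xmin, xmax) × [ymin, ymax)`),
which makes IoU arithmetic exact and edge-adjacent boxes disjoint; PASCAL
VOC's 1-based inclusive convention is converted at the I/O boundary only,
and the conversion is a bijection on integer boxes.

Matching is the VOC greedy protocol: per class, detections ranked by
descending score (ties by image id then input order, so evaluation is
invariant to file row order), each matched to the unmatched same-image
ground truth of highest IoU, a true positive iff IoU ≥ 0.5 (configurable;
the upstream work does not print its cutoff, 0.5 is the VOC default).
Detections on negative images can never match and are always false
positives — the reason test sets carry explicit negatives.

"As documented in the PASCAL VOC benchmark" spans two AP definitions, so
both are implemented: all-points envelope integration (default, matching
the reference evaluators of the common detector frameworks) and the
eleven-point VOC2007 average. The precision envelope is monotone
non-increasing in recall; integrating it implies mAP can only decrease as
the confidence threshold rises, which is the property the threshold-sweep
protocol probes. `n_gt = 0` with no detections yields AP 0 with a warning
rather than NaN. VOC `difficult`/`truncated` flags are read and preserved
on round-trip but ignored by evaluation, since the upstream protocol does
not mention them.

## What the synthetic fixtures emulate — and what they do not

`generate_scene()` builds textured backgrounds (low-frequency noise fields
upscaled bilinearly, plus sinusoidal gradients and mild pixel noise) with
0–3 elliptical "animal" blobs and tight boxes; `generate_burst()` emulates
a capture event by translation (≤ 2 px), per-frame noise (σ = 2), and
global brightness shifts (≤ 10 intensity units). The texture is
deliberately low-frequency: burst translation then preserves window
correlation (intra-burst SSIM ≥ ~0.6 at defaults) while independent scenes
decorrelate (≤ ~0.33), placing the 0.4 threshold in a wide margin. These
defaults were fixed once, verified against an independent SSIM
implementation, and frozen.

The fixtures validate *logic*, not *image realism*: SSIM clustering,
splitting, and mAP arithmetic are agnostic to semantic content, so passing
tests demonstrate correctness of the algorithms, not that any particular
wildlife dataset will separate cleanly at 0.8/0.4. Real camera-trap
imagery adds phenomena the generator does not model — infrared night
frames, occlusion, rain on the lens, day/night exposure swings within one
event — and users should expect to inspect cluster output before deleting
anything (the removal list is written as CSV precisely so deletion can be
audited).

`simulate_detections()` plants `round(recall · n_gt)` true positives with
controllable localization noise and score distributions plus spurious
boxes; the planted truth travels with the detections, so measured TP/FP
counts can be asserted against planted ones exactly wherever no
thresholding ambiguity exists.

## Problem sizes and numerical choices

The test suite runs entirely on generated data: similarity/cluster oracles
use 500 random matrices up to 12×12 against brute-force transitive
closure; AP is checked against a naive per-recall-level oracle on hundreds
of random rankings of up to 20 detections; the end-to-end determinism
check runs a 37-image corpus (3 bursts × 4 frames + 5 distinct scenes +
20 negatives at 256×256) through the full pipeline twice and compares
artifacts byte for byte. These sizes exercise every code path while
keeping the default suite near a minute on one CPU; all scale up linearly
via the generator arguments.

Numerical notes: pixel matrices are coerced to double before the
summed-area tables (32-bit sums of squared intensities overflow on a
256×256 image); similarity CSVs are re-symmetrized and re-unit-diagonaled
on read to absorb decimal truncation; split files are written in a fixed
subset-then-id order so byte-identity is meaningful.

## Known limitations

- SSIM is computed on resized 256×256 grayscale images; extreme aspect
  ratios are distorted rather than cropped or letterboxed.
- Single-linkage clustering can chain distinct events through a bridging
  frame; the threshold is the only guard.
- The pairwise matrix is $O(n^2)$ in both time and SSIM evaluations; pools
  beyond a few thousand images should be batched (e.g. per keyword or per
  camera site) before comparison.
- COCO-style mAP@[.5:.95], polygon annotations, and YOLO/COCO annotation
  dialects are out of scope.
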