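# trapcurate

Curation and evaluation tooling for wildlife camera-trap object-detection
datasets.

Camera traps fire in bursts: one animal visit yields many near-identical
frames, and a model trained naively on such data memorizes sites instead of
animals. Conversely, web-sourced imagery (FlickR, iNaturalist) is highly
varied but needs careful deduplication and, for field deployment, a small
"infusion" of real camera-trap frames. `trapcurate` implements that curation
workflow for ecologists building location-invariant detectors, plus the
standard evaluation of the resulting detector outputs:

- **Near-duplicate removal and capture-event clustering** via the structural
  similarity index. For two images \(a, b\), per window
  \(\mathrm{SSIM} = \frac{(2\mu_a\mu_b + C_1)(2\sigma_{ab} + C_2)}
  {(\mu_a^2+\mu_b^2+C_1)(\sigma_a^2+\sigma_b^2+C_2)}\),
  averaged over a uniform 7×7 window (C₁ = (0.01·255)², C₂ = (0.03·255)²).
  Pairs scoring **above 0.8** are duplicates (one seeded-random survivor per
  connected component is kept); pairs **at or above 0.4** are clustered into
  capture events, from which one representative frame per cluster is drawn.
- **Deterministic split planning**: seeded 90/10 train/validation splits with
  round-half-up arithmetic; infusion of `round_half_up(p·N)` camera-trap
  images (p = 5–20%) into an N-image web pool *before* splitting, selecting
  one frame per SSIM cluster (smallest clusters first) to maximize
  variability; and explicit negative-sample supplementation (800 train / 200
  test by convention) appended after the split arithmetic.
- **PASCAL VOC evaluation**: IoU on half-open boxes, greedy score-ranked
  matching (each ground truth creditable once, detections on negative images
  always false positives), all-points or eleven-point interpolated average
  precision, and mAP sweeps over confidence thresholds.
- **PASCAL VOC XML + manifest I/O** (labelImg dialect, coordinates converted
  to a 0-based half-open internal convention), and a **synthetic fixture
  generator** (textured scenes, jittered bursts, detection sets with planted
  recall/false positives) so everything is testable offline.

The detector itself is a pluggable external stage: `trapcurate` prepares its
training/validation/test sets and scores its output CSVs.

## Worked example

```r
library(trapcurate)

# Plan a 5% infusion of a 333-image camera-trap pool into a 1,665-image
# web pool, split 90/10:
s <- build_infusion_split(sprintf("fin%04d", 1:1665),
                          sprintf("wcs%03d", 1:333), p = 0.05, seed = 7)
s
#> <dataset_split> train 1573 | val 175 | test 0 (positives 1573/175/0, 83 infused)
```

83 = round_half_up(0.05 × 1665) camera-trap images join the pool; the
combined 1,748 images split into 1,573 training and 175 validation.

```r
# SSIM separates burst frames from distinct scenes:
x <- generate_scene(101); y <- generate_burst(x, seed = 1)[[1]]
z <- generate_scene(202)
ssim(y$image, x$image)   # 0.804  -> same capture event (>= 0.4)
ssim(x$image, z$image)   # 0.267  -> distinct scenes    (<  0.4)

# Score simulated detections at a 30% confidence threshold:
gts <- setNames(lapply(list(x, z), `[[`, "annotation"),
                c(x$image_id, z$image_id))
sim <- simulate_detections(gts, recall = 0.75, n_false_positives = 2,
                           fp_score = c(0.05, 0.25), seed = 4)
evaluate_at_thresholds(sim$detections, gts, c(0.05, 0.30))[["conf_0.30"]]
#> <eval_report> conf >= 0.30 | IoU >= 0.50 | mAP 0.6667 | TP 2 FP 0 FN 1
#>   AP[animal] = 0.6667
```

The planted detection set covers 2 of 3 ground-truth boxes; the low-scored
false positives vanish at the 0.30 threshold, so precision is perfect and AP
equals the interpolated envelope over recall 2/3.

`run_pipeline()` chains dedup → clustering → splits → negatives →
evaluation from one (YAML-configurable) object, writing every intermediate
artifact; `inst/cli/trapcurate.R` exposes the same stages as
`simulate | dedup | cluster | split | infuse | evaluate | run` subcommands.

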