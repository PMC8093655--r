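make_gts <- function(...) as_gts(list(...))
as_gts <- function(anns) setNames(anns, vapply(anns, `[[`, "", "image_id"))

one_box <- function(id, box = c(10, 10, 50, 50), w = 100, h = 100,
                    cls = "animal") {
  annotation_set(id, w, h, data.frame(
    class_label = cls, xmin = box[1], ymin = box[2],
    xmax = box[3], ymax = box[4]))
}

det_row <- function(id, score, box, cls = "animal") {
  data.frame(image_id = id, class_label = cls, score = score,
             xmin = box[1], ymin = box[2], xmax = box[3], ymax = box[4])
}

test_that("iou follows the half-open convention", {
  expect_identical(iou(c(0, 0, 10, 10), c(0, 0, 10, 10)), 1)
  expect_identical(iou(c(0, 0, 10, 10), c(10, 0, 20, 10)), 0)
  expect_equal(iou(c(0, 0, 10, 10), c(5, 0, 15, 10)), 1 / 3)
  expect_identical(iou(c(0, 0, 10, 10), c(50, 50, 60, 60)), 0)
})

test_that("greedy matching credits at most one detection per ground truth", {
  gts <- make_gts(one_box("im1"))
  # exact hit
  m <- match_detections(det_row("im1", 0.9, c(10, 10, 50, 50)), gts)
  expect_identical(sum(m$detections$tp), 1L)
  expect_identical(unname(m$n_gt["animal"]), 1L)
  # duplicate detections: only the higher-scored is a TP
  dets <- rbind(det_row("im1", 0.9, c(10, 10, 50, 50)),
                det_row("im1", 0.8, c(11, 11, 51, 51)))
  m2 <- match_detections(dets, gts)
  expect_identical(m2$detections$tp, c(TRUE, FALSE))
  expect_identical(m2$detections$score, c(0.9, 0.8))
  # and symmetrically when the better box has the lower score
  m3 <- match_detections(dets[2:1, ], gts)
  expect_identical(sum(m3$detections$tp), 1L)
  expect_true(m3$detections$tp[m3$detections$score == 0.9])
})

test_that("detections on negative images are always false positives", {
  gts <- make_gts(one_box("im1"), annotation_set("neg1", 100, 100))
  dets <- rbind(det_row("im1", 0.5, c(10, 10, 50, 50)),
                det_row("neg1", 0.99, c(10, 10, 50, 50)))
  m <- match_detections(dets, gts)
  d <- m$detections
  expect_false(d$tp[d$image_id == "neg1"])
  expect_true(d$tp[d$image_id == "im1"])
  expect_error(match_detections(det_row("ghost", 0.5, c(0, 0, 5, 5)), gts),
               "ghost")
})

test_that("average precision reproduces hand-computed envelope values", {
  # perfect ranking
  expect_identical(average_precision(c(TRUE, TRUE), 2), 1)
  # no detections
  expect_identical(average_precision(logical(0), 3), 0)
  # [TP, FP, TP] with 2 ground truths: 1 * 0.5 + (2/3) * 0.5 = 5/6
  expect_equal(average_precision(c(TRUE, FALSE, TRUE), 2), 5 / 6)
  # same ranking, eleven-point rule: (6 * 1 + 5 * 2/3) / 11
  expect_equal(average_precision(c(TRUE, FALSE, TRUE), 2,
                                 mode = "eleven_point"), 28 / 33)
  # no ground truth and no detections: defined 0, with a warning
  expect_warning(ap0 <- average_precision(logical(0), 0), "no ground truth")
  expect_identical(ap0, 0)
})

test_that("average precision equals the naive oracle on random rankings", {
  for (seed in 1:300) {
    set.seed(seed)
    n <- sample(1:20, 1)
    n_gt <- sample(1:10, 1)
    tp <- rep(FALSE, n)
    tp[sample(n, min(n, sample(0:n_gt, 1)))] <- TRUE
    expect_equal(average_precision(tp, n_gt), naive_ap(tp, n_gt),
                 tolerance = 1e-12)
  }
})

test_that("evaluation counts and AP behave on a planted detection set", {
  scenes <- lapply(1:6, function(s) generate_scene(400 + s, width = 96,
                                                   height = 96))
  negs <- lapply(1:2, function(s)
    generate_scene(450 + s, sprintf("eneg%d", s), width = 96, height = 96,
                   n_blobs = 0))
  gts <- as_gts(lapply(c(scenes, negs), `[[`, "annotation"))
  n_gt <- sum(vapply(gts, function(a) nrow(a$objects), 0L))

  # recall 1, no FPs, exact boxes: AP = 1
  sim <- simulate_detections(gts, recall = 1, seed = 1)
  r <- evaluate_detections(sim$detections, gts)
  expect_identical(r$map, 1)
  expect_identical(r$counts$fn, 0L)

  # recall 0: AP = 0
  sim0 <- simulate_detections(gts, recall = 0, seed = 1)
  expect_identical(evaluate_detections(sim0$detections, gts)$map, 0)

  # planted recall with separated scores: thresholding removes every FP
  sim8 <- simulate_detections(gts, recall = 0.8, n_false_positives = 12,
                              tp_score = c(0.7, 1),
                              fp_score = c(0.05, 0.29), seed = 3)
  reports <- evaluate_at_thresholds(sim8$detections, gts,
                                    thresholds = c(0.05, 0.30))
  low <- reports[["conf_0.05"]]; high <- reports[["conf_0.30"]]
  planted <- sim8$truth$n_tp_planted
  expect_identical(low$counts$tp, planted)
  expect_equal(low$counts$tp / n_gt, sim8$truth$n_tp_planted / n_gt)
  expect_identical(low$counts$fp, 12L)
  expect_identical(high$counts$fp, 0L)  # precision 1 at the 0.30 threshold
  expect_identical(high$counts$tp, planted)
})

test_that("mAP is monotone non-increasing in the confidence threshold", {
  scenes <- lapply(1:5, function(s) generate_scene(470 + s, width = 96,
                                                   height = 96))
  gts <- as_gts(lapply(scenes, `[[`, "annotation"))
  for (seed in 1:10) {
    sim <- simulate_detections(gts, recall = 0.7, n_false_positives = 8,
                               loc_noise = 3, tp_score = c(0.2, 1),
                               fp_score = c(0.05, 0.8), seed = seed)
    maps <- vapply(evaluate_at_thresholds(sim$detections, gts,
                                          seq(0, 0.9, 0.1)),
                   `[[`, 0, "map")
    expect_true(all(diff(maps) <= 1e-12))
  }
  # threshold 0 is identical to unfiltered evaluation
  sim <- simulate_detections(gts, recall = 0.6, n_false_positives = 5,
                             seed = 99)
  expect_equal(evaluate_detections(sim$detections, gts,
                                   conf_threshold = 0)$map,
               evaluate_detections(sim$detections, gts)$map)
})

test_that("evaluation is invariant to detection row order", {
  scenes <- lapply(1:4, function(s) generate_scene(480 + s, width = 96,
                                                   height = 96))
  gts <- as_gts(lapply(scenes, `[[`, "annotation"))
  sim <- simulate_detections(gts, recall = 0.7, n_false_positives = 6,
                             loc_noise = 2, seed = 5)
  r1 <- evaluate_detections(sim$detections, gts)
  set.seed(1)
  shuffled <- sim$detections[sample(nrow(sim$detections)), ]
  r2 <- evaluate_detections(shuffled, gts)
  expect_identical(r1$map, r2$map)
  expect_identical(r1$counts, r2$counts)
})

test_that("detections CSV round-trips, including VOC coordinate input", {
  dir <- withr::local_tempdir()
  d <- det_row("im1", 0.5, c(10, 10, 50, 50))
  path <- file.path(dir, "d.csv")
  write.csv(d, path, row.names = FALSE)
  expect_equal(read_detections_csv(path), d)
  voc <- read_detections_csv(path, voc_coords = TRUE)
  expect_equal(voc$xmin, 9)
  expect_equal(voc$xmax, 50)
})
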