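#' Intersection over union of two boxes
#'
#' Overlap between a detection and a ground-truth box under the 0-based
#' half-open convention: edge-adjacent boxes do not intersect, so
#' `iou(c(0,0,10,10), c(10,0,20,10))` is 0. Returns `|a∩b| / |a∪b|`.
#'
#' @param a,b boxes as numeric `c(xmin, ymin, xmax, ymax)` vectors (or
#'   one-row data frames with those columns).
#' @return IoU in `[0, 1]`.
#' @export
#' @examples
#' iou(c(0, 0, 10, 10), c(5, 0, 15, 10))  # 1/3
iou <- function(a, b) {
  a <- as_box(a); b <- as_box(b)
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  union <- (a[3] - a[1]) * (a[4] - a[2]) +
    (b[3] - b[1]) * (b[4] - b[2]) - inter
  inter / union
}

as_box <- function(x) {
  if (is.data.frame(x)) x <- unlist(x[1, c("xmin", "ymin", "xmax", "ymax")])
  x <- as.numeric(x)
  if (length(x) != 4 || x[3] <= x[1] || x[4] <= x[2])
    fail("a box must be c(xmin, ymin, xmax, ymax) with positive area")
  x
}

validate_detections <- function(dets) {
  need <- c("image_id", "class_label", "score",
            "xmin", "ymin", "xmax", "ymax")
  if (!is.data.frame(dets) || !all(need %in% names(dets)))
    fail("detections must be a data frame with columns %s",
         paste(need, collapse = ", "))
  dets <- as.data.frame(dets)[need]
  if (nrow(dets)) {
    if (any(dets$score < 0 | dets$score > 1))
      fail("detection scores must lie in [0, 1]")
    if (any(dets$xmax <= dets$xmin | dets$ymax <= dets$ymin))
      fail("detection boxes must have positive area")
  }
  dets
}

#' Read a detections CSV
#'
#' Expected header: `image_id,class_label,score,xmin,ymin,xmax,ymax`.
#' Coordinates are taken as 0-based half-open unless `voc_coords = TRUE`,
#' in which case 1-based inclusive values are converted on read.
#'
#' @param path CSV path.
#' @param voc_coords logical; input uses VOC 1-based inclusive pixels.
#' @return detections data frame.
#' @export
read_detections_csv <- function(path, voc_coords = FALSE) {
  if (!file.exists(path)) fail("detections file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- validate_detections(df)
  if (voc_coords) {
    df$xmin <- df$xmin - 1
    df$ymin <- df$ymin - 1
  }
  df
}

#' Match detections to ground truth
#'
#' The PASCAL VOC greedy matcher. Per class, detections are ranked by
#' descending score (ties broken by image id, then input order, so
#' results are independent of file row order); each detection is matched
#' to the not-yet-matched ground-truth box of the same class on the same
#' image with the highest IoU. The detection is a true positive if that
#' IoU reaches `iou_threshold`, otherwise a false positive. Each
#' ground-truth box can be matched at most once, so duplicate detections
#' of one animal are false positives, and any detection on a negative
#' image is a false positive regardless of score.
#'
#' @param dets detections data frame (see [read_detections_csv()]).
#' @param gts named list of [annotation_set()] keyed by image id; must
#'   cover every image id appearing in `dets`.
#' @param iou_threshold minimum IoU for a true positive; VOC default 0.5.
#' @return list of class `match_result`: `detections` (the input rows in
#'   rank order with logical `tp` and `matched_gt` columns) and `n_gt`
#'   (named vector of ground-truth counts per class).
#' @export
match_detections <- function(dets, gts, iou_threshold = 0.5) {
  dets <- validate_detections(dets)
  if (!length(gts) || is.null(names(gts)))
    fail("gts must be a named list of annotation_set objects")
  unknown <- setdiff(unique(dets$image_id), names(gts))
  if (length(unknown))
    fail("detections reference unknown image_id(s): %s",
         paste(unknown, collapse = ", "))

  gt_tab <- do.call(rbind, c(
    list(data.frame(image_id = character(), class_label = character(),
                    xmin = numeric(), ymin = numeric(),
                    xmax = numeric(), ymax = numeric(), gt_id = integer())),
    lapply(gts, function(ann) {
      o <- ann$objects
      if (!nrow(o)) return(NULL)
      data.frame(image_id = ann$image_id, class_label = o$class_label,
                 xmin = o$xmin, ymin = o$ymin, xmax = o$xmax,
                 ymax = o$ymax, gt_id = NA_integer_)
    })))
  rownames(gt_tab) <- NULL
  if (nrow(gt_tab)) gt_tab$gt_id <- seq_len(nrow(gt_tab))

  classes <- sort(unique(c(dets$class_label, gt_tab$class_label)))
  n_gt <- vapply(classes, function(cl) sum(gt_tab$class_label == cl), 0L)

  dets$input_order <- seq_len(max(nrow(dets), 0L))
  ord <- order(dets$class_label, -dets$score, dets$image_id,
               dets$input_order)
  dets <- dets[ord, ]
  dets$tp <- logical(nrow(dets))
  dets$matched_gt <- rep(NA_integer_, nrow(dets))

  matched <- logical(nrow(gt_tab))
  for (i in seq_len(nrow(dets))) {
    cand <- which(gt_tab$image_id == dets$image_id[i] &
                    gt_tab$class_label == dets$class_label[i] & !matched)
    if (!length(cand)) next
    ious <- vapply(cand, function(j) {
      iou(c(dets$xmin[i], dets$ymin[i], dets$xmax[i], dets$ymax[i]),
          c(gt_tab$xmin[j], gt_tab$ymin[j], gt_tab$xmax[j],
            gt_tab$ymax[j]))
    }, 0)
    best <- cand[which.max(ious)]
    if (max(ious) >= iou_threshold) {
      dets$tp[i] <- TRUE
      dets$matched_gt[i] <- gt_tab$gt_id[best]
      matched[best] <- TRUE
    }
  }
  rownames(dets) <- NULL
  structure(list(detections = dets, n_gt = n_gt), class = "match_result")
}

#' PASCAL VOC average precision
#'
#' Computes AP from a ranked sequence of true-positive flags. Cumulative
#' precision and recall are formed down the ranking, the precision curve
#' is replaced by its monotone non-increasing envelope (each point takes
#' the maximum precision at equal or higher recall), and the envelope is
#' either integrated over recall (`all_points`, the default, as used by
#' the common detector reference evaluators) or averaged at the eleven
#' recall points 0.0, 0.1, ..., 1.0 (`eleven_point`, the original VOC2007
#' rule).
#'
#' @param tp logical vector of per-detection outcomes in descending-score
#'   rank order (from [match_detections()]).
#' @param n_gt number of ground-truth boxes for the class; with
#'   `n_gt = 0` and no detections AP is defined as 0 with a warning.
#' @param mode `"all_points"` or `"eleven_point"`.
#' @return AP in `[0, 1]`.
#' @export
#' @examples
#' average_precision(c(TRUE, FALSE, TRUE), n_gt = 2)  # 5/6
average_precision <- function(tp, n_gt,
                              mode = c("all_points", "eleven_point")) {
  mode <- match.arg(mode)
  tp <- as.logical(tp)
  if (n_gt < 0) fail("n_gt must be non-negative")
  if (n_gt == 0) {
    if (!length(tp)) warning("AP undefined with no ground truth; returning 0",
                             call. = FALSE)
    return(0)
  }
  if (!length(tp)) return(0)
  cum_tp <- cumsum(tp)
  precision <- cum_tp / seq_along(tp)
  recall <- cum_tp / n_gt
  envelope <- rev(cummax(rev(precision)))
  if (mode == "eleven_point") {
    mean(vapply(seq(0, 1, 0.1), function(r) {
      ok <- recall >= r - 1e-12
      if (any(ok)) max(envelope[ok]) else 0
    }, 0))
  } else {
    prev_recall <- c(0, recall[-length(recall)])
    sum((recall - prev_recall) * envelope)
  }
}

#' Evaluate a detection set at one confidence threshold
#'
#' Discards detections scoring below `conf_threshold`, matches the rest
#' to ground truth, and computes per-class AP, mAP (unweighted mean over
#' classes with ground truth), the PR curve, and TP/FP/FN counts.
#'
#' @param dets detections data frame.
#' @param gts named list of [annotation_set()].
#' @param iou_threshold IoU cutoff for a true positive.
#' @param conf_threshold minimum detection score retained.
#' @param mode AP mode, see [average_precision()].
#' @return object of class `eval_report`: list with `confidence_threshold`,
#'   `ap` (named per-class), `map`, `pr` (named list of per-class
#'   data frames with `recall`, `precision`), and `counts`
#'   (`tp`, `fp`, `fn`).
#' @export
evaluate_detections <- function(dets, gts, iou_threshold = 0.5,
                                conf_threshold = 0,
                                mode = c("all_points", "eleven_point")) {
  mode <- match.arg(mode)
  dets <- validate_detections(dets)
  dets <- dets[dets$score >= conf_threshold, , drop = FALSE]
  match <- match_detections(dets, gts, iou_threshold)
  d <- match$detections
  classes <- names(match$n_gt)
  ap <- stats::setNames(numeric(length(classes)), classes)
  pr <- stats::setNames(vector("list", length(classes)), classes)
  for (cl in classes) {
    dc <- d[d$class_label == cl, , drop = FALSE]
    ap[cl] <- average_precision(dc$tp, match$n_gt[cl], mode)
    cum_tp <- cumsum(dc$tp)
    pr[[cl]] <- data.frame(
      recall = if (match$n_gt[cl] > 0) cum_tp / match$n_gt[cl]
               else rep(NA_real_, nrow(dc)),
      precision = if (nrow(dc)) cum_tp / seq_len(nrow(dc)) else numeric())
  }
  scored <- classes[match$n_gt > 0]
  tp <- sum(d$tp)
  structure(list(
    confidence_threshold = conf_threshold,
    iou_threshold = iou_threshold,
    mode = mode,
    ap = ap,
    map = if (length(scored)) mean(ap[scored]) else 0,
    pr = pr,
    counts = list(tp = tp, fp = nrow(d) - tp,
                  fn = sum(match$n_gt) - tp)),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> conf >= %.2f | IoU >= %.2f | mAP %.4f | TP %d FP %d FN %d\n",
    x$confidence_threshold, x$iou_threshold, x$map,
    x$counts$tp, x$counts$fp, x$counts$fn))
  for (cl in names(x$ap))
    cat(sprintf("  AP[%s] = %.4f\n", cl, x$ap[[cl]]))
  invisible(x)
}

#' Sweep evaluation over confidence thresholds
#'
#' Re-evaluates the detection set at each confidence threshold in turn —
#' the protocol for choosing a deployment threshold: raising the
#' threshold trades recall (and hence AP, which never increases) for
#' fewer false positives.
#'
#' @param dets detections data frame.
#' @param gts named list of [annotation_set()].
#' @param thresholds ascending confidence thresholds in `[0, 1]`;
#'   defaults 0.05, 0.30 (a common deployment choice) and 0.50.
#' @param iou_threshold,mode passed to [evaluate_detections()].
#' @return named list of `eval_report`, one per threshold.
#' @export
evaluate_at_thresholds <- function(dets, gts,
                                   thresholds = c(0.05, 0.30, 0.50),
                                   iou_threshold = 0.5,
                                   mode = c("all_points", "eleven_point")) {
  mode <- match.arg(mode)
  if (is.unsorted(thresholds) || any(thresholds < 0 | thresholds > 1))
    fail("thresholds must be ascending values in [0, 1]")
  reports <- lapply(thresholds, function(t)
    evaluate_detections(dets, gts, iou_threshold, t, mode))
  stats::setNames(reports, sprintf("conf_%.2f", thresholds))
}

# flatten an eval_report for JSON serialization
eval_report_summary <- function(report) {
  list(confidence_threshold = report$confidence_threshold,
       iou_threshold = report$iou_threshold,
       map = unname(report$map),
       ap = as.list(report$ap),
       tp = report$counts$tp, fp = report$counts$fp,
       fn = report$counts$fn)
}
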