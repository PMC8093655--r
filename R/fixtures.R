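#' Generate a synthetic camera-trap scene
#'
#' Builds a seeded, fully reproducible test image: a textured background
#' (low-frequency sinusoidal gradient plus Gaussian pixel noise) with
#' 0-3 "animal" blobs — filled ellipses of contrasting intensity — and
#' the tight bounding box of each blob as its annotation. Zero-blob
#' scenes are negative samples. Blob geometry, SSIM behavior, splitting
#' and mAP arithmetic are all agnostic to semantic image content, so
#' geometric blobs exercise the full pipeline without any downloads.
#'
#' Pixel values are integers in `[0, 255]` (8-bit grayscale) so a written
#' PNG decodes to exactly the in-memory image.
#'
#' @param seed integer seed; the same seed yields a byte-identical scene.
#' @param image_id id for the scene; defaults to `scene_<seed>`.
#' @param width,height image size in pixels.
#' @param n_blobs number of animal blobs, 0-3; `NULL` samples 1-3
#'   (use 0 for an explicit negative).
#' @param class_label label given to every blob.
#' @return list with `image` (integer matrix, rows = y),
#'   `annotation` (an [annotation_set()]) and `image_id`.
#' @export
generate_scene <- function(seed, image_id = sprintf("scene_%05d", seed),
                           width = 256, height = 256, n_blobs = NULL,
                           class_label = "animal") {
  with_seed(seed, {
    if (is.null(n_blobs)) n_blobs <- sample(1:3, 1)
    stopifnot(n_blobs >= 0, n_blobs <= 3)
    ys <- matrix(rep(seq_len(height), width), height, width)
    xs <- matrix(rep(seq_len(width), each = height), height, width)
    # low-frequency texture: coarse noise upscaled bilinearly, so small
    # translations (a capture-event burst) keep SSIM windows correlated
    # while independent scenes decorrelate
    coarse <- matrix(stats::rnorm(ceiling(height / 12) * ceiling(width / 12)),
                     ceiling(height / 12), ceiling(width / 12))
    texture <- t(EBImage::imageData(EBImage::resize(
      EBImage::Image(t(coarse)), w = width, h = height)))
    base <- stats::runif(1, 80, 170)
    img <- base +
      stats::runif(1, -30, 30) * sin(2 * pi * ys / stats::runif(1, 90, 300)) +
      stats::runif(1, -30, 30) * cos(2 * pi * xs / stats::runif(1, 90, 300)) +
      35 * texture +
      matrix(stats::rnorm(height * width, 0, 3), height, width)

    boxes <- empty_objects()
    for (b in seq_len(n_blobs)) {
      rx <- stats::runif(1, 12, 32)
      ry <- stats::runif(1, 12, 32)
      cx <- stats::runif(1, rx + 2, width - rx - 2)
      cy <- stats::runif(1, ry + 2, height - ry - 2)
      contrast <- sample(c(-1, 1), 1) * stats::runif(1, 70, 120)
      mask <- ((xs - cx) / rx)^2 + ((ys - cy) / ry)^2 <= 1
      img[mask] <- img[mask] + contrast
      cols <- range(which(apply(mask, 2, any)))
      rows <- range(which(apply(mask, 1, any)))
      boxes <- rbind(boxes, data.frame(
        class_label = class_label,
        xmin = cols[1] - 1L, ymin = rows[1] - 1L,
        xmax = cols[2], ymax = rows[2],
        difficult = 0L, truncated = 0L))
    }
    img <- matrix(as.integer(pmin(pmax(round(img), 0), 255)),
                  height, width)
    list(image = img,
         annotation = annotation_set(image_id, width, height, boxes),
         image_id = image_id)
  })
}

# integer translate with edge replication; dx > 0 shifts content right,
# dy > 0 shifts content down
shift_image <- function(img, dx, dy) {
  h <- nrow(img); w <- ncol(img)
  src_rows <- pmin(pmax(seq_len(h) - dy, 1), h)
  src_cols <- pmin(pmax(seq_len(w) - dx, 1), w)
  img[src_rows, src_cols, drop = FALSE]
}

#' Generate a burst of near-duplicate frames
#'
#' Emulates one camera-trap capture event: `n_frames` perturbed copies of
#' a base scene, each with an integer translation of at most `jitter`
#' pixels, Gaussian pixel noise, and a global brightness shift.
#' Annotations are translated with the frame and re-clipped; a frame
#' whose jitter would push a box entirely out of the image is regenerated
#' with reduced jitter. At the default perturbation levels every
#' intra-burst pair stays well above the 0.4 clustering threshold while
#' independently generated scenes fall below it.
#'
#' @param scene a [generate_scene()] result with at least one blob if
#'   annotations matter.
#' @param n_frames number of frames in the burst.
#' @param jitter maximum absolute translation in pixels.
#' @param noise_sigma Gaussian pixel-noise standard deviation
#'   (intensity units).
#' @param brightness_delta maximum absolute global brightness shift.
#' @param seed integer seed.
#' @return list of frames, each like a [generate_scene()] result with
#'   ids `<scene_id>_f<k>`.
#' @export
generate_burst <- function(scene, n_frames = 4, jitter = 2,
                           noise_sigma = 2, brightness_delta = 10,
                           seed = 1) {
  stopifnot(n_frames >= 1)
  base <- scene$image
  ann <- scene$annotation
  with_seed(seed, {
    lapply(seq_len(n_frames), function(k) {
      j <- jitter
      repeat {
        dx <- if (j > 0) sample(-j:j, 1) else 0L
        dy <- if (j > 0) sample(-j:j, 1) else 0L
        o <- ann$objects
        if (nrow(o)) {
          o$xmin <- pmax(o$xmin + dx, 0L)
          o$xmax <- pmin(o$xmax + dx, ann$width)
          o$ymin <- pmax(o$ymin + dy, 0L)
          o$ymax <- pmin(o$ymax + dy, ann$height)
          if (any(o$xmax <= o$xmin | o$ymax <= o$ymin)) {
            j <- j - 1L
            message(sprintf("burst frame %d: reducing jitter to %d", k, j))
            next
          }
        }
        img <- shift_image(base, dx, dy) +
          (if (noise_sigma > 0)
             matrix(stats::rnorm(length(base), 0, noise_sigma),
                    nrow(base), ncol(base)) else 0) +
          (if (brightness_delta > 0)
             stats::runif(1, -brightness_delta, brightness_delta) else 0)
        img <- matrix(as.integer(pmin(pmax(round(img), 0), 255)),
                      nrow(base), ncol(base))
        id <- sprintf("%s_f%d", scene$image_id, k)
        return(list(image = img,
                    annotation = annotation_set(id, ann$width, ann$height,
                                                o),
                    image_id = id))
      }
    })
  })
}

#' Simulate a detection set with known ground truth
#'
#' Plants `round(recall * n_gt)` true-positive detections (ground-truth
#' boxes perturbed by Gaussian localization noise, scores drawn from the
#' `tp_score` range) and `n_false_positives` random boxes on random
#' images (scores from `fp_score`). The planted truth is returned
#' alongside the detections so evaluation tests can compare measured
#' against planted quantities exactly.
#'
#' @param gts named list of [annotation_set()] (negatives included; false
#'   positives may land on them).
#' @param recall proportion of ground-truth boxes detected.
#' @param n_false_positives number of spurious detections.
#' @param loc_noise standard deviation (pixels) of the corner jitter
#'   applied to true-positive boxes.
#' @param tp_score,fp_score `c(min, max)` uniform score ranges for true
#'   and false positives.
#' @param seed integer seed.
#' @param class_label class assigned to false positives.
#' @return list with `detections` (data frame) and `truth` (list:
#'   `n_gt`, `n_tp_planted`, `planted` data frame mapping detections to
#'   ground-truth boxes).
#' @export
simulate_detections <- function(gts, recall = 1, n_false_positives = 0,
                                loc_noise = 0, tp_score = c(0.7, 1),
                                fp_score = c(0.05, 0.3), seed = 1,
                                class_label = "animal") {
  stopifnot(recall >= 0, recall <= 1, n_false_positives >= 0)
  gt_tab <- do.call(rbind, lapply(gts, function(ann) {
    o <- ann$objects
    if (!nrow(o)) return(NULL)
    data.frame(image_id = ann$image_id, class_label = o$class_label,
               xmin = o$xmin, ymin = o$ymin, xmax = o$xmax, ymax = o$ymax,
               width = ann$width, height = ann$height)
  }))
  n_gt <- if (is.null(gt_tab)) 0L else nrow(gt_tab)
  n_tp <- as.integer(round(recall * n_gt))
  with_seed(seed, {
    rows <- list()
    planted <- NULL
    if (n_tp > 0) {
      idx <- sort(sample.int(n_gt, n_tp))
      for (i in idx) {
        g <- gt_tab[i, ]
        repeat {
          d <- round(c(g$xmin, g$ymin, g$xmax, g$ymax) +
                       stats::rnorm(4, 0, loc_noise))
          d[1] <- max(d[1], 0); d[2] <- max(d[2], 0)
          d[3] <- min(d[3], g$width); d[4] <- min(d[4], g$height)
          if (d[3] > d[1] && d[4] > d[2]) break
        }
        rows[[length(rows) + 1]] <- data.frame(
          image_id = g$image_id, class_label = g$class_label,
          score = stats::runif(1, tp_score[1], tp_score[2]),
          xmin = d[1], ymin = d[2], xmax = d[3], ymax = d[4])
      }
      planted <- data.frame(gt_index = idx,
                            image_id = gt_tab$image_id[idx])
    }
    img_pool <- names(gts)
    dims <- lapply(gts, function(a) c(a$width, a$height))
    for (k in seq_len(n_false_positives)) {
      im <- img_pool[sample.int(length(img_pool), 1)]
      wh <- dims[[im]]
      bw <- sample(10:60, 1); bh <- sample(10:60, 1)
      x0 <- sample.int(max(wh[1] - bw, 1), 1) - 1L
      y0 <- sample.int(max(wh[2] - bh, 1), 1) - 1L
      rows[[length(rows) + 1]] <- data.frame(
        image_id = im, class_label = class_label,
        score = stats::runif(1, fp_score[1], fp_score[2]),
        xmin = x0, ymin = y0,
        xmax = min(x0 + bw, wh[1]), ymax = min(y0 + bh, wh[2]))
    }
    detections <- if (length(rows)) do.call(rbind, rows) else
      data.frame(image_id = character(), class_label = character(),
                 score = numeric(), xmin = numeric(), ymin = numeric(),
                 xmax = numeric(), ymax = numeric())
    rownames(detections) <- NULL
    list(detections = detections,
         truth = list(n_gt = n_gt, n_tp_planted = n_tp,
                      planted = planted))
  })
}

#' Write a scene (image + VOC XML) to disk
#'
#' @param scene a [generate_scene()] or burst frame.
#' @param images_dir,annotations_dir output directories (created if
#'   needed).
#' @return the image path, invisibly.
#' @export
write_scene <- function(scene, images_dir, annotations_dir = images_dir) {
  dir.create(images_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(annotations_dir, showWarnings = FALSE, recursive = TRUE)
  img_path <- file.path(images_dir, paste0(scene$image_id, ".png"))
  png::writePNG(scene$image / 255, img_path)
  write_voc_xml(scene$annotation,
                file.path(annotations_dir,
                          paste0(scene$image_id, ".xml")))
  invisible(img_path)
}

#' Generate a complete fixture dataset on disk
#'
#' Emits the standard test corpus: `n_burst_scenes` capture-event bursts
#' of `frames_per_burst` near-duplicate frames (source tag `WCS`, the
#' camera-trap pool), `n_distinct` independent scenes (tag `FiN`, the
#' web-image pool), and `n_negatives` empty scenes (tag `NEG`), plus VOC
#' XMLs and a manifest CSV. The planted burst memberships are returned as
#' the clustering oracle.
#'
#' @param dir output directory; `images/`, `annotations/` and
#'   `manifest.csv` are created inside.
#' @param n_burst_scenes,frames_per_burst burst structure.
#' @param n_distinct number of visually independent positive scenes.
#' @param n_negatives number of empty (negative) scenes.
#' @param seed integer master seed.
#' @param width,height image size.
#' @return list with `manifest` (data frame), `manifest_path`, and
#'   `burst_members` (list of id vectors, one per planted burst).
#' @export
generate_fixture_dataset <- function(dir, n_burst_scenes = 3,
                                     frames_per_burst = 4, n_distinct = 5,
                                     n_negatives = 20, seed = 1,
                                     width = 256, height = 256) {
  images_dir <- file.path(dir, "images")
  ann_dir <- file.path(dir, "annotations")
  records <- list()
  burst_members <- list()
  add <- function(scene, tag, negative) {
    write_scene(scene, images_dir, ann_dir)
    records[[length(records) + 1]] <<- data.frame(
      image_id = scene$image_id,
      path = file.path("images", paste0(scene$image_id, ".png")),
      source_tag = tag, is_negative = negative)
  }
  for (b in seq_len(n_burst_scenes)) {
    scene <- generate_scene(derive_seed(seed, sprintf("burst%d", b)),
                            image_id = sprintf("burst%02d", b),
                            width = width, height = height)
    frames <- generate_burst(scene, n_frames = frames_per_burst,
                             seed = derive_seed(seed,
                                                sprintf("frames%d", b)))
    for (f in frames) add(f, "WCS", FALSE)
    burst_members[[b]] <- vapply(frames, `[[`, "", "image_id")
  }
  for (s in seq_len(n_distinct)) {
    scene <- generate_scene(derive_seed(seed, sprintf("distinct%d", s)),
                            image_id = sprintf("scene%02d", s),
                            width = width, height = height)
    add(scene, "FiN", FALSE)
  }
  for (g in seq_len(n_negatives)) {
    scene <- generate_scene(derive_seed(seed, sprintf("negative%d", g)),
                            image_id = sprintf("neg%02d", g),
                            width = width, height = height, n_blobs = 0)
    add(scene, "NEG", TRUE)
  }
  manifest <- do.call(rbind, records)
  manifest_path <- file.path(dir, "manifest.csv")
  write_manifest(manifest, manifest_path)
  list(manifest = manifest, manifest_path = manifest_path,
       burst_members = burst_members)
}
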