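#' SSIM comparison parameters
#'
#' Parameters of the structural similarity index used for duplicate
#' removal and capture-event clustering. The stabilization constants enter
#' as `C1 = (k1*L)^2` and `C2 = (k2*L)^2` where `L` is the dynamic range
#' of the pixel values. Before comparison every image is converted to
#' single-channel grayscale and resized (bilinear) to `comparison_size`,
#' so differently sized images are commensurable. SSIM is computed with a
#' uniform `window_size` x `window_size` window over all fully interior
#' window positions, with unbiased (n-1) variance/covariance
#' normalization, and averaged.
#'
#' @param k1,k2 positive stabilization constants (dimensionless);
#'   defaults 0.01 and 0.03 from the SSIM literature.
#' @param dynamic_range pixel dynamic range `L`; 255 for 8-bit images.
#' @param window_size odd window edge length in pixels, >= 3.
#' @param comparison_size `c(width, height)` in pixels that images are
#'   normalized to before comparison.
#' @return list of class `ssim_params`.
#' @export
ssim_params <- function(k1 = 0.01, k2 = 0.03, dynamic_range = 255,
                        window_size = 7, comparison_size = c(256, 256)) {
  if (k1 <= 0 || k2 <= 0) fail("k1 and k2 must be positive")
  window_size <- as.integer(window_size)
  if (window_size < 3 || window_size %% 2 == 0)
    fail("window_size must be odd and >= 3")
  comparison_size <- as.integer(comparison_size)
  if (length(comparison_size) != 2 || any(comparison_size < window_size))
    fail("comparison_size must be two integers >= window_size")
  structure(list(k1 = k1, k2 = k2, dynamic_range = dynamic_range,
                 window_size = window_size,
                 comparison_size = comparison_size),
            class = "ssim_params")
}

# valid-mode w x w box sum via a summed-area table; returns
# (nrow-w+1) x (ncol-w+1)
box_sum <- function(m, w) {
  n <- nrow(m); p <- ncol(m)
  S <- matrix(0, n + 1, p + 1)
  S[-1, -1] <- t(apply(apply(m, 2, cumsum), 1, cumsum))
  i <- seq_len(n - w + 1); j <- seq_len(p - w + 1)
  S[i + w, j + w, drop = FALSE] - S[i, j + w, drop = FALSE] -
    S[i + w, j, drop = FALSE] + S[i, j, drop = FALSE]
}

# mean SSIM of two equal-size numeric matrices on the [0, L] scale
ssim_matrices <- function(a, b, params) {
  if (!identical(dim(a), dim(b)))
    fail("images must have identical dimensions for SSIM")
  # integer pixel matrices overflow 32-bit arithmetic in the summed-area
  # tables (sum of squares over a 256x256 image exceeds 2^31)
  storage.mode(a) <- "double"
  storage.mode(b) <- "double"
  w <- params$window_size
  if (any(dim(a) < w)) fail("image smaller than SSIM window")
  np <- w * w
  cn <- np / (np - 1)
  ux <- box_sum(a, w) / np
  uy <- box_sum(b, w) / np
  vx <- cn * (box_sum(a * a, w) / np - ux^2)
  vy <- cn * (box_sum(b * b, w) / np - uy^2)
  vxy <- cn * (box_sum(a * b, w) / np - ux * uy)
  C1 <- (params$k1 * params$dynamic_range)^2
  C2 <- (params$k2 * params$dynamic_range)^2
  S <- ((2 * ux * uy + C1) * (2 * vxy + C2)) /
    ((ux^2 + uy^2 + C1) * (vx + vy + C2))
  mean(S)
}

#' Load an image as a grayscale comparison matrix
#'
#' Decodes a PNG/JPEG/TIFF image, converts color images to luminance
#' grayscale, resizes (bilinear) to the comparison size, and returns a
#' numeric matrix with rows = image rows (y) and values on `[0, L]`.
#'
#' @param path image file path.
#' @param params an [ssim_params()].
#' @return numeric matrix `comparison_size[2]` x `comparison_size[1]`.
#' @export
load_image_gray <- function(path, params = ssim_params()) {
  if (!file.exists(path)) fail("image not found: %s", path)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) fail("cannot decode image '%s': %s",
                                           path, conditionMessage(e)))
  if (EBImage::colorMode(img) != 0 || length(dim(img)) > 2)
    img <- EBImage::channel(img, "luminance")
  img <- EBImage::resize(img, w = params$comparison_size[1],
                         h = params$comparison_size[2])
  t(EBImage::imageData(img)) * params$dynamic_range
}

#' Structural similarity between two images
#'
#' The SSIM statistic at the heart of duplicate removal and capture-event
#' clustering: per window, luminance, contrast and structure agreement are
#' combined as
#' \deqn{\frac{(2\mu_a\mu_b + C_1)(2\sigma_{ab} + C_2)}
#'            {(\mu_a^2+\mu_b^2+C_1)(\sigma_a^2+\sigma_b^2+C_2)}}
#' and the per-window scores are averaged. The result lies in `[-1, 1]`;
#' 1 means the images are identical, scores below ~0.4 indicate visually
#' distinct scenes, and above ~0.8 near-duplicates.
#'
#' @param a,b image file paths, or numeric matrices already on the
#'   `[0, dynamic_range]` grayscale scale (matrices bypass resizing).
#' @param params an [ssim_params()].
#' @return SSIM score in `[-1, 1]`; exactly 1 for identical inputs.
#' @export
#' @examples
#' m <- matrix(runif(64 * 64, 0, 255), 64, 64)
#' ssim(m, m)  # 1
ssim <- function(a, b, params = ssim_params()) {
  if (is.character(a)) a <- load_image_gray(a, params)
  if (is.character(b)) b <- load_image_gray(b, params)
  ssim_matrices(a, b, params)
}

#' Pairwise SSIM similarity matrix
#'
#' Compares every image with every other image, returning a symmetric
#' matrix with unit diagonal. Each image is decoded and normalized once;
#' the `n(n-1)/2` pair scores are computed row-major over the id order
#' given, so the matrix is bit-reproducible.
#'
#' @param paths named character vector of image paths (names are image
#'   ids), or a `dataset_manifest` (its `image_id`/`path` columns are
#'   used).
#' @param params an [ssim_params()].
#' @return symmetric numeric matrix with image ids as dimnames, diagonal
#'   exactly 1.
#' @export
ssim_matrix <- function(paths, params = ssim_params()) {
  if (is.data.frame(paths))
    paths <- stats::setNames(paths$path, paths$image_id)
  if (is.null(names(paths)) || any(!nzchar(names(paths))))
    fail("paths must be named by image_id")
  check_ids(names(paths))
  n <- length(paths)
  if (n < 1) fail("need at least one image")
  imgs <- lapply(paths, load_image_gray, params = params)
  m <- diag(1, n)
  dimnames(m) <- list(names(paths), names(paths))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        s <- tryCatch(
          ssim_matrices(imgs[[i]], imgs[[j]], params),
          error = function(e) fail("SSIM failed for pair (%s, %s): %s",
                                   names(paths)[i], names(paths)[j],
                                   conditionMessage(e)))
        m[i, j] <- s
        m[j, i] <- s
      }
    }
  }
  m
}

validate_similarity_matrix <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    fail("similarity matrix must be square")
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
    fail("similarity matrix must have matching image-id dimnames")
  check_ids(rownames(m))
  if (any(abs(diag(m) - 1) > 1e-12))
    fail("similarity matrix diagonal must be 1.0")
  if (max(abs(m - t(m))) > 1e-9)
    fail("similarity matrix must be symmetric")
  invisible(m)
}

# connected components of the thresholded similarity graph; returns a
# list of id vectors ordered by first appearance in the matrix order
similarity_components <- function(m, threshold, strict) {
  adj <- if (strict) m > threshold else m >= threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  comps <- split(rownames(m), comp)
  first <- vapply(comps, function(ids) min(match(ids, rownames(m))), 0)
  unname(comps[order(first)])
}

#' Remove near-duplicate images
#'
#' Builds a graph joining image pairs whose SSIM exceeds `threshold`
#' (strictly, matching the "above 0.8" deletion rule) and, within every
#' connected component of two or more images, keeps exactly one
#' seeded-random representative and removes the rest. Singletons are
#' always kept, so a pool of exact duplicates collapses to one image
#' rather than vanishing.
#'
#' @param m similarity matrix from [ssim_matrix()].
#' @param threshold SSIM score above which a pair counts as duplicate;
#'   default 0.8.
#' @param seed integer seed for representative choice.
#' @return list with character vectors `kept` and `removed`
#'   (disjoint, union = all ids).
#' @export
dedup <- function(m, threshold = 0.8, seed = 1) {
  validate_similarity_matrix(m)
  comps <- similarity_components(m, threshold, strict = TRUE)
  kept <- with_seed(seed, vapply(comps, function(ids) {
    if (length(ids) == 1) ids else ids[sample.int(length(ids), 1)]
  }, ""))
  all_ids <- rownames(m)
  kept <- all_ids[all_ids %in% kept]
  list(kept = kept, removed = setdiff(all_ids, kept))
}

#' Cluster images into capture events
#'
#' Groups images by connected components of the graph joining pairs with
#' SSIM at or above `threshold` (default 0.4, below which images are
#' visually distinct scenes). A cluster usually corresponds to one capture
#' event — a burst of frames from one camera trigger — or to different
#' events with very similar composition. Single linkage is deliberate: a
#' chain of pairwise-similar frames is one event even if its endpoints
#' differ more.
#'
#' @param m similarity matrix from [ssim_matrix()].
#' @param threshold SSIM score at or above which a pair is clustered.
#' @return object of class `cluster_set`: list with `clusters` (list of
#'   disjoint id vectors partitioning the matrix ids) and `threshold`.
#' @export
cluster_events <- function(m, threshold = 0.4) {
  validate_similarity_matrix(m)
  comps <- similarity_components(m, threshold, strict = FALSE)
  structure(list(clusters = unname(comps), threshold = threshold),
            class = "cluster_set")
}

validate_cluster_set <- function(cs, ids = NULL) {
  if (!inherits(cs, "cluster_set")) fail("expected a cluster_set")
  flat <- unlist(cs$clusters, use.names = FALSE)
  check_ids(flat)
  if (!is.null(ids) && !setequal(flat, ids))
    fail("cluster_set does not partition the expected id set")
  invisible(cs)
}

#' @export
print.cluster_set <- function(x, ...) {
  sizes <- lengths(x$clusters)
  cat(sprintf("<cluster_set> %d cluster(s) over %d image(s) at SSIM >= %g\n",
              length(sizes), sum(sizes), x$threshold))
  cat("sizes:", paste(sizes, collapse = " "), "\n")
  invisible(x)
}

#' Select one representative frame per cluster
#'
#' Chooses one image uniformly at random (seeded) from each cluster —
#' the frame that represents a capture event in the curated dataset.
#'
#' @param clusters a [cluster_events()] result.
#' @param seed integer seed.
#' @return character vector with exactly one id per cluster, in cluster
#'   order.
#' @export
select_representatives <- function(clusters, seed = 1) {
  validate_cluster_set(clusters)
  with_seed(seed, vapply(clusters$clusters, function(ids) {
    ids[sample.int(length(ids), 1)]
  }, ""))
}

#' Write / read a similarity matrix as CSV
#'
#' Cache format: first column holds image ids, header row repeats them.
#'
#' @param m similarity matrix.
#' @param path CSV path.
#' @return `path` (write) or the matrix (read).
#' @export
write_similarity_csv <- function(m, path) {
  validate_similarity_matrix(m)
  df <- data.frame(image_id = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_similarity_csv
#' @export
read_similarity_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  m <- as.matrix(df[-1])
  rownames(m) <- df$image_id
  # CSV round-trip perturbs the last digits; re-impose exact invariants
  diag(m) <- 1
  m <- (m + t(m)) / 2
  validate_similarity_matrix(m)
  m
}

#' Write cluster assignments as CSV
#'
#' Emits `image_id,cluster_id` rows, cluster ids numbered from 1 in
#' cluster order.
#'
#' @param clusters a `cluster_set`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_cluster_csv <- function(clusters, path) {
  validate_cluster_set(clusters)
  df <- data.frame(
    image_id = unlist(clusters$clusters, use.names = FALSE),
    cluster_id = rep(seq_along(clusters$clusters),
                     lengths(clusters$clusters)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
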