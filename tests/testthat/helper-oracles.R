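# Independent oracles and generators shared across test files.
# These deliberately use different algorithms from the package code
# (naive loops, matrix-power reachability) so they can arbitrate.

# random annotation set with 0-4 integer boxes
random_annotation <- function(seed) {
  set.seed(seed)
  w <- sample(50:300, 1)
  h <- sample(50:300, 1)
  n <- sample(0:4, 1)
  boxes <- do.call(rbind, lapply(seq_len(n), function(i) {
    x0 <- sample(0:(w - 2), 1)
    y0 <- sample(0:(h - 2), 1)
    data.frame(class_label = sample(c("hyena", "rhino", "pig"), 1),
               xmin = x0, ymin = y0,
               xmax = sample((x0 + 1):w, 1), ymax = sample((y0 + 1):h, 1),
               difficult = sample(0:1, 1), truncated = sample(0:1, 1))
  }))
  annotation_set(sprintf("rand_%04d", seed), w, h,
                 if (is.null(boxes)) trapcurate:::empty_objects() else boxes)
}

# random symmetric similarity matrix with unit diagonal
random_similarity <- function(n, seed) {
  set.seed(seed)
  m <- matrix(runif(n * n), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  dimnames(m) <- list(sprintf("im%02d", seq_len(n)),
                      sprintf("im%02d", seq_len(n)))
  m
}

# brute-force connected components by boolean transitive closure
oracle_components <- function(m, threshold, strict = FALSE) {
  adj <- if (strict) m > threshold else m >= threshold
  diag(adj) <- TRUE
  reach <- adj
  for (k in seq_len(nrow(m))) reach <- (reach %*% reach) > 0
  groups <- unique(apply(reach, 1, paste, collapse = ""))
  lapply(groups, function(g)
    rownames(m)[apply(reach, 1, paste, collapse = "") == g])
}

# naive all-points AP: per distinct recall level, scan for the maximum
# precision at that recall or beyond
naive_ap <- function(tp, n_gt) {
  if (n_gt == 0) return(0)
  if (!length(tp)) return(0)
  prec <- numeric(length(tp)); rec <- numeric(length(tp)); t <- 0
  for (i in seq_along(tp)) {
    t <- t + tp[i]
    prec[i] <- t / i
    rec[i] <- t / n_gt
  }
  ap <- 0; prev <- 0
  for (r in unique(rec[tp])) {
    ap <- ap + (r - prev) * max(prec[rec >= r - 1e-12])
    prev <- r
  }
  ap
}

# deterministic 64x64 textured test pattern (and a shifted variant);
# pixel values on [7.5, 247.5]
sine_pattern <- function(shift = 0) {
  outer(0:63, 0:63, function(i, j)
    127.5 + 120 * sin((i + shift) / 5) * cos(j / 7))
}

# tiny manifest + annotations written to a temp dir
write_tiny_dataset <- function(dir, n_pos = 3, n_neg = 2) {
  scenes <- lapply(seq_len(n_pos), function(s)
    generate_scene(1000 + s, width = 96, height = 96))
  negs <- lapply(seq_len(n_neg), function(s)
    generate_scene(2000 + s, sprintf("tneg%02d", s),
                   width = 96, height = 96, n_blobs = 0))
  for (sc in c(scenes, negs))
    write_scene(sc, file.path(dir, "images"), file.path(dir, "annotations"))
  manifest <- data.frame(
    image_id = vapply(c(scenes, negs), `[[`, "", "image_id"),
    path = file.path("images",
                     paste0(vapply(c(scenes, negs), `[[`, "", "image_id"),
                            ".png")),
    source_tag = c(rep("FiN", n_pos), rep("NEG", n_neg)),
    is_negative = c(rep(FALSE, n_pos), rep(TRUE, n_neg)))
  write_manifest(manifest, file.path(dir, "manifest.csv"))
  list(manifest = manifest, scenes = scenes, negs = negs)
}
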