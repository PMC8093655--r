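#' Number of camera-trap images to infuse
#'
#' The infusion count at level `p` is `round_half_up(p * n_base)`: for the
#' 1,665-image web-sourced rhino pool, 5% infusion selects 83 camera-trap
#' images.
#'
#' @param n_base size of the base (web-image) pool.
#' @param p infusion proportion in `(0, 1]`; the canonical levels are
#'   0.05, 0.10, 0.15, 0.20.
#' @return integer count.
#' @export
#' @examples
#' infusion_count(1665, 0.05)  # 83
#' infusion_count(472, 0.20)   # 94
infusion_count <- function(n_base, p) {
  if (n_base < 1) fail("n_base must be >= 1")
  if (p <= 0 || p > 1) fail("p must be in (0, 1]")
  round_half_up(p * n_base)
}

new_dataset_split <- function(train_ids, val_ids, test_ids = character(),
                              provenance) {
  structure(list(train_ids = train_ids, val_ids = val_ids,
                 test_ids = test_ids, provenance = provenance),
            class = "dataset_split")
}

# provenance rows for a set of ids
prov_rows <- function(ids, subset, source_tags = NULL, infused = FALSE,
                      negative = FALSE) {
  if (!length(ids))
    return(data.frame(image_id = character(), subset = character(),
                      source_tag = character(), infused = logical(),
                      negative = logical()))
  tag <- if (is.null(source_tags)) NA_character_
         else unname(source_tags[ids])
  data.frame(image_id = ids, subset = subset, source_tag = tag,
             infused = infused, negative = negative)
}

validate_dataset_split <- function(split) {
  stopifnot(inherits(split, "dataset_split"))
  ids <- c(split$train_ids, split$val_ids, split$test_ids)
  check_ids(ids)
  if (!setequal(ids, split$provenance$image_id))
    fail("split provenance out of sync with id sets")
  invisible(split)
}

#' @export
print.dataset_split <- function(x, ...) {
  pos <- x$provenance[!x$provenance$negative, ]
  cat(sprintf(
    "<dataset_split> train %d | val %d | test %d (positives %d/%d/%d, %d infused)\n",
    length(x$train_ids), length(x$val_ids), length(x$test_ids),
    sum(pos$subset == "train"), sum(pos$subset == "val"),
    sum(pos$subset == "test"), sum(x$provenance$infused)))
  invisible(x)
}

#' Split an image pool into training and validation sets
#'
#' Performs the 90/10 (by default) random split: the pool is shuffled with
#' a seeded RNG and the first `round_half_up(train_fraction * n)` ids go
#' to training, the remainder to validation. The train count is clamped to
#' `[1, n-1]` so both sets are nonempty for degenerate pools; the clamp
#' never triggers at the canonical 0.9 fraction for pools of 10 or more.
#' Fixed seed implies an identical split on every run and platform.
#'
#' @param pool character vector of image ids (positives), length >= 2.
#' @param train_fraction proportion reserved for training, in (0, 1).
#' @param seed integer seed for the shuffle.
#' @param source_tags optional named character vector mapping id ->
#'   source tag, recorded in provenance.
#' @return a `dataset_split` with empty `test_ids`.
#' @export
#' @examples
#' s <- base_split(sprintf("img%04d", 1:1665), seed = 7)
#' length(s$train_ids)  # 1499
#' length(s$val_ids)    # 166
base_split <- function(pool, train_fraction = 0.9, seed = 1,
                       source_tags = NULL) {
  check_ids(pool)
  n <- length(pool)
  if (n < 2) fail("pool must contain at least 2 ids to form both sets")
  if (train_fraction <= 0 || train_fraction >= 1)
    fail("train_fraction must be in (0, 1)")
  n_train <- min(max(round_half_up(train_fraction * n), 1L), n - 1L)
  shuffled <- with_seed(seed, sample(pool))
  train <- shuffled[seq_len(n_train)]
  val <- shuffled[-seq_len(n_train)]
  split <- new_dataset_split(
    train, val,
    provenance = rbind(prov_rows(train, "train", source_tags),
                       prov_rows(val, "val", source_tags)))
  validate_dataset_split(split)
}

# pick k infusion ids: one seeded-random unused frame per cluster in
# ascending cluster-size order, cycling until k are chosen
select_infusion_ids <- function(infusion_pool, k, seed, clusters = NULL) {
  if (k == 0) return(character())
  if (is.null(clusters))
    return(with_seed(seed, sample(infusion_pool, k)))
  validate_cluster_set(clusters, ids = infusion_pool)
  cl <- clusters$clusters
  ord <- order(lengths(cl),
               vapply(cl, function(ids) min(sort(ids)), ""))
  cl <- cl[ord]
  with_seed(seed, {
    chosen <- character()
    remaining <- lapply(cl, identity)
    while (length(chosen) < k) {
      for (i in seq_along(remaining)) {
        if (length(chosen) >= k) break
        ids <- remaining[[i]]
        if (!length(ids)) next
        pick <- ids[sample.int(length(ids), 1)]
        chosen <- c(chosen, pick)
        remaining[[i]] <- setdiff(ids, pick)
      }
    }
    chosen
  })
}

#' Build an infusion split
#'
#' Plans one infusion experiment: `k = infusion_count(|base_pool|, p)`
#' camera-trap images are selected from the infusion pool, pooled with the
#' base (web-image) pool, and the combined pool is split
#' train/validation — so both the training and validation sets contain a
#' share of infusion images, reproducing the published split arithmetic
#' (e.g. rhino at 5%: 1665 + 83 = 1748, splitting into 1573 train and
#' 175 validation).
#'
#' When `clusters` is given (a [cluster_events()] partition of the
#' infusion pool), selection maximizes variability: clusters are visited
#' in ascending size order and one seeded-random unused frame is taken
#' per cluster, cycling until `k` frames are chosen. Without clusters the
#' selection is plain seeded-random.
#'
#' @param base_pool character ids of the base pool.
#' @param infusion_pool character ids of the camera-trap pool, disjoint
#'   from `base_pool`.
#' @param p infusion proportion (see [infusion_count()]).
#' @param train_fraction,seed passed to the combined-pool [base_split()].
#' @param infusion_seed seed for the infusion-frame selection; defaults
#'   to a stage seed derived from `seed`.
#' @param clusters optional `cluster_set` partitioning `infusion_pool`.
#' @param source_tags optional named id -> source tag vector.
#' @return a `dataset_split`; provenance marks the infused ids.
#' @export
build_infusion_split <- function(base_pool, infusion_pool, p,
                                 train_fraction = 0.9, seed = 1,
                                 infusion_seed = derive_seed(seed, "infusion"),
                                 clusters = NULL, source_tags = NULL) {
  check_ids(base_pool); check_ids(infusion_pool)
  if (length(intersect(base_pool, infusion_pool)))
    fail("base_pool and infusion_pool must be disjoint")
  k <- infusion_count(length(base_pool), p)
  if (length(infusion_pool) < k)
    fail("infusion_pool has %d ids but %d are required at p = %g",
         length(infusion_pool), k, p)
  infused <- select_infusion_ids(infusion_pool, k, infusion_seed, clusters)
  split <- base_split(c(base_pool, infused), train_fraction, seed,
                      source_tags)
  split$provenance$infused <- split$provenance$image_id %in% infused
  validate_dataset_split(split)
}

#' Supplement a split with explicit negative samples
#'
#' Appends seeded-random negative samples (images with no target object)
#' to the training and test sets: negatives teach the detector to reject
#' background and non-target species, and test-set negatives prevent a
#' biased view of false positives. Negatives are appended after the split
#' arithmetic — published split sizes count positives only — and no
#' negative is assigned to more than one subset.
#'
#' @param split a `dataset_split`.
#' @param negatives character ids of available negative samples, disjoint
#'   from the split's ids.
#' @param n_train,n_test how many negatives to append to train and test;
#'   defaults 800 and 200.
#' @param seed integer seed.
#' @param source_tags optional named id -> source tag vector.
#' @return the augmented `dataset_split`.
#' @export
supplement_negatives <- function(split, negatives, n_train = 800,
                                 n_test = 200, seed = 1,
                                 source_tags = NULL) {
  validate_dataset_split(split)
  check_ids(negatives, "negative image_id")
  used <- c(split$train_ids, split$val_ids, split$test_ids)
  if (length(intersect(negatives, used)))
    fail("negatives overlap the split's existing ids")
  need <- n_train + n_test
  if (length(negatives) < need)
    fail("need %d negatives (%d train + %d test) but only %d supplied",
         need, n_train, n_test, length(negatives))
  picked <- if (need) with_seed(seed, sample(negatives, need))
            else character()
  neg_train <- picked[seq_len(n_train)]
  neg_test <- picked[seq_len(n_test) + n_train]
  split$train_ids <- c(split$train_ids, neg_train)
  split$test_ids <- c(split$test_ids, neg_test)
  split$provenance <- rbind(
    split$provenance,
    prov_rows(neg_train, "train", source_tags, negative = TRUE),
    prov_rows(neg_test, "test", source_tags, negative = TRUE))
  validate_dataset_split(split)
}

#' Write a dataset split as CSV
#'
#' Emits `image_id,subset,source_tag,infused,negative` rows in a fixed
#' order (train, val, test) so files are byte-identical across runs with
#' the same seed.
#'
#' @param split a `dataset_split`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_split_csv <- function(split, path) {
  validate_dataset_split(split)
  p <- split$provenance
  p <- p[order(match(p$subset, c("train", "val", "test")),
               match(p$image_id, c(split$train_ids, split$val_ids,
                                   split$test_ids))), ]
  utils::write.csv(p, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Summarize split sizes for audit
#'
#' @param split a `dataset_split`.
#' @return list of counts: totals, positives, negatives and infused ids
#'   per subset.
#' @export
split_summary <- function(split) {
  validate_dataset_split(split)
  p <- split$provenance
  count <- function(subset, what) sum(p$subset == subset & what)
  list(
    train = length(split$train_ids),
    val = length(split$val_ids),
    test = length(split$test_ids),
    train_positives = count("train", !p$negative),
    val_positives = count("val", !p$negative),
    test_positives = count("test", !p$negative),
    train_negatives = count("train", p$negative),
    test_negatives = count("test", p$negative),
    infused = sum(p$infused),
    infused_train = count("train", p$infused),
    infused_val = count("val", p$infused))
}
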