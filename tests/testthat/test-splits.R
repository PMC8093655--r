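ids <- function(prefix, n) sprintf("%s%05d", prefix, seq_len(n))

test_that("infusion counts follow round-half-up of p * n_base", {
  expect_identical(infusion_count(1665, 0.05), 83L)
  expect_identical(infusion_count(472, 0.20), 94L)
  expect_identical(infusion_count(100, 0.10), 10L)
  # monotone in both arguments
  for (p in c(0.05, 0.1, 0.15, 0.2)) {
    k <- vapply(c(100, 472, 606, 1665), infusion_count, 0L, p = p)
    expect_true(all(diff(k) >= 0))
  }
  for (n in c(100, 472, 606, 1665)) {
    k <- vapply(c(0.05, 0.1, 0.15, 0.2), infusion_count, 0L, n_base = n)
    expect_true(all(diff(k) >= 0))
  }
  expect_error(infusion_count(100, 0), "p must be")
})

test_that("base split sizes use round-half-up and sets partition the pool", {
  cases <- list(c(1665, 1499, 166), c(472, 425, 47), c(10, 9, 1),
                c(606, 545, 61))
  for (case in cases) {
    pool <- ids("img", case[1])
    s <- base_split(pool, seed = 11)
    expect_length(s$train_ids, case[2])
    expect_length(s$val_ids, case[3])
    expect_length(intersect(s$train_ids, s$val_ids), 0)
    expect_setequal(c(s$train_ids, s$val_ids), pool)
  }
  expect_error(base_split("one"), "at least 2")
})

test_that("base split is deterministic per seed and varies across seeds", {
  pool <- ids("p", 200)
  expect_identical(base_split(pool, seed = 9)$train_ids,
                   base_split(pool, seed = 9)$train_ids)
  expect_false(identical(base_split(pool, seed = 9)$train_ids,
                         base_split(pool, seed = 10)$train_ids))
})

test_that("infusion split pools infusion images before splitting", {
  base <- ids("fin", 1665)
  pool <- ids("wcs", 333)
  s <- build_infusion_split(base, pool, 0.05, seed = 3)
  expect_length(s$train_ids, 1573)
  expect_length(s$val_ids, 175)
  expect_identical(sum(s$provenance$infused), 83L)
  # infused ids land in both train and validation shares
  infused <- s$provenance$image_id[s$provenance$infused]
  expect_true(all(infused %in% pool))
  expect_setequal(c(s$train_ids, s$val_ids), c(base, infused))

  s2 <- build_infusion_split(ids("f", 472), ids("w", 582), 0.10, seed = 3)
  expect_length(s2$train_ids, 467)
  expect_length(s2$val_ids, 52)
})

test_that("a vanishing infusion percent reduces to the base split", {
  base <- ids("b", 50)
  s <- build_infusion_split(base, ids("w", 20), 0.001, seed = 5)
  expect_identical(sum(s$provenance$infused), 0L)
  b <- base_split(base, seed = 5)
  expect_setequal(c(s$train_ids, s$val_ids), base)
  expect_length(s$train_ids, length(b$train_ids))
})

test_that("too-small infusion pool errors with the required count", {
  expect_error(build_infusion_split(ids("b", 1000), ids("w", 10), 0.05),
               "50")
})

test_that("cluster-guided selection takes one frame per cluster, small first", {
  base <- ids("b", 100)  # 10% -> k = 10
  pool <- c(sprintf("c1_%02d", 1:8), sprintf("c2_%02d", 1:3),
            sprintf("c3_%02d", 1:2), "c4_01")
  cs <- structure(list(clusters = list(
    sprintf("c1_%02d", 1:8), sprintf("c2_%02d", 1:3),
    sprintf("c3_%02d", 1:2), "c4_01"), threshold = 0.4),
    class = "cluster_set")
  s <- build_infusion_split(base, pool, 0.10, seed = 2, clusters = cs)
  infused <- s$provenance$image_id[s$provenance$infused]
  expect_length(infused, 10)
  # every cluster contributes before any contributes a third frame:
  # sizes 1,2,3,8 -> after round one (4 picks) and round two (3 picks),
  # the remaining 3 picks come from clusters 1 and 2
  counts <- table(substr(infused, 1, 2))
  expect_identical(as.integer(counts[c("c4", "c3")]), c(1L, 2L))
  expect_identical(as.integer(counts["c2"]), 3L)
  expect_identical(as.integer(counts["c1"]), 4L)
})

test_that("negative supplementation appends without touching positives", {
  s <- base_split(ids("pos", 100), seed = 1)
  negs <- ids("neg", 60)
  s2 <- supplement_negatives(s, negs, n_train = 40, n_test = 10, seed = 2)
  expect_length(s2$train_ids, 90 + 40)
  expect_length(s2$val_ids, 10)
  expect_length(s2$test_ids, 10)
  expect_identical(s2$train_ids[1:90], s$train_ids)
  # no negative assigned twice across train and test, over seeds
  for (seed in 1:25) {
    sx <- supplement_negatives(s, negs, 40, 10, seed = seed)
    neg_train <- intersect(sx$train_ids, negs)
    expect_length(intersect(neg_train, sx$test_ids), 0)
    expect_length(neg_train, 40)
  }
  # counts in the audit summary refer to positives vs negatives
  smry <- split_summary(s2)
  expect_identical(smry$train_positives, 90L)
  expect_identical(smry$train_negatives, 40L)
  expect_identical(smry$test_negatives, 10L)
  # zero-spec leaves the split unchanged
  s3 <- supplement_negatives(s, negs, 0, 0, seed = 1)
  expect_identical(s3$train_ids, s$train_ids)
  expect_identical(s3$test_ids, character(0))
  # shortfall errors
  expect_error(supplement_negatives(s, negs, 800, 200, 1), "800")
})

test_that("split CSV files are byte-identical across runs with one seed", {
  dir <- withr::local_tempdir()
  s <- supplement_negatives(
    build_infusion_split(ids("b", 120), ids("w", 40), 0.1, seed = 4),
    ids("n", 30), 20, 5, seed = 4)
  f1 <- file.path(dir, "a.csv"); f2 <- file.path(dir, "b.csv")
  write_split_csv(s, f1)
  write_split_csv(supplement_negatives(
    build_infusion_split(ids("b", 120), ids("w", 40), 0.1, seed = 4),
    ids("n", 30), 20, 5, seed = 4), f2)
  expect_identical(readLines(f1), readLines(f2))
})
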