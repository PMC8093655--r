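# Frozen reference values for the deterministic 64x64 sine pattern were
# computed with an independent SSIM implementation (uniform 7x7 window,
# unbiased covariance, L = 255) and agree with this one to 1e-12.
REF_SSIM_SINE_SHIFT3 <- 0.736550901003
REF_SSIM_INVERTED <- -0.685883114111

test_that("ssim matches independent reference values on frozen patterns", {
  x <- sine_pattern()
  expect_equal(ssim(x, sine_pattern(3)), REF_SSIM_SINE_SHIFT3,
               tolerance = 1e-9)
  expect_equal(ssim(x, 255 - x), REF_SSIM_INVERTED, tolerance = 1e-9)
  expect_lt(ssim(x, 255 - x), 0.4)  # inverted image is a distinct scene
})

test_that("self-similarity is exactly 1 and ssim is symmetric", {
  for (seed in 1:5) {
    set.seed(seed)
    a <- matrix(runif(48 * 48, 0, 255), 48, 48)
    b <- matrix(runif(48 * 48, 0, 255), 48, 48)
    expect_identical(ssim(a, a), 1)
    expect_identical(ssim(a, b), ssim(b, a))
  }
})

test_that("burst frames score above 0.4, independent scenes below", {
  sc1 <- generate_scene(301)
  sc2 <- generate_scene(302)
  frames <- generate_burst(sc1, n_frames = 3, seed = 7)
  for (i in 1:2) for (j in (i + 1):3)
    expect_gt(ssim(frames[[i]]$image, frames[[j]]$image), 0.4)
  expect_lt(ssim(sc1$image, sc2$image), 0.4)
  for (f in frames) expect_lt(ssim(f$image, sc2$image), 0.4)
})

test_that("pairwise matrix is symmetric, unit-diagonal, oracle-consistent", {
  dir <- withr::local_tempdir()
  sc <- generate_scene(310, width = 96, height = 96)
  frames <- generate_burst(sc, n_frames = 3, seed = 1)
  other <- generate_scene(311, width = 96, height = 96)
  for (s in c(frames, list(other))) write_scene(s, dir)
  ids <- c(vapply(frames, `[[`, "", "image_id"), other$image_id)
  paths <- setNames(file.path(dir, paste0(ids, ".png")), ids)

  m <- ssim_matrix(paths)
  expect_identical(diag(m), setNames(rep(1, 4), ids))
  expect_identical(m, t(m))
  # matrix entries equal brute-force per-pair ssim on the same files
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(m[i, j], ssim(paths[[i]], paths[[j]]), tolerance = 1e-12)
  # burst block above the clustering threshold, cross pairs below
  expect_true(all(m[1:3, 1:3] >= 0.4))
  expect_true(all(m[1:3, 4] < 0.4))

  # two identical files: all entries exactly 1
  p2 <- setNames(rep(paths[1], 2), c("copy_a", "copy_b"))
  expect_identical(unname(ssim_matrix(p2)), matrix(1, 2, 2))

  # single image: 1x1 unit matrix
  expect_identical(unname(ssim_matrix(paths[1])), matrix(1, 1, 1))

  # CSV cache round-trip preserves scores to write precision
  csv <- file.path(dir, "m.csv")
  write_similarity_csv(m, csv)
  expect_equal(read_similarity_csv(csv), m, tolerance = 1e-6)
})

test_that("dedup removes nothing below threshold, one survivor per clique", {
  m <- random_similarity(6, 1) * 0.5  # all off-diagonal < 0.8
  diag(m) <- 1
  dd <- dedup(m, 0.8, seed = 1)
  expect_identical(dd$removed, character(0))
  expect_setequal(dd$kept, rownames(m))

  m3 <- matrix(0.95, 3, 3); diag(m3) <- 1
  dimnames(m3) <- list(c("a", "b", "c"), c("a", "b", "c"))
  dd3 <- dedup(m3, 0.8, seed = 5)
  expect_length(dd3$kept, 1)
  expect_length(dd3$removed, 2)
  expect_setequal(c(dd3$kept, dd3$removed), c("a", "b", "c"))
})

test_that("dedup keeps one representative per component and is idempotent", {
  for (seed in 1:500) {
    n <- (seed %% 9) + 3
    m <- random_similarity(n, seed)
    dd <- dedup(m, threshold = 0.8, seed = seed)
    expect_setequal(c(dd$kept, dd$removed), rownames(m))
    expect_length(intersect(dd$kept, dd$removed), 0)
    comps <- oracle_components(m, 0.8, strict = TRUE)
    expect_length(dd$kept, length(comps))
    for (comp in comps)
      expect_length(intersect(dd$kept, comp), 1)
    # idempotence on the kept subset
    dd2 <- dedup(m[dd$kept, dd$kept, drop = FALSE], 0.8, seed = seed + 1)
    expect_identical(dd2$removed, character(0))
  }
})

test_that("clusters equal brute-force reachability on random matrices", {
  for (seed in 1:500) {
    n <- (seed %% 11) + 2  # up to n = 12
    m <- random_similarity(n, 10000 + seed)
    t <- runif(1, 0.2, 0.8)
    cs <- cluster_events(m, t)
    oracle <- oracle_components(m, t, strict = FALSE)
    expect_length(cs$clusters, length(oracle))
    key <- function(g) paste(sort(g), collapse = "|")
    expect_setequal(vapply(cs$clusters, key, ""),
                    vapply(oracle, key, ""))
  }
})

test_that("cluster count grows and dedup removals shrink with threshold", {
  for (seed in 1:20) {
    m <- random_similarity(10, 500 + seed)
    ts <- seq(0.1, 0.9, 0.1)
    n_clusters <- vapply(ts, function(t) length(cluster_events(m, t)$clusters), 0L)
    n_removed <- vapply(ts, function(t) length(dedup(m, t, 1)$removed), 0L)
    expect_true(all(diff(n_clusters) >= 0))
    expect_true(all(diff(n_removed) <= 0))
  }
})

test_that("representative selection is deterministic, uniform, one per cluster", {
  cs <- structure(list(clusters = list(c("a", "b", "c"), "d"),
                       threshold = 0.4), class = "cluster_set")
  expect_identical(select_representatives(cs, 42),
                   select_representatives(cs, 42))
  picks <- vapply(1:1000, function(s) select_representatives(cs, s)[1], "")
  freq <- table(factor(picks, levels = c("a", "b", "c"))) / 1000
  sd5 <- 5 * sqrt((1 / 3) * (2 / 3) / 1000)
  expect_true(all(abs(freq - 1 / 3) < sd5))
  expect_true(all(vapply(1:50, function(s)
    select_representatives(cs, s)[2] == "d", TRUE)))

  # all singletons: identity selection
  singles <- structure(list(clusters = list("x", "y", "z"),
                            threshold = 0.4), class = "cluster_set")
  expect_identical(select_representatives(singles, 1), c("x", "y", "z"))
})
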