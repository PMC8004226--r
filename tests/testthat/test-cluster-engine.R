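test_that("ward clustering splits the obvious gap and honours k bounds", {
  x <- matrix(c(0, 1, 10), dimnames = list(c("a", "b", "c"), NULL))
  d <- as.matrix(dist(x))
  cl <- ward_cluster(d, 2)
  lv <- setNames(cl$labels$cluster, cl$labels$compound_id)
  expect_equal(lv[["a"]], lv[["b"]])
  expect_false(lv[["a"]] == lv[["c"]])

  expect_equal(dplyr::n_distinct(ward_cluster(d, 3)$labels$cluster), 3)
  expect_equal(dplyr::n_distinct(ward_cluster(d, 1)$labels$cluster), 1)
  expect_error(ward_cluster(d, 4), "between 1 and")
  expect_true(all(diff(cl$height) >= -1e-12))
})

test_that("ward at k then k-1 only merges clusters, never splits them", {
  b <- make_blobs(6, sep = 4, seed = 21)
  d <- as.matrix(dist(b$x))
  for (k in 4:2) {
    hi <- ward_cluster(d, k)$labels
    lo <- ward_cluster(d, k - 1)$labels
    pairs <- dplyr::left_join(hi, lo, by = "compound_id",
                              suffix = c("_hi", "_lo"))
    # each fine cluster maps into exactly one coarse cluster
    split_count <- pairs |>
      dplyr::distinct(.data$cluster_hi, .data$cluster_lo) |>
      dplyr::count(.data$cluster_hi)
    expect_true(all(split_count$n == 1))
  }
})

test_that("ward k=2 equals the exhaustive minimum-variance bipartition on small instances", {
  for (seed in 1:5) {
    b <- make_blobs(4, sep = 5, seed = seed)
    d <- as.matrix(dist(b$x))
    got <- ward_cluster(d, 2)$labels
    lv <- setNames(got$cluster, got$compound_id)[rownames(b$x)]
    best <- oracle_best_bipartition(b$x)
    expect_equal(oracle_wss(b$x, unname(lv)), best$objective,
                 tolerance = 1e-9)
  }
})

test_that("kmeans recovers separated blobs and degenerates sensibly", {
  b <- make_blobs(20, sep = 10, seed = 3)
  km <- kmeans_cluster(b$x, 2, seed = 11)
  expect_equal(partition_agreement(
    km, tibble::tibble(compound_id = rownames(b$x), cluster = b$truth)), 1)

  km1 <- kmeans_cluster(b$x, 1, seed = 1)
  expect_equal(km1$wss, sum(sweep(b$x, 2, colMeans(b$x))^2),
               tolerance = 1e-9)

  dup <- matrix(1, nrow = 4, ncol = 2,
                dimnames = list(letters[1:4], NULL))
  expect_equal(kmeans_cluster(dup, 2, seed = 1)$wss, 0)
  expect_error(kmeans_cluster(b$x, 0, seed = 1), "positive")
})

test_that("kmeans is reproducible given a seed", {
  b <- make_blobs(10, sep = 2, seed = 8)
  k1 <- kmeans_cluster(b$x, 3, seed = 42)
  k2 <- kmeans_cluster(b$x, 3, seed = 42)
  expect_equal(k1$labels, k2$labels)
  expect_equal(k1$wss, k2$wss)
})

test_that("silhouette matches the brute-force formula and its conventions", {
  x <- matrix(c(0, 0.1, 5, 5.1), dimnames = list(letters[1:4], NULL))
  d <- as.matrix(dist(x))
  lab <- c(a = 1, b = 1, c = 2, d = 2)
  sil <- silhouette_scores(d, lab)
  expect_equal(sil$silhouette, oracle_silhouette(d, lab), tolerance = 1e-9)
  expect_equal(attr(sil, "silhouette_mean"), mean(sil$silhouette))

  # zero intra-cluster distances, positive inter: perfect separation
  d0 <- matrix(c(0, 0, 1, 1,
                 0, 0, 1, 1,
                 1, 1, 0, 0,
                 1, 1, 0, 0), 4, 4,
               dimnames = list(letters[1:4], letters[1:4]))
  expect_equal(attr(silhouette_scores(d0, lab), "silhouette_mean"), 1)

  # singleton contributes 0
  lab3 <- c(a = 1, b = 1, c = 2, d = 3)
  s3 <- silhouette_scores(d, lab3)
  expect_equal(s3$silhouette[3], 0)
  expect_equal(s3$silhouette[4], 0)
  expect_error(silhouette_scores(d, c(a = 1, b = 1, c = 1, d = 1)),
               "2 clusters")
})

test_that("silhouette agrees with the cluster package on a random instance", {
  skip_if_not_installed("cluster")
  b <- make_blobs(8, sep = 2, seed = 17)
  d <- as.matrix(dist(b$x))
  lab <- setNames(b$truth, rownames(b$x))
  ours <- silhouette_scores(d, lab)$silhouette
  ref <- cluster::silhouette(unname(lab), dmatrix = d)[, "sil_width"]
  expect_equal(ours, unname(ref), tolerance = 1e-9)
})

test_that("dunn index matches direct formula, brute force, and relabelling symmetry", {
  x <- matrix(c(0, 1, 10, 11), dimnames = list(letters[1:4], NULL))
  d <- as.matrix(dist(x))
  lab <- c(a = 1, b = 1, c = 2, d = 2)
  expect_equal(dunn_index(d, lab), 9)
  expect_equal(dunn_index(d, c(a = 2, b = 2, c = 1, d = 1)), 9)

  withr::with_seed(31, {
    y <- matrix(rnorm(16), 8, 2, dimnames = list(paste0("p", 1:8), NULL))
    dy <- as.matrix(dist(y))
    laby <- setNames(sample(1:2, 8, replace = TRUE), rownames(y))
    laby[1:2] <- 1:2  # both clusters non-empty
    expect_equal(dunn_index(dy, laby), oracle_dunn(dy, laby),
                 tolerance = 1e-12)
  })

  # all-zero diameters: sentinel
  d0 <- matrix(c(0, 0, 1, 1, 0, 0, 1, 1, 1, 1, 0, 0, 1, 1, 0, 0), 4, 4,
               dimnames = list(letters[1:4], letters[1:4]))
  expect_equal(dunn_index(d0, lab), Inf)
})

test_that("elbow picks the stated second-difference maximum with small-k ties", {
  expect_equal(elbow_k(data.frame(k = 1:4, wss = c(100, 40, 35, 33))), 2)
  expect_equal(elbow_k(data.frame(k = 1:4, wss = c(90, 80, 70, 60))), 2)
  expect_warning(
    k <- elbow_k(data.frame(k = 1:4, wss = c(50, 60, 20, 19))),
    "monotone")
  expect_equal(k, 3)  # (60-20)-(20-19) dominates despite the bump
  expect_error(elbow_k(data.frame(k = 1:2, wss = c(2, 1))), "at least 3")
})

test_that("wss decreases in k and validity indices are relabelling-invariant", {
  b <- make_blobs(10, sep = 4, seed = 2)
  d <- as.matrix(dist(b$x))
  curve <- wss_curve(d, 1:6)
  expect_true(all(diff(curve$wss) <= 1e-9))

  lab <- setNames(b$truth, rownames(b$x))
  perm <- setNames(3 - lab, names(lab))
  expect_equal(silhouette_mean(d, lab), silhouette_mean(d, perm))
  expect_equal(dunn_index(d, lab), dunn_index(d, perm))
  sil <- silhouette_scores(d, lab)
  expect_true(all(sil$silhouette >= -1 & sil$silhouette <= 1))
  expect_gte(dunn_index(d, lab), 0)
})
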