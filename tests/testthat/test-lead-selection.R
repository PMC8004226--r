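test_that("pca explains colinear data with one component and reconstructs exactly", {
  x <- tibble::tibble(compound_id = sprintf("p%d", 1:5),
                      a = 1:5, b = 2 * (1:5))
  p <- pca_descriptors(x, n_components = 2)
  expect_equal(p$explained_variance[1], 1, tolerance = 1e-9)

  withr::with_seed(4, {
    y <- tibble::tibble(compound_id = sprintf("q%d", 1:10),
                        a = rnorm(10), b = rnorm(10), c = rnorm(10))
  })
  p2 <- pca_descriptors(y, n_components = 3)
  # orthonormal loadings
  expect_equal(crossprod(p2$loadings), diag(3), tolerance = 1e-9,
               ignore_attr = TRUE)
  # full set of scores reconstructs the centered data
  ym <- as.matrix(y[, setdiff(names(y), "compound_id")])
  centered <- scale(ym, center = TRUE, scale = FALSE)
  sc <- as.matrix(p2$scores[, -1])
  expect_equal(sc %*% t(p2$loadings), unclass(centered),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("pca variances equal the covariance eigenvalues on random tables", {
  withr::with_seed(9, {
    tbl <- tibble::as_tibble(matrix(rnorm(50), 10, 5,
                                    dimnames = list(NULL, letters[1:5])))
  })
  tbl$compound_id <- sprintf("r%02d", 1:10)
  p <- pca_descriptors(tbl, n_components = 5)
  ev <- eigen(stats::cov(as.matrix(tbl[letters[1:5]])))$values
  expect_equal(p$all_variances, ev, tolerance = 1e-9)
  expect_warning(pca_descriptors(tbl, n_components = 9), "truncated")
})

test_that("isotropic 2-D data splits variance roughly evenly", {
  withr::with_seed(123, {
    tbl <- tibble::tibble(compound_id = as.character(1:500),
                          x = rnorm(500), y = rnorm(500))
  })
  p <- pca_descriptors(tbl, n_components = 2)
  expect_true(all(abs(p$explained_variance - 0.5) < 0.05))
})

test_that("lead cluster selection recovers a planted blob and reports agreement", {
  b <- make_blobs(10, dim = 3, sep = 8, seed = 6)
  tbl <- tibble::as_tibble(b$x) |>
    dplyr::mutate(compound_id = rownames(b$x), .before = 1)
  anchors <- rownames(b$x)[b$truth == 1][1:3]
  sel <- select_lead_cluster(tbl, k = 2, anchor_ids = anchors, seed = 2)
  expect_setequal(sel$compound_id, rownames(b$x)[b$truth == 1])
  expect_equal(attr(sel, "agreement"), 1)

  expect_warning(all_in <- select_lead_cluster(tbl, k = 1,
                                               anchor_ids = anchors),
                 "k = 1")
  expect_equal(nrow(all_in), 20)
  expect_error(select_lead_cluster(tbl, k = 2, anchor_ids = "nope",
                                   seed = 2), "absent")
})

test_that("evenly split anchors demand an explicit choice", {
  b <- make_blobs(10, sep = 8, seed = 6)
  tbl <- tibble::as_tibble(b$x) |>
    dplyr::mutate(compound_id = rownames(b$x), .before = 1)
  anchors <- c(rownames(b$x)[b$truth == 1][1], rownames(b$x)[b$truth == 2][1])
  expect_error(select_lead_cluster(tbl, k = 2, anchor_ids = anchors,
                                   seed = 2), "evenly")
})

test_that("lead selection is invariant to row order", {
  b <- make_blobs(8, sep = 6, seed = 14)
  tbl <- tibble::as_tibble(b$x) |>
    dplyr::mutate(compound_id = rownames(b$x), .before = 1)
  anchors <- rownames(b$x)[b$truth == 2][1:2]
  s1 <- select_lead_cluster(tbl, k = 2, anchor_ids = anchors, seed = 5)
  s2 <- select_lead_cluster(tbl[sample(nrow(tbl)), ], k = 2,
                            anchor_ids = anchors, seed = 5)
  expect_setequal(s1$compound_id, s2$compound_id)
})

test_that("the printed lead table fixture reproduces its own cluster-one membership", {
  desc <- read_descriptor_table(fixture_path(
    "table1_lead_descriptors_synthetic.csv"))
  leads <- utils::read.csv(fixture_path("table1_leads.csv"))
  sel <- select_lead_cluster(desc, k = 2, anchor_ids = leads$compound_id,
                             seed = 1)
  expect_setequal(sel$compound_id, leads$compound_id)
})

test_that("cluster affinity equals the per-point silhouette by definition", {
  b <- make_blobs(6, sep = 9, seed = 10)
  tbl <- tibble::as_tibble(b$x) |>
    dplyr::mutate(compound_id = rownames(b$x), .before = 1)
  lab <- tibble::tibble(compound_id = rownames(b$x), cluster = b$truth)
  aff <- cluster_affinity(tbl, lab, standardize = FALSE)
  sil <- silhouette_scores(as.matrix(dist(b$x)), lab)
  expect_equal(aff$affinity, sil$silhouette, tolerance = 1e-12)
  expect_true(all(aff$affinity > 0.8))  # well-separated blobs sit tight
})
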