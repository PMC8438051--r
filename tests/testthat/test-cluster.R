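test_that("adjusted Rand index matches its contingency-table definition", {
  expect_equal(ari(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(ari(c(0, 0, 1, 1), c(1, 1, 0, 0)), 1)     # relabeling invariance
  expect_equal(ari(c(0, 0, 1, 1), c(0, 1, 0, 1)), -0.5)  # contingency formula
  set.seed(41)
  for (i in 1:20) {
    a <- sample(0:3, 30, replace = TRUE)
    b <- sample(0:2, 30, replace = TRUE)
    expect_equal(ari(a, b), ari_oracle(a, b), tolerance = 1e-12)
  }
  expect_error(ari(1:3, 1:4), "length")
})

test_that("ari agrees with an established implementation", {
  skip_if_not_installed("mclust")
  set.seed(42)
  for (i in 1:10) {
    a <- sample(1:5, 50, replace = TRUE)
    b <- sample(1:4, 50, replace = TRUE)
    expect_equal(ari(a, b), mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
})

test_that("community detection recovers well-separated blobs", {
  pts <- make_blobs(60, rbind(c(0, 0), c(6, 6)), sd = 0.3, seed = 43)
  cl <- suppressWarnings(cluster_cells(pts, k = 40, seed = 1))
  expect_equal(cl$n_clusters, 2L)
  expect_equal(ari(cl$labels, rep(1:2, each = 60)), 1)
  expect_equal(sort(unique(cl$labels)), 0:1)     # contiguous from 0
  # deterministic under the seed
  cl2 <- suppressWarnings(cluster_cells(pts, k = 40, seed = 1))
  expect_identical(cl$labels, cl2$labels)
  # invariant to point order up to relabeling
  perm <- sample(nrow(pts))
  cl3 <- suppressWarnings(cluster_cells(pts[perm, ], k = 40, seed = 1))
  expect_equal(ari(cl3$labels, cl$labels[perm]), 1)
})

test_that("identical points collapse to a single cluster", {
  pts <- matrix(1, 30, 2)
  cl <- suppressWarnings(cluster_cells(pts, k = 5, seed = 1))
  expect_equal(cl$n_clusters, 1L)
})

test_that("stability scan picks the smallest stable neighbourhood size", {
  pts <- make_blobs(50, rbind(c(0, 0), c(8, 0), c(0, 8)), sd = 0.3, seed = 44)
  scan <- suppressWarnings(stability_select_k(pts, c(30, 35, 40, 45), seed = 1))
  expect_equal(scan$chosen_k, 30L)               # all partitions identical
  expect_true(isSymmetric(scan$ari_matrix))
  expect_equal(diag(scan$ari_matrix), rep(1, 4), ignore_attr = TRUE)
  expect_true(all(scan$ari_matrix >= -1 & scan$ari_matrix <= 1))
})

test_that("structureless noise fails the stability threshold", {
  set.seed(45)
  pts <- matrix(runif(300), 150, 2)
  scan <- NULL
  msgs <- testthat::capture_warnings(
    scan <- stability_select_k(pts, c(8, 20, 40),
                               stability_threshold = 0.95, seed = 1))
  expect_true(any(grepl("no k reaches", msgs)))
  # with a strict threshold nothing qualifies: the scan falls back to max k
  expect_equal(scan$chosen_k, 40L)
})

test_that("reference annotation flags true matches and masks noise", {
  set.seed(46)
  n_genes <- 120
  lab <- rep(0:1, each = 25)
  base <- matrix(rnorm(50 * n_genes), 50, n_genes,
                 dimnames = list(NULL, paste0("g", 1:n_genes)))
  shift <- rnorm(n_genes, sd = 2)
  base[lab == 1, ] <- sweep(base[lab == 1, ], 2, shift, "+")
  # reference: one column equal to cluster 1's centered median profile;
  # columns sum to zero per gene so the reference centering is the identity
  med0 <- apply(base[lab == 0, ], 2, median)
  med1 <- apply(base[lab == 1, ], 2, median)
  centered1 <- med1 - (med0 + med1) / 2
  noise <- rnorm(n_genes)
  ref <- cbind(match1 = centered1, noise = noise,
               balance = -(centered1 + noise))
  rownames(ref) <- paste0("g", 1:n_genes)
  ann <- annotate_by_reference(lab, base, ref)
  hit <- ann[ann$cluster == 1 & ann$cell_type == "match1", ]
  expect_equal(hit$r, 1, tolerance = 1e-8)
  expect_true(hit$display)
  noise_rows <- ann[ann$cell_type == "noise", ]
  expect_true(all(!noise_rows$display))
  expect_true(all(ann$r >= -1 & ann$r <= 1))
  # Pearson correlation is invariant to a positive affine map of a column
  # (scaling all columns keeps the per-gene centering proportional)
  ann2 <- annotate_by_reference(lab, base, 3 * ref)
  expect_equal(ann2$r, ann$r, tolerance = 1e-12)
  expect_error(annotate_by_reference(lab, base[, 1, drop = FALSE],
                                     ref[1, , drop = FALSE]),
               "shared genes")
})
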