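test_that("knee filter separates planted cells from ambient barcodes", {
  p <- simulation_params(n_tumor_cells = 500, n_other_cells = 0,
                         n_empty_droplets = 4000, seed = 21)
  a <- simulate_atlas(p)
  kn <- knee_filter_cells(a$counts)
  expect_lt(abs(sum(kn$mask) - 500) / 500, 0.05)
  # the retained set is definitionally {totals > cutoff}
  totals <- Matrix::rowSums(a$counts$counts)
  expect_identical(kn$mask, totals > kn$cutoff)
})

test_that("degenerate library-size distributions fall back with a warning", {
  cm <- counts_matrix(matrix(50L, 20, 2))
  expect_warning(kn <- knee_filter_cells(cm), "identical|unimodal")
  expect_true(all(kn$mask))
  expect_identical(kn$cutoff, -Inf)
})

test_that("mitochondrial filter applies a strict 25% threshold", {
  cm <- counts_matrix(matrix(c(25, 75, 26, 74, 0, 10), 3, 2, byrow = TRUE),
                      gene_ids = c("MT-1", "G1"))
  expect_identical(mito_filter(cm), c(TRUE, FALSE, TRUE))
  no_mito <- counts_matrix(matrix(1L, 3, 2), gene_ids = c("A", "B"))
  expect_warning(m <- mito_filter(no_mito), "no mitochondrial")
  expect_true(all(m))
})

test_that("complexity filter flags concentrated libraries, spares uniform ones", {
  set.seed(11)
  m <- matrix(rpois(200 * 150, 10), 200, 150)
  m[1, ] <- 0; m[1, 1] <- 5000        # all counts in one gene
  cm <- counts_matrix(m)
  mask <- complexity_filter(cm)
  expect_false(mask[1])
  expect_gte(mean(mask[-1]), 0.99)
  # homogeneous Poisson cells: at least 99% retained
  hom <- counts_matrix(matrix(rpois(500 * 200, 8), 500, 200))
  expect_gte(mean(complexity_filter(hom)), 0.99)
  expect_warning(single <- complexity_filter(counts_matrix(matrix(5L, 1, 3))),
                 "skipped")
  expect_true(all(single))
})

test_that("gene filter applies detection and bimodal low-expression rules", {
  set.seed(12)
  # 60 genes detected in many cells, one gene in only 9 cells
  m <- matrix(rpois(100 * 60, 5), 100, 60)
  m[, 60] <- 0; m[1:9, 60] <- 1
  gf <- suppressWarnings(gene_filter(counts_matrix(m), min_cells = 10))
  expect_false(gf$detection_mask[60])
  expect_true(all(gf$detection_mask[1:59]))
  # identical totals: fit degenerates, detection rule only
  flat <- counts_matrix(matrix(3L, 50, 20))
  expect_warning(gf2 <- gene_filter(flat), "bimodal fit failed")
  expect_true(all(gf2$mask))
  expect_true(is.na(gf2$cutoff_log10))
})

test_that("bimodal histogram fit recovers planted mixture cutoffs", {
  set.seed(13)
  lt <- c(rnorm(300, 2, 0.1), rnorm(700, 5, 0.2))
  f <- fit_bimodal(lt)
  # low-expression rule: cutoff mu2 - 5 sd2 ~ 4 on the log scale
  expect_lt(abs((f$mu2 - 5 * f$sd2) - 4) / 4, 0.1)
  sds <- c(rnorm(400, 0.1, 0.01), rnorm(100, 1.0, 0.1))
  f2 <- fit_bimodal(sds)
  # variable-gene rule: threshold mu2 - 1.5 sd2 ~ 0.85
  expect_lt(abs((f2$mu2 - 1.5 * f2$sd2) - 0.85) / 0.85, 0.1)
  expect_null(fit_bimodal(rep(1, 100)))
})

test_that("median normalization is exact, idempotent, and guards zero totals", {
  m <- matrix(c(60, 40, 150, 50, 120, 180), 3, 2, byrow = TRUE)
  cm <- counts_matrix(m)                        # totals 100, 200, 300
  nm <- median_normalize(cm)
  expect_equal(nm$x[1, ], m[1, ] * 2, ignore_attr = TRUE)
  expect_equal(rowSums(nm$x), rep(200, 3), ignore_attr = TRUE)
  # idempotent
  nm2 <- median_normalize(nm)
  expect_equal(nm2$x, nm$x)
  # equal totals: identity
  eq <- counts_matrix(matrix(c(5, 5, 4, 6), 2, 2, byrow = TRUE))
  expect_equal(median_normalize(eq)$x, as.matrix(eq$counts), ignore_attr = TRUE)
  z <- counts_matrix(matrix(c(1, 0, 0, 0), 2, 2, byrow = TRUE))
  expect_error(median_normalize(z), "zero-total")
})

test_that("library size is fully regressed out of the principal components", {
  set.seed(14)
  n <- 120
  lib <- exp(rnorm(n, 7, 0.4))
  signal <- rnorm(n)
  x <- cbind(outer(lib, rep(1, 10)) * runif(10),     # libsize-driven block
             outer(signal, rnorm(10)) + matrix(rnorm(n * 10, sd = 0.1), n, 10))
  nm <- structure(list(x = x, library_sizes = lib, cell_ids = paste0("c", 1:n),
                       gene_ids = paste0("g", 1:20), median_libsize = 1),
                  class = "norm_matrix")
  pcs <- pca_libsize_regressed(nm, n_pcs = 5, seed = 1)
  for (j in seq_len(ncol(pcs$scores)))
    expect_lt(abs(cor(pcs$scores[, j], lib)), 1e-8)
  expect_true(all(diff(pcs$ev_ratio) <= 1e-12))
  # constant library size: regression reduces to centering
  nm$library_sizes <- rep(100, n)
  pcs2 <- pca_libsize_regressed(nm, n_pcs = 5, seed = 1)
  expect_equal(colMeans(pcs2$scores), rep(0, 5), tolerance = 1e-10, ignore_attr = TRUE)
  # seeded determinism
  pcs3 <- pca_libsize_regressed(nm, n_pcs = 5, seed = 1)
  expect_equal(pcs2$scores, pcs3$scores, tolerance = 1e-10)
})

test_that("component count selection honors knee and target-variance rules", {
  ratios <- 0.5 * 0.5^(0:9)
  sel <- select_n_pcs(ratios, target_fraction = 0.90)
  expect_equal(sel$n_target, 4)          # 0.5+0.25+0.125+0.0625 = 0.9375
  expect_lte(sel$n_pcs, 4)
  # uniform ratios: chord rule undefined, target rule takes over
  sel2 <- select_n_pcs(rep(0.1, 10))
  expect_true(is.na(sel2$knee))
  expect_equal(sel2$n_pcs, sel2$n_target)
  # single dominant component
  sel3 <- select_n_pcs(c(0.99, 0.005, 0.005))
  expect_equal(sel3$n_pcs, 1)
})

test_that("variable-gene selection thresholds at the upper SD mode", {
  set.seed(15)
  n <- 60
  sds <- c(abs(rnorm(150, 0.1, 0.01)), rnorm(50, 1.0, 0.1))
  x <- sapply(sds, function(s) rnorm(n, sd = s))
  nm <- structure(list(x = x, library_sizes = rep(1, n)), class = "norm_matrix")
  mask <- variable_genes(nm)
  thr <- attr(mask, "threshold")
  expect_lt(abs(thr - 0.85) / 0.85, 0.15)
  # the rule deliberately trims ~the bottom 7% of the upper component
  expect_gte(mean(mask[151:200]), 0.85)
  expect_lte(mean(mask[1:150]), 0.05)
  # constant gene never selected; degenerate SDs fall back with warning
  x2 <- cbind(x, 0)
  nm2 <- structure(list(x = x2, library_sizes = rep(1, n)), class = "norm_matrix")
  expect_false(tail(variable_genes(nm2), 1))
  flat <- structure(list(x = matrix(rep(rnorm(n), 20), n, 20)),
                    class = "norm_matrix")
  expect_warning(variable_genes(flat), "fallback|top-quartile|failed")
})

test_that("QC report masks reconcile by inclusion-exclusion", {
  p <- simulation_params(n_tumor_cells = 400, n_other_cells = 0,
                         n_empty_droplets = 2000, apoptotic_fraction = 0.05,
                         seed = 22)
  a <- simulate_atlas(p)
  qc <- suppressWarnings(qc_filter(a$counts))
  expect_identical(qc$retained, qc$pass_knee & qc$pass_complexity & qc$pass_mito)
  g <- glance(qc)
  # inclusion-exclusion audit of the retained count
  fail_any <- !qc$pass_knee | !qc$pass_complexity | !qc$pass_mito
  expect_equal(g$n_cells_retained, g$n_barcodes - sum(fail_any))
  # mask conjunction makes filter order irrelevant by construction
  expect_equal(sum(qc$retained),
               sum(qc$pass_mito & qc$pass_knee & qc$pass_complexity))
})
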