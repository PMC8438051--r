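bridged_blobs <- function(seed = 71) {
  set.seed(seed)
  rbind(matrix(rnorm(60, 0, 0.25), 30, 2),
        matrix(rnorm(60, 4, 0.25), 30, 2),
        c(2, 2))                               # single bridging cell
}

test_that("diffusion map splits bridged blobs by the first component's sign", {
  pts <- bridged_blobs()
  dm <- diffusion_map(pts, k = 8, ka = 4, L_max = 5)
  expect_true(all(abs(dm$eigenvalues) < 1))
  s <- sign(dm$components[, 1])
  expect_true(all(s[1:30] == s[1]))
  expect_true(all(s[31:60] == -s[1]))
  # eigenvalue list is invariant to the ordering of cells
  perm <- sample(nrow(pts))
  dm2 <- diffusion_map(pts[perm, ], k = 8, ka = 4, L_max = 5)
  expect_equal(dm2$eigenvalues, dm$eigenvalues, tolerance = 1e-8)
})

test_that("disconnected graphs are rejected with component sizes", {
  pts <- rbind(matrix(rnorm(40, 0, 0.1), 20, 2),
               matrix(rnorm(40, 100, 0.1), 20, 2))
  expect_error(diffusion_map(pts, k = 5, ka = 3), "component sizes")
})

test_that("multi-scale distance matches its closed forms", {
  dm <- fake_dm(0.5, matrix(c(1, 0), 2, 1), L = 1)
  expect_equal(multiscale_distance(dm, 1, 1), 0)
  # single component, lambda 0.5, unit difference: 0.5/(1-0.5) = 1
  expect_equal(multiscale_distance(dm, 1, 2), 1.0, tolerance = 1e-12)
  # single-t mode, t = 1, difference 2: sqrt(0.25 * 4) = 1
  dm2 <- fake_dm(0.5, matrix(c(2, 0), 2, 1), L = 1)
  expect_equal(multiscale_distance(dm2, 1, 2, mode = "single-t", t = 1), 1.0)
  # random case against a literal sum-over-components oracle
  set.seed(72)
  lam <- sort(runif(4, 0.2, 0.9), decreasing = TRUE)
  comp <- matrix(rnorm(40), 10, 4)
  dm3 <- fake_dm(lam, comp, L = 4)
  for (t in c(1, 2, 5)) {
    d_oracle <- sqrt(sum(lam^(2 * t) * (comp[3, ] - comp[8, ])^2))
    expect_equal(multiscale_distance(dm3, 3, 8, mode = "single-t", t = t),
                 d_oracle, tolerance = 1e-12)
  }
  d_ms <- sqrt(sum((lam / (1 - lam))^2 * (comp[3, ] - comp[8, ])^2))
  expect_equal(multiscale_distance(dm3, 3, 8), d_ms, tolerance = 1e-12)
})

test_that("multi-scale distance is a metric on a small fixture", {
  pts <- bridged_blobs(seed = 73)[1:20, ]
  dm <- diffusion_map(pts, k = 6, ka = 3, L_max = 5)
  d <- multiscale_distance_matrix(dm)
  expect_equal(d, t(d), tolerance = 1e-12)
  expect_equal(unname(diag(d)), rep(0, 20))
  for (i in 1:20) for (j in 1:20) for (k in 1:20)
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
})

test_that("cells on a chain are ordered monotonically by the first component", {
  set.seed(74)
  pts <- cbind(seq(0, 10, length.out = 30), rnorm(30, sd = 0.05))
  dm <- diffusion_map(pts, k = 4, ka = 2, L_max = 3)
  e1 <- dm$components[, 1]
  rho <- cor(e1, seq_len(30), method = "spearman")
  expect_gt(abs(rho), 0.99)
})

test_that("PCHA reproduces exact vertices and the centroid for K = 1", {
  pts <- matrix(c(0, 0, 1, 0, 0, 1), 3, 2, byrow = TRUE)[rep(1:3, 20), ]
  fit <- pcha_fit(pts, K = 3, seed = 1)
  expect_gte(fit$explained_variance, 0.999)
  # archetypes coincide with the three distinct points
  err <- sapply(1:3, function(a)
    min(sqrt(rowSums(sweep(unique(pts), 2, fit$archetypes[a, ])^2))))
  expect_lt(max(err), 1e-3)
  # K = 1: the single archetype is the data centroid
  set.seed(75)
  cloud <- matrix(rnorm(200), 100, 2)
  f1 <- pcha_fit(cloud, K = 1, seed = 1, max_iter = 2000)
  expect_equal(as.numeric(f1$archetypes), colMeans(cloud), tolerance = 1e-2)
  # the objective trace never increases
  expect_true(all(diff(fit$objective) <= 1e-10))
  expect_true(all(diff(f1$objective) <= 1e-10))
  # convex-combination constraints
  expect_true(all(fit$S >= 0))
  expect_equal(colSums(fit$S), rep(1, nrow(pts)), tolerance = 1e-8)
  expect_true(all(fit$C >= 0))
  expect_equal(colSums(fit$C), rep(1, 3), tolerance = 1e-8)
})

test_that("noise-free corner-concentrated simplex data is recovered exactly", {
  s <- simulate_simplex(4, 500, noise_sd = 0, dim = 4,
                        dirichlet_alpha = 0.05, seed = 76)
  fit <- pcha_fit(s$points, K = 4, seed = 1)
  diam <- max(dist(s$vertices))
  err <- sapply(1:4, function(a)
    min(sqrt(rowSums(sweep(s$vertices, 2, fit$archetypes[a, ])^2))))
  expect_lt(max(err) / diam, 1e-3)
})

test_that("archetype-number selection finds the planted vertex count", {
  s <- simulate_simplex(3, 600, noise_sd = 0.01, dim = 3, seed = 77)
  sel <- select_n_archetypes(s$points, 2:6, seed = 1)
  expect_equal(sel$K, 3L)
  ev <- sel$curve$explained_variance
  expect_true(all(diff(ev) >= -1e-6))          # nested models
  # flat curve: two distinct points are explained perfectly by any K >= 2
  two <- matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE)[rep(1:2, 25), ]
  expect_warning(sel2 <- select_n_archetypes(two, 2:4, seed = 1), "flat")
  expect_equal(sel2$K, 2L)
  sel3 <- select_n_archetypes(s$points, 4, seed = 1)
  expect_equal(sel3$K, 4L)
})

test_that("archetype neighbourhoods partition cells with guarded radii", {
  set.seed(78)
  pts <- bridged_blobs(seed = 78)
  dm <- diffusion_map(pts, k = 8, ka = 4)
  fit <- pcha_fit(pts, K = 2, seed = 1)
  nb <- archetype_neighborhoods(dm, fit, pts)
  expect_equal(length(nb$anchor), 2)
  expect_true(all(nb$radius > 0))
  # anchors always belong to their own neighbourhood
  for (a in 1:2) expect_true(nb$anchor[a] %in% nb$members[[a]])
  # half-distance radii make neighbourhoods disjoint
  expect_length(intersect(nb$members[[1]], nb$members[[2]]), 0)
  # nearest-anchor assignment labels every cell exactly once
  expect_equal(nrow(nb$assignment), nrow(pts))
  expect_true(all(nb$assignment$nearest_archetype %in% 1:2))
})

test_that("earth mover's distance matches the sorted-matching oracle", {
  expect_equal(emd_score(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(emd_score(5, 9), 4)                     # point masses
  expect_equal(emd_score(c(0, 1), c(1, 2)), 1.0)
  set.seed(79)
  for (i in 1:100) {
    n <- sample(1:40, 1)
    a <- rnorm(n, sd = runif(1, 0.5, 2)); b <- rnorm(n, mean = runif(1, -1, 1))
    expect_equal(emd_score(a, b), emd_oracle(a, b), tolerance = 1e-10)
  }
  # unequal sizes against the common-refinement oracle
  for (i in 1:20) {
    a <- rnorm(sample(2:12, 1)); b <- rnorm(sample(2:12, 1))
    expect_equal(emd_score(a, b), emd_oracle(a, b), tolerance = 1e-10)
  }
  expect_error(emd_score(numeric(0), 1), "empty")
})

test_that("EMD marker scores isolate neighbourhood-exclusive genes", {
  set.seed(80)
  pts <- bridged_blobs(seed = 80)
  n <- nrow(pts)
  dm <- diffusion_map(pts, k = 8, ka = 4)
  fit <- pcha_fit(pts, K = 2, seed = 1)
  nb <- archetype_neighborhoods(dm, fit, pts)
  mem1 <- nb$members[[1]]
  expr <- cbind(exclusive = as.numeric(seq_len(n) %in% mem1),
                flat = rep(1, n),
                noise = rnorm(n, sd = 0.05))
  mk <- archetype_markers(expr, nb, n_resamples = 25, seed = 2)
  ex1 <- mk$emd[mk$archetype == 1 & mk$gene == "exclusive"]
  expect_equal(ex1, 1)                     # point mass 1 vs point mass 0
  expect_equal(mk$emd[mk$gene == "flat"], rep(0, 2))
  # the planted gene dominates the null gene for its archetype
  expect_gt(ex1, max(mk$emd[mk$archetype == 1 & mk$gene == "noise"]))
  mk2 <- archetype_markers(expr, nb, n_resamples = 25, seed = 2)
  expect_identical(mk$emd, mk2$emd)
})
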