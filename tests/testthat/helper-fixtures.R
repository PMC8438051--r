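# Shared fixtures and independent oracles used across test files.

# two (or more) Gaussian blobs in `dim` dimensions
make_blobs <- function(n_per, centers, sd = 0.3, dim = 2, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    matrix(rnorm(n_per * dim, sd = sd), n_per, dim) +
      matrix(centers[i, ], n_per, dim, byrow = TRUE)))
}

# brute-force adjusted Rand index straight from the contingency-table
# definition (independent of the package implementation)
ari_oracle <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) ifelse(x < 2, 0, choose(x, 2))
  s_ij <- sum(ch2(tab)); s_a <- sum(ch2(rowSums(tab))); s_b <- sum(ch2(colSums(tab)))
  n2 <- choose(length(a), 2)
  exp_idx <- s_a * s_b / n2
  (s_ij - exp_idx) / ((s_a + s_b) / 2 - exp_idx)
}

# sorted-matching oracle for the 1-D Wasserstein-1 distance; exact for
# equal sample sizes, and via replication to a common size otherwise
emd_oracle <- function(a, b) {
  if (length(a) != length(b)) {
    l <- vector_lcm(length(a), length(b))
    a <- rep(sort(a), each = l / length(a))
    b <- rep(sort(b), each = l / length(b))
  }
  mean(abs(sort(a) - sort(b)))
}
vector_lcm <- function(x, y) {
  g <- function(p, q) if (q == 0) p else g(q, p %% q)
  x * y / g(x, y)
}

# pseudo-determinant oracle: log10 of the product of the nonzero
# eigenvalues of stats::cov, over gene count
volume_oracle <- function(x, tol = 1e-10) {
  ev <- eigen(stats::cov(x), symmetric = TRUE, only.values = TRUE)$values
  keep <- ev > max(ev) * tol
  log10(prod(ev[keep])) / ncol(x)
}

# a tiny counts matrix with mitochondrial genes
tiny_counts <- function() {
  counts_matrix(matrix(c(1, 0, 2, 3), 2, 2, byrow = TRUE),
                cell_ids = c("c1", "c2"), gene_ids = c("A", "MT-ND1"))
}

# small fake diffusion map with known spectrum, for closed-form distance
# checks
fake_dm <- function(eigenvalues, components, L = length(eigenvalues)) {
  structure(list(eigenvalues = eigenvalues,
                 components = as.matrix(components), L = L,
                 k = NA, ka = NA),
            class = "diffusion_map")
}
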