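#' Diffusion map of a cell population
#'
#' Eigendecomposition of the cell-cell Markov matrix built from
#' adaptive-kernel affinities on the principal components of the
#' normalized (un-imputed) matrix. The decomposition goes through the
#' symmetric conjugate `D^(-1/2) A D^(-1/2)` (real spectrum guaranteed)
#' and eigenvectors are converted back to right eigenvectors of the
#' Markov matrix. The trivial unit eigenvalue is dropped; the embedding
#' dimension `L` is chosen at the largest eigengap among the top
#' eigenvalues, capped at `L_max`.
#'
#' @param pcs a `pc_space` or coordinate matrix (of un-imputed data).
#' @param k,ka adaptive-kernel parameters (defaults 27, 12).
#' @param L_max maximum embedding dimension (default 5).
#' @param n_eig eigenpairs computed before the gap is measured.
#' @return A `diffusion_map`: list with `eigenvalues` (descending,
#'   excluding the trivial one), `components` (cells x retained, unit
#'   norm), `L`, `k`, `ka`.
#' @export
diffusion_map <- function(pcs, k = 27L, ka = 12L, L_max = 5L, n_eig = 12L) {
  x <- if (inherits(pcs, "pc_space")) pcs$scores else as.matrix(pcs)
  n <- nrow(x)
  if (n < L_max + 2) abort("too few cells for the requested embedding",
                           class = "phenarch_error")
  aff <- adaptive_affinity(x, k = k, ka = ka)
  g <- igraph::graph_from_adjacency_matrix(aff$a > 0, mode = "undirected")
  comp <- igraph::components(g)
  if (comp$no > 1)
    abort(paste("affinity graph is disconnected; component sizes:",
                paste(comp$csize, collapse = ", ")),
          class = "phenarch_error")
  d <- Matrix::rowSums(aff$a)
  dhalf <- 1 / sqrt(d)
  ms <- Matrix::Diagonal(x = dhalf) %*% aff$a %*% Matrix::Diagonal(x = dhalf)
  e <- eigen(as.matrix(Matrix::forceSymmetric(ms)), symmetric = TRUE)
  # right eigenvectors of the Markov matrix: psi = D^{-1/2} phi
  n_keep <- min(n_eig + 1L, n)
  vals <- e$values[seq_len(n_keep)]
  vecs <- e$vectors[, seq_len(n_keep), drop = FALSE] * dhalf
  vecs <- sweep(vecs, 2, sqrt(colSums(vecs^2)), "/")   # unit-normalize
  vals <- vals[-1]; vecs <- vecs[, -1, drop = FALSE]   # drop trivial lambda = 1
  if (any(vals >= 1 - 1e-10))
    abort("multiple unit eigenvalues: graph effectively disconnected",
          class = "phenarch_error")
  gaps <- -diff(vals[seq_len(min(L_max, length(vals) - 1))])
  L <- if (length(gaps)) which.max(gaps) else 1L
  L <- min(max(L, 1L), L_max, length(vals))
  structure(list(eigenvalues = vals, components = vecs, L = L,
                 k = k, ka = ka),
            class = "diffusion_map")
}

#' @export
print.diffusion_map <- function(x, ...) {
  cat(sprintf("<diffusion_map> %d cells, L = %d, top eigenvalues: %s\n",
              nrow(x$components), x$L,
              paste(round(head(x$eigenvalues, 5), 4), collapse = ", ")))
  invisible(x)
}

# Embedding in which multi-scale (or single-t) diffusion distances are
# plain Euclidean distances: component l scaled by lambda_l/(1-lambda_l)
# (multiscale) or lambda_l^t (single-t).
diffusion_embedding <- function(dm, mode = c("multiscale", "single-t"), t = 3) {
  mode <- match.arg(mode)
  L <- dm$L
  lam <- dm$eigenvalues[seq_len(L)]
  if (any(lam >= 1))
    abort("retained component with eigenvalue 1", class = "phenarch_error")
  w <- if (mode == "multiscale") lam / (1 - lam) else lam^t
  sweep(dm$components[, seq_len(L), drop = FALSE], 2, w, "*")
}

#' Multi-scale diffusion distance between cells
#'
#' In multiscale mode (the default), `D(i,j)^2 = sum_l (lambda_l /
#' (1 - lambda_l))^2 (e_{l,i} - e_{l,j})^2`, which sums the single-t
#' distance over all diffusion times as a geometric series and so avoids
#' fixing `t`. Single-t mode implements
#' `D(i,j)^2 = sum_l lambda_l^(2t) (e_{l,i} - e_{l,j})^2`.
#'
#' @param dm a `diffusion_map`.
#' @param i,j cell indices (vectors allowed; recycled pairwise).
#' @param mode `"multiscale"` or `"single-t"`.
#' @param t diffusion time for single-t mode (default 3).
#' @return non-negative distance(s).
#' @export
multiscale_distance <- function(dm, i, j, mode = c("multiscale", "single-t"),
                                t = 3) {
  emb <- diffusion_embedding(dm, mode = mode, t = t)
  n <- nrow(emb)
  if (any(c(i, j) < 1) || any(c(i, j) > n))
    abort("cell index out of range", class = "phenarch_error")
  di <- emb[i, , drop = FALSE] - emb[j, , drop = FALSE]
  sqrt(rowSums(di^2))
}

#' Pairwise multi-scale diffusion distances
#'
#' @param dm a `diffusion_map`.
#' @param idx optional subset of cells (default all).
#' @inheritParams multiscale_distance
#' @return a dense symmetric distance matrix.
#' @export
multiscale_distance_matrix <- function(dm, idx = NULL,
                                       mode = c("multiscale", "single-t"),
                                       t = 3) {
  emb <- diffusion_embedding(dm, mode = mode, t = t)
  if (!is.null(idx)) emb <- emb[idx, , drop = FALSE]
  as.matrix(dist(emb))
}
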