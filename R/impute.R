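#' Adaptive-kernel affinity graph
#'
#' Builds a k-nearest-neighbour graph in PC space and converts distances
#' to affinities with an anisotropic (adaptive) Gaussian kernel: each cell
#' i uses the distance to its `ka`-th neighbour as its own scale, so
#' `affinity(i, j) = exp(-d(i, j)^2 / sigma_i^2)` over the k-NN edge set.
#' The diagonal is zero before symmetrization; the graph is symmetrized as
#' `(A + t(A)) / 2`.
#'
#' @param pcs a `pc_space`, or a plain matrix of per-cell coordinates.
#' @param k neighbours per cell (default 27).
#' @param ka index of the scale neighbour (default 12; `ka <= k`).
#' @param n_pcs coordinates used (first `n_pcs` columns; default all).
#' @return An `affinity_graph`: list with sparse symmetric `a`
#'   (affinities in \[0, 1\], zero diagonal), `k`, `ka`.
#' @export
adaptive_affinity <- function(pcs, k = 27L, ka = 12L, n_pcs = NULL) {
  x <- if (inherits(pcs, "pc_space")) pcs$scores else as.matrix(pcs)
  if (!is.null(n_pcs)) x <- x[, seq_len(min(n_pcs, ncol(x))), drop = FALSE]
  n <- nrow(x)
  if (!(ka <= k && k <= n - 1))
    abort("need ka <= k <= cells - 1", class = "phenarch_error")
  nn <- knn_search(x, k)
  sigma <- nn$distance[, ka]
  if (any(sigma == 0)) {
    warn("duplicate points give zero kernel scale: substituting smallest positive neighbour distance")
    for (i in which(sigma == 0)) {
      pos <- nn$distance[i, nn$distance[i, ] > 0]
      sigma[i] <- if (length(pos)) min(pos) else 1
    }
  }
  w <- exp(-(nn$distance / sigma)^2)
  a <- Matrix::sparseMatrix(i = rep(seq_len(n), k), j = as.vector(nn$index),
                            x = as.vector(w), dims = c(n, n))
  a <- (a + Matrix::t(a)) / 2
  structure(list(a = a, k = k, ka = ka), class = "affinity_graph")
}

#' Row-normalize an affinity graph to a Markov transition matrix
#'
#' @param aff an `affinity_graph` (or any non-negative square matrix).
#' @return A `markov_matrix`: list with sparse row-stochastic `m` and the
#'   row sums `d` of the affinity matrix.
#' @export
markov_normalize <- function(aff) {
  a <- if (inherits(aff, "affinity_graph")) aff$a else methods::as(Matrix::Matrix(aff, sparse = TRUE), "CsparseMatrix")
  rs <- Matrix::rowSums(a)
  if (any(rs <= 0)) {
    bad <- which(rs <= 0)
    abort(paste("isolated cell(s) with zero affinity:",
                paste(head(bad, 5), collapse = ", ")),
          class = "phenarch_error")
  }
  m <- Matrix::Diagonal(x = 1 / rs) %*% a
  structure(list(m = m, d = rs), class = "markov_matrix")
}

#' Diffusion imputation of expression
#'
#' Smooths expression by `t` steps of the cell-cell Markov chain:
#' `imputed = M^t %*% norm`. `t = 0` is the identity; constant genes are
#' preserved exactly for all `t` (row-stochasticity), and imputed values
#' never leave the \[min, max\] range of the input column. The power is
#' applied as `t` successive sparse multiplications.
#'
#' @param norm a `norm_matrix` (or plain matrix).
#' @param markov a `markov_matrix` over the same cells.
#' @param t non-negative integer diffusion time (default 3).
#' @return An `imputed_matrix`: list with dense `x` (cells x genes),
#'   provenance fields `t`, `k`, `ka`, and the identifiers of the input.
#' @export
impute_diffusion <- function(norm, markov, t = 3L) {
  if (t < 0) abort("t must be >= 0", class = "phenarch_error")
  x <- if (inherits(norm, "norm_matrix")) norm$x else as.matrix(norm)
  if (nrow(markov$m) != nrow(x))
    abort("Markov matrix and expression matrix disagree on cell count",
          class = "phenarch_error")
  out <- x
  for (s in seq_len(t)) out <- as.matrix(markov$m %*% out)
  structure(list(x = out, t = t,
                 k = attr(markov, "k"), ka = attr(markov, "ka"),
                 cell_ids = if (inherits(norm, "norm_matrix")) norm$cell_ids else rownames(x),
                 gene_ids = if (inherits(norm, "norm_matrix")) norm$gene_ids else colnames(x)),
            class = "imputed_matrix")
}

#' @export
print.imputed_matrix <- function(x, ...) {
  cat(sprintf("<imputed_matrix> %d cells x %d genes (t = %d)\n",
              nrow(x$x), ncol(x$x), x$t))
  invisible(x)
}

#' @export
dim.imputed_matrix <- function(x) dim(x$x)

#' One-call imputation from a normalized matrix
#'
#' Convenience wrapper: PCA (library-size regressed), adaptive-kernel
#' graph on the first `n_pcs` components, Markov normalization, and
#' `t`-step diffusion.
#'
#' @param norm a `norm_matrix`.
#' @param k,ka,t,n_pcs graph and diffusion parameters (defaults 27, 12, 3, 20).
#' @param pcs optionally, a precomputed `pc_space` to reuse.
#' @param seed seed for the randomized PCA.
#' @return An `imputed_matrix`.
#' @export
impute_magic <- function(norm, k = 27L, ka = 12L, t = 3L, n_pcs = 20L,
                         pcs = NULL, seed = 1L) {
  if (is.null(pcs))
    pcs <- pca_libsize_regressed(norm, n_pcs = min(n_pcs, ncol(norm$x), nrow(norm$x) - 1L),
                                 seed = seed)
  aff <- adaptive_affinity(pcs, k = k, ka = ka, n_pcs = n_pcs)
  mk <- markov_normalize(aff)
  out <- impute_diffusion(norm, mk, t = t)
  out$k <- k; out$ka <- ka
  out
}
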