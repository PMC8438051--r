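#' Principal components with library size regressed out
#'
#' Computes PCA of the normalized matrix with a seeded randomized SVD,
#' then replaces each score column by its ordinary-least-squares residual
#' against (intercept, library size): droplet library size partially
#' correlates with some components and is treated as a nuisance.
#' Explained-variance ratios are recorded before the regression.
#'
#' @param norm a `norm_matrix` from [median_normalize()].
#' @param n_pcs components requested (truncated to the matrix rank with a
#'   warning).
#' @param seed integer seed for the randomized SVD.
#' @param libsize optional per-cell library sizes; defaults to the totals
#'   recorded during normalization.
#' @return A `pc_space`: list with `scores` (cells x n_pcs, post
#'   regression), `loadings`, `ev_ratio` (explained-variance ratios,
#'   non-increasing), `n_pcs`, `libsize`, `cell_ids`.
#' @export
pca_libsize_regressed <- function(norm, n_pcs = 50L, seed = 1L,
                                  libsize = norm$library_sizes) {
  x <- norm$x
  r <- min(nrow(x) - 1L, ncol(x))
  if (n_pcs > r) {
    warn(sprintf("n_pcs = %d exceeds rank bound %d: truncating", n_pcs, r))
    n_pcs <- r
  }
  xc <- sweep(x, 2, colMeans(x))
  sv <- randomized_svd(xc, k = n_pcs, seed = seed)
  scores <- sv$u %*% diag(sv$d, n_pcs)
  total_var <- sum(xc^2) / (nrow(x) - 1)
  ev_ratio <- (sv$d^2 / (nrow(x) - 1)) / total_var
  # enforce descending order (randomized SVD can permute near-ties)
  ord <- order(ev_ratio, decreasing = TRUE)
  scores <- scores[, ord, drop = FALSE]
  loadings <- sv$v[, ord, drop = FALSE]
  ev_ratio <- ev_ratio[ord]
  # OLS residual of each component against (1, libsize)
  if (sd(libsize) > 0) {
    design <- cbind(1, libsize)
    scores <- scores - design %*% solve(crossprod(design), crossprod(design, scores))
  } else {
    scores <- sweep(scores, 2, colMeans(scores))
  }
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  structure(list(scores = scores, loadings = loadings, ev_ratio = ev_ratio,
                 n_pcs = ncol(scores), libsize = libsize,
                 cell_ids = norm$cell_ids),
            class = "pc_space")
}

#' @export
print.pc_space <- function(x, ...) {
  cat(sprintf("<pc_space> %d cells x %d components (%.1f%% variance)\n",
              nrow(x$scores), x$n_pcs, 100 * sum(x$ev_ratio)))
  invisible(x)
}

#' Choose the number of principal components
#'
#' Returns both the knee of the cumulative explained-variance curve
#' (maximum distance to the chord, [knee_point()]) and the smallest number
#' of components reaching `target_fraction` of the total variance; the
#' knee is used when defined, otherwise the target rule.
#'
#' @param ev_ratio non-increasing explained-variance ratios.
#' @param target_fraction cumulative-variance target (default 0.90).
#' @return list with `n_pcs` (the selection), `knee` (`NA` when the curve
#'   is flat), `n_target`, and `cumulative`.
#' @export
select_n_pcs <- function(ev_ratio, target_fraction = 0.90) {
  n <- length(ev_ratio)
  if (n < 3) return(list(n_pcs = n, knee = NA_integer_, n_target = n,
                         cumulative = cumsum(ev_ratio)))
  cum <- cumsum(ev_ratio)
  # include the origin so a dominant first component registers as the knee
  knee <- knee_point(c(0, seq_len(n)), c(0, cum))
  if (!is.na(knee)) knee <- knee - 1L
  if (!is.na(knee) && knee < 1L) knee <- NA_integer_
  frac_target <- target_fraction * sum(ev_ratio)
  n_target <- if (any(cum >= frac_target)) min(which(cum >= frac_target)) else n
  list(n_pcs = if (is.na(knee)) n_target else knee,
       knee = knee, n_target = n_target, cumulative = cum)
}

#' Select variably expressed genes
#'
#' Fits a two-Gaussian model ([fit_bimodal()]) to the distribution of
#' per-gene standard deviations of the normalized matrix and keeps genes
#' with SD above `mu2 - 1.5 * sd2`, where `(mu2, sd2)` belong to the
#' larger-mean component. When the fit fails the top quartile of SDs is
#' kept instead (with a warning). Constant genes are never selected.
#'
#' @param norm a `norm_matrix`.
#' @param n_sd distance below the second mean, in its SDs (default 1.5).
#' @return logical gene mask with attributes `threshold` and `gene_sd`.
#' @export
variable_genes <- function(norm, n_sd = 1.5) {
  if (nrow(norm$x) < 2) abort("need at least 2 cells", class = "phenarch_error")
  sds <- apply(norm$x, 2, sd)
  fit <- fit_bimodal(sds)
  if (is.null(fit)) {
    warn("bimodal fit failed for gene SDs: keeping top-quartile SD genes")
    thr <- quantile(sds, 0.75, names = FALSE)
  } else {
    thr <- fit$mu2 - n_sd * fit$sd2
  }
  mask <- sds > pmax(thr, 0)
  mask[sds == 0] <- FALSE
  attr(mask, "threshold") <- thr
  attr(mask, "gene_sd") <- sds
  mask
}
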