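#' Log phenotypic volume of a cell population
#'
#' The log pseudo-determinant of the empirical gene-gene covariance
#' matrix, normalized by the number of genes: with eigenvalues
#' `lambda_e` of the covariance (unbiased, 1/(n-1) denominator), the
#' statistic is `sum(0.5 * log10(lambda_e^2)) / d` over eigenvalues above
#' tolerance. It quantifies the transcriptional state space spanned by a
#' population; covariance must be computed on normalized, un-imputed
#' expression because diffusion imputation distorts the gene-gene
#' covariance structure.
#'
#' Eigenvalues are obtained from the smaller of the gene-gene covariance
#' and the cell-cell Gram matrix, which share their nonzero spectrum.
#'
#' @param x cells x genes numeric matrix (normalized, un-imputed;
#'   typically restricted to the variably expressed genes). A
#'   `norm_matrix` is accepted.
#' @param tol eigenvalue tolerance; eigenvalues `<= tol * max(lambda)`
#'   count as zero (default relative tolerance 1e-10).
#' @return list with `log_volume`, `eigenvalues` (all, descending),
#'   `n_retained`, `n_dropped`, `d` (gene count).
#' @export
log_phenotypic_volume <- function(x, tol = 1e-10) {
  if (inherits(x, "norm_matrix")) x <- x$x
  x <- as.matrix(x)
  n <- nrow(x); d <- ncol(x)
  if (n < 2) abort("need at least 2 cells", class = "phenarch_error")
  xc <- sweep(x, 2, colMeans(x))
  if (all(xc == 0)) abort("zero covariance", class = "phenarch_error")
  gram_side <- n <= d
  m <- if (gram_side) tcrossprod(xc) / (n - 1) else crossprod(xc) / (n - 1)
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  ev <- sort(ev, decreasing = TRUE)
  cut <- max(ev) * tol
  keep <- ev > cut
  lv <- sum(0.5 * log10(ev[keep]^2)) / d
  list(log_volume = lv, eigenvalues = ev, n_retained = sum(keep),
       n_dropped = sum(!keep), d = d)
}

#' Phenotypic-volume distribution under controlled subsampling
#'
#' Because the number of reachable cell states grows with population
#' size, groups are compared at a fixed subsample size: `n_repeats`
#' draws of `n_cells` cells without replacement, with
#' [log_phenotypic_volume()] evaluated on each draw.
#'
#' @param x cells x genes matrix (normalized, un-imputed) or `norm_matrix`.
#' @param cell_subset logical mask or integer indices selecting the group;
#'   default all cells.
#' @param n_cells subsample size (default 150); the group must contain at
#'   least this many cells.
#' @param n_repeats number of subsamples (default 100).
#' @param seed integer seed.
#' @param tol eigenvalue tolerance passed through.
#' @return A `phenotypic_volume` tibble with one row per repeat
#'   (`repeat_id`, `log_volume`, `n_retained`), and attributes `n_cells`,
#'   `d`, `tol`.
#' @export
volume_distribution <- function(x, cell_subset = NULL, n_cells = 150L,
                                n_repeats = 100L, seed = 1L, tol = 1e-10) {
  if (inherits(x, "norm_matrix")) x <- x$x
  x <- as.matrix(x)
  idx <- if (is.null(cell_subset)) seq_len(nrow(x))
         else if (is.logical(cell_subset)) which(cell_subset)
         else as.integer(cell_subset)
  if (length(idx) < n_cells)
    abort(sprintf("group has %d cells, fewer than n_cells = %d",
                  length(idx), n_cells), class = "phenarch_error")
  res <- with_seed(seed, {
    purrr::map_dfr(seq_len(n_repeats), function(r) {
      draw <- sort(sample(idx, n_cells, replace = FALSE))
      v <- log_phenotypic_volume(x[draw, , drop = FALSE], tol = tol)
      tibble::tibble(repeat_id = r, log_volume = v$log_volume,
                     n_retained = v$n_retained)
    })
  })
  structure(res, n_cells = n_cells, d = ncol(x), tol = tol,
            class = c("phenotypic_volume", class(res)))
}
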