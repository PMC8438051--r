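#' Knee-point filter separating cells from empty droplets
#'
#' Locates the cutoff between the ambient ("empty droplet") and cell modes
#' of the log10 library-size distribution. The empirical CDF of log10
#' totals is evaluated on a regular grid, smoothed with a Gaussian kernel,
#' and differentiated; the cutoff is placed at the density minimum between
#' the main (ambient) mode and the next mode above it — the point where
#' the second difference of the smoothed ECDF crosses zero as the curve
#' turns from the ambient shoulder into the cell mode. Barcodes with total
#' counts strictly above the cutoff are retained.
#'
#' @param counts a [counts_matrix()].
#' @param n_grid grid resolution over the log10 total-count range.
#' @param smooth_sigma Gaussian smoothing bandwidth in grid steps.
#' @return list with `mask` (logical, TRUE = retained), `cutoff` (total
#'   counts at the knee; `-Inf` when no knee exists) and `grid` (a tibble
#'   of the smoothed curve for plotting).
#' @export
knee_filter_cells <- function(counts, n_grid = 100L, smooth_sigma = 2) {
  totals <- Matrix::rowSums(counts$counts)
  if (length(unique(totals)) < 3) {
    warn("all library sizes (nearly) identical: no knee, retaining all barcodes")
    return(list(mask = rep(TRUE, length(totals)), cutoff = -Inf,
                grid = tibble::tibble()))
  }
  lt <- log10(pmax(totals, 0.5))
  gx <- seq(min(lt), max(lt), length.out = n_grid)
  ecdf_v <- stats::ecdf(lt)(gx)
  # Gaussian smoothing on the grid
  half <- ceiling(4 * smooth_sigma)
  kern <- stats::dnorm(seq(-half, half), sd = smooth_sigma)
  kern <- kern / sum(kern)
  pad <- c(rep(ecdf_v[1], half), ecdf_v, rep(ecdf_v[n_grid], half))
  sm <- stats::filter(pad, kern, sides = 2)[(half + 1):(half + n_grid)]
  dens <- c(diff(sm), 0)            # first difference ~ density
  d2 <- c(0, diff(dens))            # second difference of the ECDF

  peaks <- which(diff(sign(diff(dens))) < 0) + 1L
  peaks <- peaks[dens[peaks] > max(dens) * 0.01]
  if (length(peaks) < 2) {
    warn("library-size distribution is unimodal: no knee, retaining all barcodes")
    return(list(mask = rep(TRUE, length(totals)), cutoff = -Inf,
                grid = tibble::tibble(log10_total = gx, ecdf = sm, density = dens,
                                      second_diff = d2)))
  }
  main <- peaks[which.max(dens[peaks])]
  above <- peaks[peaks > main]
  if (length(above) == 0) {
    # main mode is the cell mode; knee is below it, between the two top peaks
    second <- peaks[peaks < main][which.max(dens[peaks[peaks < main]])]
    lo <- second; hi <- main
  } else {
    second <- above[which.max(dens[above])]
    lo <- main; hi <- second
  }
  valley <- lo + which.min(dens[lo:hi]) - 1L
  cutoff_log <- gx[valley]
  cutoff <- 10^cutoff_log
  list(mask = totals > cutoff, cutoff = cutoff,
       grid = tibble::tibble(log10_total = gx, ecdf = sm, density = dens,
                             second_diff = d2))
}

#' Low-complexity library filter
#'
#' Flags barcodes whose detected-gene count falls far below the trend of
#' genes-detected versus total counts: ordinary least squares of
#' log(genes detected) on log(total counts), flagging residuals below
#' `-n_mads` robust standard deviations (MAD-based). A floor of
#' `min_drop` on the log scale keeps near-saturated libraries — where the
#' residual spread collapses — from being flagged for trivial deviations:
#' a flagged barcode must detect at least `1 - exp(-min_drop)` fewer
#' genes than the trend predicts.
#'
#' @param counts a [counts_matrix()].
#' @param n_mads robust-SD threshold (default 3).
#' @param min_drop minimum log-scale shortfall below the trend (default
#'   0.3, roughly 25% fewer genes than expected).
#' @return logical mask, TRUE = retained. With fewer than 10 barcodes the
#'   filter is skipped with a warning (all TRUE).
#' @export
complexity_filter <- function(counts, n_mads = 3, min_drop = 0.3) {
  totals <- unname(Matrix::rowSums(counts$counts))
  detected <- unname(Matrix::rowSums(counts$counts > 0))
  n <- length(totals)
  if (n < 10) {
    warn("fewer than 10 barcodes: complexity filter skipped")
    return(rep(TRUE, n))
  }
  ok <- totals > 0 & detected > 0
  res <- rep(0, n)
  fit <- lm(log(detected[ok]) ~ log(totals[ok]))
  res[ok] <- resid(fit)
  s <- stats::mad(res[ok])
  if (s == 0) return(rep(TRUE, n))
  res >= -max(n_mads * s, min_drop)
}

#' Mitochondrial-fraction (apoptotic cell) filter
#'
#' Cells with strictly more than `max_fraction` of their transcripts from
#' mitochondrial genes are considered apoptotic and flagged.
#'
#' @param counts a [counts_matrix()].
#' @param max_fraction threshold (default 0.25; a cell at exactly 25% is
#'   retained).
#' @return logical mask, TRUE = retained.
#' @export
mito_filter <- function(counts, max_fraction = 0.25) {
  if (!any(counts$mito_mask)) {
    warn("no mitochondrial genes present: mito filter skipped")
    return(rep(TRUE, nrow(counts$counts)))
  }
  totals <- unname(Matrix::rowSums(counts$counts))
  mito <- unname(Matrix::rowSums(counts$counts[, counts$mito_mask, drop = FALSE]))
  frac <- ifelse(totals > 0, mito / totals, 0)
  frac <= max_fraction
}

#' Gene detection and low-expression filter
#'
#' Removes genes detected in fewer than `min_cells` cells, and
#' additionally genes whose log10 total counts fall below
#' `mu2 - n_sd * sd2`, where `(mu2, sd2)` are the larger-mean component of
#' a two-Gaussian fit ([fit_bimodal()]) to the per-gene log-total
#' distribution. When the bimodal fit fails only the detection rule
#' applies (with a warning).
#'
#' @param counts a [counts_matrix()] (cell filters already applied).
#' @param min_cells detection threshold (default 10).
#' @param n_sd distance below the second mode, in that mode's SDs (default 5).
#' @return list with `mask` (logical per gene, TRUE = retained),
#'   `detection_mask`, `expression_mask`, and `cutoff_log10` (`NA` if the
#'   fit failed).
#' @export
gene_filter <- function(counts, min_cells = 10L, n_sd = 5) {
  det <- Matrix::colSums(counts$counts > 0)
  totals <- Matrix::colSums(counts$counts)
  detection_mask <- det >= min_cells
  lt <- log10(pmax(totals, 0.5))
  fit <- fit_bimodal(lt[totals > 0])
  if (is.null(fit)) {
    warn("bimodal fit failed for gene totals: applying only the detection rule")
    cutoff <- NA_real_
    expression_mask <- rep(TRUE, length(totals))
  } else {
    cutoff <- fit$mu2 - n_sd * fit$sd2
    expression_mask <- lt >= cutoff
  }
  list(mask = detection_mask & expression_mask,
       detection_mask = detection_mask,
       expression_mask = expression_mask,
       cutoff_log10 = cutoff)
}

#' Run all quality-control filters
#'
#' Applies the knee-point, complexity and mitochondrial cell filters and
#' the gene filters, and assembles a per-barcode report. The retained set
#' is the conjunction of all masks, so filter order is irrelevant.
#'
#' @param counts a [counts_matrix()] of raw barcodes.
#' @param min_cells_per_gene,mito_max,complexity_mads filter parameters.
#' @return A `qc_report`: tibble with one row per barcode (`cell_id`,
#'   `total_counts`, `genes_detected`, `mito_fraction`, `pass_knee`,
#'   `pass_complexity`, `pass_mito`, `retained`), with attributes
#'   `gene_table` (per-gene tibble), `knee_cutoff`, `gene_cutoff_log10`,
#'   and `filtered` (the filtered [counts_matrix()]).
#' @export
qc_filter <- function(counts, min_cells_per_gene = 10L, mito_max = 0.25,
                      complexity_mads = 3) {
  totals <- Matrix::rowSums(counts$counts)
  detected <- Matrix::rowSums(counts$counts > 0)
  mito <- Matrix::rowSums(counts$counts[, counts$mito_mask, drop = FALSE])
  mito_frac <- ifelse(totals > 0, mito / totals, 0)

  knee <- knee_filter_cells(counts)
  # the complexity trend is fit on cell-like barcodes only: ambient
  # barcodes below the knee would otherwise dominate the regression
  cx <- rep(TRUE, length(knee$mask))
  if (sum(knee$mask) >= 10) {
    sub <- counts_matrix(counts$counts[knee$mask, , drop = FALSE],
                         cell_ids = counts$cell_ids[knee$mask],
                         gene_ids = counts$gene_ids)
    cx[knee$mask] <- complexity_filter(sub, n_mads = complexity_mads)
  }
  mt <- mito_filter(counts, max_fraction = mito_max)
  cell_mask <- knee$mask & cx & mt

  kept <- counts_matrix(counts$counts[cell_mask, , drop = FALSE],
                        cell_ids = counts$cell_ids[cell_mask],
                        gene_ids = counts$gene_ids)
  gf <- gene_filter(kept, min_cells = min_cells_per_gene)
  filtered <- counts_matrix(kept$counts[, gf$mask, drop = FALSE],
                            cell_ids = kept$cell_ids,
                            gene_ids = kept$gene_ids[gf$mask])

  report <- tibble::tibble(
    cell_id = counts$cell_ids,
    total_counts = as.numeric(totals),
    genes_detected = as.numeric(detected),
    mito_fraction = mito_frac,
    pass_knee = knee$mask,
    pass_complexity = cx,
    pass_mito = mt,
    retained = cell_mask)
  gene_table <- tibble::tibble(
    gene_id = counts$gene_ids,
    cells_detected = as.numeric(Matrix::colSums(kept$counts > 0)),
    total_counts = as.numeric(Matrix::colSums(kept$counts)),
    pass_detection = gf$detection_mask,
    pass_expression = gf$expression_mask,
    retained = gf$mask)
  structure(report,
            gene_table = gene_table,
            knee_cutoff = knee$cutoff,
            knee_grid = knee$grid,
            gene_cutoff_log10 = gf$cutoff_log10,
            filtered = filtered,
            class = c("qc_report", class(report)))
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d barcodes -> %d cells retained; %d/%d genes retained\n",
              nrow(x), sum(x$retained),
              sum(attr(x, "gene_table")$retained), nrow(attr(x, "gene_table"))))
  cat(sprintf("  knee cutoff: %.1f counts | failed knee %d, complexity %d, mito %d\n",
              attr(x, "knee_cutoff"), sum(!x$pass_knee),
              sum(!x$pass_complexity), sum(!x$pass_mito)))
  NextMethod()
}

#' Median library-size normalization
#'
#' Divides each cell's counts by its total and rescales by the median
#' total over all cells, so every normalized row sums to the median
#' library size.
#'
#' @param counts a [counts_matrix()] (or a `norm_matrix`, which is
#'   re-normalized — the operation is idempotent).
#' @return A `norm_matrix`: list with `x` (dense cells x genes matrix),
#'   `scale_factors`, `median_libsize`, `cell_ids`, `gene_ids`, `mito_mask`.
#' @export
median_normalize <- function(counts) {
  if (inherits(counts, "norm_matrix")) {
    m <- counts$x
    ids <- counts$cell_ids; gids <- counts$gene_ids; mm <- counts$mito_mask
  } else {
    m <- as.matrix(counts$counts)
    ids <- counts$cell_ids; gids <- counts$gene_ids; mm <- counts$mito_mask
  }
  totals <- rowSums(m)
  if (any(totals <= 0))
    abort(paste("zero-total cell(s):",
                paste(head(ids[totals <= 0], 5), collapse = ", ")),
          class = "phenarch_error")
  med <- median(totals)
  sf <- med / totals
  structure(list(x = m * sf, scale_factors = sf, median_libsize = med,
                 library_sizes = totals,
                 cell_ids = ids, gene_ids = gids, mito_mask = mm),
            class = "norm_matrix")
}

#' @export
print.norm_matrix <- function(x, ...) {
  cat(sprintf("<norm_matrix> %d cells x %d genes, median library size %.1f\n",
              nrow(x$x), ncol(x$x), x$median_libsize))
  invisible(x)
}

#' @export
dim.norm_matrix <- function(x) dim(x$x)
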