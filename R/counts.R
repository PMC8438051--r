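#' Count matrix container
#'
#' A `counts_matrix` holds integer UMI counts as a sparse cells x genes
#' matrix together with barcode and gene identifiers and a logical
#' mitochondrial-gene mask. Mitochondrial genes are recognized by the
#' "MT-" symbol prefix (case-insensitive).
#'
#' @param counts matrix or sparse Matrix of non-negative integers,
#'   cells x genes.
#' @param cell_ids character vector of unique barcodes (rows).
#' @param gene_ids character vector of unique gene symbols (columns).
#' @return A `counts_matrix` object.
#' @export
counts_matrix <- function(counts, cell_ids = rownames(counts),
                          gene_ids = colnames(counts)) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(counts)))
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(counts)))
  cell_ids <- as.character(cell_ids); gene_ids <- as.character(gene_ids)
  if (length(cell_ids) != nrow(counts) || length(gene_ids) != ncol(counts))
    abort("identifier lengths do not match matrix dimensions", class = "phenarch_error")
  if (anyDuplicated(cell_ids)) abort("duplicate cell barcodes", class = "phenarch_error")
  if (anyDuplicated(gene_ids)) abort("duplicate gene identifiers", class = "phenarch_error")
  v <- counts@x
  if (any(v < 0)) abort("negative count", class = "phenarch_error")
  if (any(v != round(v))) abort("non-integer count", class = "phenarch_error")
  dimnames(counts) <- list(cell_ids, gene_ids)
  structure(list(counts = counts,
                 cell_ids = cell_ids,
                 gene_ids = gene_ids,
                 mito_mask = grepl("^MT-", gene_ids, ignore.case = TRUE)),
            class = "counts_matrix")
}

#' @export
print.counts_matrix <- function(x, ...) {
  cat(sprintf("<counts_matrix> %d cells x %d genes (%d mitochondrial)\n",
              nrow(x$counts), ncol(x$counts), sum(x$mito_mask)))
  cat(sprintf("  total UMIs: %s, median library size: %s\n",
              format(sum(x$counts)), format(median(Matrix::rowSums(x$counts)))))
  invisible(x)
}

#' @export
dim.counts_matrix <- function(x) dim(x$counts)

#' Read a UMI count matrix
#'
#' Reads either a Matrix Market directory in the 10x convention
#' (`matrix.mtx` with genes as rows plus `barcodes.tsv` and
#' `features.tsv`/`genes.tsv`; transposed on read so cells are rows) or a
#' dense CSV with a header row of gene symbols and one row per cell.
#'
#' @param path directory (mtx-dir) or file (dense-csv).
#' @param format `"mtx-dir"` or `"dense-csv"`.
#' @return A [counts_matrix()].
#' @export
read_counts <- function(path, format = c("mtx-dir", "dense-csv")) {
  format <- match.arg(format)
  if (format == "mtx-dir") {
    mtx <- file.path(path, "matrix.mtx")
    bc <- file.path(path, "barcodes.tsv")
    ft <- file.path(path, "features.tsv")
    if (!file.exists(ft)) ft <- file.path(path, "genes.tsv")
    missing <- c(mtx, bc, ft)[!file.exists(c(mtx, bc, ft))]
    if (length(missing))
      abort(paste("missing file(s):", paste(missing, collapse = ", ")),
            class = "phenarch_io_error")
    m <- Matrix::readMM(mtx)            # genes x cells on disk (10x)
    barcodes <- readLines(bc)
    feats <- readr::read_tsv(ft, col_names = FALSE, show_col_types = FALSE,
                             progress = FALSE)
    genes <- as.character(feats[[min(2, ncol(feats))]])
    if (nrow(m) != length(genes) || ncol(m) != length(barcodes))
      abort("matrix dimensions do not match barcode/feature files",
            class = "phenarch_io_error")
    counts_matrix(Matrix::t(m), cell_ids = barcodes, gene_ids = genes)
  } else {
    if (!file.exists(path))
      abort(paste("missing file:", path), class = "phenarch_io_error")
    df <- utils::read.csv(path, check.names = FALSE)
    first_is_id <- !is.numeric(df[[1]])
    cell_ids <- if (first_is_id) as.character(df[[1]]) else NULL
    mat <- as.matrix(if (first_is_id) df[, -1, drop = FALSE] else df)
    if (!is.numeric(mat)) abort("non-numeric entries in CSV", class = "phenarch_io_error")
    counts_matrix(mat, cell_ids = cell_ids, gene_ids = colnames(mat))
  }
}

#' Write a count matrix
#'
#' Inverse of [read_counts()]: writes either an mtx-dir (genes as rows on
#' disk, 10x convention) or a dense CSV with a `barcode` column.
#'
#' @param x a [counts_matrix()].
#' @param path output directory (mtx-dir) or file (dense-csv).
#' @inheritParams read_counts
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path, format = c("mtx-dir", "dense-csv")) {
  format <- match.arg(format)
  if (format == "mtx-dir") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(Matrix::t(x$counts), file.path(path, "matrix.mtx"))
    writeLines(x$cell_ids, file.path(path, "barcodes.tsv"))
    readr::write_tsv(tibble::tibble(id = x$gene_ids, symbol = x$gene_ids),
                     file.path(path, "features.tsv"), col_names = FALSE)
  } else {
    df <- as.data.frame(as.matrix(x$counts), check.names = FALSE)
    df <- cbind(barcode = x$cell_ids, df)
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Load gene signatures
#'
#' Reads a named set of gene lists from GMT (name, description, genes...)
#' or JSON (object mapping name to a list of symbols). Genes absent from a
#' particular expression matrix are dropped at scoring time with a warning,
#' not here.
#'
#' @param path file path.
#' @param format `"gmt"` or `"json"`; guessed from the extension by default.
#' @return A named list of character vectors, class `gene_signatures`.
#' @export
load_signatures <- function(path, format = c("auto", "gmt", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "gmt"
  if (format == "gmt") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    names_ <- vapply(parts, `[[`, character(1), 1)
    sigs <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
    names(sigs) <- names_
  } else {
    sigs <- jsonlite::read_json(path, simplifyVector = TRUE)
    sigs <- lapply(sigs, function(g) unique(as.character(g)))
  }
  gene_signatures(sigs)
}

#' Construct a signature set from a named list
#'
#' @param sigs named list of character vectors of gene symbols.
#' @return The validated list with class `gene_signatures`.
#' @export
gene_signatures <- function(sigs) {
  if (is.null(names(sigs)) || any(!nzchar(names(sigs))))
    abort("signatures must be named", class = "phenarch_error")
  if (anyDuplicated(names(sigs)))
    abort("duplicate name", class = "phenarch_error")
  empty <- names(sigs)[lengths(sigs) == 0]
  if (length(empty))
    abort(paste("empty signature:", paste(empty, collapse = ", ")),
          class = "phenarch_error")
  structure(lapply(sigs, as.character), class = "gene_signatures")
}

#' @export
print.gene_signatures <- function(x, ...) {
  cat(sprintf("<gene_signatures> %d signature(s)\n", length(x)))
  for (nm in names(x))
    cat(sprintf("  %s: %d genes (%s%s)\n", nm, length(x[[nm]]),
                paste(head(x[[nm]], 4), collapse = ", "),
                if (length(x[[nm]]) > 4) ", ..." else ""))
  invisible(x)
}

#' Pipeline run configuration
#'
#' Bundles the seed and every stage parameter with its default so that a
#' serialized configuration fully determines a run. Stage functions draw
#' their defaults from here when driven by [run_atlas_pipeline()].
#'
#' @param seed integer master seed; per-stage seeds are derived from it.
#' @param ... overrides for any default parameter.
#' @return A named list of parameters, class `run_config`.
#' @export
run_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    min_cells_per_gene = 10L,   # gene detection filter
    mito_max = 0.25,            # apoptotic-cell threshold on mito fraction
    n_pcs = 50L,                # PCs computed before knee selection
    target_var = 0.90,          # cumulative-variance target for PC count
    knn_k = 27L,                # imputation graph neighbours
    knn_ka = 12L,               # adaptive-kernel scale neighbour
    diffusion_t = 3L,           # imputation diffusion time
    impute_n_pcs = 20L,         # PCs used to build the imputation graph
    cluster_k = 35L,            # community-detection neighbourhood size
    stability_threshold = 0.75, # ARI threshold in the k-stability scan
    n_components = 2L,          # mixture components for classification
    covariance = "diagonal",
    bootstrap_n_cells = 500L,
    bootstrap_n_rounds = 20L,
    volume_n_cells = 150L,
    volume_n_repeats = 100L,
    n_archetypes = 8L,
    archetype_n_pcs = 22L,
    diffusion_L = 5L,
    emd_n_resamples = 100L,
    ranked_window = 20L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    abort(paste("unknown parameter(s):", paste(bad, collapse = ", ")),
          class = "phenarch_error")
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

# Derive a reproducible sub-seed for a named stage from the master seed.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) * 7919L + h) %% 2147483647L
}
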