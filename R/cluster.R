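#' Graph community detection on PC scores
#'
#' Builds a k-nearest-neighbour graph, weights each edge by the Jaccard
#' overlap of the two endpoints' neighbour sets, and partitions the graph
#' with modularity-optimizing (Louvain) community detection. The backend
#' is deterministic under the seed. Warns when the Jaccard graph is not
#' fully connected.
#'
#' @param pcs a `pc_space` or coordinate matrix.
#' @param k neighbours for the graph.
#' @param seed integer seed (tie-breaking in the optimizer).
#' @param n_pcs columns of the score matrix used (default all).
#' @return A `cluster_labels`: list with `labels` (integers from 0),
#'   `k`, `modularity`, `n_clusters`.
#' @export
cluster_cells <- function(pcs, k = 35L, seed = 1L, n_pcs = NULL) {
  x <- if (inherits(pcs, "pc_space")) pcs$scores else as.matrix(pcs)
  if (!is.null(n_pcs)) x <- x[, seq_len(min(n_pcs, ncol(x))), drop = FALSE]
  n <- nrow(x)
  if (k >= n) abort("k must be smaller than the number of cells", class = "phenarch_error")
  nn <- knn_search(x, k)$index
  # Jaccard weight of each directed edge (i -> j): |N(i) & N(j)| / |N(i) | N(j)|
  neigh <- lapply(seq_len(n), function(i) nn[i, ])
  ii <- rep(seq_len(n), each = k)
  jj <- as.vector(t(nn))
  jac <- vapply(seq_along(ii), function(e) {
    a <- neigh[[ii[e]]]; b <- neigh[[jj[e]]]
    inter <- length(intersect(a, b))
    inter / (2 * k - inter)
  }, numeric(1))
  keep <- jac > 0
  g <- igraph::graph_from_data_frame(
    data.frame(from = ii[keep], to = jj[keep], weight = jac[keep]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  g <- igraph::simplify(g, edge.attr.comb = "max")
  if (igraph::components(g)$no > 1)
    warn(sprintf("Jaccard graph is not fully connected (%d components)",
                 igraph::components(g)$no))
  comm <- with_seed(seed, igraph::cluster_louvain(g, weights = igraph::E(g)$weight))
  memb <- igraph::membership(comm)[as.character(seq_len(n))]
  labels <- as.integer(factor(memb)) - 1L
  structure(list(labels = labels, k = k,
                 modularity = igraph::modularity(comm),
                 n_clusters = length(unique(labels))),
            class = "cluster_labels")
}

#' @export
print.cluster_labels <- function(x, ...) {
  cat(sprintf("<cluster_labels> %d cells, %d clusters (k = %d, modularity %.3f)\n",
              length(x$labels), x$n_clusters, x$k, x$modularity))
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement under the permutation model: 1 for
#' identical partitions (up to relabeling), ~0 for independent ones.
#'
#' @param labels_a,labels_b equal-length label vectors.
#' @return a number in \[-1, 1\].
#' @export
ari <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    abort("label vectors differ in length", class = "phenarch_error")
  tab <- table(labels_a, labels_b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  a <- sum(comb2(rowSums(tab)))
  b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(labels_a))
  expected <- a * b / n2
  max_index <- (a + b) / 2
  if (max_index == expected) return(1)   # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Neighbourhood-size stability scan
#'
#' Clusters at every k in the grid, computes the pairwise adjusted Rand
#' index between all assignments, and chooses the minimum k whose median
#' ARI against all larger k values exceeds `stability_threshold`. When no
#' k qualifies the maximum k is returned with a warning.
#'
#' @param pcs a `pc_space` or coordinate matrix.
#' @param k_grid integer vector of neighbourhood sizes (>= 2 values).
#' @param stability_threshold ARI threshold (default 0.75).
#' @param seed integer seed.
#' @return A `stability_scan`: list with `k_grid`, `ari_matrix`
#'   (symmetric, unit diagonal), `chosen_k`, `labels` (list per k).
#' @export
stability_select_k <- function(pcs, k_grid, stability_threshold = 0.75,
                               seed = 1L) {
  k_grid <- sort(unique(as.integer(k_grid)))
  if (length(k_grid) < 2) abort("k_grid needs >= 2 values", class = "phenarch_error")
  runs <- lapply(k_grid, function(k) cluster_cells(pcs, k = k, seed = seed))
  m <- length(k_grid)
  am <- diag(1, m)
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    am[i, j] <- am[j, i] <- ari(runs[[i]]$labels, runs[[j]]$labels)
  }
  dimnames(am) <- list(k_grid, k_grid)
  chosen <- NA_integer_
  for (i in seq_len(m - 1)) {
    if (median(am[i, (i + 1):m]) > stability_threshold) { chosen <- k_grid[i]; break }
  }
  if (is.na(chosen)) {
    warn("no k reaches the stability threshold: returning the largest k")
    chosen <- k_grid[m]
  }
  structure(list(k_grid = k_grid, ari_matrix = am, chosen_k = chosen,
                 labels = setNames(lapply(runs, `[[`, "labels"), k_grid),
                 threshold = stability_threshold),
            class = "stability_scan")
}

#' Annotate clusters against a bulk reference
#'
#' Computes the per-cluster median imputed expression of each gene,
#' centers it across clusters, centers the reference profiles across cell
#' types, and correlates cluster against cell type (Pearson) over the
#' shared genes, with the exact t-transform p-value for non-correlation.
#' Only pairs with |r| > `r_min` and p < `p_max` are flagged for display.
#'
#' @param labels a `cluster_labels` (or integer vector).
#' @param imputed an `imputed_matrix` (or plain cells x genes matrix with
#'   column names).
#' @param reference genes x cell-type matrix or data frame with gene
#'   identifiers as row names.
#' @param r_min,p_max display-mask thresholds (defaults 0.2, 0.01).
#' @return An `annotation_result` tibble (`cluster`, `cell_type`, `r`,
#'   `p_value`, `display`) with attribute `n_genes` (shared genes used).
#' @export
annotate_by_reference <- function(labels, imputed, reference,
                                  r_min = 0.2, p_max = 0.01) {
  lab <- if (inherits(labels, "cluster_labels")) labels$labels else labels
  x <- if (inherits(imputed, "imputed_matrix")) imputed$x else as.matrix(imputed)
  genes_x <- if (inherits(imputed, "imputed_matrix")) imputed$gene_ids else colnames(x)
  ref <- as.matrix(reference)
  shared <- intersect(genes_x, rownames(ref))
  if (length(shared) < 2)
    abort("fewer than 2 shared genes between matrix and reference",
          class = "phenarch_error")
  xs <- x[, match(shared, genes_x), drop = FALSE]
  refs <- ref[shared, , drop = FALSE]

  cl <- sort(unique(lab))
  singletons <- cl[tabulate(factor(lab, levels = cl)) == 1]
  if (length(singletons))
    warn(paste("single-cell cluster(s):", paste(singletons, collapse = ", ")))
  med <- vapply(cl, function(g) apply(xs[lab == g, , drop = FALSE], 2, median),
                numeric(ncol(xs)))              # genes x clusters
  med <- med - rowMeans(med)                     # center per gene across clusters
  refs <- refs - rowMeans(refs)                  # center per gene across cell types

  n <- length(shared)
  r <- cor(med, refs)                            # clusters x cell types
  tval <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE)
  out <- tidyr::expand_grid(cluster = cl, cell_type = colnames(refs)) |>
    dplyr::arrange(.data$cluster)
  out$r <- as.vector(t(r))
  out$p_value <- as.vector(t(p))
  out$display <- abs(out$r) > r_min & out$p_value < p_max
  structure(out, n_genes = n,
            class = c("annotation_result", class(out)))
}
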