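#' Run the full atlas pipeline
#'
#' Chains quality control, normalization, principal components with
#' library-size regression, diffusion imputation, signature scoring and
#' mixture classification, bootstrap class fractions, phenotypic volume
#' per class, diffusion map, archetypal analysis with neighbourhoods, and
#' EMD marker scoring — each stage seeded deterministically from the
#' configuration seed.
#'
#' @param counts a [counts_matrix()] of raw barcodes.
#' @param sigs a [gene_signatures()] set used for classification (the
#'   last signature is the class-defining axis).
#' @param config a [run_config()].
#' @param patient_ids optional per-barcode patient identifiers (same
#'   order as `counts`); defaults to a single patient.
#' @param volume_min_group smallest class size for which a volume
#'   distribution is computed (defaults to `config$volume_n_cells`).
#' @return A named list with every stage result: `qc`, `norm`, `pcs`,
#'   `n_pcs_selected`, `imputed`, `scores`, `fit`, `fractions`,
#'   `volumes` (per class), `dm`, `archetypes`, `neighborhoods`,
#'   `markers`, `variable_mask`, and `config`.
#' @export
run_atlas_pipeline <- function(counts, sigs, config = run_config(),
                               patient_ids = NULL,
                               volume_min_group = NULL) {
  seed <- config$seed
  qc <- qc_filter(counts,
                  min_cells_per_gene = config$min_cells_per_gene,
                  mito_max = config$mito_max)
  filtered <- attr(qc, "filtered")
  if (!is.null(patient_ids)) {
    patient_ids <- patient_ids[match(filtered$cell_ids, counts$cell_ids)]
  } else {
    patient_ids <- rep("P1", length(filtered$cell_ids))
  }

  norm <- median_normalize(filtered)
  n_pcs_req <- min(config$n_pcs, nrow(norm$x) - 1L, ncol(norm$x))
  pcs <- pca_libsize_regressed(norm, n_pcs = n_pcs_req,
                               seed = stage_seed(seed, "pca"))
  sel <- select_n_pcs(pcs$ev_ratio, target_fraction = config$target_var)

  imputed <- impute_magic(norm, k = config$knn_k, ka = config$knn_ka,
                          t = config$diffusion_t,
                          n_pcs = min(config$impute_n_pcs, pcs$n_pcs),
                          pcs = pcs)
  vmask <- variable_genes(norm)

  scores <- score_signature(imputed, sigs)
  fit <- fit_bgmm(scores, n_components = config$n_components,
                  covariance = config$covariance,
                  seed = stage_seed(seed, "bgmm"))
  fractions <- bootstrap_fractions(fit, patient_ids,
                                   n_cells = config$bootstrap_n_cells,
                                   n_rounds = config$bootstrap_n_rounds,
                                   seed = stage_seed(seed, "bootstrap"))

  vmin <- volume_min_group %||% config$volume_n_cells
  vol_expr <- norm$x[, vmask, drop = FALSE]
  volumes <- lapply(sort(unique(fit$labels)), function(cl) {
    idx <- which(fit$labels == cl)
    if (length(idx) < vmin) return(NULL)
    volume_distribution(vol_expr, cell_subset = idx,
                        n_cells = config$volume_n_cells,
                        n_repeats = config$volume_n_repeats,
                        seed = stage_seed(seed, paste0("volume", cl)))
  })
  names(volumes) <- paste0("class", sort(unique(fit$labels)))

  dm <- diffusion_map(pcs$scores[, seq_len(min(pcs$n_pcs, sel$n_pcs)), drop = FALSE],
                      k = config$knn_k, ka = config$knn_ka,
                      L_max = config$diffusion_L)
  arch_pcs <- pcs$scores[, seq_len(min(config$archetype_n_pcs, pcs$n_pcs)),
                         drop = FALSE]
  arch <- pcha_fit(arch_pcs, K = config$n_archetypes,
                   seed = stage_seed(seed, "pcha"))
  nbhd <- archetype_neighborhoods(dm, arch, arch_pcs)
  markers <- archetype_markers(imputed, nbhd, gene_mask = vmask,
                               n_resamples = config$emd_n_resamples,
                               seed = stage_seed(seed, "emd"))

  list(qc = qc, norm = norm, pcs = pcs, n_pcs_selected = sel,
       imputed = imputed, scores = scores, fit = fit,
       fractions = fractions, volumes = volumes, dm = dm,
       archetypes = arch, neighborhoods = nbhd, markers = markers,
       variable_mask = vmask, config = config, patient_ids = patient_ids)
}
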