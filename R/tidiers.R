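#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_col
#'   geom_errorbar geom_violin geom_vline geom_raster geom_tile labs
#'   scale_fill_gradient2 theme_minimal facet_wrap
#' @export
ggplot2::autoplot

#' Tidy a QC report
#'
#' @param x a `qc_report`.
#' @param ... unused.
#' @return the per-barcode tibble (already tidy); `glance()` returns the
#'   one-row summary with filter counts and cutoffs.
#' @exportS3Method generics::tidy
tidy.qc_report <- function(x, ...) tibble::as_tibble(unclass(x))

#' @rdname tidy.qc_report
#' @exportS3Method generics::glance
glance.qc_report <- function(x, ...) {
  gt <- attr(x, "gene_table")
  tibble::tibble(
    n_barcodes = nrow(x), n_cells_retained = sum(x$retained),
    n_fail_knee = sum(!x$pass_knee),
    n_fail_complexity = sum(!x$pass_complexity),
    n_fail_mito = sum(!x$pass_mito),
    knee_cutoff = attr(x, "knee_cutoff"),
    n_genes = nrow(gt), n_genes_retained = sum(gt$retained),
    gene_cutoff_log10 = attr(x, "gene_cutoff_log10"))
}

#' @exportS3Method generics::tidy
tidy.bgmm_fit <- function(x, ...) {
  post <- tibble::as_tibble(x$posterior, .name_repair = ~ paste0("posterior_", seq_along(.)))
  dplyr::bind_cols(
    tibble::tibble(cell_id = x$cell_ids %||% seq_along(x$labels),
                   class = x$labels),
    post)
}

#' @exportS3Method generics::glance
glance.bgmm_fit <- function(x, ...) {
  tibble::tibble(n_components = x$n_components, covariance = x$covariance,
                 converged = x$converged, n_iter = x$n_iter,
                 n_cells = length(x$labels))
}

#' @exportS3Method generics::tidy
tidy.phenotypic_volume <- function(x, ...) tibble::as_tibble(unclass(x))

#' @exportS3Method generics::glance
glance.phenotypic_volume <- function(x, ...) {
  tibble::tibble(n_repeats = nrow(x), n_cells = attr(x, "n_cells"),
                 d = attr(x, "d"),
                 median_log_volume = median(x$log_volume),
                 iqr_log_volume = stats::IQR(x$log_volume))
}

#' @exportS3Method generics::tidy
tidy.archetype_model <- function(x, ...) {
  tibble::as_tibble(x$archetypes, .name_repair = ~ paste0("dim", seq_along(.))) |>
    dplyr::mutate(archetype = dplyr::row_number(), .before = 1)
}

#' @exportS3Method generics::glance
glance.archetype_model <- function(x, ...) {
  tibble::tibble(K = x$K, explained_variance = x$explained_variance,
                 converged = x$converged, n_iter = length(x$objective) - 1,
                 delta = x$delta)
}

#' @exportS3Method generics::tidy
tidy.diffusion_map <- function(x, ...) {
  tibble::tibble(component = seq_along(x$eigenvalues),
                 eigenvalue = x$eigenvalues,
                 retained = seq_along(x$eigenvalues) <= x$L)
}

#' @exportS3Method generics::tidy
tidy.cluster_labels <- function(x, ...) {
  tibble::tibble(cell = seq_along(x$labels), cluster = x$labels)
}

#' @exportS3Method generics::tidy
tidy.stability_scan <- function(x, ...) {
  tibble::as_tibble(x$ari_matrix, rownames = "k1") |>
    tidyr::pivot_longer(-"k1", names_to = "k2", values_to = "ari") |>
    dplyr::mutate(k1 = as.integer(.data$k1), k2 = as.integer(.data$k2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- plots -----------------------------------------------------------------

#' Plot the library-size knee
#'
#' Smoothed log10 library-size density with the knee cutoff.
#'
#' @param object a `qc_report`.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.qc_report <- function(object, ...) {
  grid <- attr(object, "knee_grid")
  ggplot(grid, aes(x = .data$log10_total, y = .data$density)) +
    geom_line() +
    geom_vline(xintercept = log10(attr(object, "knee_cutoff")),
               linetype = "dashed", colour = "red") +
    labs(x = "log10 total counts per barcode", y = "smoothed density",
         title = "Library-size knee filter") +
    theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.stability_scan <- function(object, ...) {
  tidy(object) |>
    ggplot(aes(x = factor(.data$k1), y = factor(.data$k2), fill = .data$ari)) +
    geom_tile() +
    scale_fill_gradient2(limits = c(-1, 1), midpoint = 0) +
    labs(x = "k", y = "k", fill = "ARI",
         title = sprintf("Cluster stability (chosen k = %d)", object$chosen_k)) +
    theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.bgmm_fit <- function(object, ...) {
  if (length(object$score_names) < 2)
    abort("autoplot requires >= 2 score dimensions", class = "phenarch_error")
  means <- tibble::as_tibble(object$means,
                             .name_repair = ~ object$score_names)
  means$weight <- object$weights
  ggplot(means, aes(x = .data[[object$score_names[1]]],
                    y = .data[[object$score_names[2]]],
                    size = .data$weight)) +
    geom_point(shape = 4, stroke = 2, colour = "red") +
    labs(title = sprintf("%d-component mixture (%s covariance)",
                         object$n_components, object$covariance)) +
    theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.fraction_estimate <- function(object, ...) {
  ggplot(object, aes(x = .data$patient, y = .data$mean_fraction,
                     fill = factor(.data$class))) +
    geom_col(position = "stack", width = 0.7) +
    labs(x = NULL, y = "mean class fraction", fill = "class",
         title = "Bootstrapped per-patient class fractions") +
    theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.phenotypic_volume <- function(object, ...) {
  ggplot(tidy(object), aes(x = "", y = .data$log_volume)) +
    geom_violin(fill = "grey80") +
    labs(x = NULL, y = "log10 phenotypic volume") +
    theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.ranked_matrix <- function(object, ...) {
  df <- tibble::as_tibble(object$z, rownames = "gene",
                          .name_repair = "minimal")
  colnames(df) <- c("gene", seq_len(ncol(object$z)))
  df <- tidyr::pivot_longer(df, -"gene", names_to = "rank",
                            values_to = "z") |>
    dplyr::mutate(rank = as.integer(.data$rank))
  ggplot(df, aes(x = .data$rank, y = .data$gene, fill = .data$z)) +
    geom_raster() +
    scale_fill_gradient2() +
    labs(x = sprintf("cells ranked by %s score", object$rank_sig),
         y = NULL, fill = "z") +
    theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.archetype_model <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$objective) - 1,
                       objective = object$objective)
  ggplot(df, aes(x = .data$iteration, y = .data$objective)) +
    geom_line() +
    labs(title = sprintf("PCHA objective (K = %d, EV = %.3f)",
                         object$K, object$explained_variance)) +
    theme_minimal()
}

#' Plot an explained-variance model-selection curve
#'
#' @param selection result of [select_n_archetypes()].
#' @return a ggplot of explained variance against K with the chosen K.
#' @export
plot_archetype_selection <- function(selection) {
  ggplot(selection$curve, aes(x = .data$K, y = .data$explained_variance)) +
    geom_line() + geom_point() +
    geom_vline(xintercept = selection$K, linetype = "dashed", colour = "red") +
    labs(y = "explained variance", title = "Archetype number selection") +
    theme_minimal()
}
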