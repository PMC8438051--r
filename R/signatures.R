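#' Per-cell signature scores
#'
#' Scores each cell by the unweighted mean imputed expression of each
#' signature's genes. Signature genes absent from the matrix are dropped
#' with a warning; a signature with no genes present is an error.
#'
#' @param imputed an `imputed_matrix` (or any cells x genes matrix with
#'   gene names; classification reads the imputed matrix).
#' @param sigs a [gene_signatures()] set.
#' @return A `signature_scores` tibble: `cell_id` plus one numeric column
#'   per signature.
#' @export
score_signature <- function(imputed, sigs) {
  x <- if (inherits(imputed, "imputed_matrix")) imputed$x else as.matrix(imputed)
  genes <- if (inherits(imputed, "imputed_matrix")) imputed$gene_ids else colnames(x)
  cells <- if (inherits(imputed, "imputed_matrix")) imputed$cell_ids else rownames(x)
  if (is.null(cells)) cells <- paste0("cell", seq_len(nrow(x)))
  cols <- lapply(names(sigs), function(nm) {
    present <- intersect(sigs[[nm]], genes)
    if (length(present) == 0)
      abort(paste0("no genes of signature '", nm, "' present in the matrix"),
            class = "phenarch_error")
    if (length(present) < length(sigs[[nm]]))
      warn(sprintf("signature '%s': %d of %d genes absent, scoring the rest",
                   nm, length(sigs[[nm]]) - length(present), length(sigs[[nm]])))
    rowMeans(x[, match(present, genes), drop = FALSE])
  })
  names(cols) <- names(sigs)
  out <- tibble::tibble(cell_id = cells, !!!cols)
  structure(out, class = c("signature_scores", class(out)))
}

# ---- variational Bayesian Gaussian mixture ---------------------------------

#' Fit a Bayesian Gaussian mixture to signature scores
#'
#' Variational Bayesian expectation-maximization for a fixed-component
#' Gaussian mixture with diagonal, spherical, or tied covariance,
#' conjugate priors (Dirichlet weights with concentration
#' `1/n_components`, Gaussian means, Gamma/Wishart precisions) and seeded
#' k-means initialization. After fitting, components are relabeled by
#' ascending posterior mean along the class-defining axis (`order_by`,
#' default the last score column), so the highest class index is the
#' high-scoring (aggressive-signature) component.
#'
#' @param scores a `signature_scores` tibble or numeric matrix
#'   (cells x score dimensions).
#' @param n_components number of mixture components (>= 2).
#' @param covariance `"diagonal"`, `"spherical"`, or `"tied"`.
#' @param seed integer seed (k-means initialization).
#' @param order_by column name or index of the class-defining axis.
#' @param max_iter,tol VB-EM iteration cap and convergence tolerance on
#'   the per-cell evidence surrogate.
#' @return A `bgmm_fit`: list with `labels` (1..K), `posterior`
#'   (cells x K, rows sum to 1), `means` (K x D), `covariances`,
#'   `weights`, `covariance`, `converged`, `n_iter`, `score_names`,
#'   `cell_ids`.
#' @export
fit_bgmm <- function(scores, n_components = 2L,
                     covariance = c("diagonal", "spherical", "tied"),
                     seed = 1L, order_by = NULL, max_iter = 500L, tol = 1e-7) {
  covariance <- match.arg(covariance)
  if (inherits(scores, "signature_scores") || is.data.frame(scores)) {
    df <- as.data.frame(scores)
    num <- vapply(df, is.numeric, logical(1))
    x <- as.matrix(df[, num, drop = FALSE])
    cell_ids <- if ("cell_id" %in% names(df)) df$cell_id else rownames(df)
  } else {
    x <- as.matrix(scores)
    cell_ids <- rownames(x)
  }
  n <- nrow(x); D <- ncol(x); K <- as.integer(n_components)
  if (n < K) abort("fewer cells than components", class = "phenarch_error")
  if (all(apply(x, 2, sd) == 0))
    abort("no separable structure: all scores identical", class = "phenarch_error")
  if (is.null(order_by)) order_by <- D
  if (is.character(order_by)) order_by <- match(order_by, colnames(x))

  # priors
  alpha0 <- 1 / K
  beta0 <- 1
  m0 <- colMeans(x)
  v0 <- apply(x, 2, var); v0[v0 == 0] <- mean(v0[v0 > 0])
  a0 <- 1; b0_d <- v0                     # diagonal: Gamma per dim
  b0_s <- mean(v0)                        # spherical
  nu0 <- D                                # tied: Wishart
  cov_emp <- stats::cov(x) + diag(1e-8 * mean(v0), D)
  w0_inv <- cov_emp * nu0                 # prior E[Lambda] = nu0 W0 = cov^-1

  km <- with_seed(seed, kmeans(x, centers = K, nstart = 5, iter.max = 50))
  r <- matrix(1e-10, n, K)
  r[cbind(seq_len(n), km$cluster)] <- 1
  r <- r / rowSums(r)

  ll_old <- -Inf; converged <- FALSE; it <- 0L
  alpha <- beta <- Nk <- NULL; mk <- xbar <- NULL
  Elam_d <- NULL; Elam_s <- NULL; ELam_t <- NULL
  repeat {
    it <- it + 1L
    # ---- M step -------------------------------------------------------
    Nk <- colSums(r) + 1e-10
    xbar <- crossprod(r, x) / Nk                       # K x D
    alpha <- alpha0 + Nk
    beta <- beta0 + Nk
    mk <- (beta0 * matrix(m0, K, D, byrow = TRUE) + Nk * xbar) / beta
    # scatter per component, per dim: S_kd = sum_n r (x - xbar)^2 / Nk
    Skd <- (crossprod(r, x^2) - 2 * xbar * crossprod(r, x) + Nk * xbar^2) / Nk
    Skd[Skd < 0] <- 0
    dev0 <- xbar - matrix(m0, K, D, byrow = TRUE)
    extra <- (beta0 * Nk / beta) * dev0^2
    if (covariance == "diagonal") {
      a_kd <- a0 + Nk / 2
      b_kd <- matrix(b0_d, K, D, byrow = TRUE) + 0.5 * (Nk * Skd + extra)
      Elam_d <- a_kd / b_kd                            # K x D
      Eloglam_d <- digamma(a_kd) - log(b_kd)
    } else if (covariance == "spherical") {
      a_k <- a0 + Nk * D / 2
      b_k <- b0_s + 0.5 * rowSums(Nk * Skd + extra)
      Elam_s <- a_k / b_k
      Eloglam_s <- digamma(a_k) - log(b_k)
    } else {                                           # tied Wishart
      nu <- nu0 + n
      scat <- matrix(0, D, D)
      for (k in seq_len(K)) {
        xc <- sweep(x, 2, xbar[k, ])
        scat <- scat + crossprod(xc * sqrt(r[, k])) +
          (beta0 * Nk[k] / beta[k]) * tcrossprod(dev0[k, ])
      }
      w_inv <- w0_inv + scat
      w <- solve(w_inv)
      ELam_t <- nu * w
      Elogdet_t <- sum(digamma((nu + 1 - seq_len(D)) / 2)) + D * log(2) +
        determinant(w, logarithm = TRUE)$modulus[1]
    }
    # ---- E step -------------------------------------------------------
    Elogpi <- digamma(alpha) - digamma(sum(alpha))
    logr <- matrix(Elogpi, n, K, byrow = TRUE) - 0.5 * D * log(2 * pi)
    for (k in seq_len(K)) {
      d2 <- sweep(x, 2, mk[k, ])
      if (covariance == "diagonal") {
        quad <- d2^2 %*% Elam_d[k, ] + D / beta[k]
        logr[, k] <- logr[, k] + 0.5 * sum(Eloglam_d[k, ]) - 0.5 * quad
      } else if (covariance == "spherical") {
        quad <- Elam_s[k] * rowSums(d2^2) + D / beta[k]
        logr[, k] <- logr[, k] + 0.5 * D * Eloglam_s[k] - 0.5 * quad
      } else {
        quad <- rowSums((d2 %*% ELam_t) * d2) + D / beta[k]
        logr[, k] <- logr[, k] + 0.5 * Elogdet_t - 0.5 * quad
      }
    }
    mx <- apply(logr, 1, max)
    lse <- mx + log(rowSums(exp(logr - mx)))
    r <- exp(logr - lse)
    ll <- mean(lse)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * max(1, abs(ll))) {
      converged <- TRUE; break
    }
    if (it >= max_iter) break
    ll_old <- ll
  }

  # relabel by ascending mean along the class-defining axis
  ord <- order(mk[, order_by])
  r <- r[, ord, drop = FALSE]
  mk <- mk[ord, , drop = FALSE]
  covs <- switch(covariance,
                 diagonal = (if (is.null(Elam_d)) NULL else (1 / Elam_d)[ord, , drop = FALSE]),
                 spherical = 1 / Elam_s[ord],
                 tied = solve(ELam_t))
  weights <- (alpha / sum(alpha))[ord]
  labels <- max.col(r)
  structure(list(labels = labels, posterior = r, means = mk,
                 covariances = covs, weights = weights,
                 covariance = covariance, converged = converged, n_iter = it,
                 score_names = colnames(x), cell_ids = cell_ids,
                 seed = seed, n_components = K),
            class = "bgmm_fit")
}

#' @export
print.bgmm_fit <- function(x, ...) {
  cat(sprintf("<bgmm_fit> %d components (%s covariance), %d cells, %s after %d iterations\n",
              x$n_components, x$covariance, length(x$labels),
              if (x$converged) "converged" else "not converged", x$n_iter))
  print(round(x$means, 3))
  invisible(x)
}

#' Predict component membership for new score vectors
#'
#' Assigns new cells to the fitted components by posterior probability
#' under the fitted Gaussian parameters.
#'
#' @param object a `bgmm_fit`.
#' @param newdata numeric matrix or `signature_scores` with the same
#'   score columns.
#' @param ... unused.
#' @return integer component labels (1..K).
#' @export
predict.bgmm_fit <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata)) {
    as.matrix(newdata[, object$score_names, drop = FALSE])
  } else as.matrix(newdata)
  K <- object$n_components; D <- ncol(x)
  logp <- matrix(log(object$weights), nrow(x), K, byrow = TRUE)
  for (k in seq_len(K)) {
    d2 <- sweep(x, 2, object$means[k, ])
    cv <- switch(object$covariance,
                 diagonal = diag(object$covariances[k, ], D),
                 spherical = diag(rep(object$covariances[k], D), D),
                 tied = object$covariances)
    pr <- solve(cv)
    logp[, k] <- logp[, k] - 0.5 * rowSums((d2 %*% pr) * d2) -
      0.5 * determinant(cv, logarithm = TRUE)$modulus[1]
  }
  max.col(logp)
}

#' Bootstrap per-patient class fractions
#'
#' Corrects class-fraction estimates for unequal cells per patient:
#' `n_rounds` random subsets of `n_cells` cells are drawn per patient
#' (without replacement when enough cells are available, with replacement
#' otherwise), the per-class fraction is computed in each subset, and the
#' mean with a percentile 95% confidence interval across rounds is
#' reported.
#'
#' @param fit a `bgmm_fit` (or an integer label vector).
#' @param patient_ids per-cell patient identifiers, same length/order as
#'   the cells used in the fit.
#' @param n_cells cells per subset (default 500).
#' @param n_rounds subsets per patient (default 20).
#' @param seed integer seed.
#' @param conf confidence level (default 0.95, percentile CI).
#' @return A `fraction_estimate` tibble: `patient`, `class`, `mean_fraction`,
#'   `ci_lower`, `ci_upper`, `n_cells_patient`, `n_rounds`, `n_cells_round`.
#' @export
bootstrap_fractions <- function(fit, patient_ids, n_cells = 500L,
                                n_rounds = 20L, seed = 1L, conf = 0.95) {
  labels <- if (inherits(fit, "bgmm_fit")) fit$labels else as.integer(fit)
  if (length(labels) != length(patient_ids))
    abort("patient_ids must match the number of classified cells",
          class = "phenarch_error")
  classes <- sort(unique(labels))
  pr <- (1 - conf) / 2
  out <- with_seed(seed, {
    purrr::map_dfr(unique(patient_ids), function(pt) {
      idx <- which(patient_ids == pt)
      replace <- length(idx) < n_cells
      if (replace)
        inform(sprintf("patient %s has %d < %d cells: sampling with replacement",
                       pt, length(idx), n_cells))
      fr <- vapply(seq_len(n_rounds), function(r) {
        draw <- sample(idx, n_cells, replace = replace)
        vapply(classes, function(cl) mean(labels[draw] == cl), numeric(1))
      }, numeric(length(classes)))
      fr <- matrix(fr, nrow = length(classes))   # classes x rounds
      tibble::tibble(patient = pt, class = classes,
                     mean_fraction = rowMeans(fr),
                     ci_lower = apply(fr, 1, quantile, pr, names = FALSE),
                     ci_upper = apply(fr, 1, quantile, 1 - pr, names = FALSE),
                     n_cells_patient = length(idx),
                     n_rounds = n_rounds, n_cells_round = n_cells)
    })
  })
  structure(out, class = c("fraction_estimate", class(out)))
}

#' Ranked-cell smoothed expression matrix
#'
#' Orders cells by ascending signature score, z-normalizes each display
#' gene across all cells, and smooths each gene row along the ranking
#' with a centered moving average (shrunken windows at the edges) — the
#' standard presentation of expression trends along a prognostic ranking.
#'
#' @param imputed an `imputed_matrix` (or matrix with gene names).
#' @param sigs a [gene_signatures()] set containing `rank_sig`.
#' @param rank_sig name of the ranking signature.
#' @param display_genes genes to display (must be present).
#' @param window moving-average window in cells (default 20).
#' @return A `ranked_matrix`: list with `z` (genes x ranked cells),
#'   `cell_order` (indices), `scores` (sorted), `rank_sig`, `window`.
#' @export
ranked_matrix <- function(imputed, sigs, rank_sig, display_genes, window = 20L) {
  if (window < 1) abort("window must be >= 1", class = "phenarch_error")
  x <- if (inherits(imputed, "imputed_matrix")) imputed$x else as.matrix(imputed)
  genes <- if (inherits(imputed, "imputed_matrix")) imputed$gene_ids else colnames(x)
  if (window > nrow(x)) abort("window exceeds number of cells", class = "phenarch_error")
  missing <- setdiff(display_genes, genes)
  if (length(missing))
    abort(paste("display genes absent:", paste(missing, collapse = ", ")),
          class = "phenarch_error")
  sc <- score_signature(imputed, sigs[rank_sig])[[rank_sig]]
  ord <- order(sc)
  sub <- x[, match(display_genes, genes), drop = FALSE]
  sds <- apply(sub, 2, sd)
  if (any(sds == 0)) {
    warn("constant gene(s) z-normalized to zero")
  }
  z <- sweep(sub, 2, colMeans(sub))
  z <- sweep(z, 2, ifelse(sds == 0, 1, sds), "/")
  z[, sds == 0] <- 0
  z <- t(z[ord, , drop = FALSE])                 # genes x ranked cells
  z_sm <- t(apply(z, 1, moving_average, window = window))
  dimnames(z_sm) <- list(display_genes, NULL)
  structure(list(z = z_sm, cell_order = ord, scores = sc[ord],
                 rank_sig = rank_sig, window = window),
            class = "ranked_matrix")
}
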