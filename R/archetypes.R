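# Farthest-first seeding: greedy max-min selection of K well-spread data
# points, started from a random point that is itself discarded.  The
# max-min criterion cannot select two coincident points, so coincident
# hull corners are each picked at most once.
furthest_sum <- function(x, K, seed = 1L) {
  n <- nrow(x)
  with_seed(seed, {
    start <- sample.int(n, 1)
    mind <- sqrt(rowSums(sweep(x, 2, x[start, ])^2))
    sel <- integer(0)
    for (step in seq_len(K)) {
      pick <- which.max(mind)
      sel <- c(sel, pick)
      mind <- pmin(mind, sqrt(rowSums(sweep(x, 2, x[pick, ])^2)))
    }
    sel
  })
}

# project columns of m onto {v >= 0, 1 - delta <= sum(v) <= 1 + delta}
project_cols_band <- function(m, delta = 0) {
  if (delta <= 0) return(project_simplex_cols(m))
  s <- pmin(pmax(colSums(pmax(m, 0)), 1 - delta), 1 + delta)
  p <- project_simplex_cols(sweep(m, 2, s, "/"))
  sweep(p, 2, s, "*")
}

#' Principal convex hull (archetypal) analysis
#'
#' Fits K archetypes Z = X'C whose convex combinations S best
#' reconstruct the data (X ~ X C S): alternating projected-gradient
#' minimization of `||X - XCS||_F^2` with C >= 0 (columns summing to 1,
#' within a `delta` relaxation band) and S >= 0 (columns summing to 1).
#' Step sizes adapt with backtracking so the objective never increases.
#' C is seeded by farthest-first (max-min) traversal from a seeded
#' random start.
#'
#' @param pcs a `pc_space` or cells x dims coordinate matrix.
#' @param K number of archetypes (1 <= K <= cells).
#' @param delta relaxation of the C column-sum constraint (default 0,
#'   exact hull).
#' @param seed integer seed (initialization).
#' @param max_iter,tol outer-iteration cap and relative-objective
#'   convergence tolerance.
#' @param n_dims coordinates used (first columns; default all).
#' @param n_inner gradient sub-iterations per block per outer iteration.
#' @param init optional warm start: list with `C` (cells x K) and `S`
#'   (K x cells); used by [select_n_archetypes()] to nest models.
#' @return An `archetype_model`: list with `archetypes` (K x dims), `C`
#'   (cells x K), `S` (K x cells, columns sum to 1), `explained_variance`,
#'   `objective` (per-outer-iteration trace, non-increasing), `converged`,
#'   `K`, `delta`, `seed`.
#' @export
pcha_fit <- function(pcs, K, delta = 0, seed = 1L, max_iter = 200L,
                     tol = 1e-7, n_dims = NULL, n_inner = 10L, init = NULL) {
  xs <- if (inherits(pcs, "pc_space")) pcs$scores else as.matrix(pcs)
  if (!is.null(n_dims)) xs <- xs[, seq_len(min(n_dims, ncol(xs))), drop = FALSE]
  n <- nrow(xs)
  if (K < 1 || K > n) abort("need 1 <= K <= cells", class = "phenarch_error")
  x <- t(xs)                                   # dims x cells
  sst <- sum(sweep(x, 1, rowMeans(x))^2)
  if (sst == 0) abort("all points identical", class = "phenarch_error")

  if (is.null(init)) {
    anchors <- furthest_sum(xs, K, seed = seed)
    C <- matrix(0, n, K); C[cbind(anchors, seq_len(K))] <- 1
    # init S: one-hot at the nearest seeded archetype
    z <- x[, anchors, drop = FALSE]
    near <- if (K == 1) rep(1L, n) else {
      d2 <- matrix(colSums(x^2), K, n, byrow = TRUE) +
        colSums(z^2) - 2 * crossprod(z, x)
      max.col(t(-d2))
    }
    S <- matrix(0, K, n); S[cbind(near, seq_len(n))] <- 1
  } else {
    C <- init$C; S <- init$S
    stopifnot(nrow(C) == n, ncol(C) == K, nrow(S) == K, ncol(S) == n)
  }

  obj <- function(C, S) sum((x - (x %*% C) %*% S)^2)
  f <- obj(C, S)
  trace <- f
  mu_s <- 1; mu_c <- 1
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    f_prev <- f
    # --- S block: several projected-gradient steps with backtracking ---
    Z <- x %*% C                       # dims x K
    ZtZ <- crossprod(Z)
    ZtX <- crossprod(Z, x)
    for (sub in seq_len(n_inner)) {
      gS <- 2 * (ZtZ %*% S - ZtX)
      accepted <- FALSE
      for (bt in 1:20) {
        S_new <- project_simplex_cols(S - mu_s * gS)
        f_new <- sum((x - Z %*% S_new)^2)
        if (f_new <= f) { accepted <- TRUE; break }
        mu_s <- mu_s / 2
      }
      if (!accepted) break
      S <- S_new; f <- f_new; mu_s <- mu_s * 1.2
    }
    # --- C block ---
    SSt <- tcrossprod(S)
    XSt <- x %*% t(S)                  # dims x K
    XtX_C <- function(C) crossprod(x, (x %*% C))
    for (sub in seq_len(n_inner)) {
      gC <- 2 * (XtX_C(C) %*% SSt - crossprod(x, XSt))
      accepted <- FALSE
      for (bt in 1:20) {
        C_new <- project_cols_band(C - mu_c * gC, delta)
        f_new <- sum((x - (x %*% C_new) %*% S)^2)
        if (f_new <= f) { accepted <- TRUE; break }
        mu_c <- mu_c / 2
      }
      if (!accepted) break
      C <- C_new; f <- f_new; mu_c <- mu_c * 1.2
    }
    trace <- c(trace, f)
    # converged on relative improvement, or at an (effectively) exact fit
    if (f_prev - f < tol * max(f_prev, .Machine$double.eps) ||
        f < 1e-12 * sst) {
      converged <- TRUE; break
    }
  }
  if (!converged)
    warn(sprintf("PCHA did not converge in %d iterations (returning best iterate)",
                 max_iter))
  structure(list(archetypes = t(x %*% C), C = C, S = S,
                 explained_variance = max(0, 1 - f / sst),
                 objective = trace, converged = converged,
                 K = K, delta = delta, seed = seed),
            class = "archetype_model")
}

#' @export
print.archetype_model <- function(x, ...) {
  cat(sprintf("<archetype_model> K = %d, explained variance %.4f (%s)\n",
              x$K, x$explained_variance,
              if (x$converged) "converged" else "max iterations"))
  invisible(x)
}

#' Choose the number of archetypes
#'
#' Fits PCHA over a grid of K and returns the knee of the explained
#' variance versus K curve ([knee_point()], max distance to chord).
#' Successive fits are warm-started from the previous solution plus one
#' fresh archetype, which nests the models and makes explained variance
#' non-decreasing in K. A flat curve falls back to the smallest K with a
#' warning.
#'
#' @param pcs a `pc_space` or coordinate matrix.
#' @param K_grid ascending integer vector of archetype counts.
#' @param seed integer seed.
#' @param ... passed to [pcha_fit()].
#' @return list with `K` (the selection), `curve` (tibble `K`,
#'   `explained_variance`), and `fits` (the fitted models, by K).
#' @export
select_n_archetypes <- function(pcs, K_grid, seed = 1L, ...) {
  K_grid <- sort(unique(as.integer(K_grid)))
  xs <- if (inherits(pcs, "pc_space")) pcs$scores else as.matrix(pcs)
  fits <- vector("list", length(K_grid))
  prev <- NULL
  for (i in seq_along(K_grid)) {
    K <- K_grid[i]
    init <- NULL
    if (!is.null(prev) && K > prev$K) {
      # nest: keep the previous archetypes, add fresh ones at the points
      # farthest (min-distance) from the current archetype set
      C <- cbind(prev$C, matrix(0, nrow(prev$C), K - prev$K))
      S <- rbind(prev$S, matrix(0, K - prev$K, ncol(prev$S)))
      arch <- prev$archetypes
      for (k in (prev$K + 1):K) {
        d2 <- vapply(seq_len(nrow(xs)), function(p)
          min(rowSums(sweep(arch, 2, xs[p, ])^2)), numeric(1))
        pick <- which.max(d2)
        C[pick, k] <- 1
        arch <- rbind(arch, xs[pick, ])
      }
      init <- list(C = C, S = S)
    }
    fits[[i]] <- pcha_fit(xs, K, seed = seed, init = init, ...)
    prev <- fits[[i]]
  }
  ev <- vapply(fits, `[[`, numeric(1), "explained_variance")
  curve <- tibble::tibble(K = K_grid, explained_variance = ev)
  if (length(K_grid) == 1)
    return(list(K = K_grid, curve = curve, fits = setNames(fits, K_grid)))
  knee <- knee_point(K_grid, ev)
  if (is.na(knee)) {
    warn("explained-variance curve is flat: returning the smallest K")
    knee <- 1L
  }
  list(K = K_grid[knee], curve = curve, fits = setNames(fits, K_grid))
}

#' Archetype neighbourhoods in multi-scale diffusion space
#'
#' Anchors each archetype at its Euclidean-nearest cell in PC space and
#' defines a soft neighbourhood: the cells whose multi-scale diffusion
#' distance to the anchor is below half the multi-scale distance to the
#' nearest other anchor — so every neighbourhood spans a comparable range
#' on the manifold and neighbourhoods cannot overlap-collide. Every cell
#' is additionally assigned to its multi-scale-nearest anchor.
#'
#' @param dm a `diffusion_map` over the same cells.
#' @param model an `archetype_model`.
#' @param pcs the `pc_space` (or matrix) the model was fitted on.
#' @param mode,t distance mode passed to the multi-scale distance.
#' @return An `archetype_neighborhoods`: list with `anchor` (cell index
#'   per archetype), `radius`, `members` (list of cell indices), and
#'   `assignment` (tibble: `cell`, `nearest_archetype`,
#'   `distance_to_anchor`, `in_neighborhood`).
#' @export
archetype_neighborhoods <- function(dm, model, pcs,
                                    mode = c("multiscale", "single-t"), t = 3) {
  xs <- if (inherits(pcs, "pc_space")) pcs$scores else as.matrix(pcs)
  if (nrow(xs) != nrow(dm$components))
    abort("diffusion map and PC space disagree on cell count",
          class = "phenarch_error")
  K <- model$K
  arch <- model$archetypes
  xs <- xs[, seq_len(ncol(arch)), drop = FALSE]
  anchor <- vapply(seq_len(K), function(a)
    which.min(colSums((t(xs) - arch[a, ])^2)), integer(1))
  if (anyDuplicated(anchor))
    abort("degenerate archetypes: two archetypes share an anchor cell",
          class = "phenarch_error")
  emb <- diffusion_embedding(dm, mode = mode, t = t)
  # distances of every cell to every anchor
  d2a <- vapply(anchor, function(a)
    sqrt(rowSums(sweep(emb, 2, emb[a, ])^2)), numeric(nrow(emb)))
  inter <- d2a[anchor, , drop = FALSE]          # anchor-anchor distances
  radius <- vapply(seq_len(K), function(a)
    0.5 * min(inter[a, -a]), numeric(1))
  members <- lapply(seq_len(K), function(a) which(d2a[, a] < radius[a]))
  nearest <- max.col(-d2a)
  assignment <- tibble::tibble(
    cell = seq_len(nrow(emb)),
    nearest_archetype = nearest,
    distance_to_anchor = d2a[cbind(seq_len(nrow(emb)), nearest)],
    in_neighborhood = vapply(seq_len(nrow(emb)), function(i)
      i %in% members[[nearest[i]]], logical(1)))
  structure(list(anchor = anchor, radius = radius, members = members,
                 assignment = assignment, mode = match.arg(mode)),
            class = "archetype_neighborhoods")
}

#' @export
print.archetype_neighborhoods <- function(x, ...) {
  cat(sprintf("<archetype_neighborhoods> %d archetypes; neighbourhood sizes: %s\n",
              length(x$anchor), paste(lengths(x$members), collapse = ", ")))
  invisible(x)
}

#' Earth mover's distance between two samples
#'
#' The 1-D Wasserstein-1 distance between the empirical distributions of
#' two samples (equal weights within each sample; sizes may differ),
#' computed as the area between the two empirical CDFs.
#'
#' @param sample_a,sample_b non-empty numeric vectors.
#' @return a non-negative number.
#' @export
emd_score <- function(sample_a, sample_b) {
  if (length(sample_a) == 0 || length(sample_b) == 0)
    abort("empty sample", class = "phenarch_error")
  z <- sort(c(sample_a, sample_b))
  if (z[1] == z[length(z)]) return(0)
  zu <- unique(z)
  fa <- stats::ecdf(sample_a)(zu)
  fb <- stats::ecdf(sample_b)(zu)
  m <- length(zu)
  sum(abs(fa[-m] - fb[-m]) * diff(zu))
}

#' EMD marker scores per archetype
#'
#' For each archetype, compares the expression of every gene inside its
#' neighbourhood against a background of the same number of cells drawn
#' from the non-members; the earth mover's distance is averaged over
#' `n_resamples` background draws. High-scoring genes maximally
#' distinguish the bounding phenotypic state from the rest of the
#' population.
#'
#' @param imputed an `imputed_matrix` (or matrix); scored genes come from
#'   `gene_mask`.
#' @param nbhd an `archetype_neighborhoods`.
#' @param gene_mask logical mask or character vector of genes to score
#'   (typically the variably expressed set; default all genes).
#' @param n_resamples background draws per archetype (default 100).
#' @param seed integer seed.
#' @return An `emd_markers` tibble: `archetype`, `gene`, `emd` (mean
#'   score, >= 0), sorted by descending score within archetype.
#' @export
archetype_markers <- function(imputed, nbhd, gene_mask = NULL,
                              n_resamples = 100L, seed = 1L) {
  x <- if (inherits(imputed, "imputed_matrix")) imputed$x else as.matrix(imputed)
  genes <- if (inherits(imputed, "imputed_matrix")) imputed$gene_ids else colnames(x)
  if (is.null(genes)) genes <- paste0("gene", seq_len(ncol(x)))
  gidx <- if (is.null(gene_mask)) seq_len(ncol(x))
          else if (is.logical(gene_mask)) which(gene_mask)
          else match(gene_mask, genes)
  K <- length(nbhd$members)
  n <- nrow(x)
  out <- with_seed(seed, {
    purrr::map_dfr(seq_len(K), function(a) {
      mem <- nbhd$members[[a]]
      if (length(mem) == 0) {
        warn(sprintf("archetype %d has an empty neighbourhood: skipped", a))
        return(tibble::tibble())
      }
      pool <- setdiff(seq_len(n), mem)
      replace <- length(pool) < length(mem)
      if (replace)
        warn(sprintf("archetype %d: background pool smaller than neighbourhood, sampling with replacement", a))
      xm <- x[mem, gidx, drop = FALSE]
      acc <- numeric(length(gidx))
      for (r in seq_len(n_resamples)) {
        bg <- sample(pool, length(mem), replace = replace)
        xb <- x[bg, gidx, drop = FALSE]
        acc <- acc + vapply(seq_along(gidx), function(g)
          emd_score(xm[, g], xb[, g]), numeric(1))
      }
      tibble::tibble(archetype = a, gene = genes[gidx],
                     emd = acc / n_resamples) |>
        dplyr::arrange(dplyr::desc(.data$emd))
    })
  })
  structure(out, n_resamples = n_resamples,
            class = c("emd_markers", class(out)))
}
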