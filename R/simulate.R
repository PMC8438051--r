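#' Parameters for the synthetic atlas generator
#'
#' Defaults describe a droplet run of a solid-tumor biopsy: ~1000 viable
#' tumor cells on a continuum between archetypal expression programs, a
#' minority non-tumor population with private marker genes, an order of
#' magnitude more ambient-only (empty) barcodes at a few percent of a
#' cell's library size, lognormal library sizes around 2000 UMIs, ~5%
#' mitochondrial content with a small apoptotic tail above 25%.
#'
#' @param n_tumor_cells,n_other_cells,n_empty_droplets barcode counts per
#'   compartment.
#' @param n_genes total genes, including mitochondrial genes.
#' @param n_mito_genes genes named with the "MT-" prefix.
#' @param n_archetypes number of archetypal tumor expression programs (K).
#' @param dirichlet_alpha concentration of per-cell archetype weights;
#'   small values push cells toward single programs.
#' @param libsize_logmean,libsize_logsd natural-log parameters of the
#'   lognormal per-cell library-size factor.
#' @param empty_libsize_scale ambient barcode library size as a fraction of
#'   the typical cell library size (must be in (0,1)).
#' @param mito_fraction_mean mean mitochondrial fraction of healthy cells.
#' @param apoptotic_fraction fraction of cells given an elevated
#'   mitochondrial fraction (drawn around `apoptotic_mito`).
#' @param apoptotic_mito mitochondrial fraction of the apoptotic subpopulation.
#' @param n_patients patients; cells are assigned round-robin.
#' @param nb_size negative-binomial size (dispersion) parameter; `Inf`
#'   (default) gives Poisson counts.
#' @param seed integer seed; the same seed reproduces the atlas exactly.
#' @return A named list of class `simulation_params`.
#' @export
simulation_params <- function(n_tumor_cells = 1000L, n_other_cells = 200L,
                              n_empty_droplets = 10000L, n_genes = 500L,
                              n_mito_genes = 10L, n_archetypes = 4L,
                              dirichlet_alpha = 0.5,
                              libsize_logmean = log(2000), libsize_logsd = 0.35,
                              empty_libsize_scale = 0.025,
                              mito_fraction_mean = 0.05,
                              apoptotic_fraction = 0.02, apoptotic_mito = 0.4,
                              n_patients = 1L, nb_size = Inf, seed = 1L) {
  stopifnot(n_archetypes >= 2, n_genes > n_mito_genes,
            empty_libsize_scale > 0, empty_libsize_scale < 1,
            mito_fraction_mean >= 0, mito_fraction_mean <= 1)
  structure(as.list(environment()), class = "simulation_params")
}

rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), n, k)
  g / pmax(rowSums(g), .Machine$double.eps)
}

rcounts <- function(n, mu, nb_size) {
  if (is.infinite(nb_size)) rpois(n, mu)
  else stats::rnbinom(n, size = nb_size, mu = mu)
}

#' Simulate a droplet scRNA-seq atlas with planted ground truth
#'
#' Tumor-cell gene rates are convex combinations (Dirichlet weights) of K
#' archetypal programs; non-tumor cells express a private marker program;
#' a Beta-distributed fraction of each cell's rate mass is reallocated to
#' mitochondrial genes, with a designated apoptotic subpopulation above
#' 25%; empty droplets draw from the ambient profile (the mean rate of all
#' cells) at a small fraction of a typical library. Counts are Poisson (or
#' negative-binomial) at `libsize_factor * rate / sum(rate)`.
#'
#' @param params a [simulation_params()] object.
#' @return A list with `counts` (a [counts_matrix()]) and `truth`, a tibble
#'   with one row per barcode: `cell_id`, `patient`, `type`
#'   (tumor/other/empty), `libsize_factor`, `mito_fraction`, `apoptotic`,
#'   and `archetype_w1..wK` (simplex weights, tumor cells only).
#' @export
simulate_atlas <- function(params = simulation_params()) {
  p <- params
  with_seed(p$seed, {
    mito_idx <- seq_len(p$n_mito_genes)
    gene_ids <- c(paste0("MT-G", mito_idx),
                  sprintf("GENE%04d", seq_len(p$n_genes - p$n_mito_genes)))
    n_nuc <- p$n_genes - p$n_mito_genes

    # K archetypal programs over nuclear genes: shared lognormal baseline
    # plus a block of program-private high-expression genes.
    base <- rlnorm(n_nuc, meanlog = 0, sdlog = 1)
    programs <- matrix(rep(base, each = p$n_archetypes), p$n_archetypes, n_nuc)
    block <- max(1L, floor(n_nuc * 0.08))
    for (a in seq_len(p$n_archetypes)) {
      hi <- ((a - 1L) * block + 1L):(a * block)
      programs[a, hi] <- programs[a, hi] * 12
    }
    # non-tumor marker program: its own private block after the archetype blocks
    other_prog <- base
    if (p$n_other_cells > 0) {
      hi <- (p$n_archetypes * block + 1L):min((p$n_archetypes + 1L) * block, n_nuc)
      other_prog[hi] <- other_prog[hi] * 15
    }
    mito_base <- rlnorm(p$n_mito_genes, meanlog = 0, sdlog = 0.3)

    n_cells <- p$n_tumor_cells + p$n_other_cells
    w <- rdirichlet(p$n_tumor_cells, rep(p$dirichlet_alpha, p$n_archetypes))
    nuc_rate <- rbind(
      if (p$n_tumor_cells > 0) w %*% programs,
      if (p$n_other_cells > 0)
        matrix(rep(other_prog, each = p$n_other_cells), p$n_other_cells, n_nuc))
    nuc_rate <- nuc_rate / rowSums(nuc_rate)

    libsize <- rlnorm(n_cells, p$libsize_logmean, p$libsize_logsd)
    apop <- rbinom(n_cells, 1, p$apoptotic_fraction) == 1
    mito_f <- if (p$mito_fraction_mean > 0)
      rbeta(n_cells, p$mito_fraction_mean * 60, (1 - p$mito_fraction_mean) * 60)
    else rep(0, n_cells)
    mito_f[apop] <- rbeta(sum(apop), p$apoptotic_mito * 60,
                          (1 - p$apoptotic_mito) * 60)
    mito_p <- mito_base / sum(mito_base)

    rate <- cbind(outer(mito_f, mito_p), nuc_rate * (1 - mito_f))
    mu <- rate * libsize
    counts <- matrix(rcounts(length(mu), as.vector(mu), p$nb_size),
                     n_cells, p$n_genes)

    # ambient profile: mean rate of all cells, at a small library size
    if (p$n_empty_droplets > 0) {
      ambient <- colMeans(rate)
      ambient <- ambient / sum(ambient)
      empty_lib <- exp(p$libsize_logmean) * p$empty_libsize_scale *
        rlnorm(p$n_empty_droplets, 0, p$libsize_logsd)
      mu_e <- outer(empty_lib, ambient)
      empties <- matrix(rcounts(length(mu_e), as.vector(mu_e), p$nb_size),
                        p$n_empty_droplets, p$n_genes)
      counts <- rbind(counts, empties)
      libsize <- c(libsize, empty_lib)
    }

    type <- c(rep("tumor", p$n_tumor_cells), rep("other", p$n_other_cells),
              rep("empty", p$n_empty_droplets))
    n_bc <- nrow(counts)
    cell_id <- sprintf("BC%05d", seq_len(n_bc))
    patient <- paste0("P", ((seq_len(n_bc) - 1L) %% p$n_patients) + 1L)
    patient[type == "empty"] <- NA_character_

    wfull <- matrix(NA_real_, n_bc, p$n_archetypes,
                    dimnames = list(NULL, paste0("archetype_w", seq_len(p$n_archetypes))))
    if (p$n_tumor_cells > 0) wfull[seq_len(p$n_tumor_cells), ] <- w

    truth <- tibble::tibble(
      cell_id = cell_id, patient = patient, type = type,
      libsize_factor = libsize,
      mito_fraction = c(mito_f, rep(NA_real_, p$n_empty_droplets)),
      apoptotic = c(apop, rep(FALSE, p$n_empty_droplets)))
    truth <- dplyr::bind_cols(truth, tibble::as_tibble(wfull))

    list(counts = counts_matrix(counts, cell_ids = cell_id, gene_ids = gene_ids),
         truth = truth)
  })
}

# Poisson prediction of the per-gene expression separation (in pooled
# within-class SD units of a single gene's normalized count) as a function
# of the rate lift gamma, used to calibrate simulate_two_class.  Per-gene
# share p, library size L.
two_class_separation <- function(gamma, p, L) {
  delta <- p * (gamma - 1 / gamma)
  sd_pooled <- sqrt(p * (gamma + 1 / gamma) / (2 * L))
  delta / sd_pooled
}

#' Simulate a two-class (low-risk/high-risk) tumor cohort
#'
#' Plants two transcriptional classes: class-2 cells over-express each
#' class-2 signature gene and under-express each class-1 gene by a rate
#' lift calibrated (under the Poisson model) so that every signature
#' gene's normalized expression separates between classes by `separation`
#' pooled within-class standard deviations. The per-cell signature score
#' (the mean over the `n_sig_genes` genes) then separates by
#' `separation * sqrt(n_sig_genes)` score SDs along each axis — the same
#' noise averaging that makes multi-gene prognostic panels far more
#' reliable than any single marker gene. `separation = 0` gives identical
#' classes (no signal).
#'
#' @param fracs named numeric vector or list: per-patient fraction of
#'   class-2 cells, each in \[0, 1\].
#' @param separation per-gene effect size in pooled within-class SD units
#'   (>= 0).
#' @param n_cells_per_patient cells simulated per patient.
#' @param n_genes total genes; the first `2 * n_sig_genes` are the two
#'   signatures (`SIG1_*`, `SIG2_*`).
#' @param n_sig_genes genes per signature.
#' @param libsize_logmean,libsize_logsd library-size lognormal parameters.
#' @param seed integer seed.
#' @return list with `counts` ([counts_matrix()]), `truth` tibble
#'   (`cell_id`, `patient`, `class` in {1,2}), and `signatures`
#'   ([gene_signatures()] with `SIG1`, `SIG2`).
#' @export
simulate_two_class <- function(fracs, separation = 3,
                               n_cells_per_patient = 2000L,
                               n_genes = 200L, n_sig_genes = 10L,
                               libsize_logmean = log(2000),
                               libsize_logsd = 0.25, seed = 1L) {
  fracs <- unlist(fracs)
  if (any(fracs < 0 | fracs > 1)) abort("fractions outside [0,1]", class = "phenarch_error")
  if (separation < 0) abort("separation must be >= 0", class = "phenarch_error")
  if (is.null(names(fracs))) names(fracs) <- paste0("P", seq_along(fracs))
  with_seed(seed, {
    m <- n_sig_genes
    p_share <- 1 / n_genes
    L <- exp(libsize_logmean)
    gamma <- if (separation == 0) 1 else
      stats::uniroot(function(g) two_class_separation(g, p_share, L) - separation,
                     c(1 + 1e-9, 200))$root

    gene_ids <- c(paste0("SIG1_", seq_len(m)), paste0("SIG2_", seq_len(m)),
                  sprintf("BG%04d", seq_len(n_genes - 2 * m)))
    base <- rep(1, n_genes)

    n_pat <- length(fracs)
    n_total <- n_pat * n_cells_per_patient
    patient <- rep(names(fracs), each = n_cells_per_patient)
    cls <- unlist(lapply(fracs, function(f)
      1L + rbinom(n_cells_per_patient, 1, f)))

    lift1 <- ifelse(cls == 1L, gamma, 1 / gamma)   # class 1 high on SIG1
    lift2 <- ifelse(cls == 2L, gamma, 1 / gamma)
    rate <- matrix(rep(base, each = n_total), n_total, n_genes)
    rate[, seq_len(m)] <- rate[, seq_len(m)] * lift1
    rate[, m + seq_len(m)] <- rate[, m + seq_len(m)] * lift2
    rate <- rate / rowSums(rate)

    libsize <- rlnorm(n_total, libsize_logmean, libsize_logsd)
    counts <- matrix(rpois(n_total * n_genes, as.vector(rate * libsize)),
                     n_total, n_genes)
    cell_id <- sprintf("%s_C%05d", patient, seq_len(n_total))
    list(counts = counts_matrix(counts, cell_ids = cell_id, gene_ids = gene_ids),
         truth = tibble::tibble(cell_id = cell_id, patient = patient,
                                class = cls),
         signatures = gene_signatures(list(
           SIG1 = paste0("SIG1_", seq_len(m)),
           SIG2 = paste0("SIG2_", seq_len(m)))))
  })
}

#' Simulate noisy points on a simplex
#'
#' Draws `n_points` convex combinations (Dirichlet weights) of K planted
#' vertices in `dim` dimensions, plus isotropic Gaussian noise — the
#' canonical recovery fixture for archetypal analysis.
#'
#' @param K number of vertices.
#' @param n_points points to draw (>= K).
#' @param noise_sd isotropic noise SD, in the same units as the vertex
#'   coordinates (vertices have RMS coordinate ~1).
#' @param dim ambient dimension; warns when `dim < K - 1` (degenerate simplex).
#' @param dirichlet_alpha weight concentration; < 1 pushes points toward
#'   vertices so the hull is identifiable.
#' @param seed integer seed.
#' @return list with `points` (n x dim), `vertices` (K x dim) and
#'   `weights` (n x K).
#' @export
simulate_simplex <- function(K, n_points, noise_sd = 0.01, dim = max(K - 1, 1),
                             dirichlet_alpha = 0.5, seed = 1L) {
  if (K > n_points) abort("K must be <= n_points", class = "phenarch_error")
  if (dim < K - 1) warn("dim < K - 1: simplex is degenerate")
  with_seed(seed, {
    vertices <- matrix(rnorm(K * dim), K, dim)
    w <- rdirichlet(n_points, rep(dirichlet_alpha, K))
    points <- w %*% vertices +
      matrix(rnorm(n_points * dim, sd = noise_sd), n_points, dim)
    list(points = points, vertices = vertices, weights = w)
  })
}
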