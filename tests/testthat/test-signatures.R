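make_imputed <- function(x, genes = colnames(x)) {
  structure(list(x = x, gene_ids = genes,
                 cell_ids = rownames(x) %||% paste0("c", seq_len(nrow(x))),
                 t = 3),
            class = "imputed_matrix")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("signature scoring averages present genes and warns on absences", {
  x <- matrix(c(2, 4, 10, 1, 3, 20), 2, 3, byrow = TRUE,
              dimnames = list(NULL, c("A", "B", "C")))
  imp <- make_imputed(x)
  sc <- score_signature(imp, gene_signatures(list(S = c("A", "B"))))
  expect_equal(sc$S, c(3, 2))
  expect_warning(
    sc2 <- score_signature(imp, gene_signatures(list(S = c("A", "B", "ZZ")))),
    "absent")
  expect_equal(sc2$S, c(3, 2))
  expect_error(score_signature(imp, gene_signatures(list(S = "NOPE"))),
               "no genes")
  # linearity in the expression matrix
  sc3 <- score_signature(make_imputed(5 * x), gene_signatures(list(S = c("A", "B"))))
  expect_equal(sc3$S, 5 * sc$S)
})

test_that("the Bayesian mixture recovers planted components in all covariance modes", {
  set.seed(51)
  x <- rbind(cbind(rnorm(400, 0, 0.3), rnorm(400, 3, 0.3)),
             cbind(rnorm(400, 3, 0.3), rnorm(400, 0, 0.3)))
  colnames(x) <- c("S1", "S2")
  truth <- rep(c(2, 1), each = 400)        # first block is high on axis 2
  for (cv in c("diagonal", "spherical", "tied")) {
    fit <- fit_bgmm(x, 2, covariance = cv, seed = 1, order_by = "S2")
    expect_equal(ari(fit$labels, truth), 1)
    expect_equal(rowSums(fit$posterior), rep(1, 800), tolerance = 1e-8)
    expect_identical(fit$labels, max.col(fit$posterior))
    # component 2 is the one with the larger mean on the ordering axis
    expect_gt(fit$means[2, "S2"], fit$means[1, "S2"])
  }
  # seeded determinism
  f1 <- fit_bgmm(x, 2, seed = 7); f2 <- fit_bgmm(x, 2, seed = 7)
  expect_identical(f1$labels, f2$labels)
  expect_equal(f1$posterior, f2$posterior, tolerance = 1e-12)
  expect_error(fit_bgmm(matrix(1, 50, 2), 2), "no separable")
})

test_that("four well-separated groups are recovered by a spherical mixture", {
  set.seed(52)
  centers <- rbind(c(0, 0), c(5, 0), c(0, 5), c(5, 5))
  x <- make_blobs(150, centers, sd = 0.3, seed = 52)
  colnames(x) <- c("S1", "S2")
  fit <- fit_bgmm(x, 4, covariance = "spherical", seed = 1)
  expect_equal(ari(fit$labels, rep(1:4, each = 150)), 1)
})

test_that("mixture fit agrees with an established EM implementation", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  set.seed(53)
  x <- rbind(cbind(rnorm(300, 0, 0.4), rnorm(300, 4, 0.4)),
             cbind(rnorm(300, 4, 0.4), rnorm(300, 0, 0.4)))
  fit <- fit_bgmm(x, 2, "diagonal", seed = 1)
  mc <- mclust::Mclust(x, G = 2, modelNames = "VVI", verbose = FALSE)
  expect_equal(ari(fit$labels, mc$classification), 1)
})

test_that("bootstrap fractions honor planted per-patient mixtures", {
  set.seed(54)
  labels <- c(rep(2L, 800),                      # P1: pure class 2
              rbinom(2000, 1, 0.7) + 1L)         # P2: 70% class 2... in class coding
  labels[801:2800] <- ifelse(stats::runif(2000) < 0.7, 2L, 1L)
  patients <- c(rep("P1", 800), rep("P2", 2000))
  fr <- suppressMessages(bootstrap_fractions(labels, patients, seed = 2))
  p1 <- fr[fr$patient == "P1" & fr$class == 2, ]
  expect_equal(p1$mean_fraction, 1)
  expect_equal(p1$ci_lower, 1); expect_equal(p1$ci_upper, 1)
  p2 <- fr[fr$patient == "P2" & fr$class == 2, ]
  se <- sqrt(0.7 * 0.3 / 500)
  expect_lt(abs(p2$mean_fraction - 0.7), 3 * se)
  expect_true(p2$ci_lower <= p2$mean_fraction && p2$mean_fraction <= p2$ci_upper)
  # class fractions sum to one within patient
  sums <- tapply(fr$mean_fraction, fr$patient, sum)
  expect_equal(as.numeric(sums), rep(1, 2), tolerance = 1e-12)
  expect_error(bootstrap_fractions(labels, patients[-1]), "match")
})

test_that("classification power rises with per-gene separation", {
  fracs <- c(P1 = 0.5)
  acc <- sapply(c(0, 2, 4), function(s) {
    tc <- simulate_two_class(fracs, separation = s,
                             n_cells_per_patient = 800, seed = 55)
    nm <- median_normalize(tc$counts)
    sc <- score_signature(make_imputed(nm$x, nm$gene_ids), tc$signatures)
    fit <- fit_bgmm(sc, 2, "diagonal", seed = 1, order_by = "SIG2")
    mean(fit$labels == tc$truth$class)
  })
  # no signal: coin-flip accuracy; strong signal: essentially perfect
  expect_gt(acc[1], 0.40); expect_lt(acc[1], 0.60)
  expect_gt(acc[2], 0.99)
  expect_gt(acc[3], 0.999)
})

test_that("ranked matrices sort, z-normalize and smooth as specified", {
  set.seed(56)
  n <- 60
  g <- sort(rnorm(n))[sample(n)]       # a gene with distinct values
  x <- cbind(RANKGENE = g, OTHER = rnorm(n), FLAT = rep(2, n))
  imp <- make_imputed(x)
  sigs <- gene_signatures(list(RS = "RANKGENE"))
  expect_warning(
    rm <- ranked_matrix(imp, sigs, "RS", c("RANKGENE", "OTHER", "FLAT"),
                        window = 20),
    "constant")
  # constant gene: all-zero row after z-normalization
  expect_equal(unname(rm$z["FLAT", ]), rep(0, n))
  # a gene equal to the ranking score is non-decreasing after smoothing
  expect_true(all(diff(rm$z["RANKGENE", ]) >= -1e-12))
  # window = 1 is the identity on the sorted z-scores
  rm1 <- suppressWarnings(
    ranked_matrix(imp, sigs, "RS", c("RANKGENE", "OTHER"), window = 1))
  zs <- (g - mean(g)) / sd(g)
  expect_equal(unname(rm1$z["RANKGENE", ]), sort(zs), tolerance = 1e-12)
  expect_error(ranked_matrix(imp, sigs, "RS", "RANKGENE", window = 0), ">= 1")
  expect_error(ranked_matrix(imp, sigs, "RS", "MISSING"), "absent")
})
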