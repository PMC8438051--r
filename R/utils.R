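#' @importFrom rlang abort warn inform .data
#' @importFrom stats cor dist kmeans lm median prcomp quantile resid rnorm
#'   rpois runif rlnorm rbeta rbinom sd var dt setNames coef predict
#' @importFrom utils head tail
NULL

#' Knee point of a curve by maximum distance to chord
#'
#' Finds the index of the point on `(x, y)` farthest (perpendicular distance)
#' from the chord joining the first and last points. Used uniformly for
#' model-size selection (cumulative explained variance of principal
#' components, explained variance versus archetype number).
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return integer index of the knee; `NA` when the curve is flat
#'   (all points on the chord within `tol`).
#' @param tol numeric; curves whose maximum chord distance is below `tol`
#'   are declared flat.
#' @export
knee_point <- function(x, y, tol = 1e-10) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) return(if (n == 0) NA_integer_ else n)
  # scale both axes to [0,1] so the chord rule is unit-free
  xs <- (x - x[1]) / max(x[n] - x[1], .Machine$double.eps)
  ys <- (y - y[1]) / max(abs(y[n] - y[1]), .Machine$double.eps)
  # perpendicular distance to the chord from (0,0) to (1, ys[n]/|ys[n]|)
  dxv <- xs[n] - xs[1]; dyv <- ys[n] - ys[1]
  len <- sqrt(dxv^2 + dyv^2)
  d <- abs(dxv * (ys[1] - ys) - (xs[1] - xs) * dyv) / len
  if (max(d) < tol) return(NA_integer_)
  which.max(d)
}

#' Two-Gaussian least-squares fit to a histogram
#'
#' Fits the sum of two Gaussian densities to a binned histogram of `values`
#' by nonlinear least squares, initialized at the 25th/75th percentiles.
#' The "second" component is the one with the larger fitted mean. Used by
#' the gene-expression filter and the variable-gene selector, both of which
#' threshold relative to the upper mode of a bimodal distribution.
#'
#' @param values numeric vector.
#' @param bins number of histogram bins.
#' @return list with `mu1`, `sd1`, `a1`, `mu2`, `sd2`, `a2` (components
#'   ordered by ascending mean) and `converged`; or `NULL` when the fit
#'   fails or degenerates.
#' @export
fit_bimodal <- function(values, bins = 50) {
  values <- values[is.finite(values)]
  if (length(values) < 10 || sd(values) == 0) return(NULL)
  h <- graphics::hist(values, breaks = bins, plot = FALSE)
  xs <- h$mids
  ys <- h$density
  q <- quantile(values, c(0.25, 0.75), names = FALSE)
  rng <- diff(range(xs))
  try_fit <- function(s_init) {
    tryCatch(
      minpack.lm::nlsLM(
        ys ~ a1 * exp(-((xs - m1) / s1)^2 / 2) + a2 * exp(-((xs - m2) / s2)^2 / 2),
        start = list(a1 = max(ys), m1 = q[1], s1 = s_init,
                     a2 = max(ys) / 2, m2 = q[2], s2 = s_init),
        lower = c(0, min(xs), rng / (10 * bins), 0, min(xs), rng / (10 * bins)),
        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
  }
  # a fit is usable when both components carry mass and their means are
  # separated relative to the component widths; on unimodal data one
  # component collapses onto a shoulder of the other and is rejected
  validate <- function(fit) {
    if (is.null(fit)) return(NULL)
    p <- coef(fit)
    comp <- list(list(mu = p[["m1"]], sd = abs(p[["s1"]]), a = p[["a1"]]),
                 list(mu = p[["m2"]], sd = abs(p[["s2"]]), a = p[["a2"]]))
    comp <- comp[order(vapply(comp, `[[`, numeric(1), "mu"))]
    if (comp[[1]]$a <= 0.001 * max(ys) || comp[[2]]$a <= 0.001 * max(ys) ||
        comp[[2]]$mu - comp[[1]]$mu < 2 * (comp[[1]]$sd + comp[[2]]$sd))
      return(NULL)
    list(mu1 = comp[[1]]$mu, sd1 = comp[[1]]$sd, a1 = comp[[1]]$a,
         mu2 = comp[[2]]$mu, sd2 = comp[[2]]$sd, a2 = comp[[2]]$a,
         converged = TRUE)
  }
  s0 <- max((q[2] - q[1]) / 8, rng / bins)
  for (s_init in c(s0, 3 * s0, sd(values) / 2)) {
    out <- validate(try_fit(s_init))
    if (!is.null(out)) return(out)
  }
  NULL
}

# Seeded randomized SVD (range finder + power iterations).  Exact svd is
# used when the problem is small enough that randomization buys nothing.
randomized_svd <- function(x, k, n_oversample = 10, n_iter = 4, seed = NULL) {
  m <- nrow(x); n <- ncol(x)
  k <- min(k, m, n)
  if (min(m, n) <= max(2 * (k + n_oversample), 100)) {
    s <- svd(x, nu = k, nv = k)
    return(list(u = s$u[, seq_len(k), drop = FALSE], d = s$d[seq_len(k)],
                v = s$v[, seq_len(k), drop = FALSE]))
  }
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  p <- min(k + n_oversample, n)
  omega <- matrix(rnorm(n * p), n, p)
  y <- as.matrix(x %*% omega)
  q <- qr.Q(qr(y))
  for (i in seq_len(n_iter)) {
    z <- as.matrix(Matrix::crossprod(x, q))
    q <- qr.Q(qr(z))
    y <- as.matrix(x %*% q)
    q <- qr.Q(qr(y))
  }
  b <- as.matrix(Matrix::crossprod(q, x))
  s <- svd(b)
  list(u = q %*% s$u[, seq_len(k), drop = FALSE], d = s$d[seq_len(k)],
       v = s$v[, seq_len(k), drop = FALSE])
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`;
# the caller's RNG stream is untouched.  All stochastic operations in the
# package route their seeds through this helper.
with_seed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  expr
}

# k nearest neighbours by blocked Euclidean distance: returns index and
# distance matrices (n x k), excluding self.  Blocking keeps memory at
# O(block * n) for large n.
knn_search <- function(x, k, block = 1024L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k >= n) abort("k must be smaller than the number of points", class = "phenarch_error")
  sq <- rowSums(x^2)
  idx <- matrix(0L, n, k)
  dst <- matrix(0, n, k)
  starts <- seq(1L, n, by = block)
  for (s in starts) {
    e <- min(s + block - 1L, n)
    rows <- s:e
    d2 <- outer(sq[rows], sq, "+") - 2 * tcrossprod(x[rows, , drop = FALSE], x)
    d2[d2 < 0] <- 0
    for (i in seq_along(rows)) {
      di <- d2[i, ]
      di[rows[i]] <- Inf        # exclude self
      o <- order(di)[seq_len(k)]
      idx[rows[i], ] <- o
      dst[rows[i], ] <- sqrt(di[o])
    }
  }
  list(index = idx, distance = dst)
}

# Euclidean projection of each column of `m` onto the probability simplex
# (Held/Condat algorithm, fully vectorized over columns: the support of the
# projection is a prefix of the descending-sorted entries).
project_simplex_cols <- function(m) {
  k <- nrow(m); n <- ncol(m)
  if (k == 1) return(matrix(1, 1, n))
  u <- matrix(m[order(col(m), -m)], k, n)    # columns sorted descending
  css <- u
  for (i in 2:k) css[i, ] <- css[i - 1, ] + u[i, ]
  rho <- colSums(u + (1 - css) / seq_len(k) > 0)
  theta <- (css[cbind(rho, seq_len(n))] - 1) / rho
  out <- sweep(m, 2, theta, "-")
  out[out < 0] <- 0
  out
}

# Centered moving average with shrunken windows at the edges.
moving_average <- function(x, window) {
  if (window < 1) abort("window must be >= 1", class = "phenarch_error")
  if (window == 1) return(x)
  as.numeric(zoo::rollapply(zoo::zoo(x), width = window, FUN = mean,
                            partial = TRUE, align = "center"))
}
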