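#' @title Behavioral partial least squares (cross-covariance SVD)
#' @description Links the subjects x parcels explainability block X (ridge
#'   encoding R^2 profiles) to the subjects x parcels FC-strength block Y.
#'   Both blocks are column z-scored across subjects (a center-only mode is
#'   available), the cross-block matrix `C = X'Y / (n - 1)` is decomposed by
#'   SVD, and the paired singular vectors are the parcel saliences of each
#'   latent variable. Significance of each singular value comes from
#'   permuting subject rows of Y; loading stability from bootstrap
#'   resampling of subjects with sign alignment to the original saliences.
#' @name semcine-pls
NULL

pls_preprocess <- function(M, scale = TRUE) {
  mu <- colMeans(M)
  Z <- sweep(M, 2, mu, "-")
  if (scale) {
    sdv <- col_sds(M)
    flat <- which(sdv < 1e-12)
    if (length(flat) > 0) {
      warning(length(flat), " constant column(s) standardized to zero",
              call. = FALSE)
      sdv[flat] <- 1
    }
    Z <- sweep(Z, 2, sdv, "/")
    if (length(flat) > 0) Z[, flat] <- 0
  }
  Z
}

# Orient each salience column so its largest-magnitude entry is positive,
# flipping the paired column and scores identically.
orient_svd <- function(u, v) {
  sgn <- vapply(seq_len(ncol(u)), function(k) {
    uk <- u[, k]
    s <- sign(uk[which.max(abs(uk))])
    if (s == 0) 1 else s
  }, numeric(1))
  list(u = sweep(u, 2, sgn, "*"), v = sweep(v, 2, sgn, "*"), sgn = sgn)
}

#' Cross-covariance SVD of two subject-by-parcel blocks
#'
#' @param X subjects x parcels matrix (e.g. per-subject encoding R^2).
#' @param Y subjects x parcels matrix (e.g. FC-strength profiles).
#' @param K Number of latent variables to keep.
#' @param scale Logical; z-score columns (default) or center only.
#' @return A `pls_result` list: `u`, `v` (parcels x K unit-norm saliences,
#'   largest-magnitude entry positive), `x_scores`, `y_scores`
#'   (subjects x K), `singular_values` (length K, non-increasing),
#'   `covariance_explained` (sigma_k^2 / sum over all components),
#'   `block_variance_explained` (per block: var(scores_k) / total column
#'   variance of the block).
#' @export
pls_svd <- function(X, Y, K = 1, scale = TRUE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y))
    stop("X and Y must have the same subject rows", call. = FALSE)
  n <- nrow(X)
  if (n < 5) stop("need at least 5 subjects", call. = FALSE)
  K <- min(K, ncol(X), ncol(Y))
  Xt <- pls_preprocess(X, scale)
  Yt <- pls_preprocess(Y, scale)
  C <- crossprod(Xt, Yt) / (n - 1)
  sv <- svd(C)
  orf <- orient_svd(sv$u[, seq_len(K), drop = FALSE],
                    sv$v[, seq_len(K), drop = FALSE])
  res <- list(u = orf$u, v = orf$v,
              x_scores = Xt %*% orf$u,
              y_scores = Yt %*% orf$v,
              singular_values = sv$d[seq_len(K)],
              covariance_explained = sv$d[seq_len(K)]^2 / sum(sv$d^2),
              block_variance_explained = list(
                x = apply(Xt %*% orf$u, 2, stats::var) /
                  sum(apply(Xt, 2, stats::var)),
                y = apply(Yt %*% orf$v, 2, stats::var) /
                  sum(apply(Yt, 2, stats::var))),
              scale = scale)
  class(res) <- "pls_result"
  res
}

#' Permutation test for PLS singular values
#'
#' Subject rows of Y are permuted, the full SVD recomputed, and
#' `p_k = (1 + #\{sigma_k^perm >= sigma_k^obs\}) / (n_perm + 1)`; the +1
#' correction keeps p strictly positive.
#'
#' @param X,Y,K,scale As in [pls_svd()].
#' @param n_perm Number of permutations (>= 100 recommended).
#' @param seed Integer RNG seed.
#' @return Numeric vector `perm_p` of length K.
#' @export
pls_permutation_test <- function(X, Y, K = 1, n_perm = 1000, seed = 1L,
                                 scale = TRUE) {
  stopifnot(n_perm >= 1)
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  K <- min(K, ncol(X), ncol(Y))
  Xt <- pls_preprocess(X, scale)
  obs <- svd(crossprod(Xt, pls_preprocess(Y, scale)) / (n - 1))$d[seq_len(K)]
  rng <- local_rng(seed)
  exceed <- numeric(K)
  for (b in seq_len(n_perm)) {
    Yp <- Y[sample.int(n), , drop = FALSE]
    d <- svd(crossprod(Xt, pls_preprocess(Yp, scale)) / (n - 1))$d[seq_len(K)]
    exceed <- exceed + (d >= obs)
  }
  (1 + exceed) / (n_perm + 1)
}

#' Bootstrap stability of PLS saliences
#'
#' Subjects are resampled with replacement; each bootstrap salience column
#' is sign-aligned to the original by the dot product; the stability index
#' is the original salience divided by the bootstrap standard deviation of
#' the aligned saliences (a bootstrap ratio). Degenerate draws (constant
#' column in either block) are redrawn.
#'
#' @param X,Y,K,scale As in [pls_svd()].
#' @param n_boot Number of bootstrap resamples (>= 100 recommended).
#' @param seed Integer RNG seed.
#' @return List with `boot_z_u`, `boot_z_v` (parcels x K).
#' @export
pls_bootstrap_stability <- function(X, Y, K = 1, n_boot = 1000, seed = 1L,
                                    scale = TRUE) {
  stopifnot(n_boot >= 1)
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (n < 10) stop("need at least 10 subjects for bootstrap", call. = FALSE)
  K <- min(K, ncol(X), ncol(Y))
  ref <- pls_svd(X, Y, K, scale)
  us <- array(NA_real_, c(ncol(X), K, n_boot))
  vs <- array(NA_real_, c(ncol(Y), K, n_boot))
  rng <- local_rng(seed)
  b <- 1
  redraws <- 0
  while (b <= n_boot) {
    idx <- sample.int(n, n, replace = TRUE)
    Xb <- X[idx, , drop = FALSE]
    Yb <- Y[idx, , drop = FALSE]
    if (scale && (min(col_sds(Xb)) < 1e-12 || min(col_sds(Yb)) < 1e-12)) {
      redraws <- redraws + 1
      if (redraws > 10 * n_boot)
        stop("too many degenerate bootstrap draws", call. = FALSE)
      next
    }
    sb <- pls_svd(Xb, Yb, K, scale)
    for (k in seq_len(K)) {
      s <- sign(sum(sb$u[, k] * ref$u[, k]) + sum(sb$v[, k] * ref$v[, k]))
      if (s == 0) s <- 1
      us[, k, b] <- s * sb$u[, k]
      vs[, k, b] <- s * sb$v[, k]
    }
    b <- b + 1
  }
  if (redraws > 0)
    message(redraws, " degenerate bootstrap draw(s) redrawn")
  sd_u <- apply(us, c(1, 2), stats::sd)
  sd_v <- apply(vs, c(1, 2), stats::sd)
  list(boot_z_u = ref$u / sd_u, boot_z_v = ref$v / sd_v)
}
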