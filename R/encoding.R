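#' @title Per-parcel ridge encoding with leave-one-out cross-validation
#' @description For each parcel, predicts clip-mean responses from the 11
#'   semantic features by ridge regression (penalty on the standardized
#'   scale, no intercept after centering). Cross-validation is
#'   leave-one-clip-out with strict fold hygiene: predictors and response
#'   are standardized with training-fold statistics only, the held-out clip
#'   is transformed with those statistics, and the prediction is
#'   back-transformed to the original response scale. Explainability is
#'   R^2 = 1 - SS_res/SS_tot over the pooled held-out predictions, around
#'   the grand observed mean, so values can be negative when the model
#'   underperforms a mean-only baseline.
#' @name semcine-encoding
NULL

#' Ridge solution on pre-standardized data
#'
#' Solves `(Xs'Xs + lambda I) b = Xs'ys` — the minimizer of
#' `||ys - Xs b||^2 + lambda ||b||^2` — with no intercept.
#'
#' @param Xs n x p matrix, columns standardized (mean 0, sd 1, n-1
#'   denominator).
#' @param ys Standardized response vector (or n x q matrix for many
#'   responses sharing the design).
#' @param lambda Positive ridge penalty.
#' @return Coefficient vector of length p (or p x q matrix).
#' @export
ridge_fit <- function(Xs, ys, lambda) {
  Xs <- as.matrix(Xs)
  ys <- as.matrix(ys)
  if (any(!is.finite(Xs)) || any(!is.finite(ys)))
    stop("non-finite values in ridge inputs", call. = FALSE)
  stopifnot(lambda > 0, nrow(Xs) == nrow(ys), nrow(Xs) > 1)
  A <- crossprod(Xs) + diag(lambda, ncol(Xs))
  b <- solve(A, crossprod(Xs, ys))
  if (ncol(b) == 1) drop(b) else b
}

# Standardize columns with given statistics; columns with sd < 1e-12 are set
# to exactly 0 (their index is returned for warning upstream).
std_cols <- function(M, mu, sdv) {
  flat <- which(sdv < 1e-12)
  sdv[flat] <- 1
  Z <- sweep(sweep(M, 2, mu, "-"), 2, sdv, "/")
  if (length(flat) > 0) Z[, flat] <- 0
  list(Z = Z, flat = flat)
}

col_sds <- function(M) {
  n <- nrow(M)
  mu <- colMeans(M)
  sqrt(pmax(colSums(M^2) - n * mu^2, 0) / (n - 1))
}

#' Leave-one-out cross-validated encoding of clip responses
#'
#' @param features Feature table (data.frame from [read_feature_table()]) or
#'   an n_clips x 11 numeric matrix with clip ids as row names.
#' @param responses n_clips x parcels response matrix, rows aligned to the
#'   same clip ids (checked when both carry ids).
#' @param lambda Ridge penalty (the published analysis fixes 1).
#' @param schema Feature name vector.
#' @return An `encoding_result` list: `r2` (length parcels; NA and listed in
#'   `undefined_parcels` when the response is degenerate), `beta`
#'   (parcels x 11, from the all-clip standardized fit), `fold_beta_mean`
#'   (fold-averaged coefficients, diagnostics), `predictions`
#'   (n_clips x parcels, original response units), `lambda`.
#' @export
loocv_encode <- function(features, responses, lambda = 1,
                         schema = feature_schema()) {
  if (is.data.frame(features)) {
    X <- as.matrix(features[, schema])
    rownames(X) <- features$clip_id
  } else X <- as.matrix(features)
  Y <- as.matrix(responses)
  n <- nrow(X)
  p <- ncol(X)
  if (n != nrow(Y)) stop("features and responses disagree on clip count",
                         call. = FALSE)
  if (!is.null(rownames(X)) && !is.null(rownames(Y)) &&
      !identical(rownames(X), rownames(Y)))
    stop("clip ids of features and responses are not aligned", call. = FALSE)
  if (n < p + 1)
    stop("need more clips (", n, ") than features (", p, ")", call. = FALSE)
  if (any(!is.finite(X)) || any(!is.finite(Y)))
    stop("non-finite values in encoding inputs", call. = FALSE)

  n_parcels <- ncol(Y)
  undefined <- which(col_sds(Y)^2 < 1e-12)
  pred <- matrix(NA_real_, n, n_parcels, dimnames = dimnames(Y))
  beta_sum <- matrix(0, p, n_parcels)
  flat_cols <- integer(0)

  # Leave-one-out training statistics by downdating the full-data sums:
  # identical algebra to standardizing each training fold from scratch,
  # but O(p^2 parcels) per fold instead of O(n parcels).
  XtX <- crossprod(X)
  XtY <- crossprod(X, Y)
  Sx <- colSums(X);  Sxx <- colSums(X^2)
  Sy <- colSums(Y);  Syy <- colSums(Y^2)
  nt <- n - 1

  for (i in seq_len(n)) {
    xi <- X[i, ]
    yi <- Y[i, ]
    muX <- (Sx - xi) / nt
    varX <- pmax(Sxx - xi^2 - nt * muX^2, 0) / (nt - 1)
    sdX <- sqrt(varX)
    muY <- (Sy - yi) / nt
    varY <- pmax(Syy - yi^2 - nt * muY^2, 0) / (nt - 1)
    sdY <- sqrt(varY)

    flatX <- which(sdX < 1e-12)
    flat_cols <- union(flat_cols, flatX)
    dX <- sdX; dX[flatX] <- 1
    flatY <- sdY < 1e-12
    dY <- ifelse(flatY, 1, sdY)

    # centered training cross-products via downdate
    Cxx <- (XtX - tcrossprod(xi) - nt * tcrossprod(muX)) / (nt - 1)
    Cxy <- (XtY - tcrossprod(xi, yi) - nt * tcrossprod(muX, muY)) / (nt - 1)
    A <- Cxx / tcrossprod(dX)
    Bm <- Cxy / tcrossprod(dX, dY)
    if (length(flatX) > 0) {
      A[flatX, ] <- 0; A[, flatX] <- 0
      Bm[flatX, ] <- 0
    }
    # on the z scale crossprod(Xs) = (nt - 1) * corr matrix
    B <- solve((nt - 1) * A + diag(lambda, p), (nt - 1) * Bm)
    beta_sum <- beta_sum + B
    xs <- (xi - muX) / dX
    xs[flatX] <- 0
    yhat_std <- drop(xs %*% B)
    pred[i, ] <- yhat_std * ifelse(flatY, 0, sdY) + muY
  }
  if (length(flat_cols) > 0)
    warning("feature column(s) with zero variance in a training fold, ",
            "z-scores set to 0: ",
            paste(sort(flat_cols), collapse = ", "), call. = FALSE)

  ybar <- colMeans(Y)
  ss_res <- colSums((Y - pred)^2)
  ss_tot <- colSums(sweep(Y, 2, ybar, "-")^2)
  r2 <- 1 - ss_res / ss_tot
  r2[undefined] <- NA_real_
  pred[, undefined] <- NA_real_

  sfx <- std_cols(X, colMeans(X), col_sds(X))
  sfy <- std_cols(Y, colMeans(Y), col_sds(Y))
  beta_full <- solve(crossprod(sfx$Z) + diag(lambda, p),
                     crossprod(sfx$Z, sfy$Z))
  res <- list(r2 = unname(r2),
              beta = t(beta_full),
              fold_beta_mean = t(beta_sum / n),
              predictions = pred,
              undefined_parcels = as.integer(undefined),
              lambda = lambda)
  colnames(res$beta) <- colnames(res$fold_beta_mean) <-
    if (is.null(colnames(X))) schema[seq_len(p)] else colnames(X)
  class(res) <- "encoding_result"
  res
}

#' Feature importance summaries of an encoding result
#'
#' `mean_abs_beta[f]` averages `|beta[, f]|` over parcels;
#' `weighted_abs_beta[f]` weights parcels by `max(R^2, 0)` (normalized to
#' sum 1), emphasizing features that drive well-predicted regions. Parcels
#' with undefined R^2 are excluded from both.
#'
#' @param result An `encoding_result`.
#' @return List with `mean_abs_beta` and `weighted_abs_beta` (length 11,
#'   named).
#' @export
feature_importance <- function(result) {
  stopifnot(inherits(result, "encoding_result"))
  keep <- setdiff(seq_along(result$r2), result$undefined_parcels)
  ab <- abs(result$beta[keep, , drop = FALSE])
  w <- pmax(result$r2[keep], 0)
  if (sum(w) <= 0)
    stop("all R^2 <= 0: weighted importance undefined; inspect the encoding",
         call. = FALSE)
  list(mean_abs_beta = colMeans(ab),
       weighted_abs_beta = colSums(ab * (w / sum(w))))
}

#' Label-shuffled null distribution of encoding R^2
#'
#' Re-runs [loocv_encode()] with the clip labels of the feature rows
#' permuted, breaking the feature-response pairing while preserving both
#' marginals.
#'
#' @param features,responses,lambda,schema As in [loocv_encode()].
#' @param n_shuffles Number of permutations (>= 100 recommended).
#' @param seed Integer RNG seed.
#' @return List with `null_r2` (n_shuffles x parcels) and `q95` (per-parcel
#'   95th percentile of the null).
#' @export
null_encoding <- function(features, responses, n_shuffles = 100, lambda = 1,
                          seed = 1L, schema = feature_schema()) {
  stopifnot(n_shuffles >= 1)
  if (is.data.frame(features)) {
    X <- as.matrix(features[, schema])
    rownames(X) <- features$clip_id
  } else X <- as.matrix(features)
  Y <- as.matrix(responses)
  rng <- local_rng(seed)
  null_r2 <- matrix(NA_real_, n_shuffles, ncol(Y))
  for (s in seq_len(n_shuffles)) {
    Xp <- X[sample.int(nrow(X)), , drop = FALSE]
    rownames(Xp) <- rownames(Y)
    null_r2[s, ] <- loocv_encode(Xp, Y, lambda = lambda, schema = schema)$r2
  }
  list(null_r2 = null_r2,
       q95 = apply(null_r2, 2, stats::quantile, probs = 0.95, na.rm = TRUE,
                   names = FALSE))
}
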