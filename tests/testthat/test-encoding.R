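# Independent ridge oracle: augmented least squares solved by QR —
# min ||y - Xb||^2 + lambda ||b||^2 == lsfit on [X; sqrt(lambda) I].
ridge_oracle <- function(X, y, lambda) {
  Xa <- rbind(X, diag(sqrt(lambda), ncol(X)))
  ya <- c(y, rep(0, ncol(X)))
  qr.coef(qr(Xa), ya)
}

test_that("ridge_fit matches the closed-form hand case", {
  # one standardized predictor, ys = 2x, n = 5 -> beta = 2(n-1)/(n-1+1) = 1.6
  x <- as.numeric(scale(c(-2, -1, 0, 1, 2)))
  expect_equal(ridge_fit(matrix(x), 2 * x, 1), 1.6, tolerance = 1e-12)
  # infinite penalty limit
  expect_lt(abs(ridge_fit(matrix(x), 2 * x, 1e12)), 1e-9)
  expect_error(ridge_fit(matrix(c(x[-1], NA)), 2 * x, 1), "non-finite")
})

test_that("ridge_fit equals the QR oracle on random instances", {
  set.seed(31)
  for (rep in 1:25) {
    X <- scale(matrix(rnorm(20 * 11), 20, 11))
    y <- as.numeric(scale(rnorm(20)))
    lam <- runif(1, 0.1, 10)
    expect_equal(unname(ridge_fit(X, y, lam)),
                 unname(ridge_oracle(X, y, lam)), tolerance = 1e-8)
  }
})

test_that("loocv_encode matches a from-scratch fold-wise reference", {
  # reference standardizes each training fold from scratch; the package
  # uses downdated statistics -- the two must agree to numerical precision
  naive_loocv <- function(X, Y, lambda) {
    n <- nrow(X)
    pred <- matrix(NA_real_, n, ncol(Y))
    for (i in seq_len(n)) {
      tr <- setdiff(seq_len(n), i)
      Xt <- X[tr, , drop = FALSE]; Yt <- Y[tr, , drop = FALSE]
      mx <- colMeans(Xt); sx <- apply(Xt, 2, sd)
      my <- colMeans(Yt); sy <- apply(Yt, 2, sd)
      Zs <- sweep(sweep(Xt, 2, mx), 2, sx, "/")
      Ys <- sweep(sweep(Yt, 2, my), 2, sy, "/")
      B <- solve(crossprod(Zs) + diag(lambda, ncol(X)), crossprod(Zs, Ys))
      pred[i, ] <- drop(((X[i, ] - mx) / sx) %*% B) * sy + my
    }
    1 - colSums((Y - pred)^2) /
      colSums(sweep(Y, 2, colMeans(Y))^2)
  }
  set.seed(41)
  X <- matrix(runif(30 * 11), 30, 11)
  Y <- matrix(rnorm(30 * 8), 30, 8)
  expect_equal(loocv_encode(X, Y, 1)$r2, naive_loocv(X, Y, 1),
               tolerance = 1e-10)
})

test_that("noiseless synthetic data is recovered near-perfectly", {
  study <- tiny_study(n_parcels = 30, n_subjects = 4, seed = 23,
                      noise_sd = 0, n_runs = 4, segments_per_run = 6)
  mats <- lapply(study$movie, subject_clip_matrix, manifest = study$manifest,
                 timings = study$timings, config = study$config)
  g <- group_aggregate(mats, 0.05)
  enc <- loocv_encode(study$features, g, lambda = 1e-6)
  expect_true(all(enc$r2[study$truth$active_parcels] >= 0.999))
  enc1 <- loocv_encode(study$features, g, lambda = 1)
  expect_true(all(enc1$r2[study$truth$active_parcels] >= 0.95))
})

test_that("null responses give negative mean cross-validated R^2", {
  set.seed(51)
  ft <- random_feature_table(96, seed = 51)
  Y <- matrix(rnorm(96 * 100), 96, 100,
              dimnames = list(ft$clip_id, NULL))
  enc <- loocv_encode(ft, Y, lambda = 1)
  expect_lt(mean(enc$r2), 0)
  expect_true(all(enc$r2 <= 1))
})

test_that("fold hygiene: held-out response never leaks into its prediction", {
  set.seed(61)
  ft <- random_feature_table(24, seed = 61)
  Y <- matrix(rnorm(24 * 5), 24, 5, dimnames = list(ft$clip_id, NULL))
  base <- loocv_encode(ft, Y, 1)
  Y2 <- Y
  Y2[7, ] <- Y2[7, ] + 100  # corrupt one held-out clip
  alt <- loocv_encode(ft, Y2, 1)
  expect_equal(alt$predictions[7, ], base$predictions[7, ],
               tolerance = 1e-6)
})

test_that("degenerate inputs are flagged or rejected", {
  ft <- random_feature_table(20, seed = 71)
  Y <- matrix(rnorm(20 * 3), 20, 3, dimnames = list(ft$clip_id, NULL))
  Y[, 2] <- 5  # constant parcel
  enc <- loocv_encode(ft, Y, 1)
  expect_identical(enc$undefined_parcels, 2L)
  expect_true(is.na(enc$r2[2]))

  ftc <- ft; ftc$music <- 0.5  # constant feature column
  expect_warning(loocv_encode(ftc, Y[, -2, drop = FALSE], 1),
                 "zero variance")

  expect_error(loocv_encode(ft[1:10, ], Y[1:10, ], 1), "more clips")
})

test_that("feature_importance computes the two weighted summaries", {
  res <- structure(list(
    r2 = c(0.5, 0),
    beta = rbind(c(1, rep(0.2, 10)), c(5, rep(0.2, 10))),
    undefined_parcels = integer(0)), class = "encoding_result")
  imp <- feature_importance(res)
  expect_equal(unname(imp$mean_abs_beta[1]), 3.0)
  expect_equal(unname(imp$weighted_abs_beta[1]), 1.0)

  # identical |beta| rows: both metrics equal that row
  res2 <- structure(list(
    r2 = c(0.3, 0.6), beta = rbind(1:11, -(1:11)) * 0.1,
    undefined_parcels = integer(0)), class = "encoding_result")
  imp2 <- feature_importance(res2)
  expect_equal(unname(imp2$mean_abs_beta), (1:11) * 0.1)
  expect_equal(unname(imp2$weighted_abs_beta), (1:11) * 0.1)

  # negative R^2 contributes zero weight
  res3 <- structure(list(
    r2 = c(0.5, -2), beta = rbind(rep(1, 11), rep(9, 11)),
    undefined_parcels = integer(0)), class = "encoding_result")
  expect_equal(unname(feature_importance(res3)$weighted_abs_beta),
               rep(1, 11))

  res4 <- structure(list(
    r2 = c(-1, -2), beta = res3$beta, undefined_parcels = integer(0)),
    class = "encoding_result")
  expect_error(feature_importance(res4), "weighted importance undefined")
})

test_that("null_encoding is reproducible and separates signal from null", {
  study <- tiny_study(n_parcels = 16, n_subjects = 4, seed = 29,
                      noise_sd = 0.3, n_runs = 4, segments_per_run = 6)
  mats <- lapply(study$movie, subject_clip_matrix, manifest = study$manifest,
                 timings = study$timings, config = study$config)
  g <- group_aggregate(mats, 0.05)
  obs <- loocv_encode(study$features, g, 1)$r2
  nl <- null_encoding(study$features, g, n_shuffles = 30, seed = 9)
  nl2 <- null_encoding(study$features, g, n_shuffles = 30, seed = 9)
  expect_identical(nl$null_r2, nl2$null_r2)
  act <- study$truth$active_parcels
  expect_true(all(obs[act] > nl$q95[act]))
})

test_that("monotone degradation: active-parcel R^2 non-increasing in noise", {
  base <- ground_truth(n_parcels = 16, n_subjects = 1, seed = 37,
                       noise_sd = 0)
  cfg <- pipeline_config(n_parcels = 16)
  timings <- make_timing(4, 6, c(60, 60), cfg, seed = 37)
  manifest <- build_manifest(timings, cfg)
  latent <- make_latent_features(timings, seed = 37)
  features <- clip_scores_from_latent(latent, manifest)
  ssd <- signal_sd(base, latent, cfg)
  means <- vapply(c(0, 0.5, 1, 2) * ssd, function(sg) {
    tr <- base; tr$noise_sd <- sg
    mov <- make_movie_timeseries(tr, latent, cfg, seed = 37)
    Y <- subject_clip_matrix(mov[[1]], manifest, timings, cfg)
    mean(loocv_encode(features, Y, 1)$r2[base$active_parcels])
  }, numeric(1))
  inversions <- sum(diff(means) > 0)
  expect_lte(inversions, 1)  # allow one Monte-Carlo inversion
  expect_lt(means[4], means[1])
})
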