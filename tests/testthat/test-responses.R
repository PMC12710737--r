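cfg <- pipeline_config()

make_ts <- function(data, tr = 1, subject = "s001", run = "run1")
  semcine:::new_parcel_timeseries(subject, run, data, tr)

test_that("nonrest_mask follows the onset-in-interval rule", {
  rt <- semcine:::new_run_timing("run1", data.frame(
    start_s = c(0, 10), end_s = c(10, 20), label = c("movie", "rest")), 1)
  expect_identical(nonrest_mask(rt, 20, 1), rep(c(TRUE, FALSE), each = 10))

  all_movie <- one_interval_timing(15)
  expect_true(all(nonrest_mask(all_movie, 15, 1)))

  # TR = 2: onsets 0,2,4,6,8 inside [0,10) -> TRs 0..4 true
  rt2 <- one_interval_timing(10, tr = 2)
  expect_identical(which(nonrest_mask(rt2, 8, 2)), 1:5)

  expect_error(nonrest_mask(one_interval_timing(100), 20, 1), "shorter")
})

test_that("standardize_nonrest z-scores on masked TRs with n-1 sd", {
  ts <- make_ts(matrix(c(2, 4, 9, 9), 1, 4))
  mask <- c(TRUE, TRUE, FALSE, FALSE)
  out <- standardize_nonrest(ts, mask)
  expect_equal(out$data[1, 1:2], c(-1, 1) / sqrt(2), tolerance = 1e-12)

  # constant parcel: zeroed and flagged
  ts2 <- make_ts(rbind(rep(3, 6), rnorm(6)))
  out2 <- standardize_nonrest(ts2, rep(TRUE, 6))
  expect_identical(out2$data[1, ], rep(0, 6))
  expect_identical(out2$zero_variance_parcels, 1L)

  # post-condition: masked mean 0, sd 1 per non-flagged parcel
  set.seed(4)
  ts3 <- make_ts(matrix(rnorm(5 * 30), 5, 30))
  mask3 <- rep(c(TRUE, FALSE), 15)
  out3 <- standardize_nonrest(ts3, mask3)
  sub <- out3$data[, mask3]
  expect_equal(rowMeans(sub), rep(0, 5), tolerance = 1e-10)
  expect_equal(apply(sub, 1, sd), rep(1, 5), tolerance = 1e-10)

  expect_error(standardize_nonrest(ts3, c(TRUE, rep(FALSE, 29))),
               "fewer than 2")
})

test_that("remove_global_mean zeroes every column mean", {
  ts <- make_ts(matrix(c(1, 3), 2, 1))
  expect_equal(remove_global_mean(ts)$data[, 1], c(-1, 1))
  set.seed(8)
  ts2 <- make_ts(matrix(rnorm(40), 8, 5))
  expect_equal(colMeans(remove_global_mean(ts2)$data), rep(0, 5),
               tolerance = 1e-12)
})

test_that("clip_response averages the lagged half-open window", {
  # series = TR index (0-based): clip [0,20) lag 5 -> mean of 5..24 = 14.5
  ts <- make_ts(matrix(0:39, 1, 40))
  clip <- data.frame(clip_id = "c0", start_s = 0, end_s = 20)
  expect_equal(clip_response(ts, clip, cfg), 14.5)

  const <- make_ts(matrix(7, 3, 40))
  expect_equal(clip_response(const, clip, cfg), rep(7, 3))

  late <- data.frame(clip_id = "c1", start_s = 20, end_s = 40)
  expect_error(clip_response(ts, late, cfg), "c1")
})

test_that("subject_clip_matrix aligns rows to the manifest", {
  study <- tiny_study(n_parcels = 12, n_subjects = 1, seed = 13)
  m <- subject_clip_matrix(study$movie[[1]], study$manifest,
                           study$timings, study$config)
  expect_identical(rownames(m), study$manifest$clip_id)

  perm <- sample(nrow(study$manifest))
  m2 <- subject_clip_matrix(study$movie[[1]], study$manifest[perm, ],
                            study$timings, study$config)
  expect_identical(m2, structure(m[perm, ],
                                 zero_variance_parcels = integer(0)))

  bad_manifest <- study$manifest
  bad_manifest$run_id[1] <- "run9"
  expect_error(subject_clip_matrix(study$movie[[1]], bad_manifest,
                                   study$timings, study$config),
               "missing run")
})

test_that("noiseless responses are an exact linear function of clip scores", {
  study <- tiny_study(n_parcels = 20, n_subjects = 1, seed = 17,
                      noise_sd = 0)
  m <- subject_clip_matrix(study$movie[[1]], study$manifest,
                           study$timings, study$config)
  X <- as.matrix(study$features[, feature_schema()])
  for (i in study$truth$active_parcels[1:5]) {
    fit <- lm.fit(cbind(1, X), m[, i])
    expect_lt(max(abs(fit$residuals)), 1e-8)
  }
})

test_that("group_aggregate trims floor(f*N) per tail", {
  # N = 10, trim 0.05 -> k = 0 -> plain mean
  mats10 <- lapply(1:10, function(s) matrix(s, 2, 3))
  expect_equal(group_aggregate(mats10, 0.05), matrix(5.5, 2, 3))

  # N = 20, cell values 1..20 -> k = 1 -> mean of 2..19 = 10.5
  mats20 <- lapply(1:20, function(s) matrix(s, 1, 1))
  expect_equal(group_aggregate(mats20, 0.05)[1, 1], 10.5)

  # N = 40 with 2 corrupted subjects, k = 2 -> inlier range
  set.seed(6)
  mats40 <- lapply(1:40, function(s) matrix(rnorm(4), 2, 2))
  mats40[[3]][1, 1] <- 1e6
  mats40[[17]][1, 1] <- 1e6
  agg <- group_aggregate(mats40, 0.05)
  inliers <- sapply(setdiff(1:40, c(3, 17)), function(s) mats40[[s]][1, 1])
  expect_gte(agg[1, 1], min(inliers))
  expect_lte(agg[1, 1], max(inliers))

  expect_error(group_aggregate(list(matrix(0, 2, 2), matrix(0, 3, 2))),
               "mismatch")
})

test_that("group_aggregate is invariant to subject order and parcel-equivariant", {
  set.seed(14)
  mats <- lapply(1:7, function(s) matrix(rnorm(24), 4, 6))
  g1 <- group_aggregate(mats, 0.1)
  g2 <- group_aggregate(rev(mats), 0.1)
  expect_identical(g1, g2)

  perm <- sample(6)
  g3 <- group_aggregate(lapply(mats, function(m) m[, perm]), 0.1)
  expect_identical(g3, g1[, perm])
})
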