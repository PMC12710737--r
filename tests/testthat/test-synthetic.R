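cfg <- pipeline_config()

test_that("make_timing builds alternating schedules, deterministically", {
  # 8 segments of exactly 60 s with 20-s rests: run span = 8*60 + 7*20
  tms <- make_timing(4, 8, c(60, 60), cfg, seed = 3)
  expect_length(tms, 4)
  for (rt in tms) {
    expect_equal(max(rt$intervals$end_s), 8 * 60 + 7 * 20)
    expect_identical(rt$intervals$label[1], "movie")
    expect_equal(sum(rt$intervals$label == "rest"), 7)
  }

  one <- make_timing(1, 1, c(60, 60), cfg, seed = 3)
  expect_false(any(one$run1$intervals$label == "rest"))

  expect_identical(make_timing(2, 3, c(55, 70), cfg, seed = 5),
                   make_timing(2, 3, c(55, 70), cfg, seed = 5))

  expect_error(make_timing(1, 1, c(10, 60), cfg, seed = 1), "below")
})

test_that("latent courses are smooth, bounded, and zero at rest", {
  tms <- make_timing(2, 4, c(60, 60), cfg, seed = 19)
  lat <- make_latent_features(tms, smoothness_s = 8, seed = 19)
  for (id in names(lat$courses)) {
    M <- lat$courses[[id]]
    expect_true(all(M >= 0 & M <= 1))
    mask <- nonrest_mask(tms[[id]], ncol(M), 1)
    expect_true(all(M[, !mask] == 0))
    # lag-1 autocorrelation within the first movie segment
    seg <- which(mask)[1:60]
    for (f in c(1, 6, 11)) {
      x <- M[f, seg]
      expect_gt(cor(x[-1], x[-length(x)]), 0.8)
    }
  }
  expect_identical(lat, make_latent_features(tms, smoothness_s = 8,
                                             seed = 19))
})

test_that("clip scores are window means of the latent course", {
  tms <- make_timing(1, 1, c(60, 60), cfg, seed = 1)
  man <- build_manifest(tms, cfg)
  lat <- make_latent_features(tms, seed = 1)

  # constant latent 0.7 -> every clip scores 0.7
  lat_const <- lat
  lat_const$courses$run1[] <- 0.7
  mask <- nonrest_mask(tms$run1, ncol(lat$courses$run1), 1)
  lat_const$courses$run1[, !mask] <- 0
  ft <- clip_scores_from_latent(lat_const, man)
  expect_true(all(as.matrix(ft[, feature_schema()]) == 0.7))

  # linear ramp over the 20 TR onsets of clip 1 -> mean 0.5
  lat_ramp <- lat_const
  lat_ramp$courses$run1["valence", 1:20] <- seq(0, 1, length.out = 20)
  ft2 <- clip_scores_from_latent(lat_ramp, man)
  expect_equal(ft2$valence[1], 0.5)

  # identical latent stretches give identical scores
  expect_equal(ft$dialogue[1], ft$dialogue[2])

  bad_man <- man
  bad_man$end_s[1] <- 70  # spills past the movie interval
  expect_error(clip_scores_from_latent(lat, bad_man), "not inside")
})

test_that("movie series follow the planted linear generative model", {
  tms <- make_timing(1, 2, c(60, 60), cfg, seed = 7)
  lat <- make_latent_features(tms, seed = 7)

  # zero weights, zero noise -> all-zero series
  tr0 <- ground_truth(n_parcels = 8, n_subjects = 2, noise_sd = 0, seed = 7)
  tr0$B[] <- 0
  mov0 <- make_movie_timeseries(tr0, lat, cfg, seed = 7)
  expect_true(all(mov0$s001$run1$data == 0))

  # single active parcel, B = e1: course equals gain * centered lagged latent
  tr1 <- ground_truth(n_parcels = 8, n_subjects = 1, noise_sd = 0, seed = 7)
  tr1$B[] <- 0
  tr1$B[3, 1] <- 1
  tr1$active_parcels <- 3L
  tr1$subject_gain <- 1.7
  mov1 <- make_movie_timeseries(tr1, lat, cfg, seed = 7)
  M <- lat$courses$run1
  mask <- nonrest_mask(tms$run1, ncol(M), 1)
  mu1 <- mean(M[1, mask])
  lag <- round(cfg$lag_seconds / cfg$tr_seconds)
  t_check <- which(mask)[10:40]  # TRs whose lagged source is also movie
  src <- t_check - lag
  keep <- mask[src]
  expect_equal(mov1$s001$run1$data[3, t_check[keep]],
               1.7 * (M[1, src[keep]] - mu1), tolerance = 1e-12)

  # doubling the gain doubles the signal sd
  tr2 <- tr1
  tr2$subject_gain <- 2 * tr1$subject_gain
  mov2 <- make_movie_timeseries(tr2, lat, cfg, seed = 7)
  expect_equal(sd(mov2$s001$run1$data[3, ]),
               2 * sd(mov1$s001$run1$data[3, ]), tolerance = 1e-12)

  # lag exceeding the shortest segment is rejected
  cfg_long_lag <- pipeline_config(lag_seconds = 61)
  expect_error(make_movie_timeseries(tr1, lat, cfg_long_lag, seed = 1),
               "lag")
})

test_that("rest series plant a rank-one strength axis", {
  # u = +/-2: strength difference pattern correlates with w
  tr <- ground_truth(n_parcels = 100, n_subjects = 2, seed = 43)
  tr$subject_trait <- c(-2, 2)
  rest <- make_rest_timeseries(tr, 2000, seed = 43)
  S <- fc_strength_profiles(rest)
  expect_gt(cor(S[2, ] - S[1, ], tr$axis_loading), 0.8)

  expect_identical(make_rest_timeseries(tr, 300, seed = 5),
                   make_rest_timeseries(tr, 300, seed = 5))

  # u = 0 everywhere: across-subject strength variance is at the noise
  # floor (compare to a truth with no axis at all)
  tr0 <- ground_truth(n_parcels = 40, n_subjects = 20, seed = 47)
  tr0$subject_trait <- rep(0, 20)
  trf <- tr0
  trf$fc_scale <- 0
  v_flat <- apply(fc_strength_profiles(
    make_rest_timeseries(tr0, 400, seed = 47)), 2, var)
  v_none <- apply(fc_strength_profiles(
    make_rest_timeseries(trf, 400, seed = 48)), 2, var)
  expect_lt(median(v_flat) / median(v_none), 1.5)
  expect_gt(median(v_flat) / median(v_none), 1 / 1.5)
})

test_that("cognition scores follow their trait links", {
  # no link: correlations stay near zero (500 subjects)
  tr <- ground_truth(n_parcels = 4, n_subjects = 500, seed = 53,
                     cognition_link = stats::setNames(lapply(
                       cognition_schema(), function(s)
                         list(trait = "none", strength = 0, noise_sd = 1)),
                       cognition_schema()))
  cg <- make_cognition(tr, seed = 53)
  for (sc in cognition_schema())
    expect_lt(abs(cor(cg[[sc]], tr$gain_z)), 0.15)

  # noiseless link: Spearman correlation is exactly 1
  tr2 <- ground_truth(n_parcels = 4, n_subjects = 50, seed = 59,
                      cognition_link = stats::setNames(lapply(
                        cognition_schema(), function(s)
                          list(trait = "gain", strength = 1, noise_sd = 0)),
                        cognition_schema()))
  cg2 <- make_cognition(tr2, seed = 59)
  expect_equal(cor(cg2$PMAT24, tr2$gain_z, method = "spearman"), 1)

  expect_identical(names(cg)[-1], cognition_schema())
  expect_equal(unname(colMeans(as.matrix(cg[, -1]))), rep(0, 7),
               tolerance = 1e-10)

  tr_bad <- tr
  tr_bad$cognition_link <- list(Bogus = list(trait = "gain", strength = 1,
                                             noise_sd = 0))
  expect_error(make_cognition(tr_bad, seed = 1), "missing score")
  expect_error(ground_truth(cognition_link = list(
    Bogus = list(trait = "gain", strength = 1, noise_sd = 0)), seed = 1),
    "unknown cognition score")
})

test_that("simulate_study is a pure function of its seed", {
  s1 <- tiny_study(n_parcels = 10, n_subjects = 2, seed = 67,
                   n_TR_rest = 120)
  s2 <- tiny_study(n_parcels = 10, n_subjects = 2, seed = 67,
                   n_TR_rest = 120)
  expect_identical(s1$features, s2$features)
  expect_identical(s1$movie$s001$run1$data, s2$movie$s001$run1$data)
  expect_identical(s1$rest$s002$data, s2$rest$s002$data)
  expect_identical(s1$cognition, s2$cognition)
})

test_that("mean active-parcel R^2 increases with subject gain", {
  truth <- ground_truth(n_parcels = 24, n_subjects = 24, gain_sd = 0.6,
                        seed = 71)
  cfgs <- pipeline_config(n_parcels = 24)
  timings <- make_timing(4, 6, c(60, 60), cfgs, seed = 71)
  manifest <- build_manifest(timings, cfgs)
  latent <- make_latent_features(timings, seed = 72)
  truth$noise_sd <- 0.5 * signal_sd(truth, latent, cfgs)
  movie <- make_movie_timeseries(truth, latent, cfgs, seed = 73)
  features <- clip_scores_from_latent(latent, manifest)
  r2 <- subject_r2_matrix(movie, features, manifest, timings, cfgs)
  mean_r2 <- rowMeans(r2[, truth$active_parcels])
  expect_gt(cor(mean_r2, truth$subject_gain, method = "spearman"), 0.9)
})
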