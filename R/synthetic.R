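#' @title Synthetic study generator with planted ground truth
#' @description Emulates the statistical structure of a naturalistic
#'   movie-watching fMRI study so that every pipeline stage can be verified
#'   by parameter recovery: alternating movie/rest run schedules, smooth
#'   bounded latent semantic courses whose clip-window means play the role
#'   of model-derived feature scores, movie BOLD driven by a block-sparse
#'   parcels x features weight matrix through subject-specific gains, rest
#'   series with a planted rank-one axis of connectivity-strength
#'   variation, and cognitive scores linked to the latent subject traits.
#'   All generators are pure functions of their seed.
#' @name semcine-synthetic
NULL

#' Planted ground truth for a synthetic study
#'
#' @param n_parcels Number of parcels.
#' @param n_subjects Number of subjects.
#' @param active_fraction Fraction of parcels with non-zero encoding
#'   weights (block sparsity of `B`).
#' @param dominant_feature Feature whose true weights have `dominant_scale`
#'   times the standard deviation of the others (so importance metrics have
#'   a known winner).
#' @param dominant_scale Scale multiplier for the dominant feature.
#' @param gain_sd SD of log subject gain `a_s = exp(gain_sd * z1)`.
#' @param gain_trait_corr Correlation `rho_axis` of the bivariate normal
#'   copula coupling the gain trait `z1` and the connectivity trait
#'   `u_s = z2`: the single dial for the PLS effect size.
#' @param n_axis_parcels Number of parcels with non-zero entries in the
#'   unit-norm connectivity-axis loading `w`.
#' @param fc_base,fc_scale Baseline and trait scaling of the squared
#'   rest-factor loadings (`lambda_i^2 = fc_base + fc_scale * u_s * w_i`,
#'   floored at 0.05).
#' @param noise_sd SD of the additive movie noise, raw units; the default
#'   is of the order of the noise-free signal SD at these defaults (SNR
#'   near 1, a realistic regime).
#' @param gain_mode `"global"`: the gain multiplies every active parcel;
#'   `"localized"`: it multiplies only `planted_cognition_parcels`,
#'   yielding spatially specific R^2-cognition coupling.
#' @param n_cognition_parcels Planted parcels in `"localized"` mode.
#' @param cognition_link Named list over [cognition_schema()] entries, each
#'   `list(trait = "gain"|"fc"|"none", strength, noise_sd)`.
#' @param seed Integer seed; every derived generator reuses it.
#' @return A `ground_truth` list (fields as above plus `B`,
#'   `active_parcels`, `subject_gain`, `subject_trait`, `gain_z`,
#'   `axis_loading`, `planted_cognition_parcels`).
#' @export
ground_truth <- function(n_parcels = 360,
                         n_subjects = 24,
                         active_fraction = 0.3,
                         dominant_feature = "dialogue",
                         dominant_scale = 2.5,
                         gain_sd = 0.4,
                         gain_trait_corr = 0.6,
                         n_axis_parcels = 40,
                         fc_base = 0.6,
                         fc_scale = 0.8,
                         noise_sd = 0.3,
                         gain_mode = c("global", "localized"),
                         n_cognition_parcels = 20,
                         cognition_link = NULL,
                         seed = 1L) {
  gain_mode <- match.arg(gain_mode)
  stopifnot(n_parcels >= 2, n_subjects >= 1,
            active_fraction > 0, active_fraction <= 1,
            abs(gain_trait_corr) <= 1, noise_sd >= 0)
  schema <- feature_schema()
  if (!dominant_feature %in% schema)
    stop("unknown dominant_feature: ", dominant_feature, call. = FALSE)
  if (is.null(cognition_link)) cognition_link <- default_cognition_link()
  bad <- setdiff(names(cognition_link), cognition_schema())
  if (length(bad) > 0)
    stop("unknown cognition score name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  rng <- local_rng(seed)

  n_active <- max(1, round(active_fraction * n_parcels))
  active <- sort(sample.int(n_parcels, n_active))
  B <- matrix(0, n_parcels, length(schema), dimnames = list(NULL, schema))
  scale_f <- ifelse(schema == dominant_feature, dominant_scale, 1)
  B[active, ] <- stats::rnorm(n_active * length(schema)) *
    rep(scale_f, each = n_active)

  # bivariate normal copula for (gain trait, connectivity trait)
  z1 <- stats::rnorm(n_subjects)
  z2 <- gain_trait_corr * z1 +
    sqrt(1 - gain_trait_corr^2) * stats::rnorm(n_subjects)
  a_s <- exp(gain_sd * z1)

  # axis loading: sparse, equal-magnitude signed entries (half +, half -),
  # unit norm. Balanced signs keep the trait from shifting the global mean
  # factor loading; equal magnitudes keep the strength-vs-trait
  # correlation profile proportional to w (unequal loadings saturate at
  # different rates and distort the recoverable pattern).
  w <- numeric(n_parcels)
  k_w <- min(n_axis_parcels, n_parcels)
  idx_w <- sort(sample.int(n_parcels, k_w))
  signs <- rep(c(1, -1), length.out = k_w)[sample.int(k_w)]
  w[idx_w] <- signs / sqrt(k_w)

  planted_cog <- if (gain_mode == "localized")
    sort(sample(active, min(n_cognition_parcels, length(active))))
  else integer(0)

  truth <- list(B = B, active_parcels = active,
                subject_gain = a_s, subject_trait = z2, gain_z = z1,
                axis_loading = w, gain_trait_corr = gain_trait_corr,
                gain_sd = gain_sd, fc_base = fc_base, fc_scale = fc_scale,
                cognition_link = cognition_link,
                planted_cognition_parcels = planted_cog,
                gain_mode = gain_mode, noise_sd = noise_sd,
                n_parcels = n_parcels, n_subjects = n_subjects,
                dominant_feature = dominant_feature, seed = as.integer(seed))
  class(truth) <- "ground_truth"
  truth
}

# Default trait links for the seven scores: the fluid/crystallized composites
# and fluid intelligence track the encoding-gain trait most strongly, memory
# scores weakly, and the speeded executive measures not at all.
default_cognition_link <- function() {
  mk <- function(trait, strength)
    list(trait = trait, strength = strength,
         noise_sd = sqrt(max(1 - strength^2, 0)))
  list(PMAT24 = mk("gain", 0.5),
       PicSeq = mk("gain", 0.3),
       ListSort = mk("gain", 0.3),
       CardSort = mk("none", 0),
       Flanker = mk("none", 0),
       CogFluidComp = mk("gain", 0.5),
       CogCrystalComp = mk("gain", 0.5))
}

#' Synthetic run timing tables
#'
#' Each run alternates movie segments (lengths uniform in
#' `segment_length_range`, rounded to whole TRs) with fixation blocks of
#' `config$rest_block_s`; no trailing rest after the final segment.
#'
#' @param n_runs,segments_per_run Schedule size.
#' @param segment_length_range `(s_min, s_max)` in seconds; `s_min` must be
#'   at least `clip_min_s + end_buffer_s` so every segment can host a clip.
#' @param config A [pipeline_config()].
#' @param seed Integer seed.
#' @return Named list of `run_timing` objects (`run1`, `run2`, ...).
#' @export
make_timing <- function(n_runs = 4, segments_per_run = 6,
                        segment_length_range = c(60, 60),
                        config = pipeline_config(), seed = 1L) {
  validate_config(config)
  s_min <- segment_length_range[1]
  if (s_min < config$clip_min_s + config$end_buffer_s)
    stop("segment_length_range minimum (", s_min, " s) below clip_min_s + ",
         "end_buffer_s (", config$clip_min_s + config$end_buffer_s, " s)",
         call. = FALSE)
  rng <- local_rng(seed)
  tr <- config$tr_seconds
  timings <- list()
  for (r in seq_len(n_runs)) {
    lens <- stats::runif(segments_per_run, segment_length_range[1],
                         segment_length_range[2])
    lens <- round(lens / tr) * tr
    t0 <- 0
    rows <- list()
    for (k in seq_len(segments_per_run)) {
      rows[[length(rows) + 1]] <-
        data.frame(start_s = t0, end_s = t0 + lens[k], label = "movie")
      t0 <- t0 + lens[k]
      if (k < segments_per_run) {
        rows[[length(rows) + 1]] <-
          data.frame(start_s = t0, end_s = t0 + config$rest_block_s,
                     label = "rest")
        t0 <- t0 + config$rest_block_s
      }
    }
    id <- paste0("run", r)
    timings[[id]] <- new_run_timing(id, do.call(rbind, rows), tr)
  }
  timings
}

#' Smooth bounded latent semantic courses
#'
#' Per run and feature: Gaussian-kernel-smoothed white noise,
#' re-standardized, squashed to `[0, 1]` by a logistic, and zeroed on rest
#' TRs. Smoothness 8 s gives lag-1 autocorrelation well above 0.8 at
#' TR = 1 s.
#'
#' @param timings Named list of `run_timing` objects.
#' @param smoothness_s Gaussian kernel SD (s).
#' @param squash_scale Logistic steepness applied to the standardized
#'   course (larger values spread scores toward 0/1); used when `windows`
#'   is absent.
#' @param windows Optional clip manifest. When given (and a run hosts at
#'   least 12 clips), the courses are linearly recombined so their
#'   clip-window means are exactly uncorrelated across features, and
#'   mapped to `[0, 1]` affinely so that orthogonality survives: with few
#'   effective samples (strong smoothing, few segments) raw draws carry
#'   chance feature correlations of 0.4-0.6 that would confound
#'   coefficient-recovery tests. Features are independent by construction
#'   in this world; the recombination enforces that where the encoding
#'   model actually looks.
#' @param seed Integer seed.
#' @return A `latent_course` list: `courses` (per run, 11 x n_TR matrices),
#'   `timings`, `tr_seconds`, `smoothness_s`.
#' @export
make_latent_features <- function(timings, smoothness_s = 8,
                                 squash_scale = 1.7, windows = NULL,
                                 seed = 1L) {
  stopifnot(smoothness_s > 0)
  rng <- local_rng(seed)
  schema <- feature_schema()
  tr <- timings[[1]]$tr_seconds
  # When every run has the same interval layout (the default synthetic
  # schedule), one latent realization is drawn and reused for all runs:
  # the per-run z-scoring of the evoked signal is then a fixed linear map,
  # so noiseless responses stay exactly linear in the clip scores across
  # the pooled clip set. Runs with differing layouts get independent draws.
  layouts <- vapply(timings, function(rt)
    paste(rt$intervals$start_s, rt$intervals$end_s, rt$intervals$label,
          collapse = ";"), character(1))
  shared <- length(unique(layouts)) == 1
  courses <- list()
  draw_course <- function(rt) {
    n_TR <- ceiling(max(rt$intervals$end_s) / tr)
    sd_tr <- smoothness_s / tr
    half <- ceiling(4 * sd_tr)
    kern <- stats::dnorm(seq(-half, half), sd = sd_tr)
    kern <- kern / sum(kern)
    mask <- nonrest_mask(rt, n_TR, tr)
    S <- matrix(0, n_TR, length(schema))
    for (f in seq_along(schema)) {
      x <- stats::rnorm(n_TR + 2 * half)
      sm <- stats::convolve(x, rev(kern), type = "filter")
      S[, f] <- sm - mean(sm)
    }
    clips <- if (is.null(windows)) NULL
             else windows[windows$run_id == rt$run_id, , drop = FALSE]
    if (!is.null(clips) && nrow(clips) >= 2 * length(schema)) {
      # (with fewer than ~2x features clips the centered window-mean
      # matrix is too close to singular for a stable recombination; such
      # small worlds take the generic path below)
      # recombine so clip-window means are exactly uncorrelated, then map
      # to [0, 1] affinely (per feature) to preserve that orthogonality
      onsets <- (seq_len(n_TR) - 1) * tr
      W <- matrix(0, nrow(clips), n_TR)
      for (i in seq_len(nrow(clips))) {
        idx <- which(onsets >= clips$start_s[i] & onsets < clips$end_s[i])
        W[i, idx] <- 1 / length(idx)
      }
      A <- W %*% S
      A <- sweep(A, 2, colMeans(A), "-")
      S <- S %*% solve(qr.R(qr(A)))
      # one common scale for all features: the recombined window means are
      # orthonormal, i.e. every feature's clip scores have the same SD,
      # and a shared affine map into [0, 1] keeps it that way
      M <- t(0.5 + 0.45 * S / max(abs(S)))
    } else {
      # no window information: TR-level orthogonalization + logistic squash
      Q <- qr.Q(qr(S))
      Q <- sweep(Q, 2, apply(Q, 2, stats::sd), "/")
      M <- t(stats::plogis(squash_scale * Q))
    }
    dimnames(M) <- list(schema, NULL)
    M[, !mask] <- 0
    M
  }
  if (shared) {
    M1 <- draw_course(timings[[1]])
    for (id in names(timings)) courses[[id]] <- M1
  } else {
    for (id in names(timings)) courses[[id]] <- draw_course(timings[[id]])
  }
  out <- list(courses = courses, timings = timings, tr_seconds = tr,
              smoothness_s = smoothness_s)
  class(out) <- "latent_course"
  out
}

#' Clip feature scores as window means of the latent course
#'
#' Each clip's score is the mean of the latent course over the TR onsets in
#' its (unlagged) window, so the encoding model is correctly specified at
#' the clip level. Clips must lie inside a movie interval.
#'
#' @param latent A `latent_course`.
#' @param manifest Clip manifest data.frame.
#' @return Feature table data.frame (`clip_id` + 11 columns in schema
#'   order).
#' @export
clip_scores_from_latent <- function(latent, manifest) {
  stopifnot(inherits(latent, "latent_course"))
  tr <- latent$tr_seconds
  schema <- feature_schema()
  scores <- matrix(NA_real_, nrow(manifest), length(schema),
                   dimnames = list(manifest$clip_id, schema))
  for (i in seq_len(nrow(manifest))) {
    cl <- manifest[i, ]
    rt <- latent$timings[[cl$run_id]]
    movie <- rt$intervals[rt$intervals$label == "movie", , drop = FALSE]
    inside <- any(cl$start_s >= movie$start_s & cl$end_s <= movie$end_s)
    if (!inside)
      stop("clip ", cl$clip_id, " is not inside a movie interval",
           call. = FALSE)
    M <- latent$courses[[cl$run_id]]
    onsets <- (seq_len(ncol(M)) - 1) * tr
    idx <- which(onsets >= cl$start_s & onsets < cl$end_s)
    scores[i, ] <- rowMeans(M[, idx, drop = FALSE])
  }
  out <- data.frame(clip_id = manifest$clip_id, scores, row.names = NULL,
                    check.names = FALSE)
  validate_feature_table(out)
}

#' Subject movie-run parcel time series from the planted truth
#'
#' At movie TR `t`, parcel `i` of subject `s` carries
#' `gain[s, i] * sum_f B[i, f] * (latent[f, t - lag] - mean_f) + noise`;
#' rest TRs carry noise only (`mean_f` is the latent mean over the run's
#' movie TRs). The gain is `a_s` on gain-modulated parcels (all active
#' parcels in `"global"` mode, `planted_cognition_parcels` in
#' `"localized"` mode) and 1 elsewhere.
#'
#' @param truth A [ground_truth()].
#' @param latent A `latent_course` (shared by all subjects).
#' @param config A [pipeline_config()].
#' @param seed Integer seed.
#' @return List over subjects (`s001`, ...) of named lists over runs of
#'   `parcel_timeseries`.
#' @export
make_movie_timeseries <- function(truth, latent, config = pipeline_config(),
                                  seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"), inherits(latent, "latent_course"))
  tr <- latent$tr_seconds
  lag_TRs <- round(config$lag_seconds / tr)
  seg_lens <- unlist(lapply(latent$timings, function(rt) {
    iv <- rt$intervals
    iv$end_s[iv$label == "movie"] - iv$start_s[iv$label == "movie"]
  }))
  if (config$lag_seconds > min(seg_lens))
    stop("lag (", config$lag_seconds, " s) longer than shortest movie ",
         "segment (", min(seg_lens), " s)", call. = FALSE)
  rng <- local_rng(seed)
  subjects <- sprintf("s%03d", seq_len(truth$n_subjects))
  gain_parcels <- if (truth$gain_mode == "localized")
    truth$planted_cognition_parcels else truth$active_parcels

  # signal at unit gain, shared across subjects, computed once per run
  signal0 <- list()
  for (id in names(latent$timings)) {
    M <- latent$courses[[id]]
    mask <- nonrest_mask(latent$timings[[id]], ncol(M), tr)
    mu_f <- rowMeans(M[, mask, drop = FALSE])
    lagged <- matrix(0, nrow(M), ncol(M))
    src <- seq_len(ncol(M)) - lag_TRs
    ok <- src >= 1
    lagged[, ok] <- M[, src[ok], drop = FALSE]
    centered <- lagged - mu_f
    # stimulus contributes only where the (lagged) source TR was movie
    src_movie <- rep(FALSE, ncol(M))
    src_movie[ok] <- mask[src[ok]]
    centered[, !src_movie] <- 0
    sig <- truth$B %*% centered
    sig[, !mask] <- 0  # rest TRs carry noise only
    signal0[[id]] <- sig
  }

  out <- list()
  for (s in seq_along(subjects)) {
    gains <- rep(1, truth$n_parcels)
    gains[gain_parcels] <- truth$subject_gain[s]
    runs <- list()
    for (id in names(latent$timings)) {
      sig <- signal0[[id]] * gains
      noise <- matrix(stats::rnorm(length(sig), sd = truth$noise_sd),
                      nrow(sig), ncol(sig))
      runs[[id]] <- new_parcel_timeseries(subjects[s], id, sig + noise, tr)
    }
    out[[subjects[s]]] <- runs
  }
  out
}

#' Mean noise-free signal SD over active parcels at unit gain
#'
#' Reference scale for choosing movie noise levels (e.g. "noise at one
#' quarter of the signal SD").
#'
#' @param truth A [ground_truth()].
#' @param latent A `latent_course`.
#' @param config A [pipeline_config()].
#' @return Positive scalar.
#' @export
signal_sd <- function(truth, latent, config = pipeline_config()) {
  noiseless <- truth
  noiseless$noise_sd <- 0
  noiseless$n_subjects <- 1L
  noiseless$subject_gain <- 1
  ts <- make_movie_timeseries(noiseless, latent, config, seed = 1L)[[1]]
  sds <- unlist(lapply(names(ts), function(id) {
    mask <- nonrest_mask(latent$timings[[id]], ncol(ts[[id]]$data),
                         latent$tr_seconds)
    apply(ts[[id]]$data[truth$active_parcels, mask, drop = FALSE], 1,
          stats::sd)
  }))
  mean(sds)
}

#' Subject rest-run parcel time series with a planted strength axis
#'
#' Single-factor model: parcel `i` of subject `s` is
#' `lambda_i(s) g(t) + e_i(t)` with iid standard normal `g`, `e` and
#' `lambda_i(s)^2 = fc_base + fc_scale * u_s * w_i` (floored at 0.05), so
#' the across-subject variation of nodewise connectivity strength is
#' rank-one with loading `w` scaled by the trait `u_s`.
#'
#' @param truth A [ground_truth()].
#' @param n_TR_rest Number of rest TRs (>= 100).
#' @param tr_seconds Sampling interval (s).
#' @param seed Integer seed.
#' @return Named list over subjects of `parcel_timeseries` (run id
#'   `"rest"`).
#' @export
make_rest_timeseries <- function(truth, n_TR_rest = 1200, tr_seconds = 1.0,
                                 seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"), n_TR_rest >= 100)
  rng <- local_rng(seed)
  subjects <- sprintf("s%03d", seq_len(truth$n_subjects))
  out <- list()
  for (s in seq_along(subjects)) {
    lam2 <- pmax(truth$fc_base +
                   truth$fc_scale * truth$subject_trait[s] *
                   truth$axis_loading, 0.05)
    lam <- sqrt(lam2)
    # fix the factor's sample moments: otherwise its realized variance
    # shifts every pairwise correlation of the subject coherently, adding
    # a subject-level common mode to the strength profiles that masks the
    # planted rank-one axis
    g <- stats::rnorm(n_TR_rest)
    g <- (g - mean(g)) / stats::sd(g)
    E <- matrix(stats::rnorm(truth$n_parcels * n_TR_rest),
                truth$n_parcels, n_TR_rest)
    out[[subjects[s]]] <- new_parcel_timeseries(
      subjects[s], "rest", outer(lam, g) + E, tr_seconds)
  }
  out
}

#' Synthetic cognition table
#'
#' Each score is `strength * trait + Normal(0, noise_sd^2)` with the trait
#' given by `cognition_link` (`"gain"` = standardized log-gain, `"fc"` =
#' connectivity trait, `"none"` = pure noise), then z-scored across
#' subjects.
#'
#' @param truth A [ground_truth()].
#' @param seed Integer seed.
#' @return data.frame `subject_id` + the 7 score columns.
#' @export
make_cognition <- function(truth, seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  schema <- cognition_schema()
  miss <- setdiff(schema, names(truth$cognition_link))
  if (length(miss) > 0)
    stop("cognition_link missing score(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  rng <- local_rng(seed)
  n <- truth$n_subjects
  out <- data.frame(subject_id = sprintf("s%03d", seq_len(n)))
  for (sc in schema) {
    lk <- truth$cognition_link[[sc]]
    trait <- switch(lk$trait,
                    gain = truth$gain_z,
                    fc = truth$subject_trait,
                    none = rep(0, n),
                    stop("unknown trait '", lk$trait, "' for score ", sc,
                         call. = FALSE))
    raw <- lk$strength * trait + stats::rnorm(n, sd = lk$noise_sd)
    s <- stats::sd(raw)
    out[[sc]] <- if (!is.finite(s) || s < 1e-12) raw - mean(raw)
                 else (raw - mean(raw)) / s
  }
  out
}

#' Generate a complete synthetic study
#'
#' Ties the generators together: timing -> manifest -> latent courses ->
#' clip feature scores -> per-subject movie and rest series -> cognition.
#' Each stage uses a seed derived deterministically from `seed`.
#'
#' @param truth A [ground_truth()].
#' @param config A [pipeline_config()].
#' @param n_runs,segments_per_run,segment_length_range Schedule parameters
#'   for [make_timing()].
#' @param n_TR_rest Rest-run length in TRs.
#' @param seed Integer master seed.
#' @return List with `truth`, `config`, `timings`, `manifest`, `latent`,
#'   `features`, `movie` (subjects -> runs -> `parcel_timeseries`), `rest`,
#'   `cognition`.
#' @export
simulate_study <- function(truth = ground_truth(),
                           config = pipeline_config(),
                           n_runs = 4, segments_per_run = 6,
                           segment_length_range = c(60, 60),
                           n_TR_rest = 1200,
                           seed = 1L) {
  timings <- make_timing(n_runs, segments_per_run, segment_length_range,
                         config, seed = child_seed(seed, 1))
  manifest <- build_manifest(timings, config)
  latent <- make_latent_features(timings, windows = manifest,
                                 seed = child_seed(seed, 2))
  features <- clip_scores_from_latent(latent, manifest)
  movie <- make_movie_timeseries(truth, latent, config,
                                 seed = child_seed(seed, 3))
  rest <- make_rest_timeseries(truth, n_TR_rest,
                               tr_seconds = config$tr_seconds,
                               seed = child_seed(seed, 4))
  cognition <- make_cognition(truth, seed = child_seed(seed, 5))
  list(truth = truth, config = config, timings = timings,
       manifest = manifest, latent = latent, features = features,
       movie = movie, rest = rest, cognition = cognition)
}
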