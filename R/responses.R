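#' @title Clip-wise parcel responses
#' @description Track from raw parcel time series to the clips x parcels
#'   response matrices. Per run: z-score each parcel on non-rest TRs only
#'   (n-1 denominator; constant parcels flagged and zeroed), remove the
#'   frame-wise global mean, then average each parcel over the
#'   hemodynamically lagged clip window. A TR belongs to a window iff its
#'   onset `t * TR` lies inside the half-open window, which stays
#'   unambiguous for non-integer lags and TR != 1 s. Subject matrices are
#'   aggregated with a per-tail trimmed mean.
#' @name semcine-responses
NULL

#' Boolean mask of non-rest TRs
#'
#' TR `t` (0-based) is non-rest iff its onset `t * tr_seconds` lies inside a
#' movie interval of the run timing.
#'
#' @param timing A `run_timing` object.
#' @param n_TR Number of TRs in the run.
#' @param tr_seconds Sampling interval (s).
#' @return Logical vector of length `n_TR`.
#' @export
nonrest_mask <- function(timing, n_TR, tr_seconds) {
  validate_run_timing(timing)
  last_end <- max(timing$intervals$end_s)
  if (n_TR * tr_seconds < last_end - tr_seconds)
    stop("TR grid (", n_TR, " TRs of ", tr_seconds,
         " s) shorter than timing (ends ", last_end, " s)", call. = FALSE)
  onsets <- (seq_len(n_TR) - 1) * tr_seconds
  mask <- rep(FALSE, n_TR)
  movie <- timing$intervals[timing$intervals$label == "movie", , drop = FALSE]
  for (k in seq_len(nrow(movie)))
    mask <- mask | (onsets >= movie$start_s[k] & onsets < movie$end_s[k])
  mask
}

#' Standardize a parcel time series on non-rest statistics
#'
#' Per parcel, subtracts the mean and divides by the standard deviation
#' (n-1 denominator) computed over masked TRs only, applied to all TRs.
#' Parcels with non-rest sd below `1e-12` are zeroed out and recorded in
#' `zero_variance_parcels`.
#'
#' @param ts A `parcel_timeseries`.
#' @param mask Logical non-rest mask of length `ncol(ts$data)`.
#' @return A standardized `parcel_timeseries`.
#' @export
standardize_nonrest <- function(ts, mask) {
  stopifnot(inherits(ts, "parcel_timeseries"), length(mask) == ncol(ts$data))
  if (sum(mask) < 2)
    stop("fewer than 2 non-rest TRs; cannot standardize", call. = FALSE)
  sub <- ts$data[, mask, drop = FALSE]
  mu <- rowMeans(sub)
  sdv <- apply(sub, 1, stats::sd)
  flat <- which(sdv < 1e-12)
  sdv[flat] <- 1
  out <- (ts$data - mu) / sdv
  out[flat, ] <- 0
  new_parcel_timeseries(ts$subject_id, ts$run_id, out, ts$tr_seconds,
                        zero_variance_parcels =
                          sort(union(ts$zero_variance_parcels, flat)))
}

#' Remove the frame-wise global mean
#'
#' Subtracts, at each TR, the mean signal across all parcels, so that every
#' column of the result sums to zero.
#'
#' @param ts A (standardized) `parcel_timeseries`.
#' @return A `parcel_timeseries` with zero column means.
#' @export
remove_global_mean <- function(ts) {
  stopifnot(inherits(ts, "parcel_timeseries"))
  out <- sweep(ts$data, 2, colMeans(ts$data), "-")
  new_parcel_timeseries(ts$subject_id, ts$run_id, out, ts$tr_seconds,
                        zero_variance_parcels = ts$zero_variance_parcels)
}

#' Mean parcel response over a lagged clip window
#'
#' Averages each parcel over the TRs whose onsets fall inside the clip
#' window shifted forward by the hemodynamic lag,
#' `[start_s + lag, end_s + lag)`.
#'
#' @param ts A processed `parcel_timeseries`.
#' @param clip One-row slice of a clip manifest (needs `clip_id`, `start_s`,
#'   `end_s`).
#' @param config A [pipeline_config()].
#' @return Numeric vector of length `nrow(ts$data)`.
#' @export
clip_response <- function(ts, clip, config) {
  lo <- clip$start_s + config$lag_seconds
  hi <- clip$end_s + config$lag_seconds
  n_TR <- ncol(ts$data)
  onsets <- (seq_len(n_TR) - 1) * ts$tr_seconds
  idx <- which(onsets >= lo & onsets < hi)
  if (length(idx) == 0 || hi > n_TR * ts$tr_seconds + 1e-9)
    stop("lagged window of clip ", clip$clip_id, " [", lo, ", ", hi,
         ") exceeds run of ", n_TR, " TRs", call. = FALSE)
  rowMeans(ts$data[, idx, drop = FALSE])
}

#' Subject-level clip response matrix
#'
#' Applies per run: [nonrest_mask()] -> [standardize_nonrest()] ->
#' [remove_global_mean()], then extracts [clip_response()] for every clip of
#' the manifest, in manifest order.
#'
#' @param ts_by_run Named list of `parcel_timeseries`, one per run id.
#' @param manifest Clip manifest data.frame.
#' @param timings Named list of `run_timing` objects.
#' @param config A [pipeline_config()].
#' @return Matrix n_clips x parcels with clip ids as row names; attribute
#'   `zero_variance_parcels` lists parcels flagged in any run.
#' @export
subject_clip_matrix <- function(ts_by_run, manifest, timings, config) {
  runs_needed <- unique(manifest$run_id)
  miss <- setdiff(runs_needed, names(ts_by_run))
  if (length(miss) > 0)
    stop("missing run(s) referenced by manifest: ",
         paste(miss, collapse = ", "), call. = FALSE)
  processed <- list()
  zv <- integer(0)
  for (r in runs_needed) {
    ts <- ts_by_run[[r]]
    mask <- nonrest_mask(timings[[r]], ncol(ts$data), ts$tr_seconds)
    ts <- remove_global_mean(standardize_nonrest(ts, mask))
    zv <- union(zv, ts$zero_variance_parcels)
    processed[[r]] <- ts
  }
  n_parcels <- nrow(processed[[runs_needed[1]]]$data)
  out <- matrix(NA_real_, nrow(manifest), n_parcels,
                dimnames = list(manifest$clip_id,
                                paste0("parcel", seq_len(n_parcels))))
  for (i in seq_len(nrow(manifest)))
    out[i, ] <- clip_response(processed[[manifest$run_id[i]]],
                              manifest[i, ], config)
  attr(out, "zero_variance_parcels") <- sort(zv)
  out
}

#' Trimmed-mean group aggregation of subject clip matrices
#'
#' Per clip x parcel cell, drops the `k = floor(trim_fraction * N)` largest
#' and `k` smallest values across the `N` subjects and averages the rest
#' (5% per tail by default, i.e. 10% of subjects removed in total).
#'
#' @param subject_matrices List of identically shaped n_clips x parcels
#'   matrices.
#' @param trim_fraction Fraction trimmed from each tail.
#' @return Group-level n_clips x parcels matrix.
#' @export
group_aggregate <- function(subject_matrices, trim_fraction = 0.05) {
  stopifnot(length(subject_matrices) >= 1,
            trim_fraction >= 0, trim_fraction < 0.5)
  dims <- lapply(subject_matrices, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1)
    stop("subject matrices have mismatched shapes", call. = FALSE)
  N <- length(subject_matrices)
  k <- floor(trim_fraction * N)
  arr <- array(unlist(subject_matrices, use.names = FALSE),
               dim = c(dims[[1]], N))
  if (k == 0) {
    out <- apply(arr, c(1, 2), mean)
  } else {
    keep <- (k + 1):(N - k)
    out <- apply(arr, c(1, 2), function(v) mean(sort(v)[keep]))
  }
  dimnames(out) <- dimnames(subject_matrices[[1]])
  out
}
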