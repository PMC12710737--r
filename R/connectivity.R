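#' @title Resting-state connectivity strength
#' @description Pairwise Pearson correlations between parcel time series,
#'   Fisher-z transformed, summarized per parcel as the mean
#'   positively-clipped z with all other parcels. Correlations are clipped
#'   to `1 - 1e-7` in magnitude before `atanh` so duplicated or degenerate
#'   parcels cannot inject infinities; zero-variance parcels get zero
#'   rows/columns and are flagged.
#' @name semcine-connectivity
NULL

#' Fisher-z functional connectivity matrix
#'
#' @param rest A `parcel_timeseries` (rest run) or a parcels x TRs matrix.
#' @return parcels x parcels symmetric matrix of Fisher-z correlations,
#'   zero diagonal; attribute `zero_variance_parcels` lists flagged rows.
#' @export
fc_matrix <- function(rest) {
  M <- if (inherits(rest, "parcel_timeseries")) rest$data else as.matrix(rest)
  if (ncol(M) < 10) stop("need at least 10 TRs for FC", call. = FALSE)
  sdv <- apply(M, 1, stats::sd)
  flat <- which(sdv < 1e-12)
  r <- suppressWarnings(stats::cor(t(M)))
  r[flat, ] <- 0
  r[, flat] <- 0
  r <- pmin(pmax(r, -1 + 1e-7), 1 - 1e-7)
  z <- atanh(r)
  diag(z) <- 0
  z <- (z + t(z)) / 2
  attr(z, "zero_variance_parcels") <- flat
  z
}

#' Nodewise connectivity strength
#'
#' `strength[i]` is the mean over `j != i` of `max(z[i, j], 0)`: negative
#' connections are set to zero before averaging and the diagonal is
#' excluded.
#'
#' @param z Square symmetric Fisher-z matrix with zero diagonal.
#' @return Non-negative numeric vector of length `nrow(z)`.
#' @export
fc_strength <- function(z) {
  z <- as.matrix(z)
  if (nrow(z) != ncol(z) || max(abs(z - t(z))) > 1e-8)
    stop("fc_strength requires a square symmetric matrix", call. = FALSE)
  zp <- pmax(z, 0)
  diag(zp) <- 0
  rowSums(zp) / (nrow(z) - 1)
}

#' FC-strength profiles for a set of subjects
#'
#' @param rest_by_subject Named list of rest `parcel_timeseries` (or
#'   matrices), one per subject.
#' @return subjects x parcels matrix of strength profiles.
#' @export
fc_strength_profiles <- function(rest_by_subject) {
  out <- t(vapply(rest_by_subject,
                  function(ts) fc_strength(fc_matrix(ts)),
                  numeric(if (inherits(rest_by_subject[[1]],
                                       "parcel_timeseries"))
                    nrow(rest_by_subject[[1]]$data)
                    else nrow(rest_by_subject[[1]]))))
  rownames(out) <- names(rest_by_subject)
  out
}
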