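#' @title Brain-behavior coupling maps
#' @description Cross-subject Spearman rank correlation between per-parcel
#'   encoding R^2 and each cognitive score, with multiplicity control by
#'   the Benjamini-Hochberg step-up procedure applied to all parcel x score
#'   p-values pooled into a single vector.
#' @name semcine-cognition
NULL

#' Spearman correlation maps between subject R^2 profiles and scores
#'
#' Spearman rho is the Pearson correlation of average-ranked values;
#' p-values come from the large-sample t approximation with n - 2 degrees
#' of freedom. Parcels with any missing R^2 (degenerate upstream) get NaN
#' rho and are excluded from FDR pooling; constant score columns yield NaN
#' with a warning.
#'
#' @param subject_r2 subjects x parcels matrix of encoding R^2.
#' @param cognition Cognition table (data.frame from [read_cognition()]) or
#'   a subjects x scores numeric matrix; subject rows must align.
#' @return List with `rho` and `p` (parcels x scores matrices).
#' @export
spearman_map <- function(subject_r2, cognition) {
  X <- as.matrix(subject_r2)
  S <- if (is.data.frame(cognition))
    as.matrix(cognition[, setdiff(names(cognition), "subject_id")])
  else as.matrix(cognition)
  n <- nrow(X)
  if (n != nrow(S))
    stop("subject_r2 and cognition disagree on subject count", call. = FALSE)
  if (n < 10) stop("need at least 10 subjects", call. = FALSE)
  if (is.data.frame(cognition) && "subject_id" %in% names(cognition) &&
      !is.null(rownames(X)) &&
      !identical(rownames(X), as.character(cognition$subject_id)))
    stop("subject ids of R^2 matrix and cognition table are not aligned",
         call. = FALSE)

  const_s <- which(apply(S, 2, function(v) stats::sd(v) < 1e-12))
  if (length(const_s) > 0)
    warning("constant score column(s): ",
            paste(colnames(S)[const_s], collapse = ", "), call. = FALSE)
  bad_p <- which(apply(X, 2, function(v) anyNA(v) || stats::sd(v) < 1e-12))

  Rx <- apply(X, 2, rank, ties.method = "average", na.last = "keep")
  Rs <- apply(S, 2, rank, ties.method = "average")
  rho <- suppressWarnings(stats::cor(Rx, Rs))
  rho[bad_p, ] <- NaN
  rho[, const_s] <- NaN
  tt <- rho * sqrt((n - 2) / pmax(1 - rho^2, 1e-15))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  p[!is.finite(rho)] <- NaN
  dimnames(rho) <- dimnames(p) <- list(colnames(X), colnames(S))
  list(rho = rho, p = p)
}

#' Benjamini-Hochberg step-up rejection mask
#'
#' Sorts the p-values ascending, finds the largest `i` with
#' `p_(i) <= i q / m`, and rejects every hypothesis with `p <= p_(i)`.
#' NaN entries are excluded from `m` and never rejected.
#'
#' @param p_values Numeric vector (or matrix) of p-values in `[0, 1]`.
#' @param q FDR level in (0, 1).
#' @return Logical vector/matrix of the same shape (FALSE for NaN input).
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  if (!(q > 0 && q < 1)) stop("q must lie in (0, 1)", call. = FALSE)
  p <- as.vector(p_values)
  ok <- which(!is.na(p))
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("p-values outside [0, 1]", call. = FALSE)
  rej <- rep(FALSE, length(p))
  m <- length(ok)
  if (m > 0) {
    ps <- sort(p[ok])
    pass <- which(ps <= seq_len(m) * q / m)
    if (length(pass) > 0)
      rej[ok] <- p[ok] <= ps[max(pass)]
  }
  if (is.matrix(p_values))
    rej <- matrix(rej, nrow(p_values), dimnames = dimnames(p_values))
  rej
}

#' Full cognition-coupling analysis
#'
#' Runs [spearman_map()], pools all finite p-values into one vector for
#' [bh_fdr()], and computes the pairwise Pearson similarity between the
#' per-score rho maps over parcels.
#'
#' @param subject_r2,cognition As in [spearman_map()].
#' @param q FDR level.
#' @return A `coupling_result` list: `rho`, `p`, `significant` (logical,
#'   FDR-corrected), `q`, `map_similarity` (scores x scores).
#' @export
couple <- function(subject_r2, cognition, q = 0.05) {
  sm <- spearman_map(subject_r2, cognition)
  sig <- bh_fdr(sm$p, q)
  finite_rows <- stats::complete.cases(sm$rho)
  ms <- suppressWarnings(stats::cor(sm$rho[finite_rows, , drop = FALSE]))
  res <- list(rho = sm$rho, p = sm$p, significant = sig, q = q,
              map_similarity = ms)
  class(res) <- "coupling_result"
  res
}
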