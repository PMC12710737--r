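#' @title File readers and writers
#' @description All on-disk times are seconds. Tabular files are plain CSV /
#'   TSV; parcel time-series matrices are TSV with a small `#`-prefixed
#'   header recording subject, run, and TR so that units are never
#'   reinterpreted silently. Every writer emits full precision so that
#'   write-then-read round-trips are bitwise exact.
#' @name semcine-io
NULL

# ---- run timing ------------------------------------------------------------

new_run_timing <- function(run_id, intervals, tr_seconds = 1.0) {
  stopifnot(is.data.frame(intervals),
            all(c("start_s", "end_s", "label") %in% names(intervals)))
  x <- list(run_id = as.character(run_id),
            intervals = intervals[, c("start_s", "end_s", "label")],
            tr_seconds = as.numeric(tr_seconds))
  class(x) <- "run_timing"
  x
}

validate_run_timing <- function(rt) {
  iv <- rt$intervals
  bad_lab <- setdiff(unique(iv$label), c("movie", "rest"))
  if (length(bad_lab) > 0)
    stop("run ", rt$run_id, ": unknown interval label(s): ",
         paste(bad_lab, collapse = ", "), call. = FALSE)
  if (any(iv$end_s <= iv$start_s))
    stop("run ", rt$run_id, ": interval with non-positive length at row ",
         which(iv$end_s <= iv$start_s)[1], call. = FALSE)
  if (nrow(iv) > 1) {
    unsorted <- which(diff(iv$start_s) < 0)
    if (length(unsorted) > 0)
      stop("run ", rt$run_id, ": intervals not sorted at row ",
           unsorted[1] + 1, call. = FALSE)
    overlap <- which(iv$start_s[-1] < iv$end_s[-nrow(iv)])
    if (length(overlap) > 0)
      stop("run ", rt$run_id, ": overlapping intervals at row ",
           overlap[1] + 1, call. = FALSE)
  }
  invisible(rt)
}

#' Read run timing tables
#'
#' Parses a CSV with columns `run_id, start_s, end_s, label` (label `movie`
#' or `rest`; intervals half-open `[start_s, end_s)` in seconds) into one
#' `run_timing` record per run. Intervals within a run must be sorted and
#' non-overlapping.
#'
#' @param path CSV file path.
#' @param tr_seconds Sampling interval attached to each run (s).
#' @return Named list of `run_timing` objects, one per `run_id`.
#' @export
read_timing <- function(path, tr_seconds = 1.0) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("run_id", "start_s", "end_s", "label")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("timing file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  timings <- lapply(split(df, factor(df$run_id, levels = unique(df$run_id))),
                    function(d) {
    rt <- new_run_timing(d$run_id[1],
                         data.frame(start_s = as.numeric(d$start_s),
                                    end_s = as.numeric(d$end_s),
                                    label = as.character(d$label)),
                         tr_seconds)
    validate_run_timing(rt)
  })
  timings[unique(df$run_id)]
}

#' @rdname read_timing
#' @param timings List of `run_timing` objects to serialize.
#' @export
write_timing <- function(timings, path) {
  rows <- do.call(rbind, lapply(timings, function(rt) {
    data.frame(run_id = rt$run_id, start_s = rt$intervals$start_s,
               end_s = rt$intervals$end_s, label = rt$intervals$label)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- feature table ---------------------------------------------------------

#' Read a clip-level semantic feature table
#'
#' CSV with a `clip_id` column plus exactly the eleven schema columns (any
#' order; reordered to [feature_schema()] order on read). Values must lie in
#' `[0, 1]` and clip ids must be unique.
#'
#' @param path CSV file path.
#' @param schema Feature name vector; defaults to [feature_schema()].
#' @return data.frame with `clip_id` followed by the 11 feature columns.
#' @export
read_feature_table <- function(path, schema = feature_schema()) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        check.names = FALSE)
  if (!"clip_id" %in% names(df))
    stop("feature table missing clip_id column", call. = FALSE)
  miss <- setdiff(schema, names(df))
  if (length(miss) > 0)
    stop("feature table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df <- df[, c("clip_id", schema)]
  validate_feature_table(df, schema)
}

validate_feature_table <- function(df, schema = feature_schema()) {
  dup <- df$clip_id[duplicated(df$clip_id)]
  if (length(dup) > 0)
    stop("duplicate clip_id: ", dup[1], call. = FALSE)
  for (col in schema) {
    v <- df[[col]]
    if (anyNA(v) || !is.numeric(v))
      stop("feature column ", col, " has missing or non-numeric values",
           call. = FALSE)
    bad <- which(v < 0 | v > 1)
    if (length(bad) > 0)
      stop("feature value out of [0,1] for clip ", df$clip_id[bad[1]],
           ", column ", col, call. = FALSE)
  }
  df
}

#' @rdname read_feature_table
#' @param df Feature table to serialize.
#' @export
write_feature_table <- function(df, path, schema = feature_schema()) {
  validate_feature_table(df, schema)
  out <- df[, c("clip_id", schema)]
  for (col in schema) out[[col]] <- sprintf("%.17g", out[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- parcel time series ----------------------------------------------------

new_parcel_timeseries <- function(subject_id, run_id, data, tr_seconds,
                                  zero_variance_parcels = integer(0)) {
  stopifnot(is.matrix(data))
  if (any(!is.finite(data)))
    stop("parcel time series contains NaN/Inf", call. = FALSE)
  x <- list(subject_id = as.character(subject_id),
            run_id = as.character(run_id),
            data = data,
            tr_seconds = as.numeric(tr_seconds),
            zero_variance_parcels = as.integer(zero_variance_parcels))
  class(x) <- "parcel_timeseries"
  x
}

#' Read / write a parcel-by-TR BOLD matrix
#'
#' TSV: `#`-prefixed header lines carry `subject_id`, `run_id`, and
#' `tr_seconds`; the body is the parcels x TRs matrix at full precision
#' (bitwise round-trip). NaN or infinite entries are rejected; if
#' `expected_parcels` is given, a row-count mismatch is an error.
#'
#' @param path TSV file path (`.gz` accepted).
#' @param expected_parcels Optional required parcel count.
#' @return A `parcel_timeseries` object (fields `subject_id`, `run_id`,
#'   `data` parcels x TRs, `tr_seconds`).
#' @export
read_parcel_timeseries <- function(path, expected_parcels = NULL) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  hdr <- character(0)
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0 || !startsWith(line, "#")) break
    hdr <- c(hdr, line)
  }
  meta <- list(subject_id = NA_character_, run_id = NA_character_,
               tr_seconds = NA_real_)
  for (h in hdr) {
    kv <- strsplit(sub("^#\\s*", "", h), ":\\s*")[[1]]
    if (length(kv) == 2 && kv[1] %in% names(meta)) meta[[kv[1]]] <- kv[2]
  }
  if (is.na(meta$subject_id) || is.na(meta$run_id) || is.na(meta$tr_seconds))
    stop("parcel time-series header must carry subject_id, run_id, tr_seconds",
         call. = FALSE)
  body <- c(line, readLines(con))
  body <- body[nzchar(body)]
  data <- do.call(rbind, lapply(strsplit(body, "\t", fixed = TRUE), as.numeric))
  if (any(!is.finite(data)))
    stop("parcel time series contains NaN/Inf: ", path, call. = FALSE)
  if (!is.null(expected_parcels) && nrow(data) != expected_parcels)
    stop("parcel count mismatch: file has ", nrow(data), ", expected ",
         expected_parcels, call. = FALSE)
  new_parcel_timeseries(meta$subject_id, meta$run_id, data,
                        as.numeric(meta$tr_seconds))
}

#' @rdname read_parcel_timeseries
#' @param ts A `parcel_timeseries` object.
#' @export
write_parcel_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "parcel_timeseries"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# subject_id: ", ts$subject_id),
               paste0("# run_id: ", ts$run_id),
               paste0("# tr_seconds: ", sprintf("%.17g", ts$tr_seconds))), con)
  writeLines(apply(ts$data, 1, function(r)
    paste(sprintf("%.17g", r), collapse = "\t")), con)
  invisible(path)
}

# ---- cognition table -------------------------------------------------------

#' Read a subject cognition table
#'
#' CSV with `subject_id` plus the seven age-adjusted score columns of
#' [cognition_schema()].
#'
#' @param path CSV file path.
#' @return data.frame with `subject_id` followed by the 7 score columns.
#' @export
read_cognition <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("subject_id", cognition_schema())
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("cognition table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyNA(df[, cognition_schema()]))
    stop("cognition table has missing values", call. = FALSE)
  df[, need]
}

#' @rdname read_cognition
#' @param df Cognition table to serialize.
#' @export
write_cognition <- function(df, path) {
  out <- df[, c("subject_id", cognition_schema())]
  for (col in cognition_schema()) out[[col]] <- sprintf("%.17g", out[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- numeric matrices with provenance --------------------------------------

#' Write / read a numeric matrix as TSV with a provenance comment
#'
#' Used for group response matrices, subject R-squared matrices, FC-strength
#' profiles, saliences, and similar outputs. Row and column names are
#' preserved; values are written at full precision.
#'
#' @param m Numeric matrix.
#' @param path TSV file path.
#' @param provenance Optional character scalar written as a `#` comment.
#' @return `read_matrix_tsv` returns the matrix; writers return `path`.
#' @export
write_matrix_tsv <- function(m, path, provenance = NULL) {
  stopifnot(is.matrix(m))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
  cn <- if (is.null(colnames(m))) paste0("c", seq_len(ncol(m))) else colnames(m)
  rn <- if (is.null(rownames(m))) paste0("r", seq_len(nrow(m))) else rownames(m)
  writeLines(paste(c("id", cn), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(m)), function(i)
    paste(c(rn[i], sprintf("%.17g", m[i, ])), collapse = "\t"), character(1))
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

provenance_line <- function(cfg) {
  paste0("config: ", config_hash(cfg), " seed: ", cfg$rng_seed)
}
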