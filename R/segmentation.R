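#' @title Sliding-window clip segmentation
#' @description Converts run timing tables into the overlapping clip
#'   manifest. Each continuous movie interval `[a, b)` is reduced to a
#'   usable window `[a, b - end_buffer_s)`; candidate clip onsets advance in
#'   `clip_step_s` steps from `a`; each candidate spans
#'   `min(clip_target_s, usable_end - start)` seconds and is kept iff at
#'   least `clip_min_s` long. Enumeration halts at the first rejected
#'   candidate, so a single shortened clip may appear at a segment tail.
#'   Clips never span two movie intervals and never touch rest blocks.
#' @name semcine-segmentation
NULL

#' Segment one run into clip records
#'
#' @param timing A `run_timing` object (see [read_timing()]).
#' @param config A [pipeline_config()].
#' @return data.frame with columns `run_id, start_s, end_s, duration_s`,
#'   one row per clip in temporal order. A movie interval too short to host
#'   any clip contributes zero rows (not an error).
#' @export
segment_run <- function(timing, config) {
  validate_run_timing(timing)
  validate_config(config)
  iv <- timing$intervals
  movie <- iv[iv$label == "movie", , drop = FALSE]
  out <- vector("list", nrow(movie))
  for (k in seq_len(nrow(movie))) {
    a <- movie$start_s[k]
    usable_end <- movie$end_s[k] - config$end_buffer_s
    starts <- numeric(0)
    ends <- numeric(0)
    s <- a
    while (s < usable_end) {
      len <- min(config$clip_target_s, usable_end - s)
      if (len < config$clip_min_s) break
      starts <- c(starts, s)
      ends <- c(ends, s + len)
      s <- s + config$clip_step_s
    }
    out[[k]] <- data.frame(run_id = rep(timing$run_id, length(starts)),
                           start_s = starts,
                           end_s = ends, duration_s = ends - starts)
  }
  empty <- data.frame(run_id = character(0), start_s = numeric(0),
                      end_s = numeric(0), duration_s = numeric(0))
  do.call(rbind, c(list(empty), out, list(make.row.names = FALSE)))
}

#' Build the clip manifest over all runs
#'
#' Concatenates [segment_run()] outputs in run order then temporal order and
#' assigns clip ids `run_id:index` (0-based within run).
#'
#' @param timings List of `run_timing` objects with unique run ids.
#' @param config A [pipeline_config()].
#' @return data.frame (`clip_manifest`) with columns
#'   `clip_id, run_id, start_s, end_s, duration_s`.
#' @export
build_manifest <- function(timings, config) {
  ids <- vapply(timings, function(t) t$run_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate run_id: ", ids[duplicated(ids)][1], call. = FALSE)
  parts <- lapply(timings, segment_run, config = config)
  parts <- lapply(parts, function(d) {
    if (is.null(d) || nrow(d) == 0) return(NULL)
    d$clip_id <- paste0(d$run_id, ":", seq_len(nrow(d)) - 1L)
    d
  })
  parts <- Filter(Negate(is.null), parts)
  if (length(parts) == 0) {
    manifest <- data.frame(clip_id = character(0), run_id = character(0),
                           start_s = numeric(0), end_s = numeric(0),
                           duration_s = numeric(0))
  } else {
    manifest <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
  }
  manifest <- manifest[, c("clip_id", "run_id", "start_s", "end_s",
                           "duration_s")]
  attr(manifest, "config_hash") <- config_hash(config)
  class(manifest) <- c("clip_manifest", "data.frame")
  manifest
}

#' Read / write a clip manifest CSV
#' @param path CSV file path.
#' @return `read_manifest` returns the manifest data.frame.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("clip_id", "run_id", "start_s", "end_s", "duration_s")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("manifest missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df <- df[, need]
  class(df) <- c("clip_manifest", "data.frame")
  df
}

#' @rdname read_manifest
#' @param manifest Manifest to serialize.
#' @param provenance Optional `#` comment line.
#' @export
write_manifest <- function(manifest, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
  out <- as.data.frame(manifest)
  for (col in c("start_s", "end_s", "duration_s"))
    out[[col]] <- sprintf("%.17g", out[[col]])
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
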