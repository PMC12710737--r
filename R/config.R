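#' Pipeline configuration
#'
#' Bundles every tunable constant of the analysis. All durations are in
#' seconds; conversion to TR indices happens only where time series are
#' touched. Defaults reproduce the published analysis choices: 20-s target
#' clips with a 16-s minimum and 10-s step, a 5-s end-of-segment buffer, a
#' 5-s hemodynamic lag, ridge penalty `lambda = 1` on the standardized scale,
#' a 5% per-tail trimmed mean for group aggregation, 1,000 permutations and
#' bootstraps, and Benjamini-Hochberg FDR at q = 0.05.
#'
#' @param tr_seconds Sampling interval of the BOLD series (s).
#' @param lag_seconds Forward shift of clip windows for hemodynamic delay (s).
#' @param clip_target_s Target clip duration (s).
#' @param clip_min_s Minimum allowable clip duration (s).
#' @param clip_step_s Sliding-window step between consecutive clip onsets (s).
#' @param end_buffer_s Buffer reserved at the end of each movie segment (s).
#' @param rest_block_s Duration of fixation blocks between segments (s).
#' @param ridge_lambda Ridge penalty applied to standardized predictors.
#' @param trim_fraction Fraction trimmed from each tail in the group mean.
#' @param n_permutations Permutations for the PLS significance test.
#' @param n_bootstrap Bootstrap resamples for PLS loading stability.
#' @param fdr_q FDR level for the cognition coupling maps.
#' @param n_parcels Number of cortical parcels expected in all matrices.
#' @param rng_seed Integer seed recorded with every output.
#' @return An object of class `pipeline_config` (a validated named list).
#' @export
pipeline_config <- function(tr_seconds = 1.0,
                            lag_seconds = 5.0,
                            clip_target_s = 20,
                            clip_min_s = 16,
                            clip_step_s = 10,
                            end_buffer_s = 5,
                            rest_block_s = 20,
                            ridge_lambda = 1.0,
                            trim_fraction = 0.05,
                            n_permutations = 1000L,
                            n_bootstrap = 1000L,
                            fdr_q = 0.05,
                            n_parcels = 360L,
                            rng_seed = 1L) {
  cfg <- list(
    tr_seconds = as.numeric(tr_seconds),
    lag_seconds = as.numeric(lag_seconds),
    clip_target_s = as.numeric(clip_target_s),
    clip_min_s = as.numeric(clip_min_s),
    clip_step_s = as.numeric(clip_step_s),
    end_buffer_s = as.numeric(end_buffer_s),
    rest_block_s = as.numeric(rest_block_s),
    ridge_lambda = as.numeric(ridge_lambda),
    trim_fraction = as.numeric(trim_fraction),
    n_permutations = as.integer(n_permutations),
    n_bootstrap = as.integer(n_bootstrap),
    fdr_q = as.numeric(fdr_q),
    n_parcels = as.integer(n_parcels),
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  chk <- function(ok, msg) if (!isTRUE(ok)) stop("invalid config: ", msg, call. = FALSE)
  chk(cfg$tr_seconds > 0, "tr_seconds must be positive")
  chk(cfg$lag_seconds >= 0, "lag_seconds must be non-negative")
  chk(cfg$clip_target_s > 0, "clip_target_s must be positive")
  chk(cfg$clip_min_s > 0 && cfg$clip_min_s <= cfg$clip_target_s,
      "clip_min_s must be positive and <= clip_target_s")
  chk(cfg$clip_step_s > 0 && cfg$clip_step_s <= cfg$clip_target_s,
      "clip_step_s must be positive and <= clip_target_s")
  chk(cfg$end_buffer_s >= 0, "end_buffer_s must be non-negative")
  chk(cfg$rest_block_s > 0, "rest_block_s must be positive")
  chk(cfg$ridge_lambda > 0, "ridge_lambda must be positive")
  chk(cfg$trim_fraction >= 0 && cfg$trim_fraction < 0.5,
      "trim_fraction must lie in [0, 0.5)")
  chk(cfg$n_permutations >= 1, "n_permutations must be a positive integer")
  chk(cfg$n_bootstrap >= 1, "n_bootstrap must be a positive integer")
  chk(cfg$fdr_q > 0 && cfg$fdr_q < 1, "fdr_q must lie in (0, 1)")
  chk(cfg$n_parcels >= 1, "n_parcels must be a positive integer")
  invisible(cfg)
}

#' Read or write a pipeline configuration as YAML
#'
#' Round-trips losslessly: every field of [pipeline_config()] is written and
#' read back with full numeric precision.
#'
#' @param path Path to a YAML file.
#' @param cfg A `pipeline_config` object.
#' @return `read_config` returns a `pipeline_config`; `write_config` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0)
    stop("unknown config field(s): ", paste(extra, collapse = ", "), call. = FALSE)
  do.call(pipeline_config, raw)
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  # emit doubles via %.17g so the round-trip is bitwise lossless
  yaml::write_yaml(unclass(cfg), path, handlers = list(
    numeric = function(y) structure(sprintf("%.17g", y),
                                    class = "verbatim")))
  invisible(path)
}

#' Short hash of a configuration, recorded as provenance in output files.
#' @param cfg A `pipeline_config`.
#' @return A character scalar (truncated md5 of the serialized fields).
#' @export
config_hash <- function(cfg) {
  validate_config(cfg)
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_config(cfg, tmp)
  substr(unname(tools::md5sum(tmp)), 1, 12)
}

#' The eleven semantic feature names, in canonical order
#'
#' Order is fixed and every feature table is reordered to it on read: motion
#' intensity, scene brightness, people presence, faces close-up, social
#' interaction, dialogue, music, valence, arousal, threat, narrative progress.
#'
#' @return Character vector of length 11.
#' @export
feature_schema <- function() {
  c("motion_intensity", "scene_brightness", "people_presence",
    "faces_closeup", "social_interaction", "dialogue", "music",
    "valence", "arousal", "threat", "narrative_progress")
}

#' The seven cognitive score names (age-adjusted HCP-style indices)
#' @return Character vector of length 7.
#' @export
cognition_schema <- function() {
  c("PMAT24", "PicSeq", "ListSort", "CardSort", "Flanker",
    "CogFluidComp", "CogCrystalComp")
}
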