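#' @title End-to-end pipeline
#' @description Orchestrates the full analysis on an in-memory study (real
#'   or synthetic): segmentation, clip responses, group aggregation,
#'   group-level and subject-level ridge encoding, FC strength, PLS with
#'   permutation and bootstrap inference, and cognition coupling. All
#'   randomness flows from `config$rng_seed`, so two runs with the same
#'   seed produce bitwise-identical outputs.
#' @name semcine-pipeline
NULL

#' Per-subject encoding R^2 matrix
#'
#' Builds each subject's clip response matrix and runs the leave-one-out
#' ridge encoding on it, collecting the R^2 profiles into the
#' subjects x parcels block used by the PLS and cognition analyses.
#'
#' @param movie Subjects -> runs -> `parcel_timeseries` list.
#' @param features Feature table aligned to the manifest.
#' @param manifest Clip manifest.
#' @param timings Named list of `run_timing`.
#' @param config A [pipeline_config()].
#' @return subjects x parcels matrix of cross-validated R^2.
#' @export
subject_r2_matrix <- function(movie, features, manifest, timings, config) {
  rows <- lapply(names(movie), function(s) {
    Y <- subject_clip_matrix(movie[[s]], manifest, timings, config)
    loocv_encode(features, Y, lambda = config$ridge_lambda)$r2
  })
  out <- do.call(rbind, rows)
  rownames(out) <- names(movie)
  out
}

#' Run the full analysis on a study object
#'
#' @param study A list as returned by [simulate_study()] (or assembled from
#'   files with the readers in this package).
#' @param config A [pipeline_config()]; defaults to `study$config`.
#' @return A list with `manifest`, `group_responses`, `group_encoding`
#'   (`encoding_result`), `importance`, `subject_r2`, `fc_strength`
#'   (subjects x parcels), `pls` (`pls_result` plus `perm_p`, `boot_z_u`,
#'   `boot_z_v`), `coupling` (`coupling_result`).
#' @export
run_pipeline <- function(study, config = study$config) {
  validate_config(config)
  manifest <- study$manifest
  timings <- study$timings
  features <- study$features
  stopifnot(identical(as.character(features$clip_id),
                      as.character(manifest$clip_id)))

  subj_mats <- lapply(study$movie, subject_clip_matrix,
                      manifest = manifest, timings = timings, config = config)
  group_resp <- group_aggregate(subj_mats, config$trim_fraction)
  group_enc <- loocv_encode(features, group_resp,
                            lambda = config$ridge_lambda)
  importance <- feature_importance(group_enc)

  subj_r2 <- do.call(rbind, lapply(subj_mats, function(Y)
    loocv_encode(features, Y, lambda = config$ridge_lambda)$r2))
  dimnames(subj_r2) <- list(names(subj_mats),
                            colnames(subj_mats[[1]]))

  strength <- fc_strength_profiles(study$rest)
  colnames(strength) <- colnames(subj_r2)

  pls <- pls_svd(subj_r2, strength, K = 1)
  pls$perm_p <- pls_permutation_test(subj_r2, strength, K = 1,
                                     n_perm = config$n_permutations,
                                     seed = child_seed(config$rng_seed, 11))
  boot <- pls_bootstrap_stability(subj_r2, strength, K = 1,
                                  n_boot = config$n_bootstrap,
                                  seed = child_seed(config$rng_seed, 12))
  pls$boot_z_u <- boot$boot_z_u
  pls$boot_z_v <- boot$boot_z_v

  coupling <- couple(subj_r2, study$cognition, q = config$fdr_q)

  list(manifest = manifest, group_responses = group_resp,
       group_encoding = group_enc, importance = importance,
       subject_r2 = subj_r2, fc_strength = strength, pls = pls,
       coupling = coupling)
}

#' Write pipeline results to a directory
#'
#' Emits manifest.csv, group_responses.tsv, r2.tsv, beta.tsv,
#' importance.tsv, subject_r2.tsv, fc_strength.tsv, pls saliences /
#' scores / varexp / perm_p / boot_z, and cognition rho / p /
#' significant / map_similarity, each with a provenance comment (config
#' hash + seed).
#'
#' @param results Output of [run_pipeline()].
#' @param config The [pipeline_config()] used.
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_results <- function(results, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  prov <- provenance_line(config)
  p <- function(f) file.path(out_dir, f)

  write_manifest(results$manifest, p("manifest.csv"), provenance = prov)
  write_matrix_tsv(results$group_responses, p("group_responses.tsv"), prov)

  enc <- results$group_encoding
  r2m <- matrix(enc$r2, ncol = 1,
                dimnames = list(paste0("parcel", seq_along(enc$r2)), "r2"))
  write_matrix_tsv(r2m, p("r2.tsv"), prov)
  bet <- enc$beta
  rownames(bet) <- paste0("parcel", seq_len(nrow(bet)))
  write_matrix_tsv(bet, p("beta.tsv"), prov)
  imp <- rbind(mean_abs_beta = results$importance$mean_abs_beta,
               weighted_abs_beta = results$importance$weighted_abs_beta)
  write_matrix_tsv(imp, p("importance.tsv"), prov)

  write_matrix_tsv(results$subject_r2, p("subject_r2.tsv"), prov)
  write_matrix_tsv(results$fc_strength, p("fc_strength.tsv"), prov)

  pls <- results$pls
  sal <- cbind(u1 = pls$u[, 1], v1 = pls$v[, 1],
               boot_z_u1 = pls$boot_z_u[, 1], boot_z_v1 = pls$boot_z_v[, 1])
  rownames(sal) <- paste0("parcel", seq_len(nrow(sal)))
  write_matrix_tsv(sal, p("pls_saliences.tsv"), prov)
  sco <- cbind(x_score1 = pls$x_scores[, 1], y_score1 = pls$y_scores[, 1])
  rownames(sco) <- rownames(results$subject_r2)
  write_matrix_tsv(sco, p("pls_scores.tsv"), prov)
  ve <- rbind(singular_value = pls$singular_values,
              covariance_explained = pls$covariance_explained,
              x_variance_explained = pls$block_variance_explained$x,
              y_variance_explained = pls$block_variance_explained$y,
              perm_p = pls$perm_p)
  colnames(ve) <- paste0("LV", seq_len(ncol(ve)))
  write_matrix_tsv(ve, p("pls_varexp.tsv"), prov)

  cp <- results$coupling
  write_matrix_tsv(cp$rho, p("cognition_rho.tsv"), prov)
  write_matrix_tsv(cp$p, p("cognition_p.tsv"), prov)
  write_matrix_tsv(cp$significant * 1, p("cognition_significant.tsv"), prov)
  write_matrix_tsv(cp$map_similarity, p("cognition_map_similarity.tsv"), prov)
  invisible(out_dir)
}

#' Write a synthetic study to a directory
#'
#' Emits timing.csv, manifest.csv, features.csv, cognition.csv, truth.json,
#' and per-subject movie/rest matrices under movie/ and rest/.
#'
#' @param study Output of [simulate_study()].
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_study <- function(study, out_dir) {
  dir.create(file.path(out_dir, "movie"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "rest"), recursive = TRUE,
             showWarnings = FALSE)
  prov <- provenance_line(study$config)
  write_timing(study$timings, file.path(out_dir, "timing.csv"))
  write_manifest(study$manifest, file.path(out_dir, "manifest.csv"),
                 provenance = prov)
  write_feature_table(study$features, file.path(out_dir, "features.csv"))
  write_cognition(study$cognition, file.path(out_dir, "cognition.csv"))
  for (s in names(study$movie))
    for (r in names(study$movie[[s]]))
      write_parcel_timeseries(study$movie[[s]][[r]],
                              file.path(out_dir, "movie",
                                        paste0(s, "_", r, ".tsv")))
  for (s in names(study$rest))
    write_parcel_timeseries(study$rest[[s]],
                            file.path(out_dir, "rest", paste0(s, ".tsv")))
  tr <- study$truth
  tr$B <- NULL  # large; regenerable from the seed
  jsonlite::write_json(
    list(seed = tr$seed, n_parcels = tr$n_parcels,
         n_subjects = tr$n_subjects,
         active_parcels = tr$active_parcels,
         planted_cognition_parcels = tr$planted_cognition_parcels,
         gain_trait_corr = tr$gain_trait_corr, noise_sd = tr$noise_sd,
         gain_mode = tr$gain_mode,
         subject_gain = tr$subject_gain, subject_trait = tr$subject_trait,
         axis_loading = tr$axis_loading),
    file.path(out_dir, "truth.json"), digits = NA)
  invisible(out_dir)
}
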