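# Fixture builders shared across test files. Everything is generated in code;
# no binary fixtures.

# timing table with a single movie interval [0, len) (plus optional rest)
one_interval_timing <- function(len, run_id = "run1", tr = 1,
                                rest_after = 0) {
  iv <- data.frame(start_s = 0, end_s = len, label = "movie")
  if (rest_after > 0)
    iv <- rbind(iv, data.frame(start_s = len, end_s = len + rest_after,
                               label = "rest"))
  semcine:::new_run_timing(run_id, iv, tr)
}

# write a timing CSV and return the path
write_timing_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# small feature table: n clips x 11 schema columns filled with `value`
const_feature_table <- function(n, value = 0.5,
                                ids = paste0("run1:", seq_len(n) - 1)) {
  out <- data.frame(clip_id = ids)
  for (f in feature_schema()) out[[f]] <- rep(value, n)
  out
}

# random feature table in [0,1]
random_feature_table <- function(n, seed = 1) {
  set.seed(seed)
  out <- data.frame(clip_id = paste0("run1:", seq_len(n) - 1))
  for (f in feature_schema()) out[[f]] <- runif(n)
  out
}

# a small complete synthetic study for pipeline-level tests
tiny_study <- function(n_parcels = 40, n_subjects = 6, seed = 7,
                       noise_sd = 0.5, n_runs = 2, segments_per_run = 3,
                       n_TR_rest = 300, ...) {
  truth <- ground_truth(n_parcels = n_parcels, n_subjects = n_subjects,
                        noise_sd = noise_sd, seed = seed, ...)
  cfg <- pipeline_config(n_parcels = n_parcels, rng_seed = seed)
  simulate_study(truth, cfg, n_runs = n_runs,
                 segments_per_run = segments_per_run,
                 n_TR_rest = n_TR_rest, seed = seed)
}

# rank-one planted PLS blocks: X = s p' + noise, Y = s q' + noise
planted_blocks <- function(n = 100, p_dim = 60, q_dim = 60,
                           n_planted = 10, snr = 1, seed = 1) {
  set.seed(seed)
  s <- rnorm(n)
  p <- numeric(p_dim); p[seq_len(n_planted)] <- 1
  q <- numeric(q_dim); q[q_dim - seq_len(n_planted) + 1] <- 1
  X <- outer(s, p) * snr + matrix(rnorm(n * p_dim), n, p_dim)
  Y <- outer(s, q) * snr + matrix(rnorm(n * q_dim), n, q_dim)
  list(X = X, Y = Y, s = s,
       p = p / sqrt(sum(p^2)), q = q / sqrt(sum(q^2)),
       planted_x = seq_len(n_planted),
       planted_y = q_dim - seq_len(n_planted) + 1)
}
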