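# Internal helpers.

# Seed the RNG for the duration of the calling function, restoring the
# caller's RNG state on exit, so generators are pure functions of their seed
# without clobbering the session stream.
local_rng <- function(seed, env = parent.frame()) {
  old <- if (exists(".Random.seed", .GlobalEnv, inherits = FALSE))
    get(".Random.seed", .GlobalEnv) else NULL
  restore <- if (is.null(old)) {
    quote(if (exists(".Random.seed", .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv))
  } else {
    bquote(assign(".Random.seed", .(old), .GlobalEnv))
  }
  do.call(base::on.exit, list(restore, add = TRUE), envir = env)
  set.seed(as.integer(seed))
  invisible(seed)
}

# Derive a child seed from a parent seed and a stream index, staying within
# 32-bit integer range.
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 1009 + 97 * k) %% .Machine$integer.max)
}
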