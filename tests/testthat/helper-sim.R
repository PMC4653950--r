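# shared fixtures, built in code at test time

small_config <- function(seed = 11L, ...) {
  sim_config(genome_length = 80000L, n_promoters = 30L, coverage = 30,
             seed = seed, ...)
}

# memoised small end-to-end run reused by several test files
shared_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- run_pipeline(sim_config(genome_length = 150000L,
                                        n_promoters = 100L, seed = 3L))
    }
    cache
  }
})

# hand-built dyad track from per-position forward raw counts
fake_track <- function(raw_fwd, raw_rev = NULL, window = 21L) {
  n <- length(raw_fwd)
  if (is.null(raw_rev)) raw_rev <- rep(0L, n)
  structure(list(
    raw = list(fwd = raw_fwd, rev = raw_rev),
    smooth = list(fwd = running_mean(raw_fwd, window),
                  rev = running_mean(raw_rev, window),
                  all = running_mean(raw_fwd + raw_rev, window)),
    core_length = 147L, window = window, genome_length = n),
    class = "dyad_track")
}

random_genome <- function(n, seed = 1L) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# constructed ancestral calls: everything determined, no mutations, then
# specific categories written in at chosen positions
constructed_calls <- function(n, mutations = NULL, seed = 1L) {
  set.seed(seed)
  anc <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  foc <- anc
  if (!is.null(mutations)) {
    for (i in seq_len(nrow(mutations))) {
      anc[mutations$pos[i]] <- mutations$from[i]
      foc[mutations$pos[i]] <- mutations$to[i]
    }
  }
  infer_ancestral_bases(foc, anc, anc)
}
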