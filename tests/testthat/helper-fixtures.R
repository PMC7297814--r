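# Shared fixtures, built in code. The study-scale simulation is expensive
# enough to be generated once per test run and reused read-only.

tiny_counts <- function(n_srna = 8, n_sample = 6, seed = 1, max_count = 50) {
  set.seed(seed)
  m <- matrix(rpois(n_srna * n_sample, max_count / 2), nrow = n_srna,
              dimnames = list(sprintf("g%02d", seq_len(n_srna)),
                              sprintf("s%02d", seq_len(n_sample))))
  srna_counts(m)
}

# deterministic random bedGraph track on a small genome
random_track <- function(seed, glen = 1000, n = 20, max_score = 1) {
  set.seed(seed)
  pos <- sort(sample(0:(glen - 1), 2 * n))
  start <- pos[seq(1, 2 * n, 2)]
  end <- pos[seq(2, 2 * n, 2)]
  keep <- end > start
  data.frame(chrom = "chrT", start = start[keep], end = end[keep],
             score = runif(sum(keep), 0, max_score))
}

# brute-force per-base expansion of a track: vector of length glen
track_per_base <- function(track, glen) {
  v <- numeric(glen)
  for (i in seq_len(nrow(track))) {
    idx <- (track$start[i] + 1):track$end[i]
    v[idx] <- track$score[i]
  }
  v
}

# independent BH step-up oracle
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- rev(cummin(rev(m * p[o] / seq_len(m))))
  pmin(1, q)[order(o)]
}

# independent Pearson chi-square oracle on a 2 x k table
chisq_oracle <- function(a, b) {
  keep <- a + b > 0
  m <- rbind(a[keep], b[keep])
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - e)^2 / e)
}

study_cache <- new.env(parent = emptyenv())

# study-scale synthetic dataset (one per seed), cached across test files
study_fixture <- function(seed = 42) {
  key <- paste0("study", seed)
  if (is.null(study_cache[[key]]))
    study_cache[[key]] <- simulate_srna_study(sim_config(seed = seed))
  study_cache[[key]]
}

de_fixture <- function(seed = 42) {
  key <- paste0("de", seed)
  if (is.null(study_cache[[key]])) {
    study <- study_fixture(seed)
    x <- filter_detectable(study$counts)
    study_cache[[key]] <- list(x = x, de = srna_de(x, study$groups))
  }
  study_cache[[key]]
}
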