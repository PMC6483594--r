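# Independent brute-force oracles used across the suite.

IUPAC_ORACLE_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

# Every concrete ACGT word a consensus denotes (cartesian product of codes).
enumerate_consensus_words <- function(consensus) {
  sets <- IUPAC_ORACLE_SETS[strsplit(consensus, "")[[1]]]
  grid <- do.call(expand.grid, c(rev(sets), stringsAsFactors = FALSE))
  apply(grid[, rev(seq_along(sets)), drop = FALSE], 1, paste, collapse = "")
}

# Mismatch count as minimum Hamming distance to any concrete word. An N in
# the query differs from every concrete base, so it always mismatches.
oracle_mismatches <- function(seq, consensus) {
  words <- enumerate_consensus_words(consensus)
  s <- strsplit(seq, "")[[1]]
  min(vapply(strsplit(words, ""), function(w) sum(w != s), integer(1)))
}

# Naive positional scanner: try every start at which the motif lies fully
# inside the biological window.
oracle_scan_starts <- function(sequence, tss_index, consensus, window_bio,
                               max_mm = 1) {
  L <- nchar(consensus)
  bio2off <- function(p) ifelse(p > 0, tss_index + p - 1, tss_index + p)
  starts <- seq(bio2off(window_bio[1]), bio2off(window_bio[2]) - L + 1)
  hits <- integer(0)
  for (o in starts) {
    sub <- substr(sequence, o + 1, o + L)
    if (oracle_mismatches(sub, consensus) <= max_mm) hits <- c(hits, o)
  }
  hits
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

random_read_table <- function(n, refs = c("reporter", "chr2"),
                              max_pos = 50L, barcodes = 20L) {
  data.frame(
    reference = sample(refs, n, replace = TRUE),
    five_prime_pos = sample.int(max_pos, n, replace = TRUE) - 1L,
    strand = sample(c("+", "-"), n, replace = TRUE),
    barcode = sprintf("BC%02d", sample.int(barcodes, n, replace = TRUE)),
    unique = sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.9, 0.1)),
    stringsAsFactors = FALSE
  )
}

# Exhaustive two-sided rank-sum p-value, written independently of the
# package implementation: enumerate every assignment of pooled observations
# to group A and compare U statistics computed from scratch.
oracle_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  m <- length(a)
  N <- length(pooled)
  midrank <- function(x, all) {
    vapply(x, function(v) sum(all < v) + (sum(all == v) + 1) / 2, numeric(1))
  }
  u_of <- function(idx) sum(midrank(pooled[idx], pooled)) - m * (m + 1) / 2
  u_obs <- u_of(seq_len(m))
  mu <- m * (N - m) / 2
  combos <- utils::combn(N, m)
  us <- apply(combos, 2, u_of)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Two-sided Fisher p for a 2x2 table by hypergeometric enumeration: sum the
# probabilities of all tables (fixed margins) no more probable than observed.
oracle_fisher_p <- function(x11, x12, x21, x22) {
  m <- x11 + x12
  n <- x21 + x22
  k <- x11 + x21
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(x11, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Build a normalized profile from one simulated library.
pipeline_profile <- function(lib, params, dedup = TRUE) {
  reads <- filter_unique(lib$reads, params$reference)
  if (dedup) reads <- dedup_reads(reads)
  prof <- build_profile(reads, params$reference, params$reference_length)
  normalize_rpm(prof, lib$genome_read_count)
}

# Simulated paired retention measurement for one half-life/treatment time.
simulated_retention <- function(h, treat_min, params, seed_pair,
                                dedup = FALSE) {
  tr <- sim_truth("sim", list(), h, treat_min = treat_min)
  ctl <- simulate_nexus_reads(tr, params, "control", 0, seed = seed_pair[1])
  tri <- simulate_nexus_reads(tr, params, "triptolide", treat_min,
                              seed = seed_pair[2])
  pc <- pipeline_profile(ctl, params, dedup)
  pt <- pipeline_profile(tri, params, dedup)
  w <- default_config()$signal_window_width
  retention_ratio(window_signal(pt, params$tss_index, w),
                  window_signal(pc, params$tss_index, w))
}
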