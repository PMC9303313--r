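# Independent oracles, deliberately written along different lines than the
# package's C++ core.

# Semi-global edit distance as a vectorized column DP: column j holds the
# distances of every pattern prefix to substrings of the text ending at j
# (free start). Vertical gap edges are resolved with the cummin trick.
oracle_sg_distance <- function(pattern, text) {
  p <- strsplit(pattern, "", fixed = TRUE)[[1]]
  m <- length(p)
  steps <- 0:m
  prev <- steps
  best <- m
  for (ch in strsplit(text, "", fixed = TRUE)[[1]]) {
    cand <- pmin(prev[1:m] + (p != ch), prev[2:(m + 1)] + 1L)
    cur <- cummin(c(0L, cand) - steps) + steps
    best <- min(best, cur[m + 1])
    prev <- cur
  }
  best
}

# base R's approximate substring matching (C implementation): the
# generalized Levenshtein distance at which the pattern occurs inside text
adist_sg_distance <- function(pattern, text) {
  as.integer(utils::adist(pattern, text, partial = TRUE))
}

rand_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# naive overlapping motif counter, independent of count_motifs()
naive_motif_count <- function(seq, motif) {
  n <- nchar(seq); k <- nchar(motif)
  hits <- 0L
  for (i in seq_len(max(n - k + 1L, 0L))) {
    if (substr(seq, i, i + k - 1L) == motif) hits <- hits + 1L
  }
  hits
}
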