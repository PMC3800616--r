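# Independent oracles and small fixture builders used across the suite.

ADAPTER <- "ATCACCGACTGCCCATAGAGAGG"  # the simulator's fixed 23-mer

# read_set builder with uniform high qualities unless given explicitly
mk_reads <- function(seqs, quals = NULL, ids = NULL, q = 35L) {
  if (is.null(ids)) ids <- sprintf("r%03d", seq_along(seqs))
  if (is.null(quals)) quals <- lapply(nchar(seqs), function(L) rep(q, L))
  read_set(ids, seqs, quals)
}

# Exhaustive Smith-Waterman score via an independent implementation
# (Biostrings pairwise alignment, linear gaps through opening 0).
oracle_sw_score <- function(read, ref, match = 2, mismatch = -2, gap = 4) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  as.integer(Biostrings::score(Biostrings::pairwiseAlignment(
    read, ref, type = "local", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = gap)))
}

# Tiny pure-R Smith-Waterman DP, used to pin down the oracle configuration
# on hand-sized cases.
sw_score_r <- function(read, ref, match = 2, mismatch = -2, gap = -4) {
  m <- nchar(read); n <- nchar(ref)
  r <- strsplit(read, "")[[1]]; f <- strsplit(ref, "")[[1]]
  H <- matrix(0, m + 1, n + 1); best <- 0
  for (i in 2:(m + 1)) for (j in 2:(n + 1)) {
    s <- if (r[i - 1] == f[j - 1] && r[i - 1] != "N") match else mismatch
    H[i, j] <- max(0, H[i - 1, j - 1] + s, H[i - 1, j] + gap,
                   H[i, j - 1] + gap)
    best <- max(best, H[i, j])
  }
  best
}

# Brute-force 3' adapter match over all (start, matched-length) pairs:
# longest matched adapter prefix length whose minimal edit distance to a
# read suffix fits the budget, with the leftmost minimizing start.
brute_adapter <- function(read, adapter, rate = 0.1, minov = 3) {
  n <- nchar(read); K <- nchar(adapter)
  best <- NULL
  for (L in minov:K) {
    ds <- vapply(1:n, function(s) {
      as.integer(adist(substr(adapter, 1, L), substr(read, s, n)))
    }, integer(1))
    if (min(ds) <= floor(rate * L)) {
      best <- list(start = which.min(ds) - 1L, L = L, edits = min(ds))
    }
  }
  if (is.null(best)) list(start = -1L, L = 0L, edits = NA_integer_)
  else best
}

# Shared exact k-mers between two sequences (seeding condition)
shares_seed <- function(a, b, k = 10L) {
  ka <- substring(a, 1:(nchar(a) - k + 1), k:nchar(a))
  kb <- substring(b, 1:(nchar(b) - k + 1), k:nchar(b))
  length(intersect(ka, kb)) > 0
}

rand_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
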