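#' Alignment parameters
#'
#' Settings for the k-mer-seeded Smith-Waterman local aligner. A read is
#' considered for a transcript only when the two share at least one exact
#' `seed_k`-mer; full local dynamic programming then scores every candidate
#' and the single best alignment is kept when its score reaches
#' `min_score_fraction` of the read's maximum attainable score
#' (`match * read_length`).
#'
#' @param seed_k exact seed length (default 10; must be >= 4).
#' @param match match score (default +2).
#' @param mismatch mismatch score (default -2).
#' @param gap per-base linear gap score (default -4).
#' @param min_score_fraction fraction of the maximum attainable score
#'   required to call a read mapped (default 0.8).
#' @param strand_mode `"forward_only"` (default; directional small-RNA
#'   libraries) or `"both"`.
#' @return An object of class `align_params`.
#' @export
align_params <- function(seed_k = 10L, match = 2L, mismatch = -2L,
                         gap = -4L, min_score_fraction = 0.8,
                         strand_mode = c("forward_only", "both")) {
  strand_mode <- match.arg(strand_mode)
  stopifnot(match > 0, mismatch < 0, gap < 0,
            min_score_fraction > 0, min_score_fraction <= 1, seed_k >= 4)
  structure(list(seed_k = as.integer(seed_k), match = as.integer(match),
                 mismatch = as.integer(mismatch), gap = as.integer(gap),
                 min_score_fraction = min_score_fraction,
                 strand_mode = strand_mode),
            class = "align_params")
}

#' Build an exact k-mer seed index over a reference set
#'
#' Maps every `seed_k`-mer occurring in the reference to its positions, as
#' a hashed environment of `kmer -> integer matrix (transcript index,
#' 0-based offset)`. Transcripts shorter than `seed_k` are indexed whole
#' (their full sequence is the key).
#'
#' @param ref a [reference_set()].
#' @param seed_k seed length.
#' @return An object of class `seed_index`.
#' @export
build_index <- function(ref, seed_k = 10L) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  n_positions <- 0L
  for (t in seq_len(nrow(ref))) {
    s <- ref$seq[t]
    L <- nchar(s)
    if (L < seed_k) {
      kmers <- s
      offs <- 0L
    } else {
      kmers <- substring(s, 1:(L - seed_k + 1), seed_k:L)
      offs <- 0:(L - seed_k)
    }
    n_positions <- n_positions + length(kmers)
    for (i in seq_along(kmers)) {
      km <- kmers[i]
      cur <- env[[km]]
      entry <- c(t, offs[i])
      env[[km]] <- if (is.null(cur)) matrix(entry, ncol = 2) else
        rbind(cur, entry)
    }
  }
  structure(list(env = env, seed_k = as.integer(seed_k),
                 n_positions = n_positions,
                 transcript_id = ref$transcript_id),
            class = "seed_index")
}

#' Number of indexed seed positions
#' @param index a `seed_index`.
#' @return Integer count of (k-mer, position) entries.
#' @export
index_size <- function(index) index$n_positions

# Candidate transcript indices sharing at least one exact seed with `seq`,
# in reference order. Sequences shorter than seed_k yield no candidates.
seed_candidates <- function(seq, index) {
  L <- nchar(seq)
  k <- index$seed_k
  if (L < k) return(integer())
  kmers <- unique(substring(seq, 1:(L - k + 1), k:L))
  hits <- mget(kmers, envir = index$env, ifnotfound = list(NULL))
  idx <- unlist(lapply(hits, function(h) if (is.null(h)) NULL else h[, 1]),
                use.names = FALSE)
  sort(unique(idx))
}

#' Align a single read against a reference set
#'
#' Candidate transcripts are those sharing at least one exact seed with the
#' read (and, in `"both"` strand mode, with its reverse complement); each
#' candidate is scored by full Smith-Waterman local dynamic programming and
#' the single best alignment is returned when its score reaches
#' `min_score_fraction * match * read_length`. Ties are broken by fewer
#' edits, then by transcript order in the reference set (and the forward
#' strand is preferred over the reverse on a full tie).
#'
#' @param seq a read sequence.
#' @param index a `seed_index` built from `ref` with [build_index()].
#' @param ref the [reference_set()].
#' @param params an [align_params()].
#' @return A list with `transcript_id`, `ref_start` (0-based),
#'   `read_start` (0-based), `cigar` (local M/I/D), `score`, `strand`,
#'   `edits`; or `NULL` if the read is unmapped.
#' @export
align_read <- function(seq, index, ref, params = align_params()) {
  threshold <- params$min_score_fraction * params$match * nchar(seq)
  best <- NULL
  strands <- if (params$strand_mode == "both") c("+", "-") else "+"
  for (st in strands) {
    qseq <- if (st == "+") seq else revcomp(seq)
    cand <- seed_candidates(qseq, index)
    if (!length(cand)) next
    hit <- .sw_best(qseq, ref$seq[cand], params$match, params$mismatch,
                    params$gap)
    if (is.na(hit$idx)) next
    if (hit$score < threshold) next
    rec <- list(transcript_id = ref$transcript_id[cand[hit$idx]],
                t_index = cand[hit$idx],
                ref_start = hit$ref_start, read_start = hit$read_start,
                cigar = hit$cigar, score = hit$score, strand = st,
                edits = hit$edits)
    if (is.null(best) ||
        rec$score > best$score ||
        (rec$score == best$score && rec$edits < best$edits) ||
        (rec$score == best$score && rec$edits == best$edits &&
         rec$t_index < best$t_index)) {
      best <- rec
    }
  }
  if (is.null(best)) return(NULL)
  best$t_index <- NULL
  best
}

#' Align a read set against a reference set
#'
#' Runs [align_read()] over every read and partitions the set into mapped
#' (one best alignment per read) and unmapped reads. Deterministic:
#' identical inputs give identical outputs.
#'
#' @param reads a [read_set()].
#' @param ref a [reference_set()].
#' @param params an [align_params()].
#' @param index optional prebuilt `seed_index` (rebuilt from `ref`
#'   otherwise).
#' @return A list with `alignments` (data frame with one row per mapped
#'   read: `read_id`, `transcript_id`, `ref_start`, `read_start`, `cigar`,
#'   `score`, `strand`, `edits`, `seq`, `qual`) and `unmapped` (a
#'   [read_set()]).
#' @export
align_batch <- function(reads, ref, params = align_params(), index = NULL) {
  if (nrow(ref) == 0) stop("empty reference set", call. = FALSE)
  if (is.null(index)) index <- build_index(ref, params$seed_k)
  n <- length(reads)
  mapped <- logical(n)
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    hit <- align_read(reads$seq[i], index, ref, params)
    if (!is.null(hit)) {
      mapped[i] <- TRUE
      recs[[i]] <- hit
    }
  }
  if (any(mapped)) {
    idx <- which(mapped)
    alignments <- data.frame(
      read_id = reads$read_id[idx],
      transcript_id = vapply(recs[idx], `[[`, character(1), "transcript_id"),
      ref_start = vapply(recs[idx], `[[`, integer(1), "ref_start"),
      read_start = vapply(recs[idx], `[[`, integer(1), "read_start"),
      cigar = vapply(recs[idx], `[[`, character(1), "cigar"),
      score = vapply(recs[idx], `[[`, integer(1), "score"),
      strand = vapply(recs[idx], `[[`, character(1), "strand"),
      edits = vapply(recs[idx], `[[`, integer(1), "edits"),
      seq = reads$seq[idx],
      qual = vapply(reads$qual[idx], encode_phred, character(1)),
      stringsAsFactors = FALSE)
  } else {
    alignments <- data.frame(
      read_id = character(), transcript_id = character(),
      ref_start = integer(), read_start = integer(), cigar = character(),
      score = integer(), strand = character(), edits = integer(),
      seq = character(), qual = character(), stringsAsFactors = FALSE)
  }
  list(alignments = alignments, unmapped = reads[!mapped])
}
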