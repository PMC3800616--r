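#' Preprocessing parameters
#'
#' Read-cleanup settings: trailing bases below `quality_threshold` are
#' trimmed from the 3' end, the 3' adapter is located and removed, and any
#' read shorter than `min_length` after either step is dropped. Short reads
#' are removed because they map ambiguously. The defaults (Q17 threshold,
#' 17-nt floor) are the standard small RNA-seq cleanup settings for
#' semiconductor sequencing libraries.
#'
#' @param adapter_seq 3' adapter nucleotide sequence (platform-specific;
#'   required for adapter trimming).
#' @param quality_threshold PHRED score below which trailing 3' bases are
#'   trimmed (default 17, about a 2% error rate).
#' @param min_length minimum kept read length in nt (default 17).
#' @param max_error_rate maximum edits per matched adapter base
#'   (default 0.1); the edit budget is `floor(rate * matched_length)`.
#' @param min_overlap minimum matched adapter prefix length (default 3).
#' @return An object of class `preprocess_params`.
#' @export
preprocess_params <- function(adapter_seq = NULL, quality_threshold = 17L,
                              min_length = 17L, max_error_rate = 0.1,
                              min_overlap = 3L) {
  stopifnot(quality_threshold >= 0, min_length >= 1,
            max_error_rate >= 0, max_error_rate < 0.5, min_overlap >= 1)
  if (!is.null(adapter_seq)) {
    adapter_seq <- toupper(adapter_seq)
    if (!nzchar(adapter_seq) || grepl("[^ACGTN]", adapter_seq)) {
      stop("adapter_seq must be a nonempty nucleotide string", call. = FALSE)
    }
  }
  structure(list(adapter_seq = adapter_seq,
                 quality_threshold = as.integer(quality_threshold),
                 min_length = as.integer(min_length),
                 max_error_rate = max_error_rate,
                 min_overlap = as.integer(min_overlap)),
            class = "preprocess_params")
}

#' Trim low-quality 3' ends
#'
#' Removes trailing bases whose quality is below `quality_threshold`,
#' stopping at the first base from the 3' end with quality at or above the
#' threshold (internal low-quality bases are retained). Reads shorter than
#' `min_length` afterwards are dropped.
#'
#' @param reads a [read_set()].
#' @param params a [preprocess_params()].
#' @return A list with elements `kept` (trimmed [read_set()]) and
#'   `dropped` (identifiers of removed reads).
#' @export
quality_trim <- function(reads, params = preprocess_params()) {
  n <- length(reads)
  if (!n) return(list(kept = reads, dropped = character()))
  keep_len <- vapply(reads$qual, function(q) {
    ok <- which(q >= params$quality_threshold)
    if (length(ok)) max(ok) else 0L
  }, integer(1))
  trimmed <- keep_len < nchar(reads$seq)
  out <- reads
  out$seq[trimmed] <- substr(out$seq[trimmed], 1L, keep_len[trimmed])
  out$qual[trimmed] <- mapply(function(q, l) q[seq_len(l)],
                              out$qual[trimmed], keep_len[trimmed],
                              SIMPLIFY = FALSE)
  removed <- nchar(reads$seq) - keep_len
  out$provenance[trimmed] <- mapply(function(p, r) {
    c(p, sprintf("quality_trim:removed=%d", r))
  }, out$provenance[trimmed], removed[trimmed], SIMPLIFY = FALSE)
  drop <- keep_len < params$min_length
  list(kept = out[!drop], dropped = reads$read_id[drop])
}

#' Trim 3' adapter read-through
#'
#' Finds the best semi-global match of a prefix of the adapter against a
#' suffix of each read (edits allowed up to
#' `floor(max_error_rate * matched_length)`, matched length at least
#' `min_overlap`) and removes everything from the match start to the read
#' end, qualities included. The longest qualifying match wins; ties go to
#' the fewest edits and then the leftmost start. Reads with no qualifying
#' match pass unchanged; reads shorter than `min_length` after trimming are
#' dropped. `N` never matches an adapter base.
#'
#' @param reads a [read_set()].
#' @param params a [preprocess_params()] with a non-`NULL` `adapter_seq`.
#' @return A list with elements `kept` and `dropped` as in
#'   [quality_trim()].
#' @export
trim_adapter <- function(reads, params) {
  if (is.null(params$adapter_seq)) {
    stop("adapter_seq is required for adapter trimming", call. = FALSE)
  }
  n <- length(reads)
  if (!n) return(list(kept = reads, dropped = character()))
  m <- .adapter_match(reads$seq, params$adapter_seq,
                      params$max_error_rate, params$min_overlap)
  hit <- m$start >= 0
  out <- reads
  out$seq[hit] <- substr(out$seq[hit], 1L, m$start[hit])
  out$qual[hit] <- mapply(function(q, l) q[seq_len(l)],
                          out$qual[hit], m$start[hit], SIMPLIFY = FALSE)
  removed <- nchar(reads$seq) - nchar(out$seq)
  out$provenance[hit] <- mapply(function(p, r, e) {
    c(p, sprintf("adapter_trim:removed=%d;edits=%d", r, e))
  }, out$provenance[hit], removed[hit], m$edits[hit], SIMPLIFY = FALSE)
  drop <- nchar(out$seq) < params$min_length
  list(kept = out[!drop], dropped = reads$read_id[drop])
}

#' Run the full read-cleanup pipeline
#'
#' Applies 3' quality trimming, the length floor, 3' adapter trimming, and
#' the length floor again, in that order. Every input read is either kept
#' or logged as dropped (with the step responsible), so
#' `length(kept) + sum(drop_counts)` equals the input count.
#'
#' @param reads a [read_set()].
#' @param params a [preprocess_params()]; adapter trimming is skipped when
#'   `adapter_seq` is `NULL`.
#' @return A list with `kept` (a [read_set()]), `drop_counts` (named
#'   integer vector: `quality_length`, `adapter_length`) and `dropped_ids`
#'   (named character vector of dropped read identifiers, names = reason).
#' @export
preprocess_stream <- function(reads, params) {
  q <- quality_trim(reads, params)
  if (!is.null(params$adapter_seq)) {
    a <- trim_adapter(q$kept, params)
  } else {
    a <- list(kept = q$kept, dropped = character())
  }
  dropped_ids <- c(setNames(q$dropped, rep("quality_length",
                                           length(q$dropped))),
                   setNames(a$dropped, rep("adapter_length",
                                           length(a$dropped))))
  list(kept = a$kept,
       drop_counts = c(quality_length = length(q$dropped),
                       adapter_length = length(a$dropped)),
       dropped_ids = dropped_ids)
}
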