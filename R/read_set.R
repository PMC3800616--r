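#' Construct a set of sequencing reads
#'
#' A `read_set` holds single-end reads as parallel vectors: identifiers,
#' nucleotide sequences over `{A,C,G,T,N}`, integer per-base PHRED scores,
#' and a per-read provenance trail of trimming steps. Sequence and quality
#' lengths are kept equal by construction, and every trimming operation
#' appends a provenance entry recording how many bases it removed, so the
#' original read length stays recoverable.
#'
#' @param read_id character vector of unique read identifiers.
#' @param seq character vector of sequences (same length as `read_id`).
#' @param qual list of integer vectors of PHRED scores, one per read, each
#'   the same length as its sequence; all scores must be >= 0.
#' @param provenance optional list of character vectors (trimming steps
#'   already applied); defaults to empty trails.
#' @return An object of class `read_set`.
#' @examples
#' rs <- read_set("r1", "ACGTACGT", list(rep(30L, 8)))
#' length(rs)
#' @export
read_set <- function(read_id = character(), seq = character(), qual = list(),
                     provenance = NULL) {
  read_id <- as.character(read_id)
  seq <- toupper(as.character(seq))
  n <- length(read_id)
  if (length(seq) != n || length(qual) != n) {
    stop("read_id, seq and qual must have equal length", call. = FALSE)
  }
  if (anyDuplicated(read_id)) {
    stop("duplicate read identifiers in read_set", call. = FALSE)
  }
  qual <- lapply(qual, function(q) as.integer(q))
  bad <- which(nchar(seq) != lengths(qual))
  if (length(bad)) {
    stop("sequence/quality length mismatch for read '", read_id[bad[1]], "'",
         call. = FALSE)
  }
  if (any(vapply(qual, function(q) any(q < 0L), logical(1)))) {
    stop("negative PHRED score in read_set", call. = FALSE)
  }
  if (is.null(provenance)) provenance <- rep(list(character()), n)
  structure(list(read_id = read_id, seq = seq, qual = qual,
                 provenance = provenance),
            class = "read_set")
}

#' @export
length.read_set <- function(x) length(x$read_id)

#' @export
`[.read_set` <- function(x, i) {
  if (is.character(i)) i <- match(i, x$read_id)
  structure(list(read_id = x$read_id[i], seq = x$seq[i], qual = x$qual[i],
                 provenance = x$provenance[i]),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat("read_set with", length(x), "reads\n")
  if (length(x)) {
    show <- head(seq_along(x$read_id), 5)
    for (i in show) {
      cat(sprintf("  %s  %s (%d nt)\n", x$read_id[i],
                  substr(x$seq[i], 1, 40), nchar(x$seq[i])))
    }
    if (length(x) > 5) cat("  ...\n")
  }
  invisible(x)
}

#' Read lengths of a read set
#' @param reads a `read_set`.
#' @return Integer vector of current sequence lengths.
#' @export
read_lengths <- function(reads) nchar(reads$seq)

#' Original (pre-trimming) read lengths
#'
#' Recovered from the provenance trail: current length plus all bases the
#' recorded trimming steps removed.
#'
#' @param reads a `read_set`.
#' @return Integer vector of original lengths.
#' @export
original_lengths <- function(reads) {
  removed <- vapply(reads$provenance, function(p) {
    if (!length(p)) return(0L)
    sum(as.integer(sub("^.*removed=(\\d+).*$", "\\1", p)))
  }, integer(1))
  nchar(reads$seq) + removed
}
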