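#' Decode an ASCII PHRED quality string
#'
#' Converts a FASTQ quality string to integer PHRED scores:
#' `score[i] = ASCII(qual[i]) - offset`. The default offset of 33 is the
#' Sanger/Ion Torrent convention.
#'
#' @param qual_string a single quality string.
#' @param offset integer ASCII offset (default 33).
#' @param read_id optional read identifier used in error messages.
#' @return Integer vector of PHRED scores.
#' @examples
#' decode_phred("!I2")   # 0, 40, 17
#' @export
decode_phred <- function(qual_string, offset = 33L, read_id = NULL) {
  codes <- utf8ToInt(qual_string)
  if (length(codes) && any(codes < offset)) {
    who <- if (is.null(read_id)) "" else paste0(" in read '", read_id, "'")
    stop("malformed FASTQ quality", who, ": character below offset ", offset,
         call. = FALSE)
  }
  as.integer(codes - offset)
}

#' Encode PHRED scores as an ASCII quality string
#'
#' Exact inverse of [decode_phred()] for scores in 0-60.
#'
#' @param scores integer vector of PHRED scores (>= 0).
#' @param offset integer ASCII offset (default 33).
#' @return A single quality string.
#' @export
encode_phred <- function(scores, offset = 33L) {
  if (!length(scores)) return("")
  if (any(scores < 0L)) stop("negative PHRED score", call. = FALSE)
  intToUtf8(as.integer(scores) + offset)
}

#' Read a FASTQ file into a read set
#'
#' Parses 4-line FASTQ records (PHRED+33 by default). Records are returned
#' in file order. Truncated records and sequence/quality length mismatches
#' raise a parse error naming the offending line.
#'
#' @param path path to an uncompressed FASTQ file.
#' @param offset PHRED ASCII offset (default 33).
#' @return A [read_set()].
#' @export
read_fastq <- function(path, offset = 33L) {
  lines <- readLines(path)
  nl <- length(lines)
  if (nl == 0) return(read_set())
  if (nl %% 4 != 0) {
    stop("truncated FASTQ record at line ", (nl %/% 4) * 4 + 1, " of ", path,
         call. = FALSE)
  }
  hdr <- lines[seq(1, nl, by = 4)]
  seqs <- toupper(lines[seq(2, nl, by = 4)])
  plus <- lines[seq(3, nl, by = 4)]
  quals <- lines[seq(4, nl, by = 4)]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad)) {
    stop("FASTQ parse error at line ", (bad[1] - 1) * 4 + 1,
         ": header must start with '@'", call. = FALSE)
  }
  bad <- which(!startsWith(plus, "+"))
  if (length(bad)) {
    stop("FASTQ parse error at line ", (bad[1] - 1) * 4 + 3,
         ": separator must start with '+'", call. = FALSE)
  }
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad)) {
    stop("FASTQ parse error at line ", (bad[1] - 1) * 4 + 4,
         ": sequence/quality length mismatch", call. = FALSE)
  }
  ids <- sub("\\s.*$", "", substring(hdr, 2))
  qual <- mapply(decode_phred, quals, offset = offset, read_id = ids,
                 SIMPLIFY = FALSE, USE.NAMES = FALSE)
  read_set(ids, seqs, qual)
}

#' Write a read set to a FASTQ file
#'
#' @param reads a [read_set()].
#' @param path output path.
#' @param offset PHRED ASCII offset (default 33).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, offset = 33L) {
  if (!length(reads)) {
    writeLines(character(), path)
    return(invisible(path))
  }
  quals <- vapply(reads$qual, encode_phred, character(1), offset = offset)
  out <- as.vector(rbind(paste0("@", reads$read_id), reads$seq, "+", quals))
  writeLines(out, path)
  invisible(path)
}
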