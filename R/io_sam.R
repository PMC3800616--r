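#' Write alignments to a SAM file
#'
#' Emits a minimal SAM v1.6 file: an `@HD` line, one `@SQ` line per
#' transcript in the reference set, and one record per mapped read with the
#' 11 mandatory fields plus `AS:i:` (alignment score) and `NM:i:` (edit
#' count) tags. `POS` is 1-based; read bases outside the local alignment
#' are soft-clipped in the CIGAR so that its read-consuming length equals
#' the read length. Unmapped reads are never written (the cascade routes
#' them onward as FASTQ). Minus-strand records carry flag 16 with `SEQ` and
#' `QUAL` reverse-complemented, per the SAM convention.
#'
#' @param alignments alignment data frame as produced by [align_batch()]
#'   (columns `read_id`, `transcript_id`, `ref_start`, `read_start`,
#'   `cigar`, `score`, `strand`, `edits`, `seq`, `qual`).
#' @param reference_set the [reference_set()] aligned against; every
#'   `transcript_id` in `alignments` must occur in it.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, reference_set, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", reference_set$transcript_id,
                   nchar(reference_set$seq)))
  if (is.null(alignments) || nrow(alignments) == 0) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  unknown <- setdiff(alignments$transcript_id, reference_set$transcript_id)
  if (length(unknown)) {
    stop("alignment to unknown transcript '", unknown[1], "'", call. = FALSE)
  }
  read_len <- nchar(alignments$seq)
  consumed <- cigar_read_length(alignments$cigar)
  lead <- alignments$read_start
  trail <- read_len - lead - consumed
  if (any(trail < 0)) stop("CIGAR consumes more bases than the read has",
                           call. = FALSE)
  full_cigar <- paste0(ifelse(lead > 0, paste0(lead, "S"), ""),
                       alignments$cigar,
                       ifelse(trail > 0, paste0(trail, "S"), ""))
  minus <- alignments$strand == "-"
  seq_out <- alignments$seq
  qual_out <- alignments$qual
  if (any(minus)) {
    seq_out[minus] <- revcomp(seq_out[minus])
    qual_out[minus] <- vapply(strsplit(qual_out[minus], ""), function(q) {
      paste(rev(q), collapse = "")
    }, character(1))
    # CIGAR and clips are reported in reference orientation
    full_cigar[minus] <- paste0(
      ifelse(trail[minus] > 0, paste0(trail[minus], "S"), ""),
      reverse_cigar(alignments$cigar[minus]),
      ifelse(lead[minus] > 0, paste0(lead[minus], "S"), ""))
  }
  rec <- sprintf("%s\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t%s\tAS:i:%d\tNM:i:%d",
                 alignments$read_id, ifelse(minus, 16L, 0L),
                 alignments$transcript_id, alignments$ref_start + 1L,
                 full_cigar, seq_out, qual_out,
                 as.integer(alignments$score), as.integer(alignments$edits))
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Structurally validate a SAM file
#'
#' Checks the properties downstream counting relies on: every record's
#' `RNAME` occurs in an `@SQ` header line, `POS >= 1`, and the CIGAR's
#' read-consuming operations (`M`, `I`, `S`, `=`, `X`) sum to the length of
#' `SEQ`.
#'
#' @param path path to a SAM file.
#' @return `TRUE` if valid, otherwise a character vector of problems.
#' @export
validate_sam <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  rec <- lines[!startsWith(lines, "@") & nzchar(lines)]
  sq <- sub("^@SQ\tSN:([^\t]+).*$", "\\1", hdr[startsWith(hdr, "@SQ")])
  problems <- character()
  if (!any(startsWith(hdr, "@HD"))) problems <- c(problems, "missing @HD")
  for (i in seq_along(rec)) {
    f <- strsplit(rec[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11) {
      problems <- c(problems, sprintf("record %d: fewer than 11 fields", i))
      next
    }
    if (!(f[3] %in% sq)) {
      problems <- c(problems, sprintf("record %d: RNAME '%s' not in @SQ",
                                      i, f[3]))
    }
    if (as.integer(f[4]) < 1) {
      problems <- c(problems, sprintf("record %d: POS < 1", i))
    }
    if (cigar_read_length(f[6]) != nchar(f[10])) {
      problems <- c(problems,
                    sprintf("record %d: CIGAR length != SEQ length", i))
    }
  }
  if (length(problems)) problems else TRUE
}

# Sum of read-consuming CIGAR operation lengths (M, I, S, =, X).
cigar_read_length <- function(cigar) {
  vapply(cigar, function(cg) {
    lens <- as.integer(regmatches(cg, gregexpr("\\d+", cg))[[1]])
    ops <- regmatches(cg, gregexpr("[MIDNSHP=X]", cg))[[1]]
    sum(lens[ops %in% c("M", "I", "S", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

# Sum of reference-consuming CIGAR operation lengths (M, D, N, =, X).
cigar_ref_length <- function(cigar) {
  vapply(cigar, function(cg) {
    lens <- as.integer(regmatches(cg, gregexpr("\\d+", cg))[[1]])
    ops <- regmatches(cg, gregexpr("[MIDNSHP=X]", cg))[[1]]
    sum(lens[ops %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

reverse_cigar <- function(cigar) {
  vapply(cigar, function(cg) {
    runs <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    paste(rev(runs), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
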