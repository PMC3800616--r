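#' Construct a class-annotated reference set
#'
#' A `reference_set` is one cascade stage's alignment target: a table of
#' transcripts, each carrying an RNA class label (`miRNA`, `tRNA`, `rRNA`,
#' `mRNA`, `ncRNA`, `other`) and an optional accession. Sequences are
#' uppercased and `U` is converted to `T` so RNA-space references align
#' against DNA-space reads.
#'
#' @param transcript_id character vector of unique transcript identifiers.
#' @param seq character vector of nonempty nucleotide sequences.
#' @param rna_class character vector of RNA classes (recycled if length 1).
#' @param accession optional character vector of accessions (`NA` allowed).
#' @param stage_label label of the cascade stage this set serves.
#' @return An object of class `reference_set` (a data frame with columns
#'   `transcript_id`, `accession`, `rna_class`, `seq` and a `stage_label`
#'   attribute).
#' @export
reference_set <- function(transcript_id, seq, rna_class,
                          accession = NA_character_,
                          stage_label = "stage") {
  transcript_id <- as.character(transcript_id)
  seq <- chartr("u", "t", toupper(as.character(seq)))
  seq <- chartr("U", "T", seq)
  if (anyDuplicated(transcript_id)) {
    stop("duplicate transcript_id in reference set '", stage_label, "'",
         call. = FALSE)
  }
  if (any(!nzchar(seq))) {
    stop("empty sequence in reference set '", stage_label, "'", call. = FALSE)
  }
  if (any(grepl("[^ACGTN]", seq))) {
    stop("non-nucleotide character in reference set '", stage_label, "'",
         call. = FALSE)
  }
  rna_class <- rep_len(as.character(rna_class), length(transcript_id))
  bad <- setdiff(unique(rna_class), RNA_CLASSES)
  if (length(bad)) {
    stop("unknown RNA class: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  accession <- rep_len(as.character(accession), length(transcript_id))
  df <- data.frame(transcript_id = transcript_id, accession = accession,
                   rna_class = rna_class, seq = seq,
                   stringsAsFactors = FALSE)
  structure(df, stage_label = stage_label,
            class = c("reference_set", "data.frame"))
}

#' Infer an RNA class from a RefSeq-style accession
#'
#' `NM_` accessions are protein-coding mRNA and `NR_` accessions are
#' noncoding RNA; anything else returns `NA`. This reproduces the usual
#' split of a RefSeq transcript reference into mRNA and ncRNA classes.
#'
#' @param accession character vector of accessions.
#' @return Character vector of classes (`"mRNA"`, `"ncRNA"` or `NA`).
#' @export
infer_class_from_accession <- function(accession) {
  accession <- as.character(accession)
  accession[is.na(accession)] <- ""
  out <- rep(NA_character_, length(accession))
  out[startsWith(accession, "NM_")] <- "mRNA"
  out[startsWith(accession, "NR_")] <- "ncRNA"
  out
}

#' Read a FASTA file into a reference set
#'
#' Headers are split on whitespace: the first token is the transcript
#' identifier and, when a second token looks like a RefSeq accession
#' (`NM_`/`NR_`), it is stored as the accession. Classes come from
#' `class_map`; records not covered fall back to accession-prefix
#' inference and then to `default_class`, and raise an error if still
#' unresolved.
#'
#' @param path path to a FASTA file.
#' @param class_map named character vector or list mapping transcript
#'   identifiers to RNA classes.
#' @param default_class class used for records absent from `class_map`.
#' @param stage_label stage label for the resulting set.
#' @return A [reference_set()].
#' @export
read_fasta <- function(path, class_map = NULL, default_class = NULL,
                       stage_label = "stage") {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) {
    return(reference_set(character(), character(), character(),
                         stage_label = stage_label))
  }
  hdr <- names(ss)
  ids <- sub("\\s.*$", "", hdr)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA header '", ids[duplicated(ids)][1], "' in ", path,
         call. = FALSE)
  }
  tok2 <- rep(NA_character_, length(hdr))
  has2 <- grepl("\\s", hdr)
  tok2[has2] <- sub("^\\S+\\s+(\\S+).*$", "\\1", hdr[has2])
  acc <- ifelse(grepl("^N[MR]_", tok2), tok2, NA_character_)

  cls <- rep(NA_character_, length(ids))
  if (!is.null(class_map)) {
    cls <- unlist(class_map)[ids]
    cls <- unname(as.character(cls))
  }
  miss <- is.na(cls)
  if (any(miss)) {
    cls[miss] <- infer_class_from_accession(acc[miss])
  }
  miss <- is.na(cls)
  if (any(miss)) {
    if (is.null(default_class)) {
      stop("no RNA class for transcript '", ids[miss][1],
           "' and no default_class given", call. = FALSE)
    }
    cls[miss] <- default_class
  }
  reference_set(ids, as.character(ss), cls, accession = acc,
                stage_label = stage_label)
}

#' Write a reference set to a FASTA file
#'
#' Accessions, when present, are written as a second header token.
#'
#' @param ref a [reference_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(ref, path) {
  hdr <- ifelse(is.na(ref$accession), ref$transcript_id,
                paste(ref$transcript_id, ref$accession))
  out <- as.vector(rbind(paste0(">", hdr), ref$seq))
  writeLines(out, path)
  invisible(path)
}
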