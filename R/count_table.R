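#' Construct a per-transcript count table
#'
#' One sample/stage's per-transcript mapped-read tallies. Rows are keyed by
#' accession when present, otherwise by transcript identifier (some genes
#' appear under several accessions and each is a distinct row). Counts may
#' be fractional for mean tables.
#'
#' @param transcript_id character vector.
#' @param count numeric vector of non-negative counts.
#' @param rna_class character vector of RNA classes (recycled).
#' @param accession optional character vector (`NA`/empty = none).
#' @param sample_id,stage_label metadata attributes.
#' @return An object of class `count_table` (data frame with columns
#'   `transcript_id`, `accession`, `rna_class`, `count`).
#' @export
count_table <- function(transcript_id, count, rna_class,
                        accession = NA_character_,
                        sample_id = "sample", stage_label = "stage") {
  transcript_id <- as.character(transcript_id)
  count <- as.numeric(count)
  if (any(is.na(count)) || any(count < 0)) {
    stop("counts must be non-negative numbers", call. = FALSE)
  }
  accession <- rep_len(as.character(accession), length(transcript_id))
  accession[!is.na(accession) & !nzchar(accession)] <- NA_character_
  rna_class <- rep_len(as.character(rna_class), length(transcript_id))
  key <- ifelse(is.na(accession), transcript_id, accession)
  if (anyDuplicated(key)) {
    stop("duplicate row key '", key[duplicated(key)][1],
         "' in count table", call. = FALSE)
  }
  df <- data.frame(transcript_id = transcript_id, accession = accession,
                   rna_class = rna_class, count = count,
                   stringsAsFactors = FALSE)
  structure(df, sample_id = sample_id, stage_label = stage_label,
            class = c("count_table", "data.frame"))
}

# Row key used for matching rows across tables: accession when present,
# transcript_id otherwise.
table_key <- function(tab) {
  ifelse(is.na(tab$accession) | !nzchar(tab$accession),
         tab$transcript_id, tab$accession)
}

#' Load a tab-separated count table
#'
#' Expects a header row and columns `transcript_id`, `accession` (may be
#' empty), `rna_class`, `count`. Row order is preserved. Counts may be
#' fractional (mean tables).
#'
#' @param path path to a TSV file.
#' @param sample_id,stage_label metadata attached to the result.
#' @return A [count_table()].
#' @export
load_count_table <- function(path, sample_id = "sample",
                             stage_label = "stage") {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "accession", "rna_class", "count")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("count table ", path, " missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df$accession <- as.character(df$accession)
  if (nrow(df) == 0) {
    return(count_table(character(), numeric(), character(),
                       sample_id = sample_id, stage_label = stage_label))
  }
  if (any(is.na(df$count)) || any(df$count < 0)) {
    stop("negative or missing count in ", path, call. = FALSE)
  }
  count_table(df$transcript_id, df$count, df$rna_class,
              accession = df$accession,
              sample_id = sample_id, stage_label = stage_label)
}

#' Write a count table as TSV
#'
#' @param tab a [count_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(tab, path) {
  out <- as.data.frame(tab)
  out$accession[is.na(out$accession)] <- ""
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
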