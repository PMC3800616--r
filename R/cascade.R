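#' Configure an iterative mapping cascade
#'
#' An ordered list of alignment stages. The conventional order for small
#' RNA libraries is: (1) miRNA hairpins plus tRNA and rRNA, (2)
#' RefSeq-style transcripts (mRNA and RefSeq ncRNA), (3) other noncoding
#' RNA. Stage labels must be unique and every stage's reference must be
#' nonempty.
#'
#' @param stages named list of [reference_set()] objects, in mapping
#'   order.
#' @return An object of class `cascade_config`.
#' @export
cascade_config <- function(stages) {
  if (!length(stages)) stop("cascade needs at least one stage",
                            call. = FALSE)
  if (is.null(names(stages)) || any(!nzchar(names(stages))) ||
      anyDuplicated(names(stages))) {
    stop("stages must have unique nonempty names", call. = FALSE)
  }
  for (lab in names(stages)) {
    if (!inherits(stages[[lab]], "reference_set")) {
      stop("stage '", lab, "' is not a reference_set", call. = FALSE)
    }
    if (nrow(stages[[lab]]) == 0) {
      stop("stage '", lab, "' has an empty reference", call. = FALSE)
    }
  }
  structure(list(stages = stages), class = "cascade_config")
}

#' Run the iterative mapping cascade
#'
#' Aligns reads to the first stage's reference; reads that fail to map
#' there are passed, unchanged, to the next stage, and so on. Each read
#' therefore maps at most once, at the earliest stage that accepts it, and
#' the per-stage mapped read-ID sets together with the final unmapped set
#' exactly partition the input.
#'
#' @param reads a preprocessed [read_set()].
#' @param config a [cascade_config()].
#' @param params an [align_params()].
#' @param sample_id sample identifier recorded on the count tables.
#' @param out_dir optional directory; when given, one SAM file and one
#'   count TSV are written per stage
#'   (`<sample>_<stage>.sam` / `<sample>_<stage>.counts.tsv`).
#' @return A list of class `cascade_result` with `stages` (a named list,
#'   one element per stage, each holding `alignments` and `counts`),
#'   `unmapped` (a [read_set()]) and `sample_id`.
#' @export
run_cascade <- function(reads, config, params = align_params(),
                        sample_id = "sample", out_dir = NULL) {
  if (!inherits(config, "cascade_config")) config <- cascade_config(config)
  remaining <- reads
  stages <- list()
  for (lab in names(config$stages)) {
    ref <- config$stages[[lab]]
    res <- align_batch(remaining, ref, params)
    counts <- tally_counts(res$alignments, ref, sample_id = sample_id,
                           stage_label = lab)
    stages[[lab]] <- list(alignments = res$alignments, counts = counts)
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_sam(res$alignments, ref,
                file.path(out_dir, sprintf("%s_%s.sam", sample_id, lab)))
      write_count_table(counts,
                        file.path(out_dir, sprintf("%s_%s.counts.tsv",
                                                   sample_id, lab)))
    }
    remaining <- res$unmapped
  }
  structure(list(stages = stages, unmapped = remaining,
                 sample_id = sample_id),
            class = "cascade_result")
}

#' Tally mapped reads per transcript
#'
#' Each mapped read contributes exactly one count to the transcript it
#' aligned to ("one read, one count"), so the column sum equals the number
#' of alignment records. A read identifier occurring twice in one stage's
#' alignments violates that rule and raises an error.
#'
#' @param alignments alignment data frame from [align_batch()].
#' @param ref the [reference_set()] aligned against (supplies accession
#'   and RNA class annotation).
#' @param sample_id,stage_label metadata for the resulting table.
#' @return A [count_table()] with one row per transcript that received at
#'   least one read.
#' @export
tally_counts <- function(alignments, ref, sample_id = "sample",
                         stage_label = "stage") {
  if (is.null(alignments) || nrow(alignments) == 0) {
    return(count_table(character(), numeric(), character(),
                       sample_id = sample_id, stage_label = stage_label))
  }
  if (anyDuplicated(alignments$read_id)) {
    stop("read '", alignments$read_id[duplicated(alignments$read_id)][1],
         "' has multiple alignment records in one stage", call. = FALSE)
  }
  tab <- table(alignments$transcript_id)
  ids <- names(tab)
  pos <- match(ids, ref$transcript_id)
  if (anyNA(pos)) {
    stop("alignment to transcript absent from reference: ",
         ids[is.na(pos)][1], call. = FALSE)
  }
  count_table(ids, as.integer(tab), ref$rna_class[pos],
              accession = ref$accession[pos],
              sample_id = sample_id, stage_label = stage_label)
}
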