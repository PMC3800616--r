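#' Percent-of-mapped normalization
#'
#' Expresses each transcript's count as a percentage of all mapped reads
#' in the sample, pooling the count tables of every cascade stage:
#' `percent(t) = 100 * count(t) / total mapped`. The percentages sum to
#' 100 by construction.
#'
#' @param tables a single [count_table()], a list of them (all stages of
#'   one sample), or a `cascade_result`.
#' @return A data frame with columns `transcript_id`, `accession`,
#'   `rna_class`, `percent`.
#' @export
normalize_percent <- function(tables) {
  tables <- as_table_list(tables)
  pooled <- do.call(rbind, lapply(tables, as.data.frame))
  total <- sum(pooled$count)
  if (is.null(total) || total <= 0) {
    stop("cannot normalize: zero mapped reads", call. = FALSE)
  }
  data.frame(transcript_id = pooled$transcript_id,
             accession = pooled$accession,
             rna_class = pooled$rna_class,
             percent = 100 * pooled$count / total,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' RNA-class composition profile
#'
#' Aggregates a sample's per-transcript counts by RNA class and reports
#' each class's share of the total mapped reads, in percent.
#'
#' @param tables as in [normalize_percent()].
#' @param sample_id identifier attached to the profile.
#' @return An object of class `composition_profile`: a data frame with
#'   columns `rna_class` and `percent` (summing to 100).
#' @export
composition_profile <- function(tables, sample_id = "sample") {
  norm <- normalize_percent(tables)
  agg <- aggregate(percent ~ rna_class, data = norm, FUN = sum)
  agg <- agg[order(-agg$percent, agg$rna_class), ]
  row.names(agg) <- NULL
  structure(agg, sample_id = sample_id,
            class = c("composition_profile", "data.frame"))
}

#' Mean raw counts over replicate libraries
#'
#' Per-transcript arithmetic mean over replicate count tables; a
#' transcript absent from a replicate contributes 0 to its mean. Means are
#' reported to 2 decimals, the conventional presentation for top-10
#' tables.
#'
#' @param replicates a list of [count_table()] objects sharing a sample
#'   type.
#' @param sample_type label for the averaged sample (e.g. `"exosome"`).
#' @return A [count_table()] whose `count` column holds the means.
#' @export
mean_counts <- function(replicates, sample_type = "sample") {
  replicates <- as_table_list(replicates)
  if (!length(replicates)) stop("mean_counts needs at least one replicate",
                                call. = FALSE)
  n_rep <- length(replicates)
  pooled <- do.call(rbind, lapply(replicates, as.data.frame))
  if (nrow(pooled) == 0) {
    return(count_table(character(), numeric(), character(),
                       sample_id = sample_type, stage_label = "mean"))
  }
  key <- ifelse(is.na(pooled$accession), pooled$transcript_id,
                pooled$accession)
  sums <- tapply(pooled$count, key, sum)
  first <- !duplicated(key)
  meta <- pooled[first, c("transcript_id", "accession", "rna_class")]
  meta_key <- key[first]
  means <- round(as.numeric(sums[meta_key]) / n_rep, 2)
  count_table(meta$transcript_id, means, meta$rna_class,
              accession = meta$accession,
              sample_id = sample_type, stage_label = "mean")
}

#' Top-N ranked transcripts of one RNA class
#'
#' Selects the `n` highest-mean transcripts of the requested class,
#' ordered from high to low; ties are broken by transcript identifier in
#' lexicographic order. If fewer than `n` transcripts exist, all are
#' returned and the list is flagged short.
#'
#' @param mean_table a [count_table()] of (mean) counts.
#' @param rna_class class to rank (e.g. `"miRNA"`).
#' @param n list length (default 10).
#' @return An object of class `ranked_list`: a data frame with columns
#'   `transcript_id`, `accession`, `mean_count`, with attributes
#'   `rna_class`, `sample_type` and `short` (TRUE when fewer than `n`
#'   transcripts were available).
#' @export
top_n <- function(mean_table, rna_class, n = 10L) {
  stopifnot(n >= 1)
  sub <- as.data.frame(mean_table)
  sub <- sub[sub$rna_class == rna_class, , drop = FALSE]
  sub <- sub[order(-sub$count, sub$transcript_id), , drop = FALSE]
  short <- nrow(sub) < n
  sub <- head(sub, n)
  out <- data.frame(transcript_id = sub$transcript_id,
                    accession = sub$accession,
                    mean_count = sub$count,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, rna_class = rna_class,
            sample_type = attr(mean_table, "sample_id"),
            short = short,
            class = c("ranked_list", "data.frame"))
}

#' Overlap between two top-N lists
#'
#' Number of entries the two ranked lists share. Entries are keyed by
#' accession when present and by transcript identifier otherwise, so a
#' gene listed under several accessions counts once per accession. Both
#' lists must rank the same RNA class. The result is symmetric and bounded
#' by the shorter list's length.
#'
#' @param list_a,list_b `ranked_list` objects from [top_n()].
#' @return Integer overlap size.
#' @export
topn_overlap <- function(list_a, list_b) {
  if (!identical(attr(list_a, "rna_class"), attr(list_b, "rna_class"))) {
    stop("ranked lists compare different RNA classes: '",
         attr(list_a, "rna_class"), "' vs '", attr(list_b, "rna_class"),
         "'", call. = FALSE)
  }
  key <- function(x) {
    ifelse(is.na(x$accession) | !nzchar(x$accession),
           x$transcript_id, x$accession)
  }
  length(intersect(key(list_a), key(list_b)))
}

#' Differential representation between two sample types
#'
#' A descriptive report comparing normalized per-transcript percentages
#' between two groups of replicate libraries (e.g. exosomes versus
#' parental cells). For every transcript seen in either group it reports
#' the group means and sample standard deviations (n-1 denominator; 0 when
#' a group has one replicate) of the normalized percent, plus their ratio
#' (group A over group B; `Inf` when the transcript is absent from group
#' B). A transcript absent from a replicate contributes 0 to that
#' replicate. No significance test is attached; the report is descriptive.
#'
#' @param percents_a,percents_b lists of [normalize_percent()] outputs,
#'   one per replicate, for sample types A and B.
#' @param labels length-2 character vector naming the two sample types.
#' @return A data frame with columns `transcript_id`, `accession`,
#'   `rna_class`, `mean_a`, `sd_a`, `mean_b`, `sd_b`, `ratio`, with a
#'   `groups` attribute carrying the labels.
#' @export
differential_table <- function(percents_a, percents_b,
                               labels = c("A", "B")) {
  if (!length(percents_a) || !length(percents_b)) {
    stop("each sample type needs at least one replicate", call. = FALSE)
  }
  if (is.data.frame(percents_a)) percents_a <- list(percents_a)
  if (is.data.frame(percents_b)) percents_b <- list(percents_b)
  all_tabs <- c(percents_a, percents_b)
  pooled <- do.call(rbind, all_tabs)
  if (is.null(pooled) || nrow(pooled) == 0) {
    out <- data.frame(transcript_id = character(), accession = character(),
                      rna_class = character(), mean_a = numeric(),
                      sd_a = numeric(), mean_b = numeric(),
                      sd_b = numeric(), ratio = numeric())
    attr(out, "groups") <- labels
    return(out)
  }
  key <- ifelse(is.na(pooled$accession) | !nzchar(pooled$accession),
                pooled$transcript_id, pooled$accession)
  first <- !duplicated(key)
  meta <- pooled[first, c("transcript_id", "accession", "rna_class")]
  keys <- key[first]

  group_stats <- function(reps) {
    m <- vapply(reps, function(tab) {
      k <- ifelse(is.na(tab$accession) | !nzchar(tab$accession),
                  tab$transcript_id, tab$accession)
      v <- setNames(tab$percent, k)[keys]
      ifelse(is.na(v), 0, v)
    }, numeric(length(keys)))
    m <- matrix(m, nrow = length(keys))
    list(mean = rowMeans(m),
         sd = if (ncol(m) > 1) apply(m, 1, sd) else rep(0, length(keys)))
  }
  a <- group_stats(percents_a)
  b <- group_stats(percents_b)
  out <- data.frame(transcript_id = meta$transcript_id,
                    accession = meta$accession,
                    rna_class = meta$rna_class,
                    mean_a = a$mean, sd_a = a$sd,
                    mean_b = b$mean, sd_b = b$sd,
                    ratio = a$mean / b$mean,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "groups") <- labels
  out
}

# Accept a count_table, a list of count_tables, or a cascade_result.
as_table_list <- function(tables) {
  if (inherits(tables, "cascade_result")) {
    return(lapply(tables$stages, `[[`, "counts"))
  }
  if (inherits(tables, "count_table")) return(list(tables))
  as.list(tables)
}
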