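#' Per-library quality summary
#'
#' Computes the standard post-trimming library diagnostics: per-cycle
#' quality quartiles, per-cycle base composition, the read-length
#' histogram, and the most highly represented k-mers (counted over every
#' overlapping window of every read). Quartiles use linear interpolation
#' (`quantile()` type 7); k-mer count ties are broken alphabetically.
#'
#' @param reads a [read_set()].
#' @param k k-mer length (default 8).
#' @param n_kmers how many top k-mers to report (default 20).
#' @return An object of class `qc_report`: a list with
#'   `per_position_quality` (data frame `cycle`, `q1`, `median`, `q3`,
#'   `n`), `base_composition` (data frame `cycle`, `A`, `C`, `G`, `T`,
#'   `N`), `length_histogram` (named integer vector) and `top_kmers`
#'   (data frame `kmer`, `count`).
#' @export
qc_summary <- function(reads, k = 8L, n_kmers = 20L) {
  stopifnot(k >= 1)
  n <- length(reads)
  if (!n) {
    return(structure(list(
      per_position_quality = data.frame(cycle = integer(), q1 = numeric(),
                                        median = numeric(), q3 = numeric(),
                                        n = integer()),
      base_composition = data.frame(cycle = integer(), A = numeric(),
                                    C = numeric(), G = numeric(),
                                    T = numeric(), N = numeric()),
      length_histogram = setNames(integer(), character()),
      top_kmers = data.frame(kmer = character(), count = integer())),
      class = "qc_report"))
  }
  lens <- nchar(reads$seq)
  maxlen <- max(lens)

  # per-cycle quality quartiles
  qual_by_cycle <- lapply(seq_len(maxlen), function(cyc) {
    v <- vapply(reads$qual, function(q) {
      if (length(q) >= cyc) q[cyc] else NA_integer_
    }, integer(1))
    v[!is.na(v)]
  })
  ppq <- data.frame(
    cycle = seq_len(maxlen),
    q1 = vapply(qual_by_cycle, function(v) unname(quantile(v, 0.25)),
                numeric(1)),
    median = vapply(qual_by_cycle, function(v) unname(quantile(v, 0.5)),
                    numeric(1)),
    q3 = vapply(qual_by_cycle, function(v) unname(quantile(v, 0.75)),
                numeric(1)),
    n = lengths(qual_by_cycle))

  # per-cycle base composition
  mat <- matrix(NA_character_, nrow = n, ncol = maxlen)
  sp <- strsplit(reads$seq, "")
  for (i in seq_len(n)) mat[i, seq_len(lens[i])] <- sp[[i]]
  comp <- t(apply(mat, 2, function(col) {
    col <- col[!is.na(col)]
    tab <- table(factor(col, levels = c("A", "C", "G", "T", "N")))
    if (sum(tab) == 0) rep(NA_real_, 5) else as.numeric(tab) / sum(tab)
  }))
  bc <- data.frame(cycle = seq_len(maxlen), comp)
  names(bc) <- c("cycle", "A", "C", "G", "T", "N")

  # read-length histogram
  lh <- table(lens)
  length_histogram <- setNames(as.integer(lh), names(lh))

  # top k-mers over all overlapping windows
  kmers <- unlist(lapply(reads$seq, function(s) {
    L <- nchar(s)
    if (L < k) return(character())
    substring(s, 1:(L - k + 1), k:L)
  }), use.names = FALSE)
  if (length(kmers)) {
    tab <- sort(table(kmers), decreasing = TRUE)
    ord <- order(-as.integer(tab), names(tab))
    tab <- tab[ord]
    top <- head(tab, n_kmers)
    top_kmers <- data.frame(kmer = names(top), count = as.integer(top),
                            stringsAsFactors = FALSE)
  } else {
    top_kmers <- data.frame(kmer = character(), count = integer())
  }

  structure(list(per_position_quality = ppq, base_composition = bc,
                 length_histogram = length_histogram, top_kmers = top_kmers),
            class = "qc_report")
}

#' Write a QC report as sectioned TSV
#'
#' @param report a `qc_report` from [qc_summary()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# per_position_quality", con)
  write.table(report$per_position_quality, con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines("# base_composition", con)
  write.table(report$base_composition, con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines("# length_histogram", con)
  write.table(data.frame(length = names(report$length_histogram),
                         count = report$length_histogram),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines("# top_kmers", con)
  write.table(report$top_kmers, con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
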