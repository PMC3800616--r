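#' Simulation configuration
#'
#' Parameters of the deterministic truth-labelled read simulator. The
#' generator emulates the salient features of a small-RNA semiconductor
#' sequencing library: short inserts (most cargo under 200 nt, with the
#' sequenced inserts in the 15-40 nt range), 3' adapter read-through on a
#' fraction of reads, a per-base substitution error rate, and a 3' quality
#' decline (a plateau followed by a linear decay with per-base jitter).
#'
#' @param seed integer seed; every random choice flows from it.
#' @param per_class_transcripts named list mapping RNA class to
#'   `c(count, min_length, max_length)` for the simulated reference.
#' @param class_mixture named numeric vector of per-class read sampling
#'   probabilities (must sum to 1).
#' @param read_count number of reads to simulate.
#' @param insert_length integer range `c(min, max)` of insert lengths.
#' @param adapter_seq fixed 3' adapter appended to read-through reads
#'   (default: the package's documented 23-mer).
#' @param adapter_fraction fraction of reads carrying adapter
#'   read-through.
#' @param error_rate per-base substitution probability.
#' @param quality_model list with `plateau` (high-quality PHRED level),
#'   `decay_start` (cycle where decline begins), `slope` (PHRED lost per
#'   cycle after onset), `floor` (minimum PHRED) and `jitter` (uniform
#'   integer noise half-width added per base).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       per_class_transcripts = list(
                         miRNA = c(20, 60, 90),
                         tRNA = c(10, 70, 90),
                         rRNA = c(3, 120, 160),
                         mRNA = c(15, 200, 400),
                         ncRNA = c(8, 90, 300),
                         other = c(8, 90, 300)),
                       class_mixture = c(miRNA = 0.25, tRNA = 0.20,
                                         rRNA = 0.20, mRNA = 0.15,
                                         ncRNA = 0.10, other = 0.10),
                       read_count = 2000L,
                       insert_length = c(15L, 40L),
                       adapter_seq = "ATCACCGACTGCCCATAGAGAGG",
                       adapter_fraction = 0.8,
                       error_rate = 0.005,
                       quality_model = list(plateau = 34, decay_start = 30,
                                            slope = 0.75, floor = 2,
                                            jitter = 2)) {
  if (!length(per_class_transcripts) ||
      sum(vapply(per_class_transcripts, `[`, numeric(1), 1)) == 0) {
    stop("per_class_transcripts must request at least one transcript",
         call. = FALSE)
  }
  bad <- setdiff(names(per_class_transcripts), RNA_CLASSES)
  if (length(bad)) stop("unknown RNA class: ", bad[1], call. = FALSE)
  if (abs(sum(class_mixture) - 1) > 1e-9) {
    stop("class_mixture probabilities must sum to 1", call. = FALSE)
  }
  stopifnot(read_count >= 0, adapter_fraction >= 0, adapter_fraction <= 1,
            error_rate >= 0, error_rate <= 1,
            insert_length[1] >= 1, insert_length[2] >= insert_length[1])
  structure(list(seed = as.integer(seed),
                 per_class_transcripts = per_class_transcripts,
                 class_mixture = class_mixture,
                 read_count = as.integer(read_count),
                 insert_length = as.integer(insert_length),
                 adapter_seq = toupper(adapter_seq),
                 adapter_fraction = adapter_fraction,
                 error_rate = error_rate,
                 quality_model = quality_model),
            class = "sim_config")
}

# Stage routing of simulated classes: hairpin/tRNA/rRNA references are the
# first target, RefSeq-style mRNA + ncRNA the second, remaining noncoding
# RNA the third.
CLASS_STAGE <- c(miRNA = "miRNA_tRNA_rRNA", tRNA = "miRNA_tRNA_rRNA",
                 rRNA = "miRNA_tRNA_rRNA", mRNA = "refseq",
                 ncRNA = "refseq", other = "noncode")

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Generate a simulated cascade reference
#'
#' Draws uniform-composition random transcripts per RNA class and assigns
#' them to cascade stages (miRNA/tRNA/rRNA to the first, mRNA and RefSeq
#' ncRNA to the second, other ncRNA to the third). mRNA/ncRNA transcripts
#' receive RefSeq-style `NM_`/`NR_` accessions. Transcripts are not forced
#' to be seed-disjoint; use [references_seed_disjoint()] to check whether
#' cross-stage seed sharing is possible. Deterministic under
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @return A list with `stages` (named list of [reference_set()], in
#'   cascade order) and `metadata` (data frame `transcript_id`,
#'   `accession`, `rna_class`, `stage`, `length`).
#' @export
generate_reference <- function(config) {
  set.seed(config$seed)
  rows <- list()
  acc_counter <- 0L
  for (cls in names(config$per_class_transcripts)) {
    spec <- config$per_class_transcripts[[cls]]
    n_t <- spec[1]
    if (n_t == 0) next
    for (i in seq_len(n_t)) {
      len <- sample(spec[2]:spec[3], 1)
      acc <- NA_character_
      if (cls == "mRNA") {
        acc_counter <- acc_counter + 1L
        acc <- sprintf("NM_9%05d", acc_counter)
      } else if (cls == "ncRNA") {
        acc_counter <- acc_counter + 1L
        acc <- sprintf("NR_9%05d", acc_counter)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = sprintf("sim_%s_%02d", cls, i),
        accession = acc, rna_class = cls, stage = CLASS_STAGE[[cls]],
        length = len, seq = random_seq(len), stringsAsFactors = FALSE)
    }
  }
  meta <- do.call(rbind, rows)
  stage_order <- intersect(c("miRNA_tRNA_rRNA", "refseq", "noncode"),
                           unique(meta$stage))
  stages <- lapply(stage_order, function(st) {
    sub <- meta[meta$stage == st, ]
    reference_set(sub$transcript_id, sub$seq, sub$rna_class,
                  accession = sub$accession, stage_label = st)
  })
  names(stages) <- stage_order
  list(stages = stages,
       metadata = meta[, c("transcript_id", "accession", "rna_class",
                           "stage", "length")])
}

#' Check cross-stage seed disjointness
#'
#' TRUE when no exact `seed_k`-mer occurs in more than one stage's
#' reference, in which case an error-free read can only map at its true
#' stage.
#'
#' @param stages named list of [reference_set()] objects.
#' @param seed_k seed length.
#' @return Logical scalar.
#' @export
references_seed_disjoint <- function(stages, seed_k = 10L) {
  kmer_sets <- lapply(stages, function(ref) {
    unique(unlist(lapply(ref$seq, function(s) {
      L <- nchar(s)
      if (L < seed_k) s else substring(s, 1:(L - seed_k + 1), seed_k:L)
    }), use.names = FALSE))
  })
  n <- length(kmer_sets)
  if (n < 2) return(TRUE)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (length(intersect(kmer_sets[[i]], kmer_sets[[j]]))) return(FALSE)
    }
  }
  TRUE
}

#' Simulate truth-labelled reads
#'
#' For each read: an RNA class is drawn from the mixture, a transcript
#' uniformly within the class, and an insert substring uniformly within
#' the transcript (insert length drawn from `insert_length`, capped at the
#' transcript length). Substitution errors are applied at `error_rate` per
#' base; `adapter_fraction` of the reads then read through into the full
#' 3' adapter. Qualities follow the plateau/decay model with jitter,
#' floored at `quality_model$floor` and capped at 40. Deterministic under
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @param reference output of [generate_reference()] (regenerated from
#'   `config` when omitted).
#' @return A list with `reads` (a [read_set()]) and `truth` (data frame
#'   `read_id`, `transcript_id`, `rna_class`, `stage`, `insert_length`,
#'   `insert_seq`, `had_adapter`, `n_errors`).
#' @export
generate_reads <- function(config, reference = NULL) {
  if (is.null(reference)) reference <- generate_reference(config)
  meta <- reference$metadata
  seqs <- setNames(
    unlist(lapply(reference$stages, function(s) s$seq), use.names = FALSE),
    unlist(lapply(reference$stages, function(s) s$transcript_id),
           use.names = FALSE))
  set.seed(config$seed + 1L)
  n <- config$read_count
  if (n == 0) {
    return(list(reads = read_set(),
                truth = data.frame(read_id = character(),
                                   transcript_id = character(),
                                   rna_class = character(),
                                   stage = character(),
                                   insert_length = integer(),
                                   insert_seq = character(),
                                   had_adapter = logical(),
                                   n_errors = integer())))
  }
  avail <- names(config$class_mixture)[config$class_mixture > 0]
  missing_cls <- setdiff(avail, unique(meta$rna_class))
  if (length(missing_cls)) {
    stop("class_mixture draws class '", missing_cls[1],
         "' absent from the reference", call. = FALSE)
  }
  cls_draw <- sample(names(config$class_mixture), n, replace = TRUE,
                     prob = config$class_mixture)
  bases <- c("A", "C", "G", "T")
  qm <- config$quality_model
  ids <- sprintf("read_%06d", seq_len(n))
  seq_out <- character(n)
  qual_out <- vector("list", n)
  t_id <- character(n)
  ins_len <- integer(n)
  ins_seq <- character(n)
  had_ad <- runif(n) < config$adapter_fraction
  n_err <- integer(n)
  for (i in seq_len(n)) {
    cand <- meta$transcript_id[meta$rna_class == cls_draw[i]]
    tid <- if (length(cand) == 1) cand else sample(cand, 1)
    tseq <- seqs[[tid]]
    tlen <- nchar(tseq)
    len <- min(sample(config$insert_length[1]:config$insert_length[2], 1),
               tlen)
    start <- sample.int(tlen - len + 1L, 1)
    insert <- substr(tseq, start, start + len - 1L)
    read <- if (had_ad[i]) paste0(insert, config$adapter_seq) else insert
    rl <- nchar(read)
    err_pos <- which(runif(rl) < config$error_rate)
    if (length(err_pos)) {
      chars <- strsplit(read, "")[[1]]
      for (p in err_pos) {
        chars[p] <- sample(setdiff(bases, chars[p]), 1)
      }
      read <- paste(chars, collapse = "")
    }
    cycles <- seq_len(rl)
    q <- qm$plateau - qm$slope * pmax(0, cycles - qm$decay_start)
    if (qm$jitter > 0) {
      q <- q + sample(seq(-qm$jitter, qm$jitter), rl, replace = TRUE)
    }
    q <- as.integer(round(pmin(40, pmax(qm$floor, q))))
    t_id[i] <- tid
    ins_len[i] <- len
    ins_seq[i] <- insert
    n_err[i] <- length(err_pos)
    seq_out[i] <- read
    qual_out[[i]] <- q
  }
  truth <- data.frame(read_id = ids, transcript_id = t_id,
                      rna_class = cls_draw,
                      stage = unname(CLASS_STAGE[cls_draw]),
                      insert_length = ins_len, insert_seq = ins_seq,
                      had_adapter = had_ad, n_errors = n_err,
                      stringsAsFactors = FALSE)
  list(reads = read_set(ids, seq_out, qual_out), truth = truth)
}

#' Packaged top-10 mean-count fixtures
#'
#' Loads the mean-count tables packaged with exocascade: the top-10
#' transcripts per RNA class for HeLa cells versus HeLa-media exosomes
#' (means of 3 replicate libraries) and for whole serum versus serum
#' exosomes (means of 2 donors), as used by the rank-overlap examples.
#'
#' @return A nested list: `hela$cells`, `hela$exosomes`, `serum$parental`,
#'   `serum$exosomes`, each a named list of [count_table()] objects keyed
#'   by RNA class (`miRNA`, `tRNA`, `mRNA`, `ncRNA`).
#' @export
packaged_fixtures <- function() {
  base <- system.file("extdata", package = "exocascade")
  groups <- list(hela = c("cells", "exosomes"),
                 serum = c("parental", "exosomes"))
  classes <- c(miRNA = "mirna", tRNA = "trna", mRNA = "mrna",
               ncRNA = "ncrna")
  out <- list()
  for (g in names(groups)) {
    out[[g]] <- list()
    for (st in groups[[g]]) {
      tabs <- lapply(names(classes), function(cls) {
        path <- file.path(base, sprintf("%s_%s_%s.tsv", g, st,
                                        classes[[cls]]))
        load_count_table(path, sample_id = paste(g, st),
                         stage_label = "mean")
      })
      names(tabs) <- names(classes)
      out[[g]][[st]] <- tabs
    }
  }
  out
}
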