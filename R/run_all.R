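#' Run the full pipeline end to end
#'
#' Drives trim, QC, the mapping cascade and the summary reports over one
#' library, writing a results directory and a run manifest. Input reads
#' come either from `input_fastq` or from the built-in simulator
#' (`simulate:` block), in which case the simulated references and truth
#' table are also written. All configuration is validated before any
#' output is produced.
#'
#' Config fields (R list or YAML file): `out_dir` (required), `seed`,
#' `sample_id`, `input_fastq` or `simulate` (list of [sim_config()]
#' overrides), `references` (named list of
#' `list(fasta=, class_tsv=/default_class=)`, in cascade order; taken from
#' the simulation when omitted), `adapter` (3' adapter; required unless
#' simulating, where it defaults to the simulator's), `quality_threshold`,
#' `min_length`, `max_error_rate`, `min_overlap`, `align` (list of
#' [align_params()] overrides), `qc_k`, `top_n`.
#'
#' @param config an R list or the path to a YAML file.
#' @return The run manifest (also written as `manifest.yaml`), invisibly.
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- config
  if (is.null(cfg$out_dir)) stop("config must name an out_dir",
                                 call. = FALSE)
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  sample_id <- if (is.null(cfg$sample_id)) "sample" else cfg$sample_id
  simulate <- !is.null(cfg$simulate)

  # pre-flight validation before any output is written
  if (!simulate) {
    if (is.null(cfg$input_fastq)) {
      stop("config needs input_fastq or a simulate block", call. = FALSE)
    }
    if (!file.exists(cfg$input_fastq)) {
      stop("input_fastq not found: ", cfg$input_fastq, call. = FALSE)
    }
    if (is.null(cfg$adapter)) {
      stop("config must name the 3' adapter sequence", call. = FALSE)
    }
    if (is.null(cfg$references) || !length(cfg$references)) {
      stop("config must list cascade reference stages", call. = FALSE)
    }
    for (lab in names(cfg$references)) {
      fa <- cfg$references[[lab]]$fasta
      if (is.null(fa) || !file.exists(fa)) {
        stop("reference FASTA for stage '", lab, "' not found",
             call. = FALSE)
      }
    }
  }

  ap_over <- cfg$align
  ap <- do.call(align_params, if (is.null(ap_over)) list() else ap_over)

  out_dir <- cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (simulate) {
    sim_over <- cfg$simulate
    sim_over$seed <- seed
    sc <- do.call(sim_config, sim_over)
    reference <- generate_reference(sc)
    sim <- generate_reads(sc, reference)
    reads <- sim$reads
    stages <- reference$stages
    for (lab in names(stages)) {
      write_fasta(stages[[lab]], file.path(out_dir,
                                           paste0("ref_", lab, ".fasta")))
    }
    write.table(sim$truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_fastq(reads, file.path(out_dir, "reads.fastq"))
    adapter <- if (is.null(cfg$adapter)) sc$adapter_seq else cfg$adapter
    input_desc <- "simulated"
  } else {
    reads <- read_fastq(cfg$input_fastq)
    stages <- lapply(names(cfg$references), function(lab) {
      spec <- cfg$references[[lab]]
      class_map <- NULL
      if (!is.null(spec$class_tsv)) {
        cm <- read.delim(spec$class_tsv, stringsAsFactors = FALSE)
        class_map <- setNames(cm$rna_class, cm$transcript_id)
      }
      read_fasta(spec$fasta, class_map = class_map,
                 default_class = spec$default_class, stage_label = lab)
    })
    names(stages) <- names(cfg$references)
    adapter <- cfg$adapter
    input_desc <- cfg$input_fastq
  }

  pp <- preprocess_params(
    adapter_seq = adapter,
    quality_threshold = cfg$quality_threshold %||% 17L,
    min_length = cfg$min_length %||% 17L,
    max_error_rate = cfg$max_error_rate %||% 0.1,
    min_overlap = cfg$min_overlap %||% 3L)

  trimmed <- preprocess_stream(reads, pp)
  write_fastq(trimmed$kept, file.path(out_dir, "clean.fastq"))
  write.table(data.frame(reason = names(trimmed$drop_counts),
                         dropped = as.integer(trimmed$drop_counts)),
              file.path(out_dir, "trim_report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  qc <- qc_summary(trimmed$kept, k = cfg$qc_k %||% 8L)
  write_qc_report(qc, file.path(out_dir, "qc_report.tsv"))

  casc <- run_cascade(trimmed$kept, cascade_config(stages), ap,
                      sample_id = sample_id, out_dir = out_dir)
  write_fastq(casc$unmapped, file.path(out_dir, "unmapped.fastq"))

  total_mapped <- sum(vapply(casc$stages,
                             function(s) sum(s$counts$count), numeric(1)))
  if (total_mapped > 0) {
    norm <- normalize_percent(casc)
    write.table(norm, file.path(out_dir, "normalized_percent.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    comp <- composition_profile(casc, sample_id)
    write.table(as.data.frame(comp), file.path(out_dir, "composition.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    pooled <- mean_counts(casc, sample_type = sample_id)
    for (cls in unique(pooled$rna_class)) {
      rl <- top_n(pooled, cls, n = cfg$top_n %||% 10L)
      write.table(as.data.frame(rl),
                  file.path(out_dir, sprintf("top_%s.tsv", cls)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  per_stage <- lapply(casc$stages, function(s) nrow(s$alignments))
  manifest <- list(
    input = input_desc,
    sample_id = sample_id,
    seed = seed,
    tool_version = as.character(packageVersion("exocascade")),
    parameters = list(
      adapter = adapter,
      quality_threshold = pp$quality_threshold,
      min_length = pp$min_length,
      max_error_rate = pp$max_error_rate,
      min_overlap = pp$min_overlap,
      align = unclass(ap)),
    reads = list(
      input = length(reads),
      dropped = as.list(as.integer(trimmed$drop_counts)) |>
        setNames(names(trimmed$drop_counts)),
      kept = length(trimmed$kept),
      mapped_per_stage = per_stage,
      unmapped = length(casc$unmapped),
      percent_mapped = if (length(trimmed$kept) > 0)
        round(100 * total_mapped / length(trimmed$kept), 2) else NA))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  message(sprintf(
    "%s: %d reads in, %d kept after trimming, %.1f%% of kept reads mapped across %d stages",
    sample_id, length(reads), length(trimmed$kept),
    if (length(trimmed$kept) > 0) 100 * total_mapped / length(trimmed$kept)
    else 0, length(casc$stages)))
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
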