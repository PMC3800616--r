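test_that("seed index records every k-mer position", {
  ref1 <- reference_set("T1", rand_seq(30), "miRNA")
  idx <- build_index(ref1, seed_k = 10)
  expect_equal(index_size(idx), 21)          # 30 - 10 + 1

  s <- rand_seq(40)
  ref2 <- reference_set(c("A", "B"), c(s, s), "miRNA")
  idx2 <- build_index(ref2, seed_k = 10)
  km <- substr(s, 1, 10)
  expect_setequal(idx2$env[[km]][, 1], c(1, 2))

  ref0 <- reference_set(character(), character(), character())
  expect_equal(index_size(build_index(ref0, 10)), 0)
})

test_that("a perfect substring read aligns full-length with maximal score", {
  set.seed(41)
  ref <- reference_set("T1", rand_seq(80), "miRNA")
  idx <- build_index(ref, 10)
  rd <- substr(ref$seq, 21, 40)
  hit <- align_read(rd, idx, ref)
  expect_identical(hit$transcript_id, "T1")
  expect_equal(hit$score, 40)                # 2 * 20
  expect_identical(hit$cigar, "20M")
  expect_equal(hit$edits, 0)
  expect_equal(hit$ref_start, 20)            # 0-based
})

test_that("seeded scores equal exhaustive Smith-Waterman whenever a seed is shared", {
  set.seed(42)
  params <- align_params()
  n_checked <- 0
  for (i in 1:120) {
    ref <- reference_set("T1", rand_seq(sample(60:200, 1)), "miRNA")
    idx <- build_index(ref, params$seed_k)
    len <- sample(18:40, 1)
    st <- sample(nchar(ref$seq) - len + 1, 1)
    rd <- substr(ref$seq, st, st + len - 1)
    ch <- strsplit(rd, "")[[1]]
    for (p in sample(len, sample(0:3, 1))) {
      ch[p] <- sample(c("A", "C", "G", "T"), 1)
    }
    rd <- paste(ch, collapse = "")
    hit <- align_read(rd, idx, ref, params)
    if (shares_seed(rd, ref$seq, params$seed_k)) {
      oracle <- oracle_sw_score(rd, ref$seq)
      if (oracle >= params$min_score_fraction * params$match * len) {
        n_checked <- n_checked + 1
        expect_equal(hit$score, oracle, info = paste("case", i))
      }
    } else {
      expect_null(hit)
    }
  }
  expect_gt(n_checked, 60)  # the battery must actually exercise the oracle
})

test_that("unrelated reads stay unmapped and mapped scores are bounded", {
  set.seed(43)
  ref <- reference_set("T1", rand_seq(100), "miRNA")
  idx <- build_index(ref, 10)
  n_mapped <- 0
  for (i in 1:50) {
    rd <- rand_seq(20)
    hit <- align_read(rd, idx, ref)
    if (!is.null(hit)) {
      n_mapped <- n_mapped + 1
      expect_identical(hit$score, oracle_sw_score(rd, ref$seq))
    }
  }
  expect_lte(n_mapped, 2)  # random 20-mers essentially never reach 80%
})

test_that("alignment is deterministic and ties resolve to the earlier transcript", {
  set.seed(44)
  s <- rand_seq(60)
  ref <- reference_set(c("first", "second"), c(s, s), "miRNA")
  reads <- mk_reads(substring(s, c(1, 11, 21), c(30, 40, 50)))
  r1 <- align_batch(reads, ref)
  r2 <- align_batch(reads, ref)
  expect_identical(r1$alignments, r2$alignments)
  expect_true(all(r1$alignments$transcript_id == "first"))
})

test_that("score bound holds across a mapped batch", {
  cfg <- sim_config(seed = 45, read_count = 300)
  ref <- generate_reference(cfg)
  sim <- generate_reads(cfg, ref)
  pre <- preprocess_stream(sim$reads,
                           preprocess_params(adapter_seq = cfg$adapter_seq))
  stage1 <- ref$stages[[1]]
  res <- align_batch(pre$kept, stage1)
  if (nrow(res$alignments) > 0) {
    expect_true(all(res$alignments$score > 0))
    expect_true(all(res$alignments$score <=
                      2 * nchar(res$alignments$seq)))
    consumed <- exocascade:::cigar_read_length(res$alignments$cigar)
    expect_true(all(consumed + res$alignments$read_start <=
                      nchar(res$alignments$seq)))
  }
})

test_that("error-free reads recover their source transcript", {
  set.seed(46)
  cfg <- sim_config(seed = 46, read_count = 400, error_rate = 0,
                    adapter_fraction = 0, insert_length = c(18L, 40L))
  ref <- generate_reference(cfg)
  sim <- generate_reads(cfg, ref)
  casc <- run_cascade(sim$reads, cascade_config(ref$stages))
  al <- do.call(rbind, lapply(casc$stages, function(s)
    s$alignments[, c("read_id", "transcript_id")]))
  m <- merge(al, sim$truth, by = "read_id")
  expect_gte(nrow(m) / length(sim$reads), 0.99)
  expect_gte(mean(m$transcript_id.x == m$transcript_id.y), 0.99)
})

test_that("reverse-complement reads map on the minus strand when allowed", {
  set.seed(47)
  ref <- reference_set("T1", rand_seq(80), "miRNA")
  rd_fwd <- substr(ref$seq, 11, 35)
  rd_rc <- exocascade:::revcomp(rd_fwd)
  idx <- build_index(ref, 10)
  expect_null(align_read(rd_rc, idx, ref, align_params()))
  hit <- align_read(rd_rc, idx, ref, align_params(strand_mode = "both"))
  expect_identical(hit$strand, "-")
  expect_equal(hit$score, 50)
  # the SAM record flags the strand and reverse-complements SEQ
  reads <- mk_reads(rd_rc)
  res <- align_batch(reads, ref, align_params(strand_mode = "both"))
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(res$alignments, ref, sam)
  rec <- strsplit(grep("^r001", readLines(sam), value = TRUE), "\t")[[1]]
  expect_identical(rec[2], "16")
  expect_identical(rec[10], rd_fwd)
  expect_true(isTRUE(validate_sam(sam)))
})
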