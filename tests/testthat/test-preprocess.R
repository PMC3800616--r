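params_noad <- preprocess_params()
params_ad <- preprocess_params(adapter_seq = ADAPTER)

test_that("3' quality trimming stops at the first good base and enforces the floor", {
  set.seed(2)
  s25 <- rand_seq(25)
  clean <- mk_reads(s25, list(rep(30L, 25)))
  res <- quality_trim(clean, params_noad)
  expect_identical(res$kept$seq, s25)            # nothing below threshold
  expect_length(res$dropped, 0)

  tail_low <- mk_reads(s25, list(c(rep(30L, 21), rep(10L, 4))))
  res <- quality_trim(tail_low, params_noad)
  expect_equal(nchar(res$kept$seq), 21)
  expect_identical(res$kept$seq, substr(s25, 1, 21))
  expect_equal(original_lengths(res$kept), 25)   # provenance keeps history

  s20 <- rand_seq(20)
  short <- mk_reads(s20, list(c(rep(30L, 15), rep(2L, 5))))
  res <- quality_trim(short, params_noad)
  expect_length(res$kept, 0)                     # 15 < 17 floor
  expect_identical(res$dropped, "r001")

  # internal low-quality bases are retained
  dip <- mk_reads(s25, list(c(rep(30L, 10), 5L, rep(30L, 14))))
  expect_identical(quality_trim(dip, params_noad)$kept$seq, s25)
})

test_that("adapter trimming removes read-through and applies the length floor", {
  set.seed(3)
  ins20 <- rand_seq(20)
  rt <- mk_reads(paste0(ins20, ADAPTER))
  res <- trim_adapter(rt, params_ad)
  expect_identical(res$kept$seq, ins20)

  noad <- mk_reads(rand_seq(25))
  m <- brute_adapter(noad$seq, ADAPTER)
  if (m$start < 0) {  # construction: random read without adapter suffix
    expect_identical(trim_adapter(noad, params_ad)$kept$seq, noad$seq)
  }

  ins10 <- rand_seq(10)
  res <- trim_adapter(mk_reads(paste0(ins10, ADAPTER)), params_ad)
  expect_length(res$kept, 0)                     # 10 < 17 floor
})

test_that("adapter matching agrees with the brute-force edit-distance oracle", {
  set.seed(4)
  for (i in 1:120) {
    ins <- rand_seq(sample(10:40, 1))
    kind <- sample(3, 1)
    rd <- switch(kind,
      paste0(ins, substr(ADAPTER, 1, sample(3:23, 1))),  # partial read-through
      ins,                                               # no adapter
      {                                                  # 2 errors in read
        x <- paste0(ins, ADAPTER)
        ch <- strsplit(x, "")[[1]]
        for (p in sample(nchar(x), 2)) ch[p] <- sample(c("A", "C", "G", "T"), 1)
        paste(ch, collapse = "")
      })
    got <- exocascade:::.adapter_match(rd, ADAPTER, 0.1, 3L)
    want <- brute_adapter(rd, ADAPTER)
    expect_equal(got$start[1], want$start,
                 info = paste("read", rd))
    expect_equal(got$length[1], want$L, info = paste("read", rd))
  }
})

test_that("N in the read never matches an adapter base", {
  ins <- strrep("C", 20)
  rd <- paste0(ins, chartr("A", "N", ADAPTER))
  # every former A of the adapter now mismatches; budget still allows a match
  m <- exocascade:::.adapter_match(rd, ADAPTER, 0.4, 3L)
  expect_true(m$edits[1] > 0)
})

test_that("preprocessing conserves reads, shortens them, and respects the floor", {
  cfg <- sim_config(seed = 21, read_count = 800)
  sim <- generate_reads(cfg)
  res <- preprocess_stream(sim$reads, preprocess_params(adapter_seq = cfg$adapter_seq))

  # conservation: kept + dropped == input
  expect_equal(length(res$kept) + sum(res$drop_counts), length(sim$reads))
  expect_setequal(c(res$kept$read_id, unname(res$dropped_ids)),
                  sim$reads$read_id)

  # monotonicity and floor
  orig <- setNames(nchar(sim$reads$seq), sim$reads$read_id)
  expect_true(all(nchar(res$kept$seq) <= orig[res$kept$read_id]))
  expect_true(all(nchar(res$kept$seq) >= 17))

  # kept reads end in a base at or above Q17 whenever quality trimming fired
  fired <- vapply(res$kept$provenance, function(p) {
    any(startsWith(p, "quality_trim"))
  }, logical(1))
  last_q <- vapply(res$kept$qual, function(q) q[length(q)], integer(1))
  expect_true(all(last_q[fired] >= 17))
})

test_that("planted read-through reads are trimmed back to their exact inserts", {
  cfg <- sim_config(seed = 22, read_count = 600, error_rate = 0,
                    adapter_fraction = 1, insert_length = c(18L, 40L))
  sim <- generate_reads(cfg)
  res <- preprocess_stream(sim$reads,
                           preprocess_params(adapter_seq = cfg$adapter_seq))
  tr <- sim$truth[match(res$kept$read_id, sim$truth$read_id), ]
  expect_gte(mean(res$kept$seq == tr$insert_seq), 0.99)
})

test_that("preprocessing is idempotent when spurious matches are excluded", {
  cfg <- sim_config(seed = 23, read_count = 300, error_rate = 0)
  sim <- generate_reads(cfg)
  p <- preprocess_params(adapter_seq = cfg$adapter_seq, min_overlap = 10L)
  once <- preprocess_stream(sim$reads, p)
  twice <- preprocess_stream(once$kept, p)
  expect_identical(twice$kept$seq, once$kept$seq)
  expect_equal(sum(twice$drop_counts), 0)
})

test_that("empty input passes through preprocessing untouched", {
  res <- preprocess_stream(read_set(), params_ad)
  expect_length(res$kept, 0)
  expect_equal(sum(res$drop_counts), 0)
})
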