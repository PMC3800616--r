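ct <- function(ids, counts, cls = "miRNA", acc = NA_character_, ...) {
  count_table(ids, counts, cls, accession = acc, ...)
}

test_that("percent-of-mapped normalization sums to 100 across stages", {
  n <- normalize_percent(ct(c("A", "B"), c(3, 1)))
  expect_equal(setNames(n$percent, n$transcript_id), c(A = 75, B = 25))

  expect_equal(normalize_percent(ct("A", 5))$percent, 100)

  two <- list(ct("A", 2, stage_label = "s1"),
              ct("B", 2, cls = "mRNA", stage_label = "s2"))
  n2 <- normalize_percent(two)
  expect_equal(n2$percent, c(50, 50))   # total is cross-stage

  expect_error(normalize_percent(ct(character(), numeric(), character())),
               "zero mapped")
})

test_that("composition profiles aggregate by RNA class", {
  p <- composition_profile(ct(c("m1", "m2"), c(4, 6)))
  expect_equal(p$percent, 100)
  expect_identical(p$rna_class, "miRNA")

  mix <- ct(c("r1", "o1", "o2"), c(40, 35, 25),
            cls = c("rRNA", "other", "other"))
  p2 <- composition_profile(mix)
  expect_equal(setNames(p2$percent, p2$rna_class),
               c(other = 60, rRNA = 40))
})

test_that("simulated mixtures are recovered within binomial sampling error", {
  cfg <- sim_config(seed = 61, read_count = 4000,
                    class_mixture = c(miRNA = 0.5, rRNA = 0.5),
                    error_rate = 0, adapter_fraction = 1,
                    insert_length = c(18L, 40L))
  ref <- generate_reference(cfg)
  sim <- generate_reads(cfg, ref)
  pre <- preprocess_stream(sim$reads,
                           preprocess_params(adapter_seq = cfg$adapter_seq))
  casc <- run_cascade(pre$kept, cascade_config(ref$stages))
  p <- composition_profile(casc)
  # 99% binomial CI half-width on a 50/50 split of 4000 reads is ~2%
  for (cl in c("miRNA", "rRNA")) {
    expect_lt(abs(p$percent[p$rna_class == cl] - 50), 2.5)
  }
})

test_that("mean counts average replicates with absent transcripts as zero", {
  reps <- list(ct("A", 1), ct("A", 2), ct("A", 3))
  m <- mean_counts(reps)
  expect_equal(m$count, 2.00)

  m2 <- mean_counts(list(ct("A", 4), ct(character(), numeric(), character())))
  expect_equal(m2$count, 2.00)

  # a top-table mean over 3 replicate libraries: 6046 / 3 -> 2015.33
  reps3 <- list(ct("hsa-mir-21", 2000), ct("hsa-mir-21", 2100),
                ct("hsa-mir-21", 1946))
  expect_equal(mean_counts(reps3)$count, 2015.33)

  expect_error(mean_counts(list()), "at least one replicate")
})

test_that("top-N ranking orders by mean with lexicographic tie-breaks", {
  fx <- packaged_fixtures()
  top <- top_n(fx$hela$exosomes$miRNA, "miRNA", 10)
  expect_identical(top$transcript_id[1:2], c("hsa-mir-21", "hsa-mir-3160-1"))
  expect_true(all(diff(top$mean_count) <= 0))
  expect_false(attr(top, "short"))

  small <- ct(c("x", "y", "z"), c(3, 2, 1))
  t3 <- top_n(small, "miRNA", 10)
  expect_equal(nrow(t3), 3)
  expect_true(attr(t3, "short"))

  tied <- ct(c("beta", "alpha"), c(5, 5))
  expect_identical(top_n(tied, "miRNA", 2)$transcript_id,
                   c("alpha", "beta"))
})

test_that("top-N overlap is keyed by accession, symmetric and bounded", {
  fx <- packaged_fixtures()
  a <- top_n(fx$hela$cells$tRNA, "tRNA", 10)
  b <- top_n(fx$hela$exosomes$tRNA, "tRNA", 10)
  expect_equal(topn_overlap(a, b), 7)
  expect_equal(topn_overlap(b, a), 7)
  expect_lte(topn_overlap(a, b), min(nrow(a), nrow(b)))

  expect_equal(topn_overlap(a, a), 10)

  sn <- top_n(fx$serum$parental$ncRNA, "ncRNA", 10)
  se <- top_n(fx$serum$exosomes$ncRNA, "ncRNA", 10)
  expect_equal(topn_overlap(sn, se), 4)

  disj <- top_n(ct(c("p", "q"), c(2, 1)), "miRNA", 2)
  other <- top_n(ct(c("u", "v"), c(2, 1)), "miRNA", 2)
  expect_equal(topn_overlap(disj, other), 0)

  mism <- top_n(ct("t", 1, cls = "tRNA"), "tRNA", 1)
  expect_error(topn_overlap(a, mism), NA)  # same class is fine
  expect_error(topn_overlap(top_n(ct("m", 1), "miRNA", 1), mism),
               "different RNA classes")
})

test_that("differential tables report group means, sds and ratios", {
  pa <- list(normalize_percent(ct(c("A", "B"), c(3, 1))),
             normalize_percent(ct(c("A", "B"), c(3, 1))))
  pb <- list(normalize_percent(ct(c("A", "B"), c(1, 3))))
  d <- differential_table(pa, pb, labels = c("exo", "cells"))
  expect_equal(d$sd_a, c(0, 0))        # identical replicates
  expect_equal(d$sd_b, c(0, 0))        # single replicate
  expect_equal(d$mean_a, c(75, 25))
  expect_equal(d$ratio, c(3, 1 / 3))

  # transcript present only in group A: group B mean is 0
  pa2 <- list(normalize_percent(ct(c("A", "X"), c(1, 1))))
  pb2 <- list(normalize_percent(ct("A", 2)))
  d2 <- differential_table(pa2, pb2)
  expect_equal(d2$mean_b[d2$transcript_id == "X"], 0)
  expect_true(is.infinite(d2$ratio[d2$transcript_id == "X"]))

  expect_error(differential_table(list(), pb), "at least one replicate")
})

test_that("a planted enrichment is recovered within sampling error", {
  set.seed(62)
  # group A carries transcript E at 4x the relative abundance of group B
  draw <- function(p_e, n = 20000) {
    k <- rbinom(1, n, p_e)
    normalize_percent(ct(c("E", "rest"), c(k, n - k),
                         cls = c("miRNA", "other")))
  }
  pa <- lapply(1:3, function(i) draw(0.08))
  pb <- lapply(1:3, function(i) draw(0.02))
  d <- differential_table(pa, pb)
  ratio <- d$ratio[d$transcript_id == "E"]
  expect_lt(abs(ratio - 4), 0.4)
})
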