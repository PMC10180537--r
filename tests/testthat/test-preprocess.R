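make_read <- function(seq, q = "I") {
  tibble::tibble(read_id = "r", sequence = seq,
                 quality = strrep(q, nchar(seq)))
}

test_that("adapter trimming finds the leftmost 3' adapter match", {
  cfg <- preprocess_config(adapter_3p = "AACTGTAGGCACCATCAAT")
  insert <- "TGACAGAAGAGAGTGAGCACA"

  full <- trim_adapter(make_read(paste0(insert, cfg$adapter_3p)), cfg)
  expect_equal(full$sequence, insert)
  expect_equal(nchar(full$quality), nchar(insert))
  expect_equal(full$trim_status, "trimmed")

  at0 <- trim_adapter(make_read(cfg$adapter_3p), cfg)
  expect_equal(at0$trim_status, "empty")
  expect_equal(at0$sequence, "")

  # adapter prefix one base short of min_overlap: passes untrimmed
  short <- trim_adapter(
    make_read(paste0(insert, substr(cfg$adapter_3p, 1, cfg$min_overlap - 1L))),
    cfg)
  expect_equal(short$trim_status, "untrimmed")
  expect_equal(nchar(short$sequence), nchar(insert) + cfg$min_overlap - 1L)

  # a partial adapter at the very 3' end is still found
  partial <- trim_adapter(
    make_read(paste0(insert, substr(cfg$adapter_3p, 1, cfg$min_overlap))),
    cfg)
  expect_equal(partial$trim_status, "trimmed")
  expect_equal(partial$sequence, insert)
})

test_that("quality filter applies mean-Q30 and N rules", {
  cfg <- preprocess_config()
  expect_true(quality_filter(make_read("ACGTACGTACGT", q = "I"), cfg)$keep_quality)  # Q40
  expect_false(quality_filter(make_read("ACGTACGTACGT", q = ">"), cfg)$keep_quality) # Q29
  expect_true(quality_filter(make_read("ACGTACGTACGT", q = "?"), cfg)$keep_quality)  # Q30 boundary
  withN <- make_read("ACGTNACGTACG", q = "D")  # Q35, one N
  expect_false(quality_filter(withN, cfg)$keep_quality)
  keepN <- preprocess_config(discard_n = FALSE)
  expect_true(quality_filter(withN, keepN)$keep_quality)
})

test_that("ncRNA subtraction is exact substring matching on both strands", {
  trna <- tibble::tibble(seq_id = "tRNA-1",
                         sequence = paste0("GGGCCCGT", "TGACAGAAGAGAGTGAGCACA",
                                           "ACGTACGGT"))
  slice <- "TGACAGAAGAGAGTGAGCACA"
  mism <- "TGACAGAAGACAGTGAGCACA"
  rc_slice <- reverse_complement(slice)
  tags <- tibble::tibble(sequence = c(slice, mism, rc_slice),
                         length = nchar(c(slice, mism, rc_slice)),
                         count = c(5L, 4L, 3L))
  res <- subtract_ncrna(tags, trna)
  expect_setequal(res$removed$sequence, c(slice, rc_slice))
  expect_equal(res$retained$sequence, mism)
  expect_equal(nrow(res$removed) + nrow(res$retained), nrow(tags))
  expect_warning(subtract_ncrna(tags, trna[0, ]), "empty")
})

test_that("length histogram reports mode and percentages on unique tags", {
  tags <- tibble::tibble(sequence = c("A", "B", "C", "D", "E"),
                         length = c(21L, 21L, 24L, 24L, 24L),
                         count = c(9L, 9L, 1L, 1L, 1L))
  h <- length_histogram(tags)
  expect_equal(attr(h, "mode_length"), 24L)
  expect_equal(attr(h, "mode_pct"), 60)
  expect_equal(sum(h$pct), 100)

  single <- length_histogram(tags[1, ])
  expect_equal(attr(single, "mode_pct"), 100)
  expect_equal(nrow(length_histogram(tags[0, ])), 0L)
})

test_that("full preprocessing conserves reads and matches generator truth", {
  gen <- make_genome(8, 0, contig_len = 3000L, seed = 101)
  ncr <- make_ncrna_reference(seed = 102)
  sim <- simulate_reads(gen$truth, meanlog = 3.5, error_rate = 0,
                        ncrna_fraction = 0.2, ncrna_ref = ncr,
                        star_fraction = 0, seed = 103)
  prep <- run_preprocess(sim$reads, preprocess_config(), ncr)

  acc <- prep$accounting
  terminal <- acc[acc$terminal, ]
  expect_equal(sum(terminal$reads), acc$reads[acc$category == "total"])

  # with zero sequencing error the planted tag counts come back exactly
  joined <- dplyr::inner_join(prep$tags, sim$tag_truth,
                              by = "sequence")
  expect_equal(nrow(joined), nrow(sim$tag_truth))
  expect_equal(joined$count, joined$true_count)

  # every planted contaminant is subtracted, and nothing else
  expect_setequal(prep$ncrna_tags$sequence, sim$contaminants)

  # contaminant volume is near the configured fraction
  n_cont <- acc$reads[acc$category == "ncrna_matched"]
  frac <- n_cont / acc$reads[acc$category == "total"]
  expect_gt(frac, 0.10)
  expect_lt(frac, 0.30)
})

test_that("length bounds use post-trim length and empty input yields zeros", {
  cfg <- preprocess_config()
  # 21-nt insert + 19-nt adapter = 40-nt raw read: kept because the
  # length filter sees the trimmed insert
  insert <- "TGACAGAAGAGAGTGAGCACA"
  reads <- make_read(paste0(insert, cfg$adapter_3p))
  prep <- run_preprocess(reads, cfg)
  expect_equal(prep$tags$sequence, insert)

  prep0 <- run_preprocess(tibble::tibble(read_id = character(),
                                         sequence = character(),
                                         quality = character()), cfg)
  expect_true(all(prep0$accounting$reads == 0))
  expect_equal(nrow(prep0$tags), 0L)
})
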