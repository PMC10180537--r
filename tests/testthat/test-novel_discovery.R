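test_that("exact mapping reports loci on both strands and drops repeats", {
  contig <- paste0(random_dna_str(60), "TGACAGAAGAGAGTGAGCACA",
                   random_dna_str(60))
  contigs <- tibble::tibble(seq_id = "c1",
                            sequence = reverse_complement(contig))
  tags <- tibble::tibble(sequence = c("TGACAGAAGAGAGTGAGCACA",
                                      "CCCCCCCCCCCCCCCCCCCCC"),
                         length = 21L, count = c(4L, 1L))
  loci <- map_tags(tags, contigs)
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$strand, "-")
  expect_equal(loci$end - loci$start, 21L)
  # the tag really is the reverse complement of the mapped slice
  slice <- substr(contigs$sequence, loci$start + 1L, loci$end)
  expect_equal(reverse_complement(slice), tags$sequence[1])

  # repetitive tag dropped beyond max_loci
  rep_contig <- tibble::tibble(seq_id = "r",
                               sequence = strrep("TGACAGAAGAGAGTGAGCACAAA", 30))
  expect_equal(nrow(map_tags(tags[1, ], rep_contig, max_loci = 5L)), 0L)
})

test_that("mapping recovers every planted locus exactly", {
  gen <- make_genome(6, 6, contig_len = 3000L, n_contigs = 2L, seed = 301)
  tr <- gen$truth[gen$truth$type == "precursor", ]
  tags <- tibble::tibble(sequence = tr$mature_tag,
                         length = nchar(tr$mature_tag), count = 1L)
  loci <- map_tags(tags, gen$contigs)
  expect_equal(nrow(loci), nrow(tr))
  for (i in seq_len(nrow(tr))) {
    l <- loci[loci$sequence == tr$mature_tag[i], ]
    expect_equal(l$contig_id, tr$contig_id[i])
    expect_equal(l$strand, tr$strand[i])
    expect_gte(l$start, tr$start[i])
    expect_lte(l$end, tr$end[i])
  }
})

test_that("window excision follows the flank grid, clipped to bounds", {
  contigs <- tibble::tibble(seq_id = "c1", sequence = random_dna_str(2000))
  interior <- list(contig_id = "c1", start = 900L, end = 922L,
                   strand = "+")
  win <- excise_windows(interior, contigs)
  expect_equal(nrow(win), 36L)  # 6 x 6 grid, no clipping, no duplicates
  expect_true(all(win$window_start >= 0 & win$window_end <= 2000))
  expect_true(all(substr(win$precursor_seq, win$mature_start,
                         win$mature_end) ==
                    substr(contigs$sequence, 901, 922)))

  near_start <- list(contig_id = "c1", start = 30L, end = 52L, strand = "+")
  win2 <- excise_windows(near_start, contigs)
  expect_lt(nrow(win2), 36L)     # upstream extents clip and deduplicate
  expect_true(all(win2$window_start >= 0))

  # minus-strand windows carry the tag on the excised strand
  minus <- list(contig_id = "c1", start = 900L, end = 922L, strand = "-")
  win3 <- excise_windows(minus, contigs)
  tag_rc <- reverse_complement(substr(contigs$sequence, 901, 922))
  expect_true(all(substr(win3$precursor_seq, win3$mature_start,
                         win3$mature_end) == tag_rc))
})

test_that("candidate evaluation applies the acceptance rules in order", {
  pre <- make_precursor("TGACAGAAGAGAGTGAGCACAT", star_mismatches = 0,
                        arm = "5p", seed = 21)
  ev <- evaluate_candidate(pre$precursor, pre$mature_span)
  expect_true(ev$accepted)
  expect_true(is.na(ev$reason))
  expect_gte(ev$mfei, 0.70)

  # an otherwise-perfect hairpin fails a raised MFEI threshold with the
  # threshold named in the reason
  strict <- precursor_criteria(min_mfei = 99)
  ev2 <- evaluate_candidate(pre$precursor, pre$mature_span,
                            criteria = strict)
  expect_false(ev2$accepted)
  expect_match(ev2$reason, "MFEI < 99")

  # mature spanning the terminal loop is rejected by rule (a)
  loop_mid <- round(mean(pre$loop_span))
  ev3 <- evaluate_candidate(pre$precursor, c(loop_mid - 10L, loop_mid + 10L))
  expect_false(ev3$accepted)
  expect_equal(ev3$reason, "loop overlap")

  # a heavily mismatched star violates the duplex rule
  pre8 <- make_precursor("TGACAGAAGAGAGTGAGCACAT", star_mismatches = 8,
                         arm = "5p", seed = 22)
  ev4 <- evaluate_candidate(pre8$precursor, pre8$mature_span)
  expect_false(ev4$accepted)
})

test_that("raising the MFEI threshold never admits more candidates", {
  gen <- make_genome(4, 0, contig_len = 2500L, seed = 303)
  tr <- gen$truth
  # mature spans from the construction geometry (25-nt extension, 8-nt loop)
  spans <- lapply(seq_len(nrow(tr)), function(i) {
    m <- nchar(tr$mature_tag[i])
    if (tr$arm[i] == "5p") c(26L, 25L + m) else c(34L + m, 33L + 2L * m)
  })
  counts <- vapply(c(0.5, 0.9, 1.3, 2.0, 99), function(th) {
    n <- 0L
    for (i in seq_len(nrow(tr))) {
      ev <- evaluate_candidate(tr$precursor_seq[i], spans[[i]],
                               criteria = precursor_criteria(min_mfei = th))
      n <- n + ev$accepted
    }
    n
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("novel calls recover planted precursors and only them", {
  gen <- make_genome(3, 12, contig_len = 3000L, n_contigs = 2L, seed = 305)
  tr <- gen$truth[gen$truth$type == "precursor", ]
  sim <- simulate_reads(gen$truth, error_rate = 0, star_fraction = 0.1,
                        seed = 306)
  prep <- run_preprocess(sim$reads, preprocess_config())
  novel <- call_novel(prep$tags, gen$contigs)
  expect_equal(nrow(novel), 3L)
  got <- dplyr::inner_join(
    dplyr::mutate(novel, dna = to_dna(sequence)),
    dplyr::select(tr, feature, mature_tag, t_strand = strand, t_arm = arm),
    by = c(dna = "mature_tag"))
  expect_equal(nrow(got), 3L)
  expect_equal(got$strand, got$t_strand)
  expect_equal(got$arm, got$t_arm)
  # names run in descending read-count order
  expect_equal(novel$name, sprintf("cci-miRN%d-%s", 1:3, novel$arm))
  expect_true(all(diff(novel$read_count) <= 0))
  # accepted candidates re-check against every criterion
  crit <- precursor_criteria()
  for (i in seq_len(nrow(novel))) {
    ev <- evaluate_candidate(novel$precursor_seq[i],
                             c(novel$mature_start[i], novel$mature_end[i]))
    expect_true(ev$accepted)
    expect_gte(ev$mfei, crit$min_mfei)
    expect_gte(ev$n_paired, crit$min_paired)
  }
  expect_equal(nrow(call_novel(prep$tags[0, ], gen$contigs)), 0L)
})

test_that("published novel-miRNA table passes the MFEI acceptance rule", {
  novel_tbl <- cumin_novel_table()
  expect_equal(nrow(novel_tbl), 39L)
  expect_equal(sum(novel_tbl$mfei >= 0.70), 39L)
})
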