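test_that("copy-number gate is inclusive at the threshold", {
  x <- tibble::tibble(name = c("a", "b", "c"), count = c(5L, 4L, 6L))
  expect_equal(filter_queries(x)$name, c("a", "c"))
  expect_equal(nrow(filter_queries(dplyr::mutate(x, count = 1L))), 0L)
  # the published novel table keeps 37 of 39 entries at the default gate
  novel_tbl <- cumin_novel_table()
  expect_equal(nrow(filter_queries(novel_tbl)), 37L)
  expect_setequal(filter_queries(novel_tbl, 1L)$read_count[
    !filter_queries(novel_tbl, 1L)$read_count >= 5], c(2L, 3L))
})

test_that("duplex scoring weights the seed and distinguishes pair classes", {
  mir <- "UGACAGAAGAGAGUGAGCACA"                       # 21 nt
  perfect <- reverse_string(to_rna(reverse_complement(mir)))
  expect_equal(score_duplex(mir, perfect), 0)

  mismatch_at <- function(p) {
    s <- strsplit(perfect, "")[[1]]
    s[p] <- c(A = "C", U = "C", G = "A", C = "A")[[substr(mir, p, p)]]
    paste(s, collapse = "")
  }
  expect_equal(score_duplex(mir, mismatch_at(15)), 1)
  expect_equal(score_duplex(mir, mismatch_at(3)), 2)   # seed doubling

  wobble_at <- function(p) {
    s <- strsplit(perfect, "")[[1]]
    s[p] <- if (substr(mir, p, p) == "G") "U" else "G"
    paste(s, collapse = "")
  }
  expect_equal(score_duplex(mir, wobble_at(15)), 0.5)  # position 15 is G
  expect_error(score_duplex("", ""), "empty")
  expect_error(score_duplex(mir, "AU"), "equal length")
  # adding a mismatch never lowers the expectation
  expect_gte(score_duplex(mir, mismatch_at(15)), score_duplex(mir, perfect))
})

test_that("transcript scanning reports planted sites at exact coordinates", {
  mir <- "UGACAGAAGAGAGUGAGCACA"
  site <- reverse_complement(mir)
  tr <- paste0(random_dna_str(40), site, random_dna_str(40))
  hits <- scan_transcript(mir, tr)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 41L)
  expect_equal(hits$end, 61L)
  expect_equal(hits$expectation, 0)
  expect_equal(hits$inhibition, "cleavage")

  # expectation just above the cutoff is not reported
  strict <- target_scheme(cutoff = 5)
  mirnas <- tibble::tibble(name = "m", sequence = mir)
  tx <- make_transcriptome(mirnas,
                           tibble::tibble(mirna_id = "m", expectation = 5.5),
                           n_transcripts = 1, seed = 41)
  hits2 <- scan_transcript(mir, tx$transcripts$sequence[1], strict)
  expect_false(tx$truth$start %in% hits2$start)
})

test_that("scanning equals brute-force enumeration on random pairs", {
  set.seed(55)
  for (k in 1:12) {
    mir <- random_rna(sample(19:23, 1))
    tr <- random_dna_str(120)
    a <- scan_transcript(mir, tr)
    b <- oracle_scan(mir, tr)
    expect_equal(nrow(a), nrow(b))
    if (nrow(a)) {
      expect_equal(a$start, b$start)
      expect_equal(a$end, b$end)
      expect_equal(a$expectation, b$expectation)
      expect_equal(a$n_gaps, b$n_gaps)
    }
  }
})

test_that("intermolecular duplex energy sums the packaged stack table", {
  model <- energy_model()
  mir <- "UGACAGAAGAGAGUGAGCACA"
  site <- reverse_string(to_rna(reverse_complement(mir)))
  # hand sum: 20 adjacent stacks of the aligned pair codes
  m <- strsplit(mir, "")[[1]]
  s <- strsplit(site, "")[[1]]
  codes <- match(paste0(m, s), c("AU", "UA", "GC", "CG", "GU", "UG"))
  hand <- sum(vapply(1:20, function(i) model$stack[codes[i], codes[i + 1]],
                     numeric(1))) / 10
  expect_equal(duplex_mfe(mir, site, model), hand)
  expect_lte(duplex_mfe(mir, site, model), 0)

  # no allowed pairs: zero
  expect_equal(duplex_mfe("AAAA", "AAAA", model), 0)
  # reversing both strands leaves the energy unchanged
  expect_equal(duplex_mfe(reverse_string(site), reverse_string(mir), model),
               duplex_mfe(mir, site, model))
})

test_that("designed-expectation sites score exactly their design value", {
  mirnas <- tibble::tibble(
    name = c("m1", "m2"),
    sequence = c("UGACAGAAGAGAGUGAGCACA", "GCUCUCUAUGCUUCUGUCAUCA"))
  ps <- tibble::tibble(mirna_id = c("m1", "m2", "m1"),
                       expectation = c(0, 2, 3.5))
  tx <- make_transcriptome(mirnas, ps, n_transcripts = 3, seed = 43)
  for (r in seq_len(nrow(tx$truth))) {
    t <- tx$truth[r, ]
    mir <- mirnas$sequence[mirnas$name == t$mirna_id]
    trs <- tx$transcripts$sequence[tx$transcripts$seq_id == t$transcript_id]
    hit <- scan_transcript(mir, trs)
    hit <- hit[hit$start == t$start, ]
    expect_equal(nrow(hit), 1L)
    expect_equal(hit$expectation, t$designed_expectation)
  }
  # identical seed, identical FASTA
  tx2 <- make_transcriptome(mirnas, ps, n_transcripts = 3, seed = 43)
  expect_identical(tx$transcripts, tx2$transcripts)
})

test_that("predict_targets gates queries and annotates duplex energy", {
  mir <- "UGACAGAAGAGAGUGAGCACA"
  mirnas <- tibble::tibble(name = c("hi", "lo"), sequence = c(mir, mir),
                           count = c(10L, 2L))
  tr <- tibble::tibble(seq_id = "t1",
                       sequence = paste0(random_dna_str(30),
                                         reverse_complement(mir),
                                         random_dna_str(30)))
  sites <- predict_targets(mirnas, tr)
  expect_equal(unique(sites$mirna_id), "hi")   # count 2 gated out
  expect_true(all(sites$duplex_mfe < 0))
})
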