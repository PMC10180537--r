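test_that("hamming distance unifies U/T and rejects unequal lengths", {
  expect_equal(hamming("TGACAGAAGAGAGTGAGCACA", "TGACAGAAGAGAGTGAGCACA"), 0)
  expect_equal(hamming("TGACAGAAGAGAGTGAGCACA", "TGACAGAAGAGAGTGAGCACC"), 1)
  expect_equal(hamming("AU", "AT"), 0)
  expect_error(hamming("ACG", "ACGT"), "equal-length")
})

test_that("conserved matching picks fewest mismatches with content tie-breaks", {
  ref <- tibble::tibble(
    mirbase_id = c("ath-miR159a", "osa-miR159a", "stu-miR156d-3p"),
    sequence = c("UUUGGAUUGAAGGGAGCUCUA", "UUUGGAUUGAAGGGAGCUCUC",
                 "GCUCUCUAUGCUUCUGUCAUCA"))
  tags <- tibble::tibble(
    sequence = c("TTTGGATTGAAGGGAGCTCTA",   # 0 mm to ath, 1 to osa
                 "GCTCTCTATGCTTCTGTCATCA",  # 0 mm to stu
                 "TTTGGATTGAAGGGAGCTGGG"),  # 2+ mm everywhere
    length = c(21L, 22L, 21L), count = c(10L, 5L, 2L))
  hits <- match_conserved(tags, ref)
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$mirbase_id[hits$sequence == tags$sequence[1]],
               "ath-miR159a")
  expect_equal(hits$mismatches, c(0L, 0L))
  # classification is invariant under reference shuffling
  hits_shuf <- match_conserved(tags, ref[c(3, 1, 2), ])
  expect_equal(dplyr::arrange(hits, sequence),
               dplyr::arrange(hits_shuf, sequence))
})

test_that("classifier agrees with the brute-force all-pairs oracle", {
  set.seed(77)
  ref <- tibble::tibble(
    mirbase_id = sprintf("%s-miR%d%s",
                         sample(c("ath", "osa", "stu", "gma"), 60, TRUE),
                         sample(150:9999, 60),
                         sample(c("", "a", "b-5p", "c-3p"), 60, TRUE)),
    sequence = replicate(60, random_rna(sample(19:24, 1))))
  ref <- dplyr::distinct(ref, mirbase_id, .keep_all = TRUE)
  tags <- tibble::tibble(sequence = vapply(1:120, function(i) {
    base <- chartr("U", "T", ref$sequence[sample.int(nrow(ref), 1)])
    n_mut <- sample(0:3, 1)
    ch <- strsplit(base, "")[[1]]
    if (n_mut > 0) {
      pos <- sample(seq_along(ch), n_mut)
      ch[pos] <- vapply(ch[pos], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    }
    paste(ch, collapse = "")
  }, character(1)))
  tags <- dplyr::mutate(dplyr::distinct(tags), length = nchar(sequence),
                        count = 1L)
  hits <- match_conserved(tags, ref, max_mismatches = 1L)
  for (i in seq_len(nrow(tags))) {
    o <- oracle_match(tags$sequence[i], ref$mirbase_id, ref$sequence, 1L)
    h <- hits[hits$sequence == tags$sequence[i], ]
    if (is.null(o)) {
      expect_equal(nrow(h), 0L)
    } else {
      expect_equal(h$mirbase_id, o$id)
      expect_equal(h$mismatches, o$mm)
      # every hit re-checks against hamming directly
      expect_equal(hamming(h$sequence, h$ref_sequence), h$mismatches)
    }
  }
})

test_that("cci- names drop the species prefix and disambiguate collisions", {
  ref <- tibble::tibble(
    mirbase_id = c("ath-miR159a", "osa-miR827", "bdi-miR827"),
    sequence = c("UUUGGAUUGAAGGGAGCUCUA", "UUAGAUGACCAUCAGCAAACA",
                 "UUAGAUGACCAUCAGCAAACG"))
  tags <- tibble::tibble(
    sequence = c("TTTGGATTGAAGGGAGCTCTA",
                 "TTAGATGACCATCAGCAAACA",   # 0 mm to osa-miR827
                 "TTAGATGACCATCAGCAAACC"),  # 1 mm to osa-miR827 (ties name)
    length = c(21L, 21L, 21L), count = c(3L, 10L, 2L))
  named <- assign_names(match_conserved(tags, ref))
  expect_true("cci-miR159a" %in% named$assigned_name)
  m827 <- sort(named$assigned_name[grepl("miR827", named$assigned_name)])
  expect_equal(m827, c("cci-miR827", "cci-miR827-1"))
  # the lowest-mismatch sequence keeps the plain name
  expect_equal(named$assigned_name[named$mismatches == 0 &
                                     grepl("miR827", named$mirbase_id)],
               "cci-miR827")
  expect_equal(nrow(assign_names(named[0, ])), 0L)
})

test_that("family summaries count members and reads in order", {
  hits <- tibble::tibble(
    sequence = c("A1", "A2", "A3", "B1"),
    count = c(5L, 2L, 1L, 7L),
    family = c("MIR156", "MIR156", "MIR156", "MIR159"))
  fam <- summarize_families(hits)
  expect_equal(fam$family[1], "MIR156")
  expect_equal(fam$member_count, c(3L, 1L))
  expect_equal(fam$total_read_count, c(8L, 7L))
  expect_equal(nrow(summarize_families(hits[0, ])), 0L)
})

test_that("published MIR166 member read counts sum as printed", {
  tbl <- cumin_conserved_table()
  mir166 <- tbl[tbl$family == "MIR166", ]
  expect_equal(nrow(mir166), 3L)
  expect_equal(sum(mir166$read_count), 140263 + 2404 + 1176)
})

test_that("conserved classification splits off the unmatched remainder", {
  ref <- tibble::tibble(mirbase_id = "ath-miR159a",
                        sequence = "UUUGGAUUGAAGGGAGCUCUA")
  tags <- tibble::tibble(
    sequence = c("TTTGGATTGAAGGGAGCTCTA", "ACGTACGTACGTACGTACGTA"),
    length = c(21L, 21L), count = c(2L, 9L))
  res <- classify_conserved(tags, ref)
  expect_equal(nrow(res$hits), 1L)
  expect_equal(res$unmatched$sequence, "ACGTACGTACGTACGTACGTA")
})
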