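# Preprocessing cascade: adapter trim -> quality filter -> length bounds ->
# collapse -> ncRNA subtraction, with read accounting at each step.

#' Preprocessing configuration
#'
#' Bundles the thresholds of the small-RNA cleaning cascade. Defaults follow
#' the study conditions: mean read quality at least Q30, insert lengths 16-40
#' nt, reads containing N discarded.
#'
#' @param adapter_3p 3' adapter sequence (DNA). Default is the QIAseq miRNA
#'   library 3' adapter.
#' @param min_overlap Minimum number of adapter bases that must align at the
#'   read 3' end before trimming (default 8).
#' @param max_adapter_mismatch_rate Maximum fraction of mismatches in the
#'   adapter alignment (default 0.1).
#' @param min_mean_quality Minimum mean Phred score to keep a read
#'   (default 30).
#' @param min_len,max_len Inclusive post-trim length bounds (defaults 16, 40).
#' @param discard_n Discard reads containing N (default TRUE).
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(adapter_3p = "AACTGTAGGCACCATCAAT",
                              min_overlap = 8L,
                              max_adapter_mismatch_rate = 0.1,
                              min_mean_quality = 30,
                              min_len = 16L,
                              max_len = 40L,
                              discard_n = TRUE) {
  stopifnot(nzchar(adapter_3p), min_len <= max_len,
            max_adapter_mismatch_rate >= 0, max_adapter_mismatch_rate <= 1,
            min_overlap >= 1)
  structure(list(adapter_3p = toupper(to_dna(adapter_3p)),
                 min_overlap = as.integer(min_overlap),
                 max_adapter_mismatch_rate = max_adapter_mismatch_rate,
                 min_mean_quality = min_mean_quality,
                 min_len = as.integer(min_len),
                 max_len = as.integer(max_len),
                 discard_n = isTRUE(discard_n)),
            class = "preprocess_config")
}

# Leftmost 3'-adapter occurrence in one read. The adapter (or a prefix of it,
# when the read ends inside the adapter) must align with >= min_overlap bases
# and a mismatch rate <= the configured maximum. Returns the 0-based trim
# position, or -1L when no acceptable alignment exists.
find_adapter_start <- function(sequence, cfg) {
  n <- nchar(sequence)
  ad <- cfg$adapter_3p
  la <- nchar(ad)
  sv <- strsplit(sequence, "")[[1]]
  av <- strsplit(ad, "")[[1]]
  for (start in 0:(n - cfg$min_overlap)) {
    k <- min(la, n - start)            # bases of adapter visible in the read
    if (k < cfg$min_overlap) break
    mm <- sum(sv[(start + 1):(start + k)] != av[1:k])
    if (mm / k <= cfg$max_adapter_mismatch_rate) return(start)
  }
  -1L
}

#' Trim the 3' adapter from reads
#'
#' Finds the leftmost position where a prefix of the adapter aligns at the
#' read 3' end with at least `min_overlap` bases and at most the configured
#' mismatch rate, and truncates sequence and quality there. Reads without a
#' detectable adapter pass through unmodified and are flagged `"untrimmed"`;
#' reads whose insert is empty after trimming are flagged `"empty"`.
#'
#' @param reads Read tibble (`read_id`, `sequence`, `quality`).
#' @param config A [preprocess_config()].
#' @return The read tibble with `sequence`/`quality` trimmed and a new
#'   `trim_status` column in `c("trimmed", "untrimmed", "empty")`.
#' @export
trim_adapter <- function(reads, config = preprocess_config()) {
  if (nrow(reads) == 0L) {
    return(dplyr::mutate(reads, trim_status = character()))
  }
  pos <- vapply(reads$sequence, find_adapter_start, integer(1),
                cfg = config, USE.NAMES = FALSE)
  status <- dplyr::case_when(pos < 0L ~ "untrimmed",
                             pos == 0L ~ "empty",
                             TRUE ~ "trimmed")
  keep_len <- ifelse(pos < 0L, nchar(reads$sequence), pos)
  dplyr::mutate(reads,
                sequence = substr(.data$sequence, 1L, keep_len),
                quality = substr(.data$quality, 1L, keep_len),
                trim_status = status)
}

#' Mean-quality and N filter
#'
#' A read is kept iff its mean Phred score is at least `min_mean_quality`
#' and, when `discard_n` is set, it contains no N.
#'
#' @inheritParams trim_adapter
#' @return The read tibble with a logical `keep_quality` column.
#' @export
quality_filter <- function(reads, config = preprocess_config()) {
  if (nrow(reads) == 0L) {
    return(dplyr::mutate(reads, keep_quality = logical()))
  }
  mean_q <- vapply(phred_scores(reads$quality),
                   function(q) if (length(q)) mean(q) else 0,
                   numeric(1))
  has_n <- grepl("N", reads$sequence, fixed = TRUE)
  dplyr::mutate(reads,
                keep_quality = mean_q >= config$min_mean_quality &
                  !(config$discard_n & has_n))
}

#' Subtract tags matching a non-coding RNA reference
#'
#' A tag is removed iff its sequence, or its reverse complement, occurs as an
#' exact substring of any reference sequence (rRNA, tRNA, snRNA, snoRNA ...).
#' The partition is exhaustive and disjoint; exactness keeps the rule
#' reproducible.
#'
#' @param tags Unique-tag tibble (`sequence`, `length`, `count`).
#' @param ncrna_ref Reference tibble (`seq_id`, `sequence`), e.g. from
#'   [read_fasta()].
#' @return A list with elements `retained` and `removed`, both tag tibbles.
#' @export
subtract_ncrna <- function(tags, ncrna_ref) {
  if (nrow(ncrna_ref) == 0L) {
    warning("empty ncRNA reference: no tags subtracted", call. = FALSE)
    return(list(retained = tags, removed = tags[0, ]))
  }
  haystack <- paste(ncrna_ref$sequence, collapse = "|")
  hit <- vapply(tags$sequence, function(s) {
    grepl(s, haystack, fixed = TRUE) ||
      grepl(reverse_complement(s), haystack, fixed = TRUE)
  }, logical(1), USE.NAMES = FALSE)
  list(retained = tags[!hit, ], removed = tags[hit, ])
}

#' Length distribution of unique tags
#'
#' Tabulates tag counts per length on the unique-tag basis (each distinct
#' sequence counted once), with percentages and the modal length.
#'
#' @param tags Unique-tag tibble.
#' @param min_len,max_len Range reported; lengths outside are pooled into an
#'   `out_of_range` attribute.
#' @return A tibble of class `length_distribution` with columns `length`,
#'   `n_tags`, `pct`; attributes `mode_length`, `mode_pct`, `out_of_range`.
#' @export
length_histogram <- function(tags, min_len = 16L, max_len = 40L) {
  in_range <- tags$length >= min_len & tags$length <= max_len
  dist <- tags[in_range, ] |>
    dplyr::count(.data$length, name = "n_tags") |>
    dplyr::arrange(.data$length)
  n_in <- sum(dist$n_tags)
  dist <- dplyr::mutate(dist,
                        pct = if (n_in > 0) 100 * .data$n_tags / n_in else numeric(nrow(dist)))
  mode_idx <- if (nrow(dist)) which.max(dist$n_tags) else integer()
  structure(dist,
            class = c("length_distribution", class(dist)),
            mode_length = if (length(mode_idx)) dist$length[mode_idx] else NA_integer_,
            mode_pct = if (length(mode_idx)) dist$pct[mode_idx] else NA_real_,
            out_of_range = sum(!in_range))
}

#' Run the full preprocessing cascade
#'
#' Applies, in order: 3' adapter trimming, mean-quality/N filtering,
#' post-trim length bounds, read collapsing, and ncRNA subtraction. Every
#' input read lands in exactly one terminal accounting category, so category
#' totals always sum to the input size.
#'
#' @param fastq Path to a FASTQ file, or a read tibble as from [read_fastq()].
#' @param config A [preprocess_config()].
#' @param ncrna_ref ncRNA reference tibble (possibly empty).
#' @return A list of class `srna_preprocess` with elements `tags` (clean
#'   unique tags), `accounting` (category tibble), `length_dist`
#'   (a [length_histogram()] of the clean tags), and `ncrna_tags`.
#' @export
run_preprocess <- function(fastq, config = preprocess_config(),
                           ncrna_ref = NULL) {
  reads <- if (is.character(fastq)) read_fastq(fastq) else fastq
  total <- nrow(reads)

  trimmed <- trim_adapter(reads, config)
  n_empty <- sum(trimmed$trim_status == "empty")
  n_trimmed <- sum(trimmed$trim_status == "trimmed")
  surv <- trimmed[trimmed$trim_status != "empty", ]

  surv <- quality_filter(surv, config)
  n_lowq <- sum(!surv$keep_quality)
  surv <- surv[surv$keep_quality, ]

  len <- nchar(surv$sequence)
  n_short <- sum(len < config$min_len)
  n_long <- sum(len > config$max_len)
  surv <- surv[len >= config$min_len & len <= config$max_len, ]

  tags <- collapse_reads(surv)
  sub <- if (is.null(ncrna_ref) || nrow(ncrna_ref) == 0L) {
    list(retained = tags, removed = tags[0, ])
  } else {
    subtract_ncrna(tags, ncrna_ref)
  }
  n_ncrna_reads <- sum(sub$removed$count)
  n_retained_reads <- sum(sub$retained$count)

  accounting <- tibble(
    category = c("total", "adapter_trimmed", "empty_after_trim",
                 "low_quality", "too_short", "too_long",
                 "ncrna_matched", "retained"),
    reads = c(total, n_trimmed, n_empty, n_lowq, n_short, n_long,
              n_ncrna_reads, n_retained_reads),
    unique_tags = c(NA, NA, NA, NA, NA, NA,
                    nrow(sub$removed), nrow(sub$retained)),
    terminal = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE)
  )

  structure(list(tags = sub$retained,
                 ncrna_tags = sub$removed,
                 accounting = accounting,
                 length_dist = length_histogram(sub$retained,
                                                config$min_len,
                                                config$max_len),
                 config = config),
            class = "srna_preprocess")
}

#' @export
print.srna_preprocess <- function(x, ...) {
  cat("Small-RNA preprocessing result\n")
  cat(sprintf("  reads in: %d, clean unique tags: %d\n",
              x$accounting$reads[x$accounting$category == "total"],
              nrow(x$tags)))
  ml <- attr(x$length_dist, "mode_length")
  if (!is.na(ml)) {
    cat(sprintf("  modal tag length: %d nt (%.2f%% of clean tags)\n",
                ml, attr(x$length_dist, "mode_pct")))
  }
  invisible(x)
}
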