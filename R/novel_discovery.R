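# Novel-miRNA discovery: exact mapping of homology-unexplained tags to
# reference contigs, precursor-window excision on a fixed flank grid,
# folding, and the acceptance criteria (hairpin geometry + MFEI >= 0.70).

#' Map unique tags to reference contigs by exact full-length match
#'
#' Reports every exact occurrence of each tag on both strands of the
#' contigs (0-based half-open coordinates). Tags occurring more than
#' `max_loci` times are flagged repetitive and dropped.
#'
#' @param tags Unique-tag tibble.
#' @param contigs Contig tibble (`seq_id`, `sequence`), e.g. [read_fasta()].
#' @param max_loci Maximum mapping multiplicity before a tag is considered
#'   repetitive (default 20).
#' @return A tibble with columns `sequence`, `count`, `contig_id`, `start`,
#'   `end`, `strand`.
#' @export
map_tags <- function(tags, contigs, max_loci = 20L) {
  empty <- tibble(sequence = character(), count = integer(),
                  contig_id = character(), start = integer(),
                  end = integer(), strand = character())
  if (nrow(tags) == 0L || nrow(contigs) == 0L) return(empty)
  subject <- Biostrings::DNAStringSet(contigs$sequence)
  names(subject) <- contigs$seq_id
  one_tag <- function(seq, count) {
    hit_strand <- function(pattern, strand) {
      m <- Biostrings::vmatchPattern(pattern, subject)
      purrr::imap(as.list(m), function(ir, cid) {
        if (length(ir) == 0L) return(NULL)
        tibble(sequence = seq, count = count, contig_id = cid,
               start = BiocGenerics::start(ir) - 1L,
               end = BiocGenerics::end(ir), strand = strand)
      })
    }
    rows <- c(hit_strand(seq, "+"),
              hit_strand(reverse_complement(seq), "-"))
    dplyr::bind_rows(rows)
  }
  loci <- purrr::map2(tags$sequence, tags$count, one_tag) |>
    dplyr::bind_rows()
  if (nrow(loci) == 0L) return(empty)
  loci |>
    dplyr::group_by(.data$sequence) |>
    dplyr::filter(dplyr::n() <= max_loci) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$sequence, .data$contig_id, .data$start)
}

#' Excise candidate precursor windows around a mapped locus
#'
#' Emits windows extending the locus upstream and downstream by every
#' combination of flank extents on a fixed grid, clipped to contig bounds,
#' strand-resolved (minus-strand windows are reverse-complemented) and
#' deduplicated.
#'
#' @param locus One-row tibble or list with `contig_id`, `start`, `end`,
#'   `strand` (0-based half-open).
#' @param contigs Contig tibble.
#' @param flanks Integer grid of flank extents
#'   (default `c(0, 20, 50, 100, 150, 250)`).
#' @return A tibble with columns `window_start`, `window_end` (0-based
#'   half-open on the contig), `strand`, `precursor_seq` (strand-resolved
#'   DNA), `mature_start`, `mature_end` (1-based inclusive within
#'   `precursor_seq`).
#' @export
excise_windows <- function(locus, contigs,
                           flanks = c(0L, 20L, 50L, 100L, 150L, 250L)) {
  contig <- contigs$sequence[contigs$seq_id == locus$contig_id]
  stopifnot(length(contig) == 1L)
  clen <- nchar(contig)
  grid <- tidyr::expand_grid(up = flanks, down = flanks)
  win <- grid |>
    dplyr::mutate(window_start = pmax(0L, locus$start - .data$up),
                  window_end = pmin(clen, locus$end + .data$down)) |>
    dplyr::distinct(.data$window_start, .data$window_end)
  seqs <- substr(rep(contig, nrow(win)), win$window_start + 1L,
                 win$window_end)
  tag_len <- locus$end - locus$start
  if (locus$strand == "+") {
    mstart <- locus$start - win$window_start + 1L
  } else {
    seqs <- reverse_complement(seqs)
    mstart <- win$window_end - locus$end + 1L
  }
  win |>
    dplyr::mutate(strand = locus$strand,
                  precursor_seq = seqs,
                  mature_start = as.integer(mstart),
                  mature_end = as.integer(mstart + tag_len - 1L)) |>
    dplyr::arrange(.data$window_end - .data$window_start)
}

#' Precursor acceptance criteria
#'
#' The MFEI threshold of 0.70 is the study's stated rule; the structural
#' limits follow standard plant-miRNA annotation practice and are
#' configurable.
#'
#' @param min_mfei Minimum precursor MFEI (default 0.70).
#' @param min_paired Minimum paired mature bases in the hairpin
#'   (default 14).
#' @param max_star_mismatch Maximum unpaired mature positions against the
#'   star region (default 4).
#' @param max_bulge Maximum asymmetric bulge in the mature/star duplex
#'   (default 2).
#' @param min_loop Minimum terminal loop size in nt (default 3).
#' @return A list of class `precursor_criteria`.
#' @export
precursor_criteria <- function(min_mfei = 0.70, min_paired = 14L,
                               max_star_mismatch = 4L, max_bulge = 2L,
                               min_loop = 3L) {
  structure(list(min_mfei = min_mfei, min_paired = as.integer(min_paired),
                 max_star_mismatch = as.integer(max_star_mismatch),
                 max_bulge = as.integer(max_bulge),
                 min_loop = as.integer(min_loop)),
            class = "precursor_criteria")
}

#' Evaluate one precursor window
#'
#' Folds the window and applies the acceptance rules in order: (a) mature
#' entirely on one arm, (b) enough mature bases paired, (c) star duplex
#' with limited mismatches and bulges, (d) MFEI at least the threshold,
#' (e) terminal loop large enough. The verdict records the first failed
#' rule.
#'
#' @param window_seq Precursor candidate sequence (strand-resolved DNA or
#'   RNA).
#' @param mature_span `c(start, end)` of the mature tag within the window
#'   (1-based inclusive).
#' @param model An [energy_model()].
#' @param criteria A [precursor_criteria()].
#' @return A one-row tibble with the fold statistics (`mfe`, `gc_percent`,
#'   `amfe`, `mfei`), hairpin geometry (`arm`, `n_paired`, `n_unpaired`,
#'   `max_asym_bulge`, `terminal_loop`, `star_start`, `star_end`),
#'   `accepted`, `reason`, and the `structure` (list column).
#' @export
evaluate_candidate <- function(window_seq, mature_span,
                               model = energy_model(),
                               criteria = precursor_criteria()) {
  struct <- fold_mfe(window_seq, model)
  len <- nchar(window_seq)
  gc <- gc_content(window_seq)
  mfei_val <- if (gc > 0) mfei(struct$mfe, len, gc) else 0
  feat <- hairpin_features(struct, mature_span)

  reason <- NA_character_
  if (feat$arm %in% c("loop-spanning", "unpaired")) {
    reason <- "loop overlap"
  } else if (feat$n_paired < criteria$min_paired) {
    reason <- sprintf("paired mature bases < %d", criteria$min_paired)
  } else if (feat$n_unpaired > criteria$max_star_mismatch) {
    reason <- sprintf("star mismatches > %d", criteria$max_star_mismatch)
  } else if (!is.na(feat$max_asym_bulge) &&
             feat$max_asym_bulge > criteria$max_bulge) {
    reason <- sprintf("asymmetric bulge > %d", criteria$max_bulge)
  } else if (mfei_val < criteria$min_mfei) {
    reason <- sprintf("MFEI < %.2f", criteria$min_mfei)
  } else if (is.na(feat$terminal_loop) ||
             feat$terminal_loop < criteria$min_loop) {
    reason <- sprintf("terminal loop < %d nt", criteria$min_loop)
  }

  tibble(precursor_seq = toupper(to_dna(window_seq)),
         length = len,
         mfe = struct$mfe,
         gc_percent = gc,
         amfe = amfe(struct$mfe, len),
         mfei = mfei_val,
         arm = feat$arm,
         n_paired = feat$n_paired,
         n_unpaired = feat$n_unpaired,
         max_asym_bulge = feat$max_asym_bulge,
         terminal_loop = feat$terminal_loop,
         star_start = feat$star_span[1],
         star_end = feat$star_span[2],
         mature_start = mature_span[1],
         mature_end = mature_span[2],
         accepted = is.na(reason),
         reason = reason,
         structure = list(struct))
}

#' Call novel miRNAs from homology-unexplained tags
#'
#' Maps tags to the contigs, excises precursor windows on the flank grid,
#' folds and evaluates each, keeps per tag the best accepted candidate
#' (highest MFEI, ties to the shortest window), and names the calls
#' `cci-miRN1 ...` in order of descending read count (ties by sequence)
#' with the arm suffix taken from the hairpin geometry.
#'
#' @param tags Tag tibble (the conserved-unexplained set).
#' @param contigs Contig tibble.
#' @param model An [energy_model()].
#' @param criteria A [precursor_criteria()].
#' @param max_loci Passed to [map_tags()].
#' @param flanks Passed to [excise_windows()].
#' @return A tibble of novel miRNAs with columns `name`, `sequence` (RNA),
#'   `length`, `read_count`, `strand`, `mfei`, plus locus and precursor
#'   details; the full candidate evaluations (including rejections) are in
#'   `attr(, "candidates")`.
#' @export
call_novel <- function(tags, contigs, model = energy_model(),
                       criteria = precursor_criteria(),
                       max_loci = 20L,
                       flanks = c(0L, 20L, 50L, 100L, 150L, 250L)) {
  empty <- tibble(name = character(), sequence = character(),
                  length = integer(), read_count = integer(),
                  strand = character(), mfei = numeric(),
                  contig_id = character(), precursor_seq = character(),
                  arm = character())
  loci <- map_tags(tags, contigs, max_loci)
  if (nrow(loci) == 0L) {
    attr(empty, "candidates") <- tibble()
    return(empty)
  }
  cand <- purrr::map(seq_len(nrow(loci)), function(i) {
    locus <- loci[i, ]
    wins <- excise_windows(locus, contigs, flanks)
    purrr::map(seq_len(nrow(wins)), function(w) {
      ev <- evaluate_candidate(wins$precursor_seq[w],
                               c(wins$mature_start[w], wins$mature_end[w]),
                               model, criteria)
      dplyr::bind_cols(
        tibble(sequence = locus$sequence, count = locus$count,
               contig_id = locus$contig_id, locus_start = locus$start,
               locus_end = locus$end, strand = locus$strand,
               window_start = wins$window_start[w],
               window_end = wins$window_end[w]),
        ev)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  best <- cand |>
    dplyr::filter(.data$accepted) |>
    dplyr::group_by(.data$sequence) |>
    dplyr::arrange(dplyr::desc(.data$mfei), .data$length,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::arrange(dplyr::desc(.data$count), .data$sequence)

  # one call per hairpin locus: tags whose chosen precursor windows overlap
  # on a contig (e.g. mature and star arms of the same stem-loop) collapse
  # to the best-supported tag
  if (nrow(best) > 1L) {
    best <- best |>
      dplyr::group_by(.data$contig_id) |>
      dplyr::arrange(.data$window_start, .by_group = TRUE) |>
      dplyr::mutate(cluster = cumsum(
        dplyr::lag(cummax(.data$window_end), default = -1L) <=
          .data$window_start)) |>
      dplyr::group_by(.data$contig_id, .data$cluster) |>
      dplyr::arrange(dplyr::desc(.data$count), .data$sequence,
                     .by_group = TRUE) |>
      dplyr::slice(1) |>
      dplyr::ungroup() |>
      dplyr::select(-"cluster") |>
      dplyr::arrange(dplyr::desc(.data$count), .data$sequence)
  }

  if (nrow(best) == 0L) {
    attr(empty, "candidates") <- cand
    return(empty)
  }
  out <- best |>
    dplyr::mutate(name = sprintf("cci-miRN%d-%s", dplyr::row_number(),
                                 .data$arm),
                  mirna_sequence = to_rna(.data$sequence),
                  read_count = .data$count,
                  mfei = round(.data$mfei, 2)) |>
    dplyr::select(name, sequence = "mirna_sequence", length = "length",
                  read_count = "read_count", strand = "strand",
                  mfei = "mfei", contig_id = "contig_id",
                  locus_start = "locus_start", locus_end = "locus_end",
                  precursor_seq = "precursor_seq", arm = "arm",
                  mature_start = "mature_start", mature_end = "mature_end",
                  star_start = "star_start", star_end = "star_end")
  out$length <- nchar(out$sequence)
  attr(out, "candidates") <- cand
  out
}
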