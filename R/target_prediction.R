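# Plant-style miRNA target prediction: position-weighted expectation
# scoring of antiparallel miRNA:mRNA duplexes, transcript scanning with at
# most one bulged gap, and intermolecular duplex MFE.

#' Target-scoring scheme
#'
#' Penalty constants of the expectation score, following the published
#' plant-target-prediction conventions: mismatch 1, G:U wobble 0.5, gap 2,
#' penalties doubled within the seed (miRNA positions 2-13 from the 5'
#' end), sites reported up to expectation 5.
#'
#' @param mismatch,wobble,gap Per-position penalties.
#' @param seed_start,seed_end 1-based seed bounds on the miRNA.
#' @param seed_multiplier Penalty multiplier within the seed.
#' @param cutoff Maximum reported expectation.
#' @param max_gaps Maximum bulged gaps per site (0 or 1).
#' @return A list of class `target_scheme`.
#' @export
target_scheme <- function(mismatch = 1, wobble = 0.5, gap = 2,
                          seed_start = 2L, seed_end = 13L,
                          seed_multiplier = 2, cutoff = 5, max_gaps = 1L) {
  stopifnot(mismatch >= 0, wobble >= 0, gap >= 0, seed_start <= seed_end,
            max_gaps %in% c(0L, 1L))
  structure(list(mismatch = mismatch, wobble = wobble, gap = gap,
                 seed_start = as.integer(seed_start),
                 seed_end = as.integer(seed_end),
                 seed_multiplier = seed_multiplier,
                 cutoff = cutoff, max_gaps = as.integer(max_gaps)),
            class = "target_scheme")
}

#' Keep query miRNAs with enough read support
#'
#' Filters a tibble carrying read counts to entries sequenced at least
#' `min_copies` times (inclusive), the usual copy-number gate before target
#' prediction.
#'
#' @param x Tibble with a `count` or `read_count` column.
#' @param min_copies Minimum copy number (default 5).
#' @return The filtered tibble.
#' @export
filter_queries <- function(x, min_copies = 5L) {
  col <- if ("count" %in% names(x)) "count" else "read_count"
  stopifnot(col %in% names(x))
  x[x[[col]] >= min_copies, ]
}

# Is (a, b) a Watson-Crick pair / a G:U wobble? RNA alphabet.
is_complement <- function(a, b) {
  paste0(a, b) %in% c("AU", "UA", "GC", "CG")
}
is_wobble <- function(a, b) {
  paste0(a, b) %in% c("GU", "UG")
}

#' Score an aligned miRNA:target duplex
#'
#' Inputs are the two strands of the duplex in antiparallel alignment:
#' the miRNA 5'-3' and the target site 3'-5', equal length, possibly
#' containing `-` for bulged gaps. Each column contributes 0 for a
#' Watson-Crick pair, `wobble` for G:U, `mismatch` otherwise, and `gap`
#' when either strand is gapped; contributions are multiplied by
#' `seed_multiplier` when the governing miRNA position (for a gap column,
#' the next miRNA base) lies within the seed.
#'
#' @param mirna Aligned miRNA strand, 5'-3' (U or T).
#' @param site Aligned target strand, 3'-5' (U or T).
#' @param scheme A [target_scheme()].
#' @return The expectation score (lower = better complementarity).
#' @examples
#' score_duplex("UGACAGAAGAGAGUGAGCACA",
#'              reverse_string(to_rna(reverse_complement("UGACAGAAGAGAGUGAGCACA"))))
#' @export
score_duplex <- function(mirna, site, scheme = target_scheme()) {
  m <- strsplit(toupper(to_rna(mirna)), "")[[1]]
  s <- strsplit(toupper(to_rna(site)), "")[[1]]
  if (length(m) == 0L || length(s) == 0L) {
    stop("empty duplex strand", call. = FALSE)
  }
  if (length(m) != length(s)) {
    stop("aligned duplex strands must have equal length", call. = FALSE)
  }
  total <- 0
  mir_pos <- 0L
  for (i in seq_along(m)) {
    if (m[i] != "-") mir_pos <- mir_pos + 1L
    governing <- if (m[i] == "-") mir_pos + 1L else mir_pos
    pen <- if (m[i] == "-" || s[i] == "-") {
      scheme$gap
    } else if (is_complement(m[i], s[i])) {
      0
    } else if (is_wobble(m[i], s[i])) {
      scheme$wobble
    } else {
      scheme$mismatch
    }
    if (governing >= scheme$seed_start && governing <= scheme$seed_end) {
      pen <- pen * scheme$seed_multiplier
    }
    total <- total + pen
  }
  total
}

#' Reverse a string
#'
#' @param x Character vector.
#' @return Each string reversed.
#' @export
reverse_string <- function(x) {
  vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""),
         character(1), USE.NAMES = FALSE)
}

# Alignment pattern symbols: | pair, o wobble, . mismatch, - gap.
alignment_pattern <- function(mirna, site) {
  m <- strsplit(mirna, "")[[1]]; s <- strsplit(site, "")[[1]]
  ifelse(m == "-" | s == "-", "-",
         ifelse(is_complement(m, s), "|",
                ifelse(is_wobble(m, s), "o", "."))) |>
    paste(collapse = "")
}

# Vectorized evaluation of one alignment template over all window starts.
# A template fixes the aligned miRNA characters, the per-column governing
# miRNA position, and the per-column transcript offset (NA for a site gap);
# expectations for every start come from one penalty-matrix colSums.
scan_template <- function(mir_aln, governing, offsets, tr_chars, starts,
                          scheme) {
  if (length(starts) == 0L) return(numeric())
  seed_mult <- ifelse(governing >= scheme$seed_start &
                        governing <= scheme$seed_end,
                      scheme$seed_multiplier, 1)
  pen <- matrix(0, nrow = length(mir_aln), ncol = length(starts))
  for (i in seq_along(mir_aln)) {
    if (mir_aln[i] == "-" || is.na(offsets[i])) {
      pen[i, ] <- scheme$gap
    } else {
      bases <- tr_chars[starts + offsets[i]]
      duo <- paste0(mir_aln[i], bases)
      pen[i, ] <- ifelse(duo %in% c("AU", "UA", "GC", "CG"), 0,
                         ifelse(duo %in% c("GU", "UG"), scheme$wobble,
                                scheme$mismatch))
    }
    pen[i, ] <- pen[i, ] * seed_mult[i]
  }
  colSums(pen)
}

# All candidate alignments of a miRNA over a transcript, as a tibble with
# start, end, expectation, n_gaps and template descriptors.
scan_candidates <- function(mir, tr_chars, scheme) {
  mirc <- strsplit(mir, "")[[1]]
  m <- length(mirc)
  L <- length(tr_chars)
  out <- list()
  push <- function(starts, end_off, exps, n_gaps, gap_in, gap_pos) {
    if (length(starts) == 0L) return(invisible())
    out[[length(out) + 1L]] <<- tibble(
      start = starts, end = starts + end_off, expectation = exps,
      n_gaps = n_gaps, gap_in = gap_in, gap_pos = gap_pos)
  }
  # ungapped: column i pairs transcript position s + m - i
  starts <- seq_len(max(0L, L - m + 1L))
  push(starts, m - 1L,
       scan_template(mirc, seq_len(m), m - seq_len(m), tr_chars, starts,
                     scheme),
       0L, NA_character_, NA_integer_)
  if (scheme$max_gaps >= 1L && m >= 3L) {
    # gap in the site: m - 1 transcript bases, '-' at column g
    starts <- seq_len(max(0L, L - m + 2L))
    for (g in 2L:(m - 1L)) {
      offs <- ifelse(seq_len(m) < g, m - 1L - seq_len(m),
                     ifelse(seq_len(m) == g, NA_integer_, m - seq_len(m)))
      push(starts, m - 2L,
           scan_template(mirc, seq_len(m), offs, tr_chars, starts, scheme),
           1L, "site", g)
    }
    # gap in the miRNA: m + 1 transcript bases, '-' in the miRNA at column g
    starts <- seq_len(max(0L, L - m))
    for (g in 2L:m) {
      mir_aln <- append(mirc, "-", after = g - 1L)
      governing <- ifelse(seq_len(m + 1L) < g, seq_len(m + 1L),
                          ifelse(seq_len(m + 1L) == g, g, seq_len(m + 1L) - 1L))
      offs <- m + 1L - seq_len(m + 1L)
      push(starts, m,
           scan_template(mir_aln, governing, offs, tr_chars, starts, scheme),
           1L, "mirna", g)
    }
  }
  dplyr::bind_rows(out)
}

# Reconstruct the aligned strings of one candidate row.
candidate_alignment <- function(mir, tr_chars, row) {
  m <- nchar(mir)
  if (row$n_gaps == 0L) {
    list(mirna_aligned = mir,
         site_aligned = paste(rev(tr_chars[row$start:row$end]),
                              collapse = ""))
  } else if (row$gap_in == "site") {
    site <- append(rev(tr_chars[row$start:row$end]), "-",
                   after = row$gap_pos - 1L)
    list(mirna_aligned = mir, site_aligned = paste(site, collapse = ""))
  } else {
    mir_aln <- append(strsplit(mir, "")[[1]], "-",
                      after = row$gap_pos - 1L)
    list(mirna_aligned = paste(mir_aln, collapse = ""),
         site_aligned = paste(rev(tr_chars[row$start:row$end]),
                              collapse = ""))
  }
}

#' Scan a transcript for miRNA target sites
#'
#' Evaluates every ungapped window and every single-gap variant of the
#' miRNA against the transcript, keeps alignments with expectation at or
#' below the scheme cutoff, and reports the best site per cluster of
#' overlapping candidates (lowest expectation; ties to the leftmost,
#' then ungapped). Sites are in deterministic (position) order.
#'
#' @param mirna miRNA sequence, 5'-3' (U or T).
#' @param transcript Transcript sequence, 5'-3'.
#' @param scheme A [target_scheme()].
#' @return A tibble with columns `start`, `end` (1-based inclusive on the
#'   transcript), `expectation`, `n_gaps`, `mirna_aligned`, `site_aligned`,
#'   `pattern`, `inhibition` (`"cleavage"` or `"translation"` from central
#'   positions 9-11).
#' @export
scan_transcript <- function(mirna, transcript, scheme = target_scheme()) {
  mir <- toupper(to_rna(mirna))
  tr_chars <- strsplit(toupper(to_rna(transcript)), "")[[1]]
  m <- nchar(mir)
  stopifnot(length(tr_chars) >= m)
  empty <- tibble(start = integer(), end = integer(),
                  expectation = numeric(), n_gaps = integer(),
                  mirna_aligned = character(), site_aligned = character(),
                  pattern = character(), inhibition = character())
  cand <- scan_candidates(mir, tr_chars, scheme)
  cand <- cand[cand$expectation <= scheme$cutoff, ]
  if (nrow(cand) == 0L) return(empty)
  aln <- purrr::map(seq_len(nrow(cand)),
                    \(i) candidate_alignment(mir, tr_chars, cand[i, ]))
  cand$mirna_aligned <- purrr::map_chr(aln, "mirna_aligned")
  cand$site_aligned <- purrr::map_chr(aln, "site_aligned")
  cand <- dplyr::select(cand, -"gap_in", -"gap_pos")
  cand <- dplyr::arrange(cand, .data$start, .data$end, .data$n_gaps)
  # cluster transitively overlapping candidates, keep the best per cluster
  cl <- integer(nrow(cand))
  cur <- 0L; cur_end <- -1L
  for (i in seq_len(nrow(cand))) {
    if (cand$start[i] > cur_end) cur <- cur + 1L
    cl[i] <- cur
    cur_end <- max(cur_end, cand$end[i])
  }
  best <- cand |>
    dplyr::mutate(cluster = cl) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::arrange(.data$expectation, .data$start, .data$n_gaps,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select(-"cluster") |>
    dplyr::arrange(.data$start)
  best |>
    dplyr::mutate(
      pattern = purrr::map2_chr(.data$mirna_aligned, .data$site_aligned,
                                alignment_pattern),
      inhibition = purrr::map_chr(.data$pattern, function(pat) {
        central <- substr(pat, 9, 11)
        if (grepl("[.o-]", central)) "translation" else "cleavage"
      }))
}

#' Minimum free energy of an intermolecular miRNA:target duplex
#'
#' Sums nearest-neighbour stacking energies over adjacent paired columns of
#' the antiparallel duplex (no intramolecular structure, no loop terms);
#' gap and mismatch columns interrupt stacking. The result is clamped at 0
#' (an unpairable duplex has no stabilising energy).
#'
#' @param mirna Aligned miRNA strand, 5'-3'.
#' @param site Aligned target strand, 3'-5' (as in [score_duplex()]).
#' @param model An [energy_model()].
#' @return Duplex MFE in kcal/mol (<= 0).
#' @export
duplex_mfe <- function(mirna, site, model = energy_model()) {
  m <- strsplit(toupper(to_rna(mirna)), "")[[1]]
  s <- strsplit(toupper(to_rna(site)), "")[[1]]
  stopifnot(length(m) == length(s), length(m) > 0L)
  codes <- vapply(seq_along(m), function(i) {
    if (m[i] == "-" || s[i] == "-") return(NA_integer_)
    pc <- pair_code_r(m[i], s[i])
    if (is.na(pc)) NA_integer_ else pc
  }, integer(1))
  total <- 0L
  for (i in seq_len(length(codes) - 1L)) {
    if (!is.na(codes[i]) && !is.na(codes[i + 1L])) {
      total <- total + model$stack[codes[i], codes[i + 1L]]
    }
  }
  min(0, total / 10)
}

#' Predict targets of a set of miRNAs over a transcript set
#'
#' Applies the copy-number gate, scans every miRNA against every
#' transcript, and annotates each reported site with its duplex MFE.
#'
#' @param mirnas Tibble with columns `name` (or `assigned_name`),
#'   `sequence`, and a count column for [filter_queries()].
#' @param transcripts Transcript tibble (`seq_id`, `sequence`).
#' @param scheme A [target_scheme()].
#' @param model An [energy_model()] for duplex energies.
#' @param min_copies Copy-number gate (default 5); set to 0 to disable.
#' @return A site tibble: `mirna_id`, `transcript_id`, `start`, `end`,
#'   `expectation`, `duplex_mfe`, `n_gaps`, `pattern`, `inhibition`.
#' @export
predict_targets <- function(mirnas, transcripts, scheme = target_scheme(),
                            model = energy_model(), min_copies = 5L) {
  name_col <- intersect(c("name", "assigned_name", "mirna_id"),
                        names(mirnas))[1]
  stopifnot(!is.na(name_col), "sequence" %in% names(mirnas))
  if (min_copies > 0L) mirnas <- filter_queries(mirnas, min_copies)
  sites <- purrr::map(seq_len(nrow(mirnas)), function(i) {
    purrr::map(seq_len(nrow(transcripts)), function(j) {
      hits <- scan_transcript(mirnas$sequence[i], transcripts$sequence[j],
                              scheme)
      if (nrow(hits) == 0L) return(NULL)
      dplyr::mutate(hits,
                    mirna_id = mirnas[[name_col]][i],
                    transcript_id = transcripts$seq_id[j],
                    duplex_mfe = purrr::map2_dbl(.data$mirna_aligned,
                                                 .data$site_aligned,
                                                 duplex_mfe, model = model))
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  if (is.null(sites) || nrow(sites) == 0L) {
    return(tibble(mirna_id = character(), transcript_id = character(),
                  start = integer(), end = integer(),
                  expectation = numeric(), duplex_mfe = numeric(),
                  n_gaps = integer(), pattern = character(),
                  inhibition = character()))
  }
  dplyr::select(sites, "mirna_id", "transcript_id", "start", "end",
                "expectation", "duplex_mfe", "n_gaps", "pattern",
                "inhibition") |>
    dplyr::arrange(.data$mirna_id, .data$transcript_id, .data$start)
}
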