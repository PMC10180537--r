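# Conserved-miRNA classification: equal-length mismatch-tolerant matching of
# unique tags against a mature plant miRNA reference, `cci-` naming and
# family summaries.

#' Hamming distance between equal-length sequences
#'
#' Counts positions where two sequences differ, after U/T unification.
#' Lengths are never padded: unequal lengths are an error.
#'
#' @param a,b Nucleotide strings of equal length.
#' @return Integer mismatch count.
#' @examples
#' hamming("TGACAG", "TGACAC")
#' hamming("AU", "AT")   # 0: U and T are equivalent
#' @export
hamming <- function(a, b) {
  a <- toupper(to_dna(a)); b <- toupper(to_dna(b))
  if (nchar(a) != nchar(b)) {
    stop("hamming() requires equal-length sequences", call. = FALSE)
  }
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Mismatch counts between one tag and all equal-length db sequences at once.
mismatches_to_db <- function(tag, db_seqs) {
  n <- nchar(tag)
  same_len <- nchar(db_seqs) == n
  out <- rep(NA_integer_, length(db_seqs))
  if (!any(same_len)) return(out)
  tag_m <- matrix(utf8ToInt(tag), nrow = sum(same_len), ncol = n, byrow = TRUE)
  db_m <- matrix(unlist(lapply(db_seqs[same_len], utf8ToInt)),
                 nrow = sum(same_len), ncol = n, byrow = TRUE)
  out[same_len] <- as.integer(rowSums(tag_m != db_m))
  out
}

#' Match unique tags against a mature miRNA reference
#'
#' For each tag, finds equal-length reference entries within
#' `max_mismatches` (Hamming distance, U/T unified) and keeps the hit with
#' the fewest mismatches; ties are broken by the lexicographically smallest
#' reference id, so the classification does not depend on reference order.
#' Tags with no qualifying reference are omitted.
#'
#' @param tags Unique-tag tibble (`sequence`, `length`, `count`).
#' @param reference Mature reference tibble with columns `mirbase_id`,
#'   `sequence` (e.g. [read_fasta()] output renamed, or see
#'   [parse_mirbase_id()]).
#' @param max_mismatches Maximum Hamming distance (default 1, the usual
#'   single-mismatch homology rule).
#' @return A tibble of hits: tag columns plus `mirbase_id`, `ref_sequence`,
#'   `mismatches`, `species_prefix`, `family`, `arm`.
#' @export
match_conserved <- function(tags, reference, max_mismatches = 1L) {
  stopifnot(nrow(reference) > 0L)
  ref_seqs <- toupper(to_dna(reference$sequence))
  hit_rows <- purrr::map(seq_len(nrow(tags)), function(i) {
    mm <- mismatches_to_db(tags$sequence[i], ref_seqs)
    ok <- which(!is.na(mm) & mm <= max_mismatches)
    if (length(ok) == 0L) return(NULL)
    best_mm <- min(mm[ok])
    cand <- ok[mm[ok] == best_mm]
    best <- cand[order(reference$mirbase_id[cand])][1]
    tibble(tag_row = i, ref_row = best, mismatches = best_mm)
  })
  hits <- dplyr::bind_rows(hit_rows)
  if (is.null(hits) || nrow(hits) == 0L) {
    return(tibble(sequence = character(), length = integer(),
                  count = integer(), mirbase_id = character(),
                  ref_sequence = character(), mismatches = integer(),
                  species_prefix = character(), family = character(),
                  arm = character()))
  }
  out <- dplyr::bind_cols(
    tags[hits$tag_row, ],
    tibble(mirbase_id = reference$mirbase_id[hits$ref_row],
           ref_sequence = ref_seqs[hits$ref_row],
           mismatches = hits$mismatches)
  )
  parsed <- parse_mirbase_id(out$mirbase_id)
  dplyr::bind_cols(out, parsed[, c("species_prefix", "family", "arm")])
}

#' Assign species-local `cci-` names to conserved hits
#'
#' The assigned name is `"cci-"` plus the reference id with its species
#' prefix removed. When distinct tag sequences collide on the same local
#' name (same local name from different species), the lowest-mismatch hit
#' keeps the plain name and subsequent distinct sequences get a numeric
#' `"-<k>"` suffix.
#'
#' @param hits Hit tibble from [match_conserved()].
#' @return `hits` with an `assigned_name` column, ordered by descending read
#'   count then sequence.
#' @export
assign_names <- function(hits) {
  if (nrow(hits) == 0L) {
    return(dplyr::mutate(hits, assigned_name = character()))
  }
  local <- sub("^[A-Za-z]{3,4}-", "", hits$mirbase_id)
  hits <- hits |>
    dplyr::mutate(assigned_name = paste0("cci-", local)) |>
    dplyr::arrange(.data$mismatches, dplyr::desc(.data$count), .data$sequence)
  dup_k <- stats::ave(seq_len(nrow(hits)), hits$assigned_name,
                      FUN = seq_along) - 1L
  suffix <- ifelse(dup_k > 0L, paste0("-", dup_k), "")
  hits$assigned_name <- paste0(hits$assigned_name, suffix)
  dplyr::arrange(hits, dplyr::desc(.data$count), .data$sequence)
}

#' Summarise conserved hits by miRNA family
#'
#' One row per family with the number of distinct member tags and the total
#' read count, sorted by member count descending (ties by family name).
#'
#' @param hits Named hit tibble.
#' @return A tibble with columns `family`, `member_count`,
#'   `total_read_count`.
#' @export
summarize_families <- function(hits) {
  if (nrow(hits) == 0L) {
    return(tibble(family = character(), member_count = integer(),
                  total_read_count = integer()))
  }
  hits |>
    dplyr::group_by(.data$family) |>
    dplyr::summarise(member_count = dplyr::n_distinct(.data$sequence),
                     total_read_count = sum(.data$count),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$member_count), .data$family)
}

#' Classify tags as conserved miRNAs and split off the remainder
#'
#' Convenience wrapper: [match_conserved()] + [assign_names()], returning
#' both the named hits and the tags left unexplained by homology (the input
#' to novel-miRNA discovery).
#'
#' @inheritParams match_conserved
#' @return A list with elements `hits` (named hit tibble) and `unmatched`
#'   (tag tibble).
#' @export
classify_conserved <- function(tags, reference, max_mismatches = 1L) {
  hits <- match_conserved(tags, reference, max_mismatches)
  hits <- assign_names(hits)
  unmatched <- tags[!tags$sequence %in% hits$sequence, ]
  list(hits = hits, unmatched = unmatched)
}
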