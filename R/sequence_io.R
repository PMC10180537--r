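#' @useDynLib mirseedling, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
#' @import tibble
NULL

# Internal alphabet is DNA: U is converted to T on ingest, and mature miRNA
# sequences are reported back in RNA in novel-miRNA outputs.

#' Convert between DNA and RNA alphabets
#'
#' `to_dna()` replaces U with T (the package's internal alphabet);
#' `to_rna()` replaces T with U for reporting mature miRNA sequences.
#'
#' @param x Character vector of nucleotide sequences.
#' @return Character vector of the same length.
#' @examples
#' to_dna("UGACAG")
#' to_rna("TGACAG")
#' @export
to_dna <- function(x) chartr("Uu", "Tt", x)

#' @rdname to_dna
#' @export
to_rna <- function(x) chartr("Tt", "Uu", x)

check_alphabet <- function(x, arg = "sequence") {
  bad <- grepl("[^ACGTUN]", toupper(x))
  if (any(bad)) {
    stop(sprintf("%s contains non-nucleotide characters (first offender: '%s')",
                 arg, x[which(bad)[1]]), call. = FALSE)
  }
  invisible(x)
}

#' Read a FASTQ file of small-RNA reads
#'
#' Parses a Phred+33 four-line-per-record FASTQ file into a tibble. Sequences
#' are uppercased and U converted to T; qualities are kept as the raw encoded
#' string (use [phred_scores()] to decode). Malformed records raise an error
#' naming the offending line.
#'
#' @param path Path to an uncompressed FASTQ file.
#' @return A tibble with columns `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  n <- length(lines)
  if (n == 0L) {
    return(tibble(read_id = character(), sequence = character(),
                  quality = character()))
  }
  if (n %% 4L != 0L) {
    stop(sprintf("truncated FASTQ: %d lines is not a multiple of 4 (ends near line %d)",
                 n, n), call. = FALSE)
  }
  idx <- seq(1L, n, by = 4L)
  heads <- lines[idx]
  seqs <- toupper(to_dna(lines[idx + 1L]))
  plus <- lines[idx + 2L]
  quals <- lines[idx + 3L]
  bad_head <- !startsWith(heads, "@")
  if (any(bad_head)) {
    stop(sprintf("malformed FASTQ header at line %d (must start with '@')",
                 idx[which(bad_head)[1]]), call. = FALSE)
  }
  bad_plus <- !startsWith(plus, "+")
  if (any(bad_plus)) {
    stop(sprintf("malformed FASTQ separator at line %d (must start with '+')",
                 idx[which(bad_plus)[1]] + 2L), call. = FALSE)
  }
  bad_len <- nchar(quals) != nchar(seqs)
  if (any(bad_len)) {
    stop(sprintf("quality length differs from sequence length at line %d",
                 idx[which(bad_len)[1]] + 3L), call. = FALSE)
  }
  check_alphabet(seqs, "FASTQ sequence")
  tibble(read_id = sub("^@", "", heads), sequence = seqs, quality = quals)
}

#' Write small-RNA reads to FASTQ
#'
#' @param reads Tibble with columns `read_id`, `sequence`, `quality`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "sequence", "quality") %in% names(reads)))
  out <- character(4L * nrow(reads))
  out[seq(1L, length.out = nrow(reads), by = 4L)] <- paste0("@", reads$read_id)
  out[seq(2L, length.out = nrow(reads), by = 4L)] <- reads$sequence
  out[seq(3L, length.out = nrow(reads), by = 4L)] <- "+"
  out[seq(4L, length.out = nrow(reads), by = 4L)] <- reads$quality
  writeLines(out, path)
  invisible(path)
}

#' Decode Phred+33 quality strings
#'
#' @param quality Character vector of encoded quality strings.
#' @return List of integer vectors of per-base Phred scores.
#' @export
phred_scores <- function(quality) {
  lapply(quality, function(q) utf8ToInt(q) - 33L)
}

#' Read a FASTA file
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] returning a tibble.
#' Wrapped sequence lines are concatenated; header order is preserved;
#' duplicate ids are an error.
#'
#' @param path Path to an uncompressed FASTA file.
#' @return A tibble with columns `seq_id`, `sequence`, `description`.
#' @export
read_fasta <- function(path) {
  if (file.size(path) == 0) {
    return(tibble(seq_id = character(), sequence = character(),
                  description = character()))
  }
  ss <- Biostrings::readBStringSet(path, format = "fasta")
  headers <- names(ss)
  seq_id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  dup <- duplicated(seq_id)
  if (any(dup)) {
    stop(sprintf("duplicate FASTA id: '%s'", seq_id[which(dup)[1]]),
         call. = FALSE)
  }
  tibble(seq_id = seq_id,
         sequence = unname(toupper(to_dna(as.character(ss)))),
         description = description)
}

#' Write sequences to FASTA
#'
#' @param seqs Tibble with columns `seq_id`, `sequence` and optionally
#'   `description`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(all(c("seq_id", "sequence") %in% names(seqs)))
  headers <- seqs$seq_id
  if ("description" %in% names(seqs)) {
    has_desc <- !is.na(seqs$description) & nzchar(seqs$description)
    headers[has_desc] <- paste(headers[has_desc], seqs$description[has_desc])
  }
  ss <- Biostrings::BStringSet(seqs$sequence)
  names(ss) <- headers
  Biostrings::writeXStringSet(ss, path, format = "fasta")
  invisible(path)
}

#' Collapse reads into counted unique tags
#'
#' Deduplicates read sequences into unique tags with occurrence counts, the
#' unit in which small-RNA libraries are summarised. The sum of tag counts
#' always equals the number of input reads. Tags are ordered by descending
#' count, ties broken by sequence, so downstream reports are deterministic.
#'
#' @param reads Tibble with a `sequence` column (e.g. from [read_fastq()]).
#' @return A tibble with columns `sequence`, `length`, `count`.
#' @export
collapse_reads <- function(reads) {
  if (nrow(reads) == 0L) {
    return(tibble(sequence = character(), length = integer(),
                  count = integer()))
  }
  reads |>
    dplyr::count(.data$sequence, name = "count") |>
    dplyr::mutate(length = nchar(.data$sequence)) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$sequence) |>
    dplyr::select("sequence", "length", "count")
}

#' Parse miRBase-style mature miRNA identifiers
#'
#' Splits ids such as `stu-miR156d-3p` into species prefix, canonical family
#' (`MIR` + the leading number) and precursor arm. Ids lacking a `-5p`/`-3p`
#' suffix get arm `"unknown"`; unparseable ids get family `"NA"`.
#'
#' @param mirbase_id Character vector of identifiers.
#' @return A tibble with columns `mirbase_id`, `species_prefix`, `family`,
#'   `arm`.
#' @examples
#' parse_mirbase_id(c("stu-miR156d-3p", "ppt-miR894", "not-an-id"))
#' @export
parse_mirbase_id <- function(mirbase_id) {
  m <- regmatches(mirbase_id,
                  regexec("^([A-Za-z]{3,4})-[mM][iI][rR]([0-9]+)([A-Za-z]*)((?:[.-][0-9A-Za-z.]+)*)$",
                          mirbase_id))
  parse_one <- function(id, g) {
    if (length(g) == 0L) {
      return(list(species_prefix = NA_character_, family = "NA",
                  arm = "unknown"))
    }
    arm <- if (grepl("-5p$", id)) "5p" else if (grepl("-3p$", id)) "3p" else "unknown"
    list(species_prefix = tolower(g[2]), family = paste0("MIR", g[3]),
         arm = arm)
  }
  parsed <- purrr::map2(mirbase_id, m, parse_one)
  tibble(mirbase_id = mirbase_id,
         species_prefix = purrr::map_chr(parsed, "species_prefix"),
         family = purrr::map_chr(parsed, "family"),
         arm = purrr::map_chr(parsed, "arm"))
}

#' Reverse complement of nucleotide sequences
#'
#' U is treated as T; the operation is an involution. Characters outside
#' `{A,C,G,T,U,N}` are an error.
#'
#' @param sequence Character vector of nucleotide sequences.
#' @return Character vector of reverse complements (DNA alphabet).
#' @export
reverse_complement <- function(sequence) {
  x <- toupper(to_dna(sequence))
  check_alphabet(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Read and write unique-tag tables
#'
#' Tag tables are TSV files with columns `sequence`, `length`, `count`.
#'
#' @param path File path.
#' @return `read_tag_table()` returns a tibble; `write_tag_table()` returns
#'   `path` invisibly.
#' @export
read_tag_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    sequence = readr::col_character(),
    length = readr::col_integer(),
    count = readr::col_integer()
  ))
}

#' @rdname read_tag_table
#' @param tags Tag tibble.
#' @export
write_tag_table <- function(tags, path) {
  readr::write_tsv(tags, path)
  invisible(path)
}

#' Bundled cumin miRNA summary tables
#'
#' `cumin_conserved_table()` and `cumin_novel_table()` load the conserved and
#' novel miRNA summary tables reported for the cumin seedling small-RNA
#' library (SRA SRP376517), transcribed from the published study. The novel
#' table carries the precursor MFEI values used for the package's
#' verification statistics.
#'
#' @return A tibble. Conserved: `family`, `name`, `sequence`, `length`,
#'   `reference_mirna`, `mismatches`, `read_count`, `e_value`. Novel: `name`,
#'   `sequence`, `length`, `read_count`, `strand`, `mfei`.
#' @export
cumin_conserved_table <- function() {
  # the table's unassignable-family rows print the literal label "NA"
  readr::read_tsv(system.file("extdata", "cumin_conserved_mirnas.tsv",
                              package = "mirseedling"),
                  col_types = readr::cols(), na = character())
}

#' @rdname cumin_conserved_table
#' @export
cumin_novel_table <- function() {
  readr::read_tsv(system.file("extdata", "cumin_novel_mirnas.tsv",
                              package = "mirseedling"),
                  col_types = readr::cols())
}
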