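# Deterministic synthetic-data generator: planted stem-loop precursors,
# genomes, small-RNA read sets, ncRNA decoys and transcriptomes with
# designed target sites, each accompanied by a truth table.

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Random DNA with a target GC percentage.
random_dna <- function(n, gc = 50) {
  p <- c(gc / 200, gc / 200, (100 - gc) / 200, (100 - gc) / 200)
  paste(sample(c("G", "C", "A", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

# Random DNA without homopolymer runs longer than max_run: run-free
# sequences keep planted hairpins in a single pairing register, so the
# constructed fold is the MFE fold (a long A-run can pair against the
# star's T-run in several shifted registers and break the construction
# guarantee).
random_dna_capped <- function(n, gc = 50, max_run = 4L) {
  pat <- sprintf("(.)\\1{%d}", max_run)
  for (try in 1:100) {
    s <- random_dna(n, gc)
    if (!grepl(pat, s)) return(s)
  }
  s
}

# A base that neither Watson-Crick-pairs nor wobbles with `b` (DNA).
non_pairing_base <- function(b) {
  c(A = "C", T = "C", G = "A", C = "A")[[b]]
}

#' Construct a planted stem-loop precursor
#'
#' Builds `5' extension + arm + loop + arm + rc(extension)` where the star
#' arm is the reverse complement of the mature carrying exactly
#' `star_mismatches` pair-breaking substitutions (kept off the duplex
#' ends), the loop is pairing-poor, and the flanking extension stem
#' lengthens the hairpin. The construction guarantees a clean hairpin fold
#' with the mature fully on the requested arm.
#'
#' @param mature Mature miRNA sequence, 18-26 nt (U or T).
#' @param loop_len Terminal loop length (>= 3, default 8).
#' @param star_mismatches Substitutions planted in the star arm
#'   (default 0).
#' @param gc_target GC percentage of the random extension (default 50).
#' @param arm `"5p"` or `"3p"`: which arm carries the mature.
#' @param stem_ext Extension stem length (default 25).
#' @param seed Optional integer seed (same seed, identical sequence).
#' @return A list with `precursor` (DNA), `mature_span`, `star_span`,
#'   `loop_span` (1-based inclusive), `arm`.
#' @export
make_precursor <- function(mature, loop_len = 8L, star_mismatches = 0L,
                           gc_target = 50, arm = c("5p", "3p"),
                           stem_ext = 25L, seed = NULL) {
  arm <- match.arg(arm)
  mature <- toupper(to_dna(mature))
  m <- nchar(mature)
  if (m < 18L || m > 26L) stop("mature length must be 18-26 nt", call. = FALSE)
  if (loop_len < 3L) stop("loop_len must be >= 3", call. = FALSE)
  if (star_mismatches > m - 4L) {
    stop("star_mismatches incompatible with mature length", call. = FALSE)
  }
  with_seed(seed, {
    star <- strsplit(reverse_complement(mature), "")[[1]]
    if (star_mismatches > 0L) {
      # spaced positions (>= 3 apart) keep mismatches as isolated internal
      # loops instead of merging into larger bulges
      cand <- 3:(m - 2L)
      pos <- integer()
      for (p in sample(cand)) {
        if (all(abs(p - pos) >= 3L)) pos <- c(pos, p)
        if (length(pos) == star_mismatches) break
      }
      if (length(pos) < star_mismatches) {
        pos <- sample(cand, star_mismatches)
      }
      # star position k pairs mature position m - k + 1; break that pair
      star[pos] <- vapply(pos, function(k) {
        non_pairing_base(substr(mature, m - k + 1L, m - k + 1L))
      }, character(1))
    }
    star <- paste(star, collapse = "")
    # pairing-poor loop: A/C only never pairs internally
    loop <- paste(sample(c("A", "C"), loop_len, replace = TRUE),
                  collapse = "")
    ext <- random_dna_capped(stem_ext, gc_target)
    if (arm == "5p") {
      precursor <- paste0(ext, mature, loop, star, reverse_complement(ext))
      mature_span <- c(stem_ext + 1L, stem_ext + m)
      star_span <- c(stem_ext + m + loop_len + 1L,
                     stem_ext + m + loop_len + m)
    } else {
      precursor <- paste0(ext, star, loop, mature, reverse_complement(ext))
      star_span <- c(stem_ext + 1L, stem_ext + m)
      mature_span <- c(stem_ext + m + loop_len + 1L,
                       stem_ext + m + loop_len + m)
    }
    loop_span <- c(stem_ext + m + 1L, stem_ext + m + loop_len)
    list(precursor = precursor, mature_span = mature_span,
         star_span = star_span, loop_span = loop_span, arm = arm)
  })
}

#' Generate a synthetic genome with planted precursors and decoys
#'
#' Places `n_precursors` stem-loop precursors (random mature sequences,
#' lengths drawn with a 24-nt mode) and `n_decoys` structureless random
#' loci on random strands of random contigs, without overlap. Every
#' feature is recorded in the truth table.
#'
#' @param n_precursors,n_decoys Feature counts.
#' @param contig_len Length of each contig (default 4000).
#' @param n_contigs Number of contigs (default 1).
#' @param seed Integer seed; regeneration is bit-identical.
#' @param star_mismatches,loop_len,stem_ext Passed to [make_precursor()];
#'   the default of 2 star mismatches keeps hairpins realistic (perfect
#'   duplexes would make the mature tag match both strands).
#' @return A list with `contigs` (tibble `seq_id`, `sequence`) and `truth`
#'   (tibble: `feature`, `type`, `contig_id`, `start`, `end`, `strand`,
#'   `mature_tag`, `star_tag`, `arm`, `precursor_seq`; decoy rows carry NA
#'   tags). Coordinates are 0-based half-open on the forward strand.
#' @export
make_genome <- function(n_precursors, n_decoys, contig_len = 4000L,
                        n_contigs = 1L, seed = 1L,
                        star_mismatches = 2L, loop_len = 8L,
                        stem_ext = 25L) {
  with_seed(seed, {
    feats <- list()
    for (i in seq_len(n_precursors)) {
      mlen <- sample(c(20L, 21L, 22L, 23L, 24L), 1,
                     prob = c(0.05, 0.15, 0.10, 0.20, 0.50))
      mature <- random_dna_capped(mlen, gc = 50)
      arm <- sample(c("5p", "3p"), 1)
      pre <- make_precursor(mature, loop_len = loop_len,
                            star_mismatches = star_mismatches,
                            arm = arm, stem_ext = stem_ext)
      feats[[length(feats) + 1L]] <- list(
        feature = sprintf("precursor_%d", i), type = "precursor",
        insert = pre$precursor, mature = mature,
        star = substr(pre$precursor, pre$star_span[1], pre$star_span[2]),
        mature_span = pre$mature_span, arm = arm)
    }
    for (i in seq_len(n_decoys)) {
      feats[[length(feats) + 1L]] <- list(
        feature = sprintf("decoy_%d", i), type = "decoy",
        insert = random_dna(sample(80:140, 1), gc = 50),
        mature = NA_character_, star = NA_character_,
        mature_span = c(NA_integer_, NA_integer_), arm = NA_character_)
    }
    contigs <- vapply(seq_len(n_contigs), function(i) random_dna(contig_len),
                      character(1))
    # sequential placement with random spacers; overlap-free by construction
    feats <- feats[sample.int(length(feats))]
    truth_rows <- list()
    ci <- 1L
    cursor <- 0L
    for (f in feats) {
      len <- nchar(f$insert)
      repeat {
        gap <- sample(30:150, 1)
        if (cursor + gap + len <= contig_len) {
          cursor <- cursor + gap
          break
        }
        ci <- ci + 1L
        cursor <- 0L
        if (ci > n_contigs) stop("infeasible feature packing", call. = FALSE)
      }
      start <- cursor  # 0-based
      strand <- sample(c("+", "-"), 1)
      ins <- if (strand == "+") f$insert else reverse_complement(f$insert)
      substr(contigs[ci], start + 1L, start + len) <- ins
      cursor <- cursor + len
      truth_rows[[length(truth_rows) + 1L]] <- tibble(
        feature = f$feature, type = f$type,
        contig_id = sprintf("contig_%d", ci),
        start = start, end = start + len, strand = strand,
        mature_tag = f$mature, star_tag = f$star, arm = f$arm,
        precursor_seq = if (f$type == "precursor") f$insert else NA_character_)
    }
    list(contigs = tibble(seq_id = sprintf("contig_%d", seq_len(n_contigs)),
                          sequence = contigs),
         truth = dplyr::bind_rows(truth_rows))
  })
}

#' Generate ncRNA decoy reference sequences
#'
#' Random rRNA/tRNA-like references used both as contaminant source and as
#' the subtraction reference.
#'
#' @param n Number of sequences (default 5).
#' @param len Length of each (default 120).
#' @param seed Integer seed.
#' @return A tibble (`seq_id`, `sequence`).
#' @export
make_ncrna_reference <- function(n = 5L, len = 120L, seed = 1L) {
  with_seed(seed, {
    tibble(seq_id = sprintf("ncrna_%d", seq_len(n)),
           sequence = vapply(seq_len(n), function(i) random_dna(len, gc = 55),
                             character(1)))
  })
}

#' Simulate a small-RNA read set from planted truth
#'
#' Emits mature-arm reads with log-normally drawn per-tag counts (a few
#' high-abundance tags and a long tail down to 1-2 copies), optional
#' star-arm reads, the 3' adapter appended, substitution errors at
#' `error_rate`, and ncRNA contaminant reads (random 16-30 nt slices of
#' the reference) interleaved at `ncrna_fraction` of the output. True
#' counts are recorded before errors are applied.
#'
#' @param truth Truth tibble from [make_genome()] (precursor rows used).
#' @param meanlog,sdlog Log-normal abundance parameters
#'   (defaults 2.3, 1.6).
#' @param error_rate Per-base substitution probability (default 0).
#' @param adapter 3' adapter sequence appended to each insert.
#' @param ncrna_fraction Expected contaminant fraction of the read set
#'   (default 0).
#' @param ncrna_ref Reference tibble for contaminant slices (required when
#'   `ncrna_fraction > 0`).
#' @param star_fraction Star-arm read count as a fraction of the mature
#'   count (default 0.1; star tags with a resulting count of 0 are
#'   omitted).
#' @param seed Integer seed.
#' @return A list with `reads` (FASTQ-ready tibble: `read_id`, `sequence`,
#'   `quality`), `tag_truth` (tibble `sequence`, `true_count`, `origin`),
#'   and `contaminants` (distinct contaminant insert tags).
#' @export
simulate_reads <- function(truth, meanlog = 2.3, sdlog = 1.6,
                           error_rate = 0, adapter = "AACTGTAGGCACCATCAAT",
                           ncrna_fraction = 0, ncrna_ref = NULL,
                           star_fraction = 0.1, seed = 1L) {
  pre <- truth[truth$type == "precursor", ]
  with_seed(seed, {
    tag_rows <- list()
    for (i in seq_len(nrow(pre))) {
      n_mat <- max(1L, round(stats::rlnorm(1, meanlog, sdlog)))
      tag_rows[[length(tag_rows) + 1L]] <- tibble(
        sequence = pre$mature_tag[i], true_count = n_mat,
        origin = pre$feature[i])
      if (star_fraction > 0) {
        n_star <- round(n_mat * star_fraction)
        if (n_star >= 1L) {
          tag_rows[[length(tag_rows) + 1L]] <- tibble(
            sequence = pre$star_tag[i], true_count = n_star,
            origin = paste0(pre$feature[i], "_star"))
        }
      }
    }
    tag_truth <- dplyr::bind_rows(tag_rows)
    if (is.null(tag_truth) || nrow(tag_truth) == 0L) {
      return(list(reads = tibble(read_id = character(),
                                 sequence = character(),
                                 quality = character()),
                  tag_truth = tibble(sequence = character(),
                                     true_count = integer(),
                                     origin = character()),
                  contaminants = character()))
    }
    inserts <- rep(tag_truth$sequence, tag_truth$true_count)
    n_real <- length(inserts)
    contaminants <- character()
    if (ncrna_fraction > 0) {
      stopifnot(!is.null(ncrna_ref), nrow(ncrna_ref) > 0L)
      n_cont <- stats::rbinom(1, n_real,
                              ncrna_fraction / (1 - ncrna_fraction))
      cont <- vapply(seq_len(n_cont), function(i) {
        ref <- ncrna_ref$sequence[sample.int(nrow(ncrna_ref), 1)]
        len <- sample(16:30, 1)
        s <- sample.int(nchar(ref) - len + 1L, 1)
        substr(ref, s, s + len - 1L)
      }, character(1))
      contaminants <- unique(cont)
      inserts <- c(inserts, cont)
    }
    reads <- paste0(inserts, adapter)
    if (error_rate > 0) {
      reads <- vapply(reads, function(r) {
        ch <- strsplit(r, "")[[1]]
        hit <- stats::runif(length(ch)) < error_rate
        if (any(hit)) {
          ch[hit] <- vapply(ch[hit], function(b) {
            sample(setdiff(c("A", "C", "G", "T"), b), 1)
          }, character(1))
        }
        paste(ch, collapse = "")
      }, character(1), USE.NAMES = FALSE)
    }
    ord <- sample.int(length(reads))
    reads <- reads[ord]
    list(reads = tibble(read_id = sprintf("read_%d", seq_along(reads)),
                        sequence = reads,
                        quality = strrep("I", nchar(reads))),
         tag_truth = tag_truth,
         contaminants = contaminants)
  })
}

#' Generate transcripts with planted miRNA target sites
#'
#' Each planted site is the reverse complement of its miRNA edited to
#' score exactly the designed expectation under the default scheme:
#' integer steps are pair-breaking mismatches and a half step is a G:U
#' wobble, all placed at non-seed miRNA positions (position 1 and
#' positions past the seed end), so the design value is reproduced
#' exactly by [score_duplex()].
#'
#' @param mirnas Tibble with `name` and `sequence` columns.
#' @param planted_sites Tibble with `mirna_id` (matching `name`) and
#'   `expectation` (designed value, multiple of 0.5).
#' @param n_transcripts Number of transcripts (>= planted sites may share).
#' @param transcript_len Length of each transcript (default 500).
#' @param scheme The [target_scheme()] the design is computed under.
#' @param seed Integer seed.
#' @return A list with `transcripts` (tibble `seq_id`, `sequence`) and
#'   `truth` (tibble `transcript_id`, `mirna_id`, `start`, `end`,
#'   `designed_expectation`).
#' @export
make_transcriptome <- function(mirnas, planted_sites, n_transcripts,
                               transcript_len = 500L,
                               scheme = target_scheme(), seed = 1L) {
  stopifnot(n_transcripts >= 1L)
  with_seed(seed, {
    transcripts <- vapply(seq_len(n_transcripts),
                          function(i) random_dna(transcript_len, gc = 45),
                          character(1))
    truth_rows <- list()
    for (r in seq_len(nrow(planted_sites))) {
      mid <- planted_sites$mirna_id[r]
      design <- planted_sites$expectation[r]
      mir <- toupper(to_dna(mirnas$sequence[mirnas$name == mid]))
      stopifnot(length(mir) == 1L)
      m <- nchar(mir)
      free_pos <- setdiff(seq_len(m),
                          scheme$seed_start:scheme$seed_end)
      n_mm <- floor(design / scheme$mismatch)
      frac <- design - n_mm * scheme$mismatch
      wobble_pos <- integer()
      if (frac > 0) {
        if (abs(frac - scheme$wobble) > 1e-9) {
          stop("designed expectation not reachable in 0.5 steps",
               call. = FALSE)
        }
        cand <- free_pos[substr(rep(mir, length(free_pos)), free_pos,
                                free_pos) %in% c("G", "T")]
        if (length(cand) == 0L) {
          stop("no non-seed G/U position available for a wobble edit",
               call. = FALSE)
        }
        wobble_pos <- cand[1]
        free_pos <- setdiff(free_pos, wobble_pos)
      }
      if (n_mm > length(free_pos)) {
        stop("designed expectation not reachable with non-seed mismatches",
             call. = FALSE)
      }
      mm_pos <- if (n_mm > 0L) {
        sort(free_pos[sample.int(length(free_pos), n_mm)])
      } else integer()
      site <- strsplit(reverse_complement(mir), "")[[1]]  # 5'->3' on transcript
      # miRNA position p pairs transcript-site position m - p + 1
      for (p in mm_pos) {
        site[m - p + 1L] <- non_pairing_base(substr(mir, p, p))
      }
      for (p in wobble_pos) {
        site[m - p + 1L] <- if (substr(mir, p, p) == "G") "T" else "G"
      }
      site <- paste(site, collapse = "")
      ti <- ((r - 1L) %% n_transcripts) + 1L
      start <- sample.int(transcript_len - m + 1L, 1)
      substr(transcripts[ti], start, start + m - 1L) <- site
      truth_rows[[length(truth_rows) + 1L]] <- tibble(
        transcript_id = sprintf("transcript_%d", ti), mirna_id = mid,
        start = start, end = start + m - 1L,
        designed_expectation = design)
    }
    list(transcripts = tibble(
           seq_id = sprintf("transcript_%d", seq_len(n_transcripts)),
           sequence = transcripts),
         truth = dplyr::bind_rows(truth_rows))
  })
}

#' Generate a synthetic qPCR Ct table
#'
#' Draws Ct values for a set of assays around assay-specific means with
#' Gaussian replicate noise, always including the reference assay.
#'
#' @param assays Character vector of assay names (reference added if
#'   absent).
#' @param n_samples Biological samples (default 6).
#' @param n_replicates Technical replicates per sample (default 3).
#' @param reference_assay Endogenous control name (default "U6").
#' @param mean_ct Named numeric vector of per-assay mean Ct; unnamed
#'   assays draw from U(22, 32); the reference defaults to 18.
#' @param noise_sd Replicate noise SD in cycles (default 0.2).
#' @param seed Integer seed.
#' @return A Ct tibble (`assay_id`, `sample_id`, `replicate`, `ct`).
#' @export
make_ct_table <- function(assays, n_samples = 6L, n_replicates = 3L,
                          reference_assay = "U6", mean_ct = NULL,
                          noise_sd = 0.2, seed = 1L) {
  with_seed(seed, {
    all_assays <- union(assays, reference_assay)
    mu <- stats::setNames(stats::runif(length(all_assays), 22, 32),
                          all_assays)
    mu[reference_assay] <- 18
    if (!is.null(mean_ct)) mu[names(mean_ct)] <- mean_ct
    grid <- tidyr::expand_grid(assay_id = all_assays,
                               sample_id = sprintf("S%d", seq_len(n_samples)),
                               replicate = seq_len(n_replicates))
    dplyr::mutate(grid,
                  ct = pmin(44.9, pmax(0.1,
                    mu[.data$assay_id] +
                      stats::rnorm(nrow(grid), 0, noise_sd))))
  })
}
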