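# Secondary-structure prediction under a reduced nearest-neighbour model,
# and the precursor statistics built on it (GC%, AMFE, MFEI).

PAIR_LEVELS <- c("AU", "UA", "GC", "CG", "GU", "UG")

#' Load the nearest-neighbour energy model
#'
#' Reads the packaged stacking-energy and loop-penalty tables (kcal/mol at
#' 37 degrees C) or user-supplied replacements with the same layout.
#' Energies are stored internally in integer tenths of kcal/mol so that
#' folding, re-scoring and enumeration agree exactly. Loop penalties beyond
#' the tabulated sizes are extrapolated logarithmically
#' (`E(n) = E(max) + 1.1 ln(n/max)`).
#'
#' @param stack_file,loop_file Optional paths to TSV parameter tables; the
#'   packaged tables are used by default.
#' @return A list of class `energy_model` with elements `stack` (6x6 integer
#'   matrix over pair codes AU, UA, GC, CG, GU, UG), `hairpin`, `bulge`,
#'   `internal` (named base tables), and multiloop constants.
#' @export
energy_model <- function(stack_file = NULL, loop_file = NULL) {
  if (is.null(stack_file)) {
    stack_file <- system.file("extdata", "stack_energies.tsv",
                              package = "mirseedling")
  }
  if (is.null(loop_file)) {
    loop_file <- system.file("extdata", "loop_energies.tsv",
                             package = "mirseedling")
  }
  st <- utils::read.delim(stack_file, stringsAsFactors = FALSE)
  stopifnot(all(c("pair5", "pair3", "energy") %in% names(st)))
  stack <- matrix(0L, 6, 6, dimnames = list(PAIR_LEVELS, PAIR_LEVELS))
  for (r in seq_len(nrow(st))) {
    stack[st$pair5[r], st$pair3[r]] <- as.integer(round(st$energy[r] * 10))
  }
  lo <- utils::read.delim(loop_file, stringsAsFactors = FALSE)
  pick <- function(type) {
    rows <- lo[lo$type == type, ]
    stats::setNames(as.integer(round(rows$energy * 10)), rows$size)
  }
  const <- function(type) {
    as.integer(round(lo$energy[lo$type == type][1] * 10))
  }
  structure(list(stack = stack,
                 hairpin = pick("hairpin"),
                 bulge = pick("bulge"),
                 internal = pick("internal"),
                 ml_offset = const("multiloop_offset"),
                 ml_branch = const("multiloop_branch"),
                 ml_unpaired = const("multiloop_unpaired")),
            class = "energy_model")
}

# Loop-penalty vector (integer tenths) for sizes 0..n, with log extrapolation
# past the tabulated maximum. Index with size + 1.
loop_penalty_vector <- function(base, n) {
  sizes <- as.integer(names(base))
  out <- rep.int(NA_integer_, n + 1L)
  out[sizes + 1L] <- unname(base)
  max_sz <- max(sizes)
  if (n > max_sz) {
    big <- (max_sz + 1L):n
    out[big + 1L] <- base[[as.character(max_sz)]] +
      as.integer(round(10 * 1.1 * log(big / max_sz)))
  }
  out[is.na(out)] <- 999999L  # sizes below the table minimum are unreachable
  out
}

pair_code_r <- function(a, b) {
  match(paste0(a, b), PAIR_LEVELS)  # NA when not pairable
}

#' GC content of a sequence
#'
#' @param sequence Non-empty nucleotide string (vectorised).
#' @return Percentage of G+C bases.
#' @examples
#' gc_content("GUAC")
#' @export
gc_content <- function(sequence) {
  if (any(!nzchar(sequence))) stop("empty sequence", call. = FALSE)
  x <- toupper(sequence)
  100 * (stringr::str_count(x, "G") + stringr::str_count(x, "C")) / nchar(x)
}

#' Adjusted minimum free energy (AMFE)
#'
#' `|MFE| / length * 100`, the per-100-nt folding energy magnitude.
#'
#' @param mfe Minimum free energy in kcal/mol (<= 0).
#' @param length Sequence length in nt (> 0).
#' @return AMFE value.
#' @export
amfe <- function(mfe, length) {
  stopifnot(all(length > 0))
  abs(mfe) / length * 100
}

#' Minimal folding free energy index (MFEI)
#'
#' AMFE divided by the GC percentage: `MFEI = (|MFE| / length * 100) / GC%`.
#' Reported as a positive magnitude; values above roughly 0.70 distinguish
#' miRNA precursors from other RNAs (tRNA ~0.64, rRNA ~0.59, mRNA
#' 0.62-0.66).
#'
#' @inheritParams amfe
#' @param gc GC content percentage (> 0).
#' @return MFEI value.
#' @examples
#' mfei(-50, 100, 50)   # 1.00
#' @export
mfei <- function(mfe, length, gc) {
  if (any(gc == 0)) stop("MFEI is undefined at 0% GC", call. = FALSE)
  amfe(mfe, length) / gc
}

#' Parse dot-bracket notation into a partner map
#'
#' @param dot_bracket Balanced string over `".()"`.
#' @return Integer vector: `p[i]` is the 1-based partner of position `i`, or
#'   `NA` if unpaired.
#' @export
parse_dot_bracket <- function(dot_bracket) {
  chars <- strsplit(dot_bracket, "")[[1]]
  p <- rep(NA_integer_, length(chars))
  open <- integer()
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      open <- c(open, i)
    } else if (chars[i] == ")") {
      if (length(open) == 0L) stop("unbalanced dot-bracket", call. = FALSE)
      j <- open[length(open)]
      open <- open[-length(open)]
      p[i] <- j
      p[j] <- i
    } else if (chars[i] != ".") {
      stop("invalid dot-bracket character", call. = FALSE)
    }
  }
  if (length(open)) stop("unbalanced dot-bracket", call. = FALSE)
  p
}

#' Score a given structure under the energy model
#'
#' Decomposes a dot-bracket structure into its loops (stacks, hairpin,
#' bulge/internal, multibranch) and sums their model energies. This is the
#' model's definition of structure energy; [fold_mfe()] minimises exactly
#' this quantity, so re-scoring a folded structure reproduces its MFE.
#'
#' @param sequence Nucleotide string (U or T).
#' @param dot_bracket Structure string of the same length.
#' @param model An [energy_model()].
#' @return Energy in kcal/mol.
#' @export
structure_energy <- function(sequence, dot_bracket, model = energy_model()) {
  seq_rna <- toupper(to_rna(sequence))
  n <- nchar(seq_rna)
  stopifnot(nchar(dot_bracket) == n)
  p <- parse_dot_bracket(dot_bracket)
  bases <- strsplit(seq_rna, "")[[1]]
  hp <- loop_penalty_vector(model$hairpin, n)
  bu <- loop_penalty_vector(model$bulge, n)
  il <- loop_penalty_vector(model$internal, n)
  total <- 0L
  for (i in seq_len(n)) {
    j <- p[i]
    if (is.na(j) || j < i) next
    pc_out <- pair_code_r(bases[i], bases[j])
    if (is.na(pc_out)) stop("disallowed pair in structure", call. = FALSE)
    # children: directly nested pairs inside (i, j)
    children <- list()
    unpaired <- 0L
    k <- i + 1L
    while (k < j) {
      if (is.na(p[k])) {
        unpaired <- unpaired + 1L
        k <- k + 1L
      } else {
        children[[length(children) + 1L]] <- c(k, p[k])
        k <- p[k] + 1L
      }
    }
    nc <- length(children)
    if (nc == 0L) {
      if (unpaired < 3L) stop("hairpin loop smaller than 3 nt", call. = FALSE)
      total <- total + hp[unpaired + 1L]
    } else if (nc == 1L) {
      k <- children[[1]][1]; l <- children[[1]][2]
      l1 <- k - i - 1L; l2 <- j - l - 1L
      if (l1 == 0L && l2 == 0L) {
        pc_in <- pair_code_r(bases[k], bases[l])
        total <- total + model$stack[pc_out, pc_in]
      } else if (l1 == 0L || l2 == 0L) {
        total <- total + bu[l1 + l2 + 1L]
      } else {
        total <- total + il[l1 + l2 + 1L]
      }
    } else {
      total <- total + model$ml_offset + model$ml_branch * (nc + 1L) +
        model$ml_unpaired * unpaired
    }
  }
  total / 10
}

#' Fold a sequence to its minimum-free-energy structure
#'
#' Predicts the non-crossing secondary structure of lowest energy under the
#' reduced nearest-neighbour model via dynamic programming with traceback.
#' Deterministic: ties prefer structures whose leftmost differing position
#' is unpaired.
#'
#' @param sequence Nucleotide string, 10-600 nt (U or T accepted).
#' @param model An [energy_model()].
#' @return An object of class `rna_structure`: list with `sequence` (RNA),
#'   `dot_bracket`, `mfe` (kcal/mol), `pair_map` (1-based partner vector).
#' @examples
#' fold_mfe("GGGGAAAACCCC")
#' @export
fold_mfe <- function(sequence, model = energy_model()) {
  seq_rna <- toupper(to_rna(sequence))
  n <- nchar(seq_rna)
  if (n < 10) stop("sequence shorter than 10 nt", call. = FALSE)
  if (n > 600) stop("sequence longer than 600 nt", call. = FALSE)
  check_alphabet(seq_rna)  # N is allowed and simply never pairs
  res <- .fold_mfe_cpp(seq_rna,
                       as.integer(t(model$stack)),  # row-major for C++
                       loop_penalty_vector(model$hairpin, n),
                       loop_penalty_vector(model$bulge, n),
                       loop_penalty_vector(model$internal, n),
                       model$ml_offset, model$ml_branch, model$ml_unpaired)
  structure(list(sequence = seq_rna,
                 dot_bracket = res$dot_bracket,
                 mfe = res$mfe_tenths / 10,
                 pair_map = parse_dot_bracket(res$dot_bracket)),
            class = "rna_structure")
}

#' @export
print.rna_structure <- function(x, ...) {
  cat(x$sequence, "\n", x$dot_bracket, "\n", sep = "")
  cat(sprintf("MFE: %.1f kcal/mol\n", x$mfe))
  invisible(x)
}

#' Hairpin geometry of a mature miRNA within a folded precursor
#'
#' Locates the mature span on the hairpin and reports the arm (5p / 3p /
#' loop-spanning), the number of paired mature bases, the number of
#' unpaired (mismatched) mature positions, the largest asymmetric bulge in
#' the mature/star duplex, the terminal loop size, and the inferred star
#' span (pairing partners of the mature plus the canonical 2-nt 3' offset).
#'
#' @param struct An `rna_structure` from [fold_mfe()].
#' @param mature_span Integer vector `c(start, end)` (1-based, inclusive)
#'   of the mature miRNA within the precursor.
#' @return A list with elements `arm`, `n_paired`, `n_unpaired`,
#'   `max_asym_bulge`, `terminal_loop`, `star_span`.
#' @export
hairpin_features <- function(struct, mature_span) {
  n <- nchar(struct$sequence)
  s <- mature_span[1]; e <- mature_span[2]
  if (s < 1 || e > n || s > e) {
    stop("mature_span outside the precursor", call. = FALSE)
  }
  p <- struct$pair_map
  mat <- s:e
  partners <- p[mat]
  paired <- !is.na(partners)
  n_paired <- sum(paired)
  if (n_paired == 0L) {
    return(list(arm = "unpaired", n_paired = 0L, n_unpaired = length(mat),
                max_asym_bulge = NA_integer_, terminal_loop = NA_integer_,
                star_span = c(NA_integer_, NA_integer_)))
  }
  pp <- partners[paired]
  arm <- if (min(pp) > e) "5p" else if (max(pp) < s) "3p" else "loop-spanning"

  # hairpin (terminal) loops: innermost pairs
  loops <- list()
  for (i in seq_len(n)) {
    j <- p[i]
    if (!is.na(j) && j > i && all(is.na(p[seq(i + 1L, j - 1L)]))) {
      loops[[length(loops) + 1L]] <- c(i + 1L, j - 1L)
    }
  }
  in_loop <- function(k) {
    any(vapply(loops, function(L) k >= L[1] && k <= L[2], logical(1)))
  }
  if (arm != "loop-spanning" && length(loops) &&
      any(vapply(mat, in_loop, logical(1)))) {
    arm <- "loop-spanning"
  }

  # terminal loop of the stem holding the mature: the loop between mature
  # and its partner region
  terminal_loop <- NA_integer_
  if (length(loops)) {
    lo <- min(c(mat, pp)); hi <- max(c(mat, pp))
    inside <- Filter(function(L) L[1] > lo && L[2] < hi, loops)
    if (length(inside)) {
      terminal_loop <- max(vapply(inside, function(L) L[2] - L[1] + 1L,
                                  integer(1)))
    }
  }

  # largest asymmetric bulge between successive paired mature positions
  idx <- mat[paired]
  max_bulge <- 0L
  if (length(idx) >= 2L) {
    for (k in seq_len(length(idx) - 1L)) {
      a <- idx[k]; b <- idx[k + 1L]
      gap_m <- b - a - 1L
      gap_s <- abs(p[a] - p[b]) - 1L
      max_bulge <- max(max_bulge, abs(gap_m - gap_s))
    }
  }

  star_lo <- min(pp); star_hi <- max(pp)
  star_span <- if (arm == "5p") c(star_lo - 2L, star_hi) else c(star_lo, star_hi + 2L)
  star_span[1] <- max(1L, star_span[1]); star_span[2] <- min(n, star_span[2])

  list(arm = arm, n_paired = n_paired, n_unpaired = length(mat) - n_paired,
       max_asym_bulge = max_bulge, terminal_loop = terminal_loop,
       star_span = star_span)
}
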