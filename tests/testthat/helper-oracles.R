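# Independent oracles used across the suite: exhaustive structure
# enumeration for the folding DP, all-pairs nearest-reference search for
# the conserved classifier, and brute-force window enumeration for the
# target scanner. Each is written as plainly as possible and shares no
# code path with the implementation it checks.

ORACLE_PAIRS <- c("AU", "UA", "GC", "CG", "GU", "UG")

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Loop-decomposition scorer over a partner vector, integer tenths.
# Same energy rules as the model definition, evaluated directly.
oracle_score_pairs <- function(p, pcode, stack, hp, bu, il,
                               mlA, mlB, mlC) {
  n <- length(p)
  total <- 0L
  for (i in seq_len(n)) {
    j <- p[i]
    if (is.na(j) || j < i) next
    children_k <- integer(0)
    children_l <- integer(0)
    unpaired <- 0L
    k <- i + 1L
    while (k < j) {
      if (is.na(p[k])) {
        unpaired <- unpaired + 1L
        k <- k + 1L
      } else {
        children_k <- c(children_k, k)
        children_l <- c(children_l, p[k])
        k <- p[k] + 1L
      }
    }
    nc <- length(children_k)
    if (nc == 0L) {
      total <- total + hp[unpaired + 1L]
    } else if (nc == 1L) {
      k <- children_k[1]; l <- children_l[1]
      l1 <- k - i - 1L; l2 <- j - l - 1L
      if (l1 == 0L && l2 == 0L) {
        total <- total + stack[pcode[i, j], pcode[k, l]]
      } else if (l1 == 0L || l2 == 0L) {
        total <- total + bu[l1 + l2 + 1L]
      } else {
        total <- total + il[l1 + l2 + 1L]
      }
    } else {
      total <- total + mlA + mlB * (nc + 1L) + mlC * unpaired
    }
  }
  total
}

# Exhaustive enumeration of every non-crossing structure (minimum hairpin
# loop 3, allowed pairs only), scoring each complete structure; returns
# the minimum energy in kcal/mol.
oracle_fold_mfe <- function(sequence, model = energy_model()) {
  s <- strsplit(toupper(to_rna(sequence)), "")[[1]]
  n <- length(s)
  pcode <- outer(seq_len(n), seq_len(n), function(i, j)
    matrix(match(paste0(s[i], s[j]), ORACLE_PAIRS), length(i)))
  pairable <- !is.na(pcode)
  hp <- mirseedling:::loop_penalty_vector(model$hairpin, n)
  bu <- mirseedling:::loop_penalty_vector(model$bulge, n)
  il <- mirseedling:::loop_penalty_vector(model$internal, n)
  p <- rep(NA_integer_, n)
  best <- 0L
  rec <- function(i) {
    if (i > n) {
      e <- oracle_score_pairs(p, pcode, model$stack, hp, bu, il,
                              model$ml_offset, model$ml_branch,
                              model$ml_unpaired)
      if (e < best) best <<- e
      return(invisible())
    }
    if (!is.na(p[i])) {
      rec(i + 1L)
      return(invisible())
    }
    rec(i + 1L)  # i unpaired
    if (i + 4L <= n) {
      for (j in (i + 4L):n) {
        if (is.na(p[j]) && pairable[i, j]) {
          if (i > 1L) {
            pre <- p[seq_len(i - 1L)]
            if (any(!is.na(pre) & pre > i & pre < j)) next
          }
          p[i] <<- j; p[j] <<- i
          rec(i + 1L)
          p[i] <<- NA_integer_; p[j] <<- NA_integer_
        }
      }
    }
  }
  rec(1L)
  best / 10
}

# All-pairs nearest-reference search: for one tag, scan the whole
# reference, keep equal-length entries within max_mm, fewest mismatches,
# ties by smallest id. Returns NULL or list(id, mm).
oracle_match <- function(tag, ref_ids, ref_seqs, max_mm = 1L) {
  tag <- chartr("U", "T", toupper(tag))
  best_mm <- Inf
  best_ids <- character()
  for (r in seq_along(ref_seqs)) {
    rs <- chartr("U", "T", toupper(ref_seqs[r]))
    if (nchar(rs) != nchar(tag)) next
    mm <- sum(utf8ToInt(tag) != utf8ToInt(rs))
    if (mm > max_mm) next
    if (mm < best_mm) {
      best_mm <- mm
      best_ids <- ref_ids[r]
    } else if (mm == best_mm) {
      best_ids <- c(best_ids, ref_ids[r])
    }
  }
  if (!length(best_ids)) return(NULL)
  list(id = sort(best_ids)[1], mm = best_mm)
}

# Brute-force target scan: enumerate every ungapped window and every
# single-gap variant with straight loops, score column by column, apply
# the cutoff and cluster-best rule.
oracle_scan <- function(mirna, transcript, scheme = target_scheme()) {
  mir <- toupper(to_rna(mirna))
  m <- nchar(mir)
  trc <- strsplit(toupper(to_rna(transcript)), "")[[1]]
  L <- length(trc)
  mirc <- strsplit(mir, "")[[1]]
  score_aln <- function(ma, sa) {
    tot <- 0
    mp <- 0L
    for (i in seq_along(ma)) {
      if (ma[i] != "-") mp <- mp + 1L
      gov <- if (ma[i] == "-") mp + 1L else mp
      pen <- if (ma[i] == "-" || sa[i] == "-") {
        scheme$gap
      } else if (paste0(ma[i], sa[i]) %in% c("AU", "UA", "GC", "CG")) {
        0
      } else if (paste0(ma[i], sa[i]) %in% c("GU", "UG")) {
        scheme$wobble
      } else {
        scheme$mismatch
      }
      if (gov >= scheme$seed_start && gov <= scheme$seed_end) {
        pen <- pen * scheme$seed_multiplier
      }
      tot <- tot + pen
    }
    tot
  }
  rows <- list()
  for (s in seq_len(L - m + 2L)) {
    if (s + m - 1L <= L) {
      sa <- rev(trc[s:(s + m - 1L)])
      rows[[length(rows) + 1L]] <- data.frame(
        start = s, end = s + m - 1L,
        expectation = score_aln(mirc, sa), n_gaps = 0L)
    }
    if (scheme$max_gaps >= 1L) {
      if (s + m - 2L <= L && m >= 3L) {
        for (g in 2L:(m - 1L)) {
          sa <- append(rev(trc[s:(s + m - 2L)]), "-", after = g - 1L)
          rows[[length(rows) + 1L]] <- data.frame(
            start = s, end = s + m - 2L,
            expectation = score_aln(mirc, sa), n_gaps = 1L)
        }
      }
      if (s + m <= L && m >= 2L) {
        sa <- rev(trc[s:(s + m)])
        for (g in 2L:m) {
          ma <- append(mirc, "-", after = g - 1L)
          rows[[length(rows) + 1L]] <- data.frame(
            start = s, end = s + m,
            expectation = score_aln(ma, sa), n_gaps = 1L)
        }
      }
    }
  }
  cand <- do.call(rbind, rows)
  cand <- cand[cand$expectation <= scheme$cutoff, ]
  if (nrow(cand) == 0L) return(cand)
  cand <- cand[order(cand$start, cand$end, cand$n_gaps), ]
  cl <- integer(nrow(cand))
  cur <- 0L; cur_end <- -1L
  for (i in seq_len(nrow(cand))) {
    if (cand$start[i] > cur_end) cur <- cur + 1L
    cl[i] <- cur
    cur_end <- max(cur_end, cand$end[i])
  }
  cand$cl <- cl
  out <- do.call(rbind, lapply(split(cand, cand$cl), function(d) {
    d[order(d$expectation, d$start, d$n_gaps), ][1, ]
  }))
  out <- out[order(out$start), c("start", "end", "expectation", "n_gaps")]
  rownames(out) <- NULL
  out
}
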