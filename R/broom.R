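# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a preprocessing result
#'
#' @param x An `srna_preprocess` object.
#' @param ... Unused.
#' @return The read-accounting tibble (one row per category).
#' @export
tidy.srna_preprocess <- function(x, ...) {
  x$accounting
}

#' @rdname tidy.srna_preprocess
#' @return `glance()`: a one-row summary (totals, retention rate, modal
#'   length).
#' @export
glance.srna_preprocess <- function(x, ...) {
  total <- x$accounting$reads[x$accounting$category == "total"]
  retained <- x$accounting$reads[x$accounting$category == "retained"]
  tibble(total_reads = total,
         retained_reads = retained,
         retention_rate = if (total > 0) retained / total else NA_real_,
         unique_tags = nrow(x$tags),
         mode_length = attr(x$length_dist, "mode_length"),
         mode_pct = attr(x$length_dist, "mode_pct"))
}

#' Tidy a folded RNA structure
#'
#' @param x An `rna_structure` object.
#' @param ... Unused.
#' @return A per-position tibble: `position`, `base`, `symbol`, `partner`.
#' @export
tidy.rna_structure <- function(x, ...) {
  tibble(position = seq_len(nchar(x$sequence)),
         base = strsplit(x$sequence, "")[[1]],
         symbol = strsplit(x$dot_bracket, "")[[1]],
         partner = x$pair_map)
}

#' @rdname tidy.rna_structure
#' @return `glance()`: one row with `length`, `mfe`, `gc_percent`, `amfe`,
#'   `mfei`, `n_pairs`.
#' @export
glance.rna_structure <- function(x, ...) {
  len <- nchar(x$sequence)
  gc <- gc_content(x$sequence)
  tibble(length = len, mfe = x$mfe, gc_percent = gc,
         amfe = amfe(x$mfe, len),
         mfei = if (gc > 0) mfei(x$mfe, len, gc) else NA_real_,
         n_pairs = sum(!is.na(x$pair_map)) / 2L)
}

#' Tidy a miRNA-target network
#'
#' @param x A `mirna_network` object.
#' @param ... Unused.
#' @return The edge tibble.
#' @export
tidy.mirna_network <- function(x, ...) {
  x$edges
}

#' @rdname tidy.mirna_network
#' @return `glance()`: one row with node/edge counts and mean edge weight.
#' @export
glance.mirna_network <- function(x, ...) {
  tibble(n_mirnas = nrow(x$mirnas), n_targets = nrow(x$targets),
         n_edges = nrow(x$edges),
         mean_weight = if (nrow(x$edges)) mean(x$edges$weight) else NA_real_)
}
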