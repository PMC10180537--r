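# MFE-weighted bipartite miRNA-target network, degree summaries,
# annotation-category tabulation and interchange-file export.

#' Build the miRNA-target interaction network
#'
#' Deduplicates sites per (miRNA, transcript) pair keeping the best
#' (lowest) expectation, and assembles a bipartite edge list weighted by
#' the duplex MFE (more negative = stronger interaction).
#'
#' @param sites Site tibble from [predict_targets()].
#' @return An object of class `mirna_network`: list with `edges`
#'   (`mirna_id`, `target_id`, `weight`, `expectation`), `mirnas` and
#'   `targets` node tibbles.
#' @export
build_network <- function(sites) {
  edges <- sites |>
    dplyr::group_by(.data$mirna_id, .data$transcript_id) |>
    dplyr::arrange(.data$expectation, .data$start, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::transmute(mirna_id = .data$mirna_id,
                     target_id = .data$transcript_id,
                     weight = .data$duplex_mfe,
                     expectation = .data$expectation) |>
    dplyr::arrange(.data$mirna_id, .data$target_id)
  structure(list(edges = edges,
                 mirnas = tibble(mirna_id = sort(unique(edges$mirna_id))),
                 targets = tibble(target_id = sort(unique(edges$target_id)))),
            class = "mirna_network")
}

#' @export
print.mirna_network <- function(x, ...) {
  cat(sprintf("miRNA-target network: %d miRNAs, %d targets, %d edges\n",
              nrow(x$mirnas), nrow(x$targets), nrow(x$edges)))
  invisible(x)
}

#' Node degrees of the miRNA-target network
#'
#' @param network A `mirna_network`.
#' @return A list with `mirnas` (per-miRNA target counts) and `targets`
#'   (per-target regulator counts), both sorted by degree descending with
#'   lexicographic ties.
#' @export
degree_summary <- function(network) {
  list(
    mirnas = network$edges |>
      dplyr::count(.data$mirna_id, name = "n_targets") |>
      dplyr::arrange(dplyr::desc(.data$n_targets), .data$mirna_id),
    targets = network$edges |>
      dplyr::count(.data$target_id, name = "n_regulators") |>
      dplyr::arrange(dplyr::desc(.data$n_regulators), .data$target_id)
  )
}

#' Annotation-category percentages of network targets
#'
#' Joins the network's targets with a user-supplied annotation table and
#' reports per-category counts and percentages over the annotated targets;
#' unannotated targets are counted in a separate `"unannotated"` row whose
#' percentage is relative to all targets.
#'
#' @param targets Character vector of target ids, or a tibble with a
#'   `target_id` column.
#' @param annotation Tibble mapping `target_id` to `category`.
#' @return A tibble with columns `category`, `n`, `pct` (2-decimal), sorted
#'   by count descending.
#' @export
category_percentages <- function(targets, annotation) {
  ids <- if (is.character(targets)) targets else targets$target_id
  ids <- unique(ids)
  ann <- annotation[annotation$target_id %in% ids, ]
  annotated_ids <- unique(ann$target_id)
  n_annot <- length(annotated_ids)
  out <- ann |>
    dplyr::count(.data$category, name = "n") |>
    dplyr::mutate(pct = round(100 * .data$n / max(1L, n_annot), 2)) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$category)
  n_un <- length(setdiff(ids, annotated_ids))
  if (n_un > 0L) {
    out <- dplyr::bind_rows(out, tibble(
      category = "unannotated", n = n_un,
      pct = round(100 * n_un / length(ids), 2)))
  }
  out
}

#' Export the network in viewer-loadable form
#'
#' Writes a SIF file (`mirna targets target`) plus edge- and node-attribute
#' TSVs into `dir`. [read_network()] round-trips the export.
#'
#' @param network A `mirna_network`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_network <- function(network, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sif <- sprintf("%s\ttargets\t%s", network$edges$mirna_id,
                 network$edges$target_id)
  writeLines(sif, file.path(dir, "network.sif"))
  readr::write_tsv(network$edges, file.path(dir, "edge_attributes.tsv"))
  nodes <- dplyr::bind_rows(
    tibble(node_id = network$mirnas$mirna_id, node_type = "miRNA"),
    tibble(node_id = network$targets$target_id, node_type = "target"))
  readr::write_tsv(nodes, file.path(dir, "node_attributes.tsv"))
  invisible(dir)
}

#' @rdname write_network
#' @export
read_network <- function(dir) {
  edges <- readr::read_tsv(file.path(dir, "edge_attributes.tsv"),
                           col_types = readr::cols(
                             mirna_id = readr::col_character(),
                             target_id = readr::col_character(),
                             weight = readr::col_double(),
                             expectation = readr::col_double()))
  structure(list(edges = edges,
                 mirnas = tibble(mirna_id = sort(unique(edges$mirna_id))),
                 targets = tibble(target_id = sort(unique(edges$target_id)))),
            class = "mirna_network")
}

#' Join network targets to a pathway/enzyme map
#'
#' Emits a flat join table linking each network edge to the user-supplied
#' enzyme or pathway label of its target, for downstream pathway summaries.
#'
#' @param network A `mirna_network`.
#' @param enzyme_map Tibble with columns `target_id` and label columns
#'   (e.g. `enzyme`, `pathway`).
#' @return A tibble of edges joined with the map (inner join).
#' @export
pathway_join <- function(network, enzyme_map) {
  dplyr::inner_join(network$edges, enzyme_map, by = "target_id")
}
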