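# End-to-end driver: preprocess -> conserved classification -> novel
# discovery -> target prediction -> network, with stage TSV outputs and a
# machine-readable run manifest.

#' Pipeline configuration
#'
#' Collects the inputs and per-stage settings of the full analysis.
#' Inputs may be file paths (FASTQ/FASTA/TSV) or the corresponding
#' tibbles. Unknown arguments are rejected.
#'
#' @param fastq Small-RNA reads (path or tibble).
#' @param mature_ref Mature miRNA reference (FASTA path or tibble with
#'   `mirbase_id`/`seq_id` and `sequence`).
#' @param contigs Reference contigs for precursor excision (path or
#'   tibble); optional, skips novel discovery when absent.
#' @param transcripts Transcript set for target scanning (path or
#'   tibble); optional, skips target prediction when absent.
#' @param ncrna_ref ncRNA subtraction reference (optional).
#' @param ct_table qPCR Ct table (optional).
#' @param annotation Target annotation table (optional).
#' @param out_dir Output directory; stage TSVs and the manifest are
#'   written here (default: no file output).
#' @param preprocess A [preprocess_config()].
#' @param criteria A [precursor_criteria()].
#' @param scheme A [target_scheme()].
#' @param model An [energy_model()].
#' @param max_mismatches Conserved-matching mismatch allowance (default 1).
#' @param min_copies Copy-number gate before target prediction (default 5).
#' @param reference_assay qPCR endogenous control (default "U6").
#' @param seed Integer seed recorded in the manifest.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(fastq, mature_ref, contigs = NULL,
                            transcripts = NULL, ncrna_ref = NULL,
                            ct_table = NULL, annotation = NULL,
                            out_dir = NULL,
                            preprocess = preprocess_config(),
                            criteria = precursor_criteria(),
                            scheme = target_scheme(),
                            model = energy_model(),
                            max_mismatches = 1L, min_copies = 5L,
                            reference_assay = "U6", seed = 1L) {
  cfg <- list(fastq = fastq, mature_ref = mature_ref, contigs = contigs,
              transcripts = transcripts, ncrna_ref = ncrna_ref,
              ct_table = ct_table, annotation = annotation,
              out_dir = out_dir, preprocess = preprocess,
              criteria = criteria, scheme = scheme, model = model,
              max_mismatches = as.integer(max_mismatches),
              min_copies = as.integer(min_copies),
              reference_assay = reference_assay, seed = as.integer(seed))
  problems <- character()
  for (nm in c("fastq", "mature_ref", "contigs", "transcripts",
               "ncrna_ref", "ct_table")) {
    x <- cfg[[nm]]
    if (is.character(x) && length(x) == 1L && !file.exists(x)) {
      problems <- c(problems, sprintf("input '%s' not found: %s", nm, x))
    }
  }
  if (length(problems)) {
    stop(paste(problems, collapse = "\n"), call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

resolve_input <- function(x, reader) {
  if (is.null(x) || !is.character(x)) return(x)
  reader(x)
}

#' Run the full small-RNA analysis pipeline
#'
#' Stages run in fixed order: preprocessing, conserved classification,
#' novel discovery (when contigs are provided), target prediction and
#' network construction (when transcripts are provided), and qPCR
#' quantification (when a Ct table is provided). When `out_dir` is set,
#' every stage writes its TSV and a JSON manifest records seeds and
#' thresholds, so a rerun into a clean directory reproduces identical
#' files.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `mirseedling_run` with elements `preprocess`,
#'   `conserved`, `families`, `novel`, `sites`, `network`, `qpcr`,
#'   `summary`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  reads <- resolve_input(config$fastq, read_fastq)
  mature <- resolve_input(config$mature_ref, read_fasta)
  if (!is.null(mature) && !"mirbase_id" %in% names(mature)) {
    mature <- dplyr::rename(mature, mirbase_id = "seq_id")
  }
  ncrna <- resolve_input(config$ncrna_ref, read_fasta)
  contigs <- resolve_input(config$contigs, read_fasta)
  transcripts <- resolve_input(config$transcripts, read_fasta)
  ct <- resolve_input(config$ct_table, read_ct_table)

  prep <- run_preprocess(reads, config$preprocess, ncrna)
  cons <- classify_conserved(prep$tags, mature, config$max_mismatches)
  novel <- NULL
  if (!is.null(contigs)) {
    novel <- call_novel(cons$unmatched, contigs, config$model,
                        config$criteria)
  }
  sites <- NULL
  network <- NULL
  if (!is.null(transcripts)) {
    queries <- dplyr::bind_rows(
      if (nrow(cons$hits)) dplyr::transmute(cons$hits,
                                            name = .data$assigned_name,
                                            sequence = .data$sequence,
                                            count = .data$count),
      if (!is.null(novel) && nrow(novel)) dplyr::transmute(
        novel, name = .data$name, sequence = to_dna(.data$sequence),
        count = .data$read_count))
    sites <- predict_targets(queries, transcripts, config$scheme,
                             config$model, config$min_copies)
    network <- build_network(sites)
  }
  qpcr <- if (!is.null(ct)) {
    relative_expression(ct, config$reference_assay)
  }

  summary_tbl <- dplyr::bind_rows(
    prep$accounting |>
      dplyr::transmute(item = paste0("reads_", .data$category),
                       value = .data$reads),
    tibble(item = c("unique_tags", "conserved_tags", "conserved_families",
                    "novel_mirnas", "target_sites"),
           value = c(nrow(prep$tags), nrow(cons$hits),
                     nrow(summarize_families(cons$hits)),
                     if (is.null(novel)) NA_integer_ else nrow(novel),
                     if (is.null(sites)) NA_integer_ else nrow(sites))))

  result <- structure(list(preprocess = prep, conserved = cons$hits,
                           unmatched = cons$unmatched,
                           families = summarize_families(cons$hits),
                           novel = novel, sites = sites, network = network,
                           qpcr = qpcr, summary = summary_tbl,
                           config = config),
                      class = "mirseedling_run")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    w <- function(x, f) if (!is.null(x)) readr::write_tsv(x, file.path(config$out_dir, f))
    w(prep$tags, "clean_tags.tsv")
    w(prep$accounting, "read_accounting.tsv")
    w(tibble::as_tibble(prep$length_dist), "length_distribution.tsv")
    w(dplyr::select(cons$hits, -dplyr::any_of("structure")), "conserved_mirnas.tsv")
    w(result$families, "family_summary.tsv")
    if (!is.null(novel)) {
      w(dplyr::select(novel, "name", "sequence", "length", "read_count",
                      "strand", "mfei"), "novel_mirnas.tsv")
      write_fasta(tibble(seq_id = novel$name,
                         sequence = novel$precursor_seq),
                  file.path(config$out_dir, "novel_precursors.fasta"))
      rej <- attr(novel, "candidates")
      if (!is.null(rej) && nrow(rej)) {
        w(dplyr::select(rej, -dplyr::any_of("structure")),
          "precursor_candidates.tsv")
      }
    }
    w(sites, "target_sites.tsv")
    if (!is.null(network)) write_network(network, file.path(config$out_dir, "network"))
    w(qpcr, "qpcr_results.tsv")
    w(summary_tbl, "run_summary.tsv")
    manifest <- list(package = "mirseedling",
                     version = as.character(utils::packageVersion("mirseedling")),
                     seed = config$seed,
                     max_mismatches = config$max_mismatches,
                     min_copies = config$min_copies,
                     min_mfei = config$criteria$min_mfei,
                     min_len = config$preprocess$min_len,
                     max_len = config$preprocess$max_len,
                     min_mean_quality = config$preprocess$min_mean_quality,
                     expectation_cutoff = config$scheme$cutoff)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  result
}

#' @export
print.mirseedling_run <- function(x, ...) {
  cat("mirseedling pipeline run\n")
  print(x$summary, n = Inf)
  invisible(x)
}
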