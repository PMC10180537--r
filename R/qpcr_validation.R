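# qPCR relative expression: Ct tables normalised to an endogenous control
# (U6), technical replicates collapsed first, 2^(-dCt) quantification.

#' Read a Ct table
#'
#' Expects a TSV with columns `assay_id`, `sample_id`, `replicate`, `ct`.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_ct_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    assay_id = readr::col_character(),
    sample_id = readr::col_character(),
    replicate = readr::col_integer(),
    ct = readr::col_double()))
}

#' Relative expression normalised to an endogenous control
#'
#' Technical replicates are averaged first within each (assay, sample);
#' then per sample `dCt = Ct_assay - Ct_reference`, and the assay's
#' relative expression is `2^(-mean dCt)` over samples (efficiency
#' configurable), with the SD taken over the per-sample `2^(-dCt)` values.
#' Assay/reference measurements are paired by `sample_id`; a sample present
#' for an assay but missing for the reference is an error.
#'
#' @param ct_data Tibble with columns `assay_id`, `sample_id`, `replicate`,
#'   `ct` (Ct in cycles, 0-45).
#' @param reference_assay Name of the endogenous control assay
#'   (default `"U6"`).
#' @param efficiency Amplification base (default 2).
#' @return A tibble of class `qpcr_result` with columns `assay_id`,
#'   `n_samples`, `mean_dct`, `relative_expression`, `sd`.
#' @export
relative_expression <- function(ct_data, reference_assay = "U6",
                                efficiency = 2) {
  stopifnot(all(c("assay_id", "sample_id", "ct") %in% names(ct_data)))
  if (any(ct_data$ct <= 0 | ct_data$ct >= 45)) {
    stop("Ct values must lie in (0, 45) cycles", call. = FALSE)
  }
  if (!reference_assay %in% ct_data$assay_id) {
    stop(sprintf("reference assay '%s' not present", reference_assay),
         call. = FALSE)
  }
  tech <- ct_data |>
    dplyr::group_by(.data$assay_id, .data$sample_id) |>
    dplyr::summarise(ct = mean(.data$ct), .groups = "drop")
  ref <- tech[tech$assay_id == reference_assay,
              c("sample_id", "ct")]
  names(ref)[2] <- "ct_ref"
  tgt <- tech[tech$assay_id != reference_assay, ]
  missing_ref <- setdiff(unique(tgt$sample_id), ref$sample_id)
  if (length(missing_ref)) {
    stop(sprintf("sample(s) without reference measurement: %s",
                 paste(missing_ref, collapse = ", ")), call. = FALSE)
  }
  out <- tgt |>
    dplyr::inner_join(ref, by = "sample_id") |>
    dplyr::mutate(dct = .data$ct - .data$ct_ref,
                  rel = efficiency^(-.data$dct)) |>
    dplyr::group_by(.data$assay_id) |>
    dplyr::summarise(n_samples = dplyr::n(),
                     mean_dct = mean(.data$dct),
                     relative_expression = efficiency^(-mean(.data$dct)),
                     sd = stats::sd(.data$rel),
                     .groups = "drop") |>
    dplyr::mutate(sd = ifelse(is.na(.data$sd), 0, .data$sd)) |>
    dplyr::arrange(.data$assay_id)
  class(out) <- c("qpcr_result", class(out))
  attr(out, "reference_assay") <- reference_assay
  attr(out, "efficiency") <- efficiency
  out
}

#' Fold change between two conditions (ddCt form)
#'
#' `2^(-(dCt_a - dCt_b))` using each condition's mean dCt; satisfies
#' `fold_change(a, b) * fold_change(b, a) == 1`.
#'
#' @param condition_a,condition_b `qpcr_result` rows (or tibbles) for the
#'   same assay(s), matched by `assay_id`.
#' @return A tibble with `assay_id`, `ddct`, `fold_change`.
#' @export
fold_change <- function(condition_a, condition_b) {
  eff <- attr(condition_a, "efficiency")
  if (is.null(eff)) eff <- 2
  dplyr::inner_join(
    condition_a[, c("assay_id", "mean_dct")],
    condition_b[, c("assay_id", "mean_dct")],
    by = "assay_id", suffix = c("_a", "_b")) |>
    dplyr::mutate(ddct = .data$mean_dct_a - .data$mean_dct_b,
                  fold_change = eff^(-.data$ddct)) |>
    dplyr::select("assay_id", "ddct", "fold_change")
}

#' Long-format table for expression bar charts
#'
#' @param result A `qpcr_result`.
#' @return A tibble with `assay_id`, `relative_expression`, `ymin`, `ymax`
#'   (mean +/- SD, floored at 0), ordered by expression descending.
#' @export
qpcr_plot_table <- function(result) {
  result |>
    dplyr::transmute(assay_id = .data$assay_id,
                     relative_expression = .data$relative_expression,
                     ymin = pmax(0, .data$relative_expression - .data$sd),
                     ymax = .data$relative_expression + .data$sd) |>
    dplyr::arrange(dplyr::desc(.data$relative_expression))
}
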