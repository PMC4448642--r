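# Whole-chromosome copy-number calls from relative DNA sequencing depth.

#' Call chromosome copy number from relative DNA depth
#'
#' Per strain and chromosome, takes the median of per-gene log2 DNA
#' abundance ratios relative to a euploid control (subtelomeric genes
#' excluded) and maps it through half-open threshold windows:
#' `[t3_low, t4_low)` calls 3 copies, `[t4_low, Inf)` calls 4 copies,
#' anything below `t3_low` stays at the diploid baseline of 2. The defaults
#' (0.4 and 0.7 on the log2 scale) bracket the expected trisomic
#' (`log2(3/2) = 0.585`) and tetrasomic (`log2(2) = 1`) depth shifts.
#'
#' Chromosomes with fewer than `min_genes` informative genes are still
#' called but flagged `low_confidence`.
#'
#' @param ratios Long tibble of per-gene DNA log2 ratios. Accepts either the
#'   output of [compute_log_ratios()] (columns `gene_id`, `sample_id`,
#'   `log2_ratio`, optionally `strain`) or a ratio panel (column `x` used,
#'   one value per gene and strain).
#' @param ann Annotation tibble with `gene_id`, `chromosome`, `subtelomeric`.
#' @param t3_low,t4_low Lower edges of the trisomy / tetrasomy windows.
#' @param min_genes Minimum informative genes for a confident call.
#' @return A tibble `strain`, `chromosome`, `median_log2`, `copies`,
#'   `n_genes`, `low_confidence`.
#' @export
call_chromosome_copy <- function(ratios, ann, t3_low = 0.4, t4_low = 0.7,
                                 min_genes = 10) {
  if (t3_low >= t4_low) rlang::abort("need t3_low < t4_low")
  value_col <- if ("x" %in% names(ratios)) "x" else "log2_ratio"
  group_col <- if ("strain" %in% names(ratios)) "strain" else "sample_id"
  keep <- ann |> filter(!.data$subtelomeric) |>
    select("gene_id", "chromosome")
  calls <- ratios |>
    distinct(.data$gene_id, .data[[group_col]], .keep_all = TRUE) |>
    inner_join(keep, by = "gene_id") |>
    group_by(strain = .data[[group_col]], .data$chromosome) |>
    summarise(median_log2 = stats::median(.data[[value_col]]),
              n_genes = dplyr::n(), .groups = "drop") |>
    mutate(
      copies = case_when(
        .data$median_log2 >= t4_low ~ 4L,
        .data$median_log2 >= t3_low ~ 3L,
        TRUE ~ 2L),
      low_confidence = .data$n_genes < min_genes)
  if (any(calls$low_confidence)) {
    rlang::inform(paste0(sum(calls$low_confidence),
                         " chromosome calls are low-confidence (< ",
                         min_genes, " informative genes)"))
  }
  calls |>
    select("strain", "chromosome", "median_log2", "copies", "n_genes",
           "low_confidence")
}
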