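# Classification of amplified genes in aneuploid-euploid strain pairs using
# chromosome-calibrated, gene-specific expression cutoffs.

#' Gene-specific mRNA cutoffs from the chromosome-wide DNA distribution
#'
#' For one amplified chromosome in one strain pair: takes each gene's mean
#' log2 DNA ratio over replicates and subtracts `sd_multiplier` times the
#' chromosome-wide standard deviation of those per-gene DNA ratios. A gene
#' whose mRNA ratio falls below this cutoff in every replicate is expressed
#' lower than its copy number predicts. Use `sd_multiplier = 2` for strains
#' with a single mRNA replicate (a stricter cutoff compensating the lost
#' replicate requirement).
#'
#' Subtelomeric genes must be excluded beforehand (they are dropped here via
#' the annotation flag): their copy number varies between strains and skews
#' the chromosome-wide statistics.
#'
#' @param panel Ratio panel tibble restricted to one strain
#'   (`gene_id`, `x`, `y`, replicate rows).
#' @param ann Annotation tibble (`gene_id`, `chromosome`, `subtelomeric`).
#' @param chromosome Chromosome whose amplified genes are being scored.
#' @param sd_multiplier Number of chromosome-wide SDs to subtract (default 1).
#' @return A tibble `gene_id`, `dna_mean`, `cutoff`, `chromosome_sd`.
#' @export
compute_gene_cutoffs <- function(panel, ann, chromosome, sd_multiplier = 1) {
  genes <- ann |>
    filter(.data$chromosome == !!chromosome, !.data$subtelomeric) |>
    pull("gene_id")
  per_gene <- panel |>
    filter(.data$gene_id %in% genes) |>
    group_by(.data$gene_id) |>
    summarise(dna_mean = mean(.data$x), .groups = "drop")
  if (nrow(per_gene) == 0L) {
    rlang::abort(paste0("no retained genes on chromosome ", chromosome))
  }
  if (nrow(per_gene) < 2L) {
    rlang::abort("need at least 2 genes to estimate the chromosome-wide SD")
  }
  chr_sd <- stats::sd(per_gene$dna_mean)
  per_gene |>
    mutate(cutoff = .data$dna_mean - sd_multiplier * chr_sd,
           chromosome_sd = chr_sd)
}

#' Classify amplified genes in a strain pair
#'
#' Applies the rule set for aneuploid-euploid pairs, with strict
#' inequalities throughout:
#'
#' * `excluded_repressed` — some replicate `y` below `repressed` (default
#'   -0.6, i.e. more than 1.5-fold *below* the euploid control; such genes
#'   are likely affected by something other than failed dosage response);
#' * `lower_than_expected` — every replicate `y` below the gene's cutoff
#'   (dosage compensation candidate);
#' * `excluded_overexpressed` — every replicate at/above the cutoff but some
#'   replicate above `overexpressed` (default `log2(2.5)`);
#' * `higher_than_expected` — every replicate at/above the cutoff, within
#'   the overexpression bound, and `y >= x + amplified_margin` (default
#'   `log2(1.5)`) in every replicate;
#' * `proportionate` — every replicate at/above the cutoff and within
#'   bounds; `unscored` — replicates disagree about the cutoff, or the gene
#'   has no cutoff.
#'
#' `margin_on` selects whether the 1.5-fold margin is measured against the
#' copy-number expectation (`y - x`, default) or the euploid control (`y`).
#'
#' @param panel Ratio panel tibble for one strain (replicate rows per gene).
#' @param cutoffs Output of [compute_gene_cutoffs()].
#' @param repressed Lower exclusion bound on `y` (log2; default -0.6).
#' @param overexpressed Upper exclusion bound on `y` (default `log2(2.5)`).
#' @param amplified_margin Margin for the higher-than-expected flag
#'   (default `log2(1.5)`).
#' @param margin_on `"expected"` or `"euploid"`.
#' @return A tibble `gene_id`, `strain`, `dna_mean`, `cutoff`, `call`,
#'   `n_replicates`, `y_values` (list column).
#' @export
classify_pairwise <- function(panel, cutoffs,
                              repressed = -0.6,
                              overexpressed = log2(2.5),
                              amplified_margin = log2(1.5),
                              margin_on = c("expected", "euploid")) {
  margin_on <- match.arg(margin_on)
  strain <- if ("strain" %in% names(panel)) panel$strain[1] else NA_character_
  by_gene <- panel |>
    group_by(.data$gene_id) |>
    summarise(y_values = list(.data$y), .groups = "drop") |>
    left_join(cutoffs |> select("gene_id", "dna_mean", "cutoff"),
              by = "gene_id")
  call_one <- function(y, dna_mean, cutoff) {
    if (is.na(cutoff)) return("unscored")
    if (any(y < repressed)) return("excluded_repressed")
    if (all(y < cutoff)) return("lower_than_expected")
    if (all(y >= cutoff)) {
      if (any(y > overexpressed)) return("excluded_overexpressed")
      margin_base <- if (margin_on == "expected") y - dna_mean else y
      if (all(margin_base >= amplified_margin)) return("higher_than_expected")
      return("proportionate")
    }
    "unscored"
  }
  by_gene |>
    mutate(strain = strain,
           call = purrr::pmap_chr(
             list(.data$y_values, .data$dna_mean, .data$cutoff), call_one),
           n_replicates = purrr::map_int(.data$y_values, length)) |>
    select("gene_id", "strain", "dna_mean", "cutoff", "call",
           "n_replicates", "y_values")
}

#' Cross-strain common-response filter for unamplified genes
#'
#' Flags genes whose expression differs from the euploid control by more
#' than `fold_threshold` (log2; default 0.4, i.e. 1.3-fold) in at least
#' `min_strains` strains. With `consistent_sign = TRUE` (default) the
#' responding strains must all move in the same direction, yielding
#' separate up- and down-regulated sets. Inequalities are strict: a gene at
#' exactly the threshold in the minimum number of strains is excluded.
#'
#' Restrict the input to chromosomes that are *not* amplified in the
#' respective strain before calling.
#'
#' @param multi_strain Long tibble `gene_id`, `strain`, `y`.
#' @param fold_threshold Log2 change threshold (default 0.4).
#' @param min_strains Minimum number of responding strains (default 3).
#' @param consistent_sign Require a common direction (default TRUE).
#' @return A tibble `gene_id`, `n_up`, `n_down`, `included`, `direction`.
#' @export
common_response_filter <- function(multi_strain, fold_threshold = 0.4,
                                   min_strains = 3, consistent_sign = TRUE) {
  n_strains <- dplyr::n_distinct(multi_strain$strain)
  if (n_strains < min_strains) {
    rlang::abort(paste0("only ", n_strains, " strains present; need >= ",
                        min_strains))
  }
  out <- multi_strain |>
    group_by(.data$gene_id) |>
    summarise(n_up = sum(.data$y > fold_threshold),
              n_down = sum(.data$y < -fold_threshold),
              .groups = "drop")
  if (consistent_sign) {
    out <- out |> mutate(
      included = .data$n_up >= min_strains | .data$n_down >= min_strains,
      direction = case_when(
        .data$n_up >= min_strains & .data$n_down >= min_strains ~ "mixed",
        .data$n_up >= min_strains ~ "up",
        .data$n_down >= min_strains ~ "down",
        TRUE ~ NA_character_))
    # a gene cannot respond up in >= k strains and down in >= k of 6 when
    # k > n/2; "mixed" only arises for small min_strains and is excluded
    out$included[out$direction %in% "mixed"] <- FALSE
  } else {
    out <- out |> mutate(
      included = (.data$n_up + .data$n_down) >= min_strains,
      direction = case_when(
        !.data$included ~ NA_character_,
        .data$n_up >= .data$n_down ~ "up",
        TRUE ~ "down"))
  }
  out
}
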