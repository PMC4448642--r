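# ggplot2 views of the main result types.

#' Per-gene depth ratios along a chromosome with ploidy windows
#'
#' @param ratios Long DNA ratio tibble (`gene_id`, `log2_ratio` or `x`).
#' @param ann Annotation tibble (`gene_id`, `chromosome`, `start`).
#' @param t3_low,t4_low Ploidy window edges drawn as horizontal guides.
#' @return A ggplot object.
#' @export
plot_chromosome_depth <- function(ratios, ann, t3_low = 0.4, t4_low = 0.7) {
  value_col <- if ("x" %in% names(ratios)) "x" else "log2_ratio"
  df <- ratios |>
    distinct(.data$gene_id, .keep_all = TRUE) |>
    inner_join(ann |> select("gene_id", "chromosome", "start"),
               by = "gene_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$start / 1e3,
                                   y = .data[[value_col]])) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = c(0, t3_low, t4_low),
                        linetype = c("solid", "dashed", "dashed"),
                        colour = c("grey40", "steelblue", "firebrick")) +
    ggplot2::facet_wrap(~chromosome, scales = "free_x") +
    ggplot2::labs(x = "position (kb)", y = "log2 DNA ratio vs euploid") +
    ggplot2::theme_minimal()
}

#' Dose-response scatter of a strain pair, colored by call
#'
#' @param classification Output of [classify_pairwise()].
#' @return A ggplot object.
#' @export
plot_pairwise <- function(classification) {
  df <- classification |>
    tidyr::unnest_longer("y_values", values_to = "y")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dna_mean, y = .data$y,
                                   colour = .data$call)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::labs(x = "log2 DNA ratio (gene mean)",
                  y = "log2 mRNA ratio (replicate)") +
    ggplot2::theme_minimal()
}

#' Plot a fitted mixture of linear regressions
#'
#' Shows each gene's OLS (intercept, slope) colored by its max-posterior
#' class, with the constraint lines `slope = 1` and `intercept = 0`.
#'
#' @param object An `mlr_fit`.
#' @param ... Unused.
#' @method autoplot mlr_fit
#' @return A ggplot object.
#' @export
autoplot.mlr_fit <- function(object, ...) {
  df <- classify_genes(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ols_slope,
                                   y = .data$ols_intercept,
                                   colour = .data$class)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::geom_vline(xintercept = 1, colour = "grey60") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::labs(x = "per-gene OLS slope", y = "per-gene OLS intercept",
                  colour = "class") +
    ggplot2::theme_minimal()
}

#' Group comparison boxplots for buffering metrics
#'
#' @param records Tibble from [compute_bv()].
#' @param groups Named list of gene-id vectors.
#' @param metric `"log2_vgvm"` or `"log2_bv"`.
#' @return A ggplot object.
#' @export
plot_buffering_groups <- function(records, groups,
                                  metric = c("log2_vgvm", "log2_bv")) {
  metric <- match.arg(metric)
  v <- if (metric == "log2_vgvm") log2(records$vgvm) else log2(records$Bv)
  base <- tibble(gene_id = records$gene_id, value = v)
  df <- bind_rows(
    base |> mutate(group = "all genes"),
    purrr::imap(groups, \(ids, nm) base |>
                  filter(.data$gene_id %in% ids) |> mutate(group = nm)))
  ggplot2::ggplot(df |> filter(is.finite(.data$value)),
                  ggplot2::aes(x = .data$group, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
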