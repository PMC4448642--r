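# CNV-buffering analysis: amplification calls from aCGH, strain
# deduplication, profile-similarity weights, the Vg/Vm expression-constraint
# ratio, and the buffering score Bv.

cgh_matrix <- function(cgh) {
  m <- as.matrix(cgh[setdiff(names(cgh), "strain_id")])
  rownames(m) <- cgh$strain_id
  m
}

#' Call gene amplifications from relative aCGH abundance
#'
#' An entry is amplified when the strain's relative gene abundance reaches
#' `fold` (default 1.6) times the reference.
#'
#' @param cgh Wide tibble: `strain_id` plus one positive-abundance column
#'   per gene.
#' @param fold Amplification fold threshold (> 1; default 1.6).
#' @return A logical tibble of the same shape.
#' @export
call_amplifications <- function(cgh, fold = 1.6) {
  if (fold <= 1) rlang::abort("fold must be > 1")
  m <- cgh_matrix(cgh)
  if (any(!is.finite(m)) || any(m <= 0)) {
    rlang::abort("relative abundance must be positive and finite")
  }
  out <- as_tibble(as.data.frame(m >= fold))
  bind_cols(tibble(strain_id = cgh$strain_id), out)
}

strain_correlation <- function(cgh) {
  m <- cgh_matrix(cgh)
  stats::cor(t(m))
}

#' Collapse near-identical strains to single representatives
#'
#' Strains whose aCGH profiles correlate above `r_threshold` are grouped by
#' single-linkage (connected components over high-correlation pairs) and
#' each group is represented by one randomly chosen member, so that highly
#' related strains do not dominate downstream amplification counts.
#'
#' @param cgh Wide aCGH tibble.
#' @param r_threshold Pearson correlation threshold (default 0.9, strict
#'   `>`).
#' @param seed Seed for the random choice of representative.
#' @return A list: `retained` (character vector of strain ids) and `groups`
#'   (tibble `strain_id`, `group`, `retained`).
#' @export
deduplicate_strains <- function(cgh, r_threshold = 0.9, seed = 1L) {
  ids <- cgh$strain_id
  n <- length(ids)
  if (n < 2) {
    return(list(retained = ids,
                groups = tibble(strain_id = ids, group = seq_len(n),
                                retained = TRUE)))
  }
  r <- strain_correlation(cgh)
  adj <- r > r_threshold
  diag(adj) <- FALSE
  # connected components by BFS (single linkage)
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    k <- k + 1L
    queue <- i
    comp[i] <- k
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & is.na(comp))
      comp[nb] <- k
      queue <- c(queue, nb)
    }
  }
  retained <- with_seed(seed, {
    vapply(split(seq_len(n), comp), function(m) m[sample.int(length(m), 1)],
           integer(1))
  })
  keep <- ids[sort(unname(retained))]
  list(retained = keep,
       groups = tibble(strain_id = ids, group = comp,
                       retained = ids %in% keep))
}

#' Per-strain similarity weights
#'
#' Down-weights strains with close relatives so that shared (inherited)
#' amplification events are not counted once per relative. The weight is
#' the scheme used by hierarchical-clustering tools:
#' `w_i = 1 / (1 + sum_{j != i} max(0, (r_ij - cutoff)/(1 - cutoff))^exponent)`,
#' so an isolated strain gets weight 1 and each member of a pair of exact
#' duplicates gets 1/2.
#'
#' @param cgh Wide aCGH tibble (weights are computed from profile Pearson
#'   correlations).
#' @param cutoff Correlation below which strains are considered unrelated
#'   (in `[0, 1)`; default 0.4).
#' @param exponent Sharpness of the similarity contribution (> 0; default 1).
#' @return A tibble `strain_id`, `weight` with weights in (0, 1].
#' @export
compute_similarity_weights <- function(cgh, cutoff = 0.4, exponent = 1) {
  if (cutoff < 0 || cutoff >= 1) rlang::abort("cutoff must be in [0, 1)")
  if (exponent <= 0) rlang::abort("exponent must be > 0")
  ids <- cgh$strain_id
  if (length(ids) == 1) return(tibble(strain_id = ids, weight = 1))
  r <- strain_correlation(cgh)
  contrib <- pmax((r - cutoff) / (1 - cutoff), 0)^exponent
  diag(contrib) <- 0
  tibble(strain_id = ids, weight = unname(1 / (1 + rowSums(contrib))))
}

#' Expression-constraint ratio Vg/Vm
#'
#' `V_g` is the sample variance of a gene's expression across wild isolates
#' (mutation plus selection); `V_m` the sample variance across
#' mutation-accumulation lines (mutation with minimal selection). Small
#' `V_g / V_m` marks genes whose expression variation is removed by
#' purifying selection.
#'
#' @param wild_expression Tibble `gene_id` plus one column per wild strain.
#' @param ma_expression Tibble `gene_id` plus one column per MA line.
#' @param min_values Minimum informative (non-missing) values per gene on
#'   each side (default 3); genes below it are flagged, not dropped.
#' @return A tibble `gene_id`, `n_wild`, `n_ma`, `V_g`, `V_m`, `vgvm`,
#'   `flag` (`"ok"`, `"insufficient_data"`, `"vm_zero"`).
#' @export
compute_vg_vm <- function(wild_expression, ma_expression, min_values = 3) {
  row_var <- function(x) {
    m <- as.matrix(x[setdiff(names(x), "gene_id")])
    n <- rowSums(!is.na(m))
    v <- apply(m, 1, stats::var, na.rm = TRUE)
    tibble(gene_id = x$gene_id, n = n, v = v)
  }
  w <- row_var(wild_expression)
  m <- row_var(ma_expression)
  out <- w |>
    rename(n_wild = "n", V_g = "v") |>
    inner_join(m |> rename(n_ma = "n", V_m = "v"), by = "gene_id") |>
    mutate(
      flag = case_when(
        .data$n_wild < min_values | .data$n_ma < min_values ~ "insufficient_data",
        .data$V_m <= 0 ~ "vm_zero",
        TRUE ~ "ok"),
      vgvm = ifelse(.data$flag == "ok", .data$V_g / .data$V_m, NA_real_))
  if (any(out$flag != "ok")) {
    rlang::inform(paste0(sum(out$flag != "ok"),
                         " genes flagged (insufficient data or zero V_m)"))
  }
  out |> select("gene_id", "n_wild", "n_ma", "V_g", "V_m", "vgvm", "flag")
}

#' CNV-buffering score Bv
#'
#' For each gene, sums amplification events over strains weighted by the
#' strain similarity weights (so clusters of related strains contribute
#' about one event), then divides by the gene's `V_g / V_m`. Large scores
#' mark genes that are frequently amplified in natural populations yet
#' tightly constrained in expression — the signature of buffered copy
#' number.
#'
#' @param amp Logical amplification tibble from [call_amplifications()]
#'   (deduplicated strains).
#' @param weights Tibble `strain_id`, `weight` from
#'   [compute_similarity_weights()] on the same strains.
#' @param vgvm Tibble `gene_id`, `vgvm` (plus optional columns, kept) from
#'   [compute_vg_vm()].
#' @return A tibble per gene: `gene_id`, `V_g`, `V_m`, `vgvm`, `amp_count`,
#'   `weighted_amp`, `Bv`, `Bv_defined`.
#' @export
compute_bv <- function(amp, weights, vgvm) {
  if (!setequal(amp$strain_id, weights$strain_id)) {
    rlang::abort("strain sets of amplification matrix and weights differ")
  }
  m <- cgh_matrix(amp)
  w <- weights$weight[match(rownames(m), weights$strain_id)]
  weighted_amp <- unname(colSums(m * w))
  amp_count <- unname(colSums(m))
  res <- tibble(gene_id = colnames(m),
                amp_count = as.integer(amp_count),
                weighted_amp = weighted_amp)
  keep_cols <- intersect(c("gene_id", "V_g", "V_m", "vgvm"), names(vgvm))
  out <- res |> inner_join(vgvm[keep_cols], by = "gene_id")
  out |>
    mutate(
      Bv_defined = .data$weighted_amp == 0 |
        (!is.na(.data$vgvm) & .data$vgvm > 0),
      Bv = case_when(
        .data$weighted_amp == 0 ~ 0,
        is.na(.data$vgvm) | .data$vgvm <= 0 ~ NA_real_,
        TRUE ~ .data$weighted_amp / .data$vgvm)) |>
    select(dplyr::any_of(c("gene_id", "V_g", "V_m", "vgvm", "amp_count",
                           "weighted_amp", "Bv", "Bv_defined")))
}

#' Compare gene groups on constraint, CNV and buffering metrics
#'
#' For each named gene group, summarizes a metric and scores a two-sided
#' Wilcoxon rank-sum test of the group against the full set of scored
#' genes. Metrics: `log2_vgvm` (expression constraint), `cnv_fraction`
#' (share of genes amplified in at least one retained strain), `log2_bv`
#' (buffering score). An optional permutation test on the difference of
#' group mean vs overall mean is available via `n_perm`.
#'
#' @param records Tibble from [compute_bv()].
#' @param groups Named list of gene-id character vectors.
#' @param metric One of `"log2_vgvm"`, `"cnv_fraction"`, `"log2_bv"`.
#' @param n_perm If > 0, also compute a permutation p-value with this many
#'   permutations.
#' @param seed Seed for the permutation test.
#' @return A tibble `group`, `metric`, `n`, `median`, `p_value`
#'   (and `p_perm` when requested).
#' @export
compare_groups <- function(records, groups,
                           metric = c("log2_vgvm", "cnv_fraction", "log2_bv"),
                           n_perm = 0, seed = 1L) {
  metric <- match.arg(metric)
  vals <- switch(metric,
    log2_vgvm = stats::setNames(log2(records$vgvm), records$gene_id),
    cnv_fraction = stats::setNames(as.numeric(records$amp_count >= 1),
                                   records$gene_id),
    log2_bv = stats::setNames(log2(records$Bv), records$gene_id))
  vals <- vals[is.finite(vals)]
  all_vals <- unname(vals)
  one <- function(name, ids) {
    if (!length(ids)) rlang::abort(paste0("empty group: ", name))
    gv <- vals[intersect(ids, names(vals))]
    if (!length(gv)) rlang::abort(paste0("group has no scored genes: ", name))
    p <- suppressWarnings(
      stats::wilcox.test(unname(gv), all_vals, exact = FALSE)$p.value)
    res <- tibble(group = name, metric = metric, n = length(gv),
                  median = stats::median(gv), p_value = p)
    if (n_perm > 0) {
      obs <- mean(gv) - mean(all_vals)
      perm <- with_seed(seed, {
        replicate(n_perm, {
          mean(sample(all_vals, length(gv))) - mean(all_vals)
        })
      })
      res$p_perm <- (1 + sum(abs(perm) >= abs(obs))) / (n_perm + 1)
    }
    res
  }
  bind_rows(purrr::imap(groups, \(ids, nm) one(nm, ids)))
}
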