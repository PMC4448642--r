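#' @importFrom rlang .data abort warn inform `%||%`
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# ---- validation helpers -----------------------------------------------------

sample_cols <- function(x) setdiff(names(x), c("gene_id", "length_bp"))

validate_count_matrix <- function(x, what = "count matrix") {
  if (nrow(x) == 0L) abort(paste0(what, ": no genes"))
  if (!all(c("gene_id", "length_bp") %in% names(x))) {
    abort(paste0(what, ": needs columns 'gene_id' and 'length_bp'"))
  }
  dup <- x$gene_id[duplicated(x$gene_id)]
  if (length(dup)) {
    abort(paste0(what, ": duplicate gene ids: ", paste(unique(dup), collapse = ", ")))
  }
  if (any(!is.finite(x$length_bp)) || any(x$length_bp <= 0)) {
    bad <- x$gene_id[!is.finite(x$length_bp) | x$length_bp <= 0]
    abort(paste0(what, ": nonpositive or missing gene length for: ",
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  sc <- sample_cols(x)
  if (!length(sc)) abort(paste0(what, ": no sample columns"))
  for (s in sc) {
    v <- x[[s]]
    if (!is.numeric(v)) abort(paste0(what, ": non-numeric counts in sample ", s))
    if (anyNA(v) || any(v < 0)) {
      bad <- x$gene_id[is.na(v) | v < 0][1]
      abort(paste0(what, ": negative or missing count for gene ", bad,
                   " in sample ", s))
    }
  }
  invisible(x)
}

# ---- readers / writers ------------------------------------------------------

#' Read a per-gene count matrix
#'
#' The expected format is tab-separated with a header row: first column
#' `gene_id`, second `length_bp`, and one integer column of summed read
#' counts per sample. Input gene order is preserved.
#'
#' @param path Path to a TSV file.
#' @param assay `"mRNA"` or `"DNA"`; recorded as an attribute.
#' @return A tibble with columns `gene_id`, `length_bp` and one column per
#'   sample, with attribute `assay`.
#' @export
read_count_matrix <- function(path, assay = c("mRNA", "DNA")) {
  assay <- match.arg(assay)
  x <- suppressWarnings(
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE))
  if (nrow(x) == 0L || ncol(x) < 3L) abort("no genes in count matrix file")
  names(x)[1:2] <- c("gene_id", "length_bp")
  x <- validate_count_matrix(as_tibble(x), what = basename(path))
  attr(x, "assay") <- assay
  x
}

#' Write a count matrix as TSV
#' @param x Count tibble as returned by [read_count_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Read a gene annotation table
#'
#' TSV with columns `gene_id`, `chromosome`, `start`, `end` (1-based,
#' inclusive) and optional `subtelomeric` (0/1). Genes near chromosome ends
#' are routinely excluded from chromosome-wide statistics because their copy
#' number varies between strains; if the flag is absent it can be derived
#' with [derive_subtelomeric()].
#'
#' @param path Path to a TSV file.
#' @return A tibble with a logical `subtelomeric` column.
#' @export
read_annotation <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("gene_id", "chromosome", "start", "end")
  if (!all(need %in% names(x))) {
    abort(paste0("annotation needs columns: ", paste(need, collapse = ", ")))
  }
  if (any(x$start > x$end)) abort("annotation: start > end")
  if (anyDuplicated(x$gene_id)) abort("annotation: duplicate gene ids")
  if (!"subtelomeric" %in% names(x)) x$subtelomeric <- FALSE
  x$subtelomeric <- as.logical(x$subtelomeric)
  as_tibble(x)
}

#' Flag subtelomeric genes by distance to the chromosome end
#'
#' @param ann Annotation tibble.
#' @param chrom_lengths Named vector (or tibble with `chromosome`, `length_bp`)
#'   of chromosome lengths.
#' @param margin_bp Genes starting within this distance of either end are
#'   flagged (default 25 kb).
#' @return `ann` with `subtelomeric` recomputed.
#' @export
derive_subtelomeric <- function(ann, chrom_lengths, margin_bp = 25000) {
  if (is.data.frame(chrom_lengths)) {
    len <- stats::setNames(chrom_lengths$length_bp, chrom_lengths$chromosome)
  } else {
    len <- chrom_lengths
  }
  L <- unname(len[as.character(ann$chromosome)])
  if (anyNA(L)) abort("chromosome length missing for some genes")
  ann$subtelomeric <- ann$start <= margin_bp | ann$end >= (L - margin_bp)
  ann
}

#' Read a sample sheet
#'
#' TSV with columns `sample_id`, `strain`, `assay` (mRNA|DNA), `dose`
#' (2n|3n|4n|pair), `replicate`, `reference_sample_id`.
#' @param path Path to a TSV file.
#' @return A tibble.
#' @export
read_sample_sheet <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", "strain", "assay", "dose", "replicate",
            "reference_sample_id")
  if (!all(need %in% names(x))) {
    abort(paste0("sample sheet needs columns: ", paste(need, collapse = ", ")))
  }
  as_tibble(x)
}

# ---- normalization ----------------------------------------------------------

#' Reads per kilobase per million mapped reads
#'
#' Normalizes raw counts for gene length and library size:
#' `rpkm[g, s] = counts[g, s] / (length_kb[g] * total[s] / 1e6)`, where
#' `total[s]` is the column sum of counts.
#'
#' @param counts Count tibble (`gene_id`, `length_bp`, sample columns).
#' @return A tibble of the same shape with RPKM values in the sample columns.
#' @export
compute_rpkm <- function(counts) {
  validate_count_matrix(counts, "compute_rpkm input")
  sc <- sample_cols(counts)
  out <- counts
  len_kb <- counts$length_bp / 1000
  for (s in sc) {
    total <- sum(counts[[s]])
    if (total <= 0) abort(paste0("sample ", s, ": zero total reads, RPKM undefined"))
    out[[s]] <- counts[[s]] / (len_kb * total / 1e6)
  }
  attr(out, "assay") <- attr(counts, "assay")
  out
}

# ---- log ratios -------------------------------------------------------------

#' Per-gene log2 abundance ratios versus a paired reference
#'
#' For each test sample and its paired reference sample computes
#' `log2((rpkm_test + pseudocount) / (rpkm_ref + pseudocount))`. Observations
#' where both members of a pair fall below `min_rpkm` are dropped (reported
#' via a message and the `n_dropped` attribute); a zero/zero ratio with
#' pseudocount 0 is likewise dropped with a warning rather than emitted as
#' NaN. `center = "median"` subtracts each sample's median ratio, which
#' removes the compositional shift that amplification of one chromosome
#' imposes on all other genes' relative abundances.
#'
#' @param test,reference RPKM tibbles from [compute_rpkm()].
#' @param pairing Named character vector mapping test sample id ->
#'   reference sample id, or a tibble with columns `sample_id` and
#'   `reference_sample_id`.
#' @param pseudocount Nonnegative value added to both numerator and
#'   denominator (default 0).
#' @param min_rpkm Minimum-abundance floor: an observation is kept when the
#'   test or the reference RPKM reaches it (default 1).
#' @param center `"none"` or `"median"`.
#' @return A long tibble `gene_id`, `sample_id`, `log2_ratio`.
#' @export
compute_log_ratios <- function(test, reference, pairing, pseudocount = 0,
                               min_rpkm = 1, center = c("none", "median")) {
  center <- match.arg(center)
  if (pseudocount < 0) abort("pseudocount must be >= 0")
  if (is.data.frame(pairing)) {
    pairing <- stats::setNames(pairing$reference_sample_id, pairing$sample_id)
  }
  test_samples <- names(pairing)
  missing_t <- setdiff(test_samples, sample_cols(test))
  missing_r <- setdiff(unname(pairing), sample_cols(reference))
  if (length(missing_t) || length(missing_r)) {
    abort(paste0("unmapped samples: ",
                 paste(c(missing_t, missing_r), collapse = ", ")))
  }
  common <- intersect(test$gene_id, reference$gene_id)
  ref_idx <- match(common, reference$gene_id)
  test_idx <- match(common, test$gene_id)

  n_dropped <- 0L
  zero_zero <- FALSE
  res <- purrr::map(test_samples, function(s) {
    t_v <- test[[s]][test_idx]
    r_v <- reference[[pairing[[s]]]][ref_idx]
    keep <- (t_v >= min_rpkm) | (r_v >= min_rpkm)
    ratio <- log2((t_v + pseudocount) / (r_v + pseudocount))
    bad <- !is.finite(ratio)
    if (any(bad & keep)) zero_zero <<- TRUE
    keep <- keep & !bad
    n_dropped <<- n_dropped + sum(!keep)
    tibble(gene_id = common[keep], sample_id = s, log2_ratio = ratio[keep])
  })
  out <- bind_rows(res)
  if (zero_zero) {
    warn("genes with undefined ratios (zero in both samples, pseudocount 0) were dropped")
  }
  if (n_dropped > 0) {
    inform(paste0(n_dropped, " low-abundance or undefined observations dropped"))
  }
  if (center == "median") {
    out <- out |>
      group_by(.data$sample_id) |>
      mutate(log2_ratio = .data$log2_ratio - stats::median(.data$log2_ratio)) |>
      ungroup()
  }
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Assemble a dosage-panel ratio table
#'
#' Joins per-sample mRNA log ratios (`y`) with strain-level DNA log ratios
#' (`x`, averaged over DNA replicates of the same strain) so each row is one
#' mRNA observation of one gene: `gene_id`, `sample_id`, `strain`, `dose`,
#' `x`, `y`.
#'
#' @param mrna_ratios,dna_ratios Long ratio tibbles from
#'   [compute_log_ratios()].
#' @param sample_sheet Tibble with at least `sample_id`, `strain`, `assay`,
#'   `dose`.
#' @return The ratio panel tibble.
#' @export
build_ratio_panel <- function(mrna_ratios, dna_ratios, sample_sheet) {
  ss <- sample_sheet
  dna_strain <- dna_ratios |>
    inner_join(ss |> filter(.data$assay == "DNA") |>
                 select("sample_id", "strain"), by = "sample_id") |>
    group_by(.data$gene_id, .data$strain) |>
    summarise(x = mean(.data$log2_ratio), .groups = "drop")
  mrna_ratios |>
    inner_join(ss |> filter(.data$assay == "mRNA") |>
                 select("sample_id", "strain", "dose"), by = "sample_id") |>
    rename(y = "log2_ratio") |>
    inner_join(dna_strain, by = c("gene_id", "strain")) |>
    select("gene_id", "sample_id", "strain", "dose", "x", "y")
}

#' Write / read a ratio panel TSV
#' @param panel Ratio panel tibble.
#' @param path File path.
#' @return `path` (write) or the tibble (read).
#' @export
write_ratio_panel <- function(panel, path) {
  readr::write_tsv(panel, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_ratio_panel
#' @export
read_ratio_panel <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
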