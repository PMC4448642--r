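# Synthetic dosage-panel, aCGH and variance-table generators with known truth.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

dose_copy <- c("2n" = 2, "3n" = 3, "4n" = 4)

#' Configuration for the dosage-panel simulator
#'
#' Defaults emulate an isogenic diploid panel carrying 2, 3 or 4 copies of
#' one chromosome, with amplified genes split over six dose-response classes:
#' nonlinear outliers, proportionate response (class 1), heritably shifted
#' intercept (2a down / 2b up), and sub-/super-proportional slope (3a / 3b).
#' Class proportions default to values typical of such panels (roughly 7%
#' nonlinear, 16% class 1, 28% 2a, 1% 2b, 28% 3a, 20% 3b).
#'
#' @param n_genes_amplified Genes on the amplified chromosome.
#' @param n_genes_background Genes on unamplified chromosomes. The default
#'   keeps the amplified chromosome at ~8% of the genome, as for a large
#'   yeast chromosome; ratio median-centering assumes the amplified
#'   fraction is a minority of genes.
#' @param doses Subset of `c("2n","3n","4n")`.
#' @param replicates_per_dose mRNA replicates per panel strain.
#' @param class_proportions Named probabilities over
#'   `c("nonlinear","1","2a","2b","3a","3b")`; must sum to 1.
#' @param residual_sd Log2-scale biological noise added per mRNA observation.
#' @param baseline_mean Mean expression baseline (expected reads per gene).
#'   The default emulates deeply sequenced libraries, where counting noise
#'   is small next to `residual_sd`, the biological noise scale.
#' @param dispersion Negative-binomial dispersion of mRNA counts (technical;
#'   biological variation enters through `residual_sd`); 0 gives
#'   deterministic rounded means.
#' @param dna_dispersion Negative-binomial dispersion of DNA counts
#'   (genomic coverage is more uniform than mRNA).
#' @param dna_depth_per_kb Expected DNA reads per kilobase at copy 2.
#' @param gene_length_bp Gene length (single value or per-gene vector).
#' @param baseline_sdlog Log-normal spread of per-gene expression baselines.
#' @param alpha_mean,alpha_sd Magnitude distribution of class 2a/2b intercepts
#'   (`alpha = -|N(alpha_mean, alpha_sd)|` for 2a, mirrored for 2b).
#' @param beta_range_3a,beta_range_3b Uniform slope ranges for classes 3a/3b.
#' @param class3_alpha_sd SD of the free Gaussian intercept in classes 3a/3b.
#' @param kink_size Minimum absolute dose-specific deviation given to
#'   nonlinear-class genes (applied at the top dose only).
#' @param seed Integer seed; the simulation is fully reproducible from it.
#' @return A list of class `panel_config`.
#' @export
panel_config <- function(n_genes_amplified = 500,
                         n_genes_background = 5500,
                         doses = c("2n", "3n", "4n"),
                         replicates_per_dose = 3,
                         class_proportions = c(nonlinear = 0.07, `1` = 0.16,
                                               `2a` = 0.28, `2b` = 0.01,
                                               `3a` = 0.28, `3b` = 0.20),
                         residual_sd = 0.15,
                         baseline_mean = 5000,
                         dispersion = 5e-4,
                         dna_dispersion = 5e-4,
                         dna_depth_per_kb = 2000,
                         gene_length_bp = 1000,
                         baseline_sdlog = 0.7,
                         alpha_mean = 0.4, alpha_sd = 0.15,
                         beta_range_3a = c(0.2, 0.8),
                         beta_range_3b = c(1.2, 1.8),
                         class3_alpha_sd = 0.1,
                         kink_size = 0.8,
                         seed = 1L) {
  cfg <- as.list(environment())
  if (abs(sum(class_proportions) - 1) > 1e-8) {
    rlang::abort("class_proportions must sum to 1")
  }
  if (residual_sd < 0) rlang::abort("residual_sd must be >= 0")
  if (replicates_per_dose < 1) rlang::abort("replicates_per_dose must be >= 1")
  if (!all(doses %in% names(dose_copy))) rlang::abort("doses must be 2n/3n/4n")
  class(cfg) <- "panel_config"
  cfg
}

rcounts <- function(mu, dispersion) {
  if (dispersion <= 0) return(round(mu))
  stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
}

#' Simulate a dosage strain panel with known truth
#'
#' Generates mRNA and DNA count matrices for a panel of isogenic strains
#' carrying 2/3/4 copies of one chromosome plus a euploid reference strain.
#' Per amplified gene the expected DNA log2 ratio is `log2(copy/2)` and the
#' expected mRNA log2 ratio is `alpha + beta * log2(copy/2)` (plus a
#' dose-specific kink for nonlinear-class genes and `N(0, residual_sd)`
#' noise per observation). Counts are negative-binomial around those means.
#'
#' @param cfg A [panel_config()].
#' @return A list: `mrna` and `dna` count tibbles, `annotation`,
#'   `sample_sheet`, and `truth` (tibbles `genes` with per-gene class /
#'   alpha / beta, and `copies` with per-strain chromosome copy number).
#' @export
simulate_panel <- function(cfg = panel_config()) {
  stopifnot(inherits(cfg, "panel_config"))
  with_seed(cfg$seed, {
    n_amp <- cfg$n_genes_amplified
    n_bg <- cfg$n_genes_background
    n <- n_amp + n_bg
    gene_id <- sprintf("g%04d", seq_len(n))
    chromosome <- rep(c("chrA", "chrB"), c(n_amp, n_bg))
    len <- rep_len(cfg$gene_length_bp, n)

    classes <- c("nonlinear", "1", "2a", "2b", "3a", "3b")
    cls <- sample(classes, n_amp, replace = TRUE, prob = cfg$class_proportions)
    alpha <- beta <- numeric(n_amp)
    kink <- numeric(n_amp)
    beta[] <- 1
    i2a <- cls == "2a"; i2b <- cls == "2b"
    alpha[i2a] <- -abs(stats::rnorm(sum(i2a), cfg$alpha_mean, cfg$alpha_sd))
    alpha[i2b] <- abs(stats::rnorm(sum(i2b), cfg$alpha_mean, cfg$alpha_sd))
    i3a <- cls == "3a"; i3b <- cls == "3b"
    beta[i3a] <- stats::runif(sum(i3a), cfg$beta_range_3a[1], cfg$beta_range_3a[2])
    beta[i3b] <- stats::runif(sum(i3b), cfg$beta_range_3b[1], cfg$beta_range_3b[2])
    alpha[i3a | i3b] <- stats::rnorm(sum(i3a | i3b), 0, cfg$class3_alpha_sd)
    inl <- cls == "nonlinear"
    kink[inl] <- sample(c(-1, 1), sum(inl), replace = TRUE) *
      (cfg$kink_size + stats::rexp(sum(inl), 2))

    base_expr <- stats::rlnorm(n, log(cfg$baseline_mean), cfg$baseline_sdlog)
    base_dna <- cfg$dna_depth_per_kb * len / 1000

    truth_genes <- tibble(
      gene_id = gene_id, chromosome = chromosome,
      amplified = chromosome == "chrA",
      class = c(cls, rep(NA_character_, n_bg)),
      alpha = c(alpha, rep(NA_real_, n_bg)),
      beta = c(beta, rep(NA_real_, n_bg)))

    ann <- tibble(gene_id = gene_id, chromosome = chromosome,
                  start = ave(seq_len(n), chromosome, FUN = seq_along) * 1500L - 1499L,
                  end = NA_integer_, subtelomeric = FALSE)
    ann$end <- ann$start + as.integer(len) - 1L

    top_dose <- cfg$doses[length(cfg$doses)]
    reps <- cfg$replicates_per_dose
    # sample layout: aneuploid strains per dose + euploid reference strain
    mrna <- tibble(gene_id = gene_id, length_bp = as.integer(len))
    dna <- tibble(gene_id = gene_id, length_bp = as.integer(len))
    ss <- list()

    mrna_mu <- function(copy, dose) {
      lx <- log2(copy / 2)
      shift <- c(alpha + beta * lx + if (dose == top_dose) kink else 0,
                 rep(0, n_bg))
      noise <- stats::rnorm(n, 0, cfg$residual_sd)
      base_expr * 2^(shift + noise)
    }
    for (d in cfg$doses) {
      copy <- dose_copy[[d]]
      strain <- paste0("panel_", d)
      for (r in seq_len(reps)) {
        sid <- paste0("mRNA_", d, "_r", r)
        mrna[[sid]] <- rcounts(mrna_mu(copy, d), cfg$dispersion)
        ss[[length(ss) + 1]] <- tibble(
          sample_id = sid, strain = strain, assay = "mRNA", dose = d,
          replicate = r, reference_sample_id = paste0("mRNA_ref_r", r))
      }
      for (r in 1:2) {
        sid <- paste0("DNA_", d, "_r", r)
        mu <- base_dna * c(rep(copy / 2, n_amp), rep(1, n_bg))
        dna[[sid]] <- rcounts(mu, cfg$dna_dispersion)
        ss[[length(ss) + 1]] <- tibble(
          sample_id = sid, strain = strain, assay = "DNA", dose = d,
          replicate = r, reference_sample_id = paste0("DNA_ref_r", r))
      }
    }
    for (r in seq_len(reps)) {
      sid <- paste0("mRNA_ref_r", r)
      mrna[[sid]] <- rcounts(base_expr, cfg$dispersion)
      ss[[length(ss) + 1]] <- tibble(
        sample_id = sid, strain = "reference", assay = "mRNA", dose = "2n",
        replicate = r, reference_sample_id = NA_character_)
    }
    for (r in 1:2) {
      sid <- paste0("DNA_ref_r", r)
      dna[[sid]] <- rcounts(base_dna, cfg$dna_dispersion)
      ss[[length(ss) + 1]] <- tibble(
        sample_id = sid, strain = "reference", assay = "DNA", dose = "2n",
        replicate = r, reference_sample_id = NA_character_)
    }
    copies <- tibble(strain = paste0("panel_", cfg$doses),
                     chromosome = "chrA",
                     copies = unname(dose_copy[cfg$doses]))
    list(mrna = mrna, dna = dna, annotation = ann,
         sample_sheet = bind_rows(ss),
         truth = list(genes = truth_genes, copies = copies))
  })
}

#' Ratio panel straight from a simulated panel
#'
#' Convenience wrapper: RPKM-normalizes the simulated counts, computes
#' median-centered log2 ratios against the paired reference samples, and
#' assembles the dose-panel table of `(x, y)` observations.
#'
#' @param sim Output of [simulate_panel()].
#' @param pseudocount_mrna,pseudocount_dna Pseudocounts for the two assays.
#' @param min_rpkm Minimum-abundance floor passed to [compute_log_ratios()].
#' @param center Ratio centering mode (default `"median"`).
#' @return A ratio panel tibble (`gene_id`, `sample_id`, `strain`, `dose`,
#'   `x`, `y`).
#' @export
ratio_panel_from_sim <- function(sim, pseudocount_mrna = 0.5,
                                 pseudocount_dna = 0, min_rpkm = 1,
                                 center = "median") {
  ss <- sim$sample_sheet
  pair_of <- function(assay) {
    p <- ss[ss$assay == assay & !is.na(ss$reference_sample_id), ]
    stats::setNames(p$reference_sample_id, p$sample_id)
  }
  mrna_rpkm <- compute_rpkm(sim$mrna)
  dna_rpkm <- compute_rpkm(sim$dna)
  suppressMessages({
    y <- compute_log_ratios(mrna_rpkm, mrna_rpkm, pair_of("mRNA"),
                            pseudocount = pseudocount_mrna,
                            min_rpkm = min_rpkm, center = center)
    x <- compute_log_ratios(dna_rpkm, dna_rpkm, pair_of("DNA"),
                            pseudocount = pseudocount_dna,
                            min_rpkm = min_rpkm, center = center)
  })
  build_ratio_panel(y, x, ss)
}

#' Simulate an aCGH relative-abundance matrix with clade structure
#'
#' Strains are partitioned into clades; amplification events are drawn per
#' clade and inherited by each member with probability `within_correlation`,
#' otherwise redrawn independently at the same marginal `amplification_rate`.
#' Amplified entries get a relative abundance of at least `min_fold`;
#' unamplified entries sit near 1.0 with multiplicative log-normal noise.
#'
#' @param n_strains,n_genes Matrix dimensions.
#' @param clade_sizes Integer partition of `n_strains` (default: clades of 4).
#' @param within_correlation Probability that a strain inherits its clade's
#'   amplification profile at a gene.
#' @param amplification_rate Marginal per-entry amplification probability.
#' @param min_fold Lower bound of the amplified-entry abundance ratio.
#' @param max_fold Upper bound of amplified-entry ratios.
#' @param noise_sd SD of log2 multiplicative noise on unamplified entries.
#' @param seed Integer seed.
#' @return A list: `cgh` (wide tibble, `strain_id` + one column per gene)
#'   and `truth` (logical amplification tibble of the same shape).
#' @export
simulate_acgh <- function(n_strains = 100, n_genes = 500,
                          clade_sizes = NULL, within_correlation = 0.8,
                          amplification_rate = 0.05,
                          min_fold = 1.7, max_fold = 4,
                          noise_sd = 0.08, seed = 1L) {
  if (amplification_rate < 0 || amplification_rate > 1) {
    rlang::abort("amplification_rate must be in [0, 1]")
  }
  if (is.null(clade_sizes)) {
    clade_sizes <- rep(4L, ceiling(n_strains / 4))
    clade_sizes[length(clade_sizes)] <- n_strains - sum(clade_sizes[-length(clade_sizes)])
  }
  if (any(clade_sizes < 1) || sum(clade_sizes) != n_strains) {
    rlang::abort("clade_sizes must be a positive partition of n_strains")
  }
  with_seed(seed, {
    clade <- rep(seq_along(clade_sizes), clade_sizes)
    amp <- matrix(FALSE, n_strains, n_genes)
    ratio <- matrix(NA_real_, n_strains, n_genes)
    rfold <- function(n) 2^stats::runif(n, log2(min_fold), log2(max_fold))
    for (k in seq_along(clade_sizes)) {
      members <- which(clade == k)
      shared <- stats::runif(n_genes) < amplification_rate
      shared_fold <- rfold(n_genes)  # inherited events share the fold change
      for (s in members) {
        inherit <- stats::runif(n_genes) < within_correlation
        own <- stats::runif(n_genes) < amplification_rate
        amp[s, ] <- ifelse(inherit, shared, own)
        fold_s <- ifelse(inherit, shared_fold, rfold(n_genes))
        ratio[s, ] <- ifelse(amp[s, ], fold_s,
                             2^stats::rnorm(n_genes, 0, noise_sd))
      }
    }
    gene_id <- sprintf("g%04d", seq_len(n_genes))
    strain_id <- sprintf("strain%03d", seq_len(n_strains))
    cgh <- as_tibble(as.data.frame(ratio, col.names = gene_id))
    names(cgh) <- gene_id
    truth <- as_tibble(as.data.frame(amp))
    names(truth) <- gene_id
    list(cgh = bind_cols(tibble(strain_id = strain_id), cgh),
         truth = bind_cols(tibble(strain_id = strain_id), truth),
         clade = tibble(strain_id = strain_id, clade = clade))
  })
}

#' Simulate wild-strain and mutation-accumulation variance tables
#'
#' Draws per-gene mutational variances (`V_m`) and genetic variances
#' (`V_g = V_m * ratio * coupling`) and emits matching expression tables
#' (wild strains and MA lines) whose sample variances estimate them. Groups
#' with reduced coupling emulate genes under strong expression constraint
#' (low `V_g / V_m`).
#'
#' @param n_genes Number of genes.
#' @param n_wild Wild isolates (default 22).
#' @param n_ma Mutation-accumulation lines.
#' @param vm_meanlog,vm_sdlog Log-normal parameters of `V_m`.
#' @param ratio_meanlog,ratio_sdlog Log-normal parameters of the baseline
#'   `V_g / V_m` ratio.
#' @param groups Named list of `list(frac=, coupling=)` entries planting
#'   gene groups whose `V_g` is multiplied by `coupling`.
#' @param seed Integer seed.
#' @return A list: `wild` and `ma` expression tibbles (`gene_id` + columns
#'   per strain/line) and `truth` (`gene_id`, `group`, `V_g`, `V_m`).
#' @export
simulate_variance_tables <- function(n_genes = 1000, n_wild = 22, n_ma = 10,
                                     vm_meanlog = log(0.02), vm_sdlog = 0.6,
                                     ratio_meanlog = log(4), ratio_sdlog = 0.8,
                                     groups = list(), seed = 1L) {
  with_seed(seed, {
    gene_id <- sprintf("g%04d", seq_len(n_genes))
    vm <- stats::rlnorm(n_genes, vm_meanlog, vm_sdlog)
    n_redraw <- 0L
    while (any(vm <= 0)) {  # guard: lognormal is positive, but honor contract
      idx <- vm <= 0
      n_redraw <- n_redraw + sum(idx)
      vm[idx] <- stats::rlnorm(sum(idx), vm_meanlog, vm_sdlog)
    }
    ratio <- stats::rlnorm(n_genes, ratio_meanlog, ratio_sdlog)
    group <- rep("background", n_genes)
    pos <- seq_len(n_genes)
    for (g in names(groups)) {
      k <- round(groups[[g]]$frac * n_genes)
      take <- sample(pos, min(k, length(pos)))
      pos <- setdiff(pos, take)
      group[take] <- g
      ratio[take] <- ratio[take] * groups[[g]]$coupling
    }
    vg <- vm * ratio
    mu <- stats::rnorm(n_genes, 8, 1.5)
    wild <- matrix(stats::rnorm(n_genes * n_wild, mu, sqrt(vg)), n_genes, n_wild)
    ma <- matrix(stats::rnorm(n_genes * n_ma, mu, sqrt(vm)), n_genes, n_ma)
    wild <- as_tibble(as.data.frame(wild))
    names(wild) <- sprintf("wild%02d", seq_len(n_wild))
    ma <- as_tibble(as.data.frame(ma))
    names(ma) <- sprintf("ma%02d", seq_len(n_ma))
    if (n_redraw > 0) rlang::inform(paste0(n_redraw, " nonpositive V_m draws redrawn"))
    list(wild = bind_cols(tibble(gene_id = gene_id), wild),
         ma = bind_cols(tibble(gene_id = gene_id), ma),
         truth = tibble(gene_id = gene_id, group = group, V_g = vg, V_m = vm))
  })
}
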