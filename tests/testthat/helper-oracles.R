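# Independent oracles used across the suite. These deliberately reimplement
# the target quantities by brute force (quadrature, elementwise loops,
# literal rule transcription) and never call the code paths they check.

# numerical-quadrature marginal density for every mixture class
quad_marginal_density <- function(x, y, class, p) {
  se <- p$sigma_e
  lik <- function(a, b) prod(stats::dnorm(y - a - b * x, 0, se))
  if (class == "1") return(lik(0, 1))
  if (class %in% c("2a", "2b")) {
    mu <- if (class == "2a") p$mu_alpha_2a else p$mu_alpha_2b
    s <- if (class == "2a") p$sigma_alpha_2a else p$sigma_alpha_2b
    lo <- if (class == "2a") -Inf else 0
    hi <- if (class == "2a") 0 else Inf
    z <- if (class == "2a") stats::pnorm(0, mu, s) else stats::pnorm(0, mu, s, lower.tail = FALSE)
    f <- Vectorize(function(a) lik(a, 1) * stats::dnorm(a, mu, s))
    return(stats::integrate(f, lo, hi, rel.tol = 1e-10,
                            abs.tol = 0)$value / z)
  }
  mu_b <- if (class == "3a") p$mu_beta_3a else p$mu_beta_3b
  s_b <- if (class == "3a") p$sigma_beta_3a else p$sigma_beta_3b
  lo <- if (class == "3a") -Inf else 1
  hi <- if (class == "3a") 1 else Inf
  z <- if (class == "3a") stats::pnorm(1, mu_b, s_b) else stats::pnorm(1, mu_b, s_b, lower.tail = FALSE)
  inner <- function(b) {
    stats::integrate(Vectorize(function(a) lik(a, b) *
                                 stats::dnorm(a, p$mu_alpha_3, p$sigma_alpha_3)),
                     -Inf, Inf, rel.tol = 1e-10, abs.tol = 0)$value
  }
  f <- Vectorize(function(b) inner(b) * stats::dnorm(b, mu_b, s_b))
  stats::integrate(f, lo, hi, rel.tol = 1e-9, abs.tol = 0)$value / z
}

# literal transcription of the pairwise rule set, one gene at a time
oracle_pairwise_call <- function(y, dna_mean, cutoff,
                                 repressed = -0.6,
                                 overexpressed = log2(2.5),
                                 margin = log2(1.5)) {
  if (is.na(cutoff)) return("unscored")
  if (any(y < repressed)) return("excluded_repressed")
  below <- y < cutoff
  if (all(below)) return("lower_than_expected")
  if (any(below)) return("unscored")
  if (any(y > overexpressed)) return("excluded_overexpressed")
  if (all(y - dna_mean >= margin)) return("higher_than_expected")
  "proportionate"
}

# small handmade strain-pair panel: n genes on one chromosome, two replicates
make_pair_panel <- function(dna_mean, y1, y2, chromosome = "chrX") {
  n <- length(dna_mean)
  ids <- sprintf("p%03d", seq_len(n))
  panel <- dplyr::bind_rows(
    tibble::tibble(gene_id = ids, sample_id = "s1", strain = "pair",
                   dose = "pair", x = dna_mean, y = y1),
    tibble::tibble(gene_id = ids, sample_id = "s2", strain = "pair",
                   dose = "pair", x = dna_mean, y = y2))
  ann <- tibble::tibble(gene_id = ids, chromosome = chromosome,
                        start = seq_len(n) * 1000L,
                        end = seq_len(n) * 1000L + 500L,
                        subtelomeric = FALSE)
  list(panel = panel, ann = ann)
}

# simple dosage panel straight at the ratio level (bypasses counts)
make_ratio_panel <- function(alpha, beta, residual_sd = 0, reps = 3,
                             doses = c(0, log2(1.5), 1), seed = 1) {
  withr::with_seed(seed, {
    n <- length(alpha)
    ids <- sprintf("g%03d", seq_len(n))
    purrr::map_dfr(seq_along(doses), function(d) {
      purrr::map_dfr(seq_len(reps), function(r) {
        tibble::tibble(
          gene_id = ids,
          sample_id = paste0("d", d, "r", r),
          strain = paste0("d", d),
          dose = c("2n", "3n", "4n")[d],
          x = doses[d],
          y = alpha + beta * doses[d] + stats::rnorm(n, 0, residual_sd))
      })
    })
  })
}
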