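# Mixture of linear regressions over dosage panels.
#
# Model: for gene g with observations (x_i, y_i) — x the log2 DNA ratio and
# y the log2 mRNA ratio vs a euploid control — y_i = alpha_g + beta_g x_i +
# e_i, e ~ N(0, sigma_e^2). Five classes constrain the gene-level random
# effects:
#   class 1 : alpha = 0, beta = 1 (point masses)
#   class 2a: alpha < 0 (one-sided truncated normal), beta = 1
#   class 2b: alpha > 0, beta = 1
#   class 3a: alpha ~ N (free), beta < 1 (truncated normal about 1)
#   class 3b: alpha ~ N (free), beta > 1
# Gene effects are integrated out analytically: conjugate Gaussian algebra
# plus one normal-CDF factor per truncated effect.

MLR_CLASSES <- c("1", "2a", "2b", "3a", "3b")

#' Parameter set of the five-class mixture of linear regressions
#'
#' @param pi Named mixture weights over `c("1","2a","2b","3a","3b")`.
#' @param sigma_e Shared residual SD (> 0).
#' @param mu_alpha_2a,sigma_alpha_2a Truncated-normal (negative side)
#'   intercept-effect parameters of class 2a.
#' @param mu_alpha_2b,sigma_alpha_2b Class 2b (positive side).
#' @param mu_alpha_3,sigma_alpha_3 Free Gaussian intercept of classes 3a/3b.
#' @param mu_beta_3a,sigma_beta_3a Truncated-normal (below 1) slope of 3a.
#' @param mu_beta_3b,sigma_beta_3b Truncated-normal (above 1) slope of 3b.
#' @return An object of class `mlr_parameters`.
#' @export
mlr_parameters <- function(pi = stats::setNames(rep(0.2, 5), MLR_CLASSES),
                           sigma_e = 0.15,
                           mu_alpha_2a = -0.4, sigma_alpha_2a = 0.2,
                           mu_alpha_2b = 0.4, sigma_alpha_2b = 0.2,
                           mu_alpha_3 = 0, sigma_alpha_3 = 0.1,
                           mu_beta_3a = 0.5, sigma_beta_3a = 0.3,
                           mu_beta_3b = 1.5, sigma_beta_3b = 0.3) {
  p <- as.list(environment())
  if (abs(sum(pi) - 1) > 1e-6) rlang::abort("mixture weights must sum to 1")
  if (sigma_e <= 0) rlang::abort("sigma_e must be > 0")
  sds <- c(sigma_alpha_2a, sigma_alpha_2b, sigma_alpha_3,
           sigma_beta_3a, sigma_beta_3b)
  if (any(sds <= 0)) rlang::abort("effect SDs must be > 0")
  names(p$pi) <- MLR_CLASSES
  class(p) <- "mlr_parameters"
  p
}

#' @export
print.mlr_parameters <- function(x, ...) {
  cat("Mixture of linear regressions parameters\n")
  cat("  pi:     ", paste(sprintf("%s=%.3f", names(x$pi), x$pi), collapse = " "), "\n")
  cat("  sigma_e:", format(x$sigma_e, digits = 4), "\n")
  cat(sprintf("  2a: alpha ~ TN-(%.3f, %.3f)   2b: alpha ~ TN+(%.3f, %.3f)\n",
              x$mu_alpha_2a, x$sigma_alpha_2a, x$mu_alpha_2b, x$sigma_alpha_2b))
  cat(sprintf("  3:  alpha ~ N(%.3f, %.3f); 3a beta ~ TN<1(%.3f, %.3f), 3b beta ~ TN>1(%.3f, %.3f)\n",
              x$mu_alpha_3, x$sigma_alpha_3, x$mu_beta_3a, x$sigma_beta_3a,
              x$mu_beta_3b, x$sigma_beta_3b))
  invisible(x)
}

# per-gene sufficient statistics for the vectorized densities
gene_stats <- function(panel) {
  panel |>
    group_by(.data$gene_id) |>
    summarise(n = dplyr::n(),
              sx = sum(.data$x), sy = sum(.data$y),
              sxx = sum(.data$x^2), syy = sum(.data$y^2),
              sxy = sum(.data$x * .data$y), .groups = "drop")
}

# vectorized log marginal density for one class given the stats table
class_logdens_stats <- function(st, class, p) {
  n <- st$n
  s2e <- p$sigma_e^2
  if (class == "1") {
    ssr <- st$syy - 2 * st$sxy + st$sxx  # sum (y - x)^2
    return(-(n / 2) * log(2 * pi * s2e) - ssr / (2 * s2e))
  }
  if (class %in% c("2a", "2b")) {
    mu <- if (class == "2a") p$mu_alpha_2a else p$mu_alpha_2b
    s2a <- (if (class == "2a") p$sigma_alpha_2a else p$sigma_alpha_2b)^2
    lower <- class == "2b"  # 2b truncated to alpha > 0
    sr <- st$sy - st$sx
    srr <- st$syy - 2 * st$sxy + st$sxx
    rbar <- sr / n
    ssw <- srr - n * rbar^2
    v <- 1 / (1 / s2a + n / s2e)
    m <- v * (mu / s2a + n * rbar / s2e)
    # trunc at 0: 2a keeps lower tail, 2b the upper tail
    lt <- stats::pnorm(0, m, sqrt(v), lower.tail = !lower, log.p = TRUE) -
      stats::pnorm(0, mu, sqrt(s2a), lower.tail = !lower, log.p = TRUE)
    return(-(n / 2) * log(2 * pi * s2e) - ssw / (2 * s2e) +
             0.5 * log(2 * pi * s2e / n) +
             stats::dnorm(rbar, mu, sqrt(s2a + s2e / n), log = TRUE) + lt)
  }
  if (class %in% c("3a", "3b")) {
    mu_a <- p$mu_alpha_3
    s2a <- p$sigma_alpha_3^2
    mu_b <- if (class == "3a") p$mu_beta_3a else p$mu_beta_3b
    s2b <- (if (class == "3a") p$sigma_beta_3a else p$sigma_beta_3b)^2
    lower <- class == "3b"  # 3b truncated to beta > 1
    cc <- s2a / (s2e + n * s2a)
    a <- (st$sxx - cc * st$sx^2) / s2e
    sz <- st$sy - n * mu_a
    sxz <- st$sxy - mu_a * st$sx
    szz <- st$syy - 2 * mu_a * st$sy + n * mu_a^2
    b <- (sxz - cc * st$sx * sz) / s2e
    q <- (szz - cc * sz^2) / s2e
    logdet <- (n - 1) * log(s2e) + log(s2e + n * s2a)
    vb <- 1 / (a + 1 / s2b)
    mb <- vb * (b + mu_b / s2b)
    lt <- stats::pnorm(1, mb, sqrt(vb), lower.tail = !lower, log.p = TRUE) -
      stats::pnorm(1, mu_b, sqrt(s2b), lower.tail = !lower, log.p = TRUE)
    return(-(n / 2) * log(2 * pi) - logdet / 2 - (q - b^2 / a) / 2 +
             0.5 * log(2 * pi / a) +
             stats::dnorm(b / a, mu_b, sqrt(s2b + 1 / a), log = TRUE) + lt)
  }
  rlang::abort(paste0("unknown class: ", class))
}

#' Marginal density of one gene's data under one mixture class
#'
#' Gene-level random effects (intercept and/or slope) are integrated out in
#' closed form. For sign-constrained effects (one-sided truncated normal
#' laws) the integral reduces to Gaussian conjugate algebra times a ratio
#' of normal CDF terms; the free intercept of classes 3a/3b enters through
#' a rank-one covariance update.
#'
#' @param x,y Numeric vectors: design (log2 DNA ratio) and response
#'   (log2 mRNA ratio) for a single gene.
#' @param class One of `"1"`, `"2a"`, `"2b"`, `"3a"`, `"3b"`.
#' @param params An [mlr_parameters()] object.
#' @param log Return the log density?
#' @return A single nonnegative density value (or its log).
#' @export
class_marginal_density <- function(x, y, class, params, log = FALSE) {
  stopifnot(inherits(params, "mlr_parameters"), length(x) == length(y))
  class <- match.arg(as.character(class), MLR_CLASSES)
  st <- tibble(gene_id = "g", n = length(x), sx = sum(x), sy = sum(y),
               sxx = sum(x^2), syy = sum(y^2), sxy = sum(x * y))
  ld <- class_logdens_stats(st, class, params)
  if (log) ld else exp(ld)
}

log_sum_exp_rows <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

# pack/unpack the free parameters for the numeric M-step (sigmas on log scale)
pack_params <- function(p) {
  c(p$mu_alpha_2a, log(p$sigma_alpha_2a),
    p$mu_alpha_2b, log(p$sigma_alpha_2b),
    p$mu_alpha_3, log(p$sigma_alpha_3),
    p$mu_beta_3a, log(p$sigma_beta_3a),
    p$mu_beta_3b, log(p$sigma_beta_3b),
    log(p$sigma_e))
}

unpack_params <- function(theta, pi) {
  # hot path of the M-step: build the object directly, skip revalidation
  structure(list(
    pi = pi, sigma_e = exp(theta[11]),
    mu_alpha_2a = theta[1], sigma_alpha_2a = exp(theta[2]),
    mu_alpha_2b = theta[3], sigma_alpha_2b = exp(theta[4]),
    mu_alpha_3 = theta[5], sigma_alpha_3 = exp(theta[6]),
    mu_beta_3a = theta[7], sigma_beta_3a = exp(theta[8]),
    mu_beta_3b = theta[9], sigma_beta_3b = exp(theta[10])),
    class = "mlr_parameters")
}

# identifiability: truncation-parent means stay on their class's side
theta_lower <- c(-5, log(1e-3), 0, log(1e-3), -5, log(1e-3),
                 -4, log(1e-3), 1, log(1e-3), log(1e-4))
theta_upper <- c(0, log(3), 5, log(3), 5, log(3),
                 1, log(3), 6, log(3), log(3))

logdens_matrix <- function(st, p) {
  vapply(MLR_CLASSES, function(k) class_logdens_stats(st, k, p),
         numeric(nrow(st)))
}

ols_per_gene <- function(st) {
  sxx_c <- st$sxx - st$sx^2 / st$n
  sxy_c <- st$sxy - st$sx * st$sy / st$n
  slope <- ifelse(sxx_c > 1e-12, sxy_c / sxx_c, 1)
  intercept <- st$sy / st$n - slope * st$sx / st$n
  rss <- pmax(st$syy - st$sy^2 / st$n - ifelse(sxx_c > 1e-12, sxy_c^2 / sxx_c, 0), 0)
  tibble(gene_id = st$gene_id, ols_intercept = intercept, ols_slope = slope,
         rss = rss, n = st$n)
}

init_from_ols <- function(ols, delta = 0.1) {
  cls <- with(ols, ifelse(
    abs(ols_slope - 1) <= delta,
    ifelse(abs(ols_intercept) <= 0.1, "1",
           ifelse(ols_intercept < 0, "2a", "2b")),
    ifelse(ols_slope < 1, "3a", "3b")))
  counts <- table(factor(cls, levels = MLR_CLASSES))
  pi0 <- pmax(as.numeric(counts) / sum(counts), 0.02)
  pi0 <- stats::setNames(pi0 / sum(pi0), MLR_CLASSES)
  sig_e <- sqrt(max(sum(ols$rss) / max(sum(ols$n - 2), 1), 1e-4))
  a2a <- ols$ols_intercept[cls == "2a"]
  a2b <- ols$ols_intercept[cls == "2b"]
  b3a <- ols$ols_slope[cls == "3a"]
  b3b <- ols$ols_slope[cls == "3b"]
  mlr_parameters(
    pi = pi0, sigma_e = sig_e,
    mu_alpha_2a = if (length(a2a)) min(mean(a2a), -0.05) else -0.4,
    sigma_alpha_2a = max(if (length(a2a) >= 2) stats::sd(a2a) else 0.2, 0.05),
    mu_alpha_2b = if (length(a2b)) max(mean(a2b), 0.05) else 0.4,
    sigma_alpha_2b = max(if (length(a2b) >= 2) stats::sd(a2b) else 0.2, 0.05),
    mu_alpha_3 = 0, sigma_alpha_3 = 0.1,
    mu_beta_3a = if (length(b3a)) min(mean(b3a), 0.95) else 0.5,
    sigma_beta_3a = max(if (length(b3a) >= 2) stats::sd(b3a) else 0.3, 0.05),
    mu_beta_3b = if (length(b3b)) max(mean(b3b), 1.05) else 1.5,
    sigma_beta_3b = max(if (length(b3b) >= 2) stats::sd(b3b) else 0.3, 0.05))
}

#' Fit the five-class mixture of linear regressions by EM
#'
#' E-step: posterior class responsibilities from the closed-form marginal
#' densities. M-step: mixture weights in closed form; effect-distribution
#' and residual parameters by bounded quasi-Newton maximization of the
#' expected complete-data log-likelihood, started from the current values
#' and accepted only if they do not decrease it (a generalized EM step, so
#' the observed-data log-likelihood is non-decreasing). Initialization seeds
#' genes to classes by where their per-gene OLS (intercept, slope) falls;
#' additional restarts jitter the initial parameters.
#'
#' @param panel Ratio panel tibble (`gene_id`, `x`, `y`), nonlinear genes
#'   already removed (see [lrt_nonlinear_filter()]).
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations per restart.
#' @param n_restarts Number of jittered restarts; the best final
#'   log-likelihood wins.
#' @param seed Integer seed for the restart jitter.
#' @param pi_floor Lower floor on mixture weights (default 1e-6).
#' @param mstep_maxit Quasi-Newton iterations per M-step.
#' @return An object of class `mlr_fit`: `params` ([mlr_parameters()]),
#'   `posterior` (tibble `gene_id`, `post_1` ... `post_3b`), `ols`
#'   diagnostics, `loglik`, `loglik_trace`, `n_iter`, `converged`,
#'   `n_genes`.
#' @export
fit_mlr_em <- function(panel, tol = 1e-8, max_iter = 1000, n_restarts = 3,
                       seed = 1L, pi_floor = 1e-6, mstep_maxit = 30) {
  st <- gene_stats(panel)
  if (nrow(st) < 20) rlang::abort("need at least 20 genes to fit the mixture")
  if (any(st$n < 3)) rlang::abort("each gene needs at least 3 observations")
  ols <- ols_per_gene(st)
  init <- init_from_ols(ols)

  run_em <- function(p0) {
    p <- p0
    trace <- numeric(0)
    ll_old <- -Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      ld <- logdens_matrix(st, p)
      lw <- sweep(ld, 2, log(p$pi), "+")
      ll_gene <- log_sum_exp_rows(lw)
      ll <- sum(ll_gene)
      trace <- c(trace, ll)
      if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
        converged <- TRUE
        break
      }
      ll_old <- ll
      r <- exp(lw - ll_gene)  # responsibilities, rows sum to 1
      pi_new <- colMeans(r)
      pi_new <- pmax(pi_new, pi_floor)
      pi_new <- stats::setNames(pi_new / sum(pi_new), MLR_CLASSES)
      negQ <- function(theta) {
        pp <- unpack_params(theta, pi_new)
        ldq <- logdens_matrix(st, pp)
        -sum(r * ldq)
      }
      th0 <- pack_params(p)
      q0 <- negQ(th0)
      opt <- tryCatch(
        stats::optim(th0, negQ, method = "L-BFGS-B",
                     lower = theta_lower, upper = theta_upper,
                     control = list(maxit = mstep_maxit)),
        error = function(e) list(par = th0, value = q0))
      theta <- if (is.finite(opt$value) && opt$value <= q0) opt$par else th0
      p <- unpack_params(theta, pi_new)
    }
    ld <- logdens_matrix(st, p)
    lw <- sweep(ld, 2, log(p$pi), "+")
    ll_gene <- log_sum_exp_rows(lw)
    post <- exp(lw - ll_gene)
    colnames(post) <- paste0("post_", MLR_CLASSES)
    list(params = p, loglik = sum(ll_gene), trace = trace,
         posterior = bind_cols(tibble(gene_id = st$gene_id), as_tibble(post)),
         n_iter = length(trace), converged = converged)
  }

  fits <- with_seed(seed, {
    purrr::map(seq_len(n_restarts), function(i) {
      p0 <- init
      if (i > 1) {
        th <- pack_params(init)
        th <- pmin(pmax(th + stats::rnorm(length(th), 0, 0.2),
                        theta_lower), theta_upper)
        pi0 <- init$pi * exp(stats::rnorm(5, 0, 0.3))
        p0 <- unpack_params(th, stats::setNames(pi0 / sum(pi0), MLR_CLASSES))
      }
      run_em(p0)
    })
  })
  best <- fits[[which.max(purrr::map_dbl(fits, "loglik"))]]
  if (!best$converged) {
    rlang::warn("EM did not converge within max_iter; returning best iterate")
  }
  structure(list(params = best$params, posterior = best$posterior,
                 ols = ols |> select("gene_id", "ols_intercept", "ols_slope"),
                 loglik = best$loglik, loglik_trace = best$trace,
                 n_iter = best$n_iter, converged = best$converged,
                 n_genes = nrow(st), n_restarts = n_restarts),
            class = "mlr_fit")
}

#' @export
print.mlr_fit <- function(x, ...) {
  cat("Mixture-of-linear-regressions fit:", x$n_genes, "genes\n")
  cat("  log-likelihood", format(x$loglik, digits = 8), "after", x$n_iter,
      "iterations", if (x$converged) "(converged)" else "(NOT converged)", "\n")
  print(x$params)
  invisible(x)
}

#' Likelihood-ratio filter for nonlinear dose response
#'
#' Compares, per gene, the linear model `y = a + b x` against the
#' dose-saturated means model (one mean per dose level) with Gaussian
#' maximum likelihood; the statistic `2 (ll_sat - ll_lin) = n log(RSS_lin /
#' RSS_sat)` is referred to a chi-square with `n_doses - 2` degrees of
#' freedom. Genes with fewer than three distinct dose levels cannot be
#' tested and are exempted (flagged, never silently filtered).
#'
#' @param panel Ratio panel tibble (`gene_id`, `dose`, `x`, `y`).
#' @param alpha_level Significance level for filtering (default 0.01).
#' @return A tibble `gene_id`, `lrt_stat`, `lrt_pvalue`, `filtered`,
#'   `exempt`.
#' @export
lrt_nonlinear_filter <- function(panel, alpha_level = 0.01) {
  one <- function(d) {
    doses <- unique(d$dose)
    if (length(doses) < 3) {
      return(tibble(lrt_stat = NA_real_, lrt_pvalue = NA_real_,
                    filtered = FALSE, exempt = TRUE))
    }
    n <- nrow(d)
    fit_lin <- stats::lm(y ~ x, data = d)
    rss_lin <- sum(stats::resid(fit_lin)^2)
    mu_d <- stats::ave(d$y, d$dose)
    rss_sat <- sum((d$y - mu_d)^2)
    # guard against numerically-zero residuals (noise-free fixtures)
    floor_rss <- max(1e-12 * sum((d$y - mean(d$y))^2), 1e-300)
    stat <- if (rss_lin <= floor_rss) 0
            else if (rss_sat <= floor_rss) Inf
            else n * log(rss_lin / rss_sat)
    stat <- max(stat, 0)
    p <- stats::pchisq(stat, df = length(doses) - 2, lower.tail = FALSE)
    tibble(lrt_stat = stat, lrt_pvalue = p,
           filtered = p < alpha_level, exempt = FALSE)
  }
  panel |>
    group_by(.data$gene_id) |>
    group_modify(~ one(.x)) |>
    ungroup()
}

#' Max-posterior classification with the nonlinearity filter applied
#'
#' Genes failing the linearity test are labeled `nonlinear` regardless of
#' posterior; remaining genes get the class with the highest posterior
#' probability, exact ties resolved in the order 1, 2a, 2b, 3a, 3b.
#'
#' @param fit An `mlr_fit` object (or its `posterior` tibble).
#' @param lrt Output of [lrt_nonlinear_filter()]; optional.
#' @return A tibble `gene_id`, `class`, `lrt_pvalue`, the five posterior
#'   columns, `ols_intercept`, `ols_slope`.
#' @export
classify_genes <- function(fit, lrt = NULL) {
  post <- if (inherits(fit, "mlr_fit")) fit$posterior else fit
  pc <- paste0("post_", MLR_CLASSES)
  if (!all(pc %in% names(post))) rlang::abort("posterior columns missing")
  pm <- as.matrix(post[pc])
  if (anyNA(pm)) rlang::abort("missing posterior values")
  lab <- MLR_CLASSES[apply(pm, 1, which.max)]  # first max = stated tie order
  out <- post |> mutate(class = lab, .after = "gene_id")
  if (inherits(fit, "mlr_fit")) {
    out <- out |> left_join(fit$ols, by = "gene_id")
  }
  if (!is.null(lrt)) {
    # filtered genes are absent from the fit; they re-enter labeled nonlinear
    missing_genes <- setdiff(lrt$gene_id[lrt$filtered], out$gene_id)
    if (length(missing_genes)) {
      out <- bind_rows(out, tibble(gene_id = missing_genes, class = NA))
    }
    out <- out |>
      left_join(lrt |> select("gene_id", "lrt_pvalue", "filtered"),
                by = "gene_id") |>
      mutate(class = ifelse(!is.na(.data$filtered) & .data$filtered,
                            "nonlinear", .data$class)) |>
      select(-"filtered")
  }
  out
}

#' Detect unamplified genes responding to chromosome dose in trans
#'
#' For genes *not* on the amplified chromosome, regresses the mRNA log2
#' ratio on the chromosome-dose covariate (`x = log2(copies/2)` of the
#' amplified chromosome), tests the OLS slope (two-sided t-test), adjusts
#' across genes by Benjamini-Hochberg, and reports genes with adjusted
#' p below `fdr` and positive slope.
#'
#' @param background Tibble `gene_id`, `x`, `y` restricted to unamplified
#'   genes, with `x` the chromosome-dose log2 copy ratio.
#' @param fdr False-discovery-rate threshold (default 0.05).
#' @return A tibble `gene_id`, `slope`, `p`, `p_adj`, `reported`.
#' @export
detect_trans_responders <- function(background, fdr = 0.05) {
  st <- gene_stats(background)
  sxx_c <- st$sxx - st$sx^2 / st$n
  if (any(sxx_c < 1e-12)) rlang::abort("constant dose covariate for some genes")
  sxy_c <- st$sxy - st$sx * st$sy / st$n
  slope <- sxy_c / sxx_c
  rss <- pmax(st$syy - st$sy^2 / st$n - sxy_c^2 / sxx_c, 0)
  df <- st$n - 2
  se <- sqrt(rss / df / sxx_c)
  tt <- ifelse(se > 0, slope / se,
               ifelse(slope == 0, 0, sign(slope) * Inf))
  p <- 2 * stats::pt(-abs(tt), df)
  p_adj <- stats::p.adjust(p, method = "BH")
  tibble(gene_id = st$gene_id, slope = slope, p = p, p_adj = p_adj,
         reported = p_adj < fdr & slope > 0)
}
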