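# broom-style methods for the EM fit.

#' @importFrom generics tidy glance augment
#' @export
generics::tidy

#' @export
generics::glance

#' @export
generics::augment

#' Tidy the parameters of a mixture-of-linear-regressions fit
#'
#' @param x An `mlr_fit`.
#' @param ... Unused.
#' @method tidy mlr_fit
#' @return One row per class: mixture weight and the intercept/slope effect
#'   distribution with its constraint, plus the shared residual SD.
#' @export
tidy.mlr_fit <- function(x, ...) {
  p <- x$params
  tibble(
    class = MLR_CLASSES,
    pi = unname(p$pi),
    alpha_constraint = c("fixed 0", "< 0", "> 0", "free", "free"),
    mu_alpha = c(0, p$mu_alpha_2a, p$mu_alpha_2b, p$mu_alpha_3, p$mu_alpha_3),
    sigma_alpha = c(0, p$sigma_alpha_2a, p$sigma_alpha_2b,
                    p$sigma_alpha_3, p$sigma_alpha_3),
    beta_constraint = c("fixed 1", "fixed 1", "fixed 1", "< 1", "> 1"),
    mu_beta = c(1, 1, 1, p$mu_beta_3a, p$mu_beta_3b),
    sigma_beta = c(0, 0, 0, p$sigma_beta_3a, p$sigma_beta_3b),
    sigma_e = p$sigma_e)
}

#' One-row summary of a mixture-of-linear-regressions fit
#'
#' @param x An `mlr_fit`.
#' @param ... Unused.
#' @method glance mlr_fit
#' @return A one-row tibble: `logLik`, `n_genes`, `n_iter`, `converged`,
#'   `sigma_e`.
#' @export
glance.mlr_fit <- function(x, ...) {
  tibble(logLik = x$loglik, n_genes = x$n_genes, n_iter = x$n_iter,
         converged = x$converged, sigma_e = x$params$sigma_e)
}

#' Per-gene classification table from a fit
#'
#' @param x An `mlr_fit`.
#' @param lrt Optional output of [lrt_nonlinear_filter()].
#' @param ... Unused.
#' @method augment mlr_fit
#' @return The [classify_genes()] tibble.
#' @export
augment.mlr_fit <- function(x, lrt = NULL, ...) {
  classify_genes(x, lrt)
}
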