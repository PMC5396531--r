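#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the fixed effects of a mixed-model group contrast
#'
#' @param x An [fit_group_lmer()] / [fit_cognition_lmer()] result.
#' @param ... Unused.
#' @return Tibble with `term`, `role`, `estimate`, `std_error`, `z`,
#'   `p_value`.
#' @export
tidy.lmer_contrast <- function(x, ...) {
  x$coefs
}

#' One-row fit summary of a mixed-model group contrast
#'
#' @inheritParams tidy.lmer_contrast
#' @return Tibble with model-level summaries.
#' @export
glance.lmer_contrast <- function(x, ...) {
  tibble::tibble(
    variant = x$variant,
    n_obs = x$n_obs, n_subjects = x$n_subjects,
    random_effects = x$fallback, converged = x$converged,
    logLik = as.numeric(stats::logLik(x$model)),
    AIC = stats::AIC(x$model)
  )
}

#' Tidy a consensus module partition
#'
#' @param x A [consensus_partition()] result.
#' @param ... Unused.
#' @return Tibble with `name`, `module`.
#' @export
tidy.module_partition <- function(x, ...) {
  x$assignment
}

#' One-row summary of a consensus module partition
#'
#' @inheritParams tidy.module_partition
#' @return Tibble with `gamma`, `n_modules`, `Q`, `n_runs`, `tau`, `method`,
#'   `n_iter`.
#' @export
glance.module_partition <- function(x, ...) {
  tibble::tibble(
    gamma = x$gamma, n_modules = x$n_modules, Q = x$Q,
    n_runs = x$n_runs, tau = x$tau, method = x$method, n_iter = x$n_iter
  )
}

#' Tidy a length-atrophy correlation
#'
#' @param x A [length_atrophy_correlation()] result.
#' @param ... Unused.
#' @return One-row tibble with `estimate` (Spearman rho), `p_value`, `df`,
#'   `n`, `n_excluded`.
#' @export
tidy.length_atrophy_cor <- function(x, ...) {
  tibble::tibble(
    estimate = x$rho, p_value = x$p_value, df = x$df,
    n = x$n, n_excluded = x$n_excluded
  )
}
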