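#' Longitudinal mixed-effects group contrast for one connection
#'
#' Fits, by maximum likelihood, the linear mixed-effects model
#' `Y_ij = alpha + beta * t_ij + gamma * group_i + delta * group_i * t_ij +
#' theta * X_i + a_i + b_i * t_ij + e_ij`, where `t_ij = visit - 1` (years),
#' `group_i` is 0 for controls and 1 for preHD, `X_i` are baseline
#' covariates, and `(a_i, b_i)` are joint-normal random intercepts and
#' slopes. The contrasts of interest are `gamma` (cross-sectional group
#' difference at baseline) and `delta` (group difference in rate of change),
#' tested two-sided with z-ratios `z = estimate / SE`. Subjects with missing
#' visits contribute through the likelihood (missing data treated as
#' ignorable).
#'
#' If the unstructured random-effects fit is singular or fails to converge,
#' the model is refitted with independent random effects, then with a random
#' intercept only; the fallback level is recorded.
#'
#' @param long_table Long-format tibble from [build_long_table()] (columns
#'   `subject_id`, `time`, `group`, covariates, and the response).
#' @param value Name of the response column (default `"strength"`).
#' @param covariates Baseline covariate column names (default age, sex,
#'   site, education). Sex and site enter as reference-coded factors;
#'   age and education as numeric.
#' @return Object of class `lmer_contrast`: list with `coefs` (tibble
#'   `term`, `role`, `estimate`, `std_error`, `z`, `p_value`), `model`,
#'   `fallback`, `converged`, `n_obs`, `n_subjects`, `variant`.
#' @export
fit_group_lmer <- function(long_table, value = "strength",
                           covariates = c("age", "sex", "site", "education")) {
  dat <- as.data.frame(long_table)
  dat$group <- factor(dat$group, levels = c("control", "preHD"))
  dat$.y <- dat[[value]]
  check_groups(dat)
  fixed <- paste(c("time * group", covariates), collapse = " + ")
  check_design(stats::reformulate(c("time * group", covariates)), dat)
  fit <- fit_with_fallback(paste(".y ~", fixed), dat)
  roles <- c("(Intercept)" = "alpha", "time" = "beta",
             "grouppreHD" = "gamma", "time:grouppreHD" = "delta",
             "grouppreHD:time" = "delta")
  build_lmer_contrast(fit, roles, variant = "group", dat)
}

#' Cognition variant of the longitudinal mixed-effects model
#'
#' As [fit_group_lmer()], restricted to preHD subjects, with the continuous
#' baseline global cognitive composite `c_i` replacing the group dummy
#' (terms `gamma * c_i + delta * c_i * t_ij`), and covariates age, site,
#' education, CAG and a time-by-CAG interaction.
#'
#' @inheritParams fit_group_lmer
#' @param cognition Name of the baseline cognition column.
#' @return An `lmer_contrast` (roles: `gamma` = cognition main effect,
#'   `delta` = cognition-by-time interaction).
#' @export
fit_cognition_lmer <- function(long_table, value = "strength",
                               cognition = "cognition",
                               covariates = c("age", "site", "education", "CAG")) {
  dat <- as.data.frame(long_table)
  dat <- dat[dat$group == "preHD", , drop = FALSE]
  if (nrow(dat) == 0) stop("no preHD rows in long_table", call. = FALSE)
  if (any(is.na(dat[[cognition]]))) {
    stop("cognition missing for some preHD subjects", call. = FALSE)
  }
  if (stats::sd(dat[[cognition]]) == 0) {
    stop("collinear column: cognition is constant across subjects", call. = FALSE)
  }
  dat$.y <- dat[[value]]
  dat$.cog <- dat[[cognition]]
  fixed <- paste(c("time * .cog", covariates, "time:CAG"), collapse = " + ")
  check_design(stats::reformulate(c("time * .cog", covariates, "time:CAG")), dat)
  fit <- fit_with_fallback(paste(".y ~", fixed), dat)
  roles <- c("(Intercept)" = "alpha", "time" = "beta",
             ".cog" = "gamma", "time:.cog" = "delta", ".cog:time" = "delta")
  build_lmer_contrast(fit, roles, variant = "cognition", dat)
}

check_groups <- function(dat) {
  per_group <- tapply(dat$subject_id, dat$group, function(s) length(unique(s)))
  if (any(is.na(per_group)) || any(per_group < 2)) {
    stop("need at least 2 subjects per group", call. = FALSE)
  }
}

# error naming collinear columns before lme4 sees the data
check_design <- function(formula, dat) {
  for (v in all.vars(formula)) {
    col <- dat[[v]]
    if ((is.character(col) || is.factor(col)) &&
        length(unique(col)) < 2) {
      stop("singular fixed-effect design; collinear column: ", v,
           " has a single level", call. = FALSE)
    }
  }
  X <- stats::model.matrix(formula, dat)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("singular fixed-effect design; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

fit_with_fallback <- function(fixed_rhs, dat) {
  specs <- c(full = "(1 + time | subject_id)",
             diagonal = "(1 + time || subject_id)",
             intercept = "(1 | subject_id)")
  last <- NULL
  for (level in names(specs)) {
    f <- stats::as.formula(paste(fixed_rhs, "+", specs[[level]]))
    got_warning <- FALSE
    fit <- withCallingHandlers(
      tryCatch(suppressMessages(lme4::lmer(f, data = dat, REML = FALSE)),
               error = function(e) e),
      warning = function(w) {
        got_warning <<- TRUE
        invokeRestart("muffleWarning")
      }
    )
    if (inherits(fit, "error")) next
    last <- list(fit = fit, fallback = level,
                 converged = !got_warning && !lme4::isSingular(fit))
    if (last$converged) return(last)
  }
  if (is.null(last)) stop("mixed model failed to fit", call. = FALSE)
  last
}

build_lmer_contrast <- function(fitted, roles, variant, dat) {
  fit <- fitted$fit
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  role <- unname(roles[names(est)])
  role[is.na(role)] <- "theta"
  structure(
    list(
      coefs = tibble::tibble(term = names(est), role = role,
                             estimate = unname(est), std_error = unname(se),
                             z = unname(z), p_value = unname(p)),
      model = fit, fallback = fitted$fallback, converged = fitted$converged,
      n_obs = nrow(dat), n_subjects = length(unique(dat$subject_id)),
      variant = variant
    ),
    class = "lmer_contrast"
  )
}

#' @export
print.lmer_contrast <- function(x, ...) {
  cat("<lmer_contrast>", x$variant, "variant |", x$n_obs, "obs,",
      x$n_subjects, "subjects | random effects:", x$fallback, "\n")
  key <- x$coefs[x$coefs$role %in% c("gamma", "delta"), ]
  print(as.data.frame(key), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false discovery rate adjustment within one family of tests (a
#' connection subgroup).
#'
#' @param p P-values in `(0, 1]`.
#' @return Q-values, same length and order as `p`.
#' @export
fdr_bh <- function(p) {
  if (length(p) == 0) stop("empty p-value family", call. = FALSE)
  if (any(!is.finite(p) | p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Fit the group contrast for every subtype connection, with per-subtype FDR
#'
#' Maps [fit_group_lmer()] over the module-level connections in a long
#' strength table and adjusts the `gamma` (intercept difference) and `delta`
#' (slope difference) p-values by Benjamini-Hochberg within each connection
#' subtype, separately per effect, mirroring FDR "in each connection
#' subgroup".
#'
#' @param long_table Long tibble from [build_long_table()] over the output
#'   of [subtype_strength_table()] (columns `connection`, `subtype`,
#'   `strength`, `time`, `group`, covariates).
#' @inheritParams fit_group_lmer
#' @return Tibble with one row per connection and effect of interest:
#'   `connection`, `subtype`, `role`, `estimate`, `std_error`, `z`,
#'   `p_value`, `q_value`, `fallback`, `converged`.
#' @export
fit_subtype_models <- function(long_table,
                               covariates = c("age", "sex", "site", "education")) {
  fits <- long_table |>
    dplyr::group_by(.data$connection, .data$subtype) |>
    dplyr::group_modify(function(d, key) {
      fit <- fit_group_lmer(d, value = "strength", covariates = covariates)
      fit$coefs |>
        dplyr::filter(.data$role %in% c("gamma", "delta")) |>
        dplyr::mutate(fallback = fit$fallback, converged = fit$converged)
    }) |>
    dplyr::ungroup()
  fits |>
    dplyr::group_by(.data$subtype, .data$role) |>
    dplyr::mutate(q_value = fdr_bh(.data$p_value)) |>
    dplyr::ungroup() |>
    dplyr::relocate("connection", "subtype", "role", "estimate", "std_error",
                    "z", "p_value", "q_value")
}
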