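#' Cross-sectional atrophy Z-score
#'
#' Standardizes a preHD subject's connection strength against the healthy
#' control distribution for the same connection:
#' `Z_C = (c_k - mean(controls)) / sd(controls)` (sample SD).
#'
#' @param c_k PreHD strength value(s).
#' @param controls Control strength values for the same connection (>= 2).
#' @return Z-score(s); `NA` with a warning if the control SD is zero (the
#'   connection is degenerate and is excluded from correlation analyses).
#' @export
zscore_cross <- function(c_k, controls) {
  if (length(controls) < 2) stop("need at least 2 control values", call. = FALSE)
  s <- stats::sd(controls)
  if (!is.finite(s) || s == 0) {
    warning("zero control SD: connection flagged degenerate", call. = FALSE)
    return(rep(NA_real_, length(c_k)))
  }
  (c_k - mean(controls)) / s
}

#' Longitudinal (rate-of-atrophy) Z-score
#'
#' As [zscore_cross()], applied to per-subject least-squares rates of change
#' instead of strengths.
#'
#' @param r_k PreHD rate value(s).
#' @param control_rates Control rates for the same connection.
#' @return Z-score(s).
#' @export
zscore_rate <- function(r_k, control_rates) {
  zscore_cross(r_k, control_rates)
}

#' Transform an atrophy Z-score to a (0, 1) atrophy measure
#'
#' Maps a Z-score to a bounded positive atrophy score. The default
#' `"logistic"` variant is `1 / (1 + exp(z))`: strictly decreasing in `z`,
#' so weaker-than-control strength (negative `z`) maps above 0.5 and higher
#' scores represent greater connection atrophy; it satisfies
#' `score(z) + score(-z) = 1`. The `"literal"` variant
#' `1 / (exp(-z) + exp(z))` (i.e. `sech(z) / 2`) is non-monotone with
#' maximum 0.5 at `z = 0` and is retained for comparison only. Both map
#' `z = 0` to exactly 0.5.
#'
#' @param z Finite Z-score(s).
#' @param variant `"logistic"` (default) or `"literal"`.
#' @return Score(s) in (0, 1).
#' @export
transform_score <- function(z, variant = c("logistic", "literal")) {
  variant <- match.arg(variant)
  switch(variant,
    logistic = 1 / (1 + exp(z)),
    literal = 1 / (exp(-z) + exp(z))
  )
}

#' Least-squares slope of values over time
#'
#' The per-subject rate of connection atrophy: the gradient of the ordinary
#' least-squares line fitted to connection strengths across visits.
#'
#' @param times Numeric times (years since baseline), at least 2 distinct.
#' @param values Strengths at those times.
#' @return Slope (strength units per year).
#' @export
fit_subject_slope <- function(times, values) {
  stopifnot(length(times) == length(values))
  if (length(unique(times)) < 2) {
    stop("need at least 2 distinct time points", call. = FALSE)
  }
  tc <- times - mean(times)
  sum(tc * (values - mean(values))) / sum(tc^2)
}

#' Regress age and sex out of per-subject values
#'
#' Returns the residuals of an OLS regression of `values` on an intercept,
#' `age` and `sex`, removing demographic differences between the groups
#' before Z-scoring.
#'
#' @param values Numeric vector or matrix (subjects in rows; each column is
#'   residualized separately).
#' @param age Numeric ages.
#' @param sex `"M"`/`"F"` per subject.
#' @return Residuals with the same shape as `values`.
#' @export
residualize <- function(values, age, sex) {
  X <- stats::model.matrix(~ age + factor(sex, levels = c("M", "F")))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    stop("rank-deficient design: age/sex constant across subjects", call. = FALSE)
  }
  if (NROW(values) < 3) stop("need at least 3 subjects", call. = FALSE)
  qr.resid(qx, as.matrix(values))
}

#' Per-connection atrophy scores paired with path lengths
#'
#' Builds the edge-level table for the length-atrophy analysis. For every
#' analyzed region pair (cortical-cortical and striatal-cortical):
#'
#' * the shortest weighted path length `L` on the baseline control-average
#'   network;
#' * the cross-sectional atrophy score: baseline strengths are residualized
#'   on age and sex across all subjects, preHD Z-scores are computed against
#'   the control mean and SD, transformed to (0, 1), and averaged across
#'   preHD subjects;
#' * the longitudinal rate-of-atrophy score: for subjects observed at all
#'   visits, the per-subject least-squares slope over time, residualized,
#'   Z-scored against control rates, transformed, and averaged across preHD.
#'
#' Connections with zero control SD are flagged degenerate (`NA` score);
#' those with infinite `L` are retained in the table but excluded by
#' [length_atrophy_correlation()].
#'
#' @param dataset A [long_dataset].
#' @param partition Cortical module partition (see [classify_pair()]).
#' @param transform Transform variant passed to [transform_score()].
#' @param residualize_covariates Residualize on age and sex before Z-scoring
#'   (default `TRUE`).
#' @param control_network Optional pre-computed control-average baseline
#'   matrix; defaults to the average over control visit-1 observations.
#'
#' @return A tibble of class `atrophy_table`: one row per analyzed region
#'   pair with `i`, `j`, `name_i`, `name_j`, `subtype`, `L`, `score_cross`,
#'   `score_long`. Attributes record the transform, group sizes, and the
#'   number of complete-visit subjects used longitudinally.
#' @export
atrophy_table <- function(dataset, partition,
                          transform = c("logistic", "literal"),
                          residualize_covariates = TRUE,
                          control_network = NULL) {
  transform <- match.arg(transform)
  atlas <- dataset$atlas
  cohort <- dataset$cohort
  pairs <- connection_pairs(atlas, partition)
  idx <- cbind(pairs$i + 1L, pairs$j + 1L)

  controls <- cohort$subject_id[cohort$group == "control"]
  prehd <- cohort$subject_id[cohort$group == "preHD"]
  if (is.null(control_network)) {
    control_network <- average_connectomes(dataset, subjects = controls,
                                           visits = 1L)
  }
  Lmat <- path_length_matrix(control_network)
  L <- Lmat[idx]

  obs_subj <- vapply(dataset$observations, `[[`, character(1), "subject_id")
  obs_visit <- vapply(dataset$observations, `[[`, integer(1), "visit")

  # --- cross-sectional: baseline strengths, subjects x pairs
  base_i <- which(obs_visit == 1L)
  S <- t(vapply(dataset$observations[base_i], function(o) o$W[idx],
                numeric(nrow(pairs))))
  subj_base <- obs_subj[base_i]
  meta <- cohort[match(subj_base, cohort$subject_id), ]
  if (residualize_covariates) {
    S <- residualize(S, meta$age, meta$sex)
  }
  score_cross <- group_z_scores(S, meta$group == "control",
                                meta$group == "preHD", transform)

  # --- longitudinal: per-subject slopes for complete-visit subjects
  n_visits <- max(obs_visit)
  counts <- table(obs_subj)
  complete <- names(counts)[counts == n_visits]
  R <- t(vapply(complete, function(s) {
    oi <- which(obs_subj == s)
    tt <- obs_visit[oi] - 1
    Y <- t(vapply(dataset$observations[oi], function(o) o$W[idx],
                  numeric(nrow(pairs))))
    tc <- tt - mean(tt)
    colSums(tc * Y) / sum(tc^2)
  }, numeric(nrow(pairs))))
  meta_l <- cohort[match(complete, cohort$subject_id), ]
  if (residualize_covariates) {
    R <- residualize(R, meta_l$age, meta_l$sex)
  }
  score_long <- group_z_scores(R, meta_l$group == "control",
                               meta_l$group == "preHD", transform)

  out <- pairs |>
    dplyr::mutate(L = L, score_cross = score_cross, score_long = score_long)
  class(out) <- c("atrophy_table", class(out))
  attr(out, "transform") <- transform
  attr(out, "n_controls") <- length(controls)
  attr(out, "n_preHD") <- length(prehd)
  attr(out, "n_complete") <- length(complete)
  attr(out, "n_degenerate_cross") <- sum(is.na(score_cross))
  attr(out, "n_degenerate_long") <- sum(is.na(score_long))
  out
}

# columnwise: z-score preHD rows against control rows, transform, average
group_z_scores <- function(M, is_control, is_prehd, transform) {
  mu <- colMeans(M[is_control, , drop = FALSE])
  sdev <- apply(M[is_control, , drop = FALSE], 2, stats::sd)
  z <- sweep(sweep(M[is_prehd, , drop = FALSE], 2, mu), 2, sdev, `/`)
  score <- transform_score(z, transform)
  out <- colMeans(score)
  out[!is.finite(sdev) | sdev == 0] <- NA_real_
  out
}

#' Spearman correlation between path length and atrophy score
#'
#' Rank correlation (average ranks for ties) between per-connection shortest
#' weighted path lengths and group-averaged transformed atrophy scores.
#' Two-sided p-value via the t approximation on `df = n - 2`. Pairs with
#' non-finite length (disconnected) or missing score (degenerate) are
#' excluded and counted.
#'
#' @param lengths Per-connection path lengths.
#' @param scores Per-connection mean transformed atrophy scores.
#' @return Object of class `length_atrophy_cor`: list with `rho`, `p_value`,
#'   `df`, `n`, `n_excluded`.
#' @export
length_atrophy_correlation <- function(lengths, scores) {
  stopifnot(length(lengths) == length(scores))
  ok <- is.finite(lengths) & is.finite(scores)
  n <- sum(ok)
  if (n < 3) stop("need at least 3 finite pairs", call. = FALSE)
  rho <- stats::cor(rank(lengths[ok]), rank(scores[ok]))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  structure(
    list(rho = rho, p_value = p, df = n - 2L, n = n,
         n_excluded = sum(!ok)),
    class = "length_atrophy_cor"
  )
}

#' @export
print.length_atrophy_cor <- function(x, ...) {
  cat("<length_atrophy_cor> rho =", format(x$rho, digits = 3),
      "| p =", format.pval(x$p_value, digits = 3), "| df =", x$df,
      "|", x$n_excluded, "excluded\n")
  invisible(x)
}

#' One-way ANOVA of path length across connection subtypes
#'
#' Classical one-way ANOVA of per-connection shortest weighted path length
#' grouped by connection subtype, on the averaged healthy control network.
#'
#' @param data Data frame (e.g. an [atrophy_table()]).
#' @param value,group Column names of the response and the grouping factor.
#' @return Tibble with `F_value`, `df1`, `df2`, `p_value`.
#' @export
anova_subtypes <- function(data, value = "L", group = "subtype") {
  df <- prepare_anova_data(data, value, group)
  fit <- stats::aov(y ~ g, data = df)
  s <- summary(fit)[[1]]
  tibble::tibble(
    F_value = s[["F value"]][1],
    df1 = s[["Df"]][1], df2 = s[["Df"]][2],
    p_value = s[["Pr(>F)"]][1]
  )
}

#' Tukey-Kramer post-hoc comparisons of subtype path lengths
#'
#' Honest-significant-difference pairwise comparisons (Tukey-Kramer for
#' unequal group sizes) following [anova_subtypes()].
#'
#' @inheritParams anova_subtypes
#' @param conf_level Familywise confidence level.
#' @return Tibble with `comparison`, `estimate`, `conf_low`, `conf_high`,
#'   `adj_p_value`.
#' @export
tukey_kramer <- function(data, value = "L", group = "subtype",
                         conf_level = 0.95) {
  df <- prepare_anova_data(data, value, group)
  fit <- stats::aov(y ~ g, data = df)
  tk <- stats::TukeyHSD(fit, conf.level = conf_level)$g
  tibble::tibble(
    comparison = rownames(tk),
    estimate = tk[, "diff"], conf_low = tk[, "lwr"],
    conf_high = tk[, "upr"], adj_p_value = tk[, "p adj"]
  )
}

prepare_anova_data <- function(data, value, group) {
  y <- data[[value]]
  g <- data[[group]]
  ok <- is.finite(y) & !is.na(g)
  df <- data.frame(y = y[ok], g = droplevels(factor(g[ok])))
  tab <- table(df$g)
  if (length(tab) < 2 || any(tab < 2)) {
    stop("need at least 2 groups with at least 2 members each", call. = FALSE)
  }
  df
}
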