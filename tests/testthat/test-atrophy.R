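test_that("cross-sectional Z-scores standardize against control moments", {
  controls <- c(3, 5, 7)  # mean 5, sample SD 2
  expect_equal(zscore_cross(5, controls), 0)
  expect_equal(zscore_cross(5 - 2, controls), -1)
  expect_equal(zscore_cross(6, controls), 0.5)
  expect_error(zscore_cross(1, 2), "at least 2")
  expect_warning(z <- zscore_cross(1, c(2, 2, 2)), "degenerate")
  expect_true(is.na(z))
  # rate variant shares the definition
  expect_equal(zscore_rate(6, controls), 0.5)
})

test_that("transforms map Z = 0 to 0.5 and the logistic variant is a proper score", {
  expect_identical(transform_score(0, "logistic"), 0.5)
  expect_identical(transform_score(0, "literal"), 0.5)
  expect_equal(transform_score(log(3), "logistic"), 0.25)
  expect_equal(transform_score(-log(3), "logistic"), 0.75)
  # literal variant is sech(z)/2, maximal at zero
  expect_equal(transform_score(1, "literal"), 1 / (exp(-1) + exp(1)))

  z <- seq(-8, 8, by = 0.05)
  s <- transform_score(z, "logistic")
  expect_true(all(s > 0 & s < 1))
  expect_true(all(diff(s) < 0))
  expect_equal(s + rev(s), rep(1, length(z)), tolerance = 1e-12)
})

test_that("subject slopes are ordinary least-squares gradients", {
  expect_equal(fit_subject_slope(c(0, 1, 2), c(3, 2, 1)), -1)
  expect_equal(fit_subject_slope(c(0, 1, 2), c(4, 4, 4)), 0)
  # closed form: sum(tc * yc) / sum(tc^2) = 3/2
  expect_equal(fit_subject_slope(c(0, 1, 2), c(1, 1, 4)), 1.5)
  expect_error(fit_subject_slope(0, 3), "2 distinct")
  expect_error(fit_subject_slope(c(1, 1), c(2, 3)), "2 distinct")
})

test_that("residualization removes age/sex structure exactly", {
  set.seed(5)
  age <- runif(20, 30, 60)
  sex <- sample(c("M", "F"), 20, replace = TRUE)
  vals <- 2 + 0.3 * age
  expect_equal(residualize(vals, age, sex), matrix(0, 20, 1),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(residualize(1:20, rep(40, 20), rep("M", 20)), "rank")
  Y <- matrix(rnorm(20 * 4), 20, 4)
  R <- residualize(Y, age, sex)
  X <- cbind(age, sex == "F")
  expect_lt(max(abs(crossprod(X, R))), 1e-9)
  expect_lt(max(abs(colSums(R))), 1e-9)
})

test_that("Spearman correlation matches an explicit rank oracle", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(length_atrophy_correlation(x, x^3)$rho, 1)
  expect_equal(length_atrophy_correlation(x, -x)$rho, -1)

  # tied 6-point case: average ranks computed by hand
  L <- c(1, 2, 2, 3, 4, 4)
  s <- c(0.3, 0.5, 0.4, 0.4, 0.9, 0.8)
  got <- length_atrophy_correlation(L, s)
  rl <- rank(L); rs <- rank(s)
  oracle <- sum((rl - mean(rl)) * (rs - mean(rs))) /
    sqrt(sum((rl - mean(rl))^2) * sum((rs - mean(rs))^2))
  expect_equal(got$rho, oracle, tolerance = 1e-12)
  expect_equal(got$df, 4L)
  # cross-check rho against the standard implementation
  expect_equal(got$rho, unname(cor(L, s, method = "spearman")), tolerance = 1e-12)

  # non-finite lengths and missing scores are excluded with a count
  got2 <- length_atrophy_correlation(c(x, Inf), c(x^2, 1))
  expect_equal(got2$n, 5L)
  expect_equal(got2$n_excluded, 1L)
  expect_error(length_atrophy_correlation(c(1, 2), c(1, 2)), "at least 3")
})

test_that("subtype ANOVA and Tukey-Kramer match the sum-of-squares oracle", {
  df <- data.frame(
    L = c(1.1, 1.3, 1.2, 2.0, 2.2, 2.1, 3.3, 3.1, 3.0, 3.2),
    subtype = rep(c("a", "b", "c"), c(3, 3, 4))
  )
  got <- anova_subtypes(df)
  # explicit between/within sums of squares
  gm <- mean(df$L)
  ssb <- sum(tapply(df$L, df$subtype, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(unlist(tapply(df$L, df$subtype, function(v) (v - mean(v))^2)))
  f_oracle <- (ssb / 2) / (ssw / 7)
  expect_equal(got$F_value, f_oracle, tolerance = 1e-10)
  expect_equal(c(got$df1, got$df2), c(2, 7))

  tk <- tukey_kramer(df)
  expect_equal(nrow(tk), 3)
  expect_true(all(tk$adj_p_value < 0.01))

  # identical groups give F ~ 0
  df2 <- data.frame(L = rep(c(1, 2, 3), 2), subtype = rep(c("a", "b"), each = 3))
  expect_lt(anova_subtypes(df2)$F_value, 1e-10)
  expect_error(anova_subtypes(data.frame(L = 1:3, subtype = c("a", "a", "b"))),
               "at least 2 groups")
})

test_that("the atrophy table pairs scores with lengths and flags degeneracy", {
  cfg <- sim_config(n_controls = 12, n_preHD = 12, n_cortical = 20,
                    n_striatal = 2, missing_visit_prob = 0, seed = 31)
  sim <- simulate_cohort(cfg)
  atab <- atrophy_table(sim$dataset, sim$truth$partition)
  expect_s3_class(atab, "atrophy_table")
  expect_equal(nrow(atab), count_connection_level_pairs(sim$truth$atlas))
  expect_true(all(atab$score_cross > 0 & atab$score_cross < 1, na.rm = TRUE))
  expect_true(all(atab$score_long > 0 & atab$score_long < 1, na.rm = TRUE))
  expect_equal(attr(atab, "n_complete"), 24)
  # planted degeneration: preHD weaker than controls on average
  expect_gt(mean(atab$score_cross, na.rm = TRUE), 0.5)
})
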