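paper_counts <- function() {
  matrix(c(99, 5, 54, 104, 12, 69, 18, 26, 22), 3, byrow = TRUE,
         dimnames = list(c("C1", "C2", "C3"),
                         c("improved", "deteriorated", "unchanged")))
}

test_that("contingency analysis matches a brute-force chi-square oracle", {
  tab <- paper_counts()
  res <- contingency_analysis(tab)
  # oracle: sums of (O - E)^2 / E from first principles
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res$statistic, sum((tab - e)^2 / e), tolerance = 1e-12)
  expect_equal(res$expected, e, tolerance = 1e-12)
  expect_equal(res$residuals, (tab - e) / sqrt(e), tolerance = 1e-12)
  expect_identical(res$df, 4L)
  expect_equal(sum(res$observed), sum(res$expected))
})

test_that("an independent table gives zero chi-square and residuals", {
  res <- contingency_analysis(matrix(10, 2, 2))
  expect_equal(res$statistic, 0)
  expect_true(all(res$residuals == 0))
})

test_that("chi-square is permutation invariant and guards degenerate input", {
  tab <- paper_counts()
  perm <- tab[c(3, 1, 2), c(2, 3, 1)]
  expect_equal(contingency_analysis(perm)$statistic,
               contingency_analysis(tab)$statistic)
  expect_error(contingency_analysis(matrix(c(1, 2), 1, 2)), "2 rows")
  expect_error(contingency_analysis(rbind(c(0, 0), c(1, 2))), "marginal")
})

test_that("one-way ANOVA agrees with brute-force sums of squares", {
  df <- tibble::tibble(
    y = c(3, 5, 4, 8, 9, 10, 2, 1, 3),
    g = rep(c("a", "b", "c"), each = 3))
  res <- oneway_anova_bonferroni(df, "y", "g")
  grand <- mean(df$y)
  ssb <- sum(tapply(df$y, df$g, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(tapply(df$y, df$g, function(v) sum((v - mean(v))^2)))
  f_oracle <- (ssb / 2) / (ssw / 6)
  expect_equal(res$statistic, f_oracle, tolerance = 1e-12)
  expect_identical(c(res$df1, res$df2), c(2L, 6L))
  expect_equal(nrow(res$pairwise), 3)
  expect_true(all(res$pairwise$p_adjusted <= 1))
  expect_true(all(res$pairwise$p_adjusted >=
                    pmin(1, res$pairwise$p_raw)))
})

test_that("with two groups F equals the squared pooled t", {
  withr::with_seed(31, {
    df <- tibble::tibble(y = c(rnorm(12, 5), rnorm(15, 6.2)),
                         g = rep(c("a", "b"), c(12, 15)))
  })
  res <- oneway_anova_bonferroni(df, "y", "g")
  tt <- t.test(y ~ g, data = df, var.equal = TRUE)
  expect_equal(res$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-10)
})

test_that("identical group means give F near zero and adjusted p of 1", {
  df <- tibble::tibble(y = rep(c(1, 2, 3), times = 3),
                       g = rep(c("a", "b", "c"), each = 3))
  res <- oneway_anova_bonferroni(df, "y", "g")
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_true(all(res$pairwise$p_adjusted == 1))
  expect_error(oneway_anova_bonferroni(
    tibble::tibble(y = c(1, 2, 3), g = c("a", "a", "b")), "y", "g"),
    "at least 2 observations")
})

test_that("predictor screening matches the covariance-formula correlation", {
  x <- c(1, 3, 4, 6, 8)
  y <- c(2, 3, 5, 5, 9)
  res <- screen_predictors(tibble::tibble(x = x, y = y), "y", "x")
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, r_oracle, tolerance = 1e-12)
  expect_equal(screen_predictors(tibble::tibble(x = x, y = x),
                                 "y", predictors = "x")$r, 1)
  ortho <- tibble::tibble(x = c(-1, 1, -1, 1), y = c(-1, -1, 1, 1))
  expect_equal(screen_predictors(ortho, "y", "x")$r, 0)
  expect_error(screen_predictors(tibble::tibble(x = rep(1, 5), y = 1:5),
                                 "y", "x"), "zero-variance")
})

test_that("orthonormal blocks decompose R-squared additively", {
  withr::with_seed(41, {
    # orthonormal columns that are also orthogonal to the intercept
    q <- qr.Q(qr(cbind(1, matrix(rnorm(40 * 4), 40, 4))))[, 2:5]
    y <- rnorm(40)
  })
  df <- tibble::as_tibble(as.data.frame(q))
  names(df) <- paste0("x", 1:4)
  df$y <- y
  res <- hierarchical_regression(df, "y",
                                 list(b1 = c("x1", "x2"),
                                      b2 = c("x3", "x4")),
                                 exclusion_alpha = 1)
  ssy <- sum((y - mean(y))^2)
  # centred orthonormal-column algebra: each block's delta R2 is the sum
  # of squared projections of y on its columns over total SS
  dr2 <- vapply(list(c("x1", "x2"), c("x3", "x4")), function(cols) {
    sum(vapply(cols, function(cl) sum(df[[cl]] * (y - mean(y)))^2,
               numeric(1))) / ssy
  }, numeric(1))
  expect_equal(res$steps$delta_R2, dr2, tolerance = 1e-6)
  expect_equal(sum(res$steps$delta_R2), res$total_R2, tolerance = 1e-12)
  expect_true(all(diff(res$steps$R2) >= -1e-12))
})

test_that("a perfectly predictive first block saturates the fit", {
  withr::with_seed(43, {
    df <- tibble::tibble(x1 = rnorm(30), x2 = rnorm(30))
  })
  df$y <- df$x1
  res <- suppressWarnings(
    hierarchical_regression(df, "y", list(b1 = "x1", b2 = "x2")))
  expect_equal(res$steps$R2[1], 1, tolerance = 1e-12)
  expect_equal(res$steps$delta_R2[2], 0, tolerance = 1e-12)
})

test_that("non-significant predictors are excluded with reported t and p", {
  withr::with_seed(47, {
    n <- 200
    df <- tibble::tibble(x1 = rnorm(n), noise = rnorm(n))
    df$y <- df$x1 + rnorm(n)
  })
  res <- hierarchical_regression(df, "y", list(b1 = c("x1", "noise")))
  expect_identical(res$excluded$term, "noise")
  expect_true(all(c("statistic", "p_value") %in% names(res$excluded)))
  expect_gt(res$excluded$p_value, 0.05)
  expect_false("noise" %in% tidy(res)$term)
})

test_that("class dummies add explained variance on class-shifted outcomes", {
  cfg <- default_study_config()
  sim <- simulate_study(cfg, seed = 131)
  df <- sim$data$covariates
  df$phq9_screening <- sim$data$scores[, "screening"]
  df$C2 <- as.integer(sim$truth$class == 2)
  df$C3 <- as.integer(sim$truth$class == 3)
  res <- suppressMessages(hierarchical_regression(
    df, "post_phq9",
    list(intake = c("phq9_screening", "hrsd24", "apoi", "email_support"),
         class = c("C2", "C3"))))
  cls_step <- res$steps[res$steps$step == "class", ]
  expect_gt(cls_step$delta_R2, 0)
  expect_lt(cls_step$p_change, 0.05)
})

test_that("multinomial intercept-only fit recovers the log odds of proportions", {
  df <- tibble::tibble(cls = rep(c("a", "b"), times = c(300, 100)))
  fit <- multinomial_class_prediction(df, "cls", character(0))
  expect_equal(fit$coefficients$estimate[1], log(0.25 / 0.75),
               tolerance = 1e-3)
  expect_equal(fit$chisq, 0, tolerance = 1e-6)
})

test_that("a single binary predictor reproduces the cross-product odds ratio", {
  counts <- c(n00 = 40, n01 = 20, n10 = 15, n11 = 35)
  df <- tibble::tibble(
    x = c(rep(0, 60), rep(1, 50)),
    cls = c(rep("a", 40), rep("b", 20), rep("a", 15), rep("b", 35)))
  fit <- multinomial_class_prediction(df, "cls", "x", reference = "a")
  or_oracle <- (counts["n11"] * counts["n00"]) /
    (counts["n10"] * counts["n01"])
  or_fit <- fit$coefficients$odds_ratio[fit$coefficients$term == "x"]
  expect_equal(unname(or_fit), unname(or_oracle), tolerance = 1e-3)
  expect_equal(fit$coefficients$ci_lower,
               exp(fit$coefficients$estimate -
                     1.96 * fit$coefficients$std_error), tolerance = 1e-12)
  # fitted log-likelihood never below the intercept-only one
  expect_gte(fit$loglik, fit$loglik_null - 1e-8)
})

test_that("higher screening severity lowers the odds of the low-intake class", {
  cfg <- default_study_config()
  sim <- simulate_study(cfg, seed = 137)
  df <- tibble::tibble(
    cls = paste0("C", sim$truth$class),
    phq9_screening = sim$data$scores[, "screening"],
    hrsd24 = sim$data$covariates$hrsd24)
  fit <- multinomial_class_prediction(df, "cls",
                                      c("phq9_screening", "hrsd24"),
                                      reference = "C1")
  b_c2 <- fit$coefficients[fit$coefficients$class == "C2" &
                             fit$coefficients$term == "phq9_screening", ]
  expect_lt(b_c2$estimate, 0)
  expect_lt(b_c2$p_value, 0.05)
  expect_gt(fit$cox_snell, 0)
  expect_gt(fit$nagelkerke, fit$cox_snell)
})
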