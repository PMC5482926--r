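test_that("the default configuration is internally consistent", {
  cfg <- default_study_config()
  expect_equal(sum(cfg$class_prop), 1)
  expect_true(cfg$psi >= 0 && cfg$theta > 0)
  expect_true(all(cfg$miss_prob >= 0 & cfg$miss_prob <= 1))
  # slope calibration solves the early-change targets exactly on the
  # unrounded scale: -(slope1 + log10(3) slope2) / sqrt(psi + theta)
  d_implied <- -(cfg$slope1_mean + log10(3) * cfg$slope2_mean) /
    sqrt(cfg$psi + cfg$theta)
  expect_equal(d_implied, c(1.35, 0.98, -1.78), tolerance = 1e-10)
})

test_that("the noise-free limit emits exact class mean curves", {
  cfg <- default_study_config()
  cfg$psi <- 0
  cfg$theta <- 0
  cfg$post_sd <- rep(0, 3)
  cfg$miss_prob[] <- 0
  cfg$round_scores <- FALSE
  cfg$n <- 30L
  sim <- simulate_study(cfg, seed = 3)
  lam <- build_loading_matrix(cfg$grid)
  for (i in seq_len(cfg$n)) {
    k <- sim$truth$class[i]
    eta <- c(cfg$intercept_mean[k], cfg$slope1_mean[k], cfg$slope2_mean[k])
    curve <- drop(lam %*% eta)
    curve["post"] <- curve["wk12"] + cfg$post_shift[k]
    expect_equal(unname(sim$data$scores[i, ]), unname(curve),
                 tolerance = 1e-12)
  }
})

test_that("every retained subject satisfies the inclusion rule", {
  cfg <- default_study_config()
  for (s in c(1, 2, 9)) {
    sim <- simulate_study(cfg, seed = s)
    sc <- sim$data$scores
    expect_true(all(!is.na(sc[, "screening"])))
    expect_true(all(rowSums(!is.na(sc[, c("wk2", "wk4")])) > 0))
  }
})

test_that("generation is a deterministic function of config and seed", {
  cfg <- default_study_config()
  a <- simulate_study(cfg, seed = 14)
  b <- simulate_study(cfg, seed = 14)
  expect_identical(a$data$scores, b$data$scores)
  expect_identical(a$data$covariates, b$data$covariates)
  expect_identical(a$truth, b$truth)
  c2 <- simulate_study(cfg, seed = 15)
  expect_false(identical(a$data$scores, c2$data$scores))
})

test_that("large-sample draws match the configured class anchors", {
  cfg <- default_study_config()
  cfg$n <- 10000L
  sim <- simulate_study(cfg, seed = 29)
  prop <- as.numeric(table(factor(sim$truth$class, 1:3)) / cfg$n)
  expect_lt(max(abs(prop - cfg$class_prop)), 0.01)
  scr_means <- tapply(sim$data$scores[, "screening"], sim$truth$class,
                      mean)
  expect_lt(max(abs(scr_means - cfg$intercept_mean)), 0.1)
})

test_that("slope calibration reproduces the early-change effect sizes", {
  cfg <- default_study_config()
  cfg$n <- 10000L
  sim <- simulate_study(cfg, seed = 37)
  scr <- sim$data$scores[, "screening"]
  wk4 <- sim$data$scores[, "wk4"]
  d_emp <- vapply(1:3, function(k) {
    idx <- sim$truth$class == k & !is.na(wk4)
    mean(scr[idx] - wk4[idx]) / sd(scr[idx])
  }, numeric(1))
  expect_lt(max(abs(d_emp - c(1.35, 0.98, -1.78))), 0.15)
})

test_that("scale truncation stays a negligible perturbation", {
  sim <- simulate_study(default_study_config(), seed = 51)
  expect_lt(attr(sim$truth, "truncation_bias"), 0.2)
  expect_true(all(sim$data$scores >= 0 & sim$data$scores <= 27,
                  na.rm = TRUE))
})

test_that("email support follows the screening threshold rule", {
  sim <- simulate_study(default_study_config(), seed = 57)
  expect_identical(sim$data$covariates$email_support,
                   as.integer(sim$data$scores[, "screening"] >= 10))
})

test_that("an infeasible all-missing configuration is rejected", {
  cfg <- default_study_config()
  cfg$miss_prob[] <- 1
  expect_error(simulate_study(cfg, seed = 1), "all occasions missing")
})
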