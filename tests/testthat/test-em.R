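test_that("K = 1 EM agrees with a direct numerical maximizer", {
  lam <- early_lambda()
  sim <- withr::with_seed(21, simulate_pgmm(
    60, 1, matrix(c(10, -1, -1.5), 3, 1), psi = 1.2, theta = 0.9, lam))
  fit <- em_fit(sim$scores, pgmm_spec(1, lam), n_starts = 2,
                max_iter = 5000, tol = 1e-13, seed = 3)
  oracle <- optim_k1_oracle(sim$scores, lam)
  expect_equal(fit$loglik, oracle$loglik, tolerance = 1e-6)
  expect_equal(unname(fit$mu[, 1]), oracle$mu, tolerance = 1e-4)
  expect_equal(fit$psi, oracle$psi, tolerance = 1e-4)
  expect_equal(fit$theta, oracle$theta, tolerance = 1e-4)
})

test_that("two well-separated classes are recovered from synthetic truth", {
  lam <- early_lambda()
  mu_true <- matrix(c(6, -0.5, -1, 14, 0.5, 1), 3, 2)
  sim <- withr::with_seed(31, simulate_pgmm(
    400, c(0.5, 0.5), mu_true, psi = 1, theta = 1, lam))
  fit <- em_fit(sim$scores, pgmm_spec(2, lam), n_starts = 10, seed = 5)
  pm <- best_class_permutation(fit$mu["intercept", ], mu_true[1, ])
  expect_lt(max(abs(fit$pi[pm] - c(0.5, 0.5))), 0.05)
  expect_lt(max(abs(fit$mu["intercept", pm] - mu_true[1, ])), 0.5)
  expect_lt(max(abs(fit$mu["slope1", pm] - mu_true[2, ])), 0.5)
})

test_that("posteriors and weights are proper and the parameter count is right", {
  sim <- simulate_study(default_study_config(), seed = 77)
  fit <- suppressMessages(em_fit(sim$data, pgmm_spec(3, early_lambda()),
                                 n_starts = 8, seed = 2))
  expect_equal(rowSums(fit$posterior), rep(1, fit$n), tolerance = 1e-12)
  expect_equal(sum(fit$pi), 1, tolerance = 1e-12)
  expect_true(all(fit$pi >= 0))
  expect_identical(fit$p, (3 - 1) + 3 * 3 + 2)  # 13 under the constraints
  expect_equal(fit$bic, -2 * fit$loglik + fit$p * log(fit$n))
  expect_equal(fit$aic, -2 * fit$loglik + 2 * fit$p)
  expect_equal(fit$sabic, -2 * fit$loglik + fit$p * log((fit$n + 2) / 24))
})

test_that("the observed-data log-likelihood is monotone along EM", {
  lam <- early_lambda()
  for (s in c(41, 42, 43)) {
    sim <- simulate_study(default_study_config(), seed = s)
    fit <- suppressMessages(suppressWarnings(
      em_fit(sim$data, pgmm_spec(3, lam), n_starts = 4, seed = s)))
    path <- fit$convergence$ll_path
    expect_true(all(diff(path) >= -1e-8))
  }
})

test_that("the reported log-likelihood is label-permutation invariant", {
  lam <- early_lambda()
  sim <- simulate_study(default_study_config(), seed = 55)
  fit <- suppressMessages(em_fit(sim$data, pgmm_spec(3, lam),
                                 n_starts = 6, seed = 9))
  scores <- sim$data$scores[, rownames(lam)]
  ll_for_order <- function(ord) {
    pi_k <- fit$pi[ord]
    sum(vapply(seq_len(nrow(scores)), function(i) {
      y <- scores[i, ]
      mask <- !is.na(y)
      y[!mask] <- 0
      ld <- vapply(seq_along(ord), function(j) {
        marginal_loglik_subject(y, mask, fit$mu[, ord[j]], fit$psi,
                                fit$theta, lam)
      }, numeric(1))
      m <- max(ld + log(pi_k))
      m + log(sum(exp(ld + log(pi_k) - m)))
    }, numeric(1)))
  }
  expect_equal(ll_for_order(c(1, 2, 3)), fit$loglik, tolerance = 1e-8)
  expect_equal(ll_for_order(c(3, 1, 2)), fit$loglik, tolerance = 1e-8)
})

test_that("identical data, spec and seed reproduce the fit exactly", {
  sim <- simulate_study(default_study_config(), seed = 66)
  f1 <- suppressMessages(em_fit(sim$data, pgmm_spec(3, early_lambda()),
                                n_starts = 6, seed = 4))
  f2 <- suppressMessages(em_fit(sim$data, pgmm_spec(3, early_lambda()),
                                n_starts = 6, seed = 4))
  expect_identical(f1$pi, f2$pi)
  expect_identical(f1$mu, f2$mu)
  expect_identical(f1$loglik, f2$loglik)
  expect_identical(f1$posterior, f2$posterior)
  expect_identical(f1$classification, f2$classification)
})

test_that("tidy and glance return the advertised shapes", {
  sim <- simulate_study(default_study_config(), seed = 88)
  fit <- suppressMessages(em_fit(sim$data, pgmm_spec(2, early_lambda()),
                                 n_starts = 5, seed = 1))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 2)
  expect_named(td, c("class", "weight", "intercept", "slope1", "slope2",
                     "n_modal"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("bic", "sabic", "aic", "entropy") %in% names(gl)))
  expect_s3_class(autoplot(fit), "ggplot")
})
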