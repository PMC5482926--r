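# Independent oracles used across tests: dense-covariance normal density
# via base linear algebra (never the package's closed-form inverse), and
# small fixture builders.

dense_mvn_logdens <- function(y, mean, sigma) {
  r <- y - mean
  ch <- chol(sigma)
  -0.5 * (length(y) * log(2 * pi) + 2 * sum(log(diag(ch))) +
            sum(backsolve(ch, r, transpose = TRUE)^2))
}

pgmm_sigma <- function(lambda, psi, theta) {
  lambda %*% diag(c(psi, 0, 0)) %*% t(lambda) + theta * diag(nrow(lambda))
}

toy_grid3 <- function() {
  occasion_grid(c("screening", "registration", "wk2"),
                phase1 = c(0, 1, 1), phase2_time = c(0, 0, 2))
}

early_lambda <- function() build_loading_matrix(early_occasion_grid())

# Direct numerical maximization of the same marginal likelihood, used
# as an oracle for the K = 1 EM fit. Dense-covariance density only.
optim_k1_oracle <- function(scores, lambda) {
  negll <- function(par) {
    mu <- par[1:3]
    psi <- exp(par[4])
    theta <- exp(par[5])
    mean_full <- drop(lambda %*% mu)
    sigma <- pgmm_sigma(lambda, psi, theta)
    -sum(apply(scores, 1, dense_mvn_logdens, mean = mean_full,
               sigma = sigma))
  }
  start <- c(mean(scores[, 1]), 0, 0, 0, 0)
  o1 <- optim(start, negll, method = "Nelder-Mead",
              control = list(maxit = 5000, reltol = 1e-14))
  o2 <- optim(o1$par, negll, method = "BFGS",
              control = list(maxit = 2000, reltol = 1e-14))
  list(mu = o2$par[1:3], psi = exp(o2$par[4]), theta = exp(o2$par[5]),
       loglik = -o2$value)
}

# map fitted classes onto true classes by intercept-mean proximity
best_class_permutation <- function(fitted_intercepts, true_intercepts) {
  K <- length(true_intercepts)
  perms <- if (K == 2) list(1:2, 2:1) else
    list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
         c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  errs <- vapply(perms,
                 function(p) sum(abs(fitted_intercepts[p] - true_intercepts)),
                 numeric(1))
  perms[[which.min(errs)]]
}
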