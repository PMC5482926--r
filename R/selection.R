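#' Simulate score series from piecewise growth mixture parameters
#'
#' Draws latent classes from the mixing weights, adds normal intercept
#' deviations (variance `psi`) and occasion noise (variance `theta`),
#' and maps growth factors through the loading matrix. Scores are left
#' continuous (parametric-bootstrap convention); an optional observation
#' mask is reapplied verbatim so replicate data keep the parent's
#' unbalanced design.
#'
#' @param n Number of subjects.
#' @param pi Mixing weights (sum to 1).
#' @param mu 3 x K matrix of class mean growth factors.
#' @param psi Intercept variance.
#' @param theta Residual variance.
#' @param lambda T x 3 loading matrix.
#' @param mask Optional n x T logical matrix; cells with FALSE are set NA.
#'
#' @return A list with `scores` (n x T matrix) and `class` (integer
#'   vector of generating classes).
#' @export
simulate_pgmm <- function(n, pi, mu, psi, theta, lambda, mask = NULL) {
  K <- length(pi)
  stopifnot(ncol(mu) == K, abs(sum(pi) - 1) < 1e-8)
  cls <- sample.int(K, n, replace = TRUE, prob = pi)
  b <- rnorm(n, 0, sqrt(psi))
  t_n <- nrow(lambda)
  eps <- matrix(rnorm(n * t_n, 0, sqrt(theta)), n, t_n)
  scores <- t(lambda %*% mu[, cls]) + b + eps
  colnames(scores) <- rownames(lambda)
  if (!is.null(mask)) {
    stopifnot(all(dim(mask) == dim(scores)))
    scores[!mask] <- NA_real_
  }
  list(scores = scores, class = cls)
}

#' Fit models with 1..K_max latent classes
#'
#' Fits the piecewise growth mixture for each class count on the same
#' data and loading matrix, with per-K seeds derived deterministically
#' from the master seed. A K whose estimation fails is kept in the
#' sequence with a flag; fitting continues.
#'
#' @param data An `ec_data` or score matrix (see [em_fit()]).
#' @param loading T x 3 loading matrix shared by all fits.
#' @param K_max Largest class count, `>= 2`.
#' @param seed Master seed.
#' @param n_starts,max_iter,tol Passed to [em_fit()].
#'
#' @return A `pgmm_sequence`: list of fits (NULL where estimation
#'   failed), the scores/loading used, and the seed.
#' @export
fit_sequence <- function(data, loading, K_max, seed = 1, n_starts = 20,
                         max_iter = 500, tol = 1e-7) {
  stopifnot(K_max >= 2)
  scores <- .scores_for_loading(data, loading)
  if (nrow(scores) < 3 * K_max) {
    stop("underdetermined: fewer than 3*K_max subjects", call. = FALSE)
  }
  sub_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1,
                                                 K_max))
  fits <- vector("list", K_max)
  failed <- logical(K_max)
  for (K in seq_len(K_max)) {
    fits[[K]] <- tryCatch(
      em_fit(scores, pgmm_spec(K, loading), n_starts = n_starts,
             max_iter = max_iter, tol = tol, seed = sub_seeds[K]),
      error = function(e) {
        warning("K = ", K, " estimation failed: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    failed[K] <- is.null(fits[[K]])
  }
  structure(list(fits = fits, K_max = K_max, failed = failed,
                 scores = scores, loading = loading, seed = seed,
                 n_starts = n_starts, max_iter = max_iter, tol = tol),
            class = "pgmm_sequence")
}

#' Enumeration table for a fit sequence
#'
#' One row per class count with log-likelihood, information criteria and
#' entropy (the layout of a class-enumeration table).
#'
#' @param x A `pgmm_sequence`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.pgmm_sequence <- function(x, ...) {
  purrr::map_dfr(seq_len(x$K_max), function(K) {
    f <- x$fits[[K]]
    if (is.null(f)) {
      return(tibble::tibble(K = K, loglik = NA_real_, p = NA_integer_,
                            bic = NA_real_, sabic = NA_real_,
                            aic = NA_real_, entropy = NA_real_,
                            converged = FALSE))
    }
    tibble::tibble(K = K, loglik = f$loglik, p = f$p, bic = f$bic,
                   sabic = f$sabic, aic = f$aic, entropy = f$entropy,
                   converged = f$convergence$converged)
  })
}

#' @export
print.pgmm_sequence <- function(x, ...) {
  cat("PGMM fit sequence, K = 1..", x$K_max, "\n", sep = "")
  print(as.data.frame(tidy(x)), digits = 6)
  invisible(x)
}

#' Plot the information-criterion path of a fit sequence
#'
#' @param object A `pgmm_sequence`.
#' @param ... Unused.
#' @return A ggplot object with one line per criterion.
#' @export
autoplot.pgmm_sequence <- function(object, ...) {
  tab <- tidy(object)
  df <- tidyr::pivot_longer(tab[c("K", "bic", "sabic", "aic")],
                            -"K", names_to = "criterion",
                            values_to = "value")
  df$criterion <- toupper(df$criterion)
  ggplot2::ggplot(df, ggplot2::aes(.data$K, .data$value,
                                   colour = .data$criterion)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "number of classes", y = "criterion value",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Bootstrapped likelihood ratio test of K vs K-1 classes
#'
#' Parametric bootstrap of the likelihood-ratio statistic
#' `2 * (LL_K - LL_{K-1})`: each replicate simulates data of identical
#' shape and missingness from the fitted (K-1)-class model, refits both
#' models, and records the replicate statistic. Replicate fits reuse the
#' parent parameters as one EM start plus `replicate_starts - 1` random
#' perturbations (cost control). A replicate whose fits fail is redrawn
#' up to 3 times, then counted conservatively as at least as large as
#' the observed statistic. The p-value is
#' `(1 + #\{replicates >= observed\}) / (B + 1)`.
#'
#' @param data An `ec_data` or score matrix.
#' @param loading T x 3 loading matrix.
#' @param K Number of classes under the alternative, `>= 2`.
#' @param B Number of bootstrap replicates (default 99).
#' @param seed Seed for the bootstrap stream.
#' @param fit_k,fit_km1 Optional prefitted `pgmm_fit`s for K and K-1
#'   classes (refit here when NULL).
#' @param n_starts Starts for the parent fits when refitting.
#' @param replicate_starts EM starts per replicate fit (default 5).
#' @param max_iter,tol Passed to the EM runs.
#'
#' @return A `blrt_result` with the observed statistic, replicate
#'   statistics, `p_value`, `B` and `seed`.
#' @export
blrt <- function(data, loading, K, B = 99, seed = 1, fit_k = NULL,
                 fit_km1 = NULL, n_starts = 20, replicate_starts = 5,
                 max_iter = 500, tol = 1e-7) {
  stopifnot(K >= 2, B >= 1)
  scores <- .scores_for_loading(data, loading)
  n <- nrow(scores)
  seeds <- withr::with_seed(seed,
                            sample.int(.Machine$integer.max - 1, B + 2))
  if (is.null(fit_km1)) {
    fit_km1 <- em_fit(scores, pgmm_spec(K - 1, loading),
                      n_starts = n_starts, seed = seeds[B + 1],
                      max_iter = max_iter, tol = tol)
  }
  if (is.null(fit_k)) {
    fit_k <- em_fit(scores, pgmm_spec(K, loading), n_starts = n_starts,
                    seed = seeds[B + 2], max_iter = max_iter, tol = tol)
  }
  observed <- 2 * (fit_k$loglik - fit_km1$loglik)
  mask <- !is.na(scores)

  stat_b <- vapply(seq_len(B), function(b) {
    withr::with_seed(seeds[b], {
      for (attempt in 1:3) {
        sim <- simulate_pgmm(n, fit_km1$pi, fit_km1$mu, fit_km1$psi,
                             fit_km1$theta, loading, mask = mask)
        s <- .blrt_replicate_stat(sim$scores, loading, K, fit_km1, fit_k,
                                  replicate_starts, max_iter, tol)
        if (!is.na(s)) return(s)
      }
      observed                         # conservative: counts as >= observed
    })
  }, numeric(1))

  p <- (1 + sum(stat_b >= observed)) / (B + 1)
  structure(list(K = K, statistic = observed, replicates = stat_b,
                 p_value = p, B = B, seed = seed,
                 fit_k = fit_k, fit_km1 = fit_km1),
            class = "blrt_result")
}

# Replicate statistic for one simulated dataset; NA on failure.
.blrt_replicate_stat <- function(scores, loading, K, fit_km1, fit_k,
                                 replicate_starts, max_iter, tol) {
  fit_null <- .refit_from_parent(scores, loading, K - 1,
                                 list(pi = unname(fit_km1$pi),
                                      mu = unname(fit_km1$mu),
                                      psi = fit_km1$psi,
                                      theta = fit_km1$theta),
                                 replicate_starts, max_iter, tol)
  fit_alt <- .refit_from_parent(scores, loading, K,
                                list(pi = unname(fit_k$pi),
                                     mu = unname(fit_k$mu),
                                     psi = fit_k$psi,
                                     theta = fit_k$theta),
                                replicate_starts, max_iter, tol)
  if (is.null(fit_null) || is.null(fit_alt)) return(NA_real_)
  2 * (fit_alt$loglik - fit_null$loglik)
}

# Cheap best-of-starts EM with the parent parameters as start 1 and
# random perturbations as the rest. Returns NULL if all starts fail.
.refit_from_parent <- function(scores, loading, K, parent, n_starts,
                               max_iter, tol) {
  patterns <- tryCatch(.make_patterns(scores, loading),
                       error = function(e) NULL)
  if (is.null(patterns)) return(NULL)
  n <- nrow(scores)
  sd_pert <- max(sqrt(parent$psi + parent$theta), 0.5)
  inits <- c(list(parent), lapply(seq_len(max(n_starts - 1, 0)),
    function(s) {
      pi_s <- parent$pi + runif(K, 0, 0.5)
      list(pi = pi_s / sum(pi_s),
           mu = parent$mu + matrix(rnorm(3 * K, sd = sd_pert), 3, K),
           psi = parent$psi * exp(rnorm(1, sd = 0.3)),
           theta = parent$theta * exp(rnorm(1, sd = 0.3)))
    }))
  best <- NULL
  for (init in inits) {
    run <- .em_one(patterns, init, n, max_iter, tol)
    if (!run$degenerate &&
        (is.null(best) || run$loglik > best$loglik)) {
      best <- run
    }
  }
  best
}

#' @export
print.blrt_result <- function(x, ...) {
  cat(sprintf("BLRT %d vs %d classes: statistic %.3f, p = %.4g (B = %d)\n",
              x$K, x$K - 1, x$statistic, x$p_value, x$B))
  invisible(x)
}

#' Choose the number of classes by the two-fold BIC + BLRT rule
#'
#' First locates the class count at which BIC stops decreasing
#' (`BIC(k+1) >= BIC(k)`, ties stop the descent; if BIC still decreases
#' at `K_max`, the candidate is `K_max`). That candidate `k` is then
#' tested against `k - 1` with the bootstrapped likelihood ratio test:
#' a significant test accepts `k`; otherwise `k - 1` is tested against
#' `k - 2`, stepping down until a test is significant. If the loop
#' exhausts, a single class is chosen.
#'
#' @param sequence A `pgmm_sequence`, or a bare numeric vector of BIC
#'   values for K = 1..K_max (decision replay).
#' @param blrt_runner Function of one argument `K` returning an object
#'   with a `p_value` element (e.g. a [blrt()] result). When NULL and
#'   `sequence` is a `pgmm_sequence`, a default runner performing the
#'   bootstrap on the sequence's data is used.
#' @param alpha Significance level (default 0.05).
#' @param B,seed,replicate_starts Passed to the default [blrt()] runner.
#'
#' @return An `ec_selection`: chosen `K`, the BIC path, a tibble of BLRT
#'   tests performed, and the stopping reason.
#' @export
select_by_bic_blrt <- function(sequence, blrt_runner = NULL, alpha = 0.05,
                               B = 99, seed = 1, replicate_starts = 5) {
  if (inherits(sequence, "pgmm_sequence")) {
    bic <- vapply(sequence$fits,
                  function(f) if (is.null(f)) NA_real_ else f$bic,
                  numeric(1))
    if (is.null(blrt_runner)) {
      seq_obj <- sequence
      blrt_runner <- function(K) {
        blrt(seq_obj$scores, seq_obj$loading, K, B = B, seed = seed + K,
             fit_k = seq_obj$fits[[K]], fit_km1 = seq_obj$fits[[K - 1]],
             replicate_starts = replicate_starts,
             max_iter = seq_obj$max_iter, tol = seq_obj$tol)
      }
    }
  } else {
    bic <- as.numeric(sequence)
    if (is.null(blrt_runner)) {
      stop("`blrt_runner` is required when `sequence` is a BIC path",
           call. = FALSE)
    }
  }
  K_max <- length(bic)
  stopifnot(K_max >= 1)

  candidate <- K_max
  for (k in seq_len(K_max - 1)) {
    if (is.na(bic[k + 1]) || bic[k + 1] >= bic[k]) {
      candidate <- k
      break
    }
  }

  tests <- tibble::tibble(K = integer(), statistic = numeric(),
                          p_value = numeric(), significant = logical())
  chosen <- 1L
  reason <- "BLRT chain exhausted; single-class solution retained"
  if (candidate == 1L) {
    reason <- "BIC increased from K = 1; no BLRT invoked"
  } else {
    k <- candidate
    while (k >= 2) {
      res <- blrt_runner(k)
      sig <- res$p_value < alpha
      tests <- dplyr::bind_rows(tests, tibble::tibble(
        K = as.integer(k),
        statistic = res$statistic %||% NA_real_,
        p_value = res$p_value, significant = sig))
      if (sig) {
        chosen <- as.integer(k)
        reason <- sprintf("BIC stopped decreasing at K = %d; BLRT %d vs %d significant (p = %.4g)",
                          candidate, k, k - 1, res$p_value)
        break
      }
      k <- k - 1
    }
  }

  structure(list(K = chosen, candidate = as.integer(candidate),
                 bic_path = tibble::tibble(K = seq_len(K_max), bic = bic),
                 blrt_tests = tests, alpha = alpha, reason = reason),
            class = "ec_selection")
}

#' @export
print.ec_selection <- function(x, ...) {
  cat("Selected K =", x$K, "\n")
  cat(x$reason, "\n")
  cat("BIC path:", paste(round(x$bic_path$bic, 2), collapse = ", "), "\n")
  if (nrow(x$blrt_tests) > 0) {
    cat("BLRT tests:\n")
    print(as.data.frame(x$blrt_tests))
  }
  invisible(x)
}
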