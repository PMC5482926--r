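#' Specify a piecewise growth mixture model
#'
#' Fixes the number of latent classes and the loading matrix, together
#' with the variance structure used throughout this package: slope
#' variances identically zero, one intercept variance shared across
#' classes, and one residual variance shared across occasions and
#' classes. Heterogeneity in change is therefore carried entirely by the
#' class-specific mean slopes.
#'
#' @param n_classes Number of latent classes, `>= 1`.
#' @param loading T x 3 loading matrix from [build_loading_matrix()].
#'
#' @return A list of class `pgmm_spec`.
#' @export
pgmm_spec <- function(n_classes, loading) {
  n_classes <- as.integer(n_classes)
  if (is.na(n_classes) || n_classes < 1) {
    stop("`n_classes` must be a positive integer", call. = FALSE)
  }
  stopifnot(is.matrix(loading), ncol(loading) == 3)
  structure(list(n_classes = n_classes, loading = loading,
                 slope_var_zero = TRUE, equal_intercept_var = TRUE,
                 equal_residual_var = TRUE),
            class = "pgmm_spec")
}

#' Fit a piecewise growth mixture model by EM
#'
#' Maximum-likelihood estimation of the K-class piecewise growth mixture
#' model with full-information handling of missing occasions: each
#' subject contributes the marginal normal density of their observed
#' coordinates only (see [marginal_loglik_subject()]). Estimation uses EM
#' over both the latent class and the latent intercept deviation, with
#' multiple starts: the first start is seeded by a k-means partition of
#' the (screening, last-observed-early-score) pairs and the remaining
#' starts perturb it randomly. The best converged, non-degenerate start
#' (a start is degenerate when a class weight falls below `1/(2n)`) is
#' returned.
#'
#' @param data An `ec_data` object, or a numeric subject x occasion
#'   matrix with NA for missing. Columns must match the loading rows;
#'   extra occasions in an `ec_data` are dropped.
#' @param spec A [pgmm_spec()].
#' @param n_starts Number of EM starts (default 20).
#' @param max_iter Maximum EM iterations per start (default 500).
#' @param tol Relative log-likelihood convergence tolerance (default 1e-7).
#' @param seed Integer seed controlling start perturbations.
#'
#' @return A `pgmm_fit`: mixing weights `pi`, class mean growth factors
#'   `mu` (3 x K), `psi`, `theta`, `loglik`, parameter count `p`, `n`,
#'   `bic`/`sabic`/`aic`, `entropy`, `posterior` (n x K), modal
#'   `classification`, and a `convergence` record (iterations, best
#'   start, seed, per-start log-likelihoods, LL path of the best start).
#' @export
em_fit <- function(data, spec, n_starts = 20, max_iter = 500,
                   tol = 1e-7, seed = 1) {
  stopifnot(inherits(spec, "pgmm_spec"))
  lambda <- spec$loading
  scores <- .scores_for_loading(data, lambda)
  n <- nrow(scores)
  K <- spec$n_classes
  if (n < 3 * K) stop("too few subjects for ", K, " classes", call. = FALSE)
  patterns <- .make_patterns(scores, lambda)

  inits <- withr::with_seed(seed,
    .em_starts(scores, lambda, K, n_starts))

  best <- NULL
  start_ll <- rep(NA_real_, n_starts)
  n_degenerate <- 0L
  for (s in seq_len(n_starts)) {
    run <- .em_one(patterns, inits[[s]], n, max_iter, tol)
    if (run$degenerate) {
      n_degenerate <- n_degenerate + 1L
      next
    }
    start_ll[s] <- run$loglik
    if (is.null(best) || run$loglik > best$loglik + 1e-9) {
      best <- run
      best$start <- s
    }
  }
  if (n_degenerate > 0) {
    message(n_degenerate, " of ", n_starts,
            " EM start(s) discarded (degenerate class weight)")
  }
  if (is.null(best)) {
    stop("all EM starts degenerate; try fewer classes", call. = FALSE)
  }
  if (!best$converged) {
    warning("EM did not converge in ", max_iter,
            " iterations (best start ", best$start, ")", call. = FALSE)
  }

  ord <- order(best$pi, decreasing = TRUE)
  pi_hat <- best$pi[ord]
  mu_hat <- best$mu[, ord, drop = FALSE]
  dimnames(mu_hat) <- list(c("intercept", "slope1", "slope2"),
                           paste0("class", seq_len(K)))
  logd <- .class_logdens(patterns, mu_hat, best$psi, best$theta, n)
  post <- .posterior_from_logdens(logd, pi_hat)
  p <- (K - 1) + 3 * K + 2
  ic <- information_criteria(best$loglik, p, n)

  structure(list(
    pi = setNames(pi_hat, colnames(mu_hat)),
    mu = mu_hat, psi = best$psi, theta = best$theta,
    loglik = best$loglik, p = p, n = n, K = K,
    bic = ic$bic, sabic = ic$sabic, aic = ic$aic,
    entropy = if (K >= 2) relative_entropy(post$post) else NA_real_,
    posterior = post$post,
    classification = max.col(post$post, ties.method = "first"),
    subject_ids = rownames(scores),
    loading = lambda,
    convergence = list(iterations = best$iter, converged = best$converged,
                       best_start = best$start, seed = seed,
                       n_starts = n_starts,
                       n_degenerate_starts = n_degenerate,
                       start_loglik = start_ll, ll_path = best$ll_path)),
    class = "pgmm_fit")
}

.scores_for_loading <- function(data, lambda) {
  if (inherits(data, "ec_data")) {
    occ <- rownames(lambda)
    if (!is.null(occ)) {
      missing_occ <- setdiff(occ, colnames(data$scores))
      if (length(missing_occ) > 0) {
        stop("dataset lacks occasion(s): ",
             paste(missing_occ, collapse = ", "), call. = FALSE)
      }
      data$scores[, occ, drop = FALSE]
    } else {
      data$scores
    }
  } else {
    as.matrix(data)
  }
}

.posterior_from_logdens <- function(logd, pi) {
  logw <- logd + rep(log(pi), each = nrow(logd))
  m <- logw[, 1]
  for (k in seq_len(ncol(logw))[-1]) m <- pmax(m, logw[, k])
  w <- exp(logw - m)
  rs <- rowSums(w)
  list(post = w / rs, loglik = sum(m + log(rs)))
}

# Starting values: k-means on (screening, last observed early score),
# class means by per-cluster least squares on the loading rows, random
# perturbations for starts 2..n_starts. Runs under the caller's seed.
.em_starts <- function(scores, lambda, K, n_starts) {
  n <- nrow(scores)
  x1 <- scores[, 1]
  x1[is.na(x1)] <- mean(x1, na.rm = TRUE)
  last_obs <- apply(scores, 1, function(r) {
    o <- which(!is.na(r))
    r[o[length(o)]]
  })
  feat <- cbind(x1, last_obs)
  part <- if (K == 1) rep(1L, n) else {
    km <- tryCatch(suppressWarnings(kmeans(feat, centers = K, nstart = 5)),
                   error = function(e) NULL)
    if (is.null(km)) sample(rep_len(seq_len(K), n)) else km$cluster
  }
  theta0 <- max(var(as.vector(scores), na.rm = TRUE) / 2, 0.25)
  psi0 <- max(var(x1) - theta0, 0.25)
  mu0 <- vapply(seq_len(K), function(k) {
    idx <- which(part == k)
    occ_mean <- colMeans(scores[idx, , drop = FALSE], na.rm = TRUE)
    ok <- is.finite(occ_mean)
    if (sum(ok) >= 3) {
      fit <- tryCatch(qr.solve(lambda[ok, , drop = FALSE], occ_mean[ok]),
                      error = function(e) NULL)
      if (!is.null(fit)) return(fit)
    }
    c(mean(x1[idx]), 0, 0)
  }, numeric(3))
  pi0 <- tabulate(part, K) / n
  pi0 <- pmax(pi0, 0.05)
  pi0 <- pi0 / sum(pi0)
  base <- list(pi = pi0, mu = mu0, psi = psi0, theta = theta0)
  sd_feat <- max(sd(x1), 0.5)
  c(list(base), lapply(seq_len(max(n_starts - 1, 0)), function(s) {
    pi_s <- pi0 + runif(K, 0, 0.5)
    list(pi = pi_s / sum(pi_s),
         mu = mu0 + matrix(rnorm(3 * K, sd = sd_feat), 3, K),
         psi = psi0 * exp(rnorm(1, sd = 0.3)),
         theta = theta0 * exp(rnorm(1, sd = 0.3)))
  }))
}

# One EM run (compiled core). Latent variables: class membership and
# intercept deviation b_i ~ N(0, psi). Closed-form E and M steps;
# observed-data LL is monotone up to numerical tolerance.
.em_one <- function(patterns, init, n, max_iter, tol) {
  K <- length(init$pi)
  res <- em_one_cpp(unname(patterns), as.numeric(init$pi),
                    matrix(as.numeric(init$mu), 3, K),
                    max(init$psi, 1e-8), max(init$theta, 1e-8),
                    as.integer(max_iter), tol, 1 / (2 * n))
  res$pi <- as.numeric(res$pi)
  res$mu <- matrix(res$mu, 3, K)
  res
}

# Pure-R reference EM, retained for cross-checking the compiled core.
.em_one_r <- function(patterns, init, n, max_iter, tol) {
  pi_k <- init$pi
  mu <- init$mu
  psi <- max(init$psi, 1e-8)
  theta <- max(init$theta, 1e-8)
  K <- length(pi_k)
  total_t <- sum(vapply(patterns, function(p) p$t_o * length(p$idx),
                        numeric(1)))
  floor_w <- 1 / (2 * n)
  ll_path <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L

  repeat {
    iter <- iter + 1L
    # E-step quantities per pattern, reused in the M-step
    stats_old <- lapply(patterns, .pattern_resid_stats, mu = mu)
    logd <- matrix(NA_real_, n, K)
    for (j in seq_along(patterns)) {
      pat <- patterns[[j]]
      st <- stats_old[[j]]
      denom <- theta + psi * pat$t_o
      quad <- (st$rss - (psi / denom) * st$rs^2) / theta
      logd[pat$idx, ] <- -0.5 * (pat$t_o * log(2 * pi) +
                                   (pat$t_o - 1) * log(theta) +
                                   log(denom) + quad)
    }
    ps <- .posterior_from_logdens(logd, pi_k)
    post <- ps$post
    ll <- ps$loglik
    ll_path <- c(ll_path, ll)

    pi_new <- colMeans(post)
    if (any(pi_new < floor_w)) {
      return(list(degenerate = TRUE, loglik = ll, pi = pi_new, mu = mu,
                  psi = psi, theta = theta, iter = iter,
                  converged = FALSE, ll_path = ll_path))
    }
    if (is.finite(ll_old) &&
        abs(ll - ll_old) <= tol * (abs(ll_old) + 1e-10)) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    ll_old <- ll

    # E[b_i | y_i, class k] per pattern/class, under current parameters
    m_list <- vector("list", length(patterns))
    a_mat <- matrix(0, 3, 3)
    b_mat <- matrix(0, 3, K)
    a_list <- lapply(seq_len(K), function(k) matrix(0, 3, 3))
    psi_acc <- 0
    for (j in seq_along(patterns)) {
      pat <- patterns[[j]]
      st <- stats_old[[j]]
      v_p <- 1 / (1 / psi + pat$t_o / theta)
      m_ik <- (v_p / theta) * st$rs            # n_p x K
      m_list[[j]] <- list(m = m_ik, v = v_p)
      w <- post[pat$idx, , drop = FALSE]
      w_tot <- colSums(w)
      psi_acc <- psi_acc + sum(w * m_ik^2) + v_p * sum(w_tot)
      for (k in seq_len(K)) {
        a_list[[k]] <- a_list[[k]] + w_tot[k] * pat$ltl
        yw <- colSums(w[, k] * pat$y) - sum(w[, k] * m_ik[, k])
        b_mat[, k] <- b_mat[, k] + drop(crossprod(pat$lambda, yw))
      }
    }
    mu_new <- vapply(seq_len(K),
                     function(k) drop(solve(a_list[[k]], b_mat[, k])),
                     numeric(3))
    psi_new <- max(psi_acc / n, 1e-10)

    # theta update with the refreshed class means
    theta_acc <- 0
    for (j in seq_along(patterns)) {
      pat <- patterns[[j]]
      st_new <- .pattern_resid_stats(pat, mu_new)
      m_ik <- m_list[[j]]$m
      v_p <- m_list[[j]]$v
      term <- st_new$rss - 2 * m_ik * st_new$rs +
        pat$t_o * (m_ik^2 + v_p)
      theta_acc <- theta_acc + sum(post[pat$idx, , drop = FALSE] * term)
    }
    theta_new <- max(theta_acc / total_t, 1e-10)

    pi_k <- pi_new
    mu <- mu_new
    psi <- psi_new
    theta <- theta_new
  }

  list(degenerate = FALSE, pi = pi_k, mu = mu, psi = psi, theta = theta,
       loglik = ll_path[length(ll_path)], iter = iter,
       converged = converged, ll_path = ll_path)
}

#' Penalized-likelihood information criteria
#'
#' `BIC = -2 LL + p log(n)`, `AIC = -2 LL + 2 p`, and the sample-size
#' adjusted BIC `SABIC = -2 LL + p log((n + 2)/24)`.
#'
#' @param loglik Total log-likelihood.
#' @param p Number of free parameters.
#' @param n Number of subjects.
#' @return A list with `bic`, `sabic`, `aic`.
#' @export
information_criteria <- function(loglik, p, n) {
  stopifnot(n >= 1, p >= 0)
  list(bic = -2 * loglik + p * log(n),
       sabic = -2 * loglik + p * log((n + 2) / 24),
       aic = -2 * loglik + 2 * p)
}

#' Relative entropy of a posterior classification
#'
#' `1 - sum(-p_ik log p_ik) / (n log K)`: 1 for a perfectly separated
#' (0/1) posterior, 0 for a uniform one. Reported descriptively; never
#' used for class enumeration.
#'
#' @param posterior n x K matrix of posterior class probabilities
#'   (rows sum to 1).
#' @return A value in `[0, 1]`, or `NA` (with a message) when K = 1,
#'   where the quantity is undefined.
#' @export
relative_entropy <- function(posterior) {
  posterior <- as.matrix(posterior)
  K <- ncol(posterior)
  if (K < 2) {
    message("relative entropy is undefined for a single class")
    return(NA_real_)
  }
  plogp <- posterior * log(posterior)
  plogp[posterior == 0] <- 0
  1 - sum(-plogp) / (nrow(posterior) * log(K))
}

#' Modal class assignment
#'
#' Assigns each subject to the class with the largest posterior
#' probability; exact ties go to the lower class index.
#'
#' @param fit A `pgmm_fit`.
#' @return An integer vector of class labels (1..K).
#' @export
classify_subjects <- function(fit) {
  stopifnot(inherits(fit, "pgmm_fit"))
  max.col(fit$posterior, ties.method = "first")
}

#' @export
print.pgmm_fit <- function(x, ...) {
  cat("Piecewise growth mixture model, K =", x$K,
      "(n =", x$n, "subjects)\n")
  cat(sprintf("logLik %.2f | BIC %.2f | SABIC %.2f | AIC %.2f | entropy %s\n",
              x$loglik, x$bic, x$sabic, x$aic,
              ifelse(is.na(x$entropy), "-", sprintf("%.2f", x$entropy))))
  print(round(rbind(weight = x$pi, x$mu), 3))
  cat(sprintf("psi (intercept var) %.3f | theta (residual var) %.3f\n",
              x$psi, x$theta))
  invisible(x)
}

#' Tidy a fitted mixture: one row per latent class
#'
#' @param x A `pgmm_fit`.
#' @param ... Unused.
#' @return A tibble with class weights, mean growth factors and modal
#'   class sizes.
#' @export
tidy.pgmm_fit <- function(x, ...) {
  tibble::tibble(class = seq_len(x$K),
                 weight = unname(x$pi),
                 intercept = x$mu["intercept", ],
                 slope1 = x$mu["slope1", ],
                 slope2 = x$mu["slope2", ],
                 n_modal = tabulate(x$classification, x$K))
}

#' One-row fit summary: likelihood, criteria, entropy, variances
#'
#' @param x A `pgmm_fit`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.pgmm_fit <- function(x, ...) {
  tibble::tibble(n = x$n, K = x$K, loglik = x$loglik, p = x$p,
                 bic = x$bic, sabic = x$sabic, aic = x$aic,
                 entropy = x$entropy, psi = x$psi, theta = x$theta,
                 iterations = x$convergence$iterations,
                 converged = x$convergence$converged)
}

#' Posterior probabilities and modal assignment as a tibble
#'
#' @param fit A `pgmm_fit`.
#' @return A tibble with subject_id, one posterior column per class, and
#'   the modal `class`.
#' @export
posterior_table <- function(fit) {
  stopifnot(inherits(fit, "pgmm_fit"))
  post <- tibble::as_tibble(fit$posterior, .name_repair = "minimal")
  names(post) <- paste0("p_class", seq_len(fit$K))
  dplyr::bind_cols(
    tibble::tibble(subject_id = fit$subject_ids %||% seq_len(fit$n)),
    post,
    tibble::tibble(class = fit$classification))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plot class mean trajectories of a fitted model
#'
#' Model-implied mean score at each occasion per latent class
#' (`lambda %*% mu`), drawn over the modelled occasion grid.
#'
#' @param object A `pgmm_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pgmm_fit <- function(object, ...) {
  occ <- rownames(object$loading) %||%
    paste0("t", seq_len(nrow(object$loading)))
  traj <- object$loading %*% object$mu
  df <- tibble::tibble(
    occasion = factor(rep(occ, times = object$K), levels = occ),
    class = factor(rep(paste0("class ", seq_len(object$K),
                              " (", round(100 * object$pi), "%)"),
                       each = length(occ))),
    mean_score = as.vector(traj))
  ggplot2::ggplot(df, ggplot2::aes(.data$occasion, .data$mean_score,
                                   colour = .data$class,
                                   group = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = "model-implied mean score",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
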