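#' Marginal log-likelihood of one subject's observed scores
#'
#' Log-density of the observed coordinates of a subject's score series
#' under one latent class of the piecewise growth model. With growth-factor
#' means `mu`, intercept variance `psi`, residual variance `theta` and
#' loading matrix `lambda`, the full series is multivariate normal with
#' mean `lambda %*% mu` and covariance
#' `lambda %*% diag(c(psi, 0, 0)) %*% t(lambda) + theta * I`; missing
#' coordinates are marginalized by restricting mean and covariance to the
#' observed rows (full-information likelihood, no imputation). Because the
#' slope variances are fixed at zero the observed-block covariance is
#' `psi * J + theta * I`, which this function inverts in closed form.
#'
#' @param y Numeric vector of length T (scores; values at unobserved
#'   coordinates are ignored).
#' @param mask Logical vector of length T, TRUE where observed.
#' @param mu Growth-factor mean vector (intercept, slope1, slope2).
#' @param psi Intercept variance, `>= 0`.
#' @param theta Residual variance, `> 0`.
#' @param lambda T x 3 loading matrix, see [build_loading_matrix()].
#'
#' @return The log-density (scalar).
#' @export
#' @examples
#' lam <- build_loading_matrix(early_occasion_grid())
#' marginal_loglik_subject(c(10, NA, 8, 7), c(TRUE, FALSE, TRUE, TRUE),
#'                         mu = c(10, -1, -2), psi = 1, theta = 1, lam)
marginal_loglik_subject <- function(y, mask, mu, psi, theta, lambda) {
  mask <- as.logical(mask)
  stopifnot(length(y) == nrow(lambda), length(mask) == length(y),
            length(mu) == 3)
  if (!any(mask)) stop("all coordinates missing", call. = FALSE)
  if (theta <= 0) stop("`theta` must be positive", call. = FALSE)
  if (psi < 0) stop("`psi` must be nonnegative", call. = FALSE)
  t_o <- sum(mask)
  r <- y[mask] - drop(lambda[mask, , drop = FALSE] %*% mu)
  .loglik_compound(sum(r^2), sum(r), t_o, psi, theta)
}

# log N(r; 0, psi*J + theta*I) from sufficient statistics, via the
# Sherman-Morrison inverse and the matching determinant.
.loglik_compound <- function(rss, rs, t_o, psi, theta) {
  denom <- theta + psi * t_o
  if (denom <= 0) stop("implied covariance not positive definite",
                       call. = FALSE)
  quad <- (rss - (psi / denom) * rs^2) / theta
  -0.5 * (t_o * log(2 * pi) + (t_o - 1) * log(theta) + log(denom) + quad)
}

# Group a score matrix (NA = missing) by missingness pattern.
# Returns a list of pattern blocks with precomputed loading crossproducts.
.make_patterns <- function(scores, lambda) {
  stopifnot(ncol(scores) == nrow(lambda))
  if (any(rowSums(!is.na(scores)) == 0)) {
    stop("subject(s) with no observed occasion on the modelled grid",
         call. = FALSE)
  }
  key <- apply(!is.na(scores), 1, paste, collapse = "")
  lapply(split(seq_len(nrow(scores)), key), function(idx) {
    obs <- !is.na(scores[idx[1], ])
    lam <- lambda[obs, , drop = FALSE]
    y <- scores[idx, obs, drop = FALSE]
    list(idx = idx, obs = obs, t_o = sum(obs), y = y,
         ysum = rowSums(y), yss = rowSums(y^2),
         lambda = lam, ltl = crossprod(lam))
  })
}

# Per-pattern residual sufficient statistics against class means mu
# (3 x K): rs = rowsum of residuals, rss = residual sum of squares,
# both n_p x K, expanded from precomputed score sums and one
# crossproduct per pattern.
.pattern_resid_stats <- function(pat, mu) {
  means <- pat$lambda %*% mu            # t_o x K
  cross <- pat$y %*% means              # n_p x K
  msum <- colSums(means)
  mss <- colSums(means^2)
  n_p <- length(pat$idx)
  K <- ncol(means)
  list(rss = (pat$yss - 2 * cross) + rep(mss, each = n_p),
       rs = matrix(pat$ysum - rep(msum, each = n_p), n_p, K))
}

# n x K matrix of per-subject class log-densities.
.class_logdens <- function(patterns, mu, psi, theta, n) {
  K <- ncol(mu)
  out <- matrix(NA_real_, n, K)
  for (pat in patterns) {
    st <- .pattern_resid_stats(pat, mu)
    denom <- theta + psi * pat$t_o
    quad <- (st$rss - (psi / denom) * st$rs^2) / theta
    out[pat$idx, ] <- -0.5 * (pat$t_o * log(2 * pi) +
                                (pat$t_o - 1) * log(theta) +
                                log(denom) + quad)
  }
  out
}
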