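#' Contingency analysis with Pearson residuals
#'
#' Pearson chi-square test of independence on a labelled count table,
#' with expected counts and cell standardized residuals
#' `(O - E) / sqrt(E)` (the Pearson residual). Degrees of freedom are
#' the standard `(R - 1)(C - 1)`.
#'
#' @param counts A numeric matrix (or data frame) of nonnegative counts,
#'   at least 2 x 2, ideally with dimnames.
#'
#' @return A `contingency_result`: `observed`, `expected`, `statistic`,
#'   `df`, `residuals`, `p_value`.
#' @export
#' @examples
#' tab <- matrix(c(99, 5, 54, 104, 12, 69, 18, 26, 22), 3, byrow = TRUE,
#'               dimnames = list(paste0("C", 1:3),
#'                               c("improved", "deteriorated", "unchanged")))
#' contingency_analysis(tab)
contingency_analysis <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2) {
    stop("need at least 2 rows and 2 columns", call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("zero marginal row or column", call. = FALSE)
  }
  ct <- suppressWarnings(chisq.test(counts, correct = FALSE))
  structure(list(observed = counts, expected = ct$expected,
                 statistic = unname(ct$statistic),
                 df = unname(ct$parameter),
                 residuals = ct$residuals,
                 p_value = unname(ct$p.value)),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("Pearson chi-square = %.2f, df = %d, p = %.3g\n",
              x$statistic, x$df, x$p_value))
  cat("standardized residuals:\n")
  print(round(x$residuals, 2))
  invisible(x)
}

#' Cell-level view of a contingency analysis
#'
#' @param x A `contingency_result`.
#' @param ... Unused.
#' @return A tibble with one row per cell: observed, expected, residual.
#' @export
tidy.contingency_result <- function(x, ...) {
  rn <- rownames(x$observed) %||% paste0("row", seq_len(nrow(x$observed)))
  cn <- colnames(x$observed) %||% paste0("col", seq_len(ncol(x$observed)))
  tibble::tibble(row = rep(rn, times = length(cn)),
                 column = rep(cn, each = length(rn)),
                 observed = as.vector(x$observed),
                 expected = as.vector(x$expected),
                 residual = as.vector(x$residuals))
}

#' One-way ANOVA with Bonferroni pairwise contrasts
#'
#' Classical equal-variance between/within decomposition (via
#' [stats::lm()]/[stats::anova()]), followed by all pairwise two-sample
#' pooled-variance t tests with Bonferroni-multiplied p-values and a
#' pooled-SD effect size per pair (see [pooled_sd_effect_size()]).
#'
#' @param data A data frame.
#' @param value Name of the numeric response column.
#' @param group Name of the grouping column.
#'
#' @return An `anova_result`: per-group summary tibble, `statistic` (F),
#'   `df1`, `df2`, `p_value`, and a `pairwise` tibble.
#' @export
oneway_anova_bonferroni <- function(data, value, group) {
  data <- tibble::as_tibble(data)
  y <- data[[value]]
  g <- factor(data[[group]])
  keep <- !is.na(y) & !is.na(g)
  y <- y[keep]
  g <- droplevels(g[keep])
  if (nlevels(g) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(g) < 2)) {
    stop("every group needs at least 2 observations", call. = FALSE)
  }
  fit <- lm(y ~ g)
  an <- anova(fit)
  groups <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(y = y, g = g), .data$g),
    n = dplyr::n(), mean = mean(.data$y), sd = sd(.data$y),
    .groups = "drop")
  names(groups)[1] <- "group"

  pairs <- utils::combn(levels(g), 2, simplify = FALSE)
  n_comp <- length(pairs)
  pairwise <- purrr::map_dfr(pairs, function(pr) {
    y1 <- y[g == pr[1]]
    y2 <- y[g == pr[2]]
    tt <- t.test(y1, y2, var.equal = TRUE)
    tibble::tibble(
      group1 = pr[1], group2 = pr[2],
      statistic = unname(tt$statistic), df = unname(tt$parameter),
      p_raw = tt$p.value, p_adjusted = min(1, tt$p.value * n_comp),
      d = pooled_sd_effect_size(mean(y1), sd(y1), length(y1),
                                mean(y2), sd(y2), length(y2)))
  })

  structure(list(groups = groups, statistic = an$`F value`[1],
                 df1 = an$Df[1], df2 = an$Df[2],
                 p_value = an$`Pr(>F)`[1], pairwise = pairwise),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.3g\n",
              x$df1, x$df2, x$statistic, x$p_value))
  print(as.data.frame(x$groups), digits = 4)
  cat("Bonferroni pairwise contrasts:\n")
  print(as.data.frame(x$pairwise), digits = 4)
  invisible(x)
}

#' Screen candidate predictors by Pearson correlation with an outcome
#'
#' @param data A data frame.
#' @param outcome Name of the outcome column.
#' @param predictors Character vector of predictor column names
#'   (defaults to every numeric column except the outcome).
#'
#' @return A tibble with one row per predictor: n, `r`, t `statistic`,
#'   two-sided `p_value`.
#' @export
screen_predictors <- function(data, outcome, predictors = NULL) {
  data <- tibble::as_tibble(data)
  if (is.null(predictors)) {
    num <- vapply(data, is.numeric, logical(1))
    predictors <- setdiff(names(data)[num], outcome)
  }
  y <- data[[outcome]]
  purrr::map_dfr(predictors, function(p) {
    x <- data[[p]]
    keep <- !is.na(x) & !is.na(y)
    if (sum(keep) < 3) stop("fewer than 3 complete pairs for ", p,
                            call. = FALSE)
    if (sd(x[keep]) == 0) stop("zero-variance predictor: ", p,
                               call. = FALSE)
    ct <- cor.test(x[keep], y[keep], method = "pearson")
    tibble::tibble(predictor = p, n = sum(keep),
                   r = unname(ct$estimate),
                   statistic = unname(ct$statistic),
                   p_value = ct$p.value)
  })
}

#' Hierarchical (block-wise) regression with single-shot exclusion
#'
#' Ordinary least squares with predictors entered in ordered blocks.
#' After a block enters, any predictor from that block whose
#' coefficient p-value exceeds `exclusion_alpha` is dropped before the
#' next block enters; its exclusion t and p are reported. Step
#' statistics (R-squared, delta R-squared, F-change) are computed on the
#' retained model at each step, so the retained models are nested and
#' R-squared is non-decreasing. Standardized betas are reported for the
#' final model. This is deliberate block-wise entry with one exclusion
#' pass, not a full forward/backward stepwise search.
#'
#' @param data A data frame with numeric outcome and predictor columns
#'   (code factors as dummy columns first).
#' @param outcome Name of the outcome column.
#' @param blocks Ordered (optionally named) list of character vectors of
#'   predictor names.
#' @param exclusion_alpha Exclusion threshold (default 0.05).
#'
#' @return A `regression_steps`: `steps` tibble (R2, delta_R2, F_change,
#'   dfs, p_change), `coefficients` tibble per step, `excluded` tibble
#'   (term, step, t, p), total R2 and the final [stats::lm()] fit.
#' @export
hierarchical_regression <- function(data, outcome, blocks,
                                    exclusion_alpha = 0.05) {
  data <- tibble::as_tibble(data)
  all_pred <- unique(unlist(blocks))
  stopifnot(all(c(outcome, all_pred) %in% names(data)))
  cc <- stats::complete.cases(data[c(outcome, all_pred)])
  if (any(!cc)) {
    message(sum(!cc), " incomplete row(s) dropped from the regression")
  }
  data <- data[cc, , drop = FALSE]
  n <- nrow(data)
  if (n <= length(all_pred) + 1) {
    stop("more cumulative predictors than observations", call. = FALSE)
  }
  block_names <- names(blocks) %||% paste0("step", seq_along(blocks))
  if (is.null(names(blocks))) names(blocks) <- block_names

  fit_with <- function(preds) {
    if (length(preds) == 0) {
      lm(as.formula(paste(outcome, "~ 1")), data = data)
    } else {
      lm(as.formula(paste(outcome, "~",
                          paste(sprintf("`%s`", preds), collapse = " + "))),
         data = data)
    }
  }
  r2 <- function(fit) summary(fit)$r.squared

  retained <- character(0)
  prev_fit <- fit_with(retained)
  prev_r2 <- 0
  steps <- tibble::tibble()
  coefs <- tibble::tibble()
  excluded <- tibble::tibble()

  for (i in seq_along(blocks)) {
    new_terms <- setdiff(blocks[[i]], retained)
    cand_fit <- fit_with(c(retained, new_terms))
    if (any(is.na(coef(cand_fit)))) {
      stop("rank-deficient design at block ", block_names[i],
           call. = FALSE)
    }
    cs <- summary(cand_fit)$coefficients
    p_new <- cs[new_terms, "Pr(>|t|)"]
    drop_terms <- new_terms[is.na(p_new) | p_new > exclusion_alpha]
    if (length(drop_terms) > 0) {
      excluded <- dplyr::bind_rows(excluded, tibble::tibble(
        term = drop_terms, step = block_names[i],
        statistic = cs[drop_terms, "t value"],
        p_value = cs[drop_terms, "Pr(>|t|)"]))
    }
    keep_terms <- setdiff(new_terms, drop_terms)
    step_fit <- fit_with(c(retained, keep_terms))
    step_r2 <- r2(step_fit)
    if (length(keep_terms) > 0) {
      cmp <- anova(prev_fit, step_fit)
      f_change <- cmp$F[2]
      df1 <- cmp$Df[2]
      df2 <- cmp$Res.Df[2]
      p_change <- cmp$`Pr(>F)`[2]
    } else {
      f_change <- NA_real_; df1 <- 0L; df2 <- NA_integer_
      p_change <- NA_real_
    }
    steps <- dplyr::bind_rows(steps, tibble::tibble(
      step = block_names[i], R2 = step_r2, delta_R2 = step_r2 - prev_r2,
      F_change = f_change, df1 = df1, df2 = df2, p_change = p_change))
    sc <- summary(step_fit)$coefficients
    terms_now <- setdiff(rownames(sc), "(Intercept)")
    terms_clean <- gsub("`", "", terms_now)
    sd_y <- sd(data[[outcome]])
    coefs <- dplyr::bind_rows(coefs, tibble::tibble(
      step = block_names[i], term = terms_clean,
      estimate = sc[terms_now, "Estimate"],
      std_beta = sc[terms_now, "Estimate"] *
        vapply(terms_clean, function(tm) sd(data[[tm]]), numeric(1)) / sd_y,
      statistic = sc[terms_now, "t value"],
      p_value = sc[terms_now, "Pr(>|t|)"]))
    retained <- c(retained, keep_terms)
    prev_fit <- step_fit
    prev_r2 <- step_r2
  }

  structure(list(steps = steps, coefficients = coefs, excluded = excluded,
                 total_R2 = prev_r2, n = n, model = prev_fit),
            class = "regression_steps")
}

#' @export
print.regression_steps <- function(x, ...) {
  cat("Hierarchical regression (n =", x$n, "), total R2 =",
      round(x$total_R2, 3), "\n")
  print(as.data.frame(x$steps), digits = 4)
  if (nrow(x$excluded) > 0) {
    cat("excluded predictors:\n")
    print(as.data.frame(x$excluded), digits = 3)
  }
  invisible(x)
}

#' Final-step coefficients of a hierarchical regression
#'
#' @param x A `regression_steps`.
#' @param ... Unused.
#' @return A tibble of final-model terms with standardized betas.
#' @export
tidy.regression_steps <- function(x, ...) {
  last_step <- x$steps$step[nrow(x$steps)]
  x$coefficients[x$coefficients$step == last_step, ]
}

#' Multinomial logistic prediction of class membership
#'
#' Maximum-likelihood multinomial logit (via [nnet::multinom()]) of a
#' categorical class label on intake characteristics. Reports, per
#' non-reference contrast and term: coefficient B, SE, Wald z and
#' p-value, odds ratio `exp(B)` and 95% Wald CI `exp(B +/- 1.96 SE)`;
#' plus the model likelihood-ratio chi-square against the intercept-only
#' model and Cox & Snell / Nagelkerke pseudo-R-squared.
#'
#' @param data A data frame.
#' @param class Name of the class column (coerced to factor).
#' @param predictors Character vector of predictor column names; empty
#'   for an intercept-only model.
#' @param reference Reference class level (default: first level).
#'
#' @return A `multinomial_fit` with a `coefficients` tibble, model
#'   `chisq`/`df`/`p_value`, `cox_snell`, `nagelkerke`, `reference`, and
#'   the underlying `model`.
#' @export
multinomial_class_prediction <- function(data, class, predictors,
                                         reference = NULL) {
  data <- tibble::as_tibble(data)
  g <- factor(data[[class]])
  if (nlevels(g) < 2) stop("need at least 2 classes", call. = FALSE)
  if (any(table(g) == 0)) stop("empty class level", call. = FALSE)
  if (!is.null(reference)) g <- stats::relevel(g, ref = as.character(reference))
  df <- data[, predictors, drop = FALSE]
  df$.class <- g
  cc <- stats::complete.cases(df)
  df <- df[cc, , drop = FALSE]
  n <- nrow(df)

  rhs <- if (length(predictors) == 0) "1" else
    paste(sprintf("`%s`", predictors), collapse = " + ")
  fit <- nnet::multinom(as.formula(paste(".class ~", rhs)), data = df,
                        trace = FALSE, maxit = 1000)
  fit0 <- nnet::multinom(.class ~ 1, data = df, trace = FALSE)
  ll1 <- as.numeric(logLik(fit))
  ll0 <- as.numeric(logLik(fit0))
  chisq <- 2 * (ll1 - ll0)
  df_chisq <- attr(logLik(fit), "df") - attr(logLik(fit0), "df")
  cox_snell <- 1 - exp((2 / n) * (ll0 - ll1))
  nagelkerke <- cox_snell / (1 - exp((2 / n) * ll0))

  co <- summary(fit)$coefficients
  se <- summary(fit)$standard.errors
  if (is.null(dim(co))) {                      # 2-class case: vectors
    co <- matrix(co, nrow = 1,
                 dimnames = list(levels(g)[2], names(co) %||% "(Intercept)"))
    se <- matrix(se, nrow = 1, dimnames = dimnames(co))
  }
  z <- co / se
  coef_tab <- tibble::tibble(
    contrast = paste(levels(g)[1], "vs",
                     rep(rownames(co), times = ncol(co))),
    class = rep(rownames(co), times = ncol(co)),
    term = rep(gsub("`", "", colnames(co)), each = nrow(co)),
    estimate = as.vector(co), std_error = as.vector(se),
    statistic = as.vector(z),
    p_value = as.vector(2 * pnorm(-abs(z))),
    odds_ratio = as.vector(exp(co)),
    ci_lower = as.vector(exp(co - 1.96 * se)),
    ci_upper = as.vector(exp(co + 1.96 * se)))
  slope_cols <- colnames(co) != "(Intercept)"
  separated <- any(abs(co[, slope_cols]) > 15 | se[, slope_cols] > 50)
  if (separated) {
    warning("possible perfect separation: diverging coefficient(s)",
            call. = FALSE)
  }

  structure(list(coefficients = coef_tab, chisq = chisq, df = df_chisq,
                 p_value = pchisq(chisq, df_chisq, lower.tail = FALSE),
                 loglik = ll1, loglik_null = ll0,
                 cox_snell = cox_snell, nagelkerke = nagelkerke,
                 reference = levels(g)[1], n = n, separated = separated,
                 model = fit),
            class = "multinomial_fit")
}

#' @export
print.multinomial_fit <- function(x, ...) {
  cat(sprintf("Multinomial logit (reference: %s), n = %d\n",
              x$reference, x$n))
  cat(sprintf("model chi-square(%d) = %.2f, p = %.3g; Cox & Snell R2 = %.3f, Nagelkerke R2 = %.3f\n",
              x$df, x$chisq, x$p_value, x$cox_snell, x$nagelkerke))
  print(as.data.frame(x$coefficients), digits = 3)
  invisible(x)
}

#' Coefficient table of a multinomial class-prediction fit
#'
#' @param x A `multinomial_fit`.
#' @param ... Unused.
#' @return The coefficients tibble (one row per contrast x term).
#' @export
tidy.multinomial_fit <- function(x, ...) x$coefficients

#' One-row summary of a multinomial class-prediction fit
#'
#' @param x A `multinomial_fit`.
#' @param ... Unused.
#' @return A one-row tibble with chi-square and pseudo-R-squared values.
#' @export
glance.multinomial_fit <- function(x, ...) {
  tibble::tibble(n = x$n, chisq = x$chisq, df = x$df,
                 p_value = x$p_value, cox_snell = x$cox_snell,
                 nagelkerke = x$nagelkerke, loglik = x$loglik,
                 loglik_null = x$loglik_null)
}
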