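#' Configure an end-to-end analysis run
#'
#' Exactly one data source is used: a generator configuration (synthetic
#' run) or an input path (observed data). All randomness downstream
#' flows from `seed` via named substreams (generator, fit starts,
#' bootstrap), recorded in the report's provenance block.
#'
#' @param generator A `sim_config` (see [default_study_config()]), or
#'   NULL when reading from files.
#' @param input_path,covariates_path Paths for [read_long_dataset()], or
#'   NULL when simulating.
#' @param grid Occasion grid for file input (default
#'   [default_occasion_grid()]); the early-change model always uses the
#'   first four occasions.
#' @param K_max Largest class count to fit (default 4).
#' @param B Bootstrap replicates for the BLRT (default 99).
#' @param n_starts EM starts per fit (default 20).
#' @param rci_r Scale reliability for the reliable change index
#'   (default .86, the PHQ-9 test-retest value used in this design).
#' @param rci_sd Baseline SD for the RCI; NULL (default) estimates it
#'   from the screening scores.
#' @param alpha BLRT significance level (default .05).
#' @param seed Master seed.
#'
#' @return A `run_config` list.
#' @export
run_config <- function(generator = default_study_config(),
                       input_path = NULL, covariates_path = NULL,
                       grid = default_occasion_grid(), K_max = 4,
                       B = 99, n_starts = 20, rci_r = 0.86,
                       rci_sd = NULL, alpha = 0.05, seed = 1) {
  if (!is.null(generator) && !is.null(input_path)) {
    stop("supply either `generator` or `input_path`, not both",
         call. = FALSE)
  }
  if (is.null(generator) && is.null(input_path)) {
    stop("one of `generator` or `input_path` is required", call. = FALSE)
  }
  structure(list(generator = generator, input_path = input_path,
                 covariates_path = covariates_path, grid = grid,
                 K_max = as.integer(K_max), B = as.integer(B),
                 n_starts = as.integer(n_starts), rci_r = rci_r,
                 rci_sd = rci_sd, alpha = alpha, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full early-change analysis
#'
#' Stages, in order: obtain data (simulate or read), fit the piecewise
#' growth mixture for K = 1..K_max on the first four occasions only,
#' choose K by the two-fold BIC + BLRT rule, assign subjects to modal
#' classes, classify pre-post reliable change, and compute the
#' association statistics (contingency analysis of class x change,
#' ANOVAs for outcome and adherence, predictor-screening correlations,
#' hierarchical regressions, multinomial class prediction). With a
#' single-class solution the class-contrast statistics are skipped with
#' a notice.
#'
#' @param config A [run_config()].
#'
#' @return An `ec_report` bundle: `enumeration` (one row per K with
#'   BLRT p where tested), `selection`, `fit`, `classes`,
#'   `trajectories`, `change` (per-subject change classification),
#'   `outcome_table`, `anovas`, `contingency`, `correlations`,
#'   `regressions`, `multinomial`, `truth` (synthetic runs only) and a
#'   `provenance` block.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  seeds <- withr::with_seed(config$seed,
    setNames(sample.int(.Machine$integer.max - 1, 3),
             c("generator", "fits", "blrt")))

  truth <- NULL
  if (!is.null(config$generator)) {
    sim <- simulate_study(config$generator, seed = seeds[["generator"]])
    data <- apply_inclusion_rule(sim$data)
    truth <- sim$truth[sim$truth$subject_id %in% data$subject_ids, ]
  } else {
    data <- read_long_dataset(config$input_path, config$grid,
                              covariates_path = config$covariates_path)
  }
  grid <- data$grid
  early_grid <- grid_head(grid, 4L)
  lambda_early <- build_loading_matrix(early_grid)
  early_data <- restrict_occasions(data, early_grid)

  if (config$K_max == 1L) {
    fit1 <- em_fit(early_data, pgmm_spec(1, lambda_early),
                   n_starts = config$n_starts, seed = seeds[["fits"]])
    seq_fit <- structure(list(fits = list(fit1), K_max = 1L,
                              failed = FALSE,
                              scores = .scores_for_loading(early_data,
                                                           lambda_early),
                              loading = lambda_early,
                              seed = seeds[["fits"]],
                              n_starts = config$n_starts,
                              max_iter = 500, tol = 1e-7),
                         class = "pgmm_sequence")
    sel <- structure(list(K = 1L, candidate = 1L,
                          bic_path = tibble::tibble(K = 1L,
                                                    bic = fit1$bic),
                          blrt_tests = tibble::tibble(
                            K = integer(), statistic = numeric(),
                            p_value = numeric(), significant = logical()),
                          alpha = config$alpha,
                          reason = "K_max = 1: single-class model fitted without enumeration"),
                     class = "ec_selection")
  } else {
    seq_fit <- fit_sequence(early_data, lambda_early, config$K_max,
                            seed = seeds[["fits"]],
                            n_starts = config$n_starts)
    sel <- select_by_bic_blrt(seq_fit, alpha = config$alpha,
                              B = config$B, seed = seeds[["blrt"]])
  }
  fit <- seq_fit$fits[[sel$K]]
  classes <- classify_subjects(fit)

  enumeration <- dplyr::left_join(
    tidy(seq_fit),
    dplyr::select(sel$blrt_tests, "K", blrt_p = "p_value"),
    by = "K")

  screening <- data$scores[, grid$occasion[1]]
  post <- if (!is.null(data$covariates) &&
              "post_phq9" %in% names(data$covariates)) {
    data$covariates$post_phq9
  } else if ("post" %in% colnames(data$scores)) {
    data$scores[, "post"]
  } else {
    rep(NA_real_, nrow(data$scores))
  }
  df <- tibble::tibble(subject_id = data$subject_ids,
                       phq9_screening = screening,
                       post_phq9 = post,
                       class = factor(paste0("C", classes),
                                      levels = paste0("C", seq_len(sel$K))))
  if (!is.null(data$covariates)) {
    df <- dplyr::left_join(df,
                           dplyr::select(data$covariates, -dplyr::any_of("post_phq9")),
                           by = "subject_id")
  }

  rci <- compute_rci(config$rci_r,
                     config$rci_sd %||% sd(screening, na.rm = TRUE))
  change <- classify_change(df, rci, pre = "phq9_screening",
                            post = "post_phq9")

  assoc <- .pipeline_associations(df, change, sel$K)

  provenance <- list(master_seed = config$seed,
                     substream_seeds = as.list(seeds),
                     package_version =
                       as.character(utils::packageVersion("earlychange")),
                     config_hash = rlang::hash(config),
                     n_subjects = nrow(data$scores),
                     n_excluded = attr(data, "n_excluded"))

  structure(c(list(enumeration = enumeration, selection = sel,
                   fit = fit, classes = classes,
                   trajectories = tidy(fit), rci = rci, change = change,
                   data = data, truth = truth, provenance = provenance),
              assoc),
            class = "ec_report")
}

# Class-contrast statistics; NULL entries (with a notice) when K = 1 or
# required columns are absent.
.pipeline_associations <- function(df, change, K) {
  out <- list(contingency = NULL, outcome_table = NULL, anovas = NULL,
              correlations = NULL, regressions = NULL, multinomial = NULL)
  if (K < 2) {
    message("single-class solution: class-contrast statistics skipped")
    return(out)
  }

  tab <- table(change$class, change$category)
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  out$contingency <- tryCatch(contingency_analysis(tab),
                              error = function(e) {
                                message("contingency analysis skipped: ",
                                        conditionMessage(e))
                                NULL
                              })

  es <- effect_size_report(change, class = "class",
                           pre = "phq9_screening", post = "post_phq9")
  out$outcome_table <- es

  adherence_vars <- intersect(c("usage_hours", "n_modules",
                                "n_assessments"), names(df))
  change$prepost_change <- change$change
  anova_input <- list(prepost_change = change)
  for (v in adherence_vars) anova_input[[v]] <- df
  out$anovas <- purrr::imap(anova_input, function(d, v) {
    tryCatch(oneway_anova_bonferroni(d, v, "class"),
             error = function(e) NULL)
  })

  screen_vars <- intersect(c("fep2", "sf12_physical", "sf12_mental",
                             "apoi"), names(df))
  if (length(screen_vars) > 0 && !all(is.na(df$post_phq9))) {
    out$correlations <- screen_predictors(df, "post_phq9", screen_vars)
  }

  reg_base <- intersect(c("phq9_screening", "hrsd24", "apoi",
                          "email_support"), names(df))
  if (length(reg_base) >= 1) {
    dfr <- df
    for (k in 2:K) dfr[[paste0("C", k)]] <- as.integer(df$class ==
                                                         paste0("C", k))
    dummies <- paste0("C", 2:K)
    blocks <- list(intake = reg_base, class = dummies)
    outcomes <- intersect(c("post_phq9", "n_assessments", "n_modules"),
                          names(dfr))
    out$regressions <- purrr::map(setNames(outcomes, outcomes),
      function(yv) {
        tryCatch(hierarchical_regression(dfr, yv, blocks),
                 error = function(e) {
                   message("regression on ", yv, " skipped: ",
                           conditionMessage(e))
                   NULL
                 })
      })
  }

  mn_vars <- intersect(c("phq9_screening", "hrsd24", "fep2",
                         "sf12_physical", "sf12_mental", "email_support"),
                       names(df))
  if (length(mn_vars) >= 1) {
    refs <- paste0("C", seq_len(max(K - 1, 1)))
    out$multinomial <- purrr::map(setNames(refs, refs), function(r) {
      tryCatch(multinomial_class_prediction(df, "class", mn_vars,
                                            reference = r),
               error = function(e) NULL)
    })
  }
  out
}

#' @export
print.ec_report <- function(x, ...) {
  cat("== Early-change analysis report ==\n")
  cat("Selected K =", x$selection$K, "|", x$selection$reason, "\n\n")
  cat("Class enumeration:\n")
  print(as.data.frame(x$enumeration), digits = 6)
  cat("\nClass trajectories (growth-factor means):\n")
  print(as.data.frame(x$trajectories), digits = 3)
  cat("\nReliable change threshold:",
      sprintf("%.2f", x$rci$threshold), "\n")
  if (!is.null(x$contingency)) {
    cat("\nClass x reliable-change:\n")
    print(x$contingency)
  }
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Emits the report as structured JSON (`report.json`) and a
#' human-readable markdown summary (`report.md`), plus the per-subject
#' posterior table and change classification as delimited text.
#'
#' @param report An `ec_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "ec_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  json <- list(
    selection = list(K = report$selection$K,
                     reason = report$selection$reason,
                     bic_path = report$selection$bic_path,
                     blrt_tests = report$selection$blrt_tests),
    enumeration = report$enumeration,
    trajectories = report$trajectories,
    rci = report$rci[c("r", "sd", "z", "threshold")],
    fit = glance(report$fit),
    provenance = report$provenance)
  if (!is.null(report$contingency)) {
    json$contingency <- list(statistic = report$contingency$statistic,
                             df = report$contingency$df,
                             p_value = report$contingency$p_value,
                             cells = tidy(report$contingency))
  }
  if (!is.null(report$correlations)) json$correlations <- report$correlations
  if (!is.null(report$regressions)) {
    json$regressions <- purrr::map(report$regressions, function(r) {
      if (is.null(r)) NULL else list(steps = r$steps,
                                     excluded = r$excluded,
                                     total_R2 = r$total_R2)
    })
  }
  if (!is.null(report$multinomial)) {
    json$multinomial <- purrr::map(report$multinomial, function(m) {
      if (is.null(m)) NULL else list(coefficients = m$coefficients,
                                     chisq = m$chisq, df = m$df,
                                     p_value = m$p_value,
                                     cox_snell = m$cox_snell,
                                     nagelkerke = m$nagelkerke)
    })
  }
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")

  md <- c("# Early-change analysis report", "",
          paste0("Selected K = ", report$selection$K, " (",
                 report$selection$reason, ")"), "",
          "## Class enumeration", .md_table(report$enumeration), "",
          "## Class trajectories", .md_table(report$trajectories), "",
          paste0("Reliable change threshold: ",
                 sprintf("%.2f", report$rci$threshold)))
  if (!is.null(report$contingency)) {
    md <- c(md, "", "## Class x reliable change",
            sprintf("Pearson chi-square = %.2f, df = %d, p = %.3g",
                    report$contingency$statistic, report$contingency$df,
                    report$contingency$p_value),
            .md_table(tidy(report$contingency)))
  }
  writeLines(md, file.path(dir, "report.md"))

  write_posterior_table(report$fit, file.path(dir, "posterior.tsv"))
  readr::write_delim(report$change[c("subject_id", "phq9_screening",
                                     "post_phq9", "change", "category")],
                     file.path(dir, "change_classification.tsv"),
                     delim = "\t")
  write_fit_json(report$fit, file.path(dir, "fit.json"))
  invisible(dir)
}

.md_table <- function(df) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 6))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "),
                                          " |"))
  c(header, sep, rows)
}
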