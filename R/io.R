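#' Read a long-format score file (plus optional covariates)
#'
#' Reads delimited text with columns `subject_id`, `occasion`, `score`,
#' validates it against the occasion grid (unknown occasion labels and
#' duplicate subject-occasion rows are rejected, out-of-range scores are
#' reported with the offending subject/occasion), and applies the
#' inclusion rule with a logged exclusion count.
#'
#' @param path Path to the delimited score file.
#' @param grid An [occasion_grid()].
#' @param covariates_path Optional path to a per-subject covariate file
#'   (must contain `subject_id`).
#' @param delim Field delimiter (default comma).
#' @param score_range,apply_inclusion Passed to [longitudinal_dataset()].
#'
#' @return An `ec_data` object.
#' @export
read_long_dataset <- function(path, grid, covariates_path = NULL,
                              delim = ",", score_range = c(0, 27),
                              apply_inclusion = TRUE) {
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  req <- c("subject_id", "occasion", "score")
  if (!all(req %in% names(raw))) {
    stop("`", path, "` must have columns subject_id, occasion, score",
         call. = FALSE)
  }
  if (!is.numeric(raw$score)) {
    bad <- which(!is.na(raw$score) &
                   is.na(suppressWarnings(as.numeric(raw$score))))
    if (length(bad) > 0) {
      stop("non-numeric score at data row ", bad[1], " of ", path,
           call. = FALSE)
    }
    raw$score <- as.numeric(raw$score)
  }
  covariates <- if (!is.null(covariates_path)) {
    readr::read_delim(covariates_path, delim = delim,
                      show_col_types = FALSE, progress = FALSE)
  }
  longitudinal_dataset(raw, grid, covariates = covariates,
                       score_range = score_range,
                       apply_inclusion = apply_inclusion)
}

#' Write a dataset as long-format scores plus covariates
#'
#' Inverse of [read_long_dataset()]: observed scores as delimited long
#' text and, when present, the covariate table alongside.
#'
#' @param data An `ec_data`.
#' @param path Output path for the score file.
#' @param covariates_path Optional output path for covariates.
#' @param delim Field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_long_dataset <- function(data, path, covariates_path = NULL,
                               delim = ",") {
  stopifnot(inherits(data, "ec_data"))
  readr::write_delim(scores_long(data), path, delim = delim)
  if (!is.null(covariates_path) && !is.null(data$covariates)) {
    readr::write_delim(data$covariates, covariates_path, delim = delim)
  }
  invisible(path)
}

#' Write a fitted mixture summary as JSON
#'
#' Weights, class mean growth factors, variances, log-likelihood,
#' information criteria, entropy and the convergence record.
#'
#' @param fit A `pgmm_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "pgmm_fit"))
  out <- list(K = fit$K, n = fit$n,
              weights = unname(fit$pi),
              means = lapply(seq_len(fit$K),
                             function(k) as.list(fit$mu[, k])),
              psi = fit$psi, theta = fit$theta,
              loglik = fit$loglik, n_parameters = fit$p,
              bic = fit$bic, sabic = fit$sabic, aic = fit$aic,
              entropy = fit$entropy,
              convergence = fit$convergence[c("iterations", "converged",
                                              "best_start", "seed")])
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a per-subject posterior/assignment table
#'
#' @param fit A `pgmm_fit`.
#' @param path Output path (delimited text).
#' @param delim Field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_posterior_table <- function(fit, path, delim = "\t") {
  readr::write_delim(posterior_table(fit), path, delim = delim)
  invisible(path)
}
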