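#' Assemble a longitudinal symptom dataset
#'
#' Converts long-format scores (one row per subject x occasion) and an
#' optional per-subject covariate table into the container used by the
#' model-fitting functions: a subject x occasion score matrix with an
#' explicit missing mask (NA), aligned covariates, and the occasion grid.
#'
#' The study's inclusion rule is applied by default: a subject is retained
#' only if the screening score is observed and at least one score at week
#' 2 or week 4 is observed. Excluded subjects are dropped with a message
#' and their count is kept in the `n_excluded` attribute.
#'
#' @param scores A data frame with columns `subject_id`, `occasion`,
#'   `score` (observed values only, or NA rows).
#' @param grid An [occasion_grid()]; every `occasion` value must be one of
#'   its labels.
#' @param covariates Optional data frame with a `subject_id` column and
#'   per-subject numeric/binary columns.
#' @param score_range Permitted score range, default `c(0, 27)` (PHQ-9).
#'   Use `NULL` to skip range validation (e.g. unrounded simulated data).
#' @param apply_inclusion Apply the screening + week-2/4 inclusion rule.
#'
#' @return A list of class `ec_data` with elements `scores` (matrix,
#'   subjects x occasions, NA = missing), `grid`, `covariates`,
#'   `subject_ids`.
#' @export
longitudinal_dataset <- function(scores, grid, covariates = NULL,
                                 score_range = c(0, 27),
                                 apply_inclusion = TRUE) {
  stopifnot(inherits(grid, "occasion_grid"))
  req <- c("subject_id", "occasion", "score")
  if (!all(req %in% names(scores))) {
    stop("`scores` needs columns subject_id, occasion, score", call. = FALSE)
  }
  scores <- tibble::as_tibble(scores)
  bad_occ <- setdiff(unique(scores$occasion), grid$occasion)
  if (length(bad_occ) > 0) {
    stop("unknown occasion label(s): ", paste(bad_occ, collapse = ", "),
         call. = FALSE)
  }
  dup <- duplicated(scores[c("subject_id", "occasion")])
  if (any(dup)) {
    stop("duplicate (subject, occasion) rows, e.g. subject ",
         scores$subject_id[dup][1], " at ", scores$occasion[dup][1],
         call. = FALSE)
  }
  obs <- scores[!is.na(scores$score), ]
  if (!is.null(score_range)) {
    out_of_range <- obs$score < score_range[1] | obs$score > score_range[2]
    if (any(out_of_range)) {
      i <- which(out_of_range)[1]
      stop("score out of range [", score_range[1], ", ", score_range[2],
           "] for subject ", obs$subject_id[i], " at ", obs$occasion[i],
           " (value ", obs$score[i], ")", call. = FALSE)
    }
  }

  ids <- unique(scores$subject_id)
  mat <- matrix(NA_real_, nrow = length(ids), ncol = nrow(grid),
                dimnames = list(as.character(ids), grid$occasion))
  mat[cbind(match(obs$subject_id, ids), match(obs$occasion, grid$occasion))] <-
    obs$score

  if (!is.null(covariates)) {
    covariates <- tibble::as_tibble(covariates)
    if (!"subject_id" %in% names(covariates)) {
      stop("`covariates` needs a subject_id column", call. = FALSE)
    }
    covariates <- covariates[match(ids, covariates$subject_id), ]
    covariates$subject_id <- ids
  }

  x <- structure(list(scores = mat, grid = grid, covariates = covariates,
                      subject_ids = ids),
                 n_excluded = 0L, class = "ec_data")
  if (apply_inclusion) x <- apply_inclusion_rule(x) else x
}

#' Apply the early-assessment inclusion rule
#'
#' Retains subjects with an observed screening score and at least one
#' observed score at week 2 or week 4 (occasions `wk2`/`wk4` where
#' present in the grid). Mirrors the trial's analyzable-sample filter.
#'
#' @param data An `ec_data` object.
#' @return The filtered `ec_data`; attribute `n_excluded` counts drops.
#' @export
apply_inclusion_rule <- function(data) {
  stopifnot(inherits(data, "ec_data"))
  labs <- data$grid$occasion
  first <- labs[1]
  early <- intersect(c("wk2", "wk4"), labs)
  keep <- !is.na(data$scores[, first])
  if (length(early) > 0) {
    keep <- keep & rowSums(!is.na(data$scores[, early, drop = FALSE])) > 0
  }
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    message(n_drop, " subject(s) excluded by the inclusion rule ",
            "(screening plus at least one week-2/4 assessment required)")
  }
  out <- structure(list(scores = data$scores[keep, , drop = FALSE],
                        grid = data$grid,
                        covariates =
                          if (is.null(data$covariates)) NULL
                          else data$covariates[keep, , drop = FALSE],
                        subject_ids = data$subject_ids[keep]),
                   n_excluded = attr(data, "n_excluded") + n_drop,
                   class = "ec_data")
  out
}

#' Restrict a dataset to a sub-grid of occasions
#'
#' @param data An `ec_data` object.
#' @param grid An [occasion_grid()] whose labels are a subset of the
#'   dataset's occasions.
#' @return An `ec_data` on the reduced grid (no re-filtering).
#' @export
restrict_occasions <- function(data, grid) {
  stopifnot(inherits(data, "ec_data"), inherits(grid, "occasion_grid"))
  missing_labs <- setdiff(grid$occasion, colnames(data$scores))
  if (length(missing_labs) > 0) {
    stop("dataset lacks occasion(s): ", paste(missing_labs, collapse = ", "),
         call. = FALSE)
  }
  structure(list(scores = data$scores[, grid$occasion, drop = FALSE],
                 grid = grid, covariates = data$covariates,
                 subject_ids = data$subject_ids),
            n_excluded = attr(data, "n_excluded"), class = "ec_data")
}

#' @export
print.ec_data <- function(x, ...) {
  cat("<ec_data> ", nrow(x$scores), " subjects x ", ncol(x$scores),
      " occasions (", sum(is.na(x$scores)), " missing cells)\n", sep = "")
  cat("occasions:", paste(x$grid$occasion, collapse = ", "), "\n")
  if (!is.null(x$covariates)) {
    cat("covariates:", paste(setdiff(names(x$covariates), "subject_id"),
                             collapse = ", "), "\n")
  }
  invisible(x)
}

#' Long-format view of the score matrix
#'
#' @param data An `ec_data` object.
#' @param keep_missing Keep rows for unobserved cells (score NA).
#' @return A tibble with columns subject_id, occasion, score.
#' @export
scores_long <- function(data, keep_missing = FALSE) {
  stopifnot(inherits(data, "ec_data"))
  out <- tibble::tibble(
    subject_id = rep(data$subject_ids, times = ncol(data$scores)),
    occasion = rep(colnames(data$scores), each = nrow(data$scores)),
    score = as.vector(data$scores))
  out <- dplyr::arrange(out, match(.data$subject_id, data$subject_ids),
                        match(.data$occasion, data$grid$occasion))
  if (!keep_missing) out <- out[!is.na(out$score), ]
  out
}
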