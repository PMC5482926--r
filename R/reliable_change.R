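#' Jacobson-Truax reliable change index
#'
#' Threshold for a pre-post difference large enough not to be
#' attributable to measurement error:
#' `threshold = z * sqrt(2) * sd * sqrt(1 - r)`, where `r` is the scale
#' reliability and `sd` the baseline standard deviation. With the PHQ-9
#' values reported for this design (r = .86, SD = 2.37, z = 1.96) the
#' threshold is 2.46 points.
#'
#' @param r Reliability, in (0, 1].
#' @param sd Baseline standard deviation, `> 0`.
#' @param z Normal multiplier (default 1.96, two-sided 95%).
#'
#' @return An `rci_result` list: `r`, `sd`, `z`, `threshold`.
#' @export
#' @examples
#' compute_rci(r = 0.86, sd = 2.37)
compute_rci <- function(r, sd, z = 1.96) {
  if (!is.numeric(r) || r <= 0 || r > 1) {
    stop("`r` must be in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(sd) || sd <= 0) stop("`sd` must be positive",
                                       call. = FALSE)
  if (!is.numeric(z) || z <= 0) stop("`z` must be positive", call. = FALSE)
  structure(list(r = r, sd = sd, z = z,
                 threshold = z * sqrt(2) * sd * sqrt(1 - r)),
            class = "rci_result")
}

#' @export
print.rci_result <- function(x, ...) {
  cat(sprintf("Reliable change threshold: %.2f (r = %.2f, SD = %.2f, z = %.2f)\n",
              x$threshold, x$r, x$sd, x$z))
  invisible(x)
}

#' Classify pre-post change against a reliable change threshold
#'
#' A subject is `improved` when `pre - post` strictly exceeds the
#' threshold, `deteriorated` when `post - pre` strictly exceeds it, and
#' `unchanged` otherwise (a change exactly at the threshold is
#' unchanged). Rows with a missing pre or post score are excluded with a
#' message (completer analysis).
#'
#' @param data A data frame holding the pre and post scores.
#' @param rci An [compute_rci()] result (or a bare numeric threshold).
#' @param pre,post Names of the pre and post score columns.
#'
#' @return A tibble with the scores used, the change `pre - post`, and
#'   `category` (factor improved/unchanged/deteriorated); excluded-row
#'   count in attribute `n_excluded`.
#' @export
classify_change <- function(data, rci, pre = "pre", post = "post") {
  threshold <- if (inherits(rci, "rci_result")) rci$threshold
               else as.numeric(rci)
  stopifnot(threshold >= 0)
  data <- tibble::as_tibble(data)
  if (!all(c(pre, post) %in% names(data))) {
    stop("columns `", pre, "` and `", post, "` not found", call. = FALSE)
  }
  pre_v <- data[[pre]]
  post_v <- data[[post]]
  keep <- !is.na(pre_v) & !is.na(post_v)
  if (any(!keep)) {
    message(sum(!keep), " subject(s) excluded from change classification ",
            "(missing pre or post score)")
  }
  out <- data[keep, , drop = FALSE]
  change <- pre_v[keep] - post_v[keep]
  out$change <- change
  out$category <- factor(
    dplyr::case_when(change > threshold ~ "improved",
                     -change > threshold ~ "deteriorated",
                     TRUE ~ "unchanged"),
    levels = c("improved", "deteriorated", "unchanged"))
  attr(out, "n_excluded") <- sum(!keep)
  attr(out, "threshold") <- threshold
  out
}

#' Within-group pre-post effect size
#'
#' `d = mean(pre - post) / sd_baseline`; the convention divides by the
#' standard deviation of the baseline (screening) score, so improvement
#' yields a positive d.
#'
#' @param pre,post Paired numeric vectors (NA pairs dropped).
#' @param sd_baseline Baseline SD; defaults to `sd(pre)`.
#' @return The effect size d (scalar).
#' @export
within_group_effect_size <- function(pre, post, sd_baseline = NULL) {
  keep <- !is.na(pre) & !is.na(post)
  pre <- pre[keep]
  post <- post[keep]
  if (length(pre) == 0) stop("no complete pre/post pairs", call. = FALSE)
  if (is.null(sd_baseline)) sd_baseline <- sd(pre)
  if (!is.finite(sd_baseline) || sd_baseline <= 0) {
    stop("`sd_baseline` must be positive", call. = FALSE)
  }
  mean(pre - post) / sd_baseline
}

#' Between-group effect size with pooled standard deviation
#'
#' `d = (m1 - m2) / sd_pooled`, with the (n-1)-weighted pooled SD
#' `sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))`.
#'
#' @param m1,s1,n1 Mean, SD, size of group 1.
#' @param m2,s2,n2 Mean, SD, size of group 2.
#' @return The effect size d (scalar).
#' @export
#' @examples
#' pooled_sd_effect_size(9.84, 3.90, 158, 8.64, 4.52, 185)
pooled_sd_effect_size <- function(m1, s1, n1, m2, s2, n2) {
  if (n1 < 2 || n2 < 2) stop("both groups need n >= 2", call. = FALSE)
  if (s1 < 0 || s2 < 0 || (s1 == 0 && s2 == 0)) {
    stop("group SDs must be nonnegative and not both zero", call. = FALSE)
  }
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  (m1 - m2) / sp
}

#' Per-class and pairwise pre-post effect sizes
#'
#' Within-group d per class (each divided by that class's screening SD)
#' and overall, plus pairwise between-group d of the change scores with
#' pooled SDs.
#'
#' @param data Data frame with pre/post scores and a class column.
#' @param class Name of the class column.
#' @param pre,post Names of the score columns.
#' @return A list with tibbles `within` and `between`.
#' @export
effect_size_report <- function(data, class = "class", pre = "pre",
                               post = "post") {
  data <- tibble::as_tibble(data)
  keep <- !is.na(data[[pre]]) & !is.na(data[[post]])
  data <- data[keep, , drop = FALSE]
  cls <- as.character(data[[class]])
  change <- data[[pre]] - data[[post]]

  per_group <- function(idx, label) {
    tibble::tibble(group = label, n = length(idx),
                   d = within_group_effect_size(data[[pre]][idx],
                                                data[[post]][idx]),
                   mean_change = mean(change[idx]),
                   sd_change = sd(change[idx]))
  }
  groups <- sort(unique(cls))
  within <- dplyr::bind_rows(
    purrr::map(groups, ~ per_group(which(cls == .x), .x)),
    per_group(seq_along(cls), "all"))

  pairs <- if (length(groups) >= 2) utils::combn(groups, 2,
                                                 simplify = FALSE) else list()
  between <- purrr::map_dfr(pairs, function(pr) {
    i1 <- which(cls == pr[1])
    i2 <- which(cls == pr[2])
    tibble::tibble(
      group1 = pr[1], group2 = pr[2],
      d = pooled_sd_effect_size(mean(change[i1]), sd(change[i1]),
                                length(i1), mean(change[i2]),
                                sd(change[i2]), length(i2)))
  })
  list(within = within, between = between)
}
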