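#' Define an assessment-occasion grid
#'
#' An occasion grid names the measurement occasions of the study and fixes
#' the time codes of the two change phases: `phase1` is the 0/1 indicator
#' of the pre-registration phase (0 at screening, 1 from registration
#' onwards) and `phase2_time` is the nonnegative time index of the
#' intervention phase (0 at screening and registration, then 2, 3, ...).
#' The loading matrix of the piecewise growth model is built from these
#' codes, see [build_loading_matrix()].
#'
#' @param labels Character vector of unique, ordered occasion names.
#' @param phase1 Integer 0/1 vector: 0 at the first occasion, 1 after.
#' @param phase2_time Numeric vector: 0 on the first two occasions,
#'   strictly increasing afterwards.
#'
#' @return A tibble of class `occasion_grid` with columns `occasion`,
#'   `phase1`, `phase2_time`.
#' @export
#' @examples
#' occasion_grid(c("screening", "registration", "wk2", "wk4"),
#'               phase1 = c(0, 1, 1, 1), phase2_time = c(0, 0, 2, 3))
occasion_grid <- function(labels, phase1, phase2_time) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) {
    stop("occasion labels must be unique", call. = FALSE)
  }
  n <- length(labels)
  if (length(phase1) != n || length(phase2_time) != n) {
    stop("`phase1` and `phase2_time` must match `labels` in length",
         call. = FALSE)
  }
  if (!all(phase1 %in% c(0, 1)) || phase1[1] != 0 ||
      (n > 1 && any(phase1[-1] != 1))) {
    stop("`phase1` must be 0 at the first occasion and 1 at all later ones",
         call. = FALSE)
  }
  if (any(phase2_time < 0)) {
    stop("`phase2_time` must be nonnegative", call. = FALSE)
  }
  if (phase2_time[1] != 0 || (n > 1 && phase2_time[2] != 0)) {
    stop("`phase2_time` must be 0 on the first two occasions", call. = FALSE)
  }
  if (n > 2) {
    later <- phase2_time[-(1:2)]
    if (any(diff(c(0, later)) <= 0)) {
      stop("`phase2_time` must be strictly increasing after registration",
           call. = FALSE)
    }
  }
  out <- tibble::tibble(occasion = labels,
                        phase1 = as.numeric(phase1),
                        phase2_time = as.numeric(phase2_time))
  class(out) <- c("occasion_grid", class(out))
  out
}

#' Default 12-week study occasion grid
#'
#' Screening, registration, biweekly assessments through week 12, and a
#' post-treatment assessment. The intervention-phase time index is 2 at
#' week 2 and increases by 1 per biweekly occasion (so the log-linear
#' loading at week 2 is log10(2) and at week 4 is log10(3)).
#'
#' @return An [occasion_grid()] with 9 occasions.
#' @export
default_occasion_grid <- function() {
  labels <- c("screening", "registration",
              paste0("wk", seq(2, 12, by = 2)), "post")
  occasion_grid(labels,
                phase1 = c(0, rep(1, 8)),
                phase2_time = c(0, 0, seq(2, length.out = 7)))
}

#' Early-change occasion grid (first four occasions)
#'
#' The grid on which early-change trajectories are modelled: screening,
#' registration, week 2 and week 4. Later occasions are used for outcome
#' and adherence, never for the mixture fit.
#'
#' @return An [occasion_grid()] with 4 occasions.
#' @export
early_occasion_grid <- function() {
  grid_head(default_occasion_grid(), 4L)
}

#' @keywords internal
grid_head <- function(grid, n) {
  out <- grid[seq_len(n), ]
  class(out) <- class(grid)
  out
}
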