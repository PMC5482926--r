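#' Build the fixed factor-loading matrix of the piecewise growth model
#'
#' The T x 3 loading matrix has an all-ones intercept column, a first-slope
#' column equal to the phase-1 indicator (0 at screening, 1 thereafter),
#' and a second-slope column that is 0 while `phase2_time` is 0 and
#' otherwise a transformation of `phase2_time`: base-10 logarithm under
#' `"log_linear"` (the default; log10(2) at week 2, log10(3) at week 4)
#' or the raw time index under `"linear"`.
#'
#' @param grid An [occasion_grid()].
#' @param transformation `"log_linear"` or `"linear"`.
#'
#' @return A numeric matrix with columns `intercept`, `slope1`, `slope2`,
#'   rows named by occasion, and attribute `transformation`.
#' @export
#' @examples
#' build_loading_matrix(early_occasion_grid())
build_loading_matrix <- function(grid,
                                 transformation = c("log_linear", "linear")) {
  transformation <- match.arg(transformation)
  if (!inherits(grid, "occasion_grid")) {
    stop("`grid` must be an occasion_grid", call. = FALSE)
  }
  if (nrow(grid) < 2) {
    stop("the occasion grid must have at least 2 occasions", call. = FALSE)
  }
  t2 <- grid$phase2_time
  slope2 <- ifelse(t2 == 0, 0,
                   if (transformation == "log_linear") log10(t2) else t2)
  lambda <- cbind(intercept = rep(1, nrow(grid)),
                  slope1 = grid$phase1,
                  slope2 = slope2)
  rownames(lambda) <- grid$occasion
  attr(lambda, "transformation") <- transformation
  lambda
}
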