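#' DVARS: framewise root-mean-square signal change
#'
#' For each frame i >= 2, the square root of the spatial mean (over
#' features) of the squared frame-to-frame intensity difference. A standard
#' quality-control index for motion corruption of fMRI time series: DVARS is
#' invariant to feature permutation and scales with |c| when intensities are
#' scaled by c.
#'
#' @param series numeric feature x frame matrix (>= 2 frames).
#' @return numeric vector of length `n_frames - 1`.
#' @examples
#' dvars(matrix(c(1, 3), 1))        # 2
#' dvars(rbind(c(0, 3), c(0, 4)))   # sqrt((9 + 16) / 2)
#' @export
dvars <- function(series) {
  m <- as.matrix(series)
  if (ncol(m) < 2L) stop("DVARS needs at least 2 frames")
  if (anyNA(m) || any(!is.finite(m))) stop("series contains NA/Inf")
  d <- m[, -1L, drop = FALSE] - m[, -ncol(m), drop = FALSE]
  sqrt(colMeans(d^2))
}

#' Per-condition DVARS summaries
#'
#' Groups framewise DVARS values by the condition active at each frame
#' transition and returns descriptive statistics per condition.
#'
#' @param dvars_values output of [dvars] (length `n_frames - 1`).
#' @param frame_conditions character vector of length `n_frames - 1`,
#'   condition label at each frame transition.
#' @return data frame with `condition`, `n`, `mean`, `sd`, `max`.
#' @export
dvars_summary <- function(dvars_values, frame_conditions) {
  stopifnot(length(dvars_values) == length(frame_conditions))
  conds <- unique(frame_conditions)
  do.call(rbind, lapply(conds, function(cc) {
    v <- dvars_values[frame_conditions == cc]
    data.frame(condition = cc, n = length(v), mean = mean(v),
               sd = stats::sd(v), max = max(v))
  }))
}
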