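# Motion-corrected blush analysis: per-frame ROI tracks standing in for
# the observers' manual adjustment, native-vs-corrected curve comparison,
# and the paired score comparison.

#' Pearson product-moment correlation
#'
#' Standard pointwise correlation of two equal-length series. If either
#' vector is constant the correlation is undefined and is reported as
#' `NA` (flagged missing), never 0; downstream summaries skip missing
#' values with a logged count.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return A single correlation in `[-1, 1]`, or `NA`.
#' @export
pearson_r <- function(x, y) {
  x <- curve_values(x)
  y <- curve_values(y)
  if (length(x) != length(y)) abort_content("`x` and `y` lengths differ")
  if (length(x) < 3L) abort_content("pearson_r needs >= 3 points")
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}

#' Motion-corrected blush curve
#'
#' The per-frame pipeline of [compute_blush_curve()], with frame `i`
#' evaluated inside the track's `i`-th polygon and no panning correction
#' (the track already encodes the motion).
#'
#' @param seq A [frame_sequence()].
#' @param track An [roi_track()] with one polygon per frame.
#' @param opts A [blush_options()] object.
#' @return A [blush_curve()].
#' @export
motion_corrected_curve <- function(seq, track, opts = blush_options()) {
  if (!inherits(track, "roi_track")) abort_content("`track` must be an roi_track")
  compute_blush_curve(seq, track, opts)$curve
}

#' Compare native (fixed-ROI) and motion-corrected blush analyses
#'
#' Computes the native curve from the fixed ROI (with panning correction
#' as per `opts`), the corrected curve from the track, their pointwise
#' Pearson correlation, and both QuBE scores.
#'
#' @param seq A [frame_sequence()].
#' @param roi The fixed reference [roi_polygon()].
#' @param track The per-frame [roi_track()].
#' @param opts A [blush_options()] object.
#' @return An object of class `motion_comparison`: `curve_native`,
#'   `curve_corrected`, `pearson_r`, `score_native`, `score_corrected`.
#' @export
compare_native_vs_corrected <- function(seq, roi, track,
                                        opts = blush_options()) {
  native <- compute_blush_curve(seq, roi, opts)
  corrected <- compute_blush_curve(seq, track, opts)
  res_n <- qube_score(native$curve)
  res_n$offsets <- native$offsets
  res_c <- qube_score(corrected$curve)
  structure(list(curve_native = native$curve,
                 curve_corrected = corrected$curve,
                 pearson_r = pearson_r(native$curve$value,
                                       corrected$curve$value),
                 score_native = res_n, score_corrected = res_c),
            class = "motion_comparison")
}

#' @export
print.motion_comparison <- function(x, ...) {
  cat(sprintf(
    "<motion_comparison: r = %.3f, native score %.4g, corrected score %.4g>\n",
    x$pearson_r, x$score_native$score, x$score_corrected$score))
  invisible(x)
}
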