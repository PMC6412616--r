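# ggplot2 autoplot() methods for the package's result types.

#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_raster labs
#'   scale_fill_gradient facet_wrap geom_errorbar geom_boxplot
#'   position_dodge theme_minimal annotate
NULL

#' Plot a blush curve
#'
#' @param object A [blush_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.blush_curve <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$time_s, y = .data$value)) +
    geom_line() + geom_point(size = 0.8) +
    labs(x = "time (s)", y = "blush intensity") +
    theme_minimal()
}

#' Plot a QuBE result: the blush curve with its maximum rise and fall
#'
#' @param object A `qube_result` (see [qube_score()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.qube_result <- function(object, ...) {
  v <- object$curve$value
  t <- object$curve$time_s
  n <- length(v)
  # index pairs achieving the maximum rise / fall
  run_min_idx <- cummin_idx(v)
  run_max_idx <- cummax_idx(v)
  rise <- v[-1L] - v[run_min_idx][-n]
  fall <- v[run_max_idx][-n] - v[-1L]
  ja <- which.max(rise) + 1L
  ia <- run_min_idx[ja - 1L]
  jb <- which.max(fall) + 1L
  ib <- run_max_idx[jb - 1L]
  p <- autoplot.blush_curve(object$curve)
  if (object$max_increase_a > 0) {
    p <- p + annotate("segment", x = t[ia], xend = t[ja], y = v[ia],
                      yend = v[ja], colour = "#2166ac", linewidth = 1)
  }
  if (object$max_decrease_b > 0) {
    p <- p + annotate("segment", x = t[ib], xend = t[jb], y = v[ib],
                      yend = v[jb], colour = "#b2182b", linewidth = 1)
  }
  p + labs(subtitle = sprintf("QuBE score %.3g = a %.3g + b %.3g",
                              object$score, object$max_increase_a,
                              object$max_decrease_b))
}

cummin_idx <- function(v) {
  idx <- integer(length(v))
  best <- 1L
  for (i in seq_along(v)) {
    if (v[i] < v[best]) best <- i
    idx[i] <- best
  }
  idx
}

cummax_idx <- function(v) {
  idx <- integer(length(v))
  best <- 1L
  for (i in seq_along(v)) {
    if (v[i] > v[best]) best <- i
    idx[i] <- best
  }
  idx
}

#' Plot one frame of a sequence
#'
#' @param object A [frame_sequence()].
#' @param frame 0-based frame index.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.frame_sequence <- function(object, frame = 0L, ...) {
  f <- object$frames[[frame + 1L]]
  df <- tibble(row = as.vector(row(f)) - 1L, col = as.vector(col(f)) - 1L,
               intensity = as.vector(f))
  ggplot(df, aes(x = .data$col, y = .data$row, fill = .data$intensity)) +
    geom_raster() +
    scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    labs(title = sprintf("%s, frame %d", object$id, frame)) +
    theme_minimal()
}

#' Plot native and motion-corrected curves together
#'
#' @param object A `motion_comparison`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.motion_comparison <- function(object, ...) {
  ggplot(tidy(object),
         aes(x = .data$time_s, y = .data$value, colour = .data$analysis)) +
    geom_line() +
    labs(x = "time (s)", y = "blush intensity", colour = NULL,
         subtitle = sprintf("curve correlation r = %.3f", object$pearson_r)) +
    theme_minimal()
}

#' Plot a grade table: median (IQR) score per MBG grade and kernel
#'
#' @param object A [grade_table()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.grade_table <- function(object, ...) {
  df <- dplyr::mutate(object, kernel = factor(.data$kernel))
  ggplot(df, aes(x = factor(.data$mbg), y = .data$median,
                 colour = .data$kernel, group = .data$kernel)) +
    geom_point(position = position_dodge(width = 0.4)) +
    geom_errorbar(aes(ymin = .data$q1, ymax = .data$q3), width = 0.25,
                  position = position_dodge(width = 0.4)) +
    labs(x = "MBG grade", y = "QuBE score (median, IQR)",
         colour = "kernel (px)") +
    theme_minimal()
}

#' Plot per-patient scores by grade and kernel
#'
#' @param object A `kernel_experiment`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.kernel_experiment <- function(object, ...) {
  df <- dplyr::mutate(object$scores, kernel = factor(.data$kernel))
  ggplot(df, aes(x = factor(.data$mbg), y = .data$score,
                 fill = .data$kernel)) +
    geom_boxplot(outlier.size = 0.7) +
    labs(x = "MBG grade", y = "QuBE score", fill = "kernel (px)") +
    theme_minimal()
}
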