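# broom-style tidiers: tidy() returns per-component rows, glance() a
# one-row summary, so results drop straight into dplyr pipelines.

#' @describeIn qube_score Tidy the per-frame curve of a result (columns
#'   `frame_index`, `time_s`, `value`, plus `d_row`/`d_col` when panning
#'   offsets were applied).
#' @param x A `qube_result`.
#' @param ... Unused.
#' @export
tidy.qube_result <- function(x, ...) {
  out <- as_tibble(x$curve)
  if (!is.null(x$offsets)) {
    out$d_row <- x$offsets$d_row
    out$d_col <- x$offsets$d_col
  }
  out
}

#' @describeIn qube_score One-row summary: `score`, `max_increase_a`,
#'   `max_decrease_b`, `n_frames`, `frame_rate_hz`.
#' @export
glance.qube_result <- function(x, ...) {
  tibble(score = x$score, max_increase_a = x$max_increase_a,
         max_decrease_b = x$max_decrease_b, n_frames = nrow(x$curve),
         frame_rate_hz = attr(x$curve, "frame_rate_hz"))
}

#' @describeIn compare_native_vs_corrected Tidy both curves in long form
#'   (`analysis` = native/corrected).
#' @param x A `motion_comparison`.
#' @param ... Unused.
#' @export
tidy.motion_comparison <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(as_tibble(x$curve_native), analysis = "native"),
    dplyr::mutate(as_tibble(x$curve_corrected), analysis = "corrected"))
}

#' @describeIn compare_native_vs_corrected One-row summary: curves'
#'   Pearson r and both scores.
#' @export
glance.motion_comparison <- function(x, ...) {
  tibble(pearson_r = x$pearson_r,
         score_native = x$score_native$score,
         score_corrected = x$score_corrected$score,
         delta_score = x$score_corrected$score - x$score_native$score)
}

#' @describeIn make_cohort Patient labels table: `patient_id`, `mbg`,
#'   `blush_amplitude`.
#' @param x A `synthetic_cohort`.
#' @param ... Unused.
#' @export
tidy.synthetic_cohort <- function(x, ...) {
  purrr::map(x$patients, function(p) {
    tibble(patient_id = p$id, mbg = p$mbg, blush_amplitude = p$amplitude)
  }) |> purrr::list_rbind()
}

#' @describeIn kernel_comparison_experiment Per-patient, per-kernel
#'   scores.
#' @param x A `kernel_experiment`.
#' @param ... Unused.
#' @export
tidy.kernel_experiment <- function(x, ...) x$scores

#' @describeIn kernel_comparison_experiment Association statistics per
#'   kernel in one table.
#' @export
glance.kernel_experiment <- function(x, ...) x$association

#' @describeIn motion_experiment Per-patient, per-observer comparison
#'   rows.
#' @param x A `motion_experiment`.
#' @param ... Unused.
#' @export
tidy.motion_experiment <- function(x, ...) x$per_patient

#' @describeIn motion_experiment Observer summaries joined with the
#'   inter-observer concordance.
#' @export
glance.motion_experiment <- function(x, ...) {
  out <- x$observer_summary
  if (nrow(x$concordance) > 0) {
    out$lin_ccc_vs_next <- c(x$concordance$lin_ccc,
                             rep(NA_real_, nrow(out) - nrow(x$concordance)))
  }
  out
}
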