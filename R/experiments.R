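# Experiment orchestration: kernel-size comparison across MBG grades
# (median/IQR tables plus Spearman and Kruskal-Wallis per kernel) and
# the motion-correction experiment (native vs corrected curves, paired
# scores, inter-observer concordance).

#' Score a synthetic cohort
#'
#' Runs the full QuBE pipeline on every patient, once per kernel size.
#' Panning offsets are estimated once per patient (they do not depend on
#' the kernel) and reused.
#'
#' @param cohort A [make_cohort()] object.
#' @param kernels Integer vector of median-filter kernel sides.
#' @param opts Base [blush_options()]; its `kernel` is replaced by each
#'   entry of `kernels` in turn.
#' @return A tibble: `patient_id`, `mbg`, `kernel`, `score`,
#'   `max_increase_a`, `max_decrease_b`.
#' @export
score_cohort <- function(cohort, kernels = c(20L, 35L, 50L),
                         opts = blush_options()) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  rows <- purrr::map(cohort$patients, function(p) {
    offs <- if (opts$panning_correction) {
      estimate_panning_offsets(p$sequence, 0L, opts$panning_search_radius_px)
    }
    purrr::map(kernels, function(k) {
      o <- opts
      o$kernel <- as.integer(k)
      res <- qube_analyze(p$sequence, p$ground_truth$params$roi, o,
                          offsets = offs)
      tibble(patient_id = p$id, mbg = p$mbg, kernel = as.integer(k),
             score = res$score, max_increase_a = res$max_increase_a,
             max_decrease_b = res$max_decrease_b)
    }) |> purrr::list_rbind()
  })
  purrr::list_rbind(rows)
}

#' Median (IQR) score table per MBG grade and kernel
#'
#' @param scores A tibble with columns `mbg`, `kernel`, `score` (one row
#'   per patient and kernel), as returned by [score_cohort()].
#' @return A tibble of class `grade_table`: `mbg`, `n`, `kernel`,
#'   `median`, `q1`, `q3`.
#' @export
grade_table <- function(scores) {
  need <- c("mbg", "kernel", "score")
  if (!all(need %in% names(scores))) {
    abort_content("`scores` needs columns mbg, kernel, score")
  }
  out <- scores |>
    dplyr::group_by(.data$mbg, .data$kernel) |>
    dplyr::summarise(
      n = dplyr::n(),
      median = summarize_median_iqr(.data$score)[["median"]],
      q1 = summarize_median_iqr(.data$score)[["q1"]],
      q3 = summarize_median_iqr(.data$score)[["q3"]],
      .groups = "drop") |>
    dplyr::relocate("mbg", "n", "kernel", "median", "q1", "q3")
  class(out) <- c("grade_table", class(out))
  out
}

#' Write a grade table as wide CSV
#'
#' One row per MBG grade: `grade`, `n`, then `median`/`q1`/`q3` columns
#' per kernel (`median_k35` etc.).
#'
#' @param tab A [grade_table()].
#' @param path Output CSV file.
#' @return `path`, invisibly.
#' @export
write_grade_table <- function(tab, path) {
  wide <- tab |>
    tidyr::pivot_wider(
      id_cols = c("mbg", "n"),
      names_from = "kernel",
      values_from = c("median", "q1", "q3"),
      names_glue = "{.value}_k{kernel}") |>
    dplyr::rename(grade = "mbg")
  readr::write_csv(wide, path)
  invisible(path)
}

#' Kernel-size comparison experiment
#'
#' Scores every patient under each median-filter kernel, tabulates
#' median (IQR) per MBG grade and kernel, and computes the score-grade
#' association (Spearman) and between-grade differences (Kruskal-Wallis)
#' per kernel. Default kernels: the native 35 px plus the 20 px and
#' 50 px comparison sizes.
#'
#' @param cohort A [make_cohort()] cohort, or a scores tibble with
#'   columns `patient_id`, `mbg`, `kernel`, `score` (e.g. read back from
#'   CSV), in which case scoring is skipped.
#' @param kernels Kernel sides to compare.
#' @param opts Base [blush_options()].
#' @return A list of class `kernel_experiment`: `scores` (tibble),
#'   `grade_table`, `association` (tibble of stacked Spearman and
#'   Kruskal-Wallis results per kernel).
#' @export
kernel_comparison_experiment <- function(cohort, kernels = c(20L, 35L, 50L),
                                         opts = blush_options()) {
  scores <- if (inherits(cohort, "synthetic_cohort")) {
    score_cohort(cohort, kernels = kernels, opts = opts)
  } else if (is.data.frame(cohort)) {
    if (!all(c("patient_id", "mbg", "kernel", "score") %in% names(cohort))) {
      abort_content("scored table needs patient_id, mbg, kernel, score")
    }
    dplyr::filter(cohort, .data$kernel %in% as.integer(kernels))
  } else {
    abort_content("`cohort` must be a synthetic_cohort or a scores table")
  }
  assoc <- purrr::map(sort(unique(scores$kernel)), function(k) {
    sk <- dplyr::filter(scores, .data$kernel == k)
    sp <- spearman_association(sk$score, sk$mbg)
    kw <- kruskal_wallis(split(sk$score, sk$mbg))
    dplyr::bind_rows(sp, kw) |> dplyr::mutate(kernel = k, .before = 1L)
  }) |> purrr::list_rbind()
  structure(list(scores = scores, grade_table = grade_table(scores),
                 association = assoc),
            class = "kernel_experiment")
}

#' @export
print.kernel_experiment <- function(x, ...) {
  cat(sprintf("<kernel_experiment: %d patients x kernels {%s}>\n",
              length(unique(x$scores$patient_id)),
              paste(sort(unique(x$scores$kernel)), collapse = ", ")))
  print(x$grade_table)
  invisible(x)
}

#' Motion-correction experiment
#'
#' For every patient: the native fixed-ROI curve, each observer's
#' motion-corrected curve, their Pearson correlation and both QuBE
#' scores. Aggregates per observer (median and range of r, Wilcoxon
#' signed-rank p for native vs corrected scores) and Lin's concordance
#' between the observers' corrected scores for every observer pair.
#' Patients whose native-vs-corrected correlation is undefined (constant
#' curve) are skipped in the r summaries with a logged count.
#'
#' @param cohort A [make_cohort()] cohort (or subset of one).
#' @param tracks Named list, one element per observer; each element is a
#'   list of [roi_track()]s named by (or ordered as) the cohort's
#'   patient ids.
#' @param opts A [blush_options()] object (applies to the native arm;
#'   corrected curves never use panning correction).
#' @return A list of class `motion_experiment`: `per_patient` (tibble:
#'   `patient_id`, `mbg`, `observer`, `pearson_r`, `score_native`,
#'   `score_corrected`), `observer_summary` (tibble: `observer`,
#'   `median_r`, `min_r`, `max_r`, `n_missing_r`, `wilcoxon_p`),
#'   `concordance` (tibble: `observer_a`, `observer_b`, `lin_ccc`).
#' @export
motion_experiment <- function(cohort, tracks, opts = blush_options()) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!is.list(tracks) || is.null(names(tracks)) || any(names(tracks) == "")) {
    abort_content("`tracks` must be a named list (one element per observer)")
  }
  ids <- vapply(cohort$patients, function(p) p$id, "")
  for (obs in names(tracks)) {
    tr <- tracks[[obs]]
    missing <- if (!is.null(names(tr))) setdiff(ids, names(tr)) else {
      if (length(tr) < length(ids)) tail(ids, length(ids) - length(tr)) else character(0)
    }
    if (length(missing) > 0) {
      abort_content(sprintf("observer '%s' lacks track(s) for patient(s): %s",
                            obs, paste(missing, collapse = ", ")))
    }
  }
  rows <- purrr::map(seq_along(cohort$patients), function(i) {
    p <- cohort$patients[[i]]
    native <- compute_blush_curve(p$sequence, p$ground_truth$params$roi, opts)
    s_native <- qube_score(native$curve)$score
    purrr::map(names(tracks), function(obs) {
      tr <- tracks[[obs]]
      track <- if (!is.null(names(tr))) tr[[p$id]] else tr[[i]]
      corr <- compute_blush_curve(p$sequence, track, opts)
      tibble(patient_id = p$id, mbg = p$mbg, observer = obs,
             pearson_r = pearson_r(native$curve$value, corr$curve$value),
             score_native = s_native,
             score_corrected = qube_score(corr$curve)$score)
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()

  obs_sum <- rows |>
    dplyr::group_by(.data$observer) |>
    dplyr::summarise(
      median_r = median(.data$pearson_r, na.rm = TRUE),
      min_r = suppressWarnings(min(.data$pearson_r, na.rm = TRUE)),
      max_r = suppressWarnings(max(.data$pearson_r, na.rm = TRUE)),
      n_missing_r = sum(is.na(.data$pearson_r)),
      wilcoxon_p = wilcoxon_signed_rank(.data$score_native,
                                        .data$score_corrected)$p_value,
      .groups = "drop")
  n_missing <- sum(is.na(rows$pearson_r))
  if (n_missing > 0) {
    inform(sprintf("motion_experiment: %d undefined curve correlation(s) skipped",
                   n_missing))
  }
  obs_names <- names(tracks)
  conc <- if (length(obs_names) >= 2L) {
    pairs <- utils::combn(obs_names, 2L, simplify = FALSE)
    purrr::map(pairs, function(pr) {
      a <- dplyr::filter(rows, .data$observer == pr[1L]) |>
        dplyr::arrange(.data$patient_id)
      b <- dplyr::filter(rows, .data$observer == pr[2L]) |>
        dplyr::arrange(.data$patient_id)
      tibble(observer_a = pr[1L], observer_b = pr[2L],
             lin_ccc = lin_ccc(a$score_corrected, b$score_corrected))
    }) |> purrr::list_rbind()
  } else {
    tibble(observer_a = character(), observer_b = character(),
           lin_ccc = double())
  }
  structure(list(per_patient = rows, observer_summary = obs_sum,
                 concordance = conc),
            class = "motion_experiment")
}

#' @export
print.motion_experiment <- function(x, ...) {
  cat(sprintf("<motion_experiment: %d patients, %d observer(s)>\n",
              length(unique(x$per_patient$patient_id)),
              length(unique(x$per_patient$observer))))
  print(x$observer_summary)
  invisible(x)
}

#' Ground-truth observer tracks for a cohort
#'
#' Convenience builder for motion experiments on synthetic cohorts: each
#' observer's tracks are the per-patient ground-truth ROI tracks with
#' independent vertex jitter (observer variability).
#'
#' @param cohort A [make_cohort()] cohort.
#' @param observers Observer names.
#' @param sigma_px Vertex jitter SD per observer, px (recycled).
#' @param seed Integer seed.
#' @return A named list of per-patient track lists, suitable for
#'   [motion_experiment()].
#' @export
make_observer_tracks <- function(cohort, observers = c("obs1", "obs2"),
                                 sigma_px = 1, seed = 1L) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  sigma_px <- rep_len(sigma_px, length(observers))
  out <- purrr::imap(observers, function(obs, j) {
    trs <- purrr::map(seq_along(cohort$patients), function(i) {
      jitter_track(cohort$patients[[i]]$ground_truth$roi_track_truth,
                   sigma_px = sigma_px[j],
                   seed = derive_seed(seed, j * 10000L + i))
    })
    names(trs) <- vapply(cohort$patients, function(p) p$id, "")
    trs
  })
  names(out) <- observers
  out
}
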