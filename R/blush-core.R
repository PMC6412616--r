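# QuBE blush extraction and scoring.
#
# Pipeline per frame: invert contrast (so contrast density is positive),
# estimate the large-structure background with a square median filter,
# subtract it (clipping negatives), optionally shift the ROI by the
# frame's estimated panning offset, and take the mean of the brightest
# smoothed residual pixels inside the ROI as the frame's blush value.
# The QuBE score of the resulting curve is its maximum rise plus its
# maximum fall over ordered frame pairs.

#' Options for blush extraction
#'
#' The defaults reproduce the native QuBE configuration: a 35 x 35 px
#' median-filter kernel for large-structure removal, blush values from the
#' brightest residual pixels (2% of the ROI area, at least 10 pixels,
#' after 5 x 5 mean smoothing), and integer panning correction with a
#' +/-20 px search radius.
#'
#' @param kernel Median-filter kernel side in pixels (>= 3; even sides
#'   such as 20 and 50 are honoured with the window anchored at
#'   `floor(side/2)`).
#' @param top_fraction Fraction of ROI pixels averaged for the per-frame
#'   blush value, in (0, 1].
#' @param min_top_pixels Lower bound on the number of averaged pixels.
#' @param smoothing_side_px Odd side of the mean-smoothing window applied
#'   to the residual before picking the brightest pixels (1 disables).
#' @param panning_correction Estimate and apply per-frame integer
#'   translation offsets (ignored when an ROI track is supplied).
#' @param panning_search_radius_px Search radius for the offset, pixels.
#' @return A list of class `blush_options`.
#' @export
blush_options <- function(kernel = 35L, top_fraction = 0.02,
                          min_top_pixels = 10L, smoothing_side_px = 5L,
                          panning_correction = TRUE,
                          panning_search_radius_px = 20L) {
  kernel <- check_count(kernel, "kernel", min = 3L)
  check_scalar_number(top_fraction, "top_fraction")
  if (top_fraction <= 0 || top_fraction > 1) {
    abort_content("`top_fraction` must be in (0, 1]")
  }
  min_top_pixels <- check_count(min_top_pixels, "min_top_pixels", min = 1L)
  smoothing_side_px <- check_count(smoothing_side_px, "smoothing_side_px",
                                   min = 1L)
  if (smoothing_side_px %% 2L == 0L) {
    abort_content("`smoothing_side_px` must be odd")
  }
  radius <- check_count(panning_search_radius_px, "panning_search_radius_px",
                        min = 0L)
  structure(list(kernel = kernel, top_fraction = top_fraction,
                 min_top_pixels = min_top_pixels,
                 smoothing_side_px = smoothing_side_px,
                 panning_correction = isTRUE(panning_correction),
                 panning_search_radius_px = radius),
            class = "blush_options")
}

#' Read blush options from a YAML or JSON config file
#'
#' Fields mirror the arguments of [blush_options()]; absent fields keep
#' their defaults. Entries in `overrides` (e.g. parsed command-line
#' flags) take precedence over the file.
#'
#' @param path Config file (`.yaml`/`.yml` or `.json`), or `NULL` for
#'   pure defaults.
#' @param overrides Named list of option overrides.
#' @return A [blush_options()] object.
#' @export
blush_options_from_config <- function(path = NULL, overrides = list()) {
  cfg <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) abort_format(paste0("no such config: ", path))
    cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
      yaml::read_yaml(path)
    } else {
      jsonlite::read_json(path, simplifyVector = TRUE)
    }
  }
  cfg[names(overrides)] <- overrides
  known <- names(formals(blush_options))
  bad <- setdiff(names(cfg), known)
  if (length(bad) > 0) {
    abort_format(paste0("unknown blush option(s): ", paste(bad, collapse = ", ")))
  }
  do.call(blush_options, cfg)
}

#' Invert the contrast polarity of a sequence
#'
#' Iodinated contrast attenuates x-rays, so blush and vessels are dark in
#' raw angiograms. Each frame is replaced by `global_max - value`, where
#' `global_max` is the maximum intensity over the whole run, making
#' contrast density positive for all downstream arithmetic.
#'
#' @param seq A [frame_sequence()].
#' @return The inverted [frame_sequence()].
#' @export
invert_contrast <- function(seq) {
  stopifnot(inherits(seq, "frame_sequence"))
  gmax <- max(vapply(seq$frames, max, 0))
  seq$frames <- lapply(seq$frames, function(f) gmax - f)
  seq
}

#' Median-filter background estimate of a frame
#'
#' Each output pixel is the median of its `kernel` x `kernel`
#' neighbourhood (midpoint of the two central order statistics when the
#' window holds an even number of pixels). Borders are handled by edge
#' replication; even kernel sides anchor the window at `floor(side/2)`.
#'
#' @param frame Numeric matrix.
#' @param kernel Kernel side in pixels (>= 3), or a [blush_options()]
#'   object whose `kernel` is used.
#' @return The background estimate, same dimensions as `frame`.
#' @export
median_filter_background <- function(frame, kernel = 35L) {
  if (inherits(kernel, "blush_options")) kernel <- kernel$kernel
  kernel <- check_count(kernel, "kernel", min = 3L)
  if (!is.matrix(frame)) abort_content("`frame` must be a matrix")
  if (kernel > nrow(frame) || kernel > ncol(frame)) {
    abort_content("kernel larger than frame")
  }
  median_filter_cpp(frame, kernel)
}

#' Subtract a background image from a frame
#'
#' Residuals are clipped below at zero: background brighter than the
#' frame carries no contrast density.
#'
#' @param frame,background Numeric matrices of identical dimensions.
#' @return The clipped residual matrix.
#' @export
subtract_background <- function(frame, background) {
  if (!identical(dim(frame), dim(background))) {
    abort_content("frame and background dimensions differ")
  }
  pmax(frame - background, 0)
}

#' Blush value of a single residual frame
#'
#' The residual is mean-smoothed with a `smoothing_side_px` square
#' window, then the value is the mean of the `k` brightest smoothed
#' pixels inside the mask, with
#' `k = max(min_top_pixels, ceiling(top_fraction * mask_area))`.
#' The mean of the `k` largest values is well defined under ties.
#'
#' @param residual Numeric matrix (background-subtracted, inverted frame).
#' @param mask Logical matrix of the same dimensions (ROI membership).
#' @param opts A [blush_options()] object.
#' @return A single blush value.
#' @export
frame_blush_value <- function(residual, mask, opts = blush_options()) {
  if (!identical(dim(residual), dim(mask))) {
    abort_content("residual and mask dimensions differ")
  }
  npx <- sum(mask)
  if (npx == 0L) abort_content("empty ROI mask")
  sm <- box_mean(residual, opts$smoothing_side_px)
  v <- sm[mask]
  k <- max(opts$min_top_pixels, ceiling(opts$top_fraction * npx))
  k <- min(k, npx)
  mean(sort(v, decreasing = TRUE, method = "radix")[seq_len(k)])
}

#' Estimate integer panning offsets for every frame
#'
#' For each frame the integer translation within `radius_px` that
#' maximizes normalized cross-correlation with the reference frame over
#' their overlap. Ties are broken by smallest Euclidean norm, then
#' row-major order (`d_row` before `d_col`, ascending); shifts whose
#' overlap is constant in either image are excluded (if all are, the
#' offset is (0, 0)). The reference frame's offset is (0, 0) by
#' construction. The returned offset is the content translation of the
#' frame relative to the reference, so a reference-frame ROI is mapped
#' onto frame i by adding its offset.
#'
#' @param seq A [frame_sequence()].
#' @param reference_index 0-based index of the reference frame.
#' @param radius_px Search radius in pixels.
#' @return A tibble with columns `frame`, `d_row`, `d_col`.
#' @export
estimate_panning_offsets <- function(seq, reference_index = 0L,
                                     radius_px = 20L) {
  stopifnot(inherits(seq, "frame_sequence"))
  radius_px <- check_count(radius_px, "radius_px", min = 0L)
  nfr <- length(seq$frames)
  reference_index <- check_count(reference_index, "reference_index", min = 0L)
  if (reference_index >= nfr) abort_content("`reference_index` out of range")
  dims <- frame_dims(seq)
  if (radius_px >= min(dims) / 2) {
    abort_content("search radius must be below half the frame size")
  }
  ref <- seq$frames[[reference_index + 1L]]
  offsets <- matrix(0L, nfr, 2L)
  for (i in seq_len(nfr)) {
    if (i == reference_index + 1L) next
    grid <- ncc_grid_cpp(ref, seq$frames[[i]], radius_px)
    offsets[i, ] <- pick_best_offset(grid, radius_px)
  }
  tibble(frame = seq_len(nfr) - 1L, d_row = offsets[, 1L],
         d_col = offsets[, 2L])
}

pick_best_offset <- function(grid, radius) {
  if (all(is.na(grid))) return(c(0L, 0L))
  best <- max(grid, na.rm = TRUE)
  hits <- which(grid == best, arr.ind = TRUE)
  dr <- hits[, 1L] - radius - 1L
  dc <- hits[, 2L] - radius - 1L
  ord <- order(dr * dr + dc * dc, dr, dc)
  c(dr[ord[1L]], dc[ord[1L]])
}

#' Compute the blush curve of a sequence
#'
#' Runs the full per-frame pipeline: contrast inversion, median-filter
#' background subtraction, optional panning shift of the ROI, and the
#' brightest-pixel blush value. When `roi` is an [roi_track()], panning
#' correction is disabled (the track already encodes the motion) and the
#' track length must equal the frame count.
#'
#' @param seq A [frame_sequence()].
#' @param roi An [roi_polygon()] (fixed ROI) or [roi_track()].
#' @param opts A [blush_options()] object.
#' @param offsets Optional precomputed offsets tibble (as returned by
#'   [estimate_panning_offsets()]); when supplied, the estimation step is
#'   skipped. Ignored for ROI tracks.
#' @return A list with elements `curve` (a [blush_curve()]) and `offsets`
#'   (tibble, all-zero when panning correction is off).
#' @export
compute_blush_curve <- function(seq, roi, opts = blush_options(),
                                offsets = NULL) {
  stopifnot(inherits(seq, "frame_sequence"))
  nfr <- length(seq$frames)
  dims <- frame_dims(seq)
  is_track <- inherits(roi, "roi_track")
  if (is_track) {
    if (length(roi$polygons) != nfr) {
      abort_content(sprintf("ROI track length (%d) != frame count (%d)",
                            length(roi$polygons), nfr))
    }
  } else if (!inherits(roi, "roi_polygon")) {
    abort_content("`roi` must be an roi_polygon or roi_track")
  }
  if (!is_track && opts$panning_correction) {
    if (is.null(offsets)) {
      offsets <- estimate_panning_offsets(
        seq, reference_index = 0L, radius_px = opts$panning_search_radius_px)
    }
  } else {
    offsets <- tibble(frame = seq_len(nfr) - 1L, d_row = 0L, d_col = 0L)
  }
  inv <- invert_contrast(seq)
  values <- numeric(nfr)
  for (i in seq_len(nfr)) {
    bg <- median_filter_background(inv$frames[[i]], opts$kernel)
    resid <- subtract_background(inv$frames[[i]], bg)
    poly <- if (is_track) {
      roi$polygons[[i]]
    } else {
      shift_roi(roi, offsets$d_row[i], offsets$d_col[i])
    }
    mask <- tryCatch(rasterize_roi(poly, dims), error = function(e) {
      abort_content(sprintf("ROI empty after clipping at frame %d: %s",
                            i - 1L, conditionMessage(e)))
    })
    values[i] <- frame_blush_value(resid, mask, opts)
  }
  list(curve = blush_curve(values, frame_rate_hz = seq$frame_rate_hz),
       offsets = offsets)
}

#' QuBE score of a blush curve
#'
#' The maximum increase `a` is the largest rise `v[j] - v[i]` over
#' ordered frame pairs `i < j` (floored at 0); the maximum decrease `b`
#' is the largest fall, likewise; the score is `a + b`.
#'
#' @param curve A [blush_curve()] or numeric vector (>= 2 points).
#' @return An object of class `qube_result` with elements `score`,
#'   `max_increase_a`, `max_decrease_b`, `curve` and `offsets` (`NULL`
#'   unless produced by [qube_analyze()]).
#' @export
qube_score <- function(curve) {
  v <- curve_values(curve)
  if (length(v) < 2L) abort_content("a blush curve needs >= 2 points")
  if (!all(is.finite(v))) abort_content("blush curve values must be finite")
  n <- length(v)
  run_min <- cummin(v)[-n]
  run_max <- cummax(v)[-n]
  a <- max(0, max(v[-1L] - run_min))
  b <- max(0, max(run_max - v[-1L]))
  if (!inherits(curve, "blush_curve")) curve <- blush_curve(v)
  structure(list(score = a + b, max_increase_a = a, max_decrease_b = b,
                 curve = curve, offsets = NULL),
            class = "qube_result")
}

#' @export
print.qube_result <- function(x, ...) {
  cat(sprintf(
    "<qube_result: score %.4g = max increase %.4g + max decrease %.4g (%d frames)>\n",
    x$score, x$max_increase_a, x$max_decrease_b, nrow(x$curve)))
  invisible(x)
}

#' Full QuBE analysis of a sequence
#'
#' Convenience wrapper: [compute_blush_curve()] followed by
#' [qube_score()], with the panning offsets attached to the result.
#'
#' @inheritParams compute_blush_curve
#' @return A `qube_result` (see [qube_score()]) whose `offsets` field
#'   holds the per-frame panning offsets.
#' @export
qube_analyze <- function(seq, roi, opts = blush_options(), offsets = NULL) {
  cb <- compute_blush_curve(seq, roi, opts, offsets = offsets)
  res <- qube_score(cb$curve)
  res$offsets <- cb$offsets
  res
}
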