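# Containers and file I/O for angiogram runs, regions of interest and
# blush curves.
#
# Conventions used throughout the package:
#  * pixel coordinates are 0-based (row, col) with pixel centers at
#    integer coordinates;
#  * frames are numeric matrices (rows x cols), brighter = higher value;
#  * frame indices in curves and offset tables are 0-based, with frame i
#    acquired at time i / frame_rate_hz seconds.

#' Construct a frame sequence
#'
#' An ordered grayscale angiogram run. Frames are numeric matrices with
#' identical dimensions, finite non-negative intensities, and a shared
#' frame rate.
#'
#' @param frames List of numeric matrices (rows x cols), one per frame.
#' @param frame_rate_hz Acquisition rate in frames per second. Defaults to
#'   12.5, the cine rate typical of digital coronary angiography.
#' @param id Character label for the run.
#' @param bit_depth Optional original bit depth (recorded at read time,
#'   not used by the analysis, which works in floating point).
#' @return An object of class `frame_sequence`.
#' @export
frame_sequence <- function(frames, frame_rate_hz = 12.5, id = "sequence",
                           bit_depth = NULL) {
  if (!is.list(frames) || length(frames) < 2L) {
    abort_content("a frame sequence needs at least 2 frames")
  }
  if (!all(vapply(frames, is.matrix, logical(1)))) {
    abort_content("frames must be numeric matrices")
  }
  d <- dim(frames[[1L]])
  same <- vapply(frames, function(f) identical(dim(f), d), logical(1))
  if (!all(same)) abort_content("all frames must share identical dimensions")
  ok <- vapply(frames, function(f) all(is.finite(f)) && all(f >= 0), logical(1))
  if (!all(ok)) abort_content("frame intensities must be finite and >= 0")
  check_scalar_number(frame_rate_hz, "frame_rate_hz")
  if (frame_rate_hz <= 0) abort_content("`frame_rate_hz` must be > 0")
  frames <- lapply(frames, function(f) {
    storage.mode(f) <- "double"
    f
  })
  structure(
    list(frames = frames, frame_rate_hz = frame_rate_hz, id = id,
         bit_depth = bit_depth),
    class = "frame_sequence"
  )
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames[[1L]])
  cat(sprintf("<frame_sequence '%s': %d frames of %dx%d @ %.3g Hz>\n",
              x$id, length(x$frames), d[1L], d[2L], x$frame_rate_hz))
  invisible(x)
}

#' @export
length.frame_sequence <- function(x) length(x$frames)

frame_dims <- function(seq) dim(seq$frames[[1L]])

#' Construct an ROI polygon
#'
#' A simple (non self-intersecting) polygon in 0-based (row, col) pixel
#' coordinates delimiting the myocardial region whose contrast intensity
#' is tracked over the run.
#'
#' @param vertices Numeric matrix with two columns (row, col), one row per
#'   vertex, at least three vertices.
#' @return An object of class `roi_polygon`.
#' @export
roi_polygon <- function(vertices) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L || nrow(vertices) < 3L) {
    abort_content("an ROI polygon needs >= 3 (row, col) vertices")
  }
  if (!all(is.finite(vertices))) abort_content("ROI vertices must be finite")
  storage.mode(vertices) <- "double"
  colnames(vertices) <- c("row", "col")
  if (polygon_self_intersects(vertices)) {
    abort_content("ROI polygon must be simple (no self-intersection)")
  }
  structure(list(vertices = vertices), class = "roi_polygon")
}

#' @export
print.roi_polygon <- function(x, ...) {
  cat(sprintf("<roi_polygon: %d vertices>\n", nrow(x$vertices)))
  invisible(x)
}

# Segment-intersection test over non-adjacent edge pairs; shared endpoints
# of adjacent edges are allowed.
polygon_self_intersects <- function(v) {
  n <- nrow(v)
  e <- cbind(v, v[c(2:n, 1L), , drop = FALSE])
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  seg_int <- function(p) { # p: (r1,c1,r2,c2, r3,c3,r4,c4)
    d1 <- cross(p[5], p[6], p[7], p[8], p[1], p[2])
    d2 <- cross(p[5], p[6], p[7], p[8], p[3], p[4])
    d3 <- cross(p[1], p[2], p[3], p[4], p[5], p[6])
    d4 <- cross(p[1], p[2], p[3], p[4], p[7], p[8])
    ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
  }
  if (n <= 3L) return(FALSE)
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next  # adjacent through the closing edge
      if (seg_int(c(e[i, ], e[j, ]))) return(TRUE)
    }
  }
  FALSE
}

#' Construct an ROI track
#'
#' One polygon per frame, encoding a manually (or synthetically) adjusted
#' region of interest that follows the myocardium through cardiac motion.
#' Length consistency with a sequence is checked at use time.
#'
#' @param polygons List of [roi_polygon()] objects.
#' @return An object of class `roi_track`.
#' @export
roi_track <- function(polygons) {
  if (!is.list(polygons) || length(polygons) < 1L) {
    abort_content("an ROI track needs at least one polygon")
  }
  polygons <- lapply(polygons, function(p) {
    if (inherits(p, "roi_polygon")) p else roi_polygon(p)
  })
  structure(list(polygons = polygons), class = "roi_track")
}

#' @export
print.roi_track <- function(x, ...) {
  cat(sprintf("<roi_track: %d frames>\n", length(x$polygons)))
  invisible(x)
}

#' @export
length.roi_track <- function(x) length(x$polygons)

#' Shift an ROI polygon by a pixel offset
#'
#' @param roi An [roi_polygon()].
#' @param d_row,d_col Offset in pixels added to every vertex.
#' @return The shifted `roi_polygon`.
#' @export
shift_roi <- function(roi, d_row, d_col) {
  stopifnot(inherits(roi, "roi_polygon"))
  v <- roi$vertices
  v[, 1L] <- v[, 1L] + d_row
  v[, 2L] <- v[, 2L] + d_col
  roi_polygon(v)
}

#' Construct a blush curve
#'
#' Per-frame blush intensity values, returned as a tibble with columns
#' `frame_index` (0-based), `time_s` and `value`, carrying the frame rate
#' as an attribute.
#'
#' @param values Numeric vector, one blush value per frame.
#' @param frame_rate_hz Frame rate in Hz.
#' @return A tibble of class `blush_curve`.
#' @export
blush_curve <- function(values, frame_rate_hz = 12.5) {
  if (!is.numeric(values) || !all(is.finite(values))) {
    abort_content("blush curve values must be finite numbers")
  }
  check_scalar_number(frame_rate_hz, "frame_rate_hz")
  idx <- seq_along(values) - 1L
  out <- tibble(frame_index = idx, time_s = idx / frame_rate_hz,
                value = as.double(values))
  class(out) <- c("blush_curve", class(out))
  attr(out, "frame_rate_hz") <- frame_rate_hz
  out
}

curve_values <- function(curve) {
  if (inherits(curve, "blush_curve")) curve$value else as.double(curve)
}

# ---------------------------------------------------------------------------
# rasterization

#' Rasterize an ROI polygon to a binary mask
#'
#' A pixel belongs to the mask iff its center (integer 0-based
#' coordinates) lies inside the polygon by the even-odd rule; pixel
#' centers exactly on the boundary are included. The mask is clipped to
#' the frame bounds.
#'
#' @param roi An [roi_polygon()].
#' @param dims Frame dimensions `c(rows, cols)`.
#' @return Logical matrix `rows x cols`.
#' @export
rasterize_roi <- function(roi, dims) {
  stopifnot(inherits(roi, "roi_polygon"))
  rows <- check_count(dims[1L], "rows", min = 1L)
  cols <- check_count(dims[2L], "cols", min = 1L)
  v <- roi$vertices
  mask <- matrix(FALSE, rows, cols)
  r0 <- max(0L, floor(min(v[, 1L])))
  r1 <- min(rows - 1L, ceiling(max(v[, 1L])))
  c0 <- max(0L, floor(min(v[, 2L])))
  c1 <- min(cols - 1L, ceiling(max(v[, 2L])))
  if (r0 > r1 || c0 > c1) {
    abort_content("ROI mask empty after clipping to frame bounds")
  }
  pr <- rep(r0:r1, times = c1 - c0 + 1L)
  pc <- rep(c0:c1, each = r1 - r0 + 1L)
  inside <- rep(FALSE, length(pr))
  boundary <- rep(FALSE, length(pr))
  n <- nrow(v)
  eps <- 1e-9
  for (i in seq_len(n)) {
    a <- v[i, ]
    b <- v[if (i == n) 1L else i + 1L, ]
    # even-odd crossing of the horizontal ray towards +col
    crosses <- ((a[1L] > pr) != (b[1L] > pr))
    if (any(crosses)) {
      xint <- a[2L] + (pr - a[1L]) * (b[2L] - a[2L]) / (b[1L] - a[1L])
      inside <- xor(inside, crosses & (pc < xint))
    }
    # point-on-segment check
    abr <- b[1L] - a[1L]; abc <- b[2L] - a[2L]
    len2 <- abr * abr + abc * abc
    if (len2 == 0) next
    crossp <- (pr - a[1L]) * abc - (pc - a[2L]) * abr
    dotp <- (pr - a[1L]) * abr + (pc - a[2L]) * abc
    boundary <- boundary |
      (abs(crossp) <= eps * sqrt(len2) & dotp >= -eps & dotp <= len2 + eps)
  }
  sel <- inside | boundary
  mask[cbind(pr + 1L, pc + 1L)] <- sel
  if (!any(mask)) abort_content("ROI mask empty after clipping to frame bounds")
  mask
}

# ---------------------------------------------------------------------------
# sequence I/O

#' Read an angiogram sequence
#'
#' Supported containers: a multi-frame DICOM file (modality XA,
#' uncompressed little-endian transfer syntaxes, pixel data only) or a
#' directory of single-frame lossless images (TIFF or PNG), ordered
#' lexicographically by filename.
#'
#' The frame rate is taken from file metadata when present (DICOM
#' FrameTime/CineRate, or the `sequence.json` sidecar written by
#' [write_sequence()]); otherwise from `frame_rate_hz`; otherwise the
#' 12.5 Hz default.
#'
#' @param path File (DICOM) or directory (image stack).
#' @param format `"dicom"`, `"image_stack"`, or `NULL` to infer from
#'   `path` (file vs directory).
#' @param frame_rate_hz Fallback frame rate used when the file carries no
#'   rate metadata.
#' @return A [frame_sequence()].
#' @export
read_sequence <- function(path, format = NULL, frame_rate_hz = NULL) {
  if (!file.exists(path)) abort_format(paste0("no such path: ", path))
  if (is.null(format)) {
    format <- if (dir.exists(path)) "image_stack" else "dicom"
  }
  format <- match.arg(format, c("dicom", "image_stack"))
  if (format == "dicom") {
    read_sequence_dicom(path, frame_rate_hz)
  } else {
    read_sequence_stack(path, frame_rate_hz)
  }
}

read_sequence_stack <- function(path, frame_rate_hz = NULL) {
  if (!dir.exists(path)) abort_format("image_stack expects a directory")
  files <- list.files(path, pattern = "\\.(tif|tiff|png)$", ignore.case = TRUE)
  files <- files[order(files, method = "radix")]  # lexicographic, locale-free
  if (length(files) < 2L) abort_content("an image stack needs at least 2 frames")
  frames <- lapply(file.path(path, files), read_stack_frame)
  meta_path <- file.path(path, "sequence.json")
  rate <- NULL
  id <- basename(path)
  depth <- NULL
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path)
    rate <- meta$frame_rate_hz
    id <- meta$id %||% id
    depth <- meta$bit_depth
  }
  rate <- rate %||% frame_rate_hz %||% 12.5
  frame_sequence(frames, frame_rate_hz = as.double(rate), id = id,
                 bit_depth = depth)
}

read_stack_frame <- function(f) {
  ext <- tolower(tools::file_ext(f))
  if (ext %in% c("tif", "tiff")) {
    m <- tryCatch(tiff::readTIFF(f, as.is = TRUE),
                  error = function(e) abort_format(paste0("unreadable TIFF: ", f)))
  } else {
    m <- tryCatch(png::readPNG(f),
                  error = function(e) abort_format(paste0("unreadable PNG: ", f)))
    # readPNG rescales samples to [0,1]; recover integers on a 16-bit scale
    # (8-bit samples come back as exact multiples of 257)
    m <- round(m * 65535)
  }
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  storage.mode(m) <- "double"
  m
}

write_stack_frame_tiff <- function(m, f, bits) {
  tiff::writeTIFF(m / (2^bits - 1), f, bits.per.sample = bits,
                  compression = "none")
}

#' Write an angiogram sequence
#'
#' Encodings are lossless by construction: samples are stored as unsigned
#' integers (8 or 16 bit). Writing a sequence whose intensities are not
#' integer-valued within the sample range is refused as lossy; round or
#' rescale explicitly first.
#'
#' @param seq A [frame_sequence()].
#' @param path Output file (DICOM) or directory (image stack).
#' @param format `"image_stack"` (TIFF files plus a `sequence.json`
#'   sidecar holding the frame rate) or `"dicom"`.
#' @param bits Sample width, 8 or 16.
#' @return `path`, invisibly.
#' @export
write_sequence <- function(seq, path, format = c("image_stack", "dicom"),
                           bits = 16L) {
  stopifnot(inherits(seq, "frame_sequence"))
  format <- match.arg(format)
  if (!bits %in% c(8L, 16L)) abort_format("`bits` must be 8 or 16")
  maxv <- 2^bits - 1
  lossless <- vapply(seq$frames, function(f) {
    all(f == round(f)) && max(f) <= maxv
  }, logical(1))
  if (!all(lossless)) {
    abort_format(paste0(
      "refusing lossy write: intensities must be integers in [0, ", maxv, "]"))
  }
  if (format == "image_stack") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    nd <- max(4L, nchar(as.character(length(seq$frames))))
    for (i in seq_along(seq$frames)) {
      f <- file.path(path, sprintf(paste0("frame_%0", nd, "d.tif"), i))
      write_stack_frame_tiff(seq$frames[[i]], f, bits)
    }
    jsonlite::write_json(
      list(frame_rate_hz = seq$frame_rate_hz, id = seq$id, bit_depth = bits),
      file.path(path, "sequence.json"), auto_unbox = TRUE, digits = NA)
  } else {
    write_dicom_xa(seq, path, bits = bits)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# ROI and curve I/O

#' Read an ROI polygon or track from JSON
#'
#' Accepts `{"type":"roi","vertices":[[r,c],...]}` or
#' `{"type":"roi_track","frames":[[[r,c],...],...]}`. Track length
#' consistency with a sequence is checked at use time, not here.
#'
#' @param path JSON file.
#' @return An [roi_polygon()] or [roi_track()].
#' @export
read_roi <- function(path) {
  if (!file.exists(path)) abort_format(paste0("no such file: ", path))
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) abort_format("unreadable ROI JSON"))
  type <- doc$type %||% "roi"
  to_mat <- function(vv) {
    do.call(rbind, lapply(vv, function(p) c(as.double(p[[1]]), as.double(p[[2]]))))
  }
  if (identical(type, "roi")) {
    if (length(doc$vertices %||% list()) < 3L) {
      abort_content("ROI polygon needs >= 3 vertices")
    }
    roi_polygon(to_mat(doc$vertices))
  } else if (identical(type, "roi_track")) {
    roi_track(lapply(doc$frames, to_mat))
  } else {
    abort_format(paste0("unknown ROI type: ", type))
  }
}

#' Write an ROI polygon or track to JSON
#'
#' @param obj An [roi_polygon()] or [roi_track()].
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_roi <- function(obj, path) {
  unname_mat <- function(v) lapply(seq_len(nrow(v)), function(i) c(v[i, 1L], v[i, 2L]))
  doc <- if (inherits(obj, "roi_polygon")) {
    list(type = "roi", vertices = unname_mat(obj$vertices))
  } else if (inherits(obj, "roi_track")) {
    list(type = "roi_track",
         frames = lapply(obj$polygons, function(p) unname_mat(p$vertices)))
  } else {
    abort_content("`obj` must be an roi_polygon or roi_track")
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write a blush curve as CSV
#'
#' The CSV schema is `frame_index,time_s,value` with a mandatory header;
#' `frame_index` is 0-based.
#'
#' @param path CSV file.
#' @return [read_blush_curve()]: a [blush_curve()].
#' @export
read_blush_curve <- function(path) {
  if (!file.exists(path)) abort_format(paste0("no such file: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("frame_index", "time_s", "value")
  if (!all(need %in% names(df))) {
    abort_format("blush curve CSV needs columns frame_index,time_s,value")
  }
  if (nrow(df) >= 2L) {
    rate <- 1 / stats::median(diff(df$time_s))
  } else {
    rate <- 12.5
  }
  blush_curve(df$value, frame_rate_hz = rate)
}

#' @rdname read_blush_curve
#' @param curve A [blush_curve()].
#' @export
write_blush_curve <- function(curve, path) {
  stopifnot(inherits(curve, "blush_curve"))
  readr::write_csv(as_tibble(curve)[c("frame_index", "time_s", "value")], path)
  invisible(path)
}
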