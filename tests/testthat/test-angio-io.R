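# Containers, rasterization and file round-trips.

test_that("frame_sequence enforces its invariants", {
  f <- matrix(1, 8, 8)
  expect_s3_class(frame_sequence(list(f, f)), "frame_sequence")
  expect_error(frame_sequence(list(f)), class = "qube_content_error")
  expect_error(frame_sequence(list(f, matrix(1, 8, 9))),
               class = "qube_content_error")
  expect_error(frame_sequence(list(f, f - 2)), class = "qube_content_error")
  expect_error(frame_sequence(list(f, f), frame_rate_hz = 0),
               class = "qube_content_error")
})

test_that("roi_polygon rejects degenerate and self-intersecting input", {
  sq <- roi_polygon(rbind(c(10, 10), c(10, 50), c(50, 50), c(50, 10)))
  expect_s3_class(sq, "roi_polygon")
  expect_error(roi_polygon(rbind(c(0, 0), c(1, 1))),
               class = "qube_content_error")
  # bow-tie self-intersection
  expect_error(roi_polygon(rbind(c(0, 0), c(10, 10), c(0, 10), c(10, 0))),
               class = "qube_content_error")
})

test_that("ROI rasterization matches the exhaustive even-odd oracle", {
  polys <- list(
    rbind(c(10, 10), c(10, 50), c(50, 50), c(50, 10)),   # axis-aligned square
    rbind(c(0, 0), c(0, 10), c(10, 0)),                  # right triangle
    rbind(c(3.5, 2.2), c(8.7, 30.1), c(40.2, 25.4), c(28.9, 4.4)), # irregular
    rbind(c(-5, -5), c(-5, 20), c(20, 20), c(20, -5))    # clipped at bounds
  )
  for (v in polys) {
    mask <- rasterize_roi(roi_polygon(v), c(64, 64))
    expect_identical(mask, bf_rasterize(v, c(64, 64)))
  }
})

test_that("axis-aligned square mask covers boundary-inclusive pixel count", {
  sq <- roi_polygon(rbind(c(10, 10), c(10, 50), c(50, 50), c(50, 10)))
  expect_identical(sum(rasterize_roi(sq, c(64, 64))), 41L * 41L)
})

test_that("rasterizing a polygon fully outside the frame is an error", {
  out <- roi_polygon(rbind(c(100, 100), c(100, 120), c(120, 110)))
  expect_error(rasterize_roi(out, c(64, 64)), class = "qube_content_error")
})

test_that("image-stack round trip is bit-exact, 16-bit preserved", {
  seq <- tiny_int_sequence(n_frames = 5L)
  path <- withr::local_tempdir()
  write_sequence(seq, path, format = "image_stack")
  back <- read_sequence(path)
  expect_identical(back$frames, seq$frames)
  expect_identical(back$frame_rate_hz, 12.5)
  # arbitrary 16-bit values preserved without clipping
  expect_identical(max(unlist(back$frames)), max(unlist(seq$frames)))
})

test_that("lossy writes are refused", {
  f <- matrix(0.5, 8, 8)
  seq <- frame_sequence(list(f, f))
  expect_error(write_sequence(seq, tempfile(), format = "image_stack"),
               class = "qube_format_error")
  big <- frame_sequence(list(matrix(70000, 8, 8), matrix(1, 8, 8)))
  expect_error(write_sequence(big, tempfile(), format = "image_stack"),
               class = "qube_format_error")
})

test_that("a single-frame stack is refused on read-back", {
  path <- withr::local_tempdir()
  tiff::writeTIFF(matrix(0.3, 8, 8), file.path(path, "frame_0001.tif"),
                  bits.per.sample = 16)
  expect_error(read_sequence(path), class = "qube_content_error")
})

test_that("image-stack frame order is lexicographic on filename", {
  path <- withr::local_tempdir()
  vals <- c(3, 1, 2)
  names <- c("c_frame.tif", "a_frame.tif", "b_frame.tif")
  for (i in seq_along(vals)) {
    tiff::writeTIFF(matrix(vals[i] / 65535, 4, 4), file.path(path, names[i]),
                    bits.per.sample = 16)
  }
  back <- read_sequence(path)
  expect_equal(vapply(back$frames, function(f) f[1, 1], 0), c(1, 2, 3))
})

test_that("frame rate falls back to metadata, then override, then 12.5", {
  seq <- tiny_int_sequence()
  path <- withr::local_tempdir()
  write_sequence(seq, path, format = "image_stack")
  expect_identical(read_sequence(path, frame_rate_hz = 30)$frame_rate_hz, 12.5)
  file.remove(file.path(path, "sequence.json"))
  expect_identical(read_sequence(path, frame_rate_hz = 30)$frame_rate_hz, 30)
  expect_identical(read_sequence(path)$frame_rate_hz, 12.5)
})

test_that("DICOM XA round trip is bit-exact and carries the frame rate", {
  seq <- tiny_int_sequence(n_frames = 4L, dims = c(9L, 13L))
  path <- withr::local_tempfile(fileext = ".dcm")
  write_sequence(seq, path, format = "dicom")
  back <- read_sequence(path)
  expect_identical(back$frames, seq$frames)
  expect_equal(back$frame_rate_hz, 12.5, tolerance = 1e-9)
  expect_identical(back$bit_depth, 16L)
})

test_that("written DICOM is readable by an independent DICOM toolkit", {
  seq <- tiny_int_sequence(n_frames = 3L, dims = c(6L, 8L))
  path <- withr::local_tempfile(fileext = ".dcm")
  write_sequence(seq, path, format = "dicom")
  script <- paste0(
    "import pydicom,sys;d=pydicom.dcmread(sys.argv[1]);a=d.pixel_array;",
    "print(a.shape[0],a.shape[1],a.shape[2],int(a.sum()),d.Modality)")
  out <- suppressWarnings(
    system2("python", c("-c", shQuote(script), shQuote(path)), stdout = TRUE))
  expect_identical(
    out[length(out)],
    paste(3, 6, 8, format(sum(unlist(seq$frames)), scientific = FALSE), "XA"))
})

test_that("ROI JSON round trip preserves vertices exactly", {
  sq <- roi_polygon(rbind(c(10, 10), c(10, 50), c(50, 50), c(50, 10)))
  path <- withr::local_tempfile(fileext = ".json")
  write_roi(sq, path)
  expect_equal(read_roi(path)$vertices, sq$vertices, ignore_attr = TRUE)

  tr <- roi_track(replicate(4, sq$vertices + runif(1), simplify = FALSE))
  write_roi(tr, path)
  back <- read_roi(path)
  expect_s3_class(back, "roi_track")
  expect_length(back$polygons, 4L)
  expect_equal(lapply(back$polygons, `[[`, "vertices"),
               lapply(tr$polygons, `[[`, "vertices"), ignore_attr = TRUE)

  jsonlite::write_json(list(type = "roi", vertices = list(c(1, 2), c(3, 4))),
                       path, auto_unbox = TRUE)
  expect_error(read_roi(path), class = "qube_content_error")
})

test_that("blush curve CSV round trip preserves values and schema", {
  bc <- blush_curve(c(0, 1.25, 3.5, 2), frame_rate_hz = 12.5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_blush_curve(bc, path)
  header <- readLines(path, n = 1L)
  expect_identical(header, "frame_index,time_s,value")
  back <- read_blush_curve(path)
  expect_equal(back$value, bc$value)
  expect_equal(attr(back, "frame_rate_hz"), 12.5, tolerance = 1e-9)
})
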