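# Blush extraction and scoring against brute-force oracles.

test_that("contrast inversion maps the darkest pixel to the global max", {
  f1 <- matrix(seq(0, 100, length.out = 64), 8, 8)
  f2 <- matrix(50, 8, 8)
  inv <- invert_contrast(frame_sequence(list(f1, f2)))
  expect_equal(inv$frames[[1]], 100 - f1)
  expect_equal(inv$frames[[2]], matrix(50, 8, 8))
  # constant sequence maps to constant zero
  const <- invert_contrast(frame_sequence(list(f2, f2)))
  expect_true(all(unlist(const$frames) == 0))
  # involution when the sequence minimum is 0
  f1[1, 1] <- 0
  seq <- frame_sequence(list(f1, f2))
  twice <- invert_contrast(invert_contrast(seq))
  expect_equal(twice$frames, seq$frames)
})

test_that("median filter reproduces hand-derivable cases", {
  const <- matrix(7.5, 9, 9)
  expect_equal(median_filter_background(const, 3), const)
  expect_equal(median_filter_background(const, 8), const)

  spike <- matrix(0, 9, 9)
  spike[5, 5] <- 100
  expect_equal(median_filter_background(spike, 3), matrix(0, 9, 9))

  ramp <- matrix(rep(0:8, each = 9), 9, 9)  # I(r, c) = c
  filt <- median_filter_background(ramp, 3)
  expect_equal(filt[2:8, 2:8], ramp[2:8, 2:8])
})

test_that("median filter matches the exhaustive oracle on random frames", {
  withr::with_seed(7, {
    for (trial in 1:20) {
      x <- matrix(runif(32 * 32) * 100, 32, 32)
      for (side in c(3, 4, 5, 20)) {
        expect_equal(median_filter_background(x, side),
                     bf_median_filter(x, side), tolerance = 1e-12)
      }
    }
  })
})

test_that("median filter output stays within the input range", {
  withr::with_seed(11, {
    x <- matrix(rnorm(40 * 40, 50, 20), 40, 40)
    for (side in c(3, 20, 35)) {
      f <- median_filter_background(x, side)
      expect_true(all(f >= min(x) & f <= max(x)))
    }
  })
})

test_that("median filter rejects kernels larger than the frame", {
  expect_error(median_filter_background(matrix(0, 10, 10), 11),
               class = "qube_content_error")
  expect_error(blush_options(kernel = 2), class = "qube_content_error")
})

test_that("background subtraction clips negatives and checks dims", {
  f <- matrix(runif(64), 8, 8)
  expect_equal(subtract_background(f, f), matrix(0, 8, 8))
  expect_equal(subtract_background(f + 5, f), matrix(5, 8, 8))
  expect_true(all(subtract_background(f, f + 1) == 0))
  expect_error(subtract_background(f, matrix(0, 8, 9)),
               class = "qube_content_error")
})

test_that("kernel-vs-blush-scale mechanism: small kernels swallow the blush", {
  rr <- matrix(0:127, 128, 128)
  cc <- t(rr)
  blob <- 50 * exp(-((rr - 64)^2 + (cc - 64)^2) / (2 * 8^2))
  frac <- vapply(c(9, 35), function(k) {
    max(subtract_background(blob, median_filter_background(blob, k))) / 50
  }, 0)
  # direct computation gives 0.097 (kernel 9) and 0.784 (kernel 35)
  expect_lt(frac[1], 0.5)
  expect_gt(frac[2], 0.75)
  # residual amplitude non-decreasing in kernel side over {sigma, 2s, 4s}
  fr <- vapply(c(8, 16, 32), function(k) {
    max(subtract_background(blob, median_filter_background(blob, k)))
  }, 0)
  expect_true(all(diff(fr) >= 0))
})

test_that("frame blush value averages the brightest masked pixels", {
  resid <- matrix(0, 10, 10)
  mask <- matrix(TRUE, 10, 10)
  opts1 <- blush_options(top_fraction = 0.05, min_top_pixels = 5,
                         smoothing_side_px = 1, panning_correction = FALSE)
  expect_equal(frame_blush_value(resid + 3.25, mask, opts1), 3.25)
  resid[1, 1:5] <- 10
  expect_equal(frame_blush_value(resid, mask, opts1), 10)
  opts2 <- blush_options(top_fraction = 0.10, min_top_pixels = 5,
                         smoothing_side_px = 1, panning_correction = FALSE)
  expect_equal(frame_blush_value(resid, mask, opts2), 5)
  # sort-and-average oracle on a random residual
  withr::with_seed(3, {
    resid <- matrix(runif(100), 10, 10)
    k <- max(5, ceiling(0.10 * 100))
    expect_equal(frame_blush_value(resid, mask, opts2),
                 mean(sort(as.vector(resid), decreasing = TRUE)[1:k]))
  })
  expect_error(frame_blush_value(resid, mask & FALSE, opts1),
               class = "qube_content_error")
})

test_that("qube score matches the all-pairs oracle and its decomposition", {
  cases <- list(c(5, 5, 5), c(10, 15, 12, 8, 11), c(0, 1, 2, 3),
                c(3, 2, 1, 0), c(1, 5, 1, 5, 1))
  for (v in cases) {
    res <- qube_score(v)
    bf <- bf_qube_score(v)
    expect_equal(res$max_increase_a, bf$a)
    expect_equal(res$max_decrease_b, bf$b)
    expect_equal(res$score, bf$score)
    expect_equal(res$score, res$max_increase_a + res$max_decrease_b)
  }
  withr::with_seed(5, {
    for (i in 1:25) {
      v <- rnorm(sample(2:30, 1))
      res <- qube_score(v)
      bf <- bf_qube_score(v)
      expect_equal(res$max_increase_a, bf$a)
      expect_equal(res$max_decrease_b, bf$b)
      # bounds from the curve range
      expect_lte(res$score, 2 * diff(range(v)) + 1e-12)
    }
  })
  expect_error(qube_score(5), class = "qube_content_error")
})

test_that("qube score is shift-invariant, scale-equivariant, reverse-symmetric", {
  withr::with_seed(9, {
    for (i in 1:10) {
      v <- rnorm(20)
      res <- qube_score(v)
      shifted <- qube_score(v + 17.3)
      expect_equal(shifted$score, res$score)
      scaled <- qube_score(2.5 * v)
      expect_equal(scaled$score, 2.5 * res$score)
      rev_res <- qube_score(rev(v))
      expect_equal(rev_res$max_increase_a, res$max_decrease_b)
      expect_equal(rev_res$max_decrease_b, res$max_increase_a)
      expect_equal(rev_res$score, res$score)
    }
  })
})

test_that("blush options validate and load from config with overrides", {
  expect_error(blush_options(top_fraction = 0), class = "qube_content_error")
  expect_error(blush_options(smoothing_side_px = 4), class = "qube_content_error")
  cfg <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("kernel: 50", "top_fraction: 0.05"), cfg)
  o <- blush_options_from_config(cfg)
  expect_identical(o$kernel, 50L)
  expect_identical(o$top_fraction, 0.05)
  o2 <- blush_options_from_config(cfg, overrides = list(kernel = 20))
  expect_identical(o2$kernel, 20L)
  writeLines("bogus_field: 1", cfg)
  expect_error(blush_options_from_config(cfg), class = "qube_format_error")
})

test_that("constant sequences give a constant-zero blush curve", {
  f <- matrix(90, 48, 48)
  seq <- frame_sequence(list(f, f, f, f))
  roi <- roi_polygon(rbind(c(10, 10), c(10, 40), c(40, 40), c(40, 10)))
  cb <- compute_blush_curve(seq, roi, no_panning(kernel = 5))
  expect_equal(cb$curve$value, rep(0, 4))
  expect_equal(qube_score(cb$curve)$score, 0)
})

test_that("fixed ROI and an identical track give identical curves", {
  sim <- simulate_sequence(small_scene_params(
    seed = 4, cardiac_translation_px = 0, cardiac_rotation_deg = 0,
    panning_drift_px_per_frame = c(0, 0)))
  roi <- sim$ground_truth$params$roi
  track <- roi_track(replicate(length(sim$sequence), roi$vertices,
                               simplify = FALSE))
  c_fixed <- compute_blush_curve(sim$sequence, roi, no_panning())
  c_track <- compute_blush_curve(sim$sequence, track, no_panning())
  expect_equal(c_track$curve$value, c_fixed$curve$value)
})

test_that("an ROI pushed off the frame names the offending frame", {
  sim <- simulate_sequence(small_scene_params(seed = 5))
  far <- roi_polygon(rbind(c(2, 2), c(2, 8), c(8, 8), c(8, 2)))
  track <- roi_track(c(
    replicate(10, far$vertices, simplify = FALSE),
    list(far$vertices - 500),
    replicate(length(sim$sequence) - 11, far$vertices, simplify = FALSE)))
  err <- tryCatch(compute_blush_curve(sim$sequence, track, no_panning()),
                  error = identity)
  expect_s3_class(err, "qube_content_error")
  expect_match(conditionMessage(err), "frame 10")
})
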