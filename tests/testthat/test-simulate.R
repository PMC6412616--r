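# Synthetic angiogram generator: determinism, kinetics, ground truth,
# cohorts.

test_that("gamma-variate kinetics peak exactly at t0 + tp with value A", {
  expect_equal(gamma_variate(1 + 1.6, 1, 1.6, 3, 20), 20)
  expect_equal(gamma_variate(0.5, 1, 1.6, 3, 20), 0)
  # width decreases as alpha grows
  t <- seq(0, 20, by = 0.001)
  width_at_half <- function(alpha) {
    h <- gamma_variate(t, 1, 1.6, alpha, 1)
    diff(range(t[h >= 0.5]))
  }
  w <- vapply(c(1, 3, 10, 30), width_at_half, 0)
  expect_true(all(diff(w) < 0))
})

test_that("true curve peaks at the frame nearest the kinetic peak", {
  # t0 = 1 s, tp = 1.6 s at 12.5 Hz: evaluating h on the frame grid puts
  # the argmax at frame 33 (h(2.64) > h(2.56))
  p <- simulation_params(t0_s = 1, tp_s = 1.6, n_frames = 60L)
  sim <- simulate_sequence(p)
  tc <- true_blush_curve(sim$ground_truth)
  expect_identical(tc$frame_index[which.max(tc$value)], 33L)
  h <- gamma_variate(tc$time_s, 1, 1.6, 3, p$blush_amplitude)
  expect_equal(tc$value, h)
})

test_that("identical parameters and seed give bit-identical output", {
  p <- small_scene_params(seed = 21)
  s1 <- simulate_sequence(p)
  s2 <- simulate_sequence(p)
  expect_identical(s1$sequence$frames, s2$sequence$frames)
  expect_identical(s1$ground_truth$true_curve$value,
                   s2$ground_truth$true_curve$value)
  s3 <- simulate_sequence(small_scene_params(seed = 22))
  expect_false(identical(s1$sequence$frames, s3$sequence$frames))
})

test_that("a structure-free, motionless, zero-amplitude scene is constant", {
  p <- small_scene_params(
    seed = 2, noise_sigma = 0, blush_amplitude = 0, vessels = FALSE,
    diaphragm = FALSE, catheter = FALSE, cardiac_translation_px = 0,
    cardiac_rotation_deg = 0, panning_drift_px_per_frame = c(0, 0))
  sim <- simulate_sequence(p)
  expect_true(all(vapply(sim$sequence$frames, function(f) {
    all(f == p$background_level)
  }, TRUE)))
  res <- qube_analyze(sim$sequence, p$roi, no_panning())
  expect_equal(res$score, 0)
})

test_that("ground-truth ROI track is the exact image of the reference ROI", {
  p <- small_scene_params(seed = 3)
  sim <- simulate_sequence(p)
  gt <- sim$ground_truth
  expect_length(gt$roi_track_truth$polygons, p$n_frames)
  i <- 17L
  th <- gt$motion$theta_deg[i] * pi / 180
  ctr <- (p$dims - 1) / 2
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  v <- p$roi$vertices
  expected <- t(R %*% t(sweep(v, 2, ctr))) +
    rep(1, nrow(v)) %o% c(ctr[1] + gt$motion$d_row[i],
                          ctr[2] + gt$motion$d_col[i])
  expect_equal(unname(gt$roi_track_truth$polygons[[i]]$vertices),
               unname(expected), tolerance = 1e-10)
})

test_that("blush centre outside the frame is rejected", {
  expect_error(simulation_params(dims = c(64L, 64L), blush_center = c(70, 10)),
               class = "qube_content_error")
})

test_that("noise-free pipeline recovers the gamma-variate kinetics", {
  p <- simulation_params(
    blush_amplitude = 20, noise_sigma = 0, vessels = FALSE,
    diaphragm = FALSE, catheter = FALSE, cardiac_translation_px = 0,
    cardiac_rotation_deg = 0, panning_drift_px_per_frame = c(0, 0),
    dims = c(128L, 128L), n_frames = 40L, blush_center = c(64, 64),
    blush_sigma_px = 20, roi_half_side_px = 24)
  sim <- simulate_sequence(p)
  cb <- compute_blush_curve(sim$sequence, p$roi, no_panning())
  tc <- true_blush_curve(sim$ground_truth)
  expect_gte(pearson_r(cb$curve$value, tc$value), 0.99)
  expect_lte(abs(which.max(cb$curve$value) - which.max(tc$value)), 1L)
})

test_that("cohorts have the trial design: 4 grades, n per grade", {
  tiny <- small_scene_params(seed = 1)
  coh <- make_cohort(2, "associated", base_params = tiny, seed = 3)
  lab <- tidy(coh)
  expect_identical(nrow(lab), 8L)
  expect_identical(as.integer(table(lab$mbg)), rep(2L, 4))
  expect_true(all(lab$patient_id == sprintf("P%03d", 1:8)))
  # associated amplitudes track the grade mapping
  expect_true(all(lab$blush_amplitude[lab$mbg == 0] == 0))
  expect_true(mean(lab$blush_amplitude[lab$mbg == 3]) >
                mean(lab$blush_amplitude[lab$mbg == 1]))
})

test_that("null cohorts draw amplitudes independently of grade", {
  tiny <- small_scene_params(seed = 1)
  coh <- make_cohort(3, "null", base_params = tiny, seed = 4)
  lab <- tidy(coh)
  expect_true(all(lab$blush_amplitude >= 0 & lab$blush_amplitude <= 60))
  # grade 0 is not pinned at amplitude 0 in null mode
  expect_true(any(lab$blush_amplitude[lab$mbg == 0] > 0))
})

test_that("associated cohorts at zero noise give strictly increasing medians", {
  p0 <- small_scene_params(noise_sigma = 0, seed = 1)
  coh <- make_cohort(3, "associated", base_params = p0, seed = 6)
  sc <- score_cohort(coh, kernels = 35L, opts = no_panning())
  med <- tapply(sc$score, sc$mbg, median)
  expect_true(all(diff(med) > 0))
})
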