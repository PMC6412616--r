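# Shared reduced-scale simulation settings for cohort-level tests.
# Statistical invariants (grade recovery, type-I calibration, observer
# concordance) are scale-free, so they run on a 96 x 96 / 32-frame scene
# with all structures present; geometry-bound checks (kernel-size
# ordering at blush sigma 45) keep the full 256 x 256 default scene.

small_scene_params <- function(...) {
  defaults <- list(
    dims = c(96L, 96L), n_frames = 32L, blush_center = c(42, 64),
    blush_sigma_px = 15, vessel_width_px = c(3, 8), vessel_levels = 2L,
    roi_half_side_px = 18, noise_sigma = 2,
    panning_drift_px_per_frame = c(0, 0.2), seed = 1L)
  do.call(simulation_params, utils::modifyList(defaults, list(...)))
}

# blush-only moving scene for motion-correction consistency checks
blush_only_params <- function(...) {
  defaults <- list(
    dims = c(128L, 128L), n_frames = 40L, blush_center = c(64, 64),
    blush_sigma_px = 20, blush_amplitude = 40,
    vessels = FALSE, diaphragm = FALSE, catheter = FALSE,
    cardiac_translation_px = 6, cardiac_rotation_deg = 2,
    panning_drift_px_per_frame = c(0, 0), noise_sigma = 0,
    roi_half_side_px = 24, seed = 1L)
  do.call(simulation_params, utils::modifyList(defaults, list(...)))
}

no_panning <- function(...) blush_options(panning_correction = FALSE, ...)

# small integer-valued sequence for I/O round-trips
tiny_int_sequence <- function(n_frames = 3L, dims = c(12L, 10L), seed = 1L,
                              maxval = 65535L) {
  withr::with_seed(seed, {
    frames <- lapply(seq_len(n_frames), function(i) {
      matrix(as.double(sample(0:maxval, prod(dims), replace = TRUE)),
             dims[1L], dims[2L])
    })
  })
  frame_sequence(frames, frame_rate_hz = 12.5, id = "tiny")
}
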