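# Synthetic coronary-angiogram simulator.
#
# Emulates the scene a blush pipeline has to cope with: a bright field
# with a dark branching vessel tree whose opacification follows a
# contrast bolus, a soft diaphragm edge, a static catheter, and a
# mid-spatial-frequency blush region with gamma-variate kinetics, all
# rigid-motion-warped per frame (cardiac sinusoid plus linear panning
# drift) with additive Gaussian noise. Every run carries its ground
# truth: the true kinetics, per-frame motion, structure masks and the
# exact ROI track induced by the motion.

#' Gamma-variate bolus kinetics
#'
#' `h(t) = A ((t - t0)/tp)^alpha exp(alpha (1 - (t - t0)/tp))` for
#' `t > t0`, else 0. Normalized so that `h(t0 + tp) = A` exactly.
#'
#' @param t Time(s), seconds.
#' @param t0 Contrast arrival time, seconds.
#' @param tp Time to peak after arrival, seconds.
#' @param alpha Shape parameter (larger = narrower bolus).
#' @param amplitude Peak value `A`.
#' @return `h(t)`, same length as `t`.
#' @export
gamma_variate <- function(t, t0, tp, alpha, amplitude = 1) {
  x <- (t - t0) / tp
  out <- ifelse(t > t0, amplitude * x^alpha * exp(alpha * (1 - x)), 0)
  out[!is.finite(out)] <- 0
  out
}

#' Simulation parameters
#'
#' Defaults describe the reference study conditions: 256 x 256 frames at
#' 12.5 Hz for 60 frames (4.8 s), a blush blob of spatial scale 45 px,
#' gamma-variate blush kinetics arriving at 1 s and peaking 1.6 s later,
#' a 3-level random vessel tree opacified by an earlier, narrower bolus,
#' a soft diaphragm edge, a static catheter, cardiac motion with a 0.8 s
#' period (4 px translation, 1.5 degree rotation), a slow panning drift
#' of 0.3 px/frame, additive Gaussian noise (sigma 2 on a background of
#' 160), and a square reference ROI centred on the blush.
#'
#' @param dims Frame dimensions `c(rows, cols)`.
#' @param n_frames Number of frames.
#' @param frame_rate_hz Frame rate, Hz.
#' @param blush_center Blush centre, 0-based `c(row, col)`.
#' @param blush_sigma_px Spatial Gaussian scale of the blush, px.
#' @param blush_amplitude Peak blush contrast density `A` (>= 0).
#' @param t0_s,tp_s,alpha Blush kinetic parameters, see [gamma_variate()].
#' @param vessels Include the vessel tree.
#' @param vessel_amplitude Peak vessel contrast.
#' @param vessel_levels Branching depth of the random tree (2-4 typical).
#' @param vessel_width_px Range `c(min, max)` of branch half-thickness
#'   scales, px (root uses the max, distal branches taper towards the min).
#' @param vessel_t0_s,vessel_tp_s,vessel_alpha Vessel transit kinetics
#'   (unit peak).
#' @param vessel_custom Optional list of fixed branches, each a list with
#'   `p0`, `p1`, `p2` (quadratic Bezier control points, 0-based
#'   `c(row, col)`), `width`, and optional `amp_scale`; replaces the
#'   random tree.
#' @param diaphragm Include the diaphragm edge.
#' @param diaphragm_edge_row Row of the soft edge (0-based).
#' @param diaphragm_soft_px Soft-edge width, px.
#' @param diaphragm_amplitude Diaphragm darkening.
#' @param catheter Include the static catheter.
#' @param catheter_width_px Catheter half-thickness scale, px.
#' @param catheter_amplitude Catheter darkening.
#' @param cardiac_period_s Cardiac period, s.
#' @param cardiac_translation_px Cardiac translation amplitude, px.
#' @param cardiac_translation_dir Direction `c(row, col)` of the cardiac
#'   translation (normalized internally).
#' @param cardiac_rotation_deg Cardiac rotation amplitude about the image
#'   centre, degrees.
#' @param panning_drift_px_per_frame Linear panning drift `c(row, col)`,
#'   px per frame.
#' @param noise_sigma Additive Gaussian noise standard deviation.
#' @param background_level Bright-field intensity.
#' @param roi Reference [roi_polygon()]; default: a square of half-side
#'   `roi_half_side_px` centred on the blush.
#' @param roi_half_side_px Half-side of the default reference ROI, px.
#' @param quantize Round final frames to the integer grid (as a digital
#'   detector would); off by default so that numerical ground-truth
#'   comparisons are not limited by quantization.
#' @param seed Integer seed; identical parameters and seed give
#'   bit-identical output.
#' @return A list of class `simulation_params`.
#' @export
simulation_params <- function(dims = c(256L, 256L), n_frames = 60L,
                              frame_rate_hz = 12.5,
                              blush_center = c(110, 170),
                              blush_sigma_px = 45, blush_amplitude = 40,
                              t0_s = 1.0, tp_s = 1.6, alpha = 3,
                              vessels = TRUE, vessel_amplitude = 90,
                              vessel_levels = 3L, vessel_width_px = c(6, 16),
                              vessel_t0_s = 0.4, vessel_tp_s = 0.8,
                              vessel_alpha = 3, vessel_custom = NULL,
                              diaphragm = TRUE, diaphragm_edge_row = NULL,
                              diaphragm_soft_px = 8,
                              diaphragm_amplitude = 50,
                              catheter = TRUE, catheter_width_px = 2.5,
                              catheter_amplitude = 80,
                              cardiac_period_s = 0.8,
                              cardiac_translation_px = 4,
                              cardiac_translation_dir = c(0.8, 0.6),
                              cardiac_rotation_deg = 1.5,
                              panning_drift_px_per_frame = c(0, 0.3),
                              noise_sigma = 2, background_level = 160,
                              roi = NULL, roi_half_side_px = 45,
                              quantize = FALSE, seed = 1L) {
  dims <- c(check_count(dims[1L], "rows", 16L), check_count(dims[2L], "cols", 16L))
  n_frames <- check_count(n_frames, "n_frames", min = 2L)
  check_scalar_number(frame_rate_hz, "frame_rate_hz", min = 1e-6)
  check_scalar_number(blush_amplitude, "blush_amplitude", min = 0)
  check_scalar_number(blush_sigma_px, "blush_sigma_px", min = 1e-6)
  check_scalar_number(cardiac_period_s, "cardiac_period_s", min = 1e-6)
  check_scalar_number(noise_sigma, "noise_sigma", min = 0)
  check_scalar_number(vessel_amplitude, "vessel_amplitude", min = 0)
  check_scalar_number(diaphragm_amplitude, "diaphragm_amplitude", min = 0)
  check_scalar_number(catheter_amplitude, "catheter_amplitude", min = 0)
  if (blush_center[1L] < 0 || blush_center[1L] > dims[1L] - 1 ||
      blush_center[2L] < 0 || blush_center[2L] > dims[2L] - 1) {
    abort_content("blush centre outside the frame")
  }
  if (is.null(diaphragm_edge_row)) diaphragm_edge_row <- 0.76 * dims[1L]
  if (is.null(roi)) {
    h <- roi_half_side_px
    r0 <- blush_center[1L]; c0 <- blush_center[2L]
    roi <- roi_polygon(rbind(c(r0 - h, c0 - h), c(r0 - h, c0 + h),
                             c(r0 + h, c0 + h), c(r0 + h, c0 - h)))
  }
  p <- list(dims = dims, n_frames = n_frames, frame_rate_hz = frame_rate_hz,
            blush_center = blush_center, blush_sigma_px = blush_sigma_px,
            blush_amplitude = blush_amplitude,
            t0_s = t0_s, tp_s = tp_s, alpha = alpha,
            vessels = isTRUE(vessels), vessel_amplitude = vessel_amplitude,
            vessel_levels = check_count(vessel_levels, "vessel_levels", 1L),
            vessel_width_px = vessel_width_px, vessel_t0_s = vessel_t0_s,
            vessel_tp_s = vessel_tp_s, vessel_alpha = vessel_alpha,
            vessel_custom = vessel_custom,
            diaphragm = isTRUE(diaphragm),
            diaphragm_edge_row = diaphragm_edge_row,
            diaphragm_soft_px = diaphragm_soft_px,
            diaphragm_amplitude = diaphragm_amplitude,
            catheter = isTRUE(catheter),
            catheter_width_px = catheter_width_px,
            catheter_amplitude = catheter_amplitude,
            cardiac_period_s = cardiac_period_s,
            cardiac_translation_px = cardiac_translation_px,
            cardiac_translation_dir = cardiac_translation_dir,
            cardiac_rotation_deg = cardiac_rotation_deg,
            panning_drift_px_per_frame = panning_drift_px_per_frame,
            noise_sigma = noise_sigma, background_level = background_level,
            roi = roi, quantize = isTRUE(quantize),
            seed = check_count(seed, "seed"))
  structure(p, class = "simulation_params")
}

quad_bezier <- function(p0, p1, p2, n) {
  t <- seq(0, 1, length.out = n)
  cbind((1 - t)^2 * p0[1L] + 2 * t * (1 - t) * p1[1L] + t^2 * p2[1L],
        (1 - t)^2 * p0[2L] + 2 * t * (1 - t) * p1[2L] + t^2 * p2[2L])
}

# Max-composited Gaussian splats along a polyline: a tube of half-width
# scale `sigma` without double-counting where splats overlap.
splat_curve <- function(map, pts, sigma, amp) {
  nr <- nrow(map); nc <- ncol(map)
  w <- ceiling(3 * sigma)
  for (k in seq_len(nrow(pts))) {
    r <- pts[k, 1L]; c <- pts[k, 2L]
    rlo <- max(0, round(r) - w); rhi <- min(nr - 1, round(r) + w)
    clo <- max(0, round(c) - w); chi <- min(nc - 1, round(c) + w)
    if (rlo > rhi || clo > chi) next
    rs <- rlo:rhi
    cs <- clo:chi
    d2 <- outer((rs - r)^2, (cs - c)^2, "+")
    sub <- amp * exp(-d2 / (2 * sigma^2))
    map[rs + 1L, cs + 1L] <- pmax(map[rs + 1L, cs + 1L], sub)
  }
  map
}

dirvec <- function(a) c(cos(a), sin(a))  # (row, col); a = 0 points down

# Random 2-4 level quadratic-Bezier vessel tree. Returns the contrast
# map (unit transit), plus branch polylines and bifurcation points.
gen_vessel_tree <- function(params) {
  dims <- params$dims
  map <- matrix(0, dims[1L], dims[2L])
  branches <- list()
  bifurcations <- list()
  wmax <- max(params$vessel_width_px)
  wmin <- min(params$vessel_width_px)
  if (!is.null(params$vessel_custom)) {
    for (b in params$vessel_custom) {
      len <- sqrt(sum((b$p2 - b$p0)^2))
      pts <- quad_bezier(b$p0, b$p1, b$p2, max(8L, ceiling(len)))
      amp <- params$vessel_amplitude * (b$amp_scale %||% 1)
      map <- splat_curve(map, pts, b$width / 2, amp)
      branches[[length(branches) + 1L]] <- list(points = pts, width = b$width)
    }
    # children sharing a start point mark a bifurcation
    starts <- t(vapply(params$vessel_custom, function(b) b$p0, numeric(2)))
    dup <- duplicated(round(starts, 3))
    if (any(dup)) bifurcations <- lapply(which(dup), function(i) starts[i, ])
    return(list(map = map, branches = branches,
                bifurcations = do.call(rbind, bifurcations)))
  }
  recurse <- function(start, angle, len, width, level) {
    ang <- angle + rnorm(1, 0, 0.08)
    d <- dirvec(ang)
    perp <- c(-d[2L], d[1L])
    ctrl <- start + d * len * 0.5 + perp * rnorm(1, 0, 0.12 * len)
    end <- start + d * len
    pts <- quad_bezier(start, ctrl, end, max(8L, ceiling(len)))
    amp <- params$vessel_amplitude * (0.6 + 0.4 * width / wmax)
    map <<- splat_curve(map, pts, width / 2, amp)
    branches[[length(branches) + 1L]] <<- list(points = pts, width = width)
    if (level < params$vessel_levels) {
      bifurcations[[length(bifurcations) + 1L]] <<- end
      spread <- runif(1, 0.3, 0.6)
      w_child <- max(wmin, width * 0.7)
      recurse(end, ang - spread, len * 0.72, w_child, level + 1L)
      recurse(end, ang + spread, len * 0.72, w_child, level + 1L)
    }
  }
  recurse(start = c(0.04 * dims[1L], 0.12 * dims[2L]),
          angle = 0.25, len = 0.5 * min(dims), width = wmax, level = 1L)
  list(map = map, branches = branches,
       bifurcations = if (length(bifurcations)) do.call(rbind, bifurcations))
}

#' Simulate a synthetic angiogram run
#'
#' Frames are composited in a reference pose as
#' `background - vessels * g(t) - diaphragm - catheter - blush * h(t)`
#' (dark structures on a bright field, raw angiogram polarity), clipped
#' at zero, warped by the frame's rigid motion (bilinear interpolation,
#' edge replication), and Gaussian noise is added. Deterministic given
#' `params$seed`.
#'
#' @param params A [simulation_params()] object.
#' @return A list with elements `sequence` (a [frame_sequence()]) and
#'   `ground_truth` (class `synthetic_ground_truth`: `true_curve`,
#'   `motion` tibble with per-frame `d_row`, `d_col`, `theta_deg`,
#'   `structure_masks`, `roi_track_truth`, `bifurcations`, `params`).
#' @export
simulate_sequence <- function(params = simulation_params()) {
  stopifnot(inherits(params, "simulation_params"))
  withr::with_seed(params$seed, simulate_sequence_impl(params))
}

simulate_sequence_impl <- function(params) {
  dims <- params$dims
  nr <- dims[1L]; nc <- dims[2L]
  nfr <- params$n_frames
  rr <- matrix(0:(nr - 1L), nr, nc)
  cc <- matrix(0:(nc - 1L), nr, nc, byrow = TRUE)

  blush_map <- exp(-((rr - params$blush_center[1L])^2 +
                       (cc - params$blush_center[2L])^2) /
                     (2 * params$blush_sigma_px^2))
  tree <- NULL
  vessel_map <- matrix(0, nr, nc)
  if (params$vessels) {
    tree <- gen_vessel_tree(params)
    vessel_map <- tree$map
  }
  dia_map <- matrix(0, nr, nc)
  if (params$diaphragm) {
    dia_map <- params$diaphragm_amplitude /
      (1 + exp(-(rr - params$diaphragm_edge_row) / params$diaphragm_soft_px))
  }
  cath_map <- matrix(0, nr, nc)
  if (params$catheter) {
    pts <- quad_bezier(c(0, 0.07 * nc), c(0.5 * nr, 0.02 * nc),
                       c(nr - 1, 0.1 * nc), max(16L, nr))
    cath_map <- splat_curve(cath_map, pts, params$catheter_width_px / 2,
                            params$catheter_amplitude)
  }

  times <- (seq_len(nfr) - 1L) / params$frame_rate_hz
  h <- gamma_variate(times, params$t0_s, params$tp_s, params$alpha,
                     params$blush_amplitude)
  g <- gamma_variate(times, params$vessel_t0_s, params$vessel_tp_s,
                     params$vessel_alpha, 1)

  phase <- 2 * pi * times / params$cardiac_period_s
  dirn <- params$cardiac_translation_dir
  dirn <- dirn / sqrt(sum(dirn^2))
  drift <- params$panning_drift_px_per_frame
  d_row <- params$cardiac_translation_px * dirn[1L] * sin(phase) +
    drift[1L] * (seq_len(nfr) - 1L)
  d_col <- params$cardiac_translation_px * dirn[2L] * sin(phase) +
    drift[2L] * (seq_len(nfr) - 1L)
  theta <- params$cardiac_rotation_deg * pi / 180 * sin(phase)
  ctr <- (dims - 1) / 2

  no_motion <- all(abs(d_row) < 1e-12) && all(abs(d_col) < 1e-12) &&
    all(abs(theta) < 1e-12)
  frames <- vector("list", nfr)
  for (i in seq_len(nfr)) {
    scene <- params$background_level - vessel_map * g[i] - dia_map -
      cath_map - blush_map * h[i]
    scene <- pmax(scene, 0)
    fr <- if (no_motion) scene else {
      warp_rigid_cpp(scene, theta[i], d_row[i], d_col[i], ctr[1L], ctr[2L])
    }
    if (params$noise_sigma > 0) {
      fr <- fr + matrix(rnorm(nr * nc, 0, params$noise_sigma), nr, nc)
    }
    fr <- pmax(fr, 0)
    if (params$quantize) fr <- pmin(round(fr), 65535)
    frames[[i]] <- fr
  }

  rot <- function(v, th) {
    c(cos(th) * v[1L] - sin(th) * v[2L], sin(th) * v[1L] + cos(th) * v[2L])
  }
  track <- roi_track(lapply(seq_len(nfr), function(i) {
    v <- params$roi$vertices
    vt <- t(apply(v, 1L, function(p) rot(p - ctr, theta[i]) + ctr +
                    c(d_row[i], d_col[i])))
    roi_polygon(vt)
  }))

  thr <- 0.05
  gt <- structure(list(
    true_curve = blush_curve(h, frame_rate_hz = params$frame_rate_hz),
    motion = tibble(frame = seq_len(nfr) - 1L, time_s = times,
                    d_row = d_row, d_col = d_col,
                    theta_deg = theta * 180 / pi),
    structure_masks = list(
      vessels = vessel_map > thr * max(params$vessel_amplitude, 1e-12),
      diaphragm = dia_map > thr * max(params$diaphragm_amplitude, 1e-12),
      catheter = cath_map > thr * max(params$catheter_amplitude, 1e-12)),
    roi_track_truth = track,
    bifurcations = tree$bifurcations,
    params = params
  ), class = "synthetic_ground_truth")

  list(sequence = frame_sequence(frames,
                                 frame_rate_hz = params$frame_rate_hz,
                                 id = sprintf("sim_seed%d", params$seed)),
       ground_truth = gt)
}

#' True blush kinetics of a simulated run
#'
#' @param gt A `synthetic_ground_truth` object.
#' @return The ground-truth [blush_curve()] (`h` sampled at frame times).
#' @export
true_blush_curve <- function(gt) {
  stopifnot(inherits(gt, "synthetic_ground_truth"))
  gt$true_curve
}

derive_seed <- function(master, i) {
  as.integer((as.double(master) %% 2147483647 * 48271 + i * 16807) %% 2147483647)
}

#' Generate a synthetic patient cohort with MBG grades
#'
#' Each patient gets an MBG grade in 0-3 and a simulated run whose blush
#' amplitude either tracks the grade (`associated` mode: per-grade base
#' amplitudes with multiplicative log-normal jitter) or is drawn from one
#' distribution regardless of grade (`null` mode, for type-I calibration).
#' Per-patient seeds are derived deterministically from `seed`.
#'
#' @param n_per_grade Patients per MBG grade (cohort size is 4x this).
#' @param mode `"associated"` or `"null"`.
#' @param base_params A [simulation_params()] object used for every
#'   patient (its `blush_amplitude` is replaced per patient).
#' @param seed Master integer seed.
#' @param grade_amplitudes Base blush amplitude per grade 0-3
#'   (non-decreasing).
#' @param amplitude_jitter_sd Log-scale SD of the per-patient jitter in
#'   associated mode.
#' @return A list of class `synthetic_cohort` with elements `patients`
#'   (each: `id`, `mbg`, `amplitude`, `sequence`, `ground_truth`),
#'   `grade_amplitudes`, `mode`, `seed`.
#' @export
make_cohort <- function(n_per_grade = 10L,
                        mode = c("associated", "null"),
                        base_params = simulation_params(), seed = 1L,
                        grade_amplitudes = c(0, 20, 40, 60),
                        amplitude_jitter_sd = 0.15) {
  mode <- match.arg(mode)
  n_per_grade <- check_count(n_per_grade, "n_per_grade", min = 1L)
  if (is.unsorted(grade_amplitudes)) {
    abort_content("`grade_amplitudes` must be non-decreasing in grade")
  }
  grades <- rep(0:3, each = n_per_grade)
  patients <- vector("list", length(grades))
  for (idx in seq_along(grades)) {
    g <- grades[idx]
    amp <- withr::with_seed(derive_seed(seed, 2L * idx), {
      if (mode == "associated") {
        grade_amplitudes[g + 1L] * rlnorm(1, 0, amplitude_jitter_sd)
      } else {
        runif(1, min(grade_amplitudes), max(grade_amplitudes))
      }
    })
    p <- base_params
    p$blush_amplitude <- amp
    p$seed <- derive_seed(seed, 2L * idx + 1L)
    sim <- simulate_sequence(p)
    patients[[idx]] <- list(id = sprintf("P%03d", idx), mbg = g,
                            amplitude = amp, sequence = sim$sequence,
                            ground_truth = sim$ground_truth)
  }
  structure(list(patients = patients, grade_amplitudes = grade_amplitudes,
                 mode = mode, base_params = base_params, seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort: %d patients (%s mode, seed %d)>\n",
              length(x$patients), x$mode, x$seed))
  invisible(x)
}

#' Jitter an ROI track (synthetic observer variability)
#'
#' Adds independent Gaussian noise to every vertex of every polygon,
#' emulating an observer re-drawing the ROI on each frame.
#'
#' @param track An [roi_track()].
#' @param sigma_px Vertex jitter SD, px.
#' @param seed Integer seed.
#' @return The jittered [roi_track()].
#' @export
jitter_track <- function(track, sigma_px = 1, seed = 1L) {
  stopifnot(inherits(track, "roi_track"))
  withr::with_seed(seed, {
    roi_track(lapply(track$polygons, function(p) {
      v <- p$vertices
      v + matrix(rnorm(length(v), 0, sigma_px), nrow(v), ncol(v))
    }))
  })
}

#' Near-bifurcation motion scenario
#'
#' Builds a run whose fixed reference ROI sits adjacent to (but does not
#' contain) a vessel bifurcation, with cardiac motion strong enough to
#' swing the bifurcation's edge-artifact cluster in and out of the fixed
#' ROI, while the ground-truth ROI track keeps following the same
#' myocardium. This is the mechanism by which cardiac motion corrupts a
#' fixed-ROI blush curve with spikes and dips.
#'
#' @param seed Integer seed (noise realization).
#' @param noise_sigma Additive noise SD.
#' @return As [simulate_sequence()], plus element `roi` (the fixed
#'   reference ROI).
#' @export
bifurcation_scenario <- function(seed = 1L, noise_sigma = 1.5) {
  # ROI spans rows 66-126, cols 38-98; the bifurcation sits 10 px beyond
  # the ROI's right edge and every branch keeps clear of the tracked ROI,
  # so only the fixed ROI sees the bifurcation swing in at cardiac
  # extremes (translation amplitude 12 px along the column axis).
  q <- c(96, 108)
  branches <- list(
    list(p0 = c(10, 100), p1 = c(45, 115), p2 = q, width = 4),
    list(p0 = q, p1 = c(135, 112), p2 = c(170, 124), width = 3),
    list(p0 = q, p1 = c(120, 142), p2 = c(150, 168), width = 3)
  )
  params <- simulation_params(
    dims = c(192L, 192L), n_frames = 60L,
    blush_center = c(96, 68), blush_sigma_px = 30, blush_amplitude = 30,
    vessel_custom = branches, vessel_amplitude = 120,
    diaphragm_edge_row = 165,
    cardiac_translation_px = 12, cardiac_translation_dir = c(0, 1),
    cardiac_rotation_deg = 2, panning_drift_px_per_frame = c(0, 0),
    noise_sigma = noise_sigma, roi_half_side_px = 30, seed = seed)
  sim <- simulate_sequence(params)
  c(sim, list(roi = params$roi))
}
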