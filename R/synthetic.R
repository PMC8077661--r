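#' Synthetic psychometric observer
#'
#' A stand-in for the animal: per channel, an inverted-U contrast
#' sensitivity function (log-parabola in log frequency) sets the threshold
#' contrast at each spatial frequency, and responses are Bernoulli draws
#' from a logistic psychometric function of log contrast about that
#' threshold.
#'
#' The default intensity-channel curve peaks at 0.07 cycles/deg with a
#' threshold of 0.11 Michelson — the most sensitive operating point
#' measured behaviourally in shore crabs — and the polarization channel is
#' blind (infinite threshold), matching the headline finding that
#' polarization-only gratings drive no gaze stabilization.
#'
#' @param peak_freq Frequency of maximum sensitivity, cycles/deg.
#' @param peak_threshold Threshold contrast at `peak_freq` (Michelson).
#' @param bandwidth Width of the log-parabola in log10-frequency units.
#' @param slope Psychometric slope per log10 unit of contrast; the default
#'   is steep, emulating the effectively all-or-none scored responses.
#' @param guess Lower asymptote (spontaneous false-positive rate).
#' @param lapse Lapse rate (1 - upper asymptote).
#' @param polarization_threshold Threshold curve scale for the
#'   polarization channel: `Inf` for a polarization-blind observer
#'   (default), or a finite peak threshold to give the channel the same
#'   inverted-U shape.
#' @param loom_response If `TRUE`, the observer responds to looming stimuli
#'   in either channel regardless of the grating thresholds — the
#'   dissociation between object-motion and wide-field stabilization
#'   pathways.
#' @return An object of class `synthetic_observer`.
#' @export
synthetic_observer <- function(peak_freq = 0.07, peak_threshold = 0.11,
                               bandwidth = 0.8, slope = 20,
                               guess = 0, lapse = 0,
                               polarization_threshold = Inf,
                               loom_response = TRUE) {
  stopifnot(peak_freq > 0, peak_threshold > 0, bandwidth > 0, slope > 0,
            guess >= 0, guess < 1, lapse >= 0, lapse < 1)
  structure(
    list(peak_freq = peak_freq, peak_threshold = peak_threshold,
         bandwidth = bandwidth, slope = slope, guess = guess, lapse = lapse,
         polarization_threshold = polarization_threshold,
         loom_response = isTRUE(loom_response)),
    class = "synthetic_observer"
  )
}

#' Threshold contrast of a synthetic observer
#'
#' The inverted-U curve: `log10(threshold(f)) = log10(peak_threshold) +
#' ((log10 f - log10 peak_freq) / bandwidth)^2`; thresholds rise away from
#' the peak frequency. A blind channel returns `Inf`.
#'
#' @param obs A [synthetic_observer()].
#' @param freq Spatial frequency, cycles/deg (vectorized).
#' @param channel `"intensity"` or `"polarization"`.
#' @return Threshold contrast (may exceed 1 far from the peak, meaning no
#'   attainable contrast elicits a response there).
#' @export
observer_threshold <- function(obs, freq, channel = "intensity") {
  stopifnot(inherits(obs, "synthetic_observer"))
  peak <- switch(channel,
                 intensity = obs$peak_threshold,
                 polarization = obs$polarization_threshold,
                 stop_polardrum("unknown channel", "invalid_spec"))
  if (!is.finite(peak)) return(rep(Inf, length(freq)))
  10^(log10(peak) + ((log10(freq) - log10(obs$peak_freq)) / obs$bandwidth)^2)
}

#' Draw a response from a synthetic observer
#'
#' @inheritParams observer_threshold
#' @param contrast Stimulus contrast in `(0, 1]`.
#' @param seed Optional seed making the draw reproducible in isolation.
#' @return Logical response (vectorized over `contrast`/`freq`).
#' @export
observer_respond <- function(obs, freq, contrast, channel = "intensity",
                             seed = NULL) {
  n <- max(length(freq), length(contrast))
  th <- rep_len(observer_threshold(obs, freq, channel), n)
  contrast <- rep_len(contrast, n)
  p <- rep(obs$guess, n)
  fin <- is.finite(th)
  p[fin] <- obs$guess + (1 - obs$guess - obs$lapse) *
    stats::plogis(obs$slope * (log10(contrast[fin]) - log10(th[fin])))
  with_seed(seed, stats::runif(n) < p)
}

#' Wrap a synthetic observer as a staircase response function
#'
#' @param obs A [synthetic_observer()].
#' @return A function `f(freq, contrast, channel)` suitable for
#'   [run_staircase()]; draws use the ambient RNG stream, so seeding the
#'   staircase seeds the observer.
#' @export
as_observer_fn <- function(obs) {
  force(obs)
  function(freq, contrast, channel) observer_respond(obs, freq, contrast, channel)
}

#' Generate a synthetic nystagmus trace
#'
#' A piecewise eye-angle trace: slow tracking at `gain * stim_speed` until
#' the excursion reaches the saccade amplitude, then a reset opposite to
#' the stimulus completed within one sample, plus additive Gaussian noise.
#' Ground-truth phase labels are returned beside the trace.
#'
#' @param gain Tracking gain (slow-phase eye speed / stimulus speed), >= 0.
#' @param stim_speed Signed stimulus speed, deg/s.
#' @param duration Trace duration, s.
#' @param sample_rate Sampling rate, Hz.
#' @param saccade_amplitude Excursion at which a resetting saccade fires,
#'   deg.
#' @param noise_sd Gaussian angle noise s.d., deg.
#' @param seed Optional seed.
#' @return A list with `trace` (an [eye_trace()], source `"synthetic"`),
#'   `labels` (per-sample ground truth: `slow_phase`, `saccade` or
#'   `quiescent`) and the generating parameters.
#' @export
make_nystagmus_trace <- function(gain = 1, stim_speed = 6, duration = 30,
                                 sample_rate = 25, saccade_amplitude = 10,
                                 noise_sd = 0, seed = NULL) {
  stopifnot(gain >= 0, noise_sd >= 0, duration > 0, sample_rate > 0)
  t <- seq(0, duration, by = 1 / sample_rate)
  slope <- gain * stim_speed
  if (slope == 0) {
    base <- rep(0, length(t))
    labels <- rep("quiescent", length(t))
  } else {
    adv <- abs(slope) * t
    wraps <- floor(adv / saccade_amplitude)
    base <- sign(slope) * (adv - saccade_amplitude * wraps)
    labels <- ifelse(c(0, diff(wraps)) > 0, "saccade", "slow_phase")
  }
  noise <- with_seed(seed, stats::rnorm(length(t), sd = noise_sd))
  list(
    trace = eye_trace(t, base + noise, sample_rate, source = "synthetic"),
    labels = labels,
    params = list(gain = gain, stim_speed = stim_speed,
                  saccade_amplitude = saccade_amplitude,
                  noise_sd = noise_sd, seed = seed)
  )
}

#' Render a synthetic marker video
#'
#' Draws Gaussian bright spots at given trajectory positions on a dark
#' background with additive Gaussian noise — an idealized dorsal view of
#' paint markers on a carapace. The ground-truth trajectory is returned
#' beside the frames.
#'
#' @param trajectory A tibble with columns `frame`, `marker`, `x`, `y`
#'   (px; pixel (r, c) has centre (x = c, y = r)).
#' @param frame_size `c(height, width)` in px.
#' @param spot_sigma Gaussian spot s.d., px.
#' @param spot_amplitude Peak spot intensity above background.
#' @param background Background level.
#' @param noise_sd Additive Gaussian noise s.d.
#' @param occlusion Optional tibble `frame`, `marker` of spots to omit
#'   (simulated dropouts).
#' @param seed Optional seed.
#' @return A list with `frames` (list of matrices, values clipped to
#'   `[0, 255]`) and `truth` (the trajectory with an `occluded` flag and a
#'   `clipped` flag for positions outside the frame).
#' @export
make_marker_video <- function(trajectory, frame_size = c(120, 160),
                              spot_sigma = 2.5, spot_amplitude = 200,
                              background = 20, noise_sd = 0,
                              occlusion = NULL, seed = NULL) {
  traj <- tibble::as_tibble(trajectory)
  h <- frame_size[1]; w <- frame_size[2]
  traj$clipped <- traj$x < 1 | traj$x > w | traj$y < 1 | traj$y > h
  if (any(traj$clipped))
    warning("trajectory leaves the frame; positions flagged as clipped")
  traj$occluded <- FALSE
  if (!is.null(occlusion)) {
    key <- paste(traj$frame, traj$marker)
    traj$occluded <- key %in% paste(occlusion$frame, occlusion$marker)
  }
  xs <- matrix(rep(seq_len(w), each = h), h, w)
  ys <- matrix(rep(seq_len(h), times = w), h, w)
  n_frames <- max(traj$frame)
  frames <- with_seed(seed, lapply(seq_len(n_frames), function(f) {
    img <- matrix(background, h, w)
    rows <- traj[traj$frame == f & !traj$occluded, , drop = FALSE]
    for (i in seq_len(nrow(rows))) {
      img <- img + spot_amplitude *
        exp(-((xs - rows$x[i])^2 + (ys - rows$y[i])^2) / (2 * spot_sigma^2))
    }
    if (noise_sd > 0) img <- img + stats::rnorm(h * w, sd = noise_sd)
    pmax(pmin(img, 255), 0)
  }))
  list(frames = frames, truth = traj)
}

#' Forward-model a polarimetric image stack
#'
#' Applies Malus's law to ground-truth intensity/DoP/AoP maps to produce
#' the four polarizer-angle images `I_phi = I * ((1 - d)/2 +
#' d * cos^2(aop - phi))` for `phi` in 0, 45, 90, 135 degrees, optionally
#' with additive Gaussian noise. [stokes_from_stack()] inverts the
#' noiseless stack exactly.
#'
#' @param intensity,dop,aop Numeric matrices (or vectors) of identical
#'   shape: relative intensity (>= 0), degree of polarization in `[0, 1]`,
#'   angle of polarization in degrees.
#' @param noise_sd Additive Gaussian noise s.d.
#' @param seed Optional seed.
#' @return A named list `i0`, `i45`, `i90`, `i135`.
#' @export
make_polarimetric_stack <- function(intensity, dop, aop, noise_sd = 0,
                                    seed = NULL) {
  if (any(dop < 0 | dop > 1))
    stop_polardrum("ground-truth DoP must lie in [0, 1]", "validation_error")
  if (any(intensity < 0))
    stop_polardrum("ground-truth intensity must be >= 0", "validation_error")
  angles <- c(i0 = 0, i45 = 45, i90 = 90, i135 = 135)
  with_seed(seed, lapply(angles, function(phi) {
    img <- intensity * ((1 - dop) / 2 + dop * cos(deg2rad(aop - phi))^2)
    if (noise_sd > 0) img <- img + stats::rnorm(length(img), sd = noise_sd)
    img
  }))
}

#' Simulate a cohort of observers through the staircase pipeline
#'
#' Convenience closed loop: builds `n_subjects` copies of a synthetic
#' observer (optionally jittering the peak threshold across individuals),
#' runs the full per-frequency staircase for each, and assembles the
#' cohort CSF.
#'
#' @param n_subjects Number of individuals.
#' @param observer A template [synthetic_observer()].
#' @param freqs Spatial frequencies tested, cycles/deg.
#' @param channel Stimulus channel.
#' @param params [staircase_params()].
#' @param threshold_jitter_sd Across-individual s.d. of the peak threshold
#'   on the log10 scale (0 = identical observers).
#' @param seed Integer seed.
#' @return A [assemble_csf()] `csf_curve`.
#' @export
simulate_cohort_csf <- function(n_subjects = 9, observer = synthetic_observer(),
                                freqs = seq(0.02, 0.2, by = 0.02),
                                channel = "intensity",
                                params = staircase_params(),
                                threshold_jitter_sd = 0, seed = 1L) {
  jit <- with_seed(seed, stats::rnorm(n_subjects, sd = threshold_jitter_sd))
  thresholds <- purrr::map_dfr(seq_len(n_subjects), function(s) {
    obs_s <- observer
    obs_s$peak_threshold <- 10^(log10(observer$peak_threshold) + jit[s])
    csf_thresholds(as_observer_fn(obs_s), freqs = freqs, channel = channel,
                   subject = sprintf("s%02d", s), params = params,
                   seed = seed * 1000L + s)
  })
  assemble_csf(thresholds)
}
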