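test_that("marker detection hits known centres to sub-pixel accuracy", {
  traj <- tibble::tibble(frame = 1, marker = 1:2,
                         x = c(40.3, 110.7), y = c(60.2, 35.9))
  vid <- make_marker_video(traj, frame_size = c(120, 160), noise_sd = 2,
                           seed = 14)
  det <- detect_markers(vid$frames[[1]], n_markers = 2)
  expect_true(all(det$found))
  err <- sqrt((det$x - traj$x)^2 + (det$y - traj$y)^2)
  expect_lt(max(err), 0.5)
})

test_that("blank frames flag a dropout instead of failing", {
  det <- detect_markers(matrix(10, 50, 50), n_markers = 2)
  expect_true(all(!det$found))
  set.seed(2)
  noisy <- matrix(stats::rnorm(2500, 10, 2), 50, 50)
  det2 <- detect_markers(noisy, n_markers = 2)
  expect_true(all(!det2$found))
})

test_that("sub-area speckles are rejected by the area filter", {
  traj <- tibble::tibble(frame = 1, marker = 1:2,
                         x = c(30, 100), y = c(40, 80))
  vid <- make_marker_video(traj, frame_size = c(120, 160), seed = 1)
  img <- vid$frames[[1]]
  img[10, 10] <- 255   # single-pixel speckle
  det <- detect_markers(img, n_markers = 2, min_area = 4)
  expect_true(all(det$found))
  err <- sqrt((det$x - traj$x)^2 + (det$y - traj$y)^2)
  expect_lt(max(err), 0.5)
})

test_that("rigidly rotating markers produce a trace at the rotation speed", {
  # 6 deg/s at 25 fps = 0.24 deg/frame
  traj <- rigid_rotation_trajectory(100, omega_deg_per_frame = 0.24)
  vid <- make_marker_video(traj, frame_size = c(120, 160), seed = 8)
  obs <- track_markers(vid$frames, n_markers = 2)
  trace <- trace_from_markers(obs, sample_rate = 25)
  slope <- stats::coef(stats::lm(angle ~ time, data = trace))[[2]]
  expect_equal(slope, 6, tolerance = 0.1)
})

test_that("stationary markers give a constant trace", {
  traj <- rigid_rotation_trajectory(30, omega_deg_per_frame = 0)
  vid <- make_marker_video(traj, seed = 4)
  obs <- track_markers(vid$frames, n_markers = 2)
  trace <- trace_from_markers(obs, sample_rate = 25)
  expect_lt(diff(range(trace$angle)), 0.2)
})

test_that("short dropouts are interpolated and flagged, all-dropout errors", {
  traj <- rigid_rotation_trajectory(60, omega_deg_per_frame = 0.24)
  occl <- tidyr::expand_grid(frame = 30:32, marker = 1:2)
  vid <- make_marker_video(traj, occlusion = occl, seed = 5)
  obs <- track_markers(vid$frames, n_markers = 2)
  trace <- trace_from_markers(obs, sample_rate = 25, gap_limit = 5)
  expect_true(any(trace$interpolated))
  gap_times <- (30:32 - 1) / 25
  expect_true(all(gap_times %in% trace$time))
  # interpolated values lie on the rigid rotation
  idx <- trace$time %in% gap_times
  fit <- stats::lm(angle ~ time, data = trace[!idx, ])
  pred <- stats::predict(fit, newdata = trace[idx, ])
  expect_lt(max(abs(trace$angle[idx] - pred)), 0.5)

  all_out <- dplyr::mutate(obs, found = FALSE, x = NA_real_, y = NA_real_)
  expect_error(trace_from_markers(all_out), class = "polardrum_error")
})

test_that("an ideal sawtooth segments into alternating slow phases and saccades", {
  syn <- make_nystagmus_trace(gain = 1, stim_speed = 6, duration = 30,
                              noise_sd = 0)
  seg <- segment_nystagmus(syn$trace, stim_speed = 6)
  labs <- seg$intervals$label
  expect_true(all(c("slow_phase", "saccade") %in% labs))
  expect_false("quiescent" %in% labs)
  # strictly alternating
  expect_true(all(labs[-1] != labs[-length(labs)]))
  expect_equal(mean(seg$intervals$gain, na.rm = TRUE), 1, tolerance = 0.05)
  expect_true(classify_okr(seg))
})

test_that("segmentation intervals exactly partition the trace", {
  syn <- make_nystagmus_trace(gain = 0.5, noise_sd = 1, seed = 31)
  seg <- segment_nystagmus(syn$trace, stim_speed = 6)
  iv <- seg$intervals
  expect_equal(iv$start_idx[1], 1L)
  expect_equal(iv$end_idx[nrow(iv)], nrow(syn$trace))
  expect_true(all(iv$start_idx[-1] == iv$end_idx[-nrow(iv)] + 1L))
  expect_equal(nrow(seg$samples), nrow(syn$trace))
})

test_that("a flat trace is entirely quiescent and scores negative", {
  syn <- make_nystagmus_trace(gain = 0, noise_sd = 0.2, seed = 6)
  seg <- segment_nystagmus(syn$trace, stim_speed = 6)
  expect_true(all(seg$intervals$label == "quiescent"))
  expect_false(classify_okr(seg))
})

test_that("slow-phase gain is recovered across the physiological range", {
  for (g in c(0.25, 0.5, 1.0)) {
    syn <- make_nystagmus_trace(gain = g, stim_speed = 6, duration = 60,
                                noise_sd = 1, seed = 100 + round(100 * g))
    seg <- segment_nystagmus(syn$trace, stim_speed = 6)
    got <- mean(seg$intervals$gain, na.rm = TRUE)
    expect_lt(abs(got - g), 0.1)
    # saccade recall: each ground-truth reset matched by a detected saccade
    truth_times <- syn$trace$time[syn$labels == "saccade"]
    det <- seg$intervals[seg$intervals$label == "saccade", ]
    recall <- mean(vapply(truth_times, function(tt)
      any(tt >= det$start - 0.2 & tt <= det$end + 0.2), logical(1)))
    expect_gte(recall, 0.9)
    # frame-level agreement with ground truth labels
    agree <- mean(seg$samples$label == syn$labels)
    expect_gte(agree, 0.9)
  }
})

test_that("okr classification honours its closed thresholds", {
  # borderline synthetic segmentation: exactly f_min slow fraction, n_min saccades
  tr <- make_nystagmus_trace(gain = 1, stim_speed = 6, duration = 30,
                             noise_sd = 0)
  seg <- segment_nystagmus(tr$trace, stim_speed = 6)
  p_exact <- okr_params(f_min = glance(seg)$slow_fraction,
                        n_min = sum(seg$intervals$label == "saccade"))
  expect_true(classify_okr(seg, p_exact))
  p_over <- okr_params(n_min = sum(seg$intervals$label == "saccade") + 1L)
  expect_false(classify_okr(seg, p_over))
})

test_that("omr scoring enforces the full-circuit two-reversal rule", {
  sched <- build_protocol("omr", list(phase_duration_s = 100, direction = "ccw"))
  t <- seq(0, 299.9, by = 0.1)
  compliant <- ifelse(t < 100, 4 * t,
                      ifelse(t < 200, 400 - 4 * (t - 100), 4 * (t - 200)))
  h <- eye_trace(t, compliant, sample_rate = 10)
  expect_true(score_omr(h, sched))

  # ignores the first reversal
  ignorer <- eye_trace(t, 4 * t, sample_rate = 10)
  expect_false(score_omr(ignorer, sched))

  # completes only 350 deg in phase 1
  slow <- ifelse(t < 100, 3.5 * t,
                 ifelse(t < 200, 350 - 4 * (t - 100), 4 * (t - 200)))
  expect_false(score_omr(eye_trace(t, slow, sample_rate = 10), sched))

  # invariant to uniform heading noise below 5 deg
  set.seed(12)
  noisy <- compliant + stats::runif(length(t), -5, 5)
  expect_true(score_omr(eye_trace(t, noisy, sample_rate = 10), sched))

  expect_error(score_omr(h, sched[1:2, ]), class = "polardrum_error")
})

test_that("response probabilities match hand-computed contingency tables", {
  rec <- tibble::tibble(
    subject = rep(c("a", "b", "c", "d"), each = 4),
    channel = rep(c("intensity", "polarization"), times = 8),
    freq_cpd = 0.05,
    response = c(TRUE, FALSE, TRUE, FALSE,
                 TRUE, FALSE, FALSE, FALSE,
                 TRUE, FALSE, TRUE, FALSE,
                 FALSE, FALSE, TRUE, FALSE)
  )
  tab <- response_probability(rec, channel)
  int <- tab[tab$channel == "intensity", ]
  pol <- tab[tab$channel == "polarization", ]
  # intensity: a 2/2, b 1/2, c 2/2, d 1/2 -> pooled 6/8, mean 0.75
  expect_equal(int$n_pos, 6)
  expect_equal(int$prob, 0.75)
  expect_equal(int$mean_prob, 0.75)
  expect_equal(int$sem, stats::sd(c(1, 0.5, 1, 0.5)) / 2)
  # polarization: all negative
  expect_equal(pol$prob, 0)
  expect_equal(pol$sem, 0)
  # 3 of 4 positive
  one <- response_probability(
    tibble::tibble(subject = letters[1:4], response = c(TRUE, TRUE, TRUE, FALSE)))
  expect_equal(one$prob, 0.75)
})
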