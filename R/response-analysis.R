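#' Detect bright markers in a grayscale frame
#'
#' Threshold, connected components, area filter, then intensity-weighted
#' centroids of the `n_markers` brightest blobs, sorted by a stable spatial
#' key (increasing x, then y). Used to track the white paint markers on a
#' crab's dorsal carapace.
#'
#' @param frame Numeric matrix (rows = y, cols = x; values on any scale).
#' @param n_markers Expected number of markers.
#' @param threshold Absolute intensity threshold; by default adaptive at
#'   four standard deviations above the frame mean, which keeps blank or
#'   pure-noise frames from yielding spurious blobs.
#' @param min_area Minimum blob area in px; smaller speckles are rejected.
#' @return A tibble with one row per expected marker: `marker`, `x`, `y`
#'   (centroid, px; pixel (r, c) has centre (x = c, y = r)), `area`,
#'   `intensity` (summed above-threshold mass, the detection confidence)
#'   and `found`. Missing markers get `found = FALSE` and `NA` centroids —
#'   a flagged dropout, not an error.
#' @export
detect_markers <- function(frame, n_markers = 2L, threshold = NULL,
                           min_area = 4L) {
  if (!is.matrix(frame))
    stop_polardrum("`frame` must be a single-channel matrix", "invalid_frame")
  empty <- tibble::tibble(
    marker = seq_len(n_markers), x = NA_real_, y = NA_real_,
    area = NA_real_, intensity = NA_real_, found = FALSE
  )
  if (is.null(threshold)) {
    s <- stats::sd(frame)
    if (s == 0) return(empty)                 # featureless frame: dropout
    threshold <- mean(frame) + 4 * s
  }
  mask <- frame > threshold
  if (!any(mask)) return(empty)
  labels <- EBImage::bwlabel(mask)
  lab <- as.integer(labels)
  keep <- lab > 0L
  if (!any(keep)) return(empty)
  rr <- rep(seq_len(nrow(frame)), times = ncol(frame))[keep]
  cc <- rep(seq_len(ncol(frame)), each = nrow(frame))[keep]
  wv <- pmax(frame[keep] - threshold, 0)
  lb <- lab[keep]
  area <- tapply(rep(1, length(lb)), lb, sum)
  mass <- tapply(wv, lb, sum)
  cx <- tapply(wv * cc, lb, sum) / mass
  cy <- tapply(wv * rr, lb, sum) / mass
  blobs <- tibble::tibble(x = as.numeric(cx), y = as.numeric(cy),
                          area = as.numeric(area),
                          intensity = as.numeric(mass)) |>
    dplyr::filter(.data$area >= min_area) |>
    dplyr::arrange(dplyr::desc(.data$intensity)) |>
    utils::head(n_markers) |>
    dplyr::arrange(.data$x, .data$y)
  n_found <- nrow(blobs)
  if (n_found == 0L) return(empty)
  out <- dplyr::mutate(blobs, marker = dplyr::row_number(), found = TRUE) |>
    dplyr::select("marker", "x", "y", "area", "intensity", "found")
  if (n_found < n_markers) {
    out <- dplyr::bind_rows(out, empty[seq(n_found + 1L, n_markers), ])
    out$marker <- seq_len(n_markers)
  }
  out
}

#' Track markers through an image sequence
#'
#' Runs [detect_markers()] on every frame and links detections across
#' frames by nearest-neighbour matching to the previous known positions,
#' with a maximum jump radius. Marker identity is seeded by the spatial
#' sort of the first complete frame.
#'
#' @param frames A list of grayscale matrices.
#' @param n_markers Expected marker count.
#' @param max_jump Maximum allowed per-frame displacement (px) when
#'   linking; larger jumps are treated as dropouts.
#' @param ... Passed to [detect_markers()].
#' @return A tibble with columns `frame`, `marker`, `x`, `y`, `found`.
#' @export
track_markers <- function(frames, n_markers = 2L, max_jump = 20, ...) {
  det <- purrr::map(frames, detect_markers, n_markers = n_markers, ...)
  prev <- NULL
  out <- vector("list", length(det))
  for (f in seq_along(det)) {
    d <- det[[f]]
    cand <- d[d$found, , drop = FALSE]
    row <- tibble::tibble(frame = f, marker = seq_len(n_markers),
                          x = NA_real_, y = NA_real_, found = FALSE)
    if (is.null(prev)) {
      if (nrow(cand) == n_markers) {
        row$x <- cand$x; row$y <- cand$y; row$found <- TRUE
        prev <- row
      }
    } else if (nrow(cand) > 0L) {
      taken <- rep(FALSE, nrow(cand))
      for (m in seq_len(n_markers)) {
        dd <- sqrt((cand$x - prev$x[m])^2 + (cand$y - prev$y[m])^2)
        dd[taken] <- Inf
        j <- which.min(dd)
        if (length(j) == 1L && is.finite(dd[j]) && dd[j] <= max_jump) {
          row$x[m] <- cand$x[j]; row$y[m] <- cand$y[j]; row$found[m] <- TRUE
          taken[j] <- TRUE
        }
      }
      if (any(row$found)) {
        upd <- row$found
        prev$x[upd] <- row$x[upd]; prev$y[upd] <- row$y[upd]
      }
    }
    out[[f]] <- row
  }
  dplyr::bind_rows(out)
}

#' Eye/body angle trace
#'
#' @param time Strictly increasing sample times (s).
#' @param angle Unwrapped angles in degrees.
#' @param sample_rate Sampling rate in Hz.
#' @param source `"tracked"` or `"synthetic"`.
#' @param interpolated Optional logical vector flagging gap-filled samples.
#' @return A tibble of class `eye_trace` with attributes `sample_rate` and
#'   `source`.
#' @export
eye_trace <- function(time, angle, sample_rate, source = "tracked",
                      interpolated = FALSE) {
  if (any(diff(time) <= 0))
    stop_polardrum("`time` must be strictly increasing", "invalid_trace")
  if (any(!is.finite(angle)))
    stop_polardrum("angles must be finite", "invalid_trace")
  out <- tibble::tibble(time = time, angle = angle,
                        interpolated = rep_len(interpolated, length(time)))
  class(out) <- c("eye_trace", class(out))
  attr(out, "sample_rate") <- sample_rate
  attr(out, "source") <- source
  out
}

#' Convert marker observations to an angular trace
#'
#' Reduces each frame's marker centroids to a single bearing (degrees,
#' unwrapped over time) relative to the body axis: the orientation of the
#' marker pair when two or more markers are tracked, otherwise the bearing
#' of the marker from a fixed body centre. Dropout frames are filled by
#' linear interpolation up to `gap_limit` consecutive frames and flagged;
#' longer gaps are dropped.
#'
#' @param observations Output of [track_markers()] (columns `frame`,
#'   `marker`, `x`, `y`, `found`).
#' @param sample_rate Frame rate in Hz (defaults to 25, a common camcorder
#'   rate).
#' @param centre Body centre `c(x, y)` in px, used when only one marker is
#'   configured; defaults to the mean tracked position.
#' @param body_axis Reference axis in degrees subtracted from the bearing.
#' @param gap_limit Longest dropout run (frames) that is interpolated.
#' @return An [eye_trace()].
#' @export
trace_from_markers <- function(observations, sample_rate = 25, centre = NULL,
                               body_axis = 0, gap_limit = 5L) {
  obs <- tibble::as_tibble(observations)
  n_markers <- max(obs$marker)
  wide <- tidyr::pivot_wider(obs, id_cols = "frame", names_from = "marker",
                             values_from = c("x", "y", "found"))
  if (n_markers >= 2L) {
    ok <- wide$found_1 & wide$found_2
    ang <- rad2deg(atan2(wide$y_2 - wide$y_1, wide$x_2 - wide$x_1))
  } else {
    ok <- wide$found_1
    if (is.null(centre))
      centre <- c(mean(wide$x_1, na.rm = TRUE), mean(wide$y_1, na.rm = TRUE))
    ang <- rad2deg(atan2(wide$y_1 - centre[2], wide$x_1 - centre[1]))
  }
  ok[is.na(ok)] <- FALSE
  if (!any(ok)) stop_polardrum("no valid marker observations", "empty_trace")
  ang[!ok] <- NA_real_
  # unwrap over the valid samples, then interpolate short gaps
  ang[ok] <- unwrap_deg(ang[ok])
  t <- (wide$frame - 1) / sample_rate
  filled <- stats::approx(t[ok], ang[ok], xout = t, rule = 1)$y
  gap_run <- with(rle(!ok), rep(lengths * values, lengths))
  use <- ok | (!is.na(filled) & gap_run <= gap_limit)
  eye_trace(t[use], filled[use], sample_rate, source = "tracked",
            interpolated = !ok[use])
}

#' Parameters for nystagmus segmentation and OKR scoring
#'
#' Velocity thresholds and windows for splitting an eye trace into slow
#' tracking phases, resetting saccades and quiescence. The defaults follow
#' classic nystagmus-analysis practice; none of them is critical and all
#' are exposed.
#'
#' @param v_min Minimum absolute slow-phase velocity, deg/s.
#' @param v_slow_max Maximum slow-phase velocity, deg/s; default twice the
#'   stimulus speed.
#' @param v_saccade_min Minimum smoothed velocity (deg/s) for a sample to
#'   count as saccadic.
#' @param smooth_window Velocity smoothing window, s.
#' @param max_saccade_duration Longest credible saccade, s; longer
#'   fast-phase runs are demoted to quiescent.
#' @param f_min Minimum slow-phase time fraction for a positive OKR.
#' @param n_min Minimum number of resetting saccades for a positive OKR.
#' @param drop_isolated_saccades If `TRUE`, saccades not adjacent to any
#'   slow phase are demoted to quiescent — a consistency filter for
#'   isolated non-tracking eye movements (e.g. eye cleaning) that would
#'   otherwise produce false positives.
#' @return A list of class `okr_params`.
#' @export
okr_params <- function(v_min = 1, v_slow_max = NULL, v_saccade_min = 30,
                       smooth_window = 0.2, max_saccade_duration = 0.5,
                       f_min = 0.3, n_min = 2L,
                       drop_isolated_saccades = FALSE) {
  structure(
    list(v_min = v_min, v_slow_max = v_slow_max,
         v_saccade_min = v_saccade_min, smooth_window = smooth_window,
         max_saccade_duration = max_saccade_duration,
         f_min = f_min, n_min = n_min,
         drop_isolated_saccades = drop_isolated_saccades),
    class = "okr_params"
  )
}

#' Segment an eye trace into nystagmus phases
#'
#' Classifies the trace into slow stimulus-tracking phases, fast resetting
#' saccades in the opposite direction, and quiescence. Saccadic samples are
#' found on the smoothed velocity (sign opposite to the stimulus and
#' magnitude at least `v_saccade_min`); each interval between saccades is
#' then labelled by its regression slope: a slow phase if the slope matches
#' the stimulus direction with magnitude in `[v_min, v_slow_max]`,
#' quiescent otherwise. Per-slow-phase gain is the slope divided by the
#' stimulus speed.
#'
#' @param trace An [eye_trace()].
#' @param stim_speed Signed stimulus speed, deg/s (positive =
#'   azimuth-increasing).
#' @param params An [okr_params()] list.
#' @return An object of class `nystagmus_seg`: list with `intervals` (a
#'   tibble `start`, `end`, `label`, `gain` that partitions the trace),
#'   `samples` (per-sample `time`, `angle`, `velocity`, `label`),
#'   `stim_speed` and `params`.
#' @export
segment_nystagmus <- function(trace, stim_speed, params = okr_params()) {
  stopifnot(inherits(trace, "eye_trace"))
  sr <- attr(trace, "sample_rate")
  n <- nrow(trace)
  win <- max(3L, round(params$smooth_window * sr))
  if (n < 2L * win)
    stop_polardrum("trace shorter than the minimum analysis window",
                   "config_error")
  if (sr * params$smooth_window < 2)
    stop_polardrum(
      "sample rate too low to resolve saccades at this smoothing window",
      "config_error")
  v_slow_max <- params$v_slow_max
  if (is.null(v_slow_max) || is.na(v_slow_max))
    v_slow_max <- 2 * abs(stim_speed)
  s <- sign(stim_speed)
  v_raw <- c(NA, diff(trace$angle)) * sr
  v_raw[1] <- v_raw[2]
  v <- moving_average(v_raw, win)
  sac <- (sign(v) == -s) & (abs(v) >= params$v_saccade_min)

  runs <- rle(sac)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  label <- character(length(runs$lengths))
  gain <- rep(NA_real_, length(runs$lengths))
  for (j in seq_along(runs$lengths)) {
    idx <- starts[j]:ends[j]
    dur <- (length(idx) - 1) / sr
    if (runs$values[j]) {
      label[j] <- if (dur <= params$max_saccade_duration) "saccade" else "quiescent"
    } else {
      slope <- if (length(idx) >= 3L) {
        stats::cov(trace$time[idx], trace$angle[idx]) / stats::var(trace$time[idx])
      } else {
        mean(v_raw[idx])
      }
      if (sign(slope) == s && abs(slope) >= params$v_min &&
          abs(slope) <= v_slow_max) {
        label[j] <- "slow_phase"
        gain[j] <- slope / stim_speed
      } else {
        label[j] <- "quiescent"
      }
    }
  }
  if (params$drop_isolated_saccades) {
    for (j in which(label == "saccade")) {
      nb <- c(if (j > 1) label[j - 1], if (j < length(label)) label[j + 1])
      if (!any(nb == "slow_phase")) label[j] <- "quiescent"
    }
  }
  intervals <- tibble::tibble(
    start = trace$time[starts], end = trace$time[ends],
    start_idx = starts, end_idx = ends, label = label, gain = gain
  )
  samples <- tibble::tibble(
    time = trace$time, angle = trace$angle, velocity = v,
    label = rep(label, runs$lengths)
  )
  structure(
    list(intervals = intervals, samples = samples,
         stim_speed = stim_speed, params = params),
    class = "nystagmus_seg"
  )
}

#' @export
print.nystagmus_seg <- function(x, ...) {
  tab <- table(factor(x$intervals$label,
                      levels = c("slow_phase", "saccade", "quiescent")))
  cat(sprintf("<nystagmus_seg> %d intervals (%d slow, %d saccade, %d quiescent), mean gain %.2f\n",
              nrow(x$intervals), tab[[1]], tab[[2]], tab[[3]],
              mean(x$intervals$gain, na.rm = TRUE)))
  invisible(x)
}

#' Score an optokinetic response from a segmentation
#'
#' Positive when the eye spent at least a fraction `f_min` of the trace in
#' slow tracking phases and produced at least `n_min` resetting saccades
#' against the stimulus direction (both thresholds closed).
#'
#' @param seg A [segment_nystagmus()] result.
#' @param params An [okr_params()] list.
#' @return Logical.
#' @export
classify_okr <- function(seg, params = okr_params()) {
  stopifnot(inherits(seg, "nystagmus_seg"))
  iv <- seg$intervals
  total <- max(iv$end) - min(iv$start)
  slow_time <- sum((iv$end - iv$start)[iv$label == "slow_phase"])
  n_sac <- sum(iv$label == "saccade")
  (slow_time / total >= params$f_min) && (n_sac >= params$n_min)
}

#' Score an optomotor response with the two-reversal rule
#'
#' Implements the walking-response criterion for free-moving animals: the
#' animal must complete at least one full circuit (360 deg of cumulative
#' rotation in the stimulus direction) before the first direction reversal,
#' another full circuit in the new direction before the second reversal,
#' and resume following after the second reversal.
#'
#' @param heading An [eye_trace()] of body heading covering the schedule.
#' @param schedule An `"omr"` [build_protocol()] schedule (three phases,
#'   two reversals).
#' @param min_circuit Rotation (deg) required in each of the first two
#'   phases.
#' @param resume_min Rotation (deg) in the stimulus direction after the
#'   second reversal that counts as "resumed following".
#' @return Logical.
#' @export
score_omr <- function(heading, schedule, min_circuit = 360, resume_min = 90) {
  stopifnot(inherits(heading, "eye_trace"))
  sched <- tibble::as_tibble(schedule)
  if (!("phase" %in% names(sched)) || nrow(sched) < 3L)
    stop_polardrum("schedule must contain three phases (two reversals)",
                   "protocol_error")
  sched <- dplyr::arrange(sched, .data$phase)
  bounds <- c(sched$onset_s, max(heading$time) + 1e-9)
  need <- c(min_circuit, min_circuit, resume_min)
  for (ph in 1:3) {
    idx <- heading$time >= bounds[ph] & heading$time < bounds[ph + 1]
    if (sum(idx) < 2L) return(FALSE)
    s <- if (sched$direction[ph] == "ccw") 1 else -1
    excursion <- s * (heading$angle[idx] - heading$angle[idx][1])
    if (max(excursion) < need[ph]) return(FALSE)
  }
  TRUE
}

#' Aggregate response records into group probabilities
#'
#' Per-group positive fraction with binomial count bookkeeping, plus the
#' mean and standard error across individuals (each individual contributing
#' its own positive fraction), as used for cohort response-probability
#' curves.
#'
#' @param records A tibble with at least `subject` and a logical `response`
#'   column, plus any grouping columns.
#' @param ... Grouping columns (tidyselect, e.g. `channel, freq_cpd`).
#' @return A tibble with one row per group: counts (`n_trials`, `n_pos`),
#'   pooled fraction `prob`, number of individuals `n_subjects`, and the
#'   across-individual `mean_prob` and `sem`.
#' @export
response_probability <- function(records, ...) {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0L)
    stop_polardrum("`records` is empty", "invalid_records")
  grouped <- dplyr::group_by(records, ..., .drop = FALSE)
  if (any(dplyr::group_size(grouped) == 0L))
    warning("empty groups omitted from response probabilities")
  per_subj <- records |>
    dplyr::group_by(..., .data$subject) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      n_pos = sum(.data$response),
      frac = n_pos / n_trials,
      .groups = "drop_last"
    )
  dplyr::summarise(
    per_subj,
    n_subjects = dplyr::n(),
    n_trials = sum(.data$n_trials),
    n_pos = sum(.data$n_pos),
    prob = n_pos / n_trials,
    mean_prob = mean(.data$frac),
    sem = if (dplyr::n() > 1) stats::sd(.data$frac) / sqrt(dplyr::n()) else 0,
    .groups = "drop"
  )
}
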