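#' Drum-referenced grating stimulus
#'
#' Specifies a square-wave grating painted on the virtual drum: the stripe
#' pattern is defined in azimuth, so that stripes keep a constant angular
#' size when viewed from the arena centre regardless of where they fall on
#' the flat panels.
#'
#' @param spatial_freq Spatial frequency in cycles per degree of azimuth.
#' @param contrast_level Fraction in `[0, 1]` of the channel's full
#'   contrast; stripe drive values are the channel extremes scaled by this
#'   about the channel midpoint (grayscale 127).
#' @param channel `"intensity"` or `"polarization"` — which of the two
#'   independently driven screen channels carries the pattern.
#' @param speed Drum rotation speed in deg/s.
#' @param direction `"ccw"` (azimuth-increasing, viewed from above) or
#'   `"cw"`.
#' @param duration Stimulus duration in seconds.
#' @param fps Frames per second for rendering.
#' @return An object of class `grating_spec`.
#' @export
grating_spec <- function(spatial_freq, contrast_level = 1,
                         channel = c("intensity", "polarization"),
                         speed = 6, direction = c("ccw", "cw"),
                         duration = 10, fps = 30) {
  channel <- match.arg(channel)
  direction <- match.arg(direction)
  if (!is_scalar_number(spatial_freq) || spatial_freq <= 0)
    stop_polardrum("`spatial_freq` must be > 0 (cycles/deg)", "invalid_spec")
  if (!is_scalar_number(contrast_level) || contrast_level < 0 || contrast_level > 1)
    stop_polardrum("`contrast_level` must lie in [0, 1]", "invalid_spec")
  if (!is_scalar_number(fps) || fps <= 0)
    stop_polardrum("`fps` must be > 0", "invalid_spec")
  if (!is_scalar_number(duration) || duration <= 0)
    stop_polardrum("`duration` must be > 0", "invalid_spec")
  structure(
    list(spatial_freq = spatial_freq, contrast_level = contrast_level,
         channel = channel, speed = speed, direction = direction,
         duration = duration, fps = fps),
    class = "grating_spec"
  )
}

#' Looming stimulus
#'
#' An expanding disc whose angular diameter follows a geometric (constant
#' size-ratio per unit time) expansion profile pinned to a start and a
#' maximum angle.
#'
#' @param duration Expansion duration in seconds.
#' @param max_angle Final angular diameter in degrees.
#' @param start_angle Initial angular diameter in degrees; the smallest
#'   plausibly visible onset (0.5 deg) by default.
#' @param fg,bg Foreground (disc) and background drive values, grayscale
#'   0-255.
#' @param channel Which screen channel carries the loom.
#' @param centre Named vector `c(azimuth =, elevation =)` of the disc
#'   centre, degrees.
#' @param all_panels If `TRUE`, replicate the disc at the same elevation on
#'   all four wall centres (azimuth + 0/90/180/270), mirroring simultaneous
#'   presentation on every side of the arena.
#' @param fps Frames per second for rendering.
#' @return An object of class `loom_spec`.
#' @export
loom_spec <- function(duration = 5, max_angle = 34.5, start_angle = 0.5,
                      fg = 255, bg = 0,
                      channel = c("intensity", "polarization"),
                      centre = c(azimuth = 0, elevation = 0),
                      all_panels = FALSE, fps = 30) {
  channel <- match.arg(channel)
  if (!(start_angle > 0 && start_angle < max_angle && max_angle <= 180))
    stop_polardrum("need 0 < start_angle < max_angle <= 180", "invalid_spec")
  if (!is_scalar_number(duration) || duration <= 0)
    stop_polardrum("`duration` must be > 0", "invalid_spec")
  if (any(c(fg, bg) < 0 | c(fg, bg) > 255))
    stop_polardrum("drive values must lie in [0, 255]", "invalid_spec")
  structure(
    list(duration = duration, max_angle = max_angle, start_angle = start_angle,
         fg = fg, bg = bg, channel = channel,
         centre = c(azimuth = unname(centre[1]), elevation = unname(centre[2])),
         all_panels = isTRUE(all_panels), fps = fps),
    class = "loom_spec"
  )
}

# Stripe drive extremes for a contrast level about the grayscale midpoint
# 127 (the grey control drive). Full contrast reaches the 0/255 extremes.
grating_drives <- function(contrast_level) {
  c(lo = 127 * (1 - contrast_level), hi = 127 + 128 * contrast_level)
}

#' Evaluate the drum grating pattern at a time point
#'
#' Returns the pattern as a function of viewing direction, with the phase
#' advanced by `speed * t` in the signed drift direction. This is the
#' drum-referenced ground truth that the renderer samples through the
#' panel-pixel direction map.
#'
#' @param spec A [grating_spec()].
#' @param t Time in seconds.
#' @return A function `f(azimuth, elevation = 0)` returning drive values.
#' @export
drum_pattern_grating <- function(spec, t = 0) {
  stopifnot(inherits(spec, "grating_spec"))
  drv <- grating_drives(spec$contrast_level)
  s <- if (spec$direction == "ccw") 1 else -1
  sf <- spec$spatial_freq
  phase0 <- s * spec$speed * t
  function(azimuth, elevation = 0) {
    cyc <- ((azimuth - phase0) * sf) %% 1
    ifelse(cyc < 0.5, drv[["hi"]], drv[["lo"]])
  }
}

#' Angular diameter of a loom at time t
#'
#' Geometric expansion pinned to both endpoints:
#' `theta(t) = start_angle * (max_angle / start_angle)^(t / duration)`.
#'
#' @param spec A [loom_spec()].
#' @param t Time in seconds, in `[0, duration]` (vectorized).
#' @return Angular diameter in degrees.
#' @export
loom_angle_at <- function(spec, t) {
  stopifnot(inherits(spec, "loom_spec"))
  if (any(t < 0 | t > spec$duration))
    stop_polardrum("`t` must lie in [0, duration]", "range_error")
  spec$start_angle * (spec$max_angle / spec$start_angle)^(t / spec$duration)
}

# Supersampled per-panel direction maps: for each panel a list with az/el
# matrices of size (ss*H x ss*W), plus the per-pixel solid angle map (sr).
panel_direction_maps <- function(geom, supersample = 2L) {
  ss <- as.integer(supersample)
  W <- geom$panel_px_w; H <- geom$panel_px_h
  sub <- (seq_len(ss) - 0.5) / ss
  pxs <- rep(0:(W - 1), each = ss) + sub           # length ss*W
  pys <- rep(0:(H - 1), each = ss) + sub           # length ss*H
  lapply(0:3, function(k) {
    grid <- expand.grid(py = pys, px = pxs)        # column-major: rows vary fastest
    p <- panel_point_world(k, grid$px, grid$py, geom)
    dx <- p$x - geom$viewer_xy[1]
    dy <- p$y - geom$viewer_xy[2]
    dz <- p$z - geom$viewer_eye_height
    r2 <- dx^2 + dy^2 + dz^2
    az <- matrix(wrap360(rad2deg(atan2(dy, dx))), nrow = ss * H)
    el <- matrix(rad2deg(atan2(dz, sqrt(dx^2 + dy^2))), nrow = ss * H)
    # solid angle of each subsample cell: physical area x cos(incidence)/r^2
    cell <- (geom$wall_width / (ss * W)) * (geom$wall_height / (ss * H))
    d <- geom$wall_width / 2
    ang <- deg2rad(90 * k)
    # incidence cosine = component of the unit ray along the inward normal
    nx <- -cos(ang); ny <- -sin(ang)
    cosi <- abs(dx * nx + dy * ny) / sqrt(r2)
    omega <- matrix(cell * cosi / r2, nrow = ss * H)
    list(azimuth = az, elevation = el, omega = omega)
  })
}

# Great-circle angular distance (deg) between directions and a centre.
angular_distance <- function(az, el, centre_az, centre_el) {
  a <- deg2rad(az); e <- deg2rad(el)
  ca <- deg2rad(centre_az); ce <- deg2rad(centre_el)
  cosd <- sin(ce) * sin(e) + cos(ce) * cos(e) * cos(a - ca)
  rad2deg(acos(pmin(pmax(cosd, -1), 1)))
}

#' Render a stimulus to per-panel dual-channel frames
#'
#' Samples the drum-referenced pattern through the panel-pixel direction
#' map with 2x2 supersampling per pixel, producing perspective-corrected
#' frames. The channel not carrying the stimulus is held at the constant
#' grey background drive (127). Frame `i` shows the pattern at
#' `t = i / fps`, so the final frame of a loom displays exactly the maximum
#' angle.
#'
#' @param spec A [grating_spec()] or [loom_spec()].
#' @param geom An [arena_geometry()].
#' @param frames Optional integer vector of frame indices (1-based) to
#'   render; defaults to the full sequence `1:round(duration * fps)`.
#' @return An object of class `drum_frames`: a list with elements `spec`,
#'   `geom`, `times`, and `frames` — one element per frame, each a list of
#'   four panels, each panel a list of `intensity` and `polarization` drive
#'   matrices (`panel_px_h` x `panel_px_w`, values in `[0, 255]`).
#' @export
render_frames <- function(spec, geom, frames = NULL) {
  stopifnot(inherits(geom, "arena_geometry"))
  n_frames <- round(spec$duration * spec$fps)
  if (is.null(frames)) frames <- seq_len(n_frames)
  if (any(frames < 1 | frames > n_frames))
    stop_polardrum("`frames` outside the rendered sequence", "range_error")
  times <- frames / spec$fps
  maps <- panel_direction_maps(geom, supersample = 2L)
  bg_const <- matrix(127, geom$panel_px_h, geom$panel_px_w)

  if (inherits(spec, "grating_spec")) {
    # aliasing guard: at least 2 px per half-period at the panel centre
    px_deg <- wall_subtense(geom)[["horizontal"]] / geom$panel_px_w
    if ((0.5 / spec$spatial_freq) / px_deg < 2)
      stop_polardrum(
        "panel resolution too low for this spatial frequency (< 2 px per half-period)",
        "aliasing_error")
    frame_list <- lapply(times, function(t) {
      pat <- drum_pattern_grating(spec, t)
      lapply(maps, function(m) {
        img <- pool2(pat(m$azimuth, m$elevation))
        if (spec$channel == "intensity") {
          list(intensity = img, polarization = bg_const)
        } else {
          list(intensity = bg_const, polarization = img)
        }
      })
    })
  } else if (inherits(spec, "loom_spec")) {
    centres_az <- if (spec$all_panels) {
      wrap360(spec$centre[["azimuth"]] + c(0, 90, 180, 270))
    } else {
      spec$centre[["azimuth"]]
    }
    dist_maps <- lapply(maps, function(m) {
      d <- Reduce(pmin, lapply(centres_az, function(ca)
        angular_distance(m$azimuth, m$elevation, ca, spec$centre[["elevation"]])))
      d
    })
    frame_list <- lapply(times, function(t) {
      r <- loom_angle_at(spec, min(t, spec$duration)) / 2
      lapply(dist_maps, function(d) {
        img <- pool2(ifelse(d < r, spec$fg, spec$bg))
        if (spec$channel == "intensity") {
          list(intensity = img, polarization = bg_const)
        } else {
          list(intensity = bg_const, polarization = img)
        }
      })
    })
  } else {
    stop_polardrum("`spec` must be a grating_spec or loom_spec", "invalid_spec")
  }
  structure(
    list(spec = spec, geom = geom, times = times, frames = frame_list),
    class = "drum_frames"
  )
}

#' @export
print.drum_frames <- function(x, ...) {
  cat(sprintf("<drum_frames> %d frames, %d x %d px panels, %s stimulus\n",
              length(x$frames), x$geom$panel_px_h, x$geom$panel_px_w,
              class(x$spec)[1]))
  invisible(x)
}

#' Measure the azimuthal drift rate of rendered grating frames
#'
#' Inverse-maps the eye-level pixel row of every panel back onto the drum
#' (via the direction map) and estimates the pattern's azimuthal phase in
#' each frame by least-squares fit of the stripe fundamental; the drift
#' rate is the slope of unwrapped phase against time. This goes through the
#' rendered pixels only, so it measures what an observer at the centre
#' would actually see.
#'
#' @param frames A `drum_frames` object holding a rendered grating.
#' @return Drift rate in deg/s (positive = counter-clockwise).
#' @export
measure_grating_drift <- function(frames) {
  stopifnot(inherits(frames, "drum_frames"), inherits(frames$spec, "grating_spec"))
  geom <- frames$geom
  spec <- frames$spec
  ch <- spec$channel
  # eye-level row: elevation closest to zero
  row_px <- tibble::tibble(
    panel = rep(0:3, each = geom$panel_px_w),
    px = rep(0:(geom$panel_px_w - 1), times = 4),
    py = 0
  )
  # find the row whose centre elevation is nearest 0 on panel 0
  rows <- panel_pixel_to_direction(
    tibble::tibble(panel = 0, px = 0, py = 0:(geom$panel_px_h - 1)), geom)
  best_row <- rows$py[which.min(abs(rows$elevation))]
  row_px$py <- best_row
  dirs <- panel_pixel_to_direction(row_px, geom)
  omega <- 2 * pi * spec$spatial_freq       # rad per deg of azimuth
  X <- cbind(cos(omega * dirs$azimuth), sin(omega * dirs$azimuth))
  phases <- vapply(frames$frames, function(fr) {
    v <- unlist(lapply(0:3, function(k) fr[[k + 1]][[ch]][best_row + 1, ]))
    cf <- stats::lm.fit(X, v - mean(v))$coefficients
    atan2(cf[2], cf[1])
  }, numeric(1))
  ph <- unwrap_deg(rad2deg(phases))            # phase within a cycle, deg
  az_shift <- ph / 360 / spec$spatial_freq     # converted to deg of azimuth
  stats::coef(stats::lm(az_shift ~ frames$times))[[2]]
}

#' Measure the angular diameter of a rendered loom frame
#'
#' Maps the rendered disc back onto the drum: each pixel's solid angle is
#' weighted by its foreground fraction (anti-aliased edge pixels count
#' fractionally), the weighted solid angles are summed into the disc's
#' solid angle, and the equivalent spherical-cap diameter is reported.
#'
#' @param frames A `drum_frames` object holding a rendered loom.
#' @param frame Frame index to measure; defaults to the last.
#' @return Angular diameter in degrees.
#' @export
measure_loom_diameter <- function(frames, frame = length(frames$frames)) {
  stopifnot(inherits(frames, "drum_frames"), inherits(frames$spec, "loom_spec"))
  spec <- frames$spec
  if (spec$all_panels)
    stop_polardrum("diameter measurement assumes a single disc (`all_panels = FALSE`)",
                   "invalid_spec")
  maps <- panel_direction_maps(frames$geom, supersample = 2L)
  fr <- frames$frames[[frame]]
  ch <- spec$channel
  total <- 0
  for (k in 1:4) {
    img <- fr[[k]][[ch]]
    alpha <- (img - spec$bg) / (spec$fg - spec$bg)
    alpha <- pmin(pmax(alpha, 0), 1)
    # per-pixel solid angle = sum of its 2x2 subsample solid angles
    om_px <- 4 * pool2(maps[[k]]$omega)
    total <- total + sum(alpha * om_px)
  }
  # spherical cap: Omega = 2*pi*(1 - cos(theta/2))
  2 * rad2deg(acos(1 - total / (2 * pi)))
}

#' Build a trial protocol schedule
#'
#' @param kind `"loom"` (repeated looms at fixed intervals), `"grating"`
#'   (a frequency block presented in seeded random order), or `"omr"`
#'   (a single grating trial with two direction reversals, implementing the
#'   two-reversal confirmation rule for optomotor scoring).
#' @param params A list of kind-specific parameters:
#'   * loom: `n_repeats` (max 3), `interval_s` (default 60), `spec`.
#'   * grating: `freqs` (default `seq(0.02, 0.2, by = 0.02)`),
#'     `trial_duration_s` (default 60), `contrast_level`, `channel`.
#'   * omr: `phase_duration_s` (default 120), `direction` (initial),
#'     `freq`, `contrast_level`, `channel`.
#' @param seed Integer seed; the schedule is deterministic given the seed.
#' @return A tibble of trials (class `protocol_schedule`) with an
#'   `onset_s` column; `omr` schedules carry one row per phase with the
#'   active drift `direction`.
#' @export
build_protocol <- function(kind = c("loom", "grating", "omr"),
                           params = list(), seed = 1L) {
  kind <- match.arg(kind)
  p <- params
  out <- switch(kind,
    loom = {
      n <- min(p$n_repeats %||% 3L, 3L)
      interval <- p$interval_s %||% 60
      tibble::tibble(
        trial = seq_len(n),
        kind = "loom",
        onset_s = (seq_len(n) - 1) * interval
      )
    },
    grating = {
      freqs <- p$freqs %||% seq(0.02, 0.2, by = 0.02)
      dur <- p$trial_duration_s %||% 60
      ord <- with_seed(seed, sample.int(length(freqs)))
      tibble::tibble(
        trial = seq_along(freqs),
        kind = "grating",
        freq_cpd = freqs[ord],
        contrast_level = p$contrast_level %||% 1,
        channel = p$channel %||% "intensity",
        onset_s = (seq_along(freqs) - 1) * dur
      )
    },
    omr = {
      dur <- p$phase_duration_s %||% 120
      dir0 <- p$direction %||% "ccw"
      dirs <- if (dir0 == "ccw") c("ccw", "cw", "ccw") else c("cw", "ccw", "cw")
      tibble::tibble(
        trial = 1L,
        kind = "omr",
        phase = 1:3,
        direction = dirs,
        freq_cpd = p$freq %||% 0.05,
        contrast_level = p$contrast_level %||% 1,
        channel = p$channel %||% "intensity",
        onset_s = (0:2) * dur
      )
    }
  )
  class(out) <- c("protocol_schedule", class(out))
  attr(out, "seed") <- seed
  out
}
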