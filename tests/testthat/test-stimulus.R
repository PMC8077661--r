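test_that("grating stripe period and drive levels follow the spec", {
  spec <- grating_spec(spatial_freq = 0.02, contrast_level = 1)
  pat <- drum_pattern_grating(spec, t = 0)
  # period 1/0.02 = 50 deg: the pattern repeats exactly every 50 deg
  az <- seq(0, 359, by = 0.5)
  expect_equal(pat(az), pat(az + 50))
  expect_equal(360 * 0.02, 7.2)  # 7.2 periods around the drum
  # full contrast uses the channel extremes
  expect_setequal(unique(pat(az)), c(0, 255))
})

test_that("zero contrast collapses the grating to the midpoint drive", {
  spec <- grating_spec(spatial_freq = 0.1, contrast_level = 0)
  pat <- drum_pattern_grating(spec, t = 3.21)
  expect_true(all(pat(seq(0, 360, by = 0.1)) == 127))
})

test_that("the pattern drifts by speed * t degrees of azimuth", {
  spec <- grating_spec(spatial_freq = 0.1, speed = 6, direction = "ccw")
  p0 <- drum_pattern_grating(spec, t = 0)
  p1 <- drum_pattern_grating(spec, t = 1)
  az <- seq(0, 359.9, by = 0.05)
  expect_equal(p1(az), p0(az - 6))
  # cw drifts the other way
  spec_cw <- grating_spec(spatial_freq = 0.1, speed = 6, direction = "cw")
  p1cw <- drum_pattern_grating(spec_cw, t = 1)
  expect_equal(p1cw(az), p0(az + 6))
})

test_that("loom angle follows the geometric expansion pinned to both ends", {
  spec <- loom_spec()
  expect_equal(loom_angle_at(spec, 0), 0.5)
  expect_equal(loom_angle_at(spec, 5), 34.5)
  expect_equal(loom_angle_at(spec, 2.5), sqrt(0.5 * 34.5))
  # monotone non-decreasing area <=> monotone angle
  t <- seq(0, 5, by = 0.05)
  expect_true(all(diff(loom_angle_at(spec, t)) >= 0))
  expect_error(loom_angle_at(spec, 5.01), class = "polardrum_error")
  expect_error(loom_angle_at(spec, -0.1), class = "polardrum_error")
})

test_that("loom and grating specs validate their invariants", {
  expect_error(grating_spec(spatial_freq = 0), class = "polardrum_error")
  expect_error(grating_spec(0.05, contrast_level = 1.5), class = "polardrum_error")
  expect_error(loom_spec(start_angle = 40), class = "polardrum_error")
  expect_error(loom_spec(max_angle = 200, start_angle = 1),
               class = "polardrum_error")
})

test_that("rendered gratings hold a constant angular stripe width", {
  geom <- arena_geometry(panel_px_w = 96L, panel_px_h = 74L)
  spec <- grating_spec(spatial_freq = 0.05, duration = 1 / 30, fps = 30)
  fr <- render_frames(spec, geom, frames = 1L)
  # walk the eye-level row of panel 0 and measure stripe widths in azimuth
  row <- panel_pixel_to_direction(
    tibble::tibble(panel = 0, px = 0:95, py = 37), geom)
  azc <- ((row$azimuth + 180) %% 360) - 180   # monotone across the 0-deg seam
  v <- fr$frames[[1]][[1]]$intensity[38, ]
  runs <- rle(v > 127)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  # interior runs only (edge runs are truncated by the panel border)
  keep <- seq(2, length(runs$lengths) - 1)
  expect_gte(length(keep), 3)
  widths <- azc[ends[keep]] - azc[starts[keep]]
  px_deg <- 90 / 96
  # run boundaries are quantized at the local pixel size, which biases
  # bright and dark runs in opposite directions; compare like with like
  for (pol in c(TRUE, FALSE)) {
    w <- widths[runs$values[keep] == pol]
    expect_true(all(abs(w - mean(w)) < px_deg))
  }
  # adjacent bright+dark pairs span one full period (20 deg at 0.05 cyc/deg)
  pairs <- widths[-length(widths)] + widths[-1]
  expect_true(all(abs(pairs - 20) < 3 * px_deg))
})

test_that("rendering is deterministic and the idle channel stays at grey", {
  geom <- arena_geometry(panel_px_w = 48L, panel_px_h = 38L)
  spec <- grating_spec(spatial_freq = 0.05, channel = "polarization",
                       duration = 0.1, fps = 30)
  f1 <- render_frames(spec, geom)
  f2 <- render_frames(spec, geom)
  expect_identical(f1$frames, f2$frames)
  expect_true(all(f1$frames[[1]][[2]]$intensity == 127))
  expect_true(any(f1$frames[[1]][[2]]$polarization != 127))
})

test_that("zero-contrast renders are spatially and temporally constant", {
  geom <- arena_geometry(panel_px_w = 32L, panel_px_h = 24L)
  spec <- grating_spec(spatial_freq = 0.05, contrast_level = 0,
                       duration = 0.1, fps = 30)
  fr <- render_frames(spec, geom)
  expect_true(all(vapply(fr$frames, function(f)
    all(f[[1]]$intensity == 127), logical(1))))
})

test_that("under-resolved spatial frequencies raise an aliasing error", {
  geom <- arena_geometry(panel_px_w = 32L, panel_px_h = 24L)
  spec <- grating_spec(spatial_freq = 0.2, duration = 0.1)
  expect_error(render_frames(spec, geom), class = "polardrum_error")
})

test_that("measured drift of a rendered grating recovers the drum speed", {
  geom <- arena_geometry(panel_px_w = 96L, panel_px_h = 74L)
  spec <- grating_spec(spatial_freq = 0.1, speed = 6, duration = 1, fps = 30)
  fr <- render_frames(spec, geom)
  expect_equal(measure_grating_drift(fr), 6, tolerance = 0.02)
  spec_cw <- grating_spec(spatial_freq = 0.1, speed = 6, direction = "cw",
                          duration = 1, fps = 30)
  expect_equal(measure_grating_drift(render_frames(spec_cw, geom)), -6,
               tolerance = 0.02)
})

test_that("the rendered loom reaches its printed final diameter", {
  geom <- arena_geometry(panel_px_w = 96L, panel_px_h = 74L)
  spec <- loom_spec(fps = 30)
  fr <- render_frames(spec, geom, frames = 150L)
  d <- measure_loom_diameter(fr, frame = 1L)
  px_deg <- 90 / 96
  expect_lt(abs(d - 34.5), px_deg)
})

test_that("loom protocols stay within three repeats a minute apart", {
  p <- build_protocol("loom", list(n_repeats = 5), seed = 3)
  expect_lte(nrow(p), 3)
  expect_equal(diff(p$onset_s), rep(60, nrow(p) - 1))
})

test_that("protocols are deterministic and frequency blocks are permutations", {
  freqs <- seq(0.02, 0.2, by = 0.02)
  a <- build_protocol("grating", list(freqs = freqs), seed = 9)
  b <- build_protocol("grating", list(freqs = freqs), seed = 9)
  expect_identical(a, b)
  expect_setequal(a$freq_cpd, freqs)
  expect_equal(anyDuplicated(a$freq_cpd), 0)
  c <- build_protocol("grating", list(freqs = freqs), seed = 10)
  expect_false(identical(a$freq_cpd, c$freq_cpd))
})

test_that("omr protocols carry two direction reversals", {
  p <- build_protocol("omr", list(direction = "ccw"), seed = 1)
  expect_equal(p$direction, c("ccw", "cw", "ccw"))
  expect_equal(nrow(p), 3)
})
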