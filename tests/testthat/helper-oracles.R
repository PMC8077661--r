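# Independent oracles used across the suite. These re-derive expected
# values from first principles and never call the code paths they check.

# Ray-casting oracle: direction of a pixel centre built from the panel's
# corner coordinates by bilinear interpolation, entirely separate from the
# package's pixel->world arithmetic.
oracle_pixel_direction <- function(panel, px, py, wall_width, wall_height,
                                   panel_px_w, panel_px_h,
                                   viewer = c(0, 0, wall_height / 2)) {
  d <- wall_width / 2
  rot <- function(p, k) {
    a <- k * pi / 2
    c(cos(a) * p[1] - sin(a) * p[2], sin(a) * p[1] + cos(a) * p[2], p[3])
  }
  tl <- rot(c(d, -wall_width / 2, wall_height), panel)  # top, low-azimuth side
  tr <- rot(c(d, wall_width / 2, wall_height), panel)
  bl <- rot(c(d, -wall_width / 2, 0), panel)
  fx <- (px + 0.5) / panel_px_w
  fy <- (py + 0.5) / panel_px_h
  p <- tl + fx * (tr - tl) + fy * (bl - tl)
  v <- p - viewer
  az <- atan2(v[2], v[1]) * 180 / pi
  el <- atan2(v[3], sqrt(v[1]^2 + v[2]^2)) * 180 / pi
  c(azimuth = az %% 360, elevation = el)
}

# Brute-force two-axis absorber: explicit parallel/perpendicular energy
# decomposition with gain sp : 1.
oracle_quantum_catch <- function(i, d, theta_deg, axis_deg, sp) {
  x <- (theta_deg - axis_deg) * pi / 180
  e_par <- i * ((1 - d) / 2 + d * cos(x)^2)
  e_perp <- i * ((1 - d) / 2 + d * sin(x)^2)
  sp * e_par + e_perp
}

oracle_opponent_signal <- function(i, d, theta_deg, sp) {
  qh <- oracle_quantum_catch(i, d, theta_deg, 0, sp)
  qv <- oracle_quantum_catch(i, d, theta_deg, 90, sp)
  (qh - qv) / (qh + qv)
}

# Circular rigid-rotation marker trajectory around a centre (deg/frame).
rigid_rotation_trajectory <- function(n_frames, centre = c(80, 60),
                                      radii = c(10, 25),
                                      omega_deg_per_frame = 0.24,
                                      phase0 = 0) {
  purrr::map_dfr(seq_len(n_frames), function(f) {
    ang <- (phase0 + omega_deg_per_frame * (f - 1)) * pi / 180
    tibble::tibble(
      frame = f, marker = seq_along(radii),
      x = centre[1] + radii * cos(ang),
      y = centre[2] + radii * sin(ang)
    )
  })
}
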