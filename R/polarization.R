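#' Stokes description of partially linearly polarized light
#'
#' A vectorized container for the three quantities that describe the light
#' leaving each screen pixel: relative intensity, degree of linear
#' polarization (DoP, 0-1) and angle of polarization (AoP, degrees in
#' `[0, 180)`; 0 = horizontal, increasing counter-clockwise facing the
#' screen).
#'
#' @param i Relative intensity (>= 0); recycled.
#' @param dop Degree of polarization in `[0, 1]`.
#' @param aop Angle of polarization in degrees; wrapped into `[0, 180)`.
#' @return A tibble of class `stokes_state` with columns `i`, `dop`, `aop`.
#' @examples
#' stokes_state(1, dop = c(1, 0.45), aop = c(0, 90))
#' @export
stokes_state <- function(i = 1, dop = 0, aop = 0) {
  n <- max(length(i), length(dop), length(aop))
  i <- rep_len(as.numeric(i), n)
  dop <- rep_len(as.numeric(dop), n)
  aop <- wrap180(rep_len(as.numeric(aop), n))
  if (any(i < 0)) stop_polardrum("intensity must be >= 0", "invalid_stokes")
  if (any(dop < 0 | dop > 1)) stop_polardrum("DoP must lie in [0, 1]", "invalid_stokes")
  out <- tibble::tibble(i = i, dop = dop, aop = aop)
  class(out) <- c("stokes_state", class(out))
  out
}

#' Two-channel polarization receptor model
#'
#' A standard opponent pair of orthogonal polarization-sensitive channels,
#' characterized by the polarization sensitivity `sp`: the ratio of a
#' receptor's response to light polarized parallel versus perpendicular to
#' its preferred axis.
#'
#' @param sp Polarization sensitivity, >= 1. Default 10 — a typical value
#'   for crustacean photoreceptors.
#' @param axes Preferred axes of the two channels in degrees; default a
#'   horizontal/vertical pair.
#' @return An object of class `receptor_model`.
#' @export
receptor_model <- function(sp = 10, axes = c(0, 90)) {
  if (!is_scalar_number(sp) || sp < 1)
    stop_polardrum("polarization sensitivity `sp` must be >= 1", "invalid_model")
  if (length(axes) != 2L || wrap180(abs(axes[1] - axes[2])) != 90)
    stop_polardrum("the two channel axes must be orthogonal", "invalid_model")
  structure(list(sp = sp, axes = as.numeric(axes)), class = "receptor_model")
}

#' Michelson contrast
#'
#' `|L1 - L2| / (L1 + L2)` — the contrast measure used for periodic
#' (grating) stimuli.
#'
#' @param l1,l2 Non-negative radiances (vectorized).
#' @return Contrast fraction in `[0, 1]`.
#' @export
michelson_contrast <- function(l1, l2) {
  if (any(l1 < 0 | l2 < 0))
    stop_polardrum("radiances must be >= 0", "undefined_contrast")
  if (any(l1 + l2 == 0))
    stop_polardrum("Michelson contrast undefined when both radiances are 0",
                   "undefined_contrast")
  abs(l1 - l2) / (l1 + l2)
}

#' Weber contrast
#'
#' `(L_obj - L_bg) / L_bg` — the signed contrast measure used for
#' object-on-background (looming) stimuli.
#'
#' @param l_obj Object radiance.
#' @param l_bg Background radiance, > 0.
#' @return Signed Weber fraction.
#' @export
weber_contrast <- function(l_obj, l_bg) {
  if (any(l_bg <= 0))
    stop_polardrum("Weber contrast undefined for background radiance 0",
                   "undefined_contrast")
  (l_obj - l_bg) / l_bg
}

#' Receptor quantum catch for partially polarized light
#'
#' Closed form of a two-axis absorber with parallel:perpendicular gain
#' `sp : 1`:
#' `Q = I * (sp + 1) / 2 * (1 + d * ((sp - 1)/(sp + 1)) * cos 2(aop - axis))`,
#' which equals the explicit decomposition `sp * E_par + E_perp` with
#' `E_par = I * ((1 - d)/2 + d * cos^2(aop - axis))`.
#'
#' @param light A [stokes_state()] (or anything with `i`, `dop`, `aop`
#'   columns/elements).
#' @param axis Receptor preferred axis in degrees.
#' @param model A [receptor_model()] supplying the sensitivity `sp`.
#' @return Relative quantum catch (same length as `light`).
#' @export
quantum_catch <- function(light, axis, model = receptor_model()) {
  stopifnot(inherits(model, "receptor_model"))
  k <- (model$sp - 1) / (model$sp + 1)
  light$i * (model$sp + 1) / 2 *
    (1 + light$dop * k * cos(2 * deg2rad(light$aop - axis)))
}

#' Polarization distance between two light states
#'
#' Scalar contrast between an object and its background as seen by an
#' opponent pair of orthogonal polarization channels: each state is reduced
#' to the normalized opponent signal `s = (Q1 - Q2) / (Q1 + Q2)` over the
#' model's two axes, and the distance is `|s_obj - s_bkg|`. It is zero
#' exactly when the two states are indistinguishable to the receptor pair.
#'
#' @param obj,bkg [stokes_state()] rows (vectorized pairwise).
#' @param model A [receptor_model()].
#' @return Non-negative polarization distance.
#' @export
polarization_distance <- function(obj, bkg, model = receptor_model()) {
  s <- function(st) {
    q1 <- quantum_catch(st, model$axes[1], model)
    q2 <- quantum_catch(st, model$axes[2], model)
    (q1 - q2) / (q1 + q2)
  }
  abs(s(obj) - s(bkg))
}

#' Polarization-channel screen calibration
#'
#' Maps the grayscale drive (0-255) addressed to the polarization channel
#' onto the emitted light state. The default calibration is anchored at the
#' screens' measured extremes — drive 0 emits horizontally polarized light
#' with DoP = 1, drive 255 vertically polarized light with DoP = 0.45 —
#' with DoP interpolated piecewise-linearly through a zero-DoP crossover
#' (default drive 127). Emitted intensity is constant across drives: the
#' defining feature of an independently driven intensity/polarization
#' screen. A measured calibration table can be supplied instead.
#'
#' @param table Optional data frame with columns `drive`, `dop`, `aop_deg`
#'   (a measured calibration); must cover drives 0 and 255.
#' @param crossover_drive Drive value where DoP passes through zero for the
#'   default piecewise-linear calibration.
#' @param intensity Constant emitted intensity.
#' @return An object of class `screen_calibration`.
#' @export
screen_calibration <- function(table = NULL, crossover_drive = 127,
                               intensity = 1) {
  if (is.null(table)) {
    table <- tibble::tibble(
      drive = c(0, crossover_drive, 255),
      dop = c(1, 0, 0.45),
      aop_deg = c(0, 0, 90)
    )
  } else {
    table <- tibble::as_tibble(table)
    if (!all(c("drive", "dop", "aop_deg") %in% names(table)))
      stop_polardrum("calibration table needs columns drive, dop, aop_deg",
                     "invalid_calibration")
    if (min(table$drive) > 0 || max(table$drive) < 255)
      stop_polardrum("calibration table must cover drives 0 and 255",
                     "invalid_calibration")
    table <- dplyr::arrange(table, .data$drive)
  }
  structure(list(table = table, intensity = intensity),
            class = "screen_calibration")
}

#' Decode a polarization-channel drive value to a light state
#'
#' @param gv Grayscale drive values in `[0, 255]` (vectorized).
#' @param cal A [screen_calibration()].
#' @return A [stokes_state()] tibble, one row per drive value.
#' @export
decode_drive <- function(gv, cal = screen_calibration()) {
  stopifnot(inherits(cal, "screen_calibration"))
  if (any(gv < 0 | gv > 255))
    stop_polardrum("drive values must lie in [0, 255]", "bounds_error")
  tb <- cal$table
  dop <- stats::approx(tb$drive, tb$dop, xout = gv, rule = 2)$y
  # AoP labels the polarized component: it switches discretely at the
  # zero-DoP crossover (where it is physically meaningless), so carry the
  # calibration knot at/above each drive rather than interpolating.
  aop <- stats::approx(tb$drive, tb$aop_deg, xout = gv, method = "constant",
                       rule = 2, f = 1)$y
  stokes_state(i = cal$intensity, dop = dop, aop = aop)
}

#' Stokes parameters from a four-angle polarimetric stack
#'
#' Computes intensity, DoP and AoP maps from four co-registered images
#' taken through a linear polarizer at 0, 45, 90 and 135 degrees:
#' `S0 = I0 + I90`, `S1 = I0 - I90`, `S2 = I45 - I135`,
#' `DoP = sqrt(S1^2 + S2^2) / S0` (clipped to `[0, 1]`),
#' `AoP = atan2(S2, S1) / 2` mapped to `[0, 180)`.
#'
#' @param i0,i45,i90,i135 Non-negative numeric matrices (or vectors) of
#'   identical shape.
#' @return A list of class `stokes_maps` with elements `intensity`, `dop`,
#'   `aop` (same shape as the inputs; `dop`/`aop` are `NA` where
#'   `S0 = 0`).
#' @export
stokes_from_stack <- function(i0, i45, i90, i135) {
  dims <- lapply(list(i0, i45, i90, i135), dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])) ||
      !all(lengths(list(i45, i90, i135)) == length(i0)))
    stop_polardrum("the four polarizer images must have identical shapes",
                   "shape_error")
  if (any(c(i0, i45, i90, i135) < 0, na.rm = TRUE))
    stop_polardrum("polarizer images must be non-negative", "invalid_stokes")
  s0 <- i0 + i90
  s1 <- i0 - i90
  s2 <- i45 - i135
  dop <- sqrt(s1^2 + s2^2) / s0
  dop[s0 == 0] <- NA_real_
  dop <- pmin(1, pmax(0, dop))
  aop <- wrap180(rad2deg(atan2(s2, s1)) / 2)
  aop[s0 == 0] <- NA_real_
  if (!is.null(dim(i0))) {
    dim(dop) <- dim(i0); dim(aop) <- dim(i0)
  }
  structure(list(intensity = s0, dop = dop, aop = aop), class = "stokes_maps")
}

#' Read / write polarimetric image stacks
#'
#' `read_polarimetric_stack()` loads a 4-page TIFF (page order 0, 45, 90,
#' 135 degrees) or four single-page files; `write_stokes_maps()` writes the
#' derived intensity/DoP/AoP maps as 32-bit float TIFFs.
#'
#' @param path Path to a 4-page TIFF, or a character vector of four paths.
#' @return For `read_polarimetric_stack()`, a named list of four matrices
#'   (`i0`, `i45`, `i90`, `i135`).
#' @export
read_polarimetric_stack <- function(path) {
  imgs <- if (length(path) == 1L) {
    tiff::readTIFF(path, all = TRUE)
  } else if (length(path) == 4L) {
    lapply(path, tiff::readTIFF)
  } else {
    stop_polardrum("supply one 4-page TIFF or four single-page TIFFs", "io_error")
  }
  if (length(imgs) != 4L)
    stop_polardrum("expected exactly four polarizer-angle pages", "io_error")
  imgs <- lapply(imgs, function(m) if (length(dim(m)) == 3L) m[, , 1] else m)
  names(imgs) <- c("i0", "i45", "i90", "i135")
  imgs
}

#' @rdname read_polarimetric_stack
#' @param maps A `stokes_maps` object.
#' @param dir Output directory.
#' @param prefix Filename prefix.
#' @return For `write_stokes_maps()`, the written paths (invisibly).
#' @export
write_stokes_maps <- function(maps, dir, prefix = "stokes") {
  stopifnot(inherits(maps, "stokes_maps"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  norm <- function(m, scale) {
    m[is.na(m)] <- 0
    m / scale
  }
  paths <- c(
    intensity = file.path(dir, paste0(prefix, "_intensity.tif")),
    dop = file.path(dir, paste0(prefix, "_dop.tif")),
    aop = file.path(dir, paste0(prefix, "_aop.tif"))
  )
  tiff::writeTIFF(norm(maps$intensity, max(maps$intensity, 1e-12)),
                  paths[["intensity"]], bits.per.sample = 32L)
  tiff::writeTIFF(norm(maps$dop, 1), paths[["dop"]], bits.per.sample = 32L)
  tiff::writeTIFF(norm(maps$aop, 180), paths[["aop"]], bits.per.sample = 32L)
  invisible(paths)
}
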