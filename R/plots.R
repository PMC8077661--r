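#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a cohort contrast sensitivity curve
#'
#' Thin lines are individuals, the thick line the cohort mean with s.e.m.
#' error bars; the dashed line marks the non-responder sentinel (an
#' impossible Michelson contrast).
#'
#' @param object A `csf_curve`.
#' @param sentinel Sentinel value to mark.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot csf_curve
#' @export
autoplot.csf_curve <- function(object, sentinel = 1.2, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$freq_cpd, y = .data$mean)) +
    ggplot2::geom_line(
      data = object$individual,
      ggplot2::aes(y = .data$threshold, group = .data$subject),
      linewidth = 0.3, alpha = 0.4
    ) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem, ymax = .data$mean + .data$sem),
      width = 0.02
    ) +
    ggplot2::geom_line(linewidth = 1) +
    ggplot2::geom_hline(yintercept = sentinel, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$channel)) +
    ggplot2::labs(x = "spatial frequency (cycles/deg)",
                  y = "threshold (Michelson contrast)") +
    ggplot2::theme_minimal()
}

#' Plot an eye/body angle trace
#'
#' @param object An `eye_trace`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot eye_trace
#' @export
autoplot.eye_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time, .data$angle)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "angle (deg)") +
    ggplot2::theme_minimal()
}

#' Plot a segmented nystagmus trace
#'
#' @param object A `nystagmus_seg`.
#' @param ... Unused.
#' @return A ggplot with samples coloured by phase label.
#' @method autoplot nystagmus_seg
#' @export
autoplot.nystagmus_seg <- function(object, ...) {
  ggplot2::ggplot(object$samples,
                  ggplot2::aes(.data$time, .data$angle, colour = .data$label)) +
    ggplot2::geom_point(size = 0.5) +
    ggplot2::labs(x = "time (s)", y = "eye angle (deg)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot Stokes parameter maps
#'
#' Intensity, degree of polarization and angle of polarization as raster
#' facets.
#'
#' @param maps A `stokes_maps` object.
#' @return A ggplot.
#' @export
plot_stokes_maps <- function(maps) {
  stopifnot(inherits(maps, "stokes_maps"))
  as_tb <- function(m, what) {
    tibble::tibble(
      row = rep(seq_len(nrow(m)), times = ncol(m)),
      col = rep(seq_len(ncol(m)), each = nrow(m)),
      value = as.vector(m), map = what
    )
  }
  df <- dplyr::bind_rows(
    as_tb(maps$intensity, "intensity"),
    as_tb(maps$dop, "DoP"),
    as_tb(maps$aop, "AoP (deg)")
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_wrap(ggplot2::vars(.data$map), scales = "free") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot one rendered panel frame
#'
#' @param frames A `drum_frames` object.
#' @param frame Frame index (1-based).
#' @param panel Panel index (0-based).
#' @param channel `"intensity"` or `"polarization"`.
#' @return A ggplot raster of the drive values.
#' @export
plot_frame <- function(frames, frame = 1L, panel = 0L,
                       channel = c("intensity", "polarization")) {
  stopifnot(inherits(frames, "drum_frames"))
  channel <- match.arg(channel)
  m <- frames$frames[[frame]][[panel + 1L]][[channel]]
  df <- tibble::tibble(
    row = rep(seq_len(nrow(m)), times = ncol(m)),
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    drive = as.vector(m)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$drive)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 255)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("panel %d, %s, t = %.2f s",
                                  panel, channel, frames$times[frame])) +
    ggplot2::theme_minimal()
}
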