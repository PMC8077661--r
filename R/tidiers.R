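#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cohort CSF
#'
#' @param x A `csf_curve`.
#' @param ... Unused.
#' @return The per-frequency cohort summary tibble (`channel`, `freq_cpd`,
#'   `mean`, `sem`, `n`, `n_sentinel`).
#' @method tidy csf_curve
#' @export
tidy.csf_curve <- function(x, ...) x$summary

#' @rdname tidy.csf_curve
#' @return For `glance()`, a one-row tibble with cohort-level facts: the
#'   most sensitive frequency and its mean threshold, subject count, and
#'   the fraction of sentinel (non-responder) entries.
#' @method glance csf_curve
#' @export
glance.csf_curve <- function(x, ...) {
  s <- x$summary
  best <- s[which.min(s$mean), ]
  tibble::tibble(
    n_subjects = dplyr::n_distinct(x$individual$subject),
    n_freqs = dplyr::n_distinct(s$freq_cpd),
    best_freq_cpd = best$freq_cpd[1],
    best_mean_threshold = best$mean[1],
    prop_sentinel = mean(x$individual$is_sentinel)
  )
}

#' Tidy a nystagmus segmentation
#'
#' @param x A `nystagmus_seg`.
#' @param ... Unused.
#' @return The interval tibble (`start`, `end`, `label`, `gain`).
#' @method tidy nystagmus_seg
#' @export
tidy.nystagmus_seg <- function(x, ...) x$intervals

#' @rdname tidy.nystagmus_seg
#' @return For `glance()`, a one-row tibble: saccade count, slow-phase time
#'   fraction and mean slow-phase gain.
#' @method glance nystagmus_seg
#' @export
glance.nystagmus_seg <- function(x, ...) {
  iv <- x$intervals
  total <- max(iv$end) - min(iv$start)
  tibble::tibble(
    n_saccades = sum(iv$label == "saccade"),
    slow_fraction = sum((iv$end - iv$start)[iv$label == "slow_phase"]) / total,
    mean_gain = mean(iv$gain, na.rm = TRUE),
    stim_speed = x$stim_speed
  )
}

#' Tidy a staircase run
#'
#' @param x A `staircase_result`.
#' @param ... Unused.
#' @return The trial-by-trial tibble (`contrast`, `response`).
#' @method tidy staircase_result
#' @export
tidy.staircase_result <- function(x, ...) x$trials

#' @rdname tidy.staircase_result
#' @return For `glance()`, a one-row tibble: threshold, sentinel flag,
#'   trial count and truncation flag.
#' @method glance staircase_result
#' @export
glance.staircase_result <- function(x, ...) {
  tibble::tibble(
    freq_cpd = x$freq, channel = x$channel, threshold = x$threshold,
    is_sentinel = x$is_sentinel, n_trials = nrow(x$trials),
    truncated = x$truncated
  )
}
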