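#' Staircase parameters
#'
#' Controls the descending/bisection contrast staircase: starting at full
#' contrast, the contrast is lowered stepwise until the first
#' non-eliciting level, then the threshold is narrowed by bisecting the
#' bracket between the last eliciting and first non-eliciting contrast.
#'
#' @param start Starting contrast (full contrast, 1).
#' @param step_mode `"multiplicative"` (contrast scaled by `step_factor`
#'   per descending step) or `"additive"` (reduced by `step`).
#' @param step_factor Multiplicative descending step.
#' @param step Additive descending step.
#' @param resolution Bisection stops when the bracket is at most this wide
#'   (Michelson units); chosen below the finest threshold of interest.
#' @param min_contrast Lowest contrast on the grid; an observer that
#'   responds at every tested level down to this floor gets it as the
#'   threshold.
#' @param sentinel Value recorded for a non-responder (no response at full
#'   contrast) — an impossible Michelson contrast so non-responders can
#'   still contribute to cohort averages.
#' @param max_trials Hard trial cap; exceeding it flags truncation.
#' @param n_repeats Presentations per contrast level; the response at a
#'   level is the disjunction over repeats (a single positive counts).
#' @return A list of class `staircase_params`.
#' @export
staircase_params <- function(start = 1, step_mode = c("multiplicative", "additive"),
                             step_factor = 0.5, step = 0.1, resolution = 0.01,
                             min_contrast = 0.01, sentinel = 1.2,
                             max_trials = 50L, n_repeats = 1L) {
  step_mode <- match.arg(step_mode)
  stopifnot(start > 0, start <= 1, resolution > 0, min_contrast > 0,
            min_contrast < start)
  structure(
    list(start = start, step_mode = step_mode, step_factor = step_factor,
         step = step, resolution = resolution, min_contrast = min_contrast,
         sentinel = sentinel, max_trials = as.integer(max_trials),
         n_repeats = as.integer(n_repeats)),
    class = "staircase_params"
  )
}

#' Initialize a staircase
#'
#' @param params A [staircase_params()] list.
#' @return A list of class `staircase_state` holding tested contrasts with
#'   outcomes, the current bracket (`last_yes`, `first_no`) and the phase
#'   (`descending`, `bisecting` or `done`).
#' @export
new_staircase <- function(params = staircase_params()) {
  structure(
    list(trials = tibble::tibble(contrast = numeric(), response = logical()),
         phase = "descending", last_yes = NA_real_, first_no = NA_real_,
         threshold = NA_real_, is_sentinel = FALSE, params = params),
    class = "staircase_state"
  )
}

#' Next contrast to test
#'
#' @param state A `staircase_state`.
#' @return The next contrast to present, or `NULL` when the staircase is
#'   done (the threshold is then in `state$threshold`).
#' @export
staircase_next <- function(state) {
  stopifnot(inherits(state, "staircase_state"))
  p <- state$params
  if (state$phase == "done") return(NULL)
  if (nrow(state$trials) == 0L) return(p$start)
  if (state$phase == "descending") {
    last <- state$trials[nrow(state$trials), ]
    # only called after a response: a non-response switches phase in update
    cand <- if (p$step_mode == "multiplicative") {
      last$contrast * p$step_factor
    } else {
      last$contrast - p$step
    }
    return(max(cand, p$min_contrast))
  }
  # bisecting
  (state$last_yes + state$first_no) / 2
}

#' Record a trial outcome and advance the staircase
#'
#' @param state A `staircase_state`.
#' @param contrast The contrast that was presented.
#' @param response Logical outcome.
#' @return The updated state; check `state$phase == "done"`.
#' @export
staircase_update <- function(state, contrast, response) {
  stopifnot(inherits(state, "staircase_state"))
  p <- state$params
  if (contrast <= 0 && response)
    stop_polardrum("response recorded at contrast 0: protocol error",
                   "protocol_error")
  first_trial <- nrow(state$trials) == 0L
  state$trials <- dplyr::bind_rows(
    state$trials, tibble::tibble(contrast = contrast, response = response))
  if (state$phase == "descending") {
    if (response) {
      state$last_yes <- contrast
      if (contrast <= p$min_contrast) {
        # responded at the grid floor: cannot descend further
        state$phase <- "done"
        state$threshold <- p$min_contrast
      }
    } else if (first_trial) {
      # no response at full contrast: non-responder
      state$phase <- "done"
      state$threshold <- p$sentinel
      state$is_sentinel <- TRUE
    } else {
      state$first_no <- contrast
      state$phase <- "bisecting"
    }
  } else if (state$phase == "bisecting") {
    if (response) state$last_yes <- contrast else state$first_no <- contrast
  }
  if (state$phase == "bisecting" &&
      (state$last_yes - state$first_no) <= p$resolution) {
    state$phase <- "done"
    state$threshold <- state$last_yes   # the responding bound of the bracket
  }
  state
}

#' Run a full staircase against an observer
#'
#' Drives [staircase_next()]/[staircase_update()] to completion for one
#' (frequency, channel) combination. Deterministic given the seed and the
#' observer.
#'
#' @param observer A response function `f(freq, contrast, channel)`
#'   returning a logical, e.g. from [as_observer_fn()].
#' @param freq Spatial frequency, cycles/deg.
#' @param channel `"intensity"` or `"polarization"`.
#' @param params A [staircase_params()] list.
#' @param seed Optional integer seed isolating the staircase's randomness.
#' @return A list of class `staircase_result`: `threshold`, `is_sentinel`,
#'   `truncated`, `freq`, `channel` and the trial-by-trial `trials` tibble.
#' @export
run_staircase <- function(observer, freq, channel = "intensity",
                          params = staircase_params(), seed = NULL) {
  with_seed(seed, {
    state <- new_staircase(params)
    truncated <- FALSE
    repeat {
      cont <- staircase_next(state)
      if (is.null(cont)) break
      if (nrow(state$trials) >= params$max_trials) {
        truncated <- TRUE
        state$phase <- "done"
        state$threshold <- if (is.na(state$last_yes)) params$sentinel else state$last_yes
        state$is_sentinel <- is.na(state$last_yes)
        break
      }
      resp <- any(vapply(seq_len(params$n_repeats), function(i)
        isTRUE(observer(freq, cont, channel)), logical(1)))
      state <- staircase_update(state, cont, resp)
    }
    structure(
      list(threshold = state$threshold, is_sentinel = state$is_sentinel,
           truncated = truncated, freq = freq, channel = channel,
           trials = state$trials, params = params),
      class = "staircase_result"
    )
  })
}

#' @export
print.staircase_result <- function(x, ...) {
  cat(sprintf("<staircase_result> %s @ %.3g cyc/deg: threshold %.4g%s, %d trials%s\n",
              x$channel, x$freq, x$threshold,
              if (x$is_sentinel) " (non-responder sentinel)" else "",
              nrow(x$trials), if (x$truncated) " [truncated]" else ""))
  invisible(x)
}

#' Contrast thresholds across a frequency set for one subject
#'
#' Runs one independent staircase per frequency (no inter-frequency
#' carry-over), presenting frequencies in seeded random order as in the
#' behavioural protocol.
#'
#' @inheritParams run_staircase
#' @param freqs Spatial frequencies, cycles/deg.
#' @param subject Subject identifier carried into the output.
#' @param seed Integer seed controlling presentation order and any
#'   observer randomness.
#' @return A tibble: `subject`, `channel`, `freq_cpd`, `threshold`,
#'   `is_sentinel`, `truncated`, `n_trials`.
#' @export
csf_thresholds <- function(observer, freqs = seq(0.02, 0.2, by = 0.02),
                           channel = "intensity", subject = "s1",
                           params = staircase_params(), seed = NULL) {
  ord <- with_seed(seed, sample.int(length(freqs)))
  res <- purrr::map(freqs[ord], function(f)
    run_staircase(observer, f, channel, params,
                  seed = if (is.null(seed)) NULL else seed + round(1e4 * f)))
  tibble::tibble(
    subject = subject,
    channel = channel,
    freq_cpd = freqs[ord],
    threshold = purrr::map_dbl(res, "threshold"),
    is_sentinel = purrr::map_lgl(res, "is_sentinel"),
    truncated = purrr::map_lgl(res, "truncated"),
    n_trials = purrr::map_int(res, ~ nrow(.x$trials))
  ) |>
    dplyr::arrange(.data$freq_cpd)
}

#' Assemble individual thresholds into a cohort CSF
#'
#' Computes the cohort mean and s.e.m. of the threshold contrast per
#' (channel, frequency). Non-responder sentinels (1.2 by default) are
#' averaged in — they are assigned precisely so that non-responding
#' individuals still contribute to the cohort curve.
#'
#' @param thresholds A tibble as returned by [csf_thresholds()] (rows from
#'   several subjects may be bound together).
#' @return An object of class `csf_curve`: list with `individual` (the
#'   input) and `summary` (`channel`, `freq_cpd`, `mean`, `sem`, `n`,
#'   `n_sentinel`). `sem` is 0 for a single subject by convention.
#' @export
assemble_csf <- function(thresholds) {
  ind <- tibble::as_tibble(thresholds)
  if (nrow(ind) == 0L)
    stop_polardrum("no thresholds to assemble", "invalid_records")
  summary <- ind |>
    dplyr::group_by(.data$channel, .data$freq_cpd) |>
    dplyr::summarise(
      mean = mean(.data$threshold),
      sem = if (dplyr::n() > 1)
        stats::sd(.data$threshold) / sqrt(dplyr::n()) else 0,
      n = dplyr::n(),
      n_sentinel = sum(.data$is_sentinel),
      .groups = "drop"
    )
  structure(list(individual = ind, summary = summary), class = "csf_curve")
}

#' @export
print.csf_curve <- function(x, ...) {
  cat(sprintf("<csf_curve> %d subjects x %d frequencies, %d channel(s)\n",
              dplyr::n_distinct(x$individual$subject),
              dplyr::n_distinct(x$individual$freq_cpd),
              dplyr::n_distinct(x$individual$channel)))
  print(x$summary)
  invisible(x)
}
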