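#' Detect fixations with a dispersion-threshold (I-DT) algorithm
#'
#' Segments a raw gaze sample stream into fixations: maximal time windows
#' whose spatial dispersion `(max(x) - min(x)) + (max(y) - min(y))` stays at
#' or below `dispersion_px` and that last at least `min_duration_ms`.
#' Invalid samples are removed before grouping, and a hole in the sample
#' stream longer than `max_gap_ms` (a blink or tracking loss) never lies
#' inside a fixation window. The scan is greedy from the left: whenever the
#' minimal window spanning `min_duration_ms` is coherent it is grown to the
#' maximal coherent window and emitted.
#'
#' The defaults (40 px, 100 ms) approximate the customary ~1 degree /
#' 100 ms settings at about 70 cm viewing distance on a typical monitor,
#' and suit consumer-grade trackers sampling near 90 Hz.
#'
#' @param samples Tibble with columns `t_ms`, `x_px`, `y_px` and optionally
#'   `valid` (see [read_gaze_csv()]).
#' @param dispersion_px Maximum window dispersion in pixels (> 0).
#' @param min_duration_ms Minimum fixation duration in ms (> 0).
#' @param max_gap_ms Largest between-sample gap tolerated inside a fixation
#'   window, in ms.
#' @return A tibble of fixations ordered by onset, with columns `t_start`
#'   (ms), `duration` (ms), `cx`, `cy` (centroid, px) and `n_samples`. Zero
#'   valid samples yield an empty tibble, not an error.
#' @examples
#' samples <- tibble::tibble(
#'   t_ms = seq(0, 1000, length.out = 90),
#'   x_px = 100, y_px = 100, valid = TRUE
#' )
#' detect_fixations(samples)
#' @export
detect_fixations <- function(samples, dispersion_px = 40,
                             min_duration_ms = 100, max_gap_ms = 200) {
  stopifnot(all(c("t_ms", "x_px", "y_px") %in% names(samples)))
  if (!is.numeric(dispersion_px) || length(dispersion_px) != 1 || dispersion_px <= 0 ||
      !is.numeric(min_duration_ms) || length(min_duration_ms) != 1 || min_duration_ms <= 0 ||
      !is.numeric(max_gap_ms) || length(max_gap_ms) != 1 || max_gap_ms <= 0) {
    abort("dispersion_px, min_duration_ms and max_gap_ms must be positive scalars",
          class = "gazeread_validation_error")
  }
  valid <- if (is.null(samples$valid)) rep(TRUE, nrow(samples)) else samples$valid
  keep <- valid & is.finite(samples$t_ms) &
    is.finite(samples$x_px) & is.finite(samples$y_px)
  s <- samples[keep, , drop = FALSE]
  if (nrow(s) == 0) {
    return(tibble::tibble(t_start = double(), duration = double(),
                          cx = double(), cy = double(), n_samples = integer()))
  }
  s <- s[order(s$t_ms), , drop = FALSE]
  tibble::as_tibble(.idt_cpp(s$t_ms, s$x_px, s$y_px,
                             dispersion_px, min_duration_ms, max_gap_ms))
}

#' Saccade velocity
#'
#' Velocity of a saccade in px/ms: the absolute length divided by the
#' duration.
#'
#' @param signed_length Signed saccade length along the reading axis (px);
#'   vectorized.
#' @param duration Saccade duration (ms), strictly positive; vectorized.
#' @return `abs(signed_length) / duration` in px/ms.
#' @examples
#' saccade_velocity(160, 500) # 0.32
#' @export
saccade_velocity <- function(signed_length, duration) {
  if (any(!is.finite(duration)) || any(duration <= 0)) {
    abort("saccade duration must be strictly positive",
          class = "gazeread_domain_error")
  }
  abs(signed_length) / duration
}

#' Build saccades between consecutive fixations
#'
#' One saccade connects each pair of consecutive fixations. The signed
#' length is the displacement of the destination centroid from the source
#' centroid projected on the reading axis (for left-to-right text, the
#' change in `cx`); a saccade is `backward` (a regression or a return sweep
#' to the next line) iff its signed length is negative, and `forward`
#' otherwise, so a zero displacement counts as forward. The duration is the
#' gap between the end of the source fixation and the start of the
#' destination fixation, floored at one nominal inter-sample interval so
#' the velocity stays defined when fixation windows abut.
#'
#' @param fixations Fixation tibble from [detect_fixations()], ordered by
#'   onset.
#' @param reading_axis One of `"horizontal_lr"` (default), `"horizontal_rl"`,
#'   `"vertical_tb"`.
#' @param sampling_rate_hz Nominal tracker sampling rate, used only for the
#'   duration floor.
#' @return A tibble of saccades with columns `t_start`, `duration` (ms),
#'   `signed_length` (px), `velocity` (px/ms) and `direction`
#'   (`"forward"`/`"backward"`). Fewer than two fixations yield an empty
#'   tibble.
#' @export
build_saccades <- function(fixations,
                           reading_axis = c("horizontal_lr", "horizontal_rl", "vertical_tb"),
                           sampling_rate_hz = 90) {
  reading_axis <- match.arg(reading_axis)
  empty <- tibble::tibble(t_start = double(), duration = double(),
                          signed_length = double(), velocity = double(),
                          direction = character())
  n <- nrow(fixations)
  if (n < 2) return(empty)
  proj <- switch(reading_axis,
    horizontal_lr = diff(fixations$cx),
    horizontal_rl = -diff(fixations$cx),
    vertical_tb = diff(fixations$cy)
  )
  t_end <- fixations$t_start + fixations$duration
  gap <- fixations$t_start[-1] - t_end[-n]
  dur <- pmax(gap, 1000 / sampling_rate_hz)
  tibble::tibble(
    t_start = t_end[-n],
    duration = dur,
    signed_length = proj,
    velocity = saccade_velocity(proj, dur),
    direction = ifelse(proj < 0, "backward", "forward")
  )
}

#' Detect fixations and saccades in one step
#'
#' Convenience wrapper chaining [detect_fixations()] and [build_saccades()]
#' for a single recording.
#'
#' @inheritParams detect_fixations
#' @inheritParams build_saccades
#' @return An object of class `gaze_events`: a list with tibbles
#'   `fixations` and `saccades`.
#' @export
detect_events <- function(samples, dispersion_px = 40, min_duration_ms = 100,
                          max_gap_ms = 200,
                          reading_axis = c("horizontal_lr", "horizontal_rl", "vertical_tb"),
                          sampling_rate_hz = 90) {
  reading_axis <- match.arg(reading_axis)
  fix <- detect_fixations(samples, dispersion_px, min_duration_ms, max_gap_ms)
  sac <- build_saccades(fix, reading_axis, sampling_rate_hz)
  structure(list(fixations = fix, saccades = sac), class = "gaze_events")
}

#' @export
print.gaze_events <- function(x, ...) {
  nb <- sum(x$saccades$direction == "backward")
  cat("<gaze_events>", nrow(x$fixations), "fixations,",
      nrow(x$saccades), "saccades (", nb, "backward )\n")
  invisible(x)
}

#' Detect events for every recording of a cohort
#'
#' Maps [detect_events()] over a recordings tibble (for instance the
#' `recordings` element of [simulate_cohort()]'s result).
#'
#' @param recordings Tibble with columns `participant_id`, `text_id` and a
#'   list-column `samples` of gaze sample tibbles.
#' @inheritParams detect_events
#' @return The input tibble with `samples` replaced by a list-column
#'   `events` of `gaze_events`.
#' @export
extract_events <- function(recordings, dispersion_px = 40, min_duration_ms = 100,
                           max_gap_ms = 200,
                           reading_axis = c("horizontal_lr", "horizontal_rl", "vertical_tb"),
                           sampling_rate_hz = 90) {
  reading_axis <- match.arg(reading_axis)
  stopifnot(all(c("participant_id", "text_id", "samples") %in% names(recordings)))
  recordings |>
    dplyr::mutate(events = purrr::map(.data$samples, detect_events,
                                      dispersion_px = dispersion_px,
                                      min_duration_ms = min_duration_ms,
                                      max_gap_ms = max_gap_ms,
                                      reading_axis = reading_axis,
                                      sampling_rate_hz = sampling_rate_hz)) |>
    dplyr::select(-"samples")
}
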