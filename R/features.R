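pop_sd <- function(v) {
  n <- length(v)
  if (n == 0) return(0)
  sqrt(mean((v - mean(v))^2))
}

sd_by <- function(v, method) {
  if (method == "population") return(pop_sd(v))
  if (length(v) < 2) return(0)
  sd(v)
}

#' Compute the four normalized gaze features of one recording
#'
#' The per-recording feature vector `V = [f1 f2 f3 f4]`:
#' * `f1` number of fixations per text character,
#' * `f2` number of forward saccades per character,
#' * `f3` number of backward saccades (regressions and return sweeps) per
#'   character,
#' * `f4` standard deviation of the saccade velocities of the recording
#'   (px/ms, no length normalization needed).
#'
#' Counts are divided by the character count of the text so that texts of
#' different lengths are comparable. A recording without saccades yields
#' `f2 = f3 = f4 = 0` with a warning.
#'
#' @param events A `gaze_events` object from [detect_events()], or a
#'   fixation tibble (then `saccades` must be given).
#' @param n_chars Number of characters in the text (>= 1).
#' @param saccades Saccade tibble when `events` is a fixation tibble.
#' @param sd_method `"population"` (divide by n, the default) or
#'   `"sample"` (divide by n-1) for `f4`.
#' @return A one-row tibble with columns `f1`..`f4`.
#' @examples
#' ev <- structure(list(
#'   fixations = tibble::tibble(t_start = 1:10, duration = 1, cx = 0, cy = 0),
#'   saccades = tibble::tibble(
#'     velocity = rep(c(0.2, 0.4), each = 4),
#'     direction = rep(c("forward", "backward"), c(6, 2))
#'   )
#' ), class = "gaze_events")
#' compute_features(ev, n_chars = 20) # 0.5 0.3 0.1 0.1
#' @export
compute_features <- function(events, n_chars, saccades = NULL,
                             sd_method = c("population", "sample")) {
  sd_method <- match.arg(sd_method)
  if (!is.numeric(n_chars) || length(n_chars) != 1 || n_chars < 1) {
    abort("n_chars must be a scalar >= 1", class = "gazeread_validation_error")
  }
  if (inherits(events, "gaze_events")) {
    fixations <- events$fixations
    saccades <- events$saccades
  } else {
    fixations <- events
    if (is.null(saccades)) {
      abort("saccades must be supplied when events is a fixation tibble",
            class = "gazeread_validation_error")
    }
  }
  n_sac <- nrow(saccades)
  if (n_sac == 0) {
    warn("recording has no saccades; f2, f3 and f4 are 0")
    return(tibble::tibble(f1 = nrow(fixations) / n_chars, f2 = 0, f3 = 0, f4 = 0))
  }
  tibble::tibble(
    f1 = nrow(fixations) / n_chars,
    f2 = sum(saccades$direction == "forward") / n_chars,
    f3 = sum(saccades$direction == "backward") / n_chars,
    f4 = sd_by(saccades$velocity, sd_method)
  )
}

#' Extract per-recording feature vectors for a cohort
#'
#' Runs event detection (unless already done) and feature computation for
#' every recording, returning one row per (participant, text).
#'
#' @param recordings Tibble with `participant_id`, `text_id` and either a
#'   list-column `samples` (raw gaze) or `events` (`gaze_events`).
#' @param texts Tibble with `text_id` and `n_chars` (see
#'   [read_manifest()]).
#' @inheritParams detect_events
#' @inheritParams compute_features
#' @return A tibble `participant_id`, `text_id`, `f1`..`f4`.
#' @export
extract_features <- function(recordings, texts, dispersion_px = 40,
                             min_duration_ms = 100, max_gap_ms = 200,
                             reading_axis = c("horizontal_lr", "horizontal_rl", "vertical_tb"),
                             sampling_rate_hz = 90,
                             sd_method = c("population", "sample")) {
  reading_axis <- match.arg(reading_axis)
  sd_method <- match.arg(sd_method)
  stopifnot(all(c("text_id", "n_chars") %in% names(texts)))
  if (!"events" %in% names(recordings)) {
    recordings <- extract_events(recordings, dispersion_px, min_duration_ms,
                                 max_gap_ms, reading_axis, sampling_rate_hz)
  }
  missing_tx <- setdiff(recordings$text_id, texts$text_id)
  if (length(missing_tx) > 0) {
    abort(paste0("recordings reference unknown text_id(s): ",
                 paste(missing_tx, collapse = ", ")),
          class = "gazeread_reference_error")
  }
  recordings |>
    dplyr::left_join(texts[, c("text_id", "n_chars")], by = "text_id") |>
    dplyr::mutate(features = purrr::map2(.data$events, .data$n_chars,
                                         compute_features, sd_method = sd_method)) |>
    dplyr::select("participant_id", "text_id", "features") |>
    tidyr::unnest("features")
}

#' Descriptive statistics of detected eye-movement events
#'
#' Summarizes unnormalized per-recording quantities (fixation count, mean
#' fixation duration, forward / backward saccade counts and lengths,
#' forward/backward ratio, mean saccade velocity) across recordings:
#' per-recording values are computed first, then averaged. Backward saccade
#' lengths are reported signed (negative); the forward/backward ratio is
#' missing for recordings without backward saccades.
#'
#' @param events_tbl Tibble with a list-column `events` of `gaze_events`
#'   (see [extract_events()]).
#' @param sd_method Standard-deviation convention across recordings.
#' @return A tibble with columns `metric`, `mean`, `sd`.
#' @export
descriptive_stats <- function(events_tbl, sd_method = c("population", "sample")) {
  sd_method <- match.arg(sd_method)
  stopifnot("events" %in% names(events_tbl))
  if (nrow(events_tbl) == 0) {
    abort("need at least one recording", class = "gazeread_validation_error")
  }
  per <- purrr::map_dfr(events_tbl$events, function(ev) {
    fix <- ev$fixations
    sac <- ev$saccades
    fwd <- sac$signed_length[sac$direction == "forward"]
    bwd <- sac$signed_length[sac$direction == "backward"]
    tibble::tibble(
      fixation_count = nrow(fix),
      fixation_duration_ms = if (nrow(fix)) mean(fix$duration) else NA_real_,
      forward_saccade_count = length(fwd),
      backward_saccade_count = length(bwd),
      forward_backward_ratio = if (length(bwd)) length(fwd) / length(bwd) else NA_real_,
      saccade_velocity = if (nrow(sac)) mean(sac$velocity) else NA_real_,
      forward_saccade_length = if (length(fwd)) mean(fwd) else NA_real_,
      backward_saccade_length = if (length(bwd)) mean(bwd) else NA_real_
    )
  })
  per |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "metric") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      sd = sd_by(.data$value[!is.na(.data$value)], sd_method),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$metric, names(per)))
}

#' Correlate gaze features with self-rated understanding
#'
#' Pearson correlation (with two-sided p-value) between each feature and
#' the self-rated understanding, either per recording (default) or on
#' per-participant averages. Aborted texts (rating 1) are excluded. A
#' feature with zero variance gets a missing correlation.
#'
#' @param features Per-recording feature tibble (see [extract_features()]).
#' @param outcomes Outcome tibble with `participant_id`, `text_id`,
#'   `rating` (see [read_manifest()]).
#' @param by `"recording"` or `"participant"`.
#' @return A tibble `feature`, `estimate` (Pearson r), `p_value`.
#' @export
feature_rating_correlation <- function(features, outcomes,
                                       by = c("recording", "participant")) {
  by <- match.arg(by)
  df <- features |>
    dplyr::inner_join(outcomes[, c("participant_id", "text_id", "rating")],
                      by = c("participant_id", "text_id")) |>
    dplyr::filter(.data$rating >= 2)
  if (by == "participant") {
    df <- df |>
      dplyr::group_by(.data$participant_id) |>
      dplyr::summarise(dplyr::across(c("f1", "f2", "f3", "f4", "rating"), mean),
                       .groups = "drop")
  }
  if (nrow(df) < 3) {
    abort("need at least 3 paired observations", class = "gazeread_validation_error")
  }
  purrr::map_dfr(c("f1", "f2", "f3", "f4"), function(f) {
    v <- df[[f]]
    if (pop_sd(v) == 0 || pop_sd(df$rating) == 0) {
      return(tibble::tibble(feature = f, estimate = NA_real_, p_value = NA_real_))
    }
    ct <- cor.test(v, df$rating, method = "pearson")
    tibble::tibble(feature = f, estimate = unname(ct$estimate),
                   p_value = ct$p.value)
  })
}
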