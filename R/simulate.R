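#' Parameters of a virtual reader
#'
#' Bundles the generative parameters of the synthetic reading model for a
#' reader with latent understanding `u` on the continuous scale `[2, 5]`
#' (2 = understood almost nothing, 5 = understood everything). The
#' u-dependent rate profiles interpolate piecewise-linearly through the
#' empirical per-understanding feature means of the study cohort the
#' simulator emulates:
#' fixations per character falling from 0.74 at u = 2 to 0.46 at u = 5,
#' backward saccades per character rising from 0.08 to 0.14, and the
#' dispersion of saccade velocities falling from 0.20 to 0.12 px/ms. The
#' probability of answering the comprehension question correctly rises
#' linearly from 0.4 at u = 2 to 0.79 at u = 5, keeping the answer baseline
#' informative but weaker than the gaze features.
#'
#' Fixation dwell times are lognormal with mean 291.48 ms and standard
#' deviation 70.11 ms (u-independent), truncated below at 120 ms so every
#' dwell clears the detector's minimum-duration threshold. Saccade
#' velocities are Gamma distributed with mean `velocity_mean` and
#' u-dependent standard deviation; the inter-fixation interval is the
#' saccade length divided by that velocity, mimicking a consumer tracker
#' that loses samples during fast movement.
#'
#' @param u Latent understanding in `[2, 5]`.
#' @param fixations_per_char,backward_per_char,velocity_sd Functions of u
#'   giving the target fixation rate, backward-saccade rate (both per
#'   character) and velocity dispersion (px/ms); defaults interpolate the
#'   profiles above.
#' @param answer_accuracy Function of u giving the probability of a correct
#'   answer.
#' @param velocity_mean Mean saccade velocity in px/ms.
#' @param fixation_duration_mean_ms,fixation_duration_sd_ms Moments of the
#'   lognormal dwell distribution.
#' @param noise_sd_px Additive Gaussian position noise per sample.
#' @param sampling_rate_hz Nominal tracker sampling rate.
#' @param invalid_rate Fraction of samples flagged invalid (tracking loss).
#' @param text_sd Lognormal sd of the per-text multiplier on the fixation
#'   rate (between-text variability).
#' @param char_pitch_px Horizontal advance per character (a 30 pt CJK glyph
#'   including spacing).
#' @param chars_per_line,line_spacing_px Virtual text layout.
#' @param regression_jump_px Range (min, max) of regression jump lengths.
#' @return A list of class `reader_params`.
#' @seealso [simulate_recording()], [simulate_cohort()]
#' @export
reader_params <- function(u = 3.5,
                          fixations_per_char = NULL,
                          backward_per_char = NULL,
                          velocity_sd = NULL,
                          answer_accuracy = NULL,
                          velocity_mean = 0.32,
                          fixation_duration_mean_ms = 291.48,
                          fixation_duration_sd_ms = 70.11,
                          noise_sd_px = 2,
                          sampling_rate_hz = 90,
                          invalid_rate = 0.005,
                          text_sd = 0.08,
                          char_pitch_px = 45,
                          chars_per_line = 21,
                          line_spacing_px = 50,
                          regression_jump_px = c(70, 180)) {
  if (!is.numeric(u) || length(u) != 1 || u < 2 || u > 5) {
    abort("u must be a scalar in [2, 5]", class = "gazeread_validation_error")
  }
  uu <- c(2, 3, 4, 5)
  fp <- fixations_per_char %||% approxfun(uu, c(0.74, 0.71, 0.61, 0.46), rule = 2)
  bp <- backward_per_char %||% approxfun(uu, c(0.08, 0.09, 0.11, 0.14), rule = 2)
  vs <- velocity_sd %||% approxfun(uu, c(0.20, 0.18, 0.16, 0.12), rule = 2)
  aa <- answer_accuracy %||% function(u) pmin(1, pmax(0, 0.4 + 0.13 * (u - 2)))
  stopifnot(velocity_mean > 0, fixation_duration_mean_ms > 0,
            sampling_rate_hz > 0, noise_sd_px >= 0, invalid_rate >= 0,
            invalid_rate < 1, char_pitch_px > 0, chars_per_line >= 10,
            line_spacing_px > 0, length(regression_jump_px) == 2,
            all(regression_jump_px > 0))
  structure(
    list(u = u, fixations_per_char = fp, backward_per_char = bp,
         velocity_sd = vs, answer_accuracy = aa,
         velocity_mean = velocity_mean,
         fixation_duration_mean_ms = fixation_duration_mean_ms,
         fixation_duration_sd_ms = fixation_duration_sd_ms,
         noise_sd_px = noise_sd_px, sampling_rate_hz = sampling_rate_hz,
         invalid_rate = invalid_rate, text_sd = text_sd,
         char_pitch_px = char_pitch_px, chars_per_line = chars_per_line,
         line_spacing_px = line_spacing_px,
         regression_jump_px = regression_jump_px),
    class = "reader_params"
  )
}

# Designed scanpath: fixation centroids, dwells and inter-fixation gaps for
# one reading of a text. Returns centroids plus the designed event counts.
sim_scanpath <- function(params, n_chars) {
  p <- params
  n_lines <- ceiling(n_chars / p$chars_per_line)
  line_chars <- rep(p$chars_per_line, n_lines)
  line_chars[n_lines] <- n_chars - (n_lines - 1) * p$chars_per_line
  f1_nom <- p$fixations_per_char(p$u)
  f3_nom <- p$backward_per_char(p$u)
  f1 <- f1_nom * exp(rnorm(1, 0, p$text_sd))
  n_fix <- max(n_lines + 1, round(f1 * n_chars))
  n_trans <- n_fix - 1
  n_sweeps <- n_lines - 1
  bfrac <- f3_nom / max(f1_nom - 1 / n_chars, 1e-9)
  n_back <- min(max(round(bfrac * n_trans), n_sweeps), n_trans)
  n_regr <- n_back - n_sweeps
  n_base <- n_fix - n_regr

  # base left-to-right path over the virtual lines
  k_l <- diff(round(cumsum(c(0, line_chars)) / n_chars * n_base))
  k_l <- pmax(k_l, 1)
  while (sum(k_l) > n_base) k_l[which.max(k_l)] <- k_l[which.max(k_l)] - 1
  cx <- unlist(lapply(seq_len(n_lines), function(l) {
    w <- line_chars[l] * p$char_pitch_px
    ((seq_len(k_l[l]) - 0.5) / k_l[l]) * w + runif(k_l[l], -3, 3)
  }), use.names = FALSE)
  cy <- rep((seq_len(n_lines) - 1) * p$line_spacing_px, k_l) +
    runif(sum(k_l), -3, 3)
  line_of <- rep(seq_len(n_lines), k_l)
  n_base <- length(cx)

  # insert regressions after eligible within-line base fixations
  jump_min <- p$regression_jump_px[1]
  eligible <- which(line_of[-n_base] == line_of[-1] & cx[-n_base] >= jump_min + 20)
  n_regr <- min(n_regr, length(eligible))
  slots <- if (n_regr > 0) sort(sample(eligible, n_regr)) else integer(0)
  insert_after <- rep(0L, n_base)
  insert_after[slots] <- 1L
  idx <- rep(seq_len(n_base), 1L + insert_after)
  cx_full <- cx[idx]
  cy_full <- cy[idx]
  is_regr <- duplicated(idx)
  if (n_regr > 0) {
    jmp <- runif(n_regr, jump_min, p$regression_jump_px[2])
    jmp <- pmin(jmp, cx_full[is_regr] - 10)
    cx_full[is_regr] <- cx_full[is_regr] - jmp
    cy_full[is_regr] <- cy_full[is_regr] + runif(n_regr, -3, 3)
  }
  list(cx = cx_full, cy = cy_full,
       n_fixations = length(cx_full),
       n_backward = sum(diff(cx_full) < 0),
       n_forward = sum(diff(cx_full) >= 0))
}

#' Simulate one raw gaze recording
#'
#' Generates the gaze sample stream of a virtual reader with latent
#' understanding `params$u` reading one text: the text is laid out on
#' virtual lines, a fixation sequence advances left to right with
#' regression jumps at the u-dependent backward rate and a return sweep at
#' each line end, every fixation dwells for a lognormal duration, and the
#' tracker renders samples at `sampling_rate_hz` with additive Gaussian
#' position noise (no samples are emitted mid-saccade, as consumer trackers
#' lose the eye during fast movement). The result is deterministic given
#' `seed`.
#'
#' @param params A [reader_params()] object.
#' @param n_chars Number of characters of the simulated text.
#' @param seed Optional integer seed; when given, the global RNG state is
#'   left untouched.
#' @return A tibble of gaze samples (`t_ms`, `x_px`, `y_px`, `valid`) with
#'   the designed event counts attached as attribute `"design"`.
#' @examples
#' rec <- simulate_recording(reader_params(u = 4), n_chars = 60, seed = 7)
#' detect_fixations(rec)
#' @export
simulate_recording <- function(params, n_chars = 210, seed = NULL) {
  stopifnot(inherits(params, "reader_params"), n_chars >= 1)
  run <- function() {
    p <- params
    path <- sim_scanpath(p, n_chars)
    n_fix <- path$n_fixations
    dt <- 1000 / p$sampling_rate_hz

    sdlog <- sqrt(log(1 + (p$fixation_duration_sd_ms / p$fixation_duration_mean_ms)^2))
    meanlog <- log(p$fixation_duration_mean_ms) - sdlog^2 / 2
    dwell <- pmax(120, rlnorm(n_fix, meanlog, sdlog))

    dx <- diff(path$cx)
    v_sd <- p$velocity_sd(p$u)
    shape <- (p$velocity_mean / v_sd)^2
    vel <- pmax(rgamma(n_fix - 1, shape = shape, rate = shape / p$velocity_mean), 0.02)
    gap <- pmax(abs(dx) / vel, 2 * dt)
    starts <- cumsum(c(0, dwell[-n_fix] + gap))

    m <- pmax(1L, as.integer(round(dwell / dt)))
    t <- rep(starts, m + 1L) + (sequence(m + 1L) - 1) * rep(dwell / m, m + 1L)
    ns <- length(t)
    x <- rep(path$cx, m + 1L) + rnorm(ns, 0, p$noise_sd_px)
    y <- rep(path$cy, m + 1L) + rnorm(ns, 0, p$noise_sd_px)
    valid <- runif(ns) >= p$invalid_rate
    x[!valid] <- 0
    y[!valid] <- 0
    out <- tibble::tibble(t_ms = t, x_px = x, y_px = y, valid = valid)
    attr(out, "design") <- list(u = p$u, n_fixations = path$n_fixations,
                                n_backward = path$n_backward,
                                n_forward = path$n_forward)
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# Atom weights on u in {2,3,4,5} whose induced rating distribution (after
# round(u + N(0, noise_sd)) clamped to 2..5) matches the target proportions.
atom_weights <- function(rating_probs, noise_sd) {
  p <- rating_probs / sum(rating_probs)
  a <- 2:5
  M <- sapply(a, function(atom) {
    c(pnorm(2.5 - atom, sd = noise_sd),
      pnorm(3.5 - atom, sd = noise_sd) - pnorm(2.5 - atom, sd = noise_sd),
      pnorm(4.5 - atom, sd = noise_sd) - pnorm(3.5 - atom, sd = noise_sd),
      1 - pnorm(4.5 - atom, sd = noise_sd))
  })
  w <- solve(M, p)
  w[w < 0] <- 0
  w / sum(w)
}

#' Simulate a reading cohort
#'
#' Generates a full study-shaped cohort: each participant draws a latent
#' understanding level once (from atoms 2..5 weighted so that the marginal
#' self-rating distribution matches `rating_probs`, by default the
#' non-aborted rating proportions of the emulated study: 45/23/74/137 for
#' ratings 2/3/4/5), then reads every text; per text the self-rating is the
#' latent level jittered by `N(0, rating_noise_sd)`, rounded and clamped to
#' 2..5, the comprehension answer is Bernoulli with the u-dependent
#' accuracy, and a raw gaze recording is simulated with
#' [simulate_recording()]. Deterministic given `seed`.
#'
#' @param n_participants,n_texts Cohort shape (defaults 17 and 19, the
#'   emulated study's).
#' @param n_chars Characters per text (default 210), recycled to
#'   `n_texts`.
#' @param seed Mandatory integer seed.
#' @param rating_probs Named or positional weights over ratings 2..5.
#' @param rating_noise_sd Standard deviation of the self-rating jitter.
#' @param p_abort Probability that a participant aborts a text (rating 1;
#'   the recording then covers only a quarter of the text). Default 0.
#' @param keep_gaze If `FALSE`, skip rendering gaze samples (fast; only
#'   outcomes and ground truth are produced).
#' @param reader_args Extra arguments passed to [reader_params()] for every
#'   participant.
#' @return An object of class `gaze_cohort`: a list with tibbles
#'   `recordings` (`participant_id`, `text_id`, `samples` list-column;
#'   absent if `keep_gaze = FALSE`), `texts`, `outcomes` and `truth`
#'   (`participant_id`, `text_id`, `u_true`, `rating`, `answer_correct`).
#' @examples
#' coh <- simulate_cohort(n_participants = 3, n_texts = 2, n_chars = 40,
#'                        seed = 1)
#' coh$outcomes
#' @export
simulate_cohort <- function(n_participants = 17, n_texts = 19, n_chars = 210,
                            seed, rating_probs = c(45, 23, 74, 137) / 279,
                            rating_noise_sd = 0.3, p_abort = 0,
                            keep_gaze = TRUE, reader_args = list()) {
  if (missing(seed)) {
    abort("simulate_cohort requires a seed", class = "gazeread_validation_error")
  }
  if (n_participants < 3) {
    abort("need at least 3 participants", class = "gazeread_validation_error")
  }
  stopifnot(n_texts >= 1, length(rating_probs) == 4, all(rating_probs >= 0))
  n_chars <- rep_len(as.integer(n_chars), n_texts)
  withr::with_seed(seed, {
    w <- atom_weights(rating_probs, rating_noise_sd)
    pid <- sprintf("P%02d", seq_len(n_participants))
    tid <- sprintf("T%02d", seq_len(n_texts))
    texts <- tibble::tibble(
      text_id = tid, n_chars = n_chars,
      level = rep_len(c("N2", "N3", "N4", "N5"), n_texts)
    )
    u_true <- sample(c(2, 3, 4, 5), n_participants, replace = TRUE, prob = w)
    params <- lapply(u_true, function(u) {
      do.call(reader_params, c(list(u = u), reader_args))
    })
    grid_i <- rep(seq_len(n_participants), each = n_texts)
    grid_j <- rep(seq_len(n_texts), n_participants)
    n_rec <- length(grid_i)
    aborted <- if (p_abort > 0) runif(n_rec) < p_abort else rep(FALSE, n_rec)
    rating <- as.integer(pmin(5, pmax(2, round(u_true[grid_i] +
                                                 rnorm(n_rec, 0, rating_noise_sd)))))
    rating[aborted] <- 1L
    acc <- vapply(seq_len(n_participants),
                  function(i) params[[i]]$answer_accuracy(u_true[i]), numeric(1))
    truth <- tibble::tibble(
      participant_id = pid[grid_i], text_id = tid[grid_j],
      u_true = u_true[grid_i], rating = rating,
      answer_correct = rbinom(n_rec, 1, acc[grid_i])
    )
    recs <- NULL
    if (keep_gaze) {
      nc <- ifelse(aborted, pmax(10L, as.integer(round(0.25 * n_chars[grid_j]))),
                   n_chars[grid_j])
      recs <- lapply(seq_len(n_rec), function(k) {
        simulate_recording(params[[grid_i[k]]], n_chars = nc[k])
      })
    }
    outcomes <- truth |>
      dplyr::mutate(excluded = .data$rating == 1L) |>
      dplyr::select("participant_id", "text_id", "rating", "answer_correct",
                    "excluded")
    out <- list(texts = texts, outcomes = outcomes, truth = truth)
    if (keep_gaze) {
      out$recordings <- tibble::tibble(
        participant_id = truth$participant_id,
        text_id = truth$text_id,
        samples = recs
      )
    }
    structure(out, class = "gaze_cohort")
  })
}

#' @export
print.gaze_cohort <- function(x, ...) {
  cat("<gaze_cohort>", dplyr::n_distinct(x$truth$participant_id),
      "participants x", nrow(x$texts), "texts =", nrow(x$truth), "recordings\n")
  if (!is.null(x$recordings)) {
    cat("  gaze samples:", sum(purrr::map_int(x$recordings$samples, nrow)), "\n")
  }
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Writes one gaze CSV per recording, a session manifest readable by
#' [read_manifest()], and a `truth.tsv` ground-truth table.
#'
#' @param cohort A `gaze_cohort` with gaze recordings.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "gaze_cohort"), !is.null(cohort$recordings))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("%s_%s.csv", cohort$recordings$participant_id,
                   cohort$recordings$text_id)
  purrr::walk2(cohort$recordings$samples, file.path(dir, files), write_gaze_csv)
  outcomes <- cohort$outcomes
  outcomes$gaze_file <- files
  manifest_path <- file.path(dir, "manifest.yaml")
  write_manifest(cohort$texts, outcomes, manifest_path)
  readr::write_tsv(cohort$truth, file.path(dir, "truth.tsv"), progress = FALSE)
  invisible(manifest_path)
}
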