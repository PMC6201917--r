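#' Aggregate per-text features and outcomes per participant
#'
#' For each participant, averages the per-text feature vectors into the
#' vector `X = [a1 a2 a3 a4]` (the arithmetic mean of each feature over the
#' `p` texts the participant read), the mean self-rated understanding `U`
#' over included texts, and the answer score `S` (correct answers divided
#' by answered questions). Aborted texts (rating 1) are excluded from `X`,
#' `U` and `S` alike; participants whose texts were all aborted are dropped
#' with a warning.
#'
#' @param features Per-recording feature tibble
#'   (`participant_id`, `text_id`, `f1`..`f4`).
#' @param outcomes Outcome tibble with `participant_id`, `text_id`,
#'   `rating`, `answer_correct`.
#' @return A tibble with one row per participant: `participant_id`,
#'   `f1`..`f4` (the averaged X), `U`, `S`, `p`.
#' @examples
#' features <- tibble::tibble(
#'   participant_id = "P1", text_id = c("T1", "T2"),
#'   f1 = c(0.5, 0.7), f2 = c(0.3, 0.5), f3 = c(0.1, 0.1), f4 = c(0.1, 0.3)
#' )
#' outcomes <- tibble::tibble(
#'   participant_id = "P1", text_id = c("T1", "T2"),
#'   rating = c(4L, 5L), answer_correct = c(1L, 0L)
#' )
#' aggregate_participants(features, outcomes)
#' @export
aggregate_participants <- function(features, outcomes) {
  df <- features |>
    dplyr::inner_join(
      outcomes[, c("participant_id", "text_id", "rating", "answer_correct")],
      by = c("participant_id", "text_id")
    )
  kept <- df |> dplyr::filter(.data$rating >= 2)
  dropped <- setdiff(unique(df$participant_id), unique(kept$participant_id))
  if (length(dropped) > 0) {
    warn(paste0("participant(s) with only aborted texts dropped: ",
                paste(dropped, collapse = ", ")))
  }
  if (nrow(kept) == 0) {
    abort("no participant has a rated (>= 2) text with features",
          class = "gazeread_validation_error")
  }
  kept |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      dplyr::across(c("f1", "f2", "f3", "f4"), mean),
      U = mean(.data$rating),
      S = mean(.data$answer_correct),
      p = dplyr::n(),
      .groups = "drop"
    )
}

#' Mean absolute error
#'
#' `E = (1/N) * sum(|U - U_E|)` over participants.
#'
#' @param truth,estimate Numeric vectors of equal positive length.
#' @return The mean absolute error, a non-negative scalar.
#' @examples
#' mae(c(2, 5), c(3, 4)) # 1
#' @export
mae <- function(truth, estimate) {
  if (length(truth) == 0 || length(truth) != length(estimate)) {
    abort("truth and estimate must have equal length >= 1",
          class = "gazeread_validation_error")
  }
  mean(abs(truth - estimate))
}

zscore_fit <- function(X) {
  mu <- colMeans(X)
  sigma <- apply(X, 2, pop_sd)
  sigma[sigma == 0] <- 1
  list(mu = mu, sigma = sigma)
}

zscore_apply <- function(X, zs) {
  sweep(sweep(X, 2, zs$mu, "-"), 2, zs$sigma, "/")
}

#' Leave-one-participant-out evaluation of the understanding estimator
#'
#' Predicts each participant's mean self-rated understanding `U` from a
#' support-vector regression (RBF kernel, epsilon-insensitive loss) trained
#' on all other participants, so the evaluation is participant-independent.
#' The predictors are either the averaged gaze features `f1`..`f4`
#' (`estimator = "gaze"`) or the single answer score `S`
#' (`estimator = "answers"`). Inputs are z-scored with training-fold
#' statistics only, and predictions are clipped to the target interval
#' (default `[2, 5]`, the range of mean ratings once aborted texts are
#' excluded). A degenerate training fold whose targets are all equal is
#' predicted by that constant (with a warning if its inputs are also all
#' equal). The procedure is deterministic given its configuration.
#'
#' @param aggregates Per-participant tibble from
#'   [aggregate_participants()].
#' @param estimator `"gaze"` or `"answers"`.
#' @param cost,epsilon,gamma SVR hyperparameters passed to
#'   [e1071::svm()]; `gamma = NULL` uses libsvm's default `1/d`.
#' @param clip Length-2 numeric prediction interval.
#' @return An object of class `understanding_eval`: a list with
#'   `estimates` (tibble `participant_id`, `U`, `U_hat`, `abs_error`),
#'   `mae`, `estimator`, `n_participants` and `config`. Use [tidy()] /
#'   [glance()] to extract tidy summaries.
#' @seealso [estimate_understanding()], [evaluate_text_counts()]
#' @export
lopo_evaluate <- function(aggregates, estimator = c("gaze", "answers"),
                          cost = 1, epsilon = 0.1, gamma = NULL,
                          clip = c(2, 5)) {
  estimator <- match.arg(estimator)
  n <- nrow(aggregates)
  if (n < 3) {
    abort("leave-one-participant-out needs at least 3 participants",
          class = "gazeread_validation_error")
  }
  feats <- if (estimator == "gaze") c("f1", "f2", "f3", "f4") else "S"
  stopifnot(all(c(feats, "U", "participant_id") %in% names(aggregates)))
  X <- as.matrix(aggregates[, feats, drop = FALSE])
  y <- aggregates$U
  gamma_eff <- gamma %||% (1 / ncol(X))
  preds <- vapply(seq_len(n), function(i) {
    Xtr <- X[-i, , drop = FALSE]
    ytr <- y[-i]
    if (pop_sd(ytr) == 0) {
      if (all(apply(Xtr, 2, pop_sd) == 0)) {
        warn("degenerate training fold: all targets and inputs identical")
      }
      return(ytr[1])
    }
    zs <- zscore_fit(Xtr)
    fit <- e1071::svm(zscore_apply(Xtr, zs), ytr, type = "eps-regression",
                      kernel = "radial", cost = cost, epsilon = epsilon,
                      gamma = gamma_eff, scale = FALSE, fitted = FALSE)
    if (fit$tot.nSV == 0) {
      # every training target inside the epsilon tube: flat solution
      -fit$rho
    } else {
      unname(stats::predict(fit, zscore_apply(X[i, , drop = FALSE], zs)))
    }
  }, numeric(1))
  preds <- pmin(pmax(preds, clip[1]), clip[2])
  estimates <- tibble::tibble(
    participant_id = aggregates$participant_id,
    U = y,
    U_hat = preds,
    abs_error = abs(y - preds)
  )
  structure(
    list(
      estimates = estimates,
      mae = mean(estimates$abs_error),
      estimator = estimator,
      n_participants = n,
      config = list(features = feats, cost = cost, epsilon = epsilon,
                    gamma = gamma_eff, clip = clip)
    ),
    class = "understanding_eval"
  )
}

#' @export
print.understanding_eval <- function(x, ...) {
  cat("<understanding_eval>", x$estimator, "estimator,",
      x$n_participants, "participants (leave-one-participant-out)\n")
  cat("  MAE:", format(x$mae, digits = 4), "\n")
  invisible(x)
}

#' Estimate subjective understanding from per-recording data
#'
#' End-to-end convenience wrapper: aggregates per-text features and
#' outcomes per participant ([aggregate_participants()]) and evaluates the
#' chosen estimator under leave-one-participant-out ([lopo_evaluate()]).
#'
#' @inheritParams aggregate_participants
#' @inheritParams lopo_evaluate
#' @param ... Passed on to [lopo_evaluate()].
#' @return An `understanding_eval` object.
#' @export
estimate_understanding <- function(features, outcomes,
                                   estimator = c("gaze", "answers"), ...) {
  estimator <- match.arg(estimator)
  lopo_evaluate(aggregate_participants(features, outcomes), estimator, ...)
}

#' Effect of the number of read texts on estimation error
#'
#' Re-runs the leave-one-participant-out evaluation when each participant's
#' aggregate is computed from only `k` of their texts, for each requested
#' `k`: texts are drawn uniformly without replacement (a participant with
#' fewer than `k` included texts contributes all of their texts), the
#' subsample is aggregated, and the cohort MAE recorded; results are
#' averaged over `n_repeats` seeded draws. With `k` equal to the maximum
#' number of texts the evaluation coincides with the full one.
#'
#' @inheritParams aggregate_participants
#' @param counts Integer vector of text counts to evaluate (>= 1).
#' @param n_repeats Number of random subsamples per count.
#' @param seed Integer seed making the subsampling reproducible.
#' @param estimators Character vector, subset of `c("gaze", "answers")`.
#' @param ... Passed on to [lopo_evaluate()].
#' @return A tibble of class `text_count_eval` with columns `n_texts`,
#'   `estimator`, `mae` (mean over repeats), `mae_sd` and `n_repeats`.
#' @export
evaluate_text_counts <- function(features, outcomes, counts, n_repeats = 20,
                                 seed = 1L,
                                 estimators = c("gaze", "answers"), ...) {
  estimators <- match.arg(estimators, several.ok = TRUE)
  counts <- as.integer(counts)
  if (length(counts) == 0 || any(is.na(counts)) || any(counts <= 0)) {
    abort("counts must be positive integers", class = "gazeread_validation_error")
  }
  if (n_repeats < 1) {
    abort("n_repeats must be >= 1", class = "gazeread_validation_error")
  }
  keyed <- features |>
    dplyr::inner_join(
      outcomes[, c("participant_id", "text_id", "rating", "answer_correct")],
      by = c("participant_id", "text_id")
    ) |>
    dplyr::filter(.data$rating >= 2) |>
    dplyr::arrange(.data$participant_id, .data$text_id)
  ids <- split(seq_len(nrow(keyed)), keyed$participant_id)
  grid <- withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_repeats), function(rep_i) {
      purrr::map_dfr(counts, function(k) {
        take <- sort(unlist(purrr::map(ids, function(rows) {
          if (length(rows) <= k) rows else sample(rows, k)
        }), use.names = FALSE))
        sub <- keyed[take, , drop = FALSE]
        agg <- sub |>
          dplyr::group_by(.data$participant_id) |>
          dplyr::summarise(dplyr::across(c("f1", "f2", "f3", "f4"), mean),
                           U = mean(.data$rating), S = mean(.data$answer_correct),
                           p = dplyr::n(), .groups = "drop")
        purrr::map_dfr(estimators, function(est) {
          tibble::tibble(
            n_texts = k, estimator = est, repeat_id = rep_i,
            mae = lopo_evaluate(agg, est, ...)$mae
          )
        })
      })
    })
  })
  out <- grid |>
    dplyr::group_by(.data$n_texts, .data$estimator) |>
    dplyr::summarise(mae_sd = pop_sd(.data$mae), mae = mean(.data$mae),
                     n_repeats = dplyr::n(), .groups = "drop") |>
    dplyr::select("n_texts", "estimator", "mae", "mae_sd", "n_repeats")
  class(out) <- c("text_count_eval", class(out))
  out
}
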