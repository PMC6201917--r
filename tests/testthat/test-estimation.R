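test_that("participant aggregation averages features and outcomes", {
  features <- tibble::tibble(
    participant_id = "P1", text_id = c("T1", "T2"),
    f1 = c(0.5, 0.7), f2 = c(0.3, 0.5), f3 = c(0.1, 0.1), f4 = c(0.1, 0.3)
  )
  outcomes <- tibble::tibble(
    participant_id = "P1", text_id = c("T1", "T2"),
    rating = c(4L, 5L), answer_correct = c(1L, 0L)
  )
  agg <- aggregate_participants(features, outcomes)
  expect_equal(unlist(agg[, c("f1", "f2", "f3", "f4")]),
               c(f1 = 0.6, f2 = 0.4, f3 = 0.1, f4 = 0.2))
  expect_equal(agg$U, 4.5)
  expect_equal(agg$S, 0.5)
  expect_equal(agg$p, 2L)

  # single included text: X is that text's V
  agg1 <- aggregate_participants(features[1, ], outcomes[1, ])
  expect_equal(unlist(agg1[, c("f1", "f2", "f3", "f4")]),
               unlist(features[1, c("f1", "f2", "f3", "f4")]))
})

test_that("aborted texts are excluded from X, U and S alike", {
  features <- tibble::tibble(
    participant_id = "P1", text_id = c("T1", "T2", "T3"),
    f1 = c(9, 0.5, 0.7), f2 = c(9, 0.3, 0.5), f3 = c(9, 0.1, 0.1),
    f4 = c(9, 0.1, 0.3)
  )
  outcomes <- tibble::tibble(
    participant_id = "P1", text_id = c("T1", "T2", "T3"),
    rating = c(1L, 4L, 4L), answer_correct = c(0L, 1L, 1L)
  )
  agg <- aggregate_participants(features, outcomes)
  expect_equal(agg$U, 4)
  expect_equal(agg$p, 2L)
  expect_equal(agg$S, 1)
  expect_equal(agg$f1, 0.6) # the rating-1 row never enters the average

  # a participant whose texts were all aborted is dropped with a warning
  outcomes2 <- dplyr::bind_rows(
    outcomes,
    tibble::tibble(participant_id = "P2", text_id = "T1", rating = 1L,
                   answer_correct = 0L)
  )
  features2 <- dplyr::bind_rows(
    features,
    tibble::tibble(participant_id = "P2", text_id = "T1", f1 = 1, f2 = 1,
                   f3 = 1, f4 = 1)
  )
  expect_warning(agg2 <- aggregate_participants(features2, outcomes2), "P2")
  expect_equal(agg2$participant_id, "P1")
})

test_that("mean absolute error follows its definition", {
  expect_equal(mae(c(3, 4), c(3, 4)), 0)
  expect_equal(mae(c(2, 5), c(3, 4)), 1)
  expect_equal(mae(c(2, 3, 4), c(2.5, 3, 4.5)), 1 / 3)
  expect_error(mae(numeric(0), numeric(0)), class = "gazeread_validation_error")
  expect_error(mae(1:3, 1:2), class = "gazeread_validation_error")
  # non-negative, zero iff exact
  withr::with_seed(2, {
    a <- runif(20, 2, 5)
    b <- runif(20, 2, 5)
  })
  expect_gte(mae(a, b), 0)
  expect_identical(mae(a, a), 0)
})

test_that("a constant cohort is predicted at its constant", {
  agg <- tibble::tibble(
    participant_id = sprintf("P%d", 1:5),
    f1 = 0.6, f2 = 0.45, f3 = 0.1, f4 = 0.15, U = 4, S = 0.5, p = 10L
  )
  w <- testthat::capture_warnings(ev <- lopo_evaluate(agg, "gaze"))
  expect_true(any(grepl("degenerate", w)))
  expect_equal(ev$estimates$U_hat, rep(4, 5))
  expect_equal(ev$mae, 0)
})

test_that("both estimators report the same cohort structure", {
  tabs <- fake_cohort_tables(8, 6, seed = 31)
  agg <- aggregate_participants(tabs$features, tabs$outcomes)
  ev_g <- lopo_evaluate(agg, "gaze")
  ev_a <- lopo_evaluate(agg, "answers")
  expect_equal(ev_g$n_participants, ev_a$n_participants)
  expect_equal(ev_g$estimates$participant_id, ev_a$estimates$participant_id)
  expect_equal(ev_g$estimates$U, ev_a$estimates$U)
  # deterministic given the configuration
  expect_identical(ev_g$estimates, lopo_evaluate(agg, "gaze")$estimates)
  # broom-style accessors
  expect_equal(glance(ev_g)$mae, ev_g$mae)
  expect_equal(nrow(tidy(ev_g)), 8)
  expect_error(lopo_evaluate(agg[1:2, ]), class = "gazeread_validation_error")
})

test_that("predictions are always clipped to the rating interval", {
  for (s in 1:5) {
    tabs <- fake_cohort_tables(6, 4, seed = s)
    agg <- aggregate_participants(tabs$features, tabs$outcomes)
    ev <- lopo_evaluate(agg, "gaze")
    expect_true(all(ev$estimates$U_hat >= 2 & ev$estimates$U_hat <= 5))
    expect_true(all(ev$estimates$U >= 2 & ev$estimates$U <= 5))
  }
})

test_that("removing a participant leaves the other folds' training sets intact", {
  tabs <- fake_cohort_tables(7, 5, seed = 77)
  agg <- aggregate_participants(tabs$features, tabs$outcomes)
  full <- lopo_evaluate(agg, "gaze")
  # drop the last participant: the folds of the others only lose that row,
  # so re-running on the reduced cohort must equal a LOPO built by hand
  reduced <- lopo_evaluate(agg[-7, ], "gaze")
  by_hand <- vapply(1:6, function(i) {
    fit_agg <- agg[-c(i, 7), ]
    Xtr <- as.matrix(fit_agg[, c("f1", "f2", "f3", "f4")])
    mu <- colMeans(Xtr)
    sg <- apply(Xtr, 2, function(v) sqrt(mean((v - mean(v))^2)))
    f <- e1071::svm(scale(Xtr, center = mu, scale = sg), fit_agg$U,
                    type = "eps-regression", kernel = "radial", cost = 1,
                    epsilon = 0.1, gamma = 0.25, scale = FALSE, fitted = FALSE)
    xi <- (unlist(agg[i, c("f1", "f2", "f3", "f4")]) - mu) / sg
    pred <- if (f$tot.nSV == 0) -f$rho else unname(stats::predict(f, t(as.matrix(xi))))
    min(5, max(2, pred))
  }, numeric(1))
  expect_equal(reduced$estimates$U_hat, by_hand, tolerance = 1e-8)
})

test_that("text-count subsampling reduces to the full evaluation at k = max", {
  tabs <- fake_cohort_tables(8, 6, seed = 12)
  full <- estimate_understanding(tabs$features, tabs$outcomes, "gaze")
  tc <- evaluate_text_counts(tabs$features, tabs$outcomes, counts = c(2, 6),
                             n_repeats = 3, seed = 9)
  expect_equal(tc$mae[tc$n_texts == 6 & tc$estimator == "gaze"], full$mae)
  expect_equal(tc$mae_sd[tc$n_texts == 6 & tc$estimator == "gaze"], 0)
  # identical seed, identical curve
  tc2 <- evaluate_text_counts(tabs$features, tabs$outcomes, counts = c(2, 6),
                              n_repeats = 3, seed = 9)
  expect_identical(as.data.frame(tc), as.data.frame(tc2))
  expect_error(evaluate_text_counts(tabs$features, tabs$outcomes, counts = 0,
                                    n_repeats = 1, seed = 1),
               class = "gazeread_validation_error")
})

test_that("participants with fewer texts than requested contribute all their texts", {
  tabs <- fake_cohort_tables(6, 5, seed = 44)
  # strip participant P01 down to 2 texts
  keep <- !(tabs$features$participant_id == "P01" &
              tabs$features$text_id %in% c("T03", "T04", "T05"))
  feats <- tabs$features[keep, ]
  outs <- tabs$outcomes[keep, ]
  full <- estimate_understanding(feats, outs, "gaze")
  tc <- evaluate_text_counts(feats, outs, counts = 5, n_repeats = 2, seed = 3,
                             estimators = "gaze")
  expect_equal(tc$mae, full$mae)
})
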