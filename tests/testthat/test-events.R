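test_that("a stationary signal yields exactly one fixation", {
  samples <- tibble::tibble(
    t_ms = seq(0, 1000, length.out = 90),
    x_px = 100, y_px = 100, valid = TRUE
  )
  fix <- detect_fixations(samples)
  expect_equal(nrow(fix), 1)
  expect_equal(fix$duration, 1000)
  expect_equal(fix$cx, 100)
  expect_equal(fix$cy, 100)
})

test_that("two separated stationary clusters yield two fixations matching the oracle", {
  samples <- render_fixations(cx = c(100, 400), cy = c(100, 100),
                              dwell = c(300, 300), gap = 50)
  fix <- detect_fixations(samples, dispersion_px = 30, min_duration_ms = 100)
  expect_equal(nrow(fix), 2)
  oracle <- idt_oracle(samples$t_ms, samples$x_px, samples$y_px, 30, 100, 200)
  expect_equal(as.data.frame(fix), as.data.frame(oracle))
})

test_that("degenerate inputs are handled without error", {
  empty <- tibble::tibble(t_ms = double(), x_px = double(), y_px = double(),
                          valid = logical())
  expect_equal(nrow(detect_fixations(empty)), 0)
  all_invalid <- tibble::tibble(t_ms = 0:10, x_px = 1, y_px = 1, valid = FALSE)
  expect_equal(nrow(detect_fixations(all_invalid)), 0)
  expect_error(detect_fixations(empty, dispersion_px = 0),
               class = "gazeread_validation_error")
  expect_error(detect_fixations(empty, min_duration_ms = -1),
               class = "gazeread_validation_error")
})

test_that("I-DT segmentation matches the brute-force oracle on random signals", {
  withr::with_seed(99, {
    for (i in 1:30) {
      rec <- random_cluster_recording()
      disp <- sample(c(25, 40, 60), 1)
      fix <- detect_fixations(rec, dispersion_px = disp)
      oracle <- idt_oracle(rec$t_ms, rec$x_px, rec$y_px, disp, 100, 200)
      expect_equal(as.data.frame(fix), as.data.frame(oracle))
    }
  })
})

test_that("a long hole in the stream never lies inside a fixation", {
  # two stationary halves split by a 500 ms blink at the same position
  a <- render_fixations(150, 150, 300, numeric(0))
  b <- a
  b$t_ms <- b$t_ms + 800
  rec <- dplyr::bind_rows(a, b)
  fix <- detect_fixations(rec, max_gap_ms = 200)
  expect_equal(nrow(fix), 2)
  fix2 <- detect_fixations(rec, max_gap_ms = 600)
  expect_equal(nrow(fix2), 1)
})

test_that("saccades connect consecutive fixations with signed axis projection", {
  fix <- tibble::tibble(t_start = c(0, 400, 800), duration = c(300, 300, 300),
                        cx = c(100, 215, 400), cy = c(100, 100, 100),
                        n_samples = 10L)
  sac <- build_saccades(fix)
  expect_equal(nrow(sac), 2)
  expect_equal(sac$signed_length[1], 115)
  expect_equal(sac$direction[1], "forward")

  fix2 <- tibble::tibble(t_start = c(0, 500), duration = c(300, 300),
                         cx = c(400, 73), cy = c(100, 100), n_samples = 10L)
  sac2 <- build_saccades(fix2)
  expect_equal(sac2$signed_length, -327)
  expect_equal(sac2$direction, "backward")

  expect_equal(nrow(build_saccades(fix[1, ])), 0)
  # zero displacement is not a regression
  fix3 <- tibble::tibble(t_start = c(0, 500), duration = c(300, 300),
                         cx = c(100, 100), cy = c(100, 150), n_samples = 10L)
  expect_equal(build_saccades(fix3)$direction, "forward")
})

test_that("saccade duration is floored at one inter-sample interval", {
  fix <- tibble::tibble(t_start = c(0, 300), duration = c(300, 200),
                        cx = c(0, 100), cy = 0, n_samples = 10L)
  sac <- build_saccades(fix, sampling_rate_hz = 90)
  expect_equal(sac$duration, 1000 / 90)
  expect_equal(sac$velocity, 100 / (1000 / 90))
})

test_that("saccade velocity is |length| / duration with a positive-duration domain", {
  expect_equal(saccade_velocity(160, 500), 0.32)
  expect_equal(saccade_velocity(-160, 500), 0.32)
  expect_equal(saccade_velocity(0, 123), 0)
  expect_error(saccade_velocity(100, 0), class = "gazeread_domain_error")
  expect_error(saccade_velocity(100, -5), class = "gazeread_domain_error")
})

test_that("one saccade per consecutive fixation pair, across reading axes", {
  withr::with_seed(5, {
    rec <- simulate_recording(reader_params(u = 3), n_chars = 63)
  })
  ev <- detect_events(rec)
  expect_gt(nrow(ev$fixations), 2)
  expect_equal(nrow(ev$saccades), nrow(ev$fixations) - 1)
  # right-to-left axis flips every direction
  sac_rl <- build_saccades(ev$fixations, reading_axis = "horizontal_rl")
  expect_equal(sac_rl$signed_length, -ev$saccades$signed_length)
})

test_that("event detection is invariant under spatial translation", {
  withr::with_seed(21, {
    rec <- random_cluster_recording()
  })
  shifted <- dplyr::mutate(rec, x_px = x_px + 137.5, y_px = y_px - 41.25)
  ev <- detect_events(rec)
  ev_s <- detect_events(shifted)
  expect_equal(nrow(ev_s$fixations), nrow(ev$fixations))
  expect_equal(ev_s$fixations$duration, ev$fixations$duration)
  expect_equal(ev_s$saccades$signed_length, ev$saccades$signed_length)
  expect_equal(ev_s$saccades$velocity, ev$saccades$velocity)
})

test_that("time reversal swaps forward and backward saccade counts", {
  withr::with_seed(8, {
    rec <- simulate_recording(reader_params(u = 2), n_chars = 105)
  })
  rev_rec <- tibble::tibble(
    t_ms = max(rec$t_ms) - rev(rec$t_ms),
    x_px = rev(rec$x_px), y_px = rev(rec$y_px), valid = rev(rec$valid)
  )
  ev <- detect_events(rec)
  ev_r <- detect_events(rev_rec)
  expect_equal(nrow(ev_r$fixations), nrow(ev$fixations))
  expect_equal(sum(ev_r$saccades$direction == "forward"),
               sum(ev$saccades$direction == "backward"))
  expect_equal(sum(ev_r$saccades$direction == "backward"),
               sum(ev$saccades$direction == "forward"))
})
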