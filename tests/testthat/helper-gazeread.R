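# Brute-force dispersion-threshold oracle, independent of the package's
# scanning implementation: for every candidate start it recomputes, from
# scratch, the maximal window whose between-sample gaps stay within max_gap
# and whose dispersion (x range + y range) stays within the threshold, then
# greedily emits every such window that spans the minimum duration.
idt_oracle <- function(t, x, y, dispersion, min_duration, max_gap) {
  n <- length(t)
  disp <- function(i, j) diff(range(x[i:j])) + diff(range(y[i:j]))
  max_end <- function(i) {
    j <- i
    while (j + 1 <= n &&
           t[j + 1] - t[j] <= max_gap &&
           disp(i, j + 1) <= dispersion) {
      j <- j + 1
    }
    j
  }
  out <- list()
  i <- 1
  while (i <= n) {
    j <- max_end(i)
    if (t[j] - t[i] >= min_duration) {
      out[[length(out) + 1]] <- data.frame(
        t_start = t[i], duration = t[j] - t[i],
        cx = mean(x[i:j]), cy = mean(y[i:j]), n_samples = j - i + 1L
      )
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(t_start = double(), duration = double(),
                          cx = double(), cy = double(), n_samples = integer()))
  }
  tibble::as_tibble(do.call(rbind, out))
}

# Hand-built sample stream: stationary cluster per fixation centre, exact
# dwells and gaps, no noise unless asked for.
render_fixations <- function(cx, cy, dwell, gap, rate = 90, noise_sd = 0) {
  dt <- 1000 / rate
  starts <- cumsum(c(0, head(dwell, -1) + gap))
  m <- pmax(1L, as.integer(round(dwell / dt)))
  t <- rep(starts, m + 1L) + (sequence(m + 1L) - 1) * rep(dwell / m, m + 1L)
  tibble::tibble(
    t_ms = t,
    x_px = rep(cx, m + 1L) + rnorm(length(t), 0, noise_sd),
    y_px = rep(cy, m + 1L) + rnorm(length(t), 0, noise_sd),
    valid = TRUE
  )
}

# Random stationary-cluster signal with drifting transition samples, for
# property-based comparison against the oracle. Draws from the current RNG
# state (seed fixed by the caller).
random_cluster_recording <- function(max_clusters = 6, rate = 90) {
  n_clusters <- sample(seq_len(max_clusters), 1)
  dt <- 1000 / rate
  t_now <- 0
  ts <- xs <- ys <- numeric(0)
  cx <- runif(1, 0, 800)
  cy <- runif(1, 0, 400)
  for (k in seq_len(n_clusters)) {
    dwell <- runif(1, 40, 400) # some clusters too short to be fixations
    m <- max(2L, round(dwell / dt))
    ts <- c(ts, t_now + seq(0, dwell, length.out = m))
    xs <- c(xs, cx + rnorm(m, 0, runif(1, 1, 12)))
    ys <- c(ys, cy + rnorm(m, 0, 6))
    t_now <- t_now + dwell
    ncx <- cx + sample(c(-1, 1), 1) * runif(1, 20, 400)
    ncy <- cy + runif(1, -60, 60)
    gapd <- runif(1, 20, 300)
    n_tr <- sample(0:4, 1)
    if (n_tr > 0) {
      frac <- seq_len(n_tr) / (n_tr + 1)
      ts <- c(ts, t_now + frac * gapd)
      xs <- c(xs, cx + frac * (ncx - cx) + rnorm(n_tr, 0, 3))
      ys <- c(ys, cy + frac * (ncy - cy) + rnorm(n_tr, 0, 3))
    }
    t_now <- t_now + gapd
    cx <- ncx
    cy <- ncy
  }
  tibble::tibble(t_ms = ts, x_px = xs, y_px = ys, valid = TRUE)
}

# Per-recording feature and outcome tables with a known participant-level
# understanding, without simulating raw gaze (fast path for estimation
# tests).
fake_cohort_tables <- function(n_participants = 8, n_texts = 6, seed = 1) {
  withr::with_seed(seed, {
    u <- sample(c(2, 3, 4, 5), n_participants, replace = TRUE)
    grid <- expand.grid(i = seq_len(n_participants), j = seq_len(n_texts))
    features <- tibble::tibble(
      participant_id = sprintf("P%02d", grid$i),
      text_id = sprintf("T%02d", grid$j),
      f1 = 0.93 - 0.093 * u[grid$i] + rnorm(nrow(grid), 0, 0.02),
      f2 = 0.7 - 0.1 * u[grid$i] + rnorm(nrow(grid), 0, 0.02),
      f3 = 0.04 + 0.02 * u[grid$i] + rnorm(nrow(grid), 0, 0.005),
      f4 = 0.25 - 0.027 * u[grid$i] + rnorm(nrow(grid), 0, 0.01)
    )
    outcomes <- tibble::tibble(
      participant_id = sprintf("P%02d", grid$i),
      text_id = sprintf("T%02d", grid$j),
      rating = as.integer(pmin(5, pmax(2, round(u[grid$i] + rnorm(nrow(grid), 0, 0.3))))),
      answer_correct = rbinom(nrow(grid), 1, 0.4 + 0.13 * (u[grid$i] - 2))
    )
    list(features = features, outcomes = outcomes,
         u_true = tibble::tibble(participant_id = sprintf("P%02d", seq_len(n_participants)),
                                 u = u))
  })
}
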