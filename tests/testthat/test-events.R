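# dF/F0, peak detection criteria, event grouping (with brute-force oracle),
# frequencies, terminal averaging, ABR wave-1 metrics, acoustic delay.

test_that("compute_dff follows the definition and resists slow drift", {
  fr <- 10
  tr <- new_trace(1L, rep(100, 600), fr)
  expect_true(all(abs(compute_dff(tr)$dff) < 1e-12))
  # plateau of 110 on a baseline of 100 -> dff 0.1
  f <- rep(100, 1200); f[600:650] <- 110
  tr <- compute_dff(new_trace(1L, f, fr))
  expect_equal(max(tr$dff), 0.1, tolerance = 1e-6)
  # a fixed-amplitude transient on a slow linear drift keeps its amplitude
  t <- seq_len(3000) / fr
  bump <- 40 * exp(-(t - 150)^2 / (2 * 2^2))
  flat <- compute_dff(new_trace(1L, 100 + bump, fr))
  drift <- compute_dff(new_trace(1L, 100 + 0.04 * t + bump, fr))
  expect_lt(abs(max(drift$dff) - max(flat$dff)) / max(flat$dff), 0.05)
  expect_error(compute_dff(new_trace(1L, rep(-1, 600), fr)),
               "non-positive")
  expect_error(compute_dff(new_trace(1L, rep(100, 600), fr),
                           baseline_window_s = 5))
})

test_that("peak criteria: amplitude > 2 SD and FWHM > 200 ms", {
  fr <- 100
  # high-SNR bump: FWHM matches the closed form 2*sigma*sqrt(2*log(2))
  tr <- bump_trace(30, 1, 0.3, duration_s = 60, frame_rate = fr,
                   noise_sd = 0.005, seed = 3)
  pk <- detect_peaks(tr)
  expect_equal(nrow(pk), 1L)
  expect_lt(abs(pk$fwhm_s - 2 * 0.3 * sqrt(2 * log(2))), 1 / fr)
  # amplitude 1.5 SD: rejected
  s0 <- 0.1
  tr <- bump_trace(30, 1.5 * s0, 0.3, frame_rate = fr, noise_sd = s0)
  expect_equal(nrow(detect_peaks(tr)), 0L)
  # amplitude 5 SD but FWHM 0.15 s: rejected
  sig_narrow <- 0.15 / (2 * sqrt(2 * log(2)))
  tr <- bump_trace(30, 5 * s0, sig_narrow, frame_rate = fr, noise_sd = s0)
  expect_equal(nrow(detect_peaks(tr)), 0L)
  # amplitude 5 SD, wide: accepted
  tr <- bump_trace(30, 5 * s0, 0.3, frame_rate = fr, noise_sd = s0)
  expect_equal(nrow(detect_peaks(tr)), 1L)
})

test_that("raising either threshold never increases accepted peaks", {
  tr <- bump_trace(c(10, 25, 40, 52), c(0.3, 0.5, 0.8, 1.2),
                   c(0.12, 0.2, 0.3, 0.5), duration_s = 60,
                   frame_rate = 50, noise_sd = 0.1, seed = 8)
  grid_amp <- c(1, 2, 3, 5, 8)
  n_by_amp <- vapply(grid_amp, function(a)
    nrow(detect_peaks(tr, min_amp_sd = a)), numeric(1))
  expect_true(all(diff(n_by_amp) <= 0))
  grid_w <- c(0.05, 0.2, 0.5, 1)
  n_by_w <- vapply(grid_w, function(w)
    nrow(detect_peaks(tr, min_fwhm_s = w)), numeric(1))
  expect_true(all(diff(n_by_w) <= 0))
})

test_that("gap spans contribute no candidate maxima", {
  fr <- 50
  tr <- bump_trace(10, 1, 0.3, duration_s = 20, frame_rate = fr)
  gap <- rep(FALSE, length(tr$dff))
  gap[490:520] <- TRUE          # covers the bump apex
  tr$gap_mask <- gap
  tr$dff[gap] <- stats::approx(which(!gap), tr$dff[!gap],
                               xout = which(gap))$y
  pk <- detect_peaks(tr)
  expect_true(all(!gap[pk$peak_frame]))
})

test_that("event grouping follows chaining, gap splitting, classification", {
  mk <- function(labels, times) {
    data.frame(roi_label = labels, peak_time_s = times)
  }
  ord <- stats::setNames(1:10, 1:10)
  # transitive chaining: 0, 1.5, 3.0 in cells 1..3 -> one multiple event
  g <- group_ihc_events(mk(1:3, c(0, 1.5, 3)), ord)
  expect_equal(nrow(g$events), 1L)
  expect_equal(g$events$n_cells, 3L)
  expect_equal(g$events$classification, "multiple")
  # exactly 2 s apart still chains; 2.1 s does not
  expect_equal(nrow(group_ihc_events(mk(1:2, c(0, 2)), ord)$events), 1L)
  expect_equal(nrow(group_ihc_events(mk(1:2, c(0, 2.1)), ord)$events), 2L)
  # five non-participating cells between 1 and 7: split into two singles
  g <- group_ihc_events(mk(c(1, 7), c(5, 5)), ord)
  expect_equal(nrow(g$events), 2L)
  expect_equal(g$events$classification, c("single", "single"))
  # four non-participating cells (1 and 6): still one event
  g <- group_ihc_events(mk(c(1, 6), c(5, 5)), ord)
  expect_equal(nrow(g$events), 1L)
  expect_equal(g$events$classification, "two_cell")
  expect_error(group_ihc_events(mk(99, 1), ord), "row index")
})

test_that("union-find grouping matches the brute-force oracle", {
  n_agree <- 0L
  n_cases <- 1000L
  withr::with_seed(99, {
    for (case in seq_len(n_cases)) {
      n_cells <- sample(1:6, 1)
      n_peaks <- sample(1:8, 1)
      labels <- sample(seq_len(n_cells), n_peaks, replace = TRUE)
      times <- round(stats::runif(n_peaks, 0, 12), 2)
      peaks <- data.frame(roi_label = labels, peak_time_s = times)
      ord <- stats::setNames(seq_len(n_cells), seq_len(n_cells))
      g <- group_ihc_events(peaks, ord)
      mine <- canonical_partition(
        split(seq_len(n_peaks), g$peaks$event_id))
      oracle <- canonical_partition(
        brute_force_grouping(times, labels))
      if (identical(mine, oracle)) n_agree <- n_agree + 1L
    }
  })
  expect_equal(n_agree, n_cases)
})

test_that("SGN grouping uses the 1-s window without spatial splitting", {
  mk <- function(labels, times) {
    data.frame(roi_label = labels, peak_time_s = times)
  }
  g <- group_sgn_events(mk(1:3, c(0, 0.4, 0.9)))
  expect_equal(nrow(g$events), 1L)
  g <- group_sgn_events(mk(1:2, c(0, 1.2)))
  expect_equal(nrow(g$events), 2L)
  g <- group_sgn_events(mk(integer(), numeric()))
  expect_equal(nrow(g$events), 0L)
})

test_that("classification fractions sum to one", {
  withr::with_seed(5, {
    peaks <- data.frame(
      roi_label = sample(1:12, 60, replace = TRUE),
      peak_time_s = stats::runif(60, 0, 300))
  })
  g <- group_ihc_events(peaks, stats::setNames(1:12, 1:12))
  cls <- table(g$events$classification)
  expect_equal(sum(cls), nrow(g$events))
  summ <- event_classification_summary(g$events)
  if (!is.na(summ$pct_single)) {
    expect_equal(summ$pct_single + summ$pct_multiple, 100)
  }
})

test_that("frequency definition and the 5-minute rule", {
  expect_equal(compute_frequency(12, 600), 1.2)
  expect_equal(compute_frequency(0, 600), 0)
  expect_true(is.na(compute_frequency(10, 200)))   # marker, not zero
  expect_error(compute_frequency(10, 0))
})

test_that("terminal-average IHC trace is pointwise and gap-aware", {
  fr <- 10
  a <- new_trace(1L, rep(0.2, 100), fr)
  b <- new_trace(2L, rep(0.4, 100), fr)
  expect_equal(sgn_ihc_average_trace(list(a, b))$f_raw, rep(0.3, 100))
  expect_equal(sgn_ihc_average_trace(list(a))$f_raw, a$f_raw)
  expect_equal(sgn_ihc_average_trace(list(a, a, a))$f_raw, a$f_raw)
  # gap in one terminal: mean over the remaining valid ones
  g <- new_trace(3L, rep(1, 100), fr,
                 gap_mask = c(rep(TRUE, 50), rep(FALSE, 50)))
  avg <- sgn_ihc_average_trace(list(a, g))
  expect_equal(avg$f_raw[1], 0.2)
  expect_equal(avg$f_raw[60], 0.6)
})

test_that("ABR wave-1 amplitude and latency", {
  t_ms <- seq(0, 8, by = 0.02)
  v <- 2 * exp(-(t_ms - 1.5)^2 / (2 * 0.2^2)) -
    1 * exp(-(t_ms - 2.2)^2 / (2 * 0.25^2))
  m <- abr_wave1_metrics(t_ms, v, p1_guess_ms = 1.4)
  expect_equal(m$amplitude_uv, max(v) - min(v), tolerance = 0.05)
  expect_equal(m$latency_ms, 1.5, tolerance = 0.03)
  # translation equivariance
  m2 <- abr_wave1_metrics(t_ms + 0.3, v, p1_guess_ms = 1.7)
  expect_equal(m2$latency_ms - m$latency_ms, 0.3, tolerance = 1e-9)
  expect_error(abr_wave1_metrics(t_ms, rep(0, length(t_ms)), 1.5),
               "extrema")
  expect_error(abr_wave1_metrics(t_ms, v, 99))
})

test_that("acoustic delay is linear and matches the 10-cm convention", {
  expect_equal(acoustic_delay(0.10, 343), 1000 * 0.10 / 343)
  expect_equal(round(acoustic_delay(0.10, 343), 1), 0.3)
  expect_equal(acoustic_delay(0), 0)
  expect_equal(acoustic_delay(0.2), 2 * acoustic_delay(0.1))
  expect_error(acoustic_delay(0.1, -1))
})
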