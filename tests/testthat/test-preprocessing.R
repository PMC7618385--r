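# Frame triage, denoising, drift correction, trace gap handling, stitching.

test_that("focus_score: zero for flat frames, monotone under blur", {
  expect_equal(focus_score(matrix(5, 20, 20)), 0)
  frame <- withr::with_seed(1, matrix(stats::runif(40 * 40), 40))
  blur3 <- cochleaCa:::conv_gauss_axis(array(frame, c(40, 40, 1)), 4, 1)
  blur3 <- cochleaCa:::conv_gauss_axis(blur3, 4, 2)
  expect_lt(focus_score(blur3[, , 1]), focus_score(frame))
  # checkerboard vs its blur: ratio > 2
  cb <- matrix(rep(c(0, 1), length.out = 40 * 40), 40)
  cb_b <- cochleaCa:::conv_gauss_axis(array(cb, c(40, 40, 1)), 2, 1)
  cb_b <- cochleaCa:::conv_gauss_axis(cb_b, 2, 2)
  expect_gt(focus_score(cb) / focus_score(cb_b[, , 1]), 2)
})

test_that("flag_out_of_focus recovers injected defocus intervals exactly", {
  cfg <- small_ihc_cfg(n_frames = 600, seed = 9)
  sc <- generate_ihc_scene(cfg)
  expect_length(flag_out_of_focus(sc$movie), 0L)
  inj <- inject_artifacts(sc$movie, blur_frames = 50:55, blur_sigma = 4)
  expect_equal(flag_out_of_focus(inj$movie), 50:55)
  # a vanishing threshold flags nothing
  expect_length(flag_out_of_focus(inj$movie, rel_threshold = 1e-6), 0L)
  expect_error(flag_out_of_focus(sc$movie, rel_threshold = 1.5))
})

test_that("replace_flagged_frames copies the last in-focus frame", {
  cfg <- small_ihc_cfg(n_frames = 30, snr = Inf, shot_noise = FALSE)
  sc <- generate_ihc_scene(cfg)
  m <- sc$movie
  m$data[, , 10] <- m$data[, , 10] + 7   # make frames distinguishable
  m$data[, , 9] <- m$data[, , 9] + 3
  out <- replace_flagged_frames(m, c(10, 11))
  expect_equal(out$data[, , 10], m$data[, , 9])
  expect_equal(out$data[, , 11], m$data[, , 9])
  expect_equal(out$removed_frames, c(10L, 11L))
  expect_equal(dim(out$data), dim(m$data))   # T preserved
  # leading-edge gap falls forward to the first in-focus frame
  out2 <- replace_flagged_frames(m, 1L)
  expect_equal(out2$data[, , 1], m$data[, , 2])
  # no flags: identity
  expect_identical(replace_flagged_frames(m, integer()), m)
})

test_that("interpolate_trace_gaps is linear with held boundaries", {
  tr <- new_trace(1L, c(1, 0, 3), 10, gap_mask = c(FALSE, TRUE, FALSE))
  expect_equal(interpolate_trace_gaps(tr)$f_raw, c(1, 2, 3))
  tr <- new_trace(1L, c(2, 0, 0, 8), 10,
                  gap_mask = c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(interpolate_trace_gaps(tr)$f_raw, c(2, 4, 6, 8))
  tr <- new_trace(1L, c(0, 5, 7), 10, gap_mask = c(TRUE, FALSE, FALSE))
  expect_equal(interpolate_trace_gaps(tr)$f_raw, c(5, 5, 7))
  tr_ok <- new_trace(1L, 1:5, 10)
  expect_identical(interpolate_trace_gaps(tr_ok), tr_ok)
  expect_error(interpolate_trace_gaps(
    new_trace(1L, c(1, 2), 10, gap_mask = c(TRUE, TRUE))))
})

test_that("gaussian_denoise preserves constants, mass and reduces variance", {
  const <- movie_stack(array(7, c(10, 12, 8)), 10, 1)
  out <- gaussian_denoise(const)
  expect_equal(out$data, const$data, tolerance = 1e-12)
  # impulse mass is conserved
  imp <- movie_stack(array(0, c(15, 15, 9)), 10, 1)
  imp$data[8, 8, 5] <- 100
  out <- gaussian_denoise(imp)
  expect_equal(sum(out$data), 100, tolerance = 0.001 * 100)
  # white noise: temporal variance strictly reduced
  noise <- movie_stack(
    array(withr::with_seed(2, stats::rnorm(10 * 10 * 50)), c(10, 10, 50)),
    10, 1)
  out <- gaussian_denoise(noise)
  expect_lt(mean(apply(out$data, c(1, 2), stats::var)),
            mean(apply(noise$data, c(1, 2), stats::var)))
})

test_that("correct_drift recovers injected drift and preserves the mean", {
  cfg <- small_ihc_cfg(n_frames = 900, seed = 12, px_size = 1,
                       height = 48, width = 144, n_ihc = 8)
  sc <- generate_ihc_scene(cfg)
  den <- gaussian_denoise(sc$movie)
  reg0 <- correct_drift(den)
  expect_true(all(abs(reg0$shifts) <= 1))   # drift-free: essentially static
  drift <- matrix(0, cfg$n_frames, 2)
  drift[, 2] <- 8 / cfg$n_frames
  inj <- inject_artifacts(sc$movie, drift_px_per_frame = drift)
  reg <- correct_drift(gaussian_denoise(inj$movie))
  resid <- reg$shifts + inj$artifacts$drift_px
  expect_lte(max(abs(resid)), 1)            # recovered within +-1 px
  expect_equal(mean(reg$movie$data), mean(gaussian_denoise(inj$movie)$data))
  # registered movie matches the undrifted original away from borders
  common_y <- 10:38; common_x <- 12:132
  r <- stats::cor(as.vector(reg$movie$data[common_y, common_x, 600]),
                  as.vector(den$data[common_y, common_x, 600]))
  expect_gt(r, 0.99)
})

test_that("stitch_recordings concatenates, pads and tracks valid time", {
  fr <- 10
  t1 <- new_trace(1L, rep(100, 3000), fr)
  t2 <- new_trace(1L, rep(110, 3000), fr)
  one <- stitch_recordings(list(list("1" = t1)))
  expect_equal(one[["1"]]$f_raw, t1$f_raw)
  both <- stitch_recordings(list(list("1" = t1), list("1" = t2)))
  expect_equal(both[["1"]]$duration_s, 600)
  expect_equal(length(both[["1"]]$f_raw), 6000)
  # cell present only in recording 1: padded with gaps, duration from rec 1
  t3 <- new_trace(2L, rep(90, 3000), fr)
  out <- stitch_recordings(list(list("1" = t1, "2" = t3), list("1" = t2)))
  expect_equal(out[["2"]]$duration_s, 300)
  expect_true(all(out[["2"]]$gap_mask[3001:6000]))
  # conflicting label map errors
  expect_error(
    stitch_recordings(list(list("1" = t1, "2" = t3)),
                      label_map = list(c("1" = 5L, "2" = 5L))),
    "conflicting")
})

test_that("clean movies pass the full chain with event counts unchanged", {
  cfg <- small_ihc_cfg(seed = 21, n_frames = 2700)
  sc <- generate_ihc_scene(cfg)
  poly <- ihc_polyline(cfg$ihc_polyline)
  detect_all <- function(movie) {
    traces <- lapply(extract_traces(movie, sc$rois), compute_dff)
    pk <- do.call(rbind, lapply(traces, detect_peaks))
    grp <- group_ihc_events(pk, cell_order_from_rois(sc$rois, poly))
    nrow(grp$events)
  }
  raw_events <- detect_all(sc$movie)
  pp <- preprocess_movie(sc$movie)
  expect_equal(detect_all(pp$movie), raw_events)
})
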