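# Forward-model properties: determinism, ground-truth bookkeeping, event
# statistics and artifact injection.

test_that("identical scene configuration reproduces the movie bit for bit", {
  cfg <- small_ihc_cfg(seed = 42, n_frames = 300)
  a <- generate_ihc_scene(cfg)
  b <- generate_ihc_scene(cfg)
  expect_identical(a$movie$data, b$movie$data)
  expect_identical(a$truth$participants, b$truth$participants)
  expect_identical(a$rois$label_image, b$rois$label_image)
  cfg2 <- small_ihc_cfg(seed = 43, n_frames = 300)
  expect_false(identical(generate_ihc_scene(cfg2)$movie$data, a$movie$data))
})

test_that("zero event rate gives a temporally constant movie before noise", {
  cfg <- small_ihc_cfg(event_rate_per_min = 0, snr = Inf,
                       shot_noise = FALSE, n_frames = 120)
  sc <- generate_ihc_scene(cfg)
  v <- apply(sc$movie$data, c(1, 2), stats::var)
  expect_equal(max(v), 0)
  expect_equal(nrow(sc$truth$events), 0L)
})

test_that("ground-truth bookkeeping: counts match and blocks are contiguous", {
  cfg <- small_ihc_cfg(seed = 3, n_frames = 1800)
  sc <- generate_ihc_scene(cfg)
  expect_equal(length(unique(sc$truth$participants$event_id)),
               nrow(sc$truth$events))
  expect_true(all(sc$truth$participants$roi_label %in% 1:10))
  expect_true(all(sc$truth$participants$onset_s >= 0))
  expect_true(all(sc$truth$participants$onset_s <
                    cfg$n_frames / cfg$frame_rate))
  # per-event cell blocks are contiguous
  for (e in unique(sc$truth$participants$event_id)) {
    cells <- sort(sc$truth$participants$roi_label[
      sc$truth$participants$event_id == e])
    expect_equal(cells, seq(min(cells), max(cells)))
  }
})

test_that("total peak count follows the configured Poisson rate", {
  # single-cell blocks: peak count is exactly Poisson(rate * cells * min)
  cfg <- scene_config("ihc", n_frames = 18000, frame_rate = 30, px_size = 2,
                      height = 32, width = 224, n_ihc = 20, seed = 1,
                      event_rate_per_min = 0.8, block_weights = 1)
  ev <- withr::with_seed(1, cochleaCa:::draw_ihc_events(cfg, 20))
  lambda <- 0.8 * 20 * 10
  expect_lt(abs(nrow(ev$participants) - lambda), 3 * sqrt(lambda))
})

test_that("per-cell event counts pass a chi-square GOF against the rate", {
  # evidence combined over five replicate draws (Fisher's method), so the
  # check has the power of 500 cells while keeping its nominal alpha
  cfg <- scene_config("ihc", n_frames = 18000, frame_rate = 30,
                      height = 32, width = 224, n_ihc = 100, seed = 2,
                      event_rate_per_min = 1.2, block_weights = 1)
  ps <- vapply(1:5, function(s) {
    ev <- withr::with_seed(s, cochleaCa:::draw_ihc_events(cfg, 100))
    counts <- tabulate(ev$participants$roi_label, 100)
    stat <- sum((counts - 1.2 * 10)^2 / (1.2 * 10))
    stats::pchisq(stat, df = 100, lower.tail = FALSE)
  }, numeric(1))
  combined <- stats::pchisq(-2 * sum(log(ps)), df = 10, lower.tail = FALSE)
  expect_gt(combined, 0.01)
})

test_that("supporting scene: circular waves, closed-form area, records", {
  cfg <- scene_config("supporting", n_frames = 400, frame_rate = 10,
                      px_size = 1, height = 128, width = 160, seed = 4,
                      wave_rate_per_min = 3, wave_min_separation_s = 12,
                      wave_axis_ratio = 1, wave_rmax_range_um = c(20, 20),
                      wave_offset_um = 35, snr = Inf, shot_noise = FALSE)
  sc <- generate_supporting_scene(cfg)
  gt <- sc$truth$waves
  expect_gt(nrow(gt), 0)
  expect_equal(gt$a_max_um, gt$b_max_um)   # axis ratio 1 -> isotropic
  # growth 10 um/s to radius 20 -> area pi * 20^2 at max
  expect_equal(gt$t_max_s - gt$t_start_s, gt$rmax_um / 10, tolerance = 1e-8)
  rec <- wave_area_series(sc$rois, 1L, cfg$frame_rate)
  expect_lt(abs(attr(rec, "max_area_um2") - pi * 400) / (pi * 400), 0.1)
  # rendered ground-truth mask is near-circular at max: anisotropy < 5%
  ext <- wave_axis_extents(sc$rois, 1L, ihc_polyline(cfg$ihc_polyline))
  expect_lt(abs(ext$longitudinal_um / ext$radial_um - 1), 0.05)
})

test_that("waves leaving the field of view are clipped and flagged", {
  cfg <- scene_config("supporting", n_frames = 300, frame_rate = 10,
                      px_size = 1, height = 64, width = 96, seed = 5,
                      wave_rate_per_min = 3, wave_min_separation_s = 25,
                      wave_rmax_range_um = c(45, 45), wave_offset_um = 10,
                      snr = Inf, shot_noise = FALSE)
  sc <- generate_supporting_scene(cfg)
  expect_true(all(sc$truth$waves$clipped))
})

test_that("sgn scene: construction, parent map and coupling", {
  cfg <- scene_config("sgn", n_frames = 900, frame_rate = 30, px_size = 1,
                      height = 48, width = 160, n_ihc = 4, seed = 6,
                      terminals_per_ihc_fixed = 3,
                      terminal_failure_rate = 0, terminal_jitter_sd_s = 0,
                      snr = Inf, shot_noise = FALSE)
  sc <- generate_sgn_scene(cfg)
  expect_equal(nrow(sc$truth$terminals), 12L)
  expect_equal(nrow(sc$rois$terminals$centroids), 12L)
  expect_true(all(sc$truth$terminals$parent_ihc %in% 1:4))
  # zero jitter, zero failure: all terminals of one IHC peak together
  pp <- sc$truth$participants
  if (nrow(pp)) {
    per_event <- split(pp, list(pp$parent_ihc, pp$event_id), drop = TRUE)
    for (g in per_event) {
      expect_lt(diff(range(g$peak_time_s)), 1e-9)
      n_terms <- sum(sc$truth$terminals$parent_ihc == g$parent_ihc[1])
      expect_equal(nrow(g), n_terms)   # no failures
    }
  }
})

test_that("terminal count per IHC samples around the configured mean", {
  cfg <- scene_config("sgn", n_frames = 30, frame_rate = 30, px_size = 1,
                      height = 80, width = 2400, n_ihc = 100, seed = 11,
                      event_rate_per_min = 0, snr = Inf, shot_noise = FALSE)
  sc <- generate_sgn_scene(cfg)
  m <- nrow(sc$truth$terminals) / 100
  expect_lt(abs(m - 3.3), 0.3)
  expect_true(all(table(sc$truth$terminals$parent_ihc) <= 8))
})

test_that("inject_artifacts: identity, pure translation, defocus", {
  cfg <- small_ihc_cfg(n_frames = 20, snr = Inf, shot_noise = FALSE)
  sc <- generate_ihc_scene(cfg)
  # empty injection is the identity
  out <- inject_artifacts(sc$movie)
  expect_identical(out$movie$data, sc$movie$data)
  # (1, 0) px/frame: frame 10 equals frame 10 of the original shifted by
  # its 10-px cumulative drift
  out <- inject_artifacts(sc$movie, drift_px_per_frame = c(1, 0))
  expect_equal(out$movie$data[11:32, , 10], sc$movie$data[1:22, , 10])
  expect_equal(out$artifacts$drift_px[10, ], c(10, 0))
  # blur drops the sharpness score below half its unblurred value
  out <- inject_artifacts(sc$movie, blur_frames = 5L, blur_sigma = 4)
  expect_lt(focus_score(out$movie$data[, , 5]),
            0.5 * focus_score(sc$movie$data[, , 5]))
  # drift out of frame errors
  expect_error(inject_artifacts(sc$movie, drift_px_per_frame = c(2, 0)),
               "out of frame")
})

test_that("overcrowded polyline placement fails loudly", {
  poly <- cbind(x = c(10, 40), y = c(16, 16))
  cfg <- scene_config("ihc", n_frames = 30, height = 32, width = 64,
                      n_ihc = 10, ihc_polyline = poly, seed = 1)
  expect_error(generate_ihc_scene(cfg), "overlap")
})
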