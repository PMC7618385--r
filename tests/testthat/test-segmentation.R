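# IHC, wave and SGN-terminal segmentation; terminal assignment and sector
# annotation.

test_that("external masks pass through segment_ihc minus erosion", {
  cfg <- small_ihc_cfg(n_frames = 30, snr = Inf, shot_noise = FALSE,
                       px_size = 1, height = 48, width = 200, n_ihc = 8)
  sc <- generate_ihc_scene(cfg)
  avg <- apply(sc$movie$data, c(1, 2), mean)
  rois <- segment_ihc(avg, erosion_px = 0, px_size = cfg$px_size,
                      masks = sc$rois$label_image)
  expect_identical(rois$label_image, sc$rois$label_image)
  # erosion: every label shrinks, none disappears at 1 px
  rois1 <- segment_ihc(avg, erosion_px = 1, px_size = cfg$px_size,
                       masks = sc$rois$label_image)
  expect_equal(nrow(rois1$centroids), nrow(sc$rois$centroids))
  a0 <- roi_areas_um2(rois)$area_um2
  a1 <- roi_areas_um2(rois1)$area_um2
  expect_true(all(a1 < a0))
  expect_error(segment_ihc(avg, erosion_px = 5))
})

test_that("threshold + watershed splits touching somata", {
  img <- matrix(0, 40, 80)
  for (cx in c(30, 45)) {
    for (i in 1:40) for (j in 1:80) {
      if (((j - cx) / 8)^2 + ((i - 20) / 8)^2 <= 1) img[i, j] <- 100
    }
  }
  rois <- segment_ihc(img, erosion_px = 1, px_size = 1)
  expect_equal(nrow(rois$centroids), 2L)
  expect_error(segment_ihc(matrix(0, 20, 20)), "flat")
})

test_that("erosion removes approximately the boundary ring of a disc", {
  img <- matrix(0, 60, 60)
  r <- 15
  for (i in 1:60) for (j in 1:60) {
    if ((i - 30)^2 + (j - 30)^2 <= r^2) img[i, j] <- 100
  }
  a1 <- roi_areas_um2(segment_ihc(img, 1, px_size = 1))$area_um2
  a3 <- roi_areas_um2(segment_ihc(img, 3, px_size = 1))$area_um2
  ring <- pi * ((r - 1)^2 - (r - 3)^2)
  expect_lt(abs((a1 - a3) - ring) / ring, 0.1)
})

test_that("erosion monotonicity and label stability", {
  cfg <- small_ihc_cfg(n_frames = 30, seed = 8, px_size = 1,
                       height = 48, width = 200, n_ihc = 8,
                       soma_a_um = 6, soma_b_um = 5)
  sc <- generate_ihc_scene(cfg)
  avg <- apply(sc$movie$data, c(1, 2), mean)
  areas <- sapply(0:3, function(e) {
    sum(roi_areas_um2(segment_ihc(avg, e, px_size = 1,
                                  masks = sc$rois$label_image))$area_um2)
  })
  expect_true(all(diff(areas) < 0))
  r1 <- segment_ihc(avg, 1, px_size = 1)
  r2 <- segment_ihc(avg, 1, px_size = 1)
  expect_identical(r1$label_image, r2$label_image)
})

test_that("wave segmentation: counts, threshold contract, separation", {
  cfg <- scene_config("supporting", n_frames = 250, frame_rate = 10,
                      px_size = 1, height = 128, width = 256, seed = 31,
                      wave_rate_per_min = 4, wave_min_separation_s = 8,
                      wave_rmax_range_um = c(18, 24), wave_offset_um = 40)
  sc <- generate_supporting_scene(cfg)
  dffm <- movie_dff(sc$movie)
  rois <- segment_waves(dffm)
  expect_equal(nrow(rois$centroids), nrow(sc$truth$waves))
  # sub-threshold movie yields no labels
  quiet <- dffm
  quiet$data <- quiet$data * 0.001
  expect_equal(nrow(segment_waves(quiet, threshold = 0.5)$centroids), 0L)
  # two waves overlapping in time but far apart stay separate: construct
  dff2 <- movie_stack(array(0, c(64, 128, 30)), 10, 2)
  for (f in 5:25) {
    r <- min(5 + f, 12)
    for (ctr in c(30, 100)) {
      ys <- pmax(1, 32 - r):pmin(64, 32 + r)
      xs <- pmax(1, ctr - r):pmin(128, ctr + r)
      blob <- outer(ys - 32, xs - ctr, function(a, b) a^2 + b^2 <= r^2)
      fr2 <- dff2$data[, , f]
      fr2[ys, xs][blob] <- 1
      dff2$data[, , f] <- fr2
    }
  }
  rois2 <- segment_waves(dff2, threshold = 0.5, min_area_um2 = 100)
  expect_equal(nrow(rois2$centroids), 2L)
})

test_that("isolated single-cell transients are excluded by the area gate", {
  dff <- movie_stack(array(0, c(64, 64, 20)), 10, 1)
  # one cell-sized blip (radius 4 um) for a few frames
  for (f in 8:12) dff$data[30:34, 30:34, f] <- 1
  rois <- segment_waves(dff, threshold = 0.5, min_area_um2 = 150)
  expect_equal(nrow(rois$centroids), 0L)
})

test_that("tophat segmentation finds hotspots even on a bright gradient", {
  withr::with_seed(4, {
    img <- outer(seq(50, 150, length.out = 64), rep(1, 96)) +
      matrix(stats::rnorm(64 * 96, 0, 1), 64)
  })
  spots <- rbind(c(20, 30), c(40, 70), c(55, 15))
  for (k in seq_len(nrow(spots))) {
    i0 <- spots[k, 1]; j0 <- spots[k, 2]
    for (i in (i0 - 2):(i0 + 2)) for (j in (j0 - 2):(j0 + 2)) {
      if ((i - i0)^2 + (j - j0)^2 <= 4) img[i, j] <- img[i, j] + 120
    }
  }
  rois <- segment_sgn_terminals(img, tophat_radius_px = 10, px_size = 1)
  expect_equal(nrow(rois$centroids), 3L)
  expect_error(segment_sgn_terminals(matrix(1, 40, 40), 10), "flat")
  expect_error(segment_sgn_terminals(img, tophat_radius_px = 25))
})

test_that("synthetic SGN scene hotspot count is recovered", {
  cfg <- scene_config("sgn", n_frames = 600, frame_rate = 30, px_size = 1,
                      height = 48, width = 160, n_ihc = 4, seed = 6,
                      terminals_per_ihc_fixed = 3)
  sc <- generate_sgn_scene(cfg)
  avg <- apply(sc$movie$data, c(1, 2), mean)
  rois <- segment_sgn_terminals(avg, tophat_radius_px = 10, px_size = 1)
  expect_equal(nrow(rois$centroids), 12L)
})

test_that("terminal assignment: proximity, correlation tie-break, accuracy", {
  # two IHC discs and two terminals, one unambiguous, one equidistant
  ihc_img <- matrix(0L, 40, 80)
  ihc_img[16:24, 16:24] <- 1L
  ihc_img[16:24, 56:64] <- 2L
  ihcs <- roi_set(ihc_img, kind = "ihc", px_size = 1)
  term_img <- matrix(0L, 40, 80)
  term_img[29:31, 19:21] <- 1L    # 5 um below IHC 1
  term_img[29:31, 39:41] <- 2L    # equidistant between the two
  terms <- roi_set(term_img, kind = "sgn_terminal", px_size = 1)
  set.seed(2)
  base <- stats::rnorm(300)
  tr <- list(
    terminal = list("1" = stats::rnorm(300), "2" = base + stats::rnorm(300, 0, 0.1)),
    ihc = list("1" = stats::rnorm(300), "2" = base))
  asn <- assign_terminals(terms, ihcs, traces = tr, margin_um = 2)
  expect_equal(asn$ihc_label[asn$terminal_label == 1], 1)
  expect_equal(asn$method[asn$terminal_label == 1], "proximity")
  expect_equal(asn$ihc_label[asn$terminal_label == 2], 2)
  expect_equal(asn$method[asn$terminal_label == 2], "correlation")
  # without traces the ambiguous case errors
  expect_error(assign_terminals(terms, ihcs, traces = NULL, margin_um = 2),
               "traces required")
  # ground-truth parentage recovered on a simulated scene
  cfg <- scene_config("sgn", n_frames = 1800, frame_rate = 30, px_size = 1,
                      height = 48, width = 200, n_ihc = 6, seed = 3, snr = 6)
  sc <- generate_sgn_scene(cfg)
  traces <- lapply(extract_traces(sc$movie, sc$rois$terminals), compute_dff)
  prox <- assign_terminals(sc$rois$terminals, sc$rois$ihcs, margin_um = -1)
  ihc_tr <- lapply(split(prox$terminal_label, prox$ihc_label), function(tl)
    sgn_ihc_average_trace(traces[as.character(tl)]))
  trl <- list(terminal = lapply(traces, `[[`, "dff"),
              ihc = lapply(ihc_tr, `[[`, "dff"))
  for (mi in setdiff(as.character(1:6), names(trl$ihc))) {
    trl$ihc[[mi]] <- rowMeans(sapply(traces, `[[`, "dff"))
  }
  asn <- assign_terminals(sc$rois$terminals, sc$rois$ihcs, traces = trl)
  truth <- sc$truth$terminals
  acc <- mean(asn$ihc_label ==
                truth$parent_ihc[match(asn$terminal_label,
                                       truth$terminal_label)])
  expect_gte(acc, 0.95)
})

test_that("sector annotation: sign, middle band, antisymmetry", {
  poly <- ihc_polyline(cbind(x = c(0, 100), y = c(20, 20)))
  ihc_img <- matrix(0L, 40, 100)
  ihc_img[15:25, 45:55] <- 1L
  ihcs <- roi_set(ihc_img, kind = "ihc", px_size = 1)
  term_img <- matrix(0L, 40, 100)
  term_img[20, 50] <- 1L      # on the line -> middle
  term_img[33, 50] <- 2L      # +13 um -> positive side
  term_img[7, 50] <- 3L       # -13 um -> mirrored
  terms <- roi_set(term_img, kind = "sgn_terminal", px_size = 1)
  asn <- data.frame(terminal_label = 1:3, ihc_label = 1L,
                    distance_um = 0, method = "proximity", tie = FALSE)
  ann <- annotate_sector(terms, ihcs, poly, asn)
  expect_equal(ann$sector, c("middle", "pillar", "modiolar"))
  flipped <- annotate_sector(terms, ihcs, poly, asn,
                             pillar_positive = FALSE)
  expect_equal(flipped$sector, c("middle", "modiolar", "pillar"))
  expect_equal(sign(ann$signed_offset_um[2]), -sign(ann$signed_offset_um[3]))
})
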