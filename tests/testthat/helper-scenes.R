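# Shared fixtures: compact synthetic scenes and independent oracles.

# Small, fast IHC scene (2 min, 10 cells by default).
small_ihc_cfg <- function(seed = 1, n_frames = 3600, px_size = 2,
                          height = 32, width = 128, n_ihc = 10, ...) {
  scene_config("ihc", n_frames = n_frames, frame_rate = 30,
               px_size = px_size, height = height, width = width,
               n_ihc = n_ihc, seed = seed, ...)
}

# Noise-free trace carrying Gaussian bumps at given times (s).
bump_trace <- function(times_s, amps, sigmas_s, duration_s = 60,
                       frame_rate = 100, noise_sd = 0, seed = 1) {
  n <- round(duration_s * frame_rate)
  t <- (seq_len(n) - 1) / frame_rate
  x <- numeric(n)
  for (i in seq_along(times_s)) {
    x <- x + amps[i] * exp(-(t - times_s[i])^2 / (2 * sigmas_s[i]^2))
  }
  if (noise_sd > 0) {
    x <- x + withr::with_seed(seed, stats::rnorm(n, 0, noise_sd))
  }
  tr <- new_trace(1L, 100 * (1 + x), frame_rate)
  tr$dff <- x
  tr
}

# Independent brute-force oracle for the IHC event grouping: transitive
# closure of the pairwise |dt| <= window relation by repeated set merging,
# then a row-gap split. Deliberately different machinery from the
# union-find implementation under test.
brute_force_grouping <- function(times, rows, window_s = 2, max_gap = 4) {
  n <- length(times)
  if (n == 0L) return(list())
  sets <- as.list(seq_len(n))
  repeat {
    merged <- FALSE
    for (i in seq_along(sets)) {
      if (merged) break
      for (j in seq_along(sets)) {
        if (j <= i) next
        link <- any(outer(times[sets[[i]]], times[sets[[j]]],
                          function(a, b) abs(a - b) <= window_s))
        if (link) {
          sets[[i]] <- c(sets[[i]], sets[[j]])
          sets[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
    }
    if (!merged) break
  }
  out <- list()
  for (s in sets) {
    urow <- sort(unique(rows[s]))
    cuts <- which(diff(urow) - 1 > max_gap)
    bounds <- c(0, cuts, length(urow))
    for (b in seq_len(length(bounds) - 1)) {
      seg <- urow[(bounds[b] + 1):bounds[b + 1]]
      out[[length(out) + 1L]] <- sort(s[rows[s] %in% seg])
    }
  }
  out
}

# Canonical form of a partition (list of integer index sets) for comparison.
canonical_partition <- function(p) {
  p <- unname(lapply(p, function(s) as.integer(sort(s))))
  p[order(vapply(p, min, numeric(1)))]
}

# Match detected peaks to ground-truth peaks per ROI within a tolerance;
# returns hit rate, false-positive fraction and frequency error.
match_peaks <- function(detected, truth, tol_s = 1) {
  hit <- vapply(seq_len(nrow(truth)), function(i) {
    any(detected$roi_label == truth$roi_label[i] &
          abs(detected$peak_time_s - truth$peak_time_s[i]) < tol_s)
  }, logical(1))
  fp <- vapply(seq_len(nrow(detected)), function(j) {
    !any(truth$roi_label == detected$roi_label[j] &
           abs(truth$peak_time_s - detected$peak_time_s[j]) < tol_s)
  }, logical(1))
  list(hit_rate = mean(hit), fp_rate = mean(fp),
       n_detected = nrow(detected), n_truth = nrow(truth))
}

# Row index of every IHC along the polyline, as the pipeline computes it.
cell_order_from_rois <- function(rois, poly) {
  s_along <- vapply(seq_len(nrow(rois$centroids)), function(i) {
    polyline_nearest(poly, c(rois$centroids$x_um[i],
                             rois$centroids$y_um[i]))$s
  }, numeric(1))
  stats::setNames(rank(s_along, ties.method = "first"),
                  rois$centroids$label)
}
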