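# Forward model: synthetic two-photon movies with per-event ground truth.
#
# Three scene kinds mirror the three experimental workflows: a curved row of
# IHC somata with single-cell and coordinated multi-cell transients; a
# supporting-cell epithelium with elliptical, longitudinally elongated
# propagating waves; and punctate SGN terminal hotspots clustered around IHC
# somata. All randomness flows from one seeded generator per scene, so an
# identical configuration reproduces the movie bit for bit.

#' Scene configuration for the synthetic-movie generator
#'
#' Builds a validated configuration. Defaults describe a typical apical-coil
#' field of view: resonant-scanner frame rates for somatic/terminal scenes,
#' a slower rate for the (slow) supporting-cell waves, and GCaMP6f-like
#' transient kinetics. The IHC row defaults to a circular arc, matching the
#' curvature of the apical coil.
#'
#' @param scene_kind one of `"ihc"`, `"supporting"`, `"sgn"`.
#' @param n_frames number of frames.
#' @param frame_rate acquisition rate (Hz).
#' @param px_size micrometres per pixel.
#' @param height,width field size in pixels.
#' @param seed integer seed; identical configurations give bit-identical
#'   output.
#' @param n_ihc number of IHC somata placed along the polyline.
#' @param ihc_polyline optional `n x 2` matrix of (x, y) points in
#'   micrometres tracing the IHC row; default is a circular arc.
#' @param soma_a_um,soma_b_um soma semi-axes (along/across the row).
#' @param event_rate_per_min expected transient (peak) rate per cell per
#'   minute; the generator compensates block clipping at the row ends so
#'   the expected total peak count is `rate * n_ihc * duration`.
#' @param block_weights probability weights for the number of contiguous
#'   cells recruited by one event (index = block length). The default mixes
#'   single-cell transients with coordinated blocks of about seven cells.
#' @param amp_mean,amp_cv mean and coefficient of variation of peak dF/F0
#'   amplitudes (log-normal).
#' @param snr target signal-to-noise ratio; for `ihc`/`sgn` scenes this is
#'   peak amplitude over the noise SD of a soma-average dF/F0 trace, for
#'   `supporting` scenes peak amplitude over single-pixel noise SD. Use
#'   `Inf` for no read noise.
#' @param tau_rise_s,tau_decay_s difference-of-exponentials transient
#'   kinetics (GCaMP6f-like defaults).
#' @param jitter_sd_s SD of peak-time jitter within a coordinated block
#'   (truncated at 0.9 s, well inside the 2-s grouping window).
#' @param baseline_photons,background_photons baseline counts inside
#'   somata/epithelium and in the empty background.
#' @param shot_noise logical; apply Poisson shot noise to photon counts.
#' @param wave_rate_per_min,wave_amp,wave_axis_ratio,wave_expansion_speed,wave_contraction_speed,wave_rmax_range_um,wave_offset_um,wave_min_separation_s
#'   supporting-scene wave parameters: rate, plateau dF/F0 amplitude,
#'   longitudinal:radial axis ratio, radial growth/shrink speeds (um/s) of
#'   the equivalent radius, range of maximal equivalent radii, perpendicular
#'   offset of wave origins from the IHC row, and minimum separation
#'   between consecutive wave onsets.
#' @param speed_jitter relative jitter applied to per-wave speeds.
#' @param terminals_per_ihc_mean mean SGN terminals per IHC (Poisson,
#'   clipped to 1..8).
#' @param terminals_per_ihc_fixed optional fixed terminal count per IHC
#'   (overrides the Poisson draw; useful for deterministic construction).
#' @param terminal_radius_um terminal hotspot radius.
#' @param terminal_jitter_sd_s peak-time jitter of a terminal relative to
#'   its parent IHC event (truncated at 0.9 s).
#' @param terminal_failure_rate probability that a terminal misses a parent
#'   event.
#' @param ihc_baseline_frac brightness of (unlabelled) IHC somata in SGN
#'   scenes, as a fraction of `baseline_photons`.
#' @return a list of class `scene_config`.
#' @export
scene_config <- function(scene_kind = c("ihc", "supporting", "sgn"),
                         n_frames = NULL, frame_rate = NULL, px_size = 1,
                         height = 64L, width = 256L, seed = 1L,
                         n_ihc = 20L, ihc_polyline = NULL,
                         soma_a_um = 4.5, soma_b_um = 3.2,
                         event_rate_per_min = 0.8,
                         block_weights = NULL,
                         amp_mean = 1.0, amp_cv = 0.15, snr = 8,
                         tau_rise_s = 0.1, tau_decay_s = 0.7,
                         jitter_sd_s = 0.3,
                         baseline_photons = 100, background_photons = 10,
                         shot_noise = TRUE,
                         wave_rate_per_min = 0.8, wave_amp = 1.0,
                         wave_axis_ratio = 2.0,
                         wave_expansion_speed = 10,
                         wave_contraction_speed = 5,
                         wave_rmax_range_um = c(15, 30),
                         wave_offset_um = 30,
                         wave_min_separation_s = 3,
                         speed_jitter = 0,
                         terminals_per_ihc_mean = 3.3,
                         terminals_per_ihc_fixed = NULL,
                         terminal_radius_um = 1.5,
                         terminal_jitter_sd_s = 0.2,
                         terminal_failure_rate = 0.1,
                         ihc_baseline_frac = 0.15) {
  scene_kind <- match.arg(scene_kind)
  if (is.null(frame_rate)) {
    frame_rate <- if (scene_kind == "supporting") 10 else 30
  }
  if (is.null(n_frames)) n_frames <- as.integer(round(120 * frame_rate))
  if (frame_rate <= 0) stop("frame_rate must be > 0")
  if (px_size <= 0) stop("px_size must be > 0")
  if (is.null(block_weights)) {
    len <- 1:12
    block_weights <- c(0.25, 0.05, 0.70 * stats::dnorm(3:12, mean = 7, sd = 2.5) /
                         sum(stats::dnorm(3:12, mean = 7, sd = 2.5)))
  }
  if (is.null(ihc_polyline)) {
    ihc_polyline <- default_arc_polyline(height * px_size, width * px_size)
  }
  ihc_polyline <- as.matrix(ihc_polyline)
  if (nrow(ihc_polyline) < 2L) stop("ihc_polyline needs at least 2 points")
  cfg <- list(
    scene_kind = scene_kind, n_frames = as.integer(n_frames),
    frame_rate = frame_rate, px_size = px_size,
    height = as.integer(height), width = as.integer(width),
    seed = as.integer(seed), n_ihc = as.integer(n_ihc),
    ihc_polyline = ihc_polyline,
    soma_a_um = soma_a_um, soma_b_um = soma_b_um,
    event_rate_per_min = event_rate_per_min,
    block_weights = block_weights / sum(block_weights),
    amp_mean = amp_mean, amp_cv = amp_cv, snr = snr,
    tau_rise_s = tau_rise_s, tau_decay_s = tau_decay_s,
    jitter_sd_s = jitter_sd_s,
    baseline_photons = baseline_photons,
    background_photons = background_photons,
    shot_noise = isTRUE(shot_noise),
    wave_rate_per_min = wave_rate_per_min, wave_amp = wave_amp,
    wave_axis_ratio = wave_axis_ratio,
    wave_expansion_speed = wave_expansion_speed,
    wave_contraction_speed = wave_contraction_speed,
    wave_rmax_range_um = wave_rmax_range_um,
    wave_offset_um = wave_offset_um,
    wave_min_separation_s = wave_min_separation_s,
    speed_jitter = speed_jitter,
    terminals_per_ihc_mean = terminals_per_ihc_mean,
    terminals_per_ihc_fixed = terminals_per_ihc_fixed,
    terminal_radius_um = terminal_radius_um,
    terminal_jitter_sd_s = terminal_jitter_sd_s,
    terminal_failure_rate = terminal_failure_rate,
    ihc_baseline_frac = ihc_baseline_frac)
  class(cfg) <- "scene_config"
  cfg
}

# Circular arc through the field, bulging like the apical coil. Sagitta is
# 12% of the field height; endpoints sit 16 um inside the lateral borders,
# leaving room for somata to stay clear of drift-induced border fill.
default_arc_polyline <- function(height_um, width_um, n_pts = 80L) {
  margin <- 16
  x0 <- margin; x1 <- width_um - margin
  chord <- x1 - x0
  sag <- 0.12 * height_um
  radius <- (chord^2 / 4 + sag^2) / (2 * sag)
  cy <- height_um / 2 + radius - sag
  half_angle <- asin((chord / 2) / radius)
  ang <- seq(-half_angle, half_angle, length.out = n_pts)
  cbind(x = (x0 + x1) / 2 + radius * sin(ang),
        y = cy - radius * cos(ang))
}

# Difference-of-exponentials calcium transient, normalized to unit peak.
transient_kernel <- function(t, tau_rise, tau_decay) {
  tpk <- log(tau_decay / tau_rise) / (1 / tau_rise - 1 / tau_decay)
  peak <- exp(-tpk / tau_decay) - exp(-tpk / tau_rise)
  out <- numeric(length(t))
  pos <- t >= 0
  out[pos] <- (exp(-t[pos] / tau_decay) - exp(-t[pos] / tau_rise)) / peak
  out
}

# Time from transient onset to its peak.
kernel_peak_delay <- function(tau_rise, tau_decay) {
  log(tau_decay / tau_rise) / (1 / tau_rise - 1 / tau_decay)
}

# --- geometry helpers -------------------------------------------------------

# Pixel-centre coordinate grids in micrometres.
px_grid <- function(height, width, px_size) {
  list(x = (seq_len(width) - 0.5) * px_size,
       y = (seq_len(height) - 0.5) * px_size)
}

# Pixels inside an ellipse centred at `centre` with semi-axes (a, b) and unit
# long-axis direction `u`. Returns linear indices into an H x W matrix.
ellipse_pixels <- function(height, width, px_size, centre, a, b, u) {
  g <- px_grid(height, width, px_size)
  v <- c(-u[2], u[1])
  xr <- which(abs(g$x - centre[1]) <= max(a, b))
  yr <- which(abs(g$y - centre[2]) <= max(a, b))
  if (!length(xr) || !length(yr)) return(integer())
  dx <- rep(g$x[xr] - centre[1], each = length(yr))
  dy <- rep(g$y[yr] - centre[2], times = length(xr))
  pu <- dx * u[1] + dy * u[2]
  pv <- dx * v[1] + dy * v[2]
  inside <- (pu / a)^2 + (pv / b)^2 <= 1
  rows <- rep(yr, times = length(xr))[inside]
  cols <- rep(xr, each = length(yr))[inside]
  rows + (cols - 1L) * height
}

# Place n elliptical somata along the polyline at equal arc-length spacing
# with a small positional jitter; rejects layouts with overlapping somata and
# retries the jitter a bounded number of times.
place_somata <- function(cfg, max_tries = 20L) {
  poly <- ihc_polyline(cfg$ihc_polyline)
  total <- max(poly$s)
  spacing <- total / cfg$n_ihc
  if (spacing < 1.9 * cfg$soma_a_um) {
    stop("polyline too short for requested somata: overlapping placement")
  }
  for (try in seq_len(max_tries)) {
    label <- matrix(0L, cfg$height, cfg$width)
    centres <- matrix(0, cfg$n_ihc, 2)
    tangents <- matrix(0, cfg$n_ihc, 2)
    ok <- TRUE
    for (i in seq_len(cfg$n_ihc)) {
      s <- (i - 0.5) * spacing + stats::runif(1, -0.2, 0.2) * spacing * 0.3
      pt <- polyline_point(poly, s)
      off <- stats::runif(1, -0.8, 0.8)
      centre <- pt$point + off * pt$normal
      idx <- ellipse_pixels(cfg$height, cfg$width, cfg$px_size, centre,
                            cfg$soma_a_um, cfg$soma_b_um, pt$tangent)
      if (!length(idx) || any(label[idx] != 0L)) { ok <- FALSE; break }
      label[idx] <- i
      centres[i, ] <- centre
      tangents[i, ] <- pt$tangent
    }
    if (ok) {
      return(list(label = label, centres = centres, tangents = tangents,
                  spacing = spacing))
    }
  }
  stop("could not place somata without overlap after ", max_tries, " tries")
}

# Expected block size after clipping at the row ends, for rate compensation.
expected_clipped_block <- function(n_cells, weights) {
  lens <- seq_along(weights)
  total <- 0
  for (L in lens) {
    if (weights[L] == 0) next
    lo <- -((L - 1L) %/% 2L)
    hi <- (L %/% 2L)
    for (c0 in seq_len(n_cells)) {
      kept <- min(n_cells, c0 + hi) - max(1L, c0 + lo) + 1L
      total <- total + weights[L] * kept / n_cells
    }
  }
  total
}

# Draw IHC event times, blocks and per-participant peaks. Returns the ground
# truth tables and the per-cell dF/F0 signal matrix (n_frames x n_cells).
draw_ihc_events <- function(cfg, n_cells) {
  duration <- cfg$n_frames / cfg$frame_rate
  e_block <- expected_clipped_block(n_cells, cfg$block_weights)
  rate_events_per_s <- cfg$event_rate_per_min / 60 * n_cells / e_block
  n_events <- stats::rpois(1, rate_events_per_s * duration)
  times <- sort(stats::runif(n_events, 0, duration))
  sdlog <- sqrt(log(1 + cfg$amp_cv^2))
  meanlog <- log(cfg$amp_mean) - sdlog^2 / 2
  tpk <- kernel_peak_delay(cfg$tau_rise_s, cfg$tau_decay_s)
  ev_list <- vector("list", n_events)
  for (e in seq_len(n_events)) {
    L <- sample.int(length(cfg$block_weights), 1, prob = cfg$block_weights)
    c0 <- sample.int(n_cells, 1)
    cells <- max(1L, c0 - (L - 1L) %/% 2L):min(n_cells, c0 + L %/% 2L)
    jit <- stats::rnorm(length(cells), 0, cfg$jitter_sd_s)
    jit <- pmax(pmin(jit, 0.9), -0.9)
    if (length(cells)) jit[1] <- 0  # anchor the event time
    onset <- pmax(0, pmin(times[e] + jit, duration - 1e-9))
    amp <- stats::rlnorm(length(cells), meanlog, sdlog)
    ev_list[[e]] <- data.frame(event_id = e, roi_label = cells,
                               onset_s = onset, peak_time_s = onset + tpk,
                               amplitude = amp)
  }
  participants <- if (n_events) do.call(rbind, ev_list) else
    data.frame(event_id = integer(), roi_label = integer(),
               onset_s = numeric(), peak_time_s = numeric(),
               amplitude = numeric())
  events <- if (n_events) {
    data.frame(event_id = seq_len(n_events), t_s = times,
               n_cells = vapply(ev_list, nrow, integer(1)))
  } else {
    data.frame(event_id = integer(), t_s = numeric(), n_cells = integer())
  }
  # render per-cell signal
  sig <- matrix(0, cfg$n_frames, n_cells)
  if (nrow(participants)) {
    support <- ceiling((cfg$tau_decay_s * log(1000)) * cfg$frame_rate)
    for (r in seq_len(nrow(participants))) {
      f0 <- floor(participants$onset_s[r] * cfg$frame_rate) + 1L
      ff <- f0:min(cfg$n_frames, f0 + support)
      tt <- (ff - 1) / cfg$frame_rate - participants$onset_s[r]
      sig[ff, participants$roi_label[r]] <-
        sig[ff, participants$roi_label[r]] +
        participants$amplitude[r] *
        transient_kernel(tt, cfg$tau_rise_s, cfg$tau_decay_s)
    }
  }
  list(events = events, participants = participants, signal = sig)
}

# Apply shot and read noise to a photon-count array, in place conceptually.
apply_noise <- function(a, cfg, read_sd) {
  if (cfg$shot_noise) {
    if (any(a < 0)) a[a < 0] <- 0
    a[] <- stats::rpois(length(a), a)
  }
  if (is.finite(read_sd) && read_sd > 0) {
    a <- a + stats::rnorm(length(a), 0, read_sd)
  }
  a
}

# Read-noise SD that achieves the configured trace-level SNR for a mean ROI
# of `npix` pixels at baseline B, accounting for shot noise already present.
read_noise_for_snr <- function(cfg, npix) {
  if (!is.finite(cfg$snr)) return(0)
  target_var <- npix * (cfg$amp_mean * cfg$baseline_photons / cfg$snr)^2
  shot_var <- if (cfg$shot_noise) cfg$baseline_photons else 0
  sqrt(max(0, target_var - shot_var))
}

#' Generate a synthetic IHC scene
#'
#' Renders a curved row of IHC somata whose spontaneous transients occur as
#' single-cell events or coordinated contiguous blocks, with full ground
#' truth for every peak.
#'
#' @param cfg a [scene_config()] with `scene_kind = "ihc"`.
#' @return a list with elements `movie` ([movie_stack()]), `rois`
#'   ([roi_set()] of the true soma masks), and `truth` (ground-truth list
#'   with `events`, `participants`, `signal`, `artifacts`).
#' @export
generate_ihc_scene <- function(cfg) {
  stopifnot(inherits(cfg, "scene_config"), cfg$scene_kind == "ihc")
  withr::with_seed(cfg$seed, {
    placement <- place_somata(cfg)
    ev <- draw_ihc_events(cfg, cfg$n_ihc)
    hw <- cfg$height * cfg$width
    base <- matrix(cfg$background_photons, cfg$height, cfg$width)
    base[placement$label > 0L] <- cfg$baseline_photons
    m <- matrix(rep(as.numeric(base), cfg$n_frames), hw, cfg$n_frames)
    for (i in seq_len(cfg$n_ihc)) {
      idx <- which(placement$label == i)
      if (any(abs(ev$signal[, i]) > 0)) {
        m[idx, ] <- m[idx, ] + cfg$baseline_photons *
          matrix(ev$signal[, i], length(idx), cfg$n_frames, byrow = TRUE)
      }
    }
    npix <- mean(tabulate(placement$label[placement$label > 0L], cfg$n_ihc))
    read_sd <- read_noise_for_snr(cfg, npix)
    m <- apply_noise(m, cfg, read_sd)
    dim(m) <- c(cfg$height, cfg$width, cfg$n_frames)
    movie <- movie_stack(m, cfg$frame_rate, cfg$px_size)
    rm(m)
    rois <- roi_set(placement$label, kind = "ihc", px_size = cfg$px_size)
    truth <- list(events = ev$events, participants = ev$participants,
                  signal = ev$signal, centres_um = placement$centres,
                  artifacts = list())
    list(movie = movie, rois = rois, truth = truth)
  })
}

#' Generate a synthetic supporting-cell scene with propagating waves
#'
#' Calcium waves are rendered as ellipses whose long axis follows the local
#' tangent of the IHC row; the equivalent radius grows linearly at the
#' expansion speed and shrinks at the contraction speed. Waves reaching the
#' border of the field are clipped and flagged.
#'
#' @param cfg a [scene_config()] with `scene_kind = "supporting"`.
#' @return list with `movie`, `rois` (3-D ground-truth wave labels at 2x
#'   binned resolution) and `truth` (`waves` table, `artifacts`).
#' @export
generate_supporting_scene <- function(cfg) {
  stopifnot(inherits(cfg, "scene_config"), cfg$scene_kind == "supporting")
  withr::with_seed(cfg$seed, {
    duration <- cfg$n_frames / cfg$frame_rate
    poly <- ihc_polyline(cfg$ihc_polyline)
    total_s <- max(poly$s)
    rate_s <- cfg$wave_rate_per_min / 60
    onsets <- numeric(0)
    t <- 2
    repeat {
      t <- t + cfg$wave_min_separation_s + stats::rexp(1, rate_s)
      if (t >= duration - 2) break
      onsets <- c(onsets, t)
    }
    n_w <- length(onsets)
    waves <- data.frame(
      wave_id = seq_len(n_w), t_start_s = onsets,
      origin_x_um = numeric(n_w), origin_y_um = numeric(n_w),
      rmax_um = stats::runif(n_w, cfg$wave_rmax_range_um[1],
                             cfg$wave_rmax_range_um[2]),
      v_expand = cfg$wave_expansion_speed *
        (1 + stats::runif(n_w, -1, 1) * cfg$speed_jitter),
      v_contract = cfg$wave_contraction_speed *
        (1 + stats::runif(n_w, -1, 1) * cfg$speed_jitter),
      axis_ratio = rep(cfg$wave_axis_ratio, n_w),
      clipped = logical(n_w))
    tangents <- matrix(0, max(n_w, 1L), 2)
    for (k in seq_len(n_w)) {
      s <- stats::runif(1, 0.2, 0.8) * total_s
      pt <- polyline_point(poly, s)
      origin <- pt$point + cfg$wave_offset_um * pt$normal
      waves$origin_x_um[k] <- origin[1]
      waves$origin_y_um[k] <- origin[2]
      tangents[k, ] <- pt$tangent
    }
    waves$t_max_s <- waves$t_start_s + waves$rmax_um / waves$v_expand
    waves$t_end_s <- waves$t_max_s + waves$rmax_um / waves$v_contract
    waves$a_max_um <- waves$rmax_um * sqrt(waves$axis_ratio)
    waves$b_max_um <- waves$rmax_um / sqrt(waves$axis_ratio)
    waves$duration_s <- waves$t_end_s - waves$t_start_s

    hb <- cfg$height %/% 2L; wb <- cfg$width %/% 2L
    labels3d <- array(0L, c(hb, wb, cfg$n_frames))
    dff <- matrix(0, cfg$height * cfg$width, cfg$n_frames)
    g <- px_grid(cfg$height, cfg$width, cfg$px_size)
    gb <- px_grid(hb, wb, 2 * cfg$px_size)
    soft <- 0.05   # steep regenerative wavefront: 5% of the radius
    fov_w <- cfg$width * cfg$px_size
    fov_h <- cfg$height * cfg$px_size
    for (k in seq_len(n_w)) {
      u <- tangents[k, ]; v <- c(-u[2], u[1])
      f_lo <- max(1L, floor(waves$t_start_s[k] * cfg$frame_rate) + 1L)
      f_hi <- min(cfg$n_frames, ceiling(waves$t_end_s[k] * cfg$frame_rate))
      for (f in f_lo:f_hi) {
        tt <- (f - 1) / cfg$frame_rate
        r <- if (tt <= waves$t_max_s[k]) {
          waves$v_expand[k] * (tt - waves$t_start_s[k])
        } else {
          waves$rmax_um[k] - waves$v_contract[k] * (tt - waves$t_max_s[k])
        }
        if (r <= 0) next
        a <- r * sqrt(waves$axis_ratio[k])
        b <- r / sqrt(waves$axis_ratio[k])
        ctr <- c(waves$origin_x_um[k], waves$origin_y_um[k])
        if (ctr[1] - a < 0 || ctr[1] + a > fov_w ||
            ctr[2] - a < 0 || ctr[2] + a > fov_h) {
          waves$clipped[k] <- TRUE
        }
        rho <- ellipse_rho(g, ctr, a, b, u)
        val <- cfg$wave_amp * pmin(1, pmax(0, (1 - rho$rho) / soft))
        dff[rho$idx, f] <- pmax(dff[rho$idx, f], val)
        rhob <- ellipse_rho(gb, ctr, a, b, u)
        inb <- rhob$idx[rhob$rho <= 1]
        fr <- labels3d[, , f]
        fr[inb] <- k
        labels3d[, , f] <- fr
      }
    }
    m <- cfg$baseline_photons * (1 + dff)
    rm(dff)
    read_sd <- if (is.finite(cfg$snr)) {
      target <- (cfg$wave_amp * cfg$baseline_photons / cfg$snr)^2
      sqrt(max(0, target - if (cfg$shot_noise) cfg$baseline_photons else 0))
    } else 0
    m <- apply_noise(m, cfg, read_sd)
    dim(m) <- c(cfg$height, cfg$width, cfg$n_frames)
    movie <- movie_stack(m, cfg$frame_rate, cfg$px_size)
    rm(m)
    rois <- roi_set(labels3d, kind = "wave", px_size = cfg$px_size,
                    binning = 2L)
    list(movie = movie, rois = rois,
         truth = list(waves = waves, artifacts = list()))
  })
}

# Normalized elliptical radius of every pixel in the ellipse bounding box.
ellipse_rho <- function(g, centre, a, b, u) {
  v <- c(-u[2], u[1])
  height <- length(g$y)
  xr <- which(abs(g$x - centre[1]) <= max(a, b))
  yr <- which(abs(g$y - centre[2]) <= max(a, b))
  if (!length(xr) || !length(yr)) return(list(idx = integer(), rho = numeric()))
  dx <- rep(g$x[xr] - centre[1], each = length(yr))
  dy <- rep(g$y[yr] - centre[2], times = length(xr))
  pu <- dx * u[1] + dy * u[2]
  pv <- dx * v[1] + dy * v[2]
  rho <- sqrt((pu / a)^2 + (pv / b)^2)
  keep <- rho <= 1 + 1e-9
  rows <- rep(yr, times = length(xr))[keep]
  cols <- rep(xr, each = length(yr))[keep]
  list(idx = rows + (cols - 1L) * height, rho = rho[keep])
}

#' Generate a synthetic SGN-terminal scene
#'
#' Punctate hotspots (SGN synaptic terminals) cluster around faintly visible
#' IHC somata. Each terminal inherits its parent IHC's event times with
#' sub-second jitter and independent failures.
#'
#' @param cfg a [scene_config()] with `scene_kind = "sgn"`.
#' @return list with `movie`, `rois` (list with `terminals` and `ihcs`
#'   [roi_set()]s) and `truth` (`terminals` parent map with true sector
#'   offsets, `participants` per-terminal peaks, `events`).
#' @export
generate_sgn_scene <- function(cfg) {
  stopifnot(inherits(cfg, "scene_config"), cfg$scene_kind == "sgn")
  withr::with_seed(cfg$seed, {
    placement <- place_somata(cfg)
    poly <- ihc_polyline(cfg$ihc_polyline)
    n_per <- if (!is.null(cfg$terminals_per_ihc_fixed)) {
      rep(as.integer(cfg$terminals_per_ihc_fixed), cfg$n_ihc)
    } else {
      pmin(8L, pmax(1L, stats::rpois(cfg$n_ihc, cfg$terminals_per_ihc_mean)))
    }
    term_label <- matrix(0L, cfg$height, cfg$width)
    terminals <- list()
    centres_so_far <- matrix(numeric(0), ncol = 2)
    # hotspots keep a 2-um clearance so each punctum is optically resolvable
    min_sep <- 2 * cfg$terminal_radius_um + 2
    tid <- 0L
    for (i in seq_len(cfg$n_ihc)) {
      phase <- stats::runif(1, 0, 2 * pi)
      for (k in seq_len(n_per[i])) {
        u <- placement$tangents[i, ]; v <- c(-u[2], u[1])
        placed <- FALSE
        for (try in seq_len(200L)) {
          phi <- stats::runif(1, 0, 2 * pi)
          ring <- stats::runif(1, 1.15, 1.5)
          centre <- placement$centres[i, ] +
            ring * (cfg$soma_a_um * cos(phi) * u +
                      cfg$soma_b_um * sin(phi) * v)
          if (nrow(centres_so_far) &&
              min(sqrt((centres_so_far[, 1] - centre[1])^2 +
                         (centres_so_far[, 2] - centre[2])^2)) < min_sep) {
            next
          }
          idx <- ellipse_pixels(cfg$height, cfg$width, cfg$px_size, centre,
                                cfg$terminal_radius_um,
                                cfg$terminal_radius_um, c(1, 0))
          if (length(idx) >= 2L && all(term_label[idx] == 0L)) {
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          # crowded soma: fall back to a fine angular grid around the whole
          # ring; only strict pixel overlap is rejected (neighbouring
          # puncta may touch, as they do around a real IHC)
          for (try in seq_len(48L)) {
            phi <- phase + 2 * pi * (try - 1) / 48
            centre <- placement$centres[i, ] +
              1.3 * (cfg$soma_a_um * cos(phi) * u +
                       cfg$soma_b_um * sin(phi) * v)
            idx <- ellipse_pixels(cfg$height, cfg$width, cfg$px_size,
                                  centre, cfg$terminal_radius_um,
                                  cfg$terminal_radius_um, c(1, 0))
            if (length(idx) >= 2L && all(term_label[idx] == 0L)) {
              placed <- TRUE
              break
            }
          }
        }
        if (!placed) stop("could not place terminal hotspot without overlap")
        tid <- tid + 1L
        term_label[idx] <- tid
        centres_so_far <- rbind(centres_so_far, centre)
        np <- polyline_nearest(poly, centre)
        terminals[[tid]] <- data.frame(
          terminal_label = tid, parent_ihc = i,
          x_um = centre[1], y_um = centre[2],
          signed_offset_um = np$offset)
      }
    }
    terminals <- do.call(rbind, terminals)
    n_term <- tid
    ev <- draw_ihc_events(cfg, cfg$n_ihc)
    sdlog <- sqrt(log(1 + cfg$amp_cv^2))
    meanlog <- log(cfg$amp_mean) - sdlog^2 / 2
    tpk <- kernel_peak_delay(cfg$tau_rise_s, cfg$tau_decay_s)
    duration <- cfg$n_frames / cfg$frame_rate
    parts <- list()
    for (r in seq_len(nrow(ev$participants))) {
      parent <- ev$participants$roi_label[r]
      tids <- terminals$terminal_label[terminals$parent_ihc == parent]
      for (tl in tids) {
        if (stats::runif(1) < cfg$terminal_failure_rate) next
        jit <- max(-0.9, min(0.9, stats::rnorm(1, 0, cfg$terminal_jitter_sd_s)))
        onset <- max(0, min(ev$participants$onset_s[r] + jit, duration - 1e-9))
        parts[[length(parts) + 1L]] <- data.frame(
          terminal_label = tl, parent_ihc = parent,
          event_id = ev$participants$event_id[r],
          onset_s = onset, peak_time_s = onset + tpk,
          amplitude = stats::rlnorm(1, meanlog, sdlog))
      }
    }
    participants <- if (length(parts)) do.call(rbind, parts) else
      data.frame(terminal_label = integer(), parent_ihc = integer(),
                 event_id = integer(), onset_s = numeric(),
                 peak_time_s = numeric(), amplitude = numeric())
    # render
    sig <- matrix(0, cfg$n_frames, n_term)
    if (nrow(participants)) {
      support <- ceiling((cfg$tau_decay_s * log(1000)) * cfg$frame_rate)
      for (r in seq_len(nrow(participants))) {
        f0 <- floor(participants$onset_s[r] * cfg$frame_rate) + 1L
        ff <- f0:min(cfg$n_frames, f0 + support)
        tt <- (ff - 1) / cfg$frame_rate - participants$onset_s[r]
        tl <- participants$terminal_label[r]
        sig[ff, tl] <- sig[ff, tl] + participants$amplitude[r] *
          transient_kernel(tt, cfg$tau_rise_s, cfg$tau_decay_s)
      }
    }
    base <- matrix(cfg$background_photons, cfg$height, cfg$width)
    base[placement$label > 0L] <-
      cfg$ihc_baseline_frac * cfg$baseline_photons + cfg$background_photons
    base[term_label > 0L] <- cfg$baseline_photons
    hw <- cfg$height * cfg$width
    m <- matrix(rep(as.numeric(base), cfg$n_frames), hw, cfg$n_frames)
    for (tl in seq_len(n_term)) {
      idx <- which(term_label == tl)
      if (any(abs(sig[, tl]) > 0)) {
        m[idx, ] <- m[idx, ] + cfg$baseline_photons *
          matrix(sig[, tl], length(idx), cfg$n_frames, byrow = TRUE)
      }
    }
    npix <- mean(tabulate(term_label[term_label > 0L], n_term))
    read_sd <- read_noise_for_snr(cfg, npix)
    m <- apply_noise(m, cfg, read_sd)
    dim(m) <- c(cfg$height, cfg$width, cfg$n_frames)
    movie <- movie_stack(m, cfg$frame_rate, cfg$px_size)
    rm(m)
    rois <- list(
      terminals = roi_set(term_label, kind = "sgn_terminal",
                          px_size = cfg$px_size),
      ihcs = roi_set(placement$label, kind = "ihc", px_size = cfg$px_size))
    truth <- list(terminals = terminals, participants = participants,
                  events = ev$events, ihc_participants = ev$participants,
                  signal = sig, artifacts = list())
    list(movie = movie, rois = rois, truth = truth)
  })
}

#' Inject acquisition artifacts into a movie
#'
#' Simulates breathing-induced defocus (Gaussian blur of listed frames) and
#' lateral drift (cumulative integer translation). The returned artifact log
#' records exactly what was injected, frame by frame.
#'
#' @param movie a [movie_stack()].
#' @param drift_px_per_frame either a length-2 vector (constant per-frame
#'   drift `c(dy, dx)` in pixels) or a `T x 2` matrix of per-frame drift
#'   increments. Cumulative drift is rounded to integer pixel shifts.
#' @param blur_frames integer frame indices to defocus.
#' @param blur_sigma Gaussian blur SD in pixels.
#' @return list with the corrupted `movie` and an `artifacts` log
#'   (`blur_frames`, `blur_sigma`, `drift_px`: `T x 2` integer cumulative
#'   shifts).
#' @export
inject_artifacts <- function(movie, drift_px_per_frame = c(0, 0),
                             blur_frames = integer(), blur_sigma = 4) {
  nt <- n_frames(movie)
  d <- dim(movie$data)
  blur_frames <- as.integer(blur_frames)
  if (any(blur_frames < 1L | blur_frames > nt)) stop("invalid blur frame index")
  if (is.matrix(drift_px_per_frame)) {
    stopifnot(nrow(drift_px_per_frame) == nt, ncol(drift_px_per_frame) == 2L)
    inc <- drift_px_per_frame
  } else {
    inc <- matrix(rep(as.numeric(drift_px_per_frame), each = nt), nt, 2)
  }
  cum <- round(apply(inc, 2, cumsum))
  if (any(abs(cum[, 1]) >= d[1]) || any(abs(cum[, 2]) >= d[2])) {
    stop("drift pushes the field fully out of frame")
  }
  out <- movie
  for (f in blur_frames) {
    fr <- array(movie$data[, , f], c(d[1], d[2], 1L))
    fr <- conv_gauss_axis(fr, blur_sigma, 1L)
    fr <- conv_gauss_axis(fr, blur_sigma, 2L)
    out$data[, , f] <- fr[, , 1L]
  }
  if (any(cum != 0)) {
    for (f in seq_len(nt)) {
      if (cum[f, 1] != 0 || cum[f, 2] != 0) {
        out$data[, , f] <- shift_frame(out$data[, , f], cum[f, 1], cum[f, 2])
      }
    }
  }
  list(movie = out,
       artifacts = list(blur_frames = blur_frames, blur_sigma = blur_sigma,
                        drift_px = cum))
}

#' Simulate spatially correlated activity traces
#'
#' Draws Gaussian dF/F0-like traces for cells at given positions along the
#' row with correlation matrix `exp(-d_ij / lambda)`, the exponential
#' distance decay observed between neighbouring IHCs. Because the population
#' correlation of every pair is known in closed form, these traces serve as
#' ground truth for the correlation-versus-distance estimator.
#'
#' @param positions_um numeric vector of cell positions (1-D arc-length
#'   coordinates, micrometres).
#' @param lambda_um correlation length of the exponential decay.
#' @param n_samples number of time samples per trace.
#' @param frame_rate sampling rate (Hz).
#' @param seed integer seed.
#' @return list with `traces` (list of trace objects, see [new_trace()]) and
#'   `positions_um`.
#' @export
simulate_correlated_traces <- function(positions_um, lambda_um,
                                       n_samples = 9000L, frame_rate = 30,
                                       seed = 1L) {
  n <- length(positions_um)
  stopifnot(n >= 2L)
  d <- abs(outer(positions_um, positions_um, "-"))
  sigma <- exp(-d / lambda_um)
  cl <- chol(sigma)
  withr::with_seed(seed, {
    z <- matrix(stats::rnorm(n_samples * n), n_samples, n)
  })
  x <- z %*% cl
  traces <- lapply(seq_len(n), function(i) {
    tr <- new_trace(roi_label = i, f_raw = 100 * (1 + 0.1 * x[, i]),
                    frame_rate = frame_rate)
    tr$dff <- 0.1 * x[, i]
    tr
  })
  list(traces = traces, positions_um = positions_um)
}
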