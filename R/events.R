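# Transient detection and the event-grouping rules: prominence-selected
# peaks gated by the >2 SD amplitude and >200 ms FWHM criteria; peaks from
# different IHCs chained into events by a 2-s window; spatial splitting at
# gaps of more than four non-participating cells; single / two-cell /
# multiple classification; frequency definitions with the 5-minute rule.

#' Detect calcium transients in a dF/F0 trace
#'
#' Candidate peaks are local maxima of the detrended trace (rolling median
#' subtracted) selected by a prominence floor. A candidate is accepted only
#' if its amplitude exceeds `min_amp_sd` times the SD of the detrended
#' trace and its interpolated full width at half maximum exceeds
#' `min_fwhm_s`. Amplitude and the half-maximum level are measured from the
#' rolling-median baseline (the zero of the detrended trace); measuring
#' them from a local pre-peak minimum would let ordinary noise excursions
#' satisfy both criteria. The apex height and the width are estimated on a
#' matched-filtered copy of the trace (Gaussian, FWHM = `min_fwhm_s`),
#' with the kernel width deconvolved from the measured width; this keeps
#' both estimates stable against shot noise without biasing them. Samples
#' inside interpolated gap spans never contribute candidate maxima.
#'
#' @param trace a trace object with `dff` computed ([compute_dff()]).
#' @param min_amp_sd amplitude threshold in trace-SD units (default 2).
#' @param min_fwhm_s minimum FWHM in seconds (default 0.2).
#' @param prominence_sd prominence floor in trace-SD units (default 1.5).
#' @param detrend_window_s rolling-median window for detrending and for
#'   the SD estimate (default 20 s).
#' @param min_separation_s minimum separation between accepted peaks of one
#'   trace (default 2 s, the event-grouping window: successive transients
#'   of one cell closer than that window are not resolvable as separate
#'   events); of two closer peaks the larger wins. This suppresses
#'   re-detection of noise shoulders riding a transient's decay.
#' @param sd_value optional externally supplied SD (overrides the trace
#'   estimate).
#' @return data.frame: `roi_label`, `peak_frame`, `peak_time_s`,
#'   `amplitude`, `prominence`, `fwhm_s`, `sd_used`.
#' @export
detect_peaks <- function(trace, min_amp_sd = 2, min_fwhm_s = 0.2,
                         prominence_sd = 1.5, detrend_window_s = 20,
                         min_separation_s = 2, sd_value = NULL) {
  if (is.null(trace$dff)) stop("compute dF/F0 first (compute_dff)")
  fr <- trace$frame_rate
  if (length(trace$dff) / fr < min_fwhm_s) stop("trace shorter than min_fwhm_s")
  x <- trace$dff - rolling_median(trace$dff, round(detrend_window_s * fr))
  s <- sd_value %||% stats::sd(x[!trace$gap_mask])
  n <- length(x)
  empty <- data.frame(roi_label = integer(), peak_frame = integer(),
                      peak_time_s = numeric(), amplitude = numeric(),
                      prominence = numeric(), fwhm_s = numeric(),
                      sd_used = numeric())
  if (!is.finite(s) || s <= 0) return(empty)
  cand <- which(diff(sign(diff(x))) < 0) + 1L    # strict rise, fall or plateau
  cand <- cand[x[cand] > pmax(min_amp_sd, prominence_sd) * s * 0.5]
  cand <- cand[!trace$gap_mask[cand]]
  # Amplitude and width are measured on a matched-filtered copy of the
  # trace (Gaussian kernel with FWHM = the minimum admissible width): the
  # raw local maximum rides the maximum of the noise, overstating the
  # apex of wide sub-threshold transients by about one noise SD, and
  # noise dips through the half level truncate widths measured on the raw
  # trace. The smoothed width is then deconvolved (in Gaussian quadrature)
  # from the known kernel width, which is exact for Gaussian transients
  # and a negligible correction for the much wider physiological ones.
  sig_frames <- min_fwhm_s / (2 * sqrt(2 * log(2))) * fr
  xs <- conv_gauss_axis(array(x, c(n, 1L, 1L)), sig_frames, 1L)[, 1, 1]
  w_apex <- max(1L, as.integer(round(min_fwhm_s * fr)))
  rows <- list()
  for (i in cand) {
    if (x[i] <= min_amp_sd * s) next
    span <- max(1L, i - w_apex):min(n, i + w_apex)
    ixs <- span[which.max(xs[span])]
    apex <- xs[ixs]
    if (apex <= min_amp_sd * s) next
    prom <- peak_prominence(x, i)
    if (prom < prominence_sd * s) next
    cross <- half_crossings(xs, ixs, apex / 2)
    if (anyNA(cross)) next
    w_meas <- (cross[2] - cross[1]) / fr
    kernel_fwhm <- 2 * sqrt(2 * log(2)) * sig_frames / fr
    fwhm <- sqrt(max(0, w_meas^2 - kernel_fwhm^2))
    if (fwhm <= min_fwhm_s) next
    rows[[length(rows) + 1L]] <- data.frame(
      roi_label = trace$roi_label, peak_frame = i,
      peak_time_s = (i - 1) / fr, amplitude = apex, prominence = prom,
      fwhm_s = fwhm, sd_used = s, left = cross[1], right = cross[2])
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  # one transient, one peak: candidates whose half-maximum supports overlap,
  # or that fall within the minimum separation of a larger peak, are
  # shoulders of the same transient; keep the highest
  out <- out[order(-out$amplitude), , drop = FALSE]
  min_sep_frames <- min_separation_s * fr
  keep <- rep(TRUE, nrow(out))
  for (k in seq_len(nrow(out))) {
    if (!keep[k]) next
    later <- which(keep & seq_len(nrow(out)) > k)
    if (!length(later)) next
    ov <- (out$left[later] <= out$right[k] &
             out$right[later] >= out$left[k]) |
      abs(out$peak_frame[later] - out$peak_frame[k]) < min_sep_frames
    keep[later[ov]] <- FALSE
  }
  out <- out[keep, , drop = FALSE]
  out$left <- NULL
  out$right <- NULL
  out <- out[order(out$peak_time_s), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Topographic prominence of the local maximum at index i: height above the
# higher of the two key saddles (lowest point between the peak and the next
# higher terrain on each side; the series edge counts as higher terrain).
peak_prominence <- function(x, i) {
  n <- length(x)
  left_min <- x[i]
  j <- i - 1L
  while (j >= 1L && x[j] <= x[i]) {
    if (x[j] < left_min) left_min <- x[j]
    j <- j - 1L
  }
  right_min <- x[i]
  j <- i + 1L
  while (j <= n && x[j] <= x[i]) {
    if (x[j] < right_min) right_min <- x[j]
    j <- j + 1L
  }
  x[i] - max(left_min, right_min)
}

# Temporal chaining shared by the IHC and SGN grouping rules: peaks belong
# to the same temporal group when they can be linked through steps of at
# most `window_s`. Implemented as union-find over time-sorted neighbours
# (for a 1-D chain relation, consecutive links generate the transitive
# closure).
chain_groups <- function(times, window_s) {
  n <- length(times)
  if (n == 0L) return(integer(0))
  ord <- order(times)
  parent <- uf_init(n)
  for (k in seq_len(n - 1L)) {
    if (times[ord[k + 1L]] - times[ord[k]] <= window_s) {
      r1 <- uf_find(parent, ord[k]); r2 <- uf_find(parent, ord[k + 1L])
      if (r1 != r2) parent[max(r1, r2)] <- min(r1, r2)
    }
  }
  root <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
  match(root, unique(root[ord]))
}

#' Group IHC peaks into events
#'
#' Peaks from any cells are assigned to the same event when their peak
#' times are chainable in steps of at most `window_s` (transitive closure
#' of the "within 2 s of one another" relation). Within each temporal
#' group, participating cells are ordered along the row and the group is
#' split wherever more than `max_gap_cells` non-participating cells
#' separate consecutive participants. Events are classified `single`
#' (1 cell), `two_cell` (2) or `multiple` (>= 3); two-cell events stay in
#' the table but are excluded from the single/multiple percentages (see
#' [event_classification_summary()]).
#'
#' @param peaks data.frame from [detect_peaks()] (rows from many cells).
#' @param cell_order named integer vector: row index along the IHC row for
#'   every `roi_label`.
#' @param window_s temporal chaining window (default 2 s).
#' @param max_gap_cells maximum tolerated gap of non-participating cells
#'   (default 4).
#' @return list with `events` (event_id, t_start_s, t_end_s, n_cells,
#'   classification) and `peaks` (input rows with `event_id`).
#' @export
group_ihc_events <- function(peaks, cell_order, window_s = 2,
                             max_gap_cells = 4) {
  if (nrow(peaks) == 0L) {
    return(list(events = data.frame(event_id = integer(),
                                    t_start_s = numeric(),
                                    t_end_s = numeric(), n_cells = integer(),
                                    classification = character()),
                peaks = cbind(peaks, event_id = integer(0))))
  }
  if (!all(as.character(peaks$roi_label) %in% names(cell_order))) {
    stop("every cell must have a row index in cell_order")
  }
  grp <- chain_groups(peaks$peak_time_s, window_s)
  rows <- cell_order[as.character(peaks$roi_label)]
  event_of <- integer(nrow(peaks))
  next_id <- 0L
  for (g in unique(grp)) {
    sel <- which(grp == g)
    urow <- sort(unique(rows[sel]))
    gapcut <- which(diff(urow) - 1L > max_gap_cells)
    bounds <- c(0L, gapcut, length(urow))
    for (b in seq_len(length(bounds) - 1L)) {
      seg_rows <- urow[(bounds[b] + 1L):bounds[b + 1L]]
      next_id <- next_id + 1L
      event_of[sel[rows[sel] %in% seg_rows]] <- next_id
    }
  }
  build_event_table(peaks, event_of)
}

#' Group SGN-terminal peaks into events
#'
#' Terminals contacting the same IHC share an event when their peaks are
#' chainable within `window_s` (default 1 s); there is no spatial
#' splitting.
#'
#' @param peaks data.frame from [detect_peaks()] for the terminals of one
#'   IHC.
#' @param window_s chaining window (default 1 s).
#' @return as [group_ihc_events()].
#' @export
group_sgn_events <- function(peaks, window_s = 1) {
  if (nrow(peaks) == 0L) {
    return(list(events = data.frame(event_id = integer(),
                                    t_start_s = numeric(),
                                    t_end_s = numeric(), n_cells = integer(),
                                    classification = character()),
                peaks = cbind(peaks, event_id = integer(0))))
  }
  build_event_table(peaks, chain_groups(peaks$peak_time_s, window_s))
}

build_event_table <- function(peaks, event_of) {
  peaks$event_id <- event_of
  ids <- sort(unique(event_of))
  ev <- do.call(rbind, lapply(ids, function(e) {
    sel <- peaks[peaks$event_id == e, ]
    n_cells <- length(unique(sel$roi_label))
    data.frame(event_id = e,
               t_start_s = min(sel$peak_time_s),
               t_end_s = max(sel$peak_time_s),
               n_cells = n_cells,
               classification = if (n_cells == 1L) "single"
               else if (n_cells == 2L) "two_cell" else "multiple")
  }))
  # renumber chronologically
  ord <- order(ev$t_start_s, ev$event_id)
  remap <- stats::setNames(seq_along(ord), ev$event_id[ord])
  ev <- ev[ord, ]
  ev$event_id <- seq_len(nrow(ev))
  peaks$event_id <- as.integer(remap[as.character(peaks$event_id)])
  rownames(ev) <- NULL
  list(events = ev, peaks = peaks)
}

#' Single/multiple event percentages
#'
#' Two-cell events are excluded from the denominator to limit the impact of
#' coincidental co-activation; their share is reported separately.
#'
#' @param events event table from [group_ihc_events()].
#' @return list with `pct_single`, `pct_multiple` (of non-two-cell events)
#'   and `pct_two_cell` (of all events).
#' @export
event_classification_summary <- function(events) {
  n_all <- nrow(events)
  n_two <- sum(events$classification == "two_cell")
  n_single <- sum(events$classification == "single")
  n_multi <- sum(events$classification == "multiple")
  denom <- n_single + n_multi
  list(pct_single = if (denom) 100 * n_single / denom else NA_real_,
       pct_multiple = if (denom) 100 * n_multi / denom else NA_real_,
       pct_two_cell = if (n_all) 100 * n_two / n_all else NA_real_)
}

#' Event or peak frequency
#'
#' Count divided by total valid duration, in events per minute. Recordings
#' shorter than `min_duration_s` are not evaluable for frequency and return
#' `NA` (a marker, not zero).
#'
#' @param x a count, or a data.frame whose rows are counted.
#' @param total_duration_s total valid recording time in seconds.
#' @param min_duration_s eligibility threshold (default 300 s).
#' @return frequency in min^-1, or `NA_real_` when not evaluable.
#' @export
compute_frequency <- function(x, total_duration_s, min_duration_s = 300) {
  if (total_duration_s <= 0) stop("total_duration_s must be > 0")
  n <- if (is.data.frame(x)) nrow(x) else as.numeric(x)
  if (total_duration_s < min_duration_s) return(NA_real_)
  n / (total_duration_s / 60)
}

#' ABR wave-1 amplitude and latency
#'
#' P1 is the local maximum nearest the supplied guess, N1 the first local
#' minimum after P1; amplitude is V(P1) - V(N1) and latency the delay of P1
#' from stimulus onset.
#'
#' @param time_ms uniform time grid (ms).
#' @param voltage_uv ABR waveform (microvolts).
#' @param p1_guess_ms initial guess for the P1 position (ms).
#' @param onset_ms stimulus onset (ms), default 0.
#' @return list with `amplitude_uv`, `latency_ms`, `p1_ms`, `n1_ms`.
#' @export
abr_wave1_metrics <- function(time_ms, voltage_uv, p1_guess_ms,
                              onset_ms = 0) {
  stopifnot(length(time_ms) == length(voltage_uv))
  if (p1_guess_ms < min(time_ms) || p1_guess_ms > max(time_ms)) {
    stop("p1_guess_ms outside the record")
  }
  dv <- diff(voltage_uv)
  maxima <- which(diff(sign(dv)) < 0) + 1L
  minima <- which(diff(sign(dv)) > 0) + 1L
  if (!length(maxima) || !length(minima)) stop("no extrema in waveform")
  p1 <- maxima[which.min(abs(time_ms[maxima] - p1_guess_ms))]
  n1_cand <- minima[minima > p1]
  if (!length(n1_cand)) stop("no trough after P1")
  n1 <- n1_cand[1]
  list(amplitude_uv = voltage_uv[p1] - voltage_uv[n1],
       latency_ms = time_ms[p1] - onset_ms,
       p1_ms = time_ms[p1], n1_ms = time_ms[n1])
}

#' Acoustic propagation delay
#'
#' Delay of a free-field stimulus over `distance_m` at the speed of sound;
#' for the conventional 10 cm speaker distance this is about 0.3 ms.
#'
#' @param distance_m speaker-to-pinna distance in metres.
#' @param speed_of_sound_mps speed of sound (default 343 m/s).
#' @return delay in milliseconds.
#' @export
acoustic_delay <- function(distance_m, speed_of_sound_mps = 343) {
  if (distance_m < 0 || speed_of_sound_mps <= 0) {
    stop("distance and speed must be positive")
  }
  1000 * distance_m / speed_of_sound_mps
}
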