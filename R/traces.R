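# Per-ROI fluorescence traces and their normalization to dF/F0.

#' Trace object
#'
#' A per-ROI fluorescence time series. `gap_mask` marks samples whose value
#' is synthetic (replaced frames, stitching gaps); `duration_s` counts only
#' valid time and drives the 5-minute eligibility rules for frequency and
#' correlation analyses.
#'
#' @param roi_label integer ROI label.
#' @param f_raw numeric vector of raw pixel-average fluorescence.
#' @param frame_rate sampling rate (Hz).
#' @param gap_mask logical vector, `TRUE` where the sample is interpolated.
#' @return object of class `ca_trace`.
#' @export
new_trace <- function(roi_label, f_raw, frame_rate,
                      gap_mask = rep(FALSE, length(f_raw))) {
  stopifnot(length(gap_mask) == length(f_raw), frame_rate > 0)
  structure(list(roi_label = as.integer(roi_label),
                 f_raw = as.numeric(f_raw),
                 dff = NULL,
                 gap_mask = as.logical(gap_mask),
                 frame_rate = frame_rate,
                 duration_s = sum(!gap_mask) / frame_rate),
            class = "ca_trace")
}

#' @export
print.ca_trace <- function(x, ...) {
  cat(sprintf("ca_trace roi %d: %d samples @ %.3g Hz (%.1f s valid)%s\n",
              x$roi_label, length(x$f_raw), x$frame_rate, x$duration_s,
              if (is.null(x$dff)) "" else ", dF/F0 computed"))
  invisible(x)
}

#' Extract pixel-average traces for every ROI
#'
#' @param movie a [movie_stack()]; its `removed_frames` become trace gaps.
#' @param rois a [roi_set()] with a 2-D label image at the movie's
#'   resolution.
#' @return named list of trace objects keyed by ROI label.
#' @export
extract_traces <- function(movie, rois) {
  stopifnot(length(dim(rois$label_image)) == 2L)
  d <- dim(movie$data)
  flat <- matrix(movie$data, d[1] * d[2], d[3])
  gap <- rep(FALSE, d[3])
  gap[movie$removed_frames] <- TRUE
  out <- lapply(roi_labels(rois), function(l) {
    idx <- which(rois$label_image == l)
    new_trace(l, .colMeans(flat[idx, , drop = FALSE], length(idx), d[3]),
              movie$frame_rate, gap)
  })
  stats::setNames(out, roi_labels(rois))
}

#' Compute dF/F0 with a sliding-percentile baseline
#'
#' F0 is a rolling low percentile (default the 8th over 30 s) of the raw
#' trace, which tracks slow drift while ignoring transients; dF/F0 is
#' `(F - F0) / F0` with F0 floored at a small positive value. Gap samples
#' are linearly interpolated first so the baseline is well defined
#' everywhere.
#'
#' @param trace a trace object ([new_trace()]).
#' @param baseline_window_s baseline window in seconds (>= 10).
#' @param baseline_percentile baseline percentile, 0-100.
#' @param f0_floor_frac floor on F0 as a fraction of the trace median.
#' @return the trace with `dff` filled in.
#' @export
compute_dff <- function(trace, baseline_window_s = 30,
                        baseline_percentile = 8, f0_floor_frac = 0.01) {
  if (baseline_window_s < 10) stop("baseline window must be >= 10 s")
  if (all(trace$f_raw <= 0)) stop("non-positive fluorescence throughout")
  tr <- interpolate_trace_gaps(trace)
  w <- max(3L, round(baseline_window_s * trace$frame_rate))
  f0 <- rolling_quantile(tr$f_raw, w, baseline_percentile)
  floor_val <- max(f0_floor_frac * stats::median(tr$f_raw),
                   .Machine$double.eps)
  f0[f0 < floor_val] <- floor_val
  trace$dff <- (tr$f_raw - f0) / f0
  trace
}

#' Pixel-average IHC trace from its SGN terminals
#'
#' Averages the traces of all terminals assigned to one IHC, pointwise and
#' gap-aware: a sample is the mean of the valid terminal samples, and a gap
#' only where every terminal has a gap.
#'
#' @param traces list of trace objects (the terminals of one IHC).
#' @return a single trace object (`roi_label` taken from the first input).
#' @export
sgn_ihc_average_trace <- function(traces) {
  stopifnot(length(traces) >= 1L)
  n <- length(traces[[1]]$f_raw)
  fr <- traces[[1]]$frame_rate
  raw <- vapply(traces, function(t) t$f_raw, numeric(n))
  gaps <- vapply(traces, function(t) t$gap_mask, logical(n))
  raw <- matrix(raw, n); gaps <- matrix(gaps, n)
  valid <- !gaps
  denom <- rowSums(valid)
  f <- rowSums(raw * valid) / pmax(denom, 1L)
  all_gap <- denom == 0L
  f[all_gap] <- 0
  out <- new_trace(traces[[1]]$roi_label, f, fr, gap_mask = all_gap)
  if (!is.null(traces[[1]]$dff)) {
    dffs <- vapply(traces, function(t) t$dff, numeric(n))
    dffs <- matrix(dffs, n)
    out$dff <- rowSums(dffs * valid) / pmax(denom, 1L)
    out$dff[all_gap] <- 0
  }
  out
}
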