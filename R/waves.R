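# Morphometry and kinetics of supporting-cell calcium waves: per-frame
# area, FWHM of the pixel-average trace, expansion/contraction speed of
# the equivalent radius, and extents along/across the IHC row.

#' Per-frame area of one 3-D wave ROI
#'
#' Labelled-pixel counts per frame converted to micrometres squared,
#' inverting the spatial binning used during segmentation.
#'
#' @param wave_rois a [roi_set()] of kind `"wave"`.
#' @param label wave label.
#' @param frame_rate acquisition rate (Hz), for the time column.
#' @return data.frame: `frame`, `t_s`, `area_um2`; attributes `max_area_um2`,
#'   `t_max_area_s`, `frame_max`.
#' @export
wave_area_series <- function(wave_rois, label, frame_rate) {
  stopifnot(wave_rois$kind == "wave")
  li <- wave_rois$label_image
  d <- dim(li)
  eff2 <- (wave_rois$px_size * wave_rois$binning)^2
  sel <- li == as.integer(label)
  per_frame <- .colSums(matrix(sel, d[1] * d[2], d[3]), d[1] * d[2], d[3])
  frames <- which(per_frame > 0)
  if (length(frames) < 2L) stop("wave must span at least 2 frames")
  span <- seq(min(frames), max(frames))
  out <- data.frame(frame = span, t_s = (span - 1) / frame_rate,
                    area_um2 = per_frame[span] * eff2)
  imax <- span[which.max(per_frame[span])]
  attr(out, "max_area_um2") <- max(out$area_um2)
  attr(out, "t_max_area_s") <- (imax - 1) / frame_rate
  attr(out, "frame_max") <- imax
  out
}

#' FWHM of a wave's pixel-average dF/F0 trace
#'
#' The trace is the pixel average of the dF/F0 movie over the wave's
#' maximal-area footprint; the full width at half maximum is taken by
#' linear interpolation of the half-crossings around the trace maximum,
#' with the dF/F0 baseline (zero) as reference level.
#'
#' @param movie a dF/F0 [movie_stack()] at the binned resolution of
#'   `wave_rois` (see [bin_movie()], [movie_dff()]).
#' @param wave_rois a [roi_set()] of kind `"wave"`.
#' @param label wave label.
#' @return FWHM in seconds.
#' @export
wave_fwhm <- function(movie, wave_rois, label) {
  stopifnot(wave_rois$kind == "wave")
  li <- wave_rois$label_image
  d <- dim(li)
  stopifnot(all(dim(movie$data)[1:2] == d[1:2]))
  sel <- li == as.integer(label)
  per_frame <- .colSums(matrix(sel, d[1] * d[2], d[3]), d[1] * d[2], d[3])
  if (!any(per_frame > 0)) stop("empty wave ROI")
  fmax <- which.max(per_frame)
  footprint <- which(sel[, , fmax])
  flat <- matrix(movie$data, d[1] * d[2], dim(movie$data)[3])
  trace <- .colMeans(flat[footprint, , drop = FALSE], length(footprint),
                     ncol(flat))
  pk <- which.max(trace)
  if (trace[pk] <= 0) stop("no peak in wave pixel-average trace")
  cross <- half_crossings(trace, pk, trace[pk] / 2)
  if (anyNA(cross)) stop("half-maximum level never crossed")
  (cross[2] - cross[1]) / movie$frame_rate
}

#' Expansion and contraction speed of a wave
#'
#' The equivalent radius `r(t) = sqrt(area(t) / pi)` is regressed on time
#' from wave onset to maximal area (expansion) and from maximal area to
#' offset (contraction); onset/offset are the first/last frames whose area
#' reaches `onset_frac` of the maximum. Waves with fewer than two frames
#' on a limb return `NA` for that speed (undefined, not zero). Manually
#' outlined 2-D waves carry no kinetics: pass `manual = TRUE` to get both
#' speeds `NA`.
#'
#' @param area_series data.frame from [wave_area_series()].
#' @param onset_frac area fraction defining onset/offset (default 0.1).
#' @param manual logical; manually outlined waves have undefined speeds.
#' @return list with `expansion_um_s`, `contraction_um_s` (both positive;
#'   `NA` when undefined).
#' @export
wave_speeds <- function(area_series, onset_frac = 0.1, manual = FALSE) {
  if (manual) return(list(expansion_um_s = NA_real_,
                          contraction_um_s = NA_real_))
  a <- area_series$area_um2
  t <- area_series$t_s
  imax <- which.max(a)
  thresh <- onset_frac * a[imax]
  on <- which(a >= thresh)
  i0 <- min(on); i1 <- max(on)
  r <- sqrt(a / pi)
  fit_slope <- function(idx) {
    if (length(idx) < 2L) return(NA_real_)
    unname(stats::coef(stats::lm(r[idx] ~ t[idx]))[2])
  }
  list(expansion_um_s = fit_slope(i0:imax),
       contraction_um_s = abs(fit_slope(imax:i1)))
}

#' Longitudinal and radial extent of a wave at maximal area
#'
#' The polyline tangent at the point nearest the wave centroid (smoothed
#' over neighbouring segments) defines the longitudinal axis; the radial
#' axis is perpendicular. Extents are peak-to-peak projections of the
#' maximal-area footprint onto the two axes, plus one binned pixel for the
#' pixel's own width.
#'
#' @param wave_rois a [roi_set()] of kind `"wave"`.
#' @param label wave label.
#' @param polyline an [ihc_polyline()].
#' @return list with `longitudinal_um`, `radial_um`, `centroid_um`.
#' @export
wave_axis_extents <- function(wave_rois, label, polyline) {
  stopifnot(wave_rois$kind == "wave")
  li <- wave_rois$label_image
  d <- dim(li)
  sel <- li == as.integer(label)
  per_frame <- .colSums(matrix(sel, d[1] * d[2], d[3]), d[1] * d[2], d[3])
  if (!any(per_frame > 0)) stop("empty wave ROI")
  fmax <- which.max(per_frame)
  idx <- which(sel[, , fmax], arr.ind = TRUE)
  eff <- wave_rois$px_size * wave_rois$binning
  pts <- cbind((idx[, 2] - 0.5) * eff, (idx[, 1] - 0.5) * eff)
  centroid <- colMeans(pts)
  u <- polyline_smoothed_tangent(polyline, centroid)
  v <- c(-u[2], u[1])
  pu <- (pts[, 1] - centroid[1]) * u[1] + (pts[, 2] - centroid[2]) * u[2]
  pv <- (pts[, 1] - centroid[1]) * v[1] + (pts[, 2] - centroid[2]) * v[2]
  list(longitudinal_um = diff(range(pu)) + eff,
       radial_um = diff(range(pv)) + eff,
       centroid_um = centroid)
}

#' Wave frequency
#'
#' Number of waves (manually outlined ones included) divided by the
#' collated duration of all recordings of the field of view, in min^-1.
#'
#' @param n_waves wave count, or a data.frame whose rows are counted.
#' @param total_duration_s collated duration (s).
#' @return waves per minute.
#' @export
wave_frequency <- function(n_waves, total_duration_s) {
  if (total_duration_s <= 0) stop("total_duration_s must be > 0")
  n <- if (is.data.frame(n_waves)) nrow(n_waves) else as.numeric(n_waves)
  n / (total_duration_s / 60)
}

#' Full morphometric record for every wave in a segmentation
#'
#' @param wave_rois a [roi_set()] of kind `"wave"`.
#' @param movie_dff_binned dF/F0 movie at the binned resolution (for the
#'   FWHM trace); `NULL` skips the FWHM column.
#' @param polyline an [ihc_polyline()].
#' @param frame_rate acquisition rate (Hz).
#' @param manual_labels labels of manually outlined 2-D waves (kinetics
#'   undefined for these).
#' @return data.frame, one row per wave: areas, times, FWHM, speeds,
#'   extents, centroid, `manual_flag`.
#' @export
summarize_waves <- function(wave_rois, movie_dff_binned, polyline,
                            frame_rate, manual_labels = integer()) {
  labs <- roi_labels(wave_rois)
  if (!length(labs)) {
    return(data.frame(wave_id = integer(), max_area_um2 = numeric(),
                      t_max_area_s = numeric(), fwhm_s = numeric(),
                      expansion_um_s = numeric(),
                      contraction_um_s = numeric(),
                      longitudinal_um = numeric(), radial_um = numeric(),
                      centroid_x_um = numeric(), centroid_y_um = numeric(),
                      manual_flag = logical()))
  }
  rows <- lapply(labs, function(l) {
    as_ <- wave_area_series(wave_rois, l, frame_rate)
    manual <- l %in% manual_labels
    sp <- wave_speeds(as_, manual = manual)
    ext <- wave_axis_extents(wave_rois, l, polyline)
    fw <- if (is.null(movie_dff_binned)) NA_real_ else
      tryCatch(wave_fwhm(movie_dff_binned, wave_rois, l),
               error = function(e) NA_real_)
    data.frame(wave_id = l,
               max_area_um2 = attr(as_, "max_area_um2"),
               t_max_area_s = attr(as_, "t_max_area_s"),
               fwhm_s = fw,
               expansion_um_s = sp$expansion_um_s,
               contraction_um_s = sp$contraction_um_s,
               longitudinal_um = ext$longitudinal_um,
               radial_um = ext$radial_um,
               centroid_x_um = ext$centroid_um[1],
               centroid_y_um = ext$centroid_um[2],
               manual_flag = manual)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
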