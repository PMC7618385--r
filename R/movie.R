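#' Movie stack container
#'
#' A `movie_stack` holds a single-channel fluorescence time-lapse as an
#' `H x W x T` numeric array together with its physical calibration. Pixel
#' values are detector counts (arbitrary units); frames removed by the
#' quality triage are tracked in `removed_frames` but their slots always hold
#' valid pixel data (they are filled from the nearest in-focus frame), so the
#' frame count `T` -- and hence timing -- never changes.
#'
#' @param data numeric `H x W x T` array of pixel intensities.
#' @param frame_rate acquisition rate in Hz (> 0).
#' @param px_size pixel size in micrometres per pixel (> 0).
#' @param removed_frames integer indices (1-based) of frames whose pixel data
#'   were replaced during triage.
#' @param frame_origin optional integer vector (length `T`) giving the source
#'   recording id of each frame when several recordings are collated.
#' @return an object of class `movie_stack`.
#' @export
movie_stack <- function(data, frame_rate, px_size, removed_frames = integer(),
                        frame_origin = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (!is.numeric(frame_rate) || frame_rate <= 0) stop("frame_rate must be > 0")
  if (!is.numeric(px_size) || px_size <= 0) stop("px_size must be > 0")
  nt <- dim(data)[3]
  removed_frames <- as.integer(removed_frames)
  if (any(removed_frames < 1L | removed_frames > nt)) {
    stop("removed_frames out of range")
  }
  if (is.null(frame_origin)) frame_origin <- rep(1L, nt)
  structure(
    list(data = data, frame_rate = frame_rate, px_size = px_size,
         removed_frames = sort(unique(removed_frames)),
         frame_origin = as.integer(frame_origin)),
    class = "movie_stack"
  )
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "movie_stack: %d x %d px, %d frames @ %.3g Hz, %.3g um/px (%d replaced)\n",
    d[1], d[2], d[3], x$frame_rate, x$px_size, length(x$removed_frames)))
  invisible(x)
}

#' @export
dim.movie_stack <- function(x) dim(x$data)

n_frames <- function(movie) dim(movie$data)[3]

#' Duration of a movie in seconds
#' @param movie a [movie_stack()].
#' @export
movie_duration_s <- function(movie) n_frames(movie) / movie$frame_rate

#' Write a movie as a multi-page 16-bit TIFF with a JSON sidecar
#'
#' Pixel values are rounded to integers and clipped to `[0, 65535]`. The
#' calibration (frame rate, pixel size) and the removed-frame list go to a
#' sidecar file `<path>.json` so that a round trip preserves the full object.
#'
#' @param movie a [movie_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path) {
  d <- dim(movie$data)
  pages <- lapply(seq_len(d[3]), function(t) {
    m <- movie$data[, , t]
    m[m < 0] <- 0
    m[m > 65535] <- 65535
    round(m) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  meta <- list(frame_rate = movie$frame_rate, px_size = movie$px_size,
               removed_frames = movie$removed_frames,
               frame_origin = movie$frame_origin)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a movie written by [write_movie()]
#'
#' @param path TIFF path.
#' @param sidecar path of the JSON metadata sidecar; defaults to
#'   `<path>.json`. Without a sidecar, `frame_rate` and `px_size` must be
#'   supplied explicitly.
#' @param frame_rate,px_size calibration overrides used when no sidecar
#'   exists.
#' @return a [movie_stack()].
#' @export
read_movie <- function(path, sidecar = paste0(path, ".json"),
                       frame_rate = NULL, px_size = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- list()
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  }
  frame_rate <- frame_rate %||% meta$frame_rate
  px_size <- px_size %||% meta$px_size
  if (is.null(frame_rate) || is.null(px_size)) {
    stop("missing sidecar metadata: frame_rate and px_size are required")
  }
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  a <- array(0, c(h, w, length(pages)))
  for (t in seq_along(pages)) a[, , t] <- pages[[t]] * 65535
  movie_stack(a, frame_rate, px_size,
              removed_frames = meta$removed_frames %||% integer(),
              frame_origin = meta$frame_origin %||% NULL)
}

#' Write a label image (ROI set) as 16-bit TIFF
#'
#' 2-D label matrices become a single page; 3-D (t, y, x) wave labels one
#' page per frame. Label 0 is background.
#'
#' @param roi a [roi_set()].
#' @param path output path.
#' @export
write_roi_set <- function(roi, path) {
  li <- roi$label_image
  if (length(dim(li)) == 2L) li <- array(li, c(dim(li), 1L))
  pages <- lapply(seq_len(dim(li)[3]), function(t) li[, , t] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Per-pixel dF/F0 movie
#'
#' Converts raw counts to relative fluorescence change per pixel, using a
#' temporal percentile of each pixel's own history as its baseline F0. Used
#' by the calcium-wave workflow, where segmentation operates on normalized
#' intensity. The default baseline is the temporal median: unlike the low
#' percentile used for (low-noise) ROI-average traces, a low percentile of
#' a noisy single-pixel history underestimates F0 by more than a noise SD,
#' while the median is unbiased as long as each pixel is active less than
#' half the time.
#'
#' @param movie a [movie_stack()].
#' @param baseline_percentile percentile (0-100) defining F0, default 50.
#' @param eps floor applied to F0 to avoid division blow-ups.
#' @return a [movie_stack()] whose `data` holds dF/F0 values.
#' @export
movie_dff <- function(movie, baseline_percentile = 50, eps = 1) {
  d <- dim(movie$data)
  flat <- matrix(movie$data, d[1] * d[2], d[3])
  f0 <- matrixStats_rowQuantile(flat, baseline_percentile / 100)
  f0[f0 < eps] <- eps
  dff <- (flat - f0) / f0
  out <- movie
  out$data <- array(dff, d)
  out
}

# Row-wise quantile without an extra dependency: sort-based, exact type-7.
matrixStats_rowQuantile <- function(m, p) {
  apply(m, 1L, stats::quantile, probs = p, names = FALSE, type = 7)
}

#' Spatially bin a movie by block averaging
#'
#' @param movie a [movie_stack()].
#' @param factor integer binning factor (default 2, the wave workflow's
#'   setting). Trailing rows/columns that do not fill a block are dropped.
#' @return a [movie_stack()] with `px_size` unchanged; callers must account
#'   for the binning factor in any area or length calculation.
#' @export
bin_movie <- function(movie, factor = 2L) {
  f <- as.integer(factor)
  d <- dim(movie$data)
  h <- (d[1] %/% f) * f
  w <- (d[2] %/% f) * f
  a <- movie$data[seq_len(h), seq_len(w), , drop = FALSE]
  hb <- h %/% f; wb <- w %/% f
  dim(a) <- c(f, hb * f * wb * d[3])
  b <- .colMeans(a, f, ncol(a))          # average rows within a block
  dim(b) <- c(hb, f, wb * d[3])
  b <- aperm(b, c(2L, 1L, 3L))
  dim(b) <- c(f, hb * wb * d[3])
  binned <- .colMeans(b, f, ncol(b))     # average columns within a block
  dim(binned) <- c(hb, wb, d[3])
  out <- movie
  out$data <- binned
  out
}
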