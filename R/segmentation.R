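# ROI segmentation for the three workflows: IHC somata from an average
# image (threshold + distance-transform watershed, or externally supplied
# masks taken as authoritative), supporting-cell waves as 3-D (y, x, t)
# labels after 2x binning and thresholding, and SGN terminals as punctate
# spots after white-tophat background suppression. The experimental analysis
# this reproduces relied on a trained segmentation model plus manual edits;
# here a deterministic classical fallback replaces the model, and external
# label masks are first-class inputs.

#' ROI set container
#'
#' @param label_image integer `H x W` matrix (IHC / SGN terminals) or
#'   `H x W x T` array (waves); 0 is background, labels are positive and
#'   unique.
#' @param kind `"ihc"`, `"sgn_terminal"` or `"wave"`.
#' @param px_size micrometres per (unbinned) pixel.
#' @param binning spatial binning factor of `label_image` relative to the
#'   original movie (2 for the wave workflow).
#' @return object of class `roi_set` with centroids in micrometres.
#' @export
roi_set <- function(label_image, kind = c("ihc", "sgn_terminal", "wave"),
                    px_size = 1, binning = 1L) {
  kind <- match.arg(kind)
  storage.mode(label_image) <- "integer"
  labs <- sort(unique(as.integer(label_image[label_image > 0L])))
  eff <- px_size * binning
  centroids <- if (length(labs)) {
    if (length(dim(label_image)) == 3L) {
      do.call(rbind, lapply(labs, function(l) {
        idx <- which(label_image == l, arr.ind = TRUE)
        data.frame(label = l,
                   x_um = mean(idx[, 2] - 0.5) * eff,
                   y_um = mean(idx[, 1] - 0.5) * eff,
                   t_frame = mean(idx[, 3]))
      }))
    } else {
      do.call(rbind, lapply(labs, function(l) {
        idx <- which(label_image == l, arr.ind = TRUE)
        data.frame(label = l,
                   x_um = mean(idx[, 2] - 0.5) * eff,
                   y_um = mean(idx[, 1] - 0.5) * eff)
      }))
    }
  } else {
    data.frame(label = integer(), x_um = numeric(), y_um = numeric())
  }
  structure(list(label_image = label_image, centroids = centroids,
                 kind = kind, px_size = px_size, binning = as.integer(binning)),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("roi_set (%s): %d ROIs\n", x$kind, nrow(x$centroids)))
  invisible(x)
}

roi_labels <- function(roi) roi$centroids$label

roi_areas_um2 <- function(roi) {
  eff <- roi$px_size * roi$binning
  counts <- tabulate(roi$label_image[roi$label_image > 0L])
  data.frame(label = which(counts > 0), area_um2 = counts[counts > 0] * eff^2)
}

# Erode every label of a 2-D label matrix independently by `px` pixels.
erode_labels <- function(label, px) {
  if (px < 1L) return(label)
  brush <- EBImage::makeBrush(2L * as.integer(px) + 1L, shape = "disc")
  out <- matrix(0L, nrow(label), ncol(label))
  for (l in sort(unique(label[label > 0L]))) {
    bin <- EBImage::erode(matrix(as.numeric(label == l), nrow(label)), brush)
    out[bin > 0.5] <- l
  }
  out
}

#' Segment IHC somata from an average-intensity image
#'
#' Bright blobs are thresholded (Otsu) and split by a distance-transform
#' watershed; masks are then eroded by 1-3 pixels to limit signal
#' contamination between adjacent cells. Externally supplied label masks
#' (e.g. manually curated) are authoritative: they skip detection and only
#' receive the erosion.
#'
#' @param avg_image `H x W` average-intensity matrix.
#' @param erosion_px erosion radius in pixels, one of 1, 2, 3 (or 0 to skip).
#' @param px_size micrometres per pixel.
#' @param masks optional externally supplied `H x W` label matrix.
#' @param min_area_px ROIs smaller than this after erosion are dropped.
#' @return a [roi_set()] of kind `"ihc"`.
#' @export
segment_ihc <- function(avg_image, erosion_px = 1L, px_size = 1,
                        masks = NULL, min_area_px = 5L) {
  if (!erosion_px %in% 0:3) stop("erosion_px must be in 0..3")
  if (is.null(masks)) {
    img <- avg_image - min(avg_image)
    if (max(img) <= 0) stop("no IHC ROIs found (flat image)")
    img <- img / max(img)
    thr <- EBImage::otsu(EBImage::Image(img), range = c(0, 1))
    bin <- img > thr
    if (!any(bin)) stop("no IHC ROIs found")
    dm <- EBImage::distmap(matrix(as.numeric(bin), nrow(bin)))
    label <- EBImage::watershed(dm, tolerance = 1)
    label <- matrix(as.integer(label), nrow(bin))
  } else {
    label <- matrix(as.integer(masks), nrow(masks))
  }
  label <- erode_labels(label, erosion_px)
  counts <- tabulate(label[label > 0L])
  drop <- which(counts > 0 & counts < min_area_px)
  if (length(drop)) label[label %in% drop] <- 0L
  keep <- sort(unique(label[label > 0L]))
  if (!length(keep)) stop("no IHC ROIs found after erosion/size gate")
  relab <- label
  for (i in seq_along(keep)) relab[label == keep[i]] <- i
  roi_set(relab, kind = "ihc", px_size = px_size)
}

#' Segment supporting-cell calcium waves as 3-D ROIs
#'
#' The dF/F0 movie is spatially binned by a factor of two, binarized
#' (default: Otsu threshold on the positive dF/F0 values), per-frame blobs
#' are split by a distance-transform watershed seeded at smoothed local
#' maxima, and blobs are linked across frames by overlap into 3-D
#' components. Components spanning fewer than two frames, or never reaching
#' the minimum area, are discarded -- the latter removes transients confined
#' to individual isolated cells, which belong to the single-cell workflow.
#'
#' @param movie a [movie_stack()] holding dF/F0 values (see [movie_dff()]).
#' @param threshold dF/F0 binarization threshold; `NULL` for Otsu.
#' @param sigma_spot smoothing SD (binned px) before maxima seeding.
#' @param min_area_um2 minimum per-frame area a component must reach.
#' @param min_frames minimum temporal span in frames.
#' @param binning spatial binning factor (default 2).
#' @return a [roi_set()] of kind `"wave"` whose `label_image` is
#'   `Hb x Wb x T`.
#' @export
segment_waves <- function(movie, threshold = NULL, sigma_spot = 2,
                          min_area_um2 = 150, min_frames = 2L, binning = 2L) {
  binned <- bin_movie(movie, binning)
  a <- binned$data
  d <- dim(a)
  if (is.null(threshold)) {
    # Half-maximum default: half of a robust wave-amplitude estimate (90th
    # percentile of supra-noise dF/F0), floored above the noise. A plain
    # Otsu threshold is unreliable here because the background class
    # dominates the voxel histogram.
    sigma <- stats::mad(a)
    cand <- a[a > 3 * sigma]
    if (length(cand) < 100L) return(empty_wave_set(d, movie$px_size, binning))
    amp_est <- stats::quantile(cand, 0.9, names = FALSE)
    threshold <- max(amp_est / 2, 3.5 * sigma)
  }
  bin <- a > threshold
  if (!any(bin)) return(empty_wave_set(d, movie$px_size, binning))
  # per-frame labelling with watershed split, then cross-frame overlap linking
  labels <- array(0L, d)
  offset <- 0L
  n_frame_labels <- integer(d[3])
  for (f in seq_len(d[3])) {
    bf <- bin[, , f]
    if (!any(bf)) next
    dm <- EBImage::distmap(matrix(as.numeric(bf), d[1]))
    if (sigma_spot > 0) {
      dm3 <- array(dm, c(d[1], d[2], 1L))
      dm3 <- conv_gauss_axis(dm3, sigma_spot, 1L)
      dm3 <- conv_gauss_axis(dm3, sigma_spot, 2L)
      dm <- dm3[, , 1L] * bf
    }
    lf <- matrix(as.integer(EBImage::watershed(dm, tolerance = 1)), d[1])
    k <- max(lf)
    lf[lf > 0L] <- lf[lf > 0L] + offset
    labels[, , f] <- lf
    n_frame_labels[f] <- k
    offset <- offset + k
  }
  if (offset == 0L) return(empty_wave_set(d, movie$px_size, binning))
  parent <- uf_init(offset)
  for (f in seq_len(d[3] - 1L)) {
    a1 <- labels[, , f]; a2 <- labels[, , f + 1L]
    both <- a1 > 0L & a2 > 0L
    if (!any(both)) next
    pairs <- unique(cbind(a1[both], a2[both]))
    for (r in seq_len(nrow(pairs))) {
      r1 <- uf_find(parent, pairs[r, 1]); r2 <- uf_find(parent, pairs[r, 2])
      if (r1 != r2) parent[max(r1, r2)] <- min(r1, r2)
    }
  }
  root <- vapply(seq_len(offset), function(i) uf_find(parent, i), integer(1))
  comp <- match(root, sort(unique(root)))
  n_comp <- max(comp)
  flat <- labels
  pos <- flat > 0L
  flat[pos] <- comp[flat[pos]]
  # gate: temporal span and maximal per-frame area, aggregated frame-wise
  eff2 <- (movie$px_size * binning)^2
  flatmat <- matrix(flat, d[1] * d[2], d[3])
  max_area <- integer(n_comp)
  span <- integer(n_comp)
  for (f in seq_len(d[3])) {
    v <- flatmat[, f]
    v <- v[v > 0L]
    if (!length(v)) next
    cnt <- tabulate(v, n_comp)
    hit <- cnt > 0L
    span[hit] <- span[hit] + 1L
    max_area <- pmax(max_area, cnt)
  }
  keep <- which(span >= min_frames & max_area * eff2 >= min_area_um2)
  map <- integer(n_comp)
  map[keep] <- seq_along(keep)
  out <- flat
  out[pos] <- map[flat[pos]]
  roi_set(out, kind = "wave", px_size = movie$px_size, binning = binning)
}

empty_wave_set <- function(d, px_size, binning) {
  roi_set(array(0L, d), kind = "wave", px_size = px_size, binning = binning)
}

#' Segment SGN terminal hotspots
#'
#' The average image is filtered with a white tophat (disc radius 10-20 px)
#' to suppress smooth background, thresholded by Otsu, and touching spots
#' are split by a watershed on the smoothed tophat response seeded at its
#' local maxima. A size gate removes specks and oversized blobs.
#'
#' @param avg_image `H x W` average-intensity matrix.
#' @param tophat_radius_px disc radius of the tophat structuring element.
#' @param px_size micrometres per pixel.
#' @param sigma_spot smoothing SD (px) before maxima seeding.
#' @param min_area_px,max_area_px inclusive size gate in pixels.
#' @return a [roi_set()] of kind `"sgn_terminal"`.
#' @export
segment_sgn_terminals <- function(avg_image, tophat_radius_px = 15L,
                                  px_size = 1, sigma_spot = 1.5,
                                  min_area_px = 3L, max_area_px = 200L) {
  if (tophat_radius_px < 10L || tophat_radius_px > 20L) {
    stop("tophat_radius_px must be in [10, 20]")
  }
  img <- avg_image - min(avg_image)
  rng <- max(img)
  if (rng <= 0) stop("no SGN terminals found (flat image)")
  img <- img / rng
  brush <- EBImage::makeBrush(2L * as.integer(tophat_radius_px) + 1L,
                              shape = "disc")
  th <- EBImage::whiteTopHat(matrix(img, nrow(img)), brush)
  thr <- EBImage::otsu(EBImage::Image(th), range = c(0, 1))
  mask <- th > thr
  if (!any(mask)) stop("no SGN terminals found")
  sm <- array(th, c(dim(th), 1L))
  sm <- conv_gauss_axis(sm, sigma_spot, 1L)
  sm <- conv_gauss_axis(sm, sigma_spot, 2L)
  hgt <- sm[, , 1L] * mask
  label <- matrix(as.integer(EBImage::watershed(hgt, tolerance = 0.01)),
                  nrow(img))
  counts <- tabulate(label[label > 0L])
  drop <- which(counts > 0 & (counts < min_area_px | counts > max_area_px))
  if (length(drop)) label[label %in% drop] <- 0L
  keep <- sort(unique(label[label > 0L]))
  if (!length(keep)) stop("no SGN terminals found after size gate")
  relab <- label
  for (i in seq_along(keep)) relab[label == keep[i]] <- i
  roi_set(relab, kind = "sgn_terminal", px_size = px_size)
}

#' Assign SGN terminals to IHCs
#'
#' Each terminal goes to the nearest IHC (centroid-to-mask distance) when
#' that choice is unambiguous; when the two nearest IHCs are within the
#' ambiguity margin of one another, the terminal goes to whichever of the
#' two has the higher Pearson correlation between its trace and the
#' terminal's trace. Correlation ties fall back to the nearer IHC and are
#' flagged.
#'
#' @param terminals [roi_set()] of kind `"sgn_terminal"`.
#' @param ihcs [roi_set()] of kind `"ihc"`.
#' @param traces optional list with elements `terminal` and `ihc`, each a
#'   list of numeric traces indexed by label, required for ambiguous cases.
#' @param margin_um ambiguity margin on the distance difference (default 2).
#' @return data.frame: `terminal_label`, `ihc_label`, `distance_um`,
#'   `method` (`"proximity"` / `"correlation"`), `tie`.
#' @export
assign_terminals <- function(terminals, ihcs, traces = NULL, margin_um = 2) {
  if (nrow(ihcs$centroids) < 1L) stop("need at least one IHC")
  ihc_px <- lapply(roi_labels(ihcs), function(l) {
    idx <- which(ihcs$label_image == l, arr.ind = TRUE)
    eff <- ihcs$px_size * ihcs$binning
    cbind((idx[, 2] - 0.5) * eff, (idx[, 1] - 0.5) * eff)
  })
  names(ihc_px) <- roi_labels(ihcs)
  out <- lapply(seq_len(nrow(terminals$centroids)), function(i) {
    p <- c(terminals$centroids$x_um[i], terminals$centroids$y_um[i])
    dists <- vapply(ihc_px, function(px) {
      min(sqrt((px[, 1] - p[1])^2 + (px[, 2] - p[2])^2))
    }, numeric(1))
    ord <- order(dists)
    lab1 <- roi_labels(ihcs)[ord[1]]
    tie <- FALSE
    method <- "proximity"
    chosen <- lab1
    if (length(dists) >= 2L && dists[ord[2]] - dists[ord[1]] <= margin_um) {
      lab2 <- roi_labels(ihcs)[ord[2]]
      if (is.null(traces)) {
        stop("ambiguous terminal ", terminals$centroids$label[i],
             ": traces required for correlation assignment")
      }
      tl <- terminals$centroids$label[i]
      r1 <- stats::cor(traces$terminal[[as.character(tl)]],
                       traces$ihc[[as.character(lab1)]])
      r2 <- stats::cor(traces$terminal[[as.character(tl)]],
                       traces$ihc[[as.character(lab2)]])
      method <- "correlation"
      if (isTRUE(all.equal(r1, r2))) {
        tie <- TRUE
        chosen <- lab1
      } else {
        chosen <- if (r2 > r1) lab2 else lab1
      }
    }
    data.frame(terminal_label = terminals$centroids$label[i],
               ihc_label = chosen,
               distance_um = dists[as.character(chosen)],
               method = method, tie = tie)
  })
  do.call(rbind, out)
}

#' Annotate terminal position around the IHC body
#'
#' The signed perpendicular offset of the terminal centroid from the IHC
#' row polyline classifies it as modiolar (one side), pillar (other side)
#' or middle (within a fraction of the IHC radius of the line). Which
#' geometric side is called "pillar" is a convention set by
#' `pillar_positive`: synthetic scenes carry no anatomy, so the traversal
#' direction of the polyline defines the sign.
#'
#' @param terminals [roi_set()] of kind `"sgn_terminal"`.
#' @param ihcs [roi_set()] of kind `"ihc"`.
#' @param polyline an [ihc_polyline()].
#' @param assignment data.frame from [assign_terminals()].
#' @param radius_fraction middle band half-width as a fraction of the
#'   assigned IHC's equivalent radius (default 1/3).
#' @param pillar_positive logical; if `TRUE`, positive offsets are pillar.
#' @return `assignment` with extra columns `signed_offset_um`, `sector`.
#' @export
annotate_sector <- function(terminals, ihcs, polyline, assignment,
                            radius_fraction = 1 / 3, pillar_positive = TRUE) {
  areas <- roi_areas_um2(ihcs)
  r_eq <- stats::setNames(sqrt(areas$area_um2 / pi), areas$label)
  off <- numeric(nrow(assignment))
  sector <- character(nrow(assignment))
  for (i in seq_len(nrow(assignment))) {
    tl <- assignment$terminal_label[i]
    j <- match(tl, terminals$centroids$label)
    p <- c(terminals$centroids$x_um[j], terminals$centroids$y_um[j])
    np <- polyline_nearest(polyline, p)
    off[i] <- np$offset
    band <- radius_fraction * r_eq[as.character(assignment$ihc_label[i])]
    if (abs(off[i]) <= band) {
      sector[i] <- "middle"
    } else if ((off[i] > 0) == pillar_positive) {
      sector[i] <- "pillar"
    } else {
      sector[i] <- "modiolar"
    }
  }
  assignment$signed_offset_um <- off
  assignment$sector <- sector
  assignment
}
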