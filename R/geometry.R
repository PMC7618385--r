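# IHC-row polyline geometry: arc-length parametrization, nearest-point
# projection with signed perpendicular offset, and locally smoothed tangents.
# The polyline traces the IHC row; "longitudinal" means along its tangent
# (the cochlear coil axis), "radial" perpendicular to it.

#' IHC row polyline
#'
#' @param points `n x 2` matrix of (x, y) points in micrometres, ordered
#'   along the row.
#' @return object of class `ihc_polyline` with points, per-vertex arc
#'   length `s`, and segment tangents.
#' @export
ihc_polyline <- function(points) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2L, nrow(points) >= 2L)
  seg <- diff(points)
  len <- sqrt(rowSums(seg^2))
  if (any(len <= 0)) stop("polyline arc length must be strictly increasing")
  s <- c(0, cumsum(len))
  tang <- seg / len
  structure(list(points = points, s = s, seg_len = len, tangents = tang),
            class = "ihc_polyline")
}

#' Point, tangent and normal at arc length `s` (clamped to the polyline)
#' @param poly an [ihc_polyline()].
#' @param s arc length in micrometres.
#' @return list with `point`, `tangent`, `normal`, `segment`.
#' @export
polyline_point <- function(poly, s) {
  s <- max(0, min(s, max(poly$s)))
  i <- findInterval(s, poly$s, rightmost.closed = TRUE)
  i <- max(1L, min(i, nrow(poly$points) - 1L))
  frac <- (s - poly$s[i]) / poly$seg_len[i]
  pt <- poly$points[i, ] + frac * (poly$points[i + 1L, ] - poly$points[i, ])
  tg <- poly$tangents[i, ]
  list(point = as.numeric(pt), tangent = as.numeric(tg),
       normal = c(-tg[2], tg[1]), segment = i)
}

#' Nearest point of the polyline to a query point
#'
#' @param poly an [ihc_polyline()].
#' @param p length-2 point (x, y) in micrometres.
#' @return list with `dist`, `s` (arc length), `point`, `segment`,
#'   `tangent`, and `offset` (signed perpendicular offset, positive on the
#'   side of the normal `(-ty, tx)`).
#' @export
polyline_nearest <- function(poly, p) {
  p <- as.numeric(p)
  best <- NULL
  n_seg <- nrow(poly$points) - 1L
  for (i in seq_len(n_seg)) {
    a <- poly$points[i, ]
    d <- poly$points[i + 1L, ] - a
    tproj <- sum((p - a) * d) / sum(d * d)
    tproj <- max(0, min(1, tproj))
    q <- a + tproj * d
    dist <- sqrt(sum((p - q)^2))
    if (is.null(best) || dist < best$dist) {
      tg <- poly$tangents[i, ]
      nv <- c(-tg[2], tg[1])
      best <- list(dist = dist, s = poly$s[i] + tproj * poly$seg_len[i],
                   point = as.numeric(q), segment = i,
                   tangent = as.numeric(tg),
                   offset = sum((p - q) * nv))
    }
  }
  best
}

#' Tangent at the polyline point nearest `p`
#'
#' Averaged over `halfwidth` segments on each side to stabilize the
#' orientation estimate on densely sampled arcs.
#' @param poly an [ihc_polyline()].
#' @param p length-2 point (x, y) in micrometres.
#' @param halfwidth number of neighbouring segments averaged per side.
#' @return unit tangent vector.
#' @export
polyline_smoothed_tangent <- function(poly, p, halfwidth = 2L) {
  np <- polyline_nearest(poly, p)
  n_seg <- nrow(poly$points) - 1L
  segs <- max(1L, np$segment - halfwidth):min(n_seg, np$segment + halfwidth)
  tg <- colSums(poly$tangents[segs, , drop = FALSE])
  tg / sqrt(sum(tg^2))
}
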