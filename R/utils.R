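# Internal numerics shared across modules.

#' Rolling median of a series
#'
#' Thin wrapper around [stats::runmed()] that accepts an arbitrary window
#' length (coerced to the nearest odd integer, capped at the series length)
#' and handles short inputs gracefully.
#'
#' @param x numeric vector.
#' @param window window length in samples.
#' @return numeric vector of the same length as `x`.
#' @keywords internal
rolling_median <- function(x, window) {
  n <- length(x)
  k <- as.integer(window)
  if (k %% 2L == 0L) k <- k + 1L
  if (k > n) k <- if (n %% 2L == 1L) n else n - 1L
  if (k < 3L) return(x)
  as.numeric(stats::runmed(x, k, endrule = "median"))
}

# Rolling percentile, evaluated on a strided grid and linearly interpolated
# back to every sample. Used for the sliding-baseline F0; the stride keeps the
# cost manageable on long recordings without visibly changing a slow baseline.
rolling_quantile <- function(x, window, prob, stride = NULL) {
  n <- length(x)
  w <- min(as.integer(window), n)
  if (is.null(stride)) stride <- max(1L, w %/% 20L)
  centres <- unique(c(seq(1L, n, by = stride), n))
  half <- w %/% 2L
  vals <- vapply(centres, function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    stats::quantile(x[lo:hi], probs = prob / 100, names = FALSE, type = 7)
  }, numeric(1))
  if (length(centres) == 1L) return(rep(vals, n))
  stats::approx(centres, vals, xout = seq_len(n), rule = 2)$y
}

# Separable Gaussian smoothing along one axis of a 3-D array with edge
# renormalisation, so constants are preserved exactly at the borders.
conv_gauss_axis <- function(a, sigma, axis) {
  if (sigma <= 0) return(a)
  d <- dim(a)
  w <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-w:w, sd = sigma)
  k <- k / sum(k)
  n <- d[axis]
  out <- array(0, d)
  norm <- numeric(n)
  for (j in -w:w) {
    src <- seq_len(n) - j
    ok <- src >= 1L & src <= n
    if (!any(ok)) next
    dst <- which(ok)
    norm[dst] <- norm[dst] + k[j + w + 1L]
    if (axis == 1L) {
      out[dst, , ] <- out[dst, , , drop = FALSE] +
        k[j + w + 1L] * a[src[ok], , , drop = FALSE]
    } else if (axis == 2L) {
      out[, dst, ] <- out[, dst, , drop = FALSE] +
        k[j + w + 1L] * a[, src[ok], , drop = FALSE]
    } else {
      out[, , dst] <- out[, , dst, drop = FALSE] +
        k[j + w + 1L] * a[, , src[ok], drop = FALSE]
    }
  }
  if (axis == 1L) {
    out <- sweep(out, 1L, norm, "/")
  } else if (axis == 2L) {
    out <- sweep(out, 2L, norm, "/")
  } else {
    out <- sweep(out, 3L, norm, "/")
  }
  out
}

# Integer translation of a 2-D frame; vacated pixels take `fill`.
shift_frame <- function(m, dy, dx, fill = stats::median(m)) {
  dy <- as.integer(round(dy)); dx <- as.integer(round(dx))
  h <- nrow(m); w <- ncol(m)
  if (abs(dy) >= h || abs(dx) >= w) stop("shift moves frame fully out of view")
  out <- matrix(fill, h, w)
  ys <- max(1L, 1L + dy):min(h, h + dy)
  xs <- max(1L, 1L + dx):min(w, w + dx)
  out[ys, xs] <- m[ys - dy, xs - dx]
  out
}

# Phase-correlation shift estimate. Returns the integer (dy, dx) such that
# shift_frame(moving, dy, dx) best aligns `moving` to `reference`. The
# search can be windowed to shifts within `max_radius` of `center`: fields
# with near-periodic structure (a regular row of somata) have correlation
# peaks at lattice offsets, and inter-frame drift is slow, so the peak
# nearest the previous estimate is the right one.
phase_corr_shift <- function(reference, moving, center = c(0, 0),
                             max_radius = Inf) {
  f1 <- stats::fft(reference)
  f2 <- stats::fft(moving)
  r <- f1 * Conj(f2)
  mag <- Mod(r)
  mag[mag < .Machine$double.eps] <- .Machine$double.eps
  cc <- Re(stats::fft(r / mag, inverse = TRUE))
  h <- nrow(reference); w <- ncol(reference)
  py <- 0:(h - 1L); py[py > h %/% 2L] <- py[py > h %/% 2L] - h
  px <- 0:(w - 1L); px[px > w %/% 2L] <- px[px > w %/% 2L] - w
  if (is.finite(max_radius)) {
    oky <- abs(py - center[1]) <= max_radius
    okx <- abs(px - center[2]) <= max_radius
    cc[!oky, ] <- -Inf
    cc[, !okx] <- -Inf
  }
  idx <- which.max(cc)
  p <- py[(idx - 1L) %% h + 1L]
  q <- px[(idx - 1L) %/% h + 1L]
  c(dy = p, dx = q)
}

# Linearly interpolated crossing times of `level` around the sample index
# `peak` of trace `x`; returns c(left, right) in (fractional) sample indices,
# NA where the trace never drops below the level on that side.
half_crossings <- function(x, peak, level) {
  n <- length(x)
  left <- NA_real_
  i <- peak
  while (i > 1L) {
    if (x[i - 1L] < level) {
      left <- (i - 1L) + (level - x[i - 1L]) / (x[i] - x[i - 1L])
      break
    }
    i <- i - 1L
  }
  right <- NA_real_
  i <- peak
  while (i < n) {
    if (x[i + 1L] < level) {
      right <- i + (x[i] - level) / (x[i] - x[i + 1L])
      break
    }
    i <- i + 1L
  }
  c(left, right)
}

# Union-find with path compression; `find_root` and `union_sets` operate on an
# integer parent vector passed by value (callers keep the returned vector).
uf_init <- function(n) seq_len(n)

uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

`%||%` <- function(a, b) if (is.null(a)) b else a
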