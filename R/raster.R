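## rendering module (part 1): exact supercover rasterization of continuous
## polylines onto the pixel grid.
##
## Pixel (ix, iy), 0-based, owns the closed unit square
## [ix - 0.5, ix + 0.5] x [iy - 0.5, iy + 0.5]; a pixel is set iff the
## polyline intersects that square.

# All canvas cells intersected by the closed segment (x0,y0)-(x1,y1),
# via Liang-Barsky clipping vectorized over the candidate cell box.
# Returns an m x 2 integer matrix of 0-based (ix, iy).
segment_cells <- function(x0, y0, x1, y1, h, w) {
  ix_lo <- max(0L, as.integer(floor(min(x0, x1) + 0.5)) - 1L)
  ix_hi <- min(w - 1L, as.integer(ceiling(max(x0, x1) - 0.5)) + 1L)
  iy_lo <- max(0L, as.integer(floor(min(y0, y1) + 0.5)) - 1L)
  iy_hi <- min(h - 1L, as.integer(ceiling(max(y0, y1) - 0.5)) + 1L)
  if (ix_lo > ix_hi || iy_lo > iy_hi) return(cbind(ix = integer(0), iy = integer(0)))

  ix <- rep(ix_lo:ix_hi, times = iy_hi - iy_lo + 1L)
  iy <- rep(iy_lo:iy_hi, each = ix_hi - ix_lo + 1L)

  dx <- x1 - x0
  dy <- y1 - y0
  t0 <- rep(0, length(ix))
  t1 <- rep(1, length(ix))
  ok <- rep(TRUE, length(ix))

  clip_axis <- function(d, s, lo, hi) {
    # clip parameter interval to lo <= s + t*d <= hi (vectorized over cells)
    if (d == 0) {
      ok <<- ok & (s >= lo) & (s <= hi)
    } else {
      ta <- (lo - s) / d
      tb <- (hi - s) / d
      tmin <- pmin(ta, tb)
      tmax <- pmax(ta, tb)
      t0 <<- pmax(t0, tmin)
      t1 <<- pmin(t1, tmax)
    }
  }
  clip_axis(dx, x0, ix - 0.5, ix + 0.5)
  clip_axis(dy, y0, iy - 0.5, iy + 0.5)
  keep <- ok & (t0 <= t1)
  cbind(ix = ix[keep], iy = iy[keep])
}

#' Rasterize a polyline onto a binary mask (supercover)
#'
#' A pixel is set iff the continuous polyline intersects the pixel's closed
#' unit square.  Segments outside the canvas are clipped; a polyline
#' entirely outside the canvas yields an empty mask.  Marked pixels of a
#' connected polyline are 8-connected.
#'
#' @param polyline an `n x 2` matrix of continuous `(x, y)` vertices
#'   (0-based pixel-center coordinates).
#' @param h,w canvas size in pixels.
#' @return an `h x w` logical matrix (rows index y, columns x).
#' @export
rasterize_polyline <- function(polyline, h, w) {
  polyline <- as.matrix(polyline)
  if (nrow(polyline) < 1) stop("polyline must have at least one vertex")
  mask <- matrix(FALSE, h, w)
  if (nrow(polyline) == 1) {
    ix <- as.integer(round(polyline[1, 1]))
    iy <- as.integer(round(polyline[1, 2]))
    if (ix >= 0 && ix < w && iy >= 0 && iy < h) mask[iy + 1L, ix + 1L] <- TRUE
    return(mask)
  }
  for (k in seq_len(nrow(polyline) - 1L)) {
    cells <- segment_cells(polyline[k, 1], polyline[k, 2],
                           polyline[k + 1L, 1], polyline[k + 1L, 2], h, w)
    if (nrow(cells) > 0) mask[cells[, 2] + 1L + h * cells[, 1]] <- TRUE
  }
  mask
}

# Truncate a polyline to its first `arc_len` of arc length.
polyline_truncate <- function(polyline, arc_len) {
  polyline <- as.matrix(polyline)
  if (arc_len <= 0 || nrow(polyline) < 2) return(polyline[1, , drop = FALSE])
  d <- sqrt(diff(polyline[, 1])^2 + diff(polyline[, 2])^2)
  cum <- cumsum(d)
  if (arc_len >= cum[length(cum)]) return(polyline)
  k <- which(cum >= arc_len)[1]
  prev <- if (k == 1) 0 else cum[k - 1]
  frac <- (arc_len - prev) / d[k]
  endpt <- polyline[k, ] + frac * (polyline[k + 1L, ] - polyline[k, ])
  rbind(polyline[seq_len(k), , drop = FALSE], endpt)
}

# Binary dilation by a Euclidean disk of integer radius (offsets with
# dx^2 + dy^2 <= r^2), used to give ground-truth masks physical width.
dilate_mask <- function(mask, radius = 1L) {
  if (radius <= 0) return(mask)
  h <- nrow(mask); w <- ncol(mask)
  out <- mask
  for (dy in -radius:radius) for (dx in -radius:radius) {
    if (dx == 0 && dy == 0) next
    if (dx * dx + dy * dy > radius * radius) next
    src_r <- max(1, 1 - dy):min(h, h - dy)
    src_c <- max(1, 1 - dx):min(w, w - dx)
    out[src_r + dy, src_c + dx] <- out[src_r + dy, src_c + dx] | mask[src_r, src_c]
  }
  out
}
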