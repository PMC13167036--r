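# Shared fixtures and independent oracles.  Everything here is built in
# code at test time; oracles deliberately take a different computational
# route than the implementation they check.

# theta for fast small-canvas tests: few short filaments, degradation off
quiet_theta <- function(h = 64, w = 64, count = 3, len = 25) {
  th <- default_theta()
  th$image_h <- h; th$image_w <- w
  th$count_mean <- count; th$count_sd <- 0
  th$fil_len_mean <- len; th$fil_len_sd <- len / 4
  th$seed_len <- 0; th$seed_gain <- 0
  th$noise_gauss_sd <- 0; th$photon_scale <- 0; th$speckle_sd <- 0
  th$vignette_strength <- 0; th$blur_sigma <- 0; th$bgfield_amp <- 0
  th$n_spots_mean <- 0; th$channel_jitter_sd <- 0
  th
}

# --- supercover oracle -------------------------------------------------
# Does the closed segment (p, q) intersect the closed axis-aligned square
# centred at (ix, iy)?  Independent route: endpoint-in-square tests plus
# segment-segment intersections with the four square edges.
seg_seg_intersect <- function(p1, p2, p3, p4) {
  o <- function(a, b, c) {
    v <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    if (abs(v) < 1e-12) 0 else sign(v)
  }
  on_seg <- function(a, b, c)  # c collinear with a-b: is c within the box?
    min(a[1], b[1]) - 1e-12 <= c[1] && c[1] <= max(a[1], b[1]) + 1e-12 &&
    min(a[2], b[2]) - 1e-12 <= c[2] && c[2] <= max(a[2], b[2]) + 1e-12
  d1 <- o(p3, p4, p1); d2 <- o(p3, p4, p2)
  d3 <- o(p1, p2, p3); d4 <- o(p1, p2, p4)
  if (d1 != d2 && d3 != d4) return(TRUE)
  (d1 == 0 && on_seg(p3, p4, p1)) || (d2 == 0 && on_seg(p3, p4, p2)) ||
  (d3 == 0 && on_seg(p1, p2, p3)) || (d4 == 0 && on_seg(p1, p2, p4))
}

oracle_segment_square <- function(p, q, ix, iy) {
  inside <- function(pt)
    pt[1] >= ix - 0.5 - 1e-12 && pt[1] <= ix + 0.5 + 1e-12 &&
    pt[2] >= iy - 0.5 - 1e-12 && pt[2] <= iy + 0.5 + 1e-12
  if (inside(p) || inside(q)) return(TRUE)
  c1 <- c(ix - 0.5, iy - 0.5); c2 <- c(ix + 0.5, iy - 0.5)
  c3 <- c(ix + 0.5, iy + 0.5); c4 <- c(ix - 0.5, iy + 0.5)
  seg_seg_intersect(p, q, c1, c2) || seg_seg_intersect(p, q, c2, c3) ||
    seg_seg_intersect(p, q, c3, c4) || seg_seg_intersect(p, q, c4, c1)
}

oracle_rasterize <- function(polyline, h, w) {
  mask <- matrix(FALSE, h, w)
  for (iy in 0:(h - 1)) for (ix in 0:(w - 1)) {
    hit <- FALSE
    for (k in seq_len(nrow(polyline) - 1)) {
      if (oracle_segment_square(polyline[k, ], polyline[k + 1, ], ix, iy)) {
        hit <- TRUE
        break
      }
    }
    mask[iy + 1, ix + 1] <- hit
  }
  mask
}

# --- mask fixtures -----------------------------------------------------
bar_mask <- function(h, w, row0, col0, len, thick) {
  m <- matrix(FALSE, h, w)
  m[row0:(row0 + thick - 1), col0:(col0 + len - 1)] <- TRUE
  m
}

ring_mask <- function(R, thick = 1.5, pad = 8) {
  n <- 2 * (R + pad) + 1
  ctr <- R + pad
  yy <- matrix(0:(n - 1), n, n); xx <- t(yy)
  r <- sqrt((yy - ctr)^2 + (xx - ctr)^2)
  abs(r - R) <= thick
}

# random blob-ish mask: a few dilated random walks
random_blob_mask <- function(h, w, n_steps = 30) {
  m <- matrix(FALSE, h, w)
  x <- sample(seq(5, w - 5), 1); y <- sample(seq(5, h - 5), 1)
  for (i in seq_len(n_steps)) {
    m[y, x] <- TRUE
    x <- min(max(x + sample(-1:1, 1), 1), w)
    y <- min(max(y + sample(-1:1, 1), 1), h)
  }
  filamentsim:::dilate_mask(m, 1L)
}

# 8-connected component count (flood fill; independent of any package code)
n_components8 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    queue <- list(c(i, j)); lab[i, j] <- cur
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        r <- p[1] + di; c <- p[2] + dj
        if (r >= 1 && r <= nrow(mask) && c >= 1 && c <= ncol(mask) &&
            mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- cur
          queue[[length(queue) + 1]] <- c(r, c)
        }
      }
    }
  }
  cur
}
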