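## geometry module: filament shapes as correlated random walks, and their
## conversion to continuous pixel-space polylines.
##
## Coordinate convention (shared by all modules): continuous coordinates,
## origin at the center of the top-left pixel, x rightward (columns),
## y downward (rows).

#' Sample one filament as a correlated random walk
#'
#' The total arc length `L` is drawn from a positive-truncated Gaussian
#' `(fil_len_mean, fil_len_sd)`.  Segment lengths are positive-truncated
#' Gaussian `(seg_len_mean, seg_len_sd)` draws accumulated until they reach
#' `L`; the last segment is truncated so the total is exactly `L`.  The
#' initial orientation is uniform on `[0, 2*pi)`.  Bend angles evolve as
#' `phi_k = phi_[k-1] + B_k * eta_k` with `eta_k ~ Gamma(bend_shape,
#' bend_scale)` and signs `B_k` in {-1, +1}: the initial sign is uniform,
#' each subsequent step flips with probability `flip_prob`, and flips are
#' suppressed once `max_flips` sign changes have occurred, so that
#' `sum |B_k - B_[k-1]| <= 2 * max_flips` always holds.
#'
#' @param theta a valid `theta_params` object.
#' @param origin numeric `(x, y)` seed origin in pixel coordinates.
#' @return an object of class `filament_spec` with fields `seg_lengths`,
#'   `bend_angles`, `signs`, `eta`, `seed_origin`, `seed_orientation`,
#'   `total_length`.
#' @export
sample_filament <- function(theta, origin = c(0, 0)) {
  assert_theta(theta)
  L <- rtrunc_pos(1, theta$fil_len_mean, theta$fil_len_sd)
  if (L <= 0) L <- .Machine$double.eps

  seg <- numeric(0)
  total <- 0
  while (total < L) {
    # draw in blocks to limit R-level looping
    block <- rtrunc_pos(8, theta$seg_len_mean, theta$seg_len_sd)
    block <- block[block > 0]
    seg <- c(seg, block)
    total <- sum(seg)
  }
  cum <- cumsum(seg)
  n <- which(cum >= L)[1]
  seg <- seg[seq_len(n)]
  seg[n] <- seg[n] - (cum[n] - L)  # truncate last segment: arc length == L
  if (seg[n] <= 0) {               # exact boundary hit: drop empty tail
    seg <- seg[seq_len(n - 1L)]
    n <- n - 1L
  }

  phi0 <- stats::runif(1, 0, 2 * pi)
  signs <- integer(n)
  eta <- numeric(n)
  phi <- numeric(n)
  signs[1] <- sample(c(-1L, 1L), 1)
  eta[1] <- 0                       # phi_0 is the seed orientation itself
  phi[1] <- phi0
  flips <- 0L
  if (n > 1) {
    eta[2:n] <- stats::rgamma(n - 1L, shape = theta$bend_shape,
                              scale = theta$bend_scale)
    flip_draws <- stats::runif(n - 1L) < theta$flip_prob
    for (k in 2:n) {
      s <- signs[k - 1L]
      if (flip_draws[k - 1L] && flips < theta$max_flips) {
        s <- -s
        flips <- flips + 1L
      }
      signs[k] <- s
      phi[k] <- phi[k - 1L] + s * eta[k]
    }
  }
  structure(list(seg_lengths = seg, bend_angles = phi, signs = signs,
                 eta = eta, seed_origin = as.numeric(origin),
                 seed_orientation = phi0, total_length = L,
                 n_flips_used = flips),
            class = "filament_spec")
}

#' Convert a filament spec to its polyline
#'
#' Vertex 0 is the seed origin; vertex `k + 1` is vertex `k` displaced by
#' `seg_lengths[k] * (cos phi_k, sin phi_k)`.  The polyline's arc length is
#' exactly the sum of the segment lengths.
#'
#' @param spec a `filament_spec`.
#' @return an `(n + 1) x 2` numeric matrix of `(x, y)` vertices.
#' @export
filament_to_polyline <- function(spec) {
  n <- length(spec$seg_lengths)
  dx <- spec$seg_lengths * cos(spec$bend_angles)
  dy <- spec$seg_lengths * sin(spec$bend_angles)
  cbind(x = spec$seed_origin[1] + c(0, cumsum(dx)),
        y = spec$seed_origin[2] + c(0, cumsum(dy)))
}

#' Sample a scene of filaments
#'
#' The filament count is the rounded value of a positive-truncated
#' Gaussian `(count_mean, count_sd)` draw; seed origins are uniform over
#' the canvas; filaments are sampled independently.  Filaments may leave
#' the canvas — clipping happens at rasterization.
#'
#' @param theta a valid `theta_params` object.
#' @return an object of class `scene`: `list(filaments, h, w)`.
#' @export
sample_scene <- function(theta) {
  assert_theta(theta)
  h <- theta$image_h; w <- theta$image_w
  count <- as.integer(round(rtrunc_pos(1, theta$count_mean, theta$count_sd)))
  filaments <- vector("list", count)
  if (count > 0) {
    for (i in seq_len(count)) {
      origin <- c(stats::runif(1, 0, w), stats::runif(1, 0, h))
      filaments[[i]] <- sample_filament(theta, origin = origin)
    }
  }
  structure(list(filaments = filaments, h = h, w = w), class = "scene")
}

#' Export a scene as JSON (debugging aid)
#'
#' Writes per-filament vertices and metadata; no standard interchange
#' format exists for this, so the layout is package-specific.
#'
#' @param scene a `scene` object.
#' @param path output path.
#' @export
write_scene_json <- function(scene, path) {
  fil <- lapply(scene$filaments, function(f) {
    p <- filament_to_polyline(f)
    list(vertices = unname(apply(p, 1, as.numeric, simplify = FALSE)),
         total_length = f$total_length,
         seed_orientation = f$seed_orientation,
         n_flips_used = f$n_flips_used)
  })
  jsonlite::write_json(list(canvas = c(scene$h, scene$w), filaments = fil),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.scene <- function(x, ...) {
  cat("<scene>", length(x$filaments), "filaments on a", x$h, "x", x$w, "canvas\n")
  invisible(x)
}
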