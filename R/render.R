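## rendering module (part 2): PSF construction, ideal-image formation,
## seed rendering and RGB composition.

#' Discretized isotropic Gaussian PSF
#'
#' Square odd-sized kernel sampled from an isotropic Gaussian, truncated
#' at `truncate_radius` standard deviations and renormalized to unit sum.
#' The Gaussian is the standard surrogate for a diffraction-limited point
#' spread function and is controlled by a single width parameter.
#'
#' @param sigma PSF width in pixels (> 0).
#' @param truncate_radius kernel support in units of `sigma` (default 4).
#' @return an odd-sized square matrix of class `psf` summing to 1.
#' @export
make_gaussian_psf <- function(sigma, truncate_radius = 4) {
  if (!is.numeric(sigma) || length(sigma) != 1 || !is.finite(sigma) || sigma <= 0)
    stop("sigma must be > 0")
  r <- max(1L, as.integer(ceiling(truncate_radius * sigma)))
  g <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- outer(g, g)
  k <- k / sum(k)
  class(k) <- c("psf", class(k))
  k
}

# Zero-padded linear convolution of an h x w matrix with an odd kernel.
convolve_img <- function(image, kernel) {
  kernel <- matrix(as.numeric(kernel), nrow(kernel), ncol(kernel))
  out <- EBImage::filter2(image, kernel, boundary = 0)
  # filter2 may return an Image object; keep plain matrices throughout
  as.matrix(out)
}

#' Render the ideal (noise-free) image
#'
#' The union of the instance masks is convolved with the PSF
#' (zero-padding at the borders), scaled by the signed contrast `A` and
#' offset by the background intensity `B`:
#' `I = A * (M * psf) + B`.  The per-instance masks are left untouched:
#' they remain the ground truth.
#'
#' @param masks list of `h x w` logical masks (may be empty, then a
#'   constant background is returned — `h`,`w` must then be given).
#' @param psf a `psf` kernel.
#' @param A signed contrast factor.
#' @param B background intensity in `[0, 1]`.
#' @param h,w canvas size, required when `masks` is empty.
#' @return an `h x w` numeric matrix (not clipped; degradation clips last).
#' @export
render_ideal <- function(masks, psf, A, B, h = NULL, w = NULL) {
  if (length(masks) == 0) {
    if (is.null(h) || is.null(w)) stop("empty mask list requires h and w")
    return(matrix(B, h, w))
  }
  dims <- vapply(masks, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("masks must share a common shape")
  union <- Reduce(`|`, masks)
  A * convolve_img(union * 1.0, psf) + B
}

#' Rasterize the seed support of a scene
#'
#' Filaments nucleate from short stabilized seeds; the seed of each
#' filament is taken to be the initial `seed_len` of its arc length.  The
#' truncated sub-polylines of all filaments are rasterized into one shared
#' seed mask.  `seed_len = 0` gives an empty mask; `seed_len >= L`
#' saturates to the filament's full mask.
#'
#' @param scene a `scene` object.
#' @param theta `theta_params` providing `seed_len`.
#' @return an `h x w` logical seed-support mask.
#' @export
render_seeds <- function(scene, theta) {
  mask <- matrix(FALSE, scene$h, scene$w)
  if (theta$seed_len <= 0) return(mask)
  for (f in scene$filaments) {
    sub <- polyline_truncate(filament_to_polyline(f), theta$seed_len)
    mask <- mask | rasterize_polyline(sub, scene$h, scene$w)
  }
  mask
}

#' Compose the 3-channel image with red seeds
#'
#' The base intensity is replicated on all three channels; the PSF-blurred
#' seed support, scaled by `seed_gain`, is added to the red channel only.
#' The result is clipped to `[0, 1]`.
#'
#' @param ideal `h x w` base intensity matrix.
#' @param seed_support `h x w` logical seed mask.
#' @param psf a `psf` kernel used to blur the seed signal.
#' @param seed_gain red-channel seed intensity gain.
#' @return an `h x w x 3` array in `[0, 1]`.
#' @export
compose_rgb <- function(ideal, seed_support, psf, seed_gain) {
  if (!all(dim(ideal) == dim(seed_support))) stop("shape mismatch")
  h <- nrow(ideal); w <- ncol(ideal)
  out <- array(0, dim = c(h, w, 3))
  base <- clip01(ideal)
  out[, , 1] <- base
  out[, , 2] <- base
  out[, , 3] <- base
  if (any(seed_support) && seed_gain != 0) {
    seed_sig <- convolve_img(seed_support * 1.0, psf) * seed_gain
    out[, , 1] <- clip01(out[, , 1] + seed_sig)
  }
  out
}
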