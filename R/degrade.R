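## degradation module: the stochastic operator applied to the ideal image.
## Stage order is fixed and documented: background field -> distractor
## spots -> blur -> vignetting -> speckle -> Poisson -> additive Gaussian
## -> per-channel gain jitter (RGB only) -> clip to [0, 1].  Stages with
## zero amplitude are skipped entirely (no RNG draws, no arithmetic), so
## the all-zero configuration is a bit-exact identity.

#' Degradation configuration
#'
#' The noise/artifact subset of the generation parameters.  Built either
#' from explicit arguments or from a full `theta_params` via
#' [theta_degradation()].  `photon_scale = 0` is the sentinel for
#' "Poisson shot noise off".
#'
#' @param noise_gauss_sd additive Gaussian noise SD.
#' @param photon_scale photons per unit intensity for Poisson shot noise
#'   (0 = off).
#' @param speckle_sd multiplicative Gaussian speckle SD.
#' @param vignette_strength radial attenuation at the farthest corner
#'   (0 = off; field value 1 at the exact center always).
#' @param blur_sigma global Gaussian blur width, pixels.
#' @param bgfield_amp,bgfield_scale amplitude and correlation length of the
#'   low-frequency multiplicative background field.
#' @param n_spots_mean Poisson mean of the distractor-spot count.
#' @param spot_radius_range,spot_gain_range uniform ranges for spot radius
#'   (pixels) and signed gain.
#' @param spot_blur_sigma blur width applied to each spot stamp (0 = none).
#' @param channel_jitter_sd SD of the per-channel multiplicative gain
#'   jitter (RGB images only).
#' @return an object of class `degradation_config`.
#' @export
degradation_config <- function(noise_gauss_sd = 0, photon_scale = 0,
                               speckle_sd = 0, vignette_strength = 0,
                               blur_sigma = 0, bgfield_amp = 0,
                               bgfield_scale = 50, n_spots_mean = 0,
                               spot_radius_range = c(2, 6),
                               spot_gain_range = c(-0.15, 0.15),
                               spot_blur_sigma = 1,
                               channel_jitter_sd = 0) {
  cfg <- list(noise_gauss_sd = noise_gauss_sd, photon_scale = photon_scale,
              speckle_sd = speckle_sd, vignette_strength = vignette_strength,
              blur_sigma = blur_sigma, bgfield_amp = bgfield_amp,
              bgfield_scale = bgfield_scale, n_spots_mean = n_spots_mean,
              spot_radius_range = spot_radius_range,
              spot_gain_range = spot_gain_range,
              spot_blur_sigma = spot_blur_sigma,
              channel_jitter_sd = channel_jitter_sd)
  amps <- c("noise_gauss_sd", "photon_scale", "speckle_sd",
            "vignette_strength", "blur_sigma", "bgfield_amp",
            "n_spots_mean", "channel_jitter_sd")
  for (f in amps) if (cfg[[f]] < 0) stop(f, " must be >= 0")
  class(cfg) <- "degradation_config"
  cfg
}

#' Extract the degradation configuration from theta
#'
#' @param theta a valid `theta_params`.
#' @return a `degradation_config`.
#' @export
theta_degradation <- function(theta) {
  degradation_config(
    noise_gauss_sd = theta$noise_gauss_sd, photon_scale = theta$photon_scale,
    speckle_sd = theta$speckle_sd, vignette_strength = theta$vignette_strength,
    blur_sigma = theta$blur_sigma, bgfield_amp = theta$bgfield_amp,
    bgfield_scale = theta$bgfield_scale, n_spots_mean = theta$n_spots_mean,
    spot_radius_range = theta$spot_radius_range,
    spot_gain_range = theta$spot_gain_range,
    spot_blur_sigma = theta$psf_sigma,
    channel_jitter_sd = theta$channel_jitter_sd)
}

#' Low-frequency multiplicative background field
#'
#' White Gaussian noise smoothed with a Gaussian kernel of width `scale`,
#' recentred to zero mean, rescaled to unit maximum absolute value, and
#' mapped to `1 + amp * G`.  `amp = 0` returns a field identically 1 (no
#' RNG draws).
#'
#' @param h,w field size.
#' @param amp amplitude (>= 0); the field stays within `[1 - amp, 1 + amp]`.
#' @param scale smoothing kernel width in pixels (> 0).
#' @return an `h x w` numeric matrix.
#' @export
make_background_field <- function(h, w, amp, scale) {
  if (amp < 0) stop("amp must be >= 0")
  if (amp == 0) return(matrix(1, h, w))
  if (scale <= 0) stop("scale must be > 0")
  g0 <- matrix(stats::rnorm(h * w), h, w)
  # cap the kernel so it stays below the image size (filter2 requirement)
  r <- min(as.integer(ceiling(2 * scale)), (min(h, w) - 1L) %/% 2L)
  r <- max(r, 1L)
  g1d <- exp(-((-r:r)^2) / (2 * scale^2))
  k <- outer(g1d, g1d); k <- k / sum(k)
  g <- convolve_img(g0, k)
  g <- g - mean(g)
  m <- max(abs(g))
  if (m > 0) g <- g / m
  1 + amp * g
}

# radial cosine-falloff vignetting field: 1 at center, 1 - strength at the
# farthest corner
vignette_field <- function(h, w, strength) {
  cy <- (h - 1) / 2; cx <- (w - 1) / 2
  yy <- matrix(0:(h - 1), h, w)
  xx <- matrix(0:(w - 1), h, w, byrow = TRUE)
  r <- sqrt((yy - cy)^2 + (xx - cx)^2)
  rmax <- sqrt(cy^2 + cx^2)
  1 - strength * (1 - cos(pi / 2 * r / rmax))
}

# apply a pixelwise operation to a matrix or each channel of an RGB array
map_channels <- function(image, f) {
  if (is_rgb(image)) {
    for (c in 1:3) image[, , c] <- f(image[, , c])
    image
  } else f(image)
}

#' Add distractor spots
#'
#' Draws `Poisson(n_spots_mean)` spots at uniform positions; each spot is
#' a disk with radius and signed gain drawn uniformly from the configured
#' ranges, blurred with a Gaussian of width `spot_blur_sigma` (0 = sharp).
#' Distractors only touch the image — ground-truth masks are never
#' modified.
#'
#' @param image matrix or RGB array.
#' @param config a `degradation_config`.
#' @return degraded image of the same shape.
#' @export
add_distractor_spots <- function(image, config) {
  if (config$n_spots_mean == 0) return(image)
  n <- stats::rpois(1, config$n_spots_mean)
  if (n == 0) return(image)
  d <- dim(image)
  h <- d[1]; w <- d[2]
  stamp_total <- matrix(0, h, w)
  for (i in seq_len(n)) {
    cx <- stats::runif(1, 0, w - 1)
    cy <- stats::runif(1, 0, h - 1)
    r <- stats::runif(1, config$spot_radius_range[1], config$spot_radius_range[2])
    gain <- stats::runif(1, config$spot_gain_range[1], config$spot_gain_range[2])
    x_lo <- max(0, floor(cx - r - 1)); x_hi <- min(w - 1, ceiling(cx + r + 1))
    y_lo <- max(0, floor(cy - r - 1)); y_hi <- min(h - 1, ceiling(cy + r + 1))
    if (x_lo > x_hi || y_lo > y_hi) next
    xs <- x_lo:x_hi; ys <- y_lo:y_hi
    disk <- outer((ys - cy)^2, (xs - cx)^2, `+`) <= r^2
    stamp_total[ys + 1, xs + 1] <- stamp_total[ys + 1, xs + 1] + gain * disk
  }
  if (config$spot_blur_sigma > 0)
    stamp_total <- convolve_img(stamp_total, make_gaussian_psf(config$spot_blur_sigma))
  map_channels(image, function(ch) ch + stamp_total)
}

#' Apply the stochastic degradation operator
#'
#' Applies, in a fixed documented order: (1) low-frequency multiplicative
#' background field, (2) distractor spots, (3) global Gaussian blur,
#' (4) vignetting, (5) multiplicative Gaussian speckle, (6) Poisson shot
#' noise at `photon_scale`, (7) additive Gaussian noise, (8) per-channel
#' gain jitter (RGB input only), (9) clipping to `[0, 1]`.  Stages at zero
#' amplitude are skipped, so the all-zero configuration returns the input
#' bit-exactly.  The same R random seed yields the same output.
#'
#' @param image `h x w` matrix or `h x w x 3` array with finite values.
#' @param config a `degradation_config`.
#' @return degraded image of the same shape, clipped to `[0, 1]`.
#' @export
degrade <- function(image, config) {
  if (!all(is.finite(image))) stop("image must be finite")
  identity_cfg <- config$noise_gauss_sd == 0 && config$photon_scale == 0 &&
    config$speckle_sd == 0 && config$vignette_strength == 0 &&
    config$blur_sigma == 0 && config$bgfield_amp == 0 &&
    config$n_spots_mean == 0 && config$channel_jitter_sd == 0
  if (identity_cfg) return(image)

  d <- dim(image)
  h <- d[1]; w <- d[2]
  if (config$bgfield_amp > 0) {
    field <- make_background_field(h, w, config$bgfield_amp, config$bgfield_scale)
    image <- map_channels(image, function(ch) ch * field)
  }
  if (config$n_spots_mean > 0)
    image <- add_distractor_spots(image, config)
  if (config$blur_sigma > 0) {
    k <- make_gaussian_psf(config$blur_sigma)
    image <- map_channels(image, function(ch) convolve_img(ch, k))
  }
  if (config$vignette_strength > 0) {
    v <- vignette_field(h, w, config$vignette_strength)
    image <- map_channels(image, function(ch) ch * v)
  }
  if (config$speckle_sd > 0)
    image <- map_channels(image, function(ch)
      ch * (1 + matrix(stats::rnorm(h * w, 0, config$speckle_sd), h, w)))
  if (config$photon_scale > 0)
    image <- map_channels(image, function(ch) {
      lam <- pmax(ch, 0) * config$photon_scale
      matrix(stats::rpois(h * w, lam), h, w) / config$photon_scale
    })
  if (config$noise_gauss_sd > 0)
    image <- map_channels(image, function(ch)
      ch + matrix(stats::rnorm(h * w, 0, config$noise_gauss_sd), h, w))
  if (config$channel_jitter_sd > 0 && is_rgb(image)) {
    gains <- 1 + stats::rnorm(3, 0, config$channel_jitter_sd)
    for (c in 1:3) image[, , c] <- image[, , c] * gains[c]
  }
  clip01(image)
}
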