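## parameters module: the generation parameter vector theta, its validation,
## serialization, and sampling from a declared search space.

#' Default generation parameter vector
#'
#' Returns the full parameter vector \eqn{\theta} controlling geometry
#' (filament count, total length, segment length, Gamma bend increments,
#' sign flips), imaging (PSF width, contrast, background, seeds) and
#' degradation (noise amplitudes, artifacts, distractors) of the simulator.
#' The defaults produce dark, gently curved filaments on a mid-gray
#' background at 512 x 512 pixels, in the style of interference reflection
#' microscopy of surface-attached microtubules.
#'
#' Units: lengths in pixels, angles in radians, intensities on `[0, 1]`.
#' `contrast` is signed; negative values render filaments darker than the
#' background (the IRM situation).  `photon_scale = 0` switches Poisson
#' shot noise off.
#'
#' @return an object of class `theta_params` (a flat named list).
#' @seealso [validate_theta()], [sample_theta()], [default_search_space()]
#' @export
default_theta <- function() {
  theta <- list(
    # geometry: per-image filament count law (truncated Gaussian, rounded)
    count_mean = 11.28, count_sd = 5.1,
    # per-segment length law, pixels
    seg_len_mean = 4, seg_len_sd = 1,
    # Gamma law of bend-angle increments, radians
    bend_shape = 2, bend_scale = 0.05,
    # bend-direction sign process
    flip_prob = 0.1, max_flips = 10,
    # total filament length law, pixels
    fil_len_mean = 148, fil_len_sd = 74,
    # imaging
    psf_sigma = 1.2,
    contrast = -0.35, background = 0.55,
    seed_len = 15, seed_gain = 0.25,
    # degradation amplitudes
    noise_gauss_sd = 0.02, photon_scale = 2000, speckle_sd = 0.02,
    vignette_strength = 0.15, blur_sigma = 0.4,
    bgfield_amp = 0.08, bgfield_scale = 60,
    n_spots_mean = 4,
    spot_radius_range = c(2, 6),
    spot_gain_range = c(-0.15, 0.15),
    channel_jitter_sd = 0.01,
    # canvas
    image_h = 512, image_w = 512
  )
  class(theta) <- "theta_params"
  theta
}

theta_field_names <- function() names(default_theta())

#' Validate a parameter vector
#'
#' Checks every invariant of the parameter vector and returns the
#' violations as data rather than raising conditions: an empty character
#' vector means the vector is valid, otherwise each element names the
#' offending field.
#'
#' @param theta a `theta_params` object (or plain named list).
#' @return character vector of violation messages (possibly empty).
#' @export
validate_theta <- function(theta) {
  v <- character(0)
  need <- theta_field_names()
  missing <- setdiff(need, names(theta))
  if (length(missing) > 0)
    return(paste0("missing field: ", missing))
  bad_scalar <- function(f) {
    x <- theta[[f]]
    !is.numeric(x) || length(x) != 1L || !is.finite(x)
  }
  scalars <- setdiff(need, c("spot_radius_range", "spot_gain_range"))
  for (f in scalars) if (bad_scalar(f)) v <- c(v, paste0(f, ": not a finite numeric scalar"))
  if (length(v) > 0) return(v)

  nonneg <- c("count_mean", "count_sd", "seg_len_sd", "bend_shape",
              "bend_scale", "max_flips", "fil_len_sd", "seed_len",
              "noise_gauss_sd", "photon_scale", "speckle_sd",
              "vignette_strength", "blur_sigma", "bgfield_amp",
              "bgfield_scale", "n_spots_mean", "channel_jitter_sd")
  for (f in nonneg) if (theta[[f]] < 0) v <- c(v, paste0(f, ": must be >= 0"))
  positive <- c("seg_len_mean", "fil_len_mean", "psf_sigma")
  for (f in positive) if (theta[[f]] <= 0) v <- c(v, paste0(f, ": must be > 0"))
  for (f in c("flip_prob", "background"))
    if (theta[[f]] < 0 || theta[[f]] > 1) v <- c(v, paste0(f, ": must be in [0, 1]"))
  if (theta$max_flips != round(theta$max_flips))
    v <- c(v, "max_flips: must be an integer")
  for (f in c("image_h", "image_w"))
    if (theta[[f]] < 1 || theta[[f]] != round(theta[[f]]))
      v <- c(v, paste0(f, ": must be a positive integer"))
  for (f in c("spot_radius_range", "spot_gain_range")) {
    x <- theta[[f]]
    if (!is.numeric(x) || length(x) != 2L || any(!is.finite(x)) || x[1] > x[2])
      v <- c(v, paste0(f, ": must be a finite (min, max) pair with min <= max"))
  }
  if (length(v) == 0 && theta$spot_radius_range[1] < 0)
    v <- c(v, "spot_radius_range: radii must be >= 0")
  v
}

assert_theta <- function(theta) {
  v <- validate_theta(theta)
  if (length(v) > 0)
    stop("invalid theta: ", paste(v, collapse = "; "))
  invisible(theta)
}

#' Write / read a parameter vector as flat YAML
#'
#' The on-disk representation is a flat key-value YAML mapping; the two
#' range fields are stored as two-element sequences.  `read_theta()` of a
#' written file is the identity on every valid parameter vector.
#'
#' @param theta a `theta_params` object.
#' @param path file path.
#' @export
write_theta <- function(theta, path) {
  writeLines(vapply(names(theta), function(f) {
    v <- theta[[f]]
    if (length(v) == 1) sprintf("%s: %s", f, num17(v))
    else sprintf("%s: [%s]", f, paste(vapply(v, num17, character(1)),
                                      collapse = ", "))
  }, character(1)), path)
  invisible(path)
}

# %.17g round-trips every double exactly through a YAML parser
num17 <- function(x) sprintf("%.17g", x)

#' @rdname write_theta
#' @export
read_theta <- function(path) {
  raw <- yaml::read_yaml(path)
  theta <- default_theta()
  unknown <- setdiff(names(raw), names(theta))
  if (length(unknown) > 0)
    stop("unknown theta field(s) in ", path, ": ", paste(unknown, collapse = ", "))
  for (f in names(raw)) theta[[f]] <- as.numeric(raw[[f]])
  assert_theta(theta)
  theta
}

#' Default search space for tuning theta
#'
#' Per-parameter `(low, high)` bounds plus a scale tag (`"linear"` or
#' `"log"`) for every tunable field.  Noise amplitudes span orders of
#' magnitude and are tuned on a log scale.  The canvas size and the two
#' distractor range fields are fixed, not tuned.  These bounds are an
#' engineering default, meant to be edited per imaging setup and shipped
#' as explicit configuration (see [read_search_space()]).
#'
#' @return an object of class `search_space`: a named list of
#'   `list(low, high, scale)` entries.
#' @export
default_search_space <- function() {
  sp <- list(
    count_mean    = list(low = 1,    high = 40,   scale = "linear"),
    count_sd      = list(low = 0.1,  high = 15,   scale = "linear"),
    seg_len_mean  = list(low = 2,    high = 8,    scale = "linear"),
    seg_len_sd    = list(low = 0.1,  high = 3,    scale = "linear"),
    bend_shape    = list(low = 0.5,  high = 5,    scale = "linear"),
    bend_scale    = list(low = 1e-3, high = 0.3,  scale = "log"),
    flip_prob     = list(low = 0,    high = 0.5,  scale = "linear"),
    fil_len_mean  = list(low = 30,   high = 400,  scale = "linear"),
    fil_len_sd    = list(low = 5,    high = 200,  scale = "linear"),
    psf_sigma     = list(low = 0.6,  high = 3,    scale = "linear"),
    contrast      = list(low = -0.6, high = 0.6,  scale = "linear"),
    background    = list(low = 0.2,  high = 0.8,  scale = "linear"),
    seed_len      = list(low = 0,    high = 40,   scale = "linear"),
    seed_gain     = list(low = 0,    high = 0.5,  scale = "linear"),
    noise_gauss_sd    = list(low = 1e-4, high = 0.1, scale = "log"),
    photon_scale      = list(low = 100,  high = 1e5, scale = "log"),
    speckle_sd        = list(low = 1e-4, high = 0.1, scale = "log"),
    vignette_strength = list(low = 0,    high = 0.5, scale = "linear"),
    blur_sigma        = list(low = 0,    high = 2,   scale = "linear"),
    bgfield_amp       = list(low = 0,    high = 0.3, scale = "linear"),
    bgfield_scale     = list(low = 10,   high = 150, scale = "linear"),
    n_spots_mean      = list(low = 0,    high = 20,  scale = "linear")
  )
  class(sp) <- "search_space"
  sp
}

#' Validate a search space
#'
#' @param space a `search_space` object.
#' @return character vector of violations (empty when valid).
#' @export
validate_search_space <- function(space) {
  v <- character(0)
  fixed <- c("spot_radius_range", "spot_gain_range", "image_h", "image_w")
  for (f in names(space)) {
    e <- space[[f]]
    if (!(f %in% theta_field_names()) || f %in% fixed) {
      v <- c(v, paste0(f, ": not a tunable theta field"))
      next
    }
    if (!is.list(e) || is.null(e$low) || is.null(e$high)) {
      v <- c(v, paste0(f, ": entry must have low/high"))
      next
    }
    if (!is.finite(e$low) || !is.finite(e$high) || e$low > e$high)
      v <- c(v, paste0(f, ": requires low <= high"))
    sc <- e$scale %||% "linear"
    if (!sc %in% c("linear", "log"))
      v <- c(v, paste0(f, ": scale must be 'linear' or 'log'"))
    else if (sc == "log" && !is.null(e$low) && is.finite(e$low) && e$low <= 0)
      v <- c(v, paste0(f, ": log scale requires low > 0"))
  }
  v
}

assert_search_space <- function(space) {
  v <- validate_search_space(space)
  if (length(v) > 0)
    stop("invalid search space: ", paste(v, collapse = "; "))
  invisible(space)
}

#' @rdname write_theta
#' @param space a `search_space` object.
#' @export
write_search_space <- function(space, path) {
  lines <- unlist(lapply(names(space), function(f) {
    e <- space[[f]]
    c(sprintf("%s:", f),
      sprintf("  low: %s", num17(e$low)),
      sprintf("  high: %s", num17(e$high)),
      sprintf("  scale: %s", e$scale %||% "linear"))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_theta
#' @export
read_search_space <- function(path) {
  sp <- yaml::read_yaml(path)
  sp <- lapply(sp, function(e) list(low = as.numeric(e$low),
                                    high = as.numeric(e$high),
                                    scale = e$scale %||% "linear"))
  class(sp) <- "search_space"
  assert_search_space(sp)
  sp
}

# Draw one named parameter list from a search space (no theta overlay).
sample_params <- function(space) {
  assert_search_space2 <- function(sp) {  # bounds-only check for non-theta uses
    for (f in names(sp)) {
      e <- sp[[f]]
      if (e$low > e$high) stop("invalid search space: ", f, " requires low <= high")
      if ((e$scale %||% "linear") == "log" && e$low <= 0)
        stop("invalid search space: ", f, " log scale requires low > 0")
    }
  }
  assert_search_space2(space)
  out <- lapply(space, function(e) {
    if (e$low == e$high) return(e$low)  # degenerate: the unique boundary point
    if ((e$scale %||% "linear") == "log")
      exp(stats::runif(1, log(e$low), log(e$high)))
    else
      stats::runif(1, e$low, e$high)
  })
  out
}

#' Sample a parameter vector from a search space
#'
#' Each tunable field is drawn uniformly within its bounds (on its declared
#' linear or log scale); all fields absent from the space are copied from
#' `base`.  Draws consume the R random stream, so a fixed `set.seed()`
#' yields identical vectors.
#'
#' @param space a `search_space` object.
#' @param base `theta_params` supplying the fixed fields.
#' @return a valid `theta_params` object within bounds.
#' @export
sample_theta <- function(space, base = default_theta()) {
  assert_search_space(space)
  draws <- sample_params(space)
  theta <- base
  for (f in names(draws)) theta[[f]] <- draws[[f]]
  if (!is.null(theta$max_flips)) theta$max_flips <- round(theta$max_flips)
  assert_theta(theta)
  theta
}

#' @export
print.theta_params <- function(x, ...) {
  cat("<theta_params>", length(x), "fields\n")
  for (f in names(x)) cat(sprintf("  %-18s %s\n", f, paste(signif(x[[f]], 6), collapse = ", ")))
  invisible(x)
}

#' @export
print.search_space <- function(x, ...) {
  cat("<search_space>", length(x), "tunable fields\n")
  for (f in names(x))
    cat(sprintf("  %-18s [%g, %g] %s\n", f, x[[f]]$low, x[[f]]$high,
                x[[f]]$scale %||% "linear"))
  invisible(x)
}
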