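#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

is_rgb <- function(image) length(dim(image)) == 3L

#' Collapse an image to grayscale
#'
#' RGB arrays are averaged over channels; matrices pass through.
#'
#' @param image numeric matrix (h x w) or array (h x w x 3) in `[0, 1]`.
#' @return numeric matrix.
#' @export
to_gray <- function(image) {
  if (is_rgb(image)) (image[, , 1] + image[, , 2] + image[, , 3]) / 3 else image
}

#' Derive a reproducible child seed from a master seed
#'
#' Mixes the master seed with any number of integer indices through a
#' Lehmer-style modular hash so that per-sample streams are reproducible
#' without storing every seed.  The result is always in `[1, 2^31 - 2]`.
#'
#' @param master integer master seed.
#' @param ... integer indices (e.g. group, set, draw).
#' @return a single integer seed.
#' @export
derive_seed <- function(master, ...) {
  m <- 2147483647  # 2^31 - 1 (Mersenne prime); products stay below 2^53
  a <- 48271
  state <- (abs(as.numeric(master)) %% m)
  for (k in as.numeric(c(...))) {
    state <- (state * a + abs(k) + 1) %% m
  }
  # a few extra scrambles so that (seed, i) and (seed + i) do not collide
  for (r in 1:3) state <- (state * a + 11) %% m
  as.integer(state %% (m - 2)) + 1L
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Positive-truncated Gaussian draw by rejection; cap redraw rounds.
rtrunc_pos <- function(n, mean, sd, cap = 1000L) {
  if (sd == 0) {
    if (mean < 0) stop("degenerate truncated Gaussian with negative mean")
    return(rep(mean, n))
  }
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < 0)
  rounds <- 0L
  while (length(bad) > 0) {
    rounds <- rounds + 1L
    if (rounds > cap)
      stop("truncated-Gaussian rejection exceeded ", cap, " rounds; ",
           "law (", mean, ", ", sd, ") is almost surely negative")
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < 0]
  }
  out
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("'", name, "' must be a finite numeric scalar")
  invisible(x)
}
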