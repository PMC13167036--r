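## domain_tuner module (part 1): embedding backends and cosine similarity.
##
## A backend is a plain contract: a deterministic map from an image to a
## fixed-length real vector.  The built-in backend is a handcrafted
## feature embedding (intensity histogram + gradient-magnitude statistics
## + radially averaged power spectrum) so the package works without any
## model weights; a deep backend (e.g. an intermediate vision-transformer
## layer) can be plugged in behind the same contract.

#' Construct an embedding backend
#'
#' @param name backend name.
#' @param embed function `image -> numeric vector` of constant length.
#' @param dim the embedding length.
#' @param deterministic whether the same image always yields the same
#'   vector.
#' @return an object of class `embedding_backend`.
#' @export
embedding_backend <- function(name, embed, dim, deterministic = TRUE) {
  if (!is.function(embed)) stop("embed must be a function")
  structure(list(name = name, embed = embed, dim = as.integer(dim),
                 deterministic = isTRUE(deterministic)),
            class = "embedding_backend")
}

#' Built-in handcrafted feature backend
#'
#' Embeds a grayscale view of the image as the concatenation of
#' a normalized intensity histogram (`hist_bins` bins on `[0, 1]`),
#' gradient-magnitude statistics (mean, SD, quartiles, 90th percentile),
#' and a radially averaged log power spectrum (`radial_bins` rings).
#' Deterministic and weight-free.
#'
#' @param hist_bins intensity histogram bins.
#' @param radial_bins power-spectrum rings.
#' @return an `embedding_backend`.
#' @export
feature_backend <- function(hist_bins = 32L, radial_bins = 16L) {
  embed <- function(image) {
    g <- to_gray(image)
    h <- nrow(g); w <- ncol(g)
    # intensity histogram
    idx <- pmin(pmax(floor(g * hist_bins) + 1L, 1L), hist_bins)
    hist_part <- tabulate(idx, nbins = hist_bins) / length(g)
    # gradient magnitude
    gx <- g[, c(2:w, w)] - g
    gy <- g[c(2:h, h), ] - g
    gm <- sqrt(gx^2 + gy^2)
    grad_part <- c(mean(gm), stats::sd(as.numeric(gm)),
                   stats::quantile(gm, c(0.25, 0.5, 0.75, 0.9), names = FALSE))
    # radially averaged power spectrum
    ps <- Mod(stats::fft(g - mean(g)))^2
    fy <- c(0:(h %/% 2), -((h - h %/% 2 - 1):1)) / h
    fx <- c(0:(w %/% 2), -((w - w %/% 2 - 1):1)) / w
    r <- sqrt(outer(fy^2, fx^2, `+`))
    ring <- pmin(floor(r / (0.5 / radial_bins)) + 1L, radial_bins)
    sums <- vapply(seq_len(radial_bins),
                   function(b) mean(ps[ring == b]), numeric(1))
    spec_part <- log1p(sums)
    spec_part <- spec_part / max(sum(abs(spec_part)), .Machine$double.eps)
    c(hist_part, grad_part, spec_part)
  }
  embedding_backend("feature", embed, hist_bins + 6L + radial_bins,
                    deterministic = TRUE)
}

#' Cosine similarity of two vectors
#'
#' @param u,v nonzero numeric vectors of equal length.
#' @return value in `[-1, 1]`; symmetric in its arguments.
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) stop("vectors must have equal length")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine similarity is undefined for a zero vector")
  max(-1, min(1, sum(u * v) / (nu * nv)))
}

#' Reference set of real frames
#'
#' @param images nonempty list of same-shape images.
#' @param domain_id identifier of the target domain.
#' @return an object of class `reference_set`.
#' @export
reference_set <- function(images, domain_id = "domain") {
  if (length(images) == 0) stop("reference set must be nonempty")
  d0 <- dim(to_gray(images[[1]]))
  for (im in images)
    if (!all(dim(to_gray(im)) == d0)) stop("reference images must share a shape")
  structure(list(images = images, domain_id = domain_id),
            class = "reference_set")
}
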