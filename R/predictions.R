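## predictions module: normalization of heterogeneous prediction dialects
## (mask stacks, integer-labeled maps, anchor-point chains) into instance
## mask stacks, plus the unified pre/postprocessing applied to every
## method's output before scoring.

#' Anchor chain
#'
#' An ordered list of at least two continuous `(x, y)` points along one
#' filament — the native output of tracing methods.
#'
#' @param points an `n x 2` numeric matrix, `n >= 2`, finite coordinates.
#' @return an object of class `anchor_chain`.
#' @export
anchor_chain <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2) stop("anchor chain needs >= 2 points")
  if (!all(is.finite(points))) stop("anchor coordinates must be finite")
  structure(points, class = c("anchor_chain", "matrix"))
}

#' Polyline length of an anchor chain
#'
#' Sum of consecutive Euclidean distances.
#'
#' @param chain an `anchor_chain` (or plain `n x 2` matrix).
#' @return length in pixels.
#' @export
anchor_length <- function(chain) {
  p <- unclass(chain)
  sum(sqrt(diff(p[, 1])^2 + diff(p[, 2])^2))
}

# drop consecutive duplicate anchors; error when nothing remains
collapse_duplicates <- function(p) {
  if (nrow(p) > 1) {
    d <- sqrt(diff(p[, 1])^2 + diff(p[, 2])^2)
    p <- p[c(TRUE, d > 0), , drop = FALSE]
  }
  if (nrow(p) < 2) stop("anchor chain is degenerate (all points identical)")
  p
}

#' Convert an anchor chain to a mask via an interpolating spline
#'
#' Fits a zero-smoothing parametric cubic spline through the anchors
#' (piecewise-linear when fewer than 4 distinct points remain), samples it
#' densely (4 samples per pixel of arc length), and supercover-rasterizes
#' the sampled polyline, clipped to the canvas.  This is the conversion
#' used on the segmentation-metrics path.
#'
#' @param chain an `anchor_chain`.
#' @param h,w canvas size.
#' @return an `h x w` logical mask.
#' @export
anchors_to_mask_spline <- function(chain, h, w) {
  p <- collapse_duplicates(unclass(chain))
  if (nrow(p) < 4) return(anchors_to_mask_lines(anchor_chain(p), h, w))
  curve <- fit_curve(p, method = "interpolating")
  arc <- curve$u_range[2]
  n_samp <- max(2L, ceiling(arc * 4))
  pts <- curve_eval(curve, seq(curve$u_range[1], curve$u_range[2],
                               length.out = n_samp))
  rasterize_polyline(pts, h, w)
}

#' Convert an anchor chain to a mask via straight lines
#'
#' Union of the supercover rasterizations of the consecutive segments.
#' This is the conversion used on the curvature-preprocessing path.
#' Closed or self-intersecting chains are allowed.
#'
#' @inheritParams anchors_to_mask_spline
#' @return an `h x w` logical mask.
#' @export
anchors_to_mask_lines <- function(chain, h, w) {
  p <- collapse_duplicates(unclass(chain))
  rasterize_polyline(p, h, w)
}

#' Prediction set in one of three dialects
#'
#' @param payload a `mask_stack` (dialect `"stack"`), an integer matrix
#'   (dialect `"labels"`), or a list of `anchor_chain`s (dialect
#'   `"anchors"`).
#' @param dialect one of `"stack"`, `"labels"`, `"anchors"`.
#' @param shape canvas `(h, w)`.
#' @return an object of class `prediction_set`.
#' @export
prediction_set <- function(payload, dialect = c("stack", "labels", "anchors"),
                           shape) {
  dialect <- match.arg(dialect)
  ok <- switch(dialect,
    stack = inherits(payload, "mask_stack"),
    labels = is.matrix(payload) && all(payload >= 0),
    anchors = is.list(payload) &&
      all(vapply(payload, inherits, logical(1), "anchor_chain")))
  if (!ok) stop("payload does not match dialect '", dialect, "'")
  structure(list(payload = payload, dialect = dialect,
                 shape = as.integer(shape)),
            class = "prediction_set")
}

#' Number of instances in a prediction set
#' @param preds a `prediction_set`.
#' @export
n_instances <- function(preds) {
  switch(preds$dialect,
         stack = length(preds$payload),
         labels = length(unique(preds$payload[preds$payload != 0])),
         anchors = length(preds$payload))
}

#' Normalize any prediction dialect to an instance mask stack
#'
#' Mask stacks pass through unchanged; labeled maps are split per nonzero
#' label; anchor chains are converted with [anchors_to_mask_spline()]
#' (the metrics path).  The number of instances never changes here.
#'
#' @param preds a `prediction_set`.
#' @return a `mask_stack`.
#' @export
normalize_predictions <- function(preds) {
  switch(preds$dialect,
    stack = preds$payload,
    labels = labeled_map_to_stack(preds$payload),
    anchors = mask_stack(lapply(preds$payload, anchors_to_mask_spline,
                                h = preds$shape[1], w = preds$shape[2])))
}

#' Plausibility thresholds from ground truth
#'
#' Minimum and maximum instance length (skeleton pixel count) and area
#' (pixel count) over the ground-truth instances, expanded by a relative
#' margin so borderline-true instances are not discarded by exact-min/max
#' filtering.
#'
#' @param gt a nonempty `mask_stack` of ground-truth instances.
#' @param margin relative expansion of the bounds (default 10%).
#' @return an object of class `gt_thresholds`:
#'   `list(min_length, max_length, min_area, max_area)`.
#' @export
compute_gt_thresholds <- function(gt, margin = 0.1) {
  if (length(gt) == 0) stop("ground truth is empty")
  lens <- vapply(gt, function(m) sum(skeletonize(m)), numeric(1))
  areas <- vapply(gt, sum, numeric(1))
  structure(list(min_length = min(lens) * (1 - margin),
                 max_length = max(lens) * (1 + margin),
                 min_area = min(areas) * (1 - margin),
                 max_area = max(areas) * (1 + margin)),
            class = "gt_thresholds")
}

#' Unified postprocessing: filter implausible instances
#'
#' Mask-dialect instances survive iff both their skeleton length and
#' their area fall within the thresholds; anchor-dialect instances are
#' filtered by their polyline length only (anchor methods carry no
#' meaningful area).  Survivor order is preserved; the operation is
#' idempotent.
#'
#' @param preds a `prediction_set`.
#' @param thresholds a `gt_thresholds`.
#' @return a filtered `prediction_set` of the same dialect (labeled maps
#'   are returned as mask stacks).
#' @export
unified_postprocess <- function(preds, thresholds) {
  if (preds$dialect == "anchors") {
    keep <- vapply(preds$payload, function(ch) {
      l <- anchor_length(ch)
      l >= thresholds$min_length && l <= thresholds$max_length
    }, logical(1))
    return(prediction_set(preds$payload[keep], "anchors", preds$shape))
  }
  stack <- normalize_predictions(preds)
  keep <- vapply(stack, function(m) {
    l <- sum(skeletonize(m))
    a <- sum(m)
    l >= thresholds$min_length && l <= thresholds$max_length &&
      a >= thresholds$min_area && a <= thresholds$max_area
  }, logical(1))
  prediction_set(mask_stack(unclass(stack)[keep]), "stack", preds$shape)
}

#' Configurable image preprocessing chain
#'
#' Applies, in the order given, steps from the menu: `"minmax"` (min-max
#' normalization to `[0, 1]`), `"stretch"` (percentile contrast stretch,
#' parameters `p_low`/`p_high` in percent), `"invert"` (intensity
#' inversion, an involution), `"denoise"` (Gaussian blur of width
#' `sigma`), `"gray2rgb"` (replicate a matrix onto 3 channels).  An empty
#' config is the identity; unknown step names are an error.  Every step
#' is optional and off by default — segmenter-specific preprocessing is
#' meant to be expressed entirely through this chain so all methods share
#' the same preprocessing capabilities.
#'
#' @param image matrix or RGB array.
#' @param config list of steps: bare step names or
#'   `list(step = <name>, ...)` with parameters.
#' @return the processed image.
#' @export
preprocess_image <- function(image, config = list()) {
  for (entry in config) {
    step <- if (is.character(entry)) entry else entry$step
    pars <- if (is.character(entry)) list() else entry
    image <- switch(step,
      minmax = {
        rng <- range(image)
        if (rng[2] > rng[1]) (image - rng[1]) / (rng[2] - rng[1]) else image
      },
      stretch = {
        p <- stats::quantile(image, c((pars$p_low %||% 1) / 100,
                                      (pars$p_high %||% 99) / 100),
                             names = FALSE)
        if (p[2] > p[1]) clip01((image - p[1]) / (p[2] - p[1])) else image
      },
      invert = 1 - image,
      denoise = {
        k <- make_gaussian_psf(pars$sigma %||% 1)
        map_channels(image, function(ch) convolve_img(ch, k))
      },
      gray2rgb = {
        if (is_rgb(image)) image
        else array(rep(image, 3), dim = c(dim(image), 3))
      },
      stop("unknown preprocessing step: ", step))
  }
  image
}

#' Read / write anchor chains as CSV or JSON
#'
#' CSV columns: `instance_id, point_index, x, y` (points ordered by
#' `point_index` within each instance, instances by first appearance).
#' JSON: a list of per-instance point arrays.
#'
#' @param path file path (`.csv` or `.json`).
#' @return list of `anchor_chain`s.
#' @export
read_anchor_chains <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    df <- utils::read.csv(path)
    need <- c("instance_id", "point_index", "x", "y")
    if (!all(need %in% names(df)))
      stop("anchor CSV must have columns: ", paste(need, collapse = ", "))
    ids <- unique(df$instance_id)
    lapply(ids, function(id) {
      sub <- df[df$instance_id == id, ]
      sub <- sub[order(sub$point_index), ]
      anchor_chain(cbind(sub$x, sub$y))
    })
  } else if (ext == "json") {
    raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    lapply(raw, function(p)
      anchor_chain(do.call(rbind, lapply(p, as.numeric))))
  } else stop("unsupported anchor format: .", ext)
}

#' @rdname read_anchor_chains
#' @param chains list of `anchor_chain`s.
#' @export
write_anchor_chains <- function(chains, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    rows <- lapply(seq_along(chains), function(i) {
      p <- unclass(chains[[i]])
      data.frame(instance_id = i, point_index = seq_len(nrow(p)),
                 x = p[, 1], y = p[, 2])
    })
    utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  } else if (ext == "json") {
    jsonlite::write_json(lapply(chains, function(ch)
      apply(unclass(ch), 1, as.numeric, simplify = FALSE)),
      path, digits = NA)
  } else stop("unsupported anchor format: .", ext)
  invisible(path)
}

#' Read an integer-labeled map from TIFF or PNG
#'
#' TIFF pages are read with raw sample values (`as.is`); 8-bit PNG values
#' are rescaled from `[0, 1]` back to integer labels.
#'
#' @param path file path.
#' @return integer matrix of labels (0 = background).
#' @export
read_labeled_map <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    m <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(m)) == 3) m <- m[, , 1]
    storage.mode(m) <- "integer"
    m
  } else if (ext == "png") {
    m <- png::readPNG(path)
    if (length(dim(m)) == 3) m <- m[, , 1]
    matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
  } else stop("unsupported labeled-map format: .", ext)
}
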