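## dataset_io module: full labeled-sample generation, dataset assembly,
## and every on-disk format (images, multi-page mask stacks, manifests).

#' Instance mask stack
#'
#' An ordered list of same-shape logical masks, one per instance.
#' Overlapping instances are permitted — that is the point of storing one
#' mask per instance rather than a labeled map.
#'
#' @param masks list of `h x w` logical matrices (possibly empty).
#' @return an object of class `mask_stack`.
#' @export
mask_stack <- function(masks = list()) {
  if (length(masks) > 0) {
    d0 <- dim(masks[[1]])
    for (i in seq_along(masks)) {
      if (!is.logical(masks[[i]]) || !all(dim(masks[[i]]) == d0))
        stop("mask ", i, " is not a logical matrix of the shared shape")
    }
  }
  structure(masks, class = "mask_stack")
}

#' Generate one labeled sample
#'
#' Runs the full pipeline — geometry, rasterization, PSF rendering, seed
#' composition, degradation — under one seeded random stream.  The
#' ground-truth stack holds one mask per filament whose in-canvas skeleton
#' covers at least 2 pixels (sub-pixel fragments are unlabelable and are
#' dropped from both image and stack); each ground-truth mask is the
#' filament's rasterized skeleton dilated by a 1-px disk so that it has
#' the physical width the PSF gives the rendered filament.
#'
#' @param theta a valid `theta_params`.
#' @param seed integer seed; the same `(theta, seed)` reproduces the
#'   sample bit-exactly.
#' @param gt_dilate_radius dilation radius (pixels) applied to each
#'   rasterized skeleton to form its ground-truth mask.
#' @return list with `image` (`h x w x 3` array in `[0, 1]`), `masks`
#'   (a `mask_stack` of dilated ground-truth masks), and `scene`.
#' @export
generate_sample <- function(theta, seed, gt_dilate_radius = 1L) {
  assert_theta(theta)
  with_seed(seed, {
    scene <- sample_scene(theta)
    h <- scene$h; w <- scene$w
    skels <- list()
    for (f in scene$filaments) {
      m <- rasterize_polyline(filament_to_polyline(f), h, w)
      if (sum(m) >= 2) skels[[length(skels) + 1L]] <- m
    }
    psf <- make_gaussian_psf(theta$psf_sigma)
    ideal <- render_ideal(skels, psf, theta$contrast, theta$background,
                          h = h, w = w)
    seeds <- render_seeds(scene, theta)
    rgb <- compose_rgb(ideal, seeds, psf, theta$seed_gain)
    image <- degrade(rgb, theta_degradation(theta))
    gt <- lapply(skels, dilate_mask, radius = gt_dilate_radius)
    list(image = image, masks = mask_stack(gt), scene = scene)
  })
}

#' Write / read an instance mask stack as multi-page TIFF
#'
#' One page per instance, stored as 8-bit 0/255; reading accepts any
#' nonzero value as foreground (released stacks in the wild use both 0/1
#' and 0/255).  An empty stack is written as a zero-byte file, and a
#' zero-byte file reads back as an empty stack.
#'
#' @param stack a `mask_stack`.
#' @param path file path (`.tif`).
#' @return `read_mask_stack` returns a `mask_stack`; round-tripping is the
#'   identity.
#' @export
write_mask_stack <- function(stack, path) {
  if (length(stack) == 0) {
    file.create(path)
    return(invisible(path))
  }
  pages <- lapply(stack, function(m) m * 1.0)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_mask_stack
#' @export
read_mask_stack <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) return(mask_stack())
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) stop("not a readable TIFF: ", path))
  if (!is.list(pages)) pages <- list(pages)
  d0 <- dim(pages[[1]])[1:2]
  masks <- vector("list", length(pages))
  for (i in seq_along(pages)) {
    p <- pages[[i]]
    if (length(dim(p)) == 3) p <- p[, , 1]
    if (!all(dim(p)[1:2] == d0))
      stop("format error: page ", i, " has inconsistent shape")
    masks[[i]] <- p != 0
  }
  mask_stack(masks)
}

#' Split an integer-labeled map into an instance mask stack
#'
#' One slice per distinct nonzero label in ascending label order; the
#' slices are pairwise disjoint and their union is the nonzero support.
#'
#' @param labeled `h x w` matrix of non-negative integers (0 = background).
#' @return a `mask_stack`.
#' @export
labeled_map_to_stack <- function(labeled) {
  if (any(labeled < 0)) stop("labeled map must be non-negative")
  labs <- sort(unique(labeled[labeled != 0]))
  mask_stack(lapply(labs, function(l) labeled == l))
}

#' Read / write grayscale or RGB images
#'
#' Supported formats are TIFF and PNG at 8 or 16 bits.  Values are floats
#' in `[0, 1]` in memory, scaled by the file bit depth; writing quantizes
#' at the configured depth (PNG is always 8-bit here), so a round trip is
#' exact to within half a quantization step.
#'
#' @param image matrix or `h x w x 3` array in `[0, 1]`.
#' @param path file path ending in `.tif`, `.tiff` or `.png`.
#' @param bits 8 or 16 (TIFF only).
#' @export
write_image <- function(image, path, bits = 8L) {
  ext <- tolower(tools::file_ext(path))
  image <- clip01(image)
  if (ext %in% c("tif", "tiff")) {
    if (!bits %in% c(8L, 16L)) stop("unsupported bit depth: ", bits)
    levels <- 2^bits - 1
    tiff::writeTIFF(round(image * levels) / levels, path,
                    bits.per.sample = as.integer(bits))
  } else if (ext == "png") {
    png::writePNG(round(image * 255) / 255, path)
  } else stop("unsupported image format: .", ext)
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
         else if (ext == "png") png::readPNG(path)
         else stop("unsupported image format: .", ext)
  if (length(dim(img)) == 3 && dim(img)[3] > 3) img <- img[, , 1:3]  # drop alpha
  img
}

#' Assemble a dataset of generated samples
#'
#' For each (domain) group and each retained parameter set in it,
#' `draws_per_set` samples are generated and written; per-sample seeds are
#' derived deterministically from the master seed and the (group, set,
#' draw) indices, so the whole dataset is reproducible byte-for-byte from
#' the manifest alone.  The manifest is JSON-lines: a header record with
#' generation metadata followed by one record per sample.
#'
#' @param groups list of groups; each group is
#'   `list(domain_id = <chr>, thetas = <list of theta_params>)`.
#' @param draws_per_set images drawn per parameter set.
#' @param master_seed integer master seed.
#' @param out_dir output directory (created if needed).
#' @param bits image bit depth (8 or 16).
#' @return an object of class `dataset_manifest` (invisible file paths in
#'   `$records`).
#' @export
assemble_dataset <- function(groups, draws_per_set, master_seed, out_dir,
                             bits = 8L) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory: ", out_dir)
  records <- vector("list", sum(vapply(groups, function(g) length(g$thetas),
                                       integer(1))) * draws_per_set)
  ri <- 0L
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    for (ti in seq_along(g$thetas)) {
      theta <- g$thetas[[ti]]
      assert_theta(theta)
      for (d in seq_len(draws_per_set)) {
        seed <- derive_seed(master_seed, gi, ti, d)
        smp <- generate_sample(theta, seed)
        stem <- sprintf("g%03d_s%02d_d%02d", gi, ti, d)
        img_path <- file.path(out_dir, paste0(stem, ".tif"))
        msk_path <- file.path(out_dir, paste0(stem, "_masks.tif"))
        write_image(smp$image, img_path, bits = bits)
        write_mask_stack(smp$masks, msk_path)
        ri <- ri + 1L
        records[[ri]] <- list(image = basename(img_path),
                              masks = basename(msk_path),
                              domain_id = g$domain_id %||% as.character(gi),
                              theta_id = ti, draw = d, seed = seed,
                              theta = unclass(theta))
      }
    }
  }
  manifest <- structure(list(
    header = list(package = "filamentsim",
                  version = as.character(utils::packageVersion("filamentsim")),
                  master_seed = master_seed, draws_per_set = draws_per_set,
                  n_records = ri, bits = bits),
    records = records[seq_len(ri)]), class = "dataset_manifest")
  write_manifest(manifest, file.path(out_dir, "manifest.jsonl"))
  manifest
}

#' Write / read a dataset manifest (JSON-lines)
#'
#' @param manifest a `dataset_manifest`.
#' @param path `.jsonl` file path.
#' @export
write_manifest <- function(manifest, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(c(list(record = "header"), manifest$header),
                              auto_unbox = TRUE, digits = NA), con)
  for (r in manifest$records)
    writeLines(jsonlite::toJSON(c(list(record = "sample"), r),
                                auto_unbox = TRUE, digits = NA), con)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  lines <- readLines(path)
  parsed <- lapply(lines, jsonlite::fromJSON)
  kinds <- vapply(parsed, function(x) x$record, character(1))
  header <- parsed[[which(kinds == "header")[1]]]
  header$record <- NULL
  records <- lapply(parsed[kinds == "sample"], function(x) { x$record <- NULL; x })
  structure(list(header = header, records = records),
            class = "dataset_manifest")
}

#' @export
print.dataset_manifest <- function(x, ...) {
  cat("<dataset_manifest>", length(x$records), "records, master seed",
      x$header$master_seed, "\n")
  invisible(x)
}
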