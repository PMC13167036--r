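test_that("anchor length sums consecutive Euclidean distances", {
  expect_equal(anchor_length(anchor_chain(rbind(c(0, 0), c(3, 4)))), 5)
  expect_equal(anchor_length(anchor_chain(rbind(c(2, 2), c(2, 2), c(2, 2)))), 0)
  set.seed(121)
  p <- cbind(runif(10, 0, 50), runif(10, 0, 50))
  oracle <- sum(sqrt(rowSums((p[-1, ] - p[-10, ])^2)))
  expect_equal(anchor_length(anchor_chain(p)), oracle, tolerance = 1e-12)
  expect_error(anchor_chain(matrix(c(1, 1), 1)), ">= 2")
})

test_that("two-anchor chains rasterize identically via spline and lines", {
  set.seed(122)
  for (i in 1:100) {
    ch <- anchor_chain(cbind(runif(2, 1, 18), runif(2, 1, 18)))
    expect_identical(anchors_to_mask_spline(ch, 20, 20),
                     anchors_to_mask_lines(ch, 20, 20))
  }
})

test_that("collinear anchors give a mask hugging the line", {
  ch <- anchor_chain(rbind(c(2, 3), c(10, 7), c(18, 11), c(26, 15), c(34, 19)))
  m <- anchors_to_mask_spline(ch, 30, 40)
  pts <- skeleton_points(m)  # all set pixels here, mask is thin
  # distance from each set pixel center to the line y = x/2 + 2
  d <- abs(pts[, 2] - (pts[, 1] / 2 + 2)) / sqrt(1 + 0.25)
  expect_lt(max(d), 0.5 + 1e-9)
})

test_that("an L-shaped 3-anchor chain equals the union of segment oracles", {
  ch <- anchor_chain(rbind(c(2, 2), c(2, 12), c(14, 12)))
  m <- anchors_to_mask_lines(ch, 18, 18)
  o1 <- oracle_rasterize(rbind(c(2, 2), c(2, 12)), 18, 18)
  o2 <- oracle_rasterize(rbind(c(2, 12), c(14, 12)), 18, 18)
  expect_identical(m, o1 | o2)
  # closed loops are allowed
  loop <- anchor_chain(rbind(c(2, 2), c(10, 2), c(10, 10), c(2, 2)))
  expect_true(any(anchors_to_mask_lines(loop, 14, 14)))
})

test_that("random in-bounds chains give nonempty in-canvas spline masks", {
  set.seed(123)
  for (i in 1:25) {
    n <- sample(2:6, 1)
    ch <- anchor_chain(cbind(runif(n, 2, 28), runif(n, 2, 28)))
    m <- anchors_to_mask_spline(ch, 31, 31)
    expect_true(any(m))
    expect_equal(dim(m), c(31, 31))
  }
  expect_error(anchors_to_mask_spline(
    anchor_chain(rbind(c(3, 3), c(3, 3))), 10, 10), "degenerate")
})

test_that("normalization preserves the instance count for all dialects", {
  a <- bar_mask(20, 20, 3, 3, 10, 2)
  b <- bar_mask(20, 20, 10, 3, 10, 2)
  ps <- prediction_set(mask_stack(list(a, b)), "stack", c(20, 20))
  expect_identical(normalize_predictions(ps), mask_stack(list(a, b)))

  map <- matrix(0L, 20, 20); map[3, 3:8] <- 1L; map[10, 3:8] <- 2L
  pl <- prediction_set(map, "labels", c(20, 20))
  expect_length(normalize_predictions(pl), 2)

  chains <- list(anchor_chain(rbind(c(2, 2), c(12, 2))),
                 anchor_chain(rbind(c(2, 8), c(12, 8))),
                 anchor_chain(rbind(c(2, 14), c(12, 14))))
  pa <- prediction_set(chains, "anchors", c(20, 20))
  st <- normalize_predictions(pa)
  expect_length(st, 3)
  expect_equal(n_instances(pa), 3)
  # order preserved: slice i covers chain i's row
  expect_true(st[[1]][3, 5]); expect_true(st[[2]][9, 5]); expect_true(st[[3]][15, 5])

  expect_error(prediction_set(map, "stack", c(20, 20)), "dialect")
})

test_that("GT thresholds match exhaustive scans and honor the margin", {
  one <- bar_mask(30, 30, 5, 3, 12, 1)
  th0 <- compute_gt_thresholds(mask_stack(list(one)), margin = 0)
  expect_equal(th0$min_length, 12); expect_equal(th0$max_length, 12)
  expect_equal(th0$min_area, 12); expect_equal(th0$max_area, 12)

  g <- mask_stack(list(bar_mask(40, 40, 3, 3, 10, 1),
                       bar_mask(40, 40, 13, 3, 20, 1),
                       bar_mask(40, 40, 23, 3, 30, 1)))
  th0 <- compute_gt_thresholds(g, margin = 0)
  expect_equal(c(th0$min_length, th0$max_length), c(10, 30))
  th10 <- compute_gt_thresholds(g, margin = 0.1)
  expect_equal(c(th10$min_length, th10$max_length), c(9, 33))

  set.seed(124)
  rnd <- mask_stack(lapply(1:5, function(i) random_blob_mask(25, 25)))
  th0 <- compute_gt_thresholds(rnd, margin = 0)
  lens <- vapply(rnd, function(m) sum(skeletonize(m)), numeric(1))
  areas <- vapply(rnd, sum, numeric(1))
  expect_equal(c(th0$min_length, th0$max_length), range(lens))
  expect_equal(c(th0$min_area, th0$max_area), range(areas))
  expect_error(compute_gt_thresholds(mask_stack()), "empty")
})

test_that("postprocessing filters by the stated rules and is idempotent", {
  mk <- function(len) bar_mask(60, 60, len %% 50 + 2, 3, len, 1)
  stack <- mask_stack(lapply(c(5, 12, 20, 28, 45), mk))
  th <- list(min_length = 10, max_length = 30, min_area = 10, max_area = 30)
  class(th) <- "gt_thresholds"
  ps <- prediction_set(stack, "stack", c(60, 60))
  out <- unified_postprocess(ps, th)
  expect_equal(n_instances(out), 3)  # 5 and 45 fall outside
  out2 <- unified_postprocess(out, th)
  expect_identical(out2$payload, out$payload)

  # all instances within bounds -> unchanged
  wide <- list(min_length = 0, max_length = 100, min_area = 0, max_area = 100)
  class(wide) <- "gt_thresholds"
  expect_length(unified_postprocess(ps, wide)$payload, 5)

  # anchor dialect ignores area bounds entirely
  narrow_area <- list(min_length = 10, max_length = 30,
                      min_area = 0, max_area = 1)
  class(narrow_area) <- "gt_thresholds"
  chains <- list(anchor_chain(rbind(c(2, 2), c(22, 2))))   # length 20
  pa <- prediction_set(chains, "anchors", c(60, 60))
  expect_length(unified_postprocess(pa, narrow_area)$payload, 1)
})

test_that("survivors keep their original order", {
  stack <- mask_stack(list(bar_mask(60, 60, 5, 3, 20, 1),
                           bar_mask(60, 60, 15, 3, 5, 1),
                           bar_mask(60, 60, 25, 3, 25, 1)))
  th <- list(min_length = 10, max_length = 30, min_area = 10, max_area = 30)
  class(th) <- "gt_thresholds"
  out <- normalize_predictions(
    unified_postprocess(prediction_set(stack, "stack", c(60, 60)), th))
  expect_identical(out[[1]], stack[[1]])
  expect_identical(out[[2]], stack[[3]])
})

test_that("preprocessing steps behave as documented", {
  set.seed(125)
  img <- matrix(runif(100, 0.2, 0.7), 10, 10)
  expect_identical(preprocess_image(img, list()), img)
  mm <- preprocess_image(img, list("minmax"))
  expect_equal(range(mm), c(0, 1))
  expect_equal(preprocess_image(img, list("invert", "invert")), img,
               tolerance = 1e-15)
  rgb <- preprocess_image(img, list("gray2rgb"))
  expect_equal(dim(rgb), c(10, 10, 3))
  sm <- preprocess_image(img, list(list(step = "denoise", sigma = 1)))
  expect_lt(sd(sm), sd(img))
  st <- preprocess_image(img, list(list(step = "stretch", p_low = 5, p_high = 95)))
  expect_gte(min(st), 0); expect_lte(max(st), 1)
  expect_error(preprocess_image(img, list("sharpen")), "unknown")
})

test_that("anchor chains round-trip through CSV and JSON", {
  set.seed(126)
  chains <- lapply(1:3, function(i)
    anchor_chain(cbind(runif(4, 0, 30), runif(4, 0, 30))))
  pcsv <- withr::local_tempfile(fileext = ".csv")
  write_anchor_chains(chains, pcsv)
  back <- read_anchor_chains(pcsv)
  expect_length(back, 3)
  for (i in 1:3)
    expect_equal(unclass(back[[i]]), unclass(chains[[i]]),
                 tolerance = 1e-12, ignore_attr = TRUE)

  pjson <- withr::local_tempfile(fileext = ".json")
  write_anchor_chains(chains, pjson)
  back <- read_anchor_chains(pjson)
  for (i in 1:3)
    expect_equal(unclass(back[[i]]), unclass(chains[[i]]),
                 tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("labeled maps round-trip through integer TIFF", {
  map <- matrix(0L, 12, 12)
  map[3, 2:9] <- 1L; map[7, 2:9] <- 2L; map[10, 2:9] <- 7L
  path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(map / 255, path, bits.per.sample = 8L)
  back <- read_labeled_map(path)
  expect_identical(back, map)
})
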