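test_that("mask length is the skeleton pixel count, scaled by pixel size", {
  line <- bar_mask(15, 15, 8, 3, 10, 1)
  expect_equal(mask_length(line)$length_px, 10)
  expect_equal(mask_length(line, pixel_size_um = 0.1)$length_um, 1.0)
  thick <- bar_mask(20, 30, 9, 4, 20, 3)
  expect_lte(abs(mask_length(thick)$length_px - 20), 2)
})

test_that("skeleton ordering starts at an endpoint and visits each pixel once", {
  line <- bar_mask(15, 15, 8, 3, 10, 1)
  path <- order_skeleton_pixels(line)
  expect_equal(nrow(path), 10)
  expect_equal(path[, 1], 2:11)           # x advances in unit steps
  expect_true(all(path[, 2] == 7))

  # L-shaped path vs an exhaustive nearest-neighbor oracle from the start
  L <- matrix(FALSE, 12, 12)
  L[3:9, 3] <- TRUE
  L[9, 3:8] <- TRUE
  path <- order_skeleton_pixels(L)
  pts <- skeleton_points(L)
  expect_equal(nrow(path), nrow(pts))
  expect_setequal(paste(path[, 1], path[, 2]), paste(pts[, 1], pts[, 2]))
  # consecutive steps are 8-neighbor moves along the L
  steps <- sqrt(diff(path[, 1])^2 + diff(path[, 2])^2)
  expect_true(all(steps <= sqrt(2) + 1e-12))
})

test_that("interpolating fit reproduces knots; 2-point path is linear", {
  set.seed(71)
  pts <- cbind(cumsum(runif(8, 0.5, 2)), cumsum(rnorm(8)))
  curve <- fit_curve(pts)
  at <- curve_eval(curve, curve$u)
  expect_equal(at[, 1], pts[, 1], tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(at[, 2], pts[, 2], tolerance = 1e-9, ignore_attr = TRUE)

  two <- fit_curve(rbind(c(0, 0), c(3, 4)))
  expect_equal(as.numeric(curve_eval(two, 2.5)), c(1.5, 2), tolerance = 1e-12)
  expect_true(all(curve_eval(two, seq(0, 5, by = 0.5), deriv = 2) == 0))
  expect_error(fit_curve(rbind(c(1, 1), c(1, 1))), "degenerate")
})

test_that("dense analytic circle: fit deviates < 0.1 px, curvature = 1/R", {
  R <- 50
  t <- seq(0, 2 * pi, length.out = 300)[-300]
  pts <- cbind(R * cos(t) + 60, R * sin(t) + 60)
  curve <- fit_curve(pts)
  g <- seq(curve$u_range[1], curve$u_range[2], length.out = 500)
  xy <- curve_eval(curve, g)
  radial <- sqrt((xy[, 1] - 60)^2 + (xy[, 2] - 60)^2)
  expect_lt(max(abs(radial - R)), 0.1)

  expect_equal(mean_curvature(curve, n_samples = 400), 1 / R, tolerance = 0.02)
})

test_that("curvature scaling law: radius 25 vs 50 gives ratio 2", {
  mk <- function(R) {
    t <- seq(0, 2 * pi, length.out = 400)[-400]
    fit_curve(cbind(R * cos(t), R * sin(t)))
  }
  k25 <- mean_curvature(mk(25), n_samples = 400)
  k50 <- mean_curvature(mk(50), n_samples = 400)
  expect_equal(k25 / k50, 2, tolerance = 0.02)
})

test_that("straight lines have vanishing measured curvature", {
  line <- fit_curve(cbind(seq(0, 40, by = 0.5), seq(0, 80, by = 1)))
  expect_lt(mean_curvature(line, n_samples = 200), 1e-8)
})

test_that("digital circle masks recover 1/R within 2% through the full chain", {
  for (R in c(25, 50)) {
    k <- instance_curvature(ring_mask(R))$curv_px
    expect_equal(k, 1 / R, tolerance = 0.02, label = paste("R =", R))
  }
  # axis-aligned digital straight line
  line <- bar_mask(15, 60, 8, 3, 50, 1)
  expect_lt(instance_curvature(line)$curv_px, 1e-8)
})

test_that("mask curvature is invariant under rotation within 3%", {
  R <- 30
  base <- instance_curvature(ring_mask(R))$curv_px
  # rotating a circle is a no-op; rotate an S-curve instead
  mk_s <- function(angle) {
    t <- seq(0, 4 * pi, length.out = 600)
    x0 <- t * 8; y0 <- 25 * sin(t / 2)
    x <- x0 * cos(angle) - y0 * sin(angle)
    y <- x0 * sin(angle) + y0 * cos(angle)
    x <- x - min(x) + 5; y <- y - min(y) + 5
    h <- ceiling(max(y)) + 6; w <- ceiling(max(x)) + 6
    filamentsim:::dilate_mask(rasterize_polyline(cbind(x, y), h, w), 1L)
  }
  k0 <- instance_curvature(mk_s(0))$curv_px
  for (a in c(0.4, 1.2)) {
    ka <- instance_curvature(mk_s(a))$curv_px
    expect_equal(ka, k0, tolerance = 0.03, label = paste("angle", a))
  }
  expect_equal(base, 1 / R, tolerance = 0.02)
})

test_that("KL divergence matches the closed-form two-bin case", {
  # P = (0.5, 0.5), Q = (0.25, 0.75) on two shared bins
  p <- c(rep(0.25, 50), rep(0.75, 50))
  q <- c(rep(0.25, 25), rep(0.75, 75))
  expected <- 0.5 * log(2) + 0.5 * log(2 / 3)
  expect_equal(kl_divergence(p, q, n_bins = 2), expected, tolerance = 1e-6)
  expect_equal(expected, 0.1438, tolerance = 5e-4)  # printed reference value

  expect_equal(kl_divergence(p, p, n_bins = 2), 0, tolerance = 1e-9)
  expect_equal(kl_divergence(rnorm(100), rnorm(100)) >= -1e-12, TRUE)
})

test_that("KL is asymmetric, non-negative, and zero iff histograms agree", {
  p <- c(rep(0.25, 50), rep(0.75, 50))
  q <- c(rep(0.25, 25), rep(0.75, 75))
  expect_false(isTRUE(all.equal(kl_divergence(p, q, 2), kl_divergence(q, p, 2))))
  set.seed(81)
  for (i in 1:20) {
    a <- runif(60); b <- runif(60)
    expect_gte(kl_divergence(a, b), -1e-12)
  }
  # same binned histogram, different samples -> 0 up to smoothing
  a <- c(0.1, 0.6); b <- c(0.15, 0.65)
  expect_lt(kl_divergence(a, b, n_bins = 2), 1e-9)
})

test_that("simulator consistency: straight filaments measure straight", {
  th <- quiet_theta(h = 200, w = 200, count = 1, len = 120)
  th$bend_scale <- 1e-9
  th$fil_len_sd <- 0
  found <- 0
  for (seed in 1:40) {
    s <- generate_sample(th, seed)
    if (length(s$masks) != 1) next
    p <- filament_to_polyline(s$scene$filaments[[1]])
    in_canvas <- all(p[, 1] >= 1 & p[, 1] <= 198 & p[, 2] >= 1 & p[, 2] <= 198)
    if (!in_canvas) next  # clipped filaments cannot recover L
    found <- found + 1
    expect_lt(instance_curvature(s$masks[[1]])$curv_px, 1e-3)
    # geometric length: arc length of the fitted centerline curve
    path <- order_skeleton_pixels(skeletonize(s$masks[[1]]))
    curve <- fit_curve(path, method = "smoothing")
    g <- seq(curve$u_range[1], curve$u_range[2], length.out = 1000)
    xy <- curve_eval(curve, g)
    arc <- sum(sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2))
    expect_lt(abs(arc - th$fil_len_mean) / th$fil_len_mean, 0.05)
    if (found >= 5) break
  }
  expect_gte(found, 3)
})

test_that("bio summary is exact on hand-built stacks and self-consistent", {
  l10 <- bar_mask(40, 40, 5, 3, 10, 1)
  l20 <- bar_mask(40, 40, 15, 3, 20, 1)
  l30 <- bar_mask(40, 40, 25, 3, 30, 1)
  stacks <- list(list(l10, l20), list(l30))
  s <- summarize_bio(stacks, stacks)
  expect_equal(unname(s$gt$count["mean"]), 1.5)
  expect_equal(unname(s$gt$count["sd"]), sd(c(2, 1)))
  expect_equal(unname(s$gt$length["mean"]), mean(c(10, 20, 30)))
  expect_equal(unname(s$gt$length["sd"]), sd(c(10, 20, 30)))
  expect_equal(s$kl_length, 0, tolerance = 1e-9)
  expect_equal(s$kl_curvature, 0, tolerance = 1e-9)
  # report schema carries the count / length / curvature / KL columns
  expect_named(s, c("units", "pred", "gt", "kl_length", "kl_curvature"))
  expect_named(s$pred, c("count", "length", "curvature"))
})

test_that("length in micrometers scales linearly with pixel size", {
  l20 <- bar_mask(40, 40, 15, 3, 20, 1)
  stacks <- list(list(l20))
  s1 <- summarize_bio(stacks, stacks, pixel_size_um = 0.1)
  s2 <- summarize_bio(stacks, stacks, pixel_size_um = 0.2)
  expect_equal(unname(s2$gt$length["mean"]) / unname(s1$gt$length["mean"]), 2)
})
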