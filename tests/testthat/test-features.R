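# features: FS1 Fourier contour descriptors, FS2 shape descriptors,
# FS3 weighted orientation histograms.

test_that("FS1: circle descriptors are near zero and dimensions are right", {
  disk <- raster_ellipse(120, 120, c(60, 60), 40, 40)
  d <- fourier_descriptors(disk, 20)
  expect_length(d, 20)
  expect_true(all(d <= 0.02))
  expect_named(d, sprintf("fs1_%02d", 0:19))
})

test_that("FS1 invariances hold by construction at the contour level", {
  set.seed(17)
  for (i in 1:10) {
    m <- raster_blob(200, 200, c(100, 100), 60, seed = i)
    poly <- herbleaf:::mask_contour(m)
    d0 <- herbleaf:::contour_fourier_descriptors(poly, 20)
    th <- runif(1, 0, 2 * pi); sc <- runif(1, 0.5, 3); tr <- runif(2, -40, 40)
    R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2)
    poly_t <- sweep(sc * t(R %*% t(poly)), 2, tr, "+")
    shift <- sample(nrow(poly), 1)
    poly_t <- poly_t[c(shift:nrow(poly_t), seq_len(shift - 1)), ]
    d1 <- herbleaf:::contour_fourier_descriptors(poly_t, 20)
    expect_lt(sqrt(sum((d0 - d1)^2)) / sqrt(sum(d0^2)), 1e-3)
  }
})

test_that("FS1 is robust to re-rasterisation at the pixel-sampling noise level", {
  # rotating/scaling the *mask* re-rasterises the shape; binary pixel
  # sampling leaves ~1e-3 per-descriptor noise that no contour estimator
  # can remove, so the attainable tolerance here is 1e-2 (see vignette)
  m1 <- raster_ellipse(260, 260, c(130, 130), 80, 40)
  m2 <- raster_ellipse(500, 500, c(247, 255), 160, 80, 37)
  d1 <- fourier_descriptors(m1); d2 <- fourier_descriptors(m2)
  expect_lt(sqrt(sum((d1 - d2)^2)) / sqrt(sum(d1^2)), 1e-2)
})

test_that("FS1 ellipse coefficient matches a direct-summation DFT oracle", {
  m <- raster_ellipse(300, 300, c(150, 150), 80, 40)
  d <- fourier_descriptors(m, 20)
  # oracle: brute-force DFT of the analytic ellipse contour resampled
  # uniformly in arc length (matching the descriptor's parameterisation)
  Nd <- 32768L
  td <- 2 * pi * (seq_len(Nd) - 1) / Nd
  dense <- complex(real = 80 * cos(td), imaginary = 40 * sin(td))
  seg <- Mod(diff(c(dense, dense[1])))
  cum <- c(0, cumsum(seg))
  N <- 4096L
  s <- seq(0, cum[Nd + 1], length.out = N + 1L)[seq_len(N)]
  ix <- findInterval(s, cum, rightmost.closed = TRUE)
  frac <- (s - cum[ix]) / seg[ix]
  nxt <- ifelse(ix == Nd, 1L, ix + 1L)
  z <- dense[ix] * (1 - frac) + dense[nxt] * frac
  dft <- function(m_) sum(z * exp(-2i * pi * m_ * (seq_len(N) - 1) / N)) / N
  want <- Mod(dft(-1)) / Mod(dft(1))
  # frequency -1 is the 10th descriptor in the (-10..-1, 2..11) layout
  expect_equal(unname(d["fs1_09"]), want, tolerance = 0.01)
})

test_that("FS2 closed forms: circle, square, L-shape, triangle", {
  disk <- raster_ellipse(120, 120, c(60, 60), 40, 40)
  s <- shape_descriptors(disk)
  expect_gt(s[1], 0.95); expect_lt(s[1], 1.05)   # compactness
  expect_gt(s[2], 0.98); expect_lt(s[2], 1.02)   # convexity
  expect_gte(s[3], 0.98)                          # solidity
  expect_gte(s[9], 1.0); expect_lt(s[9], 1.05)    # dispersion

  sq <- matrix(FALSE, 70, 70); sq[11:60, 11:60] <- TRUE
  s <- shape_descriptors(sq)
  expect_gte(s[4], 0.98)                          # rectangularity
  expect_gte(s[3], 0.98)
  expect_equal(unname(s[7]), 1.0)                 # slimness

  L <- matrix(FALSE, 120, 120)
  L[11:110, 11:110] <- TRUE; L[11:60, 61:110] <- FALSE
  expect_equal(unname(shape_descriptors(L)[3]), 6 / 7, tolerance = 0.02)

  tri <- matrix(FALSE, 110, 140)
  for (r in 11:100) {
    w <- (r - 10) * 0.6
    tri[r, round(70 - w):round(70 + w)] <- TRUE
  }
  expect_lte(unname(shape_descriptors(tri)[8]), 0.05)  # widest at base

  expect_error(shape_descriptors(matrix(FALSE, 5, 5)), "empty")
})

make_normleaf <- function(image, mask, vein_column) {
  bb <- herbleaf:::mask_bbox(mask)
  structure(list(image = image, mask = mask,
                 vein_column = vein_column,
                 base_row = as.integer(bb["rmax"]),
                 tip_row = as.integer(bb["rmin"])),
            class = "herb_normleaf")
}

test_that("FS3 peaks at 90 degrees for vertical-line leaves", {
  # flank pixels next to a line legitimately collect oblique responses
  # (their best-matching template crosses the dark line), so the 90-degree
  # bin holds the dominant but not near-total mass; see the vignette
  img <- matrix(0.9, 80, 61)
  for (cc in seq(11, 51, by = 6)) img[11:70, cc] <- 0.1
  mask <- matrix(FALSE, 80, 61); mask[6:75, 6:56] <- TRUE
  nl <- make_normleaf(img, mask, 31L)
  lm <- line_response_multiscale(img, 24, 15, 3)
  fs3 <- orientation_histograms(lm, nl, 24)
  expect_length(fs3, 48)
  bin90 <- which(180 * (0:23) / 24 == 90)
  expect_equal(unname(which.max(fs3[1:24])), bin90)   # upper half peak
  expect_equal(unname(which.max(fs3[25:48])), bin90)  # lower half peak
  expect_gte(fs3[bin90], 0.4)
  expect_gte(fs3[24 + bin90], 0.4)
  expect_equal(sum(fs3[1:24]), 1, tolerance = 1e-9)
  expect_equal(sum(fs3[25:48]), 1, tolerance = 1e-9)
})

test_that("FS3 separates known lower/upper vein angles with hand-applied mirroring", {
  # left side: 45 deg lines below, 75 deg above; right side mirrored
  H <- 121; W <- 101; vc <- 51L
  img <- matrix(0.9, H, W)
  stamp <- function(img, r0, c0, ang, len = 28) {
    th <- ang * pi / 180
    k <- seq(0, len, by = 0.25)
    rr <- r0 - k * sin(th); cc <- c0 + k * cos(th)
    V <- herbleaf:::stamp_points(matrix(0, H, W), rr, cc)
    img - 0.8 * pmin(V, 1)
  }
  for (r0 in seq(75, 110, by = 9)) {
    img <- stamp(img, r0, vc - 34, 45)            # lower left: 45
    img <- stamp(img, r0, vc + 34, 180 - 45)      # lower right: mirror
  }
  for (r0 in seq(18, 52, by = 9)) {
    img <- stamp(img, r0, vc - 34, 75)            # upper left: 75
    img <- stamp(img, r0, vc + 34, 180 - 75)      # upper right: mirror
  }
  mask <- matrix(FALSE, H, W); mask[6:115, 6:95] <- TRUE
  nl <- make_normleaf(img, mask, vc)
  lm <- line_response_multiscale(img, 24, 15, 1)
  fs3 <- orientation_histograms(lm, nl, 24)
  centers <- 180 * (0:23) / 24
  peak_upper <- centers[which.max(fs3[1:24])]
  peak_lower <- centers[which.max(fs3[25:48])]
  expect_equal(peak_lower, 45)
  expect_equal(peak_upper, 75)
})

test_that("FS3 is exactly invariant to mirroring the leaf about the vein column", {
  set.seed(23)
  img <- matrix(runif(80 * 81, 0.3, 0.9), 80, 81)
  mask <- raster_ellipse(80, 81, c(40, 41), 36, 30)
  nl <- make_normleaf(img, mask, 41L)
  lm <- line_response_multiscale(img, 24, 15, 1)
  # mirror image and mask about the vein column
  img_m <- img[, ncol(img):1]
  mask_m <- mask[, ncol(mask):1]
  nl_m <- make_normleaf(img_m, mask_m, 41L)
  lm_m <- line_response_multiscale(img_m, 24, 15, 1)
  a <- orientation_histograms(lm, nl, 24)
  b <- orientation_histograms(lm_m, nl_m, 24)
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("FS3 conservation: quadrant totals equal summed positive strength", {
  sp <- leaf_spec("t", angle_lower = 40, angle_upper = 60, noise_sd = 0.02)
  lf <- render_leaf(sp, 4)
  nl <- normalize_leaf(lf$image, cleanup_mask(lf$mask), lf$petiole)
  lm <- line_response_multiscale(nl$image, 24, 15, 3)
  q <- herbleaf:::quadrant_histograms(lm, nl, 24)
  S <- pmax(lm$strength, 0)
  mid <- (nl$tip_row + nl$base_row) / 2
  # accumulation runs over the per-scale template-eroded mask (margin
  # responses describe the outline, not the venation)
  emask <- herbleaf:::fs3_accumulation_mask(lm, nl$mask)
  idx <- which(emask, arr.ind = TRUE)
  w <- S[emask]
  sel <- list(
    upper_left = idx[, 1] <= mid & idx[, 2] < nl$vein_column,
    upper_right = idx[, 1] <= mid & idx[, 2] > nl$vein_column,
    lower_left = idx[, 1] > mid & idx[, 2] < nl$vein_column,
    lower_right = idx[, 1] > mid & idx[, 2] > nl$vein_column)
  for (nm in names(sel))
    expect_equal(sum(q[[nm]]), sum(w[sel[[nm]]]), tolerance = 1e-6)
})

test_that("extract_all returns a deterministic 77-vector with named blocks", {
  disk_img <- matrix(0.8, 120, 120)
  disk <- raster_ellipse(120, 120, c(60, 60), 45, 38)
  disk_img[disk] <- 0.5
  nl <- make_normleaf(disk_img, disk, 60L)
  v1 <- extract_all(nl)
  v2 <- extract_all(nl)
  expect_length(v1, 77)
  expect_identical(unclass(v1), unclass(v2))
  expect_equal(sum(startsWith(names(v1), "fs1_")), 20)
  expect_equal(sum(startsWith(names(v1), "fs2_")), 9)
  expect_equal(sum(startsWith(names(v1), "fs3_")), 48)
})

test_that("same-species renders are closer in feature space than cross-species", {
  cfg <- pipeline_config()
  specs <- list(
    a = leaf_spec("a", family = "elliptic", width_frac = 0.25,
                  angle_lower = 30, angle_upper = 30),
    b = leaf_spec("b", family = "obovate", width_frac = 0.40,
                  angle_lower = 65, angle_upper = 40))
  fv <- function(sp, seed) {
    lf <- render_leaf(sp, seed)
    unclass(herbleaf:::features_from_leaf(lf$image, cleanup_mask(lf$mask),
                                          lf$petiole, cfg))
  }
  fa <- t(vapply(1:5, function(s) fv(specs$a, s), numeric(77)))
  fb <- t(vapply(1:5, function(s) fv(specs$b, s), numeric(77)))
  all_f <- rbind(fa, fb)
  mu <- colMeans(all_f); sdv <- pmax(apply(all_f, 2, sd), 1e-12)
  za <- sweep(sweep(fa, 2, mu), 2, sdv, "/")
  zb <- sweep(sweep(fb, 2, mu), 2, sdv, "/")
  within <- mean(dist(za)) + mean(dist(zb))
  between <- mean(sqrt(rowSums((za[rep(1:5, 5), ] - zb[rep(1:5, each = 5), ])^2)))
  expect_lt(within / 2, between)
})
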