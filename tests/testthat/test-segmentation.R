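# segmentation: scribble colour models, exact graph-cut minimisation,
# mask cleanup.

test_that("fit_color_model recovers exact scribbled colours", {
  img <- matrix(0.2, 6, 6); img[, 4:6] <- 0.9
  scr <- matrix(128L, 6, 6); scr[3, 5] <- 255L; scr[3, 1] <- 0L
  m <- fit_color_model(img, scr, K = 4)
  expect_equal(nrow(m$fg_centers), 1L)
  expect_equal(unname(m$fg_centers[1, ]), rep(0.9, 3))
  expect_equal(unname(m$bg_centers[1, ]), rep(0.2, 3))
  expect_error(fit_color_model(img, matrix(128L, 6, 6)), "foreground")
  scr2 <- matrix(128L, 6, 6); scr2[1, 1] <- 255L
  expect_error(fit_color_model(img, scr2), "background")
})

test_that("K = 1 colour model is the per-side mean", {
  set.seed(42)
  img <- matrix(runif(64), 8, 8)
  scr <- matrix(128L, 8, 8)
  scr[1:2, ] <- 255L; scr[7:8, ] <- 0L
  m <- fit_color_model(img, scr, K = 1)
  expect_equal(unname(m$fg_centers[1, 1]), mean(img[scr == 255L]))
  expect_equal(unname(m$bg_centers[1, 1]), mean(img[scr == 0L]))
})

test_that("K distinct scribble colours give one center per colour", {
  vals <- seq(0.1, 0.8, length.out = 8)
  img <- matrix(rep(vals, 2), 4, 4)
  scr <- matrix(128L, 4, 4)
  scr[1:8] <- 255L; scr[9:16] <- 0L
  m <- fit_color_model(img, scr, K = 8)
  expect_equal(sort(m$fg_centers[, 1]), sort(unique(img[scr == 255L])))
  expect_equal(sort(m$bg_centers[, 1]), sort(unique(img[scr == 0L])))
})

test_that("lazy_snap is exact on a noiseless two-tone image", {
  img <- matrix(0.15, 12, 12); img[3:9, 4:8] <- 0.85
  scr <- matrix(128L, 12, 12); scr[5, 6] <- 255L; scr[1, 1] <- 0L
  m <- lazy_snap(img, scr, K = 2, lambda_smooth = 2)
  expect_identical(m & TRUE, img == 0.85)
  expect_equal(attr(m, "area"), sum(img == 0.85))
})

test_that("lambda = 0 reduces to per-pixel nearest-cluster labelling", {
  set.seed(7)
  img <- matrix(runif(48), 6, 8)
  scr <- matrix(128L, 6, 8)
  scr[1, 1:3] <- 255L; scr[6, 6:8] <- 0L
  m <- lazy_snap(img, scr, K = 3, lambda_smooth = 0)
  model <- fit_color_model(img, scr, 3)
  terms <- herbleaf:::snap_data_terms(img, model)
  want <- terms$D_fg < terms$D_bg
  want[scr == 255L] <- TRUE; want[scr == 0L] <- FALSE
  free <- scr == 128L & abs(terms$D_fg - terms$D_bg) > 1e-12
  expect_identical((m & TRUE)[free], want[free])
})

test_that("lazy_snap achieves the exhaustive global energy minimum", {
  set.seed(11)
  for (trial in 1:25) {
    H <- sample(2:3, 1); W <- sample(2:4, 1)
    img <- matrix(runif(H * W), H, W)
    scr <- matrix(128L, H, W)
    fg <- sample(H * W, 1); bg <- sample(setdiff(seq_len(H * W), fg), 1)
    scr[fg] <- 255L; scr[bg] <- 0L
    lam <- runif(1, 0, 2)
    expect_equal(achieved_snap_energy(img, scr, 2, lam),
                 exhaustive_snap_min(img, scr, 2, lam), tolerance = 1e-10)
  }
})

test_that("increasing lambda does not increase label discontinuities", {
  set.seed(13)
  for (trial in 1:6) {
    img <- matrix(runif(30), 5, 6)
    scr <- matrix(128L, 5, 6); scr[1, 1] <- 0L; scr[5, 6] <- 255L
    n_disc <- function(lam) {
      m <- lazy_snap(img, scr, K = 2, lambda_smooth = lam)
      e <- herbleaf:::snap_edges(img, 1)
      sum(m[e[, "i"]] != m[e[, "j"]])
    }
    d <- vapply(c(0, 0.3, 1, 3, 10), n_disc, 0)
    expect_true(all(diff(d) <= 0))
  }
})

test_that("cleanup_mask keeps the largest component and fills small holes", {
  m <- matrix(FALSE, 10, 10); m[2:4, 2:4] <- TRUE
  expect_identical(cleanup_mask(m) & TRUE, m)

  two <- matrix(FALSE, 20, 20)
  two[2:11, 2:11] <- TRUE            # area 100
  two[15:17, 15:17] <- TRUE; two[15, 17] <- FALSE  # area 8
  out <- cleanup_mask(two)
  expect_true(all(out[2:11, 2:11]))
  expect_false(any(out[15:17, 15:17]))

  # 3-px hole in a large blob (hole < 0.1% of area) is filled;
  # oracle: background components not touching the border
  blob <- raster_ellipse(80, 80, c(40, 40), 35, 35)
  blob[40, 39:41] <- FALSE
  filled <- cleanup_mask(blob)
  bg_lab <- herbleaf:::.label_components_cpp(!filled, 4L)
  border <- unique(c(bg_lab[1, ], bg_lab[80, ], bg_lab[, 1], bg_lab[, 80]))
  expect_equal(setdiff(unique(as.vector(bg_lab)), c(0L, border)), integer(0))
  expect_true(all(filled[40, 39:41]))
  expect_error(cleanup_mask(matrix(FALSE, 3, 3)), "empty")
})

test_that("generous scribbles on a rendered leaf recover the true mask", {
  lf <- render_leaf(leaf_spec("t", noise_sd = 0.02, length_px = 90), seed = 5)
  scr <- matrix(128L, nrow(lf$image), ncol(lf$image))
  erode <- lf$mask & !herbleaf:::gaussian_blur(1 - lf$mask, 2) > 0.05
  core <- which(herbleaf:::gaussian_blur(lf$mask * 1, 3) > 0.95 & lf$mask)
  outside <- which(herbleaf:::gaussian_blur(lf$mask * 1, 3) < 0.05 & !lf$mask)
  set.seed(1)
  scr[sample(core, 200)] <- 255L
  scr[sample(outside, 200)] <- 0L
  m <- cleanup_mask(lazy_snap(lf$image, scr, K = 8, lambda_smooth = 10))
  iou <- sum(m & lf$mask) / sum(m | lf$mask)
  expect_gte(iou, 0.98)
})
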