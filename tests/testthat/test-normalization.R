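# normalization: tip detection, geodesic midvein tracing, cubic fitting,
# straightening.

test_that("detect_tip finds the far extreme along the petiole-centroid ray", {
  ell <- raster_ellipse(100, 60, c(50, 30), 20, 40)  # vertical ellipse
  tip <- detect_tip(ell, petiole = c(90, 30), tip_fraction = 0.02)
  expect_equal(tip[1], 10)
  expect_lt(abs(tip[2] - 30), 2)

  # 100-px vertical bar, fraction 0.02 -> tip region = top 2 px, tip topmost
  bar <- matrix(FALSE, 110, 9); bar[6:105, 5] <- TRUE
  tip <- detect_tip(bar, petiole = c(105, 5), tip_fraction = 0.02)
  expect_equal(unname(tip), c(6, 5))

  expect_error(detect_tip(bar, petiole = c(50, 9)), "bounding box")
})

test_that("trace_main_vein follows the only path in a thin bar", {
  mask <- matrix(FALSE, 30, 7); mask[5:25, 4] <- TRUE
  img <- matrix(0.9, 30, 7); img[5:25, 4] <- 0.2
  lm <- line_response_single_scale(img, 8, 3)
  mv <- trace_main_vein(lm, mask, petiole = c(25, 4), tip = c(5, 4))
  expect_equal(unname(mv$pixels[, "col"]), rep(4, 21))
  expect_equal(unname(mv$pixels[, "row"]), 25:5)
  expect_equal(mv$axis_g$angle, 90)
})

test_that("trace_main_vein cost matches the Bellman-Ford oracle on random grids", {
  set.seed(21)
  for (trial in 1:15) {
    H <- 10; W <- 10
    S <- matrix(runif(H * W), H, W)
    O <- matrix(sample(180 * (0:23) / 24, H * W, TRUE), H, W)
    mask <- matrix(runif(H * W) > 0.12, H, W)
    mask[10, 2] <- TRUE; mask[1, 9] <- TRUE
    lm <- herbleaf:::new_linemap(S, O, 24L, 1L)
    mv <- tryCatch(trace_main_vein(lm, mask, c(10, 2), c(1, 9)),
                   error = function(e) NULL)
    # oracle recomputes the cost field independently from S, O and g
    p <- c(10, 2); tp <- c(1, 9)
    ang <- (atan2(-(tp[1] - p[1]), tp[2] - p[2]) * 180 / pi) %% 180
    sm <- range(S[mask])
    Sn <- (S - sm[1]) / diff(sm)
    d <- abs(O - ang) %% 180
    eps <- (1 - Sn) + pmin(d, 180 - d) / 90
    oc <- bf_path_cost(eps, mask, p, tp)
    if (is.null(mv)) {
      expect_false(is.finite(oc))
    } else {
      expect_equal(mv$cost, oc, tolerance = 1e-10)
      # path is 8-connected, simple, inside the mask, endpoint-correct
      expect_true(all(mask[mv$pixels]))
      expect_true(all(abs(diff(mv$pixels[, 1])) <= 1 & abs(diff(mv$pixels[, 2])) <= 1))
      expect_false(any(duplicated(mv$pixels)))
      expect_equal(unname(mv$pixels[1, ]), p)
      expect_equal(unname(mv$pixels[nrow(mv$pixels), ]), tp)
    }
  }
})

test_that("traced midvein stays within 2 px of the generator's ground truth", {
  for (seed in 1:3) {
    sp <- leaf_spec("t", curvature = c(5, -7, 2), angle_lower = 45,
                    angle_upper = 45, noise_sd = 0)
    lf <- render_leaf(sp, seed)
    lm <- line_response_multiscale(lf$image, 24, 15, 3)
    mv <- trace_main_vein(lm, lf$mask, lf$petiole,
                          detect_tip(lf$mask, lf$petiole))
    truth <- lf$midvein
    dist_to_truth <- vapply(seq_len(nrow(mv$pixels)), function(i) {
      min(sqrt((truth[, 1] - mv$pixels[i, 1])^2 +
               (truth[, 2] - mv$pixels[i, 2])^2))
    }, 0)
    expect_lte(mean(dist_to_truth), 2)
  }
})

test_that("fit_midvein_cubic recovers exact and noisy cubics", {
  path <- cbind(10:60, 25)
  expect_equal(fit_midvein_cubic(path), c(25, 0, 0, 0), tolerance = 1e-9)

  co <- c(3, 0.5, -0.01, 1e-4)
  r <- seq(5, 80, by = 1)
  exact <- cbind(r, herbleaf:::eval_cubic(co, r))
  expect_equal(fit_midvein_cubic(exact), co, tolerance = 1e-6)

  set.seed(8)
  noisy <- cbind(r, herbleaf:::eval_cubic(co, r) + rnorm(length(r), 0, 1))
  fit <- fit_midvein_cubic(noisy)
  resid <- herbleaf:::eval_cubic(fit, r) - noisy[, 2]
  expect_lte(sqrt(mean(resid^2)), 1.5)

  expect_error(fit_midvein_cubic(cbind(c(1, 1, 2, 2), 1:4)), "distinct rows")
})

test_that("straightening an already-straight leaf is the identity up to padding", {
  lf <- render_leaf(leaf_spec("t", curvature = c(0, 0, 0), noise_sd = 0), 3)
  nl <- normalize_leaf(lf$image, lf$mask, lf$petiole)
  expect_equal(herbleaf:::mask_iou(nl$mask, lf$mask), 1.0, tolerance = 0.005)
  expect_lt(nl$tip_row, nl$base_row)
})

test_that("bend + straighten round-trips the mask and re-centers the vein", {
  set.seed(31)
  ious <- numeric(6)
  for (i in 1:6) {
    sp0 <- leaf_spec("t", curvature = c(0, 0, 0), angle_lower = 45,
                     angle_upper = 60, noise_sd = 0.02)
    sp1 <- sp0
    sp1$curvature <- c(runif(1, -8, 8), runif(1, -10, 10), runif(1, -4, 4))
    lf0 <- render_leaf(sp0, i)
    lf1 <- render_leaf(sp1, i)
    nl <- normalize_leaf(lf1$image, cleanup_mask(lf1$mask), lf1$petiole)
    ious[i] <- herbleaf:::mask_iou(nl$mask, lf0$mask)
    # warped mask area within 2% of the bent input's area
    expect_lte(abs(sum(nl$mask) - sum(lf1$mask)) / sum(lf1$mask), 0.02)
  }
  expect_gte(mean(ious), 0.95)
})

test_that("straightening is idempotent (IoU >= 0.99)", {
  sp <- leaf_spec("t", curvature = c(6, -9, 3), noise_sd = 0.02)
  lf <- render_leaf(sp, 12)
  n1 <- normalize_leaf(lf$image, cleanup_mask(lf$mask), lf$petiole)
  n2 <- normalize_leaf(n1$image, n1$mask)
  expect_gte(herbleaf:::mask_iou(n2$mask, n1$mask), 0.99)
})
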