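# Midvein-based normalization. The main vein is traced from the petiole to
# the leaf tip as the minimal-cost geodesic over a cost field that rewards
# high line strength and orientations aligned with the base-tip axis g,
# then approximated by a cubic, and the leaf is warped row by row so the
# midvein becomes a straight vertical line with the tip pointing up.

#' Locate the leaf tip from the segmentation mask
#'
#' All mask pixels are projected onto the ray from the petiole through the
#' mask centroid; the tip region is the outermost `tip_fraction` of the
#' segmented area along that ray (2% by default) and the returned tip is
#' the region's pixel of maximal projection (ties broken toward the
#' smallest row, then column).
#'
#' @param mask logical matrix.
#' @param petiole numeric `(row, col)` of the leaf base.
#' @param tip_fraction fraction in `(0, 0.5)`.
#' @return numeric `(row, col)` of the tip pixel.
#' @export
detect_tip <- function(mask, petiole, tip_fraction = 0.02) {
  stopifnot(tip_fraction > 0, tip_fraction < 0.5)
  bb <- mask_bbox(mask)
  if (is.null(bb)) stop("empty mask")
  if (petiole[1] < bb["rmin"] - 1 || petiole[1] > bb["rmax"] + 1 ||
      petiole[2] < bb["cmin"] - 1 || petiole[2] > bb["cmax"] + 1)
    stop("petiole lies outside the mask bounding box")
  idx <- which(mask, arr.ind = TRUE)
  centroid <- colMeans(idx)
  v <- centroid - petiole
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("petiole coincides with the mask centroid")
  u <- v / nv
  proj <- (idx[, 1] - petiole[1]) * u[1] + (idx[, 2] - petiole[2]) * u[2]
  thr <- stats::quantile(proj, 1 - tip_fraction, names = FALSE)
  region <- proj >= thr
  cand <- idx[region, , drop = FALSE]
  pr <- proj[region]
  best <- which(pr == max(pr))
  if (length(best) > 1L) {
    sub <- cand[best, , drop = FALSE]
    best <- best[order(sub[, 1], sub[, 2])[1]]
  }
  as.numeric(cand[best, ])
}

#' Trace the main vein as a minimal-cost geodesic
#'
#' The per-pixel cost is `(1 - S~) + da~`, where `S~` is the line strength
#' min-max normalised to `[0, 1]` over mask pixels and `da~` is the angle
#' between the local line orientation and the fixed base-tip axis g,
#' normalised by 90 degrees. (The raw combination `-S + delta_alpha` mixes
#' units; normalising both terms to `[0, 1]` is the minimal repair that
#' keeps costs nonnegative so an exact shortest-path search applies.)
#' A step from pixel u to v costs `step_length * (eps(u) + eps(v)) / 2`
#' with `step_length` 1 for axial and `sqrt(2)` for diagonal moves; the
#' 8-connected path inside the mask is found exactly by Dijkstra.
#'
#' @param linemap a `herb_linemap` for the same image.
#' @param mask logical matrix.
#' @param petiole,tip `(row, col)` endpoints; snapped to the nearest mask
#'   pixel when marked just off the lamina.
#' @return object of class `herb_midvein`: `pixels` (n x 2 matrix from
#'   petiole to tip), `axis_g` (endpoints and angle of g in degrees),
#'   `delta_alpha` (per-pixel raster, degrees in `[0, 90]`), `cost`, and
#'   `eps` (the cost raster actually searched).
#' @export
trace_main_vein <- function(linemap, mask, petiole, tip) {
  stopifnot(inherits(linemap, "herb_linemap"),
            all(dim(linemap$strength) == dim(mask)))
  snap <- function(p) {
    pr <- round(p[1]); pc <- round(p[2])
    if (pr >= 1 && pr <= nrow(mask) && pc >= 1 && pc <= ncol(mask) &&
        mask[pr, pc]) return(c(pr, pc))
    idx <- which(mask, arr.ind = TRUE)
    d <- (idx[, 1] - p[1])^2 + (idx[, 2] - p[2])^2
    as.numeric(idx[which.min(d), ])
  }
  p <- snap(petiole); t <- snap(tip)
  angle_g <- (atan2(-(t[1] - p[1]), t[2] - p[2]) * 180 / pi) %% 180

  S <- linemap$strength
  sm <- S[mask]
  rng <- range(sm)
  Sn <- if (diff(rng) > 0) (S - rng[1]) / diff(rng) else S * 0
  da <- angle_diff180(linemap$orientation, angle_g)
  eps <- (1 - Sn) + da / 90

  res <- .grid_dijkstra_cpp(eps, mask, p[1], p[2], t[1], t[2])
  structure(list(pixels = cbind(row = res$row, col = res$col),
                 axis_g = list(petiole = p, tip = t, angle = angle_g),
                 delta_alpha = da, cost = res$cost, eps = eps),
            class = "herb_midvein")
}

#' @export
print.herb_midvein <- function(x, ...) {
  cat(sprintf("herbleaf midvein path: %d pixels, cost %.3f, axis %.1f deg\n",
              nrow(x$pixels), x$cost, x$axis_g$angle))
  invisible(x)
}

#' Fit a cubic to a midvein path
#'
#' Least-squares cubic `col = a0 + a1 row + a2 row^2 + a3 row^3` through
#' the path pixels; intended for paths already expressed in the rotated
#' (axis-vertical) frame. The first and last `trim` fraction of path
#' points are excluded from the fit: near the forced endpoints (the
#' marked petiole and the detected tip pixel) the path traverses
#' outline-dominated territory where no midvein exists, and on
#' blunt-based or blunt-tipped leaves those excursions would otherwise
#' bias the whole fit.
#'
#' @param path n x 2 matrix of `(row, col)` points, or a `herb_midvein`.
#' @param trim fraction of path points dropped at each end (default 2%,
#'   matching the tip-region rule); set 0 to fit all pixels.
#' @return numeric coefficients `c(a0, a1, a2, a3)`.
#' @export
fit_midvein_cubic <- function(path, trim = 0.02) {
  pts <- if (inherits(path, "herb_midvein")) path$pixels else path
  pts <- matrix(as.numeric(pts), ncol = 2)
  n <- nrow(pts)
  k <- floor(trim * n)
  if (k > 0 && n - 2 * k >= 8L)
    pts <- pts[(k + 1):(n - k), , drop = FALSE]
  if (length(unique(round(pts[, 1], 6))) < 4L)
    stop("midvein path spans fewer than 4 distinct rows; cannot fit a cubic")
  r <- pts[, 1]
  fit <- stats::lm.fit(cbind(1, r, r^2, r^3), pts[, 2])
  co <- fit$coefficients
  co[is.na(co)] <- 0
  unname(co)
}

eval_cubic <- function(coef, row) {
  coef[1] + coef[2] * row + coef[3] * row^2 + coef[4] * row^3
}

# Rotation angle (degrees) that maps the petiole->tip direction onto
# "straight up" (decreasing row).
axis_rotation_angle <- function(petiole, tip) {
  v <- c(tip[1] - petiole[1], tip[2] - petiole[2])
  (pi - atan2(v[2], v[1])) * 180 / pi
}

# Rotation parameters shared by the forward point map and the composed
# warp: out = R (in - center) + offset on an expanded canvas.
axis_transform <- function(dims, angle_deg, center) {
  th <- angle_deg * pi / 180
  Rm <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
  corners <- rbind(c(1, 1), c(1, dims[2]), c(dims[1], 1), dims)
  fc <- t(Rm %*% (t(corners) - center))
  rmin <- floor(min(fc[, 1])); rmax <- ceiling(max(fc[, 1]))
  cmin <- floor(min(fc[, 2])); cmax <- ceiling(max(fc[, 2]))
  list(R = Rm, center = center, offset = c(1 - rmin, 1 - cmin),
       dims_out = c(rmax - rmin + 1L, cmax - cmin + 1L))
}

# Single-pass straightening warp: rotation (axis vertical, tip up) and the
# per-row de-bending shear are composed into ONE inverse map so the image
# is resampled only once -- resampling twice visibly blurs 1-2 px veins
# and degrades downstream orientation estimates.
straighten_warp <- function(image, mask, angle_deg, center, cubic, fill,
                            vein_column = NULL, linemap = NULL) {
  tr <- axis_transform(dim(mask), angle_deg, center)
  # leaf row range and vein column in the rotated frame
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask")
  rot_rows <- rotate_points(idx, tr)[, 1]
  rmin <- floor(min(rot_rows)); rmax <- ceiling(max(rot_rows))
  if (is.null(vein_column))
    vein_column <- round(stats::median(eval_cubic(cubic, rmin:rmax)))
  Ho <- tr$dims_out[1]; Wo <- tr$dims_out[2]
  rows <- seq_len(Ho)
  rows_cl <- pmin(pmax(rows, rmin), rmax)   # clamp cubic extrapolation
  shift <- vein_column - eval_cubic(cubic, rows_cl)
  pad_l <- max(0, ceiling(max(shift)))
  pad_r <- max(0, ceiling(max(-shift)))
  Wt <- Wo + pad_l + pad_r
  rr <- rep(rows, times = Wt)
  cc <- rep(seq_len(Wt), each = Ho) - pad_l - shift[rr]
  rel <- rbind(rr - tr$offset[1], cc - tr$offset[2])
  src <- t(tr$R) %*% rel
  sr <- src[1, ] + center[1]; sc <- src[2, ] + center[2]
  img_s <- matrix(bilinear_sample(image, sr, sc, fill), Ho, Wt)
  msk_s <- matrix(nearest_sample(mask * 1, sr, sc, 0), Ho, Wt) > 0.5
  # nearest-neighbour resampling can strand isolated pixels off thin
  # structures (tip, petiole); keep the leaf's main component
  msk_s <- cleanup_mask(msk_s) & TRUE
  bb2 <- mask_bbox(msk_s)
  out <- structure(list(image = img_s, mask = msk_s,
                        vein_column = as.integer(vein_column + pad_l),
                        base_row = as.integer(bb2["rmax"]),
                        tip_row = as.integer(bb2["rmin"]),
                        shift = shift + pad_l),
                   class = "herb_normleaf")
  if (!is.null(linemap)) {
    # carry the line map measured on the crisp original into the
    # normalized frame: strengths and winning scales via nearest
    # neighbour (no interpolation blur), orientations corrected
    # analytically by the local Jacobian of the warp, J = A(row) R with
    # A the row-shear [[1, 0], [shift'(row), 1]]
    S_w <- matrix(nearest_sample(linemap$strength, sr, sc, 0), Ho, Wt)
    O_s <- matrix(nearest_sample(linemap$orientation, sr, sc, 0), Ho, Wt)
    SC_w <- matrix(as.integer(nearest_sample(linemap$scale, sr, sc, 1)), Ho, Wt)
    dshift <- -(cubic[2] + 2 * cubic[3] * rows_cl + 3 * cubic[4] * rows_cl^2)
    dshift[rows < rmin | rows > rmax] <- 0
    th <- as.vector(O_s) * pi / 180
    v <- rbind(-sin(th), cos(th))            # (row, col) direction per pixel
    vr <- tr$R %*% v
    v_row <- vr[1, ]
    v_col <- rep(dshift, times = Wt) * vr[1, ] + vr[2, ]
    O_w <- matrix((atan2(-v_row, v_col) * 180 / pi) %% 180, Ho, Wt)
    attr(out, "linemap") <- new_linemap(S_w, O_w, linemap$n_orientations,
                                        linemap$scales_used,
                                        linemap$template_length, SC_w)
  }
  out
}

#' Straighten a leaf so the midvein is a vertical line
#'
#' Rotates image and mask so the base-tip axis g is vertical with the tip
#' pointing up, then shifts every row horizontally (linear interpolation
#' for the image, nearest-neighbour for the mask) so the fitted midvein
#' cubic becomes the straight column `vein_column`. Pixels leaving the
#' canvas are filled with the median background intensity.
#'
#' @param image numeric matrix (grayscale).
#' @param mask logical matrix.
#' @param petiole,tip `(row, col)` base and tip in the *input* frame.
#' @param cubic coefficients of `col(row)` in the rotated frame
#'   (see [fit_midvein_cubic()]).
#' @param fill background fill; default median of non-mask pixels.
#' @return object of class `herb_normleaf` with `image`, `mask`,
#'   `vein_column`, `base_row`, `tip_row`.
#' @export
straighten <- function(image, mask, petiole, tip, cubic, fill = NULL) {
  if (is.null(fill)) fill <- stats::median(image[!mask])
  ang <- axis_rotation_angle(petiole, tip)
  straighten_warp(image, mask, ang, petiole, cubic, fill)
}

#' Run the full normalization chain on one leaf
#'
#' Computes the multi-scale line map, detects the tip, traces the main
#' vein, rotates the leaf axis vertical, fits the midvein cubic in the
#' rotated frame, and straightens row-wise.
#'
#' @param image numeric matrix or RGB array.
#' @param mask logical matrix.
#' @param petiole optional `(row, col)`; when absent the lowest-row mask
#'   pixel is used (central column among ties), mirroring unattended batch
#'   processing of manifests without marked petioles.
#' @param config a [pipeline_config()].
#' @param linemap optional precomputed `herb_linemap`.
#' @return a `herb_normleaf`; the traced path, fitted cubic, tip and
#'   petiole are attached as attributes `midvein`, `cubic`, `tip`,
#'   `petiole`.
#' @export
normalize_leaf <- function(image, mask, petiole = NULL,
                           config = pipeline_config(), linemap = NULL) {
  gray <- to_gray(image)
  if (is.null(petiole)) petiole <- default_petiole(mask)
  petiole <- snap_to_mask(mask, petiole, max_dist = 10)
  if (is.null(linemap))
    linemap <- line_response_multiscale(gray, config$n_orientations,
                                        config$template_length,
                                        config$n_scales)
  tip <- detect_tip(mask, petiole, config$tip_fraction)
  mv <- trace_main_vein(linemap, mask, petiole, tip)
  fill <- stats::median(gray[!mask])
  ang <- axis_rotation_angle(mv$axis_g$petiole, mv$axis_g$tip)
  tr <- axis_transform(dim(mask), ang, mv$axis_g$petiole)
  path_rot <- rotate_points(mv$pixels, tr)
  cubic <- fit_midvein_cubic(path_rot)
  # refine the rotation with the fitted chord: the detected tip pixel can
  # sit a few px off the true axis, and any residual axis error would be
  # absorbed by the row shear, which (unlike a rotation) distorts left-
  # and right-hand vein angles asymmetrically; folding the chord slope
  # into the rotation keeps the shear purely de-bending
  rr <- range(path_rot[, 1])
  slope <- (eval_cubic(cubic, rr[2]) - eval_cubic(cubic, rr[1])) / diff(rr)
  ang <- ang - atan(slope) * 180 / pi
  tr <- axis_transform(dim(mask), ang, mv$axis_g$petiole)
  cubic <- fit_midvein_cubic(rotate_points(mv$pixels, tr))
  out <- straighten_warp(gray, mask, ang, mv$axis_g$petiole, cubic, fill,
                         linemap = linemap)
  attr(out, "midvein") <- mv
  attr(out, "cubic") <- cubic
  attr(out, "tip") <- tip
  attr(out, "petiole") <- petiole
  out
}

# User-marked petioles often sit a pixel or two off the segmented lamina
# (or segmentation clips the attachment point); snap to the nearest mask
# pixel within max_dist.
snap_to_mask <- function(mask, p, max_dist = 10) {
  pr <- round(p[1]); pc <- round(p[2])
  if (pr >= 1 && pr <= nrow(mask) && pc >= 1 && pc <= ncol(mask) &&
      mask[pr, pc]) return(c(pr, pc))
  idx <- which(mask, arr.ind = TRUE)
  d2 <- (idx[, 1] - p[1])^2 + (idx[, 2] - p[2])^2
  i <- which.min(d2)
  if (d2[i] > max_dist^2)
    stop("petiole point is more than ", max_dist, " px from the mask")
  as.numeric(idx[i, ])
}

# Fallback petiole: lowest mask row, central column among that row's pixels.
default_petiole <- function(mask) {
  bb <- mask_bbox(mask)
  if (is.null(bb)) stop("empty mask")
  cols <- which(mask[bb["rmax"], ])
  c(bb["rmax"], cols[ceiling(length(cols) / 2)])
}

#' @export
print.herb_normleaf <- function(x, ...) {
  cat(sprintf(
    "herbleaf normalized leaf: %d x %d, vein column %d, rows %d (tip) .. %d (base)\n",
    nrow(x$image), ncol(x$image), x$vein_column, x$tip_row, x$base_row))
  invisible(x)
}
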