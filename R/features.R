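# Feature extraction from a normalized leaf: FS1 Fourier contour
# descriptors (20), FS2 classical region-shape descriptors (9), FS3
# strength-weighted vein-orientation histograms (2 x 24).

# Sub-pixel outer contour of a single-component mask via marching squares
# at level 0.5 (the longest contour line wins). The binary raster is
# Gaussian-smoothed first so the level set interpolates the true boundary
# instead of the pixel staircase (without smoothing the staircase inflates
# perimeters by ~4% and injects spurious high-frequency contour energy).
# Returns an n x 2 matrix of (row, col) vertices of a closed polygon
# (last vertex != first; cyclic).
mask_contour <- function(mask, smooth_sigma = 1) {
  m <- pad_matrix(mask * 1, 3, 3, 3, 3, fill = 0)
  if (smooth_sigma > 0) m <- gaussian_blur(m, smooth_sigma)
  cl <- grDevices::contourLines(x = seq_len(nrow(m)), y = seq_len(ncol(m)),
                                z = m, levels = 0.5)
  if (!length(cl)) stop("mask has no contour")
  lens <- vapply(cl, function(p) length(p$x), 0L)
  best <- cl[[which.max(lens)]]
  pts <- cbind(row = best$x - 3, col = best$y - 3)
  if (nrow(pts) > 1 && all(pts[1, ] == pts[nrow(pts), ]))
    pts <- pts[-nrow(pts), , drop = FALSE]
  pts
}

# Resample a closed polygon to n points equally spaced in arc length.
resample_closed <- function(poly, n = 256L) {
  p <- rbind(poly, poly[1, , drop = FALSE])
  seg <- sqrt(rowSums(diff(p)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (total <= 0) stop("degenerate contour")
  s <- seq(0, total, length.out = n + 1L)[seq_len(n)]
  r <- stats::approx(cum, p[, 1], xout = s)$y
  c_ <- stats::approx(cum, p[, 2], xout = s)$y
  cbind(row = r, col = c_)
}

polygon_area <- function(poly) {
  x <- poly[, 2]; y <- poly[, 1]
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

polygon_perimeter <- function(poly) {
  p <- rbind(poly, poly[1, , drop = FALSE])
  sum(sqrt(rowSums(diff(p)^2)))
}

# Minimum-area enclosing rectangle of a point set (rotating calipers over
# the convex hull). Returns the rectangle area.
min_area_rect <- function(points) {
  hull <- points[grDevices::chull(points[, 2], points[, 1]), , drop = FALSE]
  n <- nrow(hull)
  if (n < 3L) {
    ext <- apply(hull, 2, function(v) diff(range(v)))
    return(max(ext[1], 1e-12) * max(ext[2], 1e-12))
  }
  best <- Inf
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    e <- hull[j, ] - hull[i, ]
    le <- sqrt(sum(e^2))
    if (le == 0) next
    e <- e / le
    nrm <- c(-e[2], e[1])
    pe <- hull %*% e
    pn <- hull %*% nrm
    area <- diff(range(pe)) * diff(range(pn))
    if (area < best) best <- area
  }
  best
}

check_single_component <- function(mask) {
  lab <- .label_components_cpp(mask & TRUE, 4L)
  n <- max(lab)
  if (n == 0L) stop("empty mask")
  if (n > 1L) stop("mask has ", n, " components; run cleanup_mask() first")
  invisible(TRUE)
}

#' Fourier contour descriptors (FS1)
#'
#' The outer contour is resampled to 256 equal arc-length points, read as
#' complex numbers `col + i * row`, and Fourier transformed. Descriptors
#' are the coefficient magnitudes at frequencies `-n_desc/2 .. -1` and
#' `2 .. n_desc/2 + 1`, each divided by the magnitude at frequency 1:
#' dropping frequency 0 gives translation invariance, taking magnitudes
#' gives rotation and starting-point invariance, and the division gives
#' scale invariance.
#'
#' @param mask single-component logical matrix.
#' @param n_desc even number of descriptors (20 by default).
#' @param n_points contour resampling resolution.
#' @return named numeric vector `fs1_00 ..`.
#' @export
fourier_descriptors <- function(mask, n_desc = 20L, n_points = 256L) {
  check_single_component(mask)
  poly <- mask_contour(mask)
  if (nrow(poly) < n_desc + 2L) stop("contour too short for ", n_desc, " descriptors")
  contour_fourier_descriptors(poly, n_desc, n_points)
}

# Descriptor computation from a closed contour polygon; the invariances
# (translation, rotation, scale, starting point) hold by construction at
# this level -- rasterising a transformed shape additionally injects
# pixel-sampling noise of order 1e-3 per descriptor (see vignette).
contour_fourier_descriptors <- function(poly, n_desc = 20L, n_points = 256L) {
  stopifnot(n_desc %% 2L == 0L, n_desc >= 2L)
  pts <- resample_closed(poly, n_points)
  z <- complex(real = pts[, 2], imaginary = pts[, 1])
  F <- stats::fft(z) / length(z)
  coef_at <- function(m) F[(m %% n_points) + 1L]
  fund <- Mod(coef_at(1L))
  if (fund == 0) stop("degenerate contour: zero fundamental frequency")
  freqs <- c(seq(-n_desc / 2L, -1L), seq(2L, n_desc / 2L + 1L))
  out <- vapply(freqs, function(m) Mod(coef_at(m)) / fund, 0)
  names(out) <- sprintf("fs1_%02d", seq_along(out) - 1L)
  out
}

#' Classical shape descriptors (FS2)
#'
#' Nine region-shape measures of the (tip-up, normalized) mask:
#' compactness `4 pi A / P^2`; convexity `P_hull / P`; solidity
#' `A / A_hull`; rectangularity `A / A_minrect`; circularity `mu_R /
#' sigma_R` over boundary-to-centroid radial distances; perimeter-area
#' ratio `P / A`; slimness (tight bounding-box width / height); position
#' of maximum thickness (distance of the widest row from the base, as a
#' fraction of leaf height, 0 = at base, 1 = at tip); and dispersion
#' `max_R / mu_R`. `P` is measured on the resampled sub-pixel contour,
#' `A` in pixels.
#'
#' @param mask single-component logical matrix, tip up.
#' @param tip_row,base_row optional row extent of the leaf (defaults: mask
#'   bounding box).
#' @return named numeric vector `fs2_00 .. fs2_08`.
#' @export
shape_descriptors <- function(mask, tip_row = NULL, base_row = NULL) {
  check_single_component(mask)
  A <- sum(mask)
  poly <- mask_contour(mask)
  pts <- resample_closed(poly, 256L)
  P <- polygon_perimeter(pts)
  hull <- pts[grDevices::chull(pts[, 2], pts[, 1]), , drop = FALSE]
  P_hull <- polygon_perimeter(hull)
  A_hull <- polygon_area(hull)
  A_rect <- min_area_rect(pts)
  idx <- which(mask, arr.ind = TRUE)
  centroid <- colMeans(idx)
  R <- sqrt((pts[, 1] - centroid[1])^2 + (pts[, 2] - centroid[2])^2)
  muR <- mean(R); sdR <- stats::sd(R)
  if (A == 0 || sdR == 0) stop("degenerate mask (zero area or zero radial spread)")
  bb <- mask_bbox(mask)
  tip_row <- tip_row %||% bb["rmin"]
  base_row <- base_row %||% bb["rmax"]
  height <- max(base_row - tip_row, 1)
  # per-row horizontal extent; widest row (ties -> closest to the base)
  rows <- bb["rmin"]:bb["rmax"]
  widths <- vapply(rows, function(r) {
    cc <- which(mask[r, ])
    if (!length(cc)) 0L else max(cc) - min(cc) + 1L
  }, 0L)
  widest <- rows[max(which(widths == max(widths)))]
  out <- c(
    compactness = 4 * pi * A / P^2,
    convexity = P_hull / P,
    solidity = A / A_hull,
    rectangularity = A / A_rect,
    circularity = muR / sdR,
    perimeter_area = P / A,
    slimness = (bb["cmax"] - bb["cmin"] + 1) / (bb["rmax"] - bb["rmin"] + 1),
    pos_max_thickness = min(max((base_row - widest) / height, 0), 1),
    dispersion = max(R) / muR)
  stats::setNames(unname(out), sprintf("fs2_%02d", 0:8))
}

# Chebyshev (square structuring element) erosion of a logical mask by
# radius r, via box sums: a pixel survives iff its (2r+1)^2 neighbourhood
# lies entirely inside the mask.
erode_mask_square <- function(mask, r) {
  if (r <= 0) return(mask)
  m <- pad_matrix(mask * 1, r, r, r, r, fill = 0)
  cs <- apply(m, 2, cumsum)
  rows <- (cs[(2 * r + 1):nrow(m), ] -
           rbind(0, cs[seq_len(nrow(m) - 2 * r - 1), ]))
  cs2 <- t(apply(rows, 1, cumsum))
  box <- cs2[, (2 * r + 1):ncol(m), drop = FALSE] -
    cbind(0, cs2[, seq_len(ncol(m) - 2 * r - 1), drop = FALSE])
  box >= (2 * r + 1)^2
}

# Pixels whose winning response is venation evidence rather than outline
# contamination: a response won at pyramid scale s has an effective
# template support of radius (template_length - 1)/2 * 2^(s-1) at full
# resolution; if that support reaches past the leaf margin, the template
# saw the background and its response describes the outline edge (or, at
# coarse scales, the whole narrow lamina acting as a "line"), not veins.
fs3_accumulation_mask <- function(linemap, mask) {
  r0 <- ((linemap$template_length %||% 15L) - 1L) %/% 2L
  sc <- linemap$scale
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (s in sort(unique(as.vector(sc)))) {
    er <- erode_mask_square(mask, r0 * 2^(s - 1))
    out <- out | (er & sc == s)
  }
  out
}

# Raw strength-weighted orientation histograms for the four leaf quadrants
# (upper/lower x left/right of the vein column). Pixels on the vein column
# itself are excluded so left/right mirroring is an exact symmetry, and
# accumulation is restricted to pixels whose winning template support lies
# inside the leaf (see fs3_accumulation_mask).
quadrant_histograms <- function(linemap, normleaf, n_bins) {
  stopifnot(n_bins == linemap$n_orientations)
  S <- pmax(linemap$strength, 0)
  O <- linemap$orientation
  mask <- fs3_accumulation_mask(linemap, normleaf$mask)
  if (!any(mask)) {
    warning("mask vanished under template erosion; using the full mask")
    mask <- normleaf$mask
  }
  stopifnot(all(dim(S) == dim(mask)))
  mid <- (normleaf$tip_row + normleaf$base_row) / 2
  idx <- which(mask, arr.ind = TRUE)
  bin <- (round(O[mask] / (180 / n_bins)) %% n_bins) + 1L
  w <- S[mask]
  upper <- idx[, 1] <= mid
  left <- idx[, 2] < normleaf$vein_column
  right <- idx[, 2] > normleaf$vein_column
  hsum <- function(sel) {
    h <- numeric(n_bins)
    if (any(sel)) {
      t <- tapply(w[sel], bin[sel], sum)
      h[as.integer(names(t))] <- t
    }
    h
  }
  list(upper_left = hsum(upper & left), upper_right = hsum(upper & right),
       lower_left = hsum(!upper & left), lower_right = hsum(!upper & right))
}

# Mirror a histogram over orientation bins theta -> 180 - theta.
mirror_histogram <- function(h) {
  n <- length(h)
  out <- h
  if (n > 1L) out[2:n] <- h[n:2]
  out
}

#' Strength-weighted vein-orientation histograms (FS3)
#'
#' The normalized leaf is split into upper and lower halves at the row
#' midway between tip and base, and into left and right of the vein
#' column. Each quadrant accumulates `max(S, 0)` into the orientation bin
#' of its line-map orientation; right-side histograms are mirrored
#' (`theta -> 180 - theta`) and averaged with the left side, and the two
#' resulting histograms (upper first, then lower) are each normalised to
#' unit sum. An empty or zero-strength half stays all zero with a warning.
#'
#' @param linemap `herb_linemap` computed on the *normalized* image.
#' @param normleaf a `herb_normleaf`.
#' @param n_bins histogram bins; must equal `linemap$n_orientations`.
#' @return named numeric vector `fs3_00 .. fs3_(2 n_bins - 1)`.
#' @export
orientation_histograms <- function(linemap, normleaf, n_bins = 24L) {
  q <- quadrant_histograms(linemap, normleaf, n_bins)
  halves <- list(
    upper = (q$upper_left + mirror_histogram(q$upper_right)) / 2,
    lower = (q$lower_left + mirror_histogram(q$lower_right)) / 2)
  out <- lapply(names(halves), function(nm) {
    h <- halves[[nm]]
    s <- sum(h)
    if (s > 0) h / s
    else {
      warning("zero total line strength in the ", nm, " half; histogram left at zero")
      h
    }
  })
  v <- unlist(out, use.names = FALSE)
  names(v) <- sprintf("fs3_%02d", seq_along(v) - 1L)
  v
}

#' Extract the full feature vector from a normalized leaf
#'
#' Concatenates FS1 (Fourier contour descriptors of the mask outline),
#' FS2 (shape descriptors) and FS3 (vein-orientation histograms; the line
#' map is recomputed on the normalized image). Deterministic given inputs.
#'
#' @param normleaf a `herb_normleaf`; if it carries a `linemap` attribute
#'   (the map measured on the original image and warped into the
#'   normalized frame by [normalize_leaf()], which avoids measuring on a
#'   resampled image), that map is used for FS3.
#' @param config a [pipeline_config()].
#' @param linemap optional precomputed line map in the normalized frame.
#' @return named numeric vector of length
#'   `n_fourier + 9 + 2 * n_hist_bins` with class `herb_features`; block
#'   membership is recoverable from the name prefixes.
#' @export
extract_all <- function(normleaf, config = pipeline_config(), linemap = NULL) {
  stopifnot(inherits(normleaf, "herb_normleaf"))
  if (is.null(linemap)) linemap <- attr(normleaf, "linemap")
  if (is.null(linemap))
    linemap <- line_response_multiscale(normleaf$image, config$n_orientations,
                                        config$template_length, config$n_scales)
  fs1 <- fourier_descriptors(normleaf$mask, config$n_fourier)
  fs2 <- shape_descriptors(normleaf$mask, normleaf$tip_row, normleaf$base_row)
  fs3 <- orientation_histograms(linemap, normleaf, config$n_hist_bins)
  structure(c(fs1, fs2, fs3), class = "herb_features")
}
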