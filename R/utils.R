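# Shared raster helpers: seeded evaluation, interpolation, warps, blurs,
# mask geometry. Everything works on plain numeric matrices with (row, col)
# 1-based coordinates.

# Evaluate expr under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Vectorised bilinear sampling at fractional (row, col); outside -> fill.
bilinear_sample <- function(img, r, c, fill = 0) {
  H <- nrow(img); W <- ncol(img)
  out <- rep(fill, length(r))
  ok <- r >= 1 & r <= H & c >= 1 & c <= W
  if (!any(ok)) return(out)
  r <- r[ok]; c <- c[ok]
  r0 <- pmin(floor(r), H - 1); c0 <- pmin(floor(c), W - 1)
  r0 <- pmax(r0, 1); c0 <- pmax(c0, 1)
  fr <- r - r0; fc <- c - c0
  i00 <- (c0 - 1) * H + r0
  v <- (1 - fr) * (1 - fc) * img[i00] +
       (1 - fr) * fc       * img[i00 + H] +
       fr       * (1 - fc) * img[i00 + 1] +
       fr       * fc       * img[i00 + H + 1]
  out[ok] <- v
  out
}

# Nearest-neighbour sampling; outside -> fill.
nearest_sample <- function(img, r, c, fill = 0) {
  H <- nrow(img); W <- ncol(img)
  ri <- round(r); ci <- round(c)
  out <- rep(fill, length(r))
  ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
  out[ok] <- img[(ci[ok] - 1) * H + ri[ok]]
  out
}

# Separable Gaussian blur with edge replication.
gaussian_blur <- function(img, sigma = 1) {
  rad <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-rad:rad)^2 / (2 * sigma^2))
  k <- k / sum(k)
  H <- nrow(img); W <- ncol(img)
  pad_idx <- function(n) pmin(pmax(seq(1 - rad, n + rad), 1), n)
  # rows
  tmp <- img[pad_idx(H), , drop = FALSE]
  out <- matrix(0, H, W)
  for (j in seq_along(k))
    out <- out + k[j] * tmp[j:(j + H - 1), , drop = FALSE]
  # cols
  tmp <- out[, pad_idx(W), drop = FALSE]
  out2 <- matrix(0, H, W)
  for (j in seq_along(k))
    out2 <- out2 + k[j] * tmp[, j:(j + W - 1), drop = FALSE]
  out2
}

# Downsample by 2 (rows/cols 1, 3, 5, ...).
subsample2 <- function(img) {
  img[seq(1, nrow(img), by = 2), seq(1, ncol(img), by = 2), drop = FALSE]
}

# Per-row horizontal shift: out(r, c) = in(r, c - shift[r]).
# `shift` is one value per row (fractional allowed).
shift_rows <- function(img, shift, fill = 0, interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  H <- nrow(img); W <- ncol(img)
  rr <- rep(seq_len(H), times = W)
  cc <- rep(seq_len(W), each = H) - shift[rr]
  v <- if (interp == "bilinear") bilinear_sample(img, rr, cc, fill)
       else nearest_sample(img, rr, cc, fill)
  matrix(v, H, W)
}

# Apply an axis_transform (out = R (in - center) + offset) to (row, col)
# points given as an n x 2 matrix.
rotate_points <- function(points, transform) {
  pts <- matrix(as.numeric(points), ncol = 2)
  rel <- t(transform$R %*% (t(pts) - transform$center))
  sweep(rel, 2, transform$offset, "+")
}

# Pad a matrix on all four sides with a fill value.
pad_matrix <- function(img, top = 0, bottom = 0, left = 0, right = 0, fill = 0) {
  H <- nrow(img); W <- ncol(img)
  out <- matrix(fill, H + top + bottom, W + left + right)
  out[top + seq_len(H), left + seq_len(W)] <- img
  out
}

# Bounding box of a logical mask: (rmin, rmax, cmin, cmax); NULL if empty.
mask_bbox <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  c(rmin = min(idx[, 1]), rmax = max(idx[, 1]),
    cmin = min(idx[, 2]), cmax = max(idx[, 2]))
}

# Intersection-over-union of two masks after aligning their centroids
# (canvases may differ between pipeline stages).
mask_iou <- function(a, b, align = c("centroid", "none")) {
  align <- match.arg(align)
  if (align == "none") {
    H <- max(nrow(a), nrow(b)); W <- max(ncol(a), ncol(b))
    pa <- pad_matrix(a, bottom = H - nrow(a), right = W - ncol(a), fill = FALSE)
    pb <- pad_matrix(b, bottom = H - nrow(b), right = W - ncol(b), fill = FALSE)
    return(sum(pa & pb) / sum(pa | pb))
  }
  ia <- which(a, arr.ind = TRUE); ib <- which(b, arr.ind = TRUE)
  if (nrow(ia) == 0L || nrow(ib) == 0L) return(0)
  da <- round(colMeans(ia)); db <- round(colMeans(ib))
  sa <- sweep(ia, 2, da); sb <- sweep(ib, 2, db)
  ka <- paste(sa[, 1], sa[, 2]); kb <- paste(sb[, 1], sb[, 2])
  inter <- length(intersect(ka, kb))
  inter / (nrow(ia) + nrow(ib) - inter)
}

# Smallest-angle difference between two orientations in degrees mod 180,
# folded into [0, 90].
angle_diff180 <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
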