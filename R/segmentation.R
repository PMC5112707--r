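# Scribble-seeded binary graph-cut segmentation in the lazy-snapping style:
# k-means colour models fitted to the foreground/background scribbles supply
# unary data terms, a contrast-modulated Potts term supplies smoothness, and
# the exact global optimum of the resulting submodular binary energy is found
# with a single s-t min cut.

# Deterministic Lloyd k-means with farthest-first initialisation.
# X: n x d matrix of colours. Returns a centers matrix with <= K rows
# (duplicate colours collapse; empty clusters are dropped).
det_kmeans <- function(X, K) {
  X <- as.matrix(X)
  ux <- unique(X)
  ord <- do.call(order, c(as.data.frame(ux), list(method = "radix")))
  ux <- ux[ord, , drop = FALSE]
  if (nrow(ux) <= K) return(ux)
  # farthest-first seeding from the lexicographically smallest colour
  centers <- ux[1, , drop = FALSE]
  d2 <- rowSums(sweep(ux, 2, centers[1, ])^2)
  while (nrow(centers) < K) {
    nxt <- which.max(d2)   # ties -> smallest index
    centers <- rbind(centers, ux[nxt, , drop = FALSE])
    d2 <- pmin(d2, rowSums(sweep(ux, 2, ux[nxt, ])^2))
  }
  assign_nearest <- function(C) {
    d <- outer(rowSums(X^2), rep(1, nrow(C))) - 2 * X %*% t(C) +
      outer(rep(1, nrow(X)), rowSums(C^2))
    max.col(-d, ties.method = "first")
  }
  cl <- assign_nearest(centers)
  for (it in seq_len(100L)) {
    for (k in seq_len(nrow(centers)))
      if (any(cl == k)) centers[k, ] <- colMeans(X[cl == k, , drop = FALSE])
    cl2 <- assign_nearest(centers)
    if (all(cl2 == cl)) break
    cl <- cl2
  }
  centers[sort(unique(cl)), , drop = FALSE]
}

# Flatten an image to an n_pixels x n_channels colour matrix (grayscale is
# treated as three equal channels so colour distances are comparable).
as_color_matrix <- function(image) {
  if (length(dim(image)) == 3L) {
    matrix(image, ncol = dim(image)[3])
  } else {
    v <- as.numeric(image)
    cbind(v, v, v)
  }
}

image_shape <- function(image) {
  if (length(dim(image)) == 3L) dim(image)[1:2] else dim(image)
}

#' Fit scribble colour models for segmentation
#'
#' @param image numeric matrix or 3-channel array, intensities in `[0, 1]`.
#' @param scribbles integer matrix (same height/width): 255 = foreground
#'   seed, 0 = background seed, 128 = unlabeled.
#' @param K maximum clusters per side; if a side has fewer distinct colours,
#'   fewer centers are returned.
#' @return list with `fg_centers`, `bg_centers` (matrices, one colour per
#'   row) and `K`.
#' @export
fit_color_model <- function(image, scribbles, K = 8L) {
  sh <- image_shape(image)
  stopifnot(all(dim(scribbles) == sh))
  cm <- as_color_matrix(image)
  fg <- which(scribbles == 255L)
  bg <- which(scribbles == 0L)
  if (!length(fg)) stop("no foreground scribbles (value 255) supplied")
  if (!length(bg)) stop("no background scribbles (value 0) supplied")
  list(fg_centers = det_kmeans(cm[fg, , drop = FALSE], K),
       bg_centers = det_kmeans(cm[bg, , drop = FALSE], K),
       K = as.integer(K))
}

# Normalised nearest-cluster data terms: D_fg is the cost of labelling a
# pixel foreground, D_bg of labelling it background; D_fg + D_bg = 1.
snap_data_terms <- function(image, model) {
  cm <- as_color_matrix(image)
  mind <- function(C) {
    d <- outer(rowSums(cm^2), rep(1, nrow(C))) - 2 * cm %*% t(C) +
      outer(rep(1, nrow(cm)), rowSums(C^2))
    sqrt(pmax(do.call(pmin, as.data.frame(d)), 0))
  }
  dfg <- mind(model$fg_centers)
  dbg <- mind(model$bg_centers)
  tot <- dfg + dbg
  Dfg <- ifelse(tot > 0, dfg / tot, 0.5)
  sh <- image_shape(image)
  list(D_fg = matrix(Dfg, sh[1], sh[2]),
       D_bg = matrix(1 - Dfg, sh[1], sh[2]))
}

# 4-neighbour edge list of an H x W grid, with contrast weights
# lambda / (1 + ||c_i - c_j||). Columns: i, j (column-major pixel ids), w.
snap_edges <- function(image, lambda) {
  sh <- image_shape(image)
  H <- sh[1]; W <- sh[2]
  cm <- as_color_matrix(image)
  idx <- matrix(seq_len(H * W), H, W)
  # vertical neighbours
  i1 <- as.vector(idx[-H, , drop = FALSE]); j1 <- as.vector(idx[-1, , drop = FALSE])
  # horizontal neighbours
  i2 <- as.vector(idx[, -W, drop = FALSE]); j2 <- as.vector(idx[, -1, drop = FALSE])
  ii <- c(i1, i2); jj <- c(j1, j2)
  dd <- sqrt(rowSums((cm[ii, , drop = FALSE] - cm[jj, , drop = FALSE])^2))
  cbind(i = ii, j = jj, w = lambda / (1 + dd))
}

# Total energy of a labelling (TRUE = foreground) under the lazy-snapping
# model; scribble-inconsistent labellings get +Inf. Used by tests as well.
snap_energy <- function(labels, terms, edges, scribbles = NULL) {
  if (!is.null(scribbles)) {
    if (any(!labels[scribbles == 255L]) || any(labels[scribbles == 0L]))
      return(Inf)
  }
  sum(ifelse(labels, terms$D_fg, terms$D_bg)) +
    sum(edges[, "w"] * (labels[edges[, "i"]] != labels[edges[, "j"]]))
}

#' Segment a leaf with scribble-seeded graph cuts
#'
#' Minimises `E(L) = sum_i D_i(L_i) + lambda * sum_(i,j) [L_i != L_j] /
#' (1 + ||c_i - c_j||)` over binary labellings consistent with the
#' scribbles, where `D_i` is the normalised nearest-cluster colour distance
#' (`d_fg / (d_fg + d_bg)` for the foreground label and its complement for
#' background). The energy is submodular, so the s-t min cut returns the
#' exact global optimum.
#'
#' @inheritParams fit_color_model
#' @param lambda_smooth smoothness weight (>= 0).
#' @return logical foreground mask with attribute `area`.
#' @export
lazy_snap <- function(image, scribbles, K = 8L, lambda_smooth = 10) {
  stopifnot(lambda_smooth >= 0)
  model <- fit_color_model(image, scribbles, K)
  terms <- snap_data_terms(image, model)
  edges <- snap_edges(image, lambda_smooth)
  sh <- image_shape(image)
  n <- sh[1] * sh[2]

  cap_s <- as.numeric(terms$D_bg)   # cut when pixel ends background
  cap_t <- as.numeric(terms$D_fg)   # cut when pixel ends foreground
  BIG <- sum(cap_s) + sum(cap_t) + sum(edges[, "w"]) + 1
  cap_s[scribbles == 255L] <- BIG
  cap_t[scribbles == 255L] <- 0
  cap_t[scribbles == 0L] <- BIG
  cap_s[scribbles == 0L] <- 0

  src <- n + 1L; snk <- n + 2L
  el <- rbind(cbind(src, seq_len(n)), cbind(seq_len(n), snk),
              edges[, c("i", "j"), drop = FALSE])
  caps <- c(cap_s, cap_t, edges[, "w"])
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  fl <- igraph::max_flow(g, source = src, target = snk, capacity = caps)
  fg_ids <- setdiff(as.integer(fl$partition1), c(src, snk))
  if (src %in% as.integer(fl$partition2))
    fg_ids <- setdiff(as.integer(fl$partition2), c(src, snk))

  mask <- matrix(FALSE, sh[1], sh[2])
  mask[fg_ids] <- TRUE
  if (!any(mask))
    stop("segmentation returned an empty foreground; add more scribbles")
  attr(mask, "area") <- sum(mask)
  mask
}

#' Clean a binary segmentation mask
#'
#' Keeps the largest 4-connected foreground component and fills interior
#' holes smaller than 0.1% of that component's area.
#'
#' @param mask logical matrix.
#' @return logical matrix with attribute `area`.
#' @export
cleanup_mask <- function(mask) {
  mask <- mask & TRUE  # drop attributes, coerce
  if (!any(mask)) stop("cannot clean an empty mask")
  lab <- .label_components_cpp(mask, 4L)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which.max(sizes)          # ties -> smallest label (raster order)
  out <- lab == keep
  comp_area <- sizes[keep]
  # holes: background components not touching the canvas border
  bg <- .label_components_cpp(!out, 4L)
  border_labels <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  hole_sizes <- tabulate(bg[bg > 0L])
  for (l in setdiff(seq_along(hole_sizes), border_labels)) {
    if (hole_sizes[l] > 0 && hole_sizes[l] < 0.001 * comp_area)
      out[bg == l] <- TRUE
  }
  attr(out, "area") <- sum(out)
  out
}
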