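# Programmatic raster fixtures shared across test files.

raster_ellipse <- function(H, W, ctr, a, b, angle = 0) {
  idx <- which(matrix(TRUE, H, W), arr.ind = TRUE)
  th <- angle * pi / 180
  dr <- idx[, 1] - ctr[1]; dc <- idx[, 2] - ctr[2]
  u <- dc * cos(th) + dr * sin(th)
  v <- -dc * sin(th) + dr * cos(th)
  matrix(u^2 / a^2 + v^2 / b^2 <= 1, H, W)
}

# Random smooth blob: radius = r0 * (1 + sum of low-frequency harmonics).
raster_blob <- function(H, W, ctr, r0, seed) {
  set.seed(seed)
  amp <- stats::runif(4, 0.02, 0.12)
  ph <- stats::runif(4, 0, 2 * pi)
  idx <- which(matrix(TRUE, H, W), arr.ind = TRUE)
  dr <- idx[, 1] - ctr[1]; dc <- idx[, 2] - ctr[2]
  th <- atan2(dr, dc)
  rad <- r0 * (1 + amp[1] * cos(2 * th + ph[1]) + amp[2] * cos(3 * th + ph[2]) +
                 amp[3] * cos(4 * th + ph[3]) + amp[4] * cos(5 * th + ph[4]))
  matrix(sqrt(dr^2 + dc^2) <= rad, H, W)
}

# Anti-aliased dark line through the canvas center at `angle_deg`
# (orientation convention: degrees ccw from +col axis, y up).
draw_line_image <- function(H, W, angle_deg, bg = 1, dark = 0) {
  img <- matrix(bg, H, W)
  ctr <- c((H + 1) / 2, (W + 1) / 2)
  th <- angle_deg * pi / 180
  d <- c(-sin(th), cos(th))
  k <- seq(-max(H, W), max(H, W), by = 0.25)
  rr <- ctr[1] + k * d[1]; cc <- ctr[2] + k * d[2]
  keep <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
  V <- matrix(0, H, W)
  V <- herbleaf:::stamp_points(V, rr[keep], cc[keep])
  img - (bg - dark) * pmin(V, 1)
}

# Independent Bellman-Ford shortest path cost on a masked 8-connected
# grid with trapezoidal step costs (oracle for the Dijkstra kernel).
bf_path_cost <- function(eps, mask, s, t) {
  H <- nrow(eps); W <- ncol(eps); n <- H * W
  d <- rep(Inf, n)
  d[(s[2] - 1) * H + s[1]] <- 0
  moves <- expand.grid(dr = -1:1, dc = -1:1)
  moves <- moves[!(moves$dr == 0 & moves$dc == 0), ]
  repeat {
    changed <- FALSE
    for (r in seq_len(H)) for (c in seq_len(W)) {
      if (!mask[r, c]) next
      u <- (c - 1) * H + r
      if (!is.finite(d[u])) next
      for (m in 1:8) {
        vr <- r + moves$dr[m]; vc <- c + moves$dc[m]
        if (vr < 1 || vr > H || vc < 1 || vc > W || !mask[vr, vc]) next
        step <- if (moves$dr[m] != 0 && moves$dc[m] != 0) sqrt(2) else 1
        nd <- d[u] + step * (eps[r, c] + eps[vr, vc]) / 2
        v <- (vc - 1) * H + vr
        if (nd < d[v] - 1e-12) { d[v] <- nd; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  d[(t[2] - 1) * H + t[1]]
}

# Exhaustive minimum of the lazy-snapping energy over all labellings
# consistent with the scribbles (tiny instances only).
exhaustive_snap_min <- function(img, scr, K, lambda) {
  model <- fit_color_model(img, scr, K)
  terms <- herbleaf:::snap_data_terms(img, model)
  edges <- herbleaf:::snap_edges(img, lambda)
  n <- length(scr)
  e_min <- Inf
  for (code in 0:(2^n - 1)) {
    lab <- matrix(bitwAnd(bitwShiftR(code, 0:(n - 1)), 1L) == 1L,
                  nrow(scr), ncol(scr))
    e <- herbleaf:::snap_energy(lab, terms, edges, scr)
    if (e < e_min) e_min <- e
  }
  e_min
}

# Energy actually achieved by lazy_snap on the same instance.
achieved_snap_energy <- function(img, scr, K, lambda) {
  m <- lazy_snap(img, scr, K = K, lambda_smooth = lambda)
  model <- fit_color_model(img, scr, K)
  terms <- herbleaf:::snap_data_terms(img, model)
  edges <- herbleaf:::snap_edges(img, lambda)
  herbleaf:::snap_energy(m, terms, edges, scr)
}
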