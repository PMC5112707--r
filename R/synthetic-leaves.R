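# Parametric synthetic-leaf generator with full ground truth. The
# generator emulates the statistical structure the pipeline assumes:
# species-specific outlines (entire vs lobed), secondary-vein angles that
# may differ between the lower and upper leaf half (venation
# "fingerprints"), bent/curved midveins as produced by pressing, additive
# image noise, herbivory-style bite damage and optional leaf overlap.

#' Construct a synthetic leaf species specification
#'
#' The outline is a half-width profile `w(t)` swept along the midvein,
#' `t in [0, 1]` from base to tip, with `w(0) = w(1) = 0` and `w > 0`
#' inside. Secondary veins leave the midvein at a fixed angle (degrees
#' from the midvein axis, `0 < angle < 90`), with separate angles for the
#' lower and upper leaf half.
#'
#' @param species_name label.
#' @param family outline family: `"elliptic"`, `"obovate"`, `"cordate"`
#'   or `"lobed"`.
#' @param length_px leaf length along the midvein, pixels.
#' @param width_frac maximum half-width as a fraction of `length_px`.
#' @param angle_lower,angle_upper secondary-vein angles (degrees).
#' @param vein_spacing_px spacing of secondary veins along the midvein.
#' @param curvature length-3 coefficients `(b1, b2, b3)` of the midvein
#'   bend `shift(u) = b1 u + b2 u^2 + b3 u^3` in pixels, `u in [0, 1]`
#'   from base to tip (zero shift at the base keeps the petiole fixed).
#' @param rotation_deg global rotation of the finished leaf (degrees,
#'   counterclockwise, `|rotation| < 60`), emulating how leaves lie at
#'   arbitrary angles on the herbarium sheet.
#' @param n_lobes,lobe_depth lobe count and relative depth (lobed family).
#' @param noise_sd additive Gaussian intensity noise (image scale `[0,1]`).
#' @param damage_fraction fraction of the lamina removed by bite disks,
#'   in `[0, 0.3]`.
#' @param overlap optional `(row, col)` offset of a second, occluding leaf.
#' @return object of class `leaf_spec`.
#' @export
leaf_spec <- function(species_name, family = "elliptic", length_px = 150L,
                      width_frac = 0.30, angle_lower = 50, angle_upper = 50,
                      vein_spacing_px = 14, curvature = c(0, 0, 0),
                      rotation_deg = 0,
                      n_lobes = 5L, lobe_depth = 0.35,
                      noise_sd = 0.02, damage_fraction = 0,
                      overlap = NULL) {
  family <- match.arg(family, c("elliptic", "obovate", "cordate", "lobed"))
  stopifnot(length_px >= 40L, width_frac > 0.05, width_frac < 0.6,
            angle_lower > 0, angle_lower < 90,
            angle_upper > 0, angle_upper < 90,
            vein_spacing_px >= 4,
            length(curvature) == 3L,
            abs(rotation_deg) < 60,
            damage_fraction >= 0, damage_fraction <= 0.3,
            lobe_depth >= 0, lobe_depth < 0.9)
  structure(list(species_name = species_name, family = family,
                 length_px = as.integer(length_px), width_frac = width_frac,
                 angle_lower = angle_lower, angle_upper = angle_upper,
                 vein_spacing_px = vein_spacing_px, curvature = curvature,
                 rotation_deg = rotation_deg,
                 n_lobes = as.integer(n_lobes), lobe_depth = lobe_depth,
                 noise_sd = noise_sd, damage_fraction = damage_fraction,
                 overlap = overlap),
            class = "leaf_spec")
}

# Half-width profile w(t) in pixels, t in [0, 1] from base to tip.
outline_halfwidth <- function(spec, t) {
  Wmax <- spec$width_frac * spec$length_px
  base <- switch(spec$family,
    elliptic = sin(pi * t)^0.8,
    obovate  = sin(pi * t^0.65),
    cordate  = sin(pi * t)^0.5 * (1 - 0.35 * t),
    lobed    = sin(pi * t)^0.8)
  if (spec$family == "lobed")
    base <- base * (1 - spec$lobe_depth * (0.5 + 0.5 * cos(2 * pi * spec$n_lobes * t)))
  Wmax * base
}

# Accumulate anti-aliased dark strokes: for each fractional point, its four
# integer neighbours receive the bilinear weight (max-combined).
stamp_points <- function(V, r, c) {
  H <- nrow(V); W <- ncol(V)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  put <- function(ri, ci, w) {
    ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W & w > 0
    if (!any(ok)) return(invisible())
    idx <- (ci[ok] - 1) * H + ri[ok]
    V[idx] <<- pmax(V[idx], w[ok])
    invisible()
  }
  put(r0, c0, (1 - fr) * (1 - fc))
  put(r0, c0 + 1, (1 - fr) * fc)
  put(r0 + 1, c0, fr * (1 - fc))
  put(r0 + 1, c0 + 1, fr * fc)
  V
}

#' Render a synthetic leaf with ground truth
#'
#' Produces a grayscale raster (light background, mid-tone lamina, dark
#' 1-2 px veins), the true binary mask, the true midvein pixel list and
#' the petiole coordinate. The straight leaf is built first (midvein
#' vertical); the spec's `curvature` then bends it with the same per-row
#' shift warp the normalization stage inverts. Bite damage removes random
#' disks from the lamina (kept off the midvein corridor so the leaf stays
#' traceable); `overlap` pastes a second occluding leaf. Fully
#' reproducible from `(spec, seed)`.
#'
#' @param spec a [leaf_spec()].
#' @param seed integer seed.
#' @return list with `image`, `mask`, `midvein` (n x 2 matrix, base to
#'   tip, fractional columns), `petiole`, `spec`.
#' @export
render_leaf <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "leaf_spec"))
  with_seed(seed, {
    L <- spec$length_px
    margin <- 10L
    Wmax <- ceiling(spec$width_frac * L)
    Wc <- 2L * (Wmax + margin) + 1L
    H <- L + 2L * margin
    base_row <- margin + L; tip_row <- margin
    c_mid <- (Wc + 1L) %/% 2L

    rows <- seq_len(H)
    tt <- (base_row - rows) / L
    inside <- tt >= 0 & tt <= 1
    w <- numeric(H)
    w[inside] <- outline_halfwidth(spec, pmin(pmax(tt[inside], 0), 1))
    cols <- matrix(rep(seq_len(Wc), each = H), H, Wc)
    mask <- abs(cols - c_mid) <= matrix(w, H, Wc) & matrix(inside, H, Wc)
    mask[base_row, c_mid] <- TRUE   # petiole attachment always present

    bg <- 0.85; lamina <- 0.58; vein_delta <- 0.38
    img <- matrix(bg, H, Wc)
    img[mask] <- lamina

    V <- matrix(0, H, Wc)
    # midvein: vertical stroke through the lamina
    mrows <- seq(tip_row + 1, base_row, by = 0.5)
    V <- stamp_points(V, mrows, rep(c_mid, length(mrows)))
    V <- stamp_points(V, mrows, rep(c_mid + 0.6, length(mrows)))
    # secondary veins: straight segments from the midvein to the margin
    mid_row <- (tip_row + base_row) / 2
    starts <- seq(base_row - spec$vein_spacing_px, tip_row + 4,
                  by = -spec$vein_spacing_px)
    for (r0 in starts) {
      lower <- r0 > mid_row
      ang <- if (lower) spec$angle_lower else spec$angle_upper
      for (s in c(-1, 1)) {
        step <- 0.5
        nmax <- ceiling(2.2 * Wmax / step)
        k <- seq_len(nmax) * step
        rr <- r0 - k * cos(ang * pi / 180)
        cc <- c_mid + s * k * sin(ang * pi / 180)
        t_here <- (base_row - rr) / L
        okt <- t_here > 0 & t_here < 1
        lim <- rep(-1, length(rr))
        lim[okt] <- outline_halfwidth(spec, t_here[okt])
        keep <- okt & abs(cc - c_mid) <= lim
        # steep veins rising from the lower half would otherwise run deep
        # into the upper half and wash out the half-specific angle
        # signature the generator exists to emulate
        if (lower) keep <- keep & rr > mid_row
        if (any(keep)) V <- stamp_points(V, rr[keep], cc[keep])
      }
    }
    img <- img - vein_delta * pmin(V, 1) * mask

    # herbivory: remove bite disks (off the midvein corridor)
    if (spec$damage_fraction > 0) {
      area0 <- sum(mask)
      removed <- 0L
      tries <- 0L
      while (removed < spec$damage_fraction * area0 && tries < 200L) {
        tries <- tries + 1L
        r0 <- stats::runif(1, tip_row + 5, base_row - 5)
        c0 <- stats::runif(1, 1, Wc)
        rad <- stats::runif(1, 3, 7)
        if (abs(c0 - c_mid) < rad + 4) next    # keep the midvein traceable
        if (!mask[round(r0), min(max(round(c0), 1), Wc)]) next
        d2 <- (matrix(rows, H, Wc) - r0)^2 + (cols - c0)^2
        bite <- d2 <= rad^2 & mask
        removed <- removed + sum(bite)
        mask[bite] <- FALSE
        img[bite] <- bg
      }
    }

    midvein <- cbind(row = seq(base_row, tip_row), col = c_mid)
    petiole <- c(base_row, c_mid)

    # bend: per-row shift, zero at the base
    cu <- spec$curvature
    if (any(cu != 0)) {
      u <- (base_row - rows) / L
      shift_full <- cu[1] * u + cu[2] * u^2 + cu[3] * u^3
      cubic <- row_shift_cubic(spec, base_row)
      bent <- bend_midvein(img, mask, cubic, fill = bg)
      img <- bent$image; mask <- bent$mask
      midvein <- cbind(row = midvein[, 1],
                       col = midvein[, 2] + shift_full[midvein[, 1]] +
                             bent$col_offset)
      petiole <- c(base_row, c_mid + bent$col_offset)
      Wc <- ncol(img)
    }

    rot <- spec$rotation_deg %||% 0
    if (rot != 0) {
      ctr <- c((nrow(img) + 1) / 2, (ncol(img) + 1) / 2)
      tr <- axis_transform(dim(img), rot, ctr)
      Ho <- tr$dims_out[1]; Wo <- tr$dims_out[2]
      rr <- rep(seq_len(Ho), times = Wo); cc <- rep(seq_len(Wo), each = Ho)
      rel <- rbind(rr - tr$offset[1], cc - tr$offset[2])
      src <- t(tr$R) %*% rel
      sr <- src[1, ] + ctr[1]; sc <- src[2, ] + ctr[2]
      img <- matrix(bilinear_sample(img, sr, sc, bg), Ho, Wo)
      mask <- matrix(nearest_sample(mask * 1, sr, sc, 0), Ho, Wo) > 0.5
      midvein <- structure(rotate_points(midvein, tr),
                           dimnames = list(NULL, c("row", "col")))
      petiole <- as.numeric(rotate_points(rbind(petiole), tr))
    }

    if (spec$noise_sd > 0)
      img <- img + matrix(stats::rnorm(length(img), 0, spec$noise_sd),
                          nrow(img), ncol(img))
    img <- pmin(pmax(img, 0), 1)

    if (!is.null(spec$overlap)) {
      spec2 <- spec; spec2$overlap <- NULL; spec2$curvature <- c(0, 0, 0)
      second <- render_leaf(spec2, seed + 1L)
      off <- round(spec$overlap)
      H2 <- nrow(second$image); W2 <- ncol(second$image)
      for (rr2 in seq_len(H2)) {
        r_t <- rr2 + off[1]
        if (r_t < 1 || r_t > nrow(img)) next
        cc2 <- which(second$mask[rr2, ])
        c_t <- cc2 + off[2]
        ok <- c_t >= 1 & c_t <= ncol(img)
        if (!any(ok)) next
        img[r_t, c_t[ok]] <- second$image[rr2, cc2[ok]]
        mask[r_t, c_t[ok]] <- FALSE      # occluded: no longer this leaf
      }
    }

    list(image = img, mask = mask, midvein = midvein, petiole = petiole,
         spec = spec)
  })
}

# Express the spec's bend (a polynomial in u = (base_row - row)/L) as a
# cubic in the image row, exact by construction.
row_shift_cubic <- function(spec, base_row) {
  L <- spec$length_px; cu <- spec$curvature
  r <- c(base_row, base_row - L / 3, base_row - 2 * L / 3, base_row - L)
  u <- (base_row - r) / L
  s <- cu[1] * u + cu[2] * u^2 + cu[3] * u^3
  co <- solve(cbind(1, r, r^2, r^3), s)
  as.numeric(co)
}

#' Bend a leaf by shifting each row along a cubic
#'
#' `out(r, c) = in(r, c - cubic(r))` with linear interpolation for the
#' image and nearest-neighbour for the mask -- the exact inverse family of
#' the warp [straighten()] applies. The canvas is padded so no pixel is
#' lost; the horizontal padding added on the left is returned as
#' `col_offset` so ground-truth coordinates can be updated.
#'
#' @param image numeric matrix.
#' @param mask logical matrix.
#' @param cubic coefficients `(a0, a1, a2, a3)` of the per-row shift.
#' @param fill background fill intensity.
#' @return list `image`, `mask`, `col_offset`.
#' @export
bend_midvein <- function(image, mask, cubic, fill = NULL) {
  if (is.null(fill)) fill <- stats::median(image[!mask])
  rows <- seq_len(nrow(image))
  shift <- eval_cubic(cubic, rows)
  if (max(abs(shift)) > ncol(image))
    stop("bend shift exceeds the canvas width")
  pad_l <- max(0, ceiling(max(shift)))
  pad_r <- max(0, ceiling(max(-shift)))
  img_p <- pad_matrix(image, left = pad_l, right = pad_r, fill = fill)
  msk_p <- pad_matrix(mask, left = pad_l, right = pad_r, fill = FALSE)
  list(image = shift_rows(img_p, shift, fill = fill, interp = "bilinear"),
       mask = shift_rows(msk_p * 1, shift, fill = 0, interp = "nearest") > 0.5,
       col_offset = pad_l)
}

# Deterministic species parameter table for a benchmark. "easy" species
# are well separated in (outline family, width, vein angles); "hard"
# species come in look-alike pairs whose parameter offsets are comparable
# to the within-species jitter, mimicking congeneric species.
benchmark_species_table <- function(n_species, difficulty) {
  fams <- c("elliptic", "obovate", "cordate", "lobed")
  grid <- expand.grid(width_frac = c(0.18, 0.27, 0.36, 0.45),
                      angle_lower = c(25, 45, 65),
                      family = fams, stringsAsFactors = FALSE)
  grid$angle_upper <- grid$angle_lower +
    rep_len(c(0, 18, -14, 0, 22, -16, 0, 15, -20, 0, 20, -15), nrow(grid))
  grid$angle_upper <- pmin(pmax(grid$angle_upper, 12), 84)
  grid$n_lobes <- rep_len(c(4L, 5L, 6L, 7L), nrow(grid))
  if (difficulty == "easy") {
    if (n_species > nrow(grid))
      stop("easy benchmark supports at most ", nrow(grid), " species")
    tab <- grid[seq_len(n_species), , drop = FALSE]
    tab$pair_id <- seq_len(n_species)
  } else {
    n_base <- ceiling(n_species / 2)
    if (n_base > nrow(grid))
      stop("hard benchmark supports at most ", 2L * nrow(grid), " species")
    base <- grid[seq_len(n_base), , drop = FALSE]
    twin <- base
    twin$width_frac <- twin$width_frac + 0.012
    twin$angle_lower <- pmin(twin$angle_lower + 1.0, 88)
    twin$angle_upper <- pmin(twin$angle_upper + 1.0, 88)
    src <- rbind(base, twin)
    ord <- as.vector(rbind(seq_len(n_base), n_base + seq_len(n_base)))
    tab <- src[ord[seq_len(n_species)], , drop = FALSE]
    tab$pair_id <- rep(seq_len(n_base), each = 2)[seq_len(n_species)]
  }
  tab$species <- sprintf("species_%02d", seq_len(n_species))
  rownames(tab) <- NULL
  tab
}

#' Generate a synthetic benchmark dataset
#'
#' Draws `n_species` leaf specifications from the generator's parameter
#' space and renders `n_per_species` leaves per species with per-leaf
#' parameter jitter, a random midvein bend and image noise. With
#' `difficulty = "easy"` species parameters are well separated; with
#' `"hard"` species come in look-alike pairs whose offsets are comparable
#' to the within-species jitter (look-alike pair ids are recorded).
#'
#' @param n_species number of species (>= 2).
#' @param n_per_species leaves per species.
#' @param difficulty `"easy"` or `"hard"`.
#' @param seed integer seed; everything is reproducible from it.
#' @param out_dir optional directory: when given, PGM images and masks, a
#'   `manifest.csv` and per-leaf ground-truth midvein CSVs are written.
#' @param bent apply random midvein bends (the normalization stage's
#'   raison d'etre); set `FALSE` for straight-leaf controls.
#' @param length_px leaf length in pixels (canvas scales with it).
#' @return object of class `herb_benchmark`: `leaves` (list of
#'   [render_leaf()] outputs), `labels`, `species_table` (with look-alike
#'   `pair_id`), `difficulty`, `seed`, and `out_dir` when written.
#' @export
generate_benchmark <- function(n_species = 26L, n_per_species = 10L,
                               difficulty = c("easy", "hard"), seed = 1L,
                               out_dir = NULL, bent = TRUE,
                               length_px = 150L) {
  difficulty <- match.arg(difficulty)
  stopifnot(n_species >= 2L, n_per_species >= 1L)
  if (n_per_species < 2L)
    warning("n_per_species < 2: leave-one-out cannot predict such classes")
  tab <- benchmark_species_table(n_species, difficulty)
  noise_sd <- if (difficulty == "easy") 0.02 else 0.03
  leaves <- vector("list", n_species * n_per_species)
  labels <- character(length(leaves))
  k <- 0L
  with_seed(seed, {
    for (i in seq_len(n_species)) {
      for (j in seq_len(n_per_species)) {
        k <- k + 1L
        wf <- tab$width_frac[i] * (1 + stats::rnorm(1, 0, 0.03))
        al <- tab$angle_lower[i] + stats::rnorm(1, 0, 1.5)
        au <- tab$angle_upper[i] + stats::rnorm(1, 0, 1.5)
        cu <- if (bent) c(stats::runif(1, -8, 8), stats::runif(1, -10, 10),
                          stats::runif(1, -4, 4)) else c(0, 0, 0)
        rot <- if (bent) stats::runif(1, -30, 30) else 0
        dmg <- if (difficulty == "hard" && stats::runif(1) < 0.3) 0.06 else 0
        sp <- leaf_spec(tab$species[i], family = tab$family[i],
                        length_px = length_px,
                        width_frac = min(max(wf, 0.08), 0.55),
                        angle_lower = min(max(al, 5), 85),
                        angle_upper = min(max(au, 5), 85),
                        vein_spacing_px = max(10, round(length_px / 11)),
                        curvature = cu, rotation_deg = rot,
                        n_lobes = tab$n_lobes[i],
                        noise_sd = noise_sd, damage_fraction = dmg)
        leaves[[k]] <- render_leaf(sp, seed = sample.int(.Machine$integer.max - 1L, 1))
        labels[k] <- tab$species[i]
      }
    }
  })
  bench <- structure(list(leaves = leaves, labels = labels,
                          species_table = tab, difficulty = difficulty,
                          seed = seed, n_per_species = n_per_species),
                     class = "herb_benchmark")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    recs <- vector("list", length(leaves))
    for (k in seq_along(leaves)) {
      lf <- leaves[[k]]
      id <- sprintf("%s_%03d", labels[k], k)
      ip <- file.path(out_dir, paste0(id, ".pgm"))
      mp <- file.path(out_dir, paste0(id, "_mask.pgm"))
      write_image(lf$image, ip)
      write_mask(lf$mask, mp)
      utils::write.csv(data.frame(row = lf$midvein[, 1], col = lf$midvein[, 2]),
                       file.path(out_dir, paste0(id, "_midvein.csv")),
                       row.names = FALSE)
      recs[[k]] <- data.frame(image = basename(ip), species = labels[k],
                              mask = basename(mp), scribbles = "",
                              petiole_row = lf$petiole[1],
                              petiole_col = lf$petiole[2], split = difficulty,
                              stringsAsFactors = FALSE)
    }
    utils::write.csv(do.call(rbind, recs), file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
    bench$out_dir <- out_dir
  }
  bench
}

#' @export
print.herb_benchmark <- function(x, ...) {
  cat(sprintf("herbleaf synthetic benchmark: %d leaves, %d species, difficulty '%s', seed %d\n",
              length(x$leaves), nrow(x$species_table), x$difficulty, x$seed))
  invisible(x)
}
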