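# Oriented line-operator vein maps. For each pixel the operator compares
# the mean intensity along a short line template (rotated through a set of
# orientations) against the mean of the surrounding square neighbourhood;
# the best-matching orientation gives the per-pixel line orientation O and
# the contrast gives the line strength S. Veins press as dark ridges, so
# strength is neighbourhood mean minus line mean (dark line -> positive S).
# Angles are degrees in [0, 180), measured counterclockwise from the image
# +x (column) axis with y up, i.e. a vertical vein has orientation 90.

new_linemap <- function(strength, orientation, n_orientations, scales_used,
                        template_length = 15L, scale = NULL) {
  structure(list(strength = strength, orientation = orientation,
                 n_orientations = as.integer(n_orientations),
                 scales_used = as.integer(scales_used),
                 template_length = as.integer(template_length),
                 scale = scale %||% matrix(1L, nrow(strength), ncol(strength))),
            class = "herb_linemap")
}

#' @export
print.herb_linemap <- function(x, ...) {
  cat(sprintf("herbleaf line map: %d x %d, %d orientations, %d scale(s)\n",
              nrow(x$strength), ncol(x$strength), x$n_orientations,
              x$scales_used))
  invisible(x)
}

#' Single-scale oriented line-operator response
#'
#' @param gray single-channel numeric matrix (use [to_gray()] for RGB).
#' @param n_orientations number of evenly spaced template angles in
#'   `[0, 180)`; the angular bin width is `180 / n_orientations` degrees
#'   (7.5 at the default 24).
#' @param template_length odd line-template length in pixels; the square
#'   comparison neighbourhood has the same side length.
#' @return a `herb_linemap` with `strength` (S) and `orientation` (O,
#'   degrees, one of the `n_orientations` bin centers) rasters.
#' @export
line_response_single_scale <- function(gray, n_orientations = 24L,
                                       template_length = 15L) {
  if (length(dim(gray)) == 3L)
    stop("line operator expects a single-channel image; see to_gray()")
  res <- .line_response_cpp(gray, as.integer(n_orientations),
                            as.integer(template_length))
  new_linemap(res$strength, res$orientation, n_orientations, 1L,
              template_length)
}

#' Multi-scale oriented line-operator response
#'
#' Responses are computed on a Gaussian pyramid (sigma = 1 smoothing, 2x
#' subsampling per level, `n_scales` levels including the original),
#' upsampled back to full resolution, and combined per pixel by taking the
#' scale with maximal strength (the winning scale also supplies the
#' orientation). Levels too small for the template are dropped with a
#' warning.
#'
#' @inheritParams line_response_single_scale
#' @param n_scales pyramid levels (>= 1); `n_scales = 1` is exactly the
#'   single-scale operator.
#' @return a `herb_linemap`.
#' @export
line_response_multiscale <- function(gray, n_orientations = 24L,
                                     template_length = 15L, n_scales = 3L) {
  stopifnot(n_scales >= 1L)
  H <- nrow(gray); W <- ncol(gray)
  S <- NULL; O <- NULL; SC <- NULL
  level <- gray
  used <- 0L
  for (s in seq_len(n_scales)) {
    if (nrow(level) < template_length || ncol(level) < template_length) {
      warning(sprintf("image too small for scale %d; using %d scale(s)", s, used))
      break
    }
    lm <- line_response_single_scale(level, n_orientations, template_length)
    f <- 2^(s - 1)
    if (f == 1L) {
      Su <- lm$strength; Ou <- lm$orientation
    } else {
      # nearest upsampling back to the full-resolution grid
      ri <- pmin(floor((seq_len(H) - 1) / f) + 1L, nrow(level))
      ci <- pmin(floor((seq_len(W) - 1) / f) + 1L, ncol(level))
      Su <- lm$strength[ri, ci, drop = FALSE]
      Ou <- lm$orientation[ri, ci, drop = FALSE]
    }
    if (is.null(S)) {
      S <- Su; O <- Ou; SC <- matrix(1L, H, W)
    } else {
      upd <- Su > S
      S[upd] <- Su[upd]
      O[upd] <- Ou[upd]
      SC[upd] <- s
    }
    used <- used + 1L
    if (s < n_scales) level <- subsample2(gaussian_blur(level, 1))
  }
  if (used == 0L) stop("image smaller than the line template at every scale")
  new_linemap(S, O, n_orientations, used, template_length, SC)
}
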