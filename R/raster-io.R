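#' Read a raster image (NetPBM PGM/PPM)
#'
#' Images are held in memory as numeric matrices (grayscale) or
#' height x width x 3 arrays (RGB) with intensities scaled to `[0, 1]`.
#' On disk the package speaks NetPBM: `P2`/`P5` grayscale and `P3`/`P6`
#' color rasters at 8 or 16 bit. NetPBM is the one raster family that can
#' be written as plain text, which keeps every fixture human-readable.
#'
#' @param path file path to a `.pgm`/`.ppm` raster.
#' @return numeric matrix or 3-channel array with values in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 2L || rawToChar(raw[1L]) != "P")
    stop("not a NetPBM raster: ", path)
  magic <- rawToChar(raw[1:2])
  if (!magic %in% c("P2", "P3", "P5", "P6"))
    stop("unsupported NetPBM magic '", magic, "' in ", path)
  nchan <- if (magic %in% c("P3", "P6")) 3L else 1L
  ascii <- magic %in% c("P2", "P3")

  # tokenizer over the header: whitespace-separated ints, '#' comments
  pos <- 3L
  next_token <- function() {
    repeat {
      while (pos <= length(raw) && raw[pos] %in% as.raw(c(9L, 10L, 13L, 32L)))
        pos <<- pos + 1L
      if (pos <= length(raw) && raw[pos] == as.raw(35L)) {  # '#'
        while (pos <= length(raw) && raw[pos] != as.raw(10L)) pos <<- pos + 1L
      } else break
    }
    start <- pos
    while (pos <= length(raw) && !(raw[pos] %in% as.raw(c(9L, 10L, 13L, 32L, 35L))))
      pos <<- pos + 1L
    if (pos <= start) stop("truncated NetPBM header in ", path)
    as.integer(rawToChar(raw[start:(pos - 1L)]))
  }
  w <- next_token(); h <- next_token(); maxval <- next_token()
  if (is.na(w) || is.na(h) || is.na(maxval) || w < 1L || h < 1L || maxval < 1L)
    stop("malformed NetPBM header in ", path)

  n_vals <- w * h * nchan
  if (ascii) {
    txt <- rawToChar(raw[pos:length(raw)])
    vals <- suppressWarnings(as.numeric(scan(text = txt, quiet = TRUE,
                                             comment.char = "#")))
    if (length(vals) < n_vals) stop("truncated pixel data in ", path)
    vals <- vals[seq_len(n_vals)]
  } else {
    pos <- pos + 1L  # single whitespace byte after maxval
    if (maxval < 256L) {
      if (length(raw) - pos + 1L < n_vals) stop("truncated pixel data in ", path)
      vals <- as.integer(raw[pos:(pos + n_vals - 1L)])
    } else {
      if (length(raw) - pos + 1L < 2L * n_vals) stop("truncated pixel data in ", path)
      b <- as.integer(raw[pos:(pos + 2L * n_vals - 1L)])
      vals <- b[c(TRUE, FALSE)] * 256L + b[c(FALSE, TRUE)]  # big-endian
    }
  }
  vals <- vals / maxval
  if (nchan == 1L) {
    matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  } else {
    arr <- array(0, dim = c(h, w, 3L))
    for (ch in 1:3)
      arr[, , ch] <- matrix(vals[seq(ch, n_vals, by = 3L)],
                            nrow = h, ncol = w, byrow = TRUE)
    arr
  }
}

#' Write a raster image (NetPBM PGM/PPM)
#'
#' @param img numeric matrix or 3-channel array, values in `[0, 1]`
#'   (clamped on write).
#' @param path destination path.
#' @param maxval maximum quantisation level (255 for 8-bit, 65535 for 16-bit).
#' @param ascii write the plain-text (`P2`/`P3`) variant instead of binary.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, maxval = 255L, ascii = FALSE) {
  color <- length(dim(img)) == 3L
  vals <- round(pmin(pmax(as.numeric(img), 0), 1) * maxval)
  if (color) {
    h <- dim(img)[1L]; w <- dim(img)[2L]
    # interleave channels in row-major order
    m <- array(vals, dim = dim(img))
    inter <- numeric(h * w * 3L)
    for (ch in 1:3)
      inter[seq(ch, length(inter), by = 3L)] <- as.numeric(t(m[, , ch]))
    vals <- inter
    magic <- if (ascii) "P3" else "P6"
  } else {
    h <- nrow(img); w <- ncol(img)
    vals <- round(pmin(pmax(as.numeric(t(img)), 0), 1) * maxval)
    magic <- if (ascii) "P2" else "P5"
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("%s\n%d %d\n%d\n", magic, w, h, as.integer(maxval)),
            con, eos = NULL)
  if (ascii) {
    writeChar(paste0(paste(format(as.integer(vals)), collapse = "\n"), "\n"),
              con, eos = NULL)
  } else if (maxval < 256L) {
    writeBin(as.raw(as.integer(vals)), con)
  } else {
    iv <- as.integer(vals)
    b <- as.raw(rbind(iv %/% 256L, iv %% 256L))
    writeBin(b, con)
  }
  invisible(path)
}

#' Read a binary mask from a grayscale raster
#'
#' Pixels at or above half intensity are foreground.
#' @param path PGM path.
#' @return logical matrix.
#' @export
read_mask <- function(path) {
  img <- read_image(path)
  if (length(dim(img)) == 3L) img <- to_gray(img)
  img >= 0.5
}

#' Write a binary mask as a 0/255 PGM raster
#' @param mask logical matrix.
#' @param path destination path.
#' @param ascii write plain-text PGM.
#' @export
write_mask <- function(mask, path, ascii = FALSE) {
  write_image(mask * 1.0, path, maxval = 255L, ascii = ascii)
}

#' Read a scribble raster
#'
#' Scribble convention: 0 = background seed, 255 = foreground seed,
#' 128 (or anything else mid-range) = unlabeled.
#' @param path PGM path.
#' @return integer matrix with values in `{0, 128, 255}`.
#' @export
read_scribbles <- function(path) {
  img <- read_image(path)
  if (length(dim(img)) == 3L) img <- to_gray(img)
  out <- matrix(128L, nrow(img), ncol(img))
  out[img <= 0.25] <- 0L
  out[img >= 0.75] <- 255L
  out
}

#' Write a scribble raster
#' @param scribbles integer matrix with values in `{0, 128, 255}`.
#' @param path destination path.
#' @param ascii write plain-text PGM.
#' @export
write_scribbles <- function(scribbles, path, ascii = FALSE) {
  write_image(scribbles / 255, path, maxval = 255L, ascii = ascii)
}

#' Collapse an RGB array to grayscale luminance
#' @param img matrix or 3-channel array.
#' @return numeric matrix.
#' @export
to_gray <- function(img) {
  if (length(dim(img)) == 2L) return(img)
  0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
}
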