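#' Pipeline configuration
#'
#' Central bundle of tunable parameters. Defaults follow the published
#' setup wherever one is stated: 24 template orientations, line templates
#' of length 15 px, three pyramid levels, the 2% tip rule, 20 Fourier
#' descriptors, 24 orientation-histogram bins. The remaining knobs
#' (segmentation clusters, smoothness, SVM cost) are package defaults.
#'
#' @param n_orientations number of evenly spaced line-template angles in
#'   `[0, 180)`.
#' @param template_length odd line-template length in pixels.
#' @param n_scales pyramid levels for the multi-scale line operator.
#' @param tip_fraction fraction of the leaf area defining the tip region.
#' @param n_fourier number of Fourier contour descriptors (FS1).
#' @param n_hist_bins orientation-histogram bins (FS3); must equal
#'   `n_orientations`.
#' @param svm_C soft-margin cost of the linear SVM.
#' @param seed integer seed logged with every run.
#' @param seg_K color clusters per scribble side for segmentation.
#' @param seg_lambda smoothness weight of the graph-cut energy
#'   (colors scaled to `[0, 1]`).
#' @return object of class `herb_config` (a validated named list).
#' @export
pipeline_config <- function(n_orientations = 24L, template_length = 15L,
                            n_scales = 3L, tip_fraction = 0.02,
                            n_fourier = 20L, n_hist_bins = 24L,
                            svm_C = 1.0, seed = 1L,
                            seg_K = 8L, seg_lambda = 10) {
  cfg <- list(n_orientations = as.integer(n_orientations),
              template_length = as.integer(template_length),
              n_scales = as.integer(n_scales),
              tip_fraction = tip_fraction,
              n_fourier = as.integer(n_fourier),
              n_hist_bins = as.integer(n_hist_bins),
              svm_C = svm_C, seed = as.integer(seed),
              seg_K = as.integer(seg_K), seg_lambda = seg_lambda)
  stopifnot(cfg$n_orientations >= 2L, cfg$template_length >= 3L,
            cfg$template_length %% 2L == 1L, cfg$n_scales >= 1L,
            cfg$tip_fraction > 0, cfg$tip_fraction < 0.5,
            cfg$n_fourier >= 2L, cfg$n_fourier %% 2L == 0L,
            cfg$svm_C > 0, cfg$seg_K >= 1L, cfg$seg_lambda >= 0)
  if (cfg$n_hist_bins != cfg$n_orientations)
    stop("n_hist_bins must equal n_orientations")
  class(cfg) <- "herb_config"
  cfg
}

#' @export
print.herb_config <- function(x, ...) {
  cat("herbleaf pipeline configuration\n")
  for (k in names(x)) cat(sprintf("  %-16s %s\n", k, format(x[[k]])))
  invisible(x)
}

#' Write a configuration as `key: value` text
#' @param cfg a `herb_config`.
#' @param path destination path.
#' @export
write_config <- function(cfg, path) {
  writeLines(sprintf("%s: %s", names(cfg),
                     vapply(cfg, function(v) format(v, digits = 15), "")),
             path)
  invisible(path)
}

#' Read a `key: value` configuration file
#' @param path path written by [write_config()] (unknown keys rejected).
#' @return a `herb_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ln <- grep("^\\s*(#|$)", readLines(path), value = TRUE, invert = TRUE)
  kv <- regmatches(ln, regexec("^\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", ln))
  bad <- vapply(kv, length, 0L) != 3L
  if (any(bad)) stop("malformed config line(s): ", paste(ln[bad], collapse = "; "))
  keys <- vapply(kv, `[`, "", 2L)
  vals <- vapply(kv, `[`, "", 3L)
  defaults <- pipeline_config()
  unknown <- setdiff(keys, names(defaults))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  args <- as.list(defaults)
  class(args) <- NULL
  args[keys] <- lapply(vals, function(v) as.numeric(v))
  do.call(pipeline_config, args)
}

new_leaf_record <- function(image, species, mask = NA_character_,
                            scribbles = NA_character_,
                            petiole = NULL, split = "") {
  list(image_path = image, species = species, mask_path = mask,
       scribble_path = scribbles, petiole = petiole, split_tag = split)
}

#' Read a dataset manifest
#'
#' The manifest is a UTF-8 comma-separated file with a header. Required
#' columns: `image`, `species`. Optional columns: `mask`, `scribbles`,
#' `petiole_row`, `petiole_col` (1-based pixel coordinates of the
#' user-marked petiole point), `split`. Records are returned in a
#' deterministic order (species, then image path). Rows whose image file
#' does not exist are collected and reported as a warning rather than
#' aborting the batch.
#'
#' @param path manifest CSV path.
#' @param check_files verify that referenced image files exist.
#' @return object of class `herb_manifest` with elements `records`
#'   (list of leaf records), `n_species`, `n_per_species`, `errors`.
#' @export
read_manifest <- function(path, check_files = TRUE) {
  if (!file.exists(path)) stop("manifest file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = TRUE)
  need <- c("image", "species")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("manifest is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0L)
    warning("manifest has a header but no records: ", path)

  base <- dirname(normalizePath(path, mustWork = TRUE))
  resolve <- function(p) {
    if (is.na(p) || !nzchar(p)) return(NA_character_)
    if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
  }
  errors <- character()
  records <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    row <- df[i, , drop = FALSE]
    img <- resolve(row$image)
    if (is.na(img) || !nzchar(row$image)) {
      errors <- c(errors, sprintf("line %d: empty image path", i + 1L))
      next
    }
    if (!nzchar(trimws(row$species %||% ""))) {
      errors <- c(errors, sprintf("line %d: empty species label", i + 1L))
      next
    }
    if (check_files && !file.exists(img)) {
      errors <- c(errors, sprintf("line %d: image file not found: %s", i + 1L, img))
      next
    }
    pet <- NULL
    if (all(c("petiole_row", "petiole_col") %in% names(df))) {
      pr <- suppressWarnings(as.numeric(row$petiole_row))
      pc <- suppressWarnings(as.numeric(row$petiole_col))
      if (is.finite(pr) && is.finite(pc)) pet <- c(pr, pc)
    }
    records[[i]] <- new_leaf_record(
      image = img, species = trimws(row$species),
      mask = if ("mask" %in% names(df)) resolve(row$mask) else NA_character_,
      scribbles = if ("scribbles" %in% names(df)) resolve(row$scribbles) else NA_character_,
      petiole = pet,
      split = if ("split" %in% names(df)) row$split %||% "" else "")
  }
  records <- Filter(Negate(is.null), records)
  ord <- order(vapply(records, `[[`, "", "species"),
               vapply(records, `[[`, "", "image_path"), method = "radix")
  records <- records[ord]
  if (length(errors))
    warning("manifest problems:\n  ", paste(errors, collapse = "\n  "))
  counts <- table(vapply(records, `[[`, "", "species"))
  structure(list(records = records,
                 n_species = length(counts),
                 n_per_species = as.list(counts),
                 errors = errors),
            class = "herb_manifest")
}

#' Write a dataset manifest
#' @param manifest a `herb_manifest`.
#' @param path destination CSV path.
#' @export
write_manifest <- function(manifest, path) {
  recs <- manifest$records
  df <- data.frame(
    image = vapply(recs, `[[`, "", "image_path"),
    species = vapply(recs, `[[`, "", "species"),
    mask = vapply(recs, function(r) r$mask_path %||% NA_character_, ""),
    scribbles = vapply(recs, function(r) r$scribble_path %||% NA_character_, ""),
    petiole_row = vapply(recs, function(r)
      if (is.null(r$petiole)) NA_real_ else r$petiole[1], 0),
    petiole_col = vapply(recs, function(r)
      if (is.null(r$petiole)) NA_real_ else r$petiole[2], 0),
    split = vapply(recs, function(r) r$split_tag %||% "", ""),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.herb_manifest <- function(x, ...) {
  cat(sprintf("herbleaf manifest: %d records, %d species\n",
              length(x$records), x$n_species))
  invisible(x)
}

#' Write a confusion matrix (CSV + PGM heat map)
#'
#' @param cm a `herb_confusion` (or plain labeled square matrix): rows are
#'   true classes, columns predicted classes.
#' @param path CSV destination; a grayscale heat-map raster is written next
#'   to it with extension `.pgm` (rows normalised so each true class's
#'   brightest cell is white).
#' @export
write_confusion <- function(cm, path) {
  m <- if (inherits(cm, "herb_confusion")) cm$counts else cm
  if (nrow(m) != ncol(m)) stop("confusion matrix must be square")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("confusion matrix must have labeled axes")
  zero_rows <- rownames(m)[rowSums(m) == 0]
  if (length(zero_rows))
    warning("class(es) with no samples: ", paste(zero_rows, collapse = ", "))
  df <- data.frame(true = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  rs <- pmax(apply(m, 1, max), 1)
  heat <- sweep(m, 1, rs, "/")
  # upscale cells for legibility
  f <- max(1L, 256L %/% nrow(m))
  big <- heat[rep(seq_len(nrow(m)), each = f), rep(seq_len(ncol(m)), each = f)]
  write_image(big, sub("\\.[A-Za-z]+$", ".pgm", path))
  invisible(path)
}

#' Read a confusion matrix CSV written by [write_confusion()]
#' @param path CSV path.
#' @return labeled integer matrix.
#' @export
read_confusion <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Write a feature table
#'
#' Columns: `id`, `species`, then `fs1_00..`, `fs2_00..`, `fs3_00..`.
#' @param features list of feature vectors (class `herb_features`) or a
#'   numeric matrix with proper column names.
#' @param ids sample identifiers.
#' @param species species labels.
#' @param path destination CSV.
#' @export
write_features <- function(features, ids, species, path) {
  m <- if (is.matrix(features)) features else do.call(rbind, lapply(features, unclass))
  df <- data.frame(id = ids, species = species, m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_features()]
#' @param path CSV path.
#' @return list with `x` (numeric matrix, feature columns), `ids`, `species`.
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  x <- as.matrix(df[, setdiff(names(df), c("id", "species")), drop = FALSE])
  list(x = x, ids = df$id, species = df$species)
}

# Block-name helpers shared by features/classification: feature columns are
# fs1_00.., fs2_00.., fs3_00..
feature_block_columns <- function(colnames, blocks) {
  blocks <- tolower(blocks)
  bad <- setdiff(blocks, c("fs1", "fs2", "fs3"))
  if (length(bad)) stop("unknown feature block(s): ", paste(bad, collapse = ", "))
  if (!length(blocks)) stop("empty feature subset")
  unlist(lapply(blocks, function(b) grep(paste0("^", b, "_"), colnames, value = TRUE)))
}
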