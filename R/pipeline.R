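# End-to-end orchestration: segment -> vein map -> normalize -> features
# -> evaluate over a manifest, with per-leaf fault isolation and a
# resumable feature cache.

# Extract the feature vector for one leaf. With normalize = FALSE the
# leaf is used as segmented (no axis rotation, no midvein straightening):
# the vein column is taken as the mask's central column and the row
# extent from its bounding box, which is exactly the ablation baseline.
features_from_leaf <- function(image, mask, petiole = NULL,
                               config = pipeline_config(),
                               normalize = TRUE) {
  gray <- to_gray(image)
  if (normalize) {
    nl <- normalize_leaf(gray, mask, petiole, config)
  } else {
    bb <- mask_bbox(mask)
    nl <- structure(list(image = gray, mask = mask,
                         vein_column = as.integer(round((bb["cmin"] + bb["cmax"]) / 2)),
                         base_row = as.integer(bb["rmax"]),
                         tip_row = as.integer(bb["rmin"])),
                    class = "herb_normleaf")
  }
  extract_all(nl, config)
}

# Feature matrix + labels for an in-memory synthetic benchmark.
benchmark_features <- function(bench, config = pipeline_config(),
                               normalize = TRUE) {
  stopifnot(inherits(bench, "herb_benchmark"))
  rows <- lapply(bench$leaves, function(lf) {
    m <- cleanup_mask(lf$mask)
    features_from_leaf(lf$image, m, lf$petiole, config, normalize)
  })
  x <- do.call(rbind, lapply(rows, unclass))
  rownames(x) <- NULL
  list(x = x, labels = bench$labels)
}

#' Run the full pipeline over a manifest
#'
#' For every record: obtain a mask (ground-truth mask file if present,
#' otherwise scribble-seeded graph-cut segmentation), clean it, normalize
#' the leaf (unless `normalize = FALSE`), and extract FS1/FS2/FS3. Leaves
#' whose processing fails are recorded and skipped -- herbarium material
#' is messy and one bad sheet must not abort the batch. Finally a linear
#' one-against-one SVM is evaluated leave-one-out per feature subset, and
#' all artifacts (feature table, confusion matrix + heat map, per-subset
#' accuracies, resolved configuration, run report) are written under
#' `out_dir`. Per-leaf features are cached in `out_dir/cache` keyed by
#' image name and configuration, so an interrupted run resumes cheaply.
#'
#' @param manifest a `herb_manifest` (see [read_manifest()]).
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created).
#' @param normalize run the midvein-straightening stage.
#' @param subsets feature-block combinations to evaluate.
#' @return invisible run report: per-leaf status, accuracy table,
#'   confusion matrix, paths.
#' @export
run_pipeline <- function(manifest, config = pipeline_config(), out_dir,
                         normalize = TRUE,
                         subsets = list("fs1", "fs2", "fs3",
                                        c("fs1", "fs2", "fs3"))) {
  stopifnot(inherits(manifest, "herb_manifest"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cache_dir <- file.path(out_dir, "cache")
  dir.create(cache_dir, showWarnings = FALSE)
  write_config(config, file.path(out_dir, "config.txt"))

  cfg_tag <- paste0(vapply(unclass(config), format, ""), collapse = "|")
  status <- list()
  feats <- list(); ids <- character(); species <- character()
  for (rec in manifest$records) {
    id <- sub("\\.[A-Za-z]+$", "", basename(rec$image_path))
    cache_file <- file.path(cache_dir,
                            paste0(id, if (!normalize) "_raw", ".json"))
    res <- tryCatch({
      cached <- NULL
      if (file.exists(cache_file)) {
        cc <- jsonlite::read_json(cache_file, simplifyVector = TRUE)
        if (identical(cc$cfg_tag, cfg_tag))
          cached <- stats::setNames(as.numeric(cc$values), cc$names)
      }
      cached %||% compute_record_features(rec, config, normalize)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      status[[id]] <- list(ok = FALSE, reason = conditionMessage(res))
      next
    }
    if (!file.exists(cache_file)) {
      jsonlite::write_json(list(cfg_tag = cfg_tag, names = names(res),
                                values = unclass(res)),
                           cache_file, digits = NA, auto_unbox = TRUE)
    }
    status[[id]] <- list(ok = TRUE)
    feats[[id]] <- res
    ids <- c(ids, id)
    species <- c(species, rec$species)
  }
  if (length(feats) < 2L)
    stop("fewer than 2 leaves produced features; cannot evaluate")

  x <- do.call(rbind, feats)
  write_features(x, ids, species, file.path(out_dir, "features.csv"))

  acc <- evaluate_feature_subsets(x, species, subsets, C = config$svm_C)
  utils::write.csv(acc, file.path(out_dir, "subset_accuracy.csv"),
                   row.names = FALSE)
  full <- loo_evaluate(x, species, C = config$svm_C)
  write_confusion(full$confusion, file.path(out_dir, "confusion.csv"))

  n_fail <- sum(!vapply(status, `[[`, TRUE, "ok"))
  report <- c(sprintf("herbleaf run: %d leaves, %d failed", length(status), n_fail),
              sprintf("normalize: %s", normalize),
              sprintf("LOO accuracy (all blocks): %.4f", full$accuracy),
              sprintf("subset %s: %.4f", acc$subset, acc$accuracy),
              "config:", readLines(file.path(out_dir, "config.txt")))
  writeLines(report, file.path(out_dir, "report.txt"))

  invisible(list(status = status, accuracy = full$accuracy,
                 subset_accuracy = acc, confusion = full$confusion,
                 features = x, ids = ids, species = species,
                 out_dir = out_dir))
}

compute_record_features <- function(rec, config, normalize) {
  image <- read_image(rec$image_path)
  mask <- NULL
  if (!is.na(rec$mask_path) && nzchar(rec$mask_path) && file.exists(rec$mask_path)) {
    mask <- read_mask(rec$mask_path)
  } else if (!is.na(rec$scribble_path) && nzchar(rec$scribble_path) &&
             file.exists(rec$scribble_path)) {
    scr <- read_scribbles(rec$scribble_path)
    mask <- lazy_snap(image, scr, K = config$seg_K,
                      lambda_smooth = config$seg_lambda)
  } else {
    stop("record has neither mask nor scribbles: ", rec$image_path)
  }
  mask <- cleanup_mask(mask)
  features_from_leaf(image, mask, rec$petiole, config, normalize)
}

cli_args_to_list <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected CLI token: ", a)
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      out[[key]] <- TRUE; i <- i + 1L
    } else {
      out[[key]] <- args[i + 1L]; i <- i + 2L
    }
  }
  out
}

#' Command-line entry point
#'
#' Subcommands: `synth`, `segment`, `veinmap`, `normalize`, `features`,
#' `evaluate`, `run`. See `inst/cli/herbleaf.R` for the launcher script.
#' Returns the exit code (0 on success) invisibly.
#'
#' @param args character vector of command-line arguments (first element
#'   is the subcommand).
#' @export
herbleaf_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    message("usage: herbleaf <synth|segment|veinmap|normalize|features|evaluate|run> [--opt value ...]")
    return(invisible(1L))
  }
  cmd <- args[1L]
  opt <- cli_args_to_list(args[-1L])
  num <- function(key, default) if (is.null(opt[[key]])) default else as.numeric(opt[[key]])
  chr <- function(key, default = NULL) opt[[key]] %||% default
  cfg <- pipeline_config(seed = num("seed", 1))
  switch(cmd,
    synth = {
      generate_benchmark(n_species = num("n-species", 26),
                         n_per_species = num("n-per-species", 10),
                         difficulty = chr("difficulty", "easy"),
                         seed = num("seed", 1),
                         out_dir = chr("out-dir", stop("--out-dir required")))
    },
    segment = {
      img <- read_image(chr("image", stop("--image required")))
      scr <- read_scribbles(chr("scribbles", stop("--scribbles required")))
      m <- cleanup_mask(lazy_snap(img, scr, K = num("K", 8),
                                  lambda_smooth = num("lambda", 10)))
      write_mask(m, chr("out", stop("--out required")))
    },
    veinmap = {
      img <- to_gray(read_image(chr("image", stop("--image required"))))
      lm <- line_response_multiscale(img, cfg$n_orientations,
                                     cfg$template_length, cfg$n_scales)
      utils::write.csv(lm$strength, chr("out-strength", "strength.csv"),
                       row.names = FALSE)
      utils::write.csv(lm$orientation, chr("out-orientation", "orientation.csv"),
                       row.names = FALSE)
    },
    normalize = {
      img <- read_image(chr("image", stop("--image required")))
      msk <- read_mask(chr("mask", stop("--mask required")))
      pet <- if (!is.null(opt$petiole))
        as.numeric(strsplit(opt$petiole, ",")[[1]]) else NULL
      out_dir <- chr("out-dir", stop("--out-dir required"))
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      nl <- normalize_leaf(img, cleanup_mask(msk), pet, cfg)
      write_image(nl$image, file.path(out_dir, "normalized.pgm"))
      write_mask(nl$mask, file.path(out_dir, "normalized_mask.pgm"))
      mv <- attr(nl, "midvein")
      utils::write.csv(data.frame(row = mv$pixels[, 1], col = mv$pixels[, 2]),
                       file.path(out_dir, "midvein.csv"), row.names = FALSE)
      jsonlite::write_json(list(cubic = attr(nl, "cubic"),
                                vein_column = nl$vein_column),
                           file.path(out_dir, "cubic.json"),
                           auto_unbox = TRUE, digits = NA)
    },
    features = ,
    run = {
      man <- read_manifest(chr("manifest", stop("--manifest required")))
      run_pipeline(man, cfg, chr("out-dir", stop("--out-dir required")),
                   normalize = is.null(opt[["no-normalize"]]))
    },
    evaluate = {
      ft <- read_features(chr("features", stop("--features required")))
      out_dir <- chr("out-dir", stop("--out-dir required"))
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      acc <- evaluate_feature_subsets(ft$x, ft$species,
                                      list("fs1", "fs2", "fs3",
                                           c("fs1", "fs2", "fs3")),
                                      C = num("C", 1))
      utils::write.csv(acc, file.path(out_dir, "subset_accuracy.csv"),
                       row.names = FALSE)
      full <- loo_evaluate(ft$x, ft$species, C = num("C", 1))
      write_confusion(full$confusion, file.path(out_dir, "confusion.csv"))
    },
    stop("unknown subcommand: ", cmd))
  invisible(0L)
}
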