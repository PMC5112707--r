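# dataset_io: manifests, config, confusion matrices, feature tables,
# raster round-trips.

write_dummy_images <- function(dir, names) {
  for (nm in names)
    write_image(matrix(runif(12), 3, 4), file.path(dir, nm))
}

test_that("read_manifest parses records, counts species, orders deterministically", {
  d <- withr::local_tempdir()
  write_dummy_images(d, c("a.pgm", "b.pgm", "c.pgm"))
  writeLines(c("image,species,petiole_row,petiole_col",
               "c.pgm,quercus,,",
               "a.pgm,fagus,120,44",
               "b.pgm,quercus,7,9"),
             file.path(d, "m.csv"))
  m <- read_manifest(file.path(d, "m.csv"))
  expect_s3_class(m, "herb_manifest")
  expect_equal(m$n_species, 2L)
  expect_equal(length(m$records), 3L)
  # sorted by species then path
  expect_equal(vapply(m$records, `[[`, "", "species"),
               c("fagus", "quercus", "quercus"))
  expect_equal(m$records[[1]]$petiole, c(120, 44))
  expect_equal(m$records[[2]]$petiole, c(7, 9))
  expect_null(m$records[[3]]$petiole)
  # identical ordering on re-read
  m2 <- read_manifest(file.path(d, "m.csv"))
  expect_identical(vapply(m$records, `[[`, "", "image_path"),
                   vapply(m2$records, `[[`, "", "image_path"))
})

test_that("read_manifest handles degenerate and malformed input", {
  d <- withr::local_tempdir()
  writeLines("image,species", file.path(d, "empty.csv"))
  expect_warning(m <- read_manifest(file.path(d, "empty.csv")), "no records")
  expect_equal(length(m$records), 0L)

  expect_error(read_manifest(file.path(d, "nope.csv")), "not found")
  writeLines(c("image,label", "x.pgm,abc"), file.path(d, "badcol.csv"))
  expect_error(read_manifest(file.path(d, "badcol.csv")), "species")

  # nonexistent image: record-level error with line number, not fatal
  write_dummy_images(d, "ok.pgm")
  writeLines(c("image,species", "ok.pgm,fagus", "gone.pgm,acer"),
             file.path(d, "part.csv"))
  expect_warning(m <- read_manifest(file.path(d, "part.csv")), "line 3")
  expect_equal(length(m$records), 1L)
  expect_match(m$errors, "gone.pgm")
})

test_that("manifest round-trips through write_manifest", {
  d <- withr::local_tempdir()
  write_dummy_images(d, c("a.pgm", "b.pgm"))
  writeLines(c("image,species,petiole_row,petiole_col",
               "a.pgm,fagus,10,20", "b.pgm,acer,,"),
             file.path(d, "m.csv"))
  m <- read_manifest(file.path(d, "m.csv"))
  write_manifest(m, file.path(d, "m2.csv"))
  m2 <- read_manifest(file.path(d, "m2.csv"))
  expect_equal(m2$n_species, m$n_species)
  expect_equal(lapply(m2$records, `[[`, "petiole"),
               lapply(m$records, `[[`, "petiole"))
  expect_equal(vapply(m2$records, `[[`, "", "species"),
               vapply(m$records, `[[`, "", "species"))
})

test_that("config defaults match the published setup and round-trip", {
  cfg <- pipeline_config()
  expect_equal(cfg$n_orientations, 24L)
  expect_equal(cfg$template_length, 15L)
  expect_equal(cfg$n_scales, 3L)
  expect_equal(cfg$tip_fraction, 0.02)
  expect_equal(cfg$n_fourier, 20L)
  expect_equal(cfg$n_hist_bins, 24L)
  d <- withr::local_tempdir()
  cfg2 <- pipeline_config(n_orientations = 12, n_hist_bins = 12, svm_C = 2.5)
  write_config(cfg2, file.path(d, "cfg.txt"))
  expect_equal(read_config(file.path(d, "cfg.txt")), cfg2)
  expect_error(pipeline_config(n_hist_bins = 12), "n_hist_bins")
})

test_that("confusion matrices write CSV + heat map and warn on empty classes", {
  d <- withr::local_tempdir()
  m <- matrix(c(5L, 1L, 0L, 4L), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  p <- file.path(d, "cm.csv")
  write_confusion(m, p)
  expect_equal(read_confusion(p), m)
  expect_true(file.exists(file.path(d, "cm.pgm")))

  m0 <- m; m0["b", ] <- 0L
  expect_warning(write_confusion(m0, p), "no samples")
  expect_equal(read_confusion(p), m0)
  expect_error(write_confusion(matrix(0L, 2, 3), p), "square")
})

test_that("images, masks and scribbles round-trip through NetPBM", {
  d <- withr::local_tempdir()
  img <- matrix(runif(35), 5, 7)
  for (ascii in c(FALSE, TRUE)) {
    p <- file.path(d, sprintf("x_%d.pgm", ascii))
    write_image(img, p, maxval = 65535L, ascii = ascii)
    expect_equal(read_image(p), img, tolerance = 1e-4)
  }
  rgb <- array(runif(60), dim = c(4, 5, 3))
  p <- file.path(d, "c.ppm")
  write_image(rgb, p, maxval = 255L)
  expect_equal(read_image(p), rgb, tolerance = 1 / 254)

  mk <- matrix(c(TRUE, FALSE), 6, 4)
  write_mask(mk, file.path(d, "m.pgm"))
  expect_identical(read_mask(file.path(d, "m.pgm")), mk)

  scr <- matrix(128L, 5, 5); scr[1, ] <- 0L; scr[5, ] <- 255L
  write_scribbles(scr, file.path(d, "s.pgm"))
  expect_identical(read_scribbles(file.path(d, "s.pgm")), scr)
})

test_that("feature tables round-trip", {
  d <- withr::local_tempdir()
  x <- matrix(rnorm(6), 2, 3,
              dimnames = list(NULL, c("fs1_00", "fs2_00", "fs3_00")))
  write_features(x, c("l1", "l2"), c("acer", "fagus"), file.path(d, "f.csv"))
  ft <- read_features(file.path(d, "f.csv"))
  expect_equal(ft$x, x, ignore_attr = TRUE)
  expect_equal(colnames(ft$x), colnames(x))
  expect_equal(ft$species, c("acer", "fagus"))
  expect_equal(herbleaf:::feature_block_columns(colnames(x), c("fs1", "fs3")),
               c("fs1_00", "fs3_00"))
  expect_error(herbleaf:::feature_block_columns(colnames(x), "fs9"), "unknown")
})
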