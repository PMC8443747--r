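test_that("multi-page RGB TIFF splits into three channels in z order", {
  nz <- 5L
  pages <- lapply(seq_len(nz), function(z) {
    a <- array(0, dim = c(16, 20, 3))
    a[, , 1] <- z / 255       # red encodes the page index
    a[z, 1, 2] <- 40 / 255
    a
  })
  f <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(pages, f, bits.per.sample = 8)
  st <- read_stack(f, spacing = c(0.3, 0.3, 1))
  expect_named(st$channels, c("red", "green", "blue"))
  expect_equal(dim(st$channels$red), c(nz, 16L, 20L))
  # ascending page index = ascending z
  expect_equal(st$channels$red[, 1, 1], as.numeric(seq_len(nz)))
})

test_that("single-page grayscale files stack as z-slices of the blue channel", {
  files <- character(4)
  for (z in 1:4) {
    files[z] <- tempfile(fileext = ".tif")
    tiff::writeTIFF(matrix(z / 255, 8, 8), files[z], bits.per.sample = 8)
  }
  on.exit(unlink(files))
  st <- read_stack(files, spacing = c(1, 1, 1))
  expect_named(st$channels, "blue")
  expect_equal(dim(st$channels$blue), c(4L, 8L, 8L))
  expect_equal(st$channels$blue[, 1, 1], as.numeric(1:4))
})

test_that("mismatched page sizes and float samples are rejected", {
  f1 <- withr::local_tempfile(fileext = ".tif")
  f2 <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(0.1, 8, 8), f1, bits.per.sample = 8)
  tiff::writeTIFF(matrix(0.1, 9, 8), f2, bits.per.sample = 8)
  expect_error(read_stack(c(f1, f2), c(1, 1, 1)), "differing sizes")
  f3 <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(0.123, 4, 4), f3, bits.per.sample = 32)
  expect_error(read_stack(f3, c(1, 1, 1)), "sample format")
})

test_that("label images round-trip bit-exactly through TIFF", {
  lab <- array(0L, dim = c(3, 12, 12))
  lab[1, 2:4, 2:4] <- 1L
  lab[2:3, 6:9, 6:9] <- 2L
  f <- withr::local_tempfile(fileext = ".tif")
  write_annotated_labels(lab, f, insert_numbers = FALSE)
  expect_identical(read_labels(f), lab)
  expect_error(write_annotated_labels(array(0L, c(1, 4, 4)), f), "empty")
})

test_that("inserted numbers only touch pixels near centroids, with the label value", {
  lab <- array(0L, dim = c(1, 40, 40))
  lab[1, 5:15, 5:15] <- 1L
  lab[1, 25:35, 20:36] <- 2L
  f0 <- withr::local_tempfile(fileext = ".tif")
  f1 <- withr::local_tempfile(fileext = ".tif")
  write_annotated_labels(lab, f0, insert_numbers = FALSE)
  write_annotated_labels(lab, f1, insert_numbers = TRUE)
  plain <- read_labels(f0); ann <- read_labels(f1)
  diff <- which(plain != ann, arr.ind = TRUE)
  expect_gt(nrow(diff), 0)
  # every change lies in a digit box near some region centroid and is either
  # a glyph pixel carrying the label id or a cleared box pixel
  cents <- t(vapply(1:2, function(id) {
    w <- which(lab == id, arr.ind = TRUE); colMeans(w)[2:3]
  }, numeric(2)))
  for (k in seq_len(nrow(diff))) {
    v <- ann[diff[k, 1], diff[k, 2], diff[k, 3]]
    expect_true(v %in% c(0L, 1L, 2L))
    near <- abs(cents[, 1] - diff[k, 2]) <= 5 &
      abs(cents[, 2] - diff[k, 3]) <= 8
    expect_true(any(near))
  }
  # the digit box around each centroid shows both glyph (id) and cleared (0)
  # pixels: the number is legible against its background
  for (id in 1:2) {
    box <- ann[1, (cents[id, 1] - 3):(cents[id, 1] + 3),
               (cents[id, 2] - 3):(cents[id, 2] + 3)]
    expect_true(any(box == id) && any(box == 0L))
  }
})

test_that("region tables export with stable columns and reload to 6 sig digits", {
  ph <- make_disjoint_phantom()
  res <- run_pipeline(ph$stack, mn_params(voxel_spacing = ph$stack$spacing))
  f <- withr::local_tempfile(fileext = ".csv")
  export_region_table(res$regions, f, summary = res$summary)
  back <- read_region_table(f)
  expect_equal(nrow(back), nrow(res$regions))
  num <- c("volume_um3", "r_cal_um", "centroid_z_um", "centroid_y_um",
           "centroid_x_um", "overlap_rate_green", "overlap_rate_blue")
  for (cn in num)
    expect_equal(signif(back[[cn]], 6), signif(res$regions[[cn]], 6))
  # txt mirror exists; empty table gives a header-only file
  expect_true(file.exists(sub("\\.csv$", ".txt", f)))
  f2 <- withr::local_tempfile(fileext = ".csv")
  export_region_table(res$regions[0, ], f2)
  expect_equal(nrow(read_region_table(f2)), 0)
  expect_equal(length(readLines(f2)), 1)
})
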