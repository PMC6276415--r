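# Image / annotation I/O, rescaling and calibration.

write_bmp24 <- function(px, path) {
  # minimal uncompressed 24-bit bottom-up BMP writer (test fixture only)
  h <- nrow(px); w <- ncol(px)
  row_bytes <- ((w * 3 + 3) %/% 4) * 4
  data_size <- row_bytes * h
  le <- function(x, n) as.raw((x %/% 256^(0:(n - 1))) %% 256)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("BM"), le(54 + data_size, 4), le(0, 4), le(54, 4),
             le(40, 4), le(w, 4), le(h, 4), le(1, 2), le(24, 2), le(0, 4),
             le(data_size, 4), le(2835, 4), le(2835, 4), le(0, 4), le(0, 4)),
           con)
  for (r in h:1) {
    v <- round(px[r, ] * 255)
    row <- as.raw(rbind(v, v, v))              # B, G, R identical (gray)
    writeBin(c(row, rep(as.raw(0), row_bytes - 3 * w)), con)
  }
}

test_that("PNG loading keeps size, intensities and the calibration ratio", {
  f <- tempfile(fileext = ".png")
  png::writePNG(matrix(0, 8, 10), f)               # 8 rows x 10 cols
  img <- load_image(f, ratio = 0.1)
  expect_s3_class(img, "ceph_image")
  expect_equal(img$width, 10)
  expect_equal(img$height, 8)
  expect_true(all(img$pixels == 0))
  expect_equal(img$ratio, 0.1)
  expect_null(load_image(f)$ratio)
})

test_that("RGB images collapse to luminance; gray RGB equals the channel", {
  f <- tempfile(fileext = ".png")
  arr <- array(0.4, c(5, 4, 3))
  png::writePNG(arr, f)
  img <- load_image(f)
  expect_equal(img$pixels, matrix(0.4, 5, 4), tolerance = 1e-3)
})

test_that("uncompressed 24-bit BMP round-trips through the reader", {
  set.seed(7)
  px <- matrix(round(runif(35) * 255) / 255, 5, 7)
  f <- tempfile(fileext = ".bmp")
  write_bmp24(px, f)
  img <- load_image(f)
  expect_equal(dim(img$pixels), c(5, 7))
  expect_equal(img$pixels, px, tolerance = 1e-9)
})

test_that("TIFF images load with the same orientation as PNG", {
  px <- matrix(seq(0, 1, length.out = 12), 3, 4)
  fp <- tempfile(fileext = ".png"); ft <- tempfile(fileext = ".tiff")
  png::writePNG(px, fp)
  tiff::writeTIFF(px, ft)
  # writers may round or truncate to 8 bits; allow one quantization step
  expect_lt(max(abs(load_image(ft)$pixels - load_image(fp)$pixels)), 1.5 / 255)
  expect_equal(dim(load_image(ft)$pixels), dim(load_image(fp)$pixels))
})

test_that("rescale_to_width scales size, landmarks and ratio consistently", {
  set.seed(1)
  img <- ceph_image(matrix(runif(80 * 100), 80, 100), ratio = 0.05)
  lm <- landmark_set(cbind(runif(19, 5, 95), runif(19, 5, 75)), "ceph19")
  out <- rescale_to_width(img, lm, 50)
  expect_equal(out$factor, 0.5)
  expect_equal(out$image$width, 50)
  expect_equal(out$image$height, 40)
  expect_equal(out$landmarks$points, lm$points * 0.5)
  expect_equal(out$image$ratio, 0.1)
  # identity at the target width
  same <- rescale_to_width(img, lm, 100)
  expect_identical(same$image$pixels, img$pixels)
  expect_identical(same$landmarks$points, lm$points)
})

test_that("physical inter-landmark distances are invariant under rescale", {
  set.seed(2)
  img <- ceph_image(matrix(runif(120 * 160), 120, 160), ratio = 0.08)
  lm <- landmark_set(cbind(runif(19, 0, 159), runif(19, 0, 119)), "ceph19")
  out <- rescale_to_width(img, lm, 80)
  for (k in 1:20) {
    ij <- sample(19, 2)
    d0 <- distance_between_points(lm$points[ij[1], ], lm$points[ij[2], ],
                                  img$ratio)
    d1 <- distance_between_points(out$landmarks$points[ij[1], ],
                                  out$landmarks$points[ij[2], ],
                                  out$image$ratio)
    expect_equal(d1, d0, tolerance = 0.01)
  }
  # down-and-back returns landmarks within a pixel
  back <- rescale_to_width(out$image, out$landmarks, 160)
  expect_lt(max(abs(back$landmarks$points - lm$points)), 1)
})

test_that("annotation files round-trip to the documented precision", {
  set.seed(3)
  for (k in 1:100) {
    pts <- cbind(runif(19, 0, 489), runif(19, 0, 599))
    lm <- landmark_set(pts, "ceph19")
    f <- tempfile(fileext = ".txt")
    write_annotation(lm, f)
    back <- read_annotation(f, "ceph19")
    expect_lt(max(abs(back$points - pts)), 0.01)
    unlink(f)
  }
})

test_that("annotation reading validates line count and format", {
  f <- tempfile(fileext = ".txt")
  writeLines(rep("10.0,20.0", 19), f)
  lm <- read_annotation(f, "ceph19")
  expect_equal(nrow(lm$points), 19)
  expect_true(all(lm$points[, 1] == 10 & lm$points[, 2] == 20))

  writeLines(rep("10.0,20.0", 18), f)
  expect_error(read_annotation(f, "ceph19"), class = "cephvote_scheme_error")

  writeLines(c(rep("1,2", 4), "not-a-point", rep("1,2", 14)), f)
  expect_error(read_annotation(f, "ceph19"), "line 5",
               class = "cephvote_format_error")
})

test_that("one-based annotation files can be shifted on load", {
  f <- tempfile(fileext = ".txt")
  writeLines(rep("11,21", 19), f)
  lm <- read_annotation(f, "ceph19", one_based = TRUE)
  expect_true(all(lm$points[, 1] == 10 & lm$points[, 2] == 20))
})
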