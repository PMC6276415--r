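# Image and annotation I/O, rescaling, calibration.
#
# Coordinate convention (shared by every module): 0-based, x = column index
# increasing rightward, y = row index increasing downward.  A point (x, y)
# addresses pixel matrix cell [y + 1, x + 1].

#' Construct a grayscale cephalogram image object
#'
#' @param pixels numeric matrix of intensities, `height x width`, row = y.
#' @param ratio optional mm-per-pixel calibration scale (> 0).
#' @param id image identifier string.
#' @return an object of class `ceph_image` with fields `pixels`, `width`,
#'   `height`, `ratio`, `id`.
#' @export
ceph_image <- function(pixels, ratio = NULL, id = "") {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stopf("pixels must be a numeric matrix")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stopf("image must have width >= 1 and height >= 1")
  if (!all(is.finite(pixels)))
    stopf("image intensities must be finite")
  if (!is.null(ratio)) {
    if (!is.numeric(ratio) || length(ratio) != 1L || !is.finite(ratio) || ratio <= 0)
      stopf("ratio must be a single positive number (mm/pixel)")
    ratio <- as.numeric(ratio)
  }
  structure(
    list(pixels = pixels, width = ncol(pixels), height = nrow(pixels),
         ratio = ratio, id = as.character(id)),
    class = "ceph_image")
}

#' @export
print.ceph_image <- function(x, ...) {
  cat(sprintf("<ceph_image '%s' %dx%d px, ratio %s mm/px>\n", x$id,
              x$width, x$height,
              if (is.null(x$ratio)) "unset" else format(x$ratio)))
  invisible(x)
}

# Fixed Rec. 601 luminance weights for RGB -> gray collapse.
LUMA_WEIGHTS <- c(r = 0.299, g = 0.587, b = 0.114)

collapse_gray <- function(arr) {
  if (is.matrix(arr)) return(arr)
  if (length(dim(arr)) == 3L) {
    nc <- dim(arr)[3]
    if (nc == 1L) return(arr[, , 1L])
    if (nc >= 3L) {
      return(LUMA_WEIGHTS["r"] * arr[, , 1L] + LUMA_WEIGHTS["g"] * arr[, , 2L] +
               LUMA_WEIGHTS["b"] * arr[, , 3L])
    }
    if (nc == 2L) return(arr[, , 1L])  # gray + alpha
  }
  stopf("cannot collapse array with dims [%s] to grayscale",
        paste(dim(arr), collapse = ", "))
}

read_bmp_gray <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 54L || rawToChar(raw[1:2]) != "BM")
    stopf("not a BMP file: %s", path)
  le <- function(idx) sum(as.integer(raw[idx]) * 256^(seq_along(idx) - 1))
  data_off <- le(11:14)
  hdr_size <- le(15:18)
  w <- le(19:22)
  h_raw <- le(23:26)
  top_down <- h_raw > 2^31 / 2
  h <- if (top_down) 2^32 - h_raw else h_raw
  bpp <- le(29:30)
  compression <- le(31:34)
  if (compression != 0)
    stopf("only uncompressed BMP is supported")
  if (!bpp %in% c(8L, 24L))
    stopf("only 8-bit and 24-bit BMP are supported (got %d-bit)", bpp)
  if (w < 1 || h < 1) stopf("zero-sized BMP image")
  row_bytes <- ((w * bpp / 8 + 3) %/% 4) * 4
  px <- matrix(0, nrow = h, ncol = w)
  if (bpp == 8L) {
    pal_n <- (data_off - 14 - hdr_size) / 4
    pal <- if (pal_n >= 1) {
      p <- matrix(as.integer(raw[(14 + hdr_size + 1):(14 + hdr_size + 4 * pal_n)]),
                  nrow = 4)
      # palette entries are B,G,R,reserved
      LUMA_WEIGHTS["b"] * p[1, ] + LUMA_WEIGHTS["g"] * p[2, ] + LUMA_WEIGHTS["r"] * p[3, ]
    } else 0:255
    for (r in seq_len(h)) {
      off <- data_off + (r - 1) * row_bytes
      idx <- as.integer(raw[(off + 1):(off + w)])
      px[if (top_down) r else h - r + 1, ] <- pal[idx + 1]
    }
  } else {
    for (r in seq_len(h)) {
      off <- data_off + (r - 1) * row_bytes
      v <- as.integer(raw[(off + 1):(off + 3 * w)])
      b <- v[seq(1, 3 * w, by = 3)]
      g <- v[seq(2, 3 * w, by = 3)]
      rr <- v[seq(3, 3 * w, by = 3)]
      px[if (top_down) r else h - r + 1, ] <-
        LUMA_WEIGHTS["r"] * rr + LUMA_WEIGHTS["g"] * g + LUMA_WEIGHTS["b"] * b
    }
  }
  px / 255
}

#' Load a grayscale radiograph image
#'
#' Reads PNG, TIFF or uncompressed BMP, collapses color channels to a single
#' luminance channel with fixed Rec. 601 weights (0.299, 0.587, 0.114), and
#' attaches an optional mm-per-pixel calibration ratio.  Intensities are on
#' a `[0, 1]` scale.
#'
#' @param path image file path.
#' @param ratio optional mm-per-pixel calibration, attached unchanged.
#' @param id identifier; defaults to the file name without extension.
#' @return a [ceph_image()] object.
#' @export
load_image <- function(path, ratio = NULL, id = NULL) {
  if (!file.exists(path)) stopf("image file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    bmp = read_bmp_gray(path),
    stopf("unsupported image format '.%s' (PNG/TIFF/BMP)", ext))
  px <- collapse_gray(arr)
  if (!is.matrix(px)) px <- as.matrix(px)
  ceph_image(px, ratio = ratio,
             id = id %||% tools::file_path_sans_ext(basename(path)))
}

#' Write an image to PNG
#'
#' Intensities are clipped to `[0, 1]`.
#'
#' @param image a [ceph_image()].
#' @param path output path ending in `.png`.
#' @export
save_image <- function(image, path) {
  stopifnot(inherits(image, "ceph_image"))
  png::writePNG(clamp(image$pixels, 0, 1), target = path)
  invisible(path)
}

# Vectorized bilinear resampling of a pixel matrix to (new_h, new_w), with
# output pixel (x', y') sampling the input at (x'/fx, y'/fy) so that the
# landmark transfer x' = x * f matches the resampled grid.
bilinear_resize <- function(px, new_h, new_w) {
  h <- nrow(px); w <- ncol(px)
  fx <- new_w / w; fy <- new_h / h
  xs <- clamp((seq_len(new_w) - 1) / fx, 0, w - 1)
  ys <- clamp((seq_len(new_h) - 1) / fy, 0, h - 1)
  x0 <- floor(xs); x1 <- pmin(x0 + 1, w - 1); wx <- xs - x0
  y0 <- floor(ys); y1 <- pmin(y0 + 1, h - 1); wy <- ys - y0
  wxm <- matrix(wx, new_h, new_w, byrow = TRUE)
  wym <- matrix(wy, new_h, new_w)
  a <- px[y0 + 1, x0 + 1, drop = FALSE]; b <- px[y0 + 1, x1 + 1, drop = FALSE]
  cc <- px[y1 + 1, x0 + 1, drop = FALSE]; d <- px[y1 + 1, x1 + 1, drop = FALSE]
  (1 - wym) * ((1 - wxm) * a + wxm * b) + wym * ((1 - wxm) * cc + wxm * d)
}

#' Rescale an image (and landmarks) to a fixed working width
#'
#' All images are brought to a common pixel width before detector training
#' and prediction (the standard working width for full-size cephalograms is
#' 1960 pixels).  Height scales by the same factor so the aspect ratio is
#' preserved; landmark coordinates are multiplied by the factor, and the
#' mm/pixel ratio is divided by it so physical distances are unchanged.
#'
#' @param image a [ceph_image()].
#' @param landmarks optional [landmark_set()] in the image's coordinates.
#' @param target_width desired pixel width (>= 1).
#' @return list with elements `image`, `landmarks` (NULL if not given) and
#'   `factor` (the applied scale factor).
#' @export
rescale_to_width <- function(image, landmarks = NULL, target_width) {
  stopifnot(inherits(image, "ceph_image"))
  if (!is_count(target_width)) stopf("target_width must be a positive integer")
  f <- target_width / image$width
  if (f == 1) {
    return(list(image = image, landmarks = landmarks, factor = 1))
  }
  new_h <- max(1L, as.integer(round(image$height * f)))
  px <- bilinear_resize(image$pixels, new_h, as.integer(target_width))
  out_ratio <- if (is.null(image$ratio)) NULL else image$ratio / f
  img2 <- ceph_image(px, ratio = out_ratio, id = image$id)
  lm2 <- NULL
  if (!is.null(landmarks)) {
    stopifnot(inherits(landmarks, "ceph_landmarks"))
    lm2 <- landmarks
    lm2$points <- landmarks$points * f
  }
  list(image = img2, landmarks = lm2, factor = f)
}
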