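# SIFT-style gradient-orientation descriptors of square image patches.
#
# A patch of side 2W+1 centered on a pixel is divided into a 4x4 grid of
# cells; each cell contributes an 8-bin orientation histogram over [0, 2pi)
# in which every pixel deposits its full gradient magnitude into the single
# bin containing its gradient angle (hard assignment).  The 16 histograms,
# concatenated row-major, form the 128-long feature vector.  No trilinear
# interpolation, Gaussian windowing or normalization is applied by default;
# L2 normalization is available as an option.

#' Patch descriptor configuration
#'
#' @param W patch half-window in pixels; the patch side is `2W + 1`.
#'   The full-resolution default for cephalograms at the 1960-px working
#'   width is 48.
#' @param normalize if TRUE, descriptors are L2-normalized (all-zero
#'   descriptors are left as zero).  Default FALSE.
#' @return a list of class `ceph_patch_config`.
#' @export
patch_config <- function(W = 48, normalize = FALSE) {
  if (!is_count(W) || W < 2) stopf("W must be an integer >= 2")
  structure(list(W = as.integer(W), grid = 4L, bins = 8L,
                 normalize = isTRUE(normalize)),
            class = "ceph_patch_config")
}

# Central-difference gradients with replicated borders, along the x (dim 2)
# and y (dim 1) axes of a (side, side, n) patch stack.
grad_stack <- function(arr) {
  d <- dim(arr)
  h <- d[1]; w <- d[2]
  xr <- c(2:w, w); xl <- c(1, 1:(w - 1))
  yd <- c(2:h, h); yu <- c(1, 1:(h - 1))
  if (length(d) == 3L) {
    px <- (arr[, xr, , drop = FALSE] - arr[, xl, , drop = FALSE]) / 2
    py <- (arr[yd, , , drop = FALSE] - arr[yu, , , drop = FALSE]) / 2
  } else {
    px <- (arr[, xr, drop = FALSE] - arr[, xl, drop = FALSE]) / 2
    py <- (arr[yd, , drop = FALSE] - arr[yu, , drop = FALSE]) / 2
  }
  gm <- sqrt(px * px + py * py)
  ga <- atan2(py, px)
  ga[ga < 0] <- ga[ga < 0] + 2 * pi
  ga[ga >= 2 * pi] <- 0
  ga[gm == 0] <- 0
  list(px = px, py = py, gm = gm, ga = ga)
}

#' Gradient field of an image patch
#'
#' Finite (central) differences with replicated borders.  The gradient
#' magnitude is `sqrt(Px^2 + Py^2)`; the gradient angle is the full-quadrant
#' arctangent of `(Py, Px)` in image coordinates (y down), mapped to
#' `[0, 2pi)`, with angle 0 by convention where the gradient vanishes.
#'
#' @param patch numeric matrix, at least 3x3.
#' @return list with matrices `px`, `py`, `gm`, `ga`.
#' @export
patch_gradient <- function(patch) {
  patch <- as.matrix(patch)
  if (nrow(patch) < 3L || ncol(patch) < 3L)
    stopf("patch must be at least 3x3")
  grad_stack(patch)
}

# 0-based cell index (0..15, row-major) of each pixel of a side x side
# patch: cell boundaries at floor(side * i / 4).
cell_index_matrix <- function(side) {
  bnd <- floor(side * (0:4) / 4)
  cell1d <- findInterval(0:(side - 1), bnd, rightmost.closed = FALSE) - 1L
  outer(cell1d, cell1d, function(r, c) r * 4L + c)
}

#' Patch descriptors for a batch of centers
#'
#' Extracts the 128-long gradient-orientation descriptor of the square patch
#' centered at every given position.  Patches overhanging the image border
#' are completed by edge replication.  The single-center convenience wrapper
#' is [sift_patch_descriptor()].
#'
#' @param image a [ceph_image()] or a plain numeric matrix.
#' @param centers n x 2 matrix of 0-based (x, y) centers, inside the image.
#' @param cfg a [patch_config()].
#' @return n x 128 numeric matrix, one descriptor per row.
#' @export
sift_descriptors <- function(image, centers, cfg = patch_config()) {
  px <- if (inherits(image, "ceph_image")) image$pixels else as.matrix(image)
  centers <- matrix(as.numeric(centers), ncol = 2L)
  h <- nrow(px); w <- ncol(px)
  cx <- round(centers[, 1]); cy <- round(centers[, 2])
  if (any(cx < 0 | cx > w - 1 | cy < 0 | cy > h - 1))
    stopf("patch center outside image bounds")
  desc <- cpp_sift_descriptors(px, as.integer(cx), as.integer(cy), cfg$W)
  if (cfg$normalize) {
    nrm <- sqrt(rowSums(desc^2))
    nz <- nrm > 0
    desc[nz, ] <- desc[nz, , drop = FALSE] / nrm[nz]
  }
  desc
}

#' Patch descriptor at a single center
#'
#' @inheritParams sift_descriptors
#' @param center length-2 numeric (x, y), 0-based, inside the image.
#' @return numeric vector of length 128.
#' @export
sift_patch_descriptor <- function(image, center, cfg = patch_config()) {
  drop(sift_descriptors(image, matrix(center, ncol = 2L), cfg))
}
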