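# Multiresolution decision-tree regression voting (MDTRV).
#
# One CART regression tree per (landmark, scale) maps SIFT-style patch
# descriptors to displacements from the patch center to the landmark.  At
# the coarsest scale, patches are sampled over the whole image; at finer
# scales they are sampled in the (2S+1) x (2S+1) neighborhood of the true
# position (training) or of the estimate propagated from the previous scale
# (detection).  Predicted displacements are accumulated by single unit
# voting and the accumulator peak is the stage estimate.  At full scale the
# estimate is refined by a bootstrap ensemble of B trees voting jointly.

#' Detector configuration
#'
#' @param scales increasing resolution schedule; the default coarse-to-fine
#'   schedule is 0.125, 0.25, 0.5, 1.
#' @param K training patches sampled per image, landmark and scale.
#' @param Kp test patches sampled per landmark and scale (K' in the usual
#'   notation).
#' @param W patch half-window in that stage's pixel units (patch side
#'   2W + 1); a single W is used at every scale.
#' @param S neighborhood half-size for patch sampling at the finer scales.
#' @param B number of bootstrap trees in the full-scale refinement ensemble.
#' @param max_splits split budget per tree (see [fit_regression_tree()]).
#' @param qed_tol per-node quadratic-error tolerance.
#' @param target_width working pixel width images are rescaled to before
#'   training/detection; `NULL` keeps images at their native width.  The
#'   standard width for full-size cephalograms is 1960.
#' @param smooth_sigma accumulator Gaussian smoothing in pixels; 0 (default)
#'   is plain single unit voting.
#' @return list of class `ceph_mdtrv_config`.
#' @export
mdtrv_config <- function(scales = c(0.125, 0.25, 0.5, 1), K = 50L, Kp = 400L,
                         W = 48L, S = 40L, B = 8L, max_splits = 256L,
                         qed_tol = 1e-6, target_width = NULL,
                         smooth_sigma = 0) {
  scales <- as.numeric(scales)
  if (length(scales) < 1L || is.unsorted(scales, strictly = TRUE) ||
      any(scales <= 0) || scales[length(scales)] != 1)
    stopf("scales must be strictly increasing, positive, and end at 1")
  stopifnot(is_count(K), is_count(Kp), is_count(W), is_count(S), is_count(B))
  structure(list(scales = scales, K = as.integer(K), Kp = as.integer(Kp),
                 W = as.integer(W), S = as.integer(S), B = as.integer(B),
                 max_splits = as.integer(max_splits), qed_tol = qed_tol,
                 target_width = target_width, smooth_sigma = smooth_sigma),
            class = "ceph_mdtrv_config")
}

#' Sample patch centers for training or prediction
#'
#' Centers are integer pixel positions drawn uniformly with replacement,
#' either from the whole image interior or from the `(2S+1) x (2S+1)`
#' neighborhood of an anchor, clipped to the image bounds.
#'
#' @param shape image shape `c(height, width)` or a [ceph_image()].
#' @param mode `"whole"` or `"neighborhood"`.
#' @param anchor (x, y) anchor, required in neighborhood mode.
#' @param S neighborhood half-size in pixels.
#' @param K number of centers.
#' @param seed optional integer; when given, sampling is seeded locally and
#'   the caller's RNG state is untouched.
#' @return K x 2 integer matrix of (x, y) centers.
#' @export
sample_patch_centers <- function(shape, mode = c("whole", "neighborhood"),
                                 anchor = NULL, S = 40L, K = 50L,
                                 seed = NULL) {
  if (inherits(shape, "ceph_image")) shape <- c(shape$height, shape$width)
  mode <- match.arg(mode)
  h <- shape[1]; w <- shape[2]
  if (h < 1 || w < 1) stopf("empty sampling region")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  if (mode == "whole") {
    xlo <- 0; xhi <- w - 1; ylo <- 0; yhi <- h - 1
  } else {
    if (is.null(anchor)) stopf("neighborhood sampling requires an anchor")
    ax <- round(anchor[1]); ay <- round(anchor[2])
    xlo <- max(0, ax - S); xhi <- min(w - 1, ax + S)
    ylo <- max(0, ay - S); yhi <- min(h - 1, ay + S)
    if (xlo > xhi || ylo > yhi) stopf("empty sampling region")
  }
  cbind(x = sample(xlo:xhi, K, replace = TRUE),
        y = sample(ylo:yhi, K, replace = TRUE))
}

gaussian_blur_matrix <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2)); k <- k / sum(k)
  pad <- function(v, n) c(rep(v[1], n), v, rep(v[length(v)], n))
  conv1 <- function(v) stats::filter(pad(v, r), k, sides = 2)[(r + 1):(r + length(v))]
  m <- apply(m, 2, conv1)
  t(apply(t(m), 2, conv1))
}

#' Accumulate displacement votes and locate the peak
#'
#' Each vote is `center + displacement`, rounded to the nearest pixel;
#' out-of-bounds votes are discarded and each in-bounds vote adds one unit
#' to its accumulator cell.  The returned position is the arithmetic mean of
#' all cells attaining the maximum count.  If every vote falls outside the
#' image, the image center is returned and `fallback` is TRUE (a warning is
#' issued).
#'
#' @param centers n x 2 matrix of (x, y) patch centers.
#' @param displacements n x 2 matrix of predicted (dx, dy).
#' @param shape image shape `c(height, width)` or a [ceph_image()].
#' @param smooth_sigma optional Gaussian smoothing (pixels) of the
#'   accumulator before peak finding; 0 = single unit voting.
#' @param accumulator if TRUE, include the full count grid in the result.
#' @return list with `position` (x, y), `peak_count`, `n_votes` (in-bounds
#'   count), `fallback`, and optionally `accumulator` (height x width
#'   matrix of counts).
#' @export
vote_landmark <- function(centers, displacements, shape, smooth_sigma = 0,
                          accumulator = FALSE) {
  if (inherits(shape, "ceph_image")) shape <- c(shape$height, shape$width)
  centers <- matrix(as.numeric(centers), ncol = 2L)
  displacements <- matrix(as.numeric(displacements), ncol = 2L)
  if (nrow(centers) != nrow(displacements))
    stopf("centers and displacements must have the same length")
  h <- shape[1]; w <- shape[2]
  vx <- round(centers[, 1] + displacements[, 1])
  vy <- round(centers[, 2] + displacements[, 2])
  ok <- vx >= 0 & vx <= w - 1 & vy >= 0 & vy <= h - 1
  if (!any(ok)) {
    warning("all votes out of bounds; falling back to the image center")
    out <- list(position = c((w - 1) / 2, (h - 1) / 2), peak_count = 0L,
                n_votes = 0L, fallback = TRUE)
    if (accumulator) out$accumulator <- matrix(0L, h, w)
    return(out)
  }
  enc <- vy[ok] * w + vx[ok]
  counts <- tabulate(enc + 1L, nbins = h * w)
  if (smooth_sigma > 0) {
    acc <- t(matrix(counts, nrow = w, ncol = h))
    sm <- gaussian_blur_matrix(acc, smooth_sigma)
    peak <- which(sm == max(sm), arr.ind = TRUE)
    pos <- c(mean(peak[, 2]) - 1, mean(peak[, 1]) - 1)
    out <- list(position = pos, peak_count = max(acc), n_votes = sum(ok),
                fallback = FALSE)
    if (accumulator) out$accumulator <- acc
    return(out)
  }
  mx <- max(counts)
  cells <- which(counts == mx) - 1L
  pos <- c(mean(cells %% w), mean(cells %/% w))
  out <- list(position = pos, peak_count = mx, n_votes = sum(ok),
              fallback = FALSE)
  if (accumulator) out$accumulator <- t(matrix(counts, nrow = w, ncol = h))
  out
}

resize_stage <- function(px, scale) {
  if (scale == 1) return(px)
  bilinear_resize(px, max(1L, as.integer(round(nrow(px) * scale))),
                  max(1L, as.integer(round(ncol(px) * scale))))
}

prep_working <- function(image, landmarks, config) {
  if (!is.null(config$target_width) && image$width != config$target_width) {
    r <- rescale_to_width(image, landmarks, config$target_width)
    list(image = r$image, landmarks = r$landmarks)
  } else list(image = image, landmarks = landmarks)
}

#' Train an MDTRV landmark detector
#'
#' For every scale in the schedule, each training image is resampled
#' (bilinear) and landmark truth rescaled accordingly; K patch centers per
#' image are drawn (whole-image at the coarsest scale, in the neighborhood
#' of the true position at the finer scales), patch descriptors and
#' displacements (truth - center) are pooled over images, and one regression
#' tree is fitted per (landmark, scale).  A refinement ensemble of B trees
#' is fitted at full scale on bootstrap resamples of that scale's pool.
#'
#' @param images list of [ceph_image()] training images.
#' @param landmarks list of [landmark_set()] ground truth, parallel to
#'   `images`.
#' @param config a [mdtrv_config()].
#' @param seed master seed; every random draw in training derives from it.
#' @param verbose print per-stage progress.
#' @return model of class `ceph_mdtrv`.
#' @export
train_mdtrv <- function(images, landmarks, config = mdtrv_config(),
                        seed = 1L, verbose = FALSE) {
  stopifnot(length(images) >= 1L, length(images) == length(landmarks))
  L <- n_landmarks(landmarks[[1]])
  for (lm in landmarks) {
    if (n_landmarks(lm) != L || !all(is.finite(lm$points)))
      stopf("every training image needs a complete landmark set")
  }
  pcfg <- patch_config(config$W)
  n_img <- length(images)
  n_stage <- length(config$scales)
  work <- lapply(seq_len(n_img), function(i) prep_working(images[[i]], landmarks[[i]], config))
  seeds <- derive_seeds(seed, n_stage + 1L)

  trees <- replicate(L, vector("list", n_stage), simplify = FALSE)
  stage1_pool <- NULL  # full-scale pool retained for the refinement forest
  for (s in seq_len(n_stage)) {
    t0 <- Sys.time()
    sc <- config$scales[s]
    set.seed(seeds[s])
    feats <- replicate(L, vector("list", n_img), simplify = FALSE)
    disps <- replicate(L, vector("list", n_img), simplify = FALSE)
    for (i in seq_len(n_img)) {
      px <- resize_stage(work[[i]]$image$pixels, sc)
      truth <- work[[i]]$landmarks$points * sc
      shape <- dim(px)
      ctrs <- lapply(seq_len(L), function(l) {
        if (s == 1L) {
          sample_patch_centers(shape, "whole", K = config$K)
        } else {
          sample_patch_centers(shape, "neighborhood", anchor = truth[l, ],
                               S = config$S, K = config$K)
        }
      })
      # one descriptor pass per image covering all landmarks' patches
      X_all <- sift_descriptors(px, do.call(rbind, ctrs), pcfg)
      for (l in seq_len(L)) {
        rows <- ((l - 1L) * config$K + 1L):(l * config$K)
        feats[[l]][[i]] <- X_all[rows, , drop = FALSE]
        disps[[l]][[i]] <- cbind(truth[l, 1] - ctrs[[l]][, 1],
                                 truth[l, 2] - ctrs[[l]][, 2])
      }
    }
    for (l in seq_len(L)) {
      X <- do.call(rbind, feats[[l]]); D <- do.call(rbind, disps[[l]])
      trees[[l]][[s]] <- fit_regression_tree(X, D, max_splits = config$max_splits,
                                             qed_tol = config$qed_tol)
      if (s == n_stage) {
        if (is.null(stage1_pool)) stage1_pool <- vector("list", L)
        stage1_pool[[l]] <- list(X = X, D = D)
      }
    }
    if (verbose)
      message(sprintf("stage %d (scale %g): trained %d trees in %.1fs",
                      s, sc, L, as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }

  # bootstrap refinement ensemble at full scale
  set.seed(seeds[n_stage + 1L])
  forest <- vector("list", L)
  for (l in seq_len(L)) {
    X <- stage1_pool[[l]]$X; D <- stage1_pool[[l]]$D
    n <- nrow(X)
    forest[[l]] <- lapply(seq_len(config$B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      fit_regression_tree(X[idx, , drop = FALSE], D[idx, , drop = FALSE],
                          max_splits = config$max_splits,
                          qed_tol = config$qed_tol)
    })
  }
  structure(list(scheme = landmarks[[1]]$scheme,
                 landmark_names = landmarks[[1]]$names,
                 config = config, trees = trees, forest = forest,
                 seed = as.integer(seed)),
            class = "ceph_mdtrv")
}

#' @export
print.ceph_mdtrv <- function(x, ...) {
  cat(sprintf("<ceph_mdtrv %d landmarks ('%s'), %d scales, %d+%d trees/landmark>\n",
              length(x$trees), x$scheme, length(x$config$scales),
              length(x$config$scales), x$config$B))
  invisible(x)
}

#' Refine a landmark estimate with the voting ensemble
#'
#' K' patch centers are drawn around the initial estimate; every tree of the
#' ensemble casts one unit vote per center, and the peak of the joint
#' accumulator (same tie rule as [vote_landmark()]) is returned.
#'
#' @param forest list of `ceph_tree` regressors for one landmark.
#' @param image full-scale [ceph_image()] or pixel matrix.
#' @param initial (x, y) initial estimate, in bounds.
#' @param config an [mdtrv_config()].
#' @return list as returned by [vote_landmark()].
#' @export
hough_refine <- function(forest, image, initial, config = mdtrv_config()) {
  px <- if (inherits(image, "ceph_image")) image$pixels else as.matrix(image)
  shape <- dim(px)
  ctr <- sample_patch_centers(shape, "neighborhood", anchor = initial,
                              S = config$S, K = config$Kp)
  X <- sift_descriptors(px, ctr, patch_config(config$W))
  all_ctr <- ctr[rep(seq_len(nrow(ctr)), length(forest)), , drop = FALSE]
  all_disp <- do.call(rbind, lapply(forest, function(tr) tree_predict(tr, X)))
  vote_landmark(all_ctr, all_disp, shape, smooth_sigma = config$smooth_sigma)
}

#' Detect landmarks in a cephalogram with a trained MDTRV model
#'
#' Runs the coarse-to-fine schedule: at the coarsest scale K' whole-image
#' patches vote for each landmark; at each finer scale the previous estimate
#' (multiplied by the dyadic resolution ratio) anchors neighborhood
#' sampling; after the full-scale stage the bootstrap ensemble refines the
#' estimate.  Positions are returned at the working resolution, clamped to
#' the image bounds.
#'
#' @param model a [train_mdtrv()] model.
#' @param image a [ceph_image()].
#' @param seed master seed for the test-time patch sampling.
#' @param keep_stages if TRUE, attach a `stages` attribute: a list (one
#'   element per scale, plus `"refined"`) of L x 2 matrices of estimates in
#'   working-resolution coordinates.
#' @return a [landmark_set()] of detected positions.
#' @export
detect_landmarks <- function(model, image, seed = 1L, keep_stages = FALSE) {
  stopifnot(inherits(model, "ceph_mdtrv"), inherits(image, "ceph_image"))
  config <- model$config
  L <- length(model$trees)
  pcfg <- patch_config(config$W)
  work <- prep_working(image, NULL, config)$image
  n_stage <- length(config$scales)
  pyr <- lapply(config$scales, function(sc) resize_stage(work$pixels, sc))
  seeds <- derive_seeds(seed, n_stage + 1L)

  est <- matrix(NA_real_, L, 2L)
  stage_rec <- if (keep_stages) vector("list", n_stage + 1L) else NULL
  for (s in seq_len(n_stage)) {
    px <- pyr[[s]]
    shape <- dim(px)
    set.seed(seeds[s])
    ctrs <- lapply(seq_len(L), function(l) {
      if (s == 1L) {
        sample_patch_centers(shape, "whole", K = config$Kp)
      } else {
        ratio_s <- config$scales[s] / config$scales[s - 1L]
        anchor <- clamp(est[l, ] * ratio_s, 0, c(shape[2] - 1, shape[1] - 1))
        sample_patch_centers(shape, "neighborhood", anchor = anchor,
                             S = config$S, K = config$Kp)
      }
    })
    X_all <- sift_descriptors(px, do.call(rbind, ctrs), pcfg)
    for (l in seq_len(L)) {
      rows <- ((l - 1L) * config$Kp + 1L):(l * config$Kp)
      disp <- tree_predict(model$trees[[l]][[s]], X_all[rows, , drop = FALSE])
      v <- vote_landmark(ctrs[[l]], disp, shape,
                         smooth_sigma = config$smooth_sigma)
      est[l, ] <- v$position
    }
    if (keep_stages)
      stage_rec[[s]] <- est / config$scales[s]
  }
  # refinement at full scale
  set.seed(seeds[n_stage + 1L])
  for (l in seq_len(L)) {
    v <- hough_refine(model$forest[[l]], pyr[[n_stage]], est[l, ], config)
    est[l, ] <- v$position
  }
  est[, 1] <- clamp(est[, 1], 0, work$width - 1)
  est[, 2] <- clamp(est[, 2], 0, work$height - 1)
  if (keep_stages) {
    stage_rec[[n_stage + 1L]] <- est
    names(stage_rec) <- c(paste0("scale_", config$scales), "refined")
  }
  out <- landmark_set(est, if (model$scheme %in% c("ceph19", "ceph45"))
    model$scheme else model$landmark_names)
  if (keep_stages) attr(out, "stages") <- stage_rec
  out
}

# --- model serialization ----------------------------------------------------

#' Write / read an MDTRV model as structured text (JSON)
#'
#' @param model a `ceph_mdtrv` model.
#' @param path file path.
#' @export
write_model <- function(model, path) {
  lst <- list(scheme = model$scheme, landmark_names = model$landmark_names,
              config = unclass(model$config), seed = model$seed,
              trees = lapply(model$trees, function(ts) lapply(ts, tree_to_list)),
              forest = lapply(model$forest, function(fs) lapply(fs, tree_to_list)))
  jsonlite::write_json(lst, path, digits = NA, auto_unbox = TRUE, null = "null",
                       na = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  cfg <- lst$config
  config <- mdtrv_config(scales = unlist(cfg$scales), K = cfg$K, Kp = cfg$Kp,
                         W = cfg$W, S = cfg$S, B = cfg$B,
                         max_splits = cfg$max_splits, qed_tol = cfg$qed_tol,
                         target_width = cfg$target_width,
                         smooth_sigma = cfg$smooth_sigma)
  relist_tree <- function(tl) {
    tl <- lapply(tl, function(v) if (is.list(v)) unlist(lapply(v, function(z)
      if (is.null(z)) NA else z)) else v)
    tree_from_list(tl)
  }
  structure(list(scheme = lst$scheme,
                 landmark_names = unlist(lst$landmark_names),
                 config = config,
                 trees = lapply(lst$trees, function(ts) lapply(ts, relist_tree)),
                 forest = lapply(lst$forest, function(fs) lapply(fs, relist_tree)),
                 seed = lst$seed),
            class = "ceph_mdtrv")
}
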