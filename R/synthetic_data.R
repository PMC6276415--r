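# Synthetic cephalogram generator with exact landmark ground truth.
#
# Images emulate the structure the detector assumes: bright smooth curves
# (cranial vault, facial soft-tissue profile, mandibular border, palatal
# line, incisor bars) on a darker background, with a localized density at
# every landmark locus, per-image shape variation (global similarity
# transform plus small per-point jitter applied identically to the rendered
# structures and to the stored truth), a smooth illumination gradient and
# additive Gaussian noise.  Ground truth is exact by construction: the
# stored landmark positions are the very control points the structures are
# drawn through.

#' Synthetic dataset configuration
#'
#' Defaults emulate a quarter-scale working cephalogram: 490 x 600 pixels
#' at 0.1 mm/px with the 19-landmark scheme.
#'
#' @param width,height canvas size in pixels.
#' @param scheme `"ceph19"` or `"ceph45"`.
#' @param ratio mm-per-pixel calibration attached to every image.
#' @param noise_sd additive Gaussian noise standard deviation (intensity
#'   units, image range is 0..1).
#' @param jitter half-range (px) of the uniform per-landmark shape jitter.
#' @param max_shift half-range (px) of the global translation.
#' @param max_rot_deg half-range (degrees) of the global rotation.
#' @param max_log_scale half-range of the global log-scale factor.
#' @param illum_amp peak-to-peak amplitude of the linear illumination field.
#' @param n_images number of images in a generated dataset.
#' @param seed master seed for [generate_dataset()].
#' @return list of class `ceph_synth_config`.
#' @export
synthetic_config <- function(width = 490L, height = 600L, scheme = "ceph19",
                             ratio = 0.1, noise_sd = 0.03, jitter = 3,
                             max_shift = 12, max_rot_deg = 3,
                             max_log_scale = 0.04, illum_amp = 0.08,
                             n_images = 25L, seed = 0L) {
  stopifnot(is_count(width), is_count(height), is_count(n_images))
  structure(list(width = as.integer(width), height = as.integer(height),
                 scheme = scheme, ratio = ratio, noise_sd = noise_sd,
                 jitter = jitter, max_shift = max_shift,
                 max_rot_deg = max_rot_deg, max_log_scale = max_log_scale,
                 illum_amp = illum_amp, n_images = as.integer(n_images),
                 seed = as.integer(seed)),
            class = "ceph_synth_config")
}

# Template landmark loci on the default 490 x 600 canvas, profile facing
# right, named by landmark symbol.  Positions are scaled to the configured
# canvas.
TEMPLATE_LOCI <- local({
  m <- rbind(
    N = c(330, 170), Ns = c(352, 172), Prn = c(400, 290), Cm = c(398, 305),
    ANS = c(370, 318), A = c(360, 330), Sn = c(385, 315), Ss = c(388, 332),
    UL = c(395, 350), Stoms = c(392, 362), Stomi = c(390, 368),
    LL = c(390, 395), Si = c(382, 415), Pos = c(375, 465), Gs = c(360, 490),
    Mes = c(330, 500), Go = c(175, 420), Me = c(320, 490), Gn = c(335, 480),
    Pg = c(345, 465), LIA = c(335, 392), B = c(350, 420), Id = c(352, 390),
    LI = c(355, 370), UI = c(360, 355), FA = c(365, 345), SPr = c(362, 342),
    UIA = c(340, 330), Or = c(320, 230), Se = c(250, 175), L6A = c(300, 400),
    UL5 = c(305, 368), L6E = c(310, 385), UL6 = c(320, 365),
    U6E = c(315, 350), U6A = c(310, 330), PNS = c(245, 320),
    Ptm = c(230, 300), S = c(200, 180), Co = c(160, 250), Ar = c(165, 270),
    Ba = c(150, 300), Bolton = c(140, 280), P = c(150, 235),
    ULI = c(357, 362))
  colnames(m) <- c("x", "y")
  m
})

# Helper (non-landmark) template points, transformed with the landmarks.
TEMPLATE_HELPERS <- rbind(
  vault_c = c(235, 190), li_root = c(338, 392), ui_root = c(342, 332),
  forehead = c(330, 120), nose_tip = c(402, 295))

template_points <- function(cfg) {
  nm <- ceph_scheme(cfg$scheme)
  sx <- cfg$width / 490; sy <- cfg$height / 600
  pts <- TEMPLATE_LOCI[nm, , drop = FALSE]
  helpers <- TEMPLATE_HELPERS
  pts[, 1] <- pts[, 1] * sx; pts[, 2] <- pts[, 2] * sy
  helpers[, 1] <- helpers[, 1] * sx; helpers[, 2] <- helpers[, 2] * sy
  list(landmarks = pts, helpers = helpers)
}

# --- rendering primitives ---------------------------------------------------

# Splat a Gaussian of amplitude `amp` and width `sigma` at each (x, y).
splat_points <- function(img, xy, sigma = 1.5, amp = 0.6) {
  h <- nrow(img); w <- ncol(img)
  r <- ceiling(3 * sigma)
  off <- -r:r
  k <- exp(-(outer(off^2, off^2, "+")) / (2 * sigma^2))
  for (i in seq_len(nrow(xy))) {
    cx <- round(xy[i, 1]); cy <- round(xy[i, 2])
    xs <- cx + off; ys <- cy + off
    okx <- xs >= 0 & xs <= w - 1; oky <- ys >= 0 & ys <= h - 1
    if (!any(okx) || !any(oky)) next
    img[ys[oky] + 1, xs[okx] + 1] <- img[ys[oky] + 1, xs[okx] + 1] +
      amp * k[oky, okx, drop = FALSE]
  }
  img
}

# Smooth open curve through control points (natural splines on arc length),
# rendered as dense Gaussian splats.
draw_curve <- function(img, ctrl, sigma = 1.4, amp = 0.10, step = 0.7) {
  if (nrow(ctrl) < 2L) return(img)
  tt <- c(0, cumsum(sqrt(rowSums(diff(ctrl)^2))))
  n <- max(2L, ceiling(tt[length(tt)] / step))
  ts <- seq(0, tt[length(tt)], length.out = n)
  if (nrow(ctrl) == 2L) {
    xs <- stats::approx(tt, ctrl[, 1], ts)$y
    ys <- stats::approx(tt, ctrl[, 2], ts)$y
  } else {
    xs <- stats::spline(tt, ctrl[, 1], xout = ts, method = "natural")$y
    ys <- stats::spline(tt, ctrl[, 2], xout = ts, method = "natural")$y
  }
  splat_points(img, cbind(xs, ys), sigma = sigma, amp = amp)
}

draw_circle <- function(img, center, radius, sigma = 1.2, amp = 0.12) {
  n <- max(8L, ceiling(2 * pi * radius / 0.7))
  th <- seq(0, 2 * pi, length.out = n + 1L)[-1]
  splat_points(img, cbind(center[1] + radius * cos(th),
                          center[2] + radius * sin(th)),
               sigma = sigma, amp = amp)
}

draw_ellipse_arc <- function(img, center, a, b, from, to, sigma = 1.6,
                             amp = 0.10) {
  len <- (to - from) * max(a, b)
  n <- max(8L, ceiling(abs(len) / 0.7))
  th <- seq(from, to, length.out = n)
  splat_points(img, cbind(center[1] + a * cos(th), center[2] + b * sin(th)),
               sigma = sigma, amp = amp)
}

# Structures drawn for a perturbed point set; `pt(nm)` returns the point
# for a landmark symbol or NULL if absent from the scheme.
render_structures <- function(img, lpts, hpts) {
  pt <- function(nm) if (nm %in% rownames(lpts)) lpts[nm, ] else NULL
  curve_through <- function(nms, ...) {
    ctrl <- do.call(rbind, Filter(Negate(is.null), lapply(nms, pt)))
    if (!is.null(ctrl) && nrow(ctrl) >= 2L) img <<- draw_curve(img, ctrl, ...)
  }
  # cranial vault: ellipse arc around the vault center helper
  img <- draw_ellipse_arc(img, hpts["vault_c", ], a = 0.42 * ncol(img),
                          b = 0.24 * nrow(img), from = -pi, to = 0.15)
  # soft-tissue facial profile
  curve_through(c("Ns", "N", "Prn", "Cm", "Sn", "Ss", "UL", "Stoms", "Stomi",
                  "LL", "Si", "Pos", "Gs", "Mes"))
  # mandibular border
  curve_through(c("Co", "Ar", "Go", "Me", "Mes", "Gn", "Pg", "B", "Id", "LI"))
  if (is.null(pt("Co")) && is.null(pt("Id")))  # 19-landmark variant
    curve_through(c("Ar", "Go", "Me", "Gn", "Pg", "B", "LI"))
  # palatal line and maxilla
  curve_through(c("PNS", "ANS", "A"))
  # cranial base line towards sella
  curve_through(c("N", "Se", "S"))
  # incisor bars
  if (!is.null(pt("UI"))) {
    root <- if (!is.null(pt("UIA"))) pt("UIA") else hpts["ui_root", ]
    img <- draw_curve(img, rbind(root, pt("UI")), sigma = 1.2, amp = 0.12)
  }
  if (!is.null(pt("LI"))) {
    img <- draw_curve(img, rbind(hpts["li_root", ], pt("LI")), sigma = 1.2,
                      amp = 0.12)
  }
  # sella ring, porion and orbitale rings
  if (!is.null(pt("S"))) img <- draw_circle(img, pt("S"), radius = 6)
  if (!is.null(pt("P"))) img <- draw_circle(img, pt("P"), radius = 4)
  if (!is.null(pt("Or"))) img <- draw_circle(img, pt("Or"), radius = 4)
  img
}

similarity_transform <- function(pts, theta, scale, shift, center) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L)
  sweep(scale * (sweep(pts, 2, center) %*% t(R)), 2, center + shift, "+")
}

#' Generate one synthetic cephalogram with exact landmark truth
#'
#' @param cfg a [synthetic_config()].
#' @param seed optional integer seed; omit to draw from the current RNG
#'   state.
#' @param id image identifier.
#' @return list with `image` (a [ceph_image()] with the configured ratio)
#'   and `landmarks` (a [landmark_set()]).
#' @export
generate_synthetic_cephalogram <- function(cfg = synthetic_config(),
                                           seed = NULL, id = "synth") {
  if (!is.null(seed)) set.seed(seed)
  tpl <- template_points(cfg)
  w <- cfg$width; h <- cfg$height
  center <- c((w - 1) / 2, (h - 1) / 2)
  margin <- 4
  for (attempt in seq_len(20L)) {
    theta <- stats::runif(1, -1, 1) * cfg$max_rot_deg * pi / 180
    scale <- exp(stats::runif(1, -1, 1) * cfg$max_log_scale)
    shift <- stats::runif(2, -1, 1) * cfg$max_shift
    lpts <- similarity_transform(tpl$landmarks, theta, scale, shift, center)
    hpts <- similarity_transform(tpl$helpers, theta, scale, shift, center)
    if (cfg$jitter > 0) {
      lpts <- lpts + matrix(stats::runif(length(lpts), -1, 1) * cfg$jitter,
                            nrow(lpts), 2L)
    }
    inside <- all(lpts[, 1] >= margin & lpts[, 1] <= w - 1 - margin &
                    lpts[, 2] >= margin & lpts[, 2] <= h - 1 - margin)
    if (inside) break
    if (attempt == 20L)
      stopf("could not place all landmarks inside the canvas in 20 attempts")
  }
  img <- matrix(0.15, h, w)
  if (cfg$illum_amp > 0) {
    gx <- stats::runif(1, -1, 1); gy <- stats::runif(1, -1, 1)
    nrm <- max(abs(gx) + abs(gy), 1e-9)
    plane <- outer((0:(h - 1)) / (h - 1) - 0.5, rep(1, w)) * gy +
      outer(rep(1, h), (0:(w - 1)) / (w - 1) - 0.5) * gx
    img <- img + cfg$illum_amp * plane / nrm
  }
  img <- render_structures(img, lpts, hpts)
  # localized density at every landmark locus
  img <- splat_points(img, lpts, sigma = 1.8, amp = 0.45)
  if (cfg$noise_sd > 0)
    img <- img + matrix(stats::rnorm(h * w, 0, cfg$noise_sd), h, w)
  img <- clamp(img, 0, 1)
  list(image = ceph_image(img, ratio = cfg$ratio, id = id),
       landmarks = landmark_set(lpts, cfg$scheme))
}

#' Generate a synthetic dataset on disk
#'
#' Writes `n_images` PNG images, one annotation text file per image
#' ([write_annotation()] format) and a `manifest.csv` (id, file names,
#' ratio, canvas size, per-image seed).  Deterministic for a given config
#' seed.
#'
#' @param cfg a [synthetic_config()].
#' @param out_dir output directory (created if missing).
#' @return the manifest data frame, invisibly written to
#'   `out_dir/manifest.csv`.
#' @export
generate_dataset <- function(cfg = synthetic_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(cfg$seed, cfg$n_images)
  rows <- vector("list", cfg$n_images)
  for (i in seq_len(cfg$n_images)) {
    id <- sprintf("synth%03d", i)
    g <- generate_synthetic_cephalogram(cfg, seed = seeds[i], id = id)
    img_file <- file.path(out_dir, paste0(id, ".png"))
    ann_file <- file.path(out_dir, paste0(id, ".txt"))
    save_image(g$image, img_file)
    write_annotation(g$landmarks, ann_file)
    rows[[i]] <- data.frame(id = id, image = basename(img_file),
                            annotation = basename(ann_file),
                            ratio = cfg$ratio, width = cfg$width,
                            height = cfg$height, seed = seeds[i],
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}

#' Generate a synthetic dataset in memory
#'
#' Convenience wrapper used by tests and examples: returns lists of images
#' and landmark sets without touching the disk.
#'
#' @inheritParams generate_dataset
#' @param n number of images; defaults to `cfg$n_images`.
#' @return list with `images`, `landmarks` and `seeds`.
#' @export
generate_images <- function(cfg = synthetic_config(), n = NULL) {
  n <- n %||% cfg$n_images
  seeds <- derive_seeds(cfg$seed, n)
  images <- vector("list", n); landmarks <- vector("list", n)
  for (i in seq_len(n)) {
    g <- generate_synthetic_cephalogram(cfg, seed = seeds[i],
                                        id = sprintf("synth%03d", i))
    images[[i]] <- g$image
    landmarks[[i]] <- g$landmarks
  }
  list(images = images, landmarks = landmarks, seeds = seeds)
}
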