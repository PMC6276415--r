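# Cephalometric measurement geometry and catalogs.
#
# Five geometry classes cover all catalog entries: the angle of three
# points (law of cosines at the vertex), the angle between two planes
# (difference of line inclinations), the distance between two points, the
# signed distance from a point to a plane, and the distance between two
# points projected onto a plane.  "Plane" means the line through two
# landmarks in the 2-D radiograph.  Composite entries (ODI, APDI, FHI, MW)
# are signed sums, a ratio, and a sign rule over these primitives.

as_pt <- function(p) {
  p <- as.numeric(p)
  if (length(p) != 2L || !all(is.finite(p))) stopf("a point must be finite (x, y)")
  p
}

check_ratio <- function(ratio) {
  if (is.null(ratio) || !is.numeric(ratio) || length(ratio) != 1L ||
      !is.finite(ratio) || ratio <= 0)
    stopf("a positive mm/pixel calibration ratio is required",
          class = "cephvote_calibration_error")
  ratio
}

#' Angle defined by three points (vertex at B)
#'
#' Law-of-cosines angle `acos((a^2 + c^2 - b^2) / (2ac))` in degrees, where
#' `a = |AB|`, `b = |AC|`, `c = |BC|`; the arccos argument is clamped to
#' `[-1, 1]`.
#'
#' @param A,B,C points (x, y); `B` is the vertex.
#' @return angle in degrees, in `[0, 180]`.
#' @export
angle_three_points <- function(A, B, C) {
  A <- as_pt(A); B <- as_pt(B); C <- as_pt(C)
  a <- sqrt(sum((A - B)^2)); b <- sqrt(sum((A - C)^2)); c <- sqrt(sum((B - C)^2))
  if (a == 0 || c == 0)
    stopf("degenerate geometry: vertex coincides with an endpoint",
          class = "cephvote_geometry_error")
  acos(clamp((a^2 + c^2 - b^2) / (2 * a * c), -1, 1)) * 180 / pi
}

# Inclination of the line through P1, P2 in degrees, reduced to (-90, 90].
# Full-quadrant arctangent of (dy, dx) in image coordinates (y down);
# vertical lines give 90.
line_inclination <- function(P1, P2) {
  d <- P2 - P1
  if (all(d == 0))
    stopf("degenerate geometry: coincident plane endpoints",
          class = "cephvote_geometry_error")
  ang <- atan2(d[2], d[1]) * 180 / pi
  ang <- ang %% 180
  if (ang > 90) ang <- ang - 180
  if (ang == -90) ang <- 90
  ang
}

#' Angle between two planes (lines) AB and CD
#'
#' Each line's inclination is the full-quadrant arctangent of
#' `(delta y, delta x)` reduced to `(-90, 90]` degrees; the result is the
#' difference `angle(AB) - angle(CD)` normalized to `(-90, 90]`.
#' `variant = "unsigned"` returns its absolute value; `variant =
#' "rear_lower"` adds 180 degrees when the signed difference is negative
#' (the convention for angles named after the rear lower sector, e.g. the
#' Z angle).
#'
#' @param A,B endpoints of the first plane; `C,D` of the second.
#' @param variant `"signed"`, `"unsigned"` or `"rear_lower"`.
#' @return angle in degrees.
#' @export
angle_between_planes <- function(A, B, C, D,
                                 variant = c("signed", "unsigned", "rear_lower")) {
  variant <- match.arg(variant)
  a1 <- line_inclination(as_pt(A), as_pt(B))
  a2 <- line_inclination(as_pt(C), as_pt(D))
  d <- a1 - a2
  if (d <= -90) d <- d + 180
  if (d > 90) d <- d - 180
  switch(variant,
         signed = d,
         unsigned = abs(d),
         rear_lower = if (d < 0) d + 180 else d)
}

#' Distance between two points in millimetres
#'
#' Euclidean pixel distance multiplied by the mm/pixel calibration ratio.
#'
#' @param A,B points (x, y) in pixels.
#' @param ratio mm-per-pixel calibration (> 0).
#' @return distance in mm.
#' @export
distance_between_points <- function(A, B, ratio) {
  check_ratio(ratio)
  A <- as_pt(A); B <- as_pt(B)
  sqrt(sum((A - B)^2)) * ratio
}

# Signed pixel distance of C from the line through A, B.  For non-vertical
# lines this equals (yC + k1 xC + k0) / sqrt(1 + k1^2) with the line written
# y + k1 x + k0 = 0; the general cross-product form below reproduces that
# sign (which flips with the x-direction of AB).  Vertical lines use the
# documented convention "positive to the right of the line".
signed_point_line_px <- function(C, A, B) {
  d <- B - A
  if (all(d == 0))
    stopf("degenerate geometry: coincident plane endpoints",
          class = "cephvote_geometry_error")
  if (d[1] == 0) return(C[1] - A[1])
  cross <- d[1] * (C[2] - A[2]) - d[2] * (C[1] - A[1])
  cross * sign(d[1]) / sqrt(sum(d^2))
}

#' Signed distance from a point to a plane, in millimetres
#'
#' The line through A and B is written `y + k1 x + k0 = 0` and the signed
#' perpendicular distance of C is `(yC + k1 xC + k0) / sqrt(1 + k1^2)`
#' times the calibration ratio; the sign indicates the side of the line.
#' Vertical planes use the equivalent general line form with positive sign
#' to the right of the line.
#'
#' @param C the point; `A`, `B` span the plane.
#' @inheritParams distance_between_points
#' @return signed distance in mm.
#' @export
distance_point_to_plane <- function(C, A, B, ratio) {
  check_ratio(ratio)
  signed_point_line_px(as_pt(C), as_pt(A), as_pt(B)) * ratio
}

#' Distance between two points projected onto a plane, in millimetres
#'
#' With `c0` the pixel distance between C and D and `c1`, `c2` their signed
#' pixel distances from the plane AB, the projected distance is
#' `sqrt(c0^2 - (c1 - c2)^2) * ratio` (the radicand is clamped at zero).
#' Using signed distances is essential: when C and D straddle the line the
#' perpendicular offset is `|c1 - c2| = |c1| + |c2|`.
#'
#' @param C,D the points; `A`, `B` span the plane.
#' @inheritParams distance_between_points
#' @return projected distance in mm (non-negative).
#' @export
distance_projected <- function(C, D, A, B, ratio) {
  check_ratio(ratio)
  C <- as_pt(C); D <- as_pt(D); A <- as_pt(A); B <- as_pt(B)
  c0 <- sqrt(sum((C - D)^2))
  c1 <- signed_point_line_px(C, A, B)
  c2 <- signed_point_line_px(D, A, B)
  sqrt(max(0, c0^2 - (c1 - c2)^2)) * ratio
}

# --- catalogs ---------------------------------------------------------------

parse_roles <- function(s) as.integer(strsplit(s, ";", fixed = TRUE)[[1]])

#' Load a measurement catalog or the classification rules
#'
#' Catalogs ship as editable CSV files under `inst/extdata`:
#' `measurements_ceph19.csv` (the 8 classification measurements of the
#' 19-landmark benchmark scheme), `measurements_ceph45.csv` (the 27 clinical
#' measurements of the 45-landmark scheme), `classification_rules.csv`
#' (anatomical-type rules for the 8 benchmark measurements) and
#' `planes.csv` (the named cephalometric planes).
#'
#' @param scheme `"ceph19"` or `"ceph45"`.
#' @return data frame.
#' @export
load_measurement_catalog <- function(scheme = "ceph19") {
  f <- system.file("extdata", sprintf("measurements_%s.csv", scheme),
                   package = "cephvote", mustWork = TRUE)
  utils::read.csv(f, stringsAsFactors = FALSE)
}

#' @rdname load_measurement_catalog
#' @export
load_classification_rules <- function() {
  f <- system.file("extdata", "classification_rules.csv",
                   package = "cephvote", mustWork = TRUE)
  utils::read.csv(f, stringsAsFactors = FALSE)
}

#' @rdname load_measurement_catalog
#' @export
load_plane_catalog <- function() {
  f <- system.file("extdata", "planes.csv", package = "cephvote",
                   mustWork = TRUE)
  utils::read.csv(f, stringsAsFactors = FALSE)
}

eval_measurement <- function(def, pts, ratio) {
  r <- parse_roles(def$roles)
  if (any(r < 1L | r > nrow(pts)))
    stopf("catalog entry '%s': landmark role out of range", def$name,
          class = "cephvote_catalog_error")
  P <- function(i) pts[r[i], ]
  switch(def$class,
    angle3 = angle_three_points(P(1), P(2), P(3)),
    angle2planes = angle_between_planes(P(1), P(2), P(3), P(4),
                                        variant = def$variant),
    dist2pts = distance_between_points(P(1), P(2), ratio),
    distPtPlane = {
      v <- distance_point_to_plane(P(1), P(2), P(3), ratio)
      if (identical(def$variant, "unsigned")) abs(v) else v
    },
    distProjected = distance_projected(P(1), P(2), P(3), P(4), ratio),
    # composite angle sums: the large term (AB-to-mandibular-plane for ODI,
    # the facial angle for APDI, both near 90 degrees clinically) uses the
    # unsigned angle, which is continuous across the +-90 inclination wrap;
    # the small tilt terms stay signed, continuous around 0.
    composite_odi = angle_between_planes(P(1), P(2), P(3), P(4),
                                         variant = "unsigned") +
      angle_between_planes(P(5), P(6), P(7), P(8)),
    composite_apdi = angle_between_planes(P(1), P(2), P(3), P(4),
                                          variant = "unsigned") +
      angle_between_planes(P(3), P(4), P(5), P(6)) +
      angle_between_planes(P(1), P(2), P(7), P(8)),
    composite_fhi = {
      num <- sqrt(sum((P(1) - P(2))^2)); den <- sqrt(sum((P(3) - P(4))^2))
      if (den == 0) stopf("degenerate geometry in FHI denominator",
                          class = "cephvote_geometry_error")
      num / den
    },
    composite_mw = {
      d <- distance_between_points(P(1), P(2), ratio)
      if (pts[r[1], 1] < pts[r[2], 1]) d else -d
    },
    stopf("unknown geometry class '%s'", def$class,
          class = "cephvote_catalog_error"))
}

#' Evaluate a measurement catalog on a landmark set
#'
#' @param landmarks a [landmark_set()].
#' @param catalog a catalog data frame ([load_measurement_catalog()]); the
#'   default loads the catalog matching the landmark scheme.
#' @param ratio mm-per-pixel calibration (required for linear entries).
#' @return data frame with columns `name`, `value`, `unit`.
#' @export
compute_catalog <- function(landmarks, catalog = NULL, ratio = NULL) {
  stopifnot(inherits(landmarks, "ceph_landmarks"))
  if (is.null(catalog)) catalog <- load_measurement_catalog(landmarks$scheme)
  pts <- landmarks$points
  vals <- vapply(seq_len(nrow(catalog)), function(i)
    eval_measurement(catalog[i, ], pts, ratio), 0)
  data.frame(name = catalog$name, value = vals, unit = catalog$unit,
             stringsAsFactors = FALSE)
}

# --- anatomical-type classification -----------------------------------------

rule_matches <- function(kind, lo, hi, v, eps = 1e-9) {
  switch(kind,
    range = v >= lo & v <= hi,   # published ranges are closed
    gt = v > lo,                 # published strict inequalities are strict
    lt = v < hi,
    eq = abs(v - lo) <= eps,
    FALSE)
}

rule_distance <- function(kind, lo, hi, v) {
  switch(kind,
    range = max(0, lo - v, v - hi),
    gt = max(0, lo - v),
    lt = max(0, v - hi),
    eq = abs(v - lo),
    Inf)
}

#' Classify anatomical types from measurement values
#'
#' Applies the standard eight-measurement classification rules (ANB, SNB,
#' SNA, ODI, APDI, FHI, FHA, MW).  Published normal ranges are closed
#' intervals; published `>` / `<` thresholds are strict.  Rules are evaluated
#' in type order and the first match wins.  Values falling in a gap that
#' the published rules do not cover (possible for ODI and MW) are labeled
#' with the nearest rule's type and flagged in the `gap` column.
#'
#' @param values named numeric vector of measurement values, or the data
#'   frame returned by [compute_catalog()].
#' @param rules rules data frame ([load_classification_rules()]).
#' @return data frame with columns `measurement`, `value`, `type`, `label`,
#'   `gap`.
#' @export
classify_types <- function(values, rules = load_classification_rules()) {
  if (is.data.frame(values)) {
    v <- values$value
    names(v) <- values$name
    values <- v
  }
  meas <- unique(rules$measurement)
  missing <- setdiff(meas, names(values))
  if (length(missing))
    stopf("missing measurement value(s): %s", paste(missing, collapse = ", "),
          class = "cephvote_classification_error")
  out <- lapply(meas, function(m) {
    rr <- rules[rules$measurement == m, , drop = FALSE]
    rr <- rr[order(rr$type), , drop = FALSE]
    v <- unname(values[[m]])
    hit <- NA_integer_
    for (i in seq_len(nrow(rr))) {
      if (rule_matches(rr$kind[i], rr$lo[i], rr$hi[i], v)) { hit <- i; break }
    }
    gap <- is.na(hit)
    if (gap) {
      dists <- vapply(seq_len(nrow(rr)), function(i)
        rule_distance(rr$kind[i], rr$lo[i], rr$hi[i], v), 0)
      hit <- which.min(dists)
    }
    data.frame(measurement = m, value = v, type = rr$type[hit],
               label = rr$label[hit], gap = gap, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
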