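# Landmark schemes and annotation files.

# The 19-landmark scheme of the public cephalometric benchmark (L1..L19) and
# the 45-landmark clinical scheme.  Order defines the line order of
# annotation files and the role indices used by the measurement catalogs.
SCHEME_19 <- c(
  "S",    # L1  sella
  "N",    # L2  nasion
  "Or",   # L3  orbitale
  "P",    # L4  porion
  "A",    # L5  subspinale
  "B",    # L6  supramentale
  "Pg",   # L7  pogonion
  "Me",   # L8  menton
  "Gn",   # L9  gnathion
  "Go",   # L10 gonion
  "LI",   # L11 lower incisal incision
  "UI",   # L12 upper incisal incision
  "UL",   # L13 upper lip
  "LL",   # L14 lower lip
  "Sn",   # L15 subnasale
  "Pos",  # L16 soft tissue pogonion
  "PNS",  # L17 posterior nasal spine
  "ANS",  # L18 anterior nasal spine
  "Ar"    # L19 articulare
)

SCHEME_45 <- c(
  "N", "Ns", "Prn", "Cm", "ANS", "A", "Sn", "Ss", "UL", "Stoms",
  "Stomi", "LL", "Si", "Pos", "Gs", "Mes", "Go", "Me", "Gn", "Pg",
  "LIA", "B", "Id", "LI", "UI", "FA", "SPr", "UIA", "Or", "Se",
  "L6A", "UL5", "L6E", "UL6", "U6E", "U6A", "PNS", "Ptm", "S", "Co",
  "Ar", "Ba", "Bolton", "P", "ULI"
)

#' Landmark naming schemes
#'
#' `ceph_scheme("ceph19")` is the 19-landmark benchmark scheme (sella,
#' nasion, orbitale, ...); `ceph_scheme("ceph45")` is the 45-landmark
#' clinical scheme.  The returned character vector gives the landmark
#' symbols in catalog order (role index `Lk` = element `k`).
#'
#' @param scheme `"ceph19"` or `"ceph45"`.
#' @return character vector of landmark symbols.
#' @export
ceph_scheme <- function(scheme) {
  switch(scheme,
    ceph19 = SCHEME_19,
    ceph45 = SCHEME_45,
    stopf("unknown landmark scheme '%s' (use 'ceph19' or 'ceph45')", scheme))
}

#' Construct an ordered set of named landmark positions
#'
#' @param points numeric n x 2 matrix of (x, y) pixel coordinates (0-based,
#'   y down), or a 2-column data frame.
#' @param scheme scheme name (`"ceph19"`, `"ceph45"`) or a character vector
#'   of unique landmark names of length `nrow(points)`.
#' @return object of class `ceph_landmarks` with fields `scheme`, `names`,
#'   `points`.
#' @export
landmark_set <- function(points, scheme = "ceph19") {
  points <- as.matrix(points)
  if (ncol(points) != 2L) stopf("points must have two columns (x, y)")
  storage.mode(points) <- "double"
  if (!all(is.finite(points))) stopf("landmark coordinates must be finite")
  if (is.character(scheme) && length(scheme) == 1L &&
      scheme %in% c("ceph19", "ceph45")) {
    nm <- ceph_scheme(scheme)
    scheme_name <- scheme
  } else {
    nm <- as.character(scheme)
    scheme_name <- sprintf("custom%d", length(nm))
  }
  if (nrow(points) != length(nm))
    stopf("scheme mismatch: %d points for the %d-landmark scheme '%s'",
          nrow(points), length(nm), scheme_name, class = "cephvote_scheme_error")
  if (anyDuplicated(nm)) stopf("landmark names must be unique")
  dimnames(points) <- list(nm, c("x", "y"))
  structure(list(scheme = scheme_name, names = nm, points = points),
            class = "ceph_landmarks")
}

#' @export
print.ceph_landmarks <- function(x, ...) {
  cat(sprintf("<ceph_landmarks scheme '%s', %d points>\n", x$scheme,
              nrow(x$points)))
  print(utils::head(round(x$points, 2), 5))
  if (nrow(x$points) > 5) cat("...\n")
  invisible(x)
}

n_landmarks <- function(lm) nrow(lm$points)

#' Read a landmark annotation file
#'
#' The file holds one `x,y` line per landmark in scheme order (0-based pixel
#' coordinates, x rightward, y downward).  Files written with 1-based
#' coordinates can be read with `one_based = TRUE`, which subtracts 1 from
#' both coordinates.
#'
#' @param path annotation text file.
#' @param scheme scheme name or character vector of names (see
#'   [landmark_set()]).
#' @param one_based set to TRUE if the file's coordinates are 1-based.
#' @return a [landmark_set()].
#' @export
read_annotation <- function(path, scheme = "ceph19", one_based = FALSE) {
  if (!file.exists(path)) stopf("annotation file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  nm <- if (length(scheme) == 1L) ceph_scheme(scheme) else as.character(scheme)
  if (length(lines) != length(nm))
    stopf("scheme mismatch: %d annotation lines for the %d-landmark scheme",
          length(lines), length(nm), class = "cephvote_scheme_error")
  pts <- matrix(NA_real_, length(lines), 2L)
  for (i in seq_along(lines)) {
    parts <- strsplit(trimws(lines[i]), ",", fixed = TRUE)[[1]]
    vals <- suppressWarnings(as.numeric(trimws(parts)))
    if (length(vals) != 2L || anyNA(vals))
      stopf("cannot parse annotation line %d: '%s'", i, lines[i],
            class = "cephvote_format_error")
    pts[i, ] <- vals
  }
  if (one_based) pts <- pts - 1
  landmark_set(pts, scheme)
}

#' Write a landmark annotation file
#'
#' Coordinates are written with four decimal places, one `x,y` line per
#' landmark in scheme order, so `write_annotation()` followed by
#' [read_annotation()] reproduces the positions to well within 0.01 px.
#'
#' @param landmarks a [landmark_set()].
#' @param path output text file.
#' @export
write_annotation <- function(landmarks, path) {
  stopifnot(inherits(landmarks, "ceph_landmarks"))
  writeLines(sprintf("%.4f,%.4f", landmarks$points[, 1], landmarks$points[, 2]),
             path)
  invisible(path)
}
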