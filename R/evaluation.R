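# Evaluation statistics for landmark detection and measurement analysis:
# radial errors, MRE/SD, SDR, confusion-matrix SCR and MAE.

#' Radial errors between predicted and true landmark sets
#'
#' The radial error of landmark i in image m is the Euclidean pixel
#' distance between prediction and truth times that image's mm/pixel ratio.
#'
#' @param predicted,truth lists of [landmark_set()] of equal length and
#'   matching schemes.
#' @param ratio mm-per-pixel calibration; a single value or one per image.
#' @return M x L matrix of radial errors in mm (rows = images, columns =
#'   landmarks).
#' @export
radial_errors <- function(predicted, truth, ratio = 1) {
  if (length(predicted) != length(truth) || !length(truth))
    stopf("predicted and truth must be non-empty lists of equal length")
  M <- length(truth)
  L <- n_landmarks(truth[[1]])
  ratio <- rep_len(ratio, M)
  E <- matrix(NA_real_, M, L, dimnames = list(NULL, truth[[1]]$names))
  for (m in seq_len(M)) {
    if (n_landmarks(predicted[[m]]) != L || n_landmarks(truth[[m]]) != L)
      stopf("scheme mismatch between predicted and truth in image %d", m)
    d <- predicted[[m]]$points - truth[[m]]$points
    E[m, ] <- sqrt(d[, 1]^2 + d[, 2]^2) * ratio[m]
  }
  E
}

#' Per-landmark mean radial error and standard deviation
#'
#' MRE is the mean radial error over images; SD is the sample standard
#' deviation with the M - 1 denominator.
#'
#' @inheritParams radial_errors
#' @return data frame with one row per landmark (`landmark`, `MRE`, `SD`)
#'   plus an `"Average"` row.
#' @export
radial_error_stats <- function(predicted, truth, ratio = 1) {
  E <- radial_errors(predicted, truth, ratio)
  if (nrow(E) < 2L) stopf("SD requires at least two images")
  mre <- colMeans(E)
  sd_ <- apply(E, 2, stats::sd)
  data.frame(landmark = c(colnames(E), "Average"),
             MRE = c(mre, mean(mre)), SD = c(sd_, mean(sd_)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Success detection rate
#'
#' Percentage of radial errors strictly below the precision range z.
#'
#' @param errors numeric vector (or matrix) of radial errors in mm.
#' @param z precision range(s) in mm; default grid 2.0, 2.5, 3.0, 4.0.
#' @return named numeric vector of percentages, one per z.
#' @export
success_detection_rate <- function(errors, z = c(2.0, 2.5, 3.0, 4.0)) {
  errors <- as.numeric(errors)
  if (!length(errors)) stopf("empty error set")
  if (any(z <= 0)) stopf("precision ranges must be positive")
  out <- vapply(z, function(zz) mean(errors < zz) * 100, 0)
  names(out) <- sprintf("%.1fmm", z)
  out
}

#' Success classification rate from anatomical-type labels
#'
#' Builds the confusion matrix (rows = ground-truth type, columns =
#' estimated type), row-normalizes it, and returns the mean of the diagonal
#' as a percentage.  Ground-truth types with no instances are excluded from
#' the diagonal average.
#'
#' @param truth_types,estimated_types equal-length vectors of type labels.
#' @param types the full type set; defaults to the union of observed labels.
#' @return list with `confusion` (row-normalized proportions), `counts`
#'   (raw counts) and `SCR` (percent).
#' @export
success_classification_rate <- function(truth_types, estimated_types,
                                        types = NULL) {
  if (length(truth_types) != length(estimated_types) || !length(truth_types))
    stopf("type sequences must be non-empty and of equal length")
  if (is.null(types)) types <- sort(unique(c(truth_types, estimated_types)))
  if (!all(truth_types %in% types) || !all(estimated_types %in% types))
    stopf("label outside the declared type set")
  tt <- factor(truth_types, levels = types)
  et <- factor(estimated_types, levels = types)
  counts <- table(truth = tt, estimated = et)
  rs <- rowSums(counts)
  present <- rs > 0
  prop <- counts
  prop[present, ] <- counts[present, , drop = FALSE] / rs[present]
  scr <- mean(diag(as.matrix(prop))[present]) * 100
  list(confusion = prop, counts = counts, SCR = scr)
}

#' Mean absolute error between estimated and true measurement values
#'
#' @param estimated,truth equal-length numeric vectors (same unit).
#' @return MAE in the measurement's unit.
#' @export
mean_absolute_error <- function(estimated, truth) {
  if (length(estimated) != length(truth) || !length(truth))
    stopf("estimated and truth must be non-empty and of equal length")
  mean(abs(estimated - truth))
}

#' Full detection evaluation report
#'
#' Per-landmark MRE/SD plus SDR at the standard precision grid, mirroring
#' the layout of benchmark result tables.
#'
#' @inheritParams radial_error_stats
#' @param z SDR precision ranges in mm.
#' @return data frame with per-landmark rows and an `"Average"` row.
#' @export
evaluation_report <- function(predicted, truth, ratio = 1,
                              z = c(2.0, 2.5, 3.0, 4.0)) {
  E <- radial_errors(predicted, truth, ratio)
  stats <- radial_error_stats(predicted, truth, ratio)
  sdr <- t(apply(E, 2, success_detection_rate, z = z))
  sdr <- rbind(sdr, Average = success_detection_rate(as.vector(E), z))
  cbind(stats, as.data.frame(sdr, row.names = NULL))
}
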