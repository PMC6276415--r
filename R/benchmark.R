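# End-to-end synthetic benchmark: generate data, train, detect, measure,
# classify, evaluate — all from one master seed.

#' Reduced detector parameters for the desk-scale synthetic benchmark
#'
#' Quarter-scale analogue of the full-size settings (K = 50, K' = 400,
#' W = 48, S = 40 at the 1960-px working width): on the 490 x 600 synthetic
#' canvas the benchmark uses K = 30, K' = 200, W = 24, S = 20.
#'
#' @param ... overrides passed to [mdtrv_config()].
#' @return an [mdtrv_config()].
#' @export
benchmark_detector_config <- function(...) {
  defaults <- list(K = 30L, Kp = 200L, W = 24L, S = 20L, B = 8L,
                   max_splits = 256L)
  args <- utils::modifyList(defaults, list(...))
  do.call(mdtrv_config, args)
}

#' Run the full synthetic train/detect/measure/evaluate pipeline
#'
#' Generates a seeded synthetic dataset, trains an MDTRV detector on the
#' first `n_train` images, detects landmarks in the remaining `n_test`
#' images, and evaluates radial errors (per stage and after refinement),
#' the measurement catalog (detected vs. ground-truth landmarks) and the
#' anatomical-type classification agreement.  Every random draw derives
#' from `seed`, so repeated calls are bit-identical.
#'
#' @param seed master seed.
#' @param n_train,n_test images for training / testing.
#' @param synth a [synthetic_config()]; its `n_images` and `seed` are
#'   overridden by `n_train + n_test` and a child of `seed`.
#' @param detector an [mdtrv_config()]; default
#'   [benchmark_detector_config()].
#' @return list with `model`, `detections`, `truth`, `errors_px` (test
#'   radial errors in working pixels), `report` (mm-scale
#'   [evaluation_report()]), `stage_mre_px` (mean radial error per scale
#'   stage and after refinement, working pixels), `measurements` (per-entry
#'   MAE), `classification` (SCR and confusion matrix), and `timings`.
#' @export
synthetic_benchmark <- function(seed = 0L, n_train = 20L, n_test = 5L,
                                synth = synthetic_config(),
                                detector = benchmark_detector_config()) {
  seeds <- derive_seeds(seed, 3L)
  synth$n_images <- as.integer(n_train + n_test)
  synth$seed <- seeds[1]
  t0 <- Sys.time()
  ds <- generate_images(synth)
  tr_idx <- seq_len(n_train)
  te_idx <- n_train + seq_len(n_test)
  t1 <- Sys.time()
  model <- train_mdtrv(ds$images[tr_idx], ds$landmarks[tr_idx], detector,
                       seed = seeds[2])
  t2 <- Sys.time()
  det_seeds <- derive_seeds(seeds[3], n_test)
  detections <- lapply(seq_len(n_test), function(i)
    detect_landmarks(model, ds$images[[te_idx[i]]], seed = det_seeds[i],
                     keep_stages = TRUE))
  t3 <- Sys.time()
  truth <- ds$landmarks[te_idx]

  E_px <- radial_errors(detections, truth, ratio = 1)
  report <- evaluation_report(detections, truth, ratio = synth$ratio)
  stage_names <- names(attr(detections[[1]], "stages"))
  stage_mre <- vapply(stage_names, function(nm) {
    mean(vapply(seq_len(n_test), function(i) {
      est <- attr(detections[[i]], "stages")[[nm]]
      mean(sqrt(rowSums((est - truth[[i]]$points)^2)))
    }, 0))
  }, 0)

  catalog <- load_measurement_catalog(synth$scheme)
  meas_det <- lapply(detections, compute_catalog, catalog = catalog,
                     ratio = synth$ratio)
  meas_tru <- lapply(truth, compute_catalog, catalog = catalog,
                     ratio = synth$ratio)
  mae <- vapply(seq_len(nrow(catalog)), function(j)
    mean_absolute_error(vapply(meas_det, function(m) m$value[j], 0),
                        vapply(meas_tru, function(m) m$value[j], 0)), 0)
  measurements <- data.frame(name = catalog$name, unit = catalog$unit,
                             MAE = mae, stringsAsFactors = FALSE)

  classification <- NULL
  if (synth$scheme == "ceph19") {
    rules <- load_classification_rules()
    cls_det <- lapply(meas_det, classify_types, rules = rules)
    cls_tru <- lapply(meas_tru, classify_types, rules = rules)
    meas_names <- cls_tru[[1]]$measurement
    per_meas <- vapply(seq_along(meas_names), function(j) {
      tt <- vapply(cls_tru, function(cc) cc$type[j], 0L)
      et <- vapply(cls_det, function(cc) cc$type[j], 0L)
      success_classification_rate(tt, et, types = 1:4)$SCR
    }, 0)
    names(per_meas) <- meas_names
    classification <- list(per_measurement = per_meas,
                           SCR = mean(per_meas))
  }
  list(model = model, detections = detections, truth = truth,
       errors_px = E_px, report = report, stage_mre_px = stage_mre,
       measurements = measurements, classification = classification,
       timings = c(generate = as.numeric(difftime(t1, t0, units = "secs")),
                   train = as.numeric(difftime(t2, t1, units = "secs")),
                   detect = as.numeric(difftime(t3, t2, units = "secs"))))
}
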