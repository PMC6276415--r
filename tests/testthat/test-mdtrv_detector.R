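# Patch sampling, vote accumulation, training and coarse-to-fine detection.

test_that("patch center sampling is seeded, contained and clipped", {
  ctr <- sample_patch_centers(c(245, 300), "whole", K = 50, seed = 9)
  expect_equal(dim(ctr), c(50, 2))
  expect_true(all(ctr[, 1] >= 0 & ctr[, 1] <= 299))
  expect_true(all(ctr[, 2] >= 0 & ctr[, 2] <= 244))
  expect_identical(ctr, sample_patch_centers(c(245, 300), "whole", K = 50,
                                             seed = 9))
  nb <- sample_patch_centers(c(245, 300), "neighborhood",
                             anchor = c(100, 100), S = 40, K = 200, seed = 1)
  expect_true(all(abs(nb[, 1] - 100) <= 40 & abs(nb[, 2] - 100) <= 40))
  corner <- sample_patch_centers(c(245, 300), "neighborhood",
                                 anchor = c(0, 0), S = 40, K = 100, seed = 2)
  expect_true(all(corner >= 0))
  expect_true(all(corner[, 1] <= 40 & corner[, 2] <= 40))
  expect_error(sample_patch_centers(c(245, 300), "neighborhood",
                                    anchor = c(-200, 0), S = 10, K = 5),
               "empty")
  expect_error(sample_patch_centers(c(245, 300), "neighborhood", K = 5),
               "anchor")
})

test_that("unit voting finds peaks, averages ties and counts conservatively", {
  K <- 37
  ctr <- matrix(rep(c(10, 15), each = K), K, 2)
  v <- vote_landmark(ctr, matrix(rep(c(20, 25), each = K), K, 2), c(100, 80))
  expect_equal(v$position, c(30, 40))
  expect_equal(v$peak_count, K)
  expect_equal(v$n_votes, K)

  ctr2 <- matrix(0, 8, 2)
  disp2 <- rbind(matrix(rep(c(10, 10), each = 5), 5, 2),
                 matrix(rep(c(50, 50), each = 3), 3, 2))
  v2 <- vote_landmark(ctr2, disp2, c(100, 100))
  expect_equal(v2$position, c(10, 10))

  # tie between (10, 10) and (12, 10) averages to (11, 10)
  ctr3 <- matrix(0, 8, 2)
  disp3 <- rbind(matrix(rep(c(10, 10), each = 4), 4, 2),
                 matrix(rep(c(12, 10), each = 4), 4, 2))
  v3 <- vote_landmark(ctr3, disp3, c(100, 100))
  expect_equal(v3$position, c(11, 10))

  acc <- vote_landmark(ctr3, disp3, c(100, 100), accumulator = TRUE)$accumulator
  expect_equal(sum(acc), 8)
  expect_equal(acc[11, 11], 4)       # (x, y) = (10, 10) is cell [y+1, x+1]

  expect_warning(v4 <- vote_landmark(matrix(0, 3, 2),
                                     matrix(500, 3, 2), c(50, 50)),
                 "out of bounds")
  expect_true(v4$fallback)
  expect_equal(v4$n_votes, 0)
})

# small shared fixture: 4 training images, tiny detector settings
tiny_cfg <- synthetic_config(width = 245, height = 300, n_images = 5, seed = 3)
tiny_det <- mdtrv_config(K = 12, Kp = 60, W = 12, S = 12, B = 2,
                         max_splits = 32)
tiny_ds <- generate_images(tiny_cfg)

test_that("training builds one tree per landmark and stage plus the forest", {
  model <- train_mdtrv(tiny_ds$images[1:4], tiny_ds$landmarks[1:4], tiny_det,
                       seed = 7)
  expect_s3_class(model, "ceph_mdtrv")
  expect_length(model$trees, 19)
  for (l in c(1, 10, 19)) {
    expect_length(model$trees[[l]], 4)       # one per scale
    for (s in 1:4) {
      tr <- model$trees[[l]][[s]]
      expect_equal(tr$n_samples[1], 12 * 4)  # K patches per training image
      expect_true(all(is.finite(tr$pred_x) & is.finite(tr$pred_y)))
    }
    expect_length(model$forest[[l]], 2)
  }
  expect_error(train_mdtrv(tiny_ds$images[1:2],
                           list(tiny_ds$landmarks[[1]],
                                landmark_set(matrix(1, 3, 2), c("a", "b", "c"))),
                           tiny_det, seed = 1),
               "complete")
})

test_that("detection on a training image recovers its own landmarks", {
  model <- train_mdtrv(tiny_ds$images[1], tiny_ds$landmarks[1],
                       mdtrv_config(K = 40, Kp = 150, W = 12, S = 12, B = 2,
                                    max_splits = 64),
                       seed = 11)
  det <- detect_landmarks(model, tiny_ds$images[[1]], seed = 12)
  err <- sqrt(rowSums((det$points - tiny_ds$landmarks[[1]]$points)^2))
  expect_lt(max(err), 5)
})

test_that("detection is deterministic and clamped to image bounds", {
  model <- train_mdtrv(tiny_ds$images[1:4], tiny_ds$landmarks[1:4], tiny_det,
                       seed = 7)
  d1 <- detect_landmarks(model, tiny_ds$images[[5]], seed = 21)
  d2 <- detect_landmarks(model, tiny_ds$images[[5]], seed = 21)
  expect_identical(d1$points, d2$points)
  expect_true(all(d1$points[, 1] >= 0 & d1$points[, 1] <= 244))
  expect_true(all(d1$points[, 2] >= 0 & d1$points[, 2] <= 299))
  d3 <- detect_landmarks(model, tiny_ds$images[[5]], seed = 22)
  expect_false(identical(d1$points, d3$points))
})

test_that("a forest of identical trees votes like the single tree", {
  model <- train_mdtrv(tiny_ds$images[1:2], tiny_ds$landmarks[1:2], tiny_det,
                       seed = 7)
  tr <- model$trees[[1]][[4]]
  img <- tiny_ds$images[[3]]
  init <- tiny_ds$landmarks[[3]]$points[1, ]
  set.seed(33)
  r1 <- hough_refine(list(tr, tr, tr), img, init, tiny_det)
  set.seed(33)
  r2 <- hough_refine(list(tr), img, init, tiny_det)
  expect_equal(r1$position, r2$position)
  expect_equal(r1$n_votes, 3 * r2$n_votes)
})

test_that("refinement cannot move an estimate beyond its reachable set", {
  model <- train_mdtrv(tiny_ds$images[1:2], tiny_ds$landmarks[1:2], tiny_det,
                       seed = 7)
  forest <- model$forest[[5]]
  img <- tiny_ds$images[[3]]
  init <- c(120, 150)
  max_disp <- max(vapply(forest, function(tr)
    max(abs(c(tr$pred_x, tr$pred_y))), 0))
  set.seed(44)
  r <- hough_refine(forest, img, init, tiny_det)
  expect_lte(max(abs(r$position - init)), tiny_det$S + max_disp + 1)
})

test_that("models round-trip through JSON serialization", {
  model <- train_mdtrv(tiny_ds$images[1:2], tiny_ds$landmarks[1:2],
                       mdtrv_config(K = 8, Kp = 30, W = 8, S = 10, B = 1,
                                    max_splits = 8),
                       seed = 7)
  f <- tempfile(fileext = ".json")
  write_model(model, f)
  back <- read_model(f)
  expect_equal(back$landmark_names, model$landmark_names)
  expect_equal(back$config$scales, model$config$scales)
  d1 <- detect_landmarks(model, tiny_ds$images[[3]], seed = 5)
  d2 <- detect_landmarks(back, tiny_ds$images[[3]], seed = 5)
  expect_identical(d1$points, d2$points)
})
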