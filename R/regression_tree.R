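# CART regression trees for 2-D displacement targets.
#
# Splits minimize the weighted mean squared displacement error: for node t
# with observation index set T, eps_t is the weighted mean of squared
# Euclidean distances ||d_j - dbar_t||^2, P_T = sum of observation weights
# in t, and the split gain is
#     delta = P_T eps_t - P_TL eps_TL - P_TR eps_TR ,
# i.e. the reduction in total weighted squared error.  Every observed value
# of every feature is a split candidate; routing is "strictly less goes
# left".  Growth is greedy best-first (largest gain next) under a total
# split budget `max_splits`; a node whose eps falls below
# `qed_tol * eps_root` is declared pure and never split.

weighted_node_stats <- function(d, w) {
  P <- sum(w)
  mx <- sum(w * d[, 1]) / P
  my <- sum(w * d[, 2]) / P
  sse <- sum(w * ((d[, 1] - mx)^2 + (d[, 2] - my)^2))
  list(P = P, mean = c(mx, my), sse = sse, eps = sse / P)
}

# Best (feature, threshold, gain) over all candidates for the samples in
# rows `idx`.  Returns NULL when no candidate has positive gain.
# Gain here is the weighted-SSE reduction  SSE_T - SSE_L - SSE_R, which
# equals P_T eps_t - P_TL eps_TL - P_TR eps_TR.  The scan runs in compiled
# code; ties keep the lowest feature index, then the smallest threshold.
best_split <- function(x, d, w, idx) {
  res <- cpp_best_split(x, d[, 1], d[, 2], w, as.integer(idx))
  if (res[1] == 0) return(NULL)
  list(feature = as.integer(res[1]), threshold = res[2], gain = res[3])
}

#' Fit a CART regression tree on 2-D displacement targets
#'
#' @param x numeric n x F feature matrix (rows = observations).
#' @param d numeric n x 2 matrix of displacement targets (dx, dy) in pixels.
#' @param w observation weights; default uniform `1/n`.
#' @param max_splits total split budget (tree has at most
#'   `max_splits + 1` leaves).
#' @param qed_tol per-node quadratic-error tolerance: a node with weighted
#'   MSE below `qed_tol` times the root MSE is pure and is not split.
#' @return object of class `ceph_tree`.
#' @export
fit_regression_tree <- function(x, d, w = NULL, max_splits = 256L,
                                qed_tol = 1e-6) {
  x <- as.matrix(x); d <- matrix(as.numeric(d), ncol = 2L)
  n <- nrow(x)
  if (n < 1L) stopf("cannot fit a tree on an empty sample set")
  if (nrow(d) != n) stopf("feature and target row counts differ")
  if (!all(is.finite(d))) stopf("displacement targets must be finite")
  if (is.null(w)) w <- rep(1 / n, n)
  if (length(w) != n || any(w <= 0)) stopf("invalid observation weights")
  if (!is_count(max_splits) && max_splits != 0) stopf("max_splits must be >= 0")

  feat <- integer(0); thr <- numeric(0); left <- integer(0); right <- integer(0)
  predx <- numeric(0); predy <- numeric(0); nsamp <- integer(0); neps <- numeric(0)
  new_node <- function(st, nn) {
    feat <<- c(feat, NA_integer_); thr <<- c(thr, NA_real_)
    left <<- c(left, NA_integer_); right <<- c(right, NA_integer_)
    predx <<- c(predx, st$mean[1]); predy <<- c(predy, st$mean[2])
    nsamp <<- c(nsamp, nn); neps <<- c(neps, st$eps)
    length(feat)
  }
  root_st <- weighted_node_stats(d, w)
  eps_root <- root_st$eps
  root_id <- new_node(root_st, n)

  # open nodes carry their index set and best candidate split
  open <- list()
  push_open <- function(id, idx, st) {
    if (st$eps < qed_tol * eps_root) return()    # pure
    cand <- best_split(x, d, w, idx)
    if (is.null(cand)) return()
    open[[length(open) + 1L]] <<- list(id = id, idx = idx, cand = cand)
  }
  push_open(root_id, seq_len(n), root_st)

  splits <- 0L
  while (splits < max_splits && length(open)) {
    gains <- vapply(open, function(o) o$cand$gain, 0)
    k <- which.max(gains)                        # earliest-created on ties
    o <- open[[k]]; open[[k]] <- NULL
    go_left <- x[o$idx, o$cand$feature] < o$cand$threshold
    idx_l <- o$idx[go_left]; idx_r <- o$idx[!go_left]
    st_l <- weighted_node_stats(d[idx_l, , drop = FALSE], w[idx_l])
    st_r <- weighted_node_stats(d[idx_r, , drop = FALSE], w[idx_r])
    id_l <- new_node(st_l, length(idx_l)); id_r <- new_node(st_r, length(idx_r))
    feat[o$id] <- o$cand$feature; thr[o$id] <- o$cand$threshold
    left[o$id] <- id_l; right[o$id] <- id_r
    splits <- splits + 1L
    push_open(id_l, idx_l, st_l)
    push_open(id_r, idx_r, st_r)
  }
  structure(list(feature = feat, threshold = thr, left = left, right = right,
                 pred_x = predx, pred_y = predy, n_samples = nsamp,
                 node_eps = neps, n_features = ncol(x),
                 max_splits = as.integer(max_splits), qed_tol = qed_tol,
                 eps_root = eps_root, n_splits = splits),
            class = "ceph_tree")
}

#' @export
print.ceph_tree <- function(x, ...) {
  cat(sprintf("<ceph_tree %d features, %d splits, %d leaves>\n",
              x$n_features, x$n_splits, x$n_splits + 1L))
  invisible(x)
}

# Leaf node id reached by each row of X.
tree_route <- function(tree, X) {
  n <- nrow(X)
  node <- rep(1L, n)
  repeat {
    f <- tree$feature[node]
    active <- !is.na(f)
    if (!any(active)) break
    i <- which(active)
    goes_left <- X[cbind(i, f[i])] < tree$threshold[node[i]]
    node[i] <- ifelse(goes_left, tree$left[node[i]], tree$right[node[i]])
  }
  node
}

#' Predict displacements with a regression tree
#'
#' Routes each feature vector from the root to a leaf by the stored split
#' rules (feature strictly less than threshold goes left) and returns the
#' leaf's mean displacement.
#'
#' @param tree a [fit_regression_tree()] result.
#' @param x a single feature vector or an n x F matrix.
#' @return n x 2 matrix of predicted (dx, dy); a vector input yields a
#'   length-2 vector.
#' @export
tree_predict <- function(tree, x) {
  stopifnot(inherits(tree, "ceph_tree"))
  single <- is.null(dim(x))
  X <- if (single) matrix(x, nrow = 1L) else as.matrix(x)
  if (ncol(X) != tree$n_features)
    stopf("feature length %d does not match training length %d",
          ncol(X), tree$n_features)
  leaf <- tree_route(tree, X)
  out <- cbind(dx = tree$pred_x[leaf], dy = tree$pred_y[leaf])
  if (single) drop(out) else out
}

#' Select the split budget by k-fold cross-validation
#'
#' Fits trees over a grid of `max_splits` values and returns the budget
#' minimizing the cross-validated mean squared displacement error; ties go
#' to the smallest budget.  The default grid is powers of two from 1 up to
#' the sample size.
#'
#' @inheritParams fit_regression_tree
#' @param grid candidate split budgets (positive integers).
#' @param folds number of folds (>= 2).
#' @param seed integer seed for the fold assignment.
#' @return list with `best` (selected budget), `grid`, and `cv_error`
#'   (mean squared displacement error per grid value).
#' @export
select_max_splits <- function(x, d, grid = NULL, folds = 5L, seed = 1L,
                              qed_tol = 1e-6) {
  x <- as.matrix(x); d <- matrix(as.numeric(d), ncol = 2L)
  n <- nrow(x)
  if (folds < 2L) stopf("folds must be >= 2")
  if (n < folds) stopf("fewer samples (%d) than folds (%d)", n, folds)
  if (is.null(grid)) grid <- unique(pmin(2^(0:ceiling(log2(n))), n))
  grid <- sort(unique(as.integer(grid)))
  if (!length(grid)) stopf("empty max_splits grid")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  fold_id <- sample(rep_len(seq_len(folds), n))
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  cv <- numeric(length(grid))
  for (gi in seq_along(grid)) {
    err <- 0
    for (k in seq_len(folds)) {
      tr <- fold_id != k
      tree <- fit_regression_tree(x[tr, , drop = FALSE], d[tr, , drop = FALSE],
                                  max_splits = grid[gi], qed_tol = qed_tol)
      p <- tree_predict(tree, x[!tr, , drop = FALSE])
      err <- err + sum((p[, 1] - d[!tr, 1])^2 + (p[, 2] - d[!tr, 2])^2)
    }
    cv[gi] <- err / n
  }
  best <- grid[which.min(cv)]   # which.min takes the first, i.e. smallest
  list(best = best, grid = grid, cv_error = cv)
}

# --- portable serialization -------------------------------------------------

# Doubles are serialized as %.17g strings: 17 significant digits identify
# every IEEE double uniquely, so the text round-trip is bit-exact.
dbl_out <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))

tree_to_list <- function(tree) {
  lst <- unclass(tree)
  for (f in c("threshold", "pred_x", "pred_y", "node_eps", "qed_tol",
              "eps_root"))
    lst[[f]] <- dbl_out(lst[[f]])
  lst
}

tree_from_list <- function(lst) {
  for (f in c("threshold", "pred_x", "pred_y", "node_eps", "qed_tol",
              "eps_root")) {
    v <- as.character(lst[[f]])
    v[v %in% c("NA", "null")] <- NA_character_
    lst[[f]] <- as.numeric(v)
  }
  lst$feature <- as.integer(lst$feature)
  lst$left <- as.integer(lst$left); lst$right <- as.integer(lst$right)
  lst$n_samples <- as.integer(lst$n_samples)
  lst$n_features <- as.integer(lst$n_features)
  lst$max_splits <- as.integer(lst$max_splits)
  lst$n_splits <- as.integer(lst$n_splits)
  structure(lst, class = "ceph_tree")
}

#' Write / read a regression tree as structured text (JSON)
#'
#' The round-trip is exact: coordinates are serialized at full double
#' precision.
#'
#' @param tree a `ceph_tree`.
#' @param path output/input file path.
#' @export
write_tree <- function(tree, path) {
  jsonlite::write_json(tree_to_list(tree), path, digits = NA, auto_unbox = TRUE,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_tree
#' @export
read_tree <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE)
  tree_from_list(lst)
}
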