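# Independent oracles used across tests.

# Exhaustive best-split search: every observed value of every feature is a
# candidate, routing "strictly less goes left"; gain computed directly from
# node SSE sums (uniform weights 1/n).  Independent of the package's split
# scan.
oracle_best_split <- function(x, d) {
  x <- as.matrix(x); d <- matrix(as.numeric(d), ncol = 2)
  n <- nrow(x)
  sse <- function(rows) {
    if (!length(rows)) return(0)
    dd <- d[rows, , drop = FALSE]
    sum(sweep(dd, 2, colMeans(dd))^2) / n   # weighted SSE with w = 1/n
  }
  total <- sse(seq_len(n))
  cands <- list()
  for (f in seq_len(ncol(x))) {
    for (thr in unique(x[, f])) {
      left <- which(x[, f] < thr)
      if (!length(left) || length(left) == n) next
      right <- setdiff(seq_len(n), left)
      gain <- total - sse(left) - sse(right)
      cands[[length(cands) + 1]] <-
        data.frame(feature = f, threshold = thr, gain = gain)
    }
  }
  if (!length(cands)) return(NULL)
  do.call(rbind, cands)
}

# Direct projected-distance oracle: |(D - C) . unit(B - A)| in pixels.
oracle_projected_px <- function(C, D, A, B) {
  u <- (B - A) / sqrt(sum((B - A)^2))
  abs(sum((D - C) * u))
}

# Brute-force descriptor of a patch matrix: per-pixel central differences
# with replicated borders, hard binning, double loop over pixels.
oracle_patch_descriptor <- function(patch) {
  side <- nrow(patch)
  bnd <- floor(side * (0:4) / 4)
  cell_of <- function(i) findInterval(i, bnd, rightmost.closed = FALSE) - 1L
  desc <- numeric(128)
  for (r in 0:(side - 1)) {
    for (cc in 0:(side - 1)) {
      cl <- max(cc - 1, 0); cr <- min(cc + 1, side - 1)
      ru <- max(r - 1, 0); rd <- min(r + 1, side - 1)
      gx <- (patch[r + 1, cr + 1] - patch[r + 1, cl + 1]) / 2
      gy <- (patch[rd + 1, cc + 1] - patch[ru + 1, cc + 1]) / 2
      gm <- sqrt(gx^2 + gy^2)
      ga <- if (gm == 0) 0 else atan2(gy, gx)
      if (ga < 0) ga <- ga + 2 * pi
      bin <- min(floor(ga * 8 / (2 * pi)), 7)
      cell <- cell_of(r) * 4 + cell_of(cc)
      desc[cell * 8 + bin + 1] <- desc[cell * 8 + bin + 1] + gm
    }
  }
  desc
}

# Small default measurement values, all inside their normal ranges, used to
# classify one measurement at a time.
normal_measurements <- function() {
  c(ANB = 4, SNB = 76, SNA = 80, ODI = 74.5, APDI = 81.4, FHI = 0.7,
    FHA = 29, MW = 3)
}

classify_one <- function(name, value) {
  v <- normal_measurements()
  v[name] <- value
  out <- classify_types(v)
  out[out$measurement == name, ]
}
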