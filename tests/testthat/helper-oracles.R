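# Shared fixtures and independent oracles used across the suite.

# a small, fast phantom: 16x16x4 grid, default regions scaled down
small_spec <- function(noise_sd = 0, ...) {
  phantom_spec(grid_shape = c(16L, 16L, 4L), voxel_size = c(4, 4, 10),
               noise_sd = noise_sd, ...)
}

default_times <- function(n = 30, dt = 2) (seq_len(n) - 1) * dt

# exhaustive voxel-enumeration oracle for confusion counts: walks every
# voxel with an explicit loop, independent of the vectorized implementation
oracle_confusion <- function(pred, ref, eval_mask) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(pred)) {
    if (!eval_mask[i]) next
    if (pred[i] && ref[i]) tp <- tp + 1L
    else if (pred[i] && !ref[i]) fp <- fp + 1L
    else if (!pred[i] && ref[i]) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sens = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       spec = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       dice = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_)
}

# polygon-area (shoelace) oracle for the area under a piecewise-linear ROC:
# close the curve through (1, 0) and take the signed area
oracle_polygon_auc <- function(fpr, sens) {
  o <- order(fpr, sens)
  x <- c(0, fpr[o], 1, 1)
  y <- c(0, sens[o], 1, 0)
  n <- length(x)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    s <- s + x[i] * y[j] - x[j] * y[i]
  }
  abs(s) / 2
}

# full-permutation enumeration oracle for the two-sided rank-sum p-value
oracle_ranksum_p <- function(x, y) {
  all_v <- c(x, y)
  n <- length(all_v)
  ranks <- rank(all_v)
  w_obs <- sum(ranks[seq_along(x)])
  combos <- utils::combn(n, length(x))
  ws <- apply(combos, 2, function(ix) sum(ranks[ix]))
  mu <- mean(ws)
  p <- mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
  min(1, p)
}
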