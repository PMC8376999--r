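# Independent oracles and shared fixtures, built in code at test time.

# Brute-force trimmed nearest-neighbour distance, kept deliberately separate
# from the package implementation (plain R, no shared helpers).
oracle_trimmed_distance <- function(q, tm, dx, dy, trim = 0.75) {
  nn <- numeric(nrow(q))
  for (i in seq_len(nrow(q))) {
    best <- Inf
    for (j in seq_len(nrow(tm))) {
      d <- sqrt((q[i, 1] - tm[j, 1] - dx)^2 + (q[i, 2] - tm[j, 2] - dy)^2)
      if (d < best) best <- d
    }
    nn[i] <- best
  }
  keep <- ceiling(trim * nrow(q))
  mean(sort(nn)[seq_len(keep)])
}

oracle_grid_search <- function(q, tm, max_shift, step, trim = 0.75) {
  g <- seq(-max_shift, max_shift, by = step)
  best <- Inf; bs <- c(0, 0)
  for (dx in g) for (dy in g) {
    d <- oracle_trimmed_distance(q, tm, dx, dy, trim)
    if (d < best) { best <- d; bs <- c(dx, dy) }
  }
  list(distance = best, shift = bs)
}

# Second-moment orientation of a logical mask (degrees), independent of the
# package's implementation.
oracle_orientation <- function(mask) {
  px <- which(mask, arr.ind = TRUE)
  x <- px[, 1] - mean(px[, 1]); y <- px[, 2] - mean(px[, 2])
  0.5 * atan2(2 * mean(x * y), mean(x^2) - mean(y^2)) * 180 / pi
}

random_pattern <- function(n, xr = c(400, 950), yr = c(50, 300)) {
  cbind(runif(n, xr[1], xr[2]), runif(n, yr[1], yr[2]))
}

# Ideal (noise-free) normalized-ROI dot positions of an identity.
ideal_roi_dots <- function(identity) {
  finprint:::project_dots_to_roi(identity$body_dots,
                                 finprint:::fish_geometry())
}

# Ground-truth dot positions projected into an extracted ROI's frame.
project_truth <- function(roi, fish_image) {
  finprint:::aff_apply(roi$transform, fish_image$truth$dots_canvas)
}

# One small trained classifier shared across test files (training is the
# expensive part; the cache lives for the duration of the test run).
.test_env <- new.env(parent = emptyenv())
get_test_classifier <- function() {
  if (is.null(.test_env$clf)) {
    ds <- generate_patches(250, seed = 11, near_dot_fraction = 0.15)
    .test_env$clf <- train_patch_classifier(ds, seed = 11)
  }
  .test_env$clf
}

# Precision/recall of detections against ground truth at a match radius.
detection_prf <- function(detected, truth, radius = 10) {
  if (nrow(detected) == 0)
    return(c(precision = 1, recall = as.numeric(nrow(truth) == 0), f1 = 0))
  dd <- sqrt(outer(truth[, 1], detected[, 1], "-")^2 +
               outer(truth[, 2], detected[, 2], "-")^2)
  tp <- sum(apply(dd, 1, min) <= radius)
  prec <- sum(apply(dd, 2, min) <= radius) / nrow(detected)
  rec <- tp / nrow(truth)
  c(precision = prec, recall = rec,
    f1 = if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec))
}
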