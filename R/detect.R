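# Dot localization in the normalized ROI.

#' Single-linkage clustering of detection points
#'
#' Detections closer than the cutoff are merged (connected components of the
#' strict `distance < cutoff` graph, which equals a single-linkage dendrogram
#' cut); the output is one arithmetic centroid per cluster. Chains merge
#' transitively, which is the documented single-linkage behaviour.
#'
#' @param points n x 2 matrix of (x, y).
#' @param cutoff Merge distance in px.
#' @return m x 2 matrix of cluster centroids (m <= n), in order of first
#'   cluster appearance.
#' @export
cluster_detections <- function(points, cutoff = 15) {
  points <- matrix(as.numeric(points), ncol = 2)
  n <- nrow(points)
  if (n == 0) return(points)
  if (n == 1) return(points)
  d <- as.matrix(stats::dist(points))
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      nb <- which(d[i, ] < cutoff)
      m <- min(comp[nb])
      if (any(comp[nb] != m)) { comp[nb] <- m; changed <- TRUE }
    }
    if (!changed) break
  }
  ids <- unique(comp)
  out <- t(vapply(ids, function(k)
    colMeans(points[comp == k, , drop = FALSE]), numeric(2)))
  out
}

# Windows fully inside the ROI, top-left on the stride grid, centre in the
# posterior two thirds (x >= width/3): the anterior third of the ROI covers
# the head region, which carries no dot pattern.
window_grid <- function(w, h, win = 25, step = 5) {
  if (w < win || h < win) return(NULL)
  tx <- seq(1, w - win + 1, by = step)
  ty <- seq(1, h - win + 1, by = step)
  cx <- tx + (win - 1) / 2
  tx <- tx[cx >= w / 3]
  if (length(tx) == 0 || length(ty) == 0) return(NULL)
  list(tx = tx, ty = ty, win = win)
}

#' Detect dots with the patch classifier
#'
#' Scans the normalized ROI with a 25 x 25 sliding window (5-px steps in x
#' and y, windows fully inside the image), classifies every window, keeps
#' window centres whose dot probability exceeds `p_min`, and merges nearby
#' candidates with [cluster_detections()]. Only windows centred in the
#' posterior 2/3 of the ROI are considered.
#'
#' @param roi A `normalized_roi` (or a grayscale matrix of width 1000).
#' @param classifier A [train_patch_classifier()] model.
#' @param step Sliding-window stride in px.
#' @param p_min Probability threshold (a window is a dot candidate when
#'   `p > p_min`).
#' @param cluster_cutoff Clustering distance in px.
#' @param ... Metadata (`image_id`, `fish_id`, `session`) stored on the
#'   pattern.
#' @return A [dot_pattern()].
#' @export
detect_dots <- function(roi, classifier, step = 5, p_min = 0.30,
                        cluster_cutoff = 15, ...) {
  img <- if (inherits(roi, "normalized_roi")) roi$image else roi
  w <- nrow(img); h <- ncol(img)
  if (w != 1000) stop("normalized ROI must be 1000 px wide")
  grid <- window_grid(w, h, 25, step)
  if (is.null(grid)) {
    warning("ROI smaller than one window; empty pattern")
    return(dot_pattern(matrix(numeric(0), 0, 2), ...))
  }
  nx <- length(grid$tx); ny <- length(grid$ty)
  wins <- array(0, c(25, 25, nx * ny))
  k <- 0
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    k <- k + 1
    wins[, , k] <- img[grid$tx[i]:(grid$tx[i] + 24),
                       grid$ty[j]:(grid$ty[j] + 24)]
  }
  p <- classify_patches(classifier, wins)
  hit <- p > p_min
  if (!any(hit)) {
    out <- dot_pattern(matrix(numeric(0), 0, 2), ...)
    attr(out, "n_candidates") <- 0L
    return(out)
  }
  ij <- arrayInd(which(hit), c(nx, ny))
  cand <- cbind(grid$tx[ij[, 1]] + 12, grid$ty[ij[, 2]] + 12)
  out <- dot_pattern(cluster_detections(cand, cluster_cutoff), ...)
  attr(out, "n_candidates") <- sum(hit)
  out
}

#' Detect dots with a deterministic blob detector
#'
#' A training-free alternative to [detect_dots()] with the same output
#' contract and head-region restriction: the ROI is flattened by dividing by
#' a heavily smoothed copy of itself (which removes illumination), dark blobs
#' become maxima of the smoothed relative-darkness map, local maxima above a
#' contrast threshold are refined to weighted centroids and merged with
#' [cluster_detections()]. Fully deterministic.
#'
#' @param roi `normalized_roi` or grayscale matrix of width 1000.
#' @param min_contrast Minimal relative intensity drop of a dot.
#' @param smooth_sigma Gaussian sigma of the darkness smoothing (px).
#' @param bg_sigma Gaussian sigma of the illumination estimate (px).
#' @param cluster_cutoff Merge distance of [cluster_detections()].
#' @param ... Metadata stored on the pattern.
#' @return A [dot_pattern()].
#' @export
detect_dots_blob <- function(roi, min_contrast = 0.10, smooth_sigma = 3,
                             bg_sigma = 20, cluster_cutoff = 15, ...) {
  img <- if (inherits(roi, "normalized_roi")) roi$image else roi
  mask <- if (inherits(roi, "normalized_roi")) roi$mask else NULL
  w <- nrow(img); h <- ncol(img)
  if (w != 1000) stop("normalized ROI must be 1000 px wide")
  if (h < 25) return(dot_pattern(matrix(numeric(0), 0, 2), ...))
  # illumination estimate on a 4x downsampled copy (the background varies on
  # a much coarser scale than the dots)
  h4 <- max(8L, round(h / 4))
  bg <- EBImage::imageData(EBImage::resize(
    EBImage::gblur(EBImage::resize(EBImage::Image(img), w = 250, h = h4),
                   sigma = bg_sigma / 4), w = w, h = h))
  rel <- (bg - img) / pmax(bg, 0.05)
  rs <- EBImage::imageData(EBImage::gblur(EBImage::Image(rel),
                                          sigma = smooth_sigma))
  mx <- EBImage::imageData(EBImage::dilate(EBImage::Image(rs),
                                           EBImage::makeBrush(15, "disc")))
  keep <- rs > min_contrast & rs >= mx - 1e-9
  # a dot must sit on the fish body: suppress responses from the body /
  # background boundary and the fin that cross the ROI rectangle
  if (!is.null(mask)) {
    core <- EBImage::imageData(EBImage::erode(EBImage::Image(mask * 1),
                                              EBImage::makeBrush(13, "disc"))) > 0.5
    keep <- keep & core
  }
  # match the sliding-window containment margin (window centres are at least
  # 13 px from the ROI border) and avoid smoothing artefacts at the edges
  keep[c(seq_len(12), w - seq_len(12) + 1), ] <- FALSE
  keep[, c(seq_len(12), h - seq_len(12) + 1)] <- FALSE
  cand <- which(keep, arr.ind = TRUE)
  if (nrow(cand) == 0) return(dot_pattern(matrix(numeric(0), 0, 2), ...))
  # refine to intensity-weighted centroids in a 9x9 neighbourhood
  ref <- t(apply(cand, 1, function(p) {
    xs <- max(1, p[1] - 4):min(w, p[1] + 4)
    ys <- max(1, p[2] - 4):min(h, p[2] + 4)
    ww <- pmax(rs[xs, ys, drop = FALSE] - min_contrast / 2, 0)
    s <- sum(ww)
    if (s <= 0) return(as.numeric(p))
    c(sum(outer(xs, rep(1, length(ys))) * ww) / s,
      sum(outer(rep(1, length(xs)), ys) * ww) / s)
  }))
  ref <- ref[ref[, 1] >= w / 3, , drop = FALSE]
  if (nrow(ref) == 0) return(dot_pattern(matrix(numeric(0), 0, 2), ...))
  dot_pattern(cluster_detections(ref, cluster_cutoff), ...)
}
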