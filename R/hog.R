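# Histogram-of-oriented-gradients template matching: the alternative matcher.

#' HOG matcher configuration
#'
#' @param sizeN Side of the normalized square patch the ROI subpart is
#'   resized to before descriptor computation (64).
#' @param offx,offy Border offsets trimmed from the subregion, in ROI px.
#' @param cell_size Cell side in px of the normalized patch (2).
#' @param block_cells Cells per block side (2 x 2 blocks, unit cell stride).
#' @param n_bins Unsigned orientation bins over 0-180 degrees.
#' @param subregion Fraction of the ROI width used, right-anchored (the
#'   anterior part of the ROI is mostly patternless head; presets 1/2, 2/3
#'   and 3/4 are the tested settings).
#' @param scan_stride Scanning step over the unknown ROI, px.
#' @return A `hog_config` list.
#' @export
hog_config <- function(sizeN = 64, offx = 10, offy = 10, cell_size = 2,
                       block_cells = 2, n_bins = 9, subregion = 2 / 3,
                       scan_stride = 4) {
  if (sizeN < 2 * cell_size) stop("sizeN must be at least two cells")
  if (sizeN %% cell_size != 0) stop("cell_size must divide sizeN")
  list(sizeN = sizeN, offx = offx, offy = offy, cell_size = cell_size,
       block_cells = block_cells, n_bins = n_bins, subregion = subregion,
       scan_stride = scan_stride, eps = 1e-6)
}

#' Compute a HOG descriptor
#'
#' Standard unsigned gradient-orientation histogram: central-difference
#' gradients, per-cell orientation histograms weighted by gradient magnitude,
#' overlapping `block_cells` x `block_cells` blocks at unit cell stride, each
#' block L2-normalized (epsilon-guarded, so a constant patch yields the zero
#' vector), concatenated. Deterministic.
#'
#' @param patch `sizeN` x `sizeN` numeric matrix.
#' @param config [hog_config()].
#' @return Numeric descriptor of length
#'   `(n_cells - block_cells + 1)^2 * block_cells^2 * n_bins`.
#' @export
compute_hog <- function(patch, config = hog_config()) {
  n <- config$sizeN
  if (!is.matrix(patch) || nrow(patch) != n || ncol(patch) != n)
    stop("patch must be ", n, " x ", n)
  # central differences with replicated borders
  xp <- patch[c(2:n, n), ]; xm <- patch[c(1, 1:(n - 1)), ]
  yp <- patch[, c(2:n, n)]; ym <- patch[, c(1, 1:(n - 1))]
  gx <- (xp - xm) / 2; gy <- (yp - ym) / 2
  mag <- sqrt(gx^2 + gy^2)
  ori <- (atan2(gy, gx) * 180 / pi) %% 180
  bin <- floor(ori / (180 / config$n_bins)) %% config$n_bins  # 0-based
  nc <- n / config$cell_size
  cx <- (rep.int(seq_len(n), n) - 1) %/% config$cell_size     # 0-based cell
  cy <- (rep(seq_len(n), each = n) - 1) %/% config$cell_size
  idx <- as.vector(bin) + config$n_bins * (cx + nc * cy) + 1
  H <- numeric(config$n_bins * nc * nc)
  acc <- rowsum(as.vector(mag), idx)
  H[as.integer(rownames(acc))] <- acc
  dim(H) <- c(config$n_bins, nc, nc)
  bc <- config$block_cells
  nb <- nc - bc + 1
  B <- array(0, c(config$n_bins * bc * bc, nb, nb))
  k <- 0
  for (dj in seq_len(bc)) for (di in seq_len(bc)) {
    B[k * config$n_bins + seq_len(config$n_bins), , ] <-
      H[, di:(di + nb - 1), dj:(dj + nb - 1)]
    k <- k + 1
  }
  nrm <- sqrt(colSums(B^2) + config$eps^2)
  B <- sweep(B, c(2, 3), nrm, `/`)
  as.vector(B)
}

# Right-anchored subregion bounds of a ROI of width w and height h.
hog_window_bounds <- function(w, h, config) {
  sub_w <- round(w * config$subregion)
  x0 <- w - sub_w + 1 + config$offx
  x1 <- w - config$offx
  y0 <- 1 + config$offy
  y1 <- h - config$offy
  if (x1 - x0 + 1 < config$sizeN / 4 || y1 - y0 + 1 < config$sizeN / 4)
    stop("degenerate HOG subregion")
  list(x = c(x0, x1), y = c(y0, y1), w = x1 - x0 + 1, h = y1 - y0 + 1)
}

resize_to <- function(img, w, h) {
  EBImage::imageData(EBImage::resize(EBImage::Image(img), w = w, h = h))
}

#' HOG template of a known fish
#'
#' Cuts the configured right-anchored subregion of the ROI (minus the border
#' offsets), resizes it to `sizeN` x `sizeN` and computes its descriptor.
#'
#' @param roi A `normalized_roi` or grayscale matrix.
#' @param config [hog_config()].
#' @param fish_id,image_id Provenance.
#' @return A `hog_template`: `vector`, the pre-resize `window` (w, h),
#'   config and provenance.
#' @export
hog_template <- function(roi, config = hog_config(), fish_id = NA,
                         image_id = NA) {
  img <- if (inherits(roi, "normalized_roi")) roi$image else roi
  b <- hog_window_bounds(nrow(img), ncol(img), config)
  patch <- resize_to(img[b$x[1]:b$x[2], b$y[1]:b$y[2]],
                     config$sizeN, config$sizeN)
  structure(list(vector = compute_hog(patch, config),
                 window = c(w = b$w, h = b$h),
                 config = config, fish_id = fish_id, image_id = image_id),
            class = "hog_template")
}

#' @export
print.hog_template <- function(x, ...) {
  cat("<hog_template>", length(x$vector), "dims, window",
      x$window["w"], "x", x$window["h"], "px\n")
  invisible(x)
}

# Descriptors of every scan placement of a wd x hd window over img.
hog_scan_descriptors <- function(img, wd, hd, config) {
  w <- nrow(img); h <- ncol(img)
  if (w < wd || h < hd) stop("unknown ROI smaller than the scan window")
  xs <- seq(1, w - wd + 1, by = config$scan_stride)
  ys <- seq(1, h - hd + 1, by = config$scan_stride)
  desc <- NULL
  k <- 0
  for (y0 in ys) for (x0 in xs) {
    v <- compute_hog(resize_to(img[x0:(x0 + wd - 1), y0:(y0 + hd - 1)],
                               config$sizeN, config$sizeN), config)
    if (is.null(desc)) desc <- matrix(0, length(v), length(xs) * length(ys))
    k <- k + 1
    desc[, k] <- v
  }
  desc
}

#' Minimal scan distance between a known template and an unknown ROI
#'
#' Slides a window of the known subpart's pre-resize dimensions over the
#' unknown ROI, computes the descriptor of each (resized) placement and
#' returns the minimal Euclidean distance to the known vector.
#'
#' @param known A [hog_template()].
#' @param unknown_roi `normalized_roi` or grayscale matrix.
#' @param config [hog_config()]; defaults to the template's.
#' @return Minimal descriptor distance (>= 0).
#' @export
hog_scan_distance <- function(known, unknown_roi, config = known$config) {
  img <- if (inherits(unknown_roi, "normalized_roi")) unknown_roi$image else
    unknown_roi
  desc <- hog_scan_descriptors(img, known$window["w"], known$window["h"],
                               config)
  sqrt(min(colSums((desc - known$vector)^2)))
}

#' HOG-based identification
#'
#' The unknown fish's similarity to each gallery fish is the minimum over all
#' combinations of its query ROIs, the fish's known ROIs and all scan
#' placements; the fish with the minimal distance wins (ties to the smallest
#' id). Short-term use passes one query ROI and two known ROIs per fish;
#' long-term use passes all images of the respective sessions.
#'
#' @param query_rois List of `normalized_roi` (or matrices) of the unknown
#'   fish.
#' @param gallery Named list: fish id -> list of known ROIs.
#' @param config [hog_config()].
#' @return A `match_result` with per-fish minimal distances.
#' @export
identify_hog <- function(query_rois, gallery, config = hog_config()) {
  if (length(gallery) == 0) stop("empty gallery")
  if (inherits(query_rois, "normalized_roi") || is.matrix(query_rois))
    query_rois <- list(query_rois)
  ids <- names(gallery) %||% as.character(seq_along(gallery))
  qimgs <- lapply(query_rois, function(r)
    if (inherits(r, "normalized_roi")) r$image else r)
  # cache scan descriptors per (query, window dims)
  cache <- new.env(parent = emptyenv())
  scan <- function(qi, wd, hd) {
    key <- paste(qi, wd, hd, sep = "_")
    if (is.null(cache[[key]]))
      cache[[key]] <- hog_scan_descriptors(qimgs[[qi]], wd, hd, config)
    cache[[key]]
  }
  dist <- rep(Inf, length(gallery))
  for (j in seq_along(gallery)) {
    kn <- gallery[[j]]
    if (inherits(kn, "normalized_roi") || is.matrix(kn)) kn <- list(kn)
    for (roi in kn) {
      tpl <- hog_template(roi, config)
      for (qi in seq_along(qimgs)) {
        d <- sqrt(min(colSums((scan(qi, tpl$window["w"], tpl$window["h"]) -
                                 tpl$vector)^2)))
        if (d < dist[j]) dist[j] <- d
      }
    }
  }
  ord <- order(dist, ids)
  structure(list(query_id = NA, predicted_id = ids[ord[1]],
                 distances = stats::setNames(dist, ids),
                 best_shifts = NULL, fallback_used = FALSE),
            class = "match_result")
}
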