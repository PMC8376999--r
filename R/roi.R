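# Landmark-based extraction of the standardized skin ROI.
#
# Coordinate convention used throughout: 1-based (x, y) with x the column
# index (rightward along the body after de-skew) and y the row index
# (downward), pixel centres at integer coordinates. Every stage keeps a 3x3
# homogeneous transform from the original canvas so ground truth can be
# projected into any frame.

#' Configuration of the ROI extraction stage
#'
#' @param green_hue Hue range (degrees, HSL space) of the background.
#' @param sat_min Minimal saturation of background pixels.
#' @param eye_threshold Gray intensity below which a pixel counts as eye
#'   (the 8-bit threshold 20, determined experimentally in the original
#'   workflow, expressed on the `[0, 1]` scale).
#' @param roi_width Width the ROI is normalized to (px).
#' @param belly_fraction Divisor interpreting the lower ROI bound as
#'   `BP.y / belly_fraction` in the fish-object frame.
#' @return A list of settings.
#' @export
roi_config <- function(green_hue = c(90, 150), sat_min = 0.3,
                       eye_threshold = 20 / 255, roi_width = 1000,
                       belly_fraction = 2) {
  list(green_hue = green_hue, sat_min = sat_min, eye_threshold = eye_threshold,
       roi_width = roi_width, belly_fraction = belly_fraction)
}

#' Segment the green background
#'
#' Marks pixels whose hue and saturation (HSL space) fall in the configured
#' green range. Pure thresholding, no learning.
#'
#' @param img RGB array (w x h x 3, values in `[0, 1]`) or a `fish_image`.
#' @param config [roi_config()].
#' @return Logical matrix, `TRUE` for background pixels.
#' @export
segment_background <- function(img, config = roi_config()) {
  if (inherits(img, "fish_image")) img <- img$img
  hsl <- rgb_to_hsl(img[, , 1], img[, , 2], img[, , 3])
  hsl$h >= config$green_hue[1] & hsl$h <= config$green_hue[2] &
    hsl$s >= config$sat_min
}

#' Locate the fish object
#'
#' The fish is the largest connected component of the non-background area,
#' with holes filled. Errors if there is no foreground at all.
#'
#' @param bg_mask Background mask from [segment_background()].
#' @param img The RGB array the mask came from.
#' @return A `fish_object`: cropped binary `mask`, RGB `crop`, the
#'   canvas-to-object `transform`, and `orientation_applied_deg = NA` (not yet
#'   de-skewed).
#' @export
locate_fish <- function(bg_mask, img) {
  if (inherits(img, "fish_image")) img <- img$img
  fg <- !bg_mask
  if (!any(fg)) stop("no fish found: empty foreground")
  lab <- EBImage::bwlabel(EBImage::Image(fg * 1))
  tab <- tabulate(as.integer(EBImage::imageData(lab)))
  if (length(tab) == 0 || max(tab) == 0) stop("no fish found: empty foreground")
  biggest <- which.max(tab)
  mask <- EBImage::imageData(lab) == biggest
  mask <- EBImage::imageData(EBImage::fillHull(EBImage::Image(mask * 1))) > 0.5
  bb <- mask_bbox(mask)
  pad <- 2
  x0 <- max(1, bb["x0"] - pad); x1 <- min(nrow(mask), bb["x1"] + pad)
  y0 <- max(1, bb["y0"] - pad); y1 <- min(ncol(mask), bb["y1"] + pad)
  structure(list(
    mask = mask[x0:x1, y0:y1],
    crop = img[x0:x1, y0:y1, , drop = FALSE],
    transform = aff_translate(1 - x0, 1 - y0),
    orientation_applied_deg = NA_real_
  ), class = "fish_object")
}

#' @export
print.fish_object <- function(x, ...) {
  cat("<fish_object>", nrow(x$mask), "x", ncol(x$mask), "px, orientation",
      if (is.na(x$orientation_applied_deg)) "not yet de-skewed" else
        sprintf("%.2f deg applied", x$orientation_applied_deg), "\n")
  invisible(x)
}

# Median colour of the border ring; used as fill when rotating so that the
# out-of-frame corners look like background instead of introducing dark
# pixels that would confound the eye detector.
border_fill <- function(crop) {
  w <- dim(crop)[1]; h <- dim(crop)[2]
  ring <- rbind(cbind(seq_len(w), 1), cbind(seq_len(w), h),
                cbind(1, seq_len(h)), cbind(w, seq_len(h)))
  vapply(1:3, function(c.) stats::median(crop[cbind(ring, c.)]), 0)
}

#' De-skew a fish object
#'
#' Rotates the object by the negative of its second-moment (ellipse
#' equivalent) orientation so the body axis is horizontal, then standardizes
#' to head-left. The head side is decided by which half contains the dark
#' (sub eye-threshold) eye pixels, falling back to the wider half when no eye
#' is visible. A degenerate object with undefined orientation is passed
#' through with rotation 0.
#'
#' @param object A `fish_object` from [locate_fish()].
#' @param config [roi_config()].
#' @param grayscale If `TRUE`, only luminance is resampled and the returned
#'   crop holds it replicated across channels (cheaper; sufficient for the
#'   ROI pipeline, whose later stages are all grayscale).
#' @return The de-skewed `fish_object`, with `orientation_applied_deg`,
#'   `flipped`, and `length_px`/`np` once [find_narrowest()] has run.
#' @export
deskew_object <- function(object, config = roi_config(), grayscale = FALSE) {
  theta <- mask_orientation(object$mask)
  w <- nrow(object$mask); h <- ncol(object$mask)
  out_w <- ceiling(abs(w * cos(theta * pi / 180)) +
                     abs(h * sin(theta * pi / 180))) + 4
  out_h <- ceiling(abs(w * sin(theta * pi / 180)) +
                     abs(h * cos(theta * pi / 180))) + 4
  A <- aff_translate((out_w + 1) / 2, (out_h + 1) / 2) %*%
    aff_rotate(-theta) %*% aff_translate(-(w + 1) / 2, -(h + 1) / 2)
  fill <- border_fill(object$crop)
  crop <- array(0, c(out_w, out_h, 3))
  if (grayscale) {
    # fast path for the ROI pipeline: every downstream consumer works on
    # luminance, so resample one gray plane and replicate it
    gray0 <- luminance(object$crop[, , 1], object$crop[, , 2],
                       object$crop[, , 3])
    planes <- affine_resample_multi(list(gray0, object$mask * 1), A,
                                    c(out_w, out_h),
                                    fill = c(luminance(fill[1], fill[2],
                                                       fill[3]), 0))
    crop[] <- planes[[1]]
    mask <- planes[[2]] > 0.5
  } else {
    planes <- affine_resample_multi(
      list(object$crop[, , 1], object$crop[, , 2], object$crop[, , 3],
           object$mask * 1), A, c(out_w, out_h), fill = c(fill, 0))
    for (c. in 1:3) crop[, , c.] <- planes[[c.]]
    mask <- planes[[4]] > 0.5
  }
  if (!any(mask)) stop("de-skew produced an empty mask")

  # head-left standardization
  gray <- luminance(crop[, , 1], crop[, , 2], crop[, , 3])
  bb <- mask_bbox(mask)
  cx <- (bb["x0"] + bb["x1"]) / 2
  dark <- mask & gray < config$eye_threshold
  flip <- if (any(dark)) {
    dk <- which(dark, arr.ind = TRUE)
    sum(dk[, 1] > cx) > sum(dk[, 1] <= cx)
  } else {
    pix <- which(mask, arr.ind = TRUE)
    sum(pix[, 1] > cx) > sum(pix[, 1] <= cx)
  }
  if (flip) {
    crop <- crop[rev(seq_len(out_w)), , , drop = FALSE]
    mask <- mask[rev(seq_len(out_w)), , drop = FALSE]
    A <- aff_flip_x(out_w) %*% A
  }
  bb <- mask_bbox(mask)
  pad <- 2
  x0 <- max(1, bb["x0"] - pad); x1 <- min(nrow(mask), bb["x1"] + pad)
  y0 <- max(1, bb["y0"] - pad); y1 <- min(ncol(mask), bb["y1"] + pad)
  A <- aff_translate(1 - x0, 1 - y0) %*% A
  structure(list(
    mask = mask[x0:x1, y0:y1],
    crop = crop[x0:x1, y0:y1, , drop = FALSE],
    transform = A %*% object$transform,
    orientation_applied_deg = -theta,
    flipped = flip
  ), class = "fish_object")
}

# Per-column vertical extent of the mask; 0 where the column is empty.
column_extent <- function(mask) {
  w <- nrow(mask)
  top <- integer(w); bot <- integer(w)
  for (x in seq_len(w)) {
    ys <- which(mask[x, ])
    if (length(ys)) { top[x] <- ys[1]; bot[x] <- ys[length(ys)] }
  }
  list(top = top, bottom = bot,
       extent = ifelse(top > 0, bot - top + 1L, 0L))
}

#' Narrowest pre-tail column
#'
#' Returns the column minimizing the vertical mask extent, searched in the
#' posterior half of the object (the tail fin is excluded by construction of
#' the landmark length). Ties break to the rightmost minimal column.
#'
#' @param object De-skewed `fish_object`.
#' @return Integer column index (the NP landmark); also the fish length in px
#'   since the head tip sits at the left edge.
#' @export
find_narrowest <- function(object) {
  ce <- column_extent(object$mask)
  w <- nrow(object$mask)
  lo <- ceiling(w / 2)
  # resampling the rotated object leaves a few partial-coverage columns at
  # the very end of the tail whose extent is spuriously small; the tail fin
  # flares outward, so drop the trailing strictly-decreasing run
  hi <- max(which(ce$extent > 0), lo)
  while (hi > lo && ce$extent[hi] < ce$extent[hi - 1]) hi <- hi - 1L
  ext <- ce$extent[lo:hi]
  valid <- ext > 0
  if (!any(valid)) stop("no mask pixels in the posterior half")
  mn <- min(ext[valid])
  idx <- which(ext == mn & valid)
  lo + idx[length(idx)] - 1L
}

#' Upper-fin beginning (UP)
#'
#' Within 3/8 to 5/8 of the fish length, takes the upper border of the mask,
#' splits it at the centre of the search window, fits a least-squares line to
#' each half and intersects the two lines. Near-parallel fits fall back to
#' the highest border point in the window.
#'
#' @param object De-skewed `fish_object`.
#' @param length_px Fish length (head tip to NP), from [find_narrowest()].
#' @return Numeric `c(x, y)` of the fin beginning.
#' @export
find_upper_fin <- function(object, length_px) {
  ce <- column_extent(object$mask)
  xw <- seq(max(1, round(3 / 8 * length_px)),
            min(nrow(object$mask), round(5 / 8 * length_px)))
  xw <- xw[ce$extent[xw] > 0]
  if (length(xw) < 4) stop("upper-fin search window is empty")
  ytop <- ce$top[xw]
  ctr <- length_px / 2
  li <- xw <= ctr
  fallback <- function() {
    i <- which.min(ytop)
    c(x = xw[i], y = ytop[i])
  }
  if (sum(li) < 2 || sum(!li) < 2) return(fallback())
  f1 <- stats::lm.fit(cbind(1, xw[li]), ytop[li])$coefficients
  f2 <- stats::lm.fit(cbind(1, xw[!li]), ytop[!li])$coefficients
  if (anyNA(c(f1, f2)) || abs(f1[2] - f2[2]) < 1e-6) return(fallback())
  x <- (f2[1] - f1[1]) / (f1[2] - f2[2])
  y <- f1[1] + f1[2] * x
  if (!is.finite(x) || x < xw[1] - 5 || x > xw[length(xw)] + 5) return(fallback())
  c(x = unname(x), y = unname(y))
}

#' Eye position (EP)
#'
#' Within the anterior third before UP (x between 0 and UP.x / 3), the eye is
#' the centroid of all pixels with gray intensity below the eye threshold
#' (20 on the 8-bit scale).
#'
#' @param object De-skewed `fish_object`.
#' @param UP `c(x, y)` from [find_upper_fin()].
#' @param config [roi_config()].
#' @return Numeric `c(x, y)` centroid of the eye pixels.
#' @export
find_eye <- function(object, UP, config = roi_config()) {
  xmax <- max(1L, floor(UP[1] / 3))
  gray <- luminance(object$crop[seq_len(xmax), , 1],
                    object$crop[seq_len(xmax), , 2],
                    object$crop[seq_len(xmax), , 3])
  dark <- which(as.matrix(gray) < config$eye_threshold, arr.ind = TRUE)
  if (nrow(dark) == 0) stop("eye not found: no pixel below the threshold")
  c(x = mean(dark[, 1]), y = mean(dark[, 2]))
}

#' Belly point (BP)
#'
#' The lowest mask pixel in the column of UP: the border of the fish belly at
#' the horizontal position of the fin beginning.
#'
#' @param object De-skewed `fish_object`.
#' @param UP `c(x, y)` landmark.
#' @return Numeric `c(x, y)`.
#' @export
find_belly <- function(object, UP) {
  col <- clamp(round(UP[1]), 1, nrow(object$mask))
  ys <- which(object$mask[col, ])
  if (length(ys) == 0) stop("no mask pixels in the UP column")
  c(x = unname(UP[1]), y = ys[length(ys)])
}

#' Cut the ROI rectangle
#'
#' The ROI spans EP.x to UP.x horizontally and `UP.y + (BP.y - UP.y)/20` to
#' `BP.y / 2` vertically, all in the de-skewed fish-object frame (origin at
#' the object bounding box top-left). Bounds are rounded outward (floor for
#' top/left, ceiling for bottom/right).
#'
#' @param object De-skewed `fish_object`.
#' @param EP,UP,BP Landmarks.
#' @param config [roi_config()].
#' @return List with the RGB `crop`, its `offset` (x0, y0) in the object
#'   frame, and the landmarks.
#' @export
extract_roi <- function(object, EP, UP, BP, config = roi_config()) {
  x1 <- EP[1]; x2 <- UP[1]
  y1 <- UP[2] + (BP[2] - UP[2]) / 20
  y2 <- BP[2] / config$belly_fraction
  if (y2 <= y1) stop("degenerate ROI: lower bound above upper bound")
  xs <- clamp(c(floor(x1), ceiling(x2)), 1, nrow(object$mask))
  ys <- clamp(c(floor(y1), ceiling(y2)), 1, ncol(object$mask))
  if (xs[2] <= xs[1] || ys[2] <= ys[1]) stop("degenerate ROI: empty rectangle")
  list(crop = object$crop[xs[1]:xs[2], ys[1]:ys[2], , drop = FALSE],
       mask = object$mask[xs[1]:xs[2], ys[1]:ys[2], drop = FALSE],
       offset = c(x0 = unname(xs[1]), y0 = unname(ys[1])),
       landmarks = list(EP = EP, UP = UP, BP = BP))
}

#' Normalize the ROI
#'
#' Converts the ROI to grayscale and resizes it (bilinear) to a width of
#' 1000 px, the height preserving the aspect ratio. Normalization removes the
#' ROI size change caused by fish growth.
#'
#' @param roi Output of [extract_roi()].
#' @param config [roi_config()].
#' @return A `normalized_roi`: `image` (matrix, width exactly
#'   `config$roi_width`), `scale`, `height`, the source landmarks and offset.
#' @export
normalize_roi <- function(roi, config = roi_config()) {
  gray <- luminance(roi$crop[, , 1], roi$crop[, , 2], roi$crop[, , 3])
  w <- nrow(gray); h <- ncol(gray)
  k <- config$roi_width / w
  hh <- max(1L, round(h * k))
  img <- EBImage::imageData(EBImage::resize(EBImage::Image(gray),
                                            w = config$roi_width, h = hh))
  msk <- if (!is.null(roi$mask))
    EBImage::imageData(EBImage::resize(EBImage::Image(roi$mask * 1),
                                       w = config$roi_width, h = hh)) > 0.5
  structure(list(image = img, mask = msk, scale = k, height = hh,
                 offset = roi$offset, landmarks = roi$landmarks),
            class = "normalized_roi")
}

#' @export
print.normalized_roi <- function(x, ...) {
  cat("<normalized_roi>", nrow(x$image), "x", ncol(x$image),
      "px (scale", round(x$scale, 3), ")\n")
  invisible(x)
}

#' Full ROI extraction pipeline
#'
#' Runs segmentation, fish localization, de-skew, landmark detection (NP, UP,
#' EP, BP), ROI cut and normalization on one image.
#'
#' @param img RGB array or `fish_image`.
#' @param config [roi_config()].
#' @return A `normalized_roi` whose `transform` maps original canvas
#'   coordinates to normalized-ROI coordinates, with the de-skewed `object`
#'   and landmarks attached.
#' @export
extract_normalized_roi <- function(img, config = roi_config()) {
  bg <- segment_background(img, config)
  obj <- locate_fish(bg, img)
  obj <- deskew_object(obj, config, grayscale = TRUE)
  np <- find_narrowest(obj)
  obj$np <- np
  obj$length_px <- np
  UP <- find_upper_fin(obj, np)
  EP <- find_eye(obj, UP, config)
  BP <- find_belly(obj, UP)
  roi <- extract_roi(obj, EP, UP, BP, config)
  out <- normalize_roi(roi, config)
  k <- out$scale
  A_norm <- aff_translate(0.5, 0.5) %*% aff_scale(k) %*%
    aff_translate(-0.5, -0.5) %*%
    aff_translate(1 - roi$offset["x0"], 1 - roi$offset["y0"])
  out$transform <- A_norm %*% obj$transform
  out$object <- obj
  out
}
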