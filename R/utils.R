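# Internal helpers shared across modules.

# Run code with a temporarily-seeded RNG, restoring the caller's RNG state.
# All generators in the package are pure functions of their seed argument.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# RGB (values in [0,1], matrices of equal dim) -> hue [0,360), saturation and
# lightness [0,1] of the HSL colour space.
rgb_to_hsl <- function(r, g, b) {
  mx <- pmax(r, g, b)
  mn <- pmin(r, g, b)
  d <- mx - mn
  l <- (mx + mn) / 2
  s <- ifelse(d < 1e-12, 0, d / (1 - abs(2 * l - 1) + 1e-12))
  h <- matrix(0, nrow(as.matrix(r)), ncol(as.matrix(r)))
  idx <- d >= 1e-12
  hr <- idx & (mx == r)
  hg <- idx & (mx == g) & !hr
  hb <- idx & !hr & !hg
  h[hr] <- 60 * (((g[hr] - b[hr]) / d[hr]) %% 6)
  h[hg] <- 60 * ((b[hg] - r[hg]) / d[hg] + 2)
  h[hb] <- 60 * ((r[hb] - g[hb]) / d[hb] + 4)
  list(h = h, s = s, l = l)
}

# Luminance conversion used everywhere a grayscale image is needed.
luminance <- function(r, g, b) 0.2126 * r + 0.7152 * g + 0.0722 * b

# Bilinear resampling of one image plane (matrix indexed [x, y], pixel centres
# at integer coordinates) under an affine map. `A` is the 3x3 matrix taking
# homogeneous input coordinates to output coordinates; sampling inverts it.
# Pixels mapping outside the source are filled with `fill`.
affine_resample <- function(plane, A, out_dim, fill = 0) {
  affine_resample_multi(list(plane), A, out_dim, fill)[[1]]
}

# Same, for several planes sharing one geometry (saves recomputing indices).
affine_resample_multi <- function(planes, A, out_dim, fill = 0) {
  w2 <- out_dim[1]; h2 <- out_dim[2]
  Ainv <- solve(A)
  xo <- rep.int(seq_len(w2), h2)
  yo <- rep(seq_len(h2), each = w2)
  xi <- Ainv[1, 1] * xo + Ainv[1, 2] * yo + Ainv[1, 3]
  yi <- Ainv[2, 1] * xo + Ainv[2, 2] * yo + Ainv[2, 3]
  w <- nrow(planes[[1]]); h <- ncol(planes[[1]])
  x0 <- floor(xi); y0 <- floor(yi)
  fx <- xi - x0;  fy <- yi - y0
  ok <- x0 >= 1 & y0 >= 1 & x0 <= w - 1 & y0 <= h - 1
  # clamp indices so the gather stays in-bounds; masked afterwards
  x0c <- clamp(x0, 1, w - 1); y0c <- clamp(y0, 1, h - 1)
  i00 <- x0c + (y0c - 1) * w
  w00 <- (1 - fx) * (1 - fy); w10 <- fx * (1 - fy)
  w01 <- (1 - fx) * fy;       w11 <- fx * fy
  bad <- !ok
  fill <- rep_len(fill, length(planes))
  lapply(seq_along(planes), function(k) {
    p <- planes[[k]]
    v <- w00 * p[i00] + w10 * p[i00 + 1] + w01 * p[i00 + w] +
      w11 * p[i00 + w + 1]
    v[bad] <- fill[k]
    matrix(v, w2, h2)
  })
}

# Affine helpers (3x3 homogeneous, coordinates are (x, y) columns).
aff_translate <- function(dx, dy) matrix(c(1, 0, 0, 0, 1, 0, dx, dy, 1), 3, 3)
aff_rotate <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}
aff_scale <- function(sx, sy = sx) matrix(c(sx, 0, 0, 0, sy, 0, 0, 0, 1), 3, 3)
aff_flip_x <- function(width) matrix(c(-1, 0, 0, 0, 1, 0, width + 1, 0, 1), 3, 3)

aff_apply <- function(A, xy) {
  xy <- matrix(xy, ncol = 2)
  out <- cbind(xy, 1) %*% t(A)
  out[, 1:2, drop = FALSE]
}

# Orientation of a binary mask from second-order central moments, in degrees,
# measured in the image frame (x rightward, y downward); the angle of the
# major axis of the ellipse with the same second moments, in (-90, 90].
mask_orientation <- function(mask) {
  pix <- which(mask, arr.ind = TRUE)
  if (nrow(pix) < 2) return(0)
  x <- pix[, 1] - mean(pix[, 1])
  y <- pix[, 2] - mean(pix[, 2])
  mxx <- mean(x * x); myy <- mean(y * y); mxy <- mean(x * y)
  if (abs(mxy) < 1e-12 && abs(mxx - myy) < 1e-12) return(0)
  0.5 * atan2(2 * mxy, mxx - myy) * 180 / pi
}

mask_bbox <- function(mask) {
  pix <- which(mask, arr.ind = TRUE)
  if (nrow(pix) == 0) stop("empty mask")
  c(x0 = min(pix[, 1]), x1 = max(pix[, 1]),
    y0 = min(pix[, 2]), y1 = max(pix[, 2]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
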