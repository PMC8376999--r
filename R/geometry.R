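# Parametric body model of a laterally viewed, head-left fish.
#
# The silhouette is a spline-like half-height profile around a horizontal
# midline, with a triangular dorsal fin, a narrow pre-tail waist and a flaring
# tail fin. It is not a species-accurate mesh: it guarantees exactly the
# features the landmark detectors rely on (pointed head, dark eye disk,
# straight-edged dorsal fin with its apex at half the body length, narrowest
# column at the waist, belly border under the fin apex).
#
# Body coordinates: u along the body axis, u = 0 at the nose tip and u = 1 at
# the narrowest pre-tail column (the landmark length); the tail fin occupies
# u in (1, 1.18]. Vertical positions are measured from the midline, y down.

fish_geometry <- function(length_px = 340) {
  L <- length_px
  g <- list(
    L = L,                    # nose tip -> narrowest column, px at growth 1
    H = 0.267 * L,            # maximal body height
    fin_span = c(0.36, 0.64), # dorsal fin base, in u
    fin_apex = 0.5,           # fin apex: the UP landmark
    fin_height = 0.055 * L,   # apex height above the dorsal border
    tail_span = 0.18,         # tail fin length in u past the waist
    tail_flare = 0.60,        # half-height factor at the tail tip
    waist = 0.17,             # half-height factor at the narrowest column
    peak_u = 0.42,            # u of maximal body height
    eye_u = 0.08,             # eye centre along the body axis (on the midline)
    eye_radius = 0.035 * L,
    eye_gray = 0.035,         # well below the 20/255 eye threshold
    roi_u = c(0.08, 0.5),     # ideal ROI span: eye centre to fin apex
    dot_u = c(0.34, 0.485),   # band holding the melanophore dots
    dot_depth = c(0.03, 0.33) # dot depth under the dorsal border, fraction of
                              # the local body height
  )
  g
}

# Half-height profile s(u) in [0, 1]; the mask half-height is s(u) * H / 2.
fish_profile <- function(u, geom) {
  s <- numeric(length(u))
  a <- !is.na(u) & u >= 0 & u <= geom$peak_u
  s[a] <- sin(pi / 2 * u[a] / geom$peak_u)^0.9
  b <- !is.na(u) & u > geom$peak_u & u <= 1
  s[b] <- geom$waist + (1 - geom$waist) *
    cos(pi / 2 * (u[b] - geom$peak_u) / (1 - geom$peak_u))^1.1
  d <- !is.na(u) & u > 1 & u <= 1 + geom$tail_span
  s[d] <- geom$waist + (geom$tail_flare - geom$waist) * (u[d] - 1) / geom$tail_span
  s
}

# Height of the dorsal fin upper edge (midline-relative, negative = up) for a
# vector of u; NA outside the fin base. Two straight edges meeting at the apex,
# so that a least-squares line fit on each side recovers the apex exactly.
fin_top_edge <- function(u, geom) {
  s_l <- fish_profile(geom$fin_span[1], geom)
  s_r <- fish_profile(geom$fin_span[2], geom)
  s_a <- fish_profile(geom$fin_apex, geom)
  yl <- -geom$H / 2 * s_l
  yr <- -geom$H / 2 * s_r
  ya <- -geom$H / 2 * s_a - geom$fin_height
  y <- rep(NA_real_, length(u))
  left <- !is.na(u) & u >= geom$fin_span[1] & u <= geom$fin_apex
  y[left] <- yl + (ya - yl) * (u[left] - geom$fin_span[1]) /
    (geom$fin_apex - geom$fin_span[1])
  right <- !is.na(u) & u > geom$fin_apex & u <= geom$fin_span[2]
  y[right] <- ya + (yr - ya) * (u[right] - geom$fin_apex) /
    (geom$fin_span[2] - geom$fin_apex)
  y
}

# Vertical body-frame position (midline-relative) of a dot at (u, v), where v
# is the depth fraction below the dorsal border. Growth scales the silhouette
# height by growth_h but the dot band depth follows growth_l: the dorsal
# pigment band rides on the back of the fish and does not deepen with the
# belly, which is what keeps dot patterns usable across months of growth.
dot_body_y <- function(u, v, geom, growth_l = 1, growth_h = 1) {
  s <- fish_profile(u, geom)
  -geom$H / 2 * s * growth_h + v * geom$H * s * growth_l
}

# y (midline-relative) of the top of the bounding box: the fin apex is the
# highest point of the silhouette.
body_top_y <- function(geom, growth_h = 1) {
  -(geom$H / 2 * fish_profile(geom$fin_apex, geom) + geom$fin_height) * growth_h
}

# Ideal landmark positions in the grown, unrotated body frame (midline y = 0).
ideal_landmarks <- function(geom, growth_l = 1, growth_h = 1) {
  s_a <- fish_profile(geom$fin_apex, geom)
  list(
    nose = c(0, 0),
    EP = c(geom$eye_u * geom$L * growth_l, 0),
    UP = c(geom$fin_apex * geom$L * growth_l,
           (-geom$H / 2 * s_a - geom$fin_height) * growth_h),
    BP = c(geom$fin_apex * geom$L * growth_l, geom$H / 2 * s_a * growth_h),
    NP = c(geom$L * growth_l, 0)
  )
}

# Scale factor from normalized-ROI pixels to body-frame pixels (the ideal ROI
# spans roi_u of the body and is normalized to width 1000).
norm_to_body_scale <- function(geom, growth_l = 1) {
  diff(geom$roi_u) * geom$L * growth_l / 1000
}

# Project body dots (u, v) to ideal normalized-ROI coordinates (width 1000).
# The ROI top edge is UP.y + (BP.y - UP.y) / 20 in the bounding-box frame.
project_dots_to_roi <- function(dots_uv, geom, growth_l = 1, growth_h = 1,
                                offsets_norm = NULL) {
  lm <- ideal_landmarks(geom, growth_l, growth_h)
  top <- body_top_y(geom, growth_h)
  up_y <- lm$UP[2] - top
  bp_y <- lm$BP[2] - top
  roi_y0 <- up_y + (bp_y - up_y) / 20
  k <- 1 / norm_to_body_scale(geom, growth_l)
  u <- dots_uv[, 1]; v <- dots_uv[, 2]
  xb <- u * geom$L * growth_l
  yb <- dot_body_y(u, v, geom, growth_l, growth_h) - top
  x <- (xb - geom$roi_u[1] * geom$L * growth_l) * k
  y <- (yb - roi_y0) * k
  out <- cbind(x = x, y = y)
  if (!is.null(offsets_norm)) out <- out + offsets_norm
  out
}
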