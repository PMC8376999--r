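#' Generate a synthetic fish identity
#'
#' An identity is the biometric ground truth for one simulated fish: a set of
#' melanophore dot positions in unit body coordinates, plus dot size and
#' contrast parameters. Dots are confined to the dorsal flank band that the
#' standardized ROI covers, always behind the head third of the body (real
#' salmon carry no dot pattern on the head), and are spaced so that the
#' 15-px detection clustering can never merge two distinct true dots.
#'
#' @param seed Integer seed; the generator is a pure function of it.
#' @param n_dots_range Length-2 integer vector, inclusive range for the number
#'   of dots. Must lie within `[4, 40]`.
#' @param fish_id Identity label, defaults to the seed.
#' @return An object of class `fish_identity` with fields `fish_id`,
#'   `body_dots` (matrix of (u, v): u along the body axis in `[0, 1]`, v the
#'   depth fraction under the dorsal border), `dot_radius` (px in the
#'   normalized ROI), `dot_contrast`, and per-dot nuisance parameters.
#' @export
generate_identity <- function(seed, n_dots_range = c(8, 30), fish_id = seed) {
  if (length(n_dots_range) != 2 || n_dots_range[1] < 4 || n_dots_range[2] > 40 ||
      n_dots_range[1] > n_dots_range[2])
    stop("n_dots_range must be an increasing pair within [4, 40]")
  geom <- fish_geometry()
  with_seed(seed, {
    n <- if (n_dots_range[1] == n_dots_range[2]) n_dots_range[1] else
      sample(seq(n_dots_range[1], n_dots_range[2]), 1)
    dot_radius <- runif(1, 8, 10)
    dot_contrast <- runif(1, 0.35, 0.6)
    minsep <- max(2 * dot_radius + 6, 32)   # normalized-ROI px: two candidate
    # clouds plus the 15-px cluster cutoff can never bridge this gap
    uv <- matrix(NA_real_, 0, 2)
    xy <- matrix(NA_real_, 0, 2)
    tries <- 0
    while (nrow(uv) < n && tries < 20000) {
      cand <- c(runif(1, geom$dot_u[1], geom$dot_u[2]),
                runif(1, geom$dot_depth[1], geom$dot_depth[2]))
      p <- project_dots_to_roi(matrix(cand, 1), geom)
      if (nrow(xy) == 0 ||
          min(sqrt((xy[, 1] - p[1])^2 + (xy[, 2] - p[2])^2)) >= minsep) {
        uv <- rbind(uv, cand)
        xy <- rbind(xy, p)
      }
      tries <- tries + 1
    }
    if (nrow(uv) < n)
      stop("could not place ", n, " dots with the required spacing")
    structure(list(
      fish_id = fish_id,
      body_dots = unname(uv),
      dot_radius = dot_radius,
      dot_contrast = dot_contrast,
      dot_scale = runif(n, 0.8, 1.2),
      dot_aspect = runif(n, 1, 1.3),
      dot_angle = runif(n, 0, pi),
      dot_contrast_k = pmin(dot_contrast * runif(n, 0.85, 1.15), 0.75)
    ), class = "fish_identity")
  })
}

#' @export
print.fish_identity <- function(x, ...) {
  cat("<fish_identity> id", x$fish_id, "-", nrow(x$body_dots), "dots,",
      "radius", round(x$dot_radius, 1), "px (normalized ROI), contrast",
      round(x$dot_contrast, 2), "\n")
  invisible(x)
}

#' Scene parameters for rendering one image
#'
#' Emulates one acquisition of a fish: in-plane rotation within +/- 45 degrees
#' (the range used when fish were repositioned between shots), translation,
#' a multiplicative illumination gain, growth factors relative to the first
#' session, optional blur (the underwater condition), and the per-image dot
#' jitter standing in for residual localization noise.
#'
#' @param rotation_deg In-plane rotation, must lie in `[-45, 45]`.
#' @param translation_px Length-2 (dx, dy) offset of the fish from the canvas
#'   centre.
#' @param illumination_gain Multiplicative intensity factor.
#' @param growth_factor_length,growth_factor_height Body scale relative to the
#'   reference size; must be in `[1, 1.6]` and `[1, 1.9]` respectively, the
#'   average growth observed over a 6-month cultivation.
#' @param blur_sigma Gaussian blur in px (0 = sharp, tent-like conditions).
#' @param dot_jitter_sd Per-image positional jitter of each dot, px per axis in
#'   normalized-ROI units.
#' @param dot_session_offsets Optional n-dots x 2 matrix of per-session dot
#'   drift (normalized-ROI px), as produced by [generate_cohort()].
#' @param session Session label (e.g. "SS", "SL1").
#' @param seed Per-image seed driving jitter, texture phases and pixel noise.
#' @return A `scene_params` list.
#' @export
scene_params <- function(rotation_deg = 0, translation_px = c(0, 0),
                         illumination_gain = 1, growth_factor_length = 1,
                         growth_factor_height = 1, blur_sigma = 0,
                         dot_jitter_sd = 0, dot_session_offsets = NULL,
                         session = "SS", seed = 1) {
  if (abs(rotation_deg) > 45)
    stop("rotation_deg must be within [-45, 45]")
  if (growth_factor_length < 1 || growth_factor_length > 1.6 ||
      growth_factor_height < 1 || growth_factor_height > 1.9)
    stop("growth factors must lie in [1, 1.6] (length) and [1, 1.9] (height)")
  structure(list(rotation_deg = rotation_deg,
                 translation_px = translation_px,
                 illumination_gain = illumination_gain,
                 growth_factor_length = growth_factor_length,
                 growth_factor_height = growth_factor_height,
                 blur_sigma = blur_sigma,
                 dot_jitter_sd = dot_jitter_sd,
                 dot_session_offsets = dot_session_offsets,
                 session = session,
                 seed = seed),
            class = "scene_params")
}

# Background chromaticity of the photographic tent; a fixed saturated green
# (hue about 134 degrees in HSL) matching the segmentation defaults.
.bg_green <- c(0.24, 0.70, 0.35)
.body_rgb <- c(0.60, 0.63, 0.66)

#' Render a synthetic fish image
#'
#' Draws one fish-shaped object (elongated body, triangular dorsal fin,
#' tapering tail with a narrowest waist, dark eye disk) on a uniform green
#' background, with dark elliptical dots at the identity's positions, under
#' the scene's rotation, translation, growth and illumination. Ground-truth
#' landmark positions and rendered dot centroids are returned as metadata so
#' the downstream stages can be validated against them.
#'
#' @param identity A [generate_identity()] object.
#' @param scene A [scene_params()] object.
#' @param canvas_size Optional (width, height); by default the smallest canvas
#'   that contains the rotated, translated fish plus a margin. An explicit
#'   canvas too small for the fish is an error.
#' @param return_mask If `TRUE`, also return the ground-truth silhouette mask.
#' @return A `fish_image`: `img` (w x h x 3 array, values in `[0, 1]`),
#'   `truth` (landmarks, dot centroids in canvas coordinates, dot positions in
#'   ideal normalized-ROI coordinates), plus the identity id, session and
#'   scene.
#' @export
render_fish <- function(identity, scene = scene_params(), canvas_size = NULL,
                        return_mask = FALSE) {
  geom <- fish_geometry()
  gl <- scene$growth_factor_length
  gh <- scene$growth_factor_height
  Lg <- geom$L * gl
  half_h_top <- -body_top_y(geom, gh)         # px above midline
  half_h_bot <- geom$H / 2 * gh               # px below midline
  xext <- c(0, (1 + geom$tail_span) * Lg)
  yext <- c(-half_h_top, half_h_bot)
  ctr <- c(mean(xext), 0)
  th <- scene$rotation_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  corners <- rbind(c(xext[1], yext[1]), c(xext[1], yext[2]),
                   c(xext[2], yext[1]), c(xext[2], yext[2]))
  rc <- sweep(corners, 2, ctr) %*% t(R)
  margin <- 10
  need_w <- diff(range(rc[, 1])) + 2 * (margin + abs(scene$translation_px[1]))
  need_h <- diff(range(rc[, 2])) + 2 * (margin + abs(scene$translation_px[2]))
  if (is.null(canvas_size)) canvas_size <- c(ceiling(need_w), ceiling(need_h))
  w <- canvas_size[1]; h <- canvas_size[2]
  if (w < diff(range(rc[, 1])) + 2 || h < diff(range(rc[, 2])) + 2)
    stop("fish does not fit on the requested canvas")

  cc <- c((w + 1) / 2 + scene$translation_px[1],
          (h + 1) / 2 + scene$translation_px[2])
  # forward body->canvas map: p_img = R %*% (p - ctr) + cc
  fwd <- function(p) {
    p <- matrix(p, ncol = 2)
    sweep(sweep(p, 2, ctr) %*% t(R), 2, cc, `+`)
  }

  with_seed(scene$seed, {
    # inverse map of the whole pixel grid to body coordinates
    X <- rep.int(seq_len(w), h); Y <- rep(seq_len(h), each = w)
    xb <- (X - cc[1]) * cos(th) + (Y - cc[2]) * sin(th) + ctr[1]
    yb <- -(X - cc[1]) * sin(th) + (Y - cc[2]) * cos(th) + ctr[2]
    u <- xb / Lg
    rel <- yb
    s_u <- fish_profile(u, geom)
    half <- geom$H / 2 * s_u * gh
    body <- s_u > 0 & abs(rel) <= half
    fin_y <- fin_top_edge(u, geom) * gh
    fin <- !is.na(fin_y) & rel >= fin_y & rel < -half + 1e-9
    fin[is.na(fin)] <- FALSE
    mask <- body | fin

    ph <- runif(3, 0, 2 * pi)
    gain <- scene$illumination_gain
    r <- rep.int(.bg_green[1], w * h)
    g <- rep.int(.bg_green[2], w * h)
    b <- rep.int(.bg_green[3], w * h)

    fi <- which(mask)
    depth <- clamp((rel[fi] + half[fi]) / (2 * pmax(half[fi], 1e-9)), 0, 1)
    tex <- 1 + 0.05 * sin(2 * pi * 2.6 * u[fi] + ph[1]) +
      0.04 * sin(2 * pi * (1.8 * u[fi] + 1.2 * depth) + ph[2])
    shade <- 0.92 + 0.1 * depth          # dorsal side slightly darker
    lum <- tex * shade
    lum[fin[fi]] <- lum[fin[fi]] * 0.97
    r[fi] <- .body_rgb[1] * lum
    g[fi] <- .body_rgb[2] * lum
    b[fi] <- .body_rgb[3] * lum

    # eye disk (interior intensity far below the 20/255 threshold)
    ec <- fwd(c(geom$eye_u * Lg, 0))
    re <- geom$eye_radius * gl
    stamp_disk <- function(cx, cy, rad, fun) {
      x0 <- max(1, floor(cx - rad - 2)); x1 <- min(w, ceiling(cx + rad + 2))
      y0 <- max(1, floor(cy - rad - 2)); y1 <- min(h, ceiling(cy + rad + 2))
      if (x0 > x1 || y0 > y1) return(invisible())
      xs <- x0:x1; ys <- y0:y1
      dd <- sqrt(outer((xs - cx)^2, (ys - cy)^2, `+`))
      cov <- clamp((rad - dd) / 1.2 + 0.5, 0, 1)
      idx <- outer(xs, (ys - 1) * w, `+`)
      fun(idx, cov)
    }
    stamp_disk(ec[1], ec[2], re, function(idx, cov) {
      r[idx] <<- r[idx] * (1 - cov) + geom$eye_gray * cov
      g[idx] <<- g[idx] * (1 - cov) + geom$eye_gray * cov
      b[idx] <<- b[idx] * (1 - cov) + geom$eye_gray * cov
    })

    # dots: session drift plus per-image jitter, both in normalized-ROI px
    nd <- nrow(identity$body_dots)
    off <- matrix(0, nd, 2)
    if (!is.null(scene$dot_session_offsets)) off <- off + scene$dot_session_offsets
    if (scene$dot_jitter_sd > 0)
      off <- off + matrix(rnorm(2 * nd, 0, scene$dot_jitter_sd), nd, 2)
    n2b <- norm_to_body_scale(geom, gl)
    ub <- identity$body_dots[, 1]; vb <- identity$body_dots[, 2]
    dot_body <- cbind(ub * Lg, dot_body_y(ub, vb, geom, gl, gh)) + off * n2b
    dot_canvas <- fwd(dot_body)
    r_obj <- identity$dot_radius * identity$dot_scale * n2b
    ca <- sqrt(identity$dot_aspect); cb <- 1 / ca
    ang <- identity$dot_angle + th
    for (k in seq_len(nd)) {
      cx <- dot_canvas[k, 1]; cy <- dot_canvas[k, 2]
      rad <- r_obj[k] * ca[k]
      x0 <- max(1, floor(cx - rad - 2)); x1 <- min(w, ceiling(cx + rad + 2))
      y0 <- max(1, floor(cy - rad - 2)); y1 <- min(h, ceiling(cy + rad + 2))
      if (x0 > x1 || y0 > y1) next
      xs <- x0:x1; ys <- y0:y1
      ex <- outer(xs - cx, rep(1, length(ys)))
      ey <- outer(rep(1, length(xs)), ys - cy)
      e1 <- ex * cos(ang[k]) + ey * sin(ang[k])
      e2 <- -ex * sin(ang[k]) + ey * cos(ang[k])
      dn <- sqrt((e1 / (r_obj[k] * ca[k]))^2 + (e2 / (r_obj[k] * cb[k]))^2)
      sdist <- (dn - 1) * r_obj[k] * cb[k]
      cov <- clamp(0.5 - sdist / 1.2, 0, 1)
      fac <- 1 - identity$dot_contrast_k[k] * cov
      idx <- outer(xs, (ys - 1) * w, `+`)
      r[idx] <- r[idx] * fac; g[idx] <- g[idx] * fac; b[idx] <- b[idx] * fac
    }

    img <- array(0, c(w, h, 3))
    img[, , 1] <- r * gain; img[, , 2] <- g * gain; img[, , 3] <- b * gain
    if (scene$blur_sigma > 0)
      img <- EBImage::imageData(EBImage::gblur(EBImage::Image(img, colormode = "Color"),
                                               sigma = scene$blur_sigma))
    noise <- matrix(rnorm(w * h, 0, 0.008), w, h)   # sensor luminance noise
    img <- clamp(img + array(noise, dim(img)), 0, 1)

    lmk <- ideal_landmarks(geom, gl, gh)
    lmk_canvas <- lapply(lmk, fwd)
    dots_roi <- project_dots_to_roi(identity$body_dots, geom, gl, gh,
                                    offsets_norm = off)
    out <- structure(list(
      img = img,
      fish_id = identity$fish_id,
      session = scene$session,
      scene = scene,
      truth = list(landmarks = lapply(lmk_canvas, as.numeric),
                   dots_canvas = dot_canvas,
                   dots_roi = dots_roi,
                   rotation_deg = scene$rotation_deg)
    ), class = "fish_image")
    if (return_mask) out$truth$mask <- matrix(mask, w, h)
    out
  })
}

#' @export
print.fish_image <- function(x, ...) {
  d <- dim(x$img)
  cat("<fish_image> fish", x$fish_id, "session", x$session,
      sprintf("(%d x %d px, rotation %.1f deg)\n", d[1], d[2],
              x$scene$rotation_deg))
  invisible(x)
}

#' Session templates for cohort simulation
#'
#' Builds the per-session scene distributions for a multi-session experiment:
#' rotation within +/- 45 degrees, translation, illumination gain, growth
#' factors interpolated geometrically up to x1.6 in length and x1.9 in height
#' across four sessions (the average growth over six months), and the
#' between-session dot drift.
#'
#' @param n_sessions Number of sessions: 1 gives a single short-term session
#'   ("SS"); more gives "SL1", "SL2", ...
#' @param growth_length,growth_height Total growth factors across the series.
#' @param drift_sd Between-session dot drift, px per axis in normalized-ROI
#'   units. The default 4.5 yields pattern displacements of the magnitude
#'   observed in manual validation of real fish.
#' @param dot_jitter_sd Per-image dot jitter, px per axis.
#' @param rotation_range,translation_max,illumination_range,blur_sigma Scene
#'   nuisance ranges shared by all sessions.
#' @return List of session template lists, one per session.
#' @export
session_templates <- function(n_sessions = 4, growth_length = 1.6,
                              growth_height = 1.9, drift_sd = 4.5,
                              dot_jitter_sd = 1.5, rotation_range = c(-45, 45),
                              translation_max = 20,
                              illumination_range = c(0.85, 1.15),
                              blur_sigma = 0) {
  labels <- if (n_sessions == 1) "SS" else paste0("SL", seq_len(n_sessions))
  lapply(seq_len(n_sessions), function(s) {
    frac <- if (n_sessions == 1) 0 else (s - 1) / (n_sessions - 1)
    list(label = labels[s],
         rotation_range = rotation_range,
         translation_max = translation_max,
         illumination_range = illumination_range,
         growth_factor_length = growth_length^frac,
         growth_factor_height = growth_height^frac,
         blur_sigma = blur_sigma,
         dot_jitter_sd = dot_jitter_sd,
         drift_sd = drift_sd)
  })
}

#' Generate a synthetic cohort
#'
#' Draws identities and, per fish and session, `images_per_fish` scenes with
#' independently drawn rotation, translation and illumination. Dot positions
#' drift between sessions by each session's `drift_sd`. Images are not
#' rasterized up front (a full cohort would not fit in memory); use
#' [render_cohort_image()] to materialize any image, deterministically.
#'
#' @param n_fish Number of identities.
#' @param images_per_fish Images per fish and session; either a scalar or an
#'   inclusive range such as `c(5, 9)` (images per fish varied from 5 to 9 in
#'   the emulated experiment) drawn per fish.
#' @param sessions Session templates from [session_templates()].
#' @param seed Cohort seed.
#' @param n_dots_range Passed to [generate_identity()].
#' @return A `fish_cohort`: `identities`, per-image `manifest` data frame
#'   (image_id, fish_id, session, scene index) and the scene list.
#' @export
generate_cohort <- function(n_fish, images_per_fish = c(5, 9),
                            sessions = session_templates(1), seed = 1,
                            n_dots_range = c(8, 30)) {
  stopifnot(n_fish >= 1)
  with_seed(seed, {
    id_seeds <- sample.int(.Machine$integer.max - 1, n_fish)
    identities <- lapply(seq_len(n_fish), function(i)
      generate_identity(id_seeds[i], n_dots_range, fish_id = i))
    n_img_fish <- if (length(images_per_fish) == 1)
      rep(images_per_fish, n_fish)
    else sample(seq(images_per_fish[1], images_per_fish[2]), n_fish,
                replace = TRUE)
    scenes <- list(); rows <- list(); k <- 0
    for (s in seq_along(sessions)) {
      tpl <- sessions[[s]]
      for (i in seq_len(n_fish)) {
        nd <- nrow(identities[[i]]$body_dots)
        drift <- if (tpl$drift_sd > 0)
          matrix(rnorm(2 * nd, 0, tpl$drift_sd), nd, 2) else matrix(0, nd, 2)
        for (j in seq_len(n_img_fish[i])) {
          k <- k + 1
          scenes[[k]] <- scene_params(
            rotation_deg = runif(1, tpl$rotation_range[1], tpl$rotation_range[2]),
            translation_px = runif(2, -tpl$translation_max, tpl$translation_max),
            illumination_gain = runif(1, tpl$illumination_range[1],
                                      tpl$illumination_range[2]),
            growth_factor_length = tpl$growth_factor_length,
            growth_factor_height = tpl$growth_factor_height,
            blur_sigma = tpl$blur_sigma,
            dot_jitter_sd = tpl$dot_jitter_sd,
            dot_session_offsets = drift,
            session = tpl$label,
            seed = sample.int(.Machine$integer.max - 1, 1))
          rows[[k]] <- data.frame(image_id = k, fish_id = i,
                                  session = tpl$label, image_index = j)
        }
      }
    }
    structure(list(identities = identities,
                   manifest = do.call(rbind, rows),
                   scenes = scenes),
              class = "fish_cohort")
  })
}

#' Render one image of a cohort
#'
#' @param cohort A [generate_cohort()] object.
#' @param image_id Row of the cohort manifest.
#' @param ... Passed to [render_fish()].
#' @return A `fish_image`.
#' @export
render_cohort_image <- function(cohort, image_id, ...) {
  row <- cohort$manifest[cohort$manifest$image_id == image_id, ]
  if (nrow(row) != 1) stop("unknown image_id ", image_id)
  render_fish(cohort$identities[[row$fish_id]], cohort$scenes[[image_id]], ...)
}

#' @export
print.fish_cohort <- function(x, ...) {
  cat("<fish_cohort>", length(x$identities), "fish,",
      nrow(x$manifest), "images,",
      length(unique(x$manifest$session)), "session(s)\n")
  invisible(x)
}

#' Write a cohort to disk
#'
#' Writes each image as PNG with a JSON ground-truth sidecar (fish id,
#' session, landmarks, true dot centroids, scene parameters) and a cohort
#' manifest CSV.
#'
#' @param cohort A `fish_cohort`.
#' @param dir Output directory (created if missing).
#' @param image_ids Subset of images to write; default all.
#' @return The manifest (invisibly), augmented with file paths.
#' @export
write_cohort <- function(cohort, dir, image_ids = cohort$manifest$image_id) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- cohort$manifest[cohort$manifest$image_id %in% image_ids, ]
  man$image_path <- file.path(dir, sprintf("img_%05d.png", man$image_id))
  for (i in seq_len(nrow(man))) {
    fi <- render_cohort_image(cohort, man$image_id[i])
    EBImage::writeImage(EBImage::Image(fi$img, colormode = "Color"),
                        man$image_path[i])
    side <- list(fish_id = fi$fish_id, session = fi$session,
                 landmarks = fi$truth$landmarks,
                 dots_canvas = fi$truth$dots_canvas,
                 scene = fi$scene[c("rotation_deg", "translation_px",
                                    "illumination_gain",
                                    "growth_factor_length",
                                    "growth_factor_height", "seed")])
    jsonlite::write_json(side, sub("\\.png$", ".json", man$image_path[i]),
                         auto_unbox = TRUE, digits = NA)
  }
  write.csv(man[, c("image_path", "fish_id", "session")],
            file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}

#' Generate a labeled 25 x 25 patch dataset
#'
#' Builds the training data for the dot / no-dot patch classifier the way
#' the reference set was built: patches are cut from normalized ROIs of
#' rendered fish. `dot` patches are windows centred within +/- 3.6 px of a
#' true dot; `no_dot` patches are windows at least 25 px away from every
#' dot, so they show whatever the ROI contains there -- skin texture, the
#' body/background boundary or plain background. The train/test split is a
#' deterministic 2/3 / 1/3 per class (test size `floor(n/3)`).
#'
#' @param n_per_class Patches per class (at least 10); 535 per class matches
#'   the reference training set size.
#' @param seed Seed.
#' @param near_dot_fraction Fraction of no-dot patches centred 10-20 px from
#'   a dot (hard negatives). The default 0 matches the plain "areas without
#'   dots" negative class; a detector intended for sliding-window scanning
#'   benefits from them (~0.15): they sharpen localization so that the
#'   candidate clustering cannot merge neighbouring dots.
#' @return A `patch_dataset`: `patches` (25 x 25 x 2n array), `labels`
#'   (factor dot/no_dot), `split` (factor train/test).
#' @export
generate_patches <- function(n_per_class = 535, seed = 1,
                             near_dot_fraction = 0) {
  if (n_per_class < 10) stop("n_per_class must be at least 10")
  ps <- 25L
  half <- (ps - 1L) %/% 2L
  with_seed(seed, {
    n <- n_per_class
    dots <- array(0, c(ps, ps, n)); nod <- array(0, c(ps, ps, n))
    nd <- 0L; nn <- 0L
    img_i <- 0L
    cut <- function(img, cx, cy) {
      x0 <- round(cx) - half; y0 <- round(cy) - half
      img[x0:(x0 + ps - 1L), y0:(y0 + ps - 1L)]
    }
    while ((nd < n || nn < n) && img_i < 40L + n) {
      img_i <- img_i + 1L
      id <- generate_identity(sample.int(.Machine$integer.max - 1, 1),
                              fish_id = img_i)
      gf <- runif(1)   # growth stage of the photographed fish
      fi <- render_fish(id, scene_params(
        rotation_deg = runif(1, -45, 45),
        translation_px = runif(2, -15, 15),
        illumination_gain = runif(1, 0.85, 1.15),
        growth_factor_length = 1.6^gf, growth_factor_height = 1.9^gf,
        session = "patches", seed = sample.int(.Machine$integer.max - 1, 1)))
      roi <- extract_normalized_roi(fi)
      truth <- finprint:::aff_apply(roi$transform, fi$truth$dots_canvas)
      w <- nrow(roi$image); h <- ncol(roi$image)
      inside <- function(cx, cy) cx >= half + 1 && cx <= w - half &&
        cy >= half + 1 && cy <= h - half
      mind <- function(cx, cy) min(sqrt((truth[, 1] - cx)^2 +
                                          (truth[, 2] - cy)^2))
      for (k in sample(nrow(truth))) {
        if (nd >= n) break
        cx <- truth[k, 1] + runif(1, -3.6, 3.6)
        cy <- truth[k, 2] + runif(1, -3.6, 3.6)
        if (!inside(cx, cy)) next
        nd <- nd + 1L
        dots[, , nd] <- cut(roi$image, cx, cy)
      }
      tries <- 0L
      want <- min(n - nn, 12L)
      while (want > 0L && tries < 200L) {
        tries <- tries + 1L
        if (runif(1) < near_dot_fraction) {
          k <- sample(nrow(truth), 1)
          ang <- runif(1, 0, 2 * pi); dist <- runif(1, 10, 20)
          cx <- truth[k, 1] + dist * cos(ang)
          cy <- truth[k, 2] + dist * sin(ang)
          if (!inside(cx, cy) || mind(cx, cy) < 10) next
        } else {
          cx <- runif(1, half + 1, w - half)
          cy <- runif(1, half + 1, h - half)
          if (mind(cx, cy) < 25) next
        }
        nn <- nn + 1L; want <- want - 1L
        nod[, , nn] <- cut(roi$image, cx, cy)
      }
    }
    if (nd < n || nn < n)
      stop("could not collect enough patches")
    patches <- array(0, c(ps, ps, 2L * n))
    patches[, , seq_len(n)] <- dots
    patches[, , n + seq_len(n)] <- nod
    labels <- factor(rep(c("dot", "no_dot"), each = n),
                     levels = c("dot", "no_dot"))
    n_test <- floor(n / 3)
    split_class <- c(rep("train", n - n_test), rep("test", n_test))
    structure(list(patches = patches, labels = labels,
                   split = factor(c(split_class, split_class),
                                  levels = c("train", "test"))),
              class = "patch_dataset")
  })
}

#' @export
print.patch_dataset <- function(x, ...) {
  cat("<patch_dataset>", dim(x$patches)[3], "patches (",
      sum(x$labels == "dot"), "dot /", sum(x$labels == "no_dot"), "no-dot ),",
      sum(x$split == "train"), "train /", sum(x$split == "test"), "test\n")
  invisible(x)
}
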