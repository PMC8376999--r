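test_that("background segmentation is pure green thresholding", {
  green <- array(0, c(40, 30, 3))
  green[, , 1] <- 0.24; green[, , 2] <- 0.7; green[, , 3] <- 0.35
  expect_true(all(segment_background(green)))
  black <- array(0, c(40, 30, 3))
  expect_false(any(segment_background(black)))

  id <- generate_identity(2)
  fi <- render_fish(id, scene_params(rotation_deg = 10, seed = 3),
                    return_mask = TRUE)
  bg <- segment_background(fi)
  # at least 99% of true fish pixels are excluded from the background
  expect_gte(mean(!bg[fi$truth$mask]), 0.99)
})

test_that("the fish is the largest filled foreground component", {
  id <- generate_identity(2)
  fi <- render_fish(id, scene_params(rotation_deg = 10, seed = 3),
                    return_mask = TRUE)
  obj <- locate_fish(segment_background(fi), fi)
  # IoU with the ground-truth silhouette
  full <- matrix(FALSE, dim(fi$img)[1], dim(fi$img)[2])
  A <- solve(obj$transform)
  px <- which(obj$mask, arr.ind = TRUE)
  orig <- round(finprint:::aff_apply(A, px))
  ok <- orig[, 1] >= 1 & orig[, 1] <= nrow(full) &
    orig[, 2] >= 1 & orig[, 2] <= ncol(full)
  full[orig[ok, , drop = FALSE]] <- TRUE
  iou <- sum(full & fi$truth$mask) / sum(full | fi$truth$mask)
  expect_gte(iou, 0.95)

  # two blobs: the larger wins
  img <- array(0, c(60, 40, 3))
  img[, , 1] <- 0.24; img[, , 2] <- 0.7; img[, , 3] <- 0.35
  img[5:10, 5:10, ] <- 0.5          # 36 px blob
  img[20:40, 10:30, ] <- 0.5        # large blob
  bg <- segment_background(img)
  obj2 <- locate_fish(bg, img)
  expect_gte(sum(obj2$mask), 21 * 21)
  ctr <- colMeans(which(obj2$mask, arr.ind = TRUE))
  orig_ctr <- finprint:::aff_apply(solve(obj2$transform), ctr)
  expect_true(orig_ctr[1] > 15 && orig_ctr[2] > 8)

  all_green <- array(0, c(20, 20, 3))
  all_green[, , 1] <- 0.24; all_green[, , 2] <- 0.7; all_green[, , 3] <- 0.35
  expect_error(locate_fish(segment_background(all_green), all_green),
               "no fish")
})

test_that("de-skew levels the body axis and standardizes head-left", {
  id <- generate_identity(4)
  for (rot in c(20, -38)) {
    fi <- render_fish(id, scene_params(rotation_deg = rot, seed = 6))
    obj <- deskew_object(locate_fish(segment_background(fi), fi))
    expect_lt(abs(oracle_orientation(obj$mask)), 1)
    expect_false(obj$flipped)
  }
  # an already horizontal fish is rotated by (almost) nothing
  fi0 <- render_fish(id, scene_params(rotation_deg = 0, seed = 6))
  obj0 <- deskew_object(locate_fish(segment_background(fi0), fi0))
  expect_lt(abs(obj0$orientation_applied_deg), 1.5)

  # a mirrored (head-right) image is flipped back to head-left
  fir <- fi0
  fir$img <- fi0$img[rev(seq_len(dim(fi0$img)[1])), , , drop = FALSE]
  objr <- deskew_object(locate_fish(segment_background(fir), fir))
  expect_true(objr$flipped)
  gray <- finprint:::luminance(objr$crop[, , 1], objr$crop[, , 2],
                               objr$crop[, , 3])
  dark <- which(gray < 20 / 255, arr.ind = TRUE)
  expect_lt(mean(dark[, 1]), nrow(objr$mask) / 2)
})

test_that("the narrowest column is found with a rightmost tie-break", {
  # hand-built mask: anterior bulk, then posterior widths 10, 8, 3, 9
  mask <- matrix(FALSE, 8, 14)
  for (x in 1:4) mask[x, 2:13] <- TRUE
  widths <- c(10, 8, 3, 9)
  for (i in seq_along(widths)) mask[4 + i, seq_len(widths[i]) + 1] <- TRUE
  obj <- structure(list(mask = mask), class = "fish_object")
  expect_equal(find_narrowest(obj), 7L)

  rect <- structure(list(mask = matrix(TRUE, 10, 6)), class = "fish_object")
  expect_equal(find_narrowest(rect), 10L)  # tie -> rightmost

  id <- generate_identity(4)
  fi <- render_fish(id, scene_params(rotation_deg = 5, seed = 2))
  obj2 <- deskew_object(locate_fish(segment_background(fi), fi))
  np <- find_narrowest(obj2)
  truth_np <- finprint:::aff_apply(obj2$transform,
                                   fi$truth$landmarks$NP)
  expect_lt(abs(np - truth_np[1]), 3)
})

test_that("the upper fin is the intersection of two fitted border lines", {
  # two symmetric ramps meeting exactly at x = 60
  mask <- matrix(FALSE, 100, 80)
  for (x in 1:100) {
    top <- 40 - max(0, 20 - abs(x - 60))  # apex y = 20 at x = 60
    mask[x, top:70] <- TRUE
  }
  obj <- structure(list(mask = mask), class = "fish_object")
  up <- find_upper_fin(obj, length_px = 100)
  expect_equal(unname(up[1]), 60, tolerance = 0.5)
  expect_equal(unname(up[2]), 20, tolerance = 1)

  # flat border: fallback to the highest border point, no error
  flat <- structure(list(mask = matrix(TRUE, 100, 40)), class = "fish_object")
  upf <- find_upper_fin(flat, 100)
  expect_true(is.finite(upf[1]) && is.finite(upf[2]))

  id <- generate_identity(4)
  fi <- render_fish(id, scene_params(rotation_deg = -12, seed = 8))
  obj2 <- deskew_object(locate_fish(segment_background(fi), fi))
  up2 <- find_upper_fin(obj2, find_narrowest(obj2))
  truth_up <- finprint:::aff_apply(obj2$transform, fi$truth$landmarks$UP)
  expect_lt(sqrt(sum((up2 - truth_up)^2)), 3)
})

test_that("the eye is the centroid of sub-threshold pixels", {
  crop <- array(0.5, c(300, 200, 3))
  crop[75:85, 115:125, ] <- 0.02
  obj <- structure(list(crop = crop, mask = matrix(TRUE, 300, 200)),
                   class = "fish_object")
  ep <- find_eye(obj, UP = c(450, 10))
  expect_equal(unname(ep), c(80, 120), tolerance = 1)

  bright <- structure(list(crop = array(0.6, c(100, 50, 3)),
                           mask = matrix(TRUE, 100, 50)),
                      class = "fish_object")
  expect_error(find_eye(bright, UP = c(90, 5)), "eye not found")

  # two dark blobs: centroid of their union
  crop2 <- array(0.5, c(300, 200, 3))
  crop2[40:42, 50:52, ] <- 0.02
  crop2[80:82, 90:92, ] <- 0.02
  obj2 <- structure(list(crop = crop2, mask = matrix(TRUE, 300, 200)),
                    class = "fish_object")
  ep2 <- find_eye(obj2, UP = c(450, 10))
  expect_equal(unname(ep2), c(61, 71), tolerance = 0.5)
})

test_that("the belly point is the lowest mask pixel under UP", {
  mask <- matrix(FALSE, 50, 60)
  mask[10:40, 5:45] <- TRUE
  obj <- structure(list(mask = mask), class = "fish_object")
  bp <- find_belly(obj, UP = c(25, 5))
  expect_equal(unname(bp), c(25, 45))
  id <- generate_identity(4)
  fi <- render_fish(id, scene_params(rotation_deg = 9, seed = 13))
  obj2 <- deskew_object(locate_fish(segment_background(fi), fi))
  up <- find_upper_fin(obj2, find_narrowest(obj2))
  bp2 <- find_belly(obj2, up)
  truth_bp <- finprint:::aff_apply(obj2$transform, fi$truth$landmarks$BP)
  expect_lt(abs(bp2[2] - truth_bp[2]), 3)
  expect_gt(bp2[2], up[2])
})

test_that("the ROI rectangle follows the landmark formula", {
  obj <- structure(list(crop = array(0.5, c(600, 500, 3)),
                        mask = matrix(TRUE, 600, 500)),
                   class = "fish_object")
  roi <- extract_roi(obj, EP = c(120, 140), UP = c(480, 60), BP = c(480, 420))
  expect_equal(unname(roi$offset), c(120, 78))
  expect_equal(dim(roi$crop)[1:2], c(480 - 120 + 1, 210 - 78 + 1))

  roi2 <- extract_roi(obj, EP = c(100, 100), UP = c(480, 0), BP = c(480, 400))
  expect_equal(unname(roi2$offset[2]), 20)
  expect_equal(dim(roi2$crop)[2], 200 - 20 + 1)

  # degenerate: BP/2 above the top bound
  expect_error(extract_roi(obj, EP = c(100, 100), UP = c(480, 380),
                           BP = c(480, 420)), "degenerate ROI")
})

test_that("ROI normalization preserves aspect at width 1000", {
  mk <- function(w, h) list(crop = array(0.5, c(w, h, 3)),
                            mask = matrix(TRUE, w, h),
                            offset = c(x0 = 1, y0 = 1), landmarks = NULL)
  expect_equal(dim(normalize_roi(mk(2000, 540))$image), c(1000, 270))
  expect_equal(dim(normalize_roi(mk(1000, 269))$image), c(1000, 269))
  expect_equal(dim(normalize_roi(mk(500, 100))$image), c(1000, 200))
})

test_that("landmarks are recovered within 5 px across the rotation range", {
  rots <- seq(-45, 45, by = 10)
  ids <- list(generate_identity(21), generate_identity(22))
  n_ok <- 0; n <- 0
  for (id in ids) for (r in rots) {
    fi <- render_fish(id, scene_params(rotation_deg = r,
                                       translation_px = c(6, -6),
                                       seed = 1000 + round(r)))
    roi <- extract_normalized_roi(fi)
    obj <- roi$object
    det <- rbind(find_eye(obj, find_upper_fin(obj, obj$np)),
                 find_upper_fin(obj, obj$np),
                 find_belly(obj, find_upper_fin(obj, obj$np)))
    tru <- finprint:::aff_apply(obj$transform,
                                rbind(fi$truth$landmarks$EP,
                                      fi$truth$landmarks$UP,
                                      fi$truth$landmarks$BP))
    err <- sqrt(rowSums((det - tru)^2))
    n <- n + 3; n_ok <- n_ok + sum(err <= 5)
    # all landmarks inside the object bounding box
    expect_true(all(det[, 1] >= 1 & det[, 1] <= nrow(obj$mask) &
                      det[, 2] >= 1 & det[, 2] <= ncol(obj$mask)))
  }
  expect_gte(n_ok / n, 0.95)
})

test_that("two renders of one fish differ by a near-pure ROI shift", {
  id <- generate_identity(30)
  f1 <- render_fish(id, scene_params(rotation_deg = -25,
                                     translation_px = c(10, 5), seed = 1))
  f2 <- render_fish(id, scene_params(rotation_deg = 35,
                                     translation_px = c(-8, 2), seed = 2))
  r1 <- extract_normalized_roi(f1); r2 <- extract_normalized_roi(f2)
  p1 <- project_truth(r1, f1); p2 <- project_truth(r2, f2)
  shift <- colMeans(p2 - p1)
  expect_true(all(abs(shift) <= 50))          # within the long-term search
  resid <- sweep(p2 - p1, 2, shift)
  expect_lt(max(abs(resid)), 5)               # residual is not a deformation
})
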