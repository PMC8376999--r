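test_that("identities satisfy their invariants and are deterministic", {
  geom <- finprint:::fish_geometry()
  for (seed in c(1, 7, 23, 99)) {
    id <- generate_identity(seed, n_dots_range = c(8, 12))
    n <- nrow(id$body_dots)
    expect_gte(n, 8); expect_lte(n, 12)
    expect_true(all(id$body_dots >= 0 & id$body_dots <= 1))
    expect_true(all(id$body_dots[, 1] >= 1 / 3))  # no dots on the head
    # spacing in rendered (normalized-ROI) pixels can never be bridged by the
    # 15-px detection clustering
    xy <- ideal_roi_dots(id)
    expect_gte(min(dist(xy)), max(2 * id$dot_radius, 26))
  }
  expect_identical(generate_identity(5), generate_identity(5))
  expect_error(generate_identity(1, n_dots_range = c(2, 10)), "4, 40")
  expect_error(generate_identity(1, n_dots_range = c(10, 60)), "4, 40")
})

test_that("identities from different seeds are pairwise distinct", {
  ids <- lapply(1:100, generate_identity)
  sig <- vapply(ids, function(id)
    paste(round(as.vector(id$body_dots), 5), collapse = ","), "")
  expect_equal(anyDuplicated(sig), 0L)
})

test_that("rendering is deterministic and matches its ground truth", {
  id <- generate_identity(3)
  sc <- scene_params(rotation_deg = 20, translation_px = c(8, -4), seed = 12)
  a <- render_fish(id, sc, return_mask = TRUE)
  b <- render_fish(id, sc)
  expect_identical(a$img, b$img)
  # the fish-shaped object lies at the scene rotation (moment orientation)
  expect_lt(abs(oracle_orientation(a$truth$mask) - 20), 1)
  # noiseless scene: dot centroids are the affine image of the body dots
  sc0 <- scene_params(rotation_deg = 0, seed = 5)
  f0 <- render_fish(id, sc0)
  roi <- extract_normalized_roi(f0)
  det <- detect_dots_blob(roi)
  truth <- project_truth(roi, f0)
  dd <- sqrt(outer(truth[, 1], det$points[, 1], "-")^2 +
               outer(truth[, 2], det$points[, 2], "-")^2)
  expect_lte(max(apply(dd, 1, min)), 3)
  expect_error(render_fish(id, sc0, canvas_size = c(50, 40)), "canvas")
})

test_that("the eye disk renders darker than the 8-bit threshold of 20", {
  id <- generate_identity(8)
  fi <- render_fish(id, scene_params(rotation_deg = -15, seed = 4,
                                     illumination_gain = 1.1))
  ep <- fi$truth$landmarks$EP
  re <- finprint:::fish_geometry()$eye_radius / 2
  xs <- round(ep[1] + seq(-re, re, by = 2)); ys <- round(ep[2] + seq(-re, re, by = 2))
  gray <- finprint:::luminance(fi$img[xs, ys, 1], fi$img[xs, ys, 2],
                               fi$img[xs, ys, 3])
  expect_true(all(gray < 20 / 255))
})

test_that("cohorts have the right structure and determinism", {
  co <- generate_cohort(328, 3, session_templates(1), seed = 42)
  expect_equal(nrow(co$manifest), 984)
  expect_equal(length(co$identities), 328)
  expect_setequal(unique(co$manifest$fish_id), 1:328)

  co4 <- generate_cohort(4, 2, session_templates(4), seed = 9)
  expect_setequal(unique(co4$manifest$session),
                  c("SL1", "SL2", "SL3", "SL4"))
  # growth schedule reaches the six-month factors
  g <- vapply(co4$scenes, function(s) s$growth_factor_length, 0)
  expect_equal(max(g), 1.6, tolerance = 1e-9)
  g2 <- vapply(co4$scenes, function(s) s$growth_factor_height, 0)
  expect_equal(max(g2), 1.9, tolerance = 1e-9)

  co1 <- generate_cohort(1, 5, session_templates(1), seed = 2)
  expect_equal(nrow(co1$manifest), 5)
  expect_true(all(co1$manifest$fish_id == 1))

  a <- generate_cohort(3, 3, session_templates(2), seed = 31)
  b <- generate_cohort(3, 3, session_templates(2), seed = 31)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$scenes, b$scenes)
  expect_identical(render_cohort_image(a, 5)$img, render_cohort_image(b, 5)$img)
})

test_that("patch datasets follow the 2/3 - 1/3 split and are deterministic", {
  ds <- generate_patches(535, seed = 1)
  expect_equal(dim(ds$patches), c(25, 25, 1070))
  expect_equal(sum(ds$split == "train"), 714)
  expect_equal(sum(ds$split == "test"), 356)
  expect_equal(as.vector(table(ds$labels)), c(535, 535))
  expect_true(all(ds$patches >= 0 & ds$patches <= 1))
  expect_identical(generate_patches(40, seed = 6), generate_patches(40, seed = 6))
  expect_error(generate_patches(5), "at least 10")
})
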