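test_that("single-linkage clustering merges points below the cutoff", {
  expect_equal(cluster_detections(rbind(c(0, 0), c(5, 0), c(40, 0))),
               rbind(c(2.5, 0), c(40, 0)))
  expect_equal(cluster_detections(rbind(c(400, 50), c(405, 50), c(440, 50))),
               rbind(c(402.5, 50), c(440, 50)))
  # chains merge transitively into one centroid
  expect_equal(cluster_detections(rbind(c(0, 0), c(10, 0), c(20, 0))),
               rbind(c(10, 0)))
  expect_equal(cluster_detections(rbind(c(3, 4))), rbind(c(3, 4)))
  expect_equal(nrow(cluster_detections(matrix(numeric(0), 0, 2))), 0)

  # conservation: never more clusters than points; centroids inside the
  # bounding box of their input
  set.seed(42)
  for (i in 1:20) {
    pts <- random_pattern(sample(2:30, 1))
    ce <- cluster_detections(pts, cutoff = 15)
    expect_lte(nrow(ce), nrow(pts))
    expect_true(all(ce[, 1] >= min(pts[, 1]) & ce[, 1] <= max(pts[, 1])))
    expect_true(all(ce[, 2] >= min(pts[, 2]) & ce[, 2] <= max(pts[, 2])))
  }
})

test_that("patch classifier training reports high held-out accuracy", {
  clf <- get_test_classifier()
  expect_gte(clf$test_accuracy, 0.95)

  # label-flipped dataset trains to the same (symmetric) separability
  ds <- generate_patches(100, seed = 13)
  flipped <- ds
  flipped$labels <- factor(ifelse(ds$labels == "dot", "no_dot", "dot"),
                           levels = c("dot", "no_dot"))
  a <- train_patch_classifier(ds, seed = 13)
  b <- train_patch_classifier(flipped, seed = 13)
  expect_gte(a$test_accuracy, 0.9)
  expect_gte(b$test_accuracy, 0.9)

  single <- ds
  single$labels <- factor(rep("dot", length(ds$labels)),
                          levels = c("dot", "no_dot"))
  expect_error(train_patch_classifier(single), "both classes")
})

test_that("trivially separable patches are classified perfectly", {
  # black disks vs flat gray: separable by a single intensity threshold
  mk <- function(dark) {
    p <- matrix(0.6, 25, 25)
    if (dark) {
      d <- sqrt(outer((1:25 - 13)^2, (1:25 - 13)^2, "+"))
      p[d < 8] <- 0.05
    }
    p
  }
  n <- 15
  patches <- array(0, c(25, 25, 2 * n))
  for (i in 1:n) patches[, , i] <- mk(TRUE)
  for (i in 1:n) patches[, , n + i] <- mk(FALSE)
  # oracle: mean intensity separates the classes perfectly
  mi <- apply(patches, 3, mean)
  expect_true(max(mi[1:n]) < min(mi[(n + 1):(2 * n)]))
  ds <- list(patches = patches,
             labels = factor(rep(c("dot", "no_dot"), each = n),
                             levels = c("dot", "no_dot")),
             split = factor(rep(rep(c("train", "test"), c(10, 5)), 2),
                            levels = c("train", "test")))
  clf <- train_patch_classifier(ds, seed = 2, epochs = 20)
  expect_equal(clf$test_accuracy, 1)
})

test_that("classify_patch returns a softmax probability pair", {
  clf <- get_test_classifier()
  ds <- generate_patches(30, seed = 21)
  dot_patch <- ds$patches[, , which(ds$labels == "dot")[1]]
  flat <- matrix(0.6, 25, 25)
  expect_gt(classify_patch(clf, dot_patch), 0.5)
  expect_lt(classify_patch(clf, flat), 0.5)
  pair <- classify_patch(clf, dot_patch, full = TRUE)
  expect_equal(sum(pair), 1, tolerance = 1e-9)
  expect_true(all(pair >= 0 & pair <= 1))
  expect_error(classify_patch(clf, matrix(0, 10, 10)), "25 x 25")
})

test_that("sliding-window detection localizes dots and honours the regions", {
  clf <- get_test_classifier()
  # well-separated dots (the candidate clouds of neighbours closer than
  # ~40 px can chain through the 15-px clustering; see the vignette)
  id <- generate_identity(6, n_dots_range = c(8, 10))
  fi <- render_fish(id, scene_params(rotation_deg = 15, seed = 78))
  roi <- extract_normalized_roi(fi)
  dp <- detect_dots(roi, clf)
  truth <- project_truth(roi, fi)
  prf <- detection_prf(dp$points, truth, radius = 10)
  expect_gte(prf["f1"], 0.95)
  dd <- sqrt(outer(truth[, 1], dp$points[, 1], "-")^2 +
               outer(truth[, 2], dp$points[, 2], "-")^2)
  expect_lte(max(apply(dd, 1, min)), 5)
  # no emitted dot in the head third
  expect_true(all(dp$points[, 1] >= 1000 / 3))

  # dots present only in the head third produce an empty pattern
  img <- matrix(0.6, 1000, 120)
  d <- sqrt(outer((1:1000 - 200)^2, (1:120 - 60)^2, "+"))
  img[d < 9] <- 0.2
  dp2 <- detect_dots(img, clf)
  expect_equal(nrow(dp2$points), 0)

  # raising the probability threshold never adds candidates
  n_lo <- attr(detect_dots(roi, clf, p_min = 0.30), "n_candidates")
  n_hi <- attr(detect_dots(roi, clf, p_min = 0.80), "n_candidates")
  expect_lte(n_hi, n_lo)

  expect_warning(detect_dots(matrix(0.5, 1000, 10), clf), "empty pattern")
})

test_that("the blob detector is deterministic and accurate", {
  id <- generate_identity(14)
  stats <- c(tp = 0, fn = 0, fp = 0)
  for (r in c(-30, 0, 30)) {
    fi <- render_fish(id, scene_params(rotation_deg = r, seed = 50 + r))
    roi <- extract_normalized_roi(fi)
    dp <- detect_dots_blob(roi)
    expect_identical(dp$points, detect_dots_blob(roi)$points)
    truth <- project_truth(roi, fi)
    prf <- detection_prf(dp$points, truth, radius = 10)
    expect_gte(prf["f1"], 0.95)
    dd <- sqrt(outer(truth[, 1], dp$points[, 1], "-")^2 +
                 outer(truth[, 2], dp$points[, 2], "-")^2)
    expect_lte(max(apply(dd, 1, min)), 3)
    expect_true(all(dp$points[, 1] >= 1000 / 3))
  }
  blank <- matrix(0.55, 1000, 200)
  expect_equal(nrow(detect_dots_blob(blank)$points), 0)
})
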