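test_that("the trimmed distance at a fixed shift matches hand computation", {
  q <- rbind(c(0, 0), c(10, 0), c(20, 0), c(100, 50))
  tm <- rbind(c(0, 0), c(10, 0), c(20, 0))
  # NN distances {0, 0, 0, sqrt(80^2+50^2)}; keep ceil(3/4 * 4) = 3 -> mean 0
  expect_equal(pattern_distance_at_shift(q, tm), 0)
  expect_equal(pattern_distance_at_shift(q, q), 0)
  expect_equal(pattern_distance_at_shift(rbind(c(0, 0)), rbind(c(3, 4))), 5)
  expect_error(pattern_distance_at_shift(matrix(numeric(0), 0, 2), tm),
               "empty")
})

test_that("the shift search finds the aligning translation", {
  set.seed(7)
  q <- random_pattern(8)
  shifted <- sweep(q, 2, c(-15, 10), `-`)   # template = query + (15, -10)...
  r <- pattern_distance(q, sweep(q, 2, c(15, -10), `+`))
  expect_equal(r$distance, 0, tolerance = 1e-10)
  expect_equal(r$shift, c(-15, 10))

  r2 <- pattern_distance(q, sweep(q, 2, c(17, 0), `+`))
  expect_lte(r2$distance, 2)
  expect_equal(r2$shift[1], -15)
})

test_that("grid search agrees exactly with a brute-force oracle", {
  set.seed(11)
  cfg <- match_config()
  for (i in 1:40) {
    q <- random_pattern(sample(2:10, 1))
    tm <- random_pattern(sample(2:10, 1)) +
      matrix(rnorm(2, 0, 10), 1)[rep(1, 1), ]
    got <- pattern_distance(q, tm, cfg)
    want <- oracle_grid_search(q, tm, cfg$max_shift, cfg$shift_step,
                               cfg$trim_fraction)
    expect_equal(got$distance, want$distance, tolerance = 1e-12)
    expect_equal(got$shift, want$shift)   # identical lexicographic tie-break
  }
})

test_that("distance invariants: self-zero, grid-shift equivariance, trim monotonicity", {
  set.seed(3)
  for (i in 1:10) {
    p <- random_pattern(sample(4:20, 1))
    r <- pattern_distance(p, p)
    expect_equal(r$distance, 0, tolerance = 1e-12)
    expect_equal(r$shift, c(0, 0))
    s <- c(sample(seq(-30, 30, 5), 1), sample(seq(-30, 30, 5), 1))
    expect_equal(pattern_distance(p, sweep(p, 2, s, `+`))$distance, 0,
                 tolerance = 1e-12)
    q <- random_pattern(8); tm <- random_pattern(10)
    d1 <- pattern_distance_at_shift(q, tm, trim_fraction = 0.5)
    d2 <- pattern_distance_at_shift(q, tm, trim_fraction = 0.75)
    d3 <- pattern_distance_at_shift(q, tm, trim_fraction = 1)
    expect_true(d1 <= d2 + 1e-12 && d2 <= d3 + 1e-12)
  }
})

test_that("the count heuristic is an inclusive factor-2 bound", {
  mk <- function(n) dot_pattern(random_pattern(n))
  set.seed(1)
  expect_true(patterns_comparable(mk(10), mk(20)))
  expect_false(patterns_comparable(mk(10), mk(21)))
  expect_true(patterns_comparable(mk(7), mk(7)))
})

test_that("nearest-neighbour identification picks the right fish", {
  set.seed(5)
  ids <- lapply(1:6, function(i) ideal_roi_dots(generate_identity(i * 11)))
  jit <- function(p, sd = 2) p + matrix(rnorm(length(p), 0, sd), ncol = 2)
  gallery <- lapply(ids, function(p) list(dot_pattern(jit(p)),
                                          dot_pattern(jit(p))))
  names(gallery) <- as.character(1:6)
  for (i in 1:6) {
    r <- identify_short_term(dot_pattern(jit(ids[[i]])), gallery)
    expect_equal(r$predicted_id, as.character(i))
  }

  single <- gallery[2]
  r1 <- identify_short_term(dot_pattern(jit(ids[[5]])), single)
  expect_equal(r1$predicted_id, "2")

  # identical templates for two fish: tie resolves to the smaller id
  twin <- list(b = gallery[[1]], a = gallery[[1]])
  r2 <- identify_short_term(gallery[[1]][[1]], twin)
  expect_equal(r2$predicted_id, "a")

  expect_error(identify_short_term(dot_pattern(ids[[1]]), list()), "empty")
})

test_that("the count heuristic never changes the prediction, only the cost", {
  set.seed(9)
  ids <- lapply(1:8, function(i)
    ideal_roi_dots(generate_identity(i * 7, n_dots_range = c(8, 30))))
  jit <- function(p) p + matrix(rnorm(length(p), 0, 2), ncol = 2)
  gallery <- lapply(ids, function(p) list(dot_pattern(jit(p))))
  names(gallery) <- as.character(1:8)
  cfg_on <- match_config(count_ratio_max = 2)
  cfg_off <- match_config(count_ratio_max = Inf)
  for (i in 1:8) {
    q <- dot_pattern(jit(ids[[i]]))
    expect_equal(identify_short_term(q, gallery, cfg_on)$predicted_id,
                 identify_short_term(q, gallery, cfg_off)$predicted_id)
  }
})

test_that("representative patterns keep recurring points only", {
  base <- rbind(c(400, 100), c(500, 150), c(600, 80), c(700, 200))
  copies <- lapply(1:6, function(i) dot_pattern(base, fish_id = 1))
  rep6 <- build_representative(copies)
  expect_equal(nrow(rep6$points), 4)
  expect_true(all(rep6$support == 6))
  expect_equal(rep6$n_source_patterns, 6)

  # N = 6: a point present in 4 aligned patterns (support >= max(3,3)) stays,
  # a point present in 2 is dropped
  ref <- rbind(base, c(800, 120), c(850, 250))       # P5 support 4, P6 support 2
  far <- function(k) cbind(runif(k, 350, 950), runif(k, 40, 300))
  set.seed(33)
  others <- list(
    dot_pattern(rbind(base, c(800, 120), far(4) + 2000)),
    dot_pattern(rbind(base, c(800, 120), c(850, 250), far(4) + 2000)),
    dot_pattern(rbind(base, c(800, 120), far(4) + 2000)),
    dot_pattern(rbind(base, far(5) + 2000)),
    dot_pattern(rbind(base, far(5) + 2000))
  )
  pats <- c(list(dot_pattern(ref, fish_id = 1)), others)
  rp <- build_representative(pats)
  expect_equal(rp$reference_index, 1)
  expect_equal(nrow(rp$points), 5)                   # base 4 + the support-4 point
  expect_true(all(rp$points[, 1] != 850))
  expect_equal(sort(unique(rp$support)), c(4, 6))

  expect_warning(r1 <- build_representative(list(dot_pattern(base))),
                 "fewer than 2")
  expect_equal(nrow(r1$points), 4)
})

test_that("representatives recover true dots from jittered patterns", {
  set.seed(17)
  id <- generate_identity(55, n_dots_range = c(15, 15))
  true_pts <- ideal_roi_dots(id)
  pats <- lapply(1:6, function(i) {
    jittered <- true_pts + matrix(rnorm(30, 0, 3), ncol = 2)
    spurious <- cbind(runif(2, 400, 950), runif(2, 50, 300))
    dot_pattern(rbind(jittered, spurious), fish_id = 1)
  })
  rp <- build_representative(pats)
  dd <- sqrt(outer(true_pts[, 1], rp$points[, 1], "-")^2 +
               outer(true_pts[, 2], rp$points[, 2], "-")^2)
  recovered <- mean(apply(dd, 1, min) <= 10)
  spurious <- mean(apply(dd, 2, min) > 10)
  expect_gte(recovered, 0.9)
  expect_lte(spurious, 0.05)
})

test_that("long-term identification of an enrolled pattern is exact", {
  set.seed(2)
  reps <- lapply(1:5, function(i)
    dot_pattern(ideal_roi_dots(generate_identity(i * 13)), fish_id = i))
  names(reps) <- as.character(1:5)
  r <- identify_long_term(reps[["3"]], reps)
  expect_equal(r$predicted_id, "3")
  expect_equal(min(r$distances), 0, tolerance = 1e-12)
})
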