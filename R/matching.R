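# Trimmed nearest-neighbour matching of dot patterns: the core biometric.

#' Construct a dot pattern
#'
#' An unordered set of 2-D dot centroids in normalized-ROI pixel coordinates;
#' the fish's biometric signature.
#'
#' @param points n x 2 matrix (x, y).
#' @param image_id,fish_id,session Optional provenance.
#' @return A `dot_pattern`.
#' @export
dot_pattern <- function(points, image_id = NA, fish_id = NA, session = NA) {
  points <- matrix(as.numeric(points), ncol = 2,
                   dimnames = list(NULL, c("x", "y")))
  if (nrow(points) > 0 && any(!is.finite(points)))
    stop("dot pattern contains non-finite coordinates")
  structure(list(points = points, image_id = image_id, fish_id = fish_id,
                 session = session),
            class = "dot_pattern")
}

#' @export
print.dot_pattern <- function(x, ...) {
  cat("<dot_pattern>", nrow(x$points), "dots",
      if (!is.na(x$fish_id)) paste0("(fish ", x$fish_id, ")") else "", "\n")
  invisible(x)
}

n_dots <- function(p) nrow(pattern_points(p))
pattern_points <- function(p) {
  if (inherits(p, "dot_pattern")) p$points else matrix(as.numeric(p), ncol = 2)
}

#' Matching configuration
#'
#' @param max_shift Maximal template shift searched, px (30 for short-term
#'   matching; 50 for long-term, where the ROI may displace more as the fish
#'   grows). Must be a multiple of `shift_step`.
#' @param shift_step Shift grid step, px.
#' @param trim_fraction Fraction of query dots kept in the trimmed mean
#'   (3/4; the largest quarter of the nearest-neighbour distances is dropped
#'   to suppress mis-detected dots).
#' @param count_ratio_max Comparability heuristic: two patterns are compared
#'   only if their dot counts differ by at most this factor (inclusive).
#' @param scale_grid Optional vector of uniform scale factors additionally
#'   searched (template scaled about its centroid); `NULL` keeps the pure
#'   translation search.
#' @return A `match_config` list.
#' @export
match_config <- function(max_shift = 30, shift_step = 5, trim_fraction = 0.75,
                         count_ratio_max = 2, scale_grid = NULL) {
  if (max_shift %% shift_step != 0)
    stop("max_shift must be a multiple of shift_step")
  if (trim_fraction <= 0 || trim_fraction > 1)
    stop("trim_fraction must be in (0, 1]")
  list(max_shift = max_shift, shift_step = shift_step,
       trim_fraction = trim_fraction, count_ratio_max = count_ratio_max,
       scale_grid = scale_grid)
}

#' Trimmed distance between two patterns at a fixed shift
#'
#' Translates the template by `shift`, finds for every query dot the nearest
#' shifted template dot, sorts those distances and averages the smallest
#' `ceil(trim_fraction * n_query)`.
#'
#' @param query,template `dot_pattern`s (or bare n x 2 matrices).
#' @param shift `c(dx, dy)` applied to the template.
#' @param trim_fraction Kept fraction of the query dots.
#' @return The trimmed mean distance in px.
#' @export
pattern_distance_at_shift <- function(query, template, shift = c(0, 0),
                                      trim_fraction = 0.75) {
  q <- pattern_points(query); t. <- pattern_points(template)
  if (nrow(q) == 0 || nrow(t.) == 0) stop("empty dot pattern")
  cpp_distance_at_shift(q, t., shift[1], shift[2], trim_fraction)
}

#' Final (shift-minimized) distance between two patterns
#'
#' Evaluates [pattern_distance_at_shift()] over the full shift grid
#' `seq(-max_shift, max_shift, shift_step)` in both axes and returns the
#' minimum together with its shift (ties resolve to the lexicographically
#' smallest `(dx, dy)`). With a `scale_grid` configured, the search is
#' repeated for each template scale (about the template centroid) and the
#' overall minimum returned.
#'
#' @param query,template `dot_pattern`s.
#' @param config [match_config()].
#' @return List with `distance` (px), `shift` `c(dx, dy)`, and `scale`.
#' @export
pattern_distance <- function(query, template, config = match_config()) {
  q <- pattern_points(query); t. <- pattern_points(template)
  if (nrow(q) == 0 || nrow(t.) == 0) stop("empty dot pattern")
  g <- seq(-config$max_shift, config$max_shift, by = config$shift_step)
  scales <- config$scale_grid %||% 1
  best <- list(distance = Inf, shift = c(0, 0), scale = 1)
  for (s in scales) {
    ts <- if (s == 1) t. else {
      ctr <- colMeans(t.)
      sweep(sweep(t., 2, ctr) * s, 2, ctr, `+`)
    }
    r <- cpp_distance_grid(q, ts, g, g, config$trim_fraction)
    if (r$distance < best$distance)
      best <- list(distance = r$distance, shift = r$shift, scale = s)
  }
  best
}

#' Are two patterns comparable under the count heuristic?
#'
#' `TRUE` iff the larger dot count is at most `count_ratio_max` times the
#' smaller (inclusive). Used to prune comparisons between patterns whose dot
#' counts make a match implausible.
#'
#' @param a,b `dot_pattern`s.
#' @param config [match_config()].
#' @return Logical.
#' @export
patterns_comparable <- function(a, b, config = match_config()) {
  na <- n_dots(a); nb <- n_dots(b)
  if (na == 0 || nb == 0) return(FALSE)
  max(na, nb) <= config$count_ratio_max * min(na, nb)
}

# Shared nearest-neighbour identification over a gallery of template lists.
identify_nn <- function(query, gallery, config) {
  if (length(gallery) == 0) stop("empty gallery")
  ids <- names(gallery) %||% as.character(seq_along(gallery))
  run <- function(use_heuristic) {
    dist <- rep(Inf, length(gallery))
    shifts <- matrix(NA_real_, length(gallery), 2)
    for (j in seq_along(gallery)) {
      tmpls <- gallery[[j]]
      if (inherits(tmpls, "dot_pattern")) tmpls <- list(tmpls)
      for (tm in tmpls) {
        if (use_heuristic && !patterns_comparable(query, tm, config)) next
        r <- pattern_distance(query, tm, config)
        if (r$distance < dist[j]) { dist[j] <- r$distance; shifts[j, ] <- r$shift }
      }
    }
    list(dist = dist, shifts = shifts)
  }
  res <- run(TRUE)
  fallback <- all(!is.finite(res$dist))
  if (fallback) res <- run(FALSE)
  ord <- order(res$dist, ids)
  structure(list(query_id = if (inherits(query, "dot_pattern"))
    query$image_id else NA,
    predicted_id = ids[ord[1]],
    distances = stats::setNames(res$dist, ids),
    best_shifts = res$shifts,
    fallback_used = fallback),
    class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat("<match_result> predicted", x$predicted_id, "at distance",
      round(min(x$distances), 2), "px\n")
  invisible(x)
}

#' Short-term identification
#'
#' Nearest-neighbour classification of a query dot pattern against a gallery
#' of template patterns (typically two per fish). The distance to a fish is
#' the minimum over its templates of the shift-minimized trimmed distance;
#' templates failing the count heuristic are skipped, and if the heuristic
#' eliminates every fish the comparison falls back to the full gallery. Ties
#' resolve to the smallest fish id.
#'
#' @param query A `dot_pattern`.
#' @param gallery Named list: fish id -> list of template `dot_pattern`s.
#' @param config [match_config()] (defaults: 30-px shift search).
#' @return A `match_result` with the predicted id and all final distances.
#' @export
identify_short_term <- function(query, gallery, config = match_config()) {
  identify_nn(query, gallery, config)
}

#' Build the representative pattern of one fish
#'
#' Distills the dot patterns of all images of one fish into a consensus
#' subset: the pattern with the minimal average distance to all others is
#' the reference; every other pattern is aligned to it by its best shift;
#' each reference point is supported by the patterns whose nearest aligned
#' point lies within `accept_dist`; points supported by at least
#' `max(3, floor(N/3) + 1)` of the N patterns are kept (with fewer than
#' three patterns everything is kept).
#'
#' @param patterns List of `dot_pattern`s of one fish.
#' @param config [match_config()] used for the alignment.
#' @param accept_dist Support radius in px.
#' @return A `representative_pattern` (also a `dot_pattern`): the retained
#'   reference points, their `support` counts and `n_source_patterns`.
#' @export
build_representative <- function(patterns, config = match_config(),
                                 accept_dist = 20) {
  N <- length(patterns)
  if (N < 2) {
    warning("fewer than 2 patterns; representative equals the input pattern")
    p <- patterns[[1]]
    out <- dot_pattern(pattern_points(p), image_id = p$image_id,
                       fish_id = p$fish_id, session = p$session)
    out$support <- rep(N, n_dots(p))
    out$n_source_patterns <- N
    class(out) <- c("representative_pattern", "dot_pattern")
    return(out)
  }
  D <- matrix(0, N, N)
  S <- array(0, c(N, N, 2))
  for (i in seq_len(N)) for (j in seq_len(N)) {
    if (i == j) next
    r <- pattern_distance(patterns[[i]], patterns[[j]], config)
    D[i, j] <- r$distance
    S[i, j, ] <- r$shift
  }
  ref_i <- which.min(rowSums(D) / (N - 1))
  ref <- pattern_points(patterns[[ref_i]])
  support <- rep(1L, nrow(ref))          # the reference supports itself
  for (k in seq_len(N)) {
    if (k == ref_i) next
    aligned <- sweep(pattern_points(patterns[[k]]), 2, S[ref_i, k, ], `+`)
    for (i in seq_len(nrow(ref))) {
      dmin <- min(sqrt((aligned[, 1] - ref[i, 1])^2 +
                         (aligned[, 2] - ref[i, 2])^2))
      if (dmin < accept_dist) support[i] <- support[i] + 1L
    }
  }
  keep <- if (N < 3) rep(TRUE, nrow(ref)) else
    support >= max(3, floor(N / 3) + 1)
  src <- patterns[[ref_i]]
  out <- dot_pattern(ref[keep, , drop = FALSE], image_id = src$image_id,
                     fish_id = src$fish_id, session = src$session)
  out$support <- support[keep]
  out$n_source_patterns <- N
  out$reference_index <- ref_i
  class(out) <- c("representative_pattern", "dot_pattern")
  out
}

#' @export
print.representative_pattern <- function(x, ...) {
  cat("<representative_pattern>", nrow(x$points), "consensus dots from",
      x$n_source_patterns, "patterns",
      if (!is.na(x$fish_id)) paste0("(fish ", x$fish_id, ")") else "", "\n")
  invisible(x)
}

#' Long-term identification
#'
#' Identical matching machinery to [identify_short_term()], applied to
#' representative patterns with a wider shift search (50 px by default): as
#' the fish grows, the ROI — and with it the whole dot pattern — may displace
#' further between sessions.
#'
#' @param query A `representative_pattern` (or any `dot_pattern`).
#' @param gallery Named list: fish id -> representative pattern (or list of
#'   patterns).
#' @param config [match_config()] with `max_shift = 50`.
#' @return A `match_result`.
#' @export
identify_long_term <- function(query, gallery,
                               config = match_config(max_shift = 50)) {
  identify_nn(query, gallery, config)
}
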