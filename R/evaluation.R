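# Accuracy bookkeeping and the pattern-stability displacement analysis.

#' Identification accuracy report
#'
#' Tallies nearest-neighbour identification results into per-session-pair
#' accuracies (percent, one decimal — the conventional reporting format).
#'
#' @param results Data frame with columns `predicted_id`, `true_id` and
#'   optionally `session_pair` (default: a single group "all").
#' @param truth Optional named vector mapping `query_id` to the true id, used
#'   when `results` lacks `true_id`.
#' @return An `accuracy_report`: `table` (session_pair, n, correct, accuracy)
#'   and `overall` accuracy in percent.
#' @export
identification_accuracy <- function(results, truth = NULL) {
  if (!("true_id" %in% names(results))) {
    if (is.null(truth)) stop("missing ground truth")
    if (!("query_id" %in% names(results))) stop("missing ground truth")
    results$true_id <- unname(truth[as.character(results$query_id)])
  }
  if (any(is.na(results$true_id))) stop("missing ground truth")
  grp <- if ("session_pair" %in% names(results))
    results$session_pair else rep("all", nrow(results))
  ok <- as.character(results$predicted_id) == as.character(results$true_id)
  tab <- do.call(rbind, lapply(split(ok, grp), function(v)
    data.frame(n = length(v), correct = sum(v),
               accuracy = round(100 * sum(v) / length(v), 1))))
  tab <- cbind(session_pair = rownames(tab), tab)
  rownames(tab) <- NULL
  structure(list(table = tab,
                 overall = round(100 * sum(ok) / length(ok), 1)),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat("<accuracy_report> overall", x$overall, "%\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Session-pair accuracy matrix
#'
#' Formats an [identification_accuracy()] report whose groups are
#' "A/B" session pairs as an upper-triangular session matrix.
#'
#' @param report An `accuracy_report`.
#' @return Numeric matrix of accuracies (from-session rows, to-session
#'   columns).
#' @export
accuracy_matrix <- function(report) {
  parts <- strsplit(as.character(report$table$session_pair), "/", fixed = TRUE)
  if (any(lengths(parts) != 2)) stop("groups are not session pairs")
  from <- vapply(parts, `[`, "", 1); to <- vapply(parts, `[`, "", 2)
  ses <- sort(unique(c(from, to)))
  m <- matrix(NA_real_, length(ses), length(ses), dimnames = list(ses, ses))
  m[cbind(from, to)] <- report$table$accuracy
  m
}

#' Least-squares similarity alignment of corresponding points
#'
#' Finds the scale, rotation and shift minimizing the summed squared
#' residuals between `scale * R %*% b + shift` and `a`, in closed form
#' (orthogonal Procrustes with scaling).
#'
#' @param a,b n x 2 matrices of corresponding points (`b` is transformed
#'   onto `a`); n >= 2.
#' @return List: `scale`, `rotation_deg`, `shift`, `aligned` (transformed
#'   `b`), per-point `residuals` and their `rms`.
#' @export
align_similarity <- function(a, b) {
  a <- matrix(as.numeric(a), ncol = 2); b <- matrix(as.numeric(b), ncol = 2)
  n <- nrow(a)
  if (n < 2 || nrow(b) != n) stop("need >= 2 corresponding point pairs")
  mu_a <- colMeans(a); mu_b <- colMeans(b)
  A0 <- sweep(a, 2, mu_a); B0 <- sweep(b, 2, mu_b)
  var_b <- sum(B0^2) / n
  if (var_b < 1e-12) stop("degenerate input: source points are coincident")
  C <- crossprod(A0, B0) / n
  sv <- svd(C)
  s_sign <- sign(det(sv$u) * det(sv$v))
  S <- diag(c(1, s_sign))
  R <- sv$u %*% S %*% t(sv$v)
  scale <- sum(sv$d * diag(S)) / var_b
  shift <- mu_a - scale * as.numeric(R %*% mu_b)
  aligned <- sweep(scale * b %*% t(R), 2, shift, `+`)
  res <- a - aligned
  list(scale = scale,
       rotation_deg = atan2(R[2, 1], R[1, 1]) * 180 / pi,
       shift = shift,
       aligned = aligned,
       residuals = res,
       rms = sqrt(mean(rowSums(res^2))))
}

#' Pattern-stability displacement analysis
#'
#' For each fish, aligns every later session's landmark set to the first
#' session by a least-squares similarity transform and reports the mean
#' absolute per-axis displacement of each point from its first-session
#' position, averaged over points, sessions and fish. This quantifies how
#' much a dot pattern truly changes over time once pose and growth are
#' compensated.
#'
#' @param series One landmark series (list of per-session K x 2 matrices,
#'   corresponding by row) or a list of such series (one per fish).
#' @return `c(mean_dx, mean_dy)` in px.
#' @export
displacement_analysis <- function(series) {
  if (is.list(series) && is.list(series[[1]]) && !is.matrix(series[[1]]))
    many <- series
  else many <- list(series)
  dx <- c(); dy <- c()
  for (s in many) {
    if (length(s) < 2) stop("need at least two sessions")
    K <- nrow(s[[1]])
    if (any(vapply(s, nrow, 0L) != K))
      stop("all sessions must label the same number of points")
    ref <- s[[1]]
    for (k in 2:length(s)) {
      al <- align_similarity(ref, s[[k]])
      d <- al$aligned - ref
      dx <- c(dx, abs(d[, 1])); dy <- c(dy, abs(d[, 2]))
    }
  }
  c(mean_dx = mean(dx), mean_dy = mean(dy))
}
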