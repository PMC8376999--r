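# A compact convolutional patch classifier, implemented directly on matrix
# algebra. The architecture has exactly five trained layers -- three 3x3
# convolutions (ReLU, 2x2 max-pooling after the first two) and two fully
# connected layers with a softmax pair output -- the smallest network of this
# class that separates 25x25 dot / no-dot skin patches. Training is plain
# minibatch Adam on cross-entropy, deterministic for a fixed seed.
#
# Tensor layout: (H, W, C, N). Convolutions are evaluated as a single matrix
# product on im2col-expanded patches.

im2col <- function(X, k) {
  d <- dim(X)
  OH <- d[1] - k + 1; OW <- d[2] - k + 1
  cols <- array(0, c(OH, OW, k, k, d[3], d[4]))
  for (di in seq_len(k)) for (dj in seq_len(k))
    cols[, , di, dj, , ] <- X[di:(di + OH - 1), dj:(dj + OW - 1), , ]
  m <- aperm(cols, c(3, 4, 5, 1, 2, 6))
  dim(m) <- c(k * k * d[3], OH * OW * d[4])
  list(mat = m, OH = OH, OW = OW)
}

conv_forward <- function(X, W, b, k) {
  d <- dim(X); K <- nrow(W)
  ic <- im2col(X, k)
  Y <- W %*% ic$mat + b
  dim(Y) <- c(K, ic$OH, ic$OW, d[4])
  list(out = aperm(Y, c(2, 3, 1, 4)), cols = ic$mat, OH = ic$OH, OW = ic$OW)
}

conv_backward <- function(dY, cols, W, k, in_dim) {
  OH <- dim(dY)[1]; OW <- dim(dY)[2]; K <- dim(dY)[3]; N <- dim(dY)[4]
  dYm <- aperm(dY, c(3, 1, 2, 4)); dim(dYm) <- c(K, OH * OW * N)
  dW <- dYm %*% t(cols)
  db <- rowSums(dYm)
  dcols <- t(W) %*% dYm
  dim(dcols) <- c(k, k, in_dim[3], OH, OW, N)
  dX <- array(0, in_dim)
  for (di in seq_len(k)) for (dj in seq_len(k)) {
    sl <- dcols[di, dj, , , , , drop = FALSE]
    dim(sl) <- c(in_dim[3], OH, OW, N)
    sl <- aperm(sl, c(2, 3, 1, 4))
    dX[di:(di + OH - 1), dj:(dj + OW - 1), , ] <-
      dX[di:(di + OH - 1), dj:(dj + OW - 1), , , drop = FALSE] + sl
  }
  list(dX = dX, dW = dW, db = db)
}

pool_forward <- function(X) {
  d <- dim(X)
  Hc <- d[1] %/% 2 * 2; Wc <- d[2] %/% 2 * 2
  i1 <- seq(1, Hc, 2); i2 <- seq(2, Hc, 2)
  j1 <- seq(1, Wc, 2); j2 <- seq(2, Wc, 2)
  s <- list(X[i1, j1, , , drop = FALSE], X[i2, j1, , , drop = FALSE],
            X[i1, j2, , , drop = FALSE], X[i2, j2, , , drop = FALSE])
  M <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
  taken <- array(FALSE, dim(M))
  masks <- vector("list", 4)
  for (q in 1:4) {   # first-match tie break: deterministic
    masks[[q]] <- (s[[q]] == M) & !taken
    taken <- taken | masks[[q]]
  }
  list(out = M, masks = masks, in_dim = d)
}

pool_backward <- function(dY, pf) {
  d <- pf$in_dim
  Hc <- d[1] %/% 2 * 2; Wc <- d[2] %/% 2 * 2
  i1 <- seq(1, Hc, 2); i2 <- seq(2, Hc, 2)
  j1 <- seq(1, Wc, 2); j2 <- seq(2, Wc, 2)
  dX <- array(0, d)
  dX[i1, j1, , ] <- dY * pf$masks[[1]]
  dX[i2, j1, , ] <- dX[i2, j1, , , drop = FALSE] + dY * pf$masks[[2]]
  dX[i1, j2, , ] <- dX[i1, j2, , , drop = FALSE] + dY * pf$masks[[3]]
  dX[i2, j2, , ] <- dX[i2, j2, , , drop = FALSE] + dY * pf$masks[[4]]
  dX
}

cnn_init <- function(seed, channels = c(8, 16, 32), hidden = 64,
                     flat_dim = 2 * 2 * 32) {
  with_seed(seed, {
    he <- function(nout, nin) matrix(rnorm(nout * nin, 0, sqrt(2 / nin)),
                                     nout, nin)
    list(
      W1 = he(channels[1], 9 * 1),          b1 = numeric(channels[1]),
      W2 = he(channels[2], 9 * channels[1]), b2 = numeric(channels[2]),
      W3 = he(channels[3], 9 * channels[2]), b3 = numeric(channels[3]),
      W4 = he(hidden, flat_dim),             b4 = numeric(hidden),
      W5 = he(2, hidden),                    b5 = numeric(2)
    )
  })
}

cnn_forward <- function(par, X, keep = FALSE) {
  N <- dim(X)[4]
  c1 <- conv_forward(X, par$W1, par$b1, 3)          # 25 -> 23
  r1 <- pmax(c1$out, 0)
  p1 <- pool_forward(r1)                            # 23 -> 11
  c2 <- conv_forward(p1$out, par$W2, par$b2, 3)     # 11 -> 9
  r2 <- pmax(c2$out, 0)
  p2 <- pool_forward(r2)                            # 9 -> 4
  c3 <- conv_forward(p2$out, par$W3, par$b3, 3)     # 4 -> 2
  r3 <- pmax(c3$out, 0)
  f <- r3; dim(f) <- c(length(f) / N, N)
  h <- pmax(par$W4 %*% f + par$b4, 0)
  z <- par$W5 %*% h + par$b5
  z <- sweep(z, 2, apply(z, 2, max))
  ez <- exp(z)
  p <- sweep(ez, 2, colSums(ez), `/`)
  if (!keep) return(p)
  list(p = p, X = X, c1 = c1, r1 = r1, p1 = p1, c2 = c2, r2 = r2, p2 = p2,
       c3 = c3, r3 = r3, f = f, h = h)
}

cnn_backward <- function(par, fw, y) {
  # y: 2 x N one-hot; returns gradients of mean cross-entropy
  N <- ncol(y)
  dz <- (fw$p - y) / N
  dW5 <- dz %*% t(fw$h); db5 <- rowSums(dz)
  dh <- t(par$W5) %*% dz
  dh[fw$h <= 0] <- 0
  dW4 <- dh %*% t(fw$f); db4 <- rowSums(dh)
  df <- t(par$W4) %*% dh
  dr3 <- array(df, dim(fw$r3))
  dr3[fw$r3 <= 0] <- 0
  b3 <- conv_backward(dr3, fw$c3$cols, par$W3, 3, dim(fw$p2$out))
  dp2 <- pool_backward(b3$dX, fw$p2)
  dp2[fw$r2 <= 0] <- 0
  b2 <- conv_backward(dp2, fw$c2$cols, par$W2, 3, dim(fw$p1$out))
  dp1 <- pool_backward(b2$dX, fw$p1)
  dp1[fw$r1 <= 0] <- 0
  b1 <- conv_backward(dp1, fw$c1$cols, par$W1, 3, dim(fw$X))
  list(W1 = b1$dW, b1 = b1$db, W2 = b2$dW, b2 = b2$db,
       W3 = b3$dW, b3 = b3$db, W4 = dW4, b4 = db4, W5 = dW5, b5 = db5)
}

#' Train the dot / no-dot patch classifier
#'
#' Trains the five-layer convolutional classifier (three convolutional + two
#' fully connected layers, ReLU activations, max-pooling between the
#' convolutions, softmax output) on the train split of a balanced 25x25 patch
#' dataset, and reports accuracy on the held-out test split. Deterministic
#' for a fixed seed.
#'
#' @param dataset A [generate_patches()] dataset (or any list with `patches`
#'   25 x 25 x N array, two-level factor `labels`, and `split`).
#' @param seed Seed for initialization and batch shuffling.
#' @param epochs Maximal training epochs (early stop on a vanishing training
#'   loss).
#' @param batch_size,learning_rate Adam minibatch settings.
#' @param channels,hidden Convolution channel counts and hidden layer width.
#' @return A `patch_classifier` with the trained parameters, configuration,
#'   `test_accuracy` (fraction), and the per-epoch loss `history`.
#' @export
train_patch_classifier <- function(dataset, seed = 1, epochs = 30,
                                   batch_size = 64, learning_rate = 1e-3,
                                   channels = c(8, 16, 32), hidden = 64) {
  labs <- dataset$labels
  if (length(unique(labs)) < 2)
    stop("training requires examples of both classes")
  tr <- dataset$split == "train"
  Xtr <- dataset$patches[, , tr, drop = FALSE] - 0.5
  dim(Xtr) <- c(25, 25, 1, sum(tr))
  ytr <- rbind(as.numeric(labs[tr] == levels(labs)[1]),
               as.numeric(labs[tr] != levels(labs)[1]))
  par <- cnn_init(seed, channels, hidden)
  mom <- lapply(par, function(p) p * 0)
  vel <- lapply(par, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  t <- 0
  history <- numeric(0)
  with_seed(seed + 1L, {
    for (ep in seq_len(epochs)) {
      idx <- sample(ncol(ytr))
      losses <- numeric(0)
      for (start in seq(1, length(idx), batch_size)) {
        bi <- idx[start:min(start + batch_size - 1, length(idx))]
        fw <- cnn_forward(par, Xtr[, , , bi, drop = FALSE], keep = TRUE)
        yb <- ytr[, bi, drop = FALSE]
        losses <- c(losses, -mean(colSums(yb * log(pmax(fw$p, 1e-12)))))
        gr <- cnn_backward(par, fw, yb)
        t <- t + 1
        for (nm in names(par)) {
          mom[[nm]] <- beta1 * mom[[nm]] + (1 - beta1) * gr[[nm]]
          vel[[nm]] <- beta2 * vel[[nm]] + (1 - beta2) * gr[[nm]]^2
          par[[nm]] <- par[[nm]] - learning_rate *
            (mom[[nm]] / (1 - beta1^t)) /
            (sqrt(vel[[nm]] / (1 - beta2^t)) + eps)
        }
      }
      history <- c(history, mean(losses))
      if (mean(losses) < 1e-3) break
    }
  })
  clf <- structure(list(par = par, channels = channels, hidden = hidden,
                        seed = seed, history = history,
                        levels = levels(labs)),
                   class = "patch_classifier")
  te <- dataset$split == "test"
  if (any(te)) {
    p <- classify_patches(clf, dataset$patches[, , te, drop = FALSE])
    pred <- ifelse(p > 0.5, levels(labs)[1], levels(labs)[2])
    clf$test_accuracy <- mean(pred == labs[te])
  }
  clf
}

#' @export
print.patch_classifier <- function(x, ...) {
  cat("<patch_classifier> 3 conv (", paste(x$channels, collapse = "/"),
      ") + 2 fc layers;", length(x$history), "epochs;",
      if (!is.null(x$test_accuracy))
        sprintf("held-out accuracy %.1f%%", 100 * x$test_accuracy) else "",
      "\n")
  invisible(x)
}

#' Classify a batch of 25 x 25 patches
#'
#' @param classifier A [train_patch_classifier()] model.
#' @param patches 25 x 25 x N array (or a single 25 x 25 matrix).
#' @return Numeric vector of probabilities of the first class ("dot").
#' @export
classify_patches <- function(classifier, patches) {
  if (is.matrix(patches)) patches <- array(patches, c(25, 25, 1))
  d <- dim(patches)
  if (d[1] != 25 || d[2] != 25)
    stop("patches must be 25 x 25")
  X <- patches - 0.5
  dim(X) <- c(25, 25, 1, d[3])
  out <- numeric(d[3])
  for (start in seq(1, d[3], 512)) {
    bi <- start:min(start + 511, d[3])
    out[bi] <- cnn_forward(classifier$par, X[, , , bi, drop = FALSE])[1, ]
  }
  out
}

#' Probability that a single patch contains a dot
#'
#' @param classifier A [train_patch_classifier()] model.
#' @param patch 25 x 25 matrix.
#' @param full If `TRUE`, return the full softmax pair (dot, no-dot).
#' @return `p(dot)`, or the probability pair.
#' @export
classify_patch <- function(classifier, patch, full = FALSE) {
  if (!is.matrix(patch) || nrow(patch) != 25 || ncol(patch) != 25)
    stop("patch must be a 25 x 25 matrix")
  p <- classify_patches(classifier, patch)
  if (full) c(dot = p, no_dot = 1 - p) else p
}
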