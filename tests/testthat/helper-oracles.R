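# Independent reference implementations used as oracles.  These are kept
# deliberately naive (loops, direct arithmetic) and separate from the
# package code paths they check.

# exhaustive greedy NMS over explicit pairwise overlap matrix
brute_nms <- function(boxes, scores, thr) {
  n <- length(scores)
  if (n == 0) return(integer(0))
  ov <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ix <- max(0, min(boxes[i, 3], boxes[j, 3]) - max(boxes[i, 1], boxes[j, 1]))
    iy <- max(0, min(boxes[i, 4], boxes[j, 4]) - max(boxes[i, 2], boxes[j, 2]))
    inter <- ix * iy
    ai <- (boxes[i, 3] - boxes[i, 1]) * (boxes[i, 4] - boxes[i, 2])
    aj <- (boxes[j, 3] - boxes[j, 1]) * (boxes[j, 4] - boxes[j, 2])
    ov[i, j] <- inter / (ai + aj - inter)
  }
  alive <- rep(TRUE, n)
  keep <- integer(0)
  ord <- order(-scores, seq_len(n))
  while (any(alive[ord])) {
    i <- ord[alive[ord]][1]
    keep <- c(keep, i)
    alive[i] <- FALSE
    for (j in seq_len(n)) if (alive[j] && ov[i, j] > thr) alive[j] <- FALSE
  }
  keep
}

# direct-area IoU, written out long-hand
direct_iou <- function(a, b) {
  xx1 <- max(a[1], b[1]); yy1 <- max(a[2], b[2])
  xx2 <- min(a[3], b[3]); yy2 <- min(a[4], b[4])
  w <- max(0, xx2 - xx1); h <- max(0, yy2 - yy1)
  inter <- w * h
  inter / ((a[3] - a[1]) * (a[4] - a[2]) +
           (b[3] - b[1]) * (b[4] - b[2]) - inter)
}

random_boxes <- function(n) {
  x1 <- runif(n, 0, 80); y1 <- runif(n, 0, 80)
  cbind(x1, y1, x1 + runif(n, 2, 40), y1 + runif(n, 2, 40))
}

# literal loop implementation of the cross-channel attention unit on one
# (H, W, C) map: pooling, bottleneck gate, 1-D conv across channels,
# sigmoid, channel rescale -- all with explicit loops
cca_loop_oracle <- function(x, params) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]
  z <- numeric(C)
  for (c in seq_len(C)) {
    s <- 0
    for (i in seq_len(H)) for (j in seq_len(W)) s <- s + x[i, j, c]
    z[c] <- s / (H * W)
  }
  Cr <- nrow(params$W1)
  h <- numeric(Cr)
  for (a in seq_len(Cr)) {
    s <- 0
    for (c in seq_len(C)) s <- s + params$W1[a, c] * z[c]
    h[a] <- max(0, s)
  }
  S <- numeric(C)
  for (c in seq_len(C)) {
    s <- 0
    for (a in seq_len(Cr)) s <- s + params$W2[c, a] * h[a]
    S[c] <- 1 / (1 + exp(-s))
  }
  k <- length(params$conv_kernel)
  p <- (k - 1) / 2
  omega <- numeric(C)
  for (c in seq_len(C)) {
    s <- if (is.null(params$conv_bias)) 0 else params$conv_bias
    for (j in seq_len(k)) {
      src <- c + j - 1 - p
      if (src >= 1 && src <= C) s <- s + params$conv_kernel[j] * S[src]
    }
    omega[c] <- 1 / (1 + exp(-s))
  }
  out <- x
  for (c in seq_len(C))
    for (i in seq_len(H)) for (j in seq_len(W))
      out[i, j, c] <- x[i, j, c] * omega[c]
  out
}

# analytic parameter count for the residual backbone: every convolution
# contributes kh*kw*cin*cout weights and its batch norm 2*cout affines
analytic_backbone_count <- function(depth, width_mult = 1) {
  blocks <- if (depth == 50) c(3, 4, 6, 3) else c(3, 4, 23, 3)
  planes <- pmax(2, round(c(64, 128, 256, 512) * width_mult))
  stem <- pmax(2, round(64 * width_mult))
  total <- 7 * 7 * 3 * stem + 2 * stem
  cin <- stem
  for (s in 1:4) {
    for (b in seq_len(blocks[s])) {
      p <- planes[s]
      total <- total + (1 * 1 * cin * p + 2 * p) +
        (3 * 3 * p * p + 2 * p) + (1 * 1 * p * 4 * p + 2 * 4 * p)
      if ((s > 1 && b == 1) || cin != 4 * p)
        total <- total + 1 * 1 * cin * 4 * p + 2 * 4 * p
      cin <- 4 * p
    }
  }
  total
}

tiny_backbone <- function(fpn_channels = 16L) {
  backbone_config(width_mult = 0.125, fpn_channels = fpn_channels,
                  blocks = c(1L, 1L, 1L, 1L))
}

# small cached fit shared by several training-layer tests
tiny_fit_cache <- new.env(parent = emptyenv())
get_tiny_fit <- function() {
  if (is.null(tiny_fit_cache$fit)) {
    ds <- make_regression_dataset(12, frames_per_video = 3, seed = 42,
                                  height = 48, width = 48, face_scale = 30)
    fit <- ccanet(ds$videos,
                  config = train_config(epochs = 2, batch_size = 16,
                                        seed = 42),
                  backbone_cfg = tiny_backbone(),
                  attention_variant = "cca", input_size = 32)
    tiny_fit_cache$fit <- fit
    tiny_fit_cache$ds <- ds
  }
  list(fit = tiny_fit_cache$fit, ds = tiny_fit_cache$ds)
}
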