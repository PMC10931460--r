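# Tape-based reverse-mode autodiff.
#
# A "node" is an environment holding `value` (numeric array), `grad`
# (accumulated upstream gradient, NULL until backward reaches it) and a
# backward closure `bw` that routes the node's gradient to its parents.
# Operations executed while a tape is active append their result node to the
# tape; `ag_backward()` walks the tape in reverse creation order, which is a
# valid topological order by construction.  Parameter nodes are created
# outside any tape so they persist across training steps and only receive
# gradient accumulation.

.ag <- new.env(parent = emptyenv())
.ag$tape <- NULL

ag_tape_new <- function() {
  e <- new.env(parent = emptyenv())
  e$ops <- vector("list", 256L)
  e$n <- 0L
  e
}

#' Run an expression with a fresh autodiff tape
#'
#' Evaluates `expr` while recording operations, so that [ag_backward()] can
#' be called on a scalar node produced inside. Used internally by all
#' training loops; exported for the gradient-check tests.
#'
#' @param expr expression building an autodiff graph.
#' @return The value of `expr`.
#' @keywords internal
#' @export
ag_with_tape <- function(expr) {
  old <- .ag$tape
  .ag$tape <- ag_tape_new()
  on.exit(.ag$tape <- old)
  expr
}

ag_node <- function(value, bw = NULL) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$grad <- NULL
  n$bw <- bw
  t <- .ag$tape
  if (!is.null(t) && !is.null(bw)) {
    t$n <- t$n + 1L
    if (t$n > length(t$ops)) t$ops <- c(t$ops, vector("list", length(t$ops)))
    t$ops[[t$n]] <- n
  }
  n
}

#' Create a trainable parameter node
#' @param value numeric array of initial values.
#' @keywords internal
#' @export
ag_param <- function(value) {
  n <- ag_node(value)
  n$param <- TRUE
  n
}

#' Wrap a constant input as an autodiff node
#' @param value numeric array.
#' @keywords internal
#' @export
ag_const <- function(value) ag_node(value)

ag_acc <- function(n, g) {
  if (is.null(n)) return(invisible(NULL))
  n$grad <- if (is.null(n$grad)) g else n$grad + g
  invisible(NULL)
}

#' Backpropagate from a scalar loss node
#' @param loss node with a scalar value, produced under [ag_with_tape()].
#' @keywords internal
#' @export
ag_backward <- function(loss) {
  tape <- .ag$tape
  if (is.null(tape)) stop("ag_backward() requires an active tape")
  loss$grad <- 1
  for (i in seq.int(tape$n, 1L)) {
    n <- tape$ops[[i]]
    if (!is.null(n$grad)) n$bw(n$grad)
  }
  invisible(NULL)
}

ag_zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# ---- elementary ops ---------------------------------------------------------

ag_add <- function(a, b) {
  ag_node(a$value + b$value, bw = function(g) { ag_acc(a, g); ag_acc(b, g) })
}

ag_relu <- function(x) {
  mask <- x$value > 0
  ag_node(x$value * mask, bw = function(g) ag_acc(x, g * mask))
}

ag_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$value))
  ag_node(s, bw = function(g) ag_acc(x, g * s * (1 - s)))
}

# x: (H,W,C,N); w: (kh,kw,Cin,Cout); b: length Cout or NULL (bias-free)
ag_conv2d <- function(x, w, b = NULL, stride = 1L, pad = 0L) {
  bv <- if (is.null(b)) numeric(dim(w$value)[4]) else b$value
  out <- conv2d_fwd_cpp(x$value, w$value, bv, as.integer(stride),
                        as.integer(pad))
  ag_node(out, bw = function(g) {
    dim(g) <- dim(out)
    gr <- conv2d_bwd_cpp(x$value, w$value, g, as.integer(stride),
                         as.integer(pad))
    ag_acc(x, gr$dx); ag_acc(w, gr$dw)
    if (!is.null(b)) ag_acc(b, gr$db)
  })
}

ag_maxpool2 <- function(x) {
  r <- maxpool2_fwd_cpp(x$value)
  xd <- dim(x$value)
  ag_node(r$out, bw = function(g) {
    dim(g) <- dim(r$out)
    ag_acc(x, maxpool2_bwd_cpp(g, r$argmax, as.integer(xd)))
  })
}

# (H,W,C,N) -> (H*W*C, N) matrix
ag_flatten <- function(x) {
  d <- dim(x$value)
  v <- x$value
  dim(v) <- c(prod(d[1:3]), d[4])
  ag_node(v, bw = function(g) { dim(g) <- d; ag_acc(x, g) })
}

# x: (in, N) matrix; W: (out, in); b: length out or NULL -> (out, N)
ag_linear <- function(x, W, b = NULL) {
  v <- W$value %*% x$value
  if (!is.null(b)) v <- v + b$value
  ag_node(v, bw = function(g) {
    dim(g) <- dim(v)
    ag_acc(W, g %*% t(x$value))
    if (!is.null(b)) ag_acc(b, rowSums(g))
    ag_acc(x, t(W$value) %*% g)
  })
}

# global max pool (H,W,C,N) -> (C,N)
ag_gmp <- function(x) {
  d <- dim(x$value)
  hw <- d[1] * d[2]
  m <- x$value
  dim(m) <- c(hw, d[3] * d[4])
  arg <- max.col(t(m))            # index into hw per (c,n)
  v <- m[cbind(arg, seq_len(d[3] * d[4]))]
  dim(v) <- c(d[3], d[4])
  ag_node(v, bw = function(g) {
    gm <- matrix(0, hw, d[3] * d[4])
    gm[cbind(arg, seq_len(d[3] * d[4]))] <- as.numeric(g)
    dim(gm) <- d
    ag_acc(x, gm)
  })
}

# per-pixel channel mean and max: (H,W,C,N) -> (H,W,2,N)
ag_channel_meanmax <- function(x) {
  d <- dim(x$value)
  C <- d[3]
  v <- array(0, dim = c(d[1], d[2], 2, d[4]))
  argm <- array(0L, dim = c(d[1], d[2], d[4]))
  for (n in seq_len(d[4])) {
    sl <- x$value[, , , n, drop = FALSE]
    dim(sl) <- c(d[1] * d[2], C)
    v[, , 1, n] <- rowMeans(sl)
    am <- max.col(sl)
    v[, , 2, n] <- sl[cbind(seq_len(d[1] * d[2]), am)]
    argm[, , n] <- am
  }
  ag_node(v, bw = function(g) {
    dim(g) <- dim(v)
    gx <- array(0, dim = d)
    for (n in seq_len(d[4])) {
      gmean <- as.numeric(g[, , 1, n]) / C
      for (c in seq_len(C)) gx[, , c, n] <- gmean
      gmax <- matrix(0, d[1] * d[2], C)
      gmax[cbind(seq_len(d[1] * d[2]), as.integer(argm[, , n]))] <-
        as.numeric(g[, , 2, n])
      dim(gmax) <- c(d[1], d[2], C)
      gx[, , , n] <- gx[, , , n] + gmax
    }
    ag_acc(x, gx)
  })
}

# multiply (H,W,C,N) by a (H,W,1,N) spatial map
ag_mul_spatial <- function(x, m) {
  d <- dim(x$value)
  marr <- array(rep(m$value, times = 1), dim = c(d[1], d[2], 1, d[4]))
  big <- array(0, dim = d)
  for (c in seq_len(d[3])) big[, , c, ] <- marr[, , 1, ]
  ag_node(x$value * big, bw = function(g) {
    dim(g) <- d
    ag_acc(x, g * big)
    s <- g * x$value
    acc <- s[, , 1, , drop = FALSE]
    if (d[3] > 1) for (c in 2:d[3]) acc <- acc + s[, , c, , drop = FALSE]
    ag_acc(m, acc)
  })
}

# global average pool (H,W,C,N) -> (C,N)
ag_gap <- function(x) {
  d <- dim(x$value)
  hw <- d[1] * d[2]
  m <- x$value
  dim(m) <- c(hw, d[3] * d[4])
  v <- colMeans(m)
  dim(v) <- c(d[3], d[4])
  ag_node(v, bw = function(g) {
    gx <- array(rep(as.numeric(g), each = hw) / hw, dim = d)
    ag_acc(x, gx)
  })
}

# channel-wise rescale: x (H,W,C,N) * w (C,N)
ag_rescale <- function(x, w) {
  d <- dim(x$value)
  hw <- d[1] * d[2]
  warr <- array(rep(as.numeric(w$value), each = hw), dim = d)
  ag_node(x$value * warr, bw = function(g) {
    dim(g) <- d
    ag_acc(x, g * warr)
    gw <- colSums(matrix(g * x$value, nrow = hw))
    dim(gw) <- c(d[3], d[4])
    ag_acc(w, gw)
  })
}

# 1-D convolution along the channel axis of a (C,N) matrix, zero padding
# (k-1)/2, shared kernel across all positions (plus optional scalar bias).
ag_conv1d_channels <- function(s, kern, bias = NULL) {
  C <- nrow(s$value); N <- ncol(s$value)
  k <- length(kern$value)
  p <- (k - 1L) %/% 2L
  shift_rows <- function(m, off) {
    # rows shifted so out[c, ] gets m[c + off, ], zeros out of range
    out <- matrix(0, C, N)
    src <- seq_len(C) + off
    ok <- src >= 1L & src <= C
    out[ok, ] <- m[src[ok], , drop = FALSE]
    out
  }
  v <- matrix(0, C, N)
  for (j in seq_len(k)) v <- v + kern$value[j] * shift_rows(s$value, j - 1L - p)
  if (!is.null(bias)) v <- v + bias$value
  ag_node(v, bw = function(g) {
    dim(g) <- c(C, N)
    gs <- matrix(0, C, N)
    gk <- numeric(k)
    for (j in seq_len(k)) {
      off <- j - 1L - p
      gs <- gs + kern$value[j] * shift_rows(g, -off)
      gk[j] <- sum(g * shift_rows(s$value, off))
    }
    ag_acc(s, gs)
    ag_acc(kern, gk)
    if (!is.null(bias)) ag_acc(bias, sum(g))
  })
}

# nearest-neighbour 2x upsample of (H,W,C,N)
ag_upsample2x <- function(x) {
  d <- dim(x$value)
  ri <- rep(seq_len(d[1]), each = 2L)
  ci <- rep(seq_len(d[2]), each = 2L)
  v <- x$value[ri, ci, , , drop = FALSE]
  ag_node(v, bw = function(g) {
    dim(g) <- dim(v)
    # sum each 2x2 block
    g1 <- g[seq(1, 2 * d[1], 2), , , , drop = FALSE] +
          g[seq(2, 2 * d[1], 2), , , , drop = FALSE]
    gx <- g1[, seq(1, 2 * d[2], 2), , , drop = FALSE] +
          g1[, seq(2, 2 * d[2], 2), , , drop = FALSE]
    ag_acc(x, gx)
  })
}

# nearest-neighbour resize of (H,W,C,N) to (Ho,Wo) using the src = dst*(S/D)
# floor+clamp coordinate transform
ag_resize_nearest <- function(x, Ho, Wo) {
  d <- dim(x$value)
  ri <- nn_index(seq_len(Ho) - 1L, d[1], Ho)
  ci <- nn_index(seq_len(Wo) - 1L, d[2], Wo)
  v <- x$value[ri, ci, , , drop = FALSE]
  ag_node(v, bw = function(g) {
    dim(g) <- dim(v)
    gx <- array(0, dim = d)
    for (a in seq_len(Ho)) {
      for (b in seq_len(Wo)) {
        gx[ri[a], ci[b], , ] <- gx[ri[a], ci[b], , ] + g[a, b, , ]
      }
    }
    ag_acc(x, gx)
  })
}

# concatenate along the channel axis
ag_concat_c <- function(xs) {
  ds <- lapply(xs, function(x) dim(x$value))
  cs <- vapply(ds, `[`, numeric(1), 3)
  v <- array(0, dim = c(ds[[1]][1], ds[[1]][2], sum(cs), ds[[1]][4]))
  at <- 0L
  for (i in seq_along(xs)) {
    v[, , at + seq_len(cs[i]), ] <- xs[[i]]$value
    at <- at + cs[i]
  }
  ag_node(v, bw = function(g) {
    dim(g) <- dim(v)
    at <- 0L
    for (i in seq_along(xs)) {
      ag_acc(xs[[i]], g[, , at + seq_len(cs[i]), , drop = FALSE])
      at <- at + cs[i]
    }
  })
}

# batch normalisation over (H,W,N) per channel; state holds running moments
ag_batchnorm <- function(x, gamma, beta, state, training = TRUE,
                         momentum = 0.1, eps = 1e-5) {
  d <- dim(x$value)
  hw <- d[1] * d[2]; C <- d[3]; N <- d[4]
  m <- matrix(x$value, nrow = hw)            # hw x (C*N)
  per_cn <- colMeans(m); dim(per_cn) <- c(C, N)
  if (training) {
    mu <- rowMeans(per_cn)
    xc <- sweep_channels(x$value, mu, "-")
    v2 <- matrix(xc^2, nrow = hw)
    vcn <- colMeans(v2); dim(vcn) <- c(C, N)
    va <- rowMeans(vcn)
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * va
  } else {
    mu <- state$mean
    va <- state$var
    xc <- sweep_channels(x$value, mu, "-")
  }
  istd <- 1 / sqrt(va + eps)
  xhat <- sweep_channels(xc, istd, "*")
  v <- sweep_channels(sweep_channels(xhat, gamma$value, "*"), beta$value, "+")
  ag_node(v, bw = function(g) {
    dim(g) <- d
    ag_acc(gamma, channel_sum(g * xhat))
    ag_acc(beta, channel_sum(g))
    dxhat <- sweep_channels(g, gamma$value, "*")
    if (training) {
      mtot <- hw * N
      s1 <- channel_sum(dxhat)
      s2 <- channel_sum(dxhat * xhat)
      dx <- sweep_channels(
        dxhat - sweep_channels(array(1, d), s1 / mtot, "*") -
          sweep_channels(xhat, s2 / mtot, "*"),
        istd, "*")
    } else {
      dx <- sweep_channels(dxhat, istd, "*")
    }
    ag_acc(x, dx)
  })
}

# broadcast a per-channel vector across (H,W,C,N)
sweep_channels <- function(x, v, op) {
  d <- dim(x)
  hw <- d[1] * d[2]
  varr <- array(rep(rep(v, each = hw), times = d[4]), dim = d)
  switch(op,
         "-" = x - varr,
         "*" = x * varr,
         "+" = x + varr,
         stop("bad op"))
}

channel_sum <- function(x) {
  d <- dim(x)
  s <- colSums(matrix(x, nrow = d[1] * d[2]))
  dim(s) <- c(d[3], d[4])
  rowSums(s)
}

# mean squared error between (K,N) prediction and target -> scalar node
ag_mse <- function(pred, target, mask = NULL) {
  diff <- pred$value - target
  if (is.null(mask)) {
    n_eff <- length(diff)
    v <- sum(diff^2) / n_eff
    ag_node(v, bw = function(g) ag_acc(pred, g * 2 * diff / n_eff))
  } else {
    # mask: length-N 0/1 over columns; mean over active samples of the
    # per-sample squared-error sums
    n_act <- max(sum(mask), 1)
    marr <- matrix(rep(mask, each = nrow(diff)), nrow = nrow(diff))
    v <- sum((diff^2) * marr) / n_act
    ag_node(v, bw = function(g) ag_acc(pred, g * 2 * diff * marr / n_act))
  }
}

# softmax cross-entropy over 2-row logits (2,N) with 0/1 labels and an
# optional per-sample 0/1 mask -> scalar node; also exposes p(face)
ag_softmax_ce <- function(logits, labels, mask = NULL) {
  z <- logits$value
  zmax <- pmax(z[1, ], z[2, ])
  ez <- rbind(exp(z[1, ] - zmax), exp(z[2, ] - zmax))
  p <- ez / rep(colSums(ez), each = 2)
  y <- rbind(1 - labels, labels)
  w <- if (is.null(mask)) rep(1, ncol(z)) else mask
  n_act <- max(sum(w), 1)
  eps <- 1e-12
  v <- -sum(w * colSums(y * log(p + eps))) / n_act
  n <- ag_node(v, bw = function(g) {
    gl <- (p - y) * rep(w, each = 2) / n_act
    ag_acc(logits, g * gl)
  })
  n$p_face <- p[2, ]
  n
}

ag_scale <- function(x, a) {
  ag_node(x$value * a, bw = function(g) ag_acc(x, g * a))
}

ag_sum_nodes <- function(xs) {
  v <- 0
  for (x in xs) v <- v + x$value
  ag_node(v, bw = function(g) for (x in xs) ag_acc(x, g))
}
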