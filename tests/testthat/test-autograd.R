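# The reverse-mode engine: analytic gradients against central finite
# differences through a composite graph exercising every layer type used
# by the models.

numeric_grad <- function(fwd, p, eps = 1e-5) {
  g <- array(0, dim = ccanet:::dim_or_len(p$value))
  for (i in seq_along(p$value)) {
    v0 <- p$value[i]
    p$value[i] <- v0 + eps; f1 <- fwd()
    p$value[i] <- v0 - eps; f2 <- fwd()
    p$value[i] <- v0
    g[i] <- (f1 - f2) / (2 * eps)
  }
  g
}

test_that("conv, batchnorm, pooling and attention gradients match finite differences", {
  set.seed(1)
  w <- ccanet:::ag_param(ccanet:::init_conv(3, 3, 2, 4))
  b <- ccanet:::ag_param(rnorm(4) * 0.1)
  gam <- ccanet:::ag_param(rep(1, 4))
  bet <- ccanet:::ag_param(numeric(4))
  st <- new.env(); st$mean <- numeric(4); st$var <- rep(1, 4)
  W1 <- ccanet:::ag_param(matrix(rnorm(8), 2, 4) * 0.5)
  W2 <- ccanet:::ag_param(matrix(rnorm(8), 4, 2) * 0.5)
  kern <- ccanet:::ag_param(rnorm(3) * 0.5)
  kb <- ccanet:::ag_param(0.1)
  hw <- ccanet:::ag_param(ccanet:::init_linear(1, 4))
  hb <- ccanet:::ag_param(0)
  x <- array(rnorm(6 * 6 * 2 * 3), dim = c(6, 6, 2, 3))
  tgt <- matrix(rnorm(3), 1)
  graph <- function(do_bw) {
    st$mean <- numeric(4); st$var <- rep(1, 4)
    ccanet:::ag_with_tape({
      h <- ccanet:::ag_conv2d(ccanet:::ag_const(x), w, b, stride = 1L,
                              pad = 1L)
      h <- ccanet:::ag_batchnorm(h, gam, bet, st, training = TRUE)
      h <- ccanet:::ag_relu(h)
      h <- ccanet:::ag_maxpool2(h)
      z <- ccanet:::ag_gap(h)
      S <- ccanet:::ag_sigmoid(ccanet:::ag_linear(
        ccanet:::ag_relu(ccanet:::ag_linear(z, W1)), W2))
      om <- ccanet:::ag_sigmoid(ccanet:::ag_conv1d_channels(S, kern, kb))
      h2 <- ccanet:::ag_rescale(h, om)
      pred <- ccanet:::ag_linear(ccanet:::ag_gap(h2), hw, hb)
      loss <- ccanet:::ag_mse(pred, tgt)
      if (do_bw) ccanet:::ag_backward(loss)
      loss$value
    })
  }
  params <- list(w = w, gam = gam, bet = bet, W1 = W1, W2 = W2,
                 kern = kern, kb = kb, hw = hw, hb = hb)
  ccanet:::ag_zero_grads(params)
  graph(TRUE)
  for (nm in names(params)) {
    p <- params[[nm]]
    ng <- numeric_grad(function() graph(FALSE), p)
    expect_lt(max(abs(ng - p$grad)), 1e-6)
  }
})

test_that("upsample, resize, concat and spatial ops backpropagate correctly", {
  set.seed(2)
  w5 <- ccanet:::ag_param(ccanet:::init_conv(1, 1, 2, 2))
  b5 <- ccanet:::ag_param(rnorm(2) * 0.1)
  x <- array(rnorm(4 * 4 * 2 * 2), dim = c(4, 4, 2, 2))
  tgt <- matrix(rnorm(2), 1)
  hw <- ccanet:::ag_param(ccanet:::init_linear(1, 4))
  graph <- function(do_bw) {
    ccanet:::ag_with_tape({
      xa <- ccanet:::ag_const(x)
      a <- ccanet:::ag_conv2d(xa, w5, b5)
      up <- ccanet:::ag_upsample2x(a)                     # 8x8
      rs <- ccanet:::ag_resize_nearest(up, 4L, 4L)        # back to 4x4
      cc <- ccanet:::ag_concat_c(list(a, rs))             # 4 channels
      pred <- ccanet:::ag_linear(ccanet:::ag_gap(cc), hw)
      loss <- ccanet:::ag_mse(pred, tgt)
      if (do_bw) ccanet:::ag_backward(loss)
      loss$value
    })
  }
  params <- list(w5 = w5, b5 = b5, hw = hw)
  ccanet:::ag_zero_grads(params)
  graph(TRUE)
  for (nm in names(params)) {
    ng <- numeric_grad(function() graph(FALSE), params[[nm]])
    expect_lt(max(abs(ng - params[[nm]]$grad)), 1e-6)
  }
})

test_that("softmax cross-entropy with sample masks matches finite differences", {
  set.seed(3)
  W <- ccanet:::ag_param(matrix(rnorm(8), 2, 4) * 0.3)
  x <- matrix(rnorm(16), 4, 4)
  y <- c(1, 0, 1, 0)
  mask <- c(1, 1, 0, 1)
  graph <- function(do_bw) {
    ccanet:::ag_with_tape({
      logits <- ccanet:::ag_linear(ccanet:::ag_const(x), W)
      loss <- ccanet:::ag_softmax_ce(logits, y, mask)
      if (do_bw) ccanet:::ag_backward(loss)
      loss$value
    })
  }
  ccanet:::ag_zero_grads(list(W))
  graph(TRUE)
  ng <- numeric_grad(function() graph(FALSE), W)
  expect_lt(max(abs(ng - W$grad)), 1e-6)
  # the masked sample contributes no gradient
  W2 <- ccanet:::ag_param(W$value)
  graph2 <- function() {
    ccanet:::ag_with_tape({
      logits <- ccanet:::ag_linear(ccanet:::ag_const(x), W2)
      loss <- ccanet:::ag_softmax_ce(logits, y, c(1, 1, 1, 1))
      loss$value
    })
  }
  expect_false(isTRUE(all.equal(graph2(), graph(FALSE))))
})

test_that("Adam decreases a convex quadratic and keeps parameter shapes", {
  p <- ccanet:::ag_param(matrix(c(5, -3, 2, 1), 2, 2))
  s <- ccanet:::ag_param(4)
  opt <- ccanet:::adam_new(list(p, s), lr = 0.1)
  loss0 <- NULL
  for (it in 1:200) {
    lv <- ccanet:::ag_with_tape({
      l <- ccanet:::ag_node(sum(p$value^2) + s$value^2, bw = NULL)
      ccanet:::ag_zero_grads(list(p, s))
      p$grad <- 2 * p$value
      s$grad <- 2 * s$value
      sum(p$value^2) + s$value^2
    })
    if (it == 1) loss0 <- lv
    ccanet:::adam_step(opt)
  }
  expect_lt(sum(p$value^2) + s$value^2, loss0 * 1e-3)
  expect_equal(dim(p$value), c(2, 2))
  expect_null(dim(s$value))
})
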