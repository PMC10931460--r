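# Channel-attention units: pooling, gates, rescale, full forward passes
# and the baseline variants.

test_that("global average pooling reduces each channel to its mean", {
  expect_equal(gap(array(3, dim = c(4, 5, 2))), c(3, 3))
  expect_equal(gap(array(c(1, 3, 2, 4), dim = c(2, 2, 1))), 2.5)
  set.seed(6)
  x <- array(rnorm(5 * 7 * 8 * 2), dim = c(5, 7, 8, 2))
  z <- gap(x)
  ref <- matrix(0, 8, 2)
  for (n in 1:2) for (c in 1:8) {
    s <- 0
    for (i in 1:5) for (j in 1:7) s <- s + x[i, j, c, n]
    ref[c, n] <- s / 35
  }
  expect_equal(z, ref, tolerance = 1e-6)
})

test_that("the bottleneck gate squashes through reduce-ReLU-expand-sigmoid", {
  p <- attention_params(4, r = 2, k = 3, seed = 1)
  p0 <- p; p0$W1[] <- 0; p0$W2[] <- 0
  expect_equal(fc_gate(c(1, 2, 3, 4), p0), rep(0.5, 4))
  # explicit matrix-vector oracle
  p$W1 <- matrix(c(1, 0, -1, 2, 0.5, 0, 1, -1), 2, 4)
  p$W2 <- matrix(seq(-0.7, 0.7, length.out = 8), 4, 2)
  z <- c(1, 0, 0, 0)
  h <- pmax(p$W1 %*% z, 0)
  expect_equal(fc_gate(z, p), as.numeric(1 / (1 + exp(-(p$W2 %*% h)))),
               tolerance = 1e-12)
  out <- fc_gate(rnorm(4) * 100, p)
  expect_true(all(out > 0 & out < 1))
  expect_error(fc_gate(1:5, p), "does not match C")
  expect_error(attention_params(10, r = 16), "divide")
  expect_error(attention_params(16, r = 16, k = 4), "odd")
})

test_that("the 1-D convolution gate slides across the channel axis", {
  p <- attention_params(6, r = 2, k = 5, seed = 1)
  p0 <- p; p0$conv_kernel[] <- 0; p0$conv_bias <- 0
  expect_equal(conv_gate(rnorm(6), p0), rep(0.5, 6))
  pid <- p; pid$conv_kernel <- c(0, 0, 1, 0, 0); pid$conv_bias <- 0
  S <- runif(6)
  expect_equal(conv_gate(S, pid), 1 / (1 + exp(-S)), tolerance = 1e-12)
  # ones-kernel on a one-hot input: sliding-window sum oracle
  pones <- p; pones$conv_kernel <- rep(1, 5); pones$conv_bias <- 0
  oh <- c(0, 0, 1, 0, 0, 0)
  pre <- vapply(1:6, function(c) sum(oh[pmax(1, c - 2):pmin(6, c + 2)]),
                numeric(1))
  expect_equal(conv_gate(oh, pones), 1 / (1 + exp(-pre)), tolerance = 1e-12)
})

test_that("rescale multiplies each channel by its weight", {
  x <- array(4, dim = c(3, 3, 2))
  expect_equal(rescale(x, c(0.5, 1 - 1e-15))[, , 1],
               matrix(2, 3, 3))
  expect_equal(rescale(x, c(1, 1)), x)
  set.seed(3)
  xr <- array(rnorm(36), dim = c(3, 3, 4))
  w <- runif(4, 0.01, 0.99)
  out <- rescale(xr, w)
  expect_true(all(abs(out) <= abs(xr) + 1e-12))
  expect_error(rescale(xr, w[1:3]), "does not match")
})

test_that("cca_forward composes the unit and treats batch elements independently", {
  p <- attention_params(16, r = 4, k = 5, seed = 8)
  set.seed(8)
  x <- array(rnorm(4 * 4 * 16), dim = c(4, 4, 16))
  expect_equal(cca_forward(x, p), cca_loop_oracle(x, p), tolerance = 1e-10)
  # batch independence: permuting samples permutes outputs
  xb <- array(rnorm(4 * 4 * 16 * 3), dim = c(4, 4, 16, 3))
  out <- cca_forward(xb, p)
  perm <- c(3, 1, 2)
  expect_equal(cca_forward(xb[, , , perm], p), out[, , , perm],
               tolerance = 1e-12)
  # attenuation: gates in (0,1) shrink every norm
  expect_lt(sqrt(sum(out^2)), sqrt(sum(xb^2)))
})

test_that("zeroed gate parameters halve then re-gate at one half", {
  p <- attention_params(8, r = 2, k = 5, seed = 1, conv_bias = TRUE)
  p$W1[] <- 0; p$W2[] <- 0; p$conv_kernel[] <- 0; p$conv_bias <- 0
  x <- array(rnorm(2 * 2 * 8), dim = c(2, 2, 8))
  expect_equal(cca_forward(x, p), x * 0.5, tolerance = 1e-12)
  expect_equal(se_forward(x, p), x * 0.5, tolerance = 1e-12)
})

test_that("the baselines share the interface and their structure", {
  p <- attention_params(16, r = 4, k = 5, variant = "cbam", seed = 2)
  set.seed(2)
  x <- array(rnorm(4 * 4 * 16 * 2), dim = c(4, 4, 16, 2))
  # ECA is the unit with the bottleneck gate replaced by identity
  expect_equal(eca_forward(x, p), rescale(x, conv_gate(gap(x), p)),
               tolerance = 1e-12)
  for (f in list(se_forward, eca_forward, cbam_forward, cca_forward))
    expect_equal(dim(f(x, p)), dim(x))
  # SE / ECA / CCA attenuate in norm
  for (f in list(se_forward, eca_forward, cca_forward))
    expect_lt(sqrt(sum(f(x, p)^2)), sqrt(sum(x^2)))
  expect_equal(attention_forward(x, attention_params(16, variant = "none")),
               x)
})

test_that("the conv gate is not channel-permutation equivariant", {
  p <- attention_params(8, r = 2, k = 5, seed = 4)
  S <- runif(8)
  perm <- 8:1
  lhs <- conv_gate(S[perm], p)
  rhs <- conv_gate(S, p)[perm]
  expect_gt(max(abs(lhs - rhs)), 1e-6)
  # while the bottleneck gate output depends on order only through its
  # (dense) weights, the conv gate's locality is what breaks equivariance
  pones <- p; pones$conv_kernel <- c(0, 0, 1, 0, 0); pones$conv_bias <- 0
  expect_equal(conv_gate(S[perm], pones), conv_gate(S, pones)[perm],
               tolerance = 1e-12)
})

test_that("variant parameter counts order as none < eca < se < cca < cbam", {
  C <- 64
  counts <- vapply(c("none", "eca", "se", "cca", "cbam"), function(v)
    ccanet:::attention_param_count(
      attention_params(C, r = 16, k = 5, variant = v)), numeric(1))
  expect_true(all(diff(counts) > 0))
  # and they match direct arithmetic
  expect_equal(unname(counts["se"]), 2 * C * (C / 16))
  expect_equal(unname(counts["eca"]), 5 + 1)
  expect_equal(unname(counts["cca"]), 2 * C * (C / 16) + 5 + 1)
})
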