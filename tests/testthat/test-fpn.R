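# Backbone feature shapes, pyramid fusion semantics and parameter counts.

test_that("backbone levels follow the stride plan and reject bad sizes", {
  cfg <- tiny_backbone()
  X <- array(runif(64 * 64 * 3 * 2), dim = c(64, 64, 3, 2))
  cs <- backbone_forward(X, cfg, seed = 1)
  expect_equal(names(cs), c("c2", "c3", "c4", "c5"))
  sizes <- vapply(cs, function(x) dim(x)[1], numeric(1))
  expect_equal(unname(sizes), c(16, 8, 4, 2))   # strides 4, 8, 16, 32
  expect_equal(unname(vapply(cs, function(x) dim(x)[4], numeric(1))),
               rep(2, 4))
  expect_true(all(vapply(cs, function(x) all(is.finite(x)), logical(1))))
  expect_error(backbone_forward(array(0, c(60, 60, 3, 1)), cfg),
               "divisible by 32")
  expect_error(backbone_config(depth = 34), "50 or 101")
})

test_that("depths 50 and 101 share output shapes but not parameter counts", {
  mult <- 0.03125
  c50 <- backbone_config(depth = 50, width_mult = mult)
  c101 <- backbone_config(depth = 101, width_mult = mult)
  X <- array(runif(32 * 32 * 3), dim = c(32, 32, 3, 1))
  s50 <- lapply(backbone_forward(X, c50, seed = 1), dim)
  s101 <- lapply(backbone_forward(X, c101, seed = 1), dim)
  expect_equal(s50, s101)
  n50 <- ccanet:::backbone_param_count(c50)
  n101 <- ccanet:::backbone_param_count(c101)
  expect_gt(n101, n50)
  # counts match the analytic oracle at full and reduced width
  for (m in c(1, mult)) {
    expect_equal(ccanet:::backbone_param_count(
                   backbone_config(depth = 50, width_mult = m)),
                 analytic_backbone_count(50, m))
    expect_equal(ccanet:::backbone_param_count(
                   backbone_config(depth = 101, width_mult = m)),
                 analytic_backbone_count(101, m))
  }
})

test_that("lateral projection changes only the channel count", {
  x <- array(rnorm(8 * 8 * 12 * 2), dim = c(8, 8, 12, 2))
  out <- lateral_project(x, fpn_channels = 20, seed = 1)
  expect_equal(dim(out), c(8, 8, 20, 2))
  # identity kernel on matching channels reproduces the input
  idk <- array(0, dim = c(1, 1, 12, 12))
  for (c in 1:12) idk[1, 1, c, c] <- 1
  expect_equal(lateral_project(x, kernel = idk), x, tolerance = 1e-12)
  # linear with zero bias
  k <- ccanet:::with_seed(4, ccanet:::init_conv(1, 1, 12, 6))
  expect_equal(lateral_project(3 * x, kernel = k),
               3 * lateral_project(x, kernel = k), tolerance = 1e-9)
})

test_that("top-down fusion sums laterals with upsampled coarser levels", {
  set.seed(9)
  cs <- list(c2 = array(rnorm(8 * 8 * 3 * 1), c(8, 8, 3, 1)),
             c3 = array(rnorm(4 * 4 * 5 * 1), c(4, 4, 5, 1)),
             c4 = array(rnorm(2 * 2 * 7 * 1), c(2, 2, 7, 1)),
             c5 = array(rnorm(1 * 1 * 9 * 1), c(1, 1, 9, 1)))
  fpn <- ccanet:::fpn_new(c(3, 5, 7, 9), fpn_channels = 4, seed = 2)
  p <- topdown_fuse(cs, fpn = fpn)
  expect_equal(names(p), c("p2", "p3", "p4", "p5"))
  expect_equal(dim(p$p4)[1:2], dim(cs$c4)[1:2])
  expect_true(all(vapply(p, function(x) dim(x)[3], numeric(1)) == 4))
  # hand-rolled oracle: conv1x1 is a channel mix; upsample replicates
  lat <- function(x, i) {
    k <- fpn$lateral[[i]]$w$value; b <- fpn$lateral[[i]]$b$value
    d <- dim(x)
    out <- array(0, dim = c(d[1], d[2], 4, 1))
    for (co in 1:4) {
      acc <- matrix(b[co], d[1], d[2])
      for (ci in seq_len(d[3])) acc <- acc + k[1, 1, ci, co] * x[, , ci, 1]
      out[, , co, 1] <- acc
    }
    out
  }
  ref5 <- lat(cs$c5, 4)
  ref4 <- lat(cs$c4, 3) + upsample_nearest_2x(ref5)
  ref3 <- lat(cs$c3, 2) + upsample_nearest_2x(ref4)
  ref2 <- lat(cs$c2, 1) + upsample_nearest_2x(ref3)
  expect_equal(p$p5, ref5, tolerance = 1e-9)
  expect_equal(p$p2, ref2, tolerance = 1e-9)
  # zero lateral kernels and biases give zero pyramids
  for (l in fpn$lateral) { l$w$value[] <- 0; l$b$value[] <- 0 }
  p0 <- topdown_fuse(cs, fpn = fpn)
  expect_true(all(vapply(p0, function(x) max(abs(x)), numeric(1)) == 0))
  expect_error(topdown_fuse(cs[1:3]), "must all be present")
  bad <- cs; bad$c3 <- array(0, c(3, 3, 5, 1))
  expect_error(topdown_fuse(bad), "stride mismatch")
})

test_that("fusion with zero biases is linear in the inputs", {
  set.seed(10)
  cs <- list(c2 = array(rnorm(8 * 8 * 2), c(8, 8, 2, 1)),
             c3 = array(rnorm(4 * 4 * 2), c(4, 4, 2, 1)),
             c4 = array(rnorm(2 * 2 * 2), c(2, 2, 2, 1)),
             c5 = array(rnorm(1 * 1 * 2), c(1, 1, 2, 1)))
  fpn <- ccanet:::fpn_new(rep(2, 4), fpn_channels = 4, seed = 3)
  for (l in fpn$lateral) l$b$value[] <- 0
  p1 <- topdown_fuse(cs, fpn = fpn)
  p2 <- topdown_fuse(lapply(cs, function(x) 2.5 * x), fpn = fpn)
  for (nm in names(p1)) expect_equal(p2[[nm]], 2.5 * p1[[nm]],
                                     tolerance = 1e-9)
})

test_that("splicing concatenates the smoothed levels at p2 resolution", {
  set.seed(12)
  p <- list(p2 = array(rnorm(8 * 8 * 4), c(8, 8, 4, 1)),
            p3 = array(rnorm(4 * 4 * 4), c(4, 4, 4, 1)),
            p4 = array(rnorm(2 * 2 * 4), c(2, 2, 4, 1)),
            p5 = array(rnorm(1 * 1 * 4), c(1, 1, 4, 1)))
  fused <- smooth_and_splice(p, seed = 4)
  expect_equal(dim(fused), c(8, 8, 16, 1))   # 4 levels x 4 channels
  # with identity smoothing kernels the channel blocks equal the resized
  # p-levels
  fpn <- ccanet:::fpn_new(rep(4, 4), fpn_channels = 4, seed = 4)
  for (nm in names(fpn$smooth)) {
    s <- fpn$smooth[[nm]]
    s$w$value[] <- 0
    kh <- dim(s$w$value)[1]
    mid <- (kh + 1) %/% 2
    for (c in 1:4) s$w$value[mid, mid, c, c] <- 1
    s$b$value[] <- 0
  }
  fused_id <- smooth_and_splice(p, fpn = fpn)
  expect_equal(fused_id[, , 1:4, , drop = FALSE], p$p2, tolerance = 1e-12)
  expect_equal(fused_id[, , 5:8, , drop = FALSE],
               resize_nearest(p$p3[, , , 1], 8, 8)[, , , drop = FALSE] |>
                 array(dim = c(8, 8, 4, 1)), tolerance = 1e-12)
  expect_error(smooth_and_splice(p[1:3]), "must all be present")
})
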