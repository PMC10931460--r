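# Residual bottleneck backbone (depths 50 / 101) and the improved feature
# pyramid: lateral 1x1 projections to 256 channels, top-down fusion by
# nearest-neighbour 2x upsampling and element-wise sum, per-level smoothing
# (1x1 on p5, 3x3 on p4/p3/p2), and a splice that resizes p3..p5 to p2's
# resolution and concatenates all four along the channel axis.

#' Backbone configuration
#'
#' Depth 50 uses stage block counts (3, 4, 6, 3); depth 101 uses
#' (3, 4, 23, 3). `width_mult` scales every channel width (1 = the
#' standard 64/128/256/512 bottleneck plan); `blocks` may override the
#' per-stage block counts for reduced desk-scale models.
#'
#' @param depth 50 or 101.
#' @param width_mult channel width multiplier.
#' @param fpn_channels pyramid channel width (default 256).
#' @param blocks optional length-4 integer override of stage block counts.
#' @return Object of class `"backbone_config"`.
#' @export
backbone_config <- function(depth = 50L, width_mult = 1,
                            fpn_channels = 256L, blocks = NULL) {
  if (!depth %in% c(50L, 101L)) stop("depth must be 50 or 101")
  blk <- if (!is.null(blocks)) as.integer(blocks)
         else if (depth == 50L) c(3L, 4L, 6L, 3L) else c(3L, 4L, 23L, 3L)
  planes <- pmax(2L, as.integer(round(c(64, 128, 256, 512) * width_mult)))
  stem <- pmax(2L, as.integer(round(64 * width_mult)))
  fpn_channels <- max(4L, as.integer(round(fpn_channels)))
  structure(list(depth = depth, width_mult = width_mult, blocks = blk,
                 planes = planes, stem = stem,
                 out_channels = 4L * planes,
                 fpn_channels = fpn_channels),
            class = "backbone_config")
}

bn_new <- function(C) {
  st <- new.env(parent = emptyenv())
  st$mean <- numeric(C); st$var <- rep(1, C)
  list(gamma = ag_param(rep(1, C)), beta = ag_param(numeric(C)), state = st)
}

conv_unit <- function(kh, kw, cin, cout) {
  list(w = ag_param(init_conv(kh, kw, cin, cout)),
       bn = bn_new(cout))
}

bottleneck_new <- function(cin, planes, stride) {
  unit <- list(
    c1 = conv_unit(1, 1, cin, planes),
    c2 = conv_unit(3, 3, planes, planes),
    c3 = conv_unit(1, 1, planes, 4L * planes),
    stride = stride)
  if (stride != 1L || cin != 4L * planes)
    unit$proj <- conv_unit(1, 1, cin, 4L * planes)
  unit
}

backbone_new <- function(config, seed = 1L) {
  with_seed(derive_seed(seed, "backbone"), {
    stages <- list()
    cin <- config$stem
    for (s in 1:4) {
      blocks <- list()
      for (b in seq_len(config$blocks[s])) {
        stride <- if (s > 1 && b == 1) 2L else 1L
        blocks[[b]] <- bottleneck_new(cin, config$planes[s], stride)
        cin <- 4L * config$planes[s]
      }
      stages[[s]] <- blocks
    }
    list(stem = conv_unit(7, 7, 3, config$stem),
         stages = stages, config = config)
  })
}

ag_conv_bn_relu <- function(x, unit, stride = 1L, pad = 0L,
                            training = TRUE, relu = TRUE) {
  h <- ag_conv2d(x, unit$w, NULL, stride = stride, pad = pad)
  h <- ag_batchnorm(h, unit$bn$gamma, unit$bn$beta, unit$bn$state,
                    training = training)
  if (relu) ag_relu(h) else h
}

bottleneck_forward <- function(x, unit, training) {
  h <- ag_conv_bn_relu(x, unit$c1, training = training)
  h <- ag_conv_bn_relu(h, unit$c2, stride = unit$stride, pad = 1L,
                       training = training)
  h <- ag_conv_bn_relu(h, unit$c3, training = training, relu = FALSE)
  sk <- if (!is.null(unit$proj))
    ag_conv_bn_relu(x, unit$proj, stride = unit$stride,
                    training = training, relu = FALSE)
  else x
  ag_relu(ag_add(h, sk))
}

backbone_forward_nodes <- function(bb, x, training = TRUE) {
  h <- ag_conv_bn_relu(x, bb$stem, stride = 2L, pad = 3L,
                       training = training)
  h <- ag_maxpool2(h)
  cs <- list()
  for (s in 1:4) {
    for (unit in bb$stages[[s]]) h <- bottleneck_forward(h, unit, training)
    cs[[paste0("c", s + 1)]] <- h
  }
  cs
}

#' Run the residual backbone on a batch of images
#'
#' @param images array `(H, W, 3, N)` with `H`, `W` divisible by 32.
#' @param config a [backbone_config()], or a backbone built by the model.
#' @param seed seed for weight initialisation when a config is given.
#' @return List of feature maps `c2, c3, c4, c5` (arrays `(h, w, C, N)` at
#'   strides 4, 8, 16, 32) with attribute `strides`.
#' @export
backbone_forward <- function(images, config = backbone_config(), seed = 1L) {
  d <- dim(images)
  if (length(d) != 4 || d[3] != 3)
    stop("images must be a (H, W, 3, N) array")
  if (d[1] %% 32 != 0 || d[2] %% 32 != 0)
    stop("input spatial size must be divisible by 32")
  bb <- if (!is.null(config$stages)) config else backbone_new(config, seed)
  cs <- backbone_forward_nodes(bb, ag_const(images), training = TRUE)
  out <- lapply(cs, function(n) n$value)
  attr(out, "strides") <- c(c2 = 4L, c3 = 8L, c4 = 16L, c5 = 32L)
  out
}

# ---- feature pyramid --------------------------------------------------------

fpn_new <- function(c_channels, fpn_channels = 256L, seed = 1L) {
  with_seed(derive_seed(seed, "fpn"), {
    lat <- lapply(c_channels, function(cc)
      list(w = ag_param(init_conv(1, 1, cc, fpn_channels)),
           b = ag_param(numeric(fpn_channels))))
    smooth <- list(
      p2 = list(w = ag_param(init_conv(3, 3, fpn_channels, fpn_channels)),
                b = ag_param(numeric(fpn_channels)), pad = 1L),
      p3 = list(w = ag_param(init_conv(3, 3, fpn_channels, fpn_channels)),
                b = ag_param(numeric(fpn_channels)), pad = 1L),
      p4 = list(w = ag_param(init_conv(3, 3, fpn_channels, fpn_channels)),
                b = ag_param(numeric(fpn_channels)), pad = 1L),
      p5 = list(w = ag_param(init_conv(1, 1, fpn_channels, fpn_channels)),
                b = ag_param(numeric(fpn_channels)), pad = 0L))
    list(lateral = lat, smooth = smooth, fpn_channels = fpn_channels)
  })
}

#' Project a backbone level to the pyramid width
#'
#' 1x1 convolution changing the channel count to the pyramid width
#' (default 256); spatial dimensions are unchanged.
#'
#' @param c_level array `(h, w, C, N)`.
#' @param kernel optional explicit `(1, 1, C, fpn_channels)` kernel (random
#'   seeded initialisation otherwise).
#' @param fpn_channels output channel count.
#' @param bias optional bias vector.
#' @param seed seed for initialisation.
#' @return Array `(h, w, fpn_channels, N)`.
#' @export
lateral_project <- function(c_level, kernel = NULL, fpn_channels = 256L,
                            bias = NULL, seed = 1L) {
  d <- dim(c_level)
  if (is.null(kernel))
    kernel <- with_seed(derive_seed(seed, "lateral"),
                        init_conv(1, 1, d[3], fpn_channels))
  if (is.null(bias)) bias <- numeric(dim(kernel)[4])
  conv2d_fwd_cpp(c_level, kernel, bias, 1L, 0L)
}

fpn_topdown_nodes <- function(fpn, cs, training = TRUE) {
  lat <- lapply(seq_along(cs), function(i)
    ag_conv2d(cs[[i]], fpn$lateral[[i]]$w, fpn$lateral[[i]]$b))
  names(lat) <- sub("^c", "p", names(cs))
  p <- list(p5 = lat$p5)
  p$p4 <- ag_add(lat$p4, ag_upsample2x(p$p5))
  p$p3 <- ag_add(lat$p3, ag_upsample2x(p$p4))
  p$p2 <- ag_add(lat$p2, ag_upsample2x(p$p3))
  p[c("p2", "p3", "p4", "p5")]
}

#' Top-down pyramid fusion
#'
#' `p5 = lateral(c5)`; `p_i = lateral(c_i) + upsample2x(p_{i+1})` for
#' i = 4, 3, 2 (element-wise sum after nearest-neighbour 2x upsampling).
#'
#' @param c_levels named list `c2..c5` of arrays `(h, w, C, N)` with
#'   dyadic stride relations (each level half the previous size).
#' @param fpn optional parameter set from the model; random seeded
#'   lateral kernels otherwise.
#' @param fpn_channels pyramid width.
#' @param seed seed for initialisation.
#' @return Named list `p2..p5` of arrays, all `fpn_channels` wide.
#' @export
topdown_fuse <- function(c_levels, fpn = NULL, fpn_channels = 256L,
                         seed = 1L) {
  need <- c("c2", "c3", "c4", "c5")
  if (!all(need %in% names(c_levels))) stop("c2..c5 must all be present")
  dims <- vapply(c_levels[need], function(x) dim(x)[1], numeric(1))
  if (!all(dims[1:3] == 2 * dims[2:4]))
    stop("stride mismatch: each level must halve the previous size")
  if (is.null(fpn))
    fpn <- fpn_new(vapply(c_levels[need], function(x) dim(x)[3], numeric(1)),
                   fpn_channels, seed)
  nodes <- lapply(c_levels[need], ag_const)
  p <- fpn_topdown_nodes(fpn, nodes)
  lapply(p, function(n) n$value)
}

fpn_splice_nodes <- function(fpn, p, training = TRUE) {
  sm <- lapply(names(p), function(nm) {
    s <- fpn$smooth[[nm]]
    ag_conv2d(p[[nm]], s$w, s$b, pad = s$pad)
  })
  names(sm) <- names(p)
  h2 <- dim(sm$p2$value)[1]; w2 <- dim(sm$p2$value)[2]
  ag_concat_c(list(sm$p2,
                   ag_resize_nearest(sm$p3, h2, w2),
                   ag_resize_nearest(sm$p4, h2, w2),
                   ag_resize_nearest(sm$p5, h2, w2)))
}

#' Smooth the pyramid levels and splice them into one map
#'
#' p5 is convolved 1x1 and p4/p3/p2 are convolved 3x3 (channel-preserving,
#' zero padding keeps spatial size); p3..p5 are then resized to p2's
#' resolution by nearest neighbour and all four are concatenated along the
#' channel axis, giving `4 * fpn_channels` channels at p2's resolution
#' (1024 channels at 32x32 for a 128x128 input at the default width).
#'
#' @param p_levels named list `p2..p5` of arrays, equal channel counts.
#' @param fpn optional parameter set from the model; seeded random
#'   smoothing kernels otherwise.
#' @param seed seed for initialisation.
#' @return Fused array `(h2, w2, 4 * fpn_channels, N)`.
#' @export
smooth_and_splice <- function(p_levels, fpn = NULL, seed = 1L) {
  need <- c("p2", "p3", "p4", "p5")
  if (!all(need %in% names(p_levels))) stop("p2..p5 must all be present")
  ch <- vapply(p_levels[need], function(x) dim(x)[3], numeric(1))
  if (length(unique(ch)) != 1)
    stop("all pyramid levels must share one channel count")
  if (is.null(fpn)) fpn <- fpn_new(rep(ch[1], 4), ch[1], seed)
  nodes <- lapply(p_levels[need], ag_const)
  fpn_splice_nodes(fpn, nodes)$value
}

backbone_param_count <- function(config) {
  n <- 0L
  count_conv <- function(kh, kw, cin, cout) kh * kw * cin * cout + 2L * cout
  n <- n + count_conv(7, 7, 3, config$stem)
  cin <- config$stem
  for (s in 1:4) {
    planes <- config$planes[s]
    for (b in seq_len(config$blocks[s])) {
      stride <- if (s > 1 && b == 1) 2L else 1L
      n <- n + count_conv(1, 1, cin, planes)
      n <- n + count_conv(3, 3, planes, planes)
      n <- n + count_conv(1, 1, planes, 4L * planes)
      if (stride != 1L || cin != 4L * planes)
        n <- n + count_conv(1, 1, cin, 4L * planes)
      cin <- 4L * planes
    }
  }
  as.integer(n)
}

fpn_param_count <- function(config) {
  fc <- config$fpn_channels
  lat <- sum(config$out_channels * fc + fc)
  smooth <- 3L * (3 * 3 * fc * fc + fc) + (fc * fc + fc)
  as.integer(lat + smooth)
}
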