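# Channel attention units.
#
# The cross-channel attention (CCA) unit: global average pooling over space,
# a reduction-r bottleneck gate S = sigmoid(W2 relu(W1 z)), a k-wide 1-D
# convolution across the channel axis omega = sigmoid(C1D_k(S)), and a
# channel-wise rescale x_c * omega_c.  SE (bottleneck gate only), ECA (1-D
# conv only) and CBAM (channel gate with avg+max pooling, then a spatial
# gate) are provided as ablation baselines behind the same interface.
#
# The plain-array functions below are the reference surface (used directly
# by tests); the trained model applies the same arithmetic through the
# autodiff ops.

as_chw_n <- function(x) {
  d <- dim(x)
  if (length(d) == 3) {
    dim(x) <- c(d, 1L)
    list(x = x, squeeze = TRUE)
  } else list(x = x, squeeze = FALSE)
}

#' Global average pooling
#'
#' `z_c = (1 / (H * W)) * sum_ij X_c(i, j)`, per batch element.
#'
#' @param x feature map array `(H, W, C)` or `(H, W, C, N)`.
#' @return Numeric vector of length `C` (single map) or matrix `(C, N)`.
#' @export
#' @examples
#' gap(array(c(1, 3, 2, 4), dim = c(2, 2, 1)))  # 2.5
gap <- function(x) {
  a <- as_chw_n(x)
  d <- dim(a$x)
  m <- matrix(a$x, nrow = d[1] * d[2])
  z <- colMeans(m)
  dim(z) <- c(d[3], d[4])
  if (a$squeeze) as.numeric(z) else z
}

#' Parameters of a channel-attention unit
#'
#' @param C channel count of the feature map the unit attaches to.
#' @param r reduction ratio of the bottleneck gate; must divide `C`
#'   (default 16).
#' @param k 1-D convolution kernel width across channels; odd (default 5).
#' @param variant one of `"cca"`, `"se"`, `"eca"`, `"cbam"`, `"none"`.
#' @param conv_bias include a bias in the 1-D convolution (default TRUE).
#' @param seed integer seed for initialisation.
#' @return Object of class `"attention_params"` holding `W1` (`C/r x C`),
#'   `W2` (`C x C/r`), `conv_kernel` (length `k`), `conv_bias`, and for
#'   CBAM the spatial-gate 7x7 kernel.
#' @export
attention_params <- function(C, r = 16L, k = 5L, variant = "cca",
                             conv_bias = TRUE, seed = 1L) {
  variant <- match.arg(variant, c("cca", "se", "eca", "cbam", "none"))
  if (variant %in% c("cca", "se", "cbam") && C %% r != 0)
    stop("reduction ratio r must divide the channel count C")
  if (k %% 2 == 0) stop("1-D convolution kernel width k must be odd")
  with_seed(derive_seed(seed, paste0("attn-", variant)), {
    Cr <- max(1L, C %/% r)
    out <- list(C = C, r = r, k = k, variant = variant,
                W1 = matrix(rnorm(Cr * C, sd = sqrt(2 / C)), Cr, C),
                W2 = matrix(rnorm(C * Cr, sd = sqrt(1 / Cr)), C, Cr),
                conv_kernel = rnorm(k, sd = sqrt(1 / k)),
                conv_bias = if (conv_bias) 0 else NULL)
    if (variant == "cbam")
      out$spatial_kernel <- array(rnorm(7 * 7 * 2, sd = sqrt(2 / 98)),
                                  dim = c(7, 7, 2, 1))
    class(out) <- "attention_params"
    out
  })
}

#' Bottleneck sigmoid gate
#'
#' `S = sigmoid(W2 relu(W1 z))`: reduce the channel descriptor to `C/r`,
#' apply ReLU, expand back to `C`, squash with the sigmoid.
#'
#' @param z channel descriptor: length-`C` vector or `(C, N)` matrix.
#' @param params an [attention_params()].
#' @return Gate values in `(0, 1)`, same shape as `z`.
#' @export
fc_gate <- function(z, params) {
  zm <- if (is.matrix(z)) z else matrix(z, ncol = 1)
  if (nrow(zm) != params$C) stop("descriptor length does not match C")
  h <- params$W1 %*% zm
  h[h < 0] <- 0
  S <- 1 / (1 + exp(-(params$W2 %*% h)))
  if (is.matrix(z)) S else as.numeric(S)
}

#' Cross-channel 1-D convolution gate
#'
#' `omega = sigmoid(C1D_k(S))`: a length-preserving 1-D convolution across
#' the channel axis with symmetric zero padding `(k - 1) / 2`, then sigmoid.
#'
#' @param S gate vector (length `C`) or `(C, N)` matrix.
#' @param params an [attention_params()].
#' @return Channel weights in `(0, 1)`, same shape as `S`.
#' @export
conv_gate <- function(S, params) {
  sm <- if (is.matrix(S)) S else matrix(S, ncol = 1)
  v <- conv1d_channels(sm, params$conv_kernel,
                       if (is.null(params$conv_bias)) 0 else params$conv_bias)
  w <- 1 / (1 + exp(-v))
  if (is.matrix(S)) w else as.numeric(w)
}

conv1d_channels <- function(sm, kern, bias = 0) {
  C <- nrow(sm); N <- ncol(sm)
  k <- length(kern); p <- (k - 1L) %/% 2L
  if (k %% 2 == 0) stop("kernel width must be odd")
  v <- matrix(bias, C, N)
  for (j in seq_len(k)) {
    off <- j - 1L - p
    src <- seq_len(C) + off
    ok <- src >= 1L & src <= C
    v[ok, ] <- v[ok, ] + kern[j] * sm[src[ok], , drop = FALSE]
  }
  v
}

#' Channel-wise rescale
#'
#' Multiplies every spatial element of channel `c` by `omega_c`.
#'
#' @param x feature map `(H, W, C)` or `(H, W, C, N)`.
#' @param omega channel weights: length-`C` vector or `(C, N)` matrix.
#' @return Rescaled feature map with the shape of `x`.
#' @export
rescale <- function(x, omega) {
  a <- as_chw_n(x)
  d <- dim(a$x)
  if (!is.matrix(omega) && length(omega) != d[3])
    stop("channel weight length does not match feature map channels")
  wm <- if (is.matrix(omega)) omega else matrix(omega, d[3], d[4])
  if (nrow(wm) != d[3] || ncol(wm) != d[4])
    stop("channel weight length does not match feature map channels")
  out <- a$x * array(rep(as.numeric(wm), each = d[1] * d[2]), dim = d)
  if (a$squeeze) { dim(out) <- d[1:3]; out } else out
}

#' Cross-channel attention forward pass
#'
#' `rescale(x, conv_gate(fc_gate(gap(x))))`, computed independently per
#' batch element.
#'
#' @param x feature map `(H, W, C)` or `(H, W, C, N)`.
#' @param params an [attention_params()] with matching `C`.
#' @return Attended feature map, same shape as `x`.
#' @export
cca_forward <- function(x, params) {
  rescale(x, conv_gate(fc_gate(gap(x), params), params))
}

#' @rdname cca_forward
#' @details `se_forward` is the squeeze-and-excitation baseline
#'   (bottleneck gate only); `eca_forward` is the efficient-channel-attention
#'   baseline (1-D convolution gate applied directly to the pooled
#'   descriptor); `cbam_forward` applies a channel gate driven by both
#'   average- and max-pooled descriptors, then a spatial gate from a 7x7
#'   convolution over the channel-wise mean and max maps.
#' @export
se_forward <- function(x, params) {
  rescale(x, fc_gate(gap(x), params))
}

#' @rdname cca_forward
#' @export
eca_forward <- function(x, params) {
  rescale(x, conv_gate(gap(x), params))
}

#' @rdname cca_forward
#' @export
cbam_forward <- function(x, params) {
  a <- as_chw_n(x)
  d <- dim(a$x)
  # channel gate: shared bottleneck MLP on avg- and max-pooled descriptors
  zavg <- gap(a$x)
  m <- matrix(a$x, nrow = d[1] * d[2])
  zmax <- apply(m, 2, max); dim(zmax) <- c(d[3], d[4])
  pre <- function(z) {
    h <- params$W1 %*% z; h[h < 0] <- 0
    params$W2 %*% h
  }
  mc <- 1 / (1 + exp(-(pre(zavg) + pre(zmax))))
  xc <- a$x * array(rep(as.numeric(mc), each = d[1] * d[2]), dim = d)
  # spatial gate: 7x7 conv over [channel-mean; channel-max] maps
  out <- xc
  for (n in seq_len(d[4])) {
    sl <- xc[, , , n, drop = FALSE]
    cm <- apply(sl[, , , 1, drop = FALSE], c(1, 2), mean)
    cx <- apply(sl[, , , 1, drop = FALSE], c(1, 2), max)
    two <- array(c(cm, cx), dim = c(d[1], d[2], 2, 1))
    ms <- conv2d_fwd_cpp(two, params$spatial_kernel, 0, 1L, 3L)
    ms <- 1 / (1 + exp(-ms[, , 1, 1]))
    for (ch in seq_len(d[3])) out[, , ch, n] <- xc[, , ch, n] * ms
  }
  if (a$squeeze) { dim(out) <- d[1:3]; out } else out
}

#' Apply an attention variant to a feature map
#'
#' @param x feature map array.
#' @param params an [attention_params()]; its `variant` field selects the
#'   unit (`"none"` returns `x` unchanged).
#' @return Attended feature map.
#' @export
attention_forward <- function(x, params) {
  switch(params$variant,
         none = x,
         cca = cca_forward(x, params),
         se = se_forward(x, params),
         eca = eca_forward(x, params),
         cbam = cbam_forward(x, params))
}

attention_param_count <- function(params) {
  if (params$variant == "none") return(0L)
  n <- switch(params$variant,
    se = length(params$W1) + length(params$W2),
    eca = length(params$conv_kernel) +
      (if (!is.null(params$conv_bias)) 1L else 0L),
    cca = length(params$W1) + length(params$W2) +
      length(params$conv_kernel) +
      (if (!is.null(params$conv_bias)) 1L else 0L),
    cbam = length(params$W1) + length(params$W2) +
      length(params$spatial_kernel))
  as.integer(n)
}

# ---- autodiff counterparts used inside the trained model -------------------

attention_params_nodes <- function(params) {
  np <- list(W1 = ag_param(params$W1), W2 = ag_param(params$W2),
             kern = ag_param(params$conv_kernel))
  if (!is.null(params$conv_bias)) np$bias <- ag_param(params$conv_bias)
  if (!is.null(params$spatial_kernel)) {
    np$spk <- ag_param(params$spatial_kernel)
    np$spb <- ag_param(0)
  }
  np
}

ag_attention <- function(x, np, variant) {
  if (variant == "none") return(x)
  z <- ag_gap(x)
  if (variant == "se") {
    S <- ag_sigmoid(ag_linear(ag_relu(ag_linear(z, np$W1, NULL)), np$W2, NULL))
    return(ag_rescale(x, S))
  }
  if (variant == "eca") {
    w <- ag_sigmoid(ag_conv1d_channels(z, np$kern, np$bias))
    return(ag_rescale(x, w))
  }
  if (variant == "cca") {
    S <- ag_sigmoid(ag_linear(ag_relu(ag_linear(z, np$W1, NULL)), np$W2, NULL))
    w <- ag_sigmoid(ag_conv1d_channels(S, np$kern, np$bias))
    return(ag_rescale(x, w))
  }
  if (variant == "cbam") {
    zx <- ag_gmp(x)
    pre <- function(zz) ag_linear(ag_relu(ag_linear(zz, np$W1, NULL)),
                                  np$W2, NULL)
    mc <- ag_sigmoid(ag_add(pre(z), pre(zx)))
    xc <- ag_rescale(x, mc)
    two <- ag_channel_meanmax(xc)
    ms <- ag_sigmoid(ag_conv2d(two, np$spk, np$spb, stride = 1L, pad = 3L))
    return(ag_mul_spatial(xc, ms))
  }
  stop("unknown attention variant")
}
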