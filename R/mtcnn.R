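# Three-stage cascaded face detector: a fully convolutional proposal
# network (P-Net, 12x12 receptive field) swept over an image pyramid, a
# refinement network (R-Net, 24x24 crops) and an output network (O-Net,
# 48x48 crops) that also regresses the five facial landmarks.  All three
# nets carry three heads (face/non-face classification, box-offset
# regression, landmark regression) trained jointly under the weighted
# multi-task objective.  Convolutions are 3x3 stride 1; pooling stride 2.

#' Cascade configuration
#'
#' @param min_face_px smallest detectable face size in pixels.
#' @param pyramid_scale_factor per-level pyramid shrink factor in `(0, 1)`.
#' @param score_thresholds length-3 stage acceptance thresholds in `(0, 1)`.
#' @param nms_thresholds length-3 stage NMS IoU thresholds in `(0, 1)`.
#' @param alpha 2x3 matrix (rows: P/R stages, O stage) of task weights
#'   (d, b, m). Defaults to the canonical weighting 1/0.5/0.5 for P and R
#'   and 1/0.5/1 for O.
#' @param crop_margin fractional square expansion per side used when
#'   cropping the final detection for the regression network.
#' @return Object of class `"cascade_config"`.
#' @export
cascade_config <- function(min_face_px = 16L,
                           pyramid_scale_factor = 0.709,
                           score_thresholds = c(0.6, 0.7, 0.7),
                           nms_thresholds = c(0.7, 0.7, 0.7),
                           alpha = rbind(PR = c(1, 0.5, 0.5),
                                         O = c(1, 0.5, 1)),
                           crop_margin = 0.15) {
  stopifnot(length(score_thresholds) == 3, length(nms_thresholds) == 3)
  if (any(score_thresholds <= 0 | score_thresholds >= 1) ||
      any(nms_thresholds <= 0 | nms_thresholds >= 1))
    stop("stage thresholds must lie in (0, 1)")
  if (any(alpha < 0)) stop("task weights alpha must be >= 0")
  if (pyramid_scale_factor <= 0 || pyramid_scale_factor >= 1)
    stop("pyramid_scale_factor must be in (0, 1)")
  structure(list(min_face_px = min_face_px,
                 pyramid_scale_factor = pyramid_scale_factor,
                 score_thresholds = score_thresholds,
                 nms_thresholds = nms_thresholds,
                 alpha = alpha,
                 crop_margin = crop_margin),
            class = "cascade_config")
}

#' Sample frames at a fixed index interval
#'
#' @param video a `labeled_video` or a list of frames.
#' @param target_count desired number of frames, `>= 1`.
#' @return List of frames: `min(target_count, available)` frames taken at
#'   stride `floor(n / target_count)` (at least 1), order preserved.
#' @export
sample_frames <- function(video, target_count) {
  frames <- if (inherits(video, "labeled_video")) video$frames else video
  n <- length(frames)
  if (n < 1) stop("video has no frames")
  if (target_count < 1) stop("target_count must be >= 1")
  stride <- max(1L, n %/% target_count)
  idx <- seq.int(1L, n, by = stride)
  idx <- idx[seq_len(min(target_count, length(idx)))]
  frames[idx]
}

#' Build the image pyramid for the proposal stage
#'
#' Level `i` has scale factor `(12 / min_face_px) * pyramid_scale_factor^i`;
#' the pyramid stops when the scaled short side would fall below 12 px
#' (the proposal network's receptive field).
#'
#' @param frame image array `(H, W, C)`.
#' @param config a [cascade_config()].
#' @return Object of class `"image_pyramid"`: list with `levels` (each:
#'   `scale`, `image`) and `base_dim`. Frames smaller than `min_face_px`
#'   yield an empty pyramid with attribute `too_small = TRUE`.
#' @export
build_image_pyramid <- function(frame, config = cascade_config()) {
  d <- dim(frame)
  out <- structure(list(levels = list(), base_dim = d[1:2]),
                   class = "image_pyramid")
  if (min(d[1:2]) < config$min_face_px) {
    attr(out, "too_small") <- TRUE
    return(out)
  }
  scale <- 12 / config$min_face_px
  while (min(d[1:2]) * scale >= 12) {
    h <- max(1L, as.integer(round(d[1] * scale)))
    w <- max(1L, as.integer(round(d[2] * scale)))
    out$levels[[length(out$levels) + 1]] <-
      list(scale = scale, image = resize_nearest(frame, h, w))
    scale <- scale * config$pyramid_scale_factor
  }
  out
}

# ---- stage networks ---------------------------------------------------------

stage_widths <- function(base, width_mult) pmax(4L, as.integer(round(base * width_mult)))

pnet_new <- function(width_mult = 1, seed = 1L) {
  w <- stage_widths(c(10, 16, 32), width_mult)
  with_seed(derive_seed(seed, "pnet"), {
    p <- list(
      c1 = ag_param(init_conv(3, 3, 3, w[1])), b1 = ag_param(numeric(w[1])),
      c2 = ag_param(init_conv(3, 3, w[1], w[2])), b2 = ag_param(numeric(w[2])),
      c3 = ag_param(init_conv(3, 3, w[2], w[3])), b3 = ag_param(numeric(w[3])),
      hc = ag_param(init_conv(1, 1, w[3], 2)), hcb = ag_param(numeric(2)),
      hb = ag_param(init_conv(1, 1, w[3], 4)), hbb = ag_param(numeric(4)),
      hm = ag_param(init_conv(1, 1, w[3], 10)), hmb = ag_param(numeric(10)))
    list(params = p, widths = w, input = 12L, stride = 2L)
  })
}

pnet_forward <- function(net, x) {
  p <- net$params
  h <- ag_relu(ag_conv2d(x, p$c1, p$b1))
  h <- ag_maxpool2(h)
  h <- ag_relu(ag_conv2d(h, p$c2, p$b2))
  h <- ag_relu(ag_conv2d(h, p$c3, p$b3))
  list(cls = ag_conv2d(h, p$hc, p$hcb),
       box = ag_conv2d(h, p$hb, p$hbb),
       lm = ag_conv2d(h, p$hm, p$hmb))
}

rnet_new <- function(width_mult = 1, seed = 1L) {
  w <- stage_widths(c(28, 48, 64), width_mult)
  fc <- max(16L, as.integer(round(128 * width_mult)))
  with_seed(derive_seed(seed, "rnet"), {
    p <- list(
      c1 = ag_param(init_conv(3, 3, 3, w[1])), b1 = ag_param(numeric(w[1])),
      c2 = ag_param(init_conv(3, 3, w[1], w[2])), b2 = ag_param(numeric(w[2])),
      c3 = ag_param(init_conv(3, 3, w[2], w[3])), b3 = ag_param(numeric(w[3])),
      fw = ag_param(init_linear(fc, 2 * 2 * w[3])), fb = ag_param(numeric(fc)),
      hc = ag_param(init_linear(2, fc)), hcb = ag_param(numeric(2)),
      hb = ag_param(init_linear(4, fc)), hbb = ag_param(numeric(4)),
      hm = ag_param(init_linear(10, fc)), hmb = ag_param(numeric(10)))
    list(params = p, widths = w, fc = fc, input = 24L)
  })
}

rnet_forward <- function(net, x) {
  p <- net$params
  h <- ag_relu(ag_conv2d(x, p$c1, p$b1))          # 22
  h <- ag_maxpool2(h)                             # 11
  h <- ag_relu(ag_conv2d(h, p$c2, p$b2))          # 9
  h <- ag_maxpool2(h)                             # 4
  h <- ag_relu(ag_conv2d(h, p$c3, p$b3))          # 2
  h <- ag_relu(ag_linear(ag_flatten(h), p$fw, p$fb))
  list(cls = ag_linear(h, p$hc, p$hcb),
       box = ag_linear(h, p$hb, p$hbb),
       lm = ag_linear(h, p$hm, p$hmb))
}

onet_new <- function(width_mult = 1, seed = 1L) {
  w <- stage_widths(c(32, 64, 64, 128), width_mult)
  fc <- max(24L, as.integer(round(256 * width_mult)))
  with_seed(derive_seed(seed, "onet"), {
    p <- list(
      c1 = ag_param(init_conv(3, 3, 3, w[1])), b1 = ag_param(numeric(w[1])),
      c2 = ag_param(init_conv(3, 3, w[1], w[2])), b2 = ag_param(numeric(w[2])),
      c3 = ag_param(init_conv(3, 3, w[2], w[3])), b3 = ag_param(numeric(w[3])),
      c4 = ag_param(init_conv(3, 3, w[3], w[4])), b4 = ag_param(numeric(w[4])),
      fw = ag_param(init_linear(fc, 2 * 2 * w[4])), fb = ag_param(numeric(fc)),
      hc = ag_param(init_linear(2, fc)), hcb = ag_param(numeric(2)),
      hb = ag_param(init_linear(4, fc)), hbb = ag_param(numeric(4)),
      hm = ag_param(init_linear(10, fc)), hmb = ag_param(numeric(10)))
    list(params = p, widths = w, fc = fc, input = 48L)
  })
}

onet_forward <- function(net, x) {
  p <- net$params
  h <- ag_relu(ag_conv2d(x, p$c1, p$b1))          # 46
  h <- ag_maxpool2(h)                             # 23
  h <- ag_relu(ag_conv2d(h, p$c2, p$b2))          # 21
  h <- ag_maxpool2(h)                             # 10
  h <- ag_relu(ag_conv2d(h, p$c3, p$b3))          # 8
  h <- ag_maxpool2(h)                             # 4
  h <- ag_relu(ag_conv2d(h, p$c4, p$b4))          # 2
  h <- ag_relu(ag_linear(ag_flatten(h), p$fw, p$fb))
  list(cls = ag_linear(h, p$hc, p$hcb),
       box = ag_linear(h, p$hb, p$hbb),
       lm = ag_linear(h, p$hm, p$hmb))
}

collect_params <- function(p) Filter(function(x) isTRUE(x$param), p)

# ---- stage training ---------------------------------------------------------

patchset_to_arrays <- function(patchset, size) {
  n <- length(patchset$patches)
  X <- array(0, dim = c(size, size, 3, n))
  box <- matrix(0, 4, n); lm <- matrix(0, 10, n)
  cls <- numeric(n)
  for (i in seq_len(n)) {
    p <- patchset$patches[[i]]
    img <- p$image
    if (dim(img)[1] != size) img <- resize_nearest(img, size, size)
    X[, , , i] <- img
    if (!is.null(p$offset)) box[, i] <- p$offset
    if (!is.null(p$landmarks)) lm[, i] <- p$landmarks
    cls[i] <- as.numeric(p$label == "face")
  }
  list(X = X, cls = cls, box = box, lm = lm,
       mask_d = as.numeric(patchset$beta[, "d"]),
       mask_b = as.numeric(patchset$beta[, "b"]),
       mask_m = as.numeric(patchset$beta[, "m"]))
}

train_stage <- function(net, forward, data, alpha, epochs, batch_size, lr,
                        seed) {
  params <- collect_params(net$params)
  opt <- adam_new(params, lr = lr)
  n <- length(data$cls)
  history <- numeric(epochs)
  with_seed(derive_seed(seed, "stage-train"), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      tot <- 0; nb <- 0
      for (start in seq(1, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1, n)]
        if (length(idx) < 2) next
        xb <- ag_const(data$X[, , , idx, drop = FALSE])
        loss_val <- ag_with_tape({
          out <- forward(net, xb)
          cls <- ag_flatten_any(out$cls)
          box <- ag_flatten_any(out$box)
          lm <- ag_flatten_any(out$lm)
          terms <- list(ag_scale(ag_softmax_ce(cls, data$cls[idx],
                                               data$mask_d[idx]), alpha[1]))
          if (alpha[2] > 0 && sum(data$mask_b[idx]) > 0)
            terms <- c(terms, list(ag_scale(
              ag_mse(box, data$box[, idx, drop = FALSE], data$mask_b[idx]),
              alpha[2])))
          if (alpha[3] > 0 && sum(data$mask_m[idx]) > 0)
            terms <- c(terms, list(ag_scale(
              ag_mse(lm, data$lm[, idx, drop = FALSE], data$mask_m[idx]),
              alpha[3])))
          loss <- ag_sum_nodes(terms)
          ag_zero_grads(params)
          ag_backward(loss)
          loss$value
        })
        if (!is.finite(loss_val)) stop("stage training diverged")
        adam_step(opt)
        tot <- tot + loss_val; nb <- nb + 1
      }
      history[ep] <- tot / max(nb, 1)
    }
  })
  history
}

# flatten a conv-map head (1,1,K,N) or matrix head (K,N) to (K,N)
ag_flatten_any <- function(x) {
  if (length(dim(x$value)) == 4) ag_flatten(x) else x
}

#' Train the face-detection cascade on synthetic patches
#'
#' Generates an annotated patch set with [make_detection_patches()] (at
#' 48 px, downsampled to each stage's input size) and trains P-Net, R-Net
#' and O-Net jointly on the classification, box and landmark tasks under
#' the weighted multi-task objective.
#'
#' @param n_face,n_nonface,n_part patch counts for training.
#' @param config a [cascade_config()].
#' @param width_mult width multiplier for the stage networks (1 =
#'   canonical widths).
#' @param epochs training epochs per stage.
#' @param batch_size minibatch size.
#' @param lr Adam learning rate.
#' @param seed integer seed controlling patch generation, initialisation
#'   and shuffling.
#' @return Object of class `"mtcnn"` with the three stage nets, the
#'   config, and per-stage loss histories. Use [predict.mtcnn()] or
#'   [run_cascade()] to detect faces.
#' @export
mtcnn_fit <- function(n_face = 600, n_nonface = 900, n_part = 500,
                      config = cascade_config(), width_mult = 0.5,
                      epochs = 12, batch_size = 64, lr = 1e-3, seed = 1L) {
  patches <- make_detection_patches(n_face, n_nonface, n_part,
                                    patch_size = 48L,
                                    seed = derive_seed(seed, "patchset"))
  nets <- list(p = pnet_new(width_mult, seed),
               r = rnet_new(width_mult, seed),
               o = onet_new(width_mult, seed))
  hist <- list(
    p = train_stage(nets$p, pnet_forward, patchset_to_arrays(patches, 12L),
                    config$alpha["PR", ], epochs, batch_size, lr,
                    derive_seed(seed, "p")),
    r = train_stage(nets$r, rnet_forward, patchset_to_arrays(patches, 24L),
                    config$alpha["PR", ], epochs, batch_size, lr,
                    derive_seed(seed, "r")),
    o = train_stage(nets$o, onet_forward, patchset_to_arrays(patches, 48L),
                    config$alpha["O", ], epochs, batch_size, lr,
                    derive_seed(seed, "o")))
  structure(list(nets = nets, config = config, history = hist,
                 width_mult = width_mult, seed = seed),
            class = "mtcnn")
}

#' @export
print.mtcnn <- function(x, ...) {
  cat("Cascaded face detector (P-Net / R-Net / O-Net)\n")
  cat(sprintf("  width multiplier: %.2f\n", x$width_mult))
  cat(sprintf("  final stage losses: P %.4f  R %.4f  O %.4f\n",
              tail_val(x$history$p), tail_val(x$history$r),
              tail_val(x$history$o)))
  invisible(x)
}

tail_val <- function(v) v[length(v)]

# ---- inference --------------------------------------------------------------

softmax2_p <- function(z) {
  # z: (..., 2, N) logits as array with channel dim 3 or matrix (2, N)
  if (is.matrix(z)) {
    zm <- pmax(z[1, ], z[2, ])
    e1 <- exp(z[1, ] - zm); e2 <- exp(z[2, ] - zm)
    e2 / (e1 + e2)
  } else {
    zm <- pmax(z[, , 1, , drop = FALSE], z[, , 2, , drop = FALSE])
    e1 <- exp(z[, , 1, , drop = FALSE] - zm)
    e2 <- exp(z[, , 2, , drop = FALSE] - zm)
    (e2 / (e1 + e2))[, , 1, ]
  }
}

# run a stage net forward without recording gradients
stage_infer <- function(net, forward, X) {
  out <- forward(net, ag_const(X))
  lapply(out, function(n) n$value)
}

crop_square_for_stage <- function(frame, box, size) {
  d <- dim(frame)
  sq <- square_box(box, margin = 0, img_w = d[2], img_h = d[1])
  x1 <- max(0, floor(sq[1])); y1 <- max(0, floor(sq[2]))
  x2 <- min(d[2], ceiling(sq[3])); y2 <- min(d[1], ceiling(sq[4]))
  if (x2 - x1 < 2 || y2 - y1 < 2) return(NULL)
  crop <- frame[(y1 + 1):y2, (x1 + 1):x2, , drop = FALSE]
  list(image = resize_nearest(crop, size, size),
       box = c(x1, y1, x2, y2))
}

#' Run the full detection cascade on one frame
#'
#' P-Net sweeps each pyramid level fully convolutionally to produce
#' candidates with box regression, filtered by per-level then global NMS;
#' R-Net rescores and refines 24x24 crops; O-Net produces the final boxes
#' with the five facial landmarks.
#'
#' @param frame image array `(H, W, 3)` in `[0, 1]`.
#' @param detector an `"mtcnn"` object from [mtcnn_fit()].
#' @param config optional [cascade_config()] overriding the detector's.
#' @return List of detections, each a list with `box` (quadruple), `score`
#'   in `[0, 1]` and `landmarks` (length 10). Empty list if nothing found.
#' @export
run_cascade <- function(frame, detector, config = NULL) {
  cfg <- if (is.null(config)) detector$config else config
  pyr <- build_image_pyramid(frame, cfg)
  if (length(pyr$levels) == 0) return(list())
  th <- cfg$score_thresholds; nt <- cfg$nms_thresholds
  cand_boxes <- NULL; cand_scores <- NULL

  for (lev in pyr$levels) {
    d <- dim(lev$image)
    if (min(d[1:2]) < 12) next
    X <- array(lev$image, dim = c(d[1], d[2], 3, 1))
    out <- stage_infer(detector$nets$p, pnet_forward, X)
    pmap <- softmax2_p(out$cls)           # (Ho, Wo)
    if (is.null(dim(pmap))) dim(pmap) <- dim(out$cls)[1:2]
    hits <- which(pmap >= th[1], arr.ind = TRUE)
    if (nrow(hits) == 0) next
    boxes <- matrix(0, nrow(hits), 4)
    scores <- numeric(nrow(hits))
    for (r in seq_len(nrow(hits))) {
      i <- hits[r, 1]; j <- hits[r, 2]
      x1 <- (j - 1) * 2 / lev$scale
      y1 <- (i - 1) * 2 / lev$scale
      side <- 12 / lev$scale
      off <- out$box[i, j, , 1]
      boxes[r, ] <- c(x1, y1, x1 + side, y1 + side) +
        off * side
      scores[r] <- pmap[i, j]
    }
    ok <- boxes[, 3] > boxes[, 1] & boxes[, 4] > boxes[, 2]
    boxes <- boxes[ok, , drop = FALSE]; scores <- scores[ok]
    if (nrow(boxes) == 0) next
    keep <- nms(boxes, scores, nt[1])
    cand_boxes <- rbind(cand_boxes, boxes[keep, , drop = FALSE])
    cand_scores <- c(cand_scores, scores[keep])
  }
  if (is.null(cand_boxes) || nrow(cand_boxes) == 0) return(list())
  keep <- nms(cand_boxes, cand_scores, nt[1])
  cand_boxes <- cand_boxes[keep, , drop = FALSE]

  refine <- function(net, forward, size, boxes, thr, nms_thr, want_lm,
                     nms_method = "union") {
    crops <- list()
    for (r in seq_len(nrow(boxes))) {
      cp <- crop_square_for_stage(frame, boxes[r, ], size)
      if (!is.null(cp)) { crops[[length(crops) + 1]] <- cp }
    }
    if (length(crops) == 0) return(list(boxes = NULL))
    X <- array(0, dim = c(size, size, 3, length(crops)))
    for (r in seq_along(crops)) X[, , , r] <- crops[[r]]$image
    out <- stage_infer(net, forward, X)
    cls <- if (length(dim(out$cls)) == 4) {
      matrix(out$cls, nrow = 2)
    } else out$cls
    p <- softmax2_p(cls)
    ok <- which(p >= thr)
    if (length(ok) == 0) return(list(boxes = NULL))
    rb <- matrix(0, length(ok), 4); rs <- numeric(length(ok))
    rl <- matrix(0, length(ok), 10)
    for (q in seq_along(ok)) {
      r <- ok[q]
      cb <- crops[[r]]$box
      side <- cb[3] - cb[1]
      off <- if (length(dim(out$box)) == 4) out$box[1, 1, , r] else out$box[, r]
      rb[q, ] <- cb + off * side
      rs[q] <- p[r]
      if (want_lm) {
        lmo <- if (length(dim(out$lm)) == 4) out$lm[1, 1, , r] else out$lm[, r]
        rl[q, ] <- rep(cb[1:2], 5) + lmo * side
      }
    }
    okb <- rb[, 3] > rb[, 1] & rb[, 4] > rb[, 2]
    rb <- rb[okb, , drop = FALSE]; rs <- rs[okb]; rl <- rl[okb, , drop = FALSE]
    if (nrow(rb) == 0) return(list(boxes = NULL))
    keep <- nms(rb, rs, nms_thr, method = nms_method)
    list(boxes = rb[keep, , drop = FALSE], scores = rs[keep],
         lm = rl[keep, , drop = FALSE])
  }

  r2 <- refine(detector$nets$r, rnet_forward, 24L, cand_boxes, th[2], nt[2],
               FALSE)
  if (is.null(r2$boxes)) return(list())
  # min-mode overlap at the output stage suppresses nested duplicate
  # windows left by imperfect box regression (canonical cascade practice)
  r3 <- refine(detector$nets$o, onet_forward, 48L, r2$boxes, th[3], nt[3],
               TRUE, nms_method = "min")
  if (is.null(r3$boxes)) return(list())
  lapply(seq_len(nrow(r3$boxes)), function(i)
    list(box = r3$boxes[i, ], score = r3$scores[i],
         landmarks = r3$lm[i, ]))
}

#' @describeIn mtcnn_fit Detect faces in a frame (or list of frames).
#' @param object an `"mtcnn"` detector.
#' @param newdata an image array `(H, W, 3)`, a `synthetic_frame`, or a
#'   list of either.
#' @param ... unused.
#' @export
predict.mtcnn <- function(object, newdata, ...) {
  as_img <- function(f) if (inherits(f, "synthetic_frame")) f$image else f
  if (is.list(newdata) && !inherits(newdata, "synthetic_frame") &&
      is.null(dim(newdata)))
    lapply(newdata, function(f) run_cascade(as_img(f), object))
  else run_cascade(as_img(newdata), object)
}
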