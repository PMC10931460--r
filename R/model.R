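# End-to-end severity regression model: residual backbone -> pyramid splice
# -> channel attention -> global average pooling -> one fully connected
# unit producing a single BDI-II score per image.  Frames inherit their
# video's score; training minimises frame-level mean squared error with
# Adam, and the checkpoint with the lowest validation loss across epochs is
# kept.

#' Training configuration
#'
#' Defaults follow the reference optimisation schedule: Adam with initial
#' learning rate 0.001 and decay rate 0.0001, batches of 128 frames, 100
#' epochs with best-validation checkpointing, and a 3:1 train:validation
#' split at the video level.
#'
#' @param learning_rate Adam learning rate.
#' @param weight_decay L2 decay rate.
#' @param batch_size frames per minibatch.
#' @param epochs number of passes ("training times"); the checkpoint with
#'   the smallest validation loss among them is kept.
#' @param train_val_ratio length-2 ratio of training to validation videos.
#' @param seed integer seed.
#' @param aggregate frame-to-video aggregation, `"mean"` (default) or
#'   `"median"`.
#' @return Object of class `"train_config"`.
#' @export
train_config <- function(learning_rate = 0.001, weight_decay = 0.0001,
                         batch_size = 128L, epochs = 100L,
                         train_val_ratio = c(3, 1), seed = 1L,
                         aggregate = c("mean", "median")) {
  if (learning_rate <= 0 || weight_decay < 0 || batch_size < 1 || epochs < 1)
    stop("invalid training configuration")
  structure(list(learning_rate = learning_rate,
                 weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 train_val_ratio = train_val_ratio,
                 seed = as.integer(seed),
                 aggregate = match.arg(aggregate)),
            class = "train_config")
}

#' Assemble the regression network
#'
#' Backbone, pyramid splice, one attention unit on the spliced map
#' (following the post-pyramid placement of the ablation variants), global
#' average pooling and a single fully connected layer giving one real
#' score per image.
#'
#' @param backbone_cfg a [backbone_config()].
#' @param attention_variant one of `"none"`, `"se"`, `"eca"`, `"cbam"`,
#'   `"cca"`.
#' @param input_size input image side (divisible by 32; default 128).
#' @param r,k attention hyperparameters (reduction ratio, 1-D kernel
#'   width).
#' @param seed initialisation seed.
#' @return Object of class `"ccanet_model"` with a `forward` closure and
#'   the flat parameter list.
#' @export
build_model <- function(backbone_cfg = backbone_config(),
                        attention_variant = "cca", input_size = 128L,
                        r = 16L, k = 5L, seed = 1L) {
  variant <- match.arg(attention_variant,
                       c("none", "se", "eca", "cbam", "cca"))
  if (input_size %% 32 != 0) stop("input_size must be divisible by 32")
  bb <- backbone_new(backbone_cfg, seed)
  fpn <- fpn_new(backbone_cfg$out_channels, backbone_cfg$fpn_channels, seed)
  fused_c <- 4L * backbone_cfg$fpn_channels
  attn_ref <- if (variant == "none") NULL else
    attention_params(fused_c, r = r, k = k, variant = variant,
                     seed = derive_seed(seed, "attn"))
  attn <- if (is.null(attn_ref)) NULL else attention_params_nodes(attn_ref)
  head <- with_seed(derive_seed(seed, "head"), list(
    W = ag_param(init_linear(1, fused_c)), b = ag_param(numeric(1))))
  model <- list(backbone = bb, fpn = fpn, attn = attn, head = head,
                variant = variant, input_size = as.integer(input_size),
                backbone_cfg = backbone_cfg, r = r, k = k, seed = seed)
  class(model) <- "ccanet_model"
  model
}

model_forward_nodes <- function(model, x, training = TRUE) {
  cs <- backbone_forward_nodes(model$backbone, x, training)
  p <- fpn_topdown_nodes(model$fpn, cs, training)
  fused <- fpn_splice_nodes(model$fpn, p, training)
  att <- if (is.null(model$attn)) fused
         else ag_attention(fused, model$attn, model$variant)
  z <- ag_gap(att)
  ag_linear(z, model$head$W, model$head$b)       # (1, N)
}

model_params <- function(model) {
  out <- list()
  walk <- function(x) {
    if (is.environment(x)) {
      if (isTRUE(x$param)) out[[length(out) + 1]] <<- x
    } else if (is.list(x)) for (el in x) walk(el)
  }
  walk(model$backbone); walk(model$fpn); walk(model$attn); walk(model$head)
  out
}

#' Number of trainable parameters in a model
#' @param model a `"ccanet_model"`.
#' @return Integer count.
#' @export
model_param_count <- function(model) {
  sum(vapply(model_params(model), function(p) length(p$value), numeric(1)))
}

#' Predict frame scores for a batch of images
#'
#' @param model a `"ccanet_model"`.
#' @param images array `(S, S, 3, N)`; normalisation constants `norm`
#'   (list of per-channel `mean`, `sd`) are applied when given.
#' @param norm optional normalisation constants.
#' @return Numeric vector of `N` raw scores.
#' @export
model_predict_frames <- function(model, images, norm = NULL) {
  if (!is.null(norm)) images <- normalize_frames(images, norm)
  out <- model_forward_nodes(model, ag_const(images), training = FALSE)
  as.numeric(out$value)
}

normalize_frames <- function(x, norm) {
  d <- dim(x)
  for (ch in 1:3) x[, , ch, ] <- (x[, , ch, ] - norm$mean[ch]) / norm$sd[ch]
  x
}

#' Split videos into training and validation sets
#'
#' Video-level split (no video contributes frames to both sides) at the
#' given ratio, seeded.
#'
#' @param videos list of labelled videos (or anything indexable).
#' @param ratio length-2 train:validation ratio (default 3:1).
#' @param seed integer seed.
#' @return List with integer index vectors `train` and `val`.
#' @export
split_dataset <- function(videos, ratio = c(3, 1), seed = 1L) {
  n <- length(videos)
  if (n < 4) stop("need at least 4 videos for a 3:1 split")
  n_train <- round(n * ratio[1] / sum(ratio))
  n_train <- min(max(n_train, 1L), n - 1L)
  idx <- with_seed(derive_seed(seed, "split"), sample.int(n))
  list(train = sort(idx[seq_len(n_train)]),
       val = sort(idx[(n_train + 1):n]))
}

# Assemble (S,S,3,N) frame tensor + labels from videos, cropping with the
# ground-truth boxes (synthetic data) or a provided detector.
frames_tensor <- function(videos, input_size, detector = NULL,
                          margin = 0.15) {
  imgs <- list(); labs <- numeric(0); vid <- character(0)
  for (v in videos) {
    for (fr in v$frames) {
      box <- if (!is.null(detector)) {
        det <- run_cascade(fr$image, detector)
        if (length(det) == 0) next
        det[[which.max(vapply(det, function(d) d$score, numeric(1)))]]$box
      } else fr$true_box
      cr <- crop_and_resize(fr$image, box, out_size = input_size,
                            margin = margin)
      imgs[[length(imgs) + 1]] <- cr$image
      labs <- c(labs, v$bdi_score)
      vid <- c(vid, v$video_id)
    }
  }
  if (length(imgs) == 0) stop("no usable frames (all detections empty)")
  X <- array(0, dim = c(input_size, input_size, 3, length(imgs)))
  for (i in seq_along(imgs)) X[, , , i] <- imgs[[i]]
  list(X = X, y = labs, video_id = vid)
}

#' Fit a cross-channel attention severity regression model
#'
#' The main fitting function: crops each frame to the network input size
#' (using ground-truth boxes for synthetic data, or a fitted [mtcnn_fit()]
#' detector), splits videos 3:1 into training and validation, normalises
#' inputs with constants computed on the training split, and minimises
#' frame-level mean squared error against the video's BDI-II label with
#' Adam. The parameter state with the smallest validation loss across
#' epochs is restored into the returned model.
#'
#' @param videos list of labelled videos (e.g. from
#'   [make_regression_dataset()]).
#' @param config a [train_config()].
#' @param backbone_cfg a [backbone_config()].
#' @param attention_variant attention unit for the spliced map.
#' @param input_size network input side (divisible by 32).
#' @param detector optional `"mtcnn"` detector; ground-truth boxes are
#'   used when absent.
#' @param verbose print per-epoch losses.
#' @return Object of class `"ccanet"`: the fitted model, training history
#'   (`data.frame` epoch/train_loss/val_loss), the split, normalisation
#'   constants, and validation predictions.
#' @export
ccanet <- function(videos, config = train_config(),
                   backbone_cfg = backbone_config(),
                   attention_variant = "cca", input_size = 128L,
                   detector = NULL, verbose = FALSE) {
  if (inherits(videos, "labeled_video")) videos <- list(videos)
  if (!is.null(videos$videos)) videos <- videos$videos
  sp <- split_dataset(videos, config$train_val_ratio, config$seed)
  tr <- frames_tensor(videos[sp$train], input_size, detector)
  va <- frames_tensor(videos[sp$val], input_size, detector)
  norm <- list(mean = vapply(1:3, function(ch) mean(tr$X[, , ch, ]),
                             numeric(1)),
               sd = vapply(1:3, function(ch)
                 max(sd(tr$X[, , ch, ]), 1e-6), numeric(1)))
  tr$X <- normalize_frames(tr$X, norm)
  va$X <- normalize_frames(va$X, norm)

  model <- build_model(backbone_cfg, attention_variant, input_size,
                       seed = derive_seed(config$seed, "init"))
  params <- model_params(model)
  opt <- adam_new(params, lr = config$learning_rate,
                  weight_decay = config$weight_decay)
  n <- length(tr$y)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0))
  best <- list(val = Inf, values = NULL)
  with_seed(derive_seed(config$seed, "shuffle"), {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      tot <- 0; nb <- 0
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1, n)]
        if (length(idx) < 2) next
        xb <- ag_const(tr$X[, , , idx, drop = FALSE])
        lv <- ag_with_tape({
          pred <- model_forward_nodes(model, xb, training = TRUE)
          loss <- ag_mse(pred, matrix(tr$y[idx], nrow = 1))
          ag_zero_grads(params)
          ag_backward(loss)
          loss$value
        })
        if (!is.finite(lv))
          stop("training diverged (non-finite loss) at epoch ", ep)
        adam_step(opt)
        tot <- tot + lv; nb <- nb + 1
      }
      val_pred <- predict_frames_batched(model, va$X)
      val_loss <- mean((val_pred - va$y)^2)
      hist <- rbind(hist, data.frame(epoch = ep, train_loss = tot / max(nb, 1),
                                     val_loss = val_loss))
      if (verbose)
        message(sprintf("epoch %d  train %.3f  val %.3f", ep,
                        tot / max(nb, 1), val_loss))
      if (val_loss < best$val) {
        best$val <- val_loss
        best$values <- lapply(params, function(p) p$value)
      }
    }
  })
  if (!is.null(best$values))
    for (i in seq_along(params)) params[[i]]$value <- best$values[[i]]

  val_pred <- predict_frames_batched(model, va$X)
  val_records <- aggregate_video_scores(va$video_id, val_pred, va$y,
                                        config$aggregate)
  out <- list(model = model, history = hist, split = sp, norm = norm,
              config = config, backbone_cfg = backbone_cfg,
              attention_variant = attention_variant,
              input_size = as.integer(input_size),
              best_val_loss = best$val,
              val_records = val_records,
              val_metrics = metrics_report(val_records))
  class(out) <- "ccanet"
  out
}

predict_frames_batched <- function(model, X, batch = 128L) {
  n <- dim(X)[4]
  out <- numeric(n)
  for (start in seq(1, n, by = batch)) {
    idx <- start:min(start + batch - 1, n)
    pred <- model_forward_nodes(model,
                                ag_const(X[, , , idx, drop = FALSE]),
                                training = FALSE)
    out[idx] <- as.numeric(pred$value)
  }
  out
}

aggregate_video_scores <- function(video_id, frame_scores, frame_labels,
                                   aggregate = "mean") {
  agg <- if (aggregate == "median") median else mean
  ids <- unique(video_id)
  do.call(rbind, lapply(ids, function(id) {
    m <- video_id == id
    data.frame(video_id = id,
               true_score = frame_labels[m][1],
               video_score = pmin(pmax(agg(frame_scores[m]), 0), 63))
  }))
}

#' Per-video prediction record
#'
#' Scores every frame with the model and aggregates to one video score
#' (arithmetic mean by default, median by config), clamped to `[0, 63]`
#' for reporting.
#'
#' @param fit a fitted `"ccanet"` object.
#' @param video a `labeled_video`.
#' @return List with `video_id`, `frame_scores`, `video_score` and
#'   `true_score`.
#' @export
predict_video <- function(fit, video) {
  if (length(video$frames) < 1) stop("video has no frames")
  fx <- frames_tensor(list(video), fit$input_size)
  fx$X <- normalize_frames(fx$X, fit$norm)
  fs <- predict_frames_batched(fit$model, fx$X)
  agg <- if (fit$config$aggregate == "median") median else mean
  list(video_id = video$video_id, frame_scores = fs,
       video_score = pmin(pmax(agg(fs), 0), 63),
       true_score = video$bdi_score)
}

#' @export
predict.ccanet <- function(object, newdata, ...) {
  if (inherits(newdata, "labeled_video"))
    return(predict_video(object, newdata))
  if (!is.null(newdata$videos)) newdata <- newdata$videos
  recs <- lapply(newdata, function(v) predict_video(object, v))
  metrics_report(recs)
}

#' @export
print.ccanet <- function(x, ...) {
  cat("Cross-channel attention severity regression model\n")
  cat(sprintf("  attention: %s   input: %dx%d   parameters: %d\n",
              x$attention_variant, x$input_size, x$input_size,
              model_param_count(x$model)))
  cat(sprintf("  epochs: %d   best validation MSE: %.4f\n",
              nrow(x$history), x$best_val_loss))
  invisible(x)
}

#' @export
summary.ccanet <- function(object, ...) {
  cat("Call: ccanet fit\n")
  print(object)
  cat("\nValidation metrics (video level):\n")
  print(object$val_metrics)
  cat("\nTraining history (last 5 epochs):\n")
  print(utils::tail(object$history, 5), row.names = FALSE)
  invisible(object)
}

#' @export
plot.ccanet <- function(x, ...) {
  plot(x$history$epoch, x$history$train_loss, type = "l",
       xlab = "epoch", ylab = "MSE loss", col = "steelblue",
       ylim = range(c(x$history$train_loss, x$history$val_loss)), ...)
  graphics::lines(x$history$epoch, x$history$val_loss, col = "firebrick")
  graphics::legend("topright", legend = c("train", "validation"),
                   col = c("steelblue", "firebrick"), lty = 1, bty = "n")
  invisible(x)
}

#' @export
residuals.ccanet <- function(object, ...) {
  r <- object$val_records
  stats::setNames(r$video_score - r$true_score, r$video_id)
}
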