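# Reading / writing datasets, detections and model checkpoints.

#' Read a frame-directory dataset written by the synthesiser
#'
#' Expects per-video subdirectories of PNG frames plus `labels.csv`
#' (`video_id,bdi_score`) and optionally `ground_truth.csv` with boxes and
#' landmarks.
#'
#' @param dir dataset directory.
#' @return List with `videos` (list of `labeled_video`) and `labels`.
#' @export
read_dataset <- function(dir) {
  labfile <- file.path(dir, "labels.csv")
  if (!file.exists(labfile)) stop("missing labels.csv in ", dir)
  labels <- read.csv(labfile, stringsAsFactors = FALSE)
  gtfile <- file.path(dir, "ground_truth.csv")
  gt <- if (file.exists(gtfile)) read.csv(gtfile) else NULL
  videos <- lapply(seq_len(nrow(labels)), function(i) {
    vid <- labels$video_id[i]
    files <- sort(list.files(file.path(dir, vid), pattern = "\\.png$",
                             full.names = TRUE))
    frames <- lapply(seq_along(files), function(j) {
      img <- png::readPNG(files[j])
      if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
      fr <- list(image = img[, , 1:3, drop = FALSE], true_box = NULL,
                 true_landmarks = NULL, severity = labels$bdi_score[i])
      if (!is.null(gt)) {
        row <- gt[gt$video_id == vid & gt$frame_idx == j - 1L, ]
        if (nrow(row) == 1) {
          fr$true_box <- as.numeric(row[c("x1", "y1", "x2", "y2")])
          fr$true_landmarks <- as.numeric(
            row[paste0("lm", rep(1:5, each = 2), c("x", "y"))])
        }
      }
      class(fr) <- "synthetic_frame"
      fr
    })
    structure(list(video_id = vid, frames = frames,
                   bdi_score = labels$bdi_score[i]),
              class = "labeled_video")
  })
  list(videos = videos, labels = labels)
}

#' Write per-frame detections as CSV
#'
#' Columns: `frame_idx,score,x1,y1,x2,y2,lm1x..lm5y` (0-based
#' inclusive-exclusive box coordinates).
#'
#' @param detections list (one element per frame) of detection lists as
#'   returned by [run_cascade()].
#' @param path output CSV path.
#' @export
write_detections_csv <- function(detections, path) {
  rows <- list()
  for (i in seq_along(detections)) {
    for (d in detections[[i]]) {
      rows[[length(rows) + 1]] <- data.frame(
        frame_idx = i - 1L, score = d$score,
        x1 = d$box[1], y1 = d$box[2], x2 = d$box[3], y2 = d$box[4],
        t(stats::setNames(d$landmarks,
            paste0("lm", rep(1:5, each = 2), c("x", "y")))))
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(frame_idx = integer(0), score = numeric(0),
               x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
               y2 = numeric(0))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# ---- checkpoints ------------------------------------------------------------

# Deterministic traversal collecting parameter nodes and batch-norm states.
collect_states <- function(x) {
  out <- list()
  walk <- function(el) {
    if (is.environment(el)) {
      if (!is.null(el$mean)) out[[length(out) + 1]] <<- el
    } else if (is.list(el)) for (e in el) walk(e)
  }
  walk(x)
  out
}

#' Save a fitted model or detector to a checkpoint file
#'
#' The checkpoint is a single serialised file with a format version tag,
#' the architecture configuration, normalisation constants and all
#' parameter values, sufficient to rebuild the object with
#' [load_checkpoint()].
#'
#' @param object a `"ccanet"` fit or an `"mtcnn"` detector.
#' @param path output file path.
#' @export
save_checkpoint <- function(object, path) {
  if (inherits(object, "ccanet")) {
    ck <- list(format = "ccanet-checkpoint-v1", kind = "ccanet",
               backbone_cfg = object$backbone_cfg,
               attention_variant = object$attention_variant,
               input_size = object$input_size,
               model_seed = object$model$seed,
               r = object$model$r, k = object$model$k,
               norm = object$norm, config = object$config,
               history = object$history,
               best_val_loss = object$best_val_loss,
               params = lapply(model_params(object$model),
                               function(p) p$value),
               bn = lapply(collect_states(object$model$backbone),
                           function(s) list(mean = s$mean, var = s$var)))
  } else if (inherits(object, "mtcnn")) {
    ck <- list(format = "ccanet-checkpoint-v1", kind = "mtcnn",
               config = object$config, width_mult = object$width_mult,
               seed = object$seed, history = object$history,
               params = lapply(object$nets, function(net)
                 lapply(collect_params(net$params), function(p) p$value)))
  } else stop("unsupported object for checkpointing")
  saveRDS(ck, path)
  invisible(path)
}

#' Load a checkpoint written by [save_checkpoint()]
#' @param path checkpoint file.
#' @return The rebuilt `"ccanet"` or `"mtcnn"` object (a `"ccanet"` fit is
#'   rebuilt for prediction: history and metrics are restored, the split is
#'   not).
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "ccanet-checkpoint-v1"))
    stop("unrecognised checkpoint format")
  if (ck$kind == "mtcnn") {
    det <- structure(list(
      nets = list(p = pnet_new(ck$width_mult, ck$seed),
                  r = rnet_new(ck$width_mult, ck$seed),
                  o = onet_new(ck$width_mult, ck$seed)),
      config = ck$config, history = ck$history,
      width_mult = ck$width_mult, seed = ck$seed), class = "mtcnn")
    for (nm in names(det$nets)) {
      ps <- collect_params(det$nets[[nm]]$params)
      for (i in seq_along(ps)) ps[[i]]$value <- ck$params[[nm]][[i]]
    }
    return(det)
  }
  model <- build_model(ck$backbone_cfg, ck$attention_variant,
                       ck$input_size, r = ck$r, k = ck$k,
                       seed = ck$model_seed)
  ps <- model_params(model)
  for (i in seq_along(ps)) ps[[i]]$value <- ck$params[[i]]
  sts <- collect_states(model$backbone)
  for (i in seq_along(sts)) {
    sts[[i]]$mean <- ck$bn[[i]]$mean
    sts[[i]]$var <- ck$bn[[i]]$var
  }
  out <- list(model = model, history = ck$history, split = NULL,
              norm = ck$norm, config = ck$config,
              backbone_cfg = ck$backbone_cfg,
              attention_variant = ck$attention_variant,
              input_size = ck$input_size,
              best_val_loss = ck$best_val_loss,
              val_records = NULL, val_metrics = NULL)
  class(out) <- "ccanet"
  out
}
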