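# Ablation harness: trains the attention variants under identical seed and
# split and tabulates per-video RMSE / MAE.

#' Run the attention ablation
#'
#' Trains one model per requested variant under identical seed, split and
#' optimisation settings and reports validation RMSE/MAE per variant,
#' mirroring the six-row comparison (FPN alone, FPN+SE, FPN+ECA, FPN+CBAM,
#' and the cross-channel attention model at both depths when requested).
#'
#' @param videos list of labelled videos.
#' @param variants character vector of attention variants (subset of
#'   `"none"`, `"se"`, `"eca"`, `"cbam"`, `"cca"`).
#' @param config a [train_config()].
#' @param backbone_cfg a [backbone_config()].
#' @param input_size network input side.
#' @param verbose print progress.
#' @return Object of class `"ablation_result"`: data.frame with columns
#'   `model`, `rmse`, `mae` plus the per-variant fits in
#'   `attr(, "fits")`. A variant whose training fails is recorded with NA
#'   metrics and the harness continues.
#' @export
run_ablation <- function(videos,
                         variants = c("none", "se", "eca", "cbam", "cca"),
                         config = train_config(),
                         backbone_cfg = backbone_config(width_mult = 0.125),
                         input_size = 32L, verbose = FALSE) {
  if (length(variants) < 1) stop("need at least one variant")
  label <- function(v) if (v == "none") "FPN" else
    paste0("FPN+", toupper(v))
  rows <- list(); fits <- list()
  for (v in variants) {
    res <- tryCatch(
      ccanet(videos, config = config, backbone_cfg = backbone_cfg,
             attention_variant = v, input_size = input_size,
             verbose = verbose),
      error = function(e) e)
    if (inherits(res, "error")) {
      rows[[v]] <- data.frame(model = label(v), rmse = NA_real_,
                              mae = NA_real_,
                              stringsAsFactors = FALSE)
      warning("variant ", v, " failed: ", conditionMessage(res))
    } else {
      m <- res$val_metrics
      rows[[v]] <- data.frame(model = label(v), rmse = m$rmse, mae = m$mae,
                              stringsAsFactors = FALSE)
      fits[[v]] <- res
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("ablation_result", "data.frame")
  attr(out, "fits") <- fits
  out
}

#' @export
print.ablation_result <- function(x, ...) {
  cat("Attention ablation (validation, video level)\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write an ablation table as CSV (Models, RMSE, MAE)
#' @param x an `"ablation_result"`.
#' @param path output CSV path.
#' @export
write_ablation_csv <- function(x, path) {
  df <- data.frame(Models = x$model, RMSE = x$rmse, MAE = x$mae)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
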