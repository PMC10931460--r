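# Evaluation metrics and BDI-II severity binning.

#' Root-mean-square error
#' @param y true BDI-II scores.
#' @param yhat predicted scores.
#' @return `sqrt(mean((y - yhat)^2))`.
#' @export
rmse <- function(y, yhat) {
  if (length(y) == 0 || length(y) != length(yhat))
    stop("y and yhat must be non-empty vectors of equal length")
  sqrt(mean((y - yhat)^2))
}

#' Mean absolute error
#' @inheritParams rmse
#' @return `mean(|y - yhat|)`.
#' @export
mae <- function(y, yhat) {
  if (length(y) == 0 || length(y) != length(yhat))
    stop("y and yhat must be non-empty vectors of equal length")
  mean(abs(y - yhat))
}

#' BDI-II severity bin
#'
#' Bins a BDI-II score into the standard severity categories:
#' None (0-13), Mild (14-19), Moderate (20-28), Severe (29-63).
#' Non-integer scores are floored to an integer before binning.
#'
#' @param score numeric in `[0, 63]` (vectorised).
#' @return Factor with levels None, Mild, Moderate, Severe.
#' @export
#' @examples
#' severity_bin(c(13, 14, 28, 29))
severity_bin <- function(score) {
  if (any(!is.finite(score)) || any(score < 0 | score > 63))
    stop("BDI-II scores must lie in [0, 63]")
  s <- floor(score)
  lv <- c("None", "Mild", "Moderate", "Severe")
  out <- ifelse(s <= 13, "None",
         ifelse(s <= 19, "Mild",
         ifelse(s <= 28, "Moderate", "Severe")))
  factor(out, levels = lv)
}

#' Build a per-video metrics report
#'
#' @param records list of prediction records as returned by
#'   [predict_video()], or a data.frame with columns `video_id`,
#'   `true_score`, `video_score`.
#' @return Object of class `"metrics_report"`: list with `rmse`, `mae`,
#'   `n_subjects` and a `records` data.frame including severity bins and
#'   per-record errors.
#' @export
metrics_report <- function(records) {
  df <- if (is.data.frame(records)) records else
    do.call(rbind, lapply(records, function(r)
      data.frame(video_id = r$video_id, true_score = r$true_score,
                 video_score = r$video_score)))
  if (nrow(df) == 0) stop("no prediction records")
  df$error <- df$video_score - df$true_score
  df$severity_true <- severity_bin(df$true_score)
  df$severity_pred <- severity_bin(pmin(pmax(df$video_score, 0), 63))
  out <- list(rmse = rmse(df$true_score, df$video_score),
              mae = mae(df$true_score, df$video_score),
              n_subjects = nrow(df),
              records = df)
  class(out) <- "metrics_report"
  out
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Depression severity metrics over %d videos\n", x$n_subjects))
  cat(sprintf("  RMSE: %.4f\n  MAE:  %.4f\n", x$rmse, x$mae))
  invisible(x)
}
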