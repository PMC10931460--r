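# Diagnostic plots: per-model prediction-error box plots and predicted vs
# true Q-Q style scatter with the y = x reference line.

open_plot_device <- function(path, width = 6, height = 5) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png" && capabilities("png")) {
    grDevices::png(path, width = width, height = height, units = "in",
                   res = 150)
  } else if (ext == "svg" && capabilities("cairo")) {
    grDevices::svg(path, width = width, height = height)
  } else {
    # fall back to PDF (always available) keeping the requested path stem
    path <- paste0(tools::file_path_sans_ext(path), ".pdf")
    grDevices::pdf(path, width = width, height = height)
  }
  path
}

#' Box plot of prediction errors per model
#'
#' @param records named list: one data.frame of prediction records per
#'   model (columns `true_score`, `video_score`), or a single data.frame.
#' @param path output image path (`.png`, `.svg`; falls back to `.pdf`).
#' @return The path actually written, invisibly.
#' @export
error_boxplot <- function(records, path) {
  if (is.data.frame(records)) records <- list(model = records)
  if (sum(vapply(records, nrow, numeric(1))) < 2)
    stop("need at least 2 prediction records")
  errs <- lapply(records, function(r) r$video_score - r$true_score)
  path <- open_plot_device(path)
  on.exit(grDevices::dev.off())
  graphics::boxplot(errs, ylab = "prediction error (BDI-II)",
                    col = "lightsteelblue", las = 2)
  graphics::abline(h = 0, lty = 3, col = "red")
  invisible(path)
}

#' Predicted-versus-true scatter with the y = x reference
#'
#' @param records data.frame with `true_score` and `video_score` columns
#'   (at least 2 rows).
#' @param path output image path.
#' @return The path actually written, invisibly.
#' @export
qq_plot <- function(records, path) {
  if (nrow(records) < 2) stop("need at least 2 prediction records")
  path <- open_plot_device(path)
  on.exit(grDevices::dev.off())
  lim <- range(c(records$true_score, records$video_score, 0, 63))
  plot(records$video_score, records$true_score,
       xlab = "predicted BDI-II", ylab = "true BDI-II",
       xlim = lim, ylim = lim, pch = 19, col = "steelblue")
  graphics::abline(0, 1, lty = 2, col = "red")
  invisible(path)
}
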