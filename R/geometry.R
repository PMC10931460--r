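# Box geometry, non-maximum suppression and nearest-neighbour resampling.
#
# Boxes are numeric quadruples c(x1, y1, x2, y2) in pixel units, 0-based,
# half-open [x1, x2) x [y1, y2), so width = x2 - x1.  Images are arrays
# (H, W, C) with intensities in [0, 1].

#' Intersection-over-union of two boxes
#'
#' @param boxA,boxB numeric quadruples `c(x1, y1, x2, y2)` with `x1 < x2`,
#'   `y1 < y2`.
#' @return IoU in `[0, 1]`.
#' @export
#' @examples
#' iou(c(0, 0, 2, 2), c(1, 1, 3, 3))  # 1/7
iou <- function(boxA, boxB) {
  check_box(boxA); check_box(boxB)
  ix <- max(0, min(boxA[3], boxB[3]) - max(boxA[1], boxB[1]))
  iy <- max(0, min(boxA[4], boxB[4]) - max(boxA[2], boxB[2]))
  inter <- ix * iy
  areaA <- (boxA[3] - boxA[1]) * (boxA[4] - boxA[2])
  areaB <- (boxB[3] - boxB[1]) * (boxB[4] - boxB[2])
  inter / (areaA + areaB - inter)
}

check_box <- function(b) {
  if (length(b) != 4 || !all(is.finite(b)))
    stop("box must be 4 finite numbers (x1, y1, x2, y2)")
  if (b[3] <= b[1] || b[4] <= b[2])
    stop("degenerate box: need x1 < x2 and y1 < y2")
  invisible(b)
}

#' Greedy non-maximum suppression
#'
#' Sorts detections by descending score, keeps the top one and discards any
#' remaining box whose IoU with a kept box exceeds `iou_threshold`; repeats
#' until the list is exhausted. Equal scores are broken by lower original
#' index, so the result is deterministic.
#'
#' @param boxes numeric matrix with one row per detection, columns
#'   `x1, y1, x2, y2`.
#' @param scores numeric vector of confidences, one per row of `boxes`.
#' @param iou_threshold overlap above which a lower-scoring box is dropped,
#'   in `(0, 1)`.
#' @param method overlap measure: `"union"` (IoU, default) or `"min"`
#'   (intersection over the smaller area, used by the cascade's output
#'   stage to suppress nested windows).
#' @return Integer vector of kept row indices, in keep order.
#' @export
nms <- function(boxes, scores, iou_threshold, method = c("union", "min")) {
  method <- match.arg(method)
  if (iou_threshold <= 0 || iou_threshold >= 1)
    stop("iou_threshold must be in (0, 1)")
  n <- length(scores)
  if (n == 0) return(integer(0))
  overlap <- function(a, b) {
    if (method == "union") return(iou(a, b))
    ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
    iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
    ix * iy / min((a[3] - a[1]) * (a[4] - a[2]),
                  (b[3] - b[1]) * (b[4] - b[2]))
  }
  ord <- order(-scores, seq_len(n))
  keep <- integer(0)
  alive <- rep(TRUE, n)
  for (i in ord) {
    if (!alive[i]) next
    keep <- c(keep, i)
    for (j in ord) {
      if (alive[j] && j != i && overlap(boxes[i, ], boxes[j, ]) > iou_threshold)
        alive[j] <- FALSE
    }
    alive[i] <- FALSE
  }
  keep
}

#' Nearest-neighbour source coordinate for resampling
#'
#' Maps a destination pixel coordinate to its source pixel under the
#' transform `src = dst * (srcW / dstW)`, taking the floor of the real-valued
#' coordinate and clamping to the valid index range. Coordinates are 0-based.
#'
#' @param dstX,dstY 0-based destination coordinates (vectors allowed).
#' @param srcW,srcH source width and height in pixels.
#' @param dstW,dstH destination width and height in pixels.
#' @return List with integer vectors `srcX` and `srcY`.
#' @export
#' @examples
#' nn_coord(3, 0, srcW = 2, srcH = 1, dstW = 4, dstH = 1)$srcX  # 1
nn_coord <- function(dstX, dstY, srcW, srcH, dstW, dstH) {
  if (any(c(srcW, srcH, dstW, dstH) < 1)) stop("all dimensions must be >= 1")
  if (any(dstX < 0 | dstX >= dstW) || any(dstY < 0 | dstY >= dstH))
    stop("destination coordinates out of range")
  sx <- pmin(pmax(floor(dstX * (srcW / dstW)), 0), srcW - 1)
  sy <- pmin(pmax(floor(dstY * (srcH / dstH)), 0), srcH - 1)
  list(srcX = as.integer(sx), srcY = as.integer(sy))
}

# 1-based source indices for an axis resize (vector over 0-based dst coords)
nn_index <- function(dst0, srcN, dstN) {
  as.integer(pmin(pmax(floor(dst0 * (srcN / dstN)), 0), srcN - 1)) + 1L
}

#' Nearest-neighbour 2x upsampling
#'
#' Each source pixel is replicated into a 2x2 block, consistent with
#' [nn_coord()] applied per output pixel.
#'
#' @param x array `(H, W, C)` or `(H, W, C, N)`.
#' @return Array with doubled spatial dimensions.
#' @export
upsample_nearest_2x <- function(x) {
  d <- dim(x)
  ri <- rep(seq_len(d[1]), each = 2L)
  ci <- rep(seq_len(d[2]), each = 2L)
  if (length(d) == 3) x[ri, ci, , drop = FALSE]
  else x[ri, ci, , , drop = FALSE]
}

#' Nearest-neighbour resize to an arbitrary size
#'
#' @param x array `(H, W, C)`.
#' @param out_h,out_w output height and width.
#' @return Array `(out_h, out_w, C)`.
#' @export
resize_nearest <- function(x, out_h, out_w) {
  d <- dim(x)
  ri <- nn_index(seq_len(out_h) - 1L, d[1], out_h)
  ci <- nn_index(seq_len(out_w) - 1L, d[2], out_w)
  x[ri, ci, , drop = FALSE]
}

#' Expand a box to a square with a margin
#'
#' Makes the box square around its centre (side = max(width, height)), then
#' grows each side by `margin` (fraction per side) and clamps to the image.
#'
#' @param box quadruple `c(x1, y1, x2, y2)`.
#' @param margin fractional expansion per side (default 0.15).
#' @param img_w,img_h image bounds for clamping (optional).
#' @return Expanded quadruple.
#' @export
square_box <- function(box, margin = 0.15, img_w = NULL, img_h = NULL) {
  check_box(box)
  cx <- (box[1] + box[3]) / 2
  cy <- (box[2] + box[4]) / 2
  side <- max(box[3] - box[1], box[4] - box[2]) * (1 + 2 * margin)
  out <- c(cx - side / 2, cy - side / 2, cx + side / 2, cy + side / 2)
  if (!is.null(img_w)) {
    out[c(1, 3)] <- pmin(pmax(out[c(1, 3)], 0), img_w)
    out[c(2, 4)] <- pmin(pmax(out[c(2, 4)], 0), img_h)
  }
  out
}

#' Crop a detection and resize to the network input size
#'
#' Expands the detection box to a square with a fixed margin, clamps it to
#' the image, and resizes the crop to `out_size` x `out_size` with the
#' nearest-neighbour coordinate transform of [nn_coord()].
#'
#' @param frame image array `(H, W, C)`.
#' @param box detection quadruple `c(x1, y1, x2, y2)` in pixels.
#' @param out_size output side length in pixels (default 128).
#' @param margin fractional square expansion per side (default 0.15).
#' @return List with `image` (`(out_size, out_size, C)` array) and `box`
#'   (the expanded box actually cropped, for mapping coordinates).
#' @export
crop_and_resize <- function(frame, box, out_size = 128L, margin = 0.15) {
  d <- dim(frame)
  sq <- square_box(box, margin = margin, img_w = d[2], img_h = d[1])
  x1 <- floor(sq[1]); y1 <- floor(sq[2])
  x2 <- ceiling(sq[3]); y2 <- ceiling(sq[4])
  x1 <- max(x1, 0); y1 <- max(y1, 0)
  x2 <- min(x2, d[2]); y2 <- min(y2, d[1])
  if (x2 - x1 < 1 || y2 - y1 < 1) stop("degenerate crop region")
  crop <- frame[(y1 + 1):y2, (x1 + 1):x2, , drop = FALSE]
  list(image = resize_nearest(crop, out_size, out_size),
       box = c(x1, y1, x2, y2))
}
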