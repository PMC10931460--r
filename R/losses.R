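# Cascade training losses and the joint multi-task objective.

#' Face classification loss (binary cross-entropy)
#'
#' `-(y log p + (1 - y) log(1 - p))` with `p` clamped away from 0 and 1 at
#' machine tolerance.
#'
#' @param p predicted face probability in `(0, 1)`.
#' @param y true label, 0 (non-face) or 1 (face).
#' @return Non-negative loss value (vectorised over `p`, `y`).
#' @export
#' @examples
#' face_cls_loss(0.5, 1)  # log(2)
face_cls_loss <- function(p, y) {
  if (!all(y %in% c(0, 1))) stop("y must be 0 or 1")
  eps <- 1e-12
  p <- pmin(pmax(p, eps), 1 - eps)
  -(y * log(p) + (1 - y) * log(1 - p))
}

#' Bounding-box regression loss (squared Euclidean)
#'
#' @param pred,true numeric quadruples `(x1, y1, x2, y2)`.
#' @return `||pred - true||^2`.
#' @export
bbox_reg_loss <- function(pred, true) {
  if (length(pred) != 4 || length(true) != 4)
    stop("box targets must have 4 components")
  if (!all(is.finite(c(pred, true)))) stop("non-finite box coordinates")
  sum((pred - true)^2)
}

#' Landmark regression loss (squared Euclidean over 10 coordinates)
#'
#' @param pred,true numeric 10-tuples (x, y for left eye, right eye, nose
#'   tip, left mouth corner, right mouth corner).
#' @return `||pred - true||^2`.
#' @export
landmark_loss <- function(pred, true) {
  if (length(pred) != 10 || length(true) != 10)
    stop("landmark targets must have 10 components")
  if (!all(is.finite(c(pred, true)))) stop("non-finite landmark coordinates")
  sum((pred - true)^2)
}

#' Weighted multi-task detection objective
#'
#' `sum_i sum_j alpha_j * beta_ij * L_ij` over tasks j in {d, b, m}
#' (detection, box, landmarks) and samples i. `beta_ij` switches a task on
#' or off per sample depending on its annotation type.
#'
#' @param losses numeric matrix `(n_samples, 3)` of per-sample per-task
#'   losses, columns ordered (d, b, m).
#' @param alpha numeric length-3 task importance weights, all `>= 0`.
#' @param beta 0/1 matrix with the shape of `losses`.
#' @return Scalar objective.
#' @export
multitask_objective <- function(losses, alpha, beta) {
  losses <- as.matrix(losses); beta <- as.matrix(beta)
  if (!all(dim(losses) == dim(beta)) || ncol(losses) != 3)
    stop("losses and beta must be (n, 3) matrices of equal shape")
  if (length(alpha) != 3 || any(alpha < 0))
    stop("alpha must be 3 non-negative weights")
  if (!all(beta %in% c(0, 1))) stop("beta entries must be 0 or 1")
  sum(sweep(losses * beta, 2, alpha, "*"))
}

#' Element-wise and mean squared-error loss
#'
#' `loss(x_i, y_i) = (x_i - y_i)^2`, with the mean over elements used as the
#' optimisation objective.
#'
#' @param x,y numeric vectors of equal length.
#' @return List with `elements` (per-element losses) and `mean`.
#' @export
#' @examples
#' mse_loss(c(0, 0), c(3, 4))$mean  # 12.5
mse_loss <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  e <- (x - y)^2
  list(elements = e, mean = mean(e))
}
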