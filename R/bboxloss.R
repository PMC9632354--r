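# Bounding-box geometry: IoU, the improved regression loss, and NMS.
# Boxes use the corner convention c(x1, y1, x2, y2) with x2 > x1, y2 > y1.

#' Construct an axis-aligned bounding box
#'
#' @param x1,y1,x2,y2 Corner coordinates in pixels; `x2 > x1`, `y2 > y1`.
#' @param score Optional detection confidence in \[0, 1\].
#' @return A named numeric vector of class `"bbox"`.
#' @examples
#' bbox(0, 0, 2, 2)
#' @export
bbox <- function(x1, y1, x2, y2, score = NA_real_) {
  b <- c(x1 = x1, y1 = y1, x2 = x2, y2 = y2, score = score)
  if (!all(is.finite(b[1:4]))) stop_invalid("box corners must be finite")
  if (x2 <= x1 || y2 <= y1)
    stop_invalid("degenerate box: need x2 > x1 and y2 > y1")
  if (!is.na(score) && (score < 0 || score > 1))
    stop_invalid("`score` must be in [0, 1]")
  class(b) <- "bbox"
  b
}

check_box <- function(b, name) {
  b <- unclass(b)
  if (length(b) < 4L || !all(is.finite(b[1:4])))
    stop_invalid("`", name, "` must supply finite x1, y1, x2, y2")
  if (b[[3]] <= b[[1]] || b[[4]] <= b[[2]])
    stop_invalid("`", name, "` is degenerate (zero or negative area)")
  unname(b[1:4])
}

#' Intersection over union of two boxes
#'
#' @param a,b Boxes as created by [bbox()] or numeric `c(x1, y1, x2, y2)`.
#' @return IoU in \[0, 1\]; 0 for disjoint boxes.
#' @examples
#' iou(bbox(0, 0, 2, 2), bbox(1, 1, 3, 3))  # 1/7
#' @export
iou <- function(a, b) {
  a <- check_box(a, "a"); b <- check_box(b, "b")
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  union <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  inter / union
}

#' Improved bounding-box regression loss
#'
#' Combines the IoU gap, the squared centre distance normalized by the
#' enclosing-box diagonal, and two arctan aspect-ratio penalty terms:
#' \deqn{L = 1 - IoU + \rho^2/c^2 +
#'       \frac{4}{\pi^2}\Delta^4 (1 - IoU) + \frac{4}{\pi^2}\Delta^2,}
#' where \eqn{\Delta = \arctan(w^{gt}/h^{gt}) - \arctan(w^{pb}/h^{pb})},
#' \eqn{\rho} is the distance between box centres and \eqn{c} the diagonal
#' of the smallest box enclosing both. The quartic term is kept as stated
#' (`variant = "quartic"`); `variant = "ciou"` gives the conventional
#' complete-IoU loss \eqn{1 - IoU + \rho^2/c^2 + \alpha v} with
#' \eqn{v = \frac{4}{\pi^2}\Delta^2} and \eqn{\alpha = v / (1 - IoU + v)}.
#'
#' @param pred,gt Predicted and ground-truth boxes.
#' @param variant `"quartic"` (default) or `"ciou"`.
#' @return Non-negative loss; 0 iff the boxes coincide.
#' @examples
#' libox(bbox(0, 0, 2, 2), bbox(0, 0, 2, 2))  # 0
#' libox(bbox(0, 0, 2, 2), bbox(1, 1, 3, 3))  # ~0.9683
#' @export
libox <- function(pred, gt, variant = c("quartic", "ciou")) {
  variant <- match.arg(variant)
  p <- check_box(pred, "pred"); g <- check_box(gt, "gt")
  ov <- iou(p, g)
  cp <- c((p[1] + p[3]) / 2, (p[2] + p[4]) / 2)
  cg <- c((g[1] + g[3]) / 2, (g[2] + g[4]) / 2)
  rho2 <- sum((cp - cg)^2)
  c2 <- (max(p[3], g[3]) - min(p[1], g[1]))^2 +
        (max(p[4], g[4]) - min(p[2], g[2]))^2
  d <- atan((g[3] - g[1]) / (g[4] - g[2])) - atan((p[3] - p[1]) / (p[4] - p[2]))
  v2 <- 4 / pi^2 * d^2
  if (variant == "quartic") {
    1 - ov + rho2 / c2 + (4 / pi^2) * d^4 * (1 - ov) + v2
  } else {
    alpha <- if (v2 > 0) v2 / ((1 - ov) + v2) else 0
    1 - ov + rho2 / c2 + alpha * v2
  }
}

#' Greedy non-maximum suppression
#'
#' Boxes are visited in descending score order; a box is suppressed when
#' its IoU with an already-retained box exceeds `iou_threshold`. Score
#' ties are broken by lower original index.
#'
#' @param boxes A data frame with columns `x1, y1, x2, y2, score`.
#' @param iou_threshold Suppression threshold, strictly between 0 and 1.
#' @return The retained rows of `boxes`, in descending score order, with a
#'   column `index` giving each row's position in the input.
#' @examples
#' b <- data.frame(x1 = c(0, 0), y1 = c(0, 0), x2 = c(2, 2), y2 = c(2, 2),
#'                 score = c(0.9, 0.8))
#' nms(b, 0.5)
#' @export
nms <- function(boxes, iou_threshold = 0.5) {
  if (!is.data.frame(boxes) ||
      !all(c("x1", "y1", "x2", "y2", "score") %in% names(boxes)))
    stop_invalid("`boxes` must be a data frame with columns x1, y1, x2, y2, score")
  if (anyNA(boxes$score)) stop_invalid("all boxes must carry a score")
  check_scalar_number(iou_threshold, "iou_threshold")
  if (iou_threshold <= 0 || iou_threshold >= 1)
    stop_invalid("`iou_threshold` must be strictly between 0 and 1")
  n <- nrow(boxes)
  if (n == 0L) return(cbind(boxes, index = integer(0)))
  ord <- order(-boxes$score, seq_len(n))
  keep <- integer(0)
  for (i in ord) {
    bi <- c(boxes$x1[i], boxes$y1[i], boxes$x2[i], boxes$y2[i])
    suppressed <- FALSE
    for (j in keep) {
      bj <- c(boxes$x1[j], boxes$y1[j], boxes$x2[j], boxes$y2[j])
      if (iou(bi, bj) > iou_threshold) { suppressed <- TRUE; break }
    }
    if (!suppressed) keep <- c(keep, i)
  }
  out <- boxes[keep, , drop = FALSE]
  out$index <- keep
  rownames(out) <- NULL
  out
}
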