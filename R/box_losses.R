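#' Axis-aligned bounding box
#'
#' Boxes are corner-format `(x_min, y_min, x_max, y_max)` in pixel units,
#' half-open (`[min, max)`), 0-based. Centre, width and height are always
#' derived, never stored, so the corner convention is the single source of
#' truth.
#'
#' @param x_min,y_min,x_max,y_max Box corners; `x_min < x_max`,
#'   `y_min < y_max` is required.
#' @return A named numeric vector of class `"bbox"`.
#' @examples
#' b <- bbox(0, 0, 640, 640)
#' bbox_area(b)
#' @export
bbox <- function(x_min, y_min, x_max, y_max) {
  b <- c(x_min = as.numeric(x_min), y_min = as.numeric(y_min),
         x_max = as.numeric(x_max), y_max = as.numeric(y_max))
  validate_bbox(b)
  class(b) <- "bbox"
  b
}

validate_bbox <- function(b) {
  if (length(b) != 4L || anyNA(b) || any(!is.finite(b)))
    stop("bbox must be 4 finite numbers")
  if (b[[1]] >= b[[3]] || b[[2]] >= b[[4]])
    stop("degenerate bbox: require x_min < x_max and y_min < y_max")
  invisible(b)
}

#' @rdname bbox
#' @param b A `bbox`.
#' @export
bbox_area <- function(b) {
  validate_bbox(b)
  (b[[3]] - b[[1]]) * (b[[4]] - b[[2]])
}

#' @rdname bbox
#' @export
bbox_center <- function(b) {
  validate_bbox(b)
  c(x = (b[[1]] + b[[3]]) / 2, y = (b[[2]] + b[[4]]) / 2)
}

#' Intersection over union of two boxes
#'
#' Overlap area divided by union area; 0 for disjoint boxes, 1 for
#' identical boxes.
#'
#' @param a,b Boxes created with [bbox()] (or any 4-vector in corner
#'   format).
#' @return A number in `[0, 1]`.
#' @examples
#' iou(bbox(0, 0, 2, 2), bbox(1, 1, 3, 3))  # 1/7
#' @export
iou <- function(a, b) {
  validate_bbox(a); validate_bbox(b)
  iw <- min(a[[3]], b[[3]]) - max(a[[1]], b[[1]])
  ih <- min(a[[4]], b[[4]]) - max(a[[2]], b[[2]])
  inter <- max(0, iw) * max(0, ih)
  union <- bbox_area(a) + bbox_area(b) - inter
  inter / union
}

#' Complete-IoU (CIoU) loss terms
#'
#' Decomposes the CIoU regression loss between a predicted and a target
#' box into its terms: the IoU; the squared centre distance `rho2`
#' normalized by the squared diagonal `c_diag2` of the smallest box
#' enclosing both; the aspect-ratio consistency penalty
#' `v = (4/pi^2) (atan(w_t/h_t) - atan(w/h))^2`; and its weight
#' `alpha = v / ((1 - IoU) + v)` (defined as 0 when `v = 0`, avoiding
#' 0/0 at perfect overlap). The loss is
#' `1 - IoU + rho2/c_diag2 + alpha * v`.
#'
#' Unlike plain IoU (and GIoU for enclosed boxes), CIoU distinguishes
#' candidate boxes with equal overlap by their centre distance, and
#' candidates with coincident centres by their aspect ratio.
#'
#' @param pred,target Boxes created with [bbox()].
#' @return A list of class `"ciou_terms"` with elements `iou`, `rho2`,
#'   `c_diag2`, `v`, `alpha`, `loss`, `w`, `h`, `w_gt`, `h_gt`.
#' @examples
#' ciou_terms(bbox(0, 0, 2, 2), bbox(0.5, 0.5, 1.5, 1.5))$loss  # 0.75
#' @export
ciou_terms <- function(pred, target) {
  validate_bbox(pred); validate_bbox(target)
  i <- iou(pred, target)
  cp <- bbox_center(pred); ct <- bbox_center(target)
  rho2 <- sum((cp - ct)^2)
  ex <- max(pred[[3]], target[[3]]) - min(pred[[1]], target[[1]])
  ey <- max(pred[[4]], target[[4]]) - min(pred[[2]], target[[2]])
  c_diag2 <- ex^2 + ey^2
  w <- pred[[3]] - pred[[1]]; h <- pred[[4]] - pred[[2]]
  w_gt <- target[[3]] - target[[1]]; h_gt <- target[[4]] - target[[2]]
  v <- (4 / pi^2) * (atan(w_gt / h_gt) - atan(w / h))^2
  alpha <- if (v == 0) 0 else v / ((1 - i) + v)
  loss <- 1 - i + rho2 / c_diag2 + alpha * v
  structure(list(iou = i, rho2 = rho2, c_diag2 = c_diag2, v = v,
                 alpha = alpha, loss = loss,
                 w = w, h = h, w_gt = w_gt, h_gt = h_gt),
            class = "ciou_terms")
}

#' @rdname ciou_terms
#' @export
ciou_loss <- function(pred, target) ciou_terms(pred, target)$loss

#' Rank candidate boxes against a target by CIoU loss
#'
#' Orders candidates by ascending CIoU loss; ties are broken by lower
#' squared centre distance, then lower aspect penalty, then input order.
#' This realises the disambiguation CIoU adds over plain IoU: among
#' candidates with equal overlap, the one whose centre is nearer the
#' target ranks first; among candidates with coincident centres, the one
#' matching the target's aspect ratio ranks first.
#'
#' @param cands A list of [bbox()] candidates (at least one).
#' @param target The target [bbox()].
#' @return An integer permutation of `seq_along(cands)`: the candidate
#'   indices from best to worst.
#' @export
rank_candidates <- function(cands, target) {
  if (length(cands) < 1L) stop("need at least one candidate")
  terms <- lapply(cands, ciou_terms, target = target)
  loss <- vapply(terms, `[[`, numeric(1), "loss")
  rho2 <- vapply(terms, `[[`, numeric(1), "rho2")
  v <- vapply(terms, `[[`, numeric(1), "v")
  order(loss, rho2, v, seq_along(cands))
}
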