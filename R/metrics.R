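#' Segmentation evaluation metrics
#'
#' The standard per-pixel and boundary metrics for comparing a predicted
#' segmentation against ground truth: global accuracy (fraction of all
#' pixels classified correctly), mean accuracy (unweighted mean of
#' per-class recall), per-class and mean intersection-over-union, weighted
#' IoU (IoU averaged with ground-truth class-frequency weights), and the
#' mean boundary-F1 score (F1 of boundary-pixel matching within a distance
#' tolerance). Masks are 0/1 matrices; class 1 is "person", class 0
#' "background". The formulas generalize to N classes; this package
#' exercises them at N = 2.
#'
#' @param pred,gt 0/1 mask matrices of identical shape (anything
#'   [as_binary_mask()] accepts).
#' @name seg-metrics
NULL

.check_pair <- function(pred, gt) {
  pred <- .as_mask(pred); gt <- .as_mask(gt)
  if (!identical(dim(pred), dim(gt)))
    stop("prediction and ground truth differ in shape", call. = FALSE)
  list(pred = pred, gt = gt)
}

#' @rdname seg-metrics
#' @return `global_accuracy`: fraction of pixels in `[0, 1]`.
#' @export
global_accuracy <- function(pred, gt) {
  p <- .check_pair(pred, gt)
  mean(p$pred == p$gt)
}

#' @rdname seg-metrics
#' @return `mean_accuracy`: unweighted mean of per-class recall; errors if
#'   a class is absent from the ground truth (its recall is undefined).
#' @export
mean_accuracy <- function(pred, gt) {
  p <- .check_pair(pred, gt)
  acc <- vapply(c(0L, 1L), function(cl) {
    n <- sum(p$gt == cl)
    if (n == 0L)
      stop("class ", cl, " absent from ground truth: per-class accuracy ",
           "undefined", call. = FALSE)
    sum(p$pred == cl & p$gt == cl) / n
  }, numeric(1))
  mean(acc)
}

#' @rdname seg-metrics
#' @return `iou_per_class`: named vector of per-class IoU
#'   (`|pred ∩ gt| / |pred ∪ gt|`; defined as 1 when the union is empty,
#'   i.e. both masks agree the class is absent).
#' @export
iou_per_class <- function(pred, gt) {
  p <- .check_pair(pred, gt)
  vapply(c(background = 0L, person = 1L), function(cl) {
    inter <- sum(p$pred == cl & p$gt == cl)
    uni <- sum(p$pred == cl | p$gt == cl)
    if (uni == 0L) 1 else inter / uni
  }, numeric(1))
}

#' @rdname seg-metrics
#' @export
mean_iou <- function(pred, gt) mean(iou_per_class(pred, gt))

#' @rdname seg-metrics
#' @return `weighted_iou`: IoU averaged over classes with weights equal to
#'   the ground-truth pixel frequency of each class.
#' @export
weighted_iou <- function(pred, gt) {
  p <- .check_pair(pred, gt)
  iou <- iou_per_class(pred, gt)
  w <- c(background = sum(p$gt == 0L), person = sum(p$gt == 1L))
  sum(w * iou) / sum(w)
}

# boundary pixels of a class: pixels of that class 4-adjacent to the other
# class or lying on the image frame
.boundary <- function(mask, cl) {
  m <- (mask == cl)
  nr <- nrow(m); nc <- ncol(m)
  other <- matrix(FALSE, nr, nc)
  # frame rows/cols always border "outside"
  pad <- function(shift_r, shift_c) {
    out <- matrix(TRUE, nr, nc)   # outside the frame counts as class change
    rs <- seq_len(nr) + shift_r
    cs <- seq_len(nc) + shift_c
    ok_r <- rs >= 1 & rs <= nr
    ok_c <- cs >= 1 & cs <= nc
    out[ok_r, ok_c] <- !m[rs[ok_r], cs[ok_c]]
    out
  }
  nb_diff <- pad(-1, 0) | pad(1, 0) | pad(0, -1) | pad(0, 1)
  m & nb_diff
}

#' @rdname seg-metrics
#' @param tol matching tolerance in pixels (Euclidean). `NULL` uses the
#'   conventional default of 0.75% of the image diagonal, rounded up.
#' @return `boundary_f1`: named vector of per-class boundary-F1 scores;
#'   `mean_bf_score`: their mean. Precision is the fraction of predicted
#'   boundary pixels within `tol` of a ground-truth boundary pixel of the
#'   same class; recall is symmetric; F1 is their harmonic mean (0 when
#'   both are 0).
#' @export
boundary_f1 <- function(pred, gt, tol = NULL) {
  p <- .check_pair(pred, gt)
  if (is.null(tol)) tol <- ceiling(0.0075 * sqrt(sum(dim(p$gt)^2)))
  if (tol < 0) stop("`tol` must be non-negative", call. = FALSE)
  vapply(c(background = 0L, person = 1L), function(cl) {
    bp <- .boundary(p$pred, cl)
    bg <- .boundary(p$gt, cl)
    if (!any(bp) && !any(bg)) return(1)   # class absent from both
    if (!any(bp) || !any(bg)) return(0)
    # distance of every pixel to the nearest boundary pixel of the other map
    dist_to <- function(b) {
      d <- EBImage::imageData(EBImage::distmap(1 - b))
      d
    }
    precision <- mean(dist_to(bg)[bp] <= tol)
    recall <- mean(dist_to(bp)[bg] <= tol)
    if (precision + recall == 0) 0 else
      2 * precision * recall / (precision + recall)
  }, numeric(1))
}

#' @rdname seg-metrics
#' @export
mean_bf_score <- function(pred, gt, tol = NULL) mean(boundary_f1(pred, gt, tol))

#' Full segmentation metrics report
#'
#' Computes the five-metric bundle used to evaluate a person-segmentation
#' model: global accuracy, mean accuracy, mean IoU, weighted IoU and mean
#' BF score, plus the per-class IoU and boundary-F1 tables.
#'
#' @inheritParams seg-metrics
#' @param tol boundary-F1 tolerance in pixels; `NULL` for the default (see
#'   [boundary_f1()]).
#' @return object of class `seg_metrics`: a list with fields
#'   `global_accuracy`, `mean_accuracy`, `mean_iou`, `weighted_iou`,
#'   `mean_bf_score`, `iou_per_class`, `bf_per_class`.
#' @export
seg_metrics <- function(pred, gt, tol = NULL) {
  bf <- boundary_f1(pred, gt, tol)
  structure(list(
    global_accuracy = global_accuracy(pred, gt),
    mean_accuracy = mean_accuracy(pred, gt),
    mean_iou = mean_iou(pred, gt),
    weighted_iou = weighted_iou(pred, gt),
    mean_bf_score = mean(bf),
    iou_per_class = iou_per_class(pred, gt),
    bf_per_class = bf), class = "seg_metrics")
}

#' @export
print.seg_metrics <- function(x, digits = 5, ...) {
  cat("Segmentation metrics:\n")
  for (f in c("global_accuracy", "mean_accuracy", "mean_iou",
              "weighted_iou", "mean_bf_score"))
    cat(sprintf("  %-16s %.*f\n", f, digits, x[[f]]))
  invisible(x)
}
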