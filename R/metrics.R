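#' Compartment volumes in millilitres
#'
#' Exact voxel-count times voxel-volume arithmetic:
#' `volume_ml = count * row_mm * col_mm * slice_mm / 1000`.  Voxels removed
#' as marrow fat are excluded from all three totals.
#'
#' @param seg a [fat_segmentation].
#' @param spacing voxel spacing `(row_mm, col_mm, slice_mm)`.
#' @return An object of class `volume_report`: `tat_ml`, `sat_ml`, `vat_ml`,
#'   `voxel_counts` (named, including `removed_bone_fat`) and `spacing`.
#' @examples
#' m <- array(FALSE, dim = c(10, 10, 10)); m[1:4, , ] <- TRUE
#' seg <- fat_segmentation(tat = m, sat = m, vat = array(FALSE, dim(m)))
#' compute_volumes(seg, spacing = c(1, 1, 2.5))
#' @export
compute_volumes <- function(seg, spacing) {
  stopifnot(inherits(seg, "fat_segmentation"))
  vx <- voxel_volume_ml(spacing)
  counts <- c(tat = sum(seg$tat), sat = sum(seg$sat), vat = sum(seg$vat),
              removed_bone_fat = sum(seg$removed_bone_fat))
  structure(list(
    tat_ml = (counts[["sat"]] + counts[["vat"]]) * vx,
    sat_ml = counts[["sat"]] * vx,
    vat_ml = counts[["vat"]] * vx,
    voxel_counts = counts,
    spacing = as.numeric(spacing)
  ), class = "volume_report")
}

#' @export
print.volume_report <- function(x, ...) {
  cat(sprintf("<volume_report> TAT %.2f mL | SAT %.2f mL | VAT %.2f mL (removed bone fat: %d voxels)\n",
              x$tat_ml, x$sat_ml, x$vat_ml, x$voxel_counts[["removed_bone_fat"]]))
  invisible(x)
}

#' Voxelwise confusion counts between two masks
#'
#' Counts true/false positives/negatives voxel by voxel, restricted to an
#' evaluation domain.  Evaluating over the whole image inflates specificity
#' and accuracy with the air background, so the domain normally is the body
#' mask.
#'
#' @param pred,truth logical masks on one grid.
#' @param domain evaluation domain mask; defaults to the whole grid.
#' @return An object of class `confusion_counts` with fields `tp`, `fp`,
#'   `tn`, `fn`.
#' @export
confusion <- function(pred, truth, domain = NULL) {
  pred <- as_mask(pred); truth <- as_mask(truth)
  if (is.null(domain)) domain <- array(TRUE, dim = dim(pred))
  domain <- as_mask(domain)
  check_same_grid(pred, truth, domain)
  p <- pred[domain]; t <- truth[domain]
  confusion_counts(tp = sum(p & t), fp = sum(p & !t),
                   tn = sum(!p & !t), fn = sum(!p & t))
}

#' @rdname confusion
#' @param tp,fp,tn,fn non-negative voxel counts.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  cnt <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(cnt < 0) || any(cnt != round(cnt)))
    stop("confusion counts must be non-negative integers")
  structure(as.list(cnt), class = "confusion_counts")
}

#' Segmentation quality metrics from confusion counts
#'
#' Sensitivity, specificity and accuracy in percent, and the Dice similarity
#' coefficient `2*tp / (2*tp + fp + fn)` on a 0--1 scale.  A ratio of the
#' form 0/0 is reported as `NA` (undefined), never as 0.
#'
#' @param counts a `confusion_counts` object.
#' @return An object of class `eval_metrics` with fields `sensitivity`,
#'   `specificity`, `accuracy` (percent) and `dsc`.
#' @examples
#' evaluate_counts(confusion_counts(tp = 90, fp = 10, tn = 890, fn = 10))
#' @export
evaluate_counts <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  if (tp + fp + tn + fn == 0)
    stop("all confusion counts are zero: nothing to evaluate")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(list(
    sensitivity = 100 * ratio(tp, tp + fn),
    specificity = 100 * ratio(tn, tn + fp),
    accuracy    = 100 * ratio(tp + tn, tp + fp + tn + fn),
    dsc         = ratio(2 * tp, 2 * tp + fp + fn)
  ), class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf("<eval_metrics> sensitivity %.2f%% | specificity %.2f%% | accuracy %.2f%% | DSC %.4f\n",
              x$sensitivity, x$specificity, x$accuracy, x$dsc))
  invisible(x)
}

#' Dice similarity coefficient of two masks
#'
#' Convenience wrapper: `2 |A & B| / (|A| + |B|)`.
#'
#' @param a,b logical masks on one grid.
#' @return DSC in \[0, 1\]; `NA` when both masks are empty.
#' @export
dice <- function(a, b) {
  a <- as_mask(a); b <- as_mask(b)
  check_same_grid(a, b)
  den <- sum(a) + sum(b)
  if (den == 0) return(NA_real_)
  2 * sum(a & b) / den
}
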