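# Pixel metrics: accuracy, Dice, Matthews correlation, AUC, HD95.

#' Pixelwise confusion counts
#'
#' @param pred binary predicted mask (0/1 matrix).
#' @param truth binary reference mask of the same size.
#' @return object of class `"confusion"`: list with `tp`, `tn`, `fp`, `fn`.
#' @export
confusion <- function(pred, truth) {
  pred <- as.matrix(pred); truth <- as.matrix(truth)
  if (!all(dim(pred) == dim(truth))) stop("shapes differ")
  check_binary(pred, "prediction"); check_binary(truth, "truth")
  structure(list(tp = sum(pred == 1 & truth == 1),
                 tn = sum(pred == 0 & truth == 0),
                 fp = sum(pred == 1 & truth == 0),
                 fn = sum(pred == 0 & truth == 1)),
            class = "confusion")
}

#' @rdname confusion
#' @param x a `"confusion"` object.
#' @param ... unused.
#' @export
print.confusion <- function(x, ...) {
  cat(sprintf("confusion counts: TP=%d TN=%d FP=%d FN=%d\n",
              x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

#' Pixel accuracy
#' @param cc a [confusion()] object.
#' @export
accuracy <- function(cc) {
  with(cc, (tp + tn) / (tp + tn + fp + fn))
}

#' Dice coefficient
#'
#' `2 TP / (2 TP + FP + FN)`.  When both masks are empty the overlap is
#' perfect by convention and 1 is returned.
#' @inheritParams accuracy
#' @export
dice <- function(cc) {
  den <- 2 * cc$tp + cc$fp + cc$fn
  if (den == 0) return(1)
  2 * cc$tp / den
}

#' Matthews correlation coefficient
#'
#' Class-imbalance robust correlation between prediction and truth.  A zero
#' denominator (a degenerate single-class margin) yields 0 with a warning.
#' @inheritParams accuracy
#' @export
mcc <- function(cc) {
  tp <- as.numeric(cc$tp); tn <- as.numeric(cc$tn)
  fp <- as.numeric(cc$fp); fn <- as.numeric(cc$fn)
  den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  if (den == 0) {
    warning("degenerate confusion margin: MCC defined as 0")
    return(0)
  }
  (tp * tn - fp * fn) / den
}

#' Area under the ROC curve
#'
#' Rank statistic (Mann-Whitney U scaled by `n1 * n0`) over all pixels,
#' with midrank handling of ties.  Undefined when the truth contains a
#' single class; `NA` is returned in that case.
#'
#' @param pred foreground-probability matrix (or vector of scores).
#' @param truth binary matrix (or vector) of the same length.
#' @export
auc_roc <- function(pred, truth) {
  s <- as.numeric(pred); g <- as.numeric(truth)
  check_binary(matrix(g), "truth")
  n1 <- sum(g == 1); n0 <- sum(g == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(s)
  (sum(r[g == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Boundary point set of a binary mask
#'
#' Foreground pixels having at least one background 4-neighbour, as a
#' two-column (row, col) matrix of 1-based pixel coordinates.
#' @param mask binary matrix.
#' @export
boundary_points <- function(mask) {
  mask <- as.matrix(mask)
  check_binary(mask)
  which(boundary_pixels(mask), arr.ind = TRUE)
}

#' 95th percentile Hausdorff distance
#'
#' Directed Euclidean distances from every boundary point of each mask to
#' the nearest boundary point of the other are pooled, and the 95th
#' percentile (linear interpolation) of the pooled list is returned.  The
#' pooling makes the statistic symmetric in its arguments.  If either
#' boundary is empty the distance is undefined and `NA` is returned.
#'
#' @param pred,truth binary masks of equal size.
#' @param pct percentile (default 95).
#' @export
hd95 <- function(pred, truth, pct = 95) {
  pred <- as.matrix(pred); truth <- as.matrix(truth)
  if (!all(dim(pred) == dim(truth))) stop("shapes differ")
  A <- boundary_pixels(pred)
  B <- boundary_pixels(truth)
  if (!any(A) || !any(B)) return(NA_real_)
  dB <- edt(B)     # distance of every pixel to the nearest B point
  dA <- edt(A)
  d_ab <- dB[A]    # directed A -> B
  d_ba <- dA[B]    # directed B -> A
  unname(stats::quantile(c(d_ab, d_ba), pct / 100, type = 7))
}

# Mean intersection-over-union across the two classes.
miou <- function(cc) {
  fg <- if (cc$tp + cc$fp + cc$fn == 0) 1 else
    cc$tp / (cc$tp + cc$fp + cc$fn)
  bg <- if (cc$tn + cc$fp + cc$fn == 0) 1 else
    cc$tn / (cc$tn + cc$fp + cc$fn)
  (fg + bg) / 2
}

#' Full metric panel for one image
#'
#' Binarises the probability map at 0.5, computes confusion-based metrics,
#' AUC from the raw probabilities, and HD95 between the boundary sets.
#'
#' @param pred foreground-probability matrix.
#' @param truth binary reference mask.
#' @param threshold binarisation threshold (probability scale).
#' @return named list: `acc`, `auc`, `dice`, `mcc`, `hd95`, `miou`.
#' @export
seg_metrics <- function(pred, truth, threshold = 0.5) {
  bin <- (as.matrix(pred) >= threshold) * 1
  cc <- confusion(bin, truth)
  list(acc = accuracy(cc), auc = auc_roc(pred, truth), dice = dice(cc),
       mcc = suppressWarnings(mcc(cc)), hd95 = hd95(bin, truth),
       miou = miou(cc))
}
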