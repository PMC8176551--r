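#' Intersection-over-union of two binary masks
#'
#' `|A n B| / |A u B|`. Two empty masks agree on absence and score 1; one
#' empty mask scores 0. Symmetric, in `[0, 1]`, and 1 iff the masks are
#' equal.
#'
#' @param a,b Logical matrices of the same shape.
#' @return A number in `[0, 1]`.
#' @export
mask_iou <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

# centroid (x, y) of a mask; NA when empty
.mask_centroid <- function(mask) {
  ij <- which(mask, arr.ind = TRUE)
  if (nrow(ij) == 0) return(c(NA_real_, NA_real_))
  c(mean(ij[, 2]), mean(ij[, 1]))
}

#' Evaluate a tracked mask sequence against ground truth
#'
#' Per frame: mask IoU, centroid distance (px), and a correctly-tracked
#' flag (`IoU >= iou_threshold`; the conventional threshold is 0.5).
#' Sequence level: the percentage of correctly tracked frames — the
#' standard accuracy figure for non-rigid trackers — plus mean IoU and the
#' number of frames with an empty predicted mask.
#'
#' @param pred,truth Lists of logical matrices of equal length and shape.
#' @param iou_threshold IoU above which a frame counts as correctly
#'   tracked (default 0.5).
#' @return An object of class `eval_report`: `per_frame` (data.frame with
#'   `frame`, `iou`, `center_error`, `correct`) and the summary fields
#'   `percent_correct`, `mean_iou`, `n_frames`, `frames_lost`.
#' @export
#' @examples
#' m <- matrix(FALSE, 8, 8); m[3:6, 3:6] <- TRUE
#' evaluate_tracking(list(m), list(m))$percent_correct
evaluate_tracking <- function(pred, truth, iou_threshold = 0.5) {
  if (length(pred) != length(truth))
    stop("prediction and truth sequences differ in length")
  n <- length(pred)
  iou <- numeric(n)
  cerr <- numeric(n)
  for (i in seq_len(n)) {
    iou[i] <- mask_iou(pred[[i]], truth[[i]])
    cp <- .mask_centroid(pred[[i]])
    ct <- .mask_centroid(truth[[i]])
    cerr[i] <- sqrt(sum((cp - ct)^2))
  }
  correct <- iou >= iou_threshold
  structure(list(per_frame = data.frame(frame = seq_len(n), iou = iou,
                                        center_error = cerr,
                                        correct = correct),
                 percent_correct = 100 * sum(correct) / n,
                 mean_iou = mean(iou),
                 n_frames = n,
                 frames_lost = sum(vapply(pred, function(m) !any(m),
                                          logical(1)))),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Tracking evaluation over %d frames\n", x$n_frames))
  cat(sprintf("  correctly tracked: %.2f%%\n", x$percent_correct))
  cat(sprintf("  mean IoU:          %.4f\n", x$mean_iou))
  cat(sprintf("  frames lost:       %d\n", x$frames_lost))
  invisible(x)
}
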