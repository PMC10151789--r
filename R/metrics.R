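#' Confusion counts
#'
#' @param tp,fp,fn Non-negative integer tallies of true positives, false
#'   positives and false negatives.
#' @return One-row tibble with class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, fn) {
  tp <- as.integer(tp); fp <- as.integer(fp); fn <- as.integer(fn)
  if (any(c(tp, fp, fn) < 0) || anyNA(c(tp, fp, fn)))
    stop("confusion counts must be non-negative integers", call. = FALSE)
  out <- tibble::tibble(tp = tp, fp = fp, fn = fn)
  class(out) <- c("confusion_counts", class(out))
  out
}

#' Precision and recall from confusion counts
#'
#' `precision = tp / (tp + fp)` and `recall = tp / (tp + fn)`. A zero
#' denominator yields an explicit `NA` marker, never a silent 0. Vectorised
#' over rows, so a per-image count table pipes straight through.
#'
#' @param counts A [confusion_counts()] tibble, any data frame with `tp`,
#'   `fp`, `fn` columns, or a named numeric vector.
#' @return The input columns plus `precision` and `recall`, as a tibble.
#' @examples
#' precision_recall(confusion_counts(215, 4, 2))
#' @export
precision_recall <- function(counts) {
  if (is.numeric(counts) && !is.null(names(counts)))
    counts <- tibble::as_tibble(as.list(counts))
  if (!is.data.frame(counts) || !all(c("tp", "fp", "fn") %in% names(counts)))
    stop("`counts` needs tp, fp and fn", call. = FALSE)
  out <- tibble::as_tibble(counts)
  out$precision <- ifelse(out$tp + out$fp > 0, out$tp / (out$tp + out$fp), NA_real_)
  out$recall <- ifelse(out$tp + out$fn > 0, out$tp / (out$tp + out$fn), NA_real_)
  out
}

#' Intersection over union of two masks
#'
#' @param a,b [instance_mask()] objects or binary matrices on one canvas.
#' @return `|A intersect B| / |A union B|` in `[0, 1]`.
#' @export
mask_iou <- function(a, b) {
  ra <- as_raster(a); rb <- as_raster(b)
  if (!all(dim(ra) == dim(rb)))
    stop("masks must share one canvas", call. = FALSE)
  u <- sum(ra | rb)
  if (u == 0) stop("IoU of two empty masks is undefined", call. = FALSE)
  sum(ra & rb) / u
}

#' Confusion counts for fruit-stem matching
#'
#' Compares predicted pairs against ground-truth pairs by exact
#' `(image_id, fruit_index, stem_index)` identity: a predicted pair with a
#' truth counterpart is a true positive, one without is a false positive,
#' and a truth pair never predicted is a false negative. Counting is per
#' ground-truth pair.
#'
#' @param predicted,truth Tibbles with columns `fruit_index` and
#'   `stem_index`, and optionally `image_id` (filled with `""` when
#'   absent).
#' @return A [confusion_counts()] tibble.
#' @export
match_confusion <- function(predicted, truth) {
  key <- function(d) {
    if (nrow(d) == 0) return(character(0))
    id <- if ("image_id" %in% names(d)) as.character(d$image_id) else ""
    paste(id, d$fruit_index, d$stem_index, sep = "|")
  }
  kp <- key(predicted); kt <- key(truth)
  confusion_counts(tp = sum(kp %in% kt), fp = sum(!(kp %in% kt)),
                   fn = sum(!(kt %in% kp)))
}

# Greedy score-descending matching at one IoU threshold; returns per-
# prediction TP flags (predictions already sorted by descending score).
ap_match_once <- function(iou, thr) {
  n_pred <- nrow(iou); n_truth <- ncol(iou)
  tp <- logical(n_pred)
  taken <- logical(n_truth)
  for (p in seq_len(n_pred)) {
    ious <- iou[p, ]
    ious[taken] <- -1
    best <- which.max(ious)
    if (length(best) && ious[best] >= thr) {
      tp[p] <- TRUE
      taken[best] <- TRUE
    }
  }
  tp
}

# All-point interpolated area under the precision-recall curve.
ap_integrate <- function(tp_flags, n_truth) {
  if (length(tp_flags) == 0 || n_truth == 0) return(0)
  ctp <- cumsum(tp_flags)
  cfp <- cumsum(!tp_flags)
  rec <- ctp / n_truth
  prec <- ctp / (ctp + cfp)
  mrec <- c(0, rec)
  mpre <- c(1, prec)
  for (i in rev(seq_len(length(mpre) - 1))) # precision envelope from the right
    mpre[i] <- max(mpre[i], mpre[i + 1])
  sum(diff(mrec) * mpre[-1])
}

#' Average precision over IoU thresholds
#'
#' COCO-protocol evaluation of scored mask predictions against ground
#' truth: at each IoU threshold predictions are matched greedily in
#' descending score order (each truth mask used at most once, a prediction
#' matching no free truth above the threshold is a false positive), the
#' all-point interpolated precision-recall curve is integrated, and the
#' resulting APs are averaged over the thresholds — by default the 10
#' thresholds 0.50 to 0.95 in steps of 0.05.
#'
#' @param predictions List of scored [instance_mask()] objects (each must
#'   carry a `score`).
#' @param truths Non-empty list of ground-truth [instance_mask()] objects.
#' @param iou_thresholds Numeric vector of IoU thresholds.
#' @param pred_image_ids,truth_image_ids Optional character vectors; when
#'   given, predictions only ever match truths from the same image.
#' @return An `ap_result` object; see [tidy.ap_result()] and
#'   [glance.ap_result()]. `$mean_ap` is the headline number.
#' @export
average_precision <- function(predictions, truths,
                              iou_thresholds = seq(0.5, 0.95, by = 0.05),
                              pred_image_ids = NULL, truth_image_ids = NULL) {
  if (length(truths) == 0)
    stop("no ground-truth masks: AP is undefined", call. = FALSE)
  if (is.null(pred_image_ids)) pred_image_ids <- rep("", length(predictions))
  if (is.null(truth_image_ids)) truth_image_ids <- rep("", length(truths))
  scores <- vapply(predictions, function(m) {
    if (is.null(m$score)) stop("every prediction needs a score", call. = FALSE)
    m$score
  }, numeric(1))
  ord <- order(-scores, seq_along(scores))
  predictions <- predictions[ord]
  pred_image_ids <- pred_image_ids[ord]
  scores <- scores[ord]
  iou <- matrix(0, length(predictions), length(truths))
  for (p in seq_along(predictions)) {
    for (t in seq_along(truths)) {
      if (pred_image_ids[p] != truth_image_ids[t]) next
      iou[p, t] <- mask_iou(predictions[[p]], truths[[t]])
    }
  }
  per <- vapply(iou_thresholds, function(thr)
    ap_integrate(ap_match_once(iou, thr), length(truths)), numeric(1))
  structure(list(
    per_threshold = tibble::tibble(iou_threshold = iou_thresholds, ap = per),
    mean_ap = mean(per),
    n_predictions = length(predictions), n_truths = length(truths)),
    class = "ap_result")
}

#' @export
print.ap_result <- function(x, ...) {
  cat(sprintf("<ap_result> mean AP %.4f over %d IoU threshold(s) (%d predictions, %d truths)\n",
              x$mean_ap, nrow(x$per_threshold), x$n_predictions, x$n_truths))
  invisible(x)
}

#' Tidy an AP evaluation
#'
#' @param x An `ap_result` from [average_precision()].
#' @param ... Unused.
#' @return Tibble with one row per IoU threshold.
#' @method tidy ap_result
#' @export
tidy.ap_result <- function(x, ...) x$per_threshold

#' One-row summary of an AP evaluation
#'
#' @inheritParams tidy.ap_result
#' @return One-row tibble with `mean_ap`, `n_predictions`, `n_truths`.
#' @method glance ap_result
#' @export
glance.ap_result <- function(x, ...) {
  tibble::tibble(mean_ap = x$mean_ap, n_predictions = x$n_predictions,
                 n_truths = x$n_truths)
}
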