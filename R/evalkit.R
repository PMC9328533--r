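#' Pixel confusion counts for a designated positive class
#'
#' @param pred,true equal-shaped class-id matrices.
#' @param positive_class the class id treated as positive (default 1,
#'   vegetation).
#' @return `list(tp, tn, fp, fn)` of class `confusion_counts`;
#'   the four counts sum to the number of evaluated pixels.
#' @export
confusion_counts <- function(pred, true, positive_class = 1L) {
  if (!all(dim(pred) == dim(true)))
    stop("`pred` and `true` must have equal shapes", call. = FALSE)
  p <- pred == positive_class
  t <- true == positive_class
  structure(list(tp = sum(p & t), tn = sum(!p & !t),
                 fp = sum(p & !t), fn = sum(!p & t)),
            class = "confusion_counts")
}

#' Combine confusion counts by pooling pixels
#' @param ... `confusion_counts` objects.
#' @return pooled `confusion_counts`.
#' @export
pool_counts <- function(...) {
  cs <- list(...)
  if (length(cs) == 1 && is.list(cs[[1]]) && !inherits(cs[[1]], "confusion_counts"))
    cs <- cs[[1]]
  structure(list(tp = sum(vapply(cs, `[[`, 0, "tp")),
                 tn = sum(vapply(cs, `[[`, 0, "tn")),
                 fp = sum(vapply(cs, `[[`, 0, "fp")),
                 fn = sum(vapply(cs, `[[`, 0, "fn"))),
            class = "confusion_counts")
}

#' Binary segmentation metrics from confusion counts
#'
#' Computes precision `tp/(tp+fp)`, recall `tp/(tp+fn)`,
#' F1 `2PR/(P+R)` and overall accuracy `(tp+tn)/(tp+tn+fp+fn)`.
#' A metric whose denominator is zero is returned as 0 and named in the
#' `degenerate` field.
#'
#' @param counts a [confusion_counts()].
#' @return `list(precision, recall, f1, overall_accuracy, degenerate)`.
#' @export
binary_metrics <- function(counts) {
  with(counts, {
    total <- tp + tn + fp + fn
    if (total == 0) stop("all confusion counts are zero", call. = FALSE)
    degen <- character(0)
    safe <- function(num, den, name) {
      if (den == 0) { degen <<- c(degen, name); 0 } else num / den
    }
    P <- safe(tp, tp + fp, "precision")
    R <- safe(tp, tp + fn, "recall")
    F1 <- safe(2 * P * R, P + R, "f1")
    list(precision = P, recall = R, f1 = F1,
         overall_accuracy = (tp + tn) / total, degenerate = degen)
  })
}

#' Per-class intersection-over-union and its mean
#'
#' `IoU_k = |pred_k intersect true_k| / |pred_k union true_k|`; classes
#' whose union is empty (absent from both rasters) are excluded from the
#' mean and reported as `NA`.
#'
#' @param pred,true equal-shaped class-id matrices.
#' @param classes class ids to score (default 0:2).
#' @return `list(iou = named per-class vector, miou = mean over classes
#'   with non-empty union)`.
#' @export
iou_scores <- function(pred, true, classes = 0:2) {
  if (!all(dim(pred) == dim(true)))
    stop("`pred` and `true` must have equal shapes", call. = FALSE)
  iou <- vapply(classes, function(k) {
    p <- pred == k; t <- true == k
    u <- sum(p | t)
    if (u == 0) NA_real_ else sum(p & t) / u
  }, numeric(1))
  names(iou) <- as.character(classes)
  list(iou = iou, miou = mean(iou, na.rm = TRUE))
}

#' Evaluate a trained model on a test set
#'
#' Predicts a mask for every pair, pools pixel confusion counts over the
#' whole set (micro-averaging) for the binary metrics, computes
#' multi-class IoU/mIoU on the pooled pixels, and reports the per-image
#' overall-accuracy spread.
#'
#' @param model a trained segmentation model (see [build_unet()]).
#' @param pairs non-empty list of [scene_pair()] objects with truth masks.
#' @param positive_class positive class id for the binary metrics.
#' @param classes class ids for IoU.
#' @return a `metric_report` list: `precision`, `recall`, `f1`,
#'   `overall_accuracy`, `iou`, `miou`, `per_image_oa` (vector),
#'   `oa_min`, `oa_max`, `n_images`.
#' @export
evaluate_testset <- function(model, pairs, positive_class = 1L,
                             classes = 0:2) {
  if (length(pairs) == 0) stop("empty test set", call. = FALSE)
  counts <- vector("list", length(pairs))
  per_oa <- numeric(length(pairs))
  inter <- stats::setNames(numeric(length(classes)), classes)
  uni <- inter
  for (i in seq_along(pairs)) {
    pred <- predict_mask(model, pairs[[i]]$image)$mask
    true <- pairs[[i]]$mask
    counts[[i]] <- confusion_counts(pred, true, positive_class)
    per_oa[i] <- mean(pred == true)
    for (k in seq_along(classes)) {
      p <- pred == classes[k]; t <- true == classes[k]
      inter[k] <- inter[k] + sum(p & t)
      uni[k] <- uni[k] + sum(p | t)
    }
  }
  pooled <- pool_counts(counts)
  m <- binary_metrics(pooled)
  iou <- ifelse(uni > 0, inter / uni, NA_real_)
  structure(c(m[c("precision", "recall", "f1", "overall_accuracy")],
              list(iou = iou, miou = mean(iou, na.rm = TRUE),
                   pooled_counts = pooled, per_image_oa = per_oa,
                   oa_min = min(per_oa), oa_max = max(per_oa),
                   n_images = length(pairs), degenerate = m$degenerate)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(paste0("<metric_report> n=%d  P=%.4f R=%.4f F1=%.4f OA=%.4f ",
                     "mIoU=%.4f  per-image OA %.3f..%.3f\n"),
              x$n_images, x$precision, x$recall, x$f1, x$overall_accuracy,
              x$miou, x$oa_min, x$oa_max))
  invisible(x)
}
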