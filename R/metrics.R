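#' Pixel Intersection-over-Union of two binary masks
#'
#' `|pred & gt| / |pred | gt|`. Two empty masks agree vacuously and score
#' 1.0 (in the evaluation pipeline this case is excluded anyway, because IoU
#' is only aggregated over true-positive images).
#'
#' @param pred,gt Binary matrices/arrays of identical shape.
#' @return IoU in \[0, 1\].
#' @export
#' @examples
#' a <- matrix(c(1, 1, 0, 0), 2, 2)
#' pixel_iou(a, a)
pixel_iou <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt)))
    stop("mask shapes differ", call. = FALSE)
  p <- pred > 0; g <- gt > 0
  u <- sum(p | g)
  if (u == 0) return(1.0)
  sum(p & g) / u
}

#' Image-level presence confusion counts per class
#'
#' A class is "present" in an image when its channel has at least one
#' positive pixel. For each class, images are tallied as TP (present in
#' ground truth and prediction), TN (absent in both), FP (predicted only)
#' or FN (ground truth only); the four counts sum to the number of images.
#'
#' @param pred,gt Equal-length lists of H x W x 5 binary arrays (paired by
#'   position).
#' @return An object of class `instance_confusion`: data frame with columns
#'   `class`, `TP`, `TN`, `FP`, `FN`.
#' @export
instance_confusion <- function(pred, gt) {
  if (length(pred) != length(gt))
    stop("prediction and ground-truth lists differ in length", call. = FALSE)
  if (length(pred) == 0L) stop("empty input", call. = FALSE)
  cls <- periseg_classes()
  tab <- data.frame(class = cls, TP = 0L, TN = 0L, FP = 0L, FN = 0L)
  for (i in seq_along(pred)) {
    pp <- apply(pred[[i]], 3L, sum) > 0
    gp <- apply(gt[[i]], 3L, sum) > 0
    tab$TP <- tab$TP + (pp & gp)
    tab$TN <- tab$TN + (!pp & !gp)
    tab$FP <- tab$FP + (pp & !gp)
    tab$FN <- tab$FN + (!pp & gp)
  }
  structure(tab, class = c("instance_confusion", "data.frame"))
}

#' Summarise confusion counts and per-image IoUs into a metrics report
#'
#' Computes, per class: accuracy `(TP+TN)/N`, specificity `TN/(TN+FP)`
#' (undefined — reported as `NA`, rendered `"-"` — when `TN+FP = 0`, i.e.
#' for classes present in every image), sensitivity/recall `TP/(TP+FN)`,
#' precision `TP/(TP+FP)`, and the mean and standard deviation of IoU over
#' true-positive images only. The weighted average IoU weights each class's
#' mean IoU by its TP count.
#'
#' @param confusion An [instance_confusion()].
#' @param ious Named list (by class) of per-image IoU vectors over
#'   true-positive images; missing/empty entries give `NA` IoU summaries.
#' @return An object of class `metrics_report`: list with `per_class` (data
#'   frame) and `weighted_iou`.
#' @export
summarize_metrics <- function(confusion, ious = NULL) {
  stopifnot(inherits(confusion, "instance_confusion"))
  cls <- periseg_classes()
  safe_div <- function(a, b) ifelse(b == 0, NA_real_, a / b)
  n <- confusion$TP + confusion$TN + confusion$FP + confusion$FN
  df <- data.frame(
    class = cls,
    TP = confusion$TP, TN = confusion$TN, FP = confusion$FP,
    FN = confusion$FN,
    accuracy = safe_div(confusion$TP + confusion$TN, n),
    specificity = safe_div(confusion$TN, confusion$TN + confusion$FP),
    sensitivity = safe_div(confusion$TP, confusion$TP + confusion$FN),
    precision = safe_div(confusion$TP, confusion$TP + confusion$FP))
  df$iou_mean <- df$iou_sd <- NA_real_
  for (k in seq_along(cls)) {
    v <- ious[[cls[k]]]
    if (!is.null(v) && length(v)) {
      df$iou_mean[k] <- mean(v)
      df$iou_sd[k] <- if (length(v) > 1L) sd(v) else 0
    }
  }
  wts <- df$TP
  ok <- !is.na(df$iou_mean) & wts > 0
  weighted_iou <- if (any(ok)) sum(wts[ok] * df$iou_mean[ok]) / sum(wts[ok])
                  else NA_real_
  structure(list(per_class = df, weighted_iou = weighted_iou),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  df <- x$per_class
  fmt <- function(v) ifelse(is.na(v), "-", sprintf("%.3f", v))
  out <- data.frame(class = df$class, TP = df$TP, TN = df$TN, FP = df$FP,
                    FN = df$FN, accuracy = fmt(df$accuracy),
                    specificity = fmt(df$specificity),
                    sensitivity = fmt(df$sensitivity),
                    precision = fmt(df$precision),
                    iou_mean = fmt(df$iou_mean), iou_sd = fmt(df$iou_sd))
  print(out, row.names = FALSE)
  cat(sprintf("weighted average IoU: %s\n",
              if (is.na(x$weighted_iou)) "-"
              else sprintf("%.3f", x$weighted_iou)))
  invisible(x)
}

#' Evaluate predicted mask stacks against ground truth
#'
#' Convenience wrapper: builds the presence confusion, collects per-class
#' IoUs over true-positive images, and summarises them into a report.
#'
#' @param pred,gt Equal-length lists of H x W x 5 binary arrays.
#' @return A `metrics_report` with the `instance_confusion` attached as
#'   `$confusion` and the raw per-class IoU vectors as `$ious`.
#' @export
evaluate_predictions <- function(pred, gt) {
  conf <- instance_confusion(pred, gt)
  cls <- periseg_classes()
  ious <- lapply(seq_along(cls), function(k) {
    v <- numeric(0)
    for (i in seq_along(pred)) {
      pp <- sum(pred[[i]][, , k]) > 0
      gp <- sum(gt[[i]][, , k]) > 0
      if (pp && gp) v <- c(v, pixel_iou(pred[[i]][, , k], gt[[i]][, , k]))
    }
    v
  })
  names(ious) <- cls
  rep <- summarize_metrics(conf, ious)
  rep$confusion <- conf
  rep$ious <- ious
  rep
}

#' Correlate per-class IoU with mask size and with presence counts
#'
#' Pearson correlations between the per-class mean IoU and (a) the mean mask
#' size in pixels, (b) the number of images in which the class is present —
#' the two dataset-imbalance effects on prediction accuracy.
#'
#' @param sizes Per-class mean mask sizes (pixels).
#' @param counts Per-class presence counts.
#' @param ious Per-class mean IoUs.
#' @return Named numeric vector `c(size_iou = , count_iou = )`; an entry is
#'   `NA` when fewer than 3 complete pairs exist or a variable is constant.
#' @export
#' @examples
#' correlate_iou(c(100, 400, 900), c(5, 20, 45), c(0.2, 0.5, 0.8))
correlate_iou <- function(sizes, counts, ious) {
  safe_cor <- function(a, b) {
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < 3L || sd(a[ok]) == 0 || sd(b[ok]) == 0) return(NA_real_)
    cor(a[ok], b[ok])
  }
  c(size_iou = safe_cor(sizes, ious), count_iou = safe_cor(counts, ious))
}

#' Write a metrics report as CSV and JSON
#'
#' The CSV mirrors the published table layout: one row per class and rate
#' (accuracy, specificity, sensitivity, precision, IoU mean/sd), with
#' undefined cells rendered as `"-"`.
#'
#' @param report A `metrics_report` (several can be passed as a named list
#'   to produce one column per model/dataset).
#' @param prefix Output prefix; `<prefix>.csv` and `<prefix>.json` are
#'   written.
#' @return `prefix`, invisibly.
#' @export
write_metrics_report <- function(report, prefix) {
  reports <- if (inherits(report, "metrics_report")) list(value = report)
             else report
  cls <- periseg_classes()
  rates <- c("accuracy", "specificity", "sensitivity", "precision",
             "iou_mean", "iou_sd")
  rows <- list()
  for (k in cls) for (r in rates)
    rows[[paste(k, r)]] <- data.frame(class = k, metric = r)
  df <- do.call(rbind, rows)
  for (nm in names(reports)) {
    pc <- reports[[nm]]$per_class
    col <- mapply(function(k, r) {
      v <- pc[pc$class == k, r]
      if (is.na(v)) "-" else sprintf("%.3f", v)
    }, df$class, df$metric)
    df[[nm]] <- unname(col)
  }
  wrow <- data.frame(class = "all", metric = "weighted_iou")
  for (nm in names(reports))
    wrow[[nm]] <- if (is.na(reports[[nm]]$weighted_iou)) "-"
                  else sprintf("%.3f", reports[[nm]]$weighted_iou)
  df <- rbind(df, wrow)
  write.csv(df, paste0(prefix, ".csv"), row.names = FALSE)
  jsonlite::write_json(
    lapply(reports, function(rep)
      list(per_class = rep$per_class, weighted_iou = rep$weighted_iou)),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA, na = "string")
  invisible(prefix)
}
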