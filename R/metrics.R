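# The seven evaluation metrics: the overlap family from pixel confusion
# counts and the average symmetric surface distance (ASSD) from boundary
# distances, with slice- and volume-level aggregation.

check_binary <- function(x, name) {
  if (!all(x %in% c(0, 1) | x %in% c(FALSE, TRUE))) {
    stop(name, " must be binary (0/1)")
  }
  invisible(x)
}

#' Pixel confusion counts
#'
#' @param pred predicted binary mask (matrix).
#' @param truth ground-truth binary mask, same extent.
#' @return list with integer `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth))) stop("mask extents differ")
  check_binary(pred, "pred")
  check_binary(truth, "truth")
  a <- pred > 0
  b <- truth > 0
  list(
    TP = sum(a & b), TN = sum(!a & !b),
    FP = sum(a & !b), FN = sum(!a & b)
  )
}

#' Overlap metrics from confusion counts
#'
#' Dice `2TP/(2TP+FP+FN)`, Jaccard `TP/(TP+FP+FN)`, VOE `1 - Jaccard`,
#' accuracy, sensitivity (recall) and specificity.  Empty-mask policy: when
#' prediction and truth are both empty, Dice and Jaccard are 1 (VOE 0) and
#' sensitivity is undefined (`NA`); sensitivity is `NA` whenever `TP+FN = 0`
#' rather than silently 0.
#'
#' @param counts list from [confusion_counts()] (or a prediction matrix, in
#'   which case `truth` must be given).
#' @param truth optional ground-truth mask.
#' @return named list of the six overlap metrics.
#' @export
overlap_metrics <- function(counts, truth = NULL) {
  if (!is.null(truth)) counts <- confusion_counts(counts, truth)
  TP <- counts$TP
  TN <- counts$TN
  FP <- counts$FP
  FN <- counts$FN
  total <- TP + TN + FP + FN
  if (total == 0) stop("empty masks")
  pos <- 2 * TP + FP + FN
  dice <- if (pos == 0) 1 else 2 * TP / pos
  jac <- if (TP + FP + FN == 0) 1 else TP / (TP + FP + FN)
  list(
    dice = dice,
    jaccard = jac,
    voe = 1 - jac,
    accuracy = (TP + TN) / total,
    sensitivity = if (TP + FN == 0) NA_real_ else TP / (TP + FN),
    specificity = if (TN + FP == 0) NA_real_ else TN / (TN + FP)
  )
}

# Boundary pixels: foreground with at least one background 4-neighbour;
# the image border counts as background.
boundary_mask <- function(m) {
  m <- m > 0
  H <- nrow(m)
  W <- ncol(m)
  pad <- matrix(FALSE, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- m
  inner <- pad[1:H, 2:(W + 1L)] & pad[3:(H + 2L), 2:(W + 1L)] &
    pad[2:(H + 1L), 1:W] & pad[2:(H + 1L), 3:(W + 2L)]
  m & !inner
}

#' Average symmetric surface distance
#'
#' Boundaries are foreground pixels with a background 4-neighbour (the image
#' border counts as background).  Distances are Euclidean point-to-boundary
#' distances computed with an exact distance transform, in pixel units, or
#' millimetres when `spacing` is given.  Undefined (`NA`) when either mask
#' is empty.
#'
#' @param pred,truth binary masks (matrices of equal extent).
#' @param spacing optional `(row, col)` pixel spacing in mm.
#' @return the ASSD, or `NA_real_` when undefined.
#' @examples
#' a <- matrix(0, 8, 8)
#' a[1, 1] <- 1
#' b <- matrix(0, 8, 8)
#' b[4, 5] <- 1
#' assd(a, b) # 5: the 3-4-5 triangle
#' @export
assd <- function(pred, truth, spacing = NULL) {
  check_binary(pred, "pred")
  check_binary(truth, "truth")
  if (!all(dim(pred) == dim(truth))) stop("mask extents differ")
  if (sum(pred) == 0 || sum(truth) == 0) {
    return(NA_real_)
  }
  s <- surface_distances(pred, truth, spacing)
  (sum(s$d_pred) + sum(s$d_truth)) / (length(s$d_pred) + length(s$d_truth))
}

# distances from each boundary pixel of one mask to the other's boundary
surface_distances <- function(pred, truth, spacing = NULL) {
  if (is.null(spacing)) spacing <- c(1, 1)
  bp <- boundary_mask(pred)
  bt <- boundary_mask(truth)
  dt_pred <- sqrt(cpp_edt(bp, spacing[1], spacing[2]))
  dt_truth <- sqrt(cpp_edt(bt, spacing[1], spacing[2]))
  list(
    d_pred = dt_truth[bp], # from predicted boundary to truth boundary
    d_truth = dt_pred[bt]
  )
}

#' Seven-metric report for a set of mask pairs
#'
#' Computes Dice, Jaccard, VOE, accuracy, sensitivity, specificity and ASSD
#' per case and aggregates them as mean and population standard deviation.
#' In volume grouping, confusion counts are pooled over each volume's slices
#' before the overlap metrics are computed, and ASSD pools all slice
#' boundary distances of the volume.  Cases with an empty prediction against
#' a non-empty truth are flagged in the `non_segmentation` column.
#'
#' @param pred binary array `(h, w, n)` of predictions.
#' @param truth binary array `(h, w, n)` of ground truth.
#' @param grouping `"slice"` or `"volume"`.
#' @param volume_ids per-slice volume assignment (volume grouping).
#' @param spacing optional pixel spacing in mm.
#' @return object of class `metric_report`: list with `cases` (per-case
#'   data frame) and `aggregate` (mean/sd per metric).
#' @export
segmentation_report <- function(pred, truth, grouping = c("slice", "volume"),
                                volume_ids = NULL, spacing = NULL) {
  grouping <- match.arg(grouping)
  n <- dim(pred)[3]
  stopifnot(all(dim(pred) == dim(truth)), n >= 1)
  if (grouping == "volume") {
    if (is.null(volume_ids)) stop("volume grouping needs volume_ids")
    groups <- split(seq_len(n), volume_ids)
  } else {
    groups <- as.list(seq_len(n))
    names(groups) <- sprintf("slice_%03d", seq_len(n))
  }
  rows <- lapply(names(groups), function(g) {
    idx <- groups[[g]]
    cc <- list(TP = 0, TN = 0, FP = 0, FN = 0)
    dp <- numeric(0)
    dt <- numeric(0)
    for (i in idx) {
      ci <- confusion_counts(pred[, , i], truth[, , i])
      cc <- Map(`+`, cc, ci)
      if (sum(pred[, , i]) > 0 && sum(truth[, , i]) > 0) {
        s <- surface_distances(pred[, , i], truth[, , i], spacing)
        dp <- c(dp, s$d_pred)
        dt <- c(dt, s$d_truth)
      }
    }
    om <- overlap_metrics(cc)
    data.frame( # column order follows the published result tables
      case = g,
      dice = om$dice,
      assd = if (length(dp) + length(dt) > 0) {
        (sum(dp) + sum(dt)) / (length(dp) + length(dt))
      } else {
        NA_real_
      },
      jaccard = om$jaccard, voe = om$voe,
      accuracy = om$accuracy, sensitivity = om$sensitivity,
      specificity = om$specificity,
      non_segmentation = cc$TP + cc$FP == 0 && cc$FN > 0,
      stringsAsFactors = FALSE
    )
  })
  cases <- do.call(rbind, rows)
  metrics <- c(
    "dice", "assd", "jaccard", "voe", "accuracy", "sensitivity",
    "specificity"
  )
  pop_sd <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) {
      return(NA_real_)
    }
    sqrt(mean((v - mean(v))^2))
  }
  agg <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(cases[[m]], na.rm = TRUE), numeric(1)),
    sd = vapply(metrics, function(m) pop_sd(cases[[m]]), numeric(1)),
    row.names = NULL
  )
  structure(
    list(
      cases = cases, aggregate = agg, grouping = grouping,
      n_non_segmentation = sum(cases$non_segmentation)
    ),
    class = "metric_report"
  )
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "Segmentation report (%s grouping, %d cases, %d non-segmentations)\n",
    x$grouping, nrow(x$cases), x$n_non_segmentation
  ))
  a <- x$aggregate
  for (i in seq_len(nrow(a))) {
    cat(sprintf("  %-12s %.4f +/- %.4f\n", a$metric[i], a$mean[i], a$sd[i]))
  }
  invisible(x)
}

#' Write a report's per-case and aggregate tables to CSV
#'
#' @param report a `metric_report`.
#' @param path_cases,path_aggregate output CSV paths (either may be `NULL`).
#' @export
write_report_csv <- function(report, path_cases = NULL, path_aggregate = NULL) {
  if (!is.null(path_cases)) write.csv(report$cases, path_cases, row.names = FALSE)
  if (!is.null(path_aggregate)) {
    write.csv(report$aggregate, path_aggregate, row.names = FALSE)
  }
  invisible(report)
}
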