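## Voxel-wise segmentation evaluation: confusion counts, the five
## overlap/ratio metrics, the exact symmetric Hausdorff distance, patient
## gathering, cross-validation grouping and paired statistics.

check_matched_volumes <- function(gt, pred) {
  validate_label_volume(gt)
  validate_label_volume(pred)
  if (!identical(dim(gt$voxels), dim(pred$voxels)))
    stop_validation("volume shapes differ: %s vs %s",
                    paste(dim(gt$voxels), collapse = "x"),
                    paste(dim(pred$voxels), collapse = "x"))
  if (max(abs(gt$spacing - pred$spacing)) > 1e-6)
    stop_validation("voxel spacings differ: (%s) vs (%s) mm",
                    paste(signif(gt$spacing, 6), collapse = ", "),
                    paste(signif(pred$spacing, 6), collapse = ", "))
  invisible(TRUE)
}

#' Voxel-wise confusion counts for one label
#'
#' Counts, over the whole matched volume pair, voxels where both volumes
#' carry `label` (TP), only the prediction does (FP), only the reference
#' does (FN), and neither does (TN).
#'
#' @param gt,pred matched [label_volume()]s (same shape and spacing).
#' @param label the label code to evaluate (1 = TL, 2 = FL).
#' @return an object of class `confusion_counts` with fields `tp`, `tn`,
#'   `fp`, `fn`, `label`, `total`.
#' @export
confusion_counts <- function(gt, pred, label) {
  check_matched_volumes(gt, pred)
  g <- gt$voxels == label
  p <- pred$voxels == label
  tp <- sum(g & p)
  fp <- sum(!g & p)
  fn <- sum(g & !p)
  tn <- length(g) - tp - fp - fn
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 label = label, total = length(g)),
            class = "confusion_counts")
}

#' Overlap and ratio metrics from confusion counts
#'
#' Computes accuracy `(TP+TN)/(TP+TN+FP+FN)`, precision `TP/(TP+FP)`,
#' recall `TP/(TP+FN)`, IoU `TP/(TP+FP+FN)` and Dice
#' `2TP/(2TP+FP+FN)`, all as fractions in `[0, 1]`. Ratios with a zero
#' denominator are returned as `NA` with a warning rather than coerced to
#' 0, so they can be excluded pairwise from downstream statistics.
#'
#' @param counts a [confusion_counts()] object, or a list with fields
#'   `tp`, `tn`, `fp`, `fn`.
#' @return an object of class `metric_set` with fields `accuracy`,
#'   `precision`, `recall`, `iou`, `dsc` and `hd` (`NA` here; see
#'   [hausdorff_distance()]).
#' @export
compute_metrics <- function(counts) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  if (any(c(tp, tn, fp, fn) < 0)) stop_validation("negative confusion counts")
  total <- tp + tn + fp + fn
  ratio <- function(num, den, name) {
    if (den == 0) {
      warning(sprintf("%s undefined (zero denominator); recorded as NA", name),
              call. = FALSE)
      return(NA_real_)
    }
    num / den
  }
  structure(list(
    accuracy = ratio(tp + tn, total, "accuracy"),
    precision = ratio(tp, tp + fp, "precision"),
    recall = ratio(tp, tp + fn, "recall"),
    iou = ratio(tp, tp + fp + fn, "IoU"),
    dsc = ratio(2 * tp, 2 * tp + fp + fn, "DSC"),
    hd = NA_real_
  ), class = "metric_set")
}

#' Symmetric Hausdorff distance between two label sets
#'
#' The point sets are the centres of all voxels carrying `label` in each
#' volume, in physical mm coordinates (0-based index times spacing). The
#' returned value is `max(h(G, P), h(P, G))` with
#' `h(A, B) = max_{a in A} min_{b in B} ||a - b||_2`, computed exactly via
#' two full-set Euclidean distance transforms (not boundary-only, which
#' is inequivalent when one set has an interior cavity).
#'
#' @param gt,pred matched [label_volume()]s.
#' @param label label code to compare.
#' @param units `"mm"` (physical, default) or `"voxel"` (unit spacing).
#' @return nonnegative distance; `+Inf` with a warning if the label is
#'   absent from either volume.
#' @export
hausdorff_distance <- function(gt, pred, label, units = c("mm", "voxel")) {
  check_matched_volumes(gt, pred)
  units <- match.arg(units)
  g <- gt$voxels == label
  p <- pred$voxels == label
  if (!any(g) || !any(p)) {
    warning(sprintf("label %s absent from %s; Hausdorff distance is +Inf",
                    label,
                    paste(c("gt", "pred")[c(!any(g), !any(p))], collapse = " and ")),
            call. = FALSE)
    return(Inf)
  }
  sp <- if (units == "mm") gt$spacing else c(1, 1, 1)
  dg <- edt_mm(g, sp)
  dp <- edt_mm(p, sp)
  max(max(dp[g]), max(dg[p]))
}

#' Patient-level metrics for TL and FL
#'
#' Gathers all slices of a matched volume pair and computes the six
#' evaluation metrics per label on a per-voxel basis over the whole 3D
#' volume (not averaged over per-slice metrics).
#'
#' @param gt,pred matched [label_volume()]s.
#' @param labels named integer vector of label codes to evaluate.
#' @param hd_units `"mm"` or `"voxel"`, passed to [hausdorff_distance()].
#' @return a `data.frame` with one row per label and columns `label`,
#'   `accuracy`, `precision`, `recall`, `iou`, `dsc` (fractions) and `hd`.
#' @export
patient_metrics <- function(gt, pred, labels = c(TL = 1L, FL = 2L),
                            hd_units = "mm") {
  rows <- lapply(seq_along(labels), function(i) {
    m <- compute_metrics(confusion_counts(gt, pred, labels[i]))
    hd <- hausdorff_distance(gt, pred, labels[i], units = hd_units)
    data.frame(label = names(labels)[i] %||% as.character(labels[i]),
               accuracy = m$accuracy, precision = m$precision,
               recall = m$recall, iou = m$iou, dsc = m$dsc, hd = hd)
  })
  do.call(rbind, rows)
}

#' Random cross-validation fold assignment
#'
#' Partitions patients into `k` folds of equal-as-possible size (sizes
#' differ by at most 1), deterministically given the seed.
#'
#' @param patient_ids vector of patient identifiers.
#' @param k number of folds (default 4).
#' @param seed integer seed.
#' @return a `data.frame` of class `cv_layout` with columns `patient_id`
#'   and `fold` (in `1..k`).
#' @export
make_cv_layout <- function(patient_ids, k = 4L, seed = 1L) {
  n <- length(patient_ids)
  if (k < 2L) stop_validation("k must be >= 2")
  if (k > n) stop_validation("k (%d) exceeds the number of patients (%d)", k, n)
  fold <- withr::with_seed(seed, sample(rep(seq_len(k), length.out = n)))
  out <- data.frame(patient_id = patient_ids, fold = fold)
  class(out) <- c("cv_layout", "data.frame")
  attr(out, "seed") <- seed
  out
}

#' Paired comparison of per-patient metric values
#'
#' Forms per-patient differences `d = a - b`, checks their normality with
#' the Shapiro-Wilk test, and compares the two conditions with a
#' two-sided paired t-test (significance at `alpha`). Pairs where either
#' value is `NA` are dropped with a warning.
#'
#' @param values_a,values_b equal-length numeric vectors paired by
#'   patient (e.g. a metric under two segmentation models).
#' @param metric_name label carried through to the result.
#' @param alpha significance level (default 0.05).
#' @return an object of class `paired_comparison` with fields
#'   `metric_name`, `differences`, `n`, `shapiro_w`, `shapiro_p`,
#'   `t_statistic`, `t_p`, `significant`, `alpha`.
#' @export
paired_comparison <- function(values_a, values_b, metric_name = "metric",
                              alpha = 0.05) {
  if (length(values_a) != length(values_b))
    stop_validation("paired vectors must have equal length (%d vs %d)",
                    length(values_a), length(values_b))
  keep <- is.finite(values_a) & is.finite(values_b)
  if (!all(keep))
    warning(sprintf("%d pair(s) with missing values excluded pairwise",
                    sum(!keep)), call. = FALSE)
  a <- values_a[keep]; b <- values_b[keep]
  if (length(a) < 3L)
    stop_validation("need >= 3 complete pairs (got %d)", length(a))
  d <- a - b
  if (sd(d) == 0)
    stop_validation("all paired differences are identical (zero variance); the paired t statistic is undefined")
  sw <- shapiro.test(d)
  tt <- t.test(a, b, paired = TRUE)
  structure(list(metric_name = metric_name,
                 differences = d,
                 n = length(d),
                 shapiro_w = unname(sw$statistic),
                 shapiro_p = sw$p.value,
                 t_statistic = unname(tt$statistic),
                 t_p = tt$p.value,
                 significant = tt$p.value < alpha,
                 alpha = alpha),
            class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("<paired_comparison> %s, n = %d\n", x$metric_name, x$n))
  cat(sprintf("  Shapiro-Wilk W = %.4f (p = %.4g)\n", x$shapiro_w, x$shapiro_p))
  cat(sprintf("  paired t = %.4f (p = %.4g)%s\n", x$t_statistic, x$t_p,
              if (x$significant) sprintf(" *significant at alpha = %g*", x$alpha) else ""))
  invisible(x)
}

#' Summarise per-patient metrics as mean and standard deviation
#'
#' Aggregates a long per-patient metric table into the usual
#' mean +/- SD presentation per condition and label, with fractions
#' rescaled to percentages (Hausdorff distances are left in their units).
#'
#' @param df `data.frame` with columns `patient_id`, `label`, the metric
#'   columns `accuracy`, `precision`, `recall`, `iou`, `dsc`, `hd`, and
#'   optionally `net` (the condition; e.g. segmentation model).
#' @return a `data.frame` with columns `net` (if present), `label`,
#'   `metric`, `mean`, `sd`, `n`.
#' @export
summarize_metrics <- function(df) {
  metric_cols <- c("accuracy", "precision", "recall", "iou", "dsc", "hd")
  by_cols <- intersect(c("net", "label"), names(df))
  groups <- unique(df[by_cols])
  rows <- list()
  for (i in seq_len(nrow(groups))) {
    sel <- rep(TRUE, nrow(df))
    for (cc in by_cols) sel <- sel & df[[cc]] == groups[[cc]][i]
    for (mc in metric_cols) {
      v <- df[[mc]][sel]
      v <- v[is.finite(v)]
      scale <- if (mc == "hd") 1 else 100
      rows[[length(rows) + 1L]] <- cbind(
        groups[i, , drop = FALSE],
        data.frame(metric = mc, mean = mean(v) * scale,
                   sd = if (length(v) > 1) sd(v) * scale else NA_real_,
                   n = length(v), row.names = NULL))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
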