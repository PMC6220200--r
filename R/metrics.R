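#' Voxelwise confusion counts
#'
#' Foreground (proximal femur) voxels are the positive class, background
#' the negative class.
#'
#' @param pred,gt aligned [label_mask()]s (prediction and ground truth).
#' @return a `confusion_counts` list with `TP`, `FP`, `FN`, `TN`.
#' @export
confusion <- function(pred, gt) {
  stopifnot(inherits(pred, "label_mask"), inherits(gt, "label_mask"))
  check_aligned(pred, gt)
  p <- pred$data == 1
  g <- gt$data == 1
  structure(list(TP = sum(p & g), FP = sum(p & !g),
                 FN = sum(!p & g), TN = sum(!p & !g)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion> TP %d  FP %d  FN %d  TN %d\n",
              x$TP, x$FP, x$FN, x$TN))
  invisible(x)
}

#' Dice similarity coefficient
#'
#' `DSC = 2 TP / (FP + 2 TP + FN)`, the standard overlap statistic (also
#' the F1 score). When both masks are empty the coefficient is defined
#' as 1 by convention, with a warning.
#'
#' @param c a `confusion_counts` from [confusion()].
#' @return DSC in `[0, 1]`.
#' @export
dsc <- function(c) {
  den <- c$FP + 2 * c$TP + c$FN
  if (den == 0) {
    warning("dsc: both masks empty; returning 1 by convention",
            call. = FALSE)
    return(1)
  }
  2 * c$TP / den
}

#' Sensitivity / recall, specificity and precision
#'
#' `recall = TP/(TP+FN)`, `specificity = TN/(TN+FP)`,
#' `precision = TP/(TP+FP)`. A zero denominator yields `NA` (a flagged
#' undefined value, excluded from aggregation) with a warning.
#'
#' @param c a `confusion_counts`.
#' @return value in `[0, 1]` or `NA`.
#' @export
recall <- function(c) safe_ratio(c$TP, c$TP + c$FN, "recall")

#' @rdname recall
#' @export
specificity <- function(c) safe_ratio(c$TN, c$TN + c$FP, "specificity")

#' @rdname recall
#' @export
precision <- function(c) safe_ratio(c$TP, c$TP + c$FP, "precision")

safe_ratio <- function(num, den, what) {
  if (den == 0) {
    warning(what, ": zero denominator; returning NA", call. = FALSE)
    return(NA_real_)
  }
  num / den
}

#' Surface voxels of a mask
#'
#' Foreground voxels with at least one face-adjacent (6-neighbourhood)
#' background neighbour; out-of-grid neighbours count as background, so
#' foreground touching the grid boundary is surface.
#'
#' @param m a nonempty [label_mask()].
#' @return a `surface_set`: voxel indices (1-based), physical mm
#'   coordinates of the voxel centers, and the spacing.
#' @export
surface_voxels <- function(m) {
  stopifnot(inherits(m, "label_mask"))
  a <- m$data == 1
  if (!any(a)) stop("surface_voxels: empty mask", call. = FALSE)
  d <- dim(a)
  pa <- array(FALSE, d + 2L)
  pa[1L + seq_len(d[1L]), 1L + seq_len(d[2L]), 1L + seq_len(d[3L])] <- a
  interior <- array(TRUE, d)
  for (off in list(c(1L, 0L, 0L), c(-1L, 0L, 0L), c(0L, 1L, 0L),
                   c(0L, -1L, 0L), c(0L, 0L, 1L), c(0L, 0L, -1L))) {
    nb <- pa[1L + off[1L] + seq_len(d[1L]),
             1L + off[2L] + seq_len(d[2L]),
             1L + off[3L] + seq_len(d[3L])]
    interior <- interior & nb
  }
  surf <- a & !interior
  idx <- which(surf, arr.ind = TRUE)
  mm <- sweep(idx - 1L, 2L, m$spacing, `*`)
  structure(list(index = idx, mm = mm, spacing = m$spacing),
            class = "surface_set")
}

#' Average symmetric surface distance (mm)
#'
#' `ASD = (sum_{x in S} d(x, G) + sum_{x in G} d(x, S)) / (N_S + N_G)`
#' with `d` the exact Euclidean nearest-neighbour distance between voxel
#' centers in physical units; `S` and `G` are the prediction and
#' ground-truth surface voxel sets.
#'
#' @param pred,gt [label_mask()]s with equal spacing.
#' @return distance in mm (`NA` with a warning when a side is empty).
#' @export
asd <- function(pred, gt) {
  sd <- surface_dists(pred, gt)
  if (is.null(sd)) return(NA_real_)
  (sum(sd$sg) + sum(sd$gs)) / (length(sd$sg) + length(sd$gs))
}

#' Maximum symmetric surface distance (symmetric Hausdorff distance, mm)
#'
#' The maximum of the two directed maximal nearest-surface distances.
#'
#' @inheritParams asd
#' @return distance in mm (`NA` with a warning when a side is empty).
#' @export
msd <- function(pred, gt) {
  sd <- surface_dists(pred, gt)
  if (is.null(sd)) return(NA_real_)
  max(max(sd$sg), max(sd$gs))
}

surface_dists <- function(pred, gt) {
  check_aligned(pred, gt)
  if (!any(pred$data == 1) || !any(gt$data == 1)) {
    warning("surface distance undefined for an empty mask; returning NA",
            call. = FALSE)
    return(NULL)
  }
  s <- surface_voxels(pred)$mm
  g <- surface_voxels(gt)$mm
  list(sg = directed_surface_dists(s, g), gs = directed_surface_dists(g, s))
}

#' ROC and precision-recall curves with AUC and average precision
#'
#' Thresholds are the unique probability values in descending order; a
#' prediction at threshold `t` is `p > t` (consistent with
#' [binarize()]), and a final all-positive point completes the curves.
#' The ROC area is computed by the trapezoidal rule over (FPR, TPR); the
#' PRC area (average precision) by the step-wise sum
#' `sum_k (R_k - R_{k-1}) P_k`, so a perfect classifier scores exactly 1.
#'
#' @param p a [probability_map()] or list of maps (pooled voxelwise).
#' @param gt a [label_mask()] or list of masks, aligned with `p`.
#' @return `list(roc, prc)`, each a `curve_result` with `thresholds`,
#'   per-threshold rates and `area`.
#' @export
curves <- function(p, gt) {
  scores <- pool_values(p, "probability_map")
  labels <- pool_values(gt, "label_mask")
  if (length(scores) != length(labels)) {
    stop("curves: probability/label size mismatch", call. = FALSE)
  }
  npos <- sum(labels == 1)
  nneg <- length(labels) - npos
  if (npos == 0 || nneg == 0) {
    stop("curves: ground truth contains a single class", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  ss <- scores[ord]
  ls <- labels[ord]
  cum_tp <- cumsum(ls)
  cum_fp <- cumsum(1 - ls)
  ends <- c(which(diff(ss) != 0), length(ss))   # last index of each value
  thresholds <- c(ss[ends], -Inf)
  at <- c(0L, ends)                              # index for "score > t"
  tp <- c(0, cum_tp)[at + 1L]
  fp <- c(0, cum_fp)[at + 1L]
  rec <- tp / npos
  fpr <- fp / nneg
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  spec <- 1 - fpr

  auc <- sum(diff(fpr) * (rec[-1L] + rec[-length(rec)]) / 2)
  pk <- ifelse(is.na(prec), 0, prec)
  ap <- sum(diff(c(0, rec)) * pk)

  roc <- structure(list(thresholds = thresholds, precision = prec,
                        recall = rec, fpr = fpr, specificity = spec,
                        area = auc, kind = "roc"),
                   class = "curve_result")
  prc <- structure(list(thresholds = thresholds, precision = prec,
                        recall = rec, fpr = fpr, specificity = spec,
                        area = ap, kind = "prc"),
                   class = "curve_result")
  list(roc = roc, prc = prc)
}

#' @export
print.curve_result <- function(x, ...) {
  cat(sprintf("<curve_result %s> %d thresholds, area %.4f\n",
              x$kind, length(x$thresholds), x$area))
  invisible(x)
}

pool_values <- function(x, klass) {
  if (inherits(x, klass)) return(as.numeric(x$data))
  if (is.list(x)) {
    return(unlist(lapply(x, function(e) {
      stopifnot(inherits(e, klass))
      as.numeric(e$data)
    }), use.names = FALSE))
  }
  as.numeric(x)
}

#' Select the operating threshold from a precision-recall curve
#'
#' Chooses the PRC point with the smallest Euclidean distance to the
#' maximum precision and recall, i.e. minimizing
#' `sqrt((1 - P)^2 + (1 - R)^2)`; this guards simultaneously against
#' under-segmentation (low recall) and over-segmentation (low
#' precision). Ties are broken towards the lowest threshold, favouring
#' recall.
#'
#' @param prc a `curve_result` from [curves()].
#' @return threshold in `[0, 1]`, usable directly with [binarize()].
#' @export
optimal_threshold <- function(prc) {
  stopifnot(inherits(prc, "curve_result"))
  ok <- !is.na(prc$precision)
  if (!any(ok)) stop("optimal_threshold: empty curve", call. = FALSE)
  d2 <- (1 - prc$precision[ok])^2 + (1 - prc$recall[ok])^2
  th <- prc$thresholds[ok]
  cand <- th[d2 <= min(d2) + 1e-15]
  t <- min(cand)
  max(t, 0)                                # the all-positive point maps to 0
}

# paired two-sided Wilcoxon signed-rank test; exact null distribution for
# n <= 25 without ties in |d|, otherwise normal approximation with tie and
# continuity correction; zero differences are discarded
wilcoxon_signed_rank <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("wilcoxon_signed_rank: all differences zero; p = 1",
            call. = FALSE)
    return(1)
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  if (n <= 25L && !ties) {
    p <- 2 * min(stats::psignrank(w, n),
                 1 - stats::psignrank(w - 1, n))
    return(min(1, p))
  }
  mu <- n * (n + 1) / 4
  tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tab^3 - tab) / 48
  z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Pairwise model comparison: Wilcoxon signed-rank with Holm correction
#'
#' For every pair of models, a two-sided paired Wilcoxon signed-rank
#' test on the per-subject scores (exact for n <= 25 without ties,
#' normal approximation with tie and continuity correction otherwise;
#' zero differences discarded), followed by Holm's step-down adjustment
#' over all pairs. Significance codes: `ns` (p >= 0.05), `*` (< 0.05),
#' `**` (< 0.01), `***` (< 0.001).
#'
#' @param scores numeric matrix or data.frame, subjects x models (e.g.
#'   per-subject average precision).
#' @return list with matrices `p_raw`, `p_holm` and `codes`.
#' @export
wilcoxon_holm <- function(scores) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 6L) {
    stop("wilcoxon_holm: need at least 6 subjects", call. = FALSE)
  }
  if (ncol(scores) < 2L) {
    stop("wilcoxon_holm: need at least 2 models", call. = FALSE)
  }
  models <- colnames(scores) %||% paste0("model", seq_len(ncol(scores)))
  m <- ncol(scores)
  p_raw <- matrix(NA_real_, m, m, dimnames = list(models, models))
  for (i in seq_len(m - 1L)) {
    for (j in seq(i + 1L, m)) {
      p_raw[i, j] <- p_raw[j, i] <-
        wilcoxon_signed_rank(scores[, i], scores[, j])
    }
  }
  upper <- p_raw[upper.tri(p_raw)]
  adj <- stats::p.adjust(upper, method = "holm")
  p_holm <- p_raw
  p_holm[upper.tri(p_holm)] <- adj
  p_holm[lower.tri(p_holm)] <- t(p_holm)[lower.tri(p_holm)]
  codes <- matrix(significance_code(p_holm), m, m,
                  dimnames = dimnames(p_raw))
  diag(codes) <- ""
  list(p_raw = p_raw, p_holm = p_holm, codes = codes)
}

significance_code <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***",
                ifelse(p < 0.01, "**",
                       ifelse(p < 0.05, "*", "ns"))))
}

#' Per-subject evaluation record
#'
#' Assembles the full per-subject metric row: overlap metrics at the
#' given mask, surface distances in mm, and the subject's average
#' precision from its probability map.
#'
#' @param p the subject's [probability_map()].
#' @param pred the binarized (and possibly post-processed)
#'   [label_mask()].
#' @param gt the ground-truth [label_mask()].
#' @return one-row data.frame
#'   `(subject_id, DSC, precision, recall, specificity, ASD, MSD, AP)`.
#' @export
subject_report <- function(p, pred, gt) {
  cc <- confusion(pred, gt)
  ap <- tryCatch(curves(p, gt)$prc$area, error = function(e) NA_real_)
  data.frame(subject_id = gt$subject_id,
             DSC = dsc(cc), precision = precision(cc), recall = recall(cc),
             specificity = specificity(cc),
             ASD = asd(pred, gt), MSD = msd(pred, gt), AP = ap,
             stringsAsFactors = FALSE)
}

#' Aggregate per-subject reports
#'
#' Mean and standard deviation for the overlap and surface metrics, and
#' median with interquartile range for average precision; flagged
#' (`NA`) values are excluded and their count reported.
#'
#' @param reports data.frame of rows from [subject_report()].
#' @return data.frame of `(metric, mean, sd, median, iqr, n, n_excluded)`.
#' @export
aggregate_reports <- function(reports) {
  metrics <- c("DSC", "precision", "recall", "specificity", "ASD", "MSD",
               "AP")
  do.call(rbind, lapply(metrics, function(mt) {
    v <- reports[[mt]]
    ok <- !is.na(v)
    data.frame(metric = mt, mean = mean(v[ok]), sd = stats::sd(v[ok]),
               median = stats::median(v[ok]),
               iqr = stats::IQR(v[ok]), n = sum(ok),
               n_excluded = sum(!ok), stringsAsFactors = FALSE)
  }))
}

#' Average fold curves onto a common grid
#'
#' Figure-style cross-validation summary: precision is averaged over
#' folds at a common recall grid (PRC) and TPR at a common FPR grid
#' (ROC). Voxel pooling across folds is available by passing pooled maps
#' to [curves()] instead.
#'
#' @param curve_list list of `curve_result`s of the same kind.
#' @param grid_n number of grid points.
#' @return list with the grid, the per-fold interpolated values, the
#'   mean curve and the mean area.
#' @export
mean_curves <- function(curve_list, grid_n = 101L) {
  stopifnot(length(curve_list) >= 1L)
  kind <- curve_list[[1L]]$kind
  grid <- seq(0, 1, length.out = grid_n)
  vals <- vapply(curve_list, function(cv) {
    if (kind == "prc") {
      ok <- !is.na(cv$precision)
      stats::approx(cv$recall[ok], cv$precision[ok], xout = grid,
                    ties = max, rule = 2)$y
    } else {
      stats::approx(cv$fpr, cv$recall, xout = grid, ties = max, rule = 2)$y
    }
  }, numeric(grid_n))
  list(kind = kind, grid = grid, folds = vals,
       mean_curve = rowMeans(vals),
       mean_area = mean(vapply(curve_list, `[[`, numeric(1L), "area")))
}
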