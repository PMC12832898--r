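## Volumetric evaluation suite: Dice, volumetric overlap (VOP), volumetric
## overreach (VOR), specificity, precision, Jaccard — all derived from one
## confusion count — plus the Wilcoxon/Bonferroni paired comparison
## harness used to compare segmentation methods across tracts.

#' Voxel-wise confusion counts between a predicted and a reference mask
#'
#' @param P Predicted binary mask (array of 0/1 or logical).
#' @param G Reference binary mask on the same grid.
#' @return List of class `confusion_counts` with integers `TP`, `FP`,
#'   `FN`, `TN` (summing to the grid size).
#' @export
confusion_counts <- function(P, G) {
  if (!identical(dim(P), dim(G)))
    stop("prediction and reference grids differ", call. = FALSE)
  p <- as.logical(P); g <- as.logical(G)
  tp <- sum(p & g)
  fp <- sum(p & !g)
  fn <- sum(!p & g)
  tn <- length(p) - tp - fp - fn
  structure(list(TP = tp, FP = fp, FN = fn, TN = tn),
            class = "confusion_counts")
}

#' Six volumetric metrics from confusion counts
#'
#' Dice = 2TP/(2TP+FP+FN); VOP (volumetric overlap, the fraction of the
#' reference volume recovered) = TP/(TP+FN); VOR (volumetric overreach,
#' false-positive volume relative to the reference volume) = FP/(TP+FN);
#' specificity = TN/(TN+FP); precision = TP/(TP+FP); Jaccard =
#' TP/(TP+FP+FN).  For a non-empty reference the identity
#' dice = 2 VOP / (1 + VOP + VOR) holds.  With an empty reference
#' (TP+FN = 0), dice/VOP/VOR are reported as `NA` sentinels, never
#' silently 0.
#'
#' @param counts A `confusion_counts` (or list with TP/FP/FN/TN).
#' @return One-row data.frame with columns dice, vop, vor, specificity,
#'   precision, jaccard.
#' @export
compute_metrics <- function(counts) {
  tp <- counts$TP; fp <- counts$FP; fn <- counts$FN; tn <- counts$TN
  g <- tp + fn
  data.frame(
    dice = if (g > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_,
    vop = if (g > 0) tp / g else NA_real_,
    vor = if (g > 0) fp / g else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    jaccard = if (tp + fp + fn > 0) tp / (tp + fp + fn) else NA_real_
  )
}

#' Evaluate a set of prediction/reference mask pairs
#'
#' @param preds,refs Lists of aligned binary masks.
#' @param subjects,tracts Optional id vectors recycled across pairs.
#' @return data.frame with one metric row per pair.
#' @export
evaluate_masks <- function(preds, refs, subjects = NULL, tracts = NULL) {
  if (length(preds) != length(refs))
    stop("prediction and reference lists differ in length", call. = FALSE)
  rows <- lapply(seq_along(preds), function(i)
    compute_metrics(confusion_counts(preds[[i]], refs[[i]])))
  out <- do.call(rbind, rows)
  out <- cbind(
    data.frame(subject = if (is.null(subjects)) sprintf("s%d", seq_along(preds)) else subjects,
               tract = if (is.null(tracts)) sprintf("t%d", seq_along(preds)) else tracts),
    out)
  out
}

#' Aggregate metric rows into mean and standard deviation
#'
#' Sample (n-1) standard deviation; `NA` sentinel rows (empty-reference
#' cases) are excluded from each column's aggregation and their count is
#' reported.
#'
#' @param rows data.frame of metric rows (as from [evaluate_masks()]).
#' @param by Optional grouping column name (e.g. `"tract"`); `NULL`
#'   aggregates everything into one row.
#' @return data.frame of means, sds and excluded-NA counts per metric.
#' @export
aggregate_metrics <- function(rows, by = NULL) {
  if (nrow(rows) == 0L) stop("no metric rows to aggregate", call. = FALSE)
  cols <- intersect(c("dice", "vop", "vor", "specificity", "precision",
                      "jaccard"), names(rows))
  agg_one <- function(d) {
    out <- list()
    for (cl in cols) {
      v <- d[[cl]]
      nas <- sum(is.na(v)); v <- v[!is.na(v)]
      out[[paste0(cl, "_mean")]] <- if (length(v)) mean(v) else NA_real_
      out[[paste0(cl, "_sd")]] <- if (length(v) > 1L) stats::sd(v) else 0
      out[[paste0(cl, "_n_excluded")]] <- nas
    }
    as.data.frame(out)
  }
  if (is.null(by)) return(agg_one(rows))
  parts <- split(rows, rows[[by]])
  out <- do.call(rbind, lapply(parts, agg_one))
  out <- cbind(stats::setNames(data.frame(names(parts)), by), out)
  rownames(out) <- NULL
  out
}

#' Paired method comparison: Wilcoxon signed-rank with Bonferroni correction
#'
#' Two-sided Wilcoxon signed-rank test on paired per-tract scores, with
#' zero differences dropped (Wilcoxon's original convention), the exact
#' null distribution for up to 25 informative pairs without ties, and the
#' normal approximation with continuity correction otherwise.  When every
#' difference is zero the methods are indistinguishable and p = 1 by
#' convention.  The adjusted p-value is
#' `min(1, n_comparisons * p)`.
#'
#' @param a,b Equal-length paired score vectors (e.g. per-tract Dice for
#'   two methods).
#' @param n_comparisons Number of simultaneous comparisons for the
#'   Bonferroni correction (default 1).
#' @return List with `statistic` (V), `p_raw`, `p_bonferroni`,
#'   `n_effective` (pairs after dropping zeros).
#' @export
compare_methods <- function(a, b, n_comparisons = 1L) {
  if (length(a) != length(b))
    stop("paired score vectors differ in length", call. = FALSE)
  d <- a - b
  d <- d[d != 0]
  if (length(d) == 0L) {
    return(list(statistic = NA_real_, p_raw = 1,
                p_bonferroni = 1, n_effective = 0L))
  }
  exact <- length(d) <= 25L && !anyDuplicated(abs(d))
  ht <- suppressWarnings(
    stats::wilcox.test(d, alternative = "two.sided",
                       exact = exact, correct = TRUE))
  p <- ht$p.value
  list(statistic = unname(ht$statistic), p_raw = p,
       p_bonferroni = min(1, n_comparisons * p),
       n_effective = length(d))
}
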