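## seg_metrics module (part 2): SKIoU, instance matching, and the
## mean-SKIoU / AP / F1 scoring protocol.
##
## SKIoU(pred, gt) = 2 |S(pred & gt)| / (|S(pred)| + |S(gt)|) where S is
## morphological thinning; the intersection is taken BEFORE
## skeletonization, which makes the metric robust to 1-px lateral shifts
## of thin objects.

#' Skeleton intersection-over-union of two masks
#'
#' `2 * |S(pred & gt)| / (|S(pred)| + |S(gt)|)` with the mask intersection
#' computed before skeletonization.  When both masks are empty the value
#' is defined as 0; the value is capped at 1.
#'
#' @param pred,gt logical masks of the same shape.
#' @return a value in `[0, 1]`.
#' @export
skiou <- function(pred, gt) {
  if (!all(dim(pred) == dim(gt))) stop("mask shape mismatch")
  den <- sum(skeletonize(pred)) + sum(skeletonize(gt))
  if (den == 0) return(0)
  num <- 2 * sum(skeletonize(pred & gt))
  min(1, num / den)
}

# Pairwise SKIoU matrix (gt rows x pred columns) with skeleton-size
# caching; pairs whose masks do not overlap are 0 without any thinning.
skiou_matrix <- function(preds, gt) {
  np <- length(preds); ng <- length(gt)
  m <- matrix(0, ng, np)
  if (np == 0 || ng == 0) return(m)
  sp <- vapply(preds, function(x) sum(skeletonize(x)), numeric(1))
  sg <- vapply(gt, function(x) sum(skeletonize(x)), numeric(1))
  for (i in seq_len(ng)) for (j in seq_len(np)) {
    den <- sp[j] + sg[i]
    if (den == 0) next
    inter <- gt[[i]] & preds[[j]]
    if (!any(inter)) next
    m[i, j] <- min(1, 2 * sum(skeletonize(inter)) / den)
  }
  m
}

#' Mean SKIoU of an image
#'
#' For each ground-truth instance the best-matching prediction's SKIoU is
#' recorded (matching is non-exclusive: one prediction may be the best
#' match of several ground-truth instances); unmatched ground truth scores
#' 0.  The mean over ground-truth instances is returned.  False positives
#' are not penalized by this metric.  An empty ground truth has no defined
#' value and returns `NA`.
#'
#' @param preds,gt instance mask stacks (lists of logical masks on the
#'   same canvas).
#' @return mean SKIoU in `[0, 1]`, or `NA` for empty ground truth.
#' @export
mean_skiou <- function(preds, gt) {
  if (length(gt) == 0) return(NA_real_)
  check_canvas(preds, gt)
  m <- skiou_matrix(preds, gt)
  if (length(preds) == 0) return(0)
  mean(apply(m, 1, max))
}

check_canvas <- function(preds, gt) {
  all_masks <- c(preds, gt)
  if (length(all_masks) < 2) return(invisible(TRUE))
  d0 <- dim(all_masks[[1]])
  for (m in all_masks[-1]) if (!all(dim(m) == d0)) stop("canvas shape mismatch")
  invisible(TRUE)
}

#' Greedy one-to-one instance matching at a SKIoU threshold
#'
#' Candidate pairs are taken in order of descending SKIoU with a
#' deterministic tie-break by (ground-truth index, prediction index); each
#' prediction and each ground-truth instance is used at most once; pairs
#' below the threshold stay unmatched.
#'
#' @param preds,gt instance mask stacks.
#' @param threshold minimum SKIoU for a valid match.
#' @param skiou_mat optional precomputed SKIoU matrix (gt x pred).
#' @return a `match_table` data frame with columns `gt`, `pred` (NA when
#'   unmatched) and `skiou`, one row per ground-truth instance; the
#'   threshold is stored as an attribute.
#' @export
match_instances <- function(preds, gt, threshold, skiou_mat = NULL) {
  m <- skiou_mat %||% {
    check_canvas(preds, gt)
    skiou_matrix(preds, gt)
  }
  ng <- nrow(m); np <- ncol(m)
  res <- data.frame(gt = seq_len(ng), pred = rep(NA_integer_, ng),
                    skiou = rep(0, ng))
  if (ng > 0 && np > 0) {
    cand <- which(m >= threshold, arr.ind = TRUE)
    if (nrow(cand) > 0) {
      ord <- order(-m[cand], cand[, 1], cand[, 2])
      cand <- cand[ord, , drop = FALSE]
      used_p <- logical(np); used_g <- logical(ng)
      for (r in seq_len(nrow(cand))) {
        i <- cand[r, 1]; j <- cand[r, 2]
        if (used_g[i] || used_p[j]) next
        used_g[i] <- TRUE; used_p[j] <- TRUE
        res$pred[i] <- j
        res$skiou[i] <- m[i, j]
      }
    }
  }
  attr(res, "threshold") <- threshold
  class(res) <- c("match_table", class(res))
  res
}

#' SKIoU-based segmentation scores for one image
#'
#' Computes the mean SKIoU and, at each threshold `tau` in 0.50, 0.55,
#' ..., 0.95, the TP/FP/FN counts from greedy one-to-one matching.  The
#' per-threshold AP is `TP / (TP + FP + FN)` (predictions carry no
#' confidence scores, so ranked-precision AP is undefined; this is the
#' cell-segmentation convention); AP is their mean over the ten
#' thresholds.  `F1@tau = 2 TP / (2 TP + FP + FN)` is reported at 0.50 and
#' 0.75.
#'
#' @param preds,gt instance mask stacks on the same canvas.
#' @param thresholds SKIoU threshold grid.
#' @return an object of class `seg_scores`: list with `mean_skiou`, `ap`,
#'   `f1_50`, `f1_75`, and a per-threshold data frame `by_threshold`.
#' @export
ap_f1_scores <- function(preds, gt, thresholds = seq(0.5, 0.95, by = 0.05)) {
  check_canvas(preds, gt)
  m <- skiou_matrix(preds, gt)
  ng <- length(gt); np <- length(preds)
  rows <- lapply(thresholds, function(tau) {
    mt <- match_instances(preds, gt, tau, skiou_mat = m)
    tp <- sum(!is.na(mt$pred))
    data.frame(threshold = tau, tp = tp, fp = np - tp, fn = ng - tp)
  })
  bt <- do.call(rbind, rows)
  bt$ap <- ifelse(bt$tp + bt$fp + bt$fn == 0, 1, bt$tp / (bt$tp + bt$fp + bt$fn))
  bt$f1 <- ifelse(2 * bt$tp + bt$fp + bt$fn == 0, 1,
                  2 * bt$tp / (2 * bt$tp + bt$fp + bt$fn))
  msk <- if (ng == 0) NA_real_ else if (np == 0) 0 else mean(apply(m, 1, max))
  out <- list(mean_skiou = msk,
              ap = mean(bt$ap),
              f1_50 = bt$f1[abs(bt$threshold - 0.50) < 1e-9],
              f1_75 = bt$f1[abs(bt$threshold - 0.75) < 1e-9],
              by_threshold = bt)
  class(out) <- "seg_scores"
  out
}

#' @export
print.seg_scores <- function(x, ...) {
  cat(sprintf("<seg_scores> mean SKIoU %.4f | AP %.4f | F1@0.50 %.4f | F1@0.75 %.4f\n",
              x$mean_skiou, x$ap, x$f1_50, x$f1_75))
  invisible(x)
}

#' Dataset-level segmentation scores (macro average)
#'
#' Scores each image with [ap_f1_scores()] and averages over images
#' (images with empty ground truth are excluded from the mean SKIoU).
#'
#' @param pred_stacks,gt_stacks parallel lists of instance mask stacks.
#' @return list with aggregate scores and the per-image data frame.
#' @export
evaluate_images <- function(pred_stacks, gt_stacks) {
  if (length(pred_stacks) != length(gt_stacks))
    stop("pred_stacks and gt_stacks must be parallel lists")
  per <- lapply(seq_along(gt_stacks), function(i) {
    s <- ap_f1_scores(pred_stacks[[i]], gt_stacks[[i]])
    data.frame(image = i, mean_skiou = s$mean_skiou, ap = s$ap,
               f1_50 = s$f1_50, f1_75 = s$f1_75)
  })
  per <- do.call(rbind, per)
  list(mean_skiou = mean(per$mean_skiou, na.rm = TRUE),
       ap = mean(per$ap),
       f1_50 = mean(per$f1_50),
       f1_75 = mean(per$f1_75),
       per_image = per)
}
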