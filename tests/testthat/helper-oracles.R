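# Independent, deliberately naive reference implementations used as
# oracles. They avoid the package's vectorized code paths: everything is
# written as explicit per-element loops straight from the definitions.

# OKS from the definition, one keypoint at a time
oracle_oks <- function(gt, det) {
  k <- kp_constants()
  s2 <- attr(gt, "scale_area")
  num <- 0
  den <- 0
  for (i in 1:18) {
    if (gt$visibility[i] >= 1) {
      den <- den + 1
      if (det$visibility[i] >= 1) {
        d2 <- (gt$x[i] - det$x[i])^2 + (gt$y[i] - det$y[i])^2
        num <- num + exp(-d2 / (2 * s2 * k[[gt$name[i]]]^2))
      }
    }
  }
  num / den
}

# Exhaustive best matching for a frame: over all injective assignments of
# detections (in any order) to ground truths, maximize the number of
# matches with OKS >= t, breaking ties by total OKS. Returns the match
# count. Only feasible for a handful of detections.
oracle_match_count <- function(oks_matrix, t) {
  nd <- nrow(oks_matrix); ng <- ncol(oks_matrix)
  if (nd == 0 || ng == 0) return(0L)
  best_n <- 0L
  assign_rec <- function(d, used, n) {
    if (d > nd) { best_n <<- max(best_n, n); return(invisible()) }
    assign_rec(d + 1L, used, n)  # leave detection d unmatched
    for (g in seq_len(ng)) {
      if (!used[g] && oks_matrix[d, g] >= t) {
        used[g] <- TRUE
        assign_rec(d + 1L, used, n + 1L)
        used[g] <- FALSE
      }
    }
  }
  assign_rec(1L, rep(FALSE, ng), 0L)
  best_n
}

# Loop-based reimplementation of the COCO keypoint AP/AR protocol.
# gt_sets / det_sets: per-frame lists of keypoint sets; detections carry a
# "score" attribute (or mean keypoint confidence).
oracle_ap_ar <- function(gt_sets, det_sets, thresholds = seq(0.5, 0.95, 0.05),
                         max_dets = 20) {
  norm <- function(x) if (inherits(x, "keypoint_set")) list(x) else x
  gt_sets <- lapply(gt_sets, norm)
  det_sets <- lapply(det_sets, norm)
  score_of <- function(s) {
    sc <- attr(s, "score")
    if (!is.null(sc)) return(sc)
    cf <- s$confidence[s$visibility >= 1]
    if (all(is.na(cf))) 0 else mean(cf, na.rm = TRUE)
  }
  n_gt <- 0
  for (g in gt_sets) n_gt <- n_gt + length(g)
  ap_list <- c(); rc_list <- c()
  for (t in thresholds) {
    scores <- c(); is_tp <- c()
    for (f in seq_along(gt_sets)) {
      dets <- det_sets[[f]]
      if (length(dets) == 0) next
      sc <- sapply(dets, score_of)
      ord <- order(sc, decreasing = TRUE)
      if (length(ord) > max_dets) ord <- ord[1:max_dets]
      gt_used <- rep(FALSE, length(gt_sets[[f]]))
      for (d in ord) {
        best_g <- 0; best_o <- -1
        for (g in seq_along(gt_sets[[f]])) {
          if (!gt_used[g]) {
            o <- oracle_oks(gt_sets[[f]][[g]], dets[[d]])
            if (o >= t && o > best_o) { best_o <- o; best_g <- g }
          }
        }
        tp <- FALSE
        if (best_g > 0) { gt_used[best_g] <- TRUE; tp <- TRUE }
        scores <- c(scores, sc[d]); is_tp <- c(is_tp, tp)
      }
    }
    if (length(scores) == 0) { ap_list <- c(ap_list, 0); rc_list <- c(rc_list, 0); next }
    ord <- order(scores, decreasing = TRUE)
    is_tp <- is_tp[ord]
    tp_cum <- 0; fp_cum <- 0; prec <- c(); rec <- c()
    for (i in seq_along(is_tp)) {
      if (is_tp[i]) tp_cum <- tp_cum + 1 else fp_cum <- fp_cum + 1
      prec <- c(prec, tp_cum / (tp_cum + fp_cum))
      rec <- c(rec, tp_cum / n_gt)
    }
    ap <- 0
    for (r in seq(0, 1, 0.01)) {
      # interpolated precision: best precision at any recall >= r
      p_at <- 0
      for (i in seq_along(rec)) if (rec[i] >= r) p_at <- max(p_at, prec[i])
      ap <- ap + p_at / 101
    }
    ap_list <- c(ap_list, ap)
    rc_list <- c(rc_list, tp_cum / n_gt)
  }
  list(AP = 100 * mean(ap_list),
       AP75 = 100 * ap_list[which.min(abs(thresholds - 0.75))],
       AR = 100 * mean(rc_list))
}
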