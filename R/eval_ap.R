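#' COCO-style keypoint detection metrics (AP, AP75, AR)
#'
#' Evaluates detections against ground truth with the object keypoint
#' similarity ([oks()]) as the match criterion, following the COCO
#' keypoint protocol: per frame and OKS threshold, detections are
#' processed in descending confidence and each is matched to the unmatched
#' ground-truth instance of highest OKS (a match requires OKS >= the
#' threshold; each ground truth is matched at most once). Precision-recall
#' is accumulated over all frames with detections ranked globally by
#' confidence, interpolated on the standard 101-point recall grid, and
#' averaged over the thresholds 0.50:0.05:0.95. AR is the mean over
#' thresholds of the final recall with at most `max_dets` detections per
#' frame. All three metrics are reported on the 0-100 scale.
#'
#' @param gt_sets List (one element per frame) of ground-truth
#'   [keypoint_set()]s, or lists of them for multi-instance frames.
#' @param det_sets Matching list of detections; each detection needs
#'   per-keypoint confidences (its instance score is their mean) or a
#'   `score` attribute.
#' @param thresholds OKS thresholds (default `seq(0.5, 0.95, 0.05)`).
#' @param max_dets Maximum detections kept per frame (default 20).
#' @return List with `AP`, `AP75`, `AR` (each in \[0, 100\]) and
#'   `per_threshold` (data frame of AP and recall per OKS threshold).
#' @export
evaluate_ap_ar <- function(gt_sets, det_sets,
                           thresholds = seq(0.5, 0.95, by = 0.05),
                           max_dets = 20L) {
  stopifnot(length(gt_sets) == length(det_sets))
  norm <- function(x) if (inherits(x, "keypoint_set")) list(x) else (x %||% list())
  gt_sets <- lapply(gt_sets, norm)
  det_sets <- lapply(det_sets, norm)
  n_gt <- sum(lengths(gt_sets))
  if (n_gt == 0L) stop("no ground-truth instances across all frames")

  det_score <- function(s) {
    sc <- attr(s, "score")
    if (!is.null(sc)) return(sc)
    cf <- s$confidence[s$visibility >= 1L]
    if (all(is.na(cf))) 0 else mean(cf, na.rm = TRUE)
  }

  # per-frame OKS matrices and score-ordered detections
  frames <- lapply(seq_along(gt_sets), function(i) {
    gts <- gt_sets[[i]]
    dets <- det_sets[[i]]
    scores <- vapply(dets, det_score, numeric(1))
    ord <- order(-scores)
    if (length(ord) > max_dets) ord <- ord[seq_len(max_dets)]
    dets <- dets[ord]; scores <- scores[ord]
    om <- matrix(0, length(dets), length(gts))
    for (d in seq_along(dets)) for (g in seq_along(gts)) {
      om[d, g] <- oks(gts[[g]], dets[[d]])
    }
    list(scores = scores, oks = om, n_gt = length(gts))
  })

  nT <- length(thresholds)
  all_scores <- unlist(lapply(frames, `[[`, "scores"))
  n_det <- length(all_scores)
  tp <- matrix(FALSE, nT, n_det)
  col0 <- 0L
  for (fr in frames) {
    nd <- length(fr$scores)
    if (nd == 0L) next
    for (ti in seq_len(nT)) {
      t <- thresholds[ti]
      matched_gt <- rep(FALSE, fr$n_gt)
      for (d in seq_len(nd)) {     # detections already in descending score
        if (fr$n_gt == 0L) break
        cand <- which(!matched_gt & fr$oks[d, ] >= t)
        if (length(cand)) {
          g <- cand[which.max(fr$oks[d, cand])]
          matched_gt[g] <- TRUE
          tp[ti, col0 + d] <- TRUE
        }
      }
    }
    col0 <- col0 + nd
  }

  rec_grid <- seq(0, 1, by = 0.01)
  ord <- order(-all_scores)
  ap_t <- numeric(nT); rc_t <- numeric(nT)
  for (ti in seq_len(nT)) {
    if (n_det == 0L) { ap_t[ti] <- 0; rc_t[ti] <- 0; next }
    flags <- tp[ti, ord]
    ctp <- cumsum(flags)
    cfp <- cumsum(!flags)
    prec <- ctp / (ctp + cfp)
    rec <- ctp / n_gt
    # precision envelope (non-increasing from the right), COCO style
    for (k in rev(seq_len(length(prec) - 1))) prec[k] <- max(prec[k], prec[k + 1])
    q <- numeric(length(rec_grid))
    idx <- findInterval(rec_grid - 1e-12, rec) + 1L   # first index with rec >= r
    ok <- idx <= length(rec)
    q[ok] <- prec[idx[ok]]
    ap_t[ti] <- mean(q)
    rc_t[ti] <- max(rec)
  }
  list(AP = 100 * mean(ap_t),
       AP75 = 100 * ap_t[which.min(abs(thresholds - 0.75))],
       AR = 100 * mean(rc_t),
       per_threshold = data.frame(threshold = thresholds, ap = 100 * ap_t,
                                  recall = 100 * rc_t))
}
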