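#' Match predicted boxes to reference boxes
#'
#' Greedy assignment in descending prediction confidence: each prediction
#' takes the still-unmatched reference with highest IoU at or above
#' `iou_thresh` (restricted to its own class when `class_aware`).
#' Confidence ties are broken by input order, making the result
#' deterministic for a given file order.
#'
#' @param refs Reference box table (confidence ignored).
#' @param preds Predicted box table with confidences.
#' @param iou_thresh Minimum IoU for a positive match (default 0.25).
#' @param class_aware Restrict matches to same-class pairs.
#' @return A list with `pairs` (data.frame `ref`, `pred`, `iou` of row
#'   indices into `refs`/`preds` and the matched IoU), `unmatched_refs`
#'   and `unmatched_preds` (integer row indices).
#' @export
match_boxes <- function(refs, preds, iou_thresh = 0.25, class_aware = TRUE) {
  if (iou_thresh <= 0 || iou_thresh >= 1)
    stop("iou_thresh must lie in (0, 1)")
  validate_boxes(refs, "refs"); validate_boxes(preds, "preds")
  nr <- nrow(refs); np <- nrow(preds)
  pairs <- data.frame(ref = integer(), pred = integer(), iou = numeric())
  if (nr > 0 && np > 0) {
    iou <- box_iou_matrix(refs, preds)
    used <- rep(FALSE, nr)
    ord <- order(-preds$confidence, seq_len(np))
    for (p in ord) {
      ok <- !used & iou[, p] >= iou_thresh
      if (class_aware) ok <- ok & refs$class == preds$class[p]
      cand <- which(ok)
      if (!length(cand)) next
      best <- cand[which.max(iou[cand, p])]
      used[best] <- TRUE
      pairs <- rbind(pairs,
                     data.frame(ref = best, pred = p, iou = iou[best, p]))
    }
  }
  list(pairs = pairs,
       unmatched_refs = setdiff(seq_len(nr), pairs$ref),
       unmatched_preds = setdiff(seq_len(np), pairs$pred))
}

#' All-point average precision for one class
#'
#' Builds the precision-recall curve by sweeping confidence-ranked
#' predictions of the class (pooled over frames) with the greedy IoU match
#' rule, then integrates the area under the interpolated (monotone
#' envelope) curve. Depends only on the confidence ranking, not on its
#' scale.
#'
#' @param gt Named list of reference [ead_frame()]s.
#' @param sub Named list of submission frames (aligned; missing frames
#'   should already be empty predictions).
#' @param class Class label to score.
#' @param iou_thresh Minimum IoU for a positive match.
#' @return AP in `[0, 1]`, or `NA` when the class has no reference boxes
#'   (not applicable; excluded from mAP).
#' @export
average_precision <- function(gt, sub, class, iou_thresh = 0.25) {
  n_gt <- 0L
  recs <- list()  # per prediction: frame, conf, order key
  for (id in names(gt)) {
    r <- gt[[id]]$boxes; r <- r[r$class == class, , drop = FALSE]
    n_gt <- n_gt + nrow(r)
    s <- if (is.null(sub[[id]])) empty_boxes() else sub[[id]]$boxes
    s <- s[s$class == class, , drop = FALSE]
    if (nrow(s))
      recs[[id]] <- data.frame(frame = id, conf = s$confidence,
                               within = seq_len(nrow(s)),
                               stringsAsFactors = FALSE)
  }
  if (n_gt == 0) return(NA_real_)
  preds <- do.call(rbind, recs)
  if (is.null(preds) || nrow(preds) == 0) return(0)
  ord <- order(-preds$conf, match(preds$frame, names(gt)), preds$within)
  preds <- preds[ord, , drop = FALSE]

  # greedy match in global confidence order, per-frame used-ref bookkeeping
  used <- lapply(gt, function(fr) rep(FALSE, sum(fr$boxes$class == class)))
  tp <- logical(nrow(preds))
  for (k in seq_len(nrow(preds))) {
    id <- preds$frame[k]
    r <- gt[[id]]$boxes; r <- r[r$class == class, , drop = FALSE]
    if (!nrow(r)) next
    s <- sub[[id]]$boxes; s <- s[s$class == class, , drop = FALSE]
    p <- s[preds$within[k], , drop = FALSE]
    iou <- box_iou_matrix(r, p)[, 1]
    cand <- which(!used[[id]] & iou >= iou_thresh)
    if (length(cand)) {
      best <- cand[which.max(iou[cand])]
      used[[id]][best] <- TRUE
      tp[k] <- TRUE
    }
  }
  cum_tp <- cumsum(tp)
  recall <- cum_tp / n_gt
  precision <- cum_tp / seq_along(tp)
  # monotone envelope from the right, integrate over recall steps
  env <- rev(cummax(rev(precision)))
  sum(diff(c(0, recall)) * env)
}

#' Score a detection submission
#'
#' Computes per-class all-point AP and per-class mean best-match IoU,
#' macro-averages both over classes with at least one reference box, and
#' combines them into the leaderboard detection score
#' `score_d = 0.6 mAP + 0.4 IoU` (weights favour retrieval of all
#' artefacts). Unmatched reference boxes contribute IoU 0, penalizing
#' missed artefacts. The mAP-IoU validity gate is evaluated alongside.
#'
#' @param gt Named list of reference frames.
#' @param sub Named list of submission frames; frames missing from `sub`
#'   are scored as empty predictions.
#' @param catalog An [ead_catalog()].
#' @param iou_thresh Minimum IoU for a positive match.
#' @param weights Detection score weights, `c(map, iou)`.
#' @return An object of class `detection_scorecard`: list with
#'   `per_class` (data.frame `class`, `ap`, `mean_iou`, `n_gt`), `mAP`,
#'   `mean_iou` (macro over classes), `pooled_iou` (over all reference
#'   boxes), `score_d`, `valid`, `validity_ratio`.
#' @export
evaluate_detection <- function(gt, sub, catalog = ead_catalog(),
                               iou_thresh = 0.25,
                               weights = c(map = 0.6, iou = 0.4)) {
  if (!length(gt)) stop("no ground-truth frames")
  sub <- align_submission(sub, gt, catalog)
  classes <- catalog$detection_classes
  if (sum(vapply(gt, function(fr) nrow(fr$boxes), integer(1))) == 0)
    stop("ground truth has no boxes in any frame")

  per_class <- data.frame(class = classes, ap = NA_real_,
                          mean_iou = NA_real_, n_gt = 0L,
                          stringsAsFactors = FALSE)
  all_ref_ious <- numeric()
  for (i in seq_along(classes)) {
    cl <- classes[i]
    per_class$ap[i] <- average_precision(gt, sub, cl, iou_thresh)
    ious <- numeric()
    for (id in names(gt)) {
      r <- gt[[id]]$boxes; r <- r[r$class == cl, , drop = FALSE]
      if (!nrow(r)) next
      s <- sub[[id]]$boxes; s <- s[s$class == cl, , drop = FALSE]
      ref_iou <- rep(0, nrow(r))
      if (nrow(s)) {
        m <- match_boxes(r, s, iou_thresh, class_aware = FALSE)
        ref_iou[m$pairs$ref] <- m$pairs$iou
      }
      ious <- c(ious, ref_iou)
    }
    per_class$n_gt[i] <- length(ious)
    if (length(ious)) per_class$mean_iou[i] <- mean(ious)
    all_ref_ious <- c(all_ref_ious, ious)
  }
  applicable <- per_class$n_gt > 0
  mAP <- mean(per_class$ap[applicable])
  mean_iou <- mean(per_class$mean_iou[applicable])
  score_d <- weights[["map"]] * mAP + weights[["iou"]] * mean_iou
  gate <- validity_check(mAP, mean_iou)
  structure(list(per_class = per_class, mAP = mAP, mean_iou = mean_iou,
                 pooled_iou = mean(all_ref_ious), score_d = score_d,
                 valid = gate$valid, validity_ratio = gate$ratio,
                 iou_thresh = iou_thresh, weights = weights),
            class = "detection_scorecard")
}

#' @export
print.detection_scorecard <- function(x, ...) {
  cat("<detection_scorecard>\n")
  print(transform(x$per_class, ap = round(ap, 4),
                  mean_iou = round(mean_iou, 4)), row.names = FALSE)
  cat(sprintf("mAP %.4f | IoU %.4f | score_d %.4f | ratio %.4f (%s)\n",
              x$mAP, x$mean_iou, x$score_d, x$validity_ratio,
              if (isTRUE(x$valid)) "valid" else "INVALID"))
  invisible(x)
}

#' mAP-IoU ratio gate for valid submissions
#'
#' The challenge constrained the mean IoU of valid submissions to within
#' 30% of the mean mAP, `0.7 < IoU/mAP < 1.3` (strict), to discourage
#' biasing one metric against the other via early or late stopping.
#'
#' @param mAP,mean_iou Aggregate detection metrics.
#' @return List with `ratio` (`IoU/mAP`; `NA` when `mAP = 0`) and `valid`.
#' @examples
#' validity_check(0.3235, 0.4172)  # ratio 1.2897, valid
#' @export
validity_check <- function(mAP, mean_iou) {
  if (mAP <= 0)
    return(list(ratio = NA_real_, valid = FALSE))
  ratio <- mean_iou / mAP
  list(ratio = ratio, valid = ratio > 0.7 && ratio < 1.3)
}

#' Class confusion matrix for detections
#'
#' Class-agnostic greedy matching (highest IoU at or above the threshold,
#' confidence-ordered) assigns each reference box to at most one predicted
#' box; the cell (reference class, predicted class) is incremented.
#' Unassigned references count in the `background` column (missed),
#' unassigned predictions in the `background` row (spurious).
#'
#' @inheritParams evaluate_detection
#' @return Integer matrix with rows = reference classes plus `background`,
#'   columns = predicted classes plus `background`.
#' @export
confusion_matrix <- function(gt, sub, catalog = ead_catalog(),
                             iou_thresh = 0.25) {
  sub <- align_submission(sub, gt, catalog)
  classes <- catalog$detection_classes
  lv <- c(classes, "background")
  cm <- matrix(0L, length(lv), length(lv), dimnames = list(ref = lv, pred = lv))
  for (id in names(gt)) {
    r <- gt[[id]]$boxes
    s <- sub[[id]]$boxes
    m <- match_boxes(r, s, iou_thresh, class_aware = FALSE)
    if (nrow(m$pairs))
      for (k in seq_len(nrow(m$pairs))) {
        rc <- r$class[m$pairs$ref[k]]; pc <- s$class[m$pairs$pred[k]]
        cm[rc, pc] <- cm[rc, pc] + 1L
      }
    for (i in m$unmatched_refs)
      cm[r$class[i], "background"] <- cm[r$class[i], "background"] + 1L
    for (j in m$unmatched_preds)
      cm["background", s$class[j]] <- cm["background", s$class[j]] + 1L
  }
  cm
}

#' Per-image F1 score
#'
#' Class-aware matching pooled over classes within each frame; F1 is the
#' harmonic mean of the frame's box-level precision and recall. A frame
#' with neither references nor predictions scores `empty_value`.
#'
#' @inheritParams evaluate_detection
#' @param empty_value Score when a frame has no boxes on either side.
#' @return Named numeric vector of F1 values keyed by frame id.
#' @export
per_image_f1 <- function(gt, sub, catalog = ead_catalog(),
                         iou_thresh = 0.25, empty_value = 1) {
  sub <- align_submission(sub, gt, catalog)
  out <- stats::setNames(numeric(length(gt)), names(gt))
  for (id in names(gt)) {
    r <- gt[[id]]$boxes; s <- sub[[id]]$boxes
    if (nrow(r) == 0 && nrow(s) == 0) { out[id] <- empty_value; next }
    m <- match_boxes(r, s, iou_thresh, class_aware = TRUE)
    pr <- precision_recall(nrow(m$pairs), nrow(s), nrow(r),
                           empty_value = 0)
    out[id] <- f_beta(pr[["precision"]], pr[["recall"]], beta = 1)
  }
  out
}
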