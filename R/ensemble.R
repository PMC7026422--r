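#' Build a consensus "super detector" frame
#'
#' Pools the predicted boxes of several submissions for one frame,
#' clusters them per class by single-linkage on pairwise IoU at
#' `iou_thresh`, and keeps each cluster supported by more than
#' `min_fraction` of the submissions (strict majority by default). A
#' submission's duplicate boxes in one cluster count once towards support.
#' The cluster representative is its highest-confidence member
#' (confidence ties broken by submission order, then input order).
#'
#' @param subs List of box tables (one per submission) for the same frame.
#' @param min_fraction Support threshold; a cluster is kept when
#'   `support / n_subs > min_fraction`.
#' @param iou_thresh IoU linkage threshold for clustering.
#' @return List with `boxes` (representative box table, with a
#'   `submission` column recording the contributing submission index) and
#'   `clusters` (per-cluster support counts).
#' @export
merge_detections <- function(subs, min_fraction = 0.5, iou_thresh = 0.25) {
  if (length(subs) < 2) stop("consensus needs at least 2 submissions")
  if (min_fraction <= 0 || min_fraction > 1)
    stop("min_fraction must lie in (0, 1]")
  if (iou_thresh <= 0 || iou_thresh >= 1)
    stop("iou_thresh must lie in (0, 1)")
  n_subs <- length(subs)
  pool <- do.call(rbind, lapply(seq_along(subs), function(k) {
    b <- subs[[k]]
    if (nrow(b) == 0) return(NULL)
    b$submission <- k
    b
  }))
  reps <- NULL
  clusters <- data.frame(class = character(), support = integer(),
                         size = integer())
  if (!is.null(pool) && nrow(pool)) {
    for (cl in unique(pool$class)) {
      pb <- pool[pool$class == cl, , drop = FALSE]
      lab <- single_linkage_clusters(pb, iou_thresh)
      for (g in unique(lab)) {
        members <- pb[lab == g, , drop = FALSE]
        support <- length(unique(members$submission))
        clusters <- rbind(clusters,
                          data.frame(class = cl, support = support,
                                     size = nrow(members)))
        if (support / n_subs > min_fraction) {
          ord <- order(-members$confidence, members$submission)
          reps <- rbind(reps, members[ord[1], , drop = FALSE])
        }
      }
    }
  }
  if (is.null(reps)) {
    reps <- empty_boxes(); reps$submission <- integer()
  }
  rownames(reps) <- NULL
  list(boxes = reps, clusters = clusters, n_subs = n_subs)
}

# Single-linkage components over the IoU >= thresh graph (within a class).
single_linkage_clusters <- function(boxes, iou_thresh) {
  n <- nrow(boxes)
  lab <- seq_len(n)
  if (n < 2) return(lab)
  iou <- box_iou_matrix(boxes, boxes)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (iou[i, j] >= iou_thresh && lab[i] != lab[j]) {
      old <- lab[j]; lab[lab == old] <- lab[i]
    }
  }
  lab
}

#' Build a consensus "super segmentation" mask set
#'
#' Per class and per pixel, the merged mask is foreground iff more than
#' `min_fraction` of the submissions mark it foreground.
#'
#' @param subs List of named mask lists (one per submission), consistent
#'   shapes and class sets.
#' @param min_fraction Strict vote threshold.
#' @return Named list of consensus 0/1 matrices.
#' @export
merge_segmentations <- function(subs, min_fraction = 0.5) {
  if (length(subs) < 2) stop("consensus needs at least 2 submissions")
  classes <- names(subs[[1]])
  n <- length(subs)
  out <- stats::setNames(vector("list", length(classes)), classes)
  for (cl in classes) {
    acc <- NULL
    for (s in subs) {
      m <- s[[cl]]
      if (is.null(m)) stop("submission missing class '", cl, "'")
      if (is.null(acc)) acc <- matrix(0L, nrow(m), ncol(m))
      if (!identical(dim(acc), dim(m)))
        stop("mask shape mismatch for class '", cl, "'")
      acc <- acc + (m > 0)
    }
    out[[cl]] <- matrix(as.integer(acc > min_fraction * n),
                        nrow(acc), ncol(acc))
  }
  out
}

#' Tally per-submission contributions to a merged detector
#'
#' Counts, per submission, how many consensus representative boxes it
#' supplied. In the challenge analysis these tallies showed the merged
#' detector drawing boxes from a mixture of high- and low-ranked teams: a
#' team contributes little if another method produced the same consensus
#' boxes with higher confidence.
#'
#' @param merged Result of [merge_detections()].
#' @param n_subs Number of submissions merged (defaults to the count
#'   recorded in `merged`).
#' @return Integer vector of counts, one per submission index.
#' @export
contribution_tally <- function(merged, n_subs = merged$n_subs) {
  counts <- integer(n_subs)
  if (nrow(merged$boxes))
    for (k in merged$boxes$submission) counts[k] <- counts[k] + 1L
  counts
}
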