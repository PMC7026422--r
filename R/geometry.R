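#' Intersection over union of two boxes
#'
#' Area overlap between two rectangles in half-open pixel coordinates:
#' `IoU(R, S) = |R ∩ S| / |R ∪ S|`. 0 for disjoint boxes, 1 iff they are
#' geometrically identical; symmetric in its arguments.
#'
#' @param a,b Numeric vectors `c(x1, y1, x2, y2)` or single-row box tables.
#' @return IoU in `[0, 1]`.
#' @examples
#' box_iou(c(0, 0, 10, 10), c(0, 0, 10, 10))  # 1
#' box_iou(c(0, 0, 2, 2), c(1, 1, 3, 3))      # 1/7
#' @export
box_iou <- function(a, b) {
  a <- as_box_vec(a)
  b <- as_box_vec(b)
  inter_w <- min(a[3], b[3]) - max(a[1], b[1])
  inter_h <- min(a[4], b[4]) - max(a[2], b[2])
  if (inter_w <= 0 || inter_h <= 0) return(0)
  inter <- inter_w * inter_h
  union <- box_area(a) + box_area(b) - inter
  inter / union
}

as_box_vec <- function(b) {
  if (is.data.frame(b)) {
    stopifnot(nrow(b) == 1)
    b <- c(b$x1, b$y1, b$x2, b$y2)
  }
  b <- as.numeric(b)
  if (length(b) != 4 || any(!is.finite(b)))
    stop("box must be four finite numbers (x1, y1, x2, y2)")
  if (b[3] <= b[1] || b[4] <= b[2])
    stop("degenerate box (x2 <= x1 or y2 <= y1)")
  b
}

box_area <- function(b) (b[3] - b[1]) * (b[4] - b[2])

# All pairwise IoUs between two box tables; rows = refs, cols = preds.
box_iou_matrix <- function(refs, preds) {
  nr <- nrow(refs); np <- nrow(preds)
  out <- matrix(0, nr, np)
  if (nr == 0 || np == 0) return(out)
  for (i in seq_len(nr)) {
    iw <- pmin(refs$x2[i], preds$x2) - pmax(refs$x1[i], preds$x1)
    ih <- pmin(refs$y2[i], preds$y2) - pmax(refs$y1[i], preds$y1)
    inter <- pmax(iw, 0) * pmax(ih, 0)
    ar <- (refs$x2[i] - refs$x1[i]) * (refs$y2[i] - refs$y1[i])
    ap <- (preds$x2 - preds$x1) * (preds$y2 - preds$y1)
    out[i, ] <- inter / (ar + ap - inter)
  }
  out
}

#' Rasterize a box onto a pixel grid
#'
#' Fills the half-open extent `[x1, x2) x [y1, y2)` with 1 on a
#' `height x width` grid (clipped to the grid). Used to derive masks from
#' box annotations and as the bridge between box IoU and mask Jaccard.
#'
#' @param box Numeric `c(x1, y1, x2, y2)`.
#' @param height,width Grid dimensions in pixels.
#' @return A 0/1 matrix of size `height x width`.
#' @export
rasterize_box <- function(box, height, width) {
  box <- as_box_vec(box)
  m <- matrix(0L, height, width)
  x_lo <- max(floor(box[1]) + 1, 1); x_hi <- min(ceiling(box[3]), width)
  y_lo <- max(floor(box[2]) + 1, 1); y_hi <- min(ceiling(box[4]), height)
  if (x_lo <= x_hi && y_lo <= y_hi)
    m[y_lo:y_hi, x_lo:x_hi] <- 1L
  m
}

check_mask_pair <- function(r, s) {
  if (!identical(dim(r), dim(s)))
    stop("mask shape mismatch: ", paste(dim(r), collapse = "x"), " vs ",
         paste(dim(s), collapse = "x"))
}

#' Jaccard index (IoU) of two binary masks
#'
#' `J(R, S) = |R ∩ S| / |R ∪ S|` over foreground pixels. When both masks
#' are empty the configured empty-vs-empty value is returned (default 1:
#' perfect agreement on absence; see the package vignette for why absent
#' classes must score positively).
#'
#' @param r,s Binary matrices of identical shape (reference, prediction).
#' @param empty_value Value returned when both masks are all-background.
#' @return Jaccard index in `[0, 1]`.
#' @export
mask_jaccard <- function(r, s, empty_value = 1) {
  check_mask_pair(r, s)
  inter <- sum(r > 0 & s > 0)
  union <- sum(r > 0 | s > 0)
  if (union == 0) return(empty_value)
  inter / union
}

#' Dice similarity coefficient of two binary masks
#'
#' `DSC(R, S) = 2 |R ∩ S| / (|R| + |S|)`, related to the Jaccard index by
#' `DSC = 2 J / (1 + J)`. Empty-vs-empty returns `empty_value` (default 1).
#'
#' @inheritParams mask_jaccard
#' @return Dice coefficient in `[0, 1]`.
#' @export
mask_dsc <- function(r, s, empty_value = 1) {
  check_mask_pair(r, s)
  nr <- sum(r > 0); ns <- sum(s > 0)
  if (nr + ns == 0) return(empty_value)
  2 * sum(r > 0 & s > 0) / (nr + ns)
}

#' Precision and recall from match counts
#'
#' `p = tp / n_pred`, `r = tp / n_gt`. A `0/0` ratio (no predictions, or no
#' ground truth) is defined as `empty_value` (default 1), so that agreement
#' on absence is not penalized.
#'
#' @param tp Number of true positives.
#' @param n_pred Number of predicted instances (boxes or pixels).
#' @param n_gt Number of ground-truth instances.
#' @param empty_value Value for the 0/0 case.
#' @return Named numeric `c(precision = , recall = )`.
#' @examples
#' precision_recall(3, 4, 6)  # 0.75, 0.5
#' @export
precision_recall <- function(tp, n_pred, n_gt, empty_value = 1) {
  stopifnot(tp >= 0, n_pred >= 0, n_gt >= 0, tp <= n_pred || n_pred == 0,
            tp <= n_gt || n_gt == 0)
  p <- if (n_pred == 0) empty_value else tp / n_pred
  r <- if (n_gt == 0) empty_value else tp / n_gt
  c(precision = p, recall = r)
}

#' Weighted harmonic mean of precision and recall
#'
#' `F_beta = (1 + beta^2) p r / (beta^2 p + r)`; `beta > 1` weights recall
#' more heavily. Returns 0 when `p = r = 0`.
#'
#' @param p,r Precision and recall in `[0, 1]`.
#' @param beta Positive weight; 1 gives the F1 score, 2 the recall-leaning
#'   F2 score.
#' @return F-score in `[0, 1]`.
#' @examples
#' f_beta(1, 0.5, beta = 2)  # 5/9
#' @export
f_beta <- function(p, r, beta = 1) {
  stopifnot(beta > 0, p >= 0, p <= 1, r >= 0, r <= 1)
  if (p == 0 && r == 0) return(0)
  (1 + beta^2) * p * r / (beta^2 * p + r)
}
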