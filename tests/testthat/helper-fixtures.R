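# Shared helpers: tiny frame builders and brute-force oracles.

box_row <- function(class, x1, y1, x2, y2, conf = NA_real_) {
  if (length(class) == 0)
    return(data.frame(class = character(), confidence = numeric(),
                      x1 = numeric(), y1 = numeric(), x2 = numeric(),
                      y2 = numeric(), stringsAsFactors = FALSE))
  data.frame(class = class, confidence = conf, x1 = x1, y1 = y1,
             x2 = x2, y2 = y2, stringsAsFactors = FALSE)
}

# Drop boxes overlapping an earlier same-class box at or above `thresh`,
# so consensus clusters correspond one-to-one to ground-truth boxes.
dedup_same_class <- function(frames, thresh = 0.25) {
  lapply(frames, function(fr) {
    b <- fr$boxes
    keep <- rep(TRUE, nrow(b))
    if (nrow(b) > 1) for (i in 2:nrow(b)) {
      prev <- which(keep[seq_len(i - 1)] &
                      b$class[seq_len(i - 1)] == b$class[i])
      if (length(prev)) {
        ious <- endoarteval:::box_iou_matrix(b[prev, , drop = FALSE],
                                             b[i, , drop = FALSE])[, 1]
        if (any(ious >= thresh)) keep[i] <- FALSE
      }
    }
    fr$boxes <- b[keep, , drop = FALSE]
    rownames(fr$boxes) <- NULL
    fr
  })
}

one_frame_gt <- function(boxes, id = "f1", image_size = NULL) {
  stats::setNames(list(ead_frame(id, boxes, image_size = image_size)), id)
}

one_frame_sub <- function(boxes, id = "f1") {
  stats::setNames(list(ead_frame(id, boxes)), id)
}

random_box <- function(field = 80, min_side = 5, max_side = 40) {
  x1 <- runif(1, 0, field); y1 <- runif(1, 0, field)
  c(x1, y1, x1 + runif(1, min_side, max_side),
    y1 + runif(1, min_side, max_side))
}

# Exhaustive maximum one-to-one assignment count over the IoU >= thresh
# bipartite graph (branch and bound over prediction order).
max_matching_count <- function(match_ok) {
  nr <- nrow(match_ok); np <- ncol(match_ok)
  if (nr == 0 || np == 0) return(0L)
  best <- 0L
  recurse <- function(p, used, cnt) {
    if (cnt + (np - p + 1) <= best) return()
    if (p > np) { best <<- max(best, cnt); return() }
    recurse(p + 1, used, cnt)
    for (r in seq_len(nr)) {
      if (!used[r] && match_ok[r, p]) {
        used2 <- used; used2[r] <- TRUE
        recurse(p + 1, used2, cnt + 1L)
      }
    }
  }
  recurse(1L, rep(FALSE, nr), 0L)
  best
}

# Exact Jonckheere-Terpstra null distribution by enumerating all ways to
# relabel the pooled values into the given group sizes.
jt_exact_p <- function(groups) {
  pool <- unlist(groups)
  sizes <- lengths(groups)
  J_obs <- endoarteval:::jt_statistic(groups)
  n <- length(pool)
  combos <- utils::combn(n, sizes[1], simplify = FALSE)
  stopifnot(length(sizes) == 2)  # two-group toys only
  ge <- 0L
  for (first in combos) {
    g <- list(pool[first], pool[-first])
    if (endoarteval:::jt_statistic(g) >= J_obs) ge <- ge + 1L
  }
  ge / length(combos)
}
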