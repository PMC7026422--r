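#' Specification for a synthetic annotation fixture
#'
#' Describes the statistical shape of a synthetic ground-truth set
#' emulating endoscopy artefact annotations: per-class box frequencies,
#' normalized box-area distributions, and the colocalization rate at
#' which small-class boxes are planted inside boxes of large classes.
#' The defaults mimic the qualitative structure reported for the
#' challenge data: specularity, artefact and bubbles are frequent, small
#' in area and heavily overlapped with other classes, while blur,
#' contrast, saturation and instrument are rarer but large.
#'
#' @param n_frames Number of frames.
#' @param image_size Frame size `c(height, width)` in pixels.
#' @param class_freqs Named expected boxes/frame (Poisson means).
#' @param size_dist Named list of `c(mean, sd)` of normalized box area
#'   (box area / frame area).
#' @param overlap_rate Probability that a small-class box (mean area
#'   < 0.05) is centred inside an existing large-class box.
#' @param seed Integer seed; identical specs generate identical fixtures.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_frames = 50,
                         image_size = c(288, 384),
                         class_freqs = c(specularity = 4, saturation = 1.2,
                                         artefact = 3, blur = 0.8,
                                         contrast = 0.8, bubbles = 2.5,
                                         instrument = 0.6),
                         size_dist = list(
                           specularity = c(0.004, 0.003),
                           saturation = c(0.08, 0.04),
                           artefact = c(0.008, 0.006),
                           blur = c(0.15, 0.08),
                           contrast = c(0.10, 0.05),
                           bubbles = c(0.012, 0.008),
                           instrument = c(0.12, 0.06)),
                         overlap_rate = 0.6,
                         seed = 1L) {
  stopifnot(n_frames >= 1, all(class_freqs >= 0),
            overlap_rate >= 0, overlap_rate <= 1)
  for (v in size_dist) stopifnot(v[1] > 0, v[1] < 1)
  structure(list(n_frames = as.integer(n_frames),
                 image_size = as.integer(image_size),
                 class_freqs = class_freqs, size_dist = size_dist,
                 overlap_rate = overlap_rate, seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a synthetic ground-truth annotation set
#'
#' Samples per-class box counts (Poisson at the spec's frequencies) and
#' box geometries (normalized areas from truncated normal distributions,
#' mildly random aspect ratios, uniform placement). Small-class boxes are
#' centred inside an existing large-class box with probability
#' `overlap_rate`, reproducing the colocalization that makes small
#' artefact classes hard to detect. Masks for the segmentation classes
#' are rasterized from the boxes as filled rectangles (with an optional
#' elliptical carving for visual variety); pass `with_masks = FALSE` for
#' detection-only fixtures. Bit-reproducible under the spec's seed.
#'
#' @param spec A [fixture_spec()].
#' @param catalog An [ead_catalog()]; classes are taken from
#'   `spec$class_freqs` names intersected with the catalog.
#' @param with_masks Rasterize per-class masks for the segmentation
#'   classes.
#' @return Named list of [ead_frame()] objects (`frame_001`, ...).
#' @export
generate_ground_truth <- function(spec = fixture_spec(),
                                  catalog = ead_catalog(),
                                  with_masks = TRUE) {
  old <- local_seed(spec$seed)
  on.exit(restore_seed(old))
  H <- spec$image_size[1]; W <- spec$image_size[2]
  classes <- intersect(names(spec$class_freqs), catalog$names)
  small <- classes[vapply(spec$size_dist[classes],
                          function(v) v[1] < 0.05, logical(1))]
  frames <- list()
  for (f in seq_len(spec$n_frames)) {
    id <- sprintf("frame_%03d", f)
    rows <- list()
    large_boxes <- NULL
    # large classes first so small boxes have hosts to colocalize with
    for (cl in c(setdiff(classes, small), small)) {
      n <- stats::rpois(1, spec$class_freqs[[cl]])
      if (n == 0) next
      for (b in seq_len(n)) {
        box <- sample_box(spec$size_dist[[cl]], H, W)
        if (cl %in% small && !is.null(large_boxes) &&
            stats::runif(1) < spec$overlap_rate) {
          host <- large_boxes[sample(nrow(large_boxes), 1), , drop = FALSE]
          box <- centre_box_inside(box, host, H, W)
        }
        rows[[length(rows) + 1]] <-
          data.frame(class = cl, confidence = NA_real_, x1 = box[1],
                     y1 = box[2], x2 = box[3], y2 = box[4],
                     stringsAsFactors = FALSE)
        if (!cl %in% small)
          large_boxes <- rbind(large_boxes,
                               data.frame(x1 = box[1], y1 = box[2],
                                          x2 = box[3], y2 = box[4]))
      }
    }
    boxes <- if (length(rows)) do.call(rbind, rows) else empty_boxes()
    masks <- NULL
    if (with_masks)
      masks <- masks_from_boxes(boxes, catalog$segmentation_classes, H, W,
                                carve = TRUE)
    frames[[id]] <- ead_frame(id, boxes, masks = masks,
                              image_size = c(H, W))
  }
  frames
}

# Sample one box with normalized area ~ N(mean, sd) truncated to
# (1e-4, 0.9); boxes larger than the frame are clipped.
sample_box <- function(area_dist, H, W) {
  a <- min(max(stats::rnorm(1, area_dist[1], area_dist[2]), 1e-4), 0.9)
  ar <- exp(stats::rnorm(1, 0, 0.3))              # width/height ratio
  area_px <- a * H * W
  w <- max(2, sqrt(area_px * ar))
  h <- max(2, area_px / w)
  w <- min(w, W); h <- min(h, H)
  x1 <- stats::runif(1, 0, W - w)
  y1 <- stats::runif(1, 0, H - h)
  round(c(x1, y1, x1 + w, y1 + h))
}

centre_box_inside <- function(box, host, H, W) {
  w <- box[3] - box[1]; h <- box[4] - box[2]
  cx <- stats::runif(1, host$x1, host$x2)
  cy <- stats::runif(1, host$y1, host$y2)
  x1 <- min(max(cx - w / 2, 0), W - w)
  y1 <- min(max(cy - h / 2, 0), H - h)
  round(c(x1, y1, x1 + w, y1 + h))
}

# Rasterize a frame's boxes into per-class masks (union of filled
# rectangles; carve=TRUE clips each rectangle to an inscribed ellipse
# for slightly less boxy shapes).
masks_from_boxes <- function(boxes, classes, H, W, carve = FALSE) {
  out <- stats::setNames(vector("list", length(classes)), classes)
  for (cl in classes) {
    m <- matrix(0L, H, W)
    bx <- boxes[boxes$class == cl, , drop = FALSE]
    if (nrow(bx)) for (i in seq_len(nrow(bx))) {
      b <- c(bx$x1[i], bx$y1[i], bx$x2[i], bx$y2[i])
      r <- rasterize_box(b, H, W)
      if (carve && (b[3] - b[1]) >= 6 && (b[4] - b[2]) >= 6)
        r <- r * ellipse_mask(b, H, W)
      m <- pmax(m, r)
    }
    out[[cl]] <- m
  }
  out
}

ellipse_mask <- function(b, H, W) {
  cx <- (b[1] + b[3]) / 2; cy <- (b[2] + b[4]) / 2
  rx <- (b[3] - b[1]) / 2; ry <- (b[4] - b[2]) / 2
  col_x <- matrix(seq_len(W) - 0.5, H, W, byrow = TRUE)
  row_y <- matrix(seq_len(H) - 0.5, H, W)
  matrix(as.integer(((col_x - cx) / rx)^2 + ((row_y - cy) / ry)^2 <= 1),
         H, W)
}

#' Specification of a controlled submission degradation
#'
#' Parameters for turning a ground-truth set into an imperfect synthetic
#' submission: localization jitter, box dropping, class mislabelling,
#' spurious detections, and a monotone IoU-to-confidence map so that
#' better-localized boxes get higher confidence.
#'
#' @param loc_noise_sd Gaussian jitter of box corners (pixels).
#' @param drop_prob Probability a ground-truth box is missed.
#' @param mislabel_prob Probability a kept box is relabelled to a random
#'   other class.
#' @param spurious_rate Expected spurious boxes per frame (Poisson).
#' @param conf_model Monotone function mapping IoU-with-truth in `[0, 1]`
#'   to a confidence in `[0, 1]`.
#' @param seed Integer seed.
#' @return A list of class `perturbation_spec`.
#' @export
perturbation_spec <- function(loc_noise_sd = 0, drop_prob = 0,
                              mislabel_prob = 0, spurious_rate = 0,
                              conf_model = function(iou) 0.1 + 0.85 * iou,
                              seed = 1L) {
  stopifnot(loc_noise_sd >= 0, drop_prob >= 0, drop_prob <= 1,
            mislabel_prob >= 0, mislabel_prob <= 1, spurious_rate >= 0)
  structure(list(loc_noise_sd = loc_noise_sd, drop_prob = drop_prob,
                 mislabel_prob = mislabel_prob,
                 spurious_rate = spurious_rate, conf_model = conf_model,
                 seed = as.integer(seed)),
            class = "perturbation_spec")
}

#' Degrade a ground-truth set into a synthetic submission
#'
#' Applies the perturbation spec to every frame: boxes are dropped,
#' jittered and mislabelled; spurious boxes are added; confidences come
#' from the monotone IoU-to-confidence map (spurious boxes get the
#' confidence of IoU 0). When the ground truth carries masks, submission
#' masks are re-rasterized from the perturbed boxes so box and mask
#' errors stay consistent. With all noise parameters 0 the submission
#' reproduces the ground truth and scores perfectly.
#'
#' @param gt Named list of ground-truth frames.
#' @param pspec A [perturbation_spec()].
#' @param catalog An [ead_catalog()].
#' @return Named list of submission [ead_frame()]s aligned with `gt`.
#' @export
perturb_to_predictions <- function(gt, pspec = perturbation_spec(),
                                   catalog = ead_catalog()) {
  old <- local_seed(pspec$seed)
  on.exit(restore_seed(old))
  classes <- catalog$detection_classes
  out <- list()
  for (id in names(gt)) {
    fr <- gt[[id]]
    H <- fr$image_size[1]; W <- fr$image_size[2]
    rows <- list()
    if (nrow(fr$boxes)) for (i in seq_len(nrow(fr$boxes))) {
      if (stats::runif(1) < pspec$drop_prob) next
      orig <- c(fr$boxes$x1[i], fr$boxes$y1[i],
                fr$boxes$x2[i], fr$boxes$y2[i])
      box <- jitter_box(orig, pspec$loc_noise_sd, H, W)
      cl <- fr$boxes$class[i]
      if (length(classes) > 1 && stats::runif(1) < pspec$mislabel_prob)
        cl <- sample(setdiff(classes, cl), 1)
      conf <- clamp01(pspec$conf_model(box_iou(orig, box)))
      rows[[length(rows) + 1]] <-
        data.frame(class = cl, confidence = conf, x1 = box[1], y1 = box[2],
                   x2 = box[3], y2 = box[4], stringsAsFactors = FALSE)
    }
    n_spur <- stats::rpois(1, pspec$spurious_rate)
    if (n_spur > 0) for (k in seq_len(n_spur)) {
      box <- sample_box(c(0.02, 0.01), H, W)
      rows[[length(rows) + 1]] <-
        data.frame(class = sample(classes, 1),
                   confidence = clamp01(pspec$conf_model(0)),
                   x1 = box[1], y1 = box[2], x2 = box[3], y2 = box[4],
                   stringsAsFactors = FALSE)
    }
    boxes <- if (length(rows)) do.call(rbind, rows) else empty_boxes()
    masks <- NULL
    if (!is.null(fr$masks))
      masks <- masks_from_boxes(boxes, catalog$segmentation_classes, H, W,
                                carve = TRUE)
    out[[id]] <- ead_frame(id, boxes, masks = masks, image_size = c(H, W))
  }
  out
}

clamp01 <- function(x) min(max(x, 0), 1)

jitter_box <- function(box, sd, H, W) {
  if (sd == 0) return(box)
  b <- box + stats::rnorm(4, 0, sd)
  x1 <- min(b[1], b[3]); x2 <- max(b[1], b[3])
  y1 <- min(b[2], b[4]); y2 <- max(b[2], b[4])
  x1 <- min(max(x1, 0), W - 1); y1 <- min(max(y1, 0), H - 1)
  x2 <- min(max(x2, x1 + 1), W); y2 <- min(max(y2, y1 + 1), H)
  c(x1, y1, x2, y2)
}

#' Published leaderboard tables as data fixtures
#'
#' Returns the per-team metric values printed on the challenge
#' leaderboards as data frames: `"table2"` carries the detection and
#' out-of-sample generalization scores (mAP_d, IoU_d, score_d, mAP_g,
#' IoU_g, dev_g per team plus baselines and the consensus "Merged"
#' super detector), `"table4"` the semantic segmentation scores (DSC,
#' Jaccard, Overlap, F2, PPV, Recall, s-score). These fixtures feed the
#' score-identity checks and the rank/clinical analyses.
#'
#' @param table_id `"table2"` or `"table4"`.
#' @return A data frame with a `team` column and metric columns.
#' @examples
#' lb <- leaderboard_fixture("table2")
#' lb[lb$team == "yangsuhui", c("mAP_d", "IoU_d", "score_d")]
#' @export
leaderboard_fixture <- function(table_id = c("table2", "table4")) {
  if (!is.character(table_id) || !table_id[1] %in% c("table2", "table4"))
    stop("unknown leaderboard table '", table_id[1], "'")
  table_id <- match.arg(table_id)
  if (table_id == "table2") detection_leaderboard() else
    segmentation_leaderboard()
}

detection_leaderboard <- function() {
  df <- utils::read.csv(text = "team,mAP_d,IoU_d,score_d,mAP_g,IoU_g,dev_g
yangsuhui,0.3235,0.4172,0.3610,0.3187,0.0734,0.1018
ZhangPY,0.3117,0.4051,0.3491,0.3518,0.0889,0.0984
Keisecker,0.3087,0.3997,0.3451,0.2848,0.3902,0.0696
VegZhang,0.3371,0.3517,0.3429,0.3991,0.1783,0.1010
YWa,0.3842,0.2368,0.3252,0.3746,0.1481,0.0424
michaelqiyao,0.3842,0.2368,0.3252,0.3746,0.1780,0.0742
ilkayoksuz,0.2719,0.3456,0.3014,0.2974,0.0688,0.0859
swtnb,0.2901,0.3180,0.3013,0.2914,0.2547,0.0854
Witt,0.3148,0.2621,0.2937,0.2897,0.1854,0.1003
akhanss,0.2581,0.3330,0.2880,0.2187,0.2262,0.0770
XiaokangWang,0.2621,0.3205,0.2855,0.2515,0.2058,0.0728
a545306097,0.2547,0.2719,0.2616,0.1122,0.2244,0.1298
nqt52798669,0.3068,0.1222,0.2330,0.3154,0.0871,0.0515
ShufanYang,0.2208,0.1955,0.2107,0.1931,0.1365,0.0478
xiaohong1,0.2416,0.3482,0.2842,0.1764,0.2671,0.0555
Faster R-CNN (baseline),0.2226,0.2751,0.2436,0.2172,0.1647,0.0893
Retinanet (baseline),0.2135,0.2270,0.2189,0.2499,0.1679,0.0665
Merged (super baseline),0.3331,0.3793,0.3516,0.3433,0.2610,0.0610",
                 stringsAsFactors = FALSE, check.names = FALSE)
  df
}

segmentation_leaderboard <- function() {
  df <- utils::read.csv(text = "team,DSC,Jaccard,Overlap,F2,PPV,Recall,s_score
yangsuhui,0.6810,0.6416,0.6612,0.6779,0.8789,0.7148,0.6654
swtnb,0.6496,0.6041,0.6269,0.6585,0.7515,0.7594,0.6348
YWa,0.6392,0.6021,0.6206,0.6243,0.9039,0.6602,0.6216
VegZhang,0.6141,0.5831,0.5986,0.6185,0.8386,0.6839,0.6036
michaelqiyao,0.6141,0.5787,0.5964,0.6171,0.8164,0.6987,0.6016
Ig920810,0.6079,0.5684,0.5882,0.5972,0.8189,0.6802,0.5904
Weiminson,0.6011,0.5631,0.5821,0.5839,0.8375,0.6598,0.5825
ZhangPY,0.5719,0.5397,0.5558,0.5701,0.7719,0.6581,0.5594
nqt52798669,0.5414,0.4998,0.5206,0.5331,0.6290,0.6887,0.5237
ShufanYang,0.4119,0.3797,0.3958,0.3998,0.6407,0.6360,0.3968
U-Net (baseline),0.5490,0.5030,0.5260,0.5580,0.6691,0.7488,0.5340
Merged (super baseline),0.6782,0.6356,0.6569,0.6703,0.8747,0.7178,0.6603",
                 stringsAsFactors = FALSE, check.names = FALSE)
  df
}
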