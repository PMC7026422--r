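test_that("greedy matching follows the confidence and threshold rules", {
  ref <- box_row("blur", 0, 0, 10, 10)
  # one ref, one matching pred
  m <- match_boxes(ref, box_row("blur", 0, 0, 10, 12, 0.8))
  expect_equal(nrow(m$pairs), 1)
  expect_length(m$unmatched_refs, 0)
  expect_length(m$unmatched_preds, 0)

  # two candidate preds: the higher-confidence one wins
  preds <- rbind(box_row("blur", 0, 0, 10, 11, 0.6),
                 box_row("blur", 0, 0, 10, 12, 0.9))
  m <- match_boxes(ref, preds)
  expect_equal(m$pairs$pred, 2)
  expect_equal(m$unmatched_preds, 1)

  # IoU below the threshold: nobody matches
  m <- match_boxes(ref, box_row("blur", 8, 8, 18, 18, 0.9))
  expect_equal(nrow(m$pairs), 0)
  expect_equal(m$unmatched_refs, 1)

  # class awareness
  m <- match_boxes(ref, box_row("contrast", 0, 0, 10, 10, 0.9))
  expect_equal(nrow(m$pairs), 0)
  m <- match_boxes(ref, box_row("contrast", 0, 0, 10, 10, 0.9),
                   class_aware = FALSE)
  expect_equal(nrow(m$pairs), 1)

  expect_error(match_boxes(ref, ref, iou_thresh = 1.2), "iou_thresh")
})

test_that("greedy tp counts equal the exhaustive assignment oracle", {
  set.seed(21)
  for (case in 1:1000) {
    nr <- sample(0:4, 1); np <- sample(0:4, 1)
    refs <- if (nr) do.call(rbind, lapply(seq_len(nr), function(i) {
      b <- random_box(); box_row("artefact", b[1], b[2], b[3], b[4])
    })) else box_row(character(0), numeric(0), numeric(0), numeric(0),
                     numeric(0))
    preds <- if (np) do.call(rbind, lapply(seq_len(np), function(i) {
      b <- random_box()
      box_row("artefact", b[1], b[2], b[3], b[4], conf = runif(1))
    })) else box_row(character(0), numeric(0), numeric(0), numeric(0),
                     numeric(0), numeric(0))
    m <- match_boxes(refs, preds, iou_thresh = 0.25)
    ok <- endoarteval:::box_iou_matrix(refs, preds) >= 0.25
    expect_identical(nrow(m$pairs), as.integer(max_matching_count(ok)))
  }
})

test_that("lowering the IoU threshold never loses matches", {
  set.seed(22)
  for (case in 1:50) {
    refs <- do.call(rbind, lapply(1:3, function(i) {
      b <- random_box(); box_row("bubbles", b[1], b[2], b[3], b[4])
    }))
    preds <- do.call(rbind, lapply(1:3, function(i) {
      b <- random_box()
      box_row("bubbles", b[1], b[2], b[3], b[4], conf = runif(1))
    }))
    tps <- vapply(c(0.6, 0.4, 0.25, 0.1), function(th)
      nrow(match_boxes(refs, preds, th)$pairs), numeric(1))
    expect_true(all(diff(tps) >= 0))
  }
})

test_that("average precision integrates the PR curve (hand-enumerated)", {
  # perfect single retrieval
  gt <- one_frame_gt(box_row("blur", 0, 0, 10, 10))
  expect_equal(average_precision(gt, one_frame_sub(
    box_row("blur", 0, 0, 10, 10, 0.4)), "blur"), 1)

  # high-confidence miss then low-confidence hit: PR (0,0) -> (1, 0.5)
  sub <- one_frame_sub(rbind(box_row("blur", 50, 50, 60, 60, 0.9),
                             box_row("blur", 0, 0, 10, 10, 0.5)))
  expect_equal(average_precision(gt, sub, "blur"), 0.5)

  # no predictions at all
  expect_equal(average_precision(gt, one_frame_sub(empty_gt <- box_row(
    character(0), numeric(0), numeric(0), numeric(0), numeric(0))),
    "blur"), 0)

  # three predictions, two refs: hand-integrated envelope area = 5/6
  gt2 <- one_frame_gt(rbind(box_row("blur", 0, 0, 10, 10),
                            box_row("blur", 20, 20, 30, 30)))
  sub2 <- one_frame_sub(rbind(
    box_row("blur", 0, 0, 10, 10, 0.9),     # tp, r 1/2 p 1
    box_row("blur", 60, 60, 70, 70, 0.8),   # fp, r 1/2 p 1/2
    box_row("blur", 20, 20, 30, 30, 0.7)))  # tp, r 1   p 2/3
  expect_equal(average_precision(gt2, sub2, "blur"), 5 / 6)

  # class with no reference boxes is not applicable
  expect_true(is.na(average_precision(gt, sub, "contrast")))
})

test_that("AP depends on the confidence ranking only", {
  set.seed(23)
  gt <- generate_ground_truth(fixture_spec(n_frames = 5, seed = 8),
                              with_masks = FALSE)
  sub <- perturb_to_predictions(gt, perturbation_spec(
    loc_noise_sd = 5, drop_prob = 0.2, spurious_rate = 1, seed = 9))
  ap1 <- average_precision(gt, sub, "specularity")
  scaled <- lapply(sub, function(fr) {
    fr$boxes$confidence <- fr$boxes$confidence * 0.31
    fr
  })
  expect_equal(average_precision(gt, scaled, "specularity"), ap1)
})

test_that("detection scorecard is exact on a perfect submission and linear", {
  gt <- generate_ground_truth(fixture_spec(n_frames = 6, seed = 10),
                              with_masks = FALSE)
  perfect <- perturb_to_predictions(gt, perturbation_spec(
    conf_model = function(iou) 0.77))
  card <- evaluate_detection(gt, perfect)
  expect_equal(card$mAP, 1)
  expect_equal(card$mean_iou, 1)
  expect_equal(card$score_d, 1)
  expect_true(card$valid)
  expect_equal(card$score_d,
               0.6 * card$mAP + 0.4 * card$mean_iou, tolerance = 1e-12)

  noisy <- perturb_to_predictions(gt, perturbation_spec(
    loc_noise_sd = 6, drop_prob = 0.2, seed = 2))
  card2 <- evaluate_detection(gt, noisy)
  expect_equal(card2$score_d, 0.6 * card2$mAP + 0.4 * card2$mean_iou,
               tolerance = 1e-12)
  expect_true(all(card2$per_class$ap <= 1 & card2$per_class$ap >= 0,
                  na.rm = TRUE))
})

test_that("missing submission frames are scored as empty predictions", {
  gt <- c(one_frame_gt(box_row("blur", 0, 0, 10, 10), "a"),
          one_frame_gt(box_row("blur", 5, 5, 15, 15), "b"))
  sub <- one_frame_sub(box_row("blur", 0, 0, 10, 10, 0.9), "a")
  card <- evaluate_detection(gt, sub)
  expect_equal(card$per_class$ap[card$per_class$class == "blur"], 0.5)
  expect_equal(card$per_class$mean_iou[card$per_class$class == "blur"], 0.5)
})

test_that("validity gate applies strict 0.7 < IoU/mAP < 1.3", {
  g <- validity_check(0.3235, 0.4172)
  expect_equal(g$ratio, 1.2897, tolerance = 1e-4)
  expect_true(g$valid)
  expect_false(validity_check(0.3, 0.5)$valid)    # ratio 1.667
  expect_true(validity_check(0.42, 0.42)$valid)   # ratio exactly 1
  expect_false(validity_check(0.3, 0.39)$valid)   # ratio exactly 1.3
  bad <- validity_check(0, 0.2)
  expect_false(bad$valid)
  expect_true(is.na(bad$ratio))
})

test_that("confusion matrix attributes boxes by geometry, not label", {
  gt <- one_frame_gt(rbind(box_row("blur", 0, 0, 10, 10),
                           box_row("contrast", 30, 30, 40, 40)))
  # right geometry, wrong class for the first box; second missed
  sub <- one_frame_sub(box_row("contrast", 0, 0, 10, 10, 0.9))
  cm <- confusion_matrix(gt, sub)
  expect_equal(cm["blur", "contrast"], 1L)
  expect_equal(cm["contrast", "background"], 1L)
  expect_equal(sum(cm), 2)

  # perfect submission: purely diagonal
  sub2 <- one_frame_sub(rbind(box_row("blur", 0, 0, 10, 10, 0.9),
                              box_row("contrast", 30, 30, 40, 40, 0.8)))
  cm2 <- confusion_matrix(gt, sub2)
  expect_equal(cm2["blur", "blur"], 1L)
  expect_equal(cm2["contrast", "contrast"], 1L)
  expect_equal(sum(cm2), 2)

  # no predictions: all mass in the background column
  cm3 <- confusion_matrix(gt, list())
  expect_equal(sum(cm3[, "background"]), 2)
  expect_equal(sum(cm3), 2)

  # row sums equal reference box counts per class
  classes <- ead_catalog()$detection_classes
  expect_equal(as.vector(rowSums(cm)[classes]),
               as.vector(table(factor(gt[["f1"]]$boxes$class,
                                      levels = classes))[classes]))
})

test_that("per-image F1 pools class-aware matches within each frame", {
  gt <- one_frame_gt(rbind(box_row("blur", 0, 0, 10, 10),
                           box_row("bubbles", 30, 30, 40, 40)))
  sub_perfect <- one_frame_sub(rbind(
    box_row("blur", 0, 0, 10, 10, 0.9),
    box_row("bubbles", 30, 30, 40, 40, 0.8)))
  expect_equal(unname(per_image_f1(gt, sub_perfect)), 1)

  expect_equal(unname(per_image_f1(gt, list())), 0)

  # tp = 1 of 2 preds and 2 refs -> p = r = 0.5 -> F1 = 0.5
  sub_half <- one_frame_sub(rbind(
    box_row("blur", 0, 0, 10, 10, 0.9),
    box_row("bubbles", 60, 60, 70, 70, 0.8)))
  expect_equal(unname(per_image_f1(gt, sub_half)), 0.5)
})
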