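# endoarteval

Scoring, ranking and consensus-ensembling toolkit for multi-class
**artefact detection and segmentation in clinical endoscopy frames**.

Endoscopy videos are routinely corrupted by specular reflections, pixel
saturation, under-exposed regions, motion blur, bubbles, debris and the
instrument itself — seven artefact classes that must be localized
(bounding boxes) and delineated (per-class binary masks) before any
quantitative analysis of the mucosal surface is trustworthy. This
package implements the complete evaluation stack used to compare such
algorithms on a common benchmark:

- **Detection**: greedy confidence-ordered box matching at IoU ≥ 0.25,
  all-point average precision per class, and the weighted leaderboard
  score `score_d = 0.6·mAP + 0.4·IoU`, with the validity gate
  `0.7 < IoU/mAP < 1.3` that discourages trading the two metrics off.
  Class confusion matrices and per-image F1 support error dissection.
- **Segmentation**: per-class Dice (DSC), Jaccard (J), Overlap
  `0.5·(DSC+J)`, F2, PPV and recall, macro-averaged over frames then
  classes, combined into the recall-leaning composite
  `score_s = 0.75·[0.5·(F1+J)] + 0.25·F2`.
- **Out-of-sample generalization**: the tolerance-gated per-class
  deviation `dev_g^i` (zero when `|mAP_d−mAP_g|/mAP_d ≤ 0.1`, else the
  absolute deviation), its class mean `dev_g`, and the rank combination
  `score_g = 1/3·Rank(dev_g) + 2/3·Rank(mAP_g)`.
- **Consensus ensembling**: "super" detectors (single-linkage IoU
  clustering, strict-majority support, highest-confidence
  representative) and "super" segmentations (per-pixel majority vote),
  with per-submission contribution tallies.
- **Rank statistics**: tie-corrected Friedman test over artefact-class
  blocks, Nemenyi critical-difference and Bonferroni-Dunn post-hocs,
  seeded-permutation Jonckheere-Terpstra trend test, and the
  clinical-applicability ranking (accuracy 0.4, consistency 0.5,
  efficiency 0.1; consistency = sd/mean of per-class scores).
- **Synthetic fixtures**: a seeded generator of EAD-shaped ground truth
  (frequent small colocalized classes, rare large ones) and controlled
  submission degradations, so the whole stack is testable without image
  downloads. The published leaderboard tables ship as data fixtures.

## Worked example

Recompute a leaderboard entry from its printed components, then score a
synthetic submission end to end:

```r
library(endoarteval)

lb <- leaderboard_fixture("table2")
ys <- lb[lb$team == "yangsuhui", ]
0.6 * ys$mAP_d + 0.4 * ys$IoU_d
#> score_d = 0.6*0.3235 + 0.4*0.4172 = 0.3610

gt  <- generate_ground_truth(fixture_spec(n_frames = 20, seed = 42))
sub <- perturb_to_predictions(gt, perturbation_spec(
  loc_noise_sd = 4, drop_prob = 0.1, mislabel_prob = 0.05,
  spurious_rate = 0.5, seed = 43))
evaluate_detection(gt, sub)
#> <detection_scorecard>
#>        class     ap mean_iou n_gt
#>  specularity 0.7333   0.4169   75
#>   saturation 0.8462   0.7243   26
#>     artefact 0.8633   0.5527   52
#>         blur 0.7391   0.6622   23
#>     contrast 0.9167   0.8060   12
#>      bubbles 0.7388   0.5422   42
#>   instrument 0.7692   0.6739   13
#> mAP 0.8009 | IoU 0.6255 | score_d 0.7308 | ratio 0.7809 (valid)

aggregate_segmentation(gt, sub)$s_score
#> [1] 0.7102
```

The scorecard reads as on the challenge leaderboards: per-class AP and
mean best-match IoU (missed boxes count 0), their macro means, the
weighted `score_d`, and the IoU/mAP validity ratio. Note the small,
heavily-overlapped classes (specularity, artefact, bubbles) drag the
IoU column down exactly as observed on real submissions.

## Command line

```sh
endoart-eval simulate --spec spec.yaml --out sim        # gt + k submissions
endoart-eval detect   --gt sim/gt --pred sim/sub_01 --out report.json
endoart-eval segment  --gt sim/gt --pred sim/sub_01 --out seg.json
endoart-eval merge    --pred sim/sub_01 --pred sim/sub_02 --out merged
endoart-eval generalize --gt-d d/gt --gt-g g/gt \
                        --pred-d d/p --pred-g g/p --out gen.json
endoart-eval rank     --leaderboard scores.csv --out rank.json
```

Ground truth and predictions are plain text: one `<frame_id>.txt` per
frame with lines `<class> [<confidence>] <x1> <y1> <x2> <y2>`
(half-open pixel coordinates), and one single-channel PNG per
segmentation class named `<frame_id>_<class>.png`.

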