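Package: endoarteval
Title: Evaluation, Ranking and Consensus Ensembling for Endoscopy
    Artefact Detection and Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scoring toolkit for multi-class artefact detection and
    semantic segmentation in clinical endoscopy frames. Implements
    confidence-ranked bounding-box matching at an IoU threshold, all-point
    average precision, the weighted detection leaderboard score
    (0.6 mAP + 0.4 IoU) with its mAP-IoU validity gate, per-class mask
    metrics (Dice, Jaccard, F-beta, PPV, recall) and the composite
    segmentation s-score, tolerance-gated out-of-sample generalization
    deviation with rank-combined scoring, consensus "super" detectors and
    segmenters built by majority voting across submissions, nonparametric
    rank statistics (Friedman with Nemenyi and Bonferroni-Dunn post-hocs,
    Jonckheere-Terpstra trend test) and a weighted clinical-applicability
    ranking. Ships a seeded synthetic fixture generator emulating the
    statistical structure of endoscopy artefact annotations (small,
    heavily colocalized classes) so every evaluator is testable without
    image downloads, plus published leaderboard tables as data fixtures,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
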