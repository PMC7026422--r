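#' Tolerance-gated per-class generalization deviation
#'
#' Deviation between a class's mAP on the detection test set (`map_d`) and
#' on the out-of-sample generalization set (`map_g`): 0 when the relative
#' deviation `|map_d - map_g| / map_d` is within the tolerance (default
#' 0.1, boundary inclusive), otherwise the absolute deviation. A small
#' fluctuation around the in-sample score is treated as noise; larger
#' drops (or jumps) are penalized by their full magnitude.
#'
#' `map_d = 0` is not covered by the published rule (division by zero):
#' with `map_g = 0` the deviation is 0; with `map_g > 0` it is `map_g`
#' (documented extension).
#'
#' @param map_d,map_g Per-class mAP on the detection and generalization
#'   sets, in `[0, 1]`.
#' @param tol Relative tolerance below which the deviation is zeroed.
#' @return Nonnegative deviation.
#' @examples
#' class_deviation(0.5, 0.46)  # 0    (relative 0.08 <= 0.1)
#' class_deviation(0.5, 0.30)  # 0.2  (relative 0.4  >  0.1)
#' @export
class_deviation <- function(map_d, map_g, tol = 0.1) {
  stopifnot(map_d >= 0, map_d <= 1, map_g >= 0, map_g <= 1, tol >= 0)
  if (map_d == 0) return(if (map_g == 0) 0 else map_g)
  dev <- abs(map_d - map_g)
  if (dev / map_d <= tol) 0 else dev
}

#' Out-of-sample generalization deviation of a submission
#'
#' Mean over the catalog's detection classes of the tolerance-gated
#' per-class deviations between two detection scorecards (in-sample and
#' out-of-sample); `dev_g = (1/N) * sum_i dev_g^i`. Near-zero values mean
#' the method performs equally well on data from an unseen institution.
#'
#' @param card_d,card_g [evaluate_detection()] scorecards on the detection
#'   and generalization sets; must cover the same class set.
#' @param tol Relative tolerance passed to [class_deviation()].
#' @return List with `per_class_dev` (named vector), `dev_g`, `mAP_d`,
#'   `mAP_g`.
#' @export
generalization_deviation <- function(card_d, card_g, tol = 0.1) {
  cd <- card_d$per_class; cg <- card_g$per_class
  if (!identical(sort(cd$class), sort(cg$class)))
    stop("scorecards cover different class sets")
  cg <- cg[match(cd$class, cg$class), , drop = FALSE]
  ap_d <- ifelse(is.na(cd$ap), 0, cd$ap)
  ap_g <- ifelse(is.na(cg$ap), 0, cg$ap)
  per <- mapply(class_deviation, ap_d, ap_g, MoreArgs = list(tol = tol))
  names(per) <- cd$class
  list(per_class_dev = per, dev_g = mean(per),
       mAP_d = card_d$mAP, mAP_g = card_g$mAP)
}

#' Rank-combined generalization score
#'
#' `score_g = 1/3 * Rank(dev_g) + 2/3 * Rank(mAP_g)`, with rank 1 the
#' smallest deviation and (by default) rank 1 the highest out-of-sample
#' mAP, so that lower `score_g` is better throughout. Ties receive average
#' ranks. Set `map_ascending = TRUE` to rank mAP_g ascending instead (the
#' alternative reading of the published rule; see the vignette).
#'
#' @param teams Data frame with columns `team`, `dev_g`, `mAP_g` (or a
#'   named list of `c(dev_g, mAP_g)` pairs).
#' @param map_ascending Rank mAP_g ascending instead of descending.
#' @return Data frame with `team`, `dev_g`, `mAP_g`, `rank_dev`,
#'   `rank_map`, `score_g`, ordered by increasing `score_g`.
#' @export
generalization_rank_score <- function(teams, map_ascending = FALSE) {
  if (!is.data.frame(teams))
    teams <- data.frame(team = names(teams),
                        dev_g = vapply(teams, `[[`, 0, "dev_g"),
                        mAP_g = vapply(teams, `[[`, 0, "mAP_g"))
  if (nrow(teams) < 2) stop("ranking needs at least 2 teams")
  rank_dev <- rank(teams$dev_g, ties.method = "average")
  map_key <- if (map_ascending) teams$mAP_g else -teams$mAP_g
  rank_map <- rank(map_key, ties.method = "average")
  teams$rank_dev <- rank_dev
  teams$rank_map <- rank_map
  teams$score_g <- rank_dev / 3 + 2 * rank_map / 3
  teams[order(teams$score_g, teams$team), , drop = FALSE]
}
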