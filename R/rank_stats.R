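#' Friedman rank test across blocks
#'
#' Nonparametric analysis of variance on ranks: methods are ranked within
#' each block (here, artefact classes serve as blocks), ties receiving
#' average ranks, and the tie-corrected chi-square approximated Friedman
#' statistic is computed from the rank sums. When every block ranks all
#' methods identically equal (all values tied) the statistic is 0 and
#' p = 1.
#'
#' @param scores Numeric matrix, methods in rows, blocks in columns;
#'   higher value = better is irrelevant (ranks are monotone-invariant).
#' @return List with `statistic`, `df`, `p_value` and `mean_ranks`
#'   (average within-block rank per method; 1 = smallest value).
#' @export
friedman_test <- function(scores) {
  scores <- as.matrix(scores)
  k <- nrow(scores); n <- ncol(scores)
  if (k < 3) stop("need at least 3 methods")
  if (n < 2) stop("need at least 2 blocks")
  if (any(!is.finite(scores))) stop("scores must be finite")
  r <- apply(scores, 2, rank)            # k x n, ranks within block
  R <- rowSums(r)
  A <- sum(r^2)
  C <- n * k * (k + 1)^2 / 4
  num <- (k - 1) * sum((R - n * (k + 1) / 2)^2)
  stat <- if (A == C) 0 else num / (A - C)
  p <- stats::pchisq(stat, df = k - 1, lower.tail = FALSE)
  list(statistic = stat, df = k - 1, p_value = p,
       mean_ranks = stats::setNames(R / n, rownames(scores)))
}

#' Nemenyi post-hoc critical-difference analysis
#'
#' After a Friedman test, two methods differ significantly when their
#' mean ranks differ by at least the critical difference
#' `CD = q_alpha * sqrt(k (k + 1) / (6 n))`, with `q_alpha` the
#' alpha-level studentized-range quantile divided by `sqrt(2)`.
#'
#' @param mean_ranks Named numeric vector of mean ranks (from
#'   [friedman_test()]).
#' @param n Number of blocks.
#' @param alpha Significance level.
#' @return List with `cd` (critical difference) and `significant`
#'   (logical method-by-method matrix).
#' @export
nemenyi_posthoc <- function(mean_ranks, n, alpha = 0.05) {
  k <- length(mean_ranks)
  q_alpha <- stats::qtukey(1 - alpha, k, Inf) / sqrt(2)
  cd <- q_alpha * sqrt(k * (k + 1) / (6 * n))
  d <- abs(outer(mean_ranks, mean_ranks, `-`))
  sig <- d >= cd
  diag(sig) <- FALSE
  list(cd = cd, q_alpha = q_alpha, significant = sig)
}

#' Bonferroni-Dunn post-hoc comparison against a control
#'
#' Dunn z statistics compare each method's mean rank against a designated
#' control (e.g. a baseline detector), with the two-sided p-values
#' compared against the Bonferroni-corrected level `alpha / (k - 1)`.
#'
#' @param mean_ranks Named numeric vector of mean ranks.
#' @param control Name of the control method.
#' @param n Number of blocks.
#' @param alpha Family-wise significance level.
#' @return Data frame with `method`, `z`, `p_value`, `significant`
#'   (control row included, never significant against itself).
#' @export
bonferroni_dunn_posthoc <- function(mean_ranks, control, n, alpha = 0.05) {
  k <- length(mean_ranks)
  if (!control %in% names(mean_ranks))
    stop("unknown control method '", control, "'")
  se <- sqrt(k * (k + 1) / (6 * n))
  z <- (mean_ranks - mean_ranks[[control]]) / se
  p <- 2 * stats::pnorm(-abs(z))
  sig <- p < alpha / (k - 1)
  sig[names(mean_ranks) == control] <- FALSE
  data.frame(method = names(mean_ranks), z = as.numeric(z),
             p_value = as.numeric(p), significant = as.logical(sig),
             row.names = NULL, stringsAsFactors = FALSE)
}

# J statistic: cross-pairs (earlier group, later group) with later > earlier,
# ties counting one half.
jt_statistic <- function(groups) {
  J <- 0
  g <- length(groups)
  for (i in seq_len(g - 1)) for (j in (i + 1):g) {
    for (x in groups[[i]])
      J <- J + sum(groups[[j]] > x) + 0.5 * sum(groups[[j]] == x)
  }
  J
}

#' Jonckheere-Terpstra trend test
#'
#' Tests for an increasing trend across ordered groups (e.g. per-class
#' detection scores with classes ordered by annotation count or mean
#' artefact size). The statistic J counts, over all pairs of an earlier
#' and a later group, the value pairs in increasing order (ties count one
#' half). The one-sided p-value is obtained by seeded permutation of group
#' membership, appropriate for the small group counts involved; a normal
#' approximation is available as an alternative.
#'
#' @param groups List of numeric vectors in hypothesized increasing order.
#' @param n_perm Number of permutations (values below 100 warn).
#' @param seed Integer seed for the permutation draw.
#' @param method `"permutation"` or `"normal"`.
#' @return List with `statistic` (J) and `p_value` (one-sided,
#'   increasing-trend alternative).
#' @examples
#' jonckheere_terpstra(list(c(1, 2), c(3, 4)), n_perm = 500)$statistic  # 4
#' @export
jonckheere_terpstra <- function(groups, n_perm = 10000, seed = 1,
                                method = c("permutation", "normal")) {
  method <- match.arg(method)
  if (length(groups) < 2) stop("need at least 2 ordered groups")
  if (any(lengths(groups) == 0)) stop("groups must be nonempty")
  J <- jt_statistic(groups)
  sizes <- lengths(groups)
  if (method == "normal") {
    n <- sum(sizes)
    mu <- (n^2 - sum(sizes^2)) / 4
    sigma2 <- (n^2 * (2 * n + 3) - sum(sizes^2 * (2 * sizes + 3))) / 72
    p <- stats::pnorm((J - mu) / sqrt(sigma2), lower.tail = FALSE)
    return(list(statistic = J, p_value = p, method = method))
  }
  if (n_perm < 100) warning("n_perm < 100: permutation p-value is coarse")
  pool <- unlist(groups)
  idx_end <- cumsum(sizes)
  idx_start <- c(1, utils::head(idx_end, -1) + 1)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  count <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample(pool)
    gp <- mapply(function(a, z) perm[a:z], idx_start, idx_end,
                 SIMPLIFY = FALSE)
    if (jt_statistic(gp) >= J) count <- count + 1L
  }
  list(statistic = J, p_value = (count + 1) / (n_perm + 1), method = method)
}

# Set the RNG reproducibly inside a function without clobbering the
# caller's stream.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old))
    rm(".Random.seed", envir = globalenv())
  else
    assign(".Random.seed", old, envir = globalenv())
}

#' Consistency ratio of per-class scores
#'
#' Coefficient of variation: sample standard deviation of a method's
#' per-class scores divided by their mean. Low values indicate
#' class-stable performance, one of the clinical-applicability criteria.
#' Scale-invariant: rescaling all scores leaves the ratio unchanged.
#'
#' @param values Numeric vector of per-class scores, mean > 0.
#' @return `sd(values) / mean(values)` (`NA` with a warning when the mean
#'   is 0).
#' @examples
#' consistency_ratio(c(2, 4))  # 0.4714
#' @export
consistency_ratio <- function(values) {
  m <- mean(values)
  if (m == 0) {
    warning("mean is 0: consistency ratio undefined")
    return(NA_real_)
  }
  stats::sd(values) / m
}

#' Clinical-applicability ranking
#'
#' Combines per-team accuracy, consistency and computational-efficiency
#' rankings into a weighted value `0.4 acc + 0.5 cons + 0.1 eff` and ranks
#' teams by it (ascending, ties averaged). Consistency is deliberately the
#' heaviest factor: a method with stable predictions across clinical
#' setups is preferred over one that is slightly more accurate in a few.
#' Missing efficiency ranks (hardware metadata unavailable) should be
#' imputed beforehand with [impute_missing_ranks()].
#'
#' @param acc_ranks,cons_ranks,eff_ranks Named numeric rank vectors over
#'   the same team set.
#' @param weights Named weights summing to 1, default
#'   `c(accuracy = 0.4, consistency = 0.5, efficiency = 0.1)`.
#' @return Data frame with `team`, the three input ranks, `weighted` and
#'   `final_rank`, ordered by `final_rank`.
#' @export
clinical_rank <- function(acc_ranks, cons_ranks, eff_ranks,
                          weights = c(accuracy = 0.4, consistency = 0.5,
                                      efficiency = 0.1)) {
  teams <- names(acc_ranks)
  if (!setequal(teams, names(cons_ranks)) ||
      !setequal(teams, names(eff_ranks)))
    stop("rank vectors must cover the same team set")
  if (abs(sum(weights) - 1) > 1e-12) stop("weights must sum to 1")
  cons_ranks <- cons_ranks[teams]; eff_ranks <- eff_ranks[teams]
  weighted <- weights[["accuracy"]] * acc_ranks +
    weights[["consistency"]] * cons_ranks +
    weights[["efficiency"]] * eff_ranks
  out <- data.frame(team = teams, accuracy = as.numeric(acc_ranks),
                    consistency = as.numeric(cons_ranks),
                    efficiency = as.numeric(eff_ranks),
                    weighted = as.numeric(weighted),
                    final_rank = rank(weighted, ties.method = "average"),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$final_rank, out$team), , drop = FALSE]
}

#' Impute missing ranks with the worst observed rank plus one
#'
#' Teams without efficiency metadata (unreported hardware or timing)
#' receive the worst observed rank + 1, mirroring the leaderboard's
#' imputed-rank convention.
#'
#' @param ranks Named numeric vector with `NA` for missing entries.
#' @return The vector with `NA`s replaced.
#' @export
impute_missing_ranks <- function(ranks) {
  if (all(is.na(ranks))) stop("all ranks missing")
  worst <- max(ranks, na.rm = TRUE)
  ranks[is.na(ranks)] <- worst + 1
  ranks
}
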