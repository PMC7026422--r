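test_that("Friedman statistic handles ties, degenerate and ordered grids", {
  # all methods identical in every block: statistic 0, p = 1
  flat <- matrix(0.5, 3, 4, dimnames = list(c("a", "b", "c"), NULL))
  ft <- friedman_test(flat)
  expect_equal(ft$statistic, 0)
  expect_equal(ft$p_value, 1)

  # strict ordering in every block: mean ranks 1, 2, 3
  ordered <- rbind(a = c(1, 2, 1, 3), b = c(2, 3, 2, 4), c = c(5, 6, 7, 8))
  ft2 <- friedman_test(ordered)
  expect_equal(unname(ft2$mean_ranks), c(1, 2, 3))

  expect_error(friedman_test(matrix(1, 2, 4)), "3 methods")
  expect_error(friedman_test(matrix(1, 3, 1)), "2 blocks")
})

test_that("Friedman agrees with the reference implementation (no ties)", {
  grid <- rbind(m1 = c(5.2, 4.8, 6.1, 5.5, 4.9),
                m2 = c(4.1, 5.9, 5.0, 6.2, 5.3),
                m3 = c(6.3, 3.7, 4.2, 4.8, 6.0),
                m4 = c(3.3, 6.6, 7.1, 3.9, 4.4))
  ours <- friedman_test(grid)
  ref <- stats::friedman.test(t(grid))
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  # and with a hand-ranked 3x2 oracle: ranks block1 (1,2,3), block2 (2,1,3)
  small <- rbind(x = c(1, 5), y = c(2, 4), z = c(9, 9.5))
  exp_stat <- 12 / (2 * 3 * 4) * sum((c(3, 3, 6) - 2 * 4 / 2)^2)
  expect_equal(friedman_test(small)$statistic, exp_stat)
})

test_that("Nemenyi critical difference matches the published q table", {
  # q_0.05 for k = 3 from the studentized-range table is 2.343
  nm <- nemenyi_posthoc(c(a = 1, b = 2, c = 3), n = 10)
  expect_equal(nm$q_alpha, 2.343, tolerance = 1e-3)
  expect_equal(nm$cd, 2.343 * sqrt(3 * 4 / 60), tolerance = 1e-3)
  # equal mean ranks: nothing significant
  nm2 <- nemenyi_posthoc(c(a = 2, b = 2, c = 2), n = 10)
  expect_false(any(nm2$significant))
  # a rank gap far beyond CD is significant
  nm3 <- nemenyi_posthoc(c(a = 1, b = 1.2, c = 9), n = 30)
  expect_true(nm3$significant["a", "c"])
  expect_false(nm3$significant["a", "b"])
})

test_that("Bonferroni-Dunn compares methods against a control", {
  mr <- c(fast = 1, mid = 2, ctrl = 3)
  out <- bonferroni_dunn_posthoc(mr, "ctrl", n = 30)
  expect_false(out$significant[out$method == "ctrl"])
  # rank gap 2 at n = 30, k = 3: z = 2 / sqrt(12/180) = 7.75
  expect_equal(out$z[out$method == "fast"], -2 / sqrt(12 / 180),
               tolerance = 1e-12)
  expect_true(out$significant[out$method == "fast"])
  # identical mean ranks: nothing significant
  out2 <- bonferroni_dunn_posthoc(c(a = 2, b = 2, ctrl = 2), "ctrl", n = 10)
  expect_false(any(out2$significant))
  expect_error(bonferroni_dunn_posthoc(mr, "nope", n = 10), "control")
})

test_that("Jonckheere-Terpstra counts cross-pairs and enumerates exactly", {
  expect_equal(jonckheere_terpstra(list(c(1, 2), c(3, 4)),
                                   n_perm = 200)$statistic, 4)
  expect_equal(jonckheere_terpstra(list(c(3, 4), c(1, 2)),
                                   n_perm = 200)$statistic, 0)
  # ties count one half
  expect_equal(jonckheere_terpstra(list(c(1, 2), c(2, 3)),
                                   n_perm = 200)$statistic, 3.5)

  # permutation p converges to the exhaustive relabelling oracle
  groups <- list(c(1, 2), c(3, 4))
  exact <- jt_exact_p(groups)           # 1/6
  expect_equal(exact, 1 / 6)
  jt <- jonckheere_terpstra(groups, n_perm = 6000, seed = 7)
  expect_equal(jt$p_value, exact, tolerance = 0.035)

  # seeded permutation is reproducible
  a <- jonckheere_terpstra(list(1:3, 2:5, 4:7), n_perm = 500, seed = 3)
  b <- jonckheere_terpstra(list(1:3, 2:5, 4:7), n_perm = 500, seed = 3)
  expect_identical(a, b)

  # normal approximation agrees in direction on a clear trend
  jn <- jonckheere_terpstra(list(1:4, 5:8, 9:12), method = "normal")
  expect_lt(jn$p_value, 0.01)
  expect_warning(jonckheere_terpstra(groups, n_perm = 50), "coarse")
  expect_error(jonckheere_terpstra(list(1:3)), "2 ordered groups")
})

test_that("consistency ratio is the CV and scale-invariant", {
  expect_equal(consistency_ratio(c(1, 1, 1)), 0)
  expect_equal(consistency_ratio(c(2, 4)), sqrt(2) / 3, tolerance = 1e-6)
  expect_equal(consistency_ratio(c(2, 4)), 0.4714, tolerance = 1e-4)
  v <- c(0.2, 0.5, 0.9)
  expect_equal(consistency_ratio(v * 3.7), consistency_ratio(v),
               tolerance = 1e-12)
  expect_warning(r <- consistency_ratio(c(-1, 1)), "undefined")
  expect_true(is.na(r))
})

test_that("clinical ranking weights accuracy .4, consistency .5, efficiency .1", {
  acc <- c(t1 = 1, t2 = 2, t3 = 3)
  cons <- c(t1 = 2, t2 = 1, t3 = 3)
  eff <- c(t1 = 3, t2 = 2, t3 = 1)
  out <- clinical_rank(acc, cons, eff)
  expect_equal(out$weighted[out$team == "t1"], 0.4 + 1.0 + 0.3)
  # t2's weighted value 1.5 beats t1's 1.7: consistency dominates
  expect_equal(out$final_rank[out$team == "t2"], 1)
  expect_equal(out$final_rank[out$team == "t1"], 2)

  # rank 1 on all three: weighted value 1 and first place
  solo <- clinical_rank(c(a = 1, b = 2), c(a = 1, b = 2), c(a = 1, b = 2))
  expect_equal(solo$weighted[solo$team == "a"], 1)
  expect_equal(solo$final_rank[solo$team == "a"], 1)

  # identical triples tie
  tie <- clinical_rank(c(a = 1, b = 1), c(a = 2, b = 2), c(a = 3, b = 3))
  expect_equal(tie$final_rank, c(1.5, 1.5))

  # ordering is invariant to a common constant shift in the inputs
  shifted <- clinical_rank(acc + 5, cons + 5, eff + 5)
  expect_equal(shifted$team, out$team)

  expect_error(clinical_rank(acc, cons[1:2], eff), "same team set")
})

test_that("missing efficiency ranks are imputed as worst + 1", {
  expect_equal(impute_missing_ranks(c(a = 1, b = NA, c = 3)),
               c(a = 1, b = 4, c = 3))
  expect_error(impute_missing_ranks(c(a = NA_real_)), "all ranks missing")
})
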