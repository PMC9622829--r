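test_that("geometric fit is the reciprocal of the mean length", {
  expect_equal(fit_geometric(rep(1L, 10))$p_hat, 1)
  expect_equal(fit_geometric(c(2, 3, 2, 2, 3))$p_hat, 1 / 2.4)
  expect_error(fit_geometric(integer(0)), "no lengths")
  expect_error(fit_geometric(c(1, 0)), ">= 1")

  # parameter recovery on simulated geometric data
  set.seed(5)
  lens <- stats::rgeom(5000, 0.5) + 1
  expect_lt(abs(fit_geometric(lens)$p_hat - 0.5), 0.02)
})

test_that("strata split the sequence list into near-equal blocks", {
  ids <- rep(c("A", "B"), 150)   # 300 sequences, but test odd n too
  h297 <- toy_hunt(rep(c("A", "B"), length.out = 297))
  st <- sequence_strata(h297, 4)
  expect_equal(as.integer(table(st)), c(75L, 74L, 74L, 74L))
  expect_true(all(diff(st) >= 0))

  set.seed(3)
  for (case in 1:20) {
    n <- sample(10:200, 1)
    K <- sample(2:6, 1)
    st <- sequence_strata(toy_hunt(rep(c("A", "B"), length.out = n)), K)
    sizes <- as.integer(table(factor(st, levels = 1:K)))
    expect_lte(max(sizes) - min(sizes), 1L)
    expect_equal(sum(sizes), n)
  }
})

test_that("dash-count strata hold near-equal numbers of dashes", {
  set.seed(9)
  ids <- random_ids(300, 5)
  h <- toy_hunt(ids)
  st <- sequence_strata(h, 4, unit = "dashes")
  seqs <- dash_sequences(h)
  per <- as.numeric(rowsum(seqs$length, st))
  expect_true(all(diff(st) >= 0))
  expect_equal(sum(per), nrow(h$events))
  # blocks within one maximal sequence length of the ideal quarter
  expect_lt(max(abs(per - nrow(h$events) / 4)), max(seqs$length) + 1)
})

test_that("trend test matches the textbook Cochran-Armitage formula", {
  # identical proportions in every stratum: statistic ~ 0
  h <- toy_hunt(rep(c("A", "A", "B", "B"), 50))  # all lengths 2, p = 0.5
  tt <- termination_trend_test(h, 4)
  expect_lt(unname(tt$statistic), 1e-9)

  # degenerate case: every dash terminates (all bouts length 1)
  tt1 <- termination_trend_test(toy_hunt(rep(c("A", "B"), 100)), 4)
  expect_equal(unname(tt1$statistic), 0)
  expect_equal(tt1$p.value, 1)

  set.seed(17)
  for (case in 1:25) {
    K <- sample(3:5, 1)
    trials <- sample(50:150, K, replace = TRUE)
    events <- mapply(function(n, p) stats::rbinom(1, n, p), trials,
                     stats::runif(K, 0.2, 0.8))
    events <- pmax(events, 1L)
    got <- stats::prop.trend.test(events, trials, score = seq_len(K))
    expect_equal(unname(got$statistic),
                 ca_trend_oracle(events, trials), tolerance = 1e-10)
  }
})

test_that("trend test detects a planted rise in termination probability", {
  s <- generate_hunt(hunt_config(
    group_sizes = c(5, 5), arrival_times_s = c(0, 800),
    termination_p = c(0.25, 0.4, 0.55, 0.7), duration_s = 2500,
    mean_dash_interval_s = 3, seed = 12))
  tt <- termination_trend_test(s$hunt, 4)
  expect_equal(tt$parameter[["df"]], 1)
  expect_lt(tt$p.value, 0.01)
  strat_tab <- attr(tt, "strata_table")
  expect_true(all(diff(strat_tab$proportion) > -0.2))  # broadly rising
})

test_that("the variance permutation test handles degenerate data", {
  # all lengths equal: variance 0, p = 1
  h <- toy_hunt(rep(c("A", "B", "C"), 10))
  vt <- sequence_length_test(h, K = 2, replicates = 50, seed = 1)
  expect_equal(vt$statistic, 0)
  expect_equal(vt$p_value, 1)
  expect_equal(vt$n_individuals_used, 3L)

  expect_error(sequence_length_test(toy_hunt(c("A", "B")), K = 1,
                                    replicates = 10),
               "fewer than 2 individuals")
})

test_that("permutation stays within strata (stratum-constant lengths)", {
  # lengths constant within each stratum but different across strata:
  # any within-stratum permutation leaves the data unchanged, so the
  # null distribution is degenerate at the observed statistic and p = 1
  ids <- c(rep(c("A", "B"), 10), rep(c("A", "C"), 10))
  lens <- rep(c(2L, 5L), each = 20)   # stratum 1 all 2s, stratum 2 all 5s
  h <- toy_hunt(rep(ids, lens))
  vt <- sequence_length_test(h, K = 2, replicates = 100, seed = 4)
  expect_gt(vt$statistic, 0)
  expect_equal(vt$p_value, 1)
  expect_equal(vt$null_mean, vt$statistic)
})

test_that("planted individual differences in bout length are detected", {
  # two types: p = 0.3 vs p = 0.7 -> mean lengths 3.3 vs 1.4
  set.seed(33)
  n_each <- 30
  ids <- rep(rep(c("S1", "S2", "F1", "F2"), each = 1), n_each)
  p_of <- c(S1 = 0.3, S2 = 0.3, F1 = 0.7, F2 = 0.7)
  lens <- stats::rgeom(length(ids), p_of[ids]) + 1L
  h <- toy_hunt(rep(ids, lens))
  vt <- sequence_length_test(h, K = 4, min_sequences = 5,
                             replicates = 499, seed = 2)
  expect_lt(vt$p_value, 0.01)
})
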