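test_that("tallies count sequences, dashes and captures per individual", {
  h <- hunt(1:6, c("A", "A", "B", "A", "B", "B"),
            c(1, 0, 1, 0, 0, 1))
  tal <- tally_individuals(h)
  a <- tal[tal$individual == "A", ]
  b <- tal[tal$individual == "B", ]
  expect_equal(a$n_sequences, 2L); expect_equal(a$n_dashes, 3L)
  expect_equal(a$n_captures, 1L)
  expect_equal(b$n_sequences, 2L); expect_equal(b$n_dashes, 3L)
  expect_equal(b$n_captures, 2L)
  expect_equal(sum(tal$n_captures), sum(h$events$capture))
  expect_equal(b$capture_efficiency, 2 / 3)

  # no captures -> efficiency 0
  h0 <- toy_hunt(c("A", "B"))
  expect_equal(tally_individuals(h0)$capture_efficiency, c(0, 0))
})

test_that("capture-share curves rank attackers and accumulate shares", {
  tal <- data.frame(individual = c("a", "b", "c", "d"),
                    n_sequences = c(10, 5, 3, 2),
                    n_dashes = c(20, 10, 6, 4),
                    n_captures = c(5, 3, 1, 1))
  sc <- share_curve(tal)
  expect_equal(sc$top_share, 80)
  expect_equal(sc$points$pct_captures[nrow(sc$points)], 100)
  expect_true(all(diff(sc$points$pct_captures) >= 0))

  # equal captures for all: the curve lies on the diagonal
  tal_eq <- transform(tal, n_captures = 2)
  sc_eq <- share_curve(tal_eq)
  expect_equal(sc_eq$points$pct_captures, sc_eq$points$pct_individuals)

  # one individual holds everything
  tal_one <- transform(tal, n_captures = c(7, 0, 0, 0))
  expect_equal(share_curve(tal_one)$top_share, 100)

  expect_error(share_curve(transform(tal, n_captures = 0)),
               "no captures")
})

test_that("uniformity test reproduces the hand-computed chi-squared", {
  u <- uniformity_test(c(5, 5, 5, 5))
  expect_equal(unname(u$statistic), 0)
  expect_equal(u$p.value, 1)
  expect_equal(unname(u$parameter), 3)

  u2 <- uniformity_test(c(10, 2))
  expect_equal(unname(u2$statistic), 16 / 6 + 16 / 6, tolerance = 1e-12)

  expect_false(attr(uniformity_test(c(20, 30, 25)), "low_expected"))
  expect_true(attr(uniformity_test(c(3, 1)), "low_expected"))
  expect_error(uniformity_test(c(0, 0)), "zero total")
})

test_that("rank correlation agrees with an independent rank computation", {
  expect_equal(rank_correlation(1:5, c(2, 4, 6, 7, 9))$rho, 1)
  expect_equal(rank_correlation(1:5, 5:1)$rho, -1)
  expect_false(rank_correlation(rep(3, 4), 1:4)$defined)

  set.seed(71)
  for (case in 1:30) {
    x <- sample(1:50, 9, replace = TRUE)
    y <- x + sample(-10:10, 9, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    rc <- rank_correlation(x, y)
    expect_equal(rc$rho, stats::cor(rank(x), rank(y)),
                 tolerance = 1e-12)
  }
})

test_that("capture-efficiency test matches the exact 2x2 computation", {
  tal <- data.frame(individual = c("a", "b"),
                    n_sequences = c(5, 5),
                    n_dashes = c(30, 25),
                    n_captures = c(12, 3))
  res <- capture_efficiency_test(tal, replicates = 20000, seed = 8)
  exact <- stats::fisher.test(res$table)$p.value
  expect_lt(abs(res$p_value - exact), 0.02)
  expect_false(res$degenerate)

  # identical rows: no evidence of differences
  tal_eq <- data.frame(individual = c("a", "b"),
                       n_sequences = c(5, 5),
                       n_dashes = c(20, 20), n_captures = c(4, 4))
  expect_gt(capture_efficiency_test(tal_eq, 2000, 1)$p_value, 0.5)

  # degenerate margin (no captures anywhere): p = 1, flagged
  tal0 <- transform(tal_eq, n_captures = 0)
  r0 <- capture_efficiency_test(tal0, 100, 1)
  expect_true(r0$degenerate)
  expect_equal(r0$p_value, 1)

  expect_error(
    capture_efficiency_test(data.frame(individual = "a",
                                       n_sequences = 1, n_dashes = 5,
                                       n_captures = 1)),
    "at least 2 individuals")
})

test_that("capture-rate series bins captures and fits a linear trend", {
  # constant counts: slope 0, no trend
  t_caps <- unlist(lapply(0:9, function(b) b * 60 + c(10, 30)))
  h <- hunt(t_caps, rep(c("A", "B"), 10), rep(TRUE, 20),
            duration_s = 600)
  cr <- capture_rate_series(h)
  expect_equal(cr$slope, 0)
  expect_equal(cr$F, 0)
  expect_equal(cr$mean, 2)

  # perfectly linear counts: slope 1, R^2 = 1
  times <- unlist(lapply(1:5, function(b) (b - 1) * 60 + seq_len(b)))
  h2 <- hunt(times, rep("A", length(times)), rep(TRUE, length(times)),
             duration_s = 300)
  cr2 <- capture_rate_series(h2)
  expect_equal(cr2$slope, 1, tolerance = 1e-10)
  expect_equal(cr2$r_squared, 1, tolerance = 1e-10)
  expect_equal(cr2$df, c(1L, 3L))

  # partial trailing bin is reported with its coverage
  h3 <- hunt(c(10, 70, 130), c("A", "B", "A"), c(TRUE, TRUE, FALSE),
             duration_s = 150)
  cr3 <- capture_rate_series(h3)
  expect_equal(nrow(cr3$series), 3L)
  expect_equal(cr3$series$coverage_s, c(60, 60, 30))

  expect_error(capture_rate_series(toy_hunt("A")), "2 bins")
})
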