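# alternating 12-dash toy hunt: A,B present from the start, C joins at
# dash 6 (epoch split 6 / 6)
two_epoch_toy <- function() {
  toy_hunt(c("A", "B", "A", "B", "A", "B", "C", "A", "C", "B", "C", "A"))
}
two_epoch_groups <- function() {
  fake_groups(list(c("A", "B"), "C"), epoch_start_seq = c(0L, 6L))
}

test_that("presence runs from the subgroup's first attack to hunt end", {
  h <- two_epoch_toy()
  sched <- presence_schedule(h, two_epoch_groups())
  expect_equal(sched$epoch_start_dash, c(0L, 6L))
  expect_equal(sched$n_epochs, 2L)
  ind <- sched$individuals
  expect_equal(ind$arrival_dash[ind$individual == "C"], 6L)
  expect_equal(ind$arrival_dash[ind$individual == "A"], 0L)

  # single group: everyone present from dash 0
  h1 <- toy_hunt(c("A", "B", "A"))
  s1 <- presence_schedule(h1, fake_groups(list(c("A", "B")), 0L))
  expect_true(all(s1$individuals$arrival_dash == 0L))

  expect_error(presence_schedule(h, fake_groups(list(c("A", "B")), 0L)),
               "missing from group assignment")
})

test_that("individuals never attack before their subgroup is present", {
  for (seed in 1:10) {
    s <- generate_hunt(hunt_config(group_sizes = c(4, 4),
                                   arrival_times_s = c(0, 400),
                                   termination_p = 0.4,
                                   duration_s = 900, seed = seed))
    sched <- presence_schedule(s$hunt, truth_groups(s))
    seqs <- dash_sequences(s$hunt)
    first_dash <- vapply(split(seqs$start_index, seqs$individual), min,
                         0L)
    ind <- sched$individuals
    expect_true(all(first_dash[ind$individual] >= ind$arrival_dash))
  }
})

test_that("equal-access expectations split dashes among those present", {
  # 10 dashes, 2 individuals present throughout: 5 each
  h <- toy_hunt(rep(c("A", "B"), 5))
  e <- expected_dashes(h, presence_schedule(
    h, fake_groups(list(c("A", "B")), 0L)))
  expect_equal(e$expected, c(5, 5))

  # 12 dashes, 6 before / 6 after C joins A,B: 3+2, 3+2, 0+2
  h2 <- two_epoch_toy()
  e2 <- expected_dashes(h2, presence_schedule(h2, two_epoch_groups()))
  get <- function(id) sum(e2$expected[e2$individual == id])
  expect_equal(get("A"), 5)
  expect_equal(get("B"), 5)
  expect_equal(get("C"), 2)
  obs <- function(id) sum(e2$observed[e2$individual == id])
  expect_equal(obs("A"), 5L)
  expect_equal(obs("B"), 4L)
  expect_equal(obs("C"), 3L)

  # conservation: expectations sum to the observed number of dashes
  expect_equal(sum(e2$expected), nrow(h2$events))
  expect_equal(sum(e2$observed), nrow(h2$events))
})

test_that("simulated access bands match the closed-form binomial null", {
  # 2 individuals, 100 dashes: per-individual count is Binomial(100, 1/2)
  h <- toy_hunt(rep(c("A", "B"), 50))
  sched <- presence_schedule(h, fake_groups(list(c("A", "B")), 0L))
  sim <- simulate_access_null(h, sched, replicates = 1e5, seed = 9)
  expect_true(all(abs(sim$lo - stats::qbinom(0.025, 100, 0.5)) <= 1))
  expect_true(all(abs(sim$hi - stats::qbinom(0.975, 100, 0.5)) <= 1))

  # every replicate conserves the number of dashes
  draws <- attr(sim, "draws")[[1L]]
  expect_true(all(colSums(draws) == 100L))

  # single individual: observed = expected = both bounds
  h1 <- toy_hunt(rep("A", 8))
  s1 <- simulate_access_null(
    h1, presence_schedule(h1, fake_groups(list("A"), 0L)),
    replicates = 500, seed = 2)
  expect_equal(s1$lo, 8)
  expect_equal(s1$hi, 8)
  expect_equal(s1$observed, 8L)
  expect_equal(s1$expected, 8)
})

test_that("simulation is deterministic given the seed", {
  h <- two_epoch_toy()
  g <- two_epoch_groups()
  a <- newly_arrived_access(h, g, replicates = 2000, seed = 5)
  b <- newly_arrived_access(h, g, replicates = 2000, seed = 5)
  expect_identical(a, b)
})

test_that("first subgroup matches its expectation as a necessity", {
  for (seed in 1:5) {
    s <- generate_hunt(hunt_config(group_sizes = c(4, 4),
                                   arrival_times_s = c(0, 500),
                                   termination_p = 0.4,
                                   duration_s = 1000, seed = seed))
    acc <- newly_arrived_access(s$hunt, truth_groups(s),
                                replicates = 500, seed = seed)
    expect_equal(acc$observed_mean[1L], acc$expected_mean[1L])
    expect_false(acc$outside[1L])
  }
})

test_that("a planted high-motivation subgroup exceeds its access band", {
  s <- generate_hunt(hunt_config(
    group_sizes = c(8, 5), arrival_times_s = c(0, 1200),
    attack_weights = c(1, 3), termination_p = 0.42,
    duration_s = 2400, mean_dash_interval_s = 3.5,
    arrival_boost = 1, seed = 404))
  acc <- newly_arrived_access(s$hunt, truth_groups(s),
                              replicates = 5000, seed = 1)
  expect_gt(acc$observed_mean[2L], acc$hi[2L])
})
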