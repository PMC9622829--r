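# Small builders and independent brute-force oracles used across tests.

# hunt from an identity vector; unit-spaced times unless given
toy_hunt <- function(ids, captures = rep(FALSE, length(ids)),
                     times = seq_along(ids), ...) {
  hunt(times, ids, captures, ...)
}

# random event log over k individuals (uses the caller's RNG state)
random_ids <- function(n, k = 4) {
  sample(LETTERS[seq_len(k)], n, replace = TRUE)
}

# brute-force run-length encoding of an identity vector
rle_oracle <- function(ids) {
  runs <- list()
  start <- 1L
  for (j in seq_along(ids)[-1L]) {
    if (ids[j] != ids[j - 1L]) {
      runs[[length(runs) + 1L]] <- c(start, j - 1L)
      start <- j
    }
  }
  runs[[length(runs) + 1L]] <- c(start, length(ids))
  data.frame(individual = vapply(runs, function(r) ids[r[1L]], ""),
             length = vapply(runs, function(r) r[2L] - r[1L] + 1L, 0L))
}

# brute-force ABA triple enumeration
brute_aba <- function(order) {
  n <- length(order)
  cnt <- 0L
  if (n < 3L) return(cnt)
  for (j in 1:(n - 2L))
    if (order[j] == order[j + 2L] && order[j] != order[j + 1L])
      cnt <- cnt + 1L
  cnt
}

# textbook Cochran-Armitage trend chi-square for proportions
# (independent of stats::prop.trend.test)
ca_trend_oracle <- function(events, trials, scores = seq_along(events)) {
  p_bar <- sum(events) / sum(trials)
  num <- sum(trials * (events / trials - p_bar) * scores)
  den <- p_bar * (1 - p_bar) *
    (sum(trials * scores^2) - sum(trials * scores)^2 / sum(trials))
  num^2 / den
}

# hand-constructed gap-statistics object with given normalized gaps r
fake_gaps <- function(r) {
  m <- length(r) + 1L
  d <- r * seq_along(r)
  gaps <- data.frame(i = seq_along(r),
                     individual = paste0("m", 2:m),
                     d = d, r = r, stringsAsFactors = FALSE)
  attr(gaps, "appearance") <- data.frame(
    individual = paste0("m", 1:m), rank = 1:m,
    first_sequence_index = cumsum(c(0, d + 1)),
    stringsAsFactors = FALSE)
  gaps
}

# hand-constructed group assignment
fake_groups <- function(member_lists, epoch_start_seq, h = NA_real_) {
  structure(list(
    h = h, groups = member_lists,
    membership = data.frame(
      individual = unlist(member_lists),
      group = rep(seq_along(member_lists), lengths(member_lists)),
      stringsAsFactors = FALSE),
    epoch_start_seq = epoch_start_seq),
    class = "group_assignment")
}
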