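#' Fit a geometric distribution to dash-sequence lengths
#'
#' Sequence lengths that follow a geometric distribution on {1, 2, ...}
#' indicate that the length of an attack bout is governed by a single
#' per-dash probability `p` of the bout ending (by interruption or prey
#' evasion), rather than by individual plans. The maximum-likelihood
#' estimate is `p_hat = 1 / mean(length)`.
#'
#' @param lengths integer vector of sequence lengths, all `>= 1`.
#' @return An object of class `"geometric_fit"`: list with `p_hat`,
#'   `n_sequences` and `log_likelihood`.
#' @export
fit_geometric <- function(lengths) {
  if (length(lengths) == 0L) stop("no lengths supplied", call. = FALSE)
  if (any(lengths < 1)) stop("lengths must be >= 1", call. = FALSE)
  p <- 1 / mean(lengths)
  ll <- sum(stats::dgeom(lengths - 1, p, log = TRUE))
  structure(list(p_hat = p, n_sequences = length(lengths),
                 log_likelihood = ll),
            class = "geometric_fit")
}

#' @export
print.geometric_fit <- function(x, ...) {
  cat(sprintf(
    "Geometric fit: p_hat = %.4f (n = %d, logLik = %.2f)\n",
    x$p_hat, x$n_sequences, x$log_likelihood))
  invisible(x)
}

#' Partition ordered dash sequences into K strata
#'
#' Splits the ordered dash-sequence list of a hunt into `K` consecutive
#' blocks. With `unit = "sequences"` (default) the blocks contain
#' near-equal numbers of sequences (sizes differing by at most 1, larger
#' blocks first); with `unit = "dashes"` block boundaries are placed so
#' each block holds a near-equal number of dashes.
#'
#' @param x a [hunt()] object.
#' @param K number of strata (`>= 1`).
#' @param unit `"sequences"` or `"dashes"`.
#' @return Integer vector of stratum labels (1..K), one per dash sequence.
#' @export
sequence_strata <- function(x, K, unit = c("sequences", "dashes")) {
  unit <- match.arg(unit)
  stopifnot(K >= 1)
  seqs <- dash_sequences(x)
  n <- nrow(seqs)
  if (unit == "sequences") {
    sizes <- rep(n %/% K, K)
    extra <- n %% K
    if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    rep.int(seq_len(K), sizes)
  } else {
    total <- sum(seqs$length)
    cuts <- total * seq_len(K) / K
    pmin(findInterval(cumsum(seqs$length), cuts,
                      left.open = TRUE) + 1L, K)
  }
}

#' Trend test on the sequence-termination probability over the hunt
#'
#' Every dash sequence ends exactly once, so within a block of the hunt the
#' proportion of dashes that terminate a sequence estimates the geometric
#' termination probability `p` in that block. A rising `p` over the hunt
#' (shorter bouts later) is detected by the chi-squared test for trend in
#' proportions (Cochran-Armitage, scores 1..K, df = 1) applied to
#' (terminating dashes / total dashes) across the `K` strata.
#'
#' @inheritParams sequence_strata
#' @return An `htest` object from [stats::prop.trend.test()], with the
#'   per-stratum successes/trials attached as attribute `"strata_table"`.
#' @export
termination_trend_test <- function(x, K = 4,
                                   unit = c("sequences", "dashes")) {
  unit <- match.arg(unit)
  stopifnot(K >= 2)
  seqs <- dash_sequences(x)
  strat <- sequence_strata(x, K, unit)
  events <- as.integer(rowsum(rep(1L, nrow(seqs)), strat)[, 1L])
  trials <- as.integer(rowsum(seqs$length, strat)[, 1L])
  if (length(trials) < K || any(trials == 0))
    stop("a stratum contains no dashes", call. = FALSE)
  if (sum(events) == sum(trials)) {
    # every dash terminates a sequence (all bouts length 1): the pooled
    # proportion is 1 and the trend statistic is identically 0
    res <- structure(list(statistic = c(`Chi-squared` = 0),
                          parameter = c(df = 1), p.value = 1,
                          method = "Chi-squared Test for Trend in Proportions",
                          data.name = "termination proportions"),
                     class = "htest")
  } else {
    # a perfectly flat proportion profile triggers a spurious
    # perfect-fit warning inside the trend test's internal regression
    res <- suppressWarnings(
      stats::prop.trend.test(events, trials, score = seq_len(K)))
  }
  attr(res, "strata_table") <- data.frame(stratum = seq_len(K),
                                          terminations = events,
                                          dashes = trials,
                                          proportion = events / trials)
  res
}

#' Stratified permutation test for individual mean sequence lengths
#'
#' Tests whether individuals differ in their mean dash-sequence length,
#' beyond what the shared (possibly time-varying) termination probability
#' explains. The test statistic is the sample variance (n-1 denominator)
#' of the per-individual mean lengths among individuals with at least
#' `min_sequences` sequences. The null distribution permutes the observed
#' length values among sequence slots, keeping each individual's number of
#' sequences fixed and permuting only within the `K` strata of the hunt
#' (so a time trend in lengths cannot masquerade as individual
#' differences). The p-value is the add-one-corrected fraction of permuted
#' statistics at least as large as observed.
#'
#' @inheritParams sequence_strata
#' @param min_sequences minimum number of sequences for an individual to
#'   enter the statistic (default 5).
#' @param replicates number of permutations (default `1e4`).
#' @param seed integer seed.
#' @return An object of class `"resampling_test"`: list with `statistic`
#'   (observed variance), `p_value`, `null_mean`, `replicates`, `seed`,
#'   `n_individuals_used`, `min_sequences`, and `means` (per-individual
#'   mean lengths used).
#' @export
sequence_length_test <- function(x, K = 4, min_sequences = 5,
                                 replicates = 1e4, seed = 1L,
                                 unit = c("sequences", "dashes")) {
  unit <- match.arg(unit)
  seqs <- dash_sequences(x)
  strat <- sequence_strata(x, K, unit)
  ids <- factor(seqs$individual)
  n_per <- table(ids)
  use <- names(n_per)[n_per >= min_sequences]
  if (length(use) < 2L)
    stop("fewer than 2 individuals with >= ", min_sequences,
         " dash sequences", call. = FALSE)
  use_rows <- seqs$individual %in% use
  id_use <- factor(seqs$individual[use_rows], levels = use)
  n_use <- as.numeric(table(id_use))

  stat_of <- function(lengths) {
    mm <- rowsum(lengths[use_rows], id_use)[, 1L] / n_use
    stats::var(mm)
  }
  observed <- stat_of(seqs$length)

  set.seed(seed)
  slots <- split(seq_len(nrow(seqs)), strat)
  null_stats <- vapply(seq_len(replicates), function(b) {
    perm <- seqs$length
    for (s in slots) perm[s] <- perm[s][sample.int(length(s))]
    stat_of(perm)
  }, numeric(1L))
  p <- (sum(null_stats >= observed) + 1) / (replicates + 1)
  means <- rowsum(seqs$length[use_rows], id_use)[, 1L] / n_use
  structure(list(statistic = observed, p_value = p,
                 null_mean = mean(null_stats),
                 replicates = replicates, seed = seed,
                 n_individuals_used = length(use),
                 min_sequences = min_sequences,
                 means = stats::setNames(means, use)),
            class = "resampling_test")
}

#' @export
print.resampling_test <- function(x, ...) {
  cat(sprintf("Permutation test: observed = %.4g, null mean = %.4g\n",
              x$statistic, x$null_mean))
  cat(sprintf("p = %.4g (%d replicates, seed %d)\n",
              x$p_value, x$replicates, x$seed))
  invisible(x)
}
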