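#' Identity order of dash sequences
#'
#' The succession of attacker identities, one entry per dash sequence. By
#' maximality of dash sequences, no two adjacent entries are equal.
#'
#' @param x a [hunt()] object.
#' @return Character vector of individual identities in attack order.
#' @export
identity_order <- function(x) {
  dash_sequences(x)$individual
}

#' Count ABA turn-interruption patterns
#'
#' An ABA pattern is an individual's dash sequence, a single dash sequence
#' by any other individual, then the first individual again - the
#' signature of a predator returning immediately after being interrupted.
#' All (overlapping) triples of consecutive slots are counted.
#'
#' @param order character vector of attacker identities (one per dash
#'   sequence), length `>= 3`.
#' @return Integer count of ABA triples.
#' @export
#' @examples
#' count_aba(c("A", "B", "A", "C", "A"))  # 2
count_aba <- function(order) {
  n <- length(order)
  if (n < 3L) return(0L)
  a <- order[1:(n - 2L)]
  b <- order[2:(n - 1L)]
  c_ <- order[3:n]
  sum(a == c_ & a != b)
}

#' Return-gap histogram of the attack order
#'
#' For each individual and each consecutive pair of its dash sequences,
#' the gap is the number of intervening dash sequences by other
#' individuals (at least 1 by adjacency). Gaps of `cap` or more are pooled
#' into the terminal bin, mirroring a "cap and above" histogram bar.
#'
#' In an observed order adjacent slots never share an identity, so all
#' gaps are `>= 1` and bin 0 is empty; permuted null orders may contain
#' adjacent equal labels (a merged-sequence artefact that is deliberately
#' not re-merged), and those gaps land in bin 0 so that the total count is
#' conserved in every replicate.
#'
#' @param order character vector of attacker identities.
#' @param cap pooling threshold for the terminal bin (default 40).
#' @return Integer vector of counts, names `0 .. cap` where bin `cap`
#'   holds all gaps `>= cap`. Total count equals the sum over individuals
#'   of (number of sequences - 1).
#' @export
gap_histogram <- function(order, cap = 40) {
  pos <- split(seq_along(order), order)
  gaps <- unlist(lapply(pos, function(p) diff(p) - 1L), use.names = FALSE)
  gaps <- pmin(gaps, cap)
  stats::setNames(tabulate(gaps + 1L, nbins = cap + 1L), 0:cap)
}

# epoch label (1-based) of each dash-sequence slot
sequence_epochs <- function(groups, n_slots) {
  findInterval(seq_len(n_slots) - 1L, groups$epoch_start_seq)
}

#' Permute the attack order within arrival epochs
#'
#' Null model for the attack order: within each epoch (the block of
#' dash-sequence slots between consecutive subgroup arrivals), the
#' identity labels are shuffled uniformly. Each individual keeps its
#' number of sequences per epoch, and no individual can appear before its
#' subgroup's arrival. Permuted orders may contain adjacent equal labels;
#' they are retained as-is so the number of slots is preserved.
#'
#' @param order character vector of attacker identities.
#' @param groups a `"group_assignment"` whose epoch starts partition the
#'   order.
#' @param seed optional integer seed (`NULL`: use the current RNG stream).
#' @return A permuted identity order of the same length.
#' @export
permute_within_epochs <- function(order, groups, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ep <- sequence_epochs(groups, length(order))
  out <- order
  for (s in split(seq_along(order), ep))
    out[s] <- out[s][sample.int(length(s))]
  out
}

#' Permutation test for excess ABA patterns
#'
#' Compares the observed ABA count with its distribution under uniform
#' shuffling of the attack order within arrival epochs (the null of no
#' motivated immediate return). The p-value is the add-one-corrected
#' fraction of permuted orders with at least as many ABA patterns.
#'
#' @inheritParams permute_within_epochs
#' @param replicates number of permutations (default `1e4`).
#' @param seed integer seed.
#' @return A `"resampling_test"`: `statistic` (observed ABA count),
#'   `null_mean`, `null_quantiles` (2.5/97.5, nearest-rank), `p_value`,
#'   `replicates`, `seed`.
#' @export
aba_test <- function(order, groups, replicates = 1e4, seed = 1L) {
  observed <- count_aba(order)
  set.seed(seed)
  ep <- sequence_epochs(groups, length(order))
  slots <- split(seq_along(order), ep)
  null_counts <- vapply(seq_len(replicates), function(b) {
    perm <- order
    for (s in slots) perm[s] <- perm[s][sample.int(length(s))]
    count_aba(perm)
  }, numeric(1L))
  p <- (sum(null_counts >= observed) + 1) / (replicates + 1)
  structure(list(statistic = observed,
                 null_mean = mean(null_counts),
                 null_quantiles = stats::quantile(null_counts,
                                                  c(0.025, 0.975),
                                                  type = 1L, names = FALSE),
                 p_value = p, replicates = replicates, seed = seed),
            class = "resampling_test")
}

#' Null bands for the return-gap histogram
#'
#' Computes, per gap bin, the mean and 2.5th/97.5th nearest-rank
#' percentiles of the bin count under the within-epoch permutation null,
#' for comparison with the observed return-gap histogram (an excess in bin
#' 1 is the ABA signal).
#'
#' @inheritParams aba_test
#' @param cap pooling threshold for the terminal bin (default 40).
#' @return A data.frame with one row per bin: `gap`, `observed`,
#'   `expected` (null mean), `lo`, `hi`. Attributes `replicates`, `seed`.
#' @export
gap_null_bands <- function(order, groups, cap = 40, replicates = 1e4,
                           seed = 1L) {
  observed <- gap_histogram(order, cap)
  set.seed(seed)
  ep <- sequence_epochs(groups, length(order))
  slots <- split(seq_along(order), ep)
  null_mat <- matrix(0L, nrow = cap + 1L, ncol = replicates)
  for (b in seq_len(replicates)) {
    perm <- order
    for (s in slots) perm[s] <- perm[s][sample.int(length(s))]
    null_mat[, b] <- gap_histogram(perm, cap)
  }
  q <- apply(null_mat, 1L, stats::quantile, probs = c(0.025, 0.975),
             type = 1L, names = FALSE)
  out <- data.frame(gap = 0:cap,
                    observed = as.integer(observed),
                    expected = rowMeans(null_mat),
                    lo = q[1L, ], hi = q[2L, ])
  attr(out, "replicates") <- replicates
  attr(out, "seed") <- seed
  out
}
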