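#' Per-individual attack and capture tallies
#'
#' @param x a [hunt()] object.
#' @param groups optional `"group_assignment"`; if supplied, each
#'   individual's subgroup is included.
#' @return A data.frame with one row per individual: `individual`,
#'   `group` (NA if `groups` is NULL), `n_sequences`, `n_dashes`,
#'   `n_captures` and `capture_efficiency` (captures / dashes).
#' @export
tally_individuals <- function(x, groups = NULL) {
  stopifnot(inherits(x, "hunt"))
  seqs <- dash_sequences(x)
  ids <- unique(x$events$individual)
  f <- factor(seqs$individual, levels = ids)
  out <- data.frame(
    individual = ids,
    group = NA_integer_,
    n_sequences = as.integer(table(f)),
    n_dashes = as.integer(rowsum(seqs$length, f)[, 1L]),
    n_captures = as.integer(rowsum(seqs$captures, f)[, 1L]),
    stringsAsFactors = FALSE)
  if (!is.null(groups)) {
    stopifnot(inherits(groups, "group_assignment"))
    out$group <- groups$membership$group[
      match(out$individual, groups$membership$individual)]
  }
  out$capture_efficiency <- out$n_captures / out$n_dashes
  out
}

#' Cumulative capture-share curve
#'
#' Sorts individuals in descending order of their number of dash sequences
#' (ties broken by descending captures, then identity) and accumulates the
#' percentage of all captures against the percentage of individuals - a
#' Lorenz-style curve of how unevenly the prey is divided. `top_share` is
#' the percentage of captures taken by the `ceiling(fraction * N)` most
#' frequently attacking individuals.
#'
#' @param tallies output of [tally_individuals()] (optionally restricted
#'   to one subgroup).
#' @param fraction fraction of top attackers for the headline share
#'   (default 0.5).
#' @return A list of class `"share_curve"`: `points` (data.frame
#'   `pct_individuals`, `pct_captures`, including the origin), `top_share`
#'   (percent), `n_individuals`, `n_captures`.
#' @export
share_curve <- function(tallies, fraction = 0.5) {
  total <- sum(tallies$n_captures)
  if (total == 0) stop("no captures", call. = FALSE)
  ord <- order(-tallies$n_sequences, -tallies$n_captures,
               tallies$individual)
  t2 <- tallies[ord, , drop = FALSE]
  n <- nrow(t2)
  pts <- data.frame(
    pct_individuals = c(0, 100 * seq_len(n) / n),
    pct_captures = c(0, 100 * cumsum(t2$n_captures) / total))
  k <- ceiling(fraction * n)
  structure(list(points = pts,
                 top_share = pts$pct_captures[k + 1L],
                 n_individuals = n, n_captures = total),
            class = "share_curve")
}

#' @export
print.share_curve <- function(x, ...) {
  cat(sprintf(
    "Capture-share curve over %d individuals, %d captures\n",
    x$n_individuals, x$n_captures))
  cat(sprintf("top 50%% most frequent attackers hold %.1f%% of captures\n",
              x$top_share))
  invisible(x)
}

#' Chi-squared test for uniform attack counts
#'
#' Tests whether dash-sequence counts within a subgroup are compatible
#' with every member attacking equally often (Pearson chi-squared against
#' equal expected counts, df = N - 1).
#'
#' @param counts integer vector of per-individual dash-sequence counts
#'   (length `>= 2`, positive total).
#' @return The `htest` from [stats::chisq.test()], with attribute
#'   `"low_expected"` set `TRUE` when any expected count is below 5 (the
#'   usual small-sample caveat).
#' @export
uniformity_test <- function(counts) {
  stopifnot(length(counts) >= 2L)
  if (sum(counts) == 0) stop("zero total count", call. = FALSE)
  res <- suppressWarnings(stats::chisq.test(counts))
  attr(res, "low_expected") <- any(res$expected < 5)
  res
}

#' Spearman correlation of attack frequency and captures
#'
#' @param n_sequences,n_captures per-individual counts within a subgroup
#'   (length `>= 3`).
#' @return A list with `rho`, `p_value` (two-sided, tie-corrected
#'   asymptotic) and `defined` (`FALSE` when either input is constant, in
#'   which case `rho` is `NA`).
#' @export
rank_correlation <- function(n_sequences, n_captures) {
  stopifnot(length(n_sequences) == length(n_captures),
            length(n_sequences) >= 3L)
  if (length(unique(n_sequences)) < 2L || length(unique(n_captures)) < 2L)
    return(list(rho = NA_real_, p_value = NA_real_, defined = FALSE))
  ct <- suppressWarnings(
    stats::cor.test(n_sequences, n_captures, method = "spearman",
                    exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, defined = TRUE)
}

# log probability of a 2 x N table under fixed margins (Fisher)
log_table_prob <- function(tab) {
  sum(lgamma(rowSums(tab) + 1)) + sum(lgamma(colSums(tab) + 1)) -
    lgamma(sum(tab) + 1) - sum(lgamma(tab + 1))
}

#' Monte-Carlo exact test for capture-efficiency differences
#'
#' Tests whether individuals differ in capture efficiency
#' (captures / dashes) via a Monte-Carlo Fisher exact test on the 2 x N
#' table of (captures, non-capture dashes) per individual: random tables
#' with the observed margins are drawn (Patefield's algorithm via
#' [stats::r2dtable()]) and the p-value is the add-one-corrected
#' proportion of tables whose probability under the fixed-margin null is
#' no larger than the observed table's.
#'
#' @param tallies output of [tally_individuals()], `>= 2` individuals with
#'   `>= 1` dash.
#' @param replicates Monte-Carlo replicates (default `1e4`).
#' @param seed integer seed.
#' @return A `"resampling_test"` with `statistic` (observed table log
#'   probability), `p_value`, `replicates`, `seed`, `degenerate` (`TRUE`,
#'   with `p_value = 1`, when a margin is zero so only one table is
#'   possible) and the observed `table`.
#' @export
capture_efficiency_test <- function(tallies, replicates = 1e4, seed = 1L) {
  use <- tallies$n_dashes >= 1L
  if (sum(use) < 2L)
    stop("need at least 2 individuals with at least 1 dash",
         call. = FALSE)
  tab <- rbind(captures = tallies$n_captures[use],
               misses = tallies$n_dashes[use] - tallies$n_captures[use])
  colnames(tab) <- tallies$individual[use]
  degenerate <- any(rowSums(tab) == 0)
  if (degenerate) {
    return(structure(list(statistic = log_table_prob(tab), p_value = 1,
                          replicates = 0L, seed = seed,
                          degenerate = TRUE, table = tab),
                     class = "resampling_test"))
  }
  set.seed(seed)
  obs_lp <- log_table_prob(tab)
  sims <- stats::r2dtable(replicates, rowSums(tab), colSums(tab))
  sim_lp <- vapply(sims, log_table_prob, numeric(1L))
  p <- (sum(sim_lp <= obs_lp + 1e-7) + 1) / (replicates + 1)
  structure(list(statistic = obs_lp, p_value = p,
                 replicates = replicates, seed = seed,
                 degenerate = FALSE, table = tab),
            class = "resampling_test")
}

#' Capture-rate time series and linear trend
#'
#' Bins the hunt into fixed-width time bins, counts captures per bin, and
#' regresses the per-bin count on the bin index (ordinary least squares) to
#' assess whether the capture rate drifted over the hunt. All bins,
#' including a final partial bin, enter the regression with their raw
#' counts; the reported series additionally carries the coverage of each
#' bin so a rate per full minute can be displayed.
#'
#' @param x a [hunt()] object.
#' @param bin_s bin width in seconds (default 60).
#' @return A list of class `"capture_rate"`: `series` (data.frame `bin`,
#'   `start_s`, `coverage_s`, `captures`), `mean`, `se`, `range` (per-bin
#'   capture counts), `slope`, `F`, `r_squared`, `df` (c(1, n_bins - 2))
#'   and `p_value`. A perfectly flat series reports slope 0, F 0, p 1.
#' @export
capture_rate_series <- function(x, bin_s = 60) {
  stopifnot(inherits(x, "hunt"))
  n_bins <- ceiling(x$duration_s / bin_s)
  if (n_bins < 2L) stop("hunt shorter than 2 bins", call. = FALSE)
  bin <- pmin(floor(x$events$time_s / bin_s) + 1L, n_bins)
  caps <- tabulate(bin[x$events$capture], nbins = n_bins)
  coverage <- rep(bin_s, n_bins)
  coverage[n_bins] <- x$duration_s - (n_bins - 1L) * bin_s
  if (stats::var(caps) == 0) {        # flat series: no trend by definition
    slope <- 0; Fstat <- 0; pval <- 1; r2 <- 0
  } else {
    fit <- stats::lm(caps ~ seq_len(n_bins))
    an <- suppressWarnings(stats::anova(fit))  # exact fits warn
    slope <- unname(stats::coef(fit)[2L])
    Fstat <- an$`F value`[1L]
    pval <- an$`Pr(>F)`[1L]
    r2 <- suppressWarnings(summary(fit))$r.squared
  }
  structure(list(
    series = data.frame(bin = seq_len(n_bins),
                        start_s = (seq_len(n_bins) - 1L) * bin_s,
                        coverage_s = coverage,
                        captures = caps),
    mean = mean(caps), se = stats::sd(caps) / sqrt(n_bins),
    range = range(caps),
    slope = slope,
    F = Fstat,
    r_squared = r2,
    df = c(1L, n_bins - 2L),
    p_value = pval),
    class = "capture_rate")
}

#' @export
print.capture_rate <- function(x, ...) {
  cat(sprintf(
    "Captures per bin: mean %.2f +/- %.2f (range %d-%d)\n",
    x$mean, x$se, x$range[1L], x$range[2L]))
  cat(sprintf("linear trend: F(%d,%d) = %.2f, p = %.3g\n",
              x$df[1L], x$df[2L], x$F, x$p_value))
  invisible(x)
}
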