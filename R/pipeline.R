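#' Run the full prey-division analysis on a hunt
#'
#' Orchestrates the whole pipeline: summary counts, arrival-subgroup
#' segmentation over a grid of thresholds, equal-access null model per
#' segmentation, dash-sequence-length statistics (geometric fit,
#' termination-probability trend, stratified permutation test), ABA and
#' return-gap attack-order tests per segmentation, prey-division
#' statistics (tallies, capture-share curves, per-subgroup uniformity and
#' rank-correlation tests, capture-efficiency exact test, capture-rate
#' trend), and optionally morphometrics. Every stochastic component
#' records its seed and replicate count, so a report can be reproduced
#' exactly from its own provenance.
#'
#' @param x a [hunt()] object (or path to an event-log file readable by
#'   [read_hunt()]).
#' @param h_grid thresholds for subgroup segmentation.
#' @param strata number of strata for the sequence-length analyses.
#' @param min_sequences qualification threshold for the sequence-length
#'   permutation test.
#' @param access_replicates replicates for the equal-access percentile
#'   bands (study-scale default `1e6`).
#' @param perm_replicates replicates for the permutation and Monte-Carlo
#'   tests (study-scale default `1e4`).
#' @param seed integer seed governing all randomness.
#' @param fast logical; `TRUE` divides both replicate counts by 100 for
#'   quick exploratory runs.
#' @param morphometrics optional measurement table (see
#'   [read_morphometrics()]) or path to one; `NULL` skips the section.
#' @param out_dir optional directory: if given, writes `report.json`,
#'   `tallies.tsv` and `gap_histogram_h<h>.tsv` there.
#' @return A list of class `"analysis_report"` with sections `summary`,
#'   `subgroups`, `access`, `sequence_lengths`, `attack_order`,
#'   `prey_division`, `morphometrics` (may be `NULL`) and `provenance`.
#' @export
run_full_analysis <- function(x, h_grid = c(1.0, 1.5, 2.0, 3.0),
                              strata = 4, min_sequences = 5,
                              access_replicates = 1e6,
                              perm_replicates = 1e4,
                              seed = 1L, fast = FALSE,
                              morphometrics = NULL, out_dir = NULL) {
  if (is.character(x)) x <- read_hunt(x)
  stopifnot(inherits(x, "hunt"))
  if (fast) {
    access_replicates <- max(100, access_replicates / 100)
    perm_replicates <- max(100, perm_replicates / 100)
  }

  summary <- hunt_summary(x)
  profile <- group_count_profile(x, h_grid)
  gaps <- gap_statistics(x)
  # one segmentation per distinct group count on the grid
  keep_h <- h_grid[!duplicated(profile$n_groups)]
  segmentations <- lapply(keep_h, function(h) segment_groups(gaps, h))
  names(segmentations) <- paste0("h", keep_h)

  access <- lapply(segmentations, function(g)
    newly_arrived_access(x, g, replicates = access_replicates,
                         seed = seed))

  seq_lengths <- list(
    fit = fit_geometric(dash_sequences(x)$length),
    trend = termination_trend_test(x, K = strata),
    variance_test = sequence_length_test(
      x, K = strata, min_sequences = min_sequences,
      replicates = perm_replicates, seed = seed))

  order <- identity_order(x)
  attack <- lapply(segmentations, function(g) list(
    aba = aba_test(order, g, replicates = perm_replicates, seed = seed),
    gap_bands = gap_null_bands(order, g, replicates = perm_replicates,
                               seed = seed)))

  g_finest <- segmentations[[which.max(vapply(segmentations, function(g)
    length(g$groups), integer(1L)))]]
  tal <- tally_individuals(x, g_finest)
  per_group <- lapply(split(tal, tal$group), function(tg) {
    list(n = nrow(tg),
         share = if (sum(tg$n_captures) > 0 && nrow(tg) >= 2L)
           share_curve(tg) else NULL,
         uniformity = if (nrow(tg) >= 2L)
           uniformity_test(tg$n_sequences) else NULL,
         spearman = if (nrow(tg) >= 3L)
           rank_correlation(tg$n_sequences, tg$n_captures) else NULL)
  })
  division <- list(
    tallies = tal,
    overall_share = share_curve(tal),
    per_group = per_group,
    efficiency = capture_efficiency_test(tal,
                                         replicates = perm_replicates,
                                         seed = seed),
    capture_rate = capture_rate_series(x))

  morph <- NULL
  if (!is.null(morphometrics)) {
    if (is.character(morphometrics))
      morphometrics <- read_morphometrics(morphometrics)
    morph <- aggregate_measurements(morphometrics)
  }

  report <- structure(list(
    summary = summary,
    subgroups = list(profile = profile, segmentations = segmentations),
    access = access,
    sequence_lengths = seq_lengths,
    attack_order = attack,
    prey_division = division,
    morphometrics = morph,
    provenance = list(seed = seed,
                      access_replicates = access_replicates,
                      perm_replicates = perm_replicates,
                      h_grid = h_grid, strata = strata,
                      min_sequences = min_sequences,
                      package_version =
                        as.character(utils::packageVersion("huntdiv")))),
    class = "analysis_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("== Hunt summary ==\n"); print(x$summary)
  cat("\n== Arrival subgroups ==\n"); print(x$subgroups$profile)
  cat("\n== Newly arrived subgroup access (finest segmentation) ==\n")
  finest <- which.max(vapply(x$subgroups$segmentations, function(g)
    length(g$groups), integer(1L)))
  print(x$access[[finest]], digits = 3)
  cat("\n== Dash-sequence lengths ==\n")
  print(x$sequence_lengths$fit)
  cat(sprintf("termination trend: chi-sq = %.2f, df = 1, p = %.3g\n",
              unname(x$sequence_lengths$trend$statistic),
              x$sequence_lengths$trend$p.value))
  print(x$sequence_lengths$variance_test)
  cat("\n== ABA patterns ==\n")
  for (nm in names(x$attack_order))
    cat(sprintf(
      "  %s: observed = %d, null mean = %.1f, p = %.3g\n", nm,
      x$attack_order[[nm]]$aba$statistic,
      x$attack_order[[nm]]$aba$null_mean,
      x$attack_order[[nm]]$aba$p_value))
  cat("\n== Prey division ==\n")
  print(x$prey_division$overall_share)
  cat(sprintf("capture-efficiency test: p = %.3g\n",
              x$prey_division$efficiency$p_value))
  print(x$prey_division$capture_rate)
  if (!is.null(x$morphometrics)) {
    cat("\n== Morphometrics ==\n"); print(x$morphometrics)
  }
  invisible(x)
}

# strip non-serialisable pieces and write the machine-readable report
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$prey_division$tallies,
                     file.path(out_dir, "tallies.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  for (nm in names(report$attack_order))
    utils::write.table(report$attack_order[[nm]]$gap_bands,
                       file.path(out_dir,
                                 paste0("gap_histogram_", nm, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  js <- list(
    summary = unclass(report$summary),
    group_profile = report$subgroups$profile,
    segmentations = lapply(report$subgroups$segmentations, function(g)
      list(h = g$h, groups = g$groups,
           epoch_start_seq = g$epoch_start_seq)),
    access = lapply(report$access, function(a)
      a[c("group", "n_members", "epoch_dashes", "observed_mean",
          "expected_mean", "lo", "hi", "outside")]),
    sequence_lengths = list(
      p_hat = report$sequence_lengths$fit$p_hat,
      trend_chisq = unname(report$sequence_lengths$trend$statistic),
      trend_p = report$sequence_lengths$trend$p.value,
      variance = report$sequence_lengths$variance_test$statistic,
      variance_p = report$sequence_lengths$variance_test$p_value),
    aba = lapply(report$attack_order, function(a)
      list(observed = a$aba$statistic, null_mean = a$aba$null_mean,
           p = a$aba$p_value)),
    prey_division = list(
      top_share = report$prey_division$overall_share$top_share,
      efficiency_p = report$prey_division$efficiency$p_value,
      capture_rate_mean = report$prey_division$capture_rate$mean,
      capture_rate_F = report$prey_division$capture_rate$F,
      capture_rate_p = report$prey_division$capture_rate$p_value),
    morphometrics = if (!is.null(report$morphometrics))
      report$morphometrics$cohort,
    provenance = report$provenance)
  jsonlite::write_json(js, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(out_dir)
}
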