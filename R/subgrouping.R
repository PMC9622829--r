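#' Appearance order of individuals
#'
#' Individuals are ranked by the dash sequence in which they first attack.
#' The appearance order is the raw material for arrival-subgroup
#' segmentation: predators that join the hunt together tend to make their
#' first attacks in quick succession.
#'
#' @param x a [hunt()] object.
#' @return A data.frame with one row per distinct individual, in appearance
#'   order: `individual`, `rank` (1-based) and `first_sequence_index`
#'   (0-based index into the dash-sequence list).
#' @export
appearance_order <- function(x) {
  stopifnot(inherits(x, "hunt"))
  seqs <- dash_sequences(x)
  first <- !duplicated(seqs$individual)
  data.frame(individual = seqs$individual[first],
             rank = seq_len(sum(first)),
             first_sequence_index = which(first) - 1L,
             stringsAsFactors = FALSE)
}

#' Normalized appearance-gap statistics
#'
#' For each pair of subsequently appearing individuals (the i-th and the
#' (i+1)-th to attack), `d_i` counts the dash sequences performed by any
#' already-present individual strictly between their two first-appearance
#' sequences. Because a newcomer facing `i` equally likely attackers waits
#' on average `i` sequences for its first turn, the gap is normalized as
#' `r_i = d_i / i`. Large `r_i` followed by small values marks the arrival
#' of a new subgroup.
#'
#' @param x a [hunt()] object with at least two individuals.
#' @return A data.frame with one row per consecutive appearance pair:
#'   `i` (rank of the earlier individual), `individual` (the later,
#'   (i+1)-th individual), `d` and `r = d / i`. The appearance-order table
#'   is attached as attribute `"appearance"`.
#' @export
gap_statistics <- function(x) {
  stopifnot(inherits(x, "hunt"))
  app <- appearance_order(x)
  m <- nrow(app)
  if (m < 2L) stop("need at least 2 individuals", call. = FALSE)
  fs <- app$first_sequence_index
  d <- fs[-1L] - fs[-m] - 1L       # sequences strictly between appearances
  i <- seq_len(m - 1L)
  out <- data.frame(i = i,
                    individual = app$individual[-1L],
                    d = d,
                    r = d / i,
                    stringsAsFactors = FALSE)
  attr(out, "appearance") <- app
  out
}

#' Segment the appearance order into arrival subgroups
#'
#' Scans the normalized gap statistics `r_i` for local maxima: the
#' (i+1)-th appearer founds a new subgroup when `r_i >= h` and
#' `r_{i+1} <= min(1, r_i)`. The first appearer founds subgroup 1; every
#' non-founder joins the subgroup current at its appearance. The last
#' appearer never founds a subgroup (a singleton would fall below the
#' minimum subgroup size of 2), so the scan for founders stops one short of
#' the final pair; a final pair arriving together can still form its own
#' subgroup.
#'
#' @param gaps output of [gap_statistics()].
#' @param h positive threshold on the normalized gap statistic.
#' @return An object of class `"group_assignment"`: a list with `h`,
#'   `groups` (ordered list of member-identity vectors), `membership`
#'   (data.frame `individual`, `group`, in appearance order) and
#'   `epoch_start_seq` (0-based dash-sequence index of each subgroup's
#'   first attack; strictly increasing).
#' @export
#' @examples
#' h <- hunt(1:10, c("A","B","A","B","A","B","C","D","C","D"),
#'           rep(FALSE, 10))
#' segment_groups(gap_statistics(h), h = 1)
segment_groups <- function(gaps, h) {
  stopifnot(is.numeric(h), length(h) == 1L, h > 0)
  app <- attr(gaps, "appearance")
  if (is.null(app))
    stop("gaps must come from gap_statistics()", call. = FALSE)
  m <- nrow(app)
  r <- gaps$r
  founds <- rep(FALSE, m)          # founds[k]: k-th appearer founds a group
  founds[1L] <- TRUE
  if (m >= 3L) {
    for (i in seq_len(m - 2L)) {   # candidate founder is appearer i + 1
      if (r[i] >= h && r[i + 1L] <= min(1, r[i]))
        founds[i + 1L] <- TRUE
    }
  }
  grp <- cumsum(founds)
  groups <- split(app$individual, grp)
  names(groups) <- NULL
  epoch_start_seq <- app$first_sequence_index[founds]
  structure(list(h = h,
                 groups = groups,
                 membership = data.frame(individual = app$individual,
                                         group = grp,
                                         stringsAsFactors = FALSE),
                 epoch_start_seq = epoch_start_seq),
            class = "group_assignment")
}

#' @export
print.group_assignment <- function(x, ...) {
  cat("Arrival subgroups at threshold h = ", format(x$h), ": ",
      length(x$groups), " group(s)\n", sep = "")
  for (k in seq_along(x$groups))
    cat(sprintf("  group %d (from sequence %d): %s\n", k,
                x$epoch_start_seq[k],
                paste(x$groups[[k]], collapse = ", ")))
  invisible(x)
}

#' Number of arrival subgroups across a grid of thresholds
#'
#' The segmentation is a heuristic whose outcome depends on the threshold
#' `h`; rather than picking a single value, the profile of group counts
#' over a grid of thresholds is carried forward. Counts are non-increasing
#' in `h`.
#'
#' @param x a [hunt()] object.
#' @param h_grid ascending vector of positive thresholds.
#' @return A data.frame with columns `h` and `n_groups`.
#' @export
group_count_profile <- function(x, h_grid) {
  stopifnot(length(h_grid) >= 1L, all(h_grid > 0),
            !is.unsorted(h_grid))
  gaps <- gap_statistics(x)
  n <- vapply(h_grid,
              function(h) length(segment_groups(gaps, h)$groups),
              integer(1L))
  data.frame(h = h_grid, n_groups = n)
}

#' Serialize a group assignment to JSON
#'
#' @param x a `"group_assignment"`.
#' @param path optional output file.
#' @return JSON string (invisibly, if written to `path`).
#' @export
groups_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "group_assignment"))
  js <- jsonlite::toJSON(list(h = x$h, groups = x$groups,
                              epoch_start_seq = x$epoch_start_seq),
                         auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
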