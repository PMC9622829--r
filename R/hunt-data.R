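#' Construct a hunt object from attack events
#'
#' A hunt is the core container of the package: an ordered log of attack
#' events ("dashes") by individually identified predators at a single prey
#' school, together with the recording duration and free-form metadata.
#' Each dash carries the time (seconds from the start of the recording),
#' the identity of the attacker, and whether the dash captured a prey item.
#'
#' Events are stored sorted by time; a stable sort is used so that events
#' with identical timestamps (e.g. scored on the same video frame) keep
#' their input order.
#'
#' @param time_s numeric vector of dash times in seconds, all `>= 0`.
#' @param individual character vector of individual identity labels
#'   (non-empty strings), one per dash.
#' @param capture logical (or 0/1) vector: did the dash capture a prey item?
#' @param duration_s recording length in seconds; defaults to the last dash
#'   time.
#' @param metadata optional named list (year, prey species, ...).
#'
#' @return An object of class `"hunt"`: a list with elements `events`
#'   (data.frame with columns `time_s`, `individual`, `capture`),
#'   `duration_s` and `metadata`.
#' @seealso [read_hunt()], [dash_sequences()], [hunt_summary()]
#' @export
#' @examples
#' h <- hunt(time_s = c(1, 2, 3), individual = c("A", "A", "B"),
#'           capture = c(FALSE, TRUE, FALSE))
#' hunt_summary(h)
hunt <- function(time_s, individual, capture, duration_s = NULL,
                 metadata = list()) {
  if (length(time_s) == 0L) stop("no events", call. = FALSE)
  if (length(individual) != length(time_s) ||
      length(capture) != length(time_s))
    stop("time_s, individual and capture must have equal length",
         call. = FALSE)
  time_s <- as.numeric(time_s)
  if (anyNA(time_s) || any(time_s < 0))
    stop("dash times must be non-negative and non-missing", call. = FALSE)
  individual <- as.character(individual)
  if (anyNA(individual) || any(!nzchar(individual)))
    stop("individual identities must be non-empty strings", call. = FALSE)
  capture <- as.logical(capture)
  if (anyNA(capture))
    stop("capture flags must be TRUE/FALSE (or 0/1)", call. = FALSE)

  ord <- order(time_s)                      # stable: ties keep input order
  events <- data.frame(time_s = time_s[ord],
                       individual = individual[ord],
                       capture = capture[ord],
                       stringsAsFactors = FALSE)
  if (is.null(duration_s)) duration_s <- max(events$time_s)
  duration_s <- as.numeric(duration_s)
  if (duration_s < max(events$time_s))
    stop("duration_s is shorter than the last event", call. = FALSE)
  structure(list(events = events, duration_s = duration_s,
                 metadata = metadata),
            class = "hunt")
}

#' @export
print.hunt <- function(x, ...) {
  s <- hunt_summary(x)
  cat("Hunt event log: ", s$n_dashes, " dashes in ", s$n_sequences,
      " dash sequences by ", s$n_individuals, " individuals\n", sep = "")
  cat("  captures: ", s$n_captures,
      ";  duration: ", format(x$duration_s), " s\n", sep = "")
  if (length(x$metadata))
    cat("  metadata: ",
        paste(names(x$metadata), unlist(x$metadata),
              sep = " = ", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read a hunt event log from a delimited text file
#'
#' The expected format is a header-named delimited table with columns
#' `time_s` (seconds from recording start), `individual` (identity label)
#' and `capture` (0/1 or TRUE/FALSE). Extra columns are ignored. Rows are
#' sorted by time on reading; ties keep file order.
#'
#' @param path path to the event-log file.
#' @param sep field separator (default comma).
#' @param duration_s,metadata passed to [hunt()].
#' @return A [hunt()] object.
#' @export
read_hunt <- function(path, sep = ",", duration_s = NULL, metadata = list()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE,
                           colClasses = NA, comment.char = "")
  need <- c("time_s", "individual", "capture")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("event log is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(tab) == 0L) stop("no events", call. = FALSE)
  tm <- suppressWarnings(as.numeric(tab$time_s))
  bad <- which(is.na(tm))
  if (length(bad))
    stop("unparseable time_s at data line ", bad[1L], call. = FALSE)
  cap_raw <- tab$capture
  cap <- if (is.logical(cap_raw)) cap_raw else {
    cv <- suppressWarnings(as.numeric(cap_raw))
    ifelse(is.na(cv), NA, cv != 0)
  }
  bad <- which(is.na(cap))
  if (length(bad))
    stop("unparseable capture flag at data line ", bad[1L], call. = FALSE)
  hunt(tm, tab$individual, cap, duration_s = duration_s, metadata = metadata)
}

#' Write a hunt event log to a delimited text file
#'
#' Inverse of [read_hunt()]: writes the event table with header
#' `time_s,individual,capture`, capture encoded 0/1.
#'
#' @param x a [hunt()] object.
#' @param path output path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_hunt <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "hunt"))
  out <- x$events
  out$capture <- as.integer(out$capture)
  utils::write.table(out, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Derive dash sequences from a hunt
#'
#' A dash sequence is a maximal run of consecutive dashes by the same
#' individual: it ends when a different individual initiates an attack.
#' Sequences are defined purely by interruption (adjacency of same-identity
#' dashes), not by elapsed time; optionally a maximum inter-dash gap
#' `max_gap_s` can additionally split runs, but by default no time rule is
#' applied.
#'
#' @param x a [hunt()] object.
#' @param max_gap_s optional: split a run when consecutive dashes of the
#'   same individual are more than this many seconds apart. Default `Inf`
#'   (off).
#' @return A data.frame with one row per dash sequence, in order:
#'   `individual`, `start_index`, `end_index` (0-based, inclusive, into the
#'   event list), `length` (number of dashes) and `captures` (number of
#'   capture dashes within).
#' @export
#' @examples
#' h <- hunt(1:4, c("A", "A", "B", "A"), c(0, 1, 0, 0))
#' dash_sequences(h)
dash_sequences <- function(x, max_gap_s = Inf) {
  stopifnot(inherits(x, "hunt"))
  ev <- x$events
  n <- nrow(ev)
  new_run <- c(TRUE, ev$individual[-1L] != ev$individual[-n])
  if (is.finite(max_gap_s) && n > 1L)
    new_run <- new_run | c(FALSE, diff(ev$time_s) > max_gap_s)
  run_id <- cumsum(new_run)
  start <- which(new_run)
  end <- c(start[-1L] - 1L, n)
  data.frame(individual = ev$individual[start],
             start_index = start - 1L,
             end_index = end - 1L,
             length = end - start + 1L,
             captures = as.integer(rowsum(as.integer(ev$capture),
                                          run_id)[, 1L]),
             stringsAsFactors = FALSE)
}

#' Truncate a hunt at a time cutoff
#'
#' Keeps all events with `time_s <= cutoff_s` and re-derives everything
#' downstream from the retained events; a dash sequence straddling the
#' cutoff is cut at the last retained dash. Used for analysing only the
#' part of a recording where capture scoring retained full precision.
#'
#' @param x a [hunt()] object.
#' @param cutoff_s cutoff in seconds (`> 0`).
#' @return A new [hunt()] object with `duration_s = min(duration, cutoff)`.
#' @export
truncate_hunt <- function(x, cutoff_s) {
  stopifnot(inherits(x, "hunt"), is.numeric(cutoff_s), cutoff_s > 0)
  keep <- x$events$time_s <= cutoff_s
  if (!any(keep)) stop("empty truncation", call. = FALSE)
  ev <- x$events[keep, , drop = FALSE]
  hunt(ev$time_s, ev$individual, ev$capture,
       duration_s = min(x$duration_s, cutoff_s),
       metadata = x$metadata)
}

#' Summary counts for a hunt
#'
#' @param x a [hunt()] object.
#' @return An object of class `"hunt_summary"`: a list with
#'   `n_individuals`, `n_dashes`, `n_sequences`, `n_captures`,
#'   `mean_sequence_length`, `se_sequence_length` (sample SD of sequence
#'   lengths over `sqrt(n_sequences)`; 0 with `se_defined = FALSE` when
#'   there is a single sequence), and `max_sequence_length`.
#' @export
hunt_summary <- function(x) {
  stopifnot(inherits(x, "hunt"))
  seqs <- dash_sequences(x)
  n_seq <- nrow(seqs)
  se_defined <- n_seq > 1L
  structure(list(
    n_individuals = length(unique(x$events$individual)),
    n_dashes = nrow(x$events),
    n_sequences = n_seq,
    n_captures = sum(x$events$capture),
    mean_sequence_length = mean(seqs$length),
    se_sequence_length = if (se_defined)
      stats::sd(seqs$length) / sqrt(n_seq) else 0,
    se_defined = se_defined,
    max_sequence_length = max(seqs$length)
  ), class = "hunt_summary")
}

#' @export
print.hunt_summary <- function(x, ...) {
  cat(sprintf(
    "%d individuals, %d dashes, %d dash sequences, %d captures\n",
    x$n_individuals, x$n_dashes, x$n_sequences, x$n_captures))
  cat(sprintf("mean sequence length %.1f +/- %.1f (max %d)\n",
              x$mean_sequence_length, x$se_sequence_length,
              x$max_sequence_length))
  invisible(x)
}

#' Export a hunt summary as JSON
#'
#' @param x a `"hunt_summary"` (or a [hunt()], which is summarised first).
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly, if written to `path`).
#' @export
summary_json <- function(x, path = NULL) {
  if (inherits(x, "hunt")) x <- hunt_summary(x)
  stopifnot(inherits(x, "hunt_summary"))
  js <- jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
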