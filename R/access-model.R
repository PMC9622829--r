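#' Presence schedule implied by arrival subgroups
#'
#' Individuals are deemed present at the prey school from the moment a
#' member of their arrival subgroup is first observed attacking, and are
#' assumed to stay until the end of the hunt. Presence is expressed in
#' dash-index coordinates (0-based): the hunt is divided into epochs, one
#' per subgroup, each starting at the first dash of the subgroup's first
#' dash sequence.
#'
#' @param x a [hunt()] object.
#' @param groups a `"group_assignment"` from [segment_groups()] covering
#'   every individual in the hunt.
#' @return An object of class `"presence_schedule"`: list with
#'   `individuals` (data.frame `individual`, `group`, `arrival_dash`),
#'   `epoch_start_dash` (0-based first dash of each epoch),
#'   `n_dashes` and `n_epochs`.
#' @export
presence_schedule <- function(x, groups) {
  stopifnot(inherits(x, "hunt"), inherits(groups, "group_assignment"))
  seqs <- dash_sequences(x)
  ids <- unique(x$events$individual)
  missing_ids <- setdiff(ids, groups$membership$individual)
  if (length(missing_ids))
    stop("individual(s) missing from group assignment: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  epoch_start_dash <- seqs$start_index[groups$epoch_start_seq + 1L]
  memb <- groups$membership
  memb$arrival_dash <- epoch_start_dash[memb$group]
  structure(list(individuals = memb,
                 epoch_start_dash = epoch_start_dash,
                 n_dashes = nrow(x$events),
                 n_epochs = length(epoch_start_dash)),
            class = "presence_schedule")
}

# dash-index (0-based) range of each epoch: [start_k, start_{k+1} - 1]
epoch_dash_counts <- function(schedule) {
  st <- schedule$epoch_start_dash
  diff(c(st, schedule$n_dashes))
}

# epoch of each dash (1-based epochs, dashes 0-based)
dash_epoch <- function(schedule) {
  findInterval(seq_len(schedule$n_dashes) - 1L,
               schedule$epoch_start_dash)
}

#' Expected dash counts under the equal-access null
#'
#' The null model of prey access: each observed dash is an opportunity, and
#' every individual present at that moment has the same chance of taking
#' it. Each dash therefore credits `1 / n_present` expected dashes to every
#' present individual; within an epoch the expectation per present
#' individual is the number of dashes in the epoch divided by the number
#' present. Summed over individuals, expectations equal the observed number
#' of dashes exactly.
#'
#' @param x a [hunt()] object.
#' @param schedule a [presence_schedule()].
#' @return A data.frame with one row per individual and epoch in which it
#'   is present: `individual`, `group`, `epoch`, `observed` and `expected`
#'   dash counts.
#' @export
expected_dashes <- function(x, schedule) {
  stopifnot(inherits(x, "hunt"), inherits(schedule, "presence_schedule"))
  memb <- schedule$individuals
  G <- schedule$n_epochs
  n_e <- epoch_dash_counts(schedule)
  ep <- dash_epoch(schedule)
  out <- vector("list", G)
  for (k in seq_len(G)) {
    present <- memb[memb$group <= k, , drop = FALSE]
    in_epoch <- x$events$individual[ep == k]
    obs <- table(factor(in_epoch, levels = present$individual))
    out[[k]] <- data.frame(individual = present$individual,
                           group = present$group,
                           epoch = k,
                           observed = as.integer(obs),
                           expected = n_e[k] / nrow(present),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Monte-Carlo percentile bands for the equal-access null
#'
#' Simulates the equal-access null: in each replicate every dash is
#' assigned uniformly at random to one of the individuals present at that
#' dash (within an epoch, the per-individual counts are a symmetric
#' multinomial). Per-individual, per-epoch 2.5th and 97.5th percentiles
#' (nearest-rank) are reported alongside the observed and expected counts.
#'
#' @param x a [hunt()] object.
#' @param schedule a [presence_schedule()].
#' @param replicates number of null replicates (the study-scale default is
#'   `1e6`; smaller values are adequate for exploration).
#' @param seed integer seed; the simulation is deterministic given the
#'   seed.
#' @param probs lower/upper percentile probabilities.
#' @return The [expected_dashes()] data.frame with extra columns `lo`,
#'   `hi`, and attributes `replicates` and `seed`. The per-replicate draws
#'   for each epoch are attached as attribute `"draws"` (a list of
#'   present-by-replicate count matrices) for reuse by group-level
#'   summaries.
#' @export
simulate_access_null <- function(x, schedule, replicates = 1e6, seed = 1L,
                                 probs = c(0.025, 0.975)) {
  stopifnot(inherits(schedule, "presence_schedule"), replicates >= 1)
  exp_tab <- expected_dashes(x, schedule)
  set.seed(seed)
  memb <- schedule$individuals
  n_e <- epoch_dash_counts(schedule)
  G <- schedule$n_epochs
  draws <- vector("list", G)
  lo <- hi <- numeric(nrow(exp_tab))
  for (k in seq_len(G)) {
    m <- sum(memb$group <= k)
    dk <- stats::rmultinom(replicates, n_e[k], rep(1 / m, m))
    rownames(dk) <- memb$individual[memb$group <= k]
    draws[[k]] <- dk
    q <- apply(dk, 1L, stats::quantile, probs = probs, type = 1L,
               names = FALSE)
    rows <- which(exp_tab$epoch == k)
    lo[rows] <- q[1L, ]
    hi[rows] <- q[2L, ]
  }
  exp_tab$lo <- lo
  exp_tab$hi <- hi
  attr(exp_tab, "draws") <- draws
  attr(exp_tab, "replicates") <- replicates
  attr(exp_tab, "seed") <- seed
  exp_tab
}

#' Access of newly arrived subgroups relative to equal chance
#'
#' For each arrival subgroup, compares the observed mean number of dashes
#' per subgroup member during the subgroup's own epoch (from its arrival
#' until the arrival of the next subgroup) with the equal-access
#' expectation, plus Monte-Carlo percentile bands on the group mean. For
#' the first subgroup the match between observed and expected group means
#' is a statistical necessity, as its members are the only ones present.
#'
#' @inheritParams simulate_access_null
#' @param groups a `"group_assignment"`; the presence schedule is derived
#'   from it.
#' @return A data.frame with one row per subgroup: `group`, `n_members`,
#'   `epoch_dashes`, `observed_mean`, `expected_mean`, `lo`, `hi` (band on
#'   the group mean) and `outside` (observed mean outside the band).
#'   Attributes `per_individual` (the [simulate_access_null()] table),
#'   `replicates`, `seed`.
#' @export
newly_arrived_access <- function(x, groups, replicates = 1e6, seed = 1L,
                                 probs = c(0.025, 0.975)) {
  schedule <- presence_schedule(x, groups)
  per_ind <- simulate_access_null(x, schedule, replicates = replicates,
                                  seed = seed, probs = probs)
  draws <- attr(per_ind, "draws")
  memb <- schedule$individuals
  n_e <- epoch_dash_counts(schedule)
  G <- schedule$n_epochs
  out <- data.frame(group = seq_len(G),
                    n_members = as.integer(table(factor(memb$group,
                                                        levels = seq_len(G)))),
                    epoch_dashes = n_e,
                    observed_mean = NA_real_, expected_mean = NA_real_,
                    lo = NA_real_, hi = NA_real_)
  for (k in seq_len(G)) {
    own <- per_ind$epoch == k & per_ind$group == k
    out$observed_mean[k] <- mean(per_ind$observed[own])
    out$expected_mean[k] <- mean(per_ind$expected[own])
    rows <- rownames(draws[[k]]) %in% memb$individual[memb$group == k]
    gm <- colSums(draws[[k]][rows, , drop = FALSE]) / sum(rows)
    q <- stats::quantile(gm, probs = probs, type = 1L, names = FALSE)
    out$lo[k] <- q[1L]
    out$hi[k] <- q[2L]
  }
  out$outside <- out$observed_mean < out$lo | out$observed_mean > out$hi
  attr(out, "per_individual") <- local({
    p <- per_ind; attr(p, "draws") <- NULL; p
  })
  attr(out, "replicates") <- replicates
  attr(out, "seed") <- seed
  out
}
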