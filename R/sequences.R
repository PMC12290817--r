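#' Generate a constrained quasi-random walk over objects
#'
#' Presentation orders of the recurring objects are random walks on a
#' [community graph][build_modular_graph] with two constraints: immediate
#' repetitions (X -> X) and direct returns (X -> Y -> X) are not allowed. The
#' walk starts at a uniformly random node; each subsequent step is chosen
#' uniformly among the current node's neighbours excluding the previous node
#' (the second step excludes only the start, since no trigram exists yet).
#'
#' @param graph A [community_graph][build_modular_graph].
#' @param n_recurring Number of steps (trials) to generate, at least 3.
#' @param seed Integer seed; all randomness in the package flows through
#'   explicit seeds.
#' @return Integer vector of `n_recurring` object ids.
#' @examples
#' w <- generate_walk(build_modular_graph(), 180, seed = 1)
#' any(w[-1] == w[-length(w)])  # no immediate repetition
#' @export
generate_walk <- function(graph, n_recurring, seed) {
  stopifnot_graph(graph)
  n_recurring <- as.integer(n_recurring)
  if (n_recurring < 3L) stop("n_recurring must be >= 3", call. = FALSE)
  adj <- graph$adjacency
  nbrs <- lapply(seq_len(nrow(adj)), function(i) which(adj[i, ]))
  if (any(lengths(nbrs) < 2L)) {
    stop("graph has a node with fewer than 2 neighbours; walk would get stuck",
      call. = FALSE
    )
  }
  withr::with_seed(seed, {
    out <- integer(n_recurring)
    cur <- sample.int(nrow(adj), 1L)
    prev <- 0L
    out[1L] <- cur
    for (k in 2:n_recurring) {
      eligible <- nbrs[[cur]]
      eligible <- eligible[eligible != prev]
      nxt <- eligible[sample.int(length(eligible), 1L)]
      prev <- cur
      cur <- nxt
      out[k] <- cur
    }
    out
  })
}

# Balance cost of a candidate walk: squared deviation of per-object counts
# from the uniform target plus squared deviation of directed-edge usage
# counts from their mean.
walk_balance_cost <- function(walk, n_nodes = 15L) {
  counts <- tabulate(walk, nbins = n_nodes)
  target <- length(walk) / n_nodes
  edge_ids <- (walk[-length(walk)] - 1L) * n_nodes + walk[-1L]
  edge_counts <- tabulate(edge_ids, nbins = n_nodes^2)
  used <- edge_counts[edge_counts > 0L]
  sum((counts - target)^2) + sum((used - mean(used))^2)
}

#' Counterbalanced walk selection
#'
#' Generates `n_candidates` constrained walks and returns the one with the
#' smallest balance cost, post-selecting for counterbalanced appearance counts
#' of objects and object transitions (least-squares criterion over per-object
#' counts and directed-edge usage counts). Deterministic given `seed`.
#'
#' @inheritParams generate_walk
#' @param n_candidates Number of candidate walks to draw (default 200).
#' @return Integer vector of `n_recurring` object ids, with attribute
#'   `"balance_cost"`.
#' @export
counterbalance_select <- function(graph, n_candidates = 200L, n_recurring = 180L,
                                  seed = 1L) {
  if (n_candidates < 1L) stop("n_candidates must be >= 1", call. = FALSE)
  cand_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max, n_candidates))
  best <- NULL
  best_cost <- Inf
  for (s in cand_seeds) {
    w <- generate_walk(graph, n_recurring, seed = s)
    cost <- walk_balance_cost(w, length(graph$node_ids))
    if (cost < best_cost) {
      best <- w
      best_cost <- cost
    }
  }
  structure(best, balance_cost = best_cost)
}

#' Intersperse singular (non-recurring) objects into a walk
#'
#' A run presents the recurring-object walk with singular objects (each shown
#' exactly once in the whole experiment) inserted at uniformly random
#' positions; the relative order of recurring trials is preserved. Trial
#' onsets are `3 * trial_index` seconds (2.5 s presentation + 0.5 s
#' transition).
#'
#' @param walk Integer vector of recurring object ids (from
#'   [generate_walk()] or [counterbalance_select()]).
#' @param n_singular Number of singular trials to insert (default 20).
#' @param seed Integer seed.
#' @param run_id Run index stored in the output.
#' @param first_singular_id Id given to the first singular object; successive
#'   singulars count up from it. Callers generating several runs must pass
#'   non-overlapping ranges so singular ids stay globally unique.
#' @return A `trial_sequence` data frame with columns `run_id`,
#'   `trial_index` (0-based), `object_id`, `is_recurring`, `onset_s`.
#' @export
insert_singulars <- function(walk, n_singular = 20L, seed = 1L, run_id = 1L,
                             first_singular_id = 1001L) {
  n_singular <- as.integer(n_singular)
  if (n_singular < 0L) stop("n_singular must be >= 0", call. = FALSE)
  n_total <- length(walk) + n_singular
  if (n_singular > 0L) {
    pos <- withr::with_seed(seed, sort(sample.int(n_total, n_singular)))
  } else {
    pos <- integer(0)
  }
  object_id <- integer(n_total)
  is_recurring <- rep(TRUE, n_total)
  is_recurring[pos] <- FALSE
  object_id[is_recurring] <- walk
  object_id[pos] <- seq(first_singular_id, length.out = n_singular)
  out <- data.frame(
    run_id = as.integer(run_id),
    trial_index = 0:(n_total - 1L),
    object_id = object_id,
    is_recurring = is_recurring,
    onset_s = 3 * (0:(n_total - 1L))
  )
  class(out) <- c("trial_sequence", "data.frame")
  out
}

walk_from_sequence <- function(x) {
  if (is.data.frame(x)) x$object_id[x$is_recurring] else as.integer(x)
}

#' Summary statistics of presentation sequences
#'
#' Computes, over a set of walks or trial sequences: the repetition latency
#' (gap in walk steps between successive occurrences of the same recurring
#' object), the community-episode length (maximal run of consecutive
#' same-community objects) in trials and seconds (3 s per trial), and
#' per-object appearance counts. Both statistics are computed on the
#' recurring-object walk, with singular trials excluded.
#'
#' @param sequences A list of integer walks and/or `trial_sequence` data
#'   frames (a single walk or sequence is also accepted).
#' @param graph The [community_graph][build_modular_graph] providing community
#'   labels (counterfactual labels for the complete graph).
#' @return A list with `median_latency`, `sd_latency`, `mean_episode_trials`,
#'   `sd_episode_trials`, `mean_episode_s`, `n_latencies`, `n_episodes` and
#'   `object_counts` (matrix: sequences x 15).
#' @export
sequence_stats <- function(sequences, graph) {
  stopifnot_graph(graph)
  if (!is.list(sequences) || is.data.frame(sequences)) sequences <- list(sequences)
  walks <- lapply(sequences, walk_from_sequence)
  n_nodes <- length(graph$node_ids)
  latencies <- vector("list", length(walks))
  episodes <- vector("list", length(walks))
  counts <- matrix(0L, length(walks), n_nodes)
  for (s in seq_along(walks)) {
    w <- walks[[s]]
    counts[s, ] <- tabulate(w, nbins = n_nodes)
    pos_by_obj <- split(seq_along(w), w)
    latencies[[s]] <- unlist(lapply(pos_by_obj, function(p) diff(p)), use.names = FALSE)
    episodes[[s]] <- rle(graph$community[w])$lengths
  }
  lat <- unlist(latencies, use.names = FALSE)
  epi <- unlist(episodes, use.names = FALSE)
  if (length(lat) == 0L) {
    warning("no object recurs within any sequence; latency statistics undefined")
  }
  list(
    median_latency = if (length(lat)) stats::median(lat) else NA_real_,
    sd_latency = if (length(lat) > 1L) stats::sd(lat) else NA_real_,
    mean_episode_trials = mean(epi),
    sd_episode_trials = if (length(epi) > 1L) stats::sd(epi) else NA_real_,
    mean_episode_s = 3 * mean(epi),
    n_latencies = length(lat),
    n_episodes = length(epi),
    object_counts = counts
  )
}

#' Write or read a trial sequence table
#'
#' Trial sequences are serialized as TSV with columns `observer_id`, `run_id`,
#' `trial_index`, `object_id`, `is_recurring`, `onset_s`.
#'
#' @param sequences A `trial_sequence` data frame or a list of them (one per
#'   run).
#' @param path Output file.
#' @param observer_id Observer label stored in the first column.
#' @return `write_sequences()` returns `path` invisibly; `read_sequences()`
#'   returns a list of `trial_sequence` data frames, one per run.
#' @export
write_sequences <- function(sequences, path, observer_id = 1L) {
  if (is.data.frame(sequences)) sequences <- list(sequences)
  tab <- do.call(rbind, sequences)
  tab <- cbind(observer_id = observer_id, tab)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sequences
#' @export
read_sequences <- function(path) {
  tab <- utils::read.delim(path)
  lapply(split(tab, tab$run_id), function(d) {
    d$observer_id <- NULL
    rownames(d) <- NULL
    class(d) <- c("trial_sequence", "data.frame")
    d
  })
}
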