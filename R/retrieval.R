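#' Retrieval-stage parameters
#'
#' Stage 1 of verification is a stochastic retrieval race: two searches,
#' one from each stimulus term, traverse associations in descending
#' strength order (iterative deepening over path length) until a
#' connecting path is found or all paths up to the stopping length are
#' exhausted. Each edge traversal costs a gamma-distributed latency with
#' mean `edge_time_base + edge_time_scale / strength`, so stronger
#' associations are retrieved sooner both in order and in time.
#'
#' @param stopping_length Maximum chain depth searched (default 2).
#' @param edge_time_base Baseline per-edge retrieval time, ms.
#' @param edge_time_scale Strength-scaled per-edge component, ms.
#' @param edge_time_shape Gamma shape of the per-edge latency (larger =
#'   less variable).
#' @param exhaustion_overhead Extra time, ms, to conclude that no path
#'   exists once both searches are exhausted.
#' @param seed Optional integer seed recorded for bookkeeping; functions
#'   draw from R's global RNG stream.
#' @return A list of class `retrieval_params`.
#' @export
retrieval_params <- function(stopping_length = 2L,
                             edge_time_base = 60,
                             edge_time_scale = 260,
                             edge_time_shape = 4,
                             exhaustion_overhead = 300,
                             seed = NULL) {
  stopifnot(stopping_length >= 1L, edge_time_base > 0, edge_time_scale > 0,
            edge_time_shape > 0, exhaustion_overhead >= 0)
  structure(list(stopping_length = as.integer(stopping_length),
                 edge_time_base = edge_time_base,
                 edge_time_scale = edge_time_scale,
                 edge_time_shape = edge_time_shape,
                 exhaustion_overhead = exhaustion_overhead,
                 seed = seed),
            class = "retrieval_params")
}

#' Sample per-edge retrieval latencies
#'
#' Gamma draws with shape `edge_time_shape` and mean
#' `edge_time_base + edge_time_scale / strength`; the expected latency is
#' strictly decreasing in strength.
#'
#' @param strength Vector of strengths in (0, 1].
#' @param params A [retrieval_params()].
#' @return Positive latencies, ms, one per strength.
#' @export
sample_edge_latency <- function(strength, params = retrieval_params()) {
  if (any(strength <= 0 | strength > 1))
    stop("strength must lie in (0, 1]")
  mu <- params$edge_time_base + params$edge_time_scale / strength
  stats::rgamma(length(strength), shape = params$edge_time_shape,
                rate = params$edge_time_shape / mu)
}

# Deterministic exploration order of one search: iterative deepening by
# path length; within a frontier, edges in descending-strength order
# (the adjacency index order). Paths never revisit a word; a branch that
# reaches `target` terminates. `target = NULL` explores everything
# (exhaustion accounting). Returns, per traversal, the edge strength,
# whether it completed a path to the target, and for hits the full path.
traversal_sequence <- function(adj, origin, target, stopping_length) {
  strengths <- numeric()
  hits <- list()            # index -> path (words, labels)
  frontier <- list(list(words = origin, labels = character()))
  k <- 0L
  for (depth in seq_len(stopping_length)) {
    nxt <- list()
    for (p in frontier) {
      e <- adj[[p$words[length(p$words)]]]
      if (is.null(e)) next
      for (i in seq_len(nrow(e))) {
        w <- e$target[i]
        if (w %in% p$words) next
        k <- k + 1L
        strengths[k] <- e$strength[i]
        path <- list(words = c(p$words, w), labels = c(p$labels, e$label[i]))
        if (!is.null(target) && w == target) {
          hits[[as.character(k)]] <- path
        } else if (depth < stopping_length) {
          nxt[[length(nxt) + 1L]] <- path
        }
      }
    }
    frontier <- nxt
    if (!length(frontier)) break
  }
  list(strengths = strengths, hits = hits, origin = origin)
}

# Run both searches of the retrieval race in simulated time. Latencies for
# every traversal are sampled (subject search first, then predicate) and
# accumulated along each search's serial clock. Returns connecting-path
# events in time order plus both exhaustion clocks. `cache` may be an
# environment memoising traversal sequences by word pair.
race_paths <- function(net, subject, predicate, params,
                       adj = NULL, cache = NULL) {
  if (is.null(adj)) adj <- network_adjacency(net)
  check_word(net, subject)
  check_word(net, predicate)
  seq_for <- function(origin, target) {
    if (!is.null(cache)) {
      key <- paste(origin, target, sep = "\r")
      got <- cache[[key]]
      if (!is.null(got)) return(got)
      val <- traversal_sequence(adj, origin, target, params$stopping_length)
      cache[[key]] <- val
      return(val)
    }
    traversal_sequence(adj, origin, target, params$stopping_length)
  }
  runs <- list(SUBJECT = seq_for(subject, predicate),
               PREDICATE = seq_for(predicate, subject))
  events <- list()
  exhaust <- c(SUBJECT = 0, PREDICATE = 0)
  for (side in names(runs)) {
    tr <- runs[[side]]
    n <- length(tr$strengths)
    if (!n) next
    clock <- cumsum(sample_edge_latency(tr$strengths, params))
    exhaust[[side]] <- clock[n]
    for (ks in names(tr$hits)) {
      k <- as.integer(ks)
      events[[length(events) + 1L]] <-
        list(time = clock[k], origin = side, path = tr$hits[[ks]])
    }
  }
  if (length(events)) {
    tm <- vapply(events, `[[`, numeric(1), "time")
    side <- vapply(events, `[[`, character(1), "origin")
    events <- events[order(tm, match(side, c("SUBJECT", "PREDICATE")))]
  }
  list(events = events, exhaust = exhaust)
}

#' Dual-origin retrieval of a connecting associative path
#'
#' Simulates the stage-1 race between the subject-origin and
#' predicate-origin searches. The outcome is that of whichever search
#' first completes a connecting path; if neither connects within the
#' stopping length the outcome is exhaustion, with latency equal to the
#' slower search's total exploration time plus the exhaustion overhead.
#' Ambiguous paths are returned like any other; filtering is the decision
#' layer's job.
#'
#' @param net A [semantic_network()].
#' @param subject,predicate Stimulus terms, both in the network.
#' @param params A [retrieval_params()].
#' @param adj Optional prebuilt [network_adjacency()] index.
#' @return A list with `status` (`"PATH_FOUND"` or `"EXHAUSTED"`), `path`
#'   (for found: list with `words`, `labels`), `origin` (`"SUBJECT"` or
#'   `"PREDICATE"`), and `latency` in ms.
#' @export
retrieve_dual <- function(net, subject, predicate,
                          params = retrieval_params(), adj = NULL) {
  race <- race_paths(net, subject, predicate, params, adj = adj)
  if (length(race$events)) {
    ev <- race$events[[1L]]
    list(status = "PATH_FOUND", path = ev$path, origin = ev$origin,
         latency = ev$time)
  } else {
    list(status = "EXHAUSTED", path = NULL, origin = NA_character_,
         latency = max(race$exhaust) + params$exhaustion_overhead)
  }
}

#' Time to exhaust all bounded paths from a word
#'
#' Samples the total serial time to traverse every acyclic path of length
#' at most the stopping length starting at `word`, plus the exhaustion
#' overhead. An isolated word costs exactly the overhead.
#'
#' @inheritParams retrieve_dual
#' @param word Word whose neighbourhood is exhausted.
#' @return Latency in ms.
#' @export
exhaustion_latency <- function(net, word, params = retrieval_params(),
                               adj = NULL) {
  if (is.null(adj)) adj <- network_adjacency(net)
  check_word(net, word)
  tr <- traversal_sequence(adj, word, NULL, params$stopping_length)
  tot <- if (length(tr$strengths))
    sum(sample_edge_latency(tr$strengths, params)) else 0
  tot + params$exhaustion_overhead
}
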