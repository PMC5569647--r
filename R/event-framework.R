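#' Ordered event pairs for a duration vector
#'
#' Enumerates the m = n(n-1)/2 ordered pairs (i, j), j > i, in the fixed
#' row order used for every duration vector in the package:
#' (1,2), (1,3), ..., (1,n), (2,3), ..., (n-1,n). Element (i, j) of a
#' duration vector equals p_j - p_i.
#'
#' @param n number of events (integer, at least 2).
#' @return integer matrix with m rows and columns `i`, `j`.
#' @export
#' @examples
#' duration_pairs(3)
duration_pairs <- function(n) {
  n <- .check_n_events(n)
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n))
  cbind(i = i, j = as.integer(j))
}

.check_n_events <- function(n) {
  if (length(n) != 1L || !is.finite(n) || n != round(n) || n < 2)
    .stop_demotime("`n` must be a single integer >= 2", "demotime_invalid")
  as.integer(n)
}

#' Linear map from n events to their pairwise durations
#'
#' Builds the m x n matrix X (m = n(n-1)/2) with entries in \{-1, 0, +1\}
#' such that `d = X %*% p` yields all pairwise durations p_j - p_i, rows
#' ordered as in [duration_pairs()]. Every row holds one -1 and one +1, so
#' row sums are zero and the map annihilates constants: durations are
#' translation invariant, and X has rank n - 1 with no inverse (events are
#' not recoverable from durations).
#'
#' @param n number of events (integer, at least 2).
#' @return integer matrix, m rows and n columns.
#' @export
#' @examples
#' difference_matrix(3)
difference_matrix <- function(n) {
  n <- .check_n_events(n)
  pairs <- duration_pairs(n)
  m <- nrow(pairs)
  X <- matrix(0L, m, n)
  X[cbind(seq_len(m), pairs[, "i"])] <- -1L
  X[cbind(seq_len(m), pairs[, "j"])] <- 1L
  rownames(X) <- sprintf("(%d,%d)", pairs[, "i"], pairs[, "j"])
  X
}

#' All pairwise durations between dated events
#'
#' @param p numeric vector of n >= 2 event times (decimal years), all
#'   finite. Durations may be negative: event order in `p` is a labelling
#'   convention, not a chronology.
#' @return named numeric vector of length n(n-1)/2; element `"(i,j)"` is
#'   `p[j] - p[i]`, ordered as in [duration_pairs()].
#' @export
#' @examples
#' durations(c(1, 2, 3))  # (1, 2, 1): same as durations(c(2, 3, 4))
durations <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)))
    .stop_demotime("`p` must be a finite numeric vector", "demotime_invalid")
  n <- .check_n_events(length(p))
  X <- difference_matrix(n)
  d <- as.vector(X %*% p)
  names(d) <- rownames(X)
  d
}

#' Count the time measures implied by n events
#'
#' n events imply m = n(n-1)/2 pairwise durations, for n(n+1)/2 time
#' measures in total (three events give the six demographic measures).
#'
#' @param n number of events (integer, at least 2).
#' @return named numeric vector `c(durations = m, total = n + m)`.
#' @export
measure_counts <- function(n) {
  n <- .check_n_events(n)
  m <- n * (n - 1) / 2
  c(durations = m, total = n + m)
}

#' Graph of time measures for n events
#'
#' The time-measure graph has n + 1 vertices: one hub (vertex 0) to which
#' all n event edges attach, and one vertex per event; the duration edge
#' for pair (i, j) connects event vertices i and j. Each triangle of
#' mutually connecting edges is a triad identity, and there are
#' choose(n + 1, 3) of them. With events (C, P, D) and duration labels
#' (A, L, T) this is the tetrahedral graph of the demographic hexad.
#'
#' @param labels character vector of n >= 2 unique event names.
#' @param duration_labels optional character vector of m = n(n-1)/2 unique
#'   duration names in [duration_pairs()] order; defaults to `"(i,j)"`.
#' @return object of class `time_graph`: list with `n`, `m`,
#'   `event_labels`, `duration_labels`, and an `edges` data frame
#'   (`label`, `v1`, `v2`, `type`), hub vertex = 0.
#' @export
#' @examples
#' g <- time_graph(c("C", "P", "D"), c("A", "L", "T"))
#' triad_identities(g)
time_graph <- function(labels, duration_labels = NULL) {
  labels <- as.character(labels)
  n <- .check_n_events(length(labels))
  pairs <- duration_pairs(n)
  m <- nrow(pairs)
  if (is.null(duration_labels))
    duration_labels <- sprintf("(%d,%d)", pairs[, "i"], pairs[, "j"])
  duration_labels <- as.character(duration_labels)
  if (length(duration_labels) != m)
    .stop_demotime(sprintf("need %d duration labels for %d events", m, n),
                   "demotime_invalid")
  all_labels <- c(labels, duration_labels)
  if (anyDuplicated(all_labels))
    .stop_demotime("edge labels must be unique", "demotime_invalid")
  edges <- rbind(
    data.frame(label = labels, v1 = 0L, v2 = seq_len(n),
               type = "event", stringsAsFactors = FALSE),
    data.frame(label = duration_labels, v1 = pairs[, "i"], v2 = pairs[, "j"],
               type = "duration", stringsAsFactors = FALSE)
  )
  structure(list(n = n, m = m, event_labels = labels,
                 duration_labels = duration_labels, edges = edges),
            class = "time_graph")
}

#' @export
print.time_graph <- function(x, ...) {
  cat(sprintf("Time-measure graph: %d events, %d durations, %d vertices, %d edges\n",
              x$n, x$m, x$n + 1L, nrow(x$edges)))
  cat("  events:    ", paste(x$event_labels, collapse = ", "), "\n")
  cat("  durations: ", paste(x$duration_labels, collapse = ", "), "\n")
  invisible(x)
}

# label of the edge between vertices u < v, or NA if absent
.edge_label <- function(graph, u, v) {
  e <- graph$edges
  hit <- (e$v1 == u & e$v2 == v) | (e$v1 == v & e$v2 == u)
  if (any(hit)) e$label[which(hit)[1L]] else NA_character_
}

#' Enumerate the triad identities of a time-measure graph
#'
#' Searches all triangles of mutually connecting edges; each is a triad
#' identity whose three edge labels determine one another pairwise. The
#' demographic graph yields APC, TPD, TAL, and LCD.
#'
#' @param graph a [time_graph()].
#' @return list of character triples (the edge labels of each triangle),
#'   of length choose(n + 1, 3).
#' @export
triad_identities <- function(graph) {
  stopifnot(inherits(graph, "time_graph"))
  verts <- 0:graph$n
  triples <- combn(verts, 3L)
  out <- list()
  for (k in seq_len(ncol(triples))) {
    u <- triples[1L, k]; v <- triples[2L, k]; w <- triples[3L, k]
    lab <- c(.edge_label(graph, u, v), .edge_label(graph, u, w),
             .edge_label(graph, v, w))
    if (!anyNA(lab)) out[[length(out) + 1L]] <- lab
  }
  out
}

#' Classify all measure dyads as informative or uninformative
#'
#' A dyad (unordered pair of time measures) is informative when its two
#' edges lie in a common triangle of the graph: the third edge is then the
#' derived measure. In the demographic graph 12 of the 15 dyads are
#' informative and LP, CT, and AD have no derived measure.
#'
#' @param graph a [time_graph()].
#' @return data frame with one row per unordered label pair: `first`,
#'   `second`, `derived` (`NA` when uninformative), `informative`.
#' @export
#' @examples
#' g <- time_graph(c("C", "P", "D"), c("A", "L", "T"))
#' subset(classify_dyads(g), !informative)
classify_dyads <- function(graph) {
  stopifnot(inherits(graph, "time_graph"))
  e <- graph$edges
  k <- nrow(e)
  idx <- combn(k, 2L)
  first <- e$label[idx[1L, ]]
  second <- e$label[idx[2L, ]]
  derived <- rep(NA_character_, ncol(idx))
  for (c0 in seq_len(ncol(idx))) {
    a <- idx[1L, c0]; b <- idx[2L, c0]
    va <- c(e$v1[a], e$v2[a]); vb <- c(e$v1[b], e$v2[b])
    shared <- intersect(va, vb)
    if (length(shared) == 1L) {
      far <- c(setdiff(va, shared), setdiff(vb, shared))
      derived[c0] <- .edge_label(graph, far[1L], far[2L])
    }
  }
  data.frame(first = first, second = second, derived = derived,
             informative = !is.na(derived), stringsAsFactors = FALSE)
}

#' Derived measure of one dyad
#'
#' @param graph a [time_graph()].
#' @param pair character vector of two measure labels present in the graph.
#' @return the derived measure label, or `NA_character_` for an
#'   uninformative dyad.
#' @export
#' @examples
#' g <- time_graph(c("C", "P", "D"), c("A", "L", "T"))
#' dyad_derived(g, c("T", "A"))  # "L"
dyad_derived <- function(graph, pair) {
  stopifnot(inherits(graph, "time_graph"))
  pair <- as.character(pair)
  all_labels <- graph$edges$label
  if (length(pair) != 2L || !all(pair %in% all_labels) || pair[1] == pair[2])
    .stop_demotime("`pair` must be two distinct edge labels of the graph",
                   "demotime_invalid")
  dy <- classify_dyads(graph)
  hit <- (dy$first == pair[1] & dy$second == pair[2]) |
    (dy$first == pair[2] & dy$second == pair[1])
  dy$derived[hit]
}

#' The demographic time-measure graph
#'
#' Convenience constructor for the three-event graph with events
#' C (birth cohort), P (period), D (death cohort) and durations
#' A = P - C, L = D - C, T = D - P.
#'
#' @return a [time_graph()].
#' @export
demographic_graph <- function() {
  time_graph(c("C", "P", "D"), c("A", "L", "T"))
}
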