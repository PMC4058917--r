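# Pareto-set algebra on annotated event count vectors.
#
# A "front" is an antichain of event count vectors <delta, theta, loss>,
# each annotated with the number of distinct reconciliations achieving it
# and (optionally) the set of events common to all of them.  Two operations
# drive the dynamic program: the merge "(+)" (union then Pareto filter;
# alternative derivations of the same vector add their counts and intersect
# their event sets) and the combine "(x)" (Cartesian sums then Pareto
# filter; counts multiply per pair and add across pairs, events union per
# pair and intersect across pairs).
#
# Internal representation: list(vec = k x 3 numeric matrix, count = numeric,
# events = list of sorted character vectors or NULL, tops = list of integer
# vectors or NULL).  `tops` records the possible top species mappings of a
# subsolution; it is what lets a transfer event name its recipient.

front_empty <- function(track_events = TRUE) {
  list(vec = matrix(numeric(0), 0, 3),
       count = numeric(0),
       events = if (track_events) list() else NULL,
       tops = if (track_events) list() else NULL)
}

front_unit <- function(track_events = TRUE, vec = c(0, 0, 0), count = 1,
                       events = character(0), tops = integer(0)) {
  list(vec = matrix(as.numeric(vec), 1, 3),
       count = count,
       events = if (track_events) list(events) else NULL,
       tops = if (track_events) list(as.integer(tops)) else NULL)
}

front_size <- function(A) nrow(A$vec)

front_tracked <- function(A) !is.null(A$events)

# strict componentwise betterness
dominates <- function(v, w) all(v <= w) && any(v < w)

#' Pareto filter of a multiset of event count vectors
#'
#' Keeps the maximal antichain: every input vector is dominated by (or equal
#' to) some retained vector and no retained vector is strictly better than
#' another.  Duplicates collapse to one copy.
#'
#' @param vectors a matrix with columns (duplications, transfers, losses),
#'   or a list of length-3 vectors.
#' @return a matrix of the Pareto-optimal vectors in lexicographic order.
#' @export
pareto_filter <- function(vectors) {
  if (is.list(vectors)) vectors <- do.call(rbind, vectors)
  if (is.null(vectors) || nrow(vectors) == 0)
    return(matrix(numeric(0), 0, 3))
  vectors <- unique(vectors)
  keep <- rep(TRUE, nrow(vectors))
  for (i in seq_len(nrow(vectors))) {
    for (j in seq_len(nrow(vectors))) {
      if (i != j && dominates(vectors[j, ], vectors[i, ])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  v <- vectors[keep, , drop = FALSE]
  v[order(v[, 1], v[, 2], v[, 3]), , drop = FALSE]
}

# Collapse duplicate vectors (counts add, events intersect, tops union),
# drop dominated vectors, sort lexicographically.
front_normalize <- function(A) {
  k <- front_size(A)
  if (k == 0) return(A)
  key <- paste(A$vec[, 1], A$vec[, 2], A$vec[, 3])
  groups <- split(seq_len(k), key)
  vec <- matrix(numeric(0), 0, 3)
  count <- numeric(0)
  events <- if (front_tracked(A)) list() else NULL
  tops <- if (front_tracked(A)) list() else NULL
  for (g in groups) {
    vec <- rbind(vec, A$vec[g[1], ])
    count <- c(count, sum(A$count[g]))
    if (front_tracked(A)) {
      events[[length(events) + 1L]] <- Reduce(intersect, A$events[g])
      tops[[length(tops) + 1L]] <- sort(unique(unlist(A$tops[g])))
    }
  }
  keep <- rep(TRUE, nrow(vec))
  for (i in seq_len(nrow(vec))) {
    for (j in seq_len(nrow(vec))) {
      if (i != j && dominates(vec[j, ], vec[i, ])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  ord <- order(vec[, 1], vec[, 2], vec[, 3])
  ord <- ord[keep[ord]]
  list(vec = vec[ord, , drop = FALSE], count = count[ord],
       events = if (front_tracked(A)) events[ord] else NULL,
       tops = if (front_tracked(A)) tops[ord] else NULL)
}

#' Merge two annotated Pareto fronts (the \eqn{\oplus} operation)
#'
#' Union of the vector sets followed by a Pareto filter.  When the same
#' vector survives from both sides the derivations are alternatives:
#' reconciliation counts add and common-event sets intersect.
#'
#' @param A,B annotated fronts (as produced by [annotated_front()] or by the
#'   dynamic program).
#' @return an annotated front.
#' @export
pareto_merge <- function(A, B) {
  if (front_size(A) == 0) return(front_normalize(B))
  if (front_size(B) == 0) return(front_normalize(A))
  te <- front_tracked(A) && front_tracked(B)
  front_normalize(list(
    vec = rbind(A$vec, B$vec),
    count = c(A$count, B$count),
    events = if (te) c(A$events, B$events) else NULL,
    tops = if (te) c(A$tops, B$tops) else NULL))
}

front_merge_all <- function(...) Reduce(pareto_merge, list(...))

#' Combine two annotated Pareto fronts (the \eqn{\otimes} operation)
#'
#' Cartesian sums of the two vector sets followed by a Pareto filter,
#' computed keeping at most one entry (the minimum-loss one) per
#' (duplication, transfer) pair so the intermediate list never grows beyond
#' one entry per pair.  Counts multiply per pair and add across pairs
#' producing the same sum; the common-event set of a result vector is the
#' intersection over contributing pairs of the union of the pair's event
#' sets.  An empty operand (an infeasible subproblem) absorbs: the result is
#' empty.
#'
#' @param A,B annotated fronts.
#' @param pair_events optional `function(i, j)` returning extra event keys
#'   contributed by the combination of entry `i` of `A` with entry `j` of
#'   `B` (used by the dynamic program to attach transfer events, whose
#'   identity depends on the recipient of the `B`-side subsolution).
#' @return an annotated front.
#' @export
pareto_combine <- function(A, B, pair_events = NULL) {
  te <- front_tracked(A) && front_tracked(B)
  if (front_size(A) == 0 || front_size(B) == 0) return(front_empty(te))
  ka <- front_size(A); kb <- front_size(B)
  ia <- rep(seq_len(ka), each = kb)
  ib <- rep(seq_len(kb), times = ka)
  sums <- A$vec[ia, , drop = FALSE] + B$vec[ib, , drop = FALSE]
  # retain only the minimum loss for each (delta, theta): all other sums are
  # dominated and their annotations are irrelevant
  dt_key <- paste(sums[, 1], sums[, 2])
  min_l <- tapply(sums[, 3], dt_key, min)
  keep <- sums[, 3] == min_l[dt_key]
  ia <- ia[keep]; ib <- ib[keep]; sums <- sums[keep, , drop = FALSE]
  key <- paste(sums[, 1], sums[, 2])
  groups <- split(seq_along(ia), key)
  vec <- matrix(numeric(0), 0, 3)
  count <- numeric(0)
  events <- if (te) list() else NULL
  for (g in groups) {
    vec <- rbind(vec, sums[g[1], ])
    count <- c(count, sum(A$count[ia[g]] * B$count[ib[g]]))
    if (te) {
      ev <- NULL
      for (p in g) {
        e <- union(A$events[[ia[p]]], B$events[[ib[p]]])
        if (!is.null(pair_events)) e <- union(e, pair_events(ia[p], ib[p]))
        ev <- if (is.null(ev)) e else intersect(ev, e)
      }
      events[[length(events) + 1L]] <- ev
    }
  }
  front_normalize(list(vec = vec, count = count, events = events,
                       tops = if (te) rep(list(integer(0)), nrow(vec)) else NULL))
}

# increment one event-count component for every entry; optionally attach an
# event key (used for the loss events added by the in(.,.) recurrence and
# the duplication events of P_Delta)
front_shift <- function(A, kind = c("D", "T", "L"), i = 1, event = NULL) {
  kind <- match.arg(kind)
  if (front_size(A) == 0) return(A)
  col <- match(kind, c("D", "T", "L"))
  A$vec[, col] <- A$vec[, col] + i
  if (front_tracked(A) && !is.null(event))
    A$events <- lapply(A$events, function(e) union(e, event))
  A
}

# attach a uniform event key to every entry
front_add_event <- function(A, event) {
  if (front_tracked(A) && front_size(A) > 0)
    A$events <- lapply(A$events, function(e) union(e, event))
  A
}

# fix the top species mapping of every entry (entries of P(t, s) map t to s)
front_set_tops <- function(A, s) {
  if (front_tracked(A) && front_size(A) > 0)
    A$tops <- rep(list(as.integer(s)), front_size(A))
  A
}

#' Construct an annotated front from vectors, counts and event sets
#'
#' Mainly for tests and for rebuilding serialized results.
#'
#' @param vectors matrix with columns (duplications, transfers, losses) or a
#'   list of length-3 vectors.
#' @param counts reconciliation counts (default 1 each).
#' @param events list of character vectors of event keys, or `NULL` to
#'   disable event tracking.
#' @return an annotated front (normalized: antichain, lexicographic order).
#' @export
annotated_front <- function(vectors, counts = NULL, events = NULL) {
  if (is.list(vectors)) vectors <- do.call(rbind, vectors)
  if (is.null(vectors)) vectors <- matrix(numeric(0), 0, 3)
  k <- nrow(vectors)
  if (is.null(counts)) counts <- rep(1, k)
  te <- !is.null(events)
  front_normalize(list(
    vec = matrix(as.numeric(vectors), k, 3),
    count = as.numeric(counts),
    events = if (te) lapply(events, as.character) else NULL,
    tops = if (te) rep(list(integer(0)), k) else NULL))
}

# equality of two fronts (vectors + counts + events); for tests
front_equal <- function(A, B, check_events = TRUE) {
  if (front_size(A) != front_size(B)) return(FALSE)
  A <- front_normalize(A); B <- front_normalize(B)
  if (!isTRUE(all.equal(unname(A$vec), unname(B$vec)))) return(FALSE)
  if (!isTRUE(all.equal(A$count, B$count))) return(FALSE)
  if (check_events && front_tracked(A) && front_tracked(B)) {
    for (i in seq_len(front_size(A)))
      if (!setequal(A$events[[i]], B$events[[i]])) return(FALSE)
  }
  TRUE
}
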