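#' Hybrid atlas obtained by merging one pair of states
#'
#' Replaces two centroids of a (K+1)-state solution by their element-wise
#' mean, producing a K-state "hybrid" atlas used to test whether the pair
#' subdivides a state of the K-state solution.
#'
#' @param child_atlas a `state_atlas` (or centroid matrix) with K+1 states.
#' @param pair integer vector of two distinct state indices to merge.
#' @return list with `centroids` ((K x n_edge) matrix; the hybrid row
#'   first named after the merged pair, remaining rows in original order)
#'   and `source` (for each hybrid row, the child state indices it came
#'   from).
#' @export
build_hybrid_atlas <- function(child_atlas, pair) {
  cent <- if (inherits(child_atlas, "state_atlas")) child_atlas$centroids
          else child_atlas
  k1 <- nrow(cent)
  pair <- as.integer(pair)
  if (length(pair) != 2L || pair[1L] == pair[2L] ||
      any(pair < 1L | pair > k1))
    stopf("pair must be two distinct state indices in 1..%d", k1)
  pair <- sort(pair)
  if (is.null(rownames(cent))) rownames(cent) <- make_state_labels(k1)
  hybrid <- (cent[pair[1L], ] + cent[pair[2L], ]) / 2
  rest <- setdiff(seq_len(k1), pair)
  out <- rbind(hybrid, cent[rest, , drop = FALSE])
  rownames(out) <- c(paste(rownames(cent)[pair], collapse = "+"),
                     rownames(cent)[rest])
  list(centroids = out,
       source = c(list(pair), as.list(rest)))
}

#' Match one hierarchy level by exhaustive hybrid-pair search
#'
#' For every one of the `(K+1)K/2` candidate pairs of child states, the
#' pair is merged into a hybrid state and the resulting K-state atlas is
#' Hungarian-matched to the parent solution (dissimilarity = 1 minus
#' centroid Pearson correlation). The pair whose hybrid atlas attains the
#' minimal total matching cost is returned; ties break to the
#' lexicographically smallest pair.
#'
#' @param parent_atlas `state_atlas` (or centroid matrix) with K states.
#' @param child_atlas `state_atlas` (or centroid matrix) with K+1 states.
#' @return object of class `hierarchy_match`: `parent_k`, `child_k`,
#'   `merged_pair`, `assignment` (hybrid-row -> parent state),
#'   `descends_from` (for each child state, the parent state it maps to),
#'   `cost`, `pair_costs` (cost of every candidate pair).
#' @export
match_hierarchy_level <- function(parent_atlas, child_atlas) {
  pc <- if (inherits(parent_atlas, "state_atlas")) parent_atlas$centroids
        else parent_atlas
  cc <- if (inherits(child_atlas, "state_atlas")) child_atlas$centroids
        else child_atlas
  k <- nrow(pc)
  if (nrow(cc) != k + 1L)
    stopf("child solution must have parent K + 1 states (%d vs %d)",
          nrow(cc), k)
  pairs <- utils::combn(k + 1L, 2L)
  best <- NULL
  pair_costs <- numeric(ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    hyb <- build_hybrid_atlas(cc, pairs[, p])
    m <- match_centroids_hungarian(hyb$centroids, pc)
    pair_costs[p] <- m$cost
    if (is.null(best) || m$cost < best$cost - 1e-12) {
      best <- list(pair = pairs[, p], match = m, hybrid = hyb,
                   cost = m$cost)
    }
  }
  # child state -> parent state: merged children map to the hybrid's
  # parent; the others follow the bijection
  descends <- integer(k + 1L)
  for (row in seq_len(k)) {
    parent_state <- best$match$assignment[row]
    for (child_state in best$hybrid$source[[row]])
      descends[child_state] <- parent_state
  }
  structure(
    list(parent_k = k, child_k = k + 1L,
         merged_pair = best$pair,
         assignment = best$match$assignment,
         descends_from = descends,
         cost = best$cost,
         pair_costs = stats::setNames(
           pair_costs, apply(pairs, 2L, paste, collapse = "+"))),
    class = "hierarchy_match")
}

#' @export
print.hierarchy_match <- function(x, ...) {
  cat(sprintf("<hierarchy_match> K=%d -> K=%d: merge (%d,%d), cost %.4f\n",
              x$child_k, x$parent_k, x$merged_pair[1], x$merged_pair[2],
              x$cost))
  invisible(x)
}

#' Hierarchy across a contiguous range of state solutions
#'
#' Applies [match_hierarchy_level()] to every adjacent pair of atlases,
#' yielding one match per level and, per level, the parent state each
#' child state descends from.
#'
#' @param atlases list of `state_atlas` objects for contiguous K values
#'   in increasing order (e.g. K = 2..8).
#' @return list of `hierarchy_match` objects, one per adjacent level,
#'   with class `state_hierarchy`.
#' @export
build_hierarchy <- function(atlases) {
  ks <- vapply(atlases, function(a)
    if (inherits(a, "state_atlas")) a$k else nrow(a), integer(1))
  if (length(atlases) < 2L) stopf("need at least two solutions")
  if (any(diff(ks) != 1L)) stopf("K range must be contiguous and increasing")
  out <- vector("list", length(atlases) - 1L)
  for (i in seq_len(length(atlases) - 1L))
    out[[i]] <- match_hierarchy_level(atlases[[i]], atlases[[i + 1L]])
  names(out) <- sprintf("K%d_to_K%d", ks[-length(ks)] + 1L,
                        ks[-length(ks)])
  class(out) <- "state_hierarchy"
  out
}

#' Hierarchy as a parent-child edge list
#'
#' @param hierarchy output of [build_hierarchy()].
#' @return data.frame: `child_k`, `child_state`, `parent_k`,
#'   `parent_state`, `merged` (TRUE if the child state is one of the
#'   merged pair).
#' @export
hierarchy_edge_list <- function(hierarchy) {
  do.call(rbind, lapply(unclass(hierarchy), function(h)
    data.frame(child_k = h$child_k,
               child_state = seq_len(h$child_k),
               parent_k = h$parent_k,
               parent_state = h$descends_from,
               merged = seq_len(h$child_k) %in% h$merged_pair)))
}
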