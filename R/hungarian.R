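#' Minimum-cost bipartite assignment (Hungarian algorithm)
#'
#' Solves the linear assignment problem for a square cost matrix using the
#' O(n^3) shortest-augmenting-path formulation with row/column potentials.
#' Used to align k-means state solutions (centroid matching, split-half
#' instability, hierarchy analysis), where n is the number of states and
#' the cost is a centroid dissimilarity.
#'
#' @param cost square numeric cost matrix; `cost[i, j]` is the cost of
#'   assigning row i to column j.
#' @return list with `assignment` (integer vector: column assigned to each
#'   row) and `cost` (total cost of the optimal assignment).
#' @export
#' @examples
#' solve_assignment(matrix(c(4, 1, 3, 2, 0, 5, 3, 2, 2), 3, 3))
solve_assignment <- function(cost) {
  if (!is.matrix(cost) || nrow(cost) != ncol(cost))
    stopf("cost must be a square matrix")
  if (any(!is.finite(cost))) stopf("cost matrix must be finite")
  n <- nrow(cost)
  if (n == 1L) return(list(assignment = 1L, cost = cost[1, 1]))
  # columns are shifted by one: index 1 is a virtual unmatched column
  u <- numeric(n)          # row potentials
  v <- numeric(n + 1L)     # column potentials (1 = virtual)
  p <- integer(n + 1L)     # p[j]: row currently matched to column j - 1
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1L)
    used <- logical(n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      js <- which(!used)
      cur <- cost[i0, js - 1L] - u[i0] - v[js]
      improved <- cur < minv[js]
      minv[js[improved]] <- cur[improved]
      way[js[improved]] <- j0
      j1 <- js[which.min(minv[js])]
      delta <- minv[j1]
      u[p[used]] <- u[p[used]] + delta
      v[used] <- v[used] - delta
      minv[!used] <- minv[!used] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    # augment along the alternating path back to the virtual column
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  assignment <- integer(n)
  assignment[p[-1L]] <- seq_len(n)
  list(assignment = assignment,
       cost = sum(cost[cbind(seq_len(n), assignment)]))
}
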