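#' Pool windowed connectivity across runs and subjects
#'
#' Stacks the z-edge rows of a list of `windowed_fc` objects into one
#' matrix for group-level clustering, keeping a provenance table.
#'
#' @param wc_list list of `windowed_fc` objects with identical edge
#'   dimension.
#' @return list with `z_edges` (pooled window x edge matrix) and `meta`
#'   (data.frame: subject_id, visit_id, run_id, window).
#' @export
pool_windows <- function(wc_list) {
  if (!length(wc_list)) stopf("no windowed connectivity supplied")
  ncols <- vapply(wc_list, function(w) ncol(w$z_edges), integer(1))
  if (length(unique(ncols)) != 1L)
    stopf("edge dimension differs across runs")
  meta <- do.call(rbind, lapply(wc_list, function(w)
    data.frame(subject_id = w$subject_id, visit_id = w$visit_id,
               run_id = w$run_id, window = seq_len(nrow(w$z_edges)))))
  list(z_edges = do.call(rbind, lapply(wc_list, `[[`, "z_edges")),
       meta = meta)
}

# Lloyd's k-means with kmeans++ initialization, deterministic restart
# seeds, and empty-cluster reseeding to the farthest point. x: n x p.
# Iterations run in compiled code (.lloyd_iterate); R owns the RNG.
# Returns centers (k x p), cluster, objective (total within-cluster SS).
kmeans_lloyd <- function(x, k, seed = NULL, n_restarts = 10L,
                         max_iter = 100L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < k) stopf("fewer points (%d) than clusters (%d)", n, k)
  xsq <- rowSums(x^2)
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      init <- x[kmeanspp_init(x, k, xsq), , drop = FALSE]
      fit <- .lloyd_iterate(x, init, max_iter)
      fit$cluster <- fit$cluster + 1L
      if (is.null(best) || fit$objective < best$objective) best <- fit
    }
    best
  })
}

# D^2-weighted (kmeans++) center selection; returns row indices
kmeanspp_init <- function(x, k, xsq = rowSums(x^2)) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1L] <- sample.int(n, 1L)
  if (k > 1L) {
    d2 <- pmax(xsq - 2 * drop(x %*% x[idx[1L], ]) + xsq[idx[1L]], 0)
    for (j in 2:k) {
      if (all(d2 == 0)) {
        idx[j] <- sample.int(n, 1L)
      } else {
        idx[j] <- sample.int(n, 1L, prob = d2)
      }
      d2 <- pmin(d2, pmax(xsq - 2 * drop(x %*% x[idx[j], ]) + xsq[idx[j]], 0))
    }
  }
  idx
}

#' Estimate a group-level brain-state atlas by k-means
#'
#' Clusters pooled z-edge window vectors into K states by standard
#' (squared-Euclidean) k-means, best of `n_restarts` deterministic
#' kmeans++ starts. States are then ordered by descending occupancy
#' (fraction of pooled windows assigned) and named `A`, `B`, `C`, ... —
#' so state A is always the most-occupied state of the solution.
#'
#' @param pooled either the `z_edges` matrix or the output of
#'   [pool_windows()].
#' @param k number of states.
#' @param seed integer seed.
#' @param n_restarts number of k-means restarts (default 10).
#' @return object of class `state_atlas`: `k`, `centroids` (K x n_edge,
#'   rows named by state), `state_labels`, `occupancy`, `assignments`
#'   (pooled-window state indices after reordering), `objective`,
#'   `pooled_window_count`, `seed`, `n_restarts`.
#' @export
cluster_states <- function(pooled, k, seed = 1L, n_restarts = 10L) {
  x <- if (is.list(pooled) && !is.null(pooled$z_edges)) pooled$z_edges
       else as.matrix(pooled)
  if (!is_count(k) || k < 1L) stopf("k must be a positive integer")
  if (nrow(x) < k) stopf("need at least k pooled windows")
  fit <- kmeans_lloyd(x, k, seed = seed, n_restarts = n_restarts)
  occ <- tabulate(fit$cluster, nbins = k) / nrow(x)
  ord <- order(occ, decreasing = TRUE)
  relabel <- match(seq_len(k), ord)
  labels <- make_state_labels(k)
  centroids <- fit$centers[ord, , drop = FALSE]
  rownames(centroids) <- labels
  structure(
    list(k = as.integer(k), centroids = centroids, state_labels = labels,
         occupancy = stats::setNames(occ[ord], labels),
         assignments = relabel[fit$cluster],
         objective = fit$objective,
         pooled_window_count = nrow(x), seed = seed,
         n_restarts = as.integer(n_restarts)),
    class = "state_atlas")
}

make_state_labels <- function(k) {
  if (k <= 26L) LETTERS[seq_len(k)]
  else c(LETTERS, paste0("A", LETTERS))[seq_len(k)]
}

#' @export
print.state_atlas <- function(x, ...) {
  cat(sprintf("<state_atlas> K=%d over %d edges (%d pooled windows)\n",
              x$k, ncol(x$centroids), x$pooled_window_count))
  cat("  occupancy:",
      paste(sprintf("%s=%.3f", names(x$occupancy), x$occupancy),
            collapse = " "), "\n")
  invisible(x)
}

# 1 - Pearson correlation between all centroid pairs of two atlases
centroid_dissimilarity <- function(cent_a, cent_b) {
  1 - stats::cor(t(cent_a), t(cent_b))
}

#' Match two state atlases by the Hungarian algorithm
#'
#' Finds the bijection between the states of two equal-K atlases that
#' minimizes total dissimilarity, where dissimilarity between two
#' centroids is 1 minus the Pearson correlation of their edge vectors.
#'
#' @param atlas_a,atlas_b `state_atlas` objects (or bare centroid
#'   matrices) with equal K.
#' @return list with `assignment` (state j of `atlas_b` matched to state
#'   j of `atlas_a`), `cost` (total matched dissimilarity), and
#'   `pair_costs`.
#' @export
match_centroids_hungarian <- function(atlas_a, atlas_b) {
  ca <- if (inherits(atlas_a, "state_atlas")) atlas_a$centroids else atlas_a
  cb <- if (inherits(atlas_b, "state_atlas")) atlas_b$centroids else atlas_b
  if (nrow(ca) != nrow(cb))
    stopf("atlases have different K (%d vs %d)", nrow(ca), nrow(cb))
  d <- centroid_dissimilarity(ca, cb)
  sol <- solve_assignment(d)
  list(assignment = sol$assignment, cost = sol$cost,
       pair_costs = d[cbind(seq_len(nrow(ca)), sol$assignment)])
}

#' Split-resampling instability of k-means state solutions
#'
#' For each K and each replicate, pooled windows are split into two random
#' halves and half the edge dimensions are independently subsampled; each
#' half is clustered on the shared edge subspace and the two solutions are
#' Hungarian-matched. The replicate's deviation is the total matched
#' dissimilarity (sum over matched pairs of 1 minus centroid correlation);
#' instability(K) is its mean over replicates. Low instability marks
#' solution sizes that can be stably estimated.
#'
#' @param pooled pooled windows as in [cluster_states()].
#' @param k_range integer vector of solution sizes (default 2:20).
#' @param n_replicates number of random splits (default 30).
#' @param seed integer seed.
#' @param edge_fraction fraction of edges kept per replicate (default 0.5).
#' @param n_restarts k-means restarts inside each half (default 4; the
#'   halves are compared to each other, not to a reference, so fewer
#'   restarts than [cluster_states()] suffice).
#' @param max_iter Lloyd iteration cap per k-means run (default 100).
#' @return object of class `instability_profile`: `k_range`,
#'   `instability` (named mean deviation per K), `replicate_deviations`
#'   (replicate x K matrix), `n_replicates`.
#' @export
instability_analysis <- function(pooled, k_range = 2:20,
                                 n_replicates = 30L, seed = 1L,
                                 edge_fraction = 0.5, n_restarts = 4L,
                                 max_iter = 100L) {
  x <- if (is.list(pooled) && !is.null(pooled$z_edges)) pooled$z_edges
       else as.matrix(pooled)
  n <- nrow(x)
  half <- n %/% 2L
  if (half < max(k_range))
    stopf("half-split size %d < max K %d", half, max(k_range))
  dev <- matrix(NA_real_, n_replicates, length(k_range),
                dimnames = list(NULL, paste0("K", k_range)))
  with_seed(seed, {
    for (rep_i in seq_len(n_replicates)) {
      perm <- sample.int(n)
      h1 <- perm[seq_len(half)]
      h2 <- perm[(half + 1L):(2L * half)]
      edges <- sort(sample.int(ncol(x), max(2L, round(edge_fraction *
                                                        ncol(x)))))
      xa <- x[h1, edges, drop = FALSE]
      xb <- x[h2, edges, drop = FALSE]
      for (ki in seq_along(k_range)) {
        k <- k_range[ki]
        fa <- kmeans_lloyd(xa, k, seed = NULL, n_restarts = n_restarts,
                           max_iter = max_iter)
        fb <- kmeans_lloyd(xb, k, seed = NULL, n_restarts = n_restarts,
                           max_iter = max_iter)
        m <- match_centroids_hungarian(fa$centers, fb$centers)
        dev[rep_i, ki] <- m$cost
      }
    }
  })
  structure(
    list(k_range = as.integer(k_range),
         instability = stats::setNames(colMeans(dev), paste0("K", k_range)),
         replicate_deviations = dev,
         n_replicates = as.integer(n_replicates)),
    class = "instability_profile")
}

#' @export
print.instability_profile <- function(x, ...) {
  cat("<instability_profile>\n")
  print(round(x$instability, 4))
  invisible(x)
}

#' Stable solution sizes from an instability profile
#'
#' Returns K values at strict local minima of the instability curve
#' (both neighbours strictly larger); an endpoint qualifies only when
#' strictly below its single neighbour.
#'
#' @param profile an `instability_profile`, or a named/plain numeric
#'   vector of instability values over a contiguous K range.
#' @param k_range K values when `profile` is a bare vector.
#' @return integer vector of stable K values (possibly empty).
#' @export
identify_stable_solutions <- function(profile, k_range = NULL) {
  if (inherits(profile, "instability_profile")) {
    v <- unname(profile$instability)
    ks <- profile$k_range
  } else {
    v <- unname(as.numeric(profile))
    ks <- if (is.null(k_range)) seq_along(v) else as.integer(k_range)
  }
  n <- length(v)
  if (n < 3L) stopf("need at least 3 K values")
  if (any(diff(ks) != 1L)) stopf("K range must be contiguous")
  keep <- vapply(seq_len(n), function(i) {
    (i == 1L || v[i] < v[i - 1L]) && (i == n || v[i] < v[i + 1L])
  }, logical(1))
  ks[keep]
}
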