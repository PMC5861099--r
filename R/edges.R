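#' Fisher z-transform of correlations
#'
#' Variance-stabilizing transform `z = atanh(r)` applied to Pearson
#' correlations before clustering and statistics. Values with `|r| = 1`
#' (degenerate windows, duplicated channels) are clipped to `1 - 1e-7` so
#' the transform stays finite while preserving ordering.
#'
#' @param r numeric vector/matrix of correlations, `|r| <= 1`.
#' @return object of the same shape on the z scale.
#' @seealso [fisher_z_inverse()]
#' @export
#' @examples
#' fisher_z(0.5)          # 0.5493
#' fisher_z_inverse(fisher_z(0.3))
fisher_z <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) > 1 + 1e-12))
    stopf("correlations must be finite with |r| <= 1")
  clip <- 1 - 1e-7
  atanh(pmin(pmax(r, -clip), clip))
}

#' @rdname fisher_z
#' @param z numeric vector/matrix on the z scale.
#' @export
fisher_z_inverse <- function(z) tanh(z)

#' Vectorize a symmetric connectivity matrix to its upper-triangle edges
#'
#' Canonical edge ordering used throughout the package: upper triangle,
#' row-major, diagonal excluded — edge 1 is (1,2), edge 2 is (1,3), ...,
#' edge R-1 is (1,R), edge R is (2,3), and so on. A matrix over R regions
#' yields R(R-1)/2 edges (6441 for the default 114-region parcellation).
#'
#' @param m square symmetric numeric matrix.
#' @return numeric vector of length `R(R-1)/2`.
#' @seealso [devectorize_connectivity()], [edge_index_table()]
#' @export
vectorize_connectivity <- function(m) {
  check_symmetric(m, tol = 1e-6, what = "connectivity matrix")
  # column-major lower triangle == row-major upper triangle for symmetric m
  m[lower.tri(m)]
}

#' Reconstruct a symmetric matrix from an edge vector
#'
#' Inverse of [vectorize_connectivity()]; the diagonal is set to 0 by
#' convention (self-correlation carries no information).
#'
#' @param v edge vector of length `R(R-1)/2`.
#' @param region_ids optional dimnames.
#' @return symmetric `R x R` matrix with zero diagonal.
#' @export
devectorize_connectivity <- function(v, region_ids = NULL) {
  n_edge <- length(v)
  r <- (1 + sqrt(1 + 8 * n_edge)) / 2
  if (abs(r - round(r)) > 1e-8)
    stopf("edge vector length %d is not R(R-1)/2 for integer R", n_edge)
  r <- as.integer(round(r))
  m <- matrix(0, r, r)
  m[lower.tri(m)] <- v
  m <- m + t(m)
  if (!is.null(region_ids)) dimnames(m) <- list(region_ids, region_ids)
  m
}

#' Edge index lookup for the canonical edge ordering
#'
#' @param n_regions number of regions R.
#' @param region_ids optional region identifiers.
#' @param network_labels optional region -> network character vector (length
#'   R); when given, each edge is annotated with its two networks and a
#'   `within_network` flag.
#' @return data.frame with one row per edge: `edge`, `i`, `j` (region
#'   indices, i < j) and optional annotation columns.
#' @export
edge_index_table <- function(n_regions, region_ids = NULL,
                             network_labels = NULL) {
  if (!is_count(n_regions) || n_regions < 2)
    stopf("n_regions must be an integer >= 2")
  lt <- lower.tri(matrix(0, n_regions, n_regions))
  idx <- which(lt, arr.ind = TRUE)
  # lower-tri (row > col): col is the smaller region index
  tab <- data.frame(edge = seq_len(nrow(idx)), i = idx[, "col"],
                    j = idx[, "row"])
  if (!is.null(region_ids)) {
    tab$region_i <- region_ids[tab$i]
    tab$region_j <- region_ids[tab$j]
  }
  if (!is.null(network_labels)) {
    tab$network_i <- network_labels[tab$i]
    tab$network_j <- network_labels[tab$j]
    tab$within_network <- tab$network_i == tab$network_j
  }
  tab
}
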