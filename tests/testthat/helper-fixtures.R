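# Shared small-scale fixtures. Everything is generated in code; sizes are
# deliberately tiny so the default suite stays fast.

# small cohort spec: 24 regions / 4 networks, K_true = 3
tiny_spec <- function(...) {
  defaults <- list(n_regions = 24L, n_networks = 4L, n_states = 3L,
                   n_controls = 4L, n_patients = 3L, n_timepoints = 60L,
                   observation_noise_sd = 0.2, seed = 42L)
  do.call(cohort_spec, utils::modifyList(defaults, list(...)))
}

# deterministic symmetric matrix with unit diagonal
toy_symmetric <- function(n, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n * n), n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  m
}

# k well-separated planted edge-vector patterns plus noisy copies
planted_windows <- function(k = 3, n_per = 30, n_edges = 120,
                            noise_sd = 0.05, seed = 1) {
  set.seed(seed)
  patterns <- matrix(rnorm(k * n_edges), k)
  x <- do.call(rbind, lapply(seq_len(k), function(j)
    matrix(rep(patterns[j, ], n_per), n_per, byrow = TRUE) +
      matrix(rnorm(n_per * n_edges, 0, noise_sd), n_per)))
  list(x = x, patterns = patterns,
       truth = rep(seq_len(k), each = n_per))
}

# brute-force linear assignment by permutation enumeration (oracle)
brute_force_assignment <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  best <- NULL
  for (p in perms(seq_len(n))) {
    cc <- sum(cost[cbind(seq_len(n), p)])
    if (is.null(best) || cc < best$cost)
      best <- list(assignment = p, cost = cc)
  }
  best
}

# concordance-probability AUC oracle (pair enumeration, ties count half)
auc_by_enumeration <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  conc <- 0
  for (a in pos) for (b in neg)
    conc <- conc + (a > b) + 0.5 * (a == b)
  conc / (length(pos) * length(neg))
}

# per-subject profile lists for fingerprint/prediction tests:
# n subjects x k states x n_edges, with shared subject signal across
# sessions (fingerprint) plus session noise
synthetic_profiles <- function(n_subjects, k = 2, n_edges = 90,
                               fingerprint_sd = 1, noise_sd = 0.2,
                               seed = 1) {
  set.seed(seed)
  base <- matrix(rnorm(k * n_edges), k)
  fp <- lapply(seq_len(n_subjects), function(i)
    matrix(rnorm(k * n_edges, 0, fingerprint_sd), k))
  session <- function() {
    out <- lapply(seq_len(n_subjects), function(i)
      base + fp[[i]] + matrix(rnorm(k * n_edges, 0, noise_sd), k))
    names(out) <- sprintf("sub%02d", seq_len(n_subjects))
    out
  }
  list(t1 = session(), t2 = session())
}
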