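#' Within- versus between-subject similarity of state profiles
#'
#' Correlates each subject's session-1 profile of a given state with
#' every subject's session-2 profile. Same-subject correlations form the
#' "within" distribution; all cross-subject pairs (both orderings) form
#' the "between" distribution; the two are compared by a Welch two-sample
#' t-test. Subjects lacking the state in either session are excluded
#' pairwise.
#'
#' @param profiles_t1,profiles_t2 named lists (by subject) of
#'   `subject_state_profile` objects from the two sessions, or of bare
#'   per-state profile matrices.
#' @param state state index.
#' @return list with `within` and `between` correlation vectors,
#'   `t_test` (htest), `mean_within`, `mean_between`, `n_subjects`.
#' @export
profile_similarity_distributions <- function(profiles_t1, profiles_t2,
                                             state) {
  p1 <- state_profile_matrix(profiles_t1, state)
  p2 <- state_profile_matrix(profiles_t2, state)
  common <- intersect(rownames(p1), rownames(p2))
  common <- common[stats::complete.cases(p1[common, , drop = FALSE]) &
                     stats::complete.cases(p2[common, , drop = FALSE])]
  if (length(common) < 2L)
    stopf("need at least 2 subjects expressing state %d in both sessions",
          state)
  r <- stats::cor(t(p1[common, , drop = FALSE]),
                  t(p2[common, , drop = FALSE]))
  within <- diag(r)
  between <- c(r[upper.tri(r)], r[lower.tri(r)])
  list(within = within, between = between,
       t_test = stats::t.test(within, between),
       mean_within = mean(within), mean_between = mean(between),
       n_subjects = length(common))
}

# subjects x edges matrix of one state's profiles; NA row = state absent
state_profile_matrix <- function(profiles, state) {
  rows <- lapply(profiles, function(p) {
    if (inherits(p, "subject_state_profile")) p$profiles[state, ]
    else p[state, ]
  })
  m <- do.call(rbind, rows)
  rownames(m) <- if (!is.null(names(profiles))) names(profiles)
                 else paste0("sub", seq_along(profiles))
  m
}

#' Rank-based permutation identification of individuals
#'
#' For each subject, ranks all session-2 profiles by Pearson correlation
#' to the subject's session-1 profile; a correct identification is rank 1
#' for the subject's own session-2 profile. The identification rate is
#' compared to a permutation null built by shuffling session-2 subject
#' labels; `p = (1 + #\{null rate >= observed\}) / (1 + n_permutations)`.
#'
#' @inheritParams profile_similarity_distributions
#' @param n_permutations number of label shuffles (default 1000).
#' @param seed integer seed for the permutations.
#' @return object of class `identification_result`: `state`,
#'   `identification_rate`, `ranks` (per subject), `p_value`,
#'   `null_rates`, `n_permutations`, `n_subjects`.
#' @export
identification_rank_test <- function(profiles_t1, profiles_t2, state,
                                     n_permutations = 1000L, seed = 1L) {
  p1 <- state_profile_matrix(profiles_t1, state)
  p2 <- state_profile_matrix(profiles_t2, state)
  common <- intersect(rownames(p1), rownames(p2))
  common <- common[stats::complete.cases(p1[common, , drop = FALSE]) &
                     stats::complete.cases(p2[common, , drop = FALSE])]
  n <- length(common)
  if (n < 3L) stopf("need at least 3 subjects with the state in both sessions")
  x1 <- p1[common, , drop = FALSE]
  x2 <- p2[common, , drop = FALSE]
  if (any(apply(x1, 1L, stats::sd) == 0) ||
      any(apply(x2, 1L, stats::sd) == 0))
    stopf("constant profile: similarity undefined")
  r <- stats::cor(t(x1), t(x2))   # r[i, j] = cor(t1 subject i, t2 subject j)
  # rank_mat[i, j]: rank of session-2 profile j among all session-2
  # profiles by similarity to session-1 profile i (1 = best; average
  # ranks for exact ties)
  rank_mat <- t(apply(-r, 1L, rank, ties.method = "average"))
  ranks <- rank_mat[cbind(seq_len(n), seq_len(n))]
  rate <- mean(ranks == 1)
  null_rates <- with_seed(seed, vapply(seq_len(n_permutations),
                                       function(b) {
    perm <- sample.int(n)   # shuffled claim of which t2 profile is "own"
    mean(rank_mat[cbind(seq_len(n), perm)] == 1)
  }, numeric(1)))
  structure(
    list(state = state, identification_rate = rate,
         ranks = stats::setNames(ranks, common),
         p_value = (1 + sum(null_rates >= rate)) / (1 + n_permutations),
         null_rates = null_rates,
         n_permutations = as.integer(n_permutations), n_subjects = n),
    class = "identification_result")
}

#' @export
print.identification_result <- function(x, ...) {
  cat(sprintf(
    "<identification_result> state %d: rate %.3f over %d subjects (p = %.4g, %d permutations)\n",
    x$state, x$identification_rate, x$n_subjects, x$p_value,
    x$n_permutations))
  invisible(x)
}
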