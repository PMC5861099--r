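#' Assign each window of a run to its nearest atlas state
#'
#' Every window's edge vector is labeled with the centroid it correlates
#' with most strongly (Pearson correlation across edges); ties go to the
#' lowest-index (most occupied) state.
#'
#' @param wc a `windowed_fc` object.
#' @param atlas a `state_atlas` with matching edge dimension/ordering.
#' @return object of class `state_sequence`: `labels` (integer state
#'   indices per window), `state_labels` (atlas names), `k`,
#'   `subject_id`, `visit_id`, `run_id`, `similarities` (window x state
#'   correlation matrix).
#' @export
assign_windows <- function(wc, atlas) {
  stopifnot(inherits(wc, "windowed_fc"), inherits(atlas, "state_atlas"))
  if (ncol(wc$z_edges) != ncol(atlas$centroids))
    stopf("edge dimension mismatch: windows %d vs atlas %d",
          ncol(wc$z_edges), ncol(atlas$centroids))
  sim <- stats::cor(t(wc$z_edges), t(atlas$centroids))
  labels <- max.col(sim, ties.method = "first")
  structure(
    list(labels = labels, state_labels = atlas$state_labels,
         k = atlas$k, subject_id = wc$subject_id,
         visit_id = wc$visit_id, run_id = wc$run_id,
         similarities = sim),
    class = "state_sequence")
}

#' @export
print.state_sequence <- function(x, ...) {
  cat(sprintf("<state_sequence> %s/%s/%s: %d windows, K=%d\n",
              x$subject_id, x$visit_id, x$run_id, length(x$labels), x$k))
  invisible(x)
}

as_label_vector <- function(seq, k = NULL) {
  if (inherits(seq, "state_sequence")) list(labels = seq$labels, k = seq$k)
  else list(labels = as.integer(seq),
            k = if (is.null(k)) max(as.integer(seq)) else as.integer(k))
}

#' Dwell fraction per state
#'
#' Fraction of a sequence's windows assigned to each state (the package's
#' reading of dwell time; an odds-style variant relative to time in all
#' other states is available via `mode = "odds"` but not endorsed).
#'
#' @param seq a `state_sequence` or integer label vector.
#' @param k number of states (inferred when `seq` is a `state_sequence`).
#' @param mode `"fraction"` (default) or `"odds"` (count(S)/count(not S)).
#' @return named numeric vector over states.
#' @export
dwell_fractions <- function(seq, k = NULL, mode = c("fraction", "odds")) {
  mode <- match.arg(mode)
  lv <- as_label_vector(seq, k)
  if (!length(lv$labels)) stopf("empty state sequence")
  counts <- tabulate(lv$labels, nbins = lv$k)
  out <- if (mode == "fraction") counts / length(lv$labels)
         else counts / pmax(length(lv$labels) - counts, 1L)
  stats::setNames(out, make_state_labels(lv$k))
}

#' Dwell, persistence and transition statistics of a state sequence
#'
#' Persistence of state S is the probability of remaining in S from one
#' window to the next: `#(S -> S) / #(transitions out of positions in S)`.
#' The conditional switch matrix row-normalizes the off-diagonal
#' transition counts over switches only (each defined row sums to 1;
#' diagonal excluded). Rows of states that are never left (or never
#' visited) are reported as `NA` and flagged, not zero-filled. Transitions
#' never bridge run boundaries: pass runs separately and pool with
#' [pool_transition_summaries()].
#'
#' @param seq a `state_sequence` or integer label vector (length >= 2 for
#'   transition statistics).
#' @param k number of states.
#' @return object of class `dwell_transition_summary`: `dwell_fraction`,
#'   `persistence`, `switch_matrix` (K x K, `NA` diagonal),
#'   `transition_counts`, `n_switches`, `undefined_states`.
#' @export
transition_statistics <- function(seq, k = NULL) {
  lv <- as_label_vector(seq, k)
  labels <- lv$labels
  kk <- lv$k
  state_names <- make_state_labels(kk)
  counts <- matrix(0L, kk, kk, dimnames = list(state_names, state_names))
  if (length(labels) >= 2L) {
    from <- labels[-length(labels)]
    to <- labels[-1L]
    for (i in seq_along(from))
      counts[from[i], to[i]] <- counts[from[i], to[i]] + 1L
  }
  out_trans <- rowSums(counts)
  persistence <- ifelse(out_trans > 0, diag(counts) / out_trans, NA_real_)
  switch_counts <- counts
  diag(switch_counts) <- 0L
  sw_tot <- rowSums(switch_counts)
  switch_matrix <- switch_counts / ifelse(sw_tot > 0, sw_tot, NA_real_)
  diag(switch_matrix) <- NA_real_
  structure(
    list(dwell_fraction = dwell_fractions(labels, kk),
         persistence = stats::setNames(persistence, state_names),
         switch_matrix = switch_matrix,
         transition_counts = counts,
         n_switches = sum(switch_counts),
         undefined_states = state_names[out_trans == 0]),
    class = "dwell_transition_summary")
}

#' @export
print.dwell_transition_summary <- function(x, ...) {
  cat("<dwell_transition_summary>\n dwell:  ")
  cat(sprintf("%s=%.3f", names(x$dwell_fraction), x$dwell_fraction),
      sep = " ")
  cat("\n persist:")
  cat(sprintf(" %s=%.3f", names(x$persistence), x$persistence), sep = "")
  cat("\n")
  invisible(x)
}

#' Pool transition summaries across runs of a subject
#'
#' Sums within-run transition counts (no transitions are counted across
#' run boundaries) and recomputes dwell, persistence and the switch
#' matrix from the pooled counts.
#'
#' @param summaries list of `dwell_transition_summary` objects sharing K.
#' @param labels_list optional list of the underlying label vectors, used
#'   to pool dwell fractions by total window count (otherwise dwell is
#'   the unweighted mean across runs).
#' @return a pooled `dwell_transition_summary`.
#' @export
pool_transition_summaries <- function(summaries, labels_list = NULL) {
  stopifnot(length(summaries) >= 1L)
  counts <- Reduce(`+`, lapply(summaries, `[[`, "transition_counts"))
  kk <- nrow(counts)
  state_names <- rownames(counts)
  out_trans <- rowSums(counts)
  persistence <- ifelse(out_trans > 0, diag(counts) / out_trans, NA_real_)
  switch_counts <- counts
  diag(switch_counts) <- 0L
  sw_tot <- rowSums(switch_counts)
  switch_matrix <- switch_counts / ifelse(sw_tot > 0, sw_tot, NA_real_)
  diag(switch_matrix) <- NA_real_
  dwell <- if (!is.null(labels_list)) {
    all_labels <- unlist(labels_list)
    tabulate(all_labels, nbins = kk) / length(all_labels)
  } else {
    colMeans(do.call(rbind, lapply(summaries, `[[`, "dwell_fraction")))
  }
  structure(
    list(dwell_fraction = stats::setNames(dwell, state_names),
         persistence = stats::setNames(persistence, state_names),
         switch_matrix = switch_matrix, transition_counts = counts,
         n_switches = sum(switch_counts),
         undefined_states = state_names[out_trans == 0]),
    class = "dwell_transition_summary")
}

#' First- versus second-half expression of a target state
#'
#' Splits each subject's window sequence at floor(W/2), computes the
#' frequency of the target state in each half, and runs a paired t-test
#' across subjects (second half minus first half).
#'
#' @param sequences named list (by subject) of `state_sequence` objects or
#'   label vectors; one sequence per subject.
#' @param target_state integer state index.
#' @return list with `per_subject` (data.frame: subject, first_half,
#'   second_half) and `test` (htest from [stats::t.test()], or `NULL`
#'   with a single subject).
#' @export
half_scan_comparison <- function(sequences, target_state) {
  freq <- t(vapply(sequences, function(s) {
    labels <- as_label_vector(s)$labels
    half <- length(labels) %/% 2L
    c(first = mean(labels[seq_len(half)] == target_state),
      second = mean(labels[(half + 1L):(2L * half)] == target_state))
  }, numeric(2)))
  per_subject <- data.frame(
    subject = if (!is.null(names(sequences))) names(sequences)
              else seq_along(sequences),
    first_half = freq[, "first"], second_half = freq[, "second"])
  diffs <- per_subject$second_half - per_subject$first_half
  test <- if (nrow(per_subject) > 1L && stats::sd(diffs) > 0)
    stats::t.test(per_subject$second_half, per_subject$first_half,
                  paired = TRUE)
  else NULL   # single subject, or constant paired differences
  list(per_subject = per_subject, test = test)
}

#' Per-subject mean connectivity profile of each state
#'
#' Element-wise mean of the subject's window edge vectors within each
#' assigned state ("collapse across all the state-S windows"). States the
#' subject never expressed are flagged absent, not zero-filled.
#'
#' @param wc_list one `windowed_fc` or a list of them (runs to pool).
#' @param seq_list matching `state_sequence`(s) from [assign_windows()].
#' @return object of class `subject_state_profile`: `profiles` (K x
#'   n_edge matrix, `NA` rows for absent states), `window_counts`,
#'   `absent_states`, `subject_id`, `k`.
#' @export
subject_state_profiles <- function(wc_list, seq_list) {
  if (inherits(wc_list, "windowed_fc")) wc_list <- list(wc_list)
  if (inherits(seq_list, "state_sequence")) seq_list <- list(seq_list)
  stopifnot(length(wc_list) == length(seq_list))
  k <- seq_list[[1L]]$k
  z <- do.call(rbind, lapply(wc_list, `[[`, "z_edges"))
  labels <- unlist(lapply(seq_list, `[[`, "labels"))
  stopifnot(nrow(z) == length(labels))
  state_names <- make_state_labels(k)
  profiles <- matrix(NA_real_, k, ncol(z),
                     dimnames = list(state_names, NULL))
  counts <- tabulate(labels, nbins = k)
  for (s in seq_len(k))
    if (counts[s] > 0)
      profiles[s, ] <- colMeans(z[labels == s, , drop = FALSE])
  structure(
    list(profiles = profiles,
         window_counts = stats::setNames(counts, state_names),
         absent_states = state_names[counts == 0],
         subject_id = wc_list[[1L]]$subject_id,
         visit_id = wc_list[[1L]]$visit_id, k = k),
    class = "subject_state_profile")
}

#' @export
print.subject_state_profile <- function(x, ...) {
  cat(sprintf("<subject_state_profile> %s (%s): K=%d, windows %s%s\n",
              x$subject_id, x$visit_id, x$k,
              paste(x$window_counts, collapse = "/"),
              if (length(x$absent_states))
                paste0(", absent: ",
                       paste(x$absent_states, collapse = ",")) else ""))
  invisible(x)
}
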