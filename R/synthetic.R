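#' Specification of a synthetic dynamic-connectivity cohort
#'
#' Describes a cohort of subjects whose region-level time series switch
#' among `n_states` latent covariance states via a Markov chain with an
#' attractor state, carry stable subject-specific connectivity
#' perturbations (fingerprints) reused across runs and visits, express
#' group-level reductions of within-network coupling confined to chosen
#' (state, network) cells, and — for patients — a binary active-psychosis
#' label generated from the true edge strengths of one designated symptom
#' state, so every downstream analysis has recoverable ground truth.
#'
#' Defaults mirror the acquisition geometry the pipeline targets: 114
#' regions (57 per hemisphere) spanning 17 networks, 120 usable time
#' points per run, four latent states of which state 1 is a muted
#' "attractor" with uniformly lower within-network coupling and elevated
#' inbound transition probability.
#'
#' @param n_regions number of regions (default 114).
#' @param n_networks number of networks (default 17); ignored when
#'   `network_labels` is supplied.
#' @param network_labels optional character vector, one network name per
#'   region.
#' @param n_states number of latent states K_true (default 4).
#' @param attractor_state index of the attractor (default 1).
#' @param transition_matrix K x K row-stochastic matrix; default favours
#'   the attractor (self-transition 0.97; other states 0.94 with two
#'   thirds of the leaving mass directed to the attractor), giving
#'   expected dwell runs well above the 11-point window width so that
#'   windowed correlations can resolve the latent states.
#' @param within_by_state K x n_networks matrix of within-network
#'   correlation block values; default gives the other states 0.25 with
#'   a boost to 0.60 on a state-specific subset of networks, and the
#'   attractor a muted (0.5x) copy of the average non-attractor profile
#'   — flat at ~0.18 within every network, i.e. uniformly lower than any
#'   other state's blocks.
#' @param between_by_state between-network couplings: either a length-K
#'   vector of flat baselines, or a list of K symmetric
#'   n_networks x n_networks matrices (diagonal ignored). The default
#'   gives each non-attractor state cohesive coupling (0.30) among its
#'   boosted networks, anticorrelation (-0.15) between the boosted set
#'   and the rest, and a 0.05 baseline elsewhere; the attractor gets a
#'   flat 0.03. State differences are thereby distributed across the
#'   whole matrix, as in empirical connectivity states, rather than
#'   confined to within-network blocks.
#' @param n_controls,n_patients cohort sizes (defaults 40 / 20).
#' @param fingerprint_sd SD of the subject-specific symmetric edge
#'   perturbation shared across states, runs and visits (default 0.02;
#'   kept small so that SPD repair of the perturbed covariance rarely
#'   binds and the planted centroids stay unbiased).
#' @param group_effect data.frame with columns `state`, `network`,
#'   `delta`: within-network correlation change applied to patients
#'   (default: none).
#' @param symptom_state state whose edges drive the symptom label
#'   (default 2).
#' @param symptom_edges integer edge indices (canonical ordering) carrying
#'   the symptom signature; default: the first 40 within-network edges of
#'   the first two networks.
#' @param symptom_effect_size logistic slope on standardized symptom-state
#'   network strength (default 2; 0 = label independent of edges).
#' @param symptom_perturbation_sd SD of the per-patient liability shift
#'   applied to symptom edges of the symptom state only (default 0.12).
#' @param n_timepoints usable time points per run (default 120).
#' @param runs_per_subject,visits_per_subject counts (defaults 1 / 1).
#' @param observation_noise_sd white measurement noise SD (default 0.3).
#' @param ar_coefficient optional AR(1) coefficient on state-conditional
#'   draws (default 0, no temporal smoothing).
#' @param window_width window width used to express ground-truth state
#'   sequences at window resolution (default 11).
#' @param panss_means,panss_sds named lists with `positive`, `negative`,
#'   `general` entries, each c(active, nonactive): generator means/SDs for
#'   PANSS-like scores (defaults 19.90/8.88 +/- 5.67/2.20 positive,
#'   13.98/10.18 +/- 7.76/3.93 negative, 31.46/26.53 +/- 7.81/7.74
#'   general).
#' @param seed integer seed for the whole cohort.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_regions = 114L, n_networks = 17L,
                        network_labels = NULL,
                        n_states = 4L, attractor_state = 1L,
                        transition_matrix = NULL,
                        within_by_state = NULL, between_by_state = NULL,
                        n_controls = 40L, n_patients = 20L,
                        fingerprint_sd = 0.02,
                        group_effect = NULL,
                        symptom_state = 2L, symptom_edges = NULL,
                        symptom_effect_size = 2,
                        symptom_perturbation_sd = 0.12,
                        n_timepoints = 120L, runs_per_subject = 1L,
                        visits_per_subject = 1L,
                        observation_noise_sd = 0.3,
                        ar_coefficient = 0,
                        window_width = 11L,
                        panss_means = NULL, panss_sds = NULL,
                        seed = 1L) {
  if (is.null(network_labels)) {
    network_labels <- default_network_labels(n_regions, n_networks)
  }
  if (length(network_labels) != n_regions)
    stopf("network_labels must cover all %d regions", n_regions)
  n_networks <- length(unique(network_labels))
  if (is.null(transition_matrix))
    transition_matrix <- attractor_transition_matrix(n_states, attractor_state)
  if (is.null(within_by_state))
    within_by_state <- default_within_blocks(n_states, n_networks,
                                             attractor_state)
  if (is.null(between_by_state))
    between_by_state <- default_between_blocks(n_states, n_networks,
                                               attractor_state)
  if (is.null(symptom_edges)) {
    nets <- unique(network_labels)
    tab <- edge_index_table(n_regions, network_labels = network_labels)
    cand <- which(tab$within_network &
                    tab$network_i %in% nets[seq_len(min(2L, length(nets)))])
    symptom_edges <- cand[seq_len(min(40L, length(cand)))]
  }
  if (is.null(group_effect))
    group_effect <- data.frame(state = integer(), network = character(),
                               delta = numeric())
  if (is.null(panss_means))
    panss_means <- list(positive = c(19.90, 8.88),
                        negative = c(13.98, 10.18),
                        general = c(31.46, 26.53))
  if (is.null(panss_sds))
    panss_sds <- list(positive = c(5.67, 2.20),
                      negative = c(7.76, 3.93),
                      general = c(7.81, 7.74))
  spec <- structure(
    list(n_regions = as.integer(n_regions),
         network_labels = as.character(network_labels),
         n_states = as.integer(n_states),
         attractor_state = as.integer(attractor_state),
         transition_matrix = transition_matrix,
         within_by_state = within_by_state,
         between_by_state = between_by_state,
         n_controls = as.integer(n_controls),
         n_patients = as.integer(n_patients),
         fingerprint_sd = fingerprint_sd,
         group_effect = group_effect,
         symptom_state = as.integer(symptom_state),
         symptom_edges = as.integer(symptom_edges),
         symptom_effect_size = symptom_effect_size,
         symptom_perturbation_sd = symptom_perturbation_sd,
         n_timepoints = as.integer(n_timepoints),
         runs_per_subject = as.integer(runs_per_subject),
         visits_per_subject = as.integer(visits_per_subject),
         observation_noise_sd = observation_noise_sd,
         ar_coefficient = ar_coefficient,
         window_width = as.integer(window_width),
         panss_means = panss_means, panss_sds = panss_sds,
         seed = as.integer(seed)),
    class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

# 114 regions / 17 networks get hemisphere-style names; otherwise networks
# are contiguous blocks of as-equal-as-possible size
default_network_labels <- function(n_regions, n_networks) {
  if (n_networks > n_regions)
    stopf("more networks (%d) than regions (%d)", n_networks, n_regions)
  if (n_regions %% 2L == 0L) {
    half <- n_regions %/% 2L
    per_hemi <- sort(rep_len(seq_len(n_networks), half))
    labels <- sprintf("Net%02d", c(per_hemi, per_hemi))
  } else {
    labels <- sprintf("Net%02d", sort(rep_len(seq_len(n_networks), n_regions)))
  }
  labels
}

# Self-transition 0.97 for the attractor and 0.94 elsewhere, with 2/3 of
# the leaving mass directed to the attractor. Expected dwell runs (~33
# and ~17 time points) comfortably exceed the 11-point window width:
# latent states must persist longer than the window for windowed
# correlations to express them, mirroring the quasi-stable expression of
# empirical brain states at the 33 s window scale.
attractor_transition_matrix <- function(n_states, attractor_state = 1L) {
  stopifnot(n_states >= 2L, attractor_state <= n_states)
  p <- matrix(0, n_states, n_states)
  for (s in seq_len(n_states)) {
    if (s == attractor_state) {
      p[s, ] <- (1 - 0.97) / (n_states - 1)
      p[s, s] <- 0.97
    } else {
      rest <- n_states - 2L
      p[s, ] <- if (rest > 0) (1 - 0.94 - 0.04) / rest else 0
      p[s, attractor_state] <- if (rest > 0) 0.04 else 0.06
      p[s, s] <- 0.94
    }
  }
  p
}

# Each non-attractor state "owns" an equally sized subset of networks;
# leftover networks stay at baseline in every state. Equal group sizes
# keep the non-attractor patterns mutually equidistant, so no state pair
# is systematically privileged when a too-small K forces a merge.
state_network_groups <- function(n_states, n_networks, attractor_state) {
  others <- setdiff(seq_len(n_states), attractor_state)
  per <- n_networks %/% length(others)
  if (per < 1L) stopf("need at least one network per non-attractor state")
  groups <- lapply(seq_along(others), function(g)
    ((g - 1L) * per + 1L):(g * per))
  names(groups) <- others
  groups
}

# The attractor is a muted (0.5x) copy of the average non-attractor
# pattern: flattened amplitude but globally structured, like the static
# connectivity pattern the most-occupied empirical state resembles.
default_within_blocks <- function(n_states, n_networks, attractor_state) {
  w <- matrix(0.25, n_states, n_networks)
  groups <- state_network_groups(n_states, n_networks, attractor_state)
  for (g in names(groups)) w[as.integer(g), groups[[g]]] <- 0.60
  others <- setdiff(seq_len(n_states), attractor_state)
  w[attractor_state, ] <- 0.5 * colMeans(w[others, , drop = FALSE])
  w
}

default_between_blocks <- function(n_states, n_networks, attractor_state) {
  groups <- state_network_groups(n_states, n_networks, attractor_state)
  out <- lapply(seq_len(n_states), function(k) {
    if (k == attractor_state) return(NULL)
    own <- seq_len(n_networks) %in% groups[[as.character(k)]]
    b <- matrix(0.05, n_networks, n_networks)
    b[own, own] <- 0.30
    b[own, !own] <- -0.15
    b[!own, own] <- -0.15
    b
  })
  others <- setdiff(seq_len(n_states), attractor_state)
  out[[attractor_state]] <- 0.5 * Reduce(`+`, out[others]) / length(others)
  out
}

validate_cohort_spec <- function(spec) {
  p <- spec$transition_matrix
  if (!is.matrix(p) || nrow(p) != spec$n_states || ncol(p) != spec$n_states)
    stopf("transition_matrix must be %d x %d", spec$n_states, spec$n_states)
  if (any(p < 0) || max(abs(rowSums(p) - 1)) > 1e-12)
    stopf("transition_matrix rows must be nonnegative and sum to 1")
  if (spec$fingerprint_sd < 0 || spec$observation_noise_sd < 0)
    stopf("noise SDs must be nonnegative")
  if (spec$n_timepoints < spec$window_width)
    stopf("n_timepoints (%d) must be >= window width (%d)",
          spec$n_timepoints, spec$window_width)
  if (spec$symptom_state > spec$n_states)
    stopf("symptom_state out of range")
  n_edge <- spec$n_regions * (spec$n_regions - 1L) / 2L
  if (length(spec$symptom_edges) &&
      (min(spec$symptom_edges) < 1 || max(spec$symptom_edges) > n_edge))
    stopf("symptom_edges out of range")
  invisible(spec)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "<cohort_spec> %d regions / %d networks, K_true=%d (attractor %d), %d controls + %d patients, %d tp x %d run(s) x %d visit(s)\n",
    x$n_regions, length(unique(x$network_labels)), x$n_states,
    x$attractor_state, x$n_controls, x$n_patients, x$n_timepoints,
    x$runs_per_subject, x$visits_per_subject))
  invisible(x)
}

#' Repair a symmetric matrix to a positive-definite correlation matrix
#'
#' Floors eigenvalues at `floor`, reconstructs, and renormalizes to unit
#' diagonal. Fails if the result is still not positive definite.
#'
#' @param m symmetric matrix.
#' @param floor eigenvalue floor (default 1e-6).
#' @return SPD correlation matrix (unit diagonal).
#' @export
spd_repair <- function(m, floor = 1e-6) {
  check_symmetric(m, what = "covariance")
  e <- eigen(m, symmetric = TRUE)
  vals <- pmax(e$values, floor)
  out <- e$vectors %*% (vals * t(e$vectors))
  out <- (out + t(out)) / 2
  d <- sqrt(diag(out))
  if (any(d <= 0)) stopf("SPD repair failed: nonpositive diagonal")
  out <- out / tcrossprod(d)
  diag(out) <- 1
  min_eig <- min(eigen(out, symmetric = TRUE, only.values = TRUE)$values)
  if (min_eig <= 0)
    stopf("SPD repair failed: min eigenvalue %.3g after renormalization",
          min_eig)
  out
}

#' Construct the latent state correlation matrices of a cohort spec
#'
#' Builds one region x region correlation matrix per state from the
#' within-network block values (`within_by_state`) and between-network
#' baseline (`between_by_state`), with unit diagonal, then repairs each to
#' SPD by eigenvalue flooring. The attractor state's uniformly lower
#' within-network blocks give it the muted, flattened connectivity profile
#' characteristic of the most-occupied state.
#'
#' @param spec a [cohort_spec()].
#' @return list of K SPD correlation matrices.
#' @export
generate_state_covariances <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  nets <- spec$network_labels
  uniq <- unique(nets)
  net_of <- match(nets, uniq)
  lapply(seq_len(spec$n_states), function(k) {
    if (is.list(spec$between_by_state)) {
      b <- spec$between_by_state[[k]]
      m <- b[net_of, net_of]
    } else {
      m <- matrix(spec$between_by_state[k], spec$n_regions,
                  spec$n_regions)
    }
    for (n in seq_along(uniq)) {
      in_net <- nets == uniq[n]
      m[in_net, in_net] <- spec$within_by_state[k, n]
    }
    diag(m) <- 1
    spd_repair(m)
  })
}

#' Simulate a latent Markov state sequence
#'
#' The initial state is drawn from the stationary distribution of the
#' chain; subsequent states follow the row-stochastic transition matrix.
#'
#' @param transition_matrix K x K row-stochastic matrix.
#' @param length sequence length.
#' @param seed integer seed (optional).
#' @return integer vector of state indices.
#' @export
simulate_state_sequence <- function(transition_matrix, length, seed = NULL) {
  p <- transition_matrix
  if (!is.matrix(p) || nrow(p) != ncol(p))
    stopf("transition matrix must be square")
  if (any(p < 0) || max(abs(rowSums(p) - 1)) > 1e-8)
    stopf("transition matrix rows must sum to 1")
  k <- nrow(p)
  with_seed(seed, {
    pi0 <- stationary_distribution(p)
    s <- integer(length)
    s[1L] <- sample.int(k, 1L, prob = pi0)
    if (length > 1L)
      for (t in 2:length) s[t] <- sample.int(k, 1L, prob = p[s[t - 1L], ])
    s
  })
}

#' Stationary distribution of a finite Markov chain
#'
#' Left eigenvector of the transition matrix for eigenvalue 1, normalized
#' to sum to 1.
#'
#' @param transition_matrix row-stochastic matrix.
#' @return probability vector.
#' @export
stationary_distribution <- function(transition_matrix) {
  e <- eigen(t(transition_matrix))
  i <- which.min(abs(e$values - 1))
  v <- abs(Re(e$vectors[, i]))
  v / sum(v)
}

# subject-specific symmetric perturbation added to every state covariance
draw_fingerprint <- function(n_regions, sd) {
  f <- matrix(0, n_regions, n_regions)
  if (sd > 0) {
    vals <- stats::rnorm(n_regions * (n_regions - 1L) / 2L, 0, sd)
    f[lower.tri(f)] <- vals
    f <- f + t(f)
  }
  f
}

# per-subject effective state covariances: base + fingerprint (+ patient
# group deltas + symptom liability shift), SPD-repaired
effective_state_covariances <- function(spec, base_covs, fingerprint,
                                        group, symptom_liability = 0) {
  nets <- spec$network_labels
  lapply(seq_len(spec$n_states), function(k) {
    m <- base_covs[[k]] + fingerprint
    if (group == "patient" && nrow(spec$group_effect)) {
      ge <- spec$group_effect[spec$group_effect$state == k, , drop = FALSE]
      for (r in seq_len(nrow(ge))) {
        in_net <- nets == ge$network[r]
        blk <- m[in_net, in_net]
        blk <- blk + ge$delta[r]
        diag(blk) <- 1
        m[in_net, in_net] <- blk
      }
    }
    if (group == "patient" && k == spec$symptom_state &&
        length(spec$symptom_edges) && symptom_liability != 0) {
      lt <- which(lower.tri(m))
      sel <- lt[spec$symptom_edges]
      m[sel] <- m[sel] + spec$symptom_perturbation_sd * symptom_liability
      m <- (m + t(m)) / 2
      m[lower.tri(m)] <- t(m)[lower.tri(m)]  # keep exact symmetry
    }
    diag(m) <- 1
    m <- pmin(pmax(m, -0.97), 0.97)
    diag(m) <- 1
    spd_repair(m)
  })
}

#' Simulate all runs of one subject
#'
#' Each time point is drawn from the zero-mean Gaussian of its latent
#' state's covariance (the subject's effective covariance: base state plus
#' fingerprint plus any patient-specific deltas, SPD-repaired), with an
#' optional AR(1) smoothing of the state-conditional draws and white
#' observation noise added. The fingerprint is drawn once per subject and
#' reused across every run and visit.
#'
#' @param spec a [cohort_spec()].
#' @param subject list with `subject_id`, `group` (`"control"`/
#'   `"patient"`), `fingerprint` (region x region symmetric matrix) and
#'   optional `symptom_liability` scalar.
#' @param seed integer seed.
#' @param base_covs optional precomputed [generate_state_covariances()]
#'   output.
#' @return list with `runs` (list over visits of lists of `parcel_ts`),
#'   `state_sequences` (matching nested list of time-point-resolution
#'   latent states), and `effective_covariances`.
#' @export
simulate_subject_timeseries <- function(spec, subject, seed = NULL,
                                        base_covs = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(base_covs)) base_covs <- generate_state_covariances(spec)
  covs <- effective_state_covariances(
    spec, base_covs, subject$fingerprint, subject$group,
    symptom_liability = subject$symptom_liability %||% 0)
  chols <- lapply(covs, chol)
  with_seed(seed, {
    runs <- vector("list", spec$visits_per_subject)
    seqs <- vector("list", spec$visits_per_subject)
    for (v in seq_len(spec$visits_per_subject)) {
      runs[[v]] <- vector("list", spec$runs_per_subject)
      seqs[[v]] <- vector("list", spec$runs_per_subject)
      for (r in seq_len(spec$runs_per_subject)) {
        s <- simulate_state_sequence(spec$transition_matrix,
                                     spec$n_timepoints)
        x <- matrix(0, spec$n_timepoints, spec$n_regions)
        innov <- matrix(stats::rnorm(spec$n_timepoints * spec$n_regions),
                        spec$n_timepoints)
        for (k in seq_len(spec$n_states)) {
          idx <- which(s == k)
          if (length(idx))
            x[idx, ] <- innov[idx, , drop = FALSE] %*% chols[[k]]
        }
        if (spec$ar_coefficient != 0) {
          rho <- spec$ar_coefficient
          for (t in 2:spec$n_timepoints)
            x[t, ] <- rho * x[t - 1L, ] + sqrt(1 - rho^2) * x[t, ]
        }
        if (spec$observation_noise_sd > 0)
          x <- x + matrix(stats::rnorm(length(x), 0,
                                       spec$observation_noise_sd),
                          nrow(x))
        runs[[v]][[r]] <- parcel_time_series(
          x, region_ids = sprintf("R%03d", seq_len(spec$n_regions)),
          network_labels = spec$network_labels,
          subject_id = subject$subject_id,
          run_id = sprintf("run%d", r), visit_id = sprintf("visit%d", v))
        seqs[[v]][[r]] <- s
      }
    }
    list(runs = runs, state_sequences = seqs,
         effective_covariances = covs)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Majority latent state within each sliding window
#'
#' Windows blur time-point-resolution transitions; ground truth at window
#' resolution is the state occupying the majority of the window's time
#' points, ties broken by the state at the window's centre time point,
#' then by lowest state index.
#'
#' @param state_sequence integer latent states at time-point resolution.
#' @param width,stride window geometry.
#' @return integer vector of length `window_count(T, width, stride)`.
#' @export
window_majority_states <- function(state_sequence, width = 11L,
                                   stride = 1L) {
  tt <- length(state_sequence)
  starts <- seq.int(1L, tt - width + 1L, by = stride)
  vapply(starts, function(s0) {
    seg <- state_sequence[s0:(s0 + width - 1L)]
    tab <- table(seg)
    top <- as.integer(names(tab)[tab == max(tab)])
    if (length(top) == 1L) return(top)
    centre <- seg[(width + 1L) %/% 2L]
    if (centre %in% top) centre else min(top)
  }, integer(1))
}

#' Generate a full synthetic cohort with ground truth
#'
#' Produces `n_controls + n_patients` subject records. Patients receive an
#' `active_psychosis` label drawn from the same logistic model the
#' prediction module fits — probability `plogis(effect * s)` where `s` is
#' the standardized sum of the subject's true symptom-state edge z-values
#' over the planted symptom edges — so the planted signal is recoverable
#' by construction. PANSS-like positive/negative/general scores are drawn
#' with higher means for active subjects.
#'
#' @param spec a [cohort_spec()].
#' @return list with `subjects` (list of subject records, each holding
#'   `subject_id`, `group`, `covariates`, `active_psychosis`, `panss`,
#'   `runs`) and `ground_truth` (`true_centroids` as K x n_edge z-matrix,
#'   `state_sequences` at time-point and window resolution,
#'   `fingerprints`, `symptom_edges`, `symptom_state`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_sub <- spec$n_controls + spec$n_patients
  if (n_sub < 1L) stopf("cohort must contain at least one subject")
  base_covs <- generate_state_covariances(spec)
  groups <- c(rep("control", spec$n_controls),
              rep("patient", spec$n_patients))
  ids <- sprintf("sub%03d", seq_len(n_sub))

  subjects <- vector("list", n_sub)
  truth_seq <- vector("list", n_sub)
  fingerprints <- vector("list", n_sub)

  meta <- with_seed(child_seed(spec$seed, 1L), {
    list(age = round(stats::rnorm(n_sub, 35, 12), 1),
         sex = stats::rbinom(n_sub, 1L, 0.5),
         motion = round(abs(stats::rnorm(n_sub, 0.05, 0.02)), 4),
         liability = stats::rnorm(n_sub))  # used for patients only
  })

  # true symptom-state strengths accumulate for label standardization
  strengths <- numeric(n_sub)
  sims <- vector("list", n_sub)
  lt_idx <- which(lower.tri(matrix(0, spec$n_regions, spec$n_regions)))

  for (i in seq_len(n_sub)) {
    fp <- with_seed(child_seed(spec$seed, 100L + i),
                    draw_fingerprint(spec$n_regions, spec$fingerprint_sd))
    fingerprints[[i]] <- fp
    subj <- list(subject_id = ids[i], group = groups[i], fingerprint = fp,
                 symptom_liability = if (groups[i] == "patient")
                   meta$liability[i] else 0)
    sims[[i]] <- simulate_subject_timeseries(
      spec, subj, seed = child_seed(spec$seed, 1000L + i),
      base_covs = base_covs)
    if (length(spec$symptom_edges)) {
      sig <- sims[[i]]$effective_covariances[[spec$symptom_state]]
      strengths[i] <- sum(fisher_z(sig[lt_idx][spec$symptom_edges]))
    }
    subjects[[i]] <- subj
  }

  pat <- which(groups == "patient")
  active <- rep(NA_integer_, n_sub)
  panss <- vector("list", n_sub)
  if (length(pat)) {
    s_pat <- strengths[pat]
    sd_pat <- if (length(s_pat) > 1L) stats::sd(s_pat) else 0
    s_std <- if (is.finite(sd_pat) && sd_pat > 0)
      (s_pat - mean(s_pat)) / sd_pat else rep(0, length(pat))
    with_seed(child_seed(spec$seed, 2L), {
      p_active <- stats::plogis(spec$symptom_effect_size * s_std)
      active[pat] <- stats::rbinom(length(pat), 1L, p_active)
      for (jj in seq_along(pat)) {
        i <- pat[jj]
        a <- active[i] == 1L
        draw <- function(scale, lo) {
          mu <- spec$panss_means[[scale]][if (a) 1L else 2L]
          sdv <- spec$panss_sds[[scale]][if (a) 1L else 2L]
          max(lo, round(stats::rnorm(1L, mu, sdv)))
        }
        panss[[i]] <- c(positive = draw("positive", 7),
                        negative = draw("negative", 7),
                        general = draw("general", 16))
      }
    })
  }

  for (i in seq_len(n_sub)) {
    subjects[[i]]$covariates <- c(age = meta$age[i], sex = meta$sex[i],
                                  motion = meta$motion[i])
    subjects[[i]]$active_psychosis <- active[i]
    subjects[[i]]$panss <- panss[[i]]
    subjects[[i]]$runs <- sims[[i]]$runs
    subjects[[i]]$fingerprint <- NULL
    truth_seq[[i]] <- lapply(sims[[i]]$state_sequences, function(v)
      lapply(v, function(s)
        list(timepoint = s,
             window = window_majority_states(s, spec$window_width))))
  }
  names(subjects) <- ids
  names(truth_seq) <- ids
  names(fingerprints) <- ids

  true_centroids <- t(vapply(base_covs, function(m) fisher_z(m[lt_idx]),
                             numeric(length(lt_idx))))
  list(subjects = subjects,
       ground_truth = list(true_centroids = true_centroids,
                           state_sequences = truth_seq,
                           fingerprints = fingerprints,
                           symptom_edges = spec$symptom_edges,
                           symptom_state = spec$symptom_state,
                           symptom_strengths = strengths,
                           base_covariances = base_covs),
       spec = spec)
}

#' Write a cohort to disk
#'
#' One TSV per run (header = region ids, rows = time points), a manifest
#' CSV (subject, group, covariates, labels, file paths) and a
#' ground-truth JSON.
#'
#' @param cohort output of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return the manifest data.frame, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (subj in cohort$subjects) {
    for (v in seq_along(subj$runs)) for (r in seq_along(subj$runs[[v]])) {
      ts <- subj$runs[[v]][[r]]
      fn <- sprintf("%s_visit%d_run%d.tsv", subj$subject_id, v, r)
      write_parcel_tsv(ts, file.path(dir, fn))
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = subj$subject_id, group = subj$group,
        visit = v, run = r,
        age = subj$covariates[["age"]], sex = subj$covariates[["sex"]],
        motion = subj$covariates[["motion"]],
        active_psychosis = subj$active_psychosis,
        panss_positive = if (is.null(subj$panss)) NA else
          subj$panss[["positive"]],
        panss_negative = if (is.null(subj$panss)) NA else
          subj$panss[["negative"]],
        panss_general = if (is.null(subj$panss)) NA else
          subj$panss[["general"]],
        path = fn)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  gt <- cohort$ground_truth
  jsonlite::write_json(
    list(symptom_state = gt$symptom_state,
         symptom_edges = gt$symptom_edges,
         true_centroids = gt$true_centroids,
         state_sequences = lapply(gt$state_sequences, function(s)
           lapply(s, function(v) lapply(v, `[[`, "timepoint"))),
         network_labels = cohort$spec$network_labels),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = 8)
  invisible(manifest)
}
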