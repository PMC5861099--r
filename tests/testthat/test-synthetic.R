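test_that("state covariances are SPD with unit diagonal and a muted attractor", {
  spec <- tiny_spec()
  covs <- generate_state_covariances(spec)
  expect_length(covs, spec$n_states)
  nets <- spec$network_labels
  within_means <- sapply(covs, function(m) {
    vals <- c()
    for (nw in unique(nets)) {
      i <- nets == nw
      vals <- c(vals, m[i, i][upper.tri(m[i, i])])
    }
    mean(vals)
  })
  # attractor (state 1) has the lowest within-network coupling
  expect_equal(which.min(within_means), 1L)
  for (m in covs) {
    expect_equal(diag(m), rep(1, spec$n_regions))
    expect_equal(m, t(m), tolerance = 1e-12)
    # eigensolver oracle: strictly positive spectrum
    expect_gt(min(eigen(m, symmetric = TRUE, only.values = TRUE)$values),
              0)
  }
})

test_that("degenerate block settings reproduce identity and plain blocks", {
  spec <- tiny_spec(within_by_state = matrix(0, 3, 4),
                    between_by_state = rep(0, 3))
  covs <- generate_state_covariances(spec)
  for (m in covs) expect_equal(m, diag(24), tolerance = 1e-12)
  spec2 <- tiny_spec(within_by_state = rbind(c(0.5, 0, 0, 0),
                                             matrix(0, 2, 4)),
                     between_by_state = rep(0, 3))
  m1 <- generate_state_covariances(spec2)[[1]]
  net1 <- spec2$network_labels == unique(spec2$network_labels)[1]
  off <- m1[net1, net1][upper.tri(m1[net1, net1])]
  expect_true(all(abs(off - 0.5) < 1e-9))
})

test_that("spd repair floors eigenvalues and errors stay informative", {
  m <- toy_symmetric(6, seed = 9) * 2   # indefinite
  diag(m) <- 1
  rep_m <- spd_repair(m)
  expect_gt(min(eigen(rep_m, symmetric = TRUE,
                      only.values = TRUE)$values), 0)
  expect_equal(diag(rep_m), rep(1, 6))
  expect_error(spd_repair(matrix(1:6, 2, 3)), "square")
})

test_that("markov sequences follow the chain law", {
  # absorbing case
  s <- simulate_state_sequence(diag(3), 50, seed = 1)
  expect_length(unique(s), 1L)
  # law of large numbers under the uniform 4-state chain
  p_unif <- matrix(0.25, 4, 4)
  s2 <- simulate_state_sequence(p_unif, 1e5, seed = 2)
  expect_true(all(abs(tabulate(s2, 4) / 1e5 - 0.25) < 0.01))
  # stationary-eigenvector oracle: sticky state dwells most
  p <- matrix(0.4 / 2, 3, 3)
  diag(p) <- 0
  p[1, 2:3] <- 0.05
  diag(p) <- 1 - rowSums(p)
  pi_oracle <- stationary_distribution(p)
  expect_equal(sum(pi_oracle), 1, tolerance = 1e-12)
  s3 <- simulate_state_sequence(p, 1e5, seed = 3)
  freq <- tabulate(s3, 3) / 1e5
  expect_equal(freq, as.numeric(pi_oracle), tolerance = 0.02)
  expect_equal(which.max(freq), 1L)
  expect_error(simulate_state_sequence(matrix(1, 2, 2), 10), "sum to 1")
})

test_that("empirical transition matrix converges to the specification", {
  spec <- tiny_spec()
  s <- simulate_state_sequence(spec$transition_matrix, 1e5, seed = 4)
  emp <- prop.table(table(factor(s[-1e5], 1:3), factor(s[-1], 1:3)), 1)
  expect_lt(max(abs(emp - spec$transition_matrix)), 0.02)
})

test_that("subject simulation is deterministic and respects the fingerprint", {
  spec <- tiny_spec()
  base <- generate_state_covariances(spec)
  subj <- list(subject_id = "sX", group = "control",
               fingerprint = matrix(0, 24, 24), symptom_liability = 0)
  a <- simulate_subject_timeseries(spec, subj, seed = 7, base_covs = base)
  b <- simulate_subject_timeseries(spec, subj, seed = 7, base_covs = base)
  expect_identical(a$runs[[1]][[1]]$values, b$runs[[1]][[1]]$values)
  # zero fingerprint: effective covariances equal the base states
  for (k in 1:3)
    expect_equal(a$effective_covariances[[k]], base[[k]],
                 tolerance = 1e-8)
})

test_that("single-state sampling matches its covariance", {
  spec <- tiny_spec(n_states = 2,
                    transition_matrix = matrix(c(1, 0, 1, 0), 2,
                                               byrow = TRUE),
                    observation_noise_sd = 0, n_timepoints = 10000L,
                    fingerprint_sd = 0)
  base <- generate_state_covariances(spec)
  subj <- list(subject_id = "s", group = "control",
               fingerprint = matrix(0, 24, 24), symptom_liability = 0)
  sim <- simulate_subject_timeseries(spec, subj, seed = 5,
                                     base_covs = base)
  emp <- cor(sim$runs[[1]][[1]]$values)
  expect_lt(max(abs(emp - base[[1]])), 0.05)
})

test_that("window majority truth respects length and tie rules", {
  s <- c(rep(1, 20), rep(2, 20))
  wm <- window_majority_states(s, width = 11)
  expect_length(wm, 30)
  expect_equal(wm[1], 1L)
  expect_equal(wm[30], 2L)
  # exact tie impossible with odd width; centre rule exercised via mix
  s2 <- c(1, 1, 2, 2, 1, 2, 1, 2, 2, 1, 1)
  expect_equal(window_majority_states(s2, 11), 1L)
})

test_that("cohort generation produces coherent records and ground truth", {
  spec <- tiny_spec(n_controls = 3, n_patients = 2)
  coh <- generate_cohort(spec)
  expect_length(coh$subjects, 5)
  groups <- vapply(coh$subjects, `[[`, character(1), "group")
  expect_equal(as.vector(table(groups)[c("control", "patient")]),
               c(3L, 2L))
  gt1 <- coh$ground_truth$state_sequences[[1]][[1]][[1]]
  expect_length(gt1$timepoint, spec$n_timepoints)
  expect_length(gt1$window, spec$n_timepoints - spec$window_width + 1)
  # controls have no psychosis label; patients do
  expect_true(all(is.na(vapply(coh$subjects[groups == "control"], `[[`,
                               integer(1), "active_psychosis"))))
  expect_true(all(vapply(coh$subjects[groups == "patient"], `[[`,
                         integer(1), "active_psychosis") %in% 0:1))
  # determinism
  coh2 <- generate_cohort(spec)
  expect_identical(coh$subjects[[4]]$runs[[1]][[1]]$values,
                   coh2$subjects[[4]]$runs[[1]][[1]]$values)
  expect_error(generate_cohort(tiny_spec(n_controls = 0, n_patients = 0)),
               "at least one subject")
})

test_that("active patients get higher PANSS positive scores", {
  spec <- tiny_spec(n_controls = 0, n_patients = 60, n_timepoints = 30,
                    n_regions = 12, n_networks = 3)
  coh <- generate_cohort(spec)
  act <- vapply(coh$subjects, `[[`, integer(1), "active_psychosis")
  pos <- vapply(coh$subjects, function(s) s$panss[["positive"]],
                numeric(1))
  expect_true(all(c(0L, 1L) %in% act))  # seeded draw yields both classes
  expect_gt(mean(pos[act == 1]), mean(pos[act == 0]))
})

test_that("fingerprints persist across visits more than between subjects", {
  spec <- tiny_spec(n_controls = 12, n_patients = 0,
                    visits_per_subject = 2, fingerprint_sd = 0.05,
                    observation_noise_sd = 0.1)
  coh <- generate_cohort(spec)
  # within-subject visit pairs share the fingerprint exactly by design
  fp <- coh$ground_truth$fingerprints
  expect_length(fp, 12)
  offdiag <- function(m) m[lower.tri(m)]
  within_sd <- sd(offdiag(fp[[1]]))
  expect_gt(within_sd, 0)
  # mean connectivity across visits correlates more within subject
  mean_conn <- function(sub, v)
    rowMeans(sapply(sub$runs[[v]], function(ts)
      vectorize_connectivity(cor(ts$values))))
  v1 <- sapply(coh$subjects, mean_conn, v = 1)
  v2 <- sapply(coh$subjects, mean_conn, v = 2)
  cc <- cor(v1, v2)
  expect_gt(mean(diag(cc)), mean(cc[row(cc) != col(cc)]))
})

test_that("cohort writes TSV, manifest and ground truth to disk", {
  spec <- tiny_spec(n_controls = 2, n_patients = 1, n_timepoints = 20)
  coh <- generate_cohort(spec)
  dir <- tempfile("cohort")
  on.exit(unlink(dir, recursive = TRUE))
  manifest <- write_cohort(coh, dir)
  expect_equal(nrow(manifest), 3)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  ts <- read_parcel_tsv(file.path(dir, manifest$path[1]))
  expect_equal(ts$values, coh$subjects[[1]]$runs[[1]][[1]]$values,
               tolerance = 1e-6)
})

test_that("null symptom effect leaves the label unrelated to edge strength", {
  spec <- tiny_spec(n_controls = 0, n_patients = 100, n_timepoints = 20,
                    n_regions = 12, n_networks = 3,
                    symptom_effect_size = 0)
  coh <- generate_cohort(spec)
  act <- vapply(coh$subjects, `[[`, integer(1), "active_psychosis")
  s <- coh$ground_truth$symptom_strengths
  expect_gt(sd(act), 0)  # seeded draw yields both classes
  expect_lt(abs(cor(s, act)), 0.2)
})
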