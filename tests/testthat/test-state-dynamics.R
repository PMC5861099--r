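make_atlas <- function(centroids) {
  k <- nrow(centroids)
  structure(list(k = k, centroids = centroids,
                 state_labels = LETTERS[seq_len(k)],
                 occupancy = rep(1 / k, k), assignments = integer(0),
                 objective = 0, pooled_window_count = 0L, seed = 1L,
                 n_restarts = 1L), class = "state_atlas")
}

make_wc <- function(z, subject = "s1", visit = "visit1", run = "run1") {
  structure(list(z_edges = z, window_width = 11L, stride = 1L,
                 window_start_indices = seq_len(nrow(z)),
                 region_ids = NULL, network_labels = NULL,
                 subject_id = subject, run_id = run, visit_id = visit),
            class = "windowed_fc")
}

test_that("window assignment picks the nearest centroid with tie to lowest index", {
  set.seed(50)
  cent <- matrix(rnorm(3 * 40), 3)
  atlas <- make_atlas(cent)
  # atlas centroids assigned to themselves: identity labeling
  sq <- assign_windows(make_wc(cent), atlas)
  expect_equal(sq$labels, 1:3)
  # exact equidistance: window correlating equally with A and B -> A
  v <- rnorm(40)
  atlas2 <- make_atlas(rbind(v, v, rnorm(40)))
  sq2 <- assign_windows(make_wc(matrix(v, 1)), atlas2)
  expect_equal(sq2$labels, 1L)
  expect_error(assign_windows(make_wc(matrix(rnorm(10), 1)), atlas),
               "dimension mismatch")
})

test_that("dwell fractions match hand counts", {
  expect_equal(dwell_fractions(c(1, 1, 2, 2, 1), k = 2),
               c(A = 0.6, B = 0.4))
  expect_equal(dwell_fractions(rep(1, 7), k = 3),
               c(A = 1, B = 0, C = 0))
  expect_equal(sum(dwell_fractions(sample(1:4, 100, TRUE), k = 4)), 1,
               tolerance = 1e-12)
  # odds variant exposed but distinct
  expect_equal(unname(dwell_fractions(c(1, 1, 2, 2, 1), k = 2,
                                      mode = "odds")),
               c(3 / 2, 2 / 3))
  expect_error(dwell_fractions(integer(0), k = 2), "empty")
})

test_that("transition statistics match hand counts and flag unvisited states", {
  # AAB: persistence(A) = 1/2, switch row A -> B = 1
  s <- transition_statistics(c(1, 1, 2), k = 2)
  expect_equal(s$persistence[["A"]], 0.5)
  expect_equal(s$switch_matrix["A", "B"], 1)
  expect_true(is.na(s$persistence[["B"]]))  # B never left
  expect_equal(s$undefined_states, "B")
  # ABABAB: persistence 0, switches certain
  s2 <- transition_statistics(c(1, 2, 1, 2, 1, 2), k = 2)
  expect_equal(unname(s2$persistence), c(0, 0))
  expect_equal(s2$switch_matrix["A", "B"], 1)
  expect_equal(s2$switch_matrix["B", "A"], 1)
  expect_equal(s2$n_switches, 5)
  # defined rows sum to 1
  set.seed(51)
  s3 <- transition_statistics(sample(1:3, 500, TRUE), k = 3)
  expect_equal(unname(rowSums(s3$switch_matrix, na.rm = TRUE)),
               rep(1, 3), tolerance = 1e-12)
  expect_equal(sum(s3$dwell_fraction), 1, tolerance = 1e-12)
})

test_that("long-chain estimates recover the generating matrix (count oracle)", {
  p <- matrix(c(0.8, 0.15, 0.05,
                0.1, 0.7, 0.2,
                0.25, 0.25, 0.5), 3, byrow = TRUE)
  s <- simulate_state_sequence(p, 1e5, seed = 52)
  st <- transition_statistics(s, k = 3)
  # dwell close to stationary distribution (eigenvector oracle)
  expect_equal(unname(st$dwell_fraction),
               as.numeric(stationary_distribution(p)), tolerance = 0.01)
  # persistence and conditional switch probabilities within 0.02
  for (i in 1:3) {
    expect_lt(abs(st$persistence[[i]] - p[i, i]), 0.02)
    for (j in setdiff(1:3, i))
      expect_lt(abs(st$switch_matrix[i, j] - p[i, j] / (1 - p[i, i])),
                0.02)
  }
})

test_that("pooled summaries never bridge run boundaries", {
  r1 <- c(1, 1, 1, 2)
  r2 <- c(2, 2, 1, 1)
  pooled <- pool_transition_summaries(
    list(transition_statistics(r1, k = 2),
         transition_statistics(r2, k = 2)),
    labels_list = list(r1, r2))
  # total transitions = (4-1) + (4-1) = 6, not 7
  expect_equal(sum(pooled$transition_counts), 6)
  expect_equal(unname(pooled$dwell_fraction), c(0.625, 0.375))
})

test_that("half-scan comparison detects asymmetric expression", {
  seqs <- list(s1 = c(rep(2, 10), rep(1, 10)),
               s2 = c(rep(2, 10), rep(1, 10)))
  hs <- half_scan_comparison(seqs, target_state = 1)
  expect_equal(hs$per_subject$first_half, c(0, 0))
  expect_equal(hs$per_subject$second_half, c(1, 1))
  expect_null(hs$test)  # constant paired differences carry no test
  # single subject: no test
  hs1 <- half_scan_comparison(seqs[1], target_state = 1)
  expect_null(hs1$test)
  # time-homogeneous null: roughly calibrated p-values
  set.seed(53)
  pvals <- replicate(40, {
    seqs_null <- lapply(1:12, function(i)
      simulate_state_sequence(matrix(0.5, 2, 2), 60))
    half_scan_comparison(seqs_null, 1)$test$p.value
  })
  expect_gt(mean(pvals > 0.01), 0.85)
})

test_that("subject state profiles average the right windows", {
  set.seed(54)
  z <- matrix(rnorm(6 * 20), 6)
  labels <- c(1, 2, 1, 2, 2, 1)
  wc <- make_wc(z)
  sq <- structure(list(labels = labels, state_labels = c("A", "B"),
                       k = 2L, subject_id = "s1", visit_id = "visit1",
                       run_id = "run1"), class = "state_sequence")
  prof <- subject_state_profiles(wc, sq)
  expect_equal(unname(prof$profiles["A", ]),
               colMeans(z[labels == 1, ]), tolerance = 1e-12)
  expect_equal(unname(prof$window_counts), c(3L, 3L))
  # absent state flagged, not zero-filled
  sq$labels <- rep(1L, 6)
  prof2 <- subject_state_profiles(wc, sq)
  expect_equal(prof2$absent_states, "B")
  expect_true(all(is.na(prof2$profiles["B", ])))
  # concatenated runs equal the weighted mean of run-wise profiles
  z2 <- matrix(rnorm(4 * 20), 4)
  lab2 <- c(1, 1, 2, 1)
  sq2 <- sq; sq2$labels <- lab2
  sqa <- sq; sqa$labels <- labels
  both <- subject_state_profiles(list(wc, make_wc(z2)),
                                 list(sqa, sq2))
  pa <- subject_state_profiles(wc, sqa)
  pb <- subject_state_profiles(make_wc(z2), sq2)
  w_a <- pa$window_counts["A"]; w_b <- pb$window_counts["A"]
  expect_equal(both$profiles["A", ],
               (pa$profiles["A", ] * w_a + pb$profiles["A", ] * w_b) /
                 (w_a + w_b), tolerance = 1e-12)
})
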