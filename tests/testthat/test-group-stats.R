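test_that("residualization removes covariate structure", {
  set.seed(70)
  n <- 200
  x <- rnorm(n)
  # orthogonal covariate: residuals are just the centered response
  y <- rnorm(n)
  z <- residualize_covariates(y, data.frame(x = rnorm(n)))
  expect_equal(cor(z, y), 1, tolerance = 0.05)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  # response equal to covariate: residuals vanish
  expect_lt(max(abs(residualize_covariates(x, data.frame(x = x)))),
            1e-10)
  # planted linear model: residual variance approaches var(e)
  e <- rnorm(500, 0, 0.5)
  x2 <- rnorm(500)
  res <- residualize_covariates(2 * x2 + e, data.frame(x = x2))
  expect_equal(var(res), 0.25, tolerance = 0.06)
  # rank deficiency is named
  expect_error(residualize_covariates(y, data.frame(a = x, b = 2 * x)),
               "collinear.*b")
})

test_that("bh_fdr implements the step-up rule (hand oracle)", {
  r <- bh_fdr(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
  expect_true(all(r$mask))
  expect_equal(bh_fdr(rep(1, 6), 0.05)$n_rejected, 0)
  expect_true(bh_fdr(0.04, 0.05)$mask)
  # oracle: independent step-up scan + p.adjust agreement
  set.seed(71)
  for (trial in 1:20) {
    p <- runif(50)^2
    r2 <- bh_fdr(p, 0.05)
    expect_equal(r2$q_values, p.adjust(p, "BH"), tolerance = 1e-12)
    ord <- order(p)
    k <- suppressWarnings(max(which(sort(p) <= seq_len(50) * 0.05 / 50)))
    expected <- logical(50)
    if (is.finite(k)) expected[ord[seq_len(k)]] <- TRUE
    expect_equal(r2$mask, expected)
  }
  # mask invariant to input order
  p <- runif(30)
  perm <- sample(30)
  expect_equal(bh_fdr(p, 0.05)$mask[perm], bh_fdr(p[perm], 0.05)$mask)
  expect_error(bh_fdr(numeric(0)), "empty")
  expect_error(bh_fdr(c(0.1, 1.2)), "0, 1")
})

make_profiles <- function(mat, k = 1) {
  # mat: subjects x edges for the single state
  out <- lapply(seq_len(nrow(mat)), function(i) {
    m <- matrix(NA_real_, k, ncol(mat))
    m[1, ] <- mat[i, ]
    m
  })
  names(out) <- sprintf("sub%03d", seq_len(nrow(mat)))
  out
}

test_that("edgewise tests are antisymmetric and null-clean", {
  set.seed(72)
  n <- 30
  mat <- matrix(rnorm(n * 80), n)
  groups <- rep(c("control", "patient"), each = n / 2)
  covs <- data.frame(age = rnorm(n))
  r1 <- edgewise_group_differences(make_profiles(mat), groups, covs, 1)
  # label swap negates estimates and t exactly (covariates unchanged)
  r2 <- edgewise_group_differences(make_profiles(mat),
                                   rev(groups), covs, 1)
  expect_equal(r1$estimate, -r2$estimate, tolerance = 1e-10)
  expect_equal(r1$t, -r2$t, tolerance = 1e-10)
  # identical groups: duplicated data -> zero estimates
  dup <- rbind(mat[1:15, ], mat[1:15, ])
  r3 <- edgewise_group_differences(make_profiles(dup), groups, NULL, 1)
  expect_lt(max(abs(r3$estimate)), 1e-12)
  expect_equal(sum(r3$mask), 0)
})

test_that("planted edge effects are detected with FDR control", {
  set.seed(73)
  n <- 200
  n_edges <- 300
  planted <- 1:50
  mat <- matrix(rnorm(n * n_edges), n)
  groups <- rep(c("control", "patient"), each = n / 2)
  mat[groups == "patient", planted] <-
    mat[groups == "patient", planted] - 0.8
  r <- edgewise_group_differences(make_profiles(mat), groups, NULL, 1)
  sens <- mean(planted %in% which(r$mask))
  fdp <- if (sum(r$mask)) mean(!(which(r$mask) %in% planted)) else 0
  expect_gte(sens, 0.8)
  expect_lte(fdp, 0.15)
  # control > patient on planted edges: positive estimates
  expect_true(all(r$estimate[planted][r$mask[planted]] > 0))
})

test_that("network-level tests flag only the planted cell", {
  set.seed(74)
  n <- 120
  n_regions <- 12
  labels <- rep(c("N1", "N2", "N3"), each = 4)
  n_edges <- n_regions * (n_regions - 1) / 2
  tab <- edge_index_table(n_regions, network_labels = labels)
  base <- matrix(rnorm(n * n_edges, 0, 0.3), n)
  groups <- rep(c("control", "patient"), each = n / 2)
  # reduce N2 within-network edges in patients, state 1 only
  e2 <- tab$edge[tab$within_network & tab$network_i == "N2"]
  mats <- list(base, base + matrix(rnorm(n * n_edges, 0, 0.01), n))
  mats[[1]][groups == "patient", e2] <-
    mats[[1]][groups == "patient", e2] - 0.4
  profs <- lapply(seq_len(n), function(i)
    rbind(mats[[1]][i, ], mats[[2]][i, ]))
  names(profs) <- sprintf("s%03d", seq_len(n))
  res <- network_level_tests(profs, groups, NULL, labels, states = 1:2)
  hit <- res[res$significant, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$state, 1)
  expect_equal(hit$network, "N2")
  expect_gt(hit$t, 0)  # control minus patient
  # percent deviation arithmetic
  nm <- rbind(A = c(0.10, 0.2), B = c(0.12, 0.1))
  expect_equal(unname(percent_deviation_from_state(nm, 1)[1, ]),
               c(20, -50))
})

test_that("dwell group tests detect planted dwell shifts and negate on swap", {
  set.seed(75)
  n <- 80
  dwell <- cbind(A = runif(n, 0.4, 0.6), B = runif(n, 0.2, 0.4))
  groups <- rep(c("control", "patient"), each = n / 2)
  dwell[groups == "patient", "B"] <- dwell[groups == "patient", "B"] + 0.15
  res <- dwell_group_tests(dwell, groups)
  expect_lt(res$p[res$state == "B"], 0.001)
  expect_lt(res$estimate[res$state == "B"], 0)  # patients higher
  expect_gt(res$p[res$state == "A"], 0.05)
  res_sw <- dwell_group_tests(dwell, rev(groups))
  expect_equal(res$t, -res_sw$t, tolerance = 1e-10)
})

test_that("cross-state variability CV uses the sample-SD convention", {
  # hand oracle: values [1,1,1,3] -> sd = 1, mean = 1.5, CV = 2/3
  m <- cbind(net1 = c(1, 1, 1, 3), net2 = c(2, 2, 2, 2))
  sols <- list(K4 = m, K5 = rbind(m, c(1.5, 2)))
  out <- cross_state_variability(sols)
  expect_equal(out$cv["K4", "net1"], 2 / 3, tolerance = 1e-12)
  expect_equal(out$cv["K4", "net2"], 0)
  expect_equal(out$ranking[1], "net1")
  # near-zero mean -> NA, not an exploding CV
  m2 <- cbind(net1 = c(-1, 1), net2 = c(1, 2))
  out2 <- cross_state_variability(list(K2 = m2))
  expect_true(is.na(out2$cv["K2", "net1"]))
})

test_that("planted high-variability networks drive the repeated-measures ANOVA", {
  set.seed(76)
  n_states <- 4
  sols <- lapply(1:5, function(s) {
    cbind(hi = rnorm(n_states, 1, 0.5), lo1 = rnorm(n_states, 1, 0.02),
          lo2 = rnorm(n_states, 1, 0.02))
  })
  names(sols) <- paste0("K", 4:8)
  out <- cross_state_variability(sols)
  expect_equal(out$ranking[1], "hi")
  expect_lt(out$anova$p, 0.01)
  expect_true(all(c("df1", "df2", "F") %in% names(out$anova)))
})
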