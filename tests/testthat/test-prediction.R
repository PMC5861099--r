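# subjects x edges matrix -> named list of single-state profile matrices
profile_list <- function(mat) {
  out <- lapply(seq_len(nrow(mat)), function(i) matrix(mat[i, ], 1))
  names(out) <- sprintf("sub%03d", seq_len(nrow(mat)))
  out
}

test_that("edge selection splits by sign and respects the threshold", {
  set.seed(80)
  n <- 60
  n_edges <- 120
  mat <- matrix(rnorm(n * n_edges), n)
  y <- rep(0:1, each = n / 2)
  up <- 1:8
  down <- 9:16
  mat[y == 1, up] <- mat[y == 1, up] + 1.2
  mat[y == 1, down] <- mat[y == 1, down] - 1.2
  fs <- select_edge_features(profile_list(mat), y, 1, 0.05)
  expect_true(all(up %in% fs$positive_edges))
  expect_true(all(down %in% fs$negative_edges))
  expect_length(intersect(fs$positive_edges, fs$negative_edges), 0)
  # sign flip of the label swaps the sets exactly
  fs2 <- select_edge_features(profile_list(mat), 1 - y, 1, 0.05)
  expect_equal(sort(fs$positive_edges), sort(fs2$negative_edges))
  expect_equal(sort(fs$negative_edges), sort(fs2$positive_edges))
  # null selection rate ~ threshold
  null_mat <- matrix(rnorm(200 * 500), 200)
  fs0 <- select_edge_features(profile_list(null_mat),
                              rep(0:1, each = 100), 1, 0.05)
  n_sel <- length(fs0$positive_edges) + length(fs0$negative_edges)
  expect_lt(abs(n_sel - 0.05 * 500), 3 * sqrt(500 * 0.05 * 0.95) + 1)
  # constant edges excluded with warning
  cmat <- cbind(mat, 1)
  expect_warning(select_edge_features(profile_list(cmat), y, 1),
                 "constant")
})

test_that("network strength sums selected edges with conventions", {
  fs <- structure(list(state = 1L, positive_edges = c(2L, 4L, 5L),
                       negative_edges = integer(0)),
                  class = "edge_feature_set")
  v <- c(0, 0.1, 0, 0.2, 0.3)
  expect_equal(network_strength(v, fs, "positive"), 0.6)
  expect_equal(network_strength(2 * v, fs, "positive"), 1.2)
  s0 <- network_strength(v, fs, "negative")
  expect_equal(as.numeric(s0), 0)
  expect_true(attr(s0, "empty"))
})

test_that("predicted probability matches the logistic closed form", {
  m0 <- list(beta0 = 0, beta1 = 0, gamma = numeric(0))
  expect_equal(predicted_probability(m0, 5), 0.5)
  m <- list(beta0 = 1, beta1 = 2, gamma = numeric(0))
  expect_equal(predicted_probability(m, 0.5), 0.8808, tolerance = 1e-4)
  expect_equal(predicted_probability(m, 0.5),
               exp(2) / (1 + exp(2)), tolerance = 1e-12)
  # complement identity and saturation
  mc <- list(beta0 = -0.3, beta1 = 1.1, gamma = c(a = 0.2))
  p <- predicted_probability(mc, 0.7, 1.5)
  expect_equal(1 - p, stats::plogis(-(-0.3 + 1.1 * 0.7 + 0.3)),
               tolerance = 1e-12)
  expect_gt(predicted_probability(m, 100), 1 - 1e-10)
  expect_error(predicted_probability(mc, 1, NULL), "gamma length")
})

test_that("roc_auc equals concordance enumeration and is antisymmetric", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))$auc, 0.75)
  expect_equal(roc_auc(1:6, c(0, 0, 0, 1, 1, 1))$auc, 1)
  expect_equal(roc_auc(6:1, c(0, 0, 0, 1, 1, 1))$auc, 0)
  expect_equal(roc_auc(rep(1, 5), c(0, 1, 0, 1, 1))$auc, 0.5)
  set.seed(81)
  for (trial in 1:20) {
    n <- sample(6:20, 1)
    scores <- round(rnorm(n), 1)   # induce ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    expect_equal(roc_auc(scores, labels)$auc,
                 auc_by_enumeration(scores, labels), tolerance = 1e-12)
    expect_equal(roc_auc(scores, labels)$auc +
                   roc_auc(-scores, labels)$auc, 1, tolerance = 1e-12)
  }
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("LOOCV keeps selection inside folds and recovers planted signal", {
  set.seed(82)
  n <- 40
  n_edges <- 60
  mat <- matrix(rnorm(n * n_edges), n)
  y <- rep(0:1, each = n / 2)
  mat[y == 1, 1:10] <- mat[y == 1, 1:10] + 1.5
  res <- fit_predict_loocv(profile_list(mat), y, 1, "positive",
                           seed = 1)
  expect_length(res$probabilities, n)
  expect_true(all(res$probabilities >= 0 & res$probabilities <= 1))
  expect_gt(res$roc$auc, 0.8)
  # null labels at n = 100: mean LOOCV AUC near chance (selection inside
  # folds gives a small pessimistic bias, hence the generous band)
  set.seed(90)
  aucs <- replicate(10, {
    m0 <- matrix(rnorm(100 * 60), 100)
    y0 <- rep(0:1, each = 50)
    fit_predict_loocv(profile_list(m0), y0, 1, "positive",
                      seed = 2)$roc$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
  expect_error(fit_predict_loocv(profile_list(mat),
                                 c(1, rep(0, n - 1)), 1),
               "lost an entire class")
})

test_that("elastic-net path runs with covariates via glmnet", {
  set.seed(83)
  n <- 60
  mat <- matrix(rnorm(n * 50), n)
  y <- rep(0:1, each = n / 2)
  mat[y == 1, 1:8] <- mat[y == 1, 1:8] + 1.5
  covs <- data.frame(age = rnorm(n), sex = rbinom(n, 1, 0.5))
  res <- fit_predict_loocv(profile_list(mat), y, 1, "positive",
                           covariates = covs, alpha = 0.5, seed = 3)
  expect_gt(res$roc$auc, 0.75)
  bundle <- train_prediction_model(profile_list(mat), y, 1, "positive",
                                   covariates = covs, seed = 4)
  expect_true(is.finite(bundle$model$beta1))
  expect_equal(names(bundle$model$gamma), c("age", "sex"))
})

test_that("permutation AUC test is calibrated and uses the add-one formula", {
  set.seed(84)
  scores <- c(rnorm(15, 1), rnorm(15, -1))
  labels <- rep(c(1, 0), each = 15)
  pipe <- function(y) roc_auc(scores, y)$auc
  pt <- permutation_auc_test(pipe, labels, n_permutations = 99,
                             seed = 5)
  expect_equal(pt$observed_auc, roc_auc(scores, labels)$auc)
  expect_equal(pt$p_value, 0.01)   # separable data, add-one floor
  expect_lt(abs(mean(pt$null_auc) - 0.5), 0.05)
  expect_error(permutation_auc_test(pipe, labels, 0), ">= 1")
})

test_that("holdout evaluation freezes the model", {
  set.seed(85)
  n <- 50
  mat <- matrix(rnorm(n * 40), n)
  y <- rep(0:1, each = n / 2)
  mat[y == 1, 1:6] <- mat[y == 1, 1:6] + 1.3
  bundle <- train_prediction_model(profile_list(mat), y, 1, "positive",
                                   seed = 6)
  before <- unserialize(serialize(bundle, NULL))
  # identity data: holdout AUC equals resubstitution AUC
  hold <- holdout_evaluate(bundle, profile_list(mat), y,
                           n_permutations = 49, seed = 7)
  s <- vapply(profile_list(mat), network_strength, numeric(1),
              feature_set = bundle$feature_set, sign = "positive")
  resub <- roc_auc(stats::plogis(bundle$model$beta0 +
                                   bundle$model$beta1 * s), y)$auc
  expect_equal(hold$roc$auc, resub, tolerance = 1e-12)
  expect_identical(serialize(bundle, NULL), serialize(before, NULL))
  # training-derived features are untouched by holdout content
  sub <- c(1:5, 26:30)   # mixed-class holdout subset
  hold2 <- holdout_evaluate(bundle, profile_list(mat[sub, ]), y[sub],
                            n_permutations = 9, seed = 8)
  expect_identical(bundle$feature_set, before$feature_set)
})

test_that("PANSS binarization reproduces printed cutoffs and boundary rule", {
  b1 <- binarize_panss(c(10, 18.46 - 6.51, 20), 18.46, 6.51)
  expect_equal(b1$cutoff, 11.95)
  # boundary score (exactly at the cutoff) is assigned high
  expect_equal(as.character(b1$labels), c("low", "high", "high"))
  expect_equal(binarize_panss(10, 13.48, 7.47)$cutoff, 6.01)
  expect_error(binarize_panss(1:3, 10, 0), "positive")
})

test_that("stratified split reproduces 91/39 and stratifies classes", {
  y <- rep(c(0, 1), c(80, 50))
  sp <- stratified_split(y, 0.7, seed = 9)
  expect_length(sp$train, 91)
  expect_length(sp$holdout, 39)
  expect_length(intersect(sp$train, sp$holdout), 0)
  # class proportions preserved to rounding
  expect_equal(sum(y[sp$train] == 1), 35)
  sp2 <- stratified_split(y, 0.7, seed = 9)
  expect_identical(sp, sp2)
  expect_error(stratified_split(y, 1.2), "train_fraction")
})

test_that("deleting a holdout subject never changes training artifacts", {
  set.seed(86)
  n <- 30
  mat <- matrix(rnorm(n * 30), n)
  y <- rep(0:1, n / 2)
  bundle_all <- train_prediction_model(profile_list(mat), y, 1,
                                       "positive", seed = 10)
  bundle_all2 <- train_prediction_model(profile_list(mat), y, 1,
                                        "positive", seed = 10)
  expect_identical(serialize(bundle_all, NULL),
                   serialize(bundle_all2, NULL))
})
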