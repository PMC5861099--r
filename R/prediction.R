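#' Select predictive edges of one state by correlation screening
#'
#' Pearson-correlates each edge of the training subjects' state profiles
#' with the binary label; edges with selection `p <= p_threshold` are
#' split by the sign of the correlation into a positive and a negative
#' feature set (for dichotomous labels this screen is equivalent to a
#' mass-univariate two-sample t-test). Constant edges are excluded with a
#' warning. Selection must only ever see training subjects.
#'
#' @param train_profiles named list (by subject) of
#'   `subject_state_profile` objects (or per-state matrices) for the
#'   training subjects.
#' @param labels binary 0/1 vector aligned with `train_profiles`.
#' @param state state index.
#' @param p_threshold selection threshold (default 0.05).
#' @return object of class `edge_feature_set`: `state`,
#'   `positive_edges`, `negative_edges` (integer indices), `r`, `p`
#'   (per selected edge).
#' @export
select_edge_features <- function(train_profiles, labels, state,
                                 p_threshold = 0.05) {
  m <- state_profile_matrix(train_profiles, state)
  keep <- stats::complete.cases(m)
  m <- m[keep, , drop = FALSE]
  y <- as.numeric(labels)[keep]
  if (length(unique(y)) != 2L) stopf("labels must contain both classes")
  if (min(table(y)) < 3L) stopf("need at least 3 subjects per class")
  n <- nrow(m)
  mu <- colMeans(m)
  sds <- sqrt(pmax(colSums(m^2) / n - mu^2, 0) * n / (n - 1))
  const <- sds < 1e-12
  if (any(const))
    warning(sprintf("%d constant edge(s) excluded from selection",
                    sum(const)))
  r <- rep(NA_real_, ncol(m))
  r[!const] <- drop(stats::cor(m[, !const, drop = FALSE], y))
  # two-sided p from the t-distributed transform of r (df = n - 2)
  t_stat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-12))
  p <- 2 * stats::pt(-abs(t_stat), n - 2)
  sel <- which(!const & p <= p_threshold)
  structure(
    list(state = state,
         positive_edges = sel[r[sel] > 0],
         negative_edges = sel[r[sel] < 0],
         r = r[sel], p = p[sel], n_train = n),
    class = "edge_feature_set")
}

#' @export
print.edge_feature_set <- function(x, ...) {
  cat(sprintf("<edge_feature_set> state %d: %d positive / %d negative edges (n_train = %d)\n",
              x$state, length(x$positive_edges),
              length(x$negative_edges), x$n_train))
  invisible(x)
}

#' Network strength of a subject for one feature set
#'
#' Aggregates (sums) the subject's z-values over the selected edge set of
#' the chosen sign. The sum convention is a positive scale factor away
#' from the mean and is absorbed by the logistic weight, leaving AUC
#' unchanged. An empty set yields strength 0 with an `empty` attribute.
#'
#' @param profile a `subject_state_profile` (its `state` row is used) or
#'   a bare edge vector.
#' @param feature_set an `edge_feature_set`.
#' @param sign `"positive"` or `"negative"`.
#' @return scalar network strength.
#' @export
network_strength <- function(profile, feature_set,
                             sign = c("positive", "negative")) {
  sign <- match.arg(sign)
  v <- if (inherits(profile, "subject_state_profile"))
    profile$profiles[feature_set$state, ] else as.numeric(profile)
  edges <- if (sign == "positive") feature_set$positive_edges
           else feature_set$negative_edges
  if (!length(edges)) return(structure(0, empty = TRUE))
  if (max(edges) > length(v)) stopf("profile is missing selected edges")
  sum(v[edges])
}

#' Predicted probability of the logistic network-strength model
#'
#' `p = logistic(b0 + b1 * s + gamma' c)` for network strength `s` and
#' covariate vector `c`; the complement identity `P(Y = 0) = 1 - p` holds
#' exactly.
#'
#' @param model list with `beta0`, `beta1`, `gamma` (possibly empty
#'   named vector).
#' @param strength scalar network strength.
#' @param covariates numeric vector matching `model$gamma` (or `NULL`).
#' @return probability in (0, 1).
#' @export
predicted_probability <- function(model, strength, covariates = NULL) {
  g <- model$gamma %||% numeric(0)
  cv <- covariates %||% numeric(0)
  if (length(g) != length(cv))
    stopf("covariate vector length %d does not match model gamma length %d",
          length(cv), length(g))
  eta <- model$beta0 + model$beta1 * strength +
    if (length(g)) sum(g * cv) else 0
  if (!is.finite(eta)) stopf("non-finite linear predictor")
  stats::plogis(eta)
}

# Elastic-net logistic fit of label on (strength, covariates); intercept
# unpenalized; lambda by inner cross-validation with seeded folds. With
# no covariates a constant padding column satisfies glmnet's two-column
# minimum (its coefficient is exactly zero). The shrinkage matters: under
# null labels the inner CV drives beta1 to zero, keeping leave-one-out
# AUC centred at chance.
fit_strength_model <- function(strength, covariates, labels, alpha = 0.5,
                               lambda_grid = NULL, inner_folds = 5L,
                               lambda_rule = c("1se", "min"),
                               seed = 1L) {
  lambda_rule <- match.arg(lambda_rule)
  y <- as.numeric(labels)
  has_cov <- !is.null(covariates) && NCOL(covariates) > 0L
  x <- if (has_cov) cbind(s = strength, as.matrix(covariates))
       else cbind(s = strength, .pad = 0)
  if (all(apply(x, 2L, stats::sd) == 0)) {
    # empty feature set (and constant covariates): intercept-only model
    gamma <- if (has_cov)
      stats::setNames(rep(0, ncol(x) - 1L),
                      colnames(as.matrix(covariates)))
    else numeric(0)
    return(list(beta0 = stats::qlogis(mean(y)), beta1 = 0,
                gamma = gamma, alpha = alpha, lambda = Inf))
  }
  n <- length(y)
  foldid <- with_seed(seed, sample(rep_len(seq_len(inner_folds), n)))
  full <- suppressWarnings(
    glmnet::glmnet(x, y, family = "binomial", alpha = alpha,
                   lambda = lambda_grid, nlambda = 40L))
  lambdas <- full$lambda
  # Inner CV by binomial deviance over the full fit's lambda path (a
  # lean re-implementation of cv.glmnet for this small, fixed-width
  # design; per-fold fits reuse the same path). The default lambda rule
  # is the one-standard-error convention: the sparsest penalty whose CV
  # deviance is within one SE of the minimum.
  dev_f <- matrix(NA_real_, inner_folds, length(lambdas))
  for (f in seq_len(inner_folds)) {
    hold <- foldid == f
    if (!any(hold) || length(unique(y[!hold])) < 2L) next
    fit_f <- suppressWarnings(
      glmnet::glmnet(x[!hold, , drop = FALSE], y[!hold],
                     family = "binomial", alpha = alpha,
                     lambda = lambdas))
    eta <- sweep(as.matrix(x[hold, , drop = FALSE] %*% fit_f$beta), 2L,
                 fit_f$a0, "+")
    p <- stats::plogis(pmin(pmax(eta, -30), 30))
    ll <- y[hold] * log(p) + (1 - y[hold]) * log(1 - p)  # recycles rows
    m <- ncol(p)
    dev_f[f, seq_len(m)] <- -2 * colMeans(ll)
    if (m < length(lambdas)) dev_f[f, (m + 1L):length(lambdas)] <- Inf
  }
  ok_f <- rowSums(is.na(dev_f)) == 0L
  dev <- colMeans(dev_f[ok_f, , drop = FALSE])
  i_min <- which.min(dev)
  best <- if (lambda_rule == "min" || sum(ok_f) < 2L) i_min else {
    se_min <- stats::sd(dev_f[ok_f, i_min]) / sqrt(sum(ok_f))
    # lambdas are decreasing: the smallest index within one SE is the
    # largest (sparsest) qualifying penalty
    which(dev <= dev[i_min] + se_min)[1L]
  }
  co <- c(full$a0[best], as.numeric(full$beta[, best]))
  gamma <- if (has_cov)
    stats::setNames(co[-(1:2)], colnames(as.matrix(covariates)))
  else numeric(0)
  list(beta0 = co[1L], beta1 = co[2L], gamma = gamma, alpha = alpha,
       lambda = lambdas[best])
}

#' Leave-one-subject-out prediction of a binary label from one state
#'
#' For each held-out subject, edge selection ([select_edge_features()]),
#' network-strength computation and elastic-net logistic fitting are
#' repeated from scratch on the remaining n - 1 subjects, and the
#' held-out subject's probability is predicted from the fold's frozen
#' model — selection never sees the test subject.
#'
#' @param profiles named list (by subject) of state profiles.
#' @param labels binary 0/1 vector per subject.
#' @param state state index.
#' @param sign `"positive"` or `"negative"` feature set.
#' @param covariates data.frame per subject, or `NULL`.
#' @param alpha elastic-net mixing parameter (default 0.5).
#' @param p_threshold edge-selection threshold (default 0.05).
#' @param seed integer seed (inner-CV folds).
#' @param inner_folds folds of the inner cross-validation selecting the
#'   elastic-net penalty (default 5).
#' @param lambda_rule penalty choice: `"1se"` (default; sparsest lambda
#'   within one standard error of the CV-minimal deviance — the usual
#'   parsimony convention, which also keeps the permutation null AUC
#'   centred at 0.5 by shrinking the strength weight to zero when the
#'   labels carry no signal) or `"min"`.
#' @return object of class `loocv_result`: `probabilities` (held-out p
#'   per subject), `scores` (intercept-free linear predictors used for
#'   the ROC), `labels`, `roc` ([roc_auc()] result), `state`, `sign`,
#'   `n`.
#'
#' @details Held-out subjects are ranked for the ROC by the
#'   intercept-free linear predictor `beta1 * s + gamma' c`. Within any
#'   one fitted model the intercept cannot change the ranking; across
#'   leave-one-out folds, however, the fold intercept tracks the
#'   training-set class composition (leaving out a case tilts the
#'   remaining class balance against that case), which alone drives AUC
#'   systematically below chance under null labels. Dropping the
#'   intercept from the ranking score removes exactly that artifact.
#' @export
fit_predict_loocv <- function(profiles, labels, state,
                              sign = c("positive", "negative"),
                              covariates = NULL, alpha = 0.5,
                              p_threshold = 0.05, seed = 1L,
                              inner_folds = 5L,
                              lambda_rule = c("1se", "min")) {
  sign <- match.arg(sign)
  lambda_rule <- match.arg(lambda_rule)
  n <- length(profiles)
  stopifnot(length(labels) == n)
  y <- as.numeric(labels)
  prob <- rep(NA_real_, n)
  score <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    if (length(unique(y[tr])) < 2L)
      stopf("leave-one-out fold %d lost an entire class", i)
    fs <- select_edge_features(profiles[tr], y[tr], state, p_threshold)
    s_tr <- vapply(profiles[tr], network_strength, numeric(1),
                   feature_set = fs, sign = sign)
    cv_tr <- if (!is.null(covariates))
      as.data.frame(covariates)[tr, , drop = FALSE] else NULL
    model <- fit_strength_model(s_tr, cv_tr, y[tr], alpha = alpha,
                                inner_folds = inner_folds,
                                lambda_rule = lambda_rule,
                                seed = child_seed(seed, i))
    s_te <- network_strength(profiles[[i]], fs, sign)
    cv_te <- if (!is.null(covariates))
      as.numeric(as.data.frame(covariates)[i, ]) else NULL
    prob[i] <- predicted_probability(model, s_te, cv_te)
    score[i] <- model$beta1 * s_te +
      if (length(model$gamma)) sum(model$gamma * cv_te) else 0
  }
  structure(
    list(probabilities = stats::setNames(prob, names(profiles)),
         scores = stats::setNames(score, names(profiles)),
         labels = y, roc = roc_auc(score, y), state = state,
         sign = sign, n = n),
    class = "loocv_result")
}

#' ROC curve and AUC by numerical integration
#'
#' Sweeps all thresholds yielding unique sensitivity/specificity pairs
#' and integrates the ROC by the trapezoidal rule; the result equals the
#' tie-adjusted concordance probability
#' `P(score_case > score_control) + 0.5 P(tie)`.
#'
#' @param scores numeric prediction scores (higher = more case-like).
#' @param labels binary 0/1 vector (1 = case).
#' @return object of class `roc_result`: `auc`, `thresholds`,
#'   `sensitivity`, `specificity`.
#' @export
roc_auc <- function(scores, labels) {
  y <- as.numeric(labels)
  if (length(unique(y)) != 2L || !all(y %in% c(0, 1)))
    stopf("labels must contain both classes coded 0/1")
  if (anyNA(scores)) stopf("scores contain NA")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  n_pos <- sum(y == 1)
  n_neg <- sum(y == 0)
  sens <- vapply(thr, function(t) sum(scores >= t & y == 1) / n_pos,
                 numeric(1))
  spec <- vapply(thr, function(t) sum(scores < t & y == 0) / n_neg,
                 numeric(1))
  fpr <- 1 - spec
  auc <- sum(diff(fpr) * (sens[-1L] + sens[-length(sens)]) / 2)
  structure(list(auc = auc, thresholds = thr, sensitivity = sens,
                 specificity = spec),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (%d thresholds)\n", x$auc,
              length(x$thresholds)))
  invisible(x)
}

#' Permutation test of a prediction pipeline's AUC
#'
#' Reruns a pipeline under `n_permutations` random permutations of the
#' labels and reports
#' `p = (1 + #\{null AUC >= observed\}) / (1 + n_permutations)`. Under
#' label exchangeability the null AUC distribution is centred near 0.5.
#' The canonical pipeline for the leave-one-out analysis is
#' [loocv_strength_pipeline()], which keeps the observed-label edge
#' selection ("correct dynamic signatures") frozen and refits only the
#' logistic weights under each permuted label vector.
#'
#' @param pipeline function(labels) -> AUC, closing over everything
#'   else.
#' @param labels the observed binary labels.
#' @param n_permutations number of permutations (default 5000).
#' @param seed integer seed.
#' @return list with `observed_auc`, `p_value`, `null_auc`
#'   (distribution), `n_permutations`.
#' @export
permutation_auc_test <- function(pipeline, labels, n_permutations = 5000L,
                                 seed = 1L) {
  if (n_permutations < 1L) stopf("n_permutations must be >= 1")
  observed <- pipeline(labels)
  null_auc <- with_seed(seed, vapply(seq_len(n_permutations), function(b)
    pipeline(sample(labels)), numeric(1)))
  list(observed_auc = observed,
       p_value = (1 + sum(null_auc >= observed)) / (1 + n_permutations),
       null_auc = null_auc, n_permutations = as.integer(n_permutations))
}

#' Leave-one-out pipeline with frozen edge signatures
#'
#' Builds the `function(labels) -> AUC` closure used for permutation
#' testing of the leave-one-out analysis. Edge selection is performed
#' once, on the profiles with the observed labels supplied here, and the
#' resulting per-subject network strengths are frozen; each call then
#' refits the elastic-net logistic weights fold by fold for the labels
#' it is given and returns the held-out AUC (intercept-free ranking as
#' in [fit_predict_loocv()]). Permuted calls therefore combine the
#' correct dynamic signatures with incorrect labels, which keeps the
#' null AUC distribution centred on 0.5.
#'
#' @inheritParams fit_predict_loocv
#' @param observed_labels the real binary labels used for the one-off
#'   edge selection.
#' @return function taking a label vector and returning an AUC.
#' @export
loocv_strength_pipeline <- function(profiles, observed_labels, state,
                                    sign = c("positive", "negative"),
                                    covariates = NULL, alpha = 0.5,
                                    p_threshold = 0.05, seed = 1L,
                                    inner_folds = 5L,
                                    lambda_rule = c("1se", "min")) {
  sign <- match.arg(sign)
  lambda_rule <- match.arg(lambda_rule)
  y_obs <- as.numeric(observed_labels)
  fs <- select_edge_features(profiles, y_obs, state, p_threshold)
  s <- vapply(profiles, network_strength, numeric(1), feature_set = fs,
              sign = sign)
  cv <- if (!is.null(covariates)) as.data.frame(covariates) else NULL
  n <- length(s)
  function(labels) {
    y <- as.numeric(labels)
    score <- numeric(n)
    for (i in seq_len(n)) {
      tr <- setdiff(seq_len(n), i)
      cv_tr <- if (!is.null(cv)) cv[tr, , drop = FALSE] else NULL
      model <- fit_strength_model(s[tr], cv_tr, y[tr], alpha = alpha,
                                  inner_folds = inner_folds,
                                  lambda_rule = lambda_rule,
                                  seed = child_seed(seed, i))
      cv_te <- if (!is.null(cv)) as.numeric(cv[i, ]) else NULL
      score[i] <- model$beta1 * s[i] +
        if (length(model$gamma)) sum(model$gamma * cv_te) else 0
    }
    roc_auc(score, y)$auc
  }
}

#' Train a frozen model bundle on the full training set
#'
#' Edge selection and elastic-net fitting on all training subjects;
#' the resulting feature set and weights are frozen for holdout
#' evaluation.
#'
#' @inheritParams fit_predict_loocv
#' @return object of class `prediction_model`: `feature_set`, `model`,
#'   `state`, `sign`, `covariate_names`.
#' @export
train_prediction_model <- function(profiles, labels, state,
                                   sign = c("positive", "negative"),
                                   covariates = NULL, alpha = 0.5,
                                   p_threshold = 0.05, seed = 1L,
                                   inner_folds = 5L,
                                   lambda_rule = c("1se", "min")) {
  sign <- match.arg(sign)
  lambda_rule <- match.arg(lambda_rule)
  y <- as.numeric(labels)
  fs <- select_edge_features(profiles, y, state, p_threshold)
  s <- vapply(profiles, network_strength, numeric(1), feature_set = fs,
              sign = sign)
  cv <- if (!is.null(covariates)) as.data.frame(covariates) else NULL
  model <- fit_strength_model(s, cv, y, alpha = alpha,
                              inner_folds = inner_folds,
                              lambda_rule = lambda_rule, seed = seed)
  structure(
    list(feature_set = fs, model = model, state = state, sign = sign,
         covariate_names = if (!is.null(cv)) names(cv) else character(0)),
    class = "prediction_model")
}

#' Evaluate a frozen model on holdout subjects
#'
#' Applies the training-set feature sets and weights, without any
#' refitting, to previously unseen subjects; reports AUC and a
#' permutation p-value obtained by permuting holdout labels only (the
#' frozen model is untouched).
#'
#' @param bundle a `prediction_model` from [train_prediction_model()].
#' @param profiles named list of holdout subjects' state profiles.
#' @param labels binary 0/1 holdout labels.
#' @param covariates holdout covariates matching the bundle's.
#' @param n_permutations label permutations for the holdout p-value
#'   (default 1000).
#' @param seed integer seed.
#' @return list with `probabilities`, `roc`, `p_value`, `null_auc`.
#' @export
holdout_evaluate <- function(bundle, profiles, labels, covariates = NULL,
                             n_permutations = 1000L, seed = 1L) {
  stopifnot(inherits(bundle, "prediction_model"))
  y <- as.numeric(labels)
  cv <- if (!is.null(covariates)) as.data.frame(covariates) else NULL
  if (length(bundle$covariate_names) &&
      (is.null(cv) || !all(bundle$covariate_names %in% names(cv))))
    stopf("holdout covariates missing: %s",
          paste(setdiff(bundle$covariate_names, names(cv)),
                collapse = ", "))
  prob <- vapply(seq_along(profiles), function(i) {
    s <- network_strength(profiles[[i]], bundle$feature_set, bundle$sign)
    c_i <- if (length(bundle$covariate_names))
      as.numeric(cv[i, bundle$covariate_names]) else NULL
    predicted_probability(bundle$model, s, c_i)
  }, numeric(1))
  roc <- roc_auc(prob, y)
  null_auc <- with_seed(seed, vapply(seq_len(n_permutations), function(b)
    roc_auc(prob, sample(y))$auc, numeric(1)))
  list(probabilities = stats::setNames(prob, names(profiles)), roc = roc,
       p_value = (1 + sum(null_auc >= roc$auc)) / (1 + n_permutations),
       null_auc = null_auc)
}

#' Binarize PANSS-like subscale scores at one SD below the mean
#'
#' Cutoff = mean - SD; scores below the cutoff are "low", scores at or
#' above it "high" (the boundary is assigned high). With the printed
#' positive-scale statistics 18.46 +/- 6.51 the cutoff is 11.95; with the
#' negative-scale 13.48 +/- 7.47 it is 6.01.
#'
#' @param scores numeric subscale scores.
#' @param subscale_mean,subscale_sd subscale mean and SD (sd > 0).
#' @return list with `labels` (factor low/high), `binary` (1 = high),
#'   `cutoff`.
#' @export
binarize_panss <- function(scores, subscale_mean, subscale_sd) {
  if (subscale_sd <= 0) stopf("subscale_sd must be positive")
  cutoff <- subscale_mean - subscale_sd
  high <- scores >= cutoff
  list(labels = factor(ifelse(high, "high", "low"),
                       levels = c("low", "high")),
       binary = as.integer(high), cutoff = cutoff)
}

#' Stratified train/holdout split
#'
#' Seeded shuffle within each class, allocating `train_fraction` of each
#' class to training with largest-remainder rounding so the total
#' training size equals `round(train_fraction * n)` (130 subjects at
#' 70/30 give 91 training and 39 holdout).
#'
#' @param labels class labels (any type).
#' @param train_fraction fraction assigned to training (default 0.7).
#' @param seed integer seed.
#' @return list with `train` and `holdout` integer index vectors.
#' @export
stratified_split <- function(labels, train_fraction = 0.7, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stopf("train_fraction must be in (0, 1)")
  n <- length(labels)
  target <- round(train_fraction * n)
  classes <- split(seq_len(n), labels)
  raw <- vapply(classes, length, integer(1)) * train_fraction
  base <- floor(raw)
  short <- target - sum(base)
  if (short > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  train <- with_seed(seed, unlist(lapply(seq_along(classes), function(i)
    sample(classes[[i]])[seq_len(base[i])]), use.names = FALSE))
  train <- sort(train)
  list(train = train, holdout = setdiff(seq_len(n), train))
}
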