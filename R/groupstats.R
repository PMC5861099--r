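#' Residualize responses on nuisance covariates
#'
#' Ordinary least-squares residuals of each response column on the
#' covariate design (with intercept), used before all group comparisons
#' so that age, sex, motion and similar nuisance effects are partialed
#' out. Residuals are centered (the intercept is absorbed, not returned).
#'
#' @param values numeric vector or subject x variable matrix.
#' @param covariates data.frame or matrix of nuisance covariates
#'   (subjects in rows), or `NULL` to just center.
#' @return residual vector/matrix of the same shape.
#' @export
residualize_covariates <- function(values, covariates = NULL) {
  v <- as.matrix(values)
  if (is.null(covariates) || NCOL(covariates) == 0L)
    return(drop(scale(v, scale = FALSE)))
  x <- stats::model.matrix(~ ., data = as.data.frame(covariates))
  if (nrow(x) != nrow(v))
    stopf("covariates have %d rows but values have %d", nrow(x), nrow(v))
  qr_x <- qr(x)
  if (qr_x$rank < ncol(x)) {
    dropped <- colnames(x)[qr_x$pivot[(qr_x$rank + 1L):ncol(x)]]
    stopf("covariate design is rank-deficient; collinear column(s): %s",
          paste(dropped, collapse = ", "))
  }
  drop(qr.resid(qr_x, v))
}

#' Benjamini-Hochberg false-discovery-rate control
#'
#' Step-up procedure at level `q`: reject the `k` smallest p-values where
#' `k` is the largest index with `p_(i) <= i q / m`. Also returns monotone
#' BH-adjusted q-values.
#'
#' @param p_values numeric vector in \[0, 1\].
#' @param q target FDR level (default 0.05).
#' @return list with `mask` (logical rejections), `q_values`, `q`,
#'   `n_rejected`.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  p <- as.numeric(p_values)
  if (!length(p)) stopf("empty p-value vector")
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stopf("p-values must lie in [0, 1]")
  m <- length(p)
  ord <- order(p)
  ranked <- p[ord]
  qv <- rev(cummin(rev(ranked * m / seq_len(m))))
  qv <- pmin(qv, 1)
  q_values <- numeric(m)
  q_values[ord] <- qv
  pass <- ranked <= seq_len(m) * q / m
  k <- if (any(pass)) max(which(pass)) else 0L
  mask <- logical(m)
  if (k > 0L) mask[ord[seq_len(k)]] <- TRUE
  list(mask = mask, q_values = q_values, q = q, n_rejected = sum(mask))
}

# pooled-variance two-sample t per column of a residual matrix;
# estimate = mean(group a) - mean(group b); F = t^2 is the one-way ANOVA F
two_sample_t_cols <- function(resid_mat, is_a) {
  resid_mat <- as.matrix(resid_mat)
  n1 <- sum(is_a); n2 <- sum(!is_a)
  if (n1 < 2L || n2 < 2L) stopf("each group needs at least 2 subjects")
  m1 <- colMeans(resid_mat[is_a, , drop = FALSE])
  m2 <- colMeans(resid_mat[!is_a, , drop = FALSE])
  v1 <- apply(resid_mat[is_a, , drop = FALSE], 2L, stats::var)
  v2 <- apply(resid_mat[!is_a, , drop = FALSE], 2L, stats::var)
  sp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp * (1 / n1 + 1 / n2))
  t_stat <- (m1 - m2) / se
  df <- n1 + n2 - 2
  list(estimate = m1 - m2, t = t_stat, df = df,
       p = 2 * stats::pt(-abs(t_stat), df))
}

#' Edgewise group differences within one state
#'
#' Residualizes each edge of the subjects' per-state mean profiles on the
#' covariates, then compares groups edge by edge with a pooled-variance
#' two-sample test (one-way ANOVA F = t^2), controlling FDR across all
#' edges of the state by Benjamini-Hochberg. Subjects who never expressed
#' the state are excluded.
#'
#' @param profiles named list (by subject) of `subject_state_profile`
#'   objects (or per-state matrices).
#' @param group_labels character/factor per subject; the first level is
#'   the reference ("control") group and estimates are reference minus
#'   other.
#' @param covariates data.frame of nuisance covariates per subject (or
#'   `NULL`).
#' @param state state index.
#' @param q FDR level (default 0.05).
#' @return object of class `edgewise_result`: `estimate`, `t`, `p`,
#'   `q_values`, `mask`, `df`, `state`, `n_per_group`.
#' @export
edgewise_group_differences <- function(profiles, group_labels,
                                       covariates = NULL, state,
                                       q = 0.05) {
  m <- state_profile_matrix(profiles, state)
  keep <- stats::complete.cases(m)
  if (!all(keep)) {
    m <- m[keep, , drop = FALSE]
    group_labels <- group_labels[keep]
    if (!is.null(covariates))
      covariates <- as.data.frame(covariates)[keep, , drop = FALSE]
  }
  gl <- as.factor(group_labels)
  if (nlevels(gl) != 2L) stopf("exactly two groups required")
  if (min(table(gl)) < 2L)
    stopf("a group is empty or singleton after exclusions")
  resid <- residualize_covariates(m, covariates)
  tt <- two_sample_t_cols(resid, gl == levels(gl)[1L])
  fdr <- bh_fdr(tt$p, q)
  structure(
    list(estimate = tt$estimate, t = tt$t, p = tt$p,
         q_values = fdr$q_values, mask = fdr$mask, df = tt$df,
         state = state,
         n_per_group = stats::setNames(as.integer(table(gl)),
                                       levels(gl))),
    class = "edgewise_result")
}

#' @export
print.edgewise_result <- function(x, ...) {
  cat(sprintf(
    "<edgewise_result> state %d: %d/%d edges significant at q <= 0.05 (n = %s)\n",
    x$state, sum(x$mask), length(x$mask),
    paste(x$n_per_group, collapse = "/")))
  invisible(x)
}

#' Within-network mean connectivity per subject and state
#'
#' @param profiles as in [edgewise_group_differences()].
#' @param network_labels region -> network character vector.
#' @param state state index.
#' @return subject x network matrix of mean within-network z values.
#' @export
within_network_means <- function(profiles, network_labels, state) {
  m <- state_profile_matrix(profiles, state)
  n_regions <- (1 + sqrt(1 + 8 * ncol(m))) / 2
  tab <- edge_index_table(as.integer(round(n_regions)),
                          network_labels = network_labels)
  nets <- unique(network_labels)
  out <- vapply(nets, function(nw) {
    e <- tab$edge[tab$within_network & tab$network_i == nw]
    if (!length(e)) stopf("network %s has no within-network edges", nw)
    rowMeans(m[, e, drop = FALSE])
  }, numeric(nrow(m)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1,
                                       dimnames = list(rownames(m), nets))
  rownames(out) <- rownames(m)
  out
}

#' Network-level group tests with Bonferroni correction
#'
#' For each requested state and network, compares subject-level mean
#' within-network connectivity between groups on covariate residuals
#' (pooled-variance t), Bonferroni-correcting across the whole
#' state x network family tested.
#'
#' @inheritParams edgewise_group_differences
#' @param network_labels region -> network character vector.
#' @param states integer vector of state indices to test.
#' @param alpha family-wise level for the Bonferroni flag (default 0.05).
#' @return data.frame: state, network, estimate, t, df, p, p_bonferroni,
#'   significant.
#' @export
network_level_tests <- function(profiles, group_labels, covariates = NULL,
                                network_labels, states, alpha = 0.05) {
  rows <- list()
  for (s in states) {
    wm <- within_network_means(profiles, network_labels, s)
    keep <- stats::complete.cases(wm)
    gl <- as.factor(group_labels[keep])
    cv <- if (!is.null(covariates))
      as.data.frame(covariates)[keep, , drop = FALSE] else NULL
    resid <- residualize_covariates(wm[keep, , drop = FALSE], cv)
    tt <- two_sample_t_cols(resid, gl == levels(gl)[1L])
    rows[[length(rows) + 1L]] <- data.frame(
      state = s, network = colnames(wm), estimate = tt$estimate,
      t = tt$t, df = tt$df, p = tt$p)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_bonferroni <- pmin(out$p * nrow(out), 1)
  out$significant <- out$p_bonferroni <= alpha
  out
}

#' Percent deviation of network connectivity from a reference state
#'
#' `100 * (value - reference) / reference` per network, e.g. the percent
#' change of states B-D relative to the attractor state A.
#'
#' @param network_means state x network matrix (e.g. group-mean
#'   within-network z values).
#' @param reference_state row index of the reference state (default 1).
#' @return matrix of percent deviations with the reference row dropped.
#' @export
percent_deviation_from_state <- function(network_means,
                                         reference_state = 1L) {
  ref <- network_means[reference_state, ]
  out <- 100 * sweep(network_means[-reference_state, , drop = FALSE], 2L,
                     ref, "-") / rep(ref, each = nrow(network_means) - 1L)
  out
}

#' Group comparison of dwell fractions per state
#'
#' Two-sample pooled t-test on covariate-residualized dwell fractions for
#' each state.
#'
#' @param dwell subject x state matrix of dwell fractions.
#' @param group_labels two-level factor per subject (first level is the
#'   reference group).
#' @param covariates optional nuisance covariates.
#' @return data.frame: state, estimate, t, df, p.
#' @export
dwell_group_tests <- function(dwell, group_labels, covariates = NULL) {
  dwell <- as.matrix(dwell)
  gl <- as.factor(group_labels)
  if (nlevels(gl) != 2L) stopf("exactly two groups required")
  resid <- residualize_covariates(dwell, covariates)
  tt <- two_sample_t_cols(resid, gl == levels(gl)[1L])
  data.frame(state = colnames(dwell) %||% seq_len(ncol(dwell)),
             estimate = tt$estimate, t = tt$t, df = tt$df, p = tt$p,
             row.names = NULL)
}

#' Cross-state variability of network connectivity
#'
#' For each clustering solution, the coefficient of variation (sample SD
#' over mean) of each network's mean within-network connectivity across
#' the solution's states; networks whose mean is near zero get `NA`
#' rather than an exploding CV. Networks are then compared by a one-way
#' repeated-measures ANOVA with solutions as the repeated measure,
#' followed by Bonferroni-corrected paired post-hoc comparisons.
#'
#' @param network_means_by_solution named list over solutions; each
#'   element a state x network matrix of mean within-network z values.
#' @param zero_tol |mean| below which CV is undefined (default 1e-8).
#' @return list with `cv` (solution x network matrix), `anova`
#'   (data.frame: effect, df1, df2, F, p), `posthoc` (pairwise data.frame
#'   with Bonferroni p), `ranking` (networks by decreasing mean CV).
#' @export
cross_state_variability <- function(network_means_by_solution,
                                    zero_tol = 1e-8) {
  cv_mat <- t(vapply(network_means_by_solution, function(m) {
    mu <- colMeans(m)
    sdv <- apply(m, 2L, stats::sd)
    ifelse(abs(mu) < zero_tol, NA_real_, sdv / mu)
  }, numeric(ncol(network_means_by_solution[[1L]]))))
  rownames(cv_mat) <- names(network_means_by_solution) %||%
    paste0("solution", seq_along(network_means_by_solution))
  df <- data.frame(
    cv = as.vector(cv_mat),
    network = factor(rep(colnames(cv_mat), each = nrow(cv_mat))),
    solution = factor(rep(rownames(cv_mat), times = ncol(cv_mat))))
  df <- df[stats::complete.cases(df), ]
  anova_df <- NULL
  if (nrow(cv_mat) >= 2L && ncol(cv_mat) >= 2L) {
    aov_fit <- stats::aov(cv ~ network + Error(solution / network),
                          data = df)
    within_tab <- summary(aov_fit)[["Error: solution:network"]][[1L]]
    rn <- trimws(rownames(within_tab))
    anova_df <- data.frame(
      effect = "network",
      df1 = within_tab[match("network", rn), "Df"],
      df2 = within_tab[match("Residuals", rn), "Df"],
      F = within_tab[match("network", rn), "F value"],
      p = within_tab[match("network", rn), "Pr(>F)"],
      row.names = NULL)
  }
  nets <- colnames(cv_mat)
  ph <- list()
  if (length(nets) > 1L && nrow(cv_mat) > 1L) {
    pairs <- utils::combn(nets, 2L)
    n_pairs <- ncol(pairs)
    for (p in seq_len(n_pairs)) {
      a <- cv_mat[, pairs[1L, p]]
      b <- cv_mat[, pairs[2L, p]]
      ok <- stats::complete.cases(a, b)
      if (sum(ok) > 1L && stats::sd(a[ok] - b[ok]) > 0) {
        tt <- stats::t.test(a[ok], b[ok], paired = TRUE)
        ph[[length(ph) + 1L]] <- data.frame(
          network_a = pairs[1L, p], network_b = pairs[2L, p],
          t = unname(tt$statistic), p = tt$p.value,
          p_bonferroni = min(1, tt$p.value * n_pairs))
      }
    }
  }
  list(cv = cv_mat, anova = anova_df,
       posthoc = if (length(ph)) do.call(rbind, ph) else NULL,
       ranking = nets[order(colMeans(cv_mat, na.rm = TRUE),
                            decreasing = TRUE)])
}
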