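#' Assemble a pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis in one list with
#' explicit seeds, so a pipeline run is fully reproducible. Any subset of
#' stages can be toggled; later stages reuse the in-memory products of
#' earlier ones.
#'
#' @param out_dir output root directory.
#' @param seed master seed; per-stage seeds are derived from it.
#' @param cohort named list of [cohort_spec()] arguments.
#' @param window list: `width`, `stride`.
#' @param subsample list: `mode`, `rate` (see [subsample_windows()]).
#' @param cluster list: `k_min`, `k_max`, `replicates` (instability),
#'   `n_restarts`, `k_use` (solution used by downstream stages; default
#'   the cohort's true K).
#' @param fingerprint list: `n_permutations`.
#' @param groupdiff list: `covariates` (character), `q`, `alpha`.
#' @param predict list: `sign`, `train_fraction`, `n_permutations`,
#'   `p_threshold`, `alpha_enet`.
#' @param stages character vector of stages to run, in dependency order;
#'   subset of `c("simulate", "windows", "cluster", "hierarchy",
#'   "dynamics", "fingerprint", "groupdiff", "predict")`.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, cohort = list(),
                            window = list(), subsample = list(),
                            cluster = list(), fingerprint = list(),
                            groupdiff = list(), predict = list(),
                            stages = c("simulate", "windows", "cluster",
                                       "hierarchy", "dynamics",
                                       "fingerprint", "groupdiff",
                                       "predict")) {
  defaults <- list(
    window = list(width = 11L, stride = 1L),
    subsample = list(mode = "stride", rate = 0.1),
    cluster = list(k_min = 2L, k_max = 6L, replicates = 10L,
                   n_restarts = 10L, k_use = NULL),
    fingerprint = list(n_permutations = 200L),
    groupdiff = list(covariates = c("age", "sex", "motion"), q = 0.05,
                     alpha = 0.05),
    predict = list(sign = "positive", train_fraction = 0.7,
                   n_permutations = 200L, p_threshold = 0.05,
                   alpha_enet = 0.5))
  merge <- function(d, user) utils::modifyList(d, user)
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), cohort = cohort,
         window = merge(defaults$window, window),
         subsample = merge(defaults$subsample, subsample),
         cluster = merge(defaults$cluster, cluster),
         fingerprint = merge(defaults$fingerprint, fingerprint),
         groupdiff = merge(defaults$groupdiff, groupdiff),
         predict = merge(defaults$predict, predict),
         stages = stages),
    class = "pipeline_config")
}

#' Run the dynamic-state pipeline end to end
#'
#' Executes the configured stages in dependency order — simulate ->
#' windows -> cluster -> hierarchy -> dynamics -> fingerprint ->
#' groupdiff -> predict — writing each stage's outputs and a provenance
#' record under its own subdirectory of `config$out_dir`. Rerunning with
#' an identical configuration reproduces identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages (default FALSE).
#' @return named list of stage results (also the in-memory objects:
#'   cohort, windows, atlases, hierarchy, dynamics, fingerprint,
#'   groupdiff, predict).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  res <- list()
  stage_dir <- function(stage) {
    d <- file.path(config$out_dir, stage)
    dir.create(d, showWarnings = FALSE)
    d
  }
  provenance <- function(stage, info) {
    jsonlite::write_json(
      c(list(stage = stage, seed = config$seed,
             package_version = as.character(
               utils::packageVersion("dynstates"))), info),
      file.path(stage_dir(stage), "provenance.json"), auto_unbox = TRUE)
  }
  want <- function(stage) stage %in% config$stages

  if (want("simulate")) {
    say("stage simulate")
    spec <- do.call(cohort_spec,
                    utils::modifyList(config$cohort,
                                      list(seed = config$seed)))
    res$cohort <- generate_cohort(spec)
    write_cohort(res$cohort, stage_dir("simulate"))
    provenance("simulate", list(n_subjects = length(res$cohort$subjects)))
  }

  if (want("windows")) {
    if (is.null(res$cohort)) stopf("windows stage requires simulate")
    say("stage windows")
    w <- config$window
    res$windows <- lapply(res$cohort$subjects, function(subj)
      lapply(subj$runs, function(visit)
        lapply(visit, sliding_window_correlations,
               width = w$width, stride = w$stride)))
    counts <- vapply(res$windows, function(s)
      sum(vapply(s, function(v)
        sum(vapply(v, function(r) nrow(r$z_edges), integer(1))),
        integer(1))), integer(1))
    utils::write.csv(
      data.frame(subject_id = names(counts), n_windows = counts),
      file.path(stage_dir("windows"), "window_counts.csv"),
      row.names = FALSE)
    provenance("windows", list(width = w$width, stride = w$stride,
                               total_windows = sum(counts)))
  }

  if (want("cluster")) {
    if (is.null(res$windows)) stopf("cluster stage requires windows")
    say("stage cluster")
    cl <- config$cluster
    # pool visit-1 windows (the atlas session), subsampled
    visit1 <- unlist(lapply(res$windows, function(s) s[[1L]]),
                     recursive = FALSE)
    sub <- lapply(visit1, subsample_windows,
                  mode = config$subsample$mode,
                  rate = config$subsample$rate)
    pooled <- pool_windows(sub)
    ks <- cl$k_min:cl$k_max
    res$atlases <- lapply(ks, function(k)
      cluster_states(pooled, k, seed = child_seed(config$seed, 10L + k),
                     n_restarts = cl$n_restarts))
    names(res$atlases) <- paste0("K", ks)
    res$instability <- instability_analysis(
      pooled, k_range = ks, n_replicates = cl$replicates,
      seed = child_seed(config$seed, 20L), n_restarts = 4L)
    res$stable_k <- identify_stable_solutions(res$instability)
    d <- stage_dir("cluster")
    for (a in res$atlases)
      utils::write.csv(a$centroids,
                       file.path(d, sprintf("atlas_K%d.csv", a$k)),
                       row.names = TRUE)
    jsonlite::write_json(
      list(k_range = ks, instability = res$instability$instability,
           stable_k = res$stable_k,
           occupancy = lapply(res$atlases, `[[`, "occupancy")),
      file.path(d, "instability.json"), auto_unbox = TRUE, digits = 8)
    provenance("cluster", list(k_range = range(ks),
                               pooled_windows = nrow(pooled$z_edges)))
  }

  k_use <- config$cluster$k_use %||%
    (if (!is.null(res$cohort)) res$cohort$spec$n_states else NULL)

  if (want("hierarchy")) {
    if (is.null(res$atlases)) stopf("hierarchy stage requires cluster")
    say("stage hierarchy")
    res$hierarchy <- build_hierarchy(res$atlases)
    d <- stage_dir("hierarchy")
    utils::write.csv(hierarchy_edge_list(res$hierarchy),
                     file.path(d, "hierarchy_edges.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      lapply(unclass(res$hierarchy), function(h)
        list(parent_k = h$parent_k, child_k = h$child_k,
             merged_pair = h$merged_pair, assignment = h$assignment,
             cost = h$cost)),
      file.path(d, "hierarchy.json"), auto_unbox = TRUE, digits = 8)
    provenance("hierarchy", list(levels = length(res$hierarchy)))
  }

  if (want("dynamics")) {
    if (is.null(res$atlases)) stopf("dynamics stage requires cluster")
    say("stage dynamics")
    atlas <- res$atlases[[paste0("K", k_use)]]
    if (is.null(atlas)) stopf("no atlas for k_use = %d", k_use)
    res$sequences <- lapply(res$windows, function(s)
      lapply(s, function(v) lapply(v, assign_windows, atlas = atlas)))
    res$summaries <- lapply(res$sequences, function(s) {
      runs <- unlist(s, recursive = FALSE)
      pool_transition_summaries(lapply(runs, transition_statistics),
                                lapply(runs, `[[`, "labels"))
    })
    res$profiles <- lapply(names(res$windows), function(id)
      subject_state_profiles(unlist(res$windows[[id]],
                                    recursive = FALSE),
                             unlist(res$sequences[[id]],
                                    recursive = FALSE)))
    names(res$profiles) <- names(res$windows)
    d <- stage_dir("dynamics")
    seq_df <- do.call(rbind, lapply(names(res$sequences), function(id) {
      runs <- unlist(res$sequences[[id]], recursive = FALSE)
      do.call(rbind, lapply(runs, function(s)
        data.frame(subject_id = id, visit_id = s$visit_id,
                   run_id = s$run_id, window = seq_along(s$labels),
                   state = s$state_labels[s$labels])))
    }))
    utils::write.csv(seq_df, file.path(d, "state_sequences.csv"),
                     row.names = FALSE)
    dw <- t(vapply(res$summaries, `[[`, numeric(k_use),
                   "dwell_fraction"))
    utils::write.csv(data.frame(subject_id = rownames(dw), dw),
                     file.path(d, "dwell_fractions.csv"),
                     row.names = FALSE)
    provenance("dynamics", list(k_use = k_use))
  }

  if (want("fingerprint")) {
    if (is.null(res$sequences)) stopf("fingerprint stage requires dynamics")
    n_visits <- length(res$windows[[1L]])
    if (n_visits < 2L) {
      say("stage fingerprint skipped: single visit")
      res$fingerprint <- NULL
    } else {
      say("stage fingerprint")
      prof_visit <- function(v) {
        out <- lapply(names(res$windows), function(id)
          subject_state_profiles(res$windows[[id]][[v]],
                                 res$sequences[[id]][[v]]))
        names(out) <- names(res$windows)
        out
      }
      p1 <- prof_visit(1L)
      p2 <- prof_visit(2L)
      res$fingerprint <- lapply(seq_len(k_use), function(s)
        identification_rank_test(
          p1, p2, s,
          n_permutations = config$fingerprint$n_permutations,
          seed = child_seed(config$seed, 30L + s)))
      d <- stage_dir("fingerprint")
      utils::write.csv(
        data.frame(
          state = seq_len(k_use),
          rate = vapply(res$fingerprint, `[[`, numeric(1),
                        "identification_rate"),
          p = vapply(res$fingerprint, `[[`, numeric(1), "p_value")),
        file.path(d, "identification.csv"), row.names = FALSE)
      provenance("fingerprint",
                 list(n_permutations =
                        config$fingerprint$n_permutations))
    }
  }

  if (want("groupdiff")) {
    if (is.null(res$profiles)) stopf("groupdiff stage requires dynamics")
    say("stage groupdiff")
    subs <- res$cohort$subjects
    groups <- factor(vapply(subs, `[[`, character(1), "group"),
                     levels = c("control", "patient"))
    cov_names <- config$groupdiff$covariates
    covs <- as.data.frame(do.call(rbind, lapply(subs, function(s)
      s$covariates[cov_names])))
    names(covs) <- cov_names
    res$groupdiff <- list(
      edgewise = lapply(seq_len(k_use), function(s)
        edgewise_group_differences(res$profiles, groups, covs, s,
                                   q = config$groupdiff$q)),
      network = network_level_tests(
        res$profiles, groups, covs,
        res$cohort$spec$network_labels, states = seq_len(k_use),
        alpha = config$groupdiff$alpha),
      dwell = dwell_group_tests(
        t(vapply(res$summaries, `[[`, numeric(k_use),
                 "dwell_fraction")), groups, covs))
    d <- stage_dir("groupdiff")
    utils::write.csv(res$groupdiff$network,
                     file.path(d, "network_tests.csv"),
                     row.names = FALSE)
    utils::write.csv(res$groupdiff$dwell,
                     file.path(d, "dwell_tests.csv"), row.names = FALSE)
    edge_summary <- data.frame(
      state = seq_len(k_use),
      n_significant = vapply(res$groupdiff$edgewise, function(e)
        sum(e$mask), integer(1)))
    utils::write.csv(edge_summary,
                     file.path(d, "edgewise_summary.csv"),
                     row.names = FALSE)
    provenance("groupdiff", list(covariates = cov_names))
  }

  if (want("predict")) {
    if (is.null(res$profiles)) stopf("predict stage requires dynamics")
    say("stage predict")
    pc <- config$predict
    subs <- res$cohort$subjects
    pat <- names(subs)[vapply(subs, `[[`, character(1),
                              "group") == "patient"]
    labels <- vapply(subs[pat], `[[`, integer(1), "active_psychosis")
    # restrict to patients who expressed every state
    expressed <- vapply(res$profiles[pat], function(p)
      length(p$absent_states) == 0L, logical(1))
    pat <- pat[expressed]
    labels <- labels[expressed]
    if (length(unique(labels)) == 2L && min(table(labels)) >= 4L) {
      split <- stratified_split(labels, pc$train_fraction,
                                seed = child_seed(config$seed, 40L))
      tr <- pat[split$train]
      ho <- pat[split$holdout]
      per_state <- lapply(seq_len(k_use), function(s) {
        loocv <- fit_predict_loocv(
          res$profiles[tr], labels[split$train], s, sign = pc$sign,
          alpha = pc$alpha_enet, p_threshold = pc$p_threshold,
          seed = child_seed(config$seed, 50L + s))
        bundle <- train_prediction_model(
          res$profiles[tr], labels[split$train], s, sign = pc$sign,
          alpha = pc$alpha_enet, p_threshold = pc$p_threshold,
          seed = child_seed(config$seed, 60L + s))
        hold <- holdout_evaluate(
          bundle, res$profiles[ho], labels[split$holdout],
          n_permutations = pc$n_permutations,
          seed = child_seed(config$seed, 70L + s))
        list(state = s, loocv_auc = loocv$roc$auc,
             holdout_auc = hold$roc$auc, holdout_p = hold$p_value)
      })
      res$predict <- per_state
      d <- stage_dir("predict")
      utils::write.csv(
        do.call(rbind, lapply(per_state, as.data.frame)),
        file.path(d, "prediction.csv"), row.names = FALSE)
      provenance("predict",
                 list(sign = pc$sign, n_train = length(tr),
                      n_holdout = length(ho)))
    } else {
      say("stage predict skipped: label classes too small")
      res$predict <- NULL
    }
  }

  res
}

#' Command-line entry point
#'
#' `Rscript -e 'dynstates::dynstates_cli()' -- simulate --out dir --seed 7`
#' or via the installed helper script `inst/cli/dynstates.R`. Subcommands:
#' `simulate` (cohort only) and `run` (full pipeline); `--config` points
#' to a JSON file of [pipeline_config()] overrides.
#'
#' @param args character vector of CLI arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return invisibly, the pipeline result.
#' @export
dynstates_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args) || args[1L] %in% c("-h", "--help")) {
    cat("usage: dynstates <simulate|run> [--config cfg.json]",
        "[--out dir] [--seed N]\n")
    return(invisible(NULL))
  }
  cmd <- args[1L]
  opt <- list(out = "dynstates_out", seed = 1L, config = NULL)
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(opt)) stopf("unknown option --%s", key)
    opt[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  opt$seed <- as.integer(opt$seed)
  overrides <- if (!is.null(opt$config))
    jsonlite::read_json(opt$config, simplifyVector = TRUE) else list()
  cfg_args <- utils::modifyList(
    list(out_dir = opt$out, seed = opt$seed), overrides)
  if (cmd == "simulate") cfg_args$stages <- c("simulate")
  else if (cmd != "run") stopf("unknown subcommand '%s'", cmd)
  config <- do.call(pipeline_config, cfg_args)
  invisible(run_pipeline(config))
}
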