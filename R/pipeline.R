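#' Run the full analysis pipeline
#'
#' Chains preparation, feature extraction, Welch/clique feature selection,
#' the cross-validated model search against the 3-feature baseline, and
#' cross-model Shapley aggregation into direction-annotated importance
#' rankings, with per-stage count logging. Input is either a list of raw
#' recordings or a [cohort_spec()] to simulate.
#'
#' @param input list of [raw_recording()]s, or a `cohort_spec`.
#' @param cfg an [acti_config()].
#' @param out_dir optional directory; when given, the feature table
#'   (TSV), retained-model metrics (JSON) and per-task importance rankings
#'   (TSV) are written there.
#' @param verbose log per-stage counts (default TRUE).
#' @return list with `features` (the normalized `feature_table`),
#'   `baselines`, `search` (all results), `retained`, `rankings` (per
#'   task), and `log` (stage counts and thresholds used).
#' @export
run_pipeline <- function(input, cfg = acti_config(), out_dir = NULL,
                         verbose = TRUE) {
  log <- list(config = unclass(cfg))
  say <- function(...) if (verbose) message("[pipeline] ", ...)

  if (inherits(input, "cohort_spec")) {
    validate_config(cfg, input$sampling_rate)
    say("simulating cohort: ",
        paste(names(input$n_per_group), input$n_per_group,
              sep = "=", collapse = ", "))
    # stream: prepare each recording as it is generated, keep epochs only
    preps <- simulate_cohort(input, process = function(r)
      prep_recording(r, cfg))$recordings
  } else {
    validate_config(cfg, input[[1]]$sampling_rate)
    preps <- lapply(input, prep_recording, cfg = cfg)
  }
  tab <- build_feature_table(preps, cfg, verbose = verbose)
  log$n_subjects <- nrow(tab)
  log$n_features <- ncol(feature_matrix(tab))
  say("feature table: ", log$n_subjects, " subjects x ",
      log$n_features, " features")

  norm <- standard_normalize(tab)
  tasks <- make_tasks(norm$group_label)
  if (length(tasks) == 0L) stop("no propensity group among the labels")

  combos <- list(); log$selection <- list()
  for (tn in names(tasks)) {
    task <- tasks[[tn]]
    sub <- norm[task$rows, , drop = FALSE]
    class(sub) <- class(norm)
    kept <- welch_filter(sub, task$labels, task$positive, cfg$welch_alpha)
    g <- build_low_correlation_graph(sub, kept, cfg$corr_edge_threshold,
                                     cfg$corr_method)
    sel <- suppressWarnings(
      select_combinations(g, cfg$n_combinations, cfg$min_clique_size,
                          seed = child_seed(cfg$rng_seed, 77L)))
    combos[[tn]] <- sel$combinations
    log$selection[[tn]] <- list(welch_kept = length(kept),
                                cliques = sel$n_cliques,
                                combinations = length(combos[[tn]]))
    say(tn, ": Welch kept ", length(kept), "/", log$n_features,
        " (alpha=", cfg$welch_alpha, "); ", sel$n_cliques,
        " cliques >= ", cfg$min_clique_size, "; ",
        length(combos[[tn]]), " combinations sampled")
  }

  base_m <- baseline_features(lapply(preps[tab$subject_id], `[[`, "epochs"))
  baselines <- baseline_results(base_m, tasks, cfg$algorithms,
                                cfg$cv_folds, cfg$rng_seed)
  search <- run_search(norm, tasks, combos, cfg$algorithms,
                       cfg$cv_folds, cfg$rng_seed, verbose = verbose)
  retained <- filter_above_baseline(search$results, baselines)
  log$n_models <- length(search$results)
  log$n_retained <- length(retained)
  say(log$n_models, " models fitted (planned ", search$n_planned,
      "); ", log$n_retained, " above baseline")

  X <- feature_matrix(norm)
  rankings <- list()
  for (tn in names(tasks)) {
    task <- tasks[[tn]]
    task_models <- Filter(function(r) r$task == tn, retained)
    if (length(task_models) == 0L) { rankings[[tn]] <- NULL; next }
    shaps <- lapply(seq_along(task_models), function(i) {
      r <- task_models[[i]]
      shapley_values(r, X[task$rows, r$features, drop = FALSE],
                     exact_max = cfg$shap_exact_max,
                     n_perm = cfg$shap_n_perm,
                     background_max = cfg$shap_background_max,
                     seed = child_seed(cfg$rng_seed, 500L + i))
    })
    agg <- aggregate_attributions(shaps)
    rankings[[tn]] <- rank_features(agg, X[task$rows, , drop = FALSE],
                                    cfg$direction_r_cut)
    say(tn, ": aggregated Shapley over ", length(task_models),
        " retained models; top feature ", rankings[[tn]]$feature[1])
  }

  out <- list(features = norm, baselines = baselines, search = search,
              retained = retained, rankings = rankings, log = log)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_feature_table(norm, file.path(out_dir, "feature_table.tsv"))
    metrics <- lapply(retained, function(r)
      r[c("algorithm", "task", "combination", "accuracy", "precision",
          "recall")])
    jsonlite::write_json(metrics, file.path(out_dir, "retained_models.json"),
                         auto_unbox = TRUE, digits = NA)
    for (tn in names(rankings))
      utils::write.table(rankings[[tn]],
                         file.path(out_dir, paste0("importance_", tn, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
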