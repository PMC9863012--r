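# One full pipeline pass on a fresh synthetic cohort, returning the
# aggregated attribution directions for the injected target features and
# whether any algorithm beat its baseline on each task. Used by the
# recovery acceptance check; 48-hour recordings and 24 sampled
# combinations per task are the scaled problem sizes.

run_recovery_seed <- function(seed, targets,
                              n_combinations = 24, days = 2) {
  cfg <- acti_config(n_combinations = n_combinations,
                     rng_seed = as.integer(seed))
  spec <- cohort_spec(days_per_subject = days, seed = as.integer(seed),
                      start_time = T0)
  coh <- simulate_cohort(spec, process = function(r) prep_recording(r, cfg))
  preps <- coh$recordings
  tab <- build_feature_table(preps, cfg)
  norm <- standard_normalize(tab)
  tasks <- make_tasks(norm$group_label)
  X <- feature_matrix(norm)

  combos <- list()
  for (tn in names(tasks)) {
    task <- tasks[[tn]]
    sub <- norm[task$rows, , drop = FALSE]
    class(sub) <- class(norm)
    kept <- welch_filter(sub, task$labels, task$positive, cfg$welch_alpha)
    g <- build_low_correlation_graph(sub, kept, cfg$corr_edge_threshold)
    sel <- suppressWarnings(
      select_combinations(g, cfg$n_combinations, cfg$min_clique_size,
                          seed = actiphen:::child_seed(cfg$rng_seed, 77L)))
    combos[[tn]] <- sel$combinations
  }

  base_m <- baseline_features(lapply(preps[tab$subject_id], `[[`, "epochs"))
  baselines <- baseline_results(base_m, tasks, cfg$algorithms,
                                cfg$cv_folds, cfg$rng_seed)
  search <- run_search(norm, tasks, combos, cfg$algorithms,
                       cfg$cv_folds, cfg$rng_seed)
  retained <- filter_above_baseline(search$results, baselines)

  directions <- list(); beats <- logical(0)
  for (tn in names(tasks)) {
    task <- tasks[[tn]]
    task_models <- Filter(function(r) r$task == tn, retained)
    beats[tn] <- length(task_models) > 0
    if (!beats[tn]) { directions[[tn]] <- character(0); next }
    shaps <- lapply(seq_along(task_models), function(i) {
      r <- task_models[[i]]
      shapley_values(r, X[task$rows, r$features, drop = FALSE],
                     exact_max = cfg$shap_exact_max,
                     n_perm = cfg$shap_n_perm,
                     background_max = cfg$shap_background_max,
                     seed = actiphen:::child_seed(cfg$rng_seed, 500L + i))
    })
    rk <- rank_features(aggregate_attributions(shaps),
                        X[task$rows, , drop = FALSE], cfg$direction_r_cut)
    directions[[tn]] <- setNames(rk$direction, rk$feature)
  }
  sign_ok <- all(vapply(names(targets), function(tn) {
    want <- targets[[tn]]
    got <- directions[[tn]][names(want)]
    !anyNA(got) && all(got == want)
  }, logical(1)))
  list(directions = directions, beats = all(beats), all_signs = sign_ok)
}
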