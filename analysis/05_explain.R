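#!/usr/bin/env Rscript

# Stage 5 — explanation: per retained model, Shapley attributions of the
# positive-class probability (exact coalition enumeration for small
# feature sets, permutation sampling otherwise), summed row-wise across
# models of each task, then ranked by mean |attribution| with a
# value-correlation direction sign.

suppressPackageStartupMessages(library(actiphen))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(w <- which(args == "--seed"))) as.integer(args[w + 1]) else 1L

cfg <- acti_config(rng_seed = seed)
norm <- read_feature_table("results/feature_table_normalized.tsv")
tasks <- make_tasks(norm$group_label)
X <- feature_matrix(norm)
ms <- jsonlite::read_json("results/model_search.json",
                          simplifyVector = FALSE)

for (tn in names(tasks)) {
  task <- tasks[[tn]]
  models <- Filter(function(r) r$task == tn, ms$retained)
  if (length(models) == 0) {
    message(tn, ": no retained model; no ranking written")
    next
  }
  y01 <- as.integer(task$labels == task$positive)
  shaps <- lapply(seq_along(models), function(i) {
    r <- models[[i]]
    feats <- unlist(r$features)
    Xt <- X[task$rows, feats, drop = FALSE]
    fit <- fit_classifier(r$algorithm, Xt, y01, seed = seed + 1000L + i)
    shapley_values(fit, Xt, exact_max = cfg$shap_exact_max,
                   n_perm = cfg$shap_n_perm,
                   background_max = cfg$shap_background_max,
                   seed = seed + 2000L + i)
  })
  rk <- rank_features(aggregate_attributions(shaps),
                      X[task$rows, , drop = FALSE], cfg$direction_r_cut)
  out <- file.path("results", paste0("importance_", tn, ".tsv"))
  write.table(rk, out, sep = "\t", quote = FALSE, row.names = FALSE)
  message(tn, ": aggregated ", length(models), " retained models; top 5: ",
          paste(head(rk$feature, 5), "(", head(rk$direction, 5), ")",
                sep = "", collapse = ", "), " -> ", out)
}
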