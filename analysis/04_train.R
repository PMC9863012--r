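#!/usr/bin/env Rscript

# Stage 4 — model search: the 3-feature ZCM baseline per algorithm and
# task, one stratified 10-fold cross-validated model per
# (algorithm x task x combination), and retention of the models that
# strictly beat their baseline accuracy.

suppressPackageStartupMessages(library(actiphen))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(w <- which(args == "--seed"))) as.integer(args[w + 1]) else 1L

cfg <- acti_config(rng_seed = seed)
norm <- read_feature_table("results/feature_table_normalized.tsv")
tasks <- make_tasks(norm$group_label)
selection <- jsonlite::read_json("results/selection.json",
                                 simplifyVector = TRUE)
combos <- lapply(selection, function(s) {
  cc <- s$combinations
  if (is.matrix(cc)) lapply(seq_len(nrow(cc)), function(i) cc[i, ])
  else lapply(cc, as.character)
})

labels <- read.table("results/labels.tsv", sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE)
epochs <- lapply(labels$subject_id, function(id)
  read_epoch_series(file.path("results/epochs",
                              paste0(id, ".tsv")))$epochs)
names(epochs) <- labels$subject_id
base_m <- baseline_features(epochs[norm$subject_id])

baselines <- baseline_results(base_m, tasks, cfg$algorithms, cfg$cv_folds,
                              seed)
for (key in names(baselines))
  message("baseline ", key, ": accuracy ",
          round(baselines[[key]]$accuracy, 3))

search <- run_search(norm, tasks, combos, cfg$algorithms, cfg$cv_folds,
                     seed, verbose = TRUE)
retained <- filter_above_baseline(search$results, baselines)
message(length(search$results), " models fitted; ", length(retained),
        " beat their baseline")

saveit <- lapply(retained, function(r)
  r[c("algorithm", "task", "combination", "accuracy", "precision",
      "recall", "features")])
jsonlite::write_json(
  list(baselines = lapply(baselines, function(b)
         b[c("algorithm", "task", "accuracy", "precision", "recall")]),
       retained = saveit,
       n_models = length(search$results)),
  "results/model_search.json", auto_unbox = TRUE, digits = NA)
message("wrote results/model_search.json")
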