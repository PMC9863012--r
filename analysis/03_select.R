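#!/usr/bin/env Rscript

# Stage 3 — feature-selection funnel per case-control task: standard
# normalization, the lenient Welch screen against control, the
# low-correlation graph (|r| <= 0.3 edges kept), maximal cliques of at
# least 8 mutually weakly-correlated features, and the random sample of
# candidate combinations.

suppressPackageStartupMessages(library(actiphen))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(w <- which(args == "--seed"))) as.integer(args[w + 1]) else 1L
n_comb <- if (length(w <- which(args == "--combinations")))
  as.integer(args[w + 1]) else 40L

cfg <- acti_config(n_combinations = n_comb, rng_seed = seed)
tab <- read_feature_table("results/feature_table.tsv")
norm <- standard_normalize(tab)
write_feature_table(norm, "results/feature_table_normalized.tsv")
tasks <- make_tasks(norm$group_label)

selection <- list()
for (tn in names(tasks)) {
  task <- tasks[[tn]]
  sub <- norm[task$rows, , drop = FALSE]; class(sub) <- class(norm)
  kept <- welch_filter(sub, task$labels, task$positive, cfg$welch_alpha)
  g <- build_low_correlation_graph(sub, kept, cfg$corr_edge_threshold)
  sel <- suppressWarnings(
    select_combinations(g, cfg$n_combinations, cfg$min_clique_size,
                        seed = seed))
  selection[[tn]] <- list(welch_kept = as.vector(kept),
                          n_cliques = sel$n_cliques,
                          enumerated = sel$enumerated,
                          combinations = sel$combinations)
  message(tn, ": Welch kept ", length(kept), "/96 at alpha ",
          cfg$welch_alpha, "; ", sel$n_cliques, " maximal cliques >= ",
          cfg$min_clique_size, "; sampled ", length(sel$combinations),
          " combinations covering ",
          length(unique(unlist(sel$combinations))), " distinct features")
}
jsonlite::write_json(selection, "results/selection.json",
                     auto_unbox = TRUE, digits = NA)
message("wrote results/selection.json")
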