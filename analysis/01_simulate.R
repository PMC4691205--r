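#!/usr/bin/env Rscript
# Generate the synthetic study that stands in for the raw arrays: a
# four-group miRNA microarray experiment (611 arrayed probes, 228
# expressed, 29 planted fold changes of magnitude 2-6 in the allergic
# group, n = 6/group), a miRNA-gene interaction network with planted
# multi-targeted hub genes, and the ground truth for both.

suppressPackageStartupMessages(library(lungmir))

seed <- 20260922
out <- "results/simdata"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

sim <- simulate_expression(expression_sim_spec(seed = seed))
write_expression_table(sim$matrix, file.path(out, "expression.tsv"),
                       design = sim$design,
                       design_path = file.path(out, "design.tsv"))
cat(sprintf("expression: %d probes x %d samples (%d expressed, %d planted DE)\n",
            nrow(sim$matrix$values), ncol(sim$matrix$values),
            length(sim$truth$expressed_ids),
            nrow(sim$truth$planted_de)))

net <- simulate_interactions(interaction_sim_spec(
  n_mirnas = 611, n_genes = 600, n_hubs = 44,
  hub_degree_range = c(6, 12), background_edge_prob = 0.005,
  de_set = setNames(ifelse(sim$truth$planted_de$fc > 0, "up", "down"),
                    sim$truth$planted_de$mirna_id),
  mirna_ids = sprintf("mir-%04d", 1:611), seed = seed + 1))
write_interactions(net$interactions, file.path(out, "interactions.tsv"))
cat(sprintf("interactions: %d edges, %d planted hub genes (degree %d-%d)\n",
            nrow(net$interactions), nrow(net$truth$hub_genes),
            min(net$truth$hub_genes$degree),
            max(net$truth$hub_genes$degree)))

jsonlite::write_json(
  list(seed = seed,
       planted_de = sim$truth$planted_de,
       expressed_ids = sim$truth$expressed_ids,
       hub_genes = net$truth$hub_genes),
  file.path(out, "truth.json"), auto_unbox = TRUE, digits = NA)
cat("truth written to", file.path(out, "truth.json"), "\n")
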