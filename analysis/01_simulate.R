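#!/usr/bin/env Rscript
# Stage 1: generate every synthetic input the downstream stages consume.
# Emulates the study design: a two-group resistant-vs-parental expression
# experiment, a tumor/normal patient cohort partially expressing the
# resistance signature, a ranked drug-perturbation library with planted
# reversers, survival times with a planted hazard ratio, and a
# planted-community interaction network.

library(sigrev)

seed <- 1
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(n_genes = 2000, n_samples_per_group = 3, de_fraction = 0.05,
                  log2_effect = 2, noise_sd = 0.5, seed = seed)
sim <- gen_two_group_matrix(cfg)
write_gct(sim$matrix, file.path(out, "two_group_expression.gct"))
write_tsv(data.frame(gene = c(sim$truth$de_up, sim$truth$de_down),
                     direction = rep(c("up", "down"),
                                     c(length(sim$truth$de_up),
                                       length(sim$truth$de_down)))),
          file.path(out, "two_group_truth.tsv"), stage = "simulate",
          params = list(seed = seed))
cat(sprintf("two-group matrix: %d genes x %d samples, %d planted DE genes\n",
            nrow(sim$matrix$values), ncol(sim$matrix$values),
            length(sim$truth$de_up) + length(sim$truth$de_down)))

labels <- stats::setNames(rep(c("positive", "negative"), each = 150),
                          sprintf("pt_%03d", 1:300))
surv <- gen_survival(labels, hazard_ratio = 2, baseline_rate = 0.02,
                     censor_rate = 0.2, seed = seed + 1)
write_tsv(surv, file.path(out, "survival.tsv"), stage = "simulate",
          params = list(hazard_ratio = 2, seed = seed + 1))
cat(sprintf("survival table: %d patients, %.0f%% events\n",
            nrow(surv), 100 * mean(surv$event)))

sbm <- gen_planted_graph(100, 4, p_in = 0.3, p_out = 0.01, seed = seed + 2)
el <- igraph::as_data_frame(sbm$graph, what = "edges")
names(el)[1:2] <- c("protein1", "protein2")
write_tsv(el, file.path(out, "ppi_edges.tsv"), stage = "simulate",
          params = list(seed = seed + 2))
write_tsv(data.frame(node = names(sbm$truth$communities),
                     community = unname(sbm$truth$communities)),
          file.path(out, "ppi_truth.tsv"), stage = "simulate",
          params = list(seed = seed + 2))
cat(sprintf("interaction network: %d nodes, %d edges, 4 planted blocks\n",
            igraph::vcount(sbm$graph), igraph::ecount(sbm$graph)))
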