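#!/usr/bin/env Rscript
# Stage 3: score the resistance signature against a ranked drug-perturbation
# library with the weighted-KS connectivity statistic; scale per library,
# average replicate perturbations per drug, and cluster a score matrix of
# several query signatures.

library(sigrev)

seed <- 1
sig <- read_gmt("results/resistance_signature.gmt")$resistance

lib <- gen_drug_library(n_drugs = 100, n_genes = 2000, signature = sig,
                        n_reversers = 3, n_mimics = 3,
                        replicates_per_drug = 3, strength = 0.8,
                        seed = seed + 10)
scores <- score_library(sig, lib$profiles)
write_tsv(scores, "results/connectivity_scores.tsv", stage = "connect",
          params = list(seed = seed + 10, strength = 0.8))

ord <- order(scores$score)
cat("most negative (predicted reversers):\n")
print(utils::head(scores[ord, ], 5), row.names = FALSE)
cat("planted reversers:", paste(lib$truth$reverser_drugs, collapse = ", "),
    "\n")
hit <- mean(lib$truth$reverser_drugs %in%
              scores$drug_id[ord][seq_len(ceiling(0.05 * nrow(scores)))])
cat(sprintf("fraction of planted reversers in the bottom 5%%: %.2f\n", hit))

# score matrix over perturbed copies of the query, clustered on both axes
set.seed(seed)
variants <- lapply(1:4, function(i) {
  keep_u <- sort(sample(seq_along(sig$up), ceiling(0.8 * length(sig$up))))
  keep_d <- sort(sample(seq_along(sig$down), ceiling(0.8 * length(sig$down))))
  gene_signature(sprintf("resistance_v%d", i), sig$up[keep_u],
                 sig$down[keep_d])
})
sm <- score_matrix(c(list(sig), variants), lib$profiles)
cl <- hcluster(sm, "rows")
cat("row dendrogram order:", paste(cl$order, collapse = " "), "\n")
write_tsv(data.frame(signature = rownames(sm), sm, check.names = FALSE),
          "results/score_matrix.tsv", stage = "connect",
          params = list(seed = seed))
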