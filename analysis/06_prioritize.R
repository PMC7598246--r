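#!/usr/bin/env Rscript
# Stage 6: apply the drug-prioritization ledger (negative connectivity,
# approved/investigational status, antineoplastic action, disease-target
# flag) to the bundled annotation table, and run the treatment-reversal
# concordance analysis on a simulated drug-treatment experiment.

library(sigrev)

seed <- 1
ann <- load_drug_annotations()
scores <- data.frame(drug_id = ann$drug_id, score = ann$score)
prio <- prioritize(scores, ann, disease_genes = load_disease_genes())
write_tsv(prio, "results/priority_table.tsv", stage = "prioritize")
cat(sprintf("prioritized drugs: %d (%d with disease-associated targets)\n",
            nrow(prio), sum(prio$disease_target_flag)))
print(prio[prio$disease_target_flag,
           c("drug_id", "score", "status", "targets")], row.names = FALSE)

# reversal concordance: treat the resistant cells with a reversing drug and
# ask which signature genes move back, concordantly with the drug reference
sig <- read_gmt("results/resistance_signature.gmt")$resistance
cfg <- sim_config(n_genes = 2000, n_samples_per_group = 3, de_fraction = 0,
                  log2_effect = 0, noise_sd = 0.3, seed = seed + 30)
sim <- gen_two_group_matrix(cfg)          # vehicle vs treated, null backbone
v <- sim$matrix$values
treated_cols <- sim$matrix$group == "case"
# the drug reverses ~70% of the resistance signature
set.seed(seed + 31)
rev_up <- sample(sig$up, round(0.7 * length(sig$up)))
rev_dn <- sample(sig$down, round(0.7 * length(sig$down)))
v[rev_up, treated_cols] <- v[rev_up, treated_cols] - 2
v[rev_dn, treated_cols] <- v[rev_dn, treated_cols] + 2
treated <- sim$matrix; treated$values <- v
de <- moderated_ttest(treated)
drug_ref <- gene_signature("drug_effect", up = rev_dn, down = rev_up)
rc <- reversal_concordance(de, drug_ref, sig, alpha = 0.05)
cat(sprintf("reversal concordance: %d up-regulated and %d down-regulated signature genes reversed (planted %d/%d)\n",
            rc$n_up_reversed, rc$n_down_reversed,
            length(rev_up), length(rev_dn)))
write_tsv(data.frame(gene = c(rc$up_genes, rc$down_genes),
                     direction = rep(c("up_reversed", "down_reversed"),
                                     c(rc$n_up_reversed,
                                       rc$n_down_reversed))),
          "results/reversal_concordance.tsv", stage = "reversal",
          params = list(alpha = 0.05, seed = seed + 30))
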