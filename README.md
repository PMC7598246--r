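# sigrev — transcriptomic signature reversal for drug repurposing

Most patients with advanced hepatocellular carcinoma (HCC) eventually stop
responding to sorafenib, the standard first-line kinase inhibitor, and few
alternatives exist. One way to find new options quickly is *connectivity
mapping*: derive a gene expression signature of the resistant state (paired
up/down gene sets), then search a library of drug-perturbation expression
profiles for drugs whose transcriptional effect *opposes* that signature —
the hypothesis being that such drugs can reverse the resistance program.

`sigrev` is an R package, with an accompanying analysis workflow, for that
whole chain:

- **Signature extraction** — noise filtering, probe collapsing, an
  empirical-Bayes moderated t-statistic
  (t̃ = Δ / (s̃·√(1/n₁+1/n₂)), with s̃² = (d₀s₀² + d_g s²_g)/(d₀+d_g) and a
  method-of-moments prior), significance control of the mean number of
  false positives (cutoff k/G), BH-FDR, fold-change cutoffs, and a
  TMM/log-CPM path for count data.
- **Connectivity scoring** — the classic rank-based weighted
  Kolmogorov–Smirnov statistic: for tag ranks V(j),
  a = maxⱼ(j/t − V(j)/n), b = maxⱼ(V(j)/n − (j−1)/t), ES = a if a > b else
  −b; raw score s = ES_up − ES_down on opposite signs, per-library scaling
  to [−1, 1], replicate averaging per drug, score matrices with
  hierarchical clustering.
- **Nearest-template prediction (NTP)** — cosine distance of z-scored
  samples to a ±1 signature template, resampling significance against
  size-matched random templates, BH-FDR across samples, SR+/SR− calls,
  sensitivity/specificity with Clopper–Pearson intervals, Fisher tests.
- **Survival** — Kaplan–Meier curves, log-rank test, observed/expected
  hazard ratio with 95% CI, median bifurcation, chi-square contingency
  analyses.
- **Network analysis** — drug-target interaction graphs from scored edge
  lists (combined score ≥ 700), degree / clustering / eigencentrality
  (power iteration) / greedy-modularity communities, binomial edge
  enrichment, top-central gene selection, per-group alteration frequencies.
- **Prioritization** — the repurposing ledger (negative connectivity AND
  approved/investigational status AND antineoplastic action, flagged when
  targets are disease-associated) and a treatment-reversal concordance
  analysis.
- **Synthetic data** — seeded generators for every input above with planted
  ground truth (DE genes, reverser drugs, signature-positive samples,
  hazard ratios, graph communities), so each stage is tested as a recovery
  problem.

## Worked example

```r
library(sigrev)

# simulate a resistant-vs-parental experiment and extract the signature
sim <- gen_two_group_matrix(sim_config(n_genes = 2000, de_fraction = 0.05,
                                       log2_effect = 2, noise_sd = 0.5,
                                       seed = 1))
de  <- moderated_ttest(noise_filter(sim$matrix))
sig <- build_signature(de, name = "resistance",
                       p_cutoff = control_mean_fp(de$p),
                       fc_up = 2, fc_down = 0.5)
sig
#> <gene_signature> resistance: 45 up / 45 down genes

# score a drug library with three planted reversers
lib <- gen_drug_library(n_drugs = 100, n_genes = 2000, signature = sig,
                        n_reversers = 3, n_mimics = 3,
                        replicates_per_drug = 3, strength = 0.8, seed = 11)
scores <- score_library(sig, lib$profiles)
head(scores[order(scores$score), ], 4)
#>   drug_id      score n_replicates_averaged
#>  drug_001 -0.9444608                     3
#>  drug_002 -0.9071361                     3
#>  drug_003 -0.8965811                     3
#>  drug_071 -0.1225511                     3
lib$truth$reverser_drugs
#> [1] "drug_001" "drug_002" "drug_003"

# classify a simulated 100-tumor cohort in which half carry the signature
coh <- gen_signature_cohort(100, 0, sig, positive_fraction = 0.5,
                            noise_sd = 0.5, n_genes = 2000, seed = 21)
classify_cohort(coh$matrix, sig, seed = 22)
#> <ntp_classification> 100 samples; 50.0% positive (FDR < 0.05)
#> NEG POS
#>  50  50
```

The three planted reversers are the three most negative scores (averaged
over dose/time replicates and scaled to [−1, 1] per library), and the NTP
classifier recovers the planted 50% signature-positive fraction.

## Analysis workflow

The `analysis/` directory is a numbered, narrative version of the full
pipeline over the package's functions; each stage prints what it found and
writes its tables under `results/`:

```sh
Rscript analysis/01_simulate.R          # all synthetic inputs + truth sidecars
Rscript analysis/02_signature.R         # DE table + GMT signature
Rscript analysis/03_connectivity.R      # drug scores, score matrix, clustering
Rscript analysis/04_classify_survival.R # NTP calls, sens/spec, log-rank + HR
Rscript analysis/05_network.R           # network metrics, enrichment, communities
Rscript analysis/06_prioritize.R        # priority table, reversal concordance
```

Bundled under `inst/extdata/` are a published per-dataset cohort
classification summary (four resistance signatures × six HCC cohorts), a
20-drug prioritized annotation table, and a disease gene list, used by the
prioritization stage and the acceptance checks.

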