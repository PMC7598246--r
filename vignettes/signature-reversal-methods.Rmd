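---
title: "Methods: transcriptomic signature reversal for drug repurposing"
author: "sigrev"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transcriptomic signature reversal for drug repurposing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigrev)
```

# Overview

`sigrev` implements a connectivity-mapping workflow for drug-resistant
cancer. The chain of reasoning is: (1) a *resistance gene signature* — paired
up/down gene sets — is derived from a two-group expression experiment
comparing resistant and parental cells; (2) drugs whose transcriptional
effect *opposes* that signature (negative connectivity score against a
library of ranked drug-perturbation profiles) are candidate resistance
reversers; (3) the clinical relevance of the signature is checked by
classifying patient tumors as signature-positive (SR+) or -negative (SR−)
with nearest-template prediction and stratifying survival; (4) the drug
candidates' targets are analyzed as a protein-interaction network; and
(5) a prioritization ledger retains drugs that are feasible to repurpose.
Because the original inputs are external microarray, RNA-seq, perturbation
and clinical resources, a synthetic-data module generates every input with
planted ground truth, so each stage is testable as a recovery problem.

# Signature extraction

Inputs are gene-level log2 intensities (arrays) or raw counts (RNA-seq).
The array path applies, in order:

1. **Noise filter** — drop genes below a log2 cutoff (default 6) in at least
   85% of samples. Both parameters are exposed; the defaults describe a
   typical array noise floor.
2. **Probe collapsing** — arithmetic mean of probe-level values per gene.
3. **Moderated t** — per-gene pooled variance $s_g^2$ on $d_g$ df is shrunk
   toward a prior: $\tilde s^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$, and
   $\tilde t = \Delta/(\tilde s\sqrt{1/n_1 + 1/n_2})$ is referred to a t
   distribution on $d_0 + d_g$ df. The prior $(s_0^2, d_0)$ is estimated by
   method of moments on $\log s_g^2$: under the scaled-F model
   $\mathrm{Var}(\log s_g^2) = \psi_1(d_g/2) + \psi_1(d_0/2)$, so $d_0$
   comes from a Newton inversion of the trigamma function and $s_0^2$ from
   the matching mean equation. Setting `d0 = 0` disables shrinkage and
   reproduces the ordinary pooled t exactly (an oracle used in the tests);
   the full path is cross-checked against limma's independent
   empirical-Bayes implementation.
4. **Significance control** — the cutoff $k/G$ for $G$ tests bounds the
   *expected number of false positives* by $k$ (default $k = 1$; for
   $G = 10^4$ genes this is the familiar $p < 10^{-4}$). A BH-adjusted
   cutoff is available as an alternative route, since published analyses of
   this kind quote both conventions.
5. **Fold-change partition** — up if fold change > 3, down if < 0.25
   (both configurable), with up/down lists ordered by $|\tilde t|$ and ties
   broken lexicographically so signatures are bit-reproducible.

The count path filters genes with counts below 5 in at least 2 samples of
any group, computes TMM normalization factors (via edgeR; the package
reports *effective* scale factors, library size × TMM factor, normalized to
geometric mean 1), transforms to $\log_2(\mathrm{CPM} + 0.5)$ and reuses the
same moderated t.

**Known limitation.** The moment estimator of $d_0$ is noisy for small gene
counts: on null simulations with 500 genes the mean number of false
positives at the $k/G$ cutoff is ≈ 0.77 rather than 1 (conservative). At
the simulated study scale of 2000 genes it is ≈ 0.94, and tail calibration
is essentially exact at 50,000 genes. Simulation-based checks therefore use
G ≥ 2000.

**Fold-change cutoffs vs planted effects.** The default asymmetric cutoffs
(3, 0.25) imply log2 thresholds (1.585, 2.0). If data are simulated with a
planted |log2 fold change| of exactly 2, the down cutoff sits at the center
of the sampling distribution of the estimate, capping full-pipeline
sensitivity near 50% for down genes no matter how the statistics are
computed. Recovery tests therefore assert detection at the significance
threshold with the default cutoffs, and full-pipeline recovery with
cutoffs matched to the planted effect (2 and 0.5).

# Connectivity scoring

A drug-perturbation profile is a full ranking of the gene universe, most
up-regulated first. For a tag set of size $t$ with ascending ranks $V(j)$
in a profile of $n$ genes, the classic rank-based statistic is

$$a = \max_j\left(\tfrac{j}{t} - \tfrac{V(j)}{n}\right),\qquad
  b = \max_j\left(\tfrac{V(j)}{n} - \tfrac{j-1}{t}\right),$$

with enrichment score $a$ if $a > b$, else $-b$. The tie $a = b$ resolves
to $-b$ (strict reading of "$a$ if $a > b$"), a convention pinned by an
exhaustive enumeration oracle in the tests. A GSEA-style weighted running
sum (`weight_exponent = 1`, centered-rank weights) is available; the
default is the classic unweighted form because the downstream sign rule
and the $[-1, 1]$ scaling convention belong to that method. A useful
discrete identity, also exercised in the tests: reversing a profile maps
the one-sided extrema as $a' = b - 1/n$, $b' = a + 1/n$, so negation under
reversal holds only to within $1/n$ and can flip to the tie branch when
$|a - b| \le 2/n$.

The raw connectivity score of a signature is $s = ES_{up} - ES_{down}$ when
the two enrichments have strictly opposite signs and 0 otherwise; negative
$s$ means the drug moves the signature's up genes down and down genes up.
Per query, positive raw scores are divided by the library's maximum
positive score and negative ones by the absolute minimum, giving scaled
scores in $[-1, 1]$; replicate perturbations (dose/time) are then averaged
per drug *on the scaled scale*. Scoring first and averaging second — rather
than averaging ranks — keeps each replicate's profile intact; the reverse
order is not reconstructible from published descriptions of the upstream
service, so the package fixes score-then-average. Query genes missing from
the library universe raise an error rather than being dropped silently,
because silent drops change scores irreproducibly.

# Nearest-template prediction

The signature defines a template of +1 (up) and −1 (down) weights. Genes
are z-scored across the cohort; a sample's distance to the template is
$d = 1 - \cos(x, w)$ over the template genes, and since the inverse
template is $-w$, $d_- = 2 - d_+$ exactly. The nearer of template and
inverse proposes the label (POS/NEG). Weights beyond ±1 are deliberately
not used by default (the source method's per-gene weighting is available as
a hook) — the ±1 reading is the minimal reproducible one.

Significance uses random templates of the same size and ±1 composition,
drawn without replacement from the matrix universe. The null statistic is
the random template's *own nearest distance* (equivalently $|\cos|$),
matching the observed statistic; with this choice null p-values are uniform
on $[0, 1]$. Comparing the raw one-sided distance instead would give
p-values uniform on $[0, 0.5]$ — a subtle miscalibration this package
avoids. p-values are $(1 + \#\{null \le obs\})/(R + 1)$, floored at
$1/(R+1)$, BH-adjusted **across samples**, and calls with FDR ≥ α
(default 0.05) are UNCLASSIFIED.

`classify_cohort()` draws one shared set of null templates per cohort
(vectorized; deterministic given the seed); `ntp_significance()` is the
single-sample contract. The reported positive fraction is POS among
*evaluable* (confidently classified) tumor samples: on simulated cohorts
this estimator recovers planted positive fractions of 0.25/0.5/0.75 within
±0.10 at realistic noise, whereas POS-among-all-tumors collapses when
positives dominate, because the per-gene z-centering tracks the mixture.
For the same reason, cohorts containing many normals with an inverse
expression pattern shift the centering and bias the tumor positive fraction
upward — visible in the bundled analysis scripts and worth remembering when
comparing percentages across cohorts with different normal fractions.

# Survival and contingency analyses

Kaplan–Meier curves and the log-rank test come from the survival package.
The hazard ratio is the observed/expected ratio from the log-rank table,
$HR = (O_2/E_2)/(O_1/E_1)$, with CI
$\exp(\log HR \pm 1.96\sqrt{1/E_1 + 1/E_2})$ — self-contained, requires no
proportional-hazards fit, and inverts exactly when groups are swapped. A
Cox model would be the natural alternative; the O/E form was chosen because
the workflow reports HR alongside a log-rank p and nothing in the outputs
requires regression. Median bifurcation assigns values equal to the median
to "low" (deterministic contract). Contingency analyses use the Pearson
chi-square without continuity correction and the two-sided Fisher exact
test (enumeration-checked in the tests).

# Network analysis

The drug-target graph is induced on the targets plus their retained direct
interactors from a scored edge list, keeping edges with combined score ≥
700 (inclusive) and, optionally, support in specific evidence channels.
Metrics: degree; local clustering $2\Delta/(k(k-1))$ (0 for degree < 2);
eigenvector centrality by power iteration on $A + I$ — the identity shift
makes the Perron eigenvalue strictly dominant so iteration converges on
bipartite components too, without changing eigenvectors — run per connected
component (tolerance $10^{-10}$, max 1000 iterations) and normalized to a
maximum of 1 per component; communities by deterministic greedy modularity
maximization, relabelled by smallest member so output is stable. Edge
enrichment uses a binomial null with a user-supplied background density:
the degree-preserving null of interaction databases needs the full
interactome, which is out of scope, and the binomial form makes the null
explicit and testable.

# Prioritization ledger and reversal concordance

A drug is retained when its averaged connectivity score is negative, its
status is approved or investigational, and `antineoplastic` appears among
its normalized action keywords (exact keyword membership, not free-text
search). Retained drugs are flagged when any target gene appears in a
user-supplied disease gene list, replacing a literature-mining service with
a local file. The bundled annotation table and disease list reproduce a
published 20-drug prioritization: all 20 retained, 8 flagged.

Reversal concordance asks, among genes significant under drug treatment
(adjusted p < 0.05), which resistance up genes moved down and down genes
moved up, *concordantly* with an independent drug-reference signature.
Concordance is by sign only; the reference may be an up/down set or a
signed fold-change vector.

# The synthetic-data module

Each generator is a pure function of its parameters and seed, and its
defaults are the study conditions used by the tests and acceptance script:

| generator | emulates | key defaults |
|---|---|---|
| `gen_two_group_matrix` | resistant vs parental arrays | 2000 genes, 3/group, 5% DE, |log2FC| = 2, Gaussian noise sd 0.5 |
| `gen_two_group_counts` | RNA-seq counts | negative binomial, log-normal gene dispersions |
| `gen_drug_library` | ranked perturbation library | replicates tagged with dose/time; reverser/mimic placement probability = `strength` |
| `gen_signature_cohort` | tumor/normal patient cohorts | positives shifted ±1 log2 unit on signature genes, noise sd 0.5 |
| `gen_survival` | stratified survival | exponential times, rate × HR for positives, uniform censoring |
| `gen_planted_graph` | interaction network | stochastic block model, scores in [700, 1000] |

Choices worth recording: noise is independent Gaussian on the log2 scale
(arrays) — no probe-level artifacts, batch effects, or realistic L1000
inference noise are simulated, so passing recovery tests demonstrates
correctness of the statistics, not robustness to those real-data
pathologies. In the cohort generator, "non-positive" tumors are neutral
while normals carry the inverse pattern: normals should oppose a
resistance signature, while a resistant-signature-negative tumor is merely
not enriched. The per-sample log2 shift of 1 for signature genes makes
single-cohort classification informative but not trivial at noise sd 0.5.
Problem sizes in the test-suite simulations (e.g. 200-drug libraries of
500-gene profiles, 100-tumor cohorts, 500-replicate calibrations) were
chosen as the smallest sizes at which the Monte-Carlo standard errors are
well below the asserted tolerances.

# Reproducibility contract

Every generator and every stochastic analysis step takes an explicit seed;
two runs with the same configuration are byte-identical, which the test
suite asserts on the persisted pipeline outputs. File formats are the
community dialects nearest this data ecosystem: GCT for matrices, GMT for
signatures (paired `_UP`/`_DN` sets), TSV with a provenance header comment
(stage, parameters, seed) for everything else. Gene identifiers are opaque
case-sensitive strings; namespace mapping is the caller's concern.
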