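# Synthetic-data generators: every input the pipeline consumes, with planted
# ground truth. All generators are pure functions of their arguments + seed.

#' Simulation configuration for two-group expression data
#'
#' @param n_genes number of genes.
#' @param n_samples_per_group samples in each of the two groups.
#' @param de_fraction fraction of genes planted as differentially expressed.
#' @param log2_effect mean absolute log2 fold change of planted DE genes.
#' @param noise_sd per-gene Gaussian sd on the log2 scale.
#' @param baseline_mean baseline log2 expression level.
#' @param seed integer seed; fully determines the generated data.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000, n_samples_per_group = 3,
                       de_fraction = 0.05, log2_effect = 2, noise_sd = 0.5,
                       baseline_mean = 7, seed = 1) {
  if (n_genes < 1 || n_samples_per_group < 1)
    stop("invalid config: dimensions must be positive")
  if (de_fraction < 0 || de_fraction > 1)
    stop("invalid config: de_fraction must lie in [0, 1]")
  if (log2_effect < 0 || noise_sd < 0)
    stop("invalid config: effect and noise must be non-negative")
  if (de_fraction > 0 && de_fraction * n_genes < 1)
    stop("invalid config: de_fraction * n_genes must be at least 1")
  structure(list(n_genes = as.integer(n_genes),
                 n_samples_per_group = as.integer(n_samples_per_group),
                 de_fraction = de_fraction, log2_effect = log2_effect,
                 noise_sd = noise_sd, baseline_mean = baseline_mean,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a two-group log2 expression matrix with planted DE genes
#'
#' Emulates a parental-vs-resistant two-group microarray design: planted up
#' genes have case-minus-control mean difference `+log2_effect`, down genes
#' `-log2_effect`, all other genes 0, with independent Gaussian noise of sd
#' `noise_sd` on the log2 scale. Up and down planted sets are equal-sized
#' halves of the DE set.
#'
#' @param cfg a [sim_config()].
#' @return `list(matrix = expr_matrix, truth = list(de_up=, de_down=))`.
#' @export
gen_two_group_matrix <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  ng <- cfg$n_genes; ns <- cfg$n_samples_per_group
  genes <- sprintf("g%04d", seq_len(ng))
  n_de <- round(cfg$de_fraction * ng)
  de <- if (n_de > 0) sample(genes, n_de) else character(0)
  up <- de[seq_len(floor(n_de / 2))]
  down <- setdiff(de, up)
  v <- matrix(stats::rnorm(ng * 2 * ns, mean = cfg$baseline_mean,
                           sd = cfg$noise_sd),
              nrow = ng, dimnames = list(genes, c(
                sprintf("control_%d", seq_len(ns)),
                sprintf("case_%d", seq_len(ns)))))
  case_cols <- ns + seq_len(ns)
  v[up, case_cols] <- v[up, case_cols] + cfg$log2_effect
  v[down, case_cols] <- v[down, case_cols] - cfg$log2_effect
  m <- expression_matrix(v, group = rep(c("control", "case"), each = ns))
  list(matrix = m, truth = list(de_up = up, de_down = down))
}

#' Simulate a two-group RNA-seq count matrix with planted DE genes
#'
#' Negative-binomial counts with gene-wise dispersions drawn from a
#' log-normal distribution; planted DE genes change their mean by
#' `2^log2_effect` in the case group. `noise_sd` of the configuration is
#' reused as the sd of the log-normal dispersion distribution's log scale.
#'
#' @param cfg a [sim_config()]; `baseline_mean` is interpreted as the log2
#'   mean count.
#' @param dispersion_meanlog mean of `log(dispersion)` (default `log(0.1)`).
#' @return `list(matrix = expr_matrix (count scale), truth = ...)`.
#' @export
gen_two_group_counts <- function(cfg, dispersion_meanlog = log(0.1)) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  ng <- cfg$n_genes; ns <- cfg$n_samples_per_group
  genes <- sprintf("g%04d", seq_len(ng))
  n_de <- round(cfg$de_fraction * ng)
  de <- if (n_de > 0) sample(genes, n_de) else character(0)
  up <- de[seq_len(floor(n_de / 2))]
  down <- setdiff(de, up)
  mu <- matrix(2^cfg$baseline_mean, nrow = ng, ncol = 2 * ns,
               dimnames = list(genes, c(sprintf("control_%d", seq_len(ns)),
                                        sprintf("case_%d", seq_len(ns)))))
  case_cols <- ns + seq_len(ns)
  mu[up, case_cols] <- mu[up, case_cols] * 2^cfg$log2_effect
  mu[down, case_cols] <- mu[down, case_cols] / 2^cfg$log2_effect
  disp <- stats::rlnorm(ng, meanlog = dispersion_meanlog, sdlog = cfg$noise_sd)
  v <- matrix(stats::rnbinom(ng * 2 * ns, mu = mu, size = 1 / disp),
              nrow = ng, dimnames = dimnames(mu))
  m <- expression_matrix(v, group = rep(c("control", "case"), each = ns),
                         scale = "count")
  list(matrix = m, truth = list(de_up = up, de_down = down))
}

#' Simulate a drug-perturbation library of ranked profiles
#'
#' Every drug gets `replicates_per_drug` full-ranking profiles tagged with
#' distinct dose/time metadata. Planted reversers rank the signature's down
#' genes near the top of the list and up genes near the bottom; mimics do the
#' opposite; all remaining drugs rank uniformly at random. Each signature
#' gene is moved to its extreme block independently with probability
#' `strength`, giving a continuous dial from the null (0) to perfect
#' reversal/mimicry (1).
#'
#' @param n_drugs,n_genes library size and gene-universe size.
#' @param signature a [gene_signature()]; its genes must be contained in the
#'   generated universe (`g0001 ... g<n_genes>`).
#' @param n_reversers,n_mimics numbers of planted reversing / mimicking drugs.
#' @param replicates_per_drug profiles per drug (default 3).
#' @param strength placement probability in \[0, 1\].
#' @param seed integer seed.
#' @return `list(profiles = list of ranked_profile, truth = list(reverser_drugs=,
#'   mimic_drugs=))`.
#' @export
gen_drug_library <- function(n_drugs, n_genes, signature, n_reversers = 1,
                             n_mimics = 0, replicates_per_drug = 3,
                             strength = 0.8, seed = 1) {
  stopifnot(inherits(signature, "gene_signature"))
  if (n_reversers + n_mimics > n_drugs)
    stop("invalid config: more planted drugs than drugs")
  if (strength < 0 || strength > 1) stop("invalid config: strength in [0,1]")
  universe <- sprintf("g%04d", seq_len(n_genes))
  missing <- setdiff(c(signature$up, signature$down), universe)
  if (length(missing) > 0)
    stop("missing gene: signature genes not in universe: ",
         paste(missing, collapse = ", "))
  set.seed(seed)
  drugs <- sprintf("drug_%03d", seq_len(n_drugs))
  reversers <- drugs[seq_len(n_reversers)]
  mimics <- if (n_mimics > 0) drugs[n_reversers + seq_len(n_mimics)] else character(0)
  doses <- c("10uM", "1uM", "0.1uM", "0.01uM")
  times <- c("6h", "24h")

  place <- function(reverse) {
    perm <- sample(universe)
    act_up <- signature$up[stats::runif(length(signature$up)) < strength]
    act_dn <- signature$down[stats::runif(length(signature$down)) < strength]
    rest <- setdiff(perm, c(act_up, act_dn))
    top <- if (reverse) act_dn else act_up
    bottom <- if (reverse) act_up else act_dn
    c(sample(top), rest, sample(bottom))
  }

  profiles <- list()
  for (d in drugs) {
    for (r in seq_len(replicates_per_drug)) {
      ranked <- if (d %in% reversers) place(TRUE)
        else if (d %in% mimics) place(FALSE)
        else sample(universe)
      profiles[[length(profiles) + 1L]] <- ranked_profile(
        drug_id = d, ranked_genes = ranked, cell_line = "HEPG2",
        dose = doses[(r - 1L) %% length(doses) + 1L],
        time = times[(r - 1L) %/% length(doses) %% length(times) + 1L])
    }
  }
  list(profiles = profiles,
       truth = list(reverser_drugs = reversers, mimic_drugs = mimics))
}

#' Simulate a tumor/normal cohort in which some tumors express a signature
#'
#' A fraction `positive_fraction` of tumor samples expresses the template (up
#' genes elevated by `effect`, down genes suppressed); the remaining tumors
#' are neutral; normal samples express the inverse pattern. Gaussian noise of
#' sd `noise_sd` is added on the log2 scale.
#'
#' @param n_tumor,n_normal sample counts (either may be 0, not both).
#' @param signature a non-empty [gene_signature()].
#' @param positive_fraction fraction of tumors carrying the signature.
#' @param noise_sd Gaussian noise sd.
#' @param n_genes gene-universe size (must cover the signature; default 1000).
#' @param effect log2 shift applied to signature genes (default 1).
#' @param baseline_mean baseline log2 level (default 7).
#' @param seed integer seed.
#' @return `list(matrix = expr_matrix (with sample_type), truth =
#'   list(positive_samples=))`.
#' @export
gen_signature_cohort <- function(n_tumor, n_normal, signature,
                                 positive_fraction = 0.5, noise_sd = 0.5,
                                 n_genes = 1000, effect = 1,
                                 baseline_mean = 7, seed = 1) {
  stopifnot(inherits(signature, "gene_signature"))
  if (length(signature$up) == 0L && length(signature$down) == 0L)
    stop("invalid signature: empty gene sets")
  if (positive_fraction < 0 || positive_fraction > 1)
    stop("invalid config: positive_fraction in [0, 1]")
  if (n_tumor + n_normal < 1) stop("invalid config: empty cohort")
  sig_genes <- c(signature$up, signature$down)
  universe <- union(sig_genes, sprintf("g%04d", seq_len(n_genes)))
  set.seed(seed)
  ids <- c(if (n_tumor > 0) sprintf("tumor_%03d", seq_len(n_tumor)),
           if (n_normal > 0) sprintf("normal_%03d", seq_len(n_normal)))
  type <- c(rep("tumor", n_tumor), rep("normal", n_normal))
  v <- matrix(stats::rnorm(length(universe) * length(ids),
                           mean = baseline_mean, sd = noise_sd),
              nrow = length(universe), dimnames = list(universe, ids))
  n_pos <- round(positive_fraction * n_tumor)
  pos <- if (n_pos > 0) sample(ids[type == "tumor"], n_pos) else character(0)
  if (length(pos) > 0) {
    v[signature$up, pos] <- v[signature$up, pos] + effect
    v[signature$down, pos] <- v[signature$down, pos] - effect
  }
  normals <- ids[type == "normal"]
  if (length(normals) > 0) {
    v[signature$up, normals] <- v[signature$up, normals] - effect
    v[signature$down, normals] <- v[signature$down, normals] + effect
  }
  m <- expression_matrix(v, group = type, sample_type = type)
  list(matrix = m, truth = list(positive_samples = pos))
}

#' Simulate survival times with a planted hazard ratio
#'
#' Exponential event times with rate `baseline_rate * hazard_ratio` for
#' positive-labelled samples and `baseline_rate` for negative ones. Each
#' record is independently censored with probability `censor_rate`, at a
#' uniform time before its event.
#'
#' @param labels named character vector mapping sample ids to
#'   `"positive"`/`"negative"`.
#' @param hazard_ratio positive real; hazard multiplier for positives.
#' @param baseline_rate events per month for negatives (default 0.02).
#' @param censor_rate per-record censoring probability (default 0.2).
#' @param seed integer seed.
#' @return A `data.frame` with columns `sample_id`, `time` (months), `event`
#'   (1 = death), `group`.
#' @export
gen_survival <- function(labels, hazard_ratio, baseline_rate = 0.02,
                         censor_rate = 0.2, seed = 1) {
  if (length(labels) == 0L) stop("invalid config: empty label set")
  if (!is.numeric(hazard_ratio) || hazard_ratio <= 0)
    stop("invalid config: hazard_ratio must be positive")
  if (censor_rate < 0 || censor_rate >= 1)
    stop("invalid config: censor_rate in [0, 1)")
  set.seed(seed)
  n <- length(labels)
  rate <- ifelse(labels == "positive", baseline_rate * hazard_ratio,
                 baseline_rate)
  t_event <- stats::rexp(n, rate = rate)
  censored <- stats::runif(n) < censor_rate
  t_obs <- ifelse(censored, stats::runif(n) * t_event, t_event)
  data.frame(sample_id = names(labels), time = t_obs,
             event = as.integer(!censored), group = unname(labels),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Simulate a protein-interaction network with planted communities
#'
#' Stochastic block model with `n_communities` near-equal blocks:
#' within-block edge probability `p_in`, between-block `p_out`. Edges carry
#' combined confidence scores drawn uniformly from \[700, 1000\] (i.e. above
#' the usual high-confidence threshold).
#'
#' @param n_nodes,n_communities graph size and number of planted blocks.
#' @param p_in,p_out edge probabilities; a warning is raised when
#'   `p_in <= p_out` (communities unrecoverable).
#' @param seed integer seed.
#' @return `list(graph = igraph (edge attribute `combined_score`), truth =
#'   list(communities = named membership vector))`.
#' @export
gen_planted_graph <- function(n_nodes, n_communities = 1, p_in = 0.3,
                              p_out = 0.01, seed = 1) {
  if (n_nodes < 1) stop("invalid config: n_nodes must be positive")
  if (p_in <= p_out)
    warning("p_in <= p_out: planted communities are unrecoverable")
  set.seed(seed)
  sizes <- rep(n_nodes %/% n_communities, n_communities)
  extra <- n_nodes - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  pm <- matrix(p_out, n_communities, n_communities)
  diag(pm) <- p_in
  g <- igraph::sample_sbm(n_nodes, pref.matrix = pm, block.sizes = sizes)
  igraph::V(g)$name <- sprintf("node_%03d", seq_len(n_nodes))
  if (igraph::ecount(g) > 0)
    igraph::E(g)$combined_score <- stats::runif(igraph::ecount(g), 700, 1000)
  membership <- stats::setNames(rep(seq_len(n_communities), sizes),
                                igraph::V(g)$name)
  list(graph = g, truth = list(communities = membership))
}
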