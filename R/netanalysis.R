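# Drug-target interaction network: construction from a scored edge list,
# node metrics, edge-count enrichment, central genes, alteration frequencies.

#' Build a drug-target interaction graph from a scored edge list
#'
#' Keeps edges with `combined_score >= threshold` (inclusive) and, when
#' `channels` is given, with a positive score in at least one of the listed
#' evidence-channel columns. The graph is induced on the target genes plus
#' their retained direct interactors; duplicate and reversed rows collapse
#' to a single edge (keeping the maximum score) and self-loops are dropped.
#'
#' @param targets character vector of target gene ids.
#' @param edge_list `data.frame` with columns `protein1`, `protein2`,
#'   `combined_score` (0-1000 scale) and optional per-channel score columns.
#' @param threshold minimum combined score (default 700).
#' @param channels optional character vector of evidence-channel column
#'   names.
#' @return An undirected simple `igraph` with edge attribute
#'   `combined_score`.
#' @export
build_graph <- function(targets, edge_list, threshold = 700, channels = NULL) {
  need <- c("protein1", "protein2", "combined_score")
  if (!all(need %in% names(edge_list)))
    stop("edge list must have columns protein1, protein2, combined_score")
  bad <- which(!is.finite(edge_list$combined_score) |
                 edge_list$combined_score < 0 | edge_list$combined_score > 1000)
  if (length(bad) > 0)
    stop("malformed edge row(s) at line(s): ", paste(bad, collapse = ", "))
  if (threshold < 0 || threshold > 1001) stop("threshold must be in [0, 1001]")
  keep <- edge_list$combined_score >= threshold
  if (!is.null(channels)) {
    missing_ch <- setdiff(channels, names(edge_list))
    if (length(missing_ch) > 0)
      stop("unknown channel column(s): ", paste(missing_ch, collapse = ", "))
    ch <- as.matrix(edge_list[, channels, drop = FALSE])
    keep <- keep & rowSums(ch > 0) > 0
  }
  el <- edge_list[keep, , drop = FALSE]
  touches <- el$protein1 %in% targets | el$protein2 %in% targets
  nodes <- union(targets, unlist(el[touches, c("protein1", "protein2")]))
  el <- el[el$protein1 %in% nodes & el$protein2 %in% nodes, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = el$protein1, to = el$protein2,
               combined_score = el$combined_score),
    directed = FALSE,
    vertices = data.frame(name = nodes))
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                   edge.attr.comb = list(combined_score = "max"))
}

# Eigenvector centrality by power iteration on A + I (the identity shift
# makes the Perron eigenvalue strictly dominant, also on bipartite
# components, without changing eigenvectors). Max-entry normalized.
power_eigencentrality <- function(adj, tol = 1e-10, max_iter = 1000) {
  n <- nrow(adj)
  if (n == 1L) return(1)
  v <- rep(1 / sqrt(n), n)
  for (i in seq_len(max_iter)) {
    w <- as.vector(adj %*% v) + v
    w <- w / sqrt(sum(w^2))
    if (max(abs(w - v)) < tol) return(w / max(w))
    v <- w
  }
  stop(sprintf(
    "power iteration did not converge in %d iterations (last delta %.3e)",
    max_iter, max(abs(w - v))))
}

#' Per-node network metrics
#'
#' Degree; local clustering coefficient `2 * triangles / (k (k - 1))`
#' (defined as 0 for degree < 2); eigenvector centrality by power iteration
#' on each connected component (tolerance 1e-10, at most 1000 iterations,
#' max entry of each component normalized to 1); community by greedy
#' modularity maximization (deterministic; communities relabelled in order
#' of their smallest member node).
#'
#' @param g an undirected simple `igraph`.
#' @return `data.frame` with columns `node`, `degree`, `clustering`,
#'   `eigencentrality`, `community`.
#' @export
node_metrics <- function(g) {
  if (igraph::vcount(g) == 0L) stop("empty graph")
  nodes <- igraph::V(g)$name
  deg <- igraph::degree(g)
  clus <- igraph::transitivity(g, type = "local", vids = igraph::V(g),
                               isolates = "zero")
  comp <- igraph::components(g)$membership
  eig <- numeric(length(nodes))
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  for (cc in unique(comp)) {
    idx <- which(comp == cc)
    eig[idx] <- power_eigencentrality(adj[idx, idx, drop = FALSE])
  }
  memb <- if (igraph::ecount(g) > 0)
    as.integer(igraph::membership(igraph::cluster_fast_greedy(g)))
  else seq_along(nodes)
  first_member <- tapply(seq_along(memb), memb, min)
  community <- match(as.character(memb), names(sort(first_member)))
  data.frame(node = nodes, degree = unname(deg), clustering = clus,
             eigencentrality = eig, community = community,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Edge-count enrichment against a background density
#'
#' Binomial null: the expected edge count is `density * choose(|V|, 2)` and
#' `p = P(X >= observed)` for `X ~ Binomial(choose(|V|, 2), density)`.
#'
#' @param g an `igraph`.
#' @param background_density background edge probability in (0, 1\].
#' @return One-sided enrichment p-value.
#' @export
ppi_enrichment <- function(g, background_density) {
  obs <- igraph::ecount(g)
  n_pairs <- choose(igraph::vcount(g), 2)
  if (background_density <= 0) {
    if (obs > 0) {
      warning("degenerate null: zero background density with observed edges")
      return(0)
    }
    return(1)
  }
  if (background_density > 1) stop("background density must be in (0, 1]")
  stats::pbinom(obs - 1, n_pairs, background_density, lower.tail = FALSE)
}

#' Top central genes by eigencentrality
#'
#' Ties broken by degree (descending) then gene id (ascending); stable
#' under node-order permutation.
#'
#' @param metrics `data.frame` from [node_metrics()].
#' @param k number of genes (default 100); capped at `|V|` with a warning.
#' @return Character vector of gene ids.
#' @export
top_central <- function(metrics, k = 100) {
  if (k > nrow(metrics)) {
    warning("k exceeds node count; returning all nodes")
    k <- nrow(metrics)
  }
  ord <- order(-metrics$eigencentrality, -metrics$degree, metrics$node)
  metrics$node[ord][seq_len(k)]
}

#' Per-group alteration frequency of a gene list
#'
#' For each sample group, the fraction of patients carrying at least one
#' alteration in any of the listed genes.
#'
#' @param alterations `data.frame` with columns `patient`, `gene` (one row
#'   per altered gene per patient).
#' @param genes character vector of genes of interest.
#' @param groups named character vector mapping every patient to a group
#'   (e.g. `"POS"`/`"NEG"`).
#' @return Named numeric vector of per-group fractions.
#' @export
alteration_frequency <- function(alterations, genes, groups) {
  stopifnot(all(c("patient", "gene") %in% names(alterations)))
  patients <- names(groups)
  if (length(patients) == 0L) stop("empty group assignment")
  hit <- alterations$patient[alterations$gene %in% genes]
  lv <- unique(unname(groups))
  out <- vapply(lv, function(g) {
    members <- patients[groups == g]
    if (length(members) == 0L) stop("undefined fraction: empty group ", g)
    mean(members %in% hit)
  }, numeric(1))
  stats::setNames(out, lv)
}
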