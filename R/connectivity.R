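# Connectivity scoring: weighted-KS enrichment of query signatures in ranked
# drug profiles, per-library scaling, replicate averaging, score matrices.

#' Kolmogorov-Smirnov enrichment of a tag set in a ranked profile
#'
#' Classic rank-based running-sum statistic. With `V(j)` the ascending ranks
#' of the `t` tag genes in a profile of `n` genes,
#' `a = max_j(j/t - V(j)/n)` and `b = max_j(V(j)/n - (j-1)/t)`; the score is
#' `a` when `a > b`, else `-b` (a tie at `a == b` resolves to `-b`).
#' Positive scores mean the tags concentrate near the top (most
#' up-regulated end) of the profile.
#'
#' `weight_exponent = 1` instead runs the GSEA-style weighted running sum
#' with centered-rank weights `|(n + 1)/2 - V|` and returns its signed
#' extremum.
#'
#' @param tags character vector of gene ids (the tag set).
#' @param profile a [ranked_profile()] whose universe contains all tags.
#' @param weight_exponent 0 (classic, default) or 1 (rank-weighted).
#' @return Enrichment score in (-1, 1).
#' @export
ks_enrichment <- function(tags, profile, weight_exponent = 0) {
  stopifnot(inherits(profile, "ranked_profile"))
  if (length(tags) < 1L) stop("empty tag set")
  pos <- match(tags, profile$ranked_genes)
  if (anyNA(pos))
    stop("missing gene: tags not in profile universe: ",
         paste(tags[is.na(pos)], collapse = ", "))
  n <- length(profile$ranked_genes)
  v <- sort(pos)
  t <- length(v)
  if (weight_exponent == 0) {
    j <- seq_len(t)
    a <- max(j / t - v / n)
    b <- max(v / n - (j - 1) / t)
    if (a > b) a else -b
  } else if (weight_exponent == 1) {
    w <- abs((n + 1) / 2 - v)
    hit <- numeric(n)
    hit[v] <- w / sum(w)
    miss <- numeric(n)
    miss[-v] <- 1 / (n - t)
    run <- cumsum(hit - miss)
    run[which.max(abs(run))]
  } else stop("weight_exponent must be 0 or 1")
}

#' Connectivity score of a signature against one profile
#'
#' Computes the KS enrichment of the signature's up and down sets in the
#' profile; the raw score is `es_up - es_down` when the two enrichments have
#' strictly opposite signs, and 0 otherwise. Negative raw scores indicate
#' that the drug's transcriptional effect opposes (reverses) the query
#' signature.
#'
#' @param sig a [gene_signature()] with non-empty up and down sets.
#' @param profile a [ranked_profile()].
#' @param weight_exponent passed to [ks_enrichment()].
#' @return One-row `data.frame`: `drug_id`, `dose`, `time`, `es_up`,
#'   `es_down`, `raw`.
#' @export
connectivity_score <- function(sig, profile, weight_exponent = 0) {
  stopifnot(inherits(sig, "gene_signature"))
  if (length(sig$up) == 0L || length(sig$down) == 0L)
    stop("signature must have non-empty up and down sets")
  es_up <- ks_enrichment(sig$up, profile, weight_exponent)
  es_down <- ks_enrichment(sig$down, profile, weight_exponent)
  raw <- if (es_up * es_down < 0) es_up - es_down else 0
  data.frame(drug_id = profile$drug_id, dose = profile$dose,
             time = profile$time, es_up = es_up, es_down = es_down,
             raw = raw, stringsAsFactors = FALSE)
}

#' Scale raw connectivity scores to \[-1, 1\]
#'
#' Per query, across a library: positive raw scores are divided by the
#' maximum positive score, negative ones by the absolute minimum negative
#' score; zeros stay zero.
#'
#' @param raw numeric vector of raw scores over a library.
#' @return Scaled scores in \[-1, 1\].
#' @export
scale_scores <- function(raw) {
  if (length(raw) == 0L) stop("empty score vector")
  out <- numeric(length(raw))
  if (any(raw > 0)) out[raw > 0] <- raw[raw > 0] / max(raw[raw > 0])
  if (any(raw < 0)) out[raw < 0] <- raw[raw < 0] / abs(min(raw[raw < 0]))
  if (all(raw == 0)) warning("degenerate library: all raw scores are zero")
  out
}

#' Average scaled scores over replicate profiles of each drug
#'
#' @param results `data.frame` with columns `drug_id` and `scaled` (one row
#'   per profile).
#' @return `data.frame` with columns `drug_id`, `score` (mean scaled score)
#'   and `n_replicates_averaged`, ordered by first appearance.
#' @export
average_replicates <- function(results) {
  stopifnot(all(c("drug_id", "scaled") %in% names(results)))
  f <- factor(results$drug_id, levels = unique(results$drug_id))
  data.frame(drug_id = levels(f),
             score = as.vector(tapply(results$scaled, f, mean)),
             n_replicates_averaged = as.vector(table(f)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Score one signature against a whole library
#'
#' Raw scores for every profile, per-library scaling, then replicate
#' averaging per drug.
#'
#' @param sig a [gene_signature()].
#' @param profiles list of [ranked_profile()] objects.
#' @param weight_exponent passed to [ks_enrichment()].
#' @return `data.frame` from [average_replicates()] (`drug_id`, `score`,
#'   `n_replicates_averaged`).
#' @export
score_library <- function(sig, profiles, weight_exponent = 0) {
  if (length(profiles) == 0L) stop("empty library")
  per <- do.call(rbind, lapply(profiles, function(p)
    connectivity_score(sig, p, weight_exponent)))
  per$scaled <- scale_scores(per$raw)
  average_replicates(per)
}

#' Connectivity score matrix for several query signatures
#'
#' @param queries list of [gene_signature()] objects (shared gene universe
#'   with the library).
#' @param profiles list of [ranked_profile()] objects.
#' @param weight_exponent passed to [ks_enrichment()].
#' @return Numeric matrix: rows = query names, columns = drug ids, values =
#'   per-query scaled, per-drug averaged scores.
#' @export
score_matrix <- function(queries, profiles, weight_exponent = 0) {
  if (length(profiles) == 0L) stop("empty library")
  if (length(queries) == 0L) stop("no query signatures")
  rows <- lapply(queries, function(q) {
    sc <- score_library(q, profiles, weight_exponent)
    stats::setNames(sc$score, sc$drug_id)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- vapply(queries, function(q) q$name, character(1))
  out
}

#' Hierarchical clustering of a score matrix axis
#'
#' Agglomerative clustering with Euclidean distance and complete linkage.
#' `hclust` processes items in input order, so label order under exact
#' distance ties follows the input order.
#'
#' @param mat numeric matrix (e.g. from [score_matrix()]).
#' @param axis `"rows"` or `"cols"`.
#' @return `list(linkage = hclust object, order = ordered labels)`.
#' @export
hcluster <- function(mat, axis = c("rows", "cols")) {
  axis <- match.arg(axis)
  x <- if (axis == "rows") mat else t(mat)
  if (nrow(x) < 2L) stop("need at least 2 items on the clustered axis")
  d <- stats::dist(x, method = "euclidean")
  if (all(d == 0)) warning("zero-distance: all items identical")
  h <- stats::hclust(d, method = "complete")
  list(linkage = h, order = rownames(x)[h$order])
}

#' Pairwise up/down overlap counts between signatures
#'
#' @param sigs list of [gene_signature()] objects (length >= 2).
#' @return `list(up = matrix, down = matrix)` of pairwise intersection
#'   counts, dimnames = signature names.
#' @export
signature_overlap <- function(sigs) {
  if (length(sigs) < 2L) stop("need at least two signatures")
  nm <- vapply(sigs, function(s) s$name, character(1))
  k <- length(sigs)
  up <- dn <- matrix(0L, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    up[i, j] <- length(intersect(sigs[[i]]$up, sigs[[j]]$up))
    dn[i, j] <- length(intersect(sigs[[i]]$down, sigs[[j]]$down))
  }
  list(up = up, down = dn)
}
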