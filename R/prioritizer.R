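# Drug prioritization ledger and treatment-reversal concordance analysis.

split_keywords <- function(x) {
  lapply(strsplit(ifelse(is.na(x), "", x), ","), function(v)
    tolower(trimws(v[nzchar(trimws(v))])))
}

#' Apply the drug-prioritization ledger
#'
#' A drug is retained when (i) its averaged connectivity score is negative
#' (predicted to reverse the query signature), (ii) its status is
#' `approved` or `investigational`, and (iii) `antineoplastic` appears in
#' its normalized action keywords. Retained drugs are flagged when any of
#' their target genes appears in the disease gene list, and sorted by
#' status (approved first) then score ascending.
#'
#' @param scores `data.frame` with columns `drug_id`, `score` (e.g. from
#'   [score_library()]).
#' @param annotations `data.frame` with columns `drug_id`, `status`,
#'   `actions` (comma-separated keywords), `targets` (comma-separated gene
#'   ids). Scored drugs without annotation are dropped with a message.
#' @param disease_genes character vector of disease-associated genes; when
#'   empty, all flags are `FALSE` (with a warning).
#' @return `data.frame` of class `priority_table`: `drug_id`, `score`,
#'   `status`, `targets`, `actions`, `disease_target_flag`.
#' @export
prioritize <- function(scores, annotations, disease_genes = character(0)) {
  stopifnot(all(c("drug_id", "score") %in% names(scores)),
            all(c("drug_id", "status", "actions", "targets") %in%
                  names(annotations)))
  if (anyDuplicated(annotations$drug_id)) stop("duplicate drug annotations")
  if (length(disease_genes) == 0L)
    warning("empty disease gene list: all disease flags FALSE")
  idx <- match(scores$drug_id, annotations$drug_id)
  n_drop <- sum(is.na(idx))
  if (n_drop > 0)
    message(n_drop, " scored drug(s) without annotation dropped")
  sc <- scores[!is.na(idx), , drop = FALSE]
  an <- annotations[idx[!is.na(idx)], , drop = FALSE]
  actions <- split_keywords(an$actions)
  targets <- split_keywords(an$targets)
  status <- tolower(trimws(an$status))
  keep <- sc$score < 0 &
    status %in% c("approved", "investigational") &
    vapply(actions, function(a) "antineoplastic" %in% a, logical(1))
  flag <- vapply(targets, function(tg)
    length(intersect(tg, tolower(disease_genes))) > 0, logical(1))
  out <- data.frame(drug_id = sc$drug_id, score = sc$score, status = status,
                    targets = an$targets, actions = an$actions,
                    disease_target_flag = flag,
                    row.names = NULL, stringsAsFactors = FALSE)[keep, ]
  out <- out[order(match(out$status, c("approved", "investigational")),
                   out$score), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("priority_table", "data.frame")
  out
}

#' Treatment-reversal concordance of a resistance signature
#'
#' Among genes significantly differentially expressed under drug treatment
#' (`adj_p < alpha`), a resistance *up* gene counts as reversed when its
#' treated fold change is negative and concordant (same sign) with the drug
#' reference signature; symmetrically, a resistance *down* gene counts when
#' its treated fold change is positive and concordant. Genes absent from
#' the drug reference or the resistance signature are not counted.
#'
#' @param treated_de a `de_result` (with `adj_p`) for treated-vs-vehicle.
#' @param drug_reference either a [gene_signature()] (sign-only reference)
#'   or a named numeric vector of signed fold changes.
#' @param resistance_sig the resistance [gene_signature()].
#' @param alpha adjusted-p cutoff (default 0.05).
#' @return `list(n_up_reversed=, n_down_reversed=, up_genes=, down_genes=,
#'   alpha=)`.
#' @export
reversal_concordance <- function(treated_de, drug_reference, resistance_sig,
                                 alpha = 0.05) {
  stopifnot(inherits(resistance_sig, "gene_signature"))
  ref_sign <- if (inherits(drug_reference, "gene_signature")) {
    stats::setNames(c(rep(1, length(drug_reference$up)),
                      rep(-1, length(drug_reference$down))),
                    c(drug_reference$up, drug_reference$down))
  } else {
    if (is.null(names(drug_reference)))
      stop("fold-change drug reference must be a named vector")
    sign(drug_reference)
  }
  sig <- treated_de[treated_de$adj_p < alpha, , drop = FALSE]
  tr_sign <- stats::setNames(sign(sig$log2fc), sig$gene)
  concord <- function(genes, wanted) {
    g <- genes[genes %in% names(tr_sign) & genes %in% names(ref_sign)]
    g[tr_sign[g] == wanted & ref_sign[g] == wanted]
  }
  up_rev <- concord(resistance_sig$up, -1)
  dn_rev <- concord(resistance_sig$down, 1)
  list(n_up_reversed = length(up_rev), n_down_reversed = length(dn_rev),
       up_genes = unname(up_rev), down_genes = unname(dn_rev), alpha = alpha)
}

#' Per-etiology signature extraction
#'
#' Runs the full signature-extraction pipeline independently on each
#' etiology-specific tumor/normal cohort.
#'
#' @param cohorts named list of [expression_matrix()] objects, each with a
#'   two-level group (reference level = normal).
#' @param ... passed to [extract_signature()].
#' @return Named list of [gene_signature()] objects.
#' @export
etiology_signatures <- function(cohorts, ...) {
  if (length(cohorts) == 0L) stop("no cohorts")
  if (is.null(names(cohorts))) names(cohorts) <- paste0("etiology", seq_along(cohorts))
  lapply(stats::setNames(names(cohorts), names(cohorts)), function(nm) {
    m <- cohorts[[nm]]
    if (nlevels(m$group) != 2L)
      stop("invalid cohort '", nm, "': need tumor and normal groups")
    extract_signature(m, name = nm, ...)
  })
}
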