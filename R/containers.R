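#' Expression matrix with sample group labels
#'
#' Light container for a gene x sample matrix of log2 intensities or raw
#' counts, together with the two-group design used by the differential
#' expression steps. Gene identifiers are opaque strings matched
#' case-sensitively; namespace mapping is the caller's concern.
#'
#' @param values numeric matrix, genes in rows (rownames required), samples in
#'   columns (colnames required).
#' @param group factor or character of length `ncol(values)`; the first factor
#'   level is treated as the reference (control) group.
#' @param scale `"log2"` for log2 intensities, `"count"` for raw counts
#'   (non-negative integers).
#' @param sample_type optional character of length `ncol(values)` with values
#'   `"tumor"`/`"normal"`, used by cohort classification summaries.
#' @return An object of class `expr_matrix`: a list with elements `values`,
#'   `group`, `scale` and optionally `sample_type`.
#' @export
expression_matrix <- function(values, group, scale = c("log2", "count"),
                              sample_type = NULL) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("invalid config: matrix dimensions must be positive")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` needs rownames (genes) and colnames (samples)")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids")
  if (length(group) != ncol(values))
    stop("`group` length must match the number of samples")
  group <- if (is.factor(group)) droplevels(group) else factor(group, levels = unique(group))
  names(group) <- colnames(values)
  if (scale == "count") {
    if (any(values < 0) || any(values != floor(values)))
      stop("wrong scale: count matrices must contain non-negative integers")
  }
  out <- list(values = values, group = group, scale = scale)
  if (!is.null(sample_type)) {
    stopifnot(length(sample_type) == ncol(values))
    out$sample_type <- stats::setNames(as.character(sample_type), colnames(values))
  }
  class(out) <- "expr_matrix"
  out
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale))
  cat("  groups:", paste(sprintf("%s=%d", levels(x$group), table(x$group)),
                         collapse = ", "), "\n")
  invisible(x)
}

#' Up/down gene signature
#'
#' Paired, ordered sets of up- and down-regulated genes defining a biological
#' state (here drug resistance), with the thresholds that produced them.
#'
#' @param name signature name.
#' @param up,down character vectors of gene ids; must be disjoint.
#' @param thresholds named list of the cutoffs used (recorded verbatim).
#' @param provenance free-text description of how the signature was derived.
#' @return An object of class `gene_signature`.
#' @export
gene_signature <- function(name, up, down, thresholds = list(), provenance = "") {
  up <- as.character(up); down <- as.character(down)
  if (anyDuplicated(up) || anyDuplicated(down))
    stop("duplicate genes within a signature set")
  if (length(intersect(up, down)) > 0L)
    stop("up and down sets must be disjoint")
  if (length(up) == 0L || length(down) == 0L)
    warning("empty signature: up or down list has no genes")
  structure(list(name = name, up = up, down = down,
                 thresholds = thresholds, provenance = provenance),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("<gene_signature> %s: %d up / %d down genes\n",
              x$name, length(x$up), length(x$down)))
  invisible(x)
}

#' One ranked drug-perturbation profile
#'
#' A single perturbation experiment represented as a full ranking of the gene
#' universe: most up-regulated gene first (rank 1), most down-regulated last.
#'
#' @param drug_id drug identifier shared by replicate profiles.
#' @param ranked_genes character vector: permutation of the library's gene
#'   universe, no duplicates.
#' @param cell_line,dose,time replicate metadata strings.
#' @return An object of class `ranked_profile`.
#' @export
ranked_profile <- function(drug_id, ranked_genes, cell_line = NA_character_,
                           dose = NA_character_, time = NA_character_) {
  ranked_genes <- as.character(ranked_genes)
  if (anyDuplicated(ranked_genes))
    stop("ranked_genes must not contain duplicates")
  structure(list(drug_id = drug_id, cell_line = cell_line, dose = dose,
                 time = time, ranked_genes = ranked_genes),
            class = "ranked_profile")
}

#' @export
print.ranked_profile <- function(x, ...) {
  cat(sprintf("<ranked_profile> %s (%s, %s, %s): %d genes\n",
              x$drug_id, x$cell_line, x$dose, x$time, length(x$ranked_genes)))
  invisible(x)
}
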