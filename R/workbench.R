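# File formats (GCT, GMT, TSV) and the end-to-end pipeline driver.
# Readers reject malformed input rather than silently coercing it.

#' Read a GCT 1.2 expression matrix
#'
#' @param path path to a GCT file (version line `#1.2`, dimension line,
#'   header `NAME`, `Description`, sample ids).
#' @param group optional group labels (length = number of samples); when
#'   omitted, a single group `"all"` is assigned.
#' @param scale `"log2"` or `"count"`.
#' @return An [expression_matrix()]; row descriptions kept as attribute
#'   `description`.
#' @export
read_gct <- function(path, group = NULL, scale = "log2") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 3L) stop("format error: truncated GCT file")
  if (!grepl("^#1\\.[23]", lines[1L]))
    stop("format error: missing GCT version line")
  dims <- as.integer(strsplit(lines[2L], "\t")[[1L]][1:2])
  body <- utils::read.delim(text = lines[-(1:2)], check.names = FALSE,
                            stringsAsFactors = FALSE)
  if (nrow(body) != dims[1L] || ncol(body) - 2L != dims[2L])
    stop(sprintf(
      "format error: dimension line says %d x %d but body is %d x %d",
      dims[1L], dims[2L], nrow(body), ncol(body) - 2L))
  v <- as.matrix(body[, -(1:2), drop = FALSE])
  if (!is.numeric(v)) stop("format error: non-numeric expression values")
  rownames(v) <- body[[1L]]
  if (is.null(group)) group <- rep("all", ncol(v))
  m <- expression_matrix(v, group = group, scale = scale)
  attr(m, "description") <- stats::setNames(body[[2L]], body[[1L]])
  m
}

#' Write an expression matrix as GCT 1.2
#'
#' @param m an [expression_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gct <- function(m, path) {
  stopifnot(inherits(m, "expr_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(m$values), ncol(m$values), sep = "\t")), con)
  header <- paste(c("NAME", "Description", colnames(m$values)), collapse = "\t")
  writeLines(header, con)
  body <- cbind(rownames(m$values), "na",
                format(m$values, trim = TRUE, digits = 15))
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read gene signatures from a GMT file
#'
#' Signatures are reconstructed from paired `<name>_UP` / `<name>_DN` sets;
#' a set without its partner is an error. Duplicate genes within a set are
#' deduplicated with a warning; empty lines are skipped.
#'
#' @param path path to a tab-separated GMT file (set name, description,
#'   genes...).
#' @return Named list of [gene_signature()] objects.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t")[[1L]]
    if (length(f) < 3L) stop("format error: GMT line with fewer than 3 fields")
    genes <- f[-(1:2)]
    if (anyDuplicated(genes)) {
      warning("duplicate gene(s) in set ", f[1L], " deduplicated")
      genes <- unique(genes)
    }
    sets[[f[1L]]] <- genes
  }
  bases_up <- sub("_UP$", "", grep("_UP$", names(sets), value = TRUE))
  bases_dn <- sub("_DN$", "", grep("_DN$", names(sets), value = TRUE))
  orphans <- c(setdiff(bases_up, bases_dn), setdiff(bases_dn, bases_up))
  if (length(orphans) > 0)
    stop("incomplete signature: missing partner set for ",
         paste(orphans, collapse = ", "))
  bases <- intersect(bases_up, bases_dn)
  if (length(bases) == 0L) stop("no _UP/_DN signature pairs in GMT")
  lapply(stats::setNames(bases, bases), function(b)
    gene_signature(b, up = sets[[paste0(b, "_UP")]],
                   down = sets[[paste0(b, "_DN")]],
                   provenance = paste("read from", basename(path))))
}

#' Write gene signatures as a GMT file
#'
#' Each signature becomes a `<name>_UP` and a `<name>_DN` line.
#'
#' @param sigs a [gene_signature()] or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sigs, path) {
  if (inherits(sigs, "gene_signature")) sigs <- list(sigs)
  lines <- unlist(lapply(sigs, function(s) c(
    paste(c(paste0(s$name, "_UP"), s$provenance, s$up), collapse = "\t"),
    paste(c(paste0(s$name, "_DN"), s$provenance, s$down), collapse = "\t"))))
  writeLines(lines, path)
  invisible(path)
}

#' Write a table as TSV with a provenance header comment
#'
#' @param df data.frame.
#' @param path output path.
#' @param stage producing stage name recorded in the header comment.
#' @param params named list of parameters recorded in the header comment.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path, stage = "sigrev", params = list()) {
  pstr <- paste(sprintf("%s=%s", names(params),
                        vapply(params, function(p) paste(format(p), collapse = ","),
                               character(1))),
                collapse = " ")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# stage=%s %s", stage, pstr), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()] (header comments skipped)
#'
#' @param path input path.
#' @return A `data.frame`.
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Bundled drug annotation table
#'
#' Published prioritized drug predictions for reversing the sorafenib
#' resistance signature: averaged connectivity score, approval status,
#' target genes and action keywords for 20 drugs.
#'
#' @return `data.frame` with columns `drug_id`, `score`, `status`,
#'   `targets`, `actions`.
#' @export
load_drug_annotations <- function() {
  read_tsv(system.file("extdata", "drug_annotations.tsv", package = "sigrev",
                       mustWork = TRUE))
}

#' Bundled disease-associated gene list
#'
#' Genes with literature support for a role in hepatocellular carcinoma,
#' used to flag prioritized drugs whose targets are disease-associated.
#'
#' @return Character vector of gene symbols.
#' @export
load_disease_genes <- function() {
  path <- system.file("extdata", "hcc_genes.txt", package = "sigrev",
                      mustWork = TRUE)
  lines <- trimws(readLines(path))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Bundled cohort classification summary
#'
#' Published per-dataset cohort statistics for four resistance signatures
#' across six HCC microarray cohorts: percentage of signature-positive
#' tumors, Fisher p-value, sensitivity and specificity of tumor/normal
#' discrimination.
#'
#' @return `data.frame` with columns `signature`, `dataset`, `pct_sr_pos`,
#'   `fisher_p`, `sensitivity`, `specificity`.
#' @export
load_cohort_summary <- function() {
  read_tsv(system.file("extdata", "cohort_summary.tsv", package = "sigrev",
                       mustWork = TRUE))
}

#' Run the synthetic end-to-end repurposing pipeline
#'
#' Generates two-group expression data, extracts the resistance signature,
#' scores a planted drug library, prioritizes drugs against the bundled
#' annotations, and (optionally) classifies a synthetic cohort and
#' stratifies synthetic survival. All intermediates are persisted under
#' `out_dir` and a `manifest.tsv` records parameters and seed.
#'
#' @param out_dir output directory (created if absent).
#' @param seed integer seed driving every stage.
#' @param cfg a [sim_config()] for the two-group stage.
#' @param n_drugs,n_reversers,strength drug-library parameters.
#' @param classify logical: also run cohort classification + survival.
#' @return Named list with the signature, drug scores, priority table and
#'   (when `classify`) the cohort classification and log-rank result.
#' @export
run_pipeline <- function(out_dir, seed = 1,
                         cfg = sim_config(seed = seed),
                         n_drugs = 50, n_reversers = 2, strength = 0.9,
                         classify = TRUE) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  sim <- gen_two_group_matrix(cfg)
  write_gct(sim$matrix, file.path(out_dir, "expression.gct"))
  sig <- extract_signature(sim$matrix, name = "resistance")
  write_gmt(sig, file.path(out_dir, "signature.gmt"))

  lib <- gen_drug_library(n_drugs = n_drugs, n_genes = cfg$n_genes,
                          signature = sig, n_reversers = n_reversers,
                          strength = strength, seed = seed + 1L)
  scores <- score_library(sig, lib$profiles)
  write_tsv(scores, file.path(out_dir, "connectivity.tsv"),
            stage = "connect", params = list(seed = seed + 1L))

  synth_ann <- data.frame(
    drug_id = scores$drug_id, status = "approved",
    actions = "antineoplastic, synthetic",
    targets = "", stringsAsFactors = FALSE)
  prio <- prioritize(scores, synth_ann, disease_genes = load_disease_genes())
  write_tsv(prio, file.path(out_dir, "priority.tsv"), stage = "prioritize",
            params = list(seed = seed))

  out <- list(signature = sig, scores = scores, priority = prio,
              truth = list(two_group = sim$truth, library = lib$truth))
  if (classify) {
    coh <- gen_signature_cohort(n_tumor = 60, n_normal = 20, signature = sig,
                                positive_fraction = 0.5, noise_sd = 0.5,
                                n_genes = cfg$n_genes, seed = seed + 2L)
    cls <- classify_cohort(coh$matrix, sig, seed = seed + 3L)
    write_tsv(cls$calls, file.path(out_dir, "ntp_calls.tsv"), stage = "ntp",
              params = list(alpha = cls$alpha, seed = seed + 3L))
    tumor_calls <- cls$calls[grepl("^tumor", cls$calls$sample_id), ]
    labels <- stats::setNames(
      ifelse(tumor_calls$label == "POS", "positive", "negative"),
      tumor_calls$sample_id)
    surv <- gen_survival(labels, hazard_ratio = 2, seed = seed + 4L)
    write_tsv(surv, file.path(out_dir, "survival.tsv"), stage = "survival",
              params = list(seed = seed + 4L))
    out$classification <- cls
    out$logrank <- if (length(unique(labels)) == 2L) logrank(surv) else NULL
  }
  manifest <- data.frame(
    key = c("package", "version", "seed", "n_genes", "n_samples_per_group",
            "n_drugs", "n_reversers", "strength"),
    value = c("sigrev", as.character(utils::packageVersion("sigrev")),
              seed, cfg$n_genes, cfg$n_samples_per_group, n_drugs,
              n_reversers, strength),
    stringsAsFactors = FALSE)
  write_tsv(manifest, file.path(out_dir, "manifest.tsv"), stage = "manifest")
  out
}
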