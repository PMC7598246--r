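# Signature extraction: filters, moderated t, significance control, thresholds.

#' Remove low-expression genes
#'
#' Drops each gene whose log2 value lies below `cutoff` in at least
#' `fraction` of the samples. The order of surviving genes is preserved.
#'
#' @param m an [expression_matrix()] on log2 scale.
#' @param cutoff log2 noise cutoff (default 6).
#' @param fraction fraction of samples that must fall below `cutoff` for the
#'   gene to be removed (default 0.85).
#' @return The filtered `expr_matrix`.
#' @export
noise_filter <- function(m, cutoff = 6, fraction = 0.85) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale != "log2")
    stop("wrong scale: noise_filter expects log2 intensities, not counts")
  below <- rowMeans(m$values < cutoff)
  keep <- below < fraction
  m$values <- m$values[keep, , drop = FALSE]
  m
}

#' Collapse probes to genes by averaging
#'
#' Replaces probe-level rows by per-gene arithmetic means of their probes'
#' log2 values. Probes absent from the map are dropped. Output genes appear
#' in order of first probe occurrence.
#'
#' @param m an [expression_matrix()] whose rownames are probe ids.
#' @param probe_to_gene named character vector: `names()` are probe ids,
#'   values are gene ids (each probe maps to at most one gene).
#' @return `expr_matrix` with gene-level rows.
#' @export
collapse_probes <- function(m, probe_to_gene) {
  stopifnot(inherits(m, "expr_matrix"))
  if (length(probe_to_gene) == 0L) stop("empty probe-to-gene mapping")
  mapped <- intersect(rownames(m$values), names(probe_to_gene))
  if (length(mapped) == 0L) stop("empty output: no probe maps to a gene")
  genes <- probe_to_gene[mapped]
  v <- m$values[mapped, , drop = FALSE]
  sums <- rowsum(v, group = genes, reorder = FALSE)
  counts <- as.vector(table(factor(genes, levels = unique(genes))))
  m$values <- sums / counts
  m
}

# Newton inversion of the trigamma function (for the prior df estimator).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif) / y < 1e-10) break
  }
  y
}

#' Empirical-Bayes moderated two-sample t-test
#'
#' Per-gene two-sample comparison (second group level minus the first/reference
#' level) on log2 data, with the pooled gene variance shrunk toward a prior:
#' `s2_tilde = (d0 * s0^2 + dg * s2_g) / (d0 + dg)`. The prior `(s0^2, d0)` is
#' estimated by method of moments from the distribution of `log(s2_g)` across
#' genes (matching the scaled-F model: the mean and variance of `log(s2_g)`
#' involve digamma/trigamma terms, and `d0` is found by trigamma inversion).
#' The moderated t is `log2fc / (s_tilde * sqrt(1/n1 + 1/n2))` on
#' `d0 + dg` degrees of freedom.
#'
#' @param m an [expression_matrix()] on log2 scale with two groups and at
#'   least two samples per group.
#' @param d0 optional prior degrees of freedom override. `d0 = 0` disables
#'   shrinkage and reproduces the ordinary pooled-variance t exactly;
#'   `d0 = Inf` forces complete shrinkage to `s0^2`.
#' @return A `data.frame` (one row per gene, class `de_result`) with columns
#'   `gene`, `log2fc`, `fold_change` (`2^log2fc`), `t_mod`, `p`, `adj_p`
#'   (Benjamini-Hochberg) and `s2_g`; attributes `s2_0`, `d_0`, `d_g`.
#' @export
moderated_ttest <- function(m, d0 = NULL) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale != "log2") stop("wrong scale: moderated_ttest expects log2 data")
  if (nlevels(m$group) != 2L) stop("exactly two groups required")
  idx1 <- m$group == levels(m$group)[1L]  # reference / control
  idx2 <- m$group == levels(m$group)[2L]  # case
  n1 <- sum(idx1); n2 <- sum(idx2)
  if (n1 < 2L || n2 < 2L)
    stop("no variance: need at least two samples per group")
  v <- m$values
  m1 <- rowMeans(v[, idx1, drop = FALSE])
  m2 <- rowMeans(v[, idx2, drop = FALSE])
  ss1 <- rowSums((v[, idx1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((v[, idx2, drop = FALSE] - m2)^2)
  dg <- n1 + n2 - 2L
  s2g <- (ss1 + ss2) / dg
  log2fc <- m2 - m1

  if (is.null(d0)) {
    z <- log(pmax(s2g, 1e-300))
    evar <- stats::var(z) - trigamma(dg / 2)
    if (is.finite(evar) && evar > 0) {
      d0 <- 2 * trigamma_inverse(evar)
      s20 <- exp(mean(z) - digamma(dg / 2) + log(dg / 2) +
                   digamma(d0 / 2) - log(d0 / 2))
    } else {
      d0 <- Inf
      s20 <- exp(mean(z) - digamma(dg / 2) + log(dg / 2))
    }
  } else {
    if (d0 < 0) stop("d0 must be non-negative")
    s20 <- if (d0 > 0) exp(mean(log(pmax(s2g, 1e-300)))) else NA_real_
  }

  s2_post <- if (is.infinite(d0)) rep(s20, length(s2g)) else
    (d0 * ifelse(d0 > 0, s20, 0) + dg * s2g) / (d0 + dg)
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t_mod <- ifelse(se > 0, log2fc / se, sign(log2fc) * Inf)
  df_total <- d0 + dg
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  out <- data.frame(gene = rownames(v), log2fc = log2fc,
                    fold_change = 2^log2fc, t_mod = t_mod, p = p,
                    adj_p = bh_fdr(p), s2_g = s2g,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "s2_0") <- s20
  attr(out, "d_0") <- d0
  attr(out, "d_g") <- dg
  class(out) <- c("de_result", "data.frame")
  out
}

#' Significance cutoff controlling the mean number of false positives
#'
#' Returns the p-value cutoff `k / G` for `G` tests, so that the expected
#' number of false positives among genes called at `p < cutoff` is at most
#' `k` under the complete null.
#'
#' @param pvals numeric vector of p-values (only its length is used).
#' @param k target mean number of false positives (default 1).
#' @return The p-value cutoff (a single number).
#' @export
control_mean_fp <- function(pvals, k = 1) {
  if (length(pvals) == 0L) stop("empty p-value vector")
  if (!is.numeric(k) || k <= 0) stop("invalid k: must be positive")
  k / length(pvals)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; monotone in rank, capped at 1, invariant to
#' input order.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @export
bh_fdr <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1))
    stop("invalid p-values: all must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Partition genes by fold-change cutoffs
#'
#' @param de a `de_result` from [moderated_ttest()].
#' @param up_min fold-change above which a gene is called up (default 3).
#' @param down_max fold-change below which a gene is called down (default 0.25).
#' @return `list(up=, down=)` of gene ids (input order); genes between the
#'   cutoffs are excluded.
#' @export
fold_change_filter <- function(de, up_min = 3, down_max = 0.25) {
  if (up_min <= down_max) stop("invalid thresholds: up_min must exceed down_max")
  list(up = de$gene[de$fold_change > up_min],
       down = de$gene[de$fold_change < down_max])
}

#' Filter low-count genes from an RNA-seq matrix
#'
#' Removes genes whose count is below `min_count` in at least `min_below`
#' samples of any single group.
#'
#' @param m an [expression_matrix()] on count scale.
#' @param min_count minimum acceptable count (default 5).
#' @param min_below number of below-threshold samples within one group that
#'   triggers removal (default 2).
#' @return The filtered `expr_matrix`.
#' @export
count_filter <- function(m, min_count = 5, min_below = 2) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale != "count") stop("wrong scale: count_filter expects raw counts")
  low_any <- Reduce(`|`, lapply(levels(m$group), function(g) {
    idx <- m$group == g
    rowSums(m$values[, idx, drop = FALSE] < min_count) >= min_below
  }))
  m$values <- m$values[!low_any, , drop = FALSE]
  m
}

#' TMM per-sample scale factors
#'
#' Trimmed-mean-of-M-values normalization: the reference sample is the one
#' whose upper quartile is closest to the mean upper quartile; M-values are
#' trimmed by 30% and A-values by 5% and combined by a precision-weighted
#' mean. Returns *effective* scale factors — library size times the TMM
#' factor — rescaled to geometric mean 1, so that dividing each sample's
#' counts by its factor puts all samples on a common scale.
#'
#' @param m an [expression_matrix()] on count scale with at least 2 samples.
#' @return Named numeric vector of effective scale factors (geometric mean 1),
#'   with attributes `tmm` (the TMM factors proper, geometric mean 1) and
#'   `lib_size`.
#' @export
tmm_normalize <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale != "count") stop("wrong scale: tmm_normalize expects raw counts")
  if (ncol(m$values) < 2L) stop("need at least two samples")
  lib <- colSums(m$values)
  if (any(lib == 0)) stop("degenerate library: sample with all-zero counts")
  tmm <- edgeR::calcNormFactors(m$values, method = "TMM")
  eff <- lib * tmm
  eff <- eff / exp(mean(log(eff)))
  names(eff) <- colnames(m$values)
  attr(eff, "tmm") <- stats::setNames(tmm / exp(mean(log(tmm))), colnames(m$values))
  attr(eff, "lib_size") <- lib
  eff
}

#' Convert counts to log2 counts-per-million
#'
#' TMM-normalized `log2(CPM + 0.5)` transform; the result is a log2-scale
#' [expression_matrix()] suitable for [moderated_ttest()].
#'
#' @param m an [expression_matrix()] on count scale.
#' @return An `expr_matrix` on log2 scale.
#' @export
counts_to_logcpm <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale != "count") stop("wrong scale: counts_to_logcpm expects raw counts")
  lib <- colSums(m$values)
  tmm <- edgeR::calcNormFactors(m$values, method = "TMM")
  cpm <- t(t(m$values) / (lib * tmm)) * 1e6
  out <- m
  out$values <- log2(cpm + 0.5)
  out$scale <- "log2"
  out
}

#' Build a gene signature from differential expression results
#'
#' Applies the significance cutoff and the fold-change partition, orders the
#' up/down lists by decreasing `|t_mod|` (ties broken lexicographically by
#' gene id), and records the thresholds in the signature's provenance.
#'
#' @param de a `de_result` from [moderated_ttest()].
#' @param name signature name.
#' @param p_cutoff cutoff applied to raw p-values (e.g. from
#'   [control_mean_fp()]); ignored when `NULL`.
#' @param adj_p_cutoff cutoff applied to BH-adjusted p-values; ignored when
#'   `NULL`. At least one of the two cutoffs must be given.
#' @param fc_up,fc_down fold-change cutoffs (defaults 3 and 0.25).
#' @return A [gene_signature()].
#' @export
build_signature <- function(de, name = "signature", p_cutoff = NULL,
                            adj_p_cutoff = NULL, fc_up = 3, fc_down = 0.25) {
  if (is.null(p_cutoff) && is.null(adj_p_cutoff))
    stop("give p_cutoff and/or adj_p_cutoff")
  sig <- rep(TRUE, nrow(de))
  if (!is.null(p_cutoff)) sig <- sig & de$p < p_cutoff
  if (!is.null(adj_p_cutoff)) sig <- sig & de$adj_p < adj_p_cutoff
  des <- de[sig, , drop = FALSE]
  part <- fold_change_filter(des, up_min = fc_up, down_max = fc_down)
  ord <- function(genes) {
    sub <- des[match(genes, des$gene), , drop = FALSE]
    genes[order(-abs(sub$t_mod), genes)]
  }
  gene_signature(
    name = name, up = ord(part$up), down = ord(part$down),
    thresholds = list(p_cutoff = p_cutoff, adj_p_cutoff = adj_p_cutoff,
                      fc_up = fc_up, fc_down = fc_down),
    provenance = sprintf(
      "moderated t on %d genes; p_cutoff=%s adj_p_cutoff=%s fc_up=%g fc_down=%g",
      nrow(de), format(p_cutoff), format(adj_p_cutoff), fc_up, fc_down))
}

#' Run the full array signature-extraction pipeline
#'
#' noise filter -> optional probe collapse -> moderated t -> significance
#' cutoff (mean-false-positive control on raw p, or an adjusted-p cutoff) ->
#' fold-change partition -> ordered signature.
#'
#' @param m an [expression_matrix()] on log2 scale.
#' @param name signature name.
#' @param probe_to_gene optional probe map for [collapse_probes()].
#' @param noise_cutoff,noise_frac noise-filter parameters.
#' @param mode `"meanfp"` (p cutoff `k/G`) or `"adj"` (BH-adjusted cutoff).
#' @param k mean-false-positive target when `mode = "meanfp"`.
#' @param adj_p_cutoff adjusted-p cutoff when `mode = "adj"` (default 0.001).
#' @param fc_up,fc_down fold-change cutoffs.
#' @return A [gene_signature()].
#' @export
extract_signature <- function(m, name = "signature", probe_to_gene = NULL,
                              noise_cutoff = 6, noise_frac = 0.85,
                              mode = c("meanfp", "adj"), k = 1,
                              adj_p_cutoff = 0.001, fc_up = 3, fc_down = 0.25) {
  mode <- match.arg(mode)
  m <- noise_filter(m, cutoff = noise_cutoff, fraction = noise_frac)
  if (!is.null(probe_to_gene)) m <- collapse_probes(m, probe_to_gene)
  de <- moderated_ttest(m)
  if (mode == "meanfp") {
    build_signature(de, name = name, p_cutoff = control_mean_fp(de$p, k = k),
                    fc_up = fc_up, fc_down = fc_down)
  } else {
    build_signature(de, name = name, adj_p_cutoff = adj_p_cutoff,
                    fc_up = fc_up, fc_down = fc_down)
  }
}
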