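# Nearest-template prediction: classify cohort samples as signature-positive
# or -negative by cosine distance to a +/-1 template, with resampling
# significance and BH-FDR across samples.

#' Build a +/-1 template from a signature
#'
#' @param sig a [gene_signature()] with non-empty up and down sets.
#' @return `data.frame` with columns `gene`, `weight` (+1 for up genes then
#'   -1 for down genes, in signature order).
#' @export
build_template <- function(sig) {
  stopifnot(inherits(sig, "gene_signature"))
  if (length(sig$up) == 0L || length(sig$down) == 0L)
    stop("template needs non-empty up and down sets")
  data.frame(gene = c(sig$up, sig$down),
             weight = c(rep(1, length(sig$up)), rep(-1, length(sig$down))),
             stringsAsFactors = FALSE)
}

#' Cosine distances of a sample to a template and its inverse
#'
#' `d_pos = 1 - cos(x, w)` over the template genes; the inverse template has
#' weights `-w`, so `d_neg = 2 - d_pos` exactly. The sample vector should be
#' per-gene standardized across the cohort before calling.
#'
#' @param x named numeric vector covering the template genes.
#' @param tpl template from [build_template()].
#' @return `c(d_pos =, d_neg =)`, both in \[0, 2\].
#' @export
ntp_distance <- function(x, tpl) {
  xv <- x[tpl$gene]
  if (anyNA(xv)) stop("sample vector does not cover the template genes")
  nx <- sqrt(sum(xv^2))
  if (nx == 0) stop("undefined distance: zero-variance sample vector")
  cosine <- sum(xv * tpl$weight) / (nx * sqrt(nrow(tpl)))
  c(d_pos = 1 - cosine, d_neg = 1 + cosine)
}

# Null |cosine| values for `r` random templates of the given up/down split,
# drawn without replacement from the rows of `z` (genes x samples).
# Returns an r x n_samples matrix of null |cosine| statistics.
null_cosines <- function(z, n_up, n_down, r) {
  t <- n_up + n_down
  ng <- nrow(z)
  if (ng < t) stop("invalid: universe smaller than template")
  out <- matrix(NA_real_, r, ncol(z))
  for (i in seq_len(r)) {
    idx <- sample.int(ng, t)
    iu <- idx[seq_len(n_up)]
    id <- idx[n_up + seq_len(n_down)]
    num <- colSums(z[iu, , drop = FALSE]) - colSums(z[id, , drop = FALSE])
    den <- sqrt(colSums(z[idx, , drop = FALSE]^2)) * sqrt(t)
    out[i, ] <- abs(num / den)
  }
  out
}

#' Resampling significance of a sample's nearest-template distance
#'
#' Draws `n_resample` random templates of the same size and +1/-1
#' composition (genes sampled without replacement from the universe) and
#' compares their nearest distance (equivalently, |cosine|) with the
#' observed nearest distance. `p = (1 + #{null <= observed nearest}) /
#' (n_resample + 1)`, so the resolution floor is `1/(n_resample + 1)`.
#'
#' @param x named numeric vector over the universe (standardized).
#' @param tpl template from [build_template()].
#' @param universe character vector of candidate genes (must contain the
#'   template genes and be larger than the template).
#' @param n_resample number of random templates (default 1000).
#' @param seed integer seed.
#' @return p-value in `[1/(n_resample+1), 1]`.
#' @export
ntp_significance <- function(x, tpl, universe, n_resample = 1000, seed = 1) {
  if (length(universe) <= nrow(tpl))
    stop("invalid: universe must be larger than the template")
  if (!all(tpl$gene %in% universe)) stop("template genes missing from universe")
  d <- ntp_distance(x, tpl)
  obs <- abs(1 - min(d))  # |cosine| of the nearest template
  set.seed(seed)
  z <- matrix(x[universe], ncol = 1, dimnames = list(universe, "s"))
  nullabs <- null_cosines(z, sum(tpl$weight > 0), sum(tpl$weight < 0),
                          n_resample)
  (1 + sum(nullabs >= obs)) / (n_resample + 1)
}

#' Classify a cohort by nearest-template prediction
#'
#' Genes are z-scored across the cohort; each sample's label candidate is
#' the nearer of the template (`POS`) and its inverse (`NEG`); resampling
#' p-values (one shared null-template set per cohort) are BH-adjusted across
#' samples and calls with `fdr >= alpha` become `UNCLASSIFIED`.
#'
#' @param m an [expression_matrix()] (log2 scale) with >= 2 samples.
#' @param sig a [gene_signature()].
#' @param alpha FDR threshold for a confident call (default 0.05).
#' @param n_resample random templates for the null (default 1000).
#' @param seed integer seed.
#' @return Object of class `ntp_classification`: `list(calls = data.frame(
#'   sample_id, d_pos, d_neg, p, fdr, label), proportion_positive, alpha)`.
#'   `proportion_positive` is the fraction of `POS` calls among evaluable
#'   (confidently classified) samples — restricted to tumor samples when the
#'   matrix carries `sample_type` — and `NA` when no sample is classified.
#' @export
classify_cohort <- function(m, sig, alpha = 0.05, n_resample = 1000, seed = 1) {
  stopifnot(inherits(m, "expr_matrix"), inherits(sig, "gene_signature"))
  if (ncol(m$values) < 2L) stop("cohort needs at least 2 samples")
  tpl <- build_template(sig)
  present <- tpl$gene %in% rownames(m$values)
  coverage <- mean(present)
  if (coverage < 0.10)
    stop(sprintf("signature coverage %.0f%% below 10%%", 100 * coverage))
  if (coverage < 0.50)
    warning(sprintf("signature coverage %.0f%% below 50%%", 100 * coverage))
  tpl <- tpl[present, , drop = FALSE]
  if (sum(tpl$weight > 0) == 0L || sum(tpl$weight < 0) == 0L)
    stop("template lost one of its up/down blocks after coverage filtering")

  z <- t(scale(t(m$values)))      # z-score each gene across the cohort
  z[!is.finite(z)] <- 0           # constant genes carry no information
  zt <- z[tpl$gene, , drop = FALSE]
  num <- colSums(zt * tpl$weight)
  den <- sqrt(colSums(zt^2)) * sqrt(nrow(tpl))
  cosine <- ifelse(den > 0, num / den, 0)
  d_pos <- 1 - cosine

  set.seed(seed)
  nullabs <- null_cosines(z, sum(tpl$weight > 0), sum(tpl$weight < 0),
                          n_resample)
  exceed <- colSums(nullabs >= matrix(abs(cosine), n_resample,
                                      ncol(z), byrow = TRUE))
  p <- (1 + exceed) / (n_resample + 1)
  fdr <- bh_fdr(p)
  label <- ifelse(fdr < alpha, ifelse(cosine > 0, "POS", "NEG"),
                  "UNCLASSIFIED")
  calls <- data.frame(sample_id = colnames(m$values), d_pos = d_pos,
                      d_neg = 2 - d_pos, p = p, fdr = fdr, label = label,
                      row.names = NULL, stringsAsFactors = FALSE)
  pool <- if (!is.null(m$sample_type))
    calls[m$sample_type[calls$sample_id] == "tumor", ] else calls
  evaluable <- pool$label != "UNCLASSIFIED"
  prop <- if (any(evaluable)) mean(pool$label[evaluable] == "POS") else NA_real_
  structure(list(calls = calls, proportion_positive = prop, alpha = alpha),
            class = "ntp_classification")
}

#' @export
print.ntp_classification <- function(x, ...) {
  cat(sprintf("<ntp_classification> %d samples; %.1f%% positive (FDR < %g)\n",
              nrow(x$calls), 100 * x$proportion_positive, x$alpha))
  print(table(x$calls$label))
  invisible(x)
}

#' Sensitivity and specificity of positive calls against tumor/normal truth
#'
#' Sensitivity = P(POS | tumor), specificity = P(not POS | normal), each
#' with a 95% Clopper-Pearson confidence interval.
#'
#' @param calls an `ntp_classification` from [classify_cohort()].
#' @param truth named character vector (`"tumor"`/`"normal"`) covering all
#'   called samples.
#' @return `list(sensitivity=, sensitivity_ci=, specificity=,
#'   specificity_ci=)`.
#' @export
sens_spec <- function(calls, truth) {
  stopifnot(inherits(calls, "ntp_classification"))
  tr <- truth[calls$calls$sample_id]
  if (anyNA(tr)) stop("truth labels do not cover all called samples")
  is_pos <- calls$calls$label == "POS"
  n_t <- sum(tr == "tumor"); n_n <- sum(tr == "normal")
  if (n_t == 0L || n_n == 0L)
    stop("undefined metric: a truth class is empty")
  x_t <- sum(is_pos & tr == "tumor")
  x_n <- sum(!is_pos & tr == "normal")
  ci <- function(x, n) as.vector(stats::binom.test(x, n)$conf.int)
  list(sensitivity = x_t / n_t, sensitivity_ci = ci(x_t, n_t),
       specificity = x_n / n_n, specificity_ci = ci(x_n, n_n))
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact hypergeometric two-sided p-value (sum over tables with probability
#' at most that of the observed table).
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value.
#' @export
fisher_2x2 <- function(table) {
  if (!all(dim(table) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(table < 0) || any(table != floor(table)))
    stop("invalid: counts must be non-negative integers")
  stats::fisher.test(table)$p.value
}

#' Mean of per-dataset statistics
#'
#' @param values numeric vector of per-dataset statistics.
#' @param digits optional rounding, to report at the inputs' printed
#'   precision.
#' @return Arithmetic mean.
#' @export
mean_across_datasets <- function(values, digits = NULL) {
  if (length(values) == 0L) stop("no values")
  m <- mean(values)
  if (!is.null(digits)) round(m, digits) else m
}
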