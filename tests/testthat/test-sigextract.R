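test_that("noise filter removes genes low in at least the cutoff fraction", {
  v <- rbind(all_low = rep(5, 10),
             few_low = c(rep(5, 2), rep(7, 8)),
             boundary = c(rep(5, 9), 7),   # 90% below, >= 85% -> removed
             high = rep(8, 10))
  colnames(v) <- paste0("s", 1:10)
  m <- toy_matrix(v)
  out <- noise_filter(m, cutoff = 6, fraction = 0.85)
  expect_identical(rownames(out$values), c("few_low", "high"))
  counts <- toy_matrix(matrix(1:4, 2, dimnames = list(c("a", "b"), c("s1", "s2"))),
                       group = c("g1", "g2"), scale = "count")
  expect_error(noise_filter(counts), "wrong scale")
})

test_that("probe collapsing averages probes per gene and drops unmapped", {
  v <- matrix(c(2, 4, 1, 2, 6, 9,
                2, 4, 1, 2, 6, 9), ncol = 2,
              dimnames = list(c("p1", "p2", "p3", "p4", "p5", "px"),
                              c("s1", "s2")))
  m <- toy_matrix(v, group = c("a", "b"))
  map <- c(p1 = "gA", p2 = "gA", p3 = "gB", p4 = "gB", p5 = "gB")
  out <- collapse_probes(m, map)
  expect_equal(out$values["gA", "s1"], 3)           # mean(2, 4)
  expect_equal(out$values["gB", "s1"], 3)           # mean(1, 2, 6)
  expect_false("px" %in% rownames(out$values))
  one <- collapse_probes(m, c(p1 = "gA"))
  expect_equal(unname(one$values["gA", ]), unname(v["p1", ]))  # identity
  expect_error(collapse_probes(m, c(zz = "gA")), "empty output")
  expect_error(collapse_probes(m, setNames(character(0), character(0))),
               "empty")
})

test_that("moderated t with d0 = 0 equals the ordinary pooled t", {
  m <- small_two_group(n_genes = 40, ns = 4, seed = 11)
  de <- moderated_ttest(m, d0 = 0)
  # textbook pooled two-sample t, computed directly
  for (i in c(1, 7, 25)) {
    x <- m$values[i, m$group == "control"]
    y <- m$values[i, m$group == "case"]
    tt <- t.test(y, x, var.equal = TRUE)
    expect_equal(de$t_mod[i], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(de$p[i], tt$p.value, tolerance = 1e-12)
  }
})

test_that("moderated t agrees with the limma empirical-Bayes route", {
  sim <- gen_two_group_matrix(sim_config(n_genes = 500, de_fraction = 0.1,
                                         noise_sd = 0.5, seed = 3))
  m <- sim$matrix
  de <- moderated_ttest(m)
  design <- model.matrix(~m$group)
  fit <- limma::eBayes(limma::lmFit(m$values, design))
  expect_equal(de$log2fc, unname(fit$coefficients[, 2]), tolerance = 1e-10)
  # same EB family, independently estimated prior: t statistics near-identical
  expect_gt(cor(de$t_mod, fit$t[, 2]), 0.9999)
  expect_lt(median(abs(de$t_mod - fit$t[, 2]) / abs(fit$t[, 2])), 0.02)
})

test_that("moderated t null case and error handling", {
  v <- rbind(g1 = c(1, 2, 3, 1, 2, 3), g2 = c(4, 5, 6, 4, 5, 6))
  colnames(v) <- paste0("s", 1:6)
  m <- toy_matrix(v, group = rep(c("a", "b"), each = 3))
  de <- moderated_ttest(m)
  expect_equal(de$t_mod, c(0, 0))                    # identical group means
  expect_equal(de$p, c(1, 1))
  m1 <- toy_matrix(matrix(1:2, 1, dimnames = list("g", c("s1", "s2"))),
                   group = c("a", "b"))
  expect_error(moderated_ttest(m1), "no variance")
})

test_that("moderated t p-values are uniform under the complete null", {
  sim <- gen_two_group_matrix(sim_config(n_genes = 2000, de_fraction = 0,
                                         log2_effect = 0, noise_sd = 0.5,
                                         seed = 5))
  de <- moderated_ttest(sim$matrix)
  expect_gt(suppressWarnings(ks.test(de$p, "punif")$p.value), 0.01)
})

test_that("mean-false-positive control yields k/G and calibrates on nulls", {
  expect_equal(control_mean_fp(runif(10000), k = 1), 1e-4)
  expect_equal(control_mean_fp(runif(10), k = 1), 0.1)
  expect_error(control_mean_fp(runif(10), k = 0), "invalid")
  expect_error(control_mean_fp(numeric(0)), "empty")
  # null simulation: mean number of calls at cutoff k/G is about k
  set.seed(1)
  n_calls <- replicate(500, {
    p <- pnorm(-abs(rnorm(400))) * 2
    sum(p < control_mean_fp(p, k = 1))
  })
  expect_gt(mean(n_calls), 0.8)
  expect_lt(mean(n_calls), 1.2)
})

test_that("BH adjustment matches the hand step-up and is order-invariant", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  set.seed(2)
  p <- runif(50)
  perm <- sample(50)
  expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]))
  expect_true(all(bh_fdr(p) >= p))
  expect_error(bh_fdr(c(0.5, 1.2)), "invalid")
})

test_that("fold-change partition applies the asymmetric cutoffs", {
  de <- data.frame(gene = c("a", "b", "c"),
                   fold_change = c(4.0, 0.2, 2.0))
  part <- fold_change_filter(de)
  expect_equal(part$up, "a")
  expect_equal(part$down, "b")
  expect_error(fold_change_filter(de, up_min = 0.2, down_max = 0.25),
               "invalid thresholds")
})

test_that("count filter removes genes low in >= 2 samples of one group", {
  v <- rbind(two_low = c(4, 4, 6, 9, 9, 9),
             one_low = c(5, 5, 0, 9, 9, 9),
             all_ok = c(5, 6, 7, 9, 9, 9))
  colnames(v) <- paste0("s", 1:6)
  m <- toy_matrix(v, group = rep(c("a", "b"), each = 3), scale = "count")
  out <- count_filter(m)
  expect_identical(rownames(out$values), c("one_low", "all_ok"))
  expect_error(count_filter(small_two_group()), "wrong scale")
})

test_that("TMM effective factors have geometric mean 1 and detect scaling", {
  set.seed(8)
  base <- matrix(rnbinom(300 * 2, mu = 100, size = 10), ncol = 2)
  v <- cbind(base[, 1], base[, 1])
  dimnames(v) <- list(paste0("g", 1:300), c("s1", "s2"))
  m <- toy_matrix(v, group = c("a", "b"), scale = "count")
  f <- tmm_normalize(m)
  expect_equal(as.numeric(f), c(1, 1))             # identical samples
  v2 <- cbind(base[, 1], base[, 1] * 2L)
  dimnames(v2) <- dimnames(v)
  f2 <- tmm_normalize(toy_matrix(v2, group = c("a", "b"), scale = "count"))
  expect_equal(as.numeric(f2), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-6)
  set.seed(9)
  v3 <- matrix(rnbinom(300 * 4, mu = 50, size = 5) + 1L, ncol = 4,
               dimnames = list(paste0("g", 1:300), paste0("s", 1:4)))
  f3 <- tmm_normalize(toy_matrix(v3, group = rep(c("a", "b"), 2),
                                 scale = "count"))
  expect_true(all(f3 > 0))
  expect_equal(exp(mean(log(f3))), 1, tolerance = 1e-12)
  v0 <- v3; v0[, 1] <- 0L
  expect_error(tmm_normalize(toy_matrix(v0, group = rep(c("a", "b"), 2),
                                        scale = "count")),
               "degenerate library")
})

test_that("build_signature recovers the planted sets in the noiseless limit", {
  cfg <- sim_config(n_genes = 200, n_samples_per_group = 3, de_fraction = 0.1,
                    log2_effect = 3, noise_sd = 0.001, seed = 13)
  sim <- gen_two_group_matrix(cfg)
  de <- moderated_ttest(sim$matrix)
  sig <- build_signature(de, p_cutoff = control_mean_fp(de$p))
  expect_setequal(sig$up, sim$truth$de_up)
  expect_setequal(sig$down, sim$truth$de_down)
  expect_equal(sig$thresholds$fc_up, 3)            # thresholds echoed
  expect_match(sig$provenance, "fc_up=3")
  # deterministic ordering under t ties: lexicographic fallback
  de_tie <- data.frame(gene = c("zz", "aa", "mm"), log2fc = c(2, 2, -2),
                       fold_change = c(4, 4, 0.2), t_mod = c(5, 5, -5),
                       p = c(1e-9, 1e-9, 1e-9), adj_p = c(1e-9, 1e-9, 1e-9))
  sig_tie <- build_signature(de_tie, p_cutoff = 0.01, fc_up = 3,
                             fc_down = 0.25)
  expect_equal(sig_tie$up, c("aa", "zz"))
})

test_that("pipeline recovers planted signatures across seeds", {
  sens_det <- sens_full <- fdr_full <- numeric(20)
  for (s in 1:20) {
    cfg <- sim_config(n_genes = 2000, de_fraction = 0.05, log2_effect = 2,
                      noise_sd = 0.5, n_samples_per_group = 3, seed = s)
    sim <- gen_two_group_matrix(cfg)
    de <- moderated_ttest(noise_filter(sim$matrix))
    truth <- c(sim$truth$de_up, sim$truth$de_down)
    cut <- control_mean_fp(de$p)
    sens_det[s] <- length(intersect(de$gene[de$p < cut], truth)) / length(truth)
    # fold-change cutoffs matched to the planted effect size
    sig <- build_signature(de, p_cutoff = cut, fc_up = 2, fc_down = 0.5)
    got <- c(sig$up, sig$down)
    sens_full[s] <- length(intersect(got, truth)) / length(truth)
    fdr_full[s] <- length(setdiff(got, truth)) / max(1, length(got))
  }
  expect_gte(mean(sens_det), 0.9)    # detection at the mean-FP threshold
  expect_gte(mean(sens_full), 0.9)
  expect_lte(mean(fdr_full), 0.1)
})

test_that("count pipeline finds planted DE genes via log-CPM moderated t", {
  cfg <- sim_config(n_genes = 500, n_samples_per_group = 3, de_fraction = 0.1,
                    log2_effect = 2, noise_sd = 0.3, baseline_mean = 7,
                    seed = 21)
  sim <- gen_two_group_counts(cfg)
  filt <- count_filter(sim$matrix)
  de <- moderated_ttest(counts_to_logcpm(filt))
  called <- de$gene[de$p < control_mean_fp(de$p, k = 1)]
  truth <- c(sim$truth$de_up, sim$truth$de_down)
  expect_gt(length(intersect(called, truth)) / length(truth), 0.7)
  expect_lt(length(setdiff(called, truth)) / max(1, length(called)), 0.1)
})
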