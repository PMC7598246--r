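test_that("template construction is a +1/-1 weight vector in block order", {
  tpl <- build_template(toy_signature(up = "A", down = "B"))
  expect_equal(tpl$gene, c("A", "B"))
  expect_equal(tpl$weight, c(1, -1))
  sig <- toy_signature(up = c("u1", "u2", "u3"), down = c("d1", "d2"))
  tpl2 <- build_template(sig)
  expect_equal(nrow(tpl2), 5)
  expect_equal(tpl2$gene, c(sig$up, sig$down))
})

test_that("cosine distances to template and inverse are complementary", {
  sig <- toy_signature(up = c("u1", "u2"), down = c("d1", "d2"))
  tpl <- build_template(sig)
  w <- setNames(tpl$weight, tpl$gene)
  expect_equal(unname(ntp_distance(w, tpl)), c(0, 2))        # perfect match
  expect_equal(unname(ntp_distance(-w, tpl)), c(2, 0))       # anti-match
  orth <- setNames(c(1, -1, 1, -1), c("u1", "u2", "d1", "d2"))
  expect_equal(unname(ntp_distance(orth, tpl)), c(1, 1))     # orthogonal
  set.seed(1)
  for (i in 1:10) {
    x <- setNames(rnorm(4), tpl$gene)
    d <- ntp_distance(x, tpl)
    expect_equal(unname(d["d_pos"] + d["d_neg"]), 2, tolerance = 1e-14)
  }
  expect_error(ntp_distance(setNames(rep(0, 4), tpl$gene), tpl),
               "undefined distance")
})

test_that("resampling significance hits the floor on perfect matches", {
  sig <- toy_signature(up = paste0("u", 1:5), down = paste0("d", 1:5))
  tpl <- build_template(sig)
  universe <- c(tpl$gene, paste0("bg", 1:200))
  x <- setNames(c(tpl$weight * 3, rnorm(200, sd = 0.1)), universe)
  p <- ntp_significance(x, tpl, universe, n_resample = 200, seed = 1)
  expect_equal(p, 1 / 201)
  expect_identical(p, ntp_significance(x, tpl, universe, 200, seed = 1))
  expect_error(ntp_significance(x, tpl, tpl$gene), "universe")
})

test_that("null significance is approximately uniform on noise samples", {
  sig <- toy_signature(up = paste0("u", 1:10), down = paste0("d", 1:10))
  tpl <- build_template(sig)
  universe <- c(tpl$gene, paste0("bg", 1:480))
  set.seed(3)
  ps <- vapply(1:200, function(i) {
    x <- setNames(rnorm(500), universe)
    ntp_significance(x, tpl, universe, n_resample = 100, seed = i)
  }, numeric(1))
  expect_lt(abs(mean(ps) - 0.5), 0.06)
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("cohort classification recovers planted positives", {
  sig <- toy_signature(up = paste0("u", 1:15), down = paste0("d", 1:15))
  # noiseless-limit: every tumor planted positive is called POS
  coh <- gen_signature_cohort(20, 10, sig, positive_fraction = 1,
                              noise_sd = 0.05, seed = 2)
  cls <- classify_cohort(coh$matrix, sig, n_resample = 500, seed = 3)
  expect_equal(cls$proportion_positive, 1)
  # planted 0.5 at realistic noise recovered within tolerance
  coh2 <- gen_signature_cohort(100, 0, sig, positive_fraction = 0.5,
                               noise_sd = 0.5, seed = 4)
  cls2 <- classify_cohort(coh2$matrix, sig, n_resample = 500, seed = 5)
  expect_lt(abs(cls2$proportion_positive - 0.5), 0.10)
  truthpos <- cls2$calls$sample_id %in% coh2$truth$positive_samples
  expect_gt(mean(cls2$calls$label[truthpos] == "POS"), 0.8)
  # alpha = 0 leaves everything unclassified
  cls0 <- classify_cohort(coh$matrix, sig, alpha = 0, n_resample = 100,
                          seed = 1)
  expect_true(all(cls0$calls$label == "UNCLASSIFIED"))
})

test_that("classification is invariant to positive per-sample scaling", {
  sig <- toy_signature(up = paste0("u", 1:10), down = paste0("d", 1:10))
  coh <- gen_signature_cohort(15, 5, sig, positive_fraction = 0.5,
                              noise_sd = 0.3, seed = 6)
  cls_a <- classify_cohort(coh$matrix, sig, n_resample = 200, seed = 7)
  m2 <- coh$matrix
  # per-gene z-scoring absorbs any per-gene affine change; per-sample
  # positive scaling changes each gene linearly across samples only if
  # shared, so rescale all samples by one positive constant
  m2$values <- m2$values * 3.7
  cls_b <- classify_cohort(m2, sig, n_resample = 200, seed = 7)
  expect_equal(cls_a$calls$label, cls_b$calls$label)
  expect_equal(cls_a$calls$p, cls_b$calls$p)
})

test_that("signature coverage below thresholds warns then errors", {
  sig <- toy_signature(up = paste0("u", 1:10), down = paste0("d", 1:10))
  coh <- gen_signature_cohort(10, 5, sig, positive_fraction = 1,
                              noise_sd = 0.2, seed = 8)
  keep <- c(sig$up[1:3], sig$down[1:3],
            grep("^g", rownames(coh$matrix$values), value = TRUE))
  m_low <- coh$matrix
  m_low$values <- m_low$values[keep, ]
  expect_warning(classify_cohort(m_low, sig, n_resample = 100, seed = 1),
                 "coverage")
  m_none <- coh$matrix
  m_none$values <- m_none$values[
    c(sig$up[1], grep("^g", rownames(coh$matrix$values), value = TRUE)), ]
  expect_error(classify_cohort(m_none, sig, n_resample = 100, seed = 1),
               "coverage")
})

test_that("sensitivity/specificity counting and Clopper-Pearson intervals", {
  calls <- structure(list(calls = data.frame(
    sample_id = paste0("s", 1:20),
    d_pos = 1, d_neg = 1, p = 0.01, fdr = 0.01,
    label = c(rep("POS", 9), "NEG", rep("POS", 2), rep("NEG", 8))),
    proportion_positive = NA, alpha = 0.05), class = "ntp_classification")
  truth <- setNames(rep(c("tumor", "normal"), each = 10), paste0("s", 1:20))
  ss <- sens_spec(calls, truth)
  expect_equal(ss$sensitivity, 0.9)
  expect_equal(ss$specificity, 0.8)
  expect_true(ss$sensitivity_ci[1] < 0.9 && ss$sensitivity_ci[2] > 0.9)
  # CI width shrinks with n at fixed rates
  wide <- diff(binom.test(9, 10)$conf.int)
  narrow <- diff(binom.test(90, 100)$conf.int)
  expect_lt(narrow, wide)
  expect_error(sens_spec(calls, setNames(rep("tumor", 20), paste0("s", 1:20))),
               "undefined metric")
})

test_that("Fisher exact p matches full hypergeometric enumeration", {
  enum_fisher <- function(tab) {
    # enumerate all tables with the observed margins; two-sided p is the
    # total probability of tables no more likely than the observed one
    r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
    lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
    probs <- vapply(lo:hi, function(a)
      dhyper(a, c1, n - c1, r1), numeric(1))
    obs <- dhyper(tab[1, 1], c1, n - c1, r1)
    sum(probs[probs <= obs * (1 + 1e-7)])
  }
  expect_equal(fisher_2x2(matrix(c(3, 1, 1, 3), 2)), 0.4857, tolerance = 1e-4)
  expect_equal(round(fisher_2x2(matrix(c(5, 0, 0, 5), 2)), 4), 0.0079)
  expect_equal(fisher_2x2(matrix(c(4, 2, 2, 1), 2)), 1)  # equal proportions
  set.seed(9)
  for (i in 1:30) {
    tab <- matrix(rpois(4, 3), 2)
    if (sum(tab) == 0 || sum(tab) > 20) next
    expect_equal(fisher_2x2(tab), enum_fisher(tab), tolerance = 1e-10)
  }
  expect_error(fisher_2x2(matrix(c(-1, 1, 1, 1), 2)), "invalid")
})

test_that("across-dataset means reproduce the bundled cohort summaries", {
  summ <- load_cohort_summary()
  huh <- summ[summ$signature == "Huh7-R-A7", ]
  expect_equal(mean_across_datasets(huh$pct_sr_pos, digits = 1), 52.7)
  xeno <- summ[summ$signature == "Xeno-R", ]
  expect_equal(mean_across_datasets(xeno$pct_sr_pos, digits = 1), 46.4)
  expect_equal(mean_across_datasets(5.5), 5.5)
  expect_error(mean_across_datasets(numeric(0)), "no values")
})
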