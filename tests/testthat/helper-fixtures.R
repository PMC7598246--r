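# Small fixtures built in code, shared across test files.

toy_matrix <- function(values, group = NULL, scale = "log2") {
  if (is.null(group)) group <- rep(c("control", "case"), each = ncol(values) / 2)
  expression_matrix(values, group = group, scale = scale)
}

# n genes x (2 * ns) samples, planted shifts, fixed seed
small_two_group <- function(n_genes = 50, ns = 4, effect = 2, noise = 0.3,
                            seed = 42) {
  set.seed(seed)
  v <- matrix(rnorm(n_genes * 2 * ns, 7, noise), nrow = n_genes,
              dimnames = list(sprintf("g%03d", 1:n_genes),
                              sprintf("s%02d", 1:(2 * ns))))
  v[1:5, (ns + 1):(2 * ns)] <- v[1:5, (ns + 1):(2 * ns)] + effect
  v[6:10, (ns + 1):(2 * ns)] <- v[6:10, (ns + 1):(2 * ns)] - effect
  toy_matrix(v)
}

toy_signature <- function(up = c("g1", "g2"), down = c("g3", "g4"),
                          name = "toy") {
  gene_signature(name, up = up, down = down)
}

# profile with given genes at the top, rest in id order
profile_with_top <- function(top, universe, drug = "d1") {
  ranked_profile(drug, c(top, setdiff(universe, top)))
}

# Brute-force running-sum oracle for the classic KS enrichment statistic:
# walks all n positions, hits step up by 1/t, misses step down by 1/n... no:
# evaluates the two one-sided extrema directly from the running difference
# between the tag ECDF and the uniform position fraction, the textbook
# definition the closed form compresses.
ks_oracle <- function(tag_positions, n) {
  v <- sort(tag_positions)
  t <- length(v)
  ecdf_before <- function(x) sum(v <= x) / t
  a <- max(vapply(seq_len(n), function(x) ecdf_before(x) - x / n, 0))
  b <- max(vapply(seq_len(n), function(x) x / n - (sum(v < x)) / t, 0))
  if (a > b) a else -b
}
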