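# Shared fixtures: small matrices built in code, no files on disk.

# genes x samples matrix of seeded normal values with valid dimnames
toy_expr <- function(n_genes = 10, n_samples = 5, seed = 1, mean = 5) {
  set.seed(seed)
  matrix(rnorm(n_genes * n_samples, mean = mean),
         nrow = n_genes,
         dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                         sprintf("S%03d", seq_len(n_samples))))
}

# covariate table matching toy_expr sample ids
toy_covariates <- function(n_samples = 5, seed = 1) {
  set.seed(seed)
  ids <- sprintf("S%03d", seq_len(n_samples))
  data.frame(sample_id = ids,
             age = rnorm(n_samples, 50, 10),
             sex = factor(sample(c("F", "M"), n_samples, replace = TRUE)),
             study = factor(sample(c("a", "b"), n_samples, replace = TRUE)),
             row.names = ids, stringsAsFactors = FALSE)
}

# brute-force step-up FDR adjustment, straight from the definition
bh_brute_force <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# one-tailed (greater) hypergeometric tail probability for a 2x2 table
# [[a, b], [c, d]], computed from factorials only
hyper_tail_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  xs <- max(0, k - n):min(k, m)
  probs <- choose(m, xs) * choose(n, k - xs) / choose(m + n, k)
  sum(probs[xs >= a])
}
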