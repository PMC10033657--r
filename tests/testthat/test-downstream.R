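test_that("covariate-free mega-analysis equals the pooled two-sample t-test", {
  set.seed(51)
  n <- 30
  ids <- sprintf("S%03d", 1:n)
  dx <- rep(c("case", "control"), each = n / 2)
  covs <- data.frame(sample_id = ids, diagnosis = factor(dx), row.names = ids)
  expr <- toy_expr(8, n, seed = 52)
  dge <- dge_mega_analysis(expr, covs)
  for (g in rownames(expr)) {
    tt <- t.test(expr[g, dx == "control"], expr[g, dx == "case"],
                 var.equal = TRUE)
    expect_equal(abs(dge$effect[dge$gene_id == g]), abs(unname(tt$statistic)),
                 tolerance = 1e-8)
    expect_equal(dge$p[dge$gene_id == g], tt$p.value, tolerance = 1e-8)
  }
})

test_that("a gene equal to the diagnosis indicator has overwhelming positive t", {
  n <- 20
  ids <- sprintf("S%03d", 1:n)
  covs <- data.frame(sample_id = ids,
                     diagnosis = factor(rep(c("control", "case"), each = 10),
                                        levels = c("control", "case")),
                     row.names = ids)
  expr <- toy_expr(3, n, seed = 53)
  expr["G001", ] <- as.numeric(covs$diagnosis == "case") + 1e-8 * rnorm(n)
  dge <- dge_mega_analysis(expr, covs)
  expect_gt(dge$effect[dge$gene_id == "G001"], 100)
  expect_lt(dge$p[dge$gene_id == "G001"], 1e-20)
})

test_that("under a permuted null the t-values are standard-normal-like", {
  set.seed(54)
  n <- 100
  ids <- sprintf("S%03d", 1:n)
  covs <- data.frame(sample_id = ids,
                     diagnosis = factor(sample(rep(c("a", "b"), n / 2))),
                     age = rnorm(n, 50, 10), row.names = ids)
  expr <- toy_expr(500, n, seed = 55)
  dge <- dge_mega_analysis(expr, covs, covariate_names = "age")
  expect_equal(var(dge$effect), 1, tolerance = 0.2)
  expect_lt(abs(mean(dge$p < 0.05) - 0.05), 0.03)
})

test_that("mega-analysis t-values are invariant to sample order and covariate scaling", {
  set.seed(56)
  n <- 40
  ids <- sprintf("S%03d", 1:n)
  covs <- data.frame(sample_id = ids,
                     diagnosis = factor(sample(rep(c("case", "control"), n / 2))),
                     age = rnorm(n, 50, 10),
                     study = factor(sample(c("x", "y"), n, TRUE)),
                     row.names = ids)
  expr <- toy_expr(10, n, seed = 57)
  base <- dge_mega_analysis(expr, covs, covariate_names = c("age", "study"))

  perm <- sample(n)
  permuted <- dge_mega_analysis(expr[, perm], covs,
                                covariate_names = c("age", "study"))
  expect_equal(base$effect, permuted$effect, tolerance = 1e-10)

  covs2 <- covs; covs2$age <- 10 * covs$age - 3
  scaled <- dge_mega_analysis(expr, covs2, covariate_names = c("age", "study"))
  expect_equal(base$effect, scaled$effect, tolerance = 1e-8)
})

test_that("mega-analysis rejects collinear designs and drops compositional fractions", {
  n <- 20
  ids <- sprintf("S%03d", 1:n)
  dx <- factor(rep(c("case", "control"), each = n / 2))
  covs <- data.frame(sample_id = ids, diagnosis = dx,
                     study = factor(rep(c("s1", "s2"), each = n / 2)),
                     frac1 = runif(n, 0.2, 0.6), row.names = ids)
  covs$frac2 <- 1 - covs$frac1
  expr <- toy_expr(4, n, seed = 58)

  # diagnosis nested in study: collinear
  expect_error(dge_mega_analysis(expr, covs, covariate_names = "study"),
               class = "ximpute_collinear_design")

  # compositional fractions: last one dropped, fit succeeds
  covs$diagnosis <- factor(rep(c("case", "control"), n / 2))
  expect_message(
    dge <- dge_mega_analysis(expr, covs,
                             covariate_names = c("frac1", "frac2"),
                             cell_fractions = c("frac1", "frac2")),
    "dropping")
  expect_equal(nrow(dge), 4)
})

test_that("concordance is symmetric, sign-aware, and supports restriction", {
  set.seed(59)
  genes <- sprintf("G%03d", 1:40)
  a <- data.frame(gene_id = genes, effect = rnorm(40))
  expect_equal(concordance(a, a)$r, 1)
  flipped <- transform(a, effect = -effect)
  expect_equal(concordance(a, flipped)$r, -1)

  b <- data.frame(gene_id = genes, effect = 0.5 * a$effect + rnorm(40))
  ab <- concordance(a, b)
  ba <- concordance(b, a)
  expect_equal(ab$r, ba$r, tolerance = 1e-12)
  expect_true(ab$ci_low <= ab$r && ab$r <= ab$ci_high)

  keep <- genes[1:10]
  restricted <- concordance(a, b, restrict_to = keep)
  prefiltered <- concordance(a[a$gene_id %in% keep, ], b[b$gene_id %in% keep, ])
  expect_equal(restricted$r, prefiltered$r, tolerance = 1e-12)
  expect_identical(restricted$n_genes, 10L)

  expect_error(concordance(a[1:2, ], b[1:2, ]),
               class = "ximpute_insufficient_data")
})

test_that("concordance recovers a known cross-vector correlation", {
  set.seed(60)
  n <- 2000
  genes <- sprintf("G%05d", 1:n)
  x <- rnorm(n)
  y <- 0.5 * x + sqrt(1 - 0.25) * rnorm(n)    # population correlation 0.5
  got <- concordance(data.frame(gene_id = genes, effect = x),
                     data.frame(gene_id = genes, effect = y))
  expect_gt(got$r, 0.45)
  expect_lt(got$r, 0.55)
})

test_that("correlation comparison z-tests match the Fisher formula and Steiger's test", {
  eq <- compare_concordance_z(0.4, 100, 0.4, 100)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)

  got <- compare_concordance_z(0.5, 103, 0.3, 103)
  z_oracle <- (atanh(0.5) - atanh(0.3)) / sqrt(2 / 100)
  expect_equal(got$z, z_oracle, tolerance = 1e-12)
  expect_equal(got$p, 2 * pnorm(-abs(z_oracle)), tolerance = 1e-12)

  # |z| strictly increases with n at fixed correlations
  zs <- vapply(c(50, 100, 500, 2000), function(n)
    abs(compare_concordance_z(0.5, n, 0.3, n)$z), numeric(1))
  expect_true(all(diff(zs) > 0))

  # dependent case: zero difference still gives z = 0; stronger shared
  # correlation tightens the test (larger |z| at the same r1, r2)
  dep0 <- compare_concordance_z(0.4, 200, 0.4, 200, dependent = TRUE, r12 = 0.3)
  expect_equal(dep0$z, 0)
  z_lo <- abs(compare_concordance_z(0.5, 200, 0.3, 200, dependent = TRUE, r12 = 0.1)$z)
  z_hi <- abs(compare_concordance_z(0.5, 200, 0.3, 200, dependent = TRUE, r12 = 0.7)$z)
  expect_gt(z_hi, z_lo)

  expect_error(compare_concordance_z(1, 50, 0.3, 50),
               class = "ximpute_degenerate_correlation")
  expect_error(compare_concordance_z(0.5, 50, 0.3, 50, dependent = TRUE),
               class = "ximpute_invalid_input")
})

test_that("enrichment p-values come from the hypergeometric tail", {
  bg <- c("G1", "G2", "G3", "G4")
  res <- fisher_enrichment(c("G1", "G2"), list(S = c("G1", "G2")), bg)
  expect_equal(res$p, 1 / 6, tolerance = 1e-12)
  expect_identical(c(res$a, res$b, res$c, res$d), c(2L, 0L, 0L, 2L))

  # a set disjoint from the significant genes shows no enrichment
  res2 <- fisher_enrichment(c("G1", "G2"), list(S = c("G3", "G4")), bg)
  expect_equal(res2$p, 1, tolerance = 1e-12)

  # doubling diagonal counts strengthens the enrichment signal
  bg_big <- sprintf("G%02d", 1:40)
  sig1 <- bg_big[1:6]; set1 <- bg_big[c(1:6, 21:26)]
  p1 <- fisher_enrichment(sig1, list(S = set1[1:8]), bg_big)$p
  p2 <- fisher_enrichment(sig1, list(S = set1[1:4]), bg_big)$p
  expect_lt(p1, p2)

  expect_error(fisher_enrichment("G9", list(S = "G1"), bg),
               class = "ximpute_invalid_input")
  expect_error(fisher_enrichment("G1", list(S = "G1"), character(0)),
               class = "ximpute_invalid_input")
})

test_that("odds ratios use the Haldane-Anscombe correction only when needed", {
  bg <- sprintf("G%02d", 1:20)
  res <- fisher_enrichment(bg[1:5], list(S = bg[c(1:3, 10:12)]), bg)
  expect_equal(res$odds_ratio, (3 * 12) / (3 * 2), tolerance = 1e-12)  # a=3 b=3 c=2 d=12
  zero <- fisher_enrichment(bg[1:5], list(S = bg[1:3]), bg)
  expect_equal(zero$odds_ratio, (3.5 * 15.5) / (0.5 * 2.5), tolerance = 1e-12)
})
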