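test_that("PCA matches a full SVD oracle up to component sign", {
  blood <- toy_expr(50, 20, seed = 11)
  pca <- fit_pca(blood, k = 2)

  Xc <- t(blood - rowMeans(blood))
  sv <- svd(Xc)
  for (j in 1:2) {
    ratio <- pca$loadings[, j] / sv$v[, j]
    expect_equal(unname(abs(ratio)), rep(1, 50), tolerance = 1e-8)
    expect_equal(unname(pca$scores[, j] / (sv$u[, j] * sv$d[j])),
                 rep(unname(ratio[1]), 20), tolerance = 1e-8)
  }
  expect_equal(pca$explained_variance_fraction,
               (sv$d^2 / sum(sv$d^2))[1:2], tolerance = 1e-10)
  # loadings orthonormal, variance fractions non-increasing
  expect_equal(crossprod(pca$loadings), diag(2), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(pca$explained_variance_fraction) <= 1e-12))
})

test_that("rank-1 data puts all variance on the first component", {
  direction <- rnorm(6)
  weights <- seq_len(8)
  blood <- outer(direction, weights) +
    matrix(0, 6, 8, dimnames = list(sprintf("G%d", 1:6), sprintf("S%d", 1:8)))
  pca <- fit_pca(blood, k = 1)
  expect_equal(pca$explained_variance_fraction[1], 1, tolerance = 1e-10)
})

test_that("PCA rejects impossible k and degenerate input", {
  blood <- toy_expr(10, 5)
  expect_error(fit_pca(blood, k = 5), class = "ximpute_too_many_components")
  flat <- matrix(3, 4, 6, dimnames = list(sprintf("G%d", 1:4), sprintf("S%d", 1:6)))
  expect_error(fit_pca(flat, k = 2), class = "ximpute_degenerate_input")
})

test_that("projection reproduces training scores and hand-computed dot products", {
  blood <- toy_expr(30, 12, seed = 4)
  pca <- fit_pca(blood, k = 3)
  expect_lt(max(abs(project_samples(pca, blood) - pca$scores)), 1e-10)

  # sample equal to the center vector projects to the origin
  center_sample <- matrix(pca$centers, ncol = 1,
                          dimnames = list(pca$gene_ids, "C1"))
  expect_lt(max(abs(project_samples(pca, center_sample))), 1e-10)

  # 3-gene, k = 1 toy: score is the centered dot product with the loading
  toy <- toy_expr(3, 5, seed = 6)
  p1 <- fit_pca(toy, k = 1)
  held <- matrix(c(4.2, 5.1, 6.3), ncol = 1, dimnames = list(rownames(toy), "H1"))
  expect_equal(unname(project_samples(p1, held))[1, 1],
               sum((held[, 1] - p1$centers) * p1$loadings[, 1]),
               tolerance = 1e-12)

  expect_error(project_samples(pca, toy),
               class = "ximpute_gene_universe_mismatch")
})

test_that("projection is linear after centering correction", {
  blood <- toy_expr(20, 10, seed = 5)
  pca <- fit_pca(blood, k = 2)
  x <- toy_expr(20, 1, seed = 21); rownames(x) <- pca$gene_ids
  y <- toy_expr(20, 1, seed = 22); rownames(y) <- pca$gene_ids
  a <- 0.7; b <- -1.3
  combo <- a * x + b * y + (1 - a - b) * pca$centers
  colnames(combo) <- "Z1"
  expect_equal(unname(project_samples(pca, combo)),
               unname(a * project_samples(pca, x) + b * project_samples(pca, y)),
               tolerance = 1e-10)
})

test_that("per-gene regressions equal the normal-equations oracle", {
  set.seed(12)
  blood <- toy_expr(40, 30, seed = 12)
  pca <- fit_pca(blood, k = 3)
  target <- toy_expr(6, 30, seed = 13)
  gm <- fit_gene_models(pca$scores, target)

  X <- cbind(1, pca$scores)
  beta_oracle <- solve(crossprod(X), crossprod(X, t(target)))
  expect_equal(unname(gm$coefficients), unname(t(beta_oracle)), tolerance = 1e-8)
})

test_that("an exactly linear target gene is recovered with R2 = 1", {
  blood <- toy_expr(30, 25, seed = 14)
  pca <- fit_pca(blood, k = 2)
  target <- matrix(1 + 2 * pca$scores[, 1], nrow = 1,
                   dimnames = list("GY", rownames(pca$scores)))
  gm <- fit_gene_models(pca$scores, target)
  expect_equal(unname(gm$coefficients["GY", ]), c(1, 2, 0), tolerance = 1e-8)
  expect_equal(unname(gm$training_r2["GY"]), 1, tolerance = 1e-8)

  fit <- ximpute(blood, target, k = 2)
  expect_lt(max(abs(predict(fit, blood) - target)), 1e-8)
})

test_that("training R2 is non-decreasing in k on the same data", {
  sim <- generate_paired(generator_spec(n_donors = 100, n_blood_genes = 80,
                                        n_brain_genes = 20, n_latent = 4,
                                        shared_variance = 0.4, seed = 15))
  fits <- lapply(c(5, 10, 20, 40), function(k)
    ximpute(sim$blood, sim$brain, k = k))
  expect_true(all(vapply(fits, function(f) identical(f$gene_ids, fits[[1]]$gene_ids),
                         logical(1))))
  r2 <- vapply(fits, function(f) mean(f$training_r2), numeric(1))
  expect_true(all(diff(r2) >= -1e-10))
  per_gene <- vapply(fits, function(f) f$training_r2, numeric(20))
  expect_true(all(apply(per_gene, 1, function(z) all(diff(z) >= -1e-10))))
})

test_that("donor order does not affect the trained model", {
  sim <- generate_paired(generator_spec(n_donors = 50, n_blood_genes = 40,
                                        n_brain_genes = 10, n_latent = 3,
                                        shared_variance = 0.5, seed = 16))
  fit1 <- ximpute(sim$blood, sim$brain, k = 3)
  perm <- sample(ncol(sim$brain))
  fit2 <- ximpute(sim$blood, sim$brain[, perm], k = 3)
  expect_equal(coef(fit1), coef(fit2), tolerance = 1e-12)

  colnames(sim$brain)[1] <- "IMPOSTOR"
  expect_error(ximpute(sim$blood, sim$brain, k = 3),
               class = "ximpute_pairing_error")
})

test_that("flipping a PC sign together with its coefficients leaves imputation unchanged", {
  sim <- generate_paired(generator_spec(n_donors = 60, n_blood_genes = 50,
                                        n_brain_genes = 8, n_latent = 3,
                                        shared_variance = 0.5, seed = 17))
  fit <- ximpute(sim$blood, sim$brain, k = 3)
  newdata <- toy_expr(50, 9, seed = 18)
  rownames(newdata) <- rownames(sim$blood)
  baseline <- predict(fit, newdata)
  set.seed(19)
  for (rep in 1:5) {
    flipped <- fit
    signs <- sample(c(-1, 1), fit$k, replace = TRUE)
    flipped$pca$loadings <- sweep(fit$pca$loadings, 2L, signs, "*")
    flipped$pca$scores <- sweep(fit$pca$scores, 2L, signs, "*")
    flipped$coefficients[, -1] <- sweep(fit$coefficients[, -1, drop = FALSE],
                                        2L, signs, "*")
    expect_lt(max(abs(predict(flipped, newdata) - baseline)), 1e-10)
  }
})

test_that("batch imputation equals sample-by-sample imputation", {
  sim <- generate_paired(generator_spec(n_donors = 40, n_blood_genes = 30,
                                        n_brain_genes = 6, n_latent = 2,
                                        shared_variance = 0.5, seed = 20))
  fit <- ximpute(sim$blood, sim$brain, k = 2)
  newdata <- toy_expr(30, 6, seed = 21)
  rownames(newdata) <- rownames(sim$blood)
  batch <- predict(fit, newdata)
  single <- vapply(seq_len(ncol(newdata)), function(j)
    predict(fit, newdata[, j, drop = FALSE])[, 1], numeric(nrow(batch)))
  expect_equal(unname(batch), unname(single), tolerance = 1e-12)
})

test_that("imputation handles restriction, constants and low coverage", {
  sim <- generate_paired(generator_spec(n_donors = 40, n_blood_genes = 40,
                                        n_brain_genes = 10, n_latent = 2,
                                        shared_variance = 0.5, seed = 22))
  fit <- ximpute(sim$blood, sim$brain, k = 2)

  # input at the training centers predicts the intercept for every gene
  centers <- matrix(rep(fit$pca$centers, 2), ncol = 2,
                    dimnames = list(fit$pca$gene_ids, c("A", "B")))
  pred <- predict(fit, centers)
  expect_equal(unname(pred[, 1]), unname(coef(fit)[, 1]), tolerance = 1e-10)

  sub <- predict(fit, centers, genes = fit$gene_ids[3:5])
  expect_identical(rownames(sub), fit$gene_ids[3:5])
  expect_error(predict(fit, centers, genes = "NOT_A_GENE"),
               class = "ximpute_invalid_input")

  tiny <- sim$blood[1:5, , drop = FALSE]
  expect_error(suppressWarnings(predict(fit, tiny)),
               class = "ximpute_low_coverage")
})
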