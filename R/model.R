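# Core model: PCA of blood expression, per-gene ordinary least squares
# of target-tissue expression on the top-k PC scores, and deployment of
# the trained model on new blood cohorts.

#' Principal component analysis of a blood expression matrix
#'
#' Computes the top-k principal components of a log-scale blood
#' expression matrix via singular value decomposition of the
#' gene-centered samples x genes matrix. Genes are centered but, by
#' default, not scaled to unit variance; set `scale = TRUE` to
#' standardize. The sign of each component is fixed by making its
#' largest-magnitude gene loading positive, so results are
#' deterministic across platforms.
#'
#' @param blood numeric matrix, genes x samples, log-scale normalized.
#' @param k number of components to retain (`1 <= k <= n_samples - 1`).
#' @param scale divide each centered gene by its standard deviation
#'   before the decomposition (default `FALSE`).
#' @return an object of class `"ximpute_pca"`: a list with `gene_ids`,
#'   `centers`, `scales` (or `NULL`), `loadings` (genes x k,
#'   orthonormal columns), `scores` (training samples x k),
#'   `explained_variance_fraction` (non-increasing), and `k`.
#' @seealso [project_samples()], [ximpute()]
#' @export
fit_pca <- function(blood, k, scale = FALSE) {
  check_expression_matrix(blood, "blood")
  n <- ncol(blood)
  k <- as.integer(k)
  stopifnot(length(k) == 1L, k >= 1L)
  if (k > n - 1L || k > nrow(blood)) {
    ximpute_stop("ximpute_too_many_components",
                 sprintf("k = %d exceeds min(n_samples - 1, n_genes) = %d",
                         k, min(n - 1L, nrow(blood))))
  }
  centers <- rowMeans(blood)
  Xc <- t(blood - centers)                       # samples x genes
  scales <- NULL
  if (scale) {
    sds <- sqrt(colSums(Xc^2) / (n - 1L))
    if (any(sds == 0)) {
      ximpute_stop("ximpute_degenerate_input",
                   "zero-variance genes cannot be scaled; filter them first")
    }
    Xc <- sweep(Xc, 2L, sds, "/")
    scales <- stats::setNames(sds, rownames(blood))
  }
  sv <- svd(Xc, nu = k, nv = k)
  if (sum(sv$d^2) <= .Machine$double.eps * n) {
    ximpute_stop("ximpute_degenerate_input", "expression matrix has zero variance")
  }
  loadings <- sv$v
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  # deterministic sign: largest-magnitude loading per component positive
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  dimnames(loadings) <- list(rownames(blood), paste0("PC", seq_len(k)))
  dimnames(scores) <- list(colnames(blood), paste0("PC", seq_len(k)))
  structure(list(
    gene_ids = rownames(blood),
    centers = stats::setNames(centers, rownames(blood)),
    scales = scales,
    loadings = loadings,
    scores = scores,
    explained_variance_fraction = sv$d[seq_len(k)]^2 / sum(sv$d^2),
    k = k
  ), class = "ximpute_pca")
}

#' @export
print.ximpute_pca <- function(x, ...) {
  cat(sprintf("Blood-expression PCA: %d genes, %d training samples, k = %d\n",
              length(x$gene_ids), nrow(x$scores), x$k))
  cat(sprintf("Cumulative variance explained: %.1f%%\n",
              100 * sum(x$explained_variance_fraction)))
  invisible(x)
}

#' Project blood samples onto a trained PCA
#'
#' Computes PC scores for new blood samples as
#' `t(values - training centers) %*% loadings` (with the training
#' scaling applied first when the PCA was fit with `scale = TRUE`).
#' The new matrix must already be aligned to the PCA's gene universe
#' (identical IDs in identical order); use [align_genes()] first.
#' Projecting the training matrix reproduces the fit-time scores.
#'
#' @param pca an `"ximpute_pca"` object.
#' @param blood_new numeric matrix, genes x samples, rows matching
#'   `pca$gene_ids` exactly.
#' @return numeric matrix of scores, samples x k.
#' @export
project_samples <- function(pca, blood_new) {
  stopifnot(inherits(pca, "ximpute_pca"))
  check_expression_matrix(blood_new, "blood_new")
  if (!identical(rownames(blood_new), pca$gene_ids)) {
    ximpute_stop("ximpute_gene_universe_mismatch",
                 "rows of `blood_new` must equal the PCA gene universe in order; use align_genes()")
  }
  Xc <- t(blood_new - pca$centers)
  if (!is.null(pca$scales)) Xc <- sweep(Xc, 2L, pca$scales, "/")
  scores <- Xc %*% pca$loadings
  rownames(scores) <- colnames(blood_new)
  scores
}

#' Per-gene linear models of target expression on PC scores
#'
#' For each target gene independently, fits ordinary least squares of
#' the gene's expression on the k PC scores plus an intercept
#' (`y ~ b0 + b1*PC1 + ... + bk*PCk`), solved by a single QR
#' decomposition shared across genes. The training R-squared
#' (`1 - SS_res/SS_tot`) is recorded per gene; genes with zero variance
#' get `NA`.
#'
#' @param scores numeric matrix of PC scores, samples x k.
#' @param target numeric matrix of target-tissue expression, genes x
#'   samples, columns matching the rows of `scores`.
#' @return list with `gene_ids`, `coefficients` (genes x (k+1), first
#'   column `(Intercept)`), and `training_r2`.
#' @export
fit_gene_models <- function(scores, target) {
  check_expression_matrix(target, "target")
  stopifnot(is.matrix(scores), is.numeric(scores))
  if (!identical(colnames(target), rownames(scores))) {
    ximpute_stop("ximpute_pairing_error",
                 "samples of `target` must match rows of `scores` in order")
  }
  n <- nrow(scores)
  k <- ncol(scores)
  if (n < k + 2L) {
    ximpute_stop("ximpute_underdetermined",
                 sprintf("need at least k + 2 = %d samples, have %d", k + 2L, n))
  }
  X <- cbind(`(Intercept)` = 1, scores)
  qrX <- qr(X)
  Y <- t(target)                                  # samples x genes
  beta <- qr.coef(qrX, Y)                         # (k+1) x genes
  fitted <- X %*% beta
  ss_res <- colSums((Y - fitted)^2)
  ss_tot <- colSums(sweep(Y, 2L, colMeans(Y))^2)
  r2 <- ifelse(ss_tot > 0, 1 - ss_res / ss_tot, NA_real_)
  coefs <- t(beta)
  dimnames(coefs) <- list(rownames(target), c("(Intercept)", colnames(scores)))
  list(gene_ids = rownames(target),
       coefficients = coefs,
       training_r2 = stats::setNames(r2, rownames(target)))
}

#' Train a cross-tissue expression imputation model
#'
#' The central fitting function: from paired blood and target-tissue
#' (e.g. a brain region) expression matrices over the same donors, it
#' (1) computes the top-k principal components of blood expression,
#' (2) projects the training samples onto them, and (3) fits, for each
#' target-tissue gene, an ordinary least-squares regression of that
#' gene's expression on the k PC scores plus an intercept. The
#' returned model imputes target-tissue expression for any new blood
#' cohort via [predict.ximpute()].
#'
#' Donors are joined by sample ID: the two matrices must contain the
#' same identifiers (any order); mismatched donor sets raise a
#' `ximpute_pairing_error` rather than being silently intersected.
#' Models are trained separately per target region; `k` in
#' `c(5, 10, 20, 40)` is the conventional model family, with 40
#' components the usual deployment default.
#'
#' @param blood numeric matrix, genes x samples, log-scale normalized
#'   blood expression.
#' @param target numeric matrix, genes x samples, log-scale normalized
#'   expression in the target tissue, same donors as `blood`.
#' @param k number of blood principal components (default 40, capped
#'   implicitly by `n - 1`).
#' @param region label for the target region stored in the model.
#' @param scale standardize genes before the PCA (default `FALSE`,
#'   i.e. centering only).
#' @return an object of class `"ximpute"`: a list with components
#'   `pca` (`"ximpute_pca"`), `coefficients` (target genes x (k+1)),
#'   `training_r2`, `region`, `k`, `n_donors`, and `call`. Methods:
#'   [predict.ximpute()], `print`, `summary`, `coef`, `fitted`,
#'   `residuals`, `plot`.
#' @examples
#' sim <- generate_paired(generator_spec(n_donors = 60, n_blood_genes = 40,
#'                                       n_brain_genes = 15, n_latent = 3,
#'                                       shared_variance = 0.5, seed = 1))
#' fit <- ximpute(sim$blood, sim$brain, k = 3, region = "toy")
#' fit
#' imputed <- predict(fit, sim$blood)
#' @export
ximpute <- function(blood, target, k = 40, region = "brain", scale = FALSE) {
  check_expression_matrix(blood, "blood")
  check_expression_matrix(target, "target")
  if (!setequal(colnames(blood), colnames(target)) ||
      ncol(blood) != ncol(target)) {
    ximpute_stop("ximpute_pairing_error",
                 "blood and target matrices must cover the same donor IDs")
  }
  target <- target[, colnames(blood), drop = FALSE]
  pca <- fit_pca(blood, k = k, scale = scale)
  gm <- fit_gene_models(pca$scores, target)
  structure(list(
    pca = pca,
    coefficients = gm$coefficients,
    training_r2 = gm$training_r2,
    gene_ids = gm$gene_ids,
    region = region,
    k = pca$k,
    n_donors = ncol(blood),
    call = match.call()
  ), class = "ximpute")
}

#' Impute target-tissue expression for new blood samples
#'
#' Deploys a trained model on an independent blood cohort: the new
#' matrix is aligned to the model's blood gene universe (absent genes
#' mean-imputed at the training centers, so they contribute zero to the
#' PC scores), samples are projected onto the training PCs, and each
#' target gene is predicted as `b0 + sum_i bi * score_i`.
#'
#' @param object an `"ximpute"` model.
#' @param newdata numeric matrix, genes x samples, blood expression
#'   normalized comparably to the training data. Defaults to the
#'   training scores (returning fitted values).
#' @param genes optional character vector restricting the output to a
#'   subset of modeled genes — typically the significant genes from
#'   [call_significant()].
#' @param min_coverage minimum fraction of the model's blood universe
#'   that must be present in `newdata`; below it an error of class
#'   `ximpute_low_coverage` is raised.
#' @param ... unused.
#' @return numeric matrix of imputed expression, genes x samples.
#' @export
predict.ximpute <- function(object, newdata = NULL, genes = NULL,
                            min_coverage = 0.5, ...) {
  if (is.null(newdata)) {
    scores <- object$pca$scores
  } else {
    check_expression_matrix(newdata, "newdata")
    aligned <- align_genes(newdata, object$pca$gene_ids,
                           policy = "mean-impute", fill = object$pca$centers,
                           min_coverage = 0, on_low_coverage = "warn")
    if (attr(aligned, "coverage") < min_coverage) {
      ximpute_stop("ximpute_low_coverage",
                   sprintf("only %.1f%% of the model's %d blood genes are present",
                           100 * attr(aligned, "coverage"),
                           length(object$pca$gene_ids)))
    }
    scores <- project_samples(object$pca, aligned)
  }
  coefs <- object$coefficients
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(coefs))
    if (length(missing)) {
      ximpute_stop("ximpute_invalid_input",
                   sprintf("genes not in the model: %s",
                           paste(utils::head(missing, 5L), collapse = ", ")))
    }
    coefs <- coefs[genes, , drop = FALSE]
  }
  out <- coefs[, -1L, drop = FALSE] %*% t(scores) + coefs[, 1L]
  dimnames(out) <- list(rownames(coefs), rownames(scores))
  out
}

#' @export
print.ximpute <- function(x, ...) {
  cat(sprintf("Cross-tissue imputation model for region '%s'\n", x$region))
  cat(sprintf("  trained on %d paired donors; %d blood genes -> %d target genes\n",
              x$n_donors, length(x$pca$gene_ids), length(x$gene_ids)))
  cat(sprintf("  k = %d blood PCs (%.1f%% of blood variance)\n",
              x$k, 100 * sum(x$pca$explained_variance_fraction)))
  invisible(x)
}

#' @export
summary.ximpute <- function(object, ...) {
  r2 <- object$training_r2
  out <- list(region = object$region, k = object$k,
              n_donors = object$n_donors,
              n_target_genes = length(object$gene_ids),
              training_r2 = summary(r2[is.finite(r2)]),
              evf = object$pca$explained_variance_fraction)
  class(out) <- "summary.ximpute"
  out
}

#' @export
print.summary.ximpute <- function(x, ...) {
  cat(sprintf("Imputation model, region '%s': %d target genes, k = %d, %d donors\n",
              x$region, x$n_target_genes, x$k, x$n_donors))
  cat("Training R-squared across target genes:\n")
  print(x$training_r2)
  cat(sprintf("Blood variance explained by the %d PCs: %.1f%%\n",
              length(x$evf), 100 * sum(x$evf)))
  invisible(x)
}

#' @export
coef.ximpute <- function(object, ...) object$coefficients

#' @export
fitted.ximpute <- function(object, ...) predict(object)

#' Training residuals of an imputation model
#'
#' Requires the training target matrix, which is not stored in the
#' model; pass it as `target`.
#'
#' @param object an `"ximpute"` model.
#' @param target the training target-tissue matrix (genes x samples).
#' @param ... unused.
#' @return matrix of residuals, genes x samples.
#' @export
residuals.ximpute <- function(object, target, ...) {
  check_expression_matrix(target, "target")
  fit <- fitted(object)
  target <- target[rownames(fit), colnames(fit), drop = FALSE]
  target - fit
}

#' @export
plot.ximpute <- function(x, ...) {
  r2 <- x$training_r2[is.finite(x$training_r2)]
  graphics::hist(r2, breaks = 30, col = "grey80", border = "grey40",
                 main = sprintf("Training R², region '%s' (k = %d)",
                                x$region, x$k),
                 xlab = expression(R^2), ...)
  invisible(x)
}
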