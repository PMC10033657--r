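# Cross-validated accuracy estimation: fold assignment, per-gene
# out-of-fold performance, the significance criterion, and
# method-vs-method accuracy comparisons.

#' Random balanced fold assignment
#'
#' Partitions samples into `n_folds` folds whose sizes differ by at
#' most one, reproducibly under `seed`. The caller's RNG stream is
#' left untouched.
#'
#' @param sample_ids character vector of unique sample identifiers.
#' @param n_folds number of folds (default 5).
#' @param seed integer seed recorded in the assignment.
#' @return object of class `"ximpute_folds"`: list with `n_folds`,
#'   `assignment` (named integer vector, sample -> fold), `seed`.
#' @export
make_folds <- function(sample_ids, n_folds = 5, seed = 1) {
  stopifnot(is.character(sample_ids), !anyDuplicated(sample_ids))
  n <- length(sample_ids)
  n_folds <- as.integer(n_folds)
  if (n_folds < 2L || n_folds > n) {
    ximpute_stop("ximpute_too_many_folds",
                 sprintf("need 2 <= n_folds <= n_samples (%d), got %d", n, n_folds))
  }
  fold <- with_seed(seed, sample(rep_len(seq_len(n_folds), n)))
  structure(list(n_folds = n_folds,
                 assignment = stats::setNames(fold, sample_ids),
                 seed = seed),
            class = "ximpute_folds")
}

#' @export
print.ximpute_folds <- function(x, ...) {
  cat(sprintf("%d-fold assignment of %d samples (seed %s); fold sizes: %s\n",
              x$n_folds, length(x$assignment), format(x$seed),
              paste(tabulate(x$assignment, x$n_folds), collapse = ", ")))
  invisible(x)
}

#' Prediction accuracy for one gene
#'
#' Pearson correlation `r` between observed and predicted expression,
#' its square `r2` (the coefficient of determination used throughout
#' for cross-validated accuracy), and the two-sided correlation-test
#' p-value (t distribution, n - 2 df). Constant vectors have no
#' defined correlation: all three values come back `NA` and such genes
#' are excluded from significance calls.
#'
#' @param observed,predicted numeric vectors of equal length >= 3.
#' @return list with `r`, `r2`, `p`.
#' @export
per_gene_accuracy <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  if (length(observed) < 3L) {
    ximpute_stop("ximpute_insufficient_data", "need at least 3 paired values")
  }
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0) {
    return(list(r = NA_real_, r2 = NA_real_, p = NA_real_))
  }
  ct <- stats::cor.test(observed, predicted)
  r <- unname(ct$estimate)
  list(r = r, r2 = r^2, p = ct$p.value)
}

# Row-wise Pearson correlation between two genes x samples matrices.
# Constant rows yield NA.
row_cor <- function(a, b) {
  ac <- a - rowMeans(a)
  bc <- b - rowMeans(b)
  num <- rowSums(ac * bc)
  den <- sqrt(rowSums(ac^2) * rowSums(bc^2))
  ifelse(den > 0, num / den, NA_real_)
}

# Fit one CV fold: PCA and per-gene models on the training folds only,
# then out-of-fold predictions for the held-out samples. Kept separate
# so the out-of-fold discipline (held-out samples cannot influence the
# fold's model) can be asserted directly.
cv_fit_fold <- function(blood, target, k, train_idx, test_idx, scale = FALSE) {
  pca <- fit_pca(blood[, train_idx, drop = FALSE], k = k, scale = scale)
  gm <- fit_gene_models(pca$scores, target[, train_idx, drop = FALSE])
  scores_te <- project_samples(pca, blood[, test_idx, drop = FALSE])
  pred <- gm$coefficients[, -1L, drop = FALSE] %*% t(scores_te) +
    gm$coefficients[, 1L]
  dimnames(pred) <- list(rownames(target), colnames(blood)[test_idx])
  list(pca = pca, coefficients = gm$coefficients, predictions = pred)
}

#' Single k-fold cross-validation of the imputation model
#'
#' Estimates per-gene out-of-sample prediction accuracy with one
#' k-fold cross-validation: for each fold, the blood PCA and all
#' per-gene regressions are fit on the training folds only, the
#' held-out samples are projected onto the training PCs, and held-out
#' predictions are scored against observation. Per-gene `r` and `R2`
#' are averaged over the validation folds; the per-gene p-value is the
#' two-sided Pearson correlation test on the pooled out-of-fold
#' predictions (each donor held out exactly once), computed after
#' centering observations and predictions within each validation fold
#' — the partial correlation given the fold factor, with the degrees
#' of freedom reduced accordingly — and q-values are
#' Benjamini-Hochberg adjusted across genes within the run.
#'
#' @param blood,target paired genes x samples matrices over the same
#'   donors (joined by sample ID).
#' @param k number of blood PCs.
#' @param folds an `"ximpute_folds"` assignment, or `NULL` to create
#'   one from `n_folds` and `seed`.
#' @param n_folds,seed used when `folds` is `NULL` (defaults: 5 folds).
#' @param scale standardize genes in the PCA (default `FALSE`).
#' @param r2_min,alpha thresholds stored for the significance flag;
#'   see [call_significant()].
#' @return object of class `"ximpute_cv"`: a data.frame with columns
#'   `gene_id`, `mean_cv_r2`, `mean_cv_r`, `p`, `q`, `significant`,
#'   plus attributes `fold_r`, `fold_r2` (genes x folds matrices),
#'   `folds`, `k`, `r2_min`, `alpha`. Genes with strongly negative
#'   pooled correlation carry `mean_cv_r < 0`; their `r2` is still the
#'   squared correlation, so inspect `mean_cv_r` before trusting a
#'   high `r2`.
#' @export
cross_validate <- function(blood, target, k, folds = NULL, n_folds = 5,
                           seed = 1, scale = FALSE,
                           r2_min = 0.01, alpha = 0.05) {
  check_expression_matrix(blood, "blood")
  check_expression_matrix(target, "target")
  if (!setequal(colnames(blood), colnames(target)) ||
      ncol(blood) != ncol(target)) {
    ximpute_stop("ximpute_pairing_error",
                 "blood and target matrices must cover the same donor IDs")
  }
  target <- target[, colnames(blood), drop = FALSE]
  if (is.null(folds)) {
    folds <- make_folds(colnames(blood), n_folds = n_folds, seed = seed)
  }
  stopifnot(inherits(folds, "ximpute_folds"))
  assign <- folds$assignment[colnames(blood)]
  if (anyNA(assign)) {
    ximpute_stop("ximpute_pairing_error",
                 "fold assignment does not cover all samples")
  }
  n <- ncol(blood)
  nf <- folds$n_folds
  m <- nrow(target)
  fold_r <- matrix(NA_real_, m, nf, dimnames = list(rownames(target), NULL))
  fold_r2 <- fold_r
  pooled <- matrix(NA_real_, m, n, dimnames = dimnames(target))
  for (f in seq_len(nf)) {
    te <- which(assign == f)
    tr <- which(assign != f)
    if (length(tr) <= k + 1L) {
      ximpute_stop("ximpute_underdetermined",
                   sprintf("training split of fold %d has %d samples for k = %d PCs",
                           f, length(tr), k))
    }
    fit <- cv_fit_fold(blood, target, k, tr, te, scale = scale)
    r <- row_cor(target[, te, drop = FALSE], fit$predictions)
    fold_r[, f] <- r
    fold_r2[, f] <- r^2
    pooled[, te] <- fit$predictions
  }
  mean_cv_r <- rowMeans(fold_r, na.rm = TRUE)
  mean_cv_r2 <- rowMeans(fold_r2, na.rm = TRUE)
  mean_cv_r[is.nan(mean_cv_r)] <- NA_real_
  mean_cv_r2[is.nan(mean_cv_r2)] <- NA_real_
  # Pool out-of-fold predictions after centering observations and
  # predictions within each validation fold: fold-specific intercept
  # offsets (each fold's model carries its own training mean) otherwise
  # induce spurious correlation under the null and the correlation test
  # loses its calibration.
  obs_c <- target
  for (f in seq_len(nf)) {
    te <- which(assign == f)
    pooled[, te] <- pooled[, te] - rowMeans(pooled[, te, drop = FALSE])
    obs_c[, te] <- obs_c[, te] - rowMeans(obs_c[, te, drop = FALSE])
  }
  r_pool <- row_cor(obs_c, pooled)
  # partial correlation given the fold factor: nf - 1 extra df spent
  df_pool <- n - 2L - (nf - 1L)
  tstat <- r_pool * sqrt(df_pool / pmax(1 - r_pool^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = df_pool)
  q <- bh_adjust(p)
  out <- data.frame(gene_id = rownames(target),
                    mean_cv_r2 = unname(mean_cv_r2),
                    mean_cv_r = unname(mean_cv_r),
                    p = unname(p), q = unname(q),
                    stringsAsFactors = FALSE)
  out$significant <- !is.na(out$mean_cv_r2) & !is.na(out$q) &
    out$mean_cv_r2 >= r2_min & out$q <= alpha
  structure(out, class = c("ximpute_cv", "data.frame"),
            fold_r = fold_r, fold_r2 = fold_r2, folds = folds, k = k,
            r2_min = r2_min, alpha = alpha)
}

#' @export
print.ximpute_cv <- function(x, ...) {
  cat(sprintf("Cross-validated imputation accuracy: %d genes, %d folds, k = %d\n",
              nrow(x), attr(x, "folds")$n_folds, attr(x, "k")))
  cat(sprintf("  significantly predicted (CV R2 >= %g, FDR q <= %g): %d (%.1f%%)\n",
              attr(x, "r2_min"), attr(x, "alpha"), sum(x$significant),
              100 * mean(x$significant)))
  cat(sprintf("  mean CV R2 = %.3f, mean CV r = %.3f over all genes\n",
              mean(x$mean_cv_r2, na.rm = TRUE), mean(x$mean_cv_r, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.ximpute_cv <- function(x, ...) {
  graphics::hist(x$mean_cv_r2, breaks = 40, col = "grey80", border = "grey40",
                 main = "Cross-validated per-gene accuracy",
                 xlab = expression("mean CV" ~ R^2), ...)
  graphics::abline(v = attr(x, "r2_min"), lty = 2)
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone, capped at 1, original order
#' restored), computed with [stats::p.adjust()]. `NA` entries are
#' passed through.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return vector of q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || any(p < 0 | p > 1, na.rm = TRUE)) {
    ximpute_stop("ximpute_invalid_input", "p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Call significantly predicted genes
#'
#' The imputability criterion: a gene is significantly predicted when
#' its mean cross-validated R-squared reaches `r2_min` (default 0.01)
#' and its BH-adjusted p-value is at most `alpha` (default 0.05). Both
#' boundaries are inclusive (`>=` / `<=`).
#'
#' @param cv an `"ximpute_cv"` result (or any data.frame with columns
#'   `gene_id`, `mean_cv_r2`, `q`).
#' @param r2_min minimum mean CV R-squared.
#' @param alpha FDR threshold.
#' @return character vector of significant gene IDs.
#' @export
call_significant <- function(cv, r2_min = 0.01, alpha = 0.05) {
  stopifnot(all(c("gene_id", "mean_cv_r2", "q") %in% colnames(cv)))
  ok <- !is.na(cv$mean_cv_r2) & !is.na(cv$q) &
    cv$mean_cv_r2 >= r2_min & cv$q <= alpha
  cv$gene_id[ok]
}

#' Compare two methods' prediction accuracies
#'
#' Two-tailed t-test on two vectors of per-gene accuracies (Pearson r
#' values), Welch-corrected by default. Use `paired = TRUE` when both
#' vectors cover the same genes in the same order. When comparing
#' across several regions, adjust the resulting p-values with
#' [bh_adjust()].
#'
#' @param r_a,r_b numeric accuracy vectors, each length >= 2.
#' @param paired paired test on the per-gene differences (default
#'   `FALSE`, two-sample).
#' @return `htest` object from [stats::t.test()].
#' @export
compare_accuracy_ttest <- function(r_a, r_b, paired = FALSE) {
  if (length(r_a) < 2L || length(r_b) < 2L) {
    ximpute_stop("ximpute_insufficient_data",
                 "each accuracy vector needs at least 2 values")
  }
  stats::t.test(r_a, r_b, paired = paired, var.equal = FALSE)
}

#' Correlation of two methods' prediction accuracies
#'
#' Pearson correlation test between per-gene accuracies of two methods
#' over the genes both predict significantly.
#'
#' @param r_a,r_b numeric accuracy vectors over the same genes,
#'   length >= 3.
#' @return `htest` object from [stats::cor.test()].
#' @export
correlate_accuracies <- function(r_a, r_b) {
  if (length(r_a) != length(r_b) || length(r_a) < 3L) {
    ximpute_stop("ximpute_insufficient_data",
                 "need >= 3 shared genes with accuracies for both methods")
  }
  stats::cor.test(r_a, r_b)
}
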