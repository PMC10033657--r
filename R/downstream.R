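# Downstream validation statistics on imputed (or measured) profiles:
# case-control differential expression by covariate-adjusted linear
# regression, concordance of effect-size vectors, z-tests comparing
# concordances, and gene-set enrichment of imputable genes.

#' Case-control differential expression mega-analysis
#'
#' Combined-samples mega-analysis: all studies' samples are pooled into
#' one per-gene ordinary least-squares regression of expression on a
#' two-level diagnosis indicator plus nuisance covariates (typically
#' study, age, sex, and circulating-leukocyte cell fractions). The
#' reported effect size per gene is the diagnosis coefficient's
#' t-value, with its standard error and two-sided p-value; t-values are
#' the effect vectors consumed by [concordance()].
#'
#' Compositional cell-fraction covariates that sum to one across each
#' sample are collinear with the intercept; name them in
#' `cell_fractions` and the last one is dropped automatically. Any
#' other rank deficiency (e.g. diagnosis nested within study) is an
#' error of class `ximpute_collinear_design`.
#'
#' @param expr numeric genes x samples matrix (imputed or measured,
#'   log-scale).
#' @param covariates data.frame with `sample_id` rownames covering all
#'   samples of `expr`.
#' @param outcome name of the two-level diagnosis column (default
#'   `"diagnosis"`).
#' @param covariate_names character vector of adjustment covariates
#'   (may be empty).
#' @param cell_fractions names of compositional cell-fraction columns
#'   among `covariate_names`.
#' @return data.frame of class `"ximpute_dge"` with columns `gene_id`,
#'   `beta` (group-difference estimate, second diagnosis level minus
#'   reference), `se`, `effect` (the t-value), `p`, `q` (BH across
#'   genes).
#' @export
dge_mega_analysis <- function(expr, covariates, outcome = "diagnosis",
                              covariate_names = character(),
                              cell_fractions = character()) {
  check_expression_matrix(expr)
  samp <- colnames(expr)
  if (!all(samp %in% rownames(covariates))) {
    ximpute_stop("ximpute_missing_covariate",
                 "all expression samples must appear in the covariate table")
  }
  covs <- covariates[samp, , drop = FALSE]
  if (!outcome %in% colnames(covs)) {
    ximpute_stop("ximpute_missing_covariate",
                 sprintf("outcome column '%s' not found", outcome))
  }
  y <- factor(covs[[outcome]])
  if (nlevels(y) != 2L) {
    ximpute_stop("ximpute_invalid_input",
                 sprintf("outcome '%s' must have exactly 2 observed levels, has %d",
                         outcome, nlevels(y)))
  }
  missing_cov <- setdiff(covariate_names, colnames(covs))
  if (length(missing_cov)) {
    ximpute_stop("ximpute_missing_covariate",
                 sprintf("covariates absent from table: %s",
                         paste(missing_cov, collapse = ", ")))
  }
  if (length(cell_fractions) > 1L &&
      all(cell_fractions %in% covariate_names)) {
    tot <- rowSums(covs[, cell_fractions, drop = FALSE])
    if (all(abs(tot - 1) < 1e-6)) {
      drop <- cell_fractions[length(cell_fractions)]
      covariate_names <- setdiff(covariate_names, drop)
      message(sprintf("cell fractions sum to 1; dropping '%s'", drop))
    }
  }
  df <- cbind(data.frame(.dx = y), covs[, covariate_names, drop = FALSE])
  if (anyNA(df)) {
    ximpute_stop("ximpute_missing_covariate", "missing covariate values")
  }
  X <- stats::model.matrix(~ ., data = df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    ximpute_stop("ximpute_collinear_design",
                 "design matrix is rank deficient (diagnosis or covariates collinear)")
  }
  n <- nrow(X); p <- ncol(X)
  if (n <= p) {
    ximpute_stop("ximpute_underdetermined",
                 sprintf("%d samples cannot identify %d design coefficients", n, p))
  }
  Y <- t(expr)
  beta <- qr.coef(qrX, Y)
  res <- qr.resid(qrX, Y)
  dfree <- n - p
  sigma2 <- colSums(res^2) / dfree
  xtx_inv <- chol2inv(chol(crossprod(X)))
  j <- match(paste0(".dx", levels(y)[2L]), colnames(X))
  se <- sqrt(sigma2 * xtx_inv[j, j])
  b <- beta[j, ]
  tval <- ifelse(se > 0, b / se, NA_real_)
  pval <- 2 * stats::pt(-abs(tval), df = dfree)
  out <- data.frame(gene_id = rownames(expr),
                    beta = unname(b), se = unname(se),
                    effect = unname(tval), p = unname(pval),
                    q = unname(bh_adjust(pval)),
                    stringsAsFactors = FALSE)
  structure(out, class = c("ximpute_dge", "data.frame"),
            outcome = outcome, contrast = paste(levels(y)[2L], "vs", levels(y)[1L]),
            covariates = covariate_names, df = dfree)
}

#' @export
print.ximpute_dge <- function(x, ...) {
  cat(sprintf("Differential expression mega-analysis: %d genes, contrast %s\n",
              nrow(x), attr(x, "contrast")))
  cat(sprintf("  covariates: %s; residual df = %d; genes at FDR q <= 0.05: %d\n",
              if (length(attr(x, "covariates"))) paste(attr(x, "covariates"), collapse = ", ") else "(none)",
              attr(x, "df"), sum(x$q <= 0.05, na.rm = TRUE)))
  invisible(x)
}

#' Concordance of two effect-size vectors
#'
#' Pearson correlation between two per-gene differential-expression
#' effect-size vectors (t-values or z-scores) over their shared genes,
#' with a two-sided p-value and 95% confidence interval from the
#' Fisher z transform. Optionally restricted to a gene list — e.g.
#' the genes significant in a reference postmortem analysis.
#'
#' @param dge_a,dge_b data.frames with columns `gene_id` and `effect`.
#' @param restrict_to optional character vector of gene IDs to keep.
#' @return object of class `"ximpute_concordance"`: list with `r`,
#'   `ci_low`, `ci_high`, `p`, `n_genes`.
#' @export
concordance <- function(dge_a, dge_b, restrict_to = NULL) {
  stopifnot(all(c("gene_id", "effect") %in% colnames(dge_a)),
            all(c("gene_id", "effect") %in% colnames(dge_b)))
  shared <- intersect(dge_a$gene_id, dge_b$gene_id)
  if (!is.null(restrict_to)) shared <- intersect(shared, restrict_to)
  a <- dge_a$effect[match(shared, dge_a$gene_id)]
  b <- dge_b$effect[match(shared, dge_b$gene_id)]
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3L) {
    ximpute_stop("ximpute_insufficient_data",
                 "need >= 3 shared genes with finite effects")
  }
  ct <- stats::cor.test(a, b, conf.level = 0.95)
  structure(list(r = unname(ct$estimate),
                 ci_low = if (!is.null(ct$conf.int)) ct$conf.int[1L] else NA_real_,
                 ci_high = if (!is.null(ct$conf.int)) ct$conf.int[2L] else NA_real_,
                 p = ct$p.value,
                 n_genes = length(a)),
            class = "ximpute_concordance")
}

#' @export
print.ximpute_concordance <- function(x, ...) {
  cat(sprintf("Effect-size concordance: Pearson r = %.3f, 95%% CI %.3f-%.3f, p = %.3g, n genes = %d\n",
              x$r, x$ci_low, x$ci_high, x$p, x$n_genes))
  invisible(x)
}

#' Compare two concordance correlations
#'
#' Tests whether two Pearson correlations differ. For independent
#' samples the Fisher r-to-z two-sample test is used:
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`. When
#' both correlations are computed against the same reference vector on
#' the same genes (e.g. imputed-vs-brain and blood-vs-brain sharing
#' the brain vector), set `dependent = TRUE` and supply `r12`, the
#' correlation between the two non-shared vectors; Steiger's test for
#' dependent correlations sharing one variable is then applied.
#'
#' @param r1,r2 the two correlations (strictly inside (-1, 1)).
#' @param n1,n2 their sample sizes (numbers of genes, each >= 4);
#'   `n2` defaults to `n1` in the dependent case.
#' @param dependent correlations share one vector (default `FALSE`).
#' @param r12 correlation between the two non-shared vectors; required
#'   when `dependent = TRUE`.
#' @return list with `z` and two-sided `p`.
#' @export
compare_concordance_z <- function(r1, n1, r2, n2 = n1,
                                  dependent = FALSE, r12 = NULL) {
  stopifnot(is.finite(r1), is.finite(r2), n1 >= 4, n2 >= 4)
  if (abs(r1) >= 1 || abs(r2) >= 1) {
    ximpute_stop("ximpute_degenerate_correlation",
                 "correlations must lie strictly inside (-1, 1)")
  }
  z1 <- atanh(r1); z2 <- atanh(r2)
  if (!dependent) {
    z <- (z1 - z2) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  } else {
    if (is.null(r12) || !is.finite(r12) || abs(r12) >= 1) {
      ximpute_stop("ximpute_invalid_input",
                   "dependent comparison requires r12 strictly inside (-1, 1)")
    }
    if (n1 != n2) {
      ximpute_stop("ximpute_invalid_input",
                   "dependent correlations must share the same n")
    }
    n <- n1
    # Steiger (1980): correlation between the two z statistics when the
    # correlations share one variable, via Dunn & Clark's covariance.
    cov_num <- r12 * (1 - r1^2 - r2^2) - 0.5 * r1 * r2 * (1 - r1^2 - r2^2 - r12^2)
    s <- cov_num / ((1 - r1^2) * (1 - r2^2))
    z <- (z1 - z2) * sqrt((n - 3) / (2 - 2 * s))
  }
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Gene-set enrichment of significantly predicted genes
#'
#' For each gene set, builds the 2x2 table of set membership against
#' membership of `significant` within `background` and applies a
#' one-tailed (greater) Fisher's exact test; p-values are BH-adjusted
#' across sets. The odds ratio reported is the sample odds ratio, with
#' a Haldane-Anscombe 0.5 correction on all cells when any cell is
#' zero; the p-value always comes from the exact test on the raw
#' counts.
#'
#' @param significant character vector of significant gene IDs (must
#'   be a subset of `background`).
#' @param gene_sets named list of gene-ID vectors (see
#'   [read_gene_sets()]); each set is intersected with `background`.
#' @param background character vector: the gene universe tested.
#' @return data.frame with columns `set`, `n_set`, `a`, `b`, `c`, `d`
#'   (in-set significant, in-set not, out-set significant, out-set
#'   not), `odds_ratio`, `p`, `q`.
#' @export
fisher_enrichment <- function(significant, gene_sets, background) {
  stopifnot(is.list(gene_sets), length(gene_sets) >= 1L)
  background <- unique(background)
  if (!length(background)) {
    ximpute_stop("ximpute_invalid_input", "background universe is empty")
  }
  significant <- unique(significant)
  if (!all(significant %in% background)) {
    ximpute_stop("ximpute_invalid_input",
                 "`significant` must be a subset of `background`")
  }
  n_bg <- length(background)
  n_sig <- length(significant)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), background)
    a <- length(intersect(set, significant))
    b <- length(set) - a
    cc <- n_sig - a
    d <- n_bg - a - b - cc
    p <- stats::fisher.test(matrix(c(a, cc, b, d), 2L),
                            alternative = "greater")$p.value
    cells <- c(a, b, cc, d)
    if (any(cells == 0)) cells <- cells + 0.5
    or <- (cells[1L] * cells[4L]) / (cells[2L] * cells[3L])
    data.frame(set = nm, n_set = a + b, a = a, b = b, c = cc, d = d,
               odds_ratio = or, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out[order(out$p), , drop = FALSE]
}
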